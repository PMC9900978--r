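#' Write a movie as multi-page TIFF with a JSON sidecar
#'
#' 16-bit grayscale pages; acquisition settings, protocol kind, seed and
#' frame count go to `<path>.json` so a round trip restores the metadata.
#'
#' @param movie A `vi_movie`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  d <- dim(movie$data)
  maxval <- 2^movie$acq$bit_depth - 1
  pages <- lapply(seq_len(d[3]), function(k) movie$data[, , k] / maxval)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  side <- list(acq = unclass(movie$acq), meta = movie$meta,
               n_frames = d[3], pixel_size = movie$acq$pixel_size)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a movie written by [write_movie()]
#'
#' 8-bit ("speed mode") files are promoted to 16-bit scale and flagged in
#' the metadata. A missing sidecar falls back to defaults with a warning; a
#' frame count short of the sidecar's raises an error naming the first
#' missing frame.
#'
#' @param path TIFF path.
#' @return A `vi_movie`.
#' @export
read_movie <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE,
                                   info = TRUE),
                    error = function(e)
                      stop(sprintf("failed to read '%s': %s", path,
                                   conditionMessage(e))))
  if (!is.list(pages)) pages <- list(pages)
  bits <- attr(pages[[1]], "bits.per.sample")
  promoted <- FALSE
  if (!is.null(bits) && bits == 8) {
    pages <- lapply(pages, function(p) p * 257L)  # 0..255 -> 0..65535
    promoted <- TRUE
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    acq <- do.call(acquisition_spec, side$acq[names(side$acq) %in%
      names(formals(acquisition_spec))])
    meta <- side$meta
    if (side$n_frames > length(pages))
      stop(sprintf("truncated movie: frame %d of %d missing in '%s'",
                   length(pages) + 1, side$n_frames, path))
  } else {
    warning("sidecar JSON missing; using default acquisition settings")
    acq <- acquisition_spec(n_rows = nrow(pages[[1]]),
                            n_cols = ncol(pages[[1]]))
    meta <- list(kind = "unknown", frame_period = acq$frame_period)
  }
  data <- array(0L, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) data[, , k] <- as.integer(pages[[k]])
  meta$promoted_from_8bit <- promoted
  structure(list(data = data, acq = acq, meta = meta), class = "vi_movie")
}

#' Write a trace as CSV
#'
#' Columns: time (ms), raw_f, baseline, dff, lit.
#'
#' @param trace A trace.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(time = trace$time, raw_f = trace$raw_f,
                   baseline = if (is.null(trace$baseline)) NA
                              else trace$baseline,
                   dff = if (is.null(trace$dff)) NA else trace$dff,
                   lit = trace$lit)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a weight mask as 32-bit float TIFF
#'
#' @param mask A [regression_weight_mask()] result or numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  w <- if (inherits(mask, "weight_mask")) mask$weights else mask
  tiff::writeTIFF(w / max(w, 1e-12), path, bits.per.sample = 32L,
                  compression = "none")
  invisible(path)
}

#' Write a metrics report as JSON
#'
#' @param metrics Named list of metric values.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
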