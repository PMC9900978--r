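test_that("GPC pi-disk mask is binary and covers the mapped disk area", {
  geom <- slm_geometry()
  m <- make_gpc_mask(spot_spec(diameter = 12), geom)
  expect_setequal(unique(as.vector(m$phase)), c(0, pi))
  # pixel-counting oracle: fraction of pi pixels = mapped disk area / panel
  frac <- mean(abs(m$phase - pi) < 1e-9)
  r_slm <- 6 * geom$demag
  expected <- pi * r_slm^2 / (geom$n_rows * geom$n_cols * geom$pitch^2)
  # one pixel-row of circumference tolerance
  tol <- 2 * pi * r_slm * geom$pitch / (geom$n_rows * geom$n_cols *
                                          geom$pitch^2)
  expect_lt(abs(frac - expected), tol)
  # degenerate disk
  m0 <- make_gpc_mask(spot_spec(diameter = 0), geom)
  expect_true(all(m0$phase == 0))
  # aperture violation names the magnified radius
  expect_error(make_gpc_mask(spot_spec(diameter = 200), geom),
               "magnified disk radius")
})

test_that("GPC synthesis produces a soma-sized flat-top with ~3x Gaussian efficiency", {
  geom <- slm_geometry()
  em <- gpc_synthesize(make_gpc_mask(spot_spec(diameter = 12), geom))
  # Parseval through the phase-contrast stage
  expect_equal(attr(em, "energy_out"), attr(em, "energy_in"),
               tolerance = 1e-9)
  bm <- beam_metrics(em)
  expect_between(bm$lateral_fwhm, 11.5, 12.5)   # 12 um +- grid tolerance
  # expanded-and-cropped Gaussian: analytic throughput, uniformity contract
  gf <- gaussian_flattop_spot(12, uniformity = 0.9)
  expect_equal(gf$throughput, 0.1)
  inside <- gf$map$intensity[gf$map$intensity > 0]
  expect_gte(min(inside) / max(inside), 0.9)
  # GPC is about three times more power-efficient for the same spot
  ratio <- attr(em, "throughput") / gf$throughput
  expect_between(ratio, 2.5, 3.5)
  expect_error(gaussian_flattop_spot(12, uniformity = 1.2))
  # uniformity -> 1 sends throughput to zero
  expect_lt(gaussian_flattop_spot(12, uniformity = 0.999)$throughput, 0.01)
})

test_that("uniform-phase mask leaves a structureless beam unchanged", {
  # a beam whose focus lies well inside the PCF and whose tails vanish
  # within the grid (structureless field)
  geom <- slm_geometry(beam_waist = 5000)
  npad <- 1024
  x <- (seq_len(npad) - npad / 2 - 1) * geom$pitch
  X <- matrix(x, npad, npad)
  A <- exp(-(X^2 + t(X)^2) / geom$beam_waist^2)  # no panel clipping
  m0 <- phase_mask(matrix(0, geom$n_rows, geom$n_cols), geom)
  em <- gpc_synthesize(m0, input_profile = A)
  expect_lt(max(abs(em$intensity - A^2)) / max(A^2), 0.02)
  expect_error(gpc_synthesize(m0, pcf_radius = 1e9), "pcf_radius")
})

test_that("Gerchberg-Saxton holograms converge onto the target disk", {
  geom <- small_geom()
  h <- gs_hologram(spot_spec(diameter = 12), geom, n_iter = 40, seed = 3)
  hist <- attr(h, "history")
  # reconstruction error is non-increasing: correlation at the end beats
  # the first iteration
  expect_gt(hist[length(hist)], hist[1])
  expect_gte(hist[length(hist)], 0.9)
  rec <- reconstruct_hologram(h)
  targ <- disk_target(spot_spec(diameter = 12), geom)
  ncc <- sum(rec$intensity * targ) /
    sqrt(sum(rec$intensity^2) * sum(targ^2))
  expect_gte(ncc, 0.8)
  # determinism: same seed, bit-identical mask
  h2 <- gs_hologram(spot_spec(diameter = 12), geom, n_iter = 40, seed = 3)
  expect_identical(h$phase, h2$phase)
  expect_error(gs_hologram(matrix(0, 512, 512), geom), "zero")
})

test_that("weighted multiplexing equalises and proportions spot intensities", {
  geom <- small_geom()
  ang <- seq(0, 2 * pi, length.out = 9)[1:8]
  spots <- lapply(ang, function(a)
    spot_spec(c(40 * cos(a), 40 * sin(a)), 12))
  wm <- weighted_gs_multiplex(spots, geom, n_iter = 40, seed = 5)
  rec <- reconstruct_hologram(wm)
  tp <- rec$intensity^2
  xs <- map_coords(rec)
  XS <- matrix(xs, length(xs), length(xs))
  pow <- vapply(spots, function(s)
    sum(tp[(XS - s$center_xyz[2])^2 + (t(XS) - s$center_xyz[1])^2 <= 36]),
    numeric(1))
  expect_lte(stats::sd(pow) / mean(pow), 0.10)
  # doubling one spot's weight doubles its integrated intensity relative to
  # the others (within 15%)
  spots2 <- spots
  spots2[[1]]$weight <- 2
  wm2 <- weighted_gs_multiplex(spots2, geom, n_iter = 40, seed = 5)
  I2 <- reconstruct_hologram(wm2)$intensity
  pint <- vapply(spots2, function(s)
    sum(I2[(XS - s$center_xyz[2])^2 + (t(XS) - s$center_xyz[1])^2 <= 36]),
    numeric(1))
  expect_between(pint[1] / mean(pint[-1]), 2 * 0.85, 2 * 1.15)
  # single spot reduces to the plain hologram's statistics
  w1 <- weighted_gs_multiplex(list(spot_spec(diameter = 12)), geom,
                              n_iter = 40, seed = 3)
  r1 <- beam_metrics(reconstruct_hologram(w1))
  expect_between(r1$lateral_fwhm, 10.5, 13.5)
  # overlap warning, field-bound error
  expect_warning(weighted_gs_multiplex(
    list(spot_spec(c(0, 0), 12), spot_spec(c(5, 0), 12)), geom,
    n_iter = 2, seed = 1), "closer than one diameter")
  expect_error(weighted_gs_multiplex(list(spot_spec(c(500, 0), 12)), geom),
               "addressable")
})
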