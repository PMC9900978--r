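# Shared fixtures. Optical tests use a reduced SLM panel whose padded grid
# is 512 (instead of 1024 for the full device); the beam waist is scaled so
# the implied focusing NA stays physical (~0.45).

small_geom <- function(beam_waist = 1200)
  slm_geometry(n_rows = 400L, n_cols = 500L, beam_waist = beam_waist)

# single-cell test movie on a compact camera grid
quick_movie <- function(kind = "protocol1", seed = 1, expression = 50,
                        responsivity_sd = 0, rate = 100, power = 0.88,
                        protocol_params = list(), cell_seed = seed + 1,
                        sensor = sensor_model()) {
  pr <- make_protocol(kind, params = utils::modifyList(
    list(acquisition_rate = rate), protocol_params))
  acq <- acquisition_spec(pixel_size = 0.325, exposure = 1000 / rate - 0.02,
                          n_rows = 50L, n_cols = 50L)
  cell <- cell_spec(expression = expression,
                    responsivity_sd = responsivity_sd, seed = cell_seed)
  sim <- render_movie(cell, pr, acq, sensor = sensor, seed = seed,
                      power_density = power, reference_density = power)
  c(sim, list(protocol = pr, acq = acq, cell = cell))
}

expect_between <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}

crop_center_test <- function(m, size) {
  n <- nrow(m)
  idx <- (n - size) %/% 2 + seq_len(size)
  m[idx, idx]
}
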