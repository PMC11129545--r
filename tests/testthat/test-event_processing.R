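# Calibration, charge-sharing discrimination and spectrum accumulation.

# peaks are symmetric about exact grid positions, so the +/-3-bin centroid
# is exact and the constructed (gain, offset) are recovered to float precision
make_pixel_spectrum <- function(module, row, col, gain, offset,
                                energies = c(59.54, 122), n = 5000) {
  adc <- 0:ceiling((energies[2] - offset) / gain + 50)
  c1 <- round((energies[1] - offset) / gain)
  c2 <- round((energies[2] - offset) / gain)
  counts <- round(n * dnorm(adc, c1, 1)) + round(n * dnorm(adc, c2, 1))
  g_true <- diff(energies) / (c2 - c1)
  list(module = module, row = row, col = col, adc = adc, counts = counts,
       gain_true = g_true, offset_true = energies[1] - g_true * c1)
}

test_that("two-point calibration recovers constructed gain and offset", {
  set.seed(4)
  gains <- runif(20, 0.02, 0.08)
  offsets <- runif(20, -2, 2)
  spectra <- lapply(1:20, function(i)
    make_pixel_spectrum(0, i, 1, gains[i], offsets[i]))
  cal <- fit_two_point_calibration(spectra)
  expect_false(any(cal$dead))
  expect_equal(cal$gain, vapply(spectra, `[[`, 1, "gain_true"),
               tolerance = 1e-12)
  expect_equal(cal$offset, vapply(spectra, `[[`, 1, "offset_true"),
               tolerance = 1e-12)
  # unit gain, zero offset -> identity map (integer peak energies keep the
  # constructed centroids on the ADC grid)
  sp1 <- make_pixel_spectrum(0, 0, 0, 1, 0, energies = c(59, 122))
  cal1 <- fit_two_point_calibration(list(sp1), energies = c(59, 122))
  expect_equal(cal1$gain, 1, tolerance = 1e-12)
  expect_equal(cal1$offset, 0, tolerance = 1e-9)
})

test_that("pixels with a missing peak are flagged dead and excluded", {
  one_peak <- make_pixel_spectrum(0, 0, 0, 0.05, 0)
  one_peak$counts[one_peak$adc > 1500] <- 0     # remove the 122 keV peak
  cal <- fit_two_point_calibration(list(one_peak,
                                        make_pixel_spectrum(0, 0, 1, 0.05, 0)))
  expect_identical(cal$dead, c(TRUE, FALSE))
  ev <- data.frame(module = 0L, row = 0L, col = c(0L, 1L), adc = c(100, 100))
  out <- apply_calibration(ev, cal)
  expect_equal(nrow(out), 1)                    # dead-pixel event dropped
  expect_equal(out$col, 1L)
})

test_that("calibration maps the source centroids to the source energies", {
  cal <- fit_two_point_calibration(list(make_pixel_spectrum(2, 3, 4, 0.06, -1)))
  adc_am <- (59.54 - (-1)) / 0.06
  adc_co <- (122 - (-1)) / 0.06
  ev <- data.frame(module = 2L, row = 3L, col = 4L,
                   adc = c(adc_am, adc_co, 0))
  out <- apply_calibration(ev, cal)
  expect_equal(out$energy_kev[1], 59.54, tolerance = 0.05)
  expect_equal(out$energy_kev[2], 122, tolerance = 0.05)
  expect_equal(out$energy_kev[3], cal$offset, tolerance = 1e-9)
  expect_error(apply_calibration(
    data.frame(module = 9L, row = 0L, col = 0L, adc = 1), cal),
    "no calibration")
})

test_that("calibration round trip is exact to numerical precision", {
  sp <- fx_spectrum(); g <- fx_geometry(); ph <- phantom_study_I()
  lm <- simulate_position(ph, 0, g, sp, 2, 1e7, seed = 8, compton = FALSE)
  ev <- lm$events
  gain <- 0.0457; offset <- -0.83
  raw <- ev; raw$adc <- (ev$energy_kev - offset) / gain
  raw$energy_kev <- NULL
  cal <- data.frame(module = rep(unique(ev$module), each = 6400),
                    row = rep(rep(0:79, each = 80), length(unique(ev$module))),
                    col = rep(0:79, 80 * length(unique(ev$module))),
                    gain = gain, offset = offset, dead = FALSE)
  out <- apply_calibration(raw, cal)
  expect_lt(max(abs(out$energy_kev - ev$energy_kev)), 1e-9)
})

test_that("CSD filter equals the brute-force all-pairs oracle on 1000 random frames", {
  total_frames <- 0
  for (trial in 1:25) {
    ev <- random_events(n = rpois(1, 120) + 2, n_frames = 40, pix = 12,
                        seed = 1000 + trial)
    total_frames <- total_frames + 40
    got <- csd_filter(ev)
    want <- csd_brute_force(ev)
    expect_identical(got, want)
  }
  expect_gte(total_frames, 1000)
})

test_that("CSD filter is idempotent and only removes events", {
  ev <- random_events(500, n_frames = 30, pix = 15, seed = 77)
  once <- csd_filter(ev)
  expect_identical(csd_filter(once), once)
  expect_lte(nrow(once), nrow(ev))
  # kept events are unmodified rows of the input
  expect_true(all(rownames(once) %in% rownames(ev)))
  expect_identical(once, ev[rownames(once), ])
  # pair rules: Chebyshev distance 1 -> both rejected; 2 -> both kept
  pair1 <- data.frame(frame = 0L, module = 0L, row = c(10L, 11L),
                      col = c(10L, 11L), energy_kev = c(30, 40))
  expect_equal(nrow(csd_filter(pair1)), 0)
  pair2 <- data.frame(frame = 0L, module = 0L, row = c(10L, 12L),
                      col = c(10L, 12L), energy_kev = c(30, 40))
  expect_equal(nrow(csd_filter(pair2)), 2)
  # different modules or frames never interact
  pair3 <- pair1; pair3$module <- c(0L, 1L)
  expect_equal(nrow(csd_filter(pair3)), 2)
  pair4 <- pair1; pair4$frame <- c(0L, 1L)
  expect_equal(nrow(csd_filter(pair4)), 2)
  expect_equal(nrow(csd_filter(pair1[1, ])), 1)
})

test_that("spectrum accumulation conserves counts and locates a blurred line", {
  set.seed(5)
  ev <- data.frame(energy_kev = rnorm(2e4, 42.75, 0.3))
  sp <- accumulate_spectrum(ev, bin_width = 0.25)
  expect_equal(sum(sp$counts), 2e4)
  # Gaussian-fit oracle: quadratic fit of log counts around the peak
  top <- which.max(sp$counts)
  i <- (top - 4):(top + 4)
  fit <- lm(log(sp$counts[i]) ~ poly(sp$energy_kev[i], 2, raw = TRUE))
  centroid <- -coef(fit)[2] / (2 * coef(fit)[3])
  expect_lt(abs(centroid - 42.75), 0.3 * 2.3548 / 10)
  # empty input -> all-zero histogram
  empty <- accumulate_spectrum(data.frame(energy_kev = numeric()))
  expect_true(all(empty$counts == 0))
})
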