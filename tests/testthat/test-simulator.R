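# Forward simulator: response model, charge sharing, yield profiles,
# event-level expectations, determinism.

test_that("energy-resolution model reproduces the measured FWHM anchors", {
  r <- detector_response()
  expect_equal(fwhm_at(r, 35), 0.5)
  expect_equal(fwhm_at(r, 60), 0.88)
  expect_equal(fwhm_at(r, 122), 1.02)
  # monotone between anchors, flat beyond
  E <- seq(30, 130, by = 1)
  expect_true(all(diff(fwhm_at(r, E)) >= 0))
  expect_equal(fwhm_at(r, 20), 0.5)
  expect_equal(fwhm_at(r, 140), 1.02)
  # blur statistics match the anchor width
  set.seed(1)
  e <- apply_response(rep(60, 2e4), r)
  expect_lt(abs(sd(e) * 2.3548 - 0.88), 0.02)
  expect_lt(abs(mean(e) - 60), 0.02)
})

test_that("charge sharing conserves energy and splits to an 8-neighbor", {
  ev <- data.frame(frame = 0:99, module = 0L, row = rep(40L, 100),
                   col = rep(40L, 100), energy_kev = runif(100, 20, 60))
  set.seed(2)
  expect_identical(simulate_charge_sharing(ev, 0), ev)
  out <- simulate_charge_sharing(ev, 1)
  expect_equal(nrow(out), 200)
  by_frame <- split(out, out$frame)
  for (f in by_frame) {
    expect_equal(nrow(f), 2)
    expect_equal(max(abs(f$row[1] - f$row[2]), abs(f$col[1] - f$col[2])), 1)
    expect_equal(sum(f$energy_kev), ev$energy_kev[ev$frame == f$frame[1]],
                 tolerance = 1e-12)
  }
  # edge pixels only split to valid neighbors
  corner <- data.frame(frame = 0:199, module = 0L, row = 0L, col = 0L,
                       energy_kev = 50)
  out2 <- simulate_charge_sharing(corner, 1)
  expect_true(all(out2$row >= 0 & out2$col >= 0))
})

test_that("XRF yield profiles have the right support, linearity and nulls", {
  sp <- fx_spectrum()
  ph <- phantom_study_I()
  # element absent everywhere -> all-zero profile
  y0 <- xrf_yield_per_path(ph, 0, sp, "Au")
  expect_true(all(y0$yield == 0))
  # yield support lies inside the metal-filled tubes (x0 = 0 crosses the
  # tubes at y = +-5.5, inner radius 1.5)
  yg <- xrf_yield_per_path(ph, 0, sp, "Gd")
  sup <- yg$y[yg$yield > 0]
  expect_true(all(abs(abs(sup) - 5.5) <= 1.5 + 0.2))
  # water-only chord: zero yield
  yw <- xrf_yield_per_path(ph, 5.5, sp, "Gd")  # crosses only the water tube
  expect_true(all(abs(yw$y[yw$yield > 0]) > 3))  # not inside the water tube
  # dilute linearity: doubling a tiny concentration doubles the yield
  mk <- function(c1) xfet_phantom(fills = list(
    solution_material(c(Gd = c1)), solution_material(),
    solution_material(), solution_material()))
  y1 <- xrf_yield_per_path(mk(1e-4), 5.5, sp, "Gd")
  y2 <- xrf_yield_per_path(mk(2e-4), 5.5, sp, "Gd")
  nz <- y1$yield > 0
  expect_true(all(abs(y2$yield[nz] / y1$yield[nz] - 2) < 1e-4))
  # beam missing the phantom
  expect_equal(nrow(xrf_yield_per_path(ph, 30, sp, "Gd")), 0)
})

test_that("detected XRF counts match the closed-form expectation", {
  sp <- fx_spectrum()
  g <- fx_geometry()
  ph <- phantom_study_I()
  resp <- detector_response(charge_sharing_prob = 0)  # count-preserving
  flux <- 2e7; dwell <- 10
  lm <- simulate_position(ph, 0, g, sp, dwell, flux, resp, seed = 9,
                          compton = FALSE)
  n_obs <- sum(grepl("XRF", lm$events$truth))
  # expectation: emissions per depth bin x solid-angle acceptance x exit
  # transmission x detector absorption, per K line
  yl <- xrf_yield_per_path(ph, 0, sp, "Gd", line = "K")
  idx <- which(yl$yield > 0)
  pts <- cbind(0, yl$y[idx], 0)
  acc <- xfetring:::.pinhole_acceptance(g, pts)
  ln <- xray_lines(); ln <- ln[ln$element == "Gd", ]
  p_line <- ln$rel_intensity / sum(ln$rel_intensity)
  cdte <- standard_material("cdte")
  n_exp <- 0
  for (li in seq_len(nrow(ln))) {
    E <- ln$energy_kev[li]
    eff <- 1 - exp(-mass_attenuation(cdte, E, "photoelectric") *
                     cdte$density * 0.1)
    for (j in seq_len(96)) {
      ppin <- unlist(g$pinholes[j, c("cx", "cy", "cz")])
      D <- t(apply(pts, 1, function(p) {
        d <- ppin - p; d / sqrt(sum(d^2))
      }))
      surv <- path_transmission(ph, pts, D, E)
      n_exp <- n_exp + flux * dwell * p_line[li] * eff *
        sum(yl$yield[idx] * acc[, j] * surv)
    }
  }
  expect_lt(abs(n_obs - n_exp), 3 * sqrt(n_exp) + 1e-9)
})

test_that("simulation is reproducible and background toggles cleanly", {
  sp <- fx_spectrum(); g <- fx_geometry(); ph <- phantom_study_I()
  a <- simulate_position(ph, 0, g, sp, 5, 1e7, seed = 21)
  b <- simulate_position(ph, 0, g, sp, 5, 1e7, seed = 21)
  expect_identical(a$events, b$events)
  # no metal -> no XRF-tagged events
  blank <- xfet_phantom(fills = replicate(4, solution_material(),
                                          simplify = FALSE))
  lw <- simulate_position(blank, 0, g, sp, 5, 1e7, seed = 3)
  expect_false(any(grepl("XRF", lw$events$truth)))
  # windowed continuum under the Gd Kalpha peak: nonzero with Compton on,
  # zero with Compton off (for the metal-free phantom)
  spec_on <- accumulate_spectrum(lw)
  w <- spec_on$energy_kev > 41.25 & spec_on$energy_kev < 44.25
  expect_gt(sum(spec_on$counts[w]), 0)
  loff <- simulate_position(blank, 0, g, sp, 5, 1e7, seed = 3,
                            compton = FALSE)
  expect_equal(nrow(loff$events), 0)
})

test_that("detected Kalpha counts are linear in concentration (dilute regime)", {
  sp <- fx_spectrum(); g <- fx_geometry()
  conc <- c(0.5, 1.5, 3)
  counts <- vapply(seq_along(conc), function(i) {
    ph <- xfet_phantom(fills = list(
      solution_material(c(Gd = conc[i])), solution_material(),
      solution_material(), solution_material()))
    lm <- simulate_position(ph, 5.5, g, sp, 10, 1e8,
                            detector_response(charge_sharing_prob = 0),
                            seed = 100 + i, compton = FALSE)
    emitted <- lm$meta$emitted$Gd
    expect_gt(emitted, 1e4)
    sum(grepl("XRF", lm$events$truth))
  }, numeric(1))
  fit <- summary(lm(counts ~ conc))
  expect_gt(fit$r.squared, 0.99)
})

test_that("per-row Kalpha peak lands at the tube depth", {
  sp <- fx_spectrum(); g <- fx_geometry()
  # single Gd tube at (0, 5.5); beam at x0 = 0
  ph <- xfet_phantom(fills = list(
    solution_material(), solution_material(c(Gd = 3)),
    solution_material(), solution_material()))
  lm <- simulate_position(ph, 0, g, sp, 10, 5e7, seed = 12, compton = FALSE)
  pro <- merge_views(split_views(csd_filter(lm), g), g)
  m <- collapse_columns(pro)
  e <- attr(m, "energy_kev")
  w <- e > 41.25 & e < 44.25
  rowc <- rowSums(m[, w])
  peak_y <- attr(m, "row_y")[which.max(rowc)]
  expect_lt(abs(peak_y - 5.5), 1.5)      # within the tube / one row
})

test_that("list-mode CSV round trip preserves events", {
  sp <- fx_spectrum(); g <- fx_geometry(); ph <- phantom_study_I()
  lm <- simulate_position(ph, 0, g, sp, 2, 1e7, seed = 5, compton = FALSE)
  f <- tempfile(fileext = ".csv")
  write_listmode_csv(lm, f)
  lm2 <- read_listmode_csv(f)
  expect_equal(nrow(lm2$events), nrow(lm$events))
  expect_equal(lm2$events$energy_kev, lm$events$energy_kev, tolerance = 1e-6)
  unlink(c(f, paste0(f, ".json")))
})
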