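# View splitting, merging, column collapse, windowed net-XRF extraction and
# image assembly.

# synthetic list mode: events at the exact projected pixel of object points
synthetic_events <- function(g, points, pinholes, energy = 42.75) {
  rows <- lapply(seq_along(pinholes), function(k) {
    pr <- project_point(g, pinholes[k], points[k, ])
    stopifnot(pr$visible)
    data.frame(frame = k - 1, module = pr$module, row = pr$row, col = pr$col,
               energy_kev = energy, truth = "synthetic")
  })
  do.call(rbind, rows)
}

test_that("events split into disjoint views; corner pixels use the half-open rule", {
  g <- fx_geometry()
  # flood: uniform events over one panel's pixels
  set.seed(11)
  n <- 96000
  ev <- data.frame(frame = seq_len(n), module = sample(0:23, n, TRUE),
                   row = sample(0:79, n, TRUE), col = sample(0:79, n, TRUE),
                   energy_kev = 40)
  st <- split_views(ev, g)
  expect_equal(nrow(st$events), n)
  expect_equal(st$dropped, 0L)
  tab <- table(factor(st$events$pinhole, levels = 0:95))
  expect_equal(length(tab), 96)
  # multinomial expectation: each view gets ~n/96, within 3 sigma
  expect_true(all(abs(tab - n / 96) < 3 * sqrt(n / 96) + 3))
  # region-corner pixel: module 0 (panel 0, upper-left), raw pixel (0, 0)
  # sits at panel corner u = -20+, v = +20-; region with u_min = -20,
  # v_max = 20 owns it
  corner <- data.frame(frame = 0L, module = 0L, row = 0L, col = 0L,
                       energy_kev = 40)
  stc <- split_views(corner, g)
  ph <- g$pinholes[g$pinholes$pinhole == stc$events$pinhole, ]
  expect_equal(ph$u_min, -20)
  expect_equal(ph$v_max, 20)
  # empty input
  st0 <- split_views(ev[0, ], g)
  expect_equal(nrow(st0$events), 0)
})

test_that("merging opposite-panel views of one point source gives a single row peak", {
  g <- fx_geometry()
  p <- c(0, 4.2, 0)
  # central pinholes of panel 0 and the opposite panel 3
  ev <- synthetic_events(g, rbind(p, p)[rep(1:2, 200), ], rep(c(6, 54), 200))
  pro <- merge_views(split_views(ev, g), g, scan_x = 0)
  m <- collapse_columns(pro)
  rowc <- rowSums(m)
  expect_equal(sum(rowc), 400)                   # count conservation
  peaks <- which(rowc > 0)
  expect_lte(diff(range(peaks)), 1)              # one merged peak, not two
  expect_lt(abs(attr(m, "row_y")[which.max(rowc)] - 4.2), 1)
})

test_that("merged counts are conserved and permutation-invariant", {
  sp <- fx_spectrum(); g <- fx_geometry(); ph <- phantom_study_I()
  lm <- simulate_position(ph, 0, g, sp, 5, 5e7, seed = 31, compton = FALSE)
  st <- split_views(csd_filter(lm), g)
  pro <- merge_views(st, g)
  expect_equal(sum(pro$counts), nrow(st$events))
  m <- collapse_columns(pro)
  expect_equal(sum(m), nrow(st$events))          # exact integer equality
  # permutation invariance
  st2 <- st
  set.seed(1); st2$events <- st2$events[sample(nrow(st2$events)), ]
  pro2 <- merge_views(st2, g)
  expect_identical(pro$counts, pro2$counts)
})

test_that("net XRF extraction is unbiased on a null background and recovers peak areas", {
  e <- seq(30, 56, by = 0.25)
  slope <- -1.2; icpt <- 120
  line <- 42.75
  # null case: pure linear background
  n_ok <- 0
  for (trial in 1:100) {
    set.seed(trial)
    counts <- rpois(length(e), icpt + slope * (e - 30))
    r <- net_xrf(e, counts, line)
    if (abs(r$net) < 3 * r$sigma) n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 95)
  # injected Gaussian of known area on the same background
  area <- 800
  n_ok <- 0
  for (trial in 1:50) {
    set.seed(200 + trial)
    lam <- icpt + slope * (e - 30) +
      area * dnorm(e, line, 0.4) * 0.25
    counts <- rpois(length(e), lam)
    r <- net_xrf(e, counts, line)
    if (abs(r$net - area) < 3 * r$sigma) n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 47)
  expect_error(net_xrf(e[e > 41 & e < 44], counts[e > 41 & e < 44], line),
               "sideband")
})

test_that("image assembly is 20 x 37 with columns following the scan plan", {
  g <- fx_geometry()
  plan <- make_scan_plan(37, 0.5, dwell = 1)
  zero <- matrix(0, 20, 596)
  attr(zero, "energy_kev") <- seq(0.125, 148.875, by = 0.25)
  attr(zero, "row_y") <- seq(-9.5, 9.5, by = 1)
  img <- assemble_image(rep(list(zero), 37), plan, "Gd")
  expect_equal(dim(img$net), c(20, 37))
  expect_true(all(img$net == 0))
  expect_equal(dim(img$sigma), dim(img$net))
  expect_error(assemble_image(rep(list(zero), 30), plan, "Gd"), "37")
})

test_that("simulated study-I tubes localize within one voxel and elements separate in study II", {
  sp <- fx_spectrum(); g <- fx_geometry()
  plan <- make_scan_plan(37, 0.5, dwell = 10)
  ph2 <- phantom_study_II()
  scan <- simulate_scan(ph2, plan, g, sp, flux = 4e7, seed = 61,
                        compton = FALSE)
  gd <- xfet_image_from_scan(scan, g, plan, "Gd")
  la <- xfet_image_from_scan(scan, g, plan, "La")
  # each element image peaks at its own highest-concentration tube
  peak_tube <- function(img) {
    means <- vapply(2:4, function(i) {
      roi_stats(img, roi_at(img, ph2$tubes$x[i], ph2$tubes$y[i]))$mean
    }, numeric(1))
    ph2$tubes$label[1 + which.max(means)]
  }
  expect_equal(peak_tube(gd), "Gd6La3")
  expect_equal(peak_tube(la), "Gd3La6")
  # localization within one voxel for every metal tube
  for (img in list(gd, la)) for (i in 2:4) {
    tr <- roi_at(img, ph2$tubes$x[i], ph2$tubes$y[i])
    sub <- img$net[(tr$row - 2):(tr$row + 2), (tr$col - 2):(tr$col + 2)]
    am <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    expect_lte(max(abs(am - 3)), 1)
  }
})
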