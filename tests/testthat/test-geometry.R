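# System geometry: construction invariants, projection, orientation,
# sensitivity, scan planning.

test_that("default geometry has 24 modules and 96 disjoint subdetector regions", {
  g <- fx_geometry()
  expect_equal(nrow(g$modules), 24)
  expect_equal(nrow(g$pinholes), 96)
  # regions tile the 96 cm^2 of detector area with no overlap
  area <- sum((g$pinholes$u_max - g$pinholes$u_min) *
                (g$pinholes$v_max - g$pinholes$v_min)) / 100
  expect_equal(area, 96)
  key <- paste(g$pinholes$panel, g$pinholes$u_min, g$pinholes$v_min)
  expect_equal(anyDuplicated(key), 0L)
  # pinhole plane from the 1:2 minification
  expect_equal(g$r_pin, 82 / 3, tolerance = 1e-12)
  # every pinhole sits inside the collimator block
  rad <- sqrt(g$pinholes$cx^2 + g$pinholes$cy^2)
  expect_true(all(rad <= g$r_det))
})

test_that("one-panel scaling and invalid configurations", {
  g1 <- xfet_geometry(n_panels = 1)
  expect_equal(nrow(g1$modules), 4)
  expect_equal(nrow(g1$pinholes), 16)
  # a minification that puts the pinhole plane outside the collimator fails
  expect_error(xfet_geometry(minification = 2), "collimator")
})

test_that("pinhole projection is inverted, minified 1:2 and invertible", {
  g <- fx_geometry()
  # FOV center images to each pinhole's region center
  for (pid in c(0, 21, 50, 95)) {
    pr <- project_point(g, pid, c(0, 0, 0))
    ph <- g$pinholes[g$pinholes$pinhole == pid, ]
    expect_true(pr$visible)
    expect_equal(pr$u, ph$u_c, tolerance = 1e-9)
    expect_equal(pr$v, ph$v_c, tolerance = 1e-9)
  }
  # +2 mm transverse displacement -> -1 mm image displacement (axial axis)
  p0 <- project_point(g, 0, c(0, 0, 0))
  p1 <- project_point(g, 0, c(0, 0, 2))
  expect_equal(p1$v - p0$v, -1, tolerance = 1e-9)
  # 20 mm object extent maps to 10 mm on the detector
  pa <- project_point(g, 5, c(0, 0, -10))
  pb <- project_point(g, 5, c(0, 0, 10))
  expect_equal(abs(pb$v - pa$v), 10, tolerance = 1e-9)
  # projection round trip: continuous image point back through the pinhole
  # recovers the source transverse position to < 0.01 mm
  ph <- g$pinholes[g$pinholes$pinhole == 6, ]
  b <- g$panels[g$panels$panel == ph$panel, ]
  p <- c(0.4, 3.7, 0.9)
  pr <- project_point(g, 6, p)
  q <- c(g$r_det * b$nx + pr$u * b$tx, g$r_det * b$ny + pr$u * b$ty, pr$v)
  cc <- c(ph$cx, ph$cy, ph$cz)
  t <- (p[1] - q[1]) / (cc[1] - q[1])
  back <- q + t * (cc - q)
  expect_lt(max(abs(back[2:3] - p[2:3])), 0.01)
})

test_that("view orientation flags encode mounting inversion and panel mirroring", {
  g <- fx_geometry()
  # reference panel, upper (non-inverted) module: no flips
  o0 <- view_orientation(g, 0)
  expect_false(o0$flip_row); expect_false(o0$flip_col)
  # physically inverted module: row and column flip
  o2 <- view_orientation(g, 2)
  expect_true(o2$flip_row); expect_true(o2$flip_col)
  # opposite panels carry mutually mirrored column flags
  for (m in 0:3) {
    a <- view_orientation(g, m)          # panel 0
    b <- view_orientation(g, m + 12)     # panel 3 (opposite)
    expect_false(a$mirrored); expect_true(b$mirrored)
    expect_true(xor(a$flip_col, b$flip_col))
  }
  expect_error(view_orientation(g, 99), "unknown")
})

test_that("MC geometric sensitivity matches the analytic solid-angle sum", {
  g <- fx_geometry()
  s <- geometric_sensitivity(g, c(0, 0, 0), n_samples = 2e5, seed = 7)
  a <- analytic_sensitivity(g, c(0, 0, 0))
  expect_lt(abs(s$sensitivity - a), 3 * s$se)
  # per-pinhole acceptances agree with A cos(theta)/(4 pi d^2) (pooled chi)
  A <- pi * (g$pinhole_diameter / 2)^2
  exp_hits <- vapply(seq_len(96), function(i) {
    ph <- g$pinholes[i, ]
    d2 <- ph$cx^2 + ph$cy^2 + ph$cz^2
    cth <- abs(ph$cx * ph$ax + ph$cy * ph$ay + ph$cz * ph$az) / sqrt(d2)
    2e5 * A * cth / (4 * pi * d2)
  }, numeric(1))
  z <- (s$per_pinhole - exp_hits) / sqrt(exp_hits)
  expect_lt(mean(z^2), 2)               # consistent with unit-variance noise
  # reproducibility
  s2 <- geometric_sensitivity(g, c(0, 0, 0), n_samples = 2e5, seed = 7)
  expect_identical(s$sensitivity, s2$sensitivity)
  # a point behind the collimator sees nothing
  s3 <- geometric_sensitivity(g, c(35, 0, 0), n_samples = 1e4, seed = 1)
  expect_equal(s3$sensitivity, 0)
})

test_that("sensitivity is invariant under 60-degree rotation about the axis", {
  g <- fx_geometry()
  p <- c(3, 0, 1)
  th <- pi / 3
  p_rot <- c(cos(th) * p[1] - sin(th) * p[2],
             sin(th) * p[1] + cos(th) * p[2], p[3])
  s1 <- geometric_sensitivity(g, p, n_samples = 1e5, seed = 3)
  s2 <- geometric_sensitivity(g, p_rot, n_samples = 1e5, seed = 4)
  expect_lt(abs(s1$sensitivity - s2$sensitivity),
            3 * sqrt(s1$se^2 + s2$se^2))
  # the analytic sum is exactly invariant
  expect_equal(analytic_sensitivity(g, p), analytic_sensitivity(g, p_rot),
               tolerance = 1e-9)
})

test_that("scan plans are symmetric, equally spaced, and validated", {
  pl <- make_scan_plan(37, 0.5, dwell = 600)
  expect_equal(length(pl$positions), 37)
  expect_equal(diff(range(pl$positions)), 18)
  expect_equal(mean(pl$positions), 0)
  expect_equal(unique(round(diff(pl$positions), 12)), 0.5)
  expect_equal(make_scan_plan(1, 0.5, 1)$positions, 0)
  expect_error(make_scan_plan(37, 0, 600), "step")
  expect_error(make_scan_plan(37, 0.5, 0), "dwell")
  expect_error(make_scan_plan(0, 0.5, 600), "position")
})
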