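# Hexagonal detector ring and 96-pinhole compound-eye aperture.
#
# Coordinate convention (right-handed): x is the lateral scan axis, y the
# pencil-beam axis, z the axial (phantom cylinder) axis.  The six detector
# panels surround the z axis with normals at 60 degree increments starting
# from +x, so the beam (+y) passes through the gap between two panels.  Panel
# local coordinates are (u, v): u along the panel tangent t = (-sin phi,
# cos phi, 0), v along +z.  Each panel carries 4 detector modules (2 x 2 of
# 80 x 80 pixels at 0.25 mm pitch) and 16 pinholes, one per 40 x 40-pixel
# (1 cm x 1 cm) subdetector region.
#
# Pinholes sit in the pinhole plane (distance panel_spacing/(1+1/m) ... see
# below) on the ray from the field-of-view center to their region center,
# with their axes aimed at the FOV center, so each pinhole images the FOV
# center onto the center of its own region and the per-pinhole minification
# along its viewing ray is exactly the configured value.

#' Construct the XFET system geometry
#'
#' Builds the hexagonal ring of 24 detector modules and the 96-pinhole
#' compound-eye aperture and validates the type invariants (module count,
#' pinhole count, pairwise-disjoint subdetector regions).
#'
#' @param panel_spacing distance between opposite detector panels, mm.
#' @param collimator_thickness tungsten collimator panel thickness, mm (the
#'   pinhole plane must fall inside it).
#' @param pinhole_diameter knife-edge aperture diameter, mm.
#' @param minification object-to-image scale (0.5 = the 1:2 compound-eye
#'   design: object-to-pinhole distance is twice pinhole-to-detector).
#' @param n_panels number of panels (6 for the hexagonal ring).
#' @param pixels,pitch per-module pixel count per side and pitch in mm.
#' @param modules_side modules per panel side (2 gives the 2 x 2 layout).
#' @param fov_diameter,fov_axial field of view, mm.
#' @param inverted_modules which module rows are mounted physically rotated by
#'   180 degrees; `"bottom"` flags the lower (v < 0) row of each panel.
#' @return an object of class `xfet_geometry` with `$modules` and `$pinholes`
#'   data frames and the scalar parameters.
#' @export
xfet_geometry <- function(panel_spacing = 82, collimator_thickness = 14,
                          pinhole_diameter = 1, minification = 0.5,
                          n_panels = 6, pixels = 80, pitch = 0.25,
                          modules_side = 2, fov_diameter = 20, fov_axial = 18,
                          inverted_modules = "bottom") {
  stopifnot(panel_spacing > 0, minification > 0, n_panels >= 1)
  r_det <- panel_spacing / 2
  r_pin <- r_det / (1 + minification)         # m = (r_det - r_pin)/r_pin
  if (r_pin < r_det - collimator_thickness - 1e-9 || r_pin > r_det)
    stop("pinhole plane at ", signif(r_pin, 5),
         " mm falls outside the collimator block", call. = FALSE)
  half <- modules_side * pixels * pitch / 2    # panel half-extent, mm (20)
  region <- pixels * pitch / 2                 # subdetector region size (10)
  n_reg_side <- modules_side * 2

  phi <- (seq_len(n_panels) - 1) * 2 * pi / n_panels
  panels <- data.frame(panel = seq_len(n_panels) - 1,
                       nx = cos(phi), ny = sin(phi), nz = 0,
                       tx = -sin(phi), ty = cos(phi), tz = 0)

  modules <- do.call(rbind, lapply(panels$panel, function(p) {
    g <- expand.grid(mu = 0:(modules_side - 1), mv = 0:(modules_side - 1))
    data.frame(module = p * modules_side^2 + g$mv * modules_side + g$mu,
               panel = p, mu = g$mu, mv = g$mv,
               inverted = if (identical(inverted_modules, "bottom"))
                 g$mv == modules_side - 1 else g$mv %in% inverted_modules)
  }))

  # region centers in panel coordinates
  rc <- (seq_len(n_reg_side) - (n_reg_side + 1) / 2) * region
  grid <- expand.grid(iu = seq_len(n_reg_side), iv = seq_len(n_reg_side))
  pinholes <- do.call(rbind, lapply(panels$panel, function(p) {
    n <- unlist(panels[panels$panel == p, c("nx", "ny", "nz")])
    t <- unlist(panels[panels$panel == p, c("tx", "ty", "tz")])
    u <- rc[grid$iu]; v <- rc[grid$iv]
    # region center on the detector plane, world coordinates
    Rx <- r_det * n[1] + u * t[1]
    Ry <- r_det * n[2] + u * t[2]
    Rz <- v
    s <- r_pin / r_det                         # scale back to the pinhole plane
    cx <- Rx * s; cy <- Ry * s; cz <- Rz * s
    d <- sqrt(cx^2 + cy^2 + cz^2)
    data.frame(pinhole = p * n_reg_side^2 + (grid$iv - 1) * n_reg_side +
                 (grid$iu - 1),
               panel = p,
               cx = cx, cy = cy, cz = cz,
               ax = -cx / d, ay = -cy / d, az = -cz / d,   # axis, inward
               u_min = u - region / 2, u_max = u + region / 2,
               v_min = v - region / 2, v_max = v + region / 2,
               u_c = u, v_c = v)
  }))

  # invariant: regions tile the panel disjointly
  for (p in panels$panel) {
    ph <- pinholes[pinholes$panel == p, ]
    o <- order(ph$v_min, ph$u_min)
    area <- sum((ph$u_max - ph$u_min) * (ph$v_max - ph$v_min))
    if (abs(area - (2 * half)^2) > 1e-6)
      stop("subdetector regions do not tile the panel", call. = FALSE)
    key <- paste(ph$u_min, ph$v_min)
    if (anyDuplicated(key))
      stop("overlapping subdetector regions", call. = FALSE)
  }

  structure(list(panels = panels, modules = modules, pinholes = pinholes,
                 panel_spacing = panel_spacing, r_det = r_det, r_pin = r_pin,
                 collimator_thickness = collimator_thickness,
                 pinhole_diameter = pinhole_diameter,
                 minification = minification,
                 pixels = pixels, pitch = pitch, modules_side = modules_side,
                 half = half, region = region,
                 fov_diameter = fov_diameter, fov_axial = fov_axial),
            class = "xfet_geometry")
}

#' @export
print.xfet_geometry <- function(x, ...) {
  cat("<xfet_geometry>", nrow(x$panels), "panels,", nrow(x$modules),
      "modules,", nrow(x$pinholes), "pinholes\n")
  cat("  detector plane", x$r_det, "mm, pinhole plane",
      signif(x$r_pin, 5), "mm, minification 1:", 1 / x$minification,
      ", aperture ", x$pinhole_diameter, " mm\n", sep = "")
  invisible(x)
}

#' Compact identity string for a geometry (used in list-mode metadata)
#' @param geometry an `xfet_geometry`.
#' @export
geometry_hash <- function(geometry) {
  paste0("ring", nrow(geometry$panels), "x", geometry$modules_side^2,
         "-s", geometry$panel_spacing, "-p", signif(geometry$r_pin, 6),
         "-a", geometry$pinhole_diameter, "-m", geometry$minification)
}

# panel basis vectors as a list of 3-vectors
.panel_basis <- function(geometry, panel) {
  pr <- geometry$panels[geometry$panels$panel == panel, ]
  list(n = c(pr$nx, pr$ny, pr$nz), t = c(pr$tx, pr$ty, pr$tz), z = c(0, 0, 1))
}

## ---- pixel index mapping ----------------------------------------------------

# panel-frame pixel indices: col 0..(2*pixels-1) along +u, row 0..(2*pixels-1)
# with row 0 at the panel top (v = +half).  Raw module-local indices apply the
# 180-degree rotation of physically inverted modules.

.panel_uv_to_pixel <- function(geometry, u, v) {
  np <- geometry$modules_side * geometry$pixels
  col <- floor((u + geometry$half) / geometry$pitch)
  row <- floor((geometry$half - v) / geometry$pitch)
  col <- pmin(pmax(col, 0), np - 1)
  row <- pmin(pmax(row, 0), np - 1)
  list(row = row, col = col)
}

.panel_pixel_to_module <- function(geometry, panel, row, col) {
  px <- geometry$pixels
  mv <- row %/% px; mu <- col %/% px
  module <- panel * geometry$modules_side^2 + mv * geometry$modules_side + mu
  r <- row %% px; c <- col %% px
  inv <- geometry$modules$inverted[match(module, geometry$modules$module)]
  list(module = module,
       row = ifelse(inv, px - 1 - r, r),
       col = ifelse(inv, px - 1 - c, c))
}

.module_pixel_to_panel <- function(geometry, module, row, col) {
  px <- geometry$pixels
  i <- match(module, geometry$modules$module)
  m <- geometry$modules[i, ]
  r <- ifelse(m$inverted, px - 1 - row, row)
  c <- ifelse(m$inverted, px - 1 - col, col)
  prow <- m$mv * px + r
  pcol <- m$mu * px + c
  u <- -geometry$half + (pcol + 0.5) * geometry$pitch
  v <- geometry$half - (prow + 0.5) * geometry$pitch
  list(panel = m$panel, u = u, v = v, prow = prow, pcol = pcol)
}

#' Orientation flags for a detector module's view
#'
#' Returns the inversions and flips that bring a module's raw pixel readout
#' into the common object-space orientation used when merging the 96 pinhole
#' views: physically inverted modules need their rows and columns flipped
#' (180-degree rotation), and panels whose tangent direction opposes the beam
#' axis see the object mirrored relative to the reference panel, so their
#' column order is mirrored once more.
#'
#' @param geometry an `xfet_geometry`.
#' @param module module id (0-23).
#' @return list with logical `flip_row`, `flip_col` and the `mirrored` state
#'   of the hosting panel.
#' @export
view_orientation <- function(geometry, module) {
  i <- match(module, geometry$modules$module)
  if (is.na(i)) stop("unknown module id", call. = FALSE)
  m <- geometry$modules[i, ]
  b <- .panel_basis(geometry, m$panel)
  mirrored <- (b$t[2] < -1e-12)      # panel tangent opposes the beam (+y) axis
  list(flip_row = m$inverted,
       flip_col = xor(m$inverted, mirrored),
       mirrored = mirrored)
}

## ---- projection -------------------------------------------------------------

#' Project an object-space point through a pinhole onto the detector
#'
#' Ideal (central) pinhole projection: the image is the intersection of the
#' line through the point and the pinhole center with the detector plane.  The
#' image is inverted and minified (1:2 in the reference design).  The point is
#' reported "not visible" when its image falls outside the pinhole's assigned
#' subdetector region or the point is on the wrong side of the pinhole plane.
#'
#' @param geometry an `xfet_geometry`.
#' @param pinhole pinhole id (0-95).
#' @param p object-space point(s), a length-3 vector or an n x 3 matrix (mm).
#' @return data frame with `visible`, panel coordinates `u`, `v`, the panel
#'   pixel indices and raw module/row/col of the containing pixel.
#' @export
project_point <- function(geometry, pinhole, p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  ph <- geometry$pinholes[match(pinhole, geometry$pinholes$pinhole), ]
  if (any(is.na(ph$pinhole))) stop("unknown pinhole id", call. = FALSE)
  b <- .panel_basis(geometry, ph$panel)
  cc <- c(ph$cx, ph$cy, ph$cz)
  dn <- (cc[1] - p[, 1]) * b$n[1] + (cc[2] - p[, 2]) * b$n[2]
  pn <- p[, 1] * b$n[1] + p[, 2] * b$n[2]
  # line p + s*(c - p); detector plane at r_det along n
  s <- (geometry$r_det - pn) / dn
  qx <- p[, 1] + s * (cc[1] - p[, 1])
  qy <- p[, 2] + s * (cc[2] - p[, 2])
  qz <- p[, 3] + s * (cc[3] - p[, 3])
  u <- qx * b$t[1] + qy * b$t[2]
  v <- qz
  visible <- is.finite(s) & s > 1 &            # image beyond the pinhole
    u >= ph$u_min & u < ph$u_max & v >= ph$v_min & v < ph$v_max
  pix <- .panel_uv_to_pixel(geometry, u, v)
  mod <- .panel_pixel_to_module(geometry, ph$panel, pix$row, pix$col)
  data.frame(visible = visible, u = u, v = v,
             panel_row = pix$row, panel_col = pix$col,
             module = mod$module, row = mod$row, col = mod$col)
}

#' Back-project detector pixels to the beam plane
#'
#' For each event, traces the ray from the hit pixel center through its
#' pinhole center into object space and intersects it with the vertical plane
#' `x = plane_x` containing the pencil beam.  This inverts the pinhole
#' projection exactly (including the perspective foreshortening of oblique
#' panels) for sources on the beam line.
#'
#' @param geometry an `xfet_geometry`.
#' @param pinhole,module,row,col event vectors (raw module-local indices).
#' @param plane_x lateral scan position of the beam, mm.
#' @return data frame with object-space `y` (beam coordinate) and `z` (axial).
#' @export
backproject_pixel <- function(geometry, pinhole, module, row, col, plane_x) {
  pp <- .module_pixel_to_panel(geometry, module, row, col)
  i <- match(pinhole, geometry$pinholes$pinhole)
  ph <- geometry$pinholes[i, ]
  pr <- geometry$panels[match(pp$panel, geometry$panels$panel), ]
  # pixel center world position
  qx <- geometry$r_det * pr$nx + pp$u * pr$tx
  qy <- geometry$r_det * pr$ny + pp$u * pr$ty
  qz <- pp$v
  dx <- ph$cx - qx; dy <- ph$cy - qy; dz <- ph$cz - qz
  t <- (plane_x - qx) / dx
  data.frame(y = qy + t * dy, z = qz + t * dz)
}

## ---- sensitivity ------------------------------------------------------------

#' Monte-Carlo geometric sensitivity
#'
#' Fraction of photons emitted isotropically from `p` that pass through any
#' pinhole aperture (ideal binary disk) and land inside that pinhole's
#' assigned subdetector region.  Reproducible for a fixed seed.
#'
#' @param geometry an `xfet_geometry`.
#' @param p emission point, mm.
#' @param n_samples number of sampled directions (>= 1e4).
#' @param seed RNG seed.
#' @return list with `sensitivity`, its Monte-Carlo standard error `se`, and
#'   the per-pinhole acceptance counts.
#' @export
geometric_sensitivity <- function(geometry, p = c(0, 0, 0), n_samples = 1e6,
                                  seed = 1) {
  stopifnot(n_samples >= 1e4)
  set.seed(seed)
  n <- as.integer(n_samples)
  z <- stats::runif(n, -1, 1)
  az <- stats::runif(n, 0, 2 * pi)
  rho <- sqrt(1 - z^2)
  wx <- rho * cos(az); wy <- rho * sin(az); wz <- z
  r2 <- (geometry$pinhole_diameter / 2)^2
  hits <- integer(nrow(geometry$pinholes))
  accepted <- logical(n)
  # first collimator facet crossed by each ray: the hexagonal collimator
  # shell is convex, so a ray can only reach pinholes of that facet (rays
  # crossing another panel's tungsten first are absorbed)
  t_first <- rep(Inf, n)
  p_first <- rep(-1L, n)
  for (k in seq_len(nrow(geometry$panels))) {
    b <- .panel_basis(geometry, geometry$panels$panel[k])
    wn <- wx * b$n[1] + wy * b$n[2]
    pn <- p[1] * b$n[1] + p[2] * b$n[2]
    tk <- (geometry$r_pin - pn) / wn
    better <- is.finite(tk) & tk > 0 & tk < t_first
    t_first[better] <- tk[better]
    p_first[better] <- geometry$panels$panel[k]
  }
  for (i in seq_len(nrow(geometry$pinholes))) {
    ph <- geometry$pinholes[i, ]
    b <- .panel_basis(geometry, ph$panel)
    # aperture disk: center c, normal = pinhole axis
    vx <- ph$cx - p[1]; vy <- ph$cy - p[2]; vz <- ph$cz - p[3]
    wa <- wx * ph$ax + wy * ph$ay + wz * ph$az
    va <- vx * ph$ax + vy * ph$ay + vz * ph$az
    t <- va / wa                                # ray meets the aperture plane
    ok <- is.finite(t) & t > 0 & p_first == ph$panel
    hx <- p[1] + t * wx - ph$cx
    hy <- p[2] + t * wy - ph$cy
    hz <- p[3] + t * wz - ph$cz
    ok <- ok & (hx^2 + hy^2 + hz^2 - (hx * ph$ax + hy * ph$ay + hz * ph$az)^2) <= r2
    if (!any(ok)) next
    # continue to the detector plane
    wn <- wx * b$n[1] + wy * b$n[2]
    pn <- p[1] * b$n[1] + p[2] * b$n[2]
    td <- (geometry$r_det - pn) / wn
    u <- (p[1] + td * wx) * b$t[1] + (p[2] + td * wy) * b$t[2]
    v <- p[3] + td * wz
    ok <- ok & is.finite(td) & td > 0 &
      u >= ph$u_min & u < ph$u_max & v >= ph$v_min & v < ph$v_max
    hits[i] <- sum(ok)
    accepted <- accepted | ok
  }
  k <- sum(accepted)
  list(sensitivity = k / n, se = sqrt(k) / n, per_pinhole = hits)
}

#' Analytic geometric sensitivity (solid-angle sum)
#'
#' Sum of A cos(theta) / (4 pi d^2) over the pinholes whose image of `p`
#' falls inside their assigned region, with A the aperture area, d the
#' point-to-pinhole distance and theta the angle between the pinhole axis and
#' the emission direction.
#'
#' @inheritParams geometric_sensitivity
#' @export
analytic_sensitivity <- function(geometry, p = c(0, 0, 0)) {
  A <- pi * (geometry$pinhole_diameter / 2)^2
  tot <- 0
  for (i in seq_len(nrow(geometry$pinholes))) {
    ph <- geometry$pinholes[i, ]
    pr <- project_point(geometry, ph$pinhole, p)
    if (!pr$visible) next
    vx <- ph$cx - p[1]; vy <- ph$cy - p[2]; vz <- ph$cz - p[3]
    d2 <- vx^2 + vy^2 + vz^2
    cth <- abs(vx * ph$ax + vy * ph$ay + vz * ph$az) / sqrt(d2)
    tot <- tot + A * cth / (4 * pi * d2)
  }
  tot
}

# per-pinhole acceptance probabilities for a set of emission points (rows of
# pts): solid angle of the aperture disk; used by the forward simulator.
.pinhole_acceptance <- function(geometry, pts) {
  A <- pi * (geometry$pinhole_diameter / 2)^2
  np <- nrow(geometry$pinholes)
  out <- matrix(0, nrow(pts), np)
  for (i in seq_len(np)) {
    ph <- geometry$pinholes[i, ]
    vx <- ph$cx - pts[, 1]; vy <- ph$cy - pts[, 2]; vz <- ph$cz - pts[, 3]
    d2 <- vx^2 + vy^2 + vz^2
    cth <- abs(vx * ph$ax + vy * ph$ay + vz * ph$az) / sqrt(d2)
    out[, i] <- A * cth / (4 * pi * d2)
  }
  out
}

## ---- scan plan --------------------------------------------------------------

#' Plan a line-by-line pencil-beam scan
#'
#' Lateral positions are equally spaced by `step` and symmetric about the
#' phantom axis (x = 0); the beam travels along +y at z = 0.
#'
#' @param n_positions number of scan positions (>= 1).
#' @param step lateral step size, mm (> 0).
#' @param dwell acquisition time per position, s (> 0).
#' @return an object of class `scan_plan`.
#' @export
make_scan_plan <- function(n_positions = 37, step = 0.5, dwell = 600) {
  if (n_positions < 1) stop("need at least one position", call. = FALSE)
  if (step <= 0) stop("step must be positive", call. = FALSE)
  if (dwell <= 0) stop("dwell must be positive", call. = FALSE)
  x <- (seq_len(n_positions) - (n_positions + 1) / 2) * step
  structure(list(positions = x, step = step, dwell = dwell,
                 n_positions = n_positions),
            class = "scan_plan")
}

#' @export
print.scan_plan <- function(x, ...) {
  cat("<scan_plan>", x$n_positions, "positions, step", x$step,
      "mm, span", diff(range(x$positions)), "mm, dwell", x$dwell, "s\n")
  invisible(x)
}

#' Export pinhole centers/axes and module layout as CSV
#' @param geometry an `xfet_geometry`.
#' @param file output path.
#' @export
write_geometry_csv <- function(geometry, file) {
  utils::write.csv(geometry$pinholes, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
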