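# Analytic phantom: a 19 mm acrylic cylinder with four PTFE tubes on a
# 5.5 mm radius, each holding a water-based fill.  All cylinders share the z
# (axial) axis direction; the pencil beam travels along +y at z = 0.

#' Construct an analytic cylinder phantom
#'
#' @param body_diameter,body_height acrylic body, mm.
#' @param tube_outer,tube_inner,tube_height PTFE tube dimensions, mm.
#' @param tube_offset radial distance of tube centers from the axis, mm.
#' @param tube_angles angular positions, degrees (0 = +x).
#' @param fills list of [xfet_material] fill materials, one per tube
#'   (typically from [solution_material]).
#' @param labels character labels per tube.
#' @return object of class `xfet_phantom`.
#' @export
xfet_phantom <- function(body_diameter = 19, body_height = 10,
                         tube_outer = 4.7, tube_inner = 3, tube_height = 8,
                         tube_offset = 5.5,
                         tube_angles = c(0, 90, 180, 270),
                         fills = list(), labels = NULL) {
  stopifnot(length(fills) == length(tube_angles))
  if (tube_offset + tube_outer / 2 > body_diameter / 2)
    stop("tubes extend outside the phantom body", call. = FALSE)
  th <- tube_angles * pi / 180
  tubes <- data.frame(tube = seq_along(th),
                      x = tube_offset * cos(th), y = tube_offset * sin(th),
                      angle = tube_angles,
                      r_outer = tube_outer / 2, r_inner = tube_inner / 2,
                      z_min = -tube_height / 2, z_max = tube_height / 2,
                      label = if (is.null(labels))
                        paste0("tube", seq_along(th)) else labels)
  structure(list(body = list(radius = body_diameter / 2,
                             z_min = -body_height / 2, z_max = body_height / 2,
                             material = standard_material("pmma")),
                 wall_material = standard_material("ptfe"),
                 tubes = tubes, fills = fills),
            class = "xfet_phantom")
}

#' @export
print.xfet_phantom <- function(x, ...) {
  cat("<xfet_phantom>", 2 * x$body$radius, "mm acrylic cylinder,",
      nrow(x$tubes), "tubes\n")
  for (i in seq_len(nrow(x$tubes)))
    cat(sprintf("  %-8s at (%.1f, %.1f): %s\n", x$tubes$label[i],
                x$tubes$x[i], x$tubes$y[i], x$fills[[i]]$name))
  invisible(x)
}

#' Phantom study I: gadolinium detection-limit series
#'
#' Four tubes: water and Gd solutions at 3, 0.6 and 0.1 mg/mL.
#' @export
phantom_study_I <- function() {
  xfet_phantom(
    fills = list(solution_material(),
                 solution_material(c(Gd = 3)),
                 solution_material(c(Gd = 0.6)),
                 solution_material(c(Gd = 0.1))),
    labels = c("water", "Gd3", "Gd0.6", "Gd0.1"))
}

#' Phantom study II: gadolinium/lanthanum mixtures
#'
#' Tubes with Gd:La concentration ratios 1:2, 1:1 and 2:1 (3:6, 3:3 and
#' 6:3 mg/mL) plus a water reference.
#' @export
phantom_study_II <- function() {
  xfet_phantom(
    fills = list(solution_material(),
                 solution_material(c(Gd = 3, La = 6)),
                 solution_material(c(Gd = 3, La = 3)),
                 solution_material(c(Gd = 6, La = 3))),
    labels = c("water", "Gd3La6", "Gd3La3", "Gd6La3"))
}

## ---- ray tracing ------------------------------------------------------------

# parametric intersection of rays with a z-capped cylinder; origins O (n x 3),
# unit directions D (n x 3); returns [t0, t1] (t1 <= t0 means no hit),
# clipped to t >= tmin
.cyl_interval <- function(O, D, cx, cy, radius, z_min, z_max, tmin = 0) {
  ox <- O[, 1] - cx; oy <- O[, 2] - cy
  a <- D[, 1]^2 + D[, 2]^2
  b <- 2 * (ox * D[, 1] + oy * D[, 2])
  cc <- ox^2 + oy^2 - radius^2
  disc <- b^2 - 4 * a * cc
  t0 <- rep(Inf, nrow(O)); t1 <- rep(-Inf, nrow(O))
  hit <- disc > 0 & a > 1e-12
  sq <- sqrt(pmax(disc, 0))
  t0[hit] <- ((-b - sq) / (2 * a))[hit]
  t1[hit] <- ((-b + sq) / (2 * a))[hit]
  vert <- a <= 1e-12 & cc < 0                   # ray parallel to the axis
  t0[vert] <- -Inf; t1[vert] <- Inf
  # clip to the z slab
  dz <- D[, 3]
  zlo <- (z_min - O[, 3]) / dz
  zhi <- (z_max - O[, 3]) / dz
  s0 <- pmin(zlo, zhi); s1 <- pmax(zlo, zhi)
  flat <- abs(dz) <= 1e-12
  s0[flat] <- ifelse(O[flat, 3] >= z_min & O[flat, 3] <= z_max, -Inf, Inf)
  s1[flat] <- ifelse(O[flat, 3] >= z_min & O[flat, 3] <= z_max, Inf, -Inf)
  t0 <- pmax(t0, s0, tmin)
  t1 <- pmin(t1, s1)
  list(t0 = t0, t1 = t1, len = pmax(t1 - t0, 0))
}

#' Material at an object-space point
#' @param phantom an `xfet_phantom`.
#' @param p point, mm.
#' @return the [xfet_material] at the point, or `NULL` outside the body.
#' @export
material_at <- function(phantom, p) {
  r2 <- p[1]^2 + p[2]^2
  b <- phantom$body
  if (r2 > b$radius^2 || p[3] < b$z_min || p[3] > b$z_max) return(NULL)
  tb <- phantom$tubes
  d2 <- (p[1] - tb$x)^2 + (p[2] - tb$y)^2
  inz <- p[3] >= tb$z_min & p[3] <= tb$z_max
  i <- which(inz & d2 <= tb$r_inner^2)
  if (length(i)) return(phantom$fills[[i[1]]])
  i <- which(inz & d2 <= tb$r_outer^2)
  if (length(i)) return(phantom$wall_material)
  b$material
}

#' Ordered material segments along a ray
#'
#' Splits the intersection of a ray with the phantom into contiguous,
#' non-overlapping segments and identifies the material of each (acrylic
#' body, PTFE tube wall, or tube fill).  Rays that miss return an empty
#' frame.
#'
#' @param phantom an `xfet_phantom`.
#' @param origin ray origin, mm.
#' @param direction ray direction (normalized internally).
#' @return data frame with `material` (label), `entry`, `exit` (mm along the
#'   ray) and the material's `mu_key` index used by [path_transmission].
#' @export
ray_segments <- function(phantom, origin, direction) {
  direction <- direction / sqrt(sum(direction^2))
  O <- matrix(origin, 1); D <- matrix(direction, 1)
  b <- phantom$body
  body <- .cyl_interval(O, D, 0, 0, b$radius, b$z_min, b$z_max)
  if (body$len <= 0) {
    return(data.frame(material = character(), entry = numeric(),
                      exit = numeric()))
  }
  cuts <- c(body$t0, body$t1)
  tb <- phantom$tubes
  for (i in seq_len(nrow(tb))) {
    for (r in c(tb$r_outer[i], tb$r_inner[i])) {
      iv <- .cyl_interval(O, D, tb$x[i], tb$y[i], r, tb$z_min[i], tb$z_max[i])
      if (iv$len > 0) cuts <- c(cuts, iv$t0, iv$t1)
    }
  }
  cuts <- sort(unique(pmax(pmin(cuts, body$t1), body$t0)))
  mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
  keep <- cuts[-1] - cuts[-length(cuts)] > 1e-9
  seg <- data.frame(entry = cuts[-length(cuts)][keep], exit = cuts[-1][keep])
  seg$material <- vapply(seq_len(nrow(seg)), function(k) {
    m <- material_at(phantom, origin + mids[keep][k] * direction)
    if (is.null(m)) "outside" else m$name
  }, character(1))
  seg[, c("material", "entry", "exit")]
}

# per-material path lengths (cm) from points P along unit directions D to the
# phantom exit; returns a matrix with one column per distinct material
.material_path_lengths <- function(phantom, P, D) {
  b <- phantom$body
  body <- .cyl_interval(P, D, 0, 0, b$radius, b$z_min, b$z_max, tmin = 0)
  n <- nrow(P)
  tb <- phantom$tubes
  L_outer <- matrix(0, n, nrow(tb)); L_inner <- matrix(0, n, nrow(tb))
  for (i in seq_len(nrow(tb))) {
    oo <- .cyl_interval(P, D, tb$x[i], tb$y[i], tb$r_outer[i],
                        tb$z_min[i], tb$z_max[i], tmin = 0)
    ii <- .cyl_interval(P, D, tb$x[i], tb$y[i], tb$r_inner[i],
                        tb$z_min[i], tb$z_max[i], tmin = 0)
    L_outer[, i] <- oo$len
    L_inner[, i] <- ii$len
  }
  walls <- L_outer - L_inner
  acrylic <- pmax(body$len - rowSums(L_outer), 0)
  cbind(acrylic = acrylic, wall = rowSums(walls), L_inner) / 10  # mm -> cm
}

#' Transmission of photons from interior points to the phantom surface
#'
#' Computes exp(-sum mu_i rho_i l_i) along each ray from `P` (inside the
#' phantom) in direction `D` at photon energy `energy`, accounting for the
#' acrylic body, PTFE walls and each tube fill.
#'
#' @param phantom an `xfet_phantom`.
#' @param P n x 3 matrix of start points, mm.
#' @param D n x 3 matrix of unit directions.
#' @param energy photon energy, keV (scalar or length n).
#' @export
path_transmission <- function(phantom, P, D, energy) {
  L <- .material_path_lengths(phantom, P, D)
  if (length(energy) == 1) energy <- rep(energy, nrow(P))
  eu <- sort(unique(energy))
  mats <- c(list(phantom$body$material, phantom$wall_material), phantom$fills)
  mu <- vapply(mats, function(m) linear_attenuation(m, eu), numeric(length(eu)))
  mu <- matrix(mu, nrow = length(eu))
  idx <- match(energy, eu)
  expo <- numeric(nrow(P))
  for (j in seq_len(ncol(L))) expo <- expo + L[, j] * mu[idx, j]
  exp(-expo)
}
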