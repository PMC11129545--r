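# Seeded Monte-Carlo forward simulator: pencil-beam excitation of XRF along
# the beam path, pinhole transport onto the detector ring, single-scatter
# Klein-Nishina Compton background, detector energy response and charge
# sharing.  Output is list-mode: (frame, module, row, col, energy, truth).

#' Detector response model
#'
#' Energy resolution is linear between the tabulated FWHM anchors and flat
#' beyond them; charge sharing splits a configurable fraction of events
#' between the struck pixel and one 8-neighbor.
#'
#' @param fwhm_anchors data frame with `energy_kev` and `fwhm_kev`; the
#'   defaults are the spectrometer's measured anchors (0.5 keV at 35 keV,
#'   0.88 keV at 60 keV, 1.02 keV at 122 keV).
#' @param charge_sharing_prob per-event probability that the deposited charge
#'   splits across two pixels.
#' @param frame_rate readout frame rate, frames/s.
#' @export
detector_response <- function(fwhm_anchors = data.frame(
                                energy_kev = c(35, 60, 122),
                                fwhm_kev = c(0.5, 0.88, 1.02)),
                              charge_sharing_prob = 0.3,
                              frame_rate = 2000) {
  stopifnot(all(diff(fwhm_anchors$energy_kev) > 0),
            all(diff(fwhm_anchors$fwhm_kev) >= 0),
            charge_sharing_prob >= 0, charge_sharing_prob <= 1,
            frame_rate > 0)
  structure(list(fwhm_anchors = fwhm_anchors,
                 charge_sharing_prob = charge_sharing_prob,
                 frame_rate = frame_rate),
            class = "detector_response")
}

#' Interpolated energy-resolution FWHM, keV
#' @param response a [detector_response].
#' @param energy photon energies, keV.
#' @export
fwhm_at <- function(response, energy) {
  a <- response$fwhm_anchors
  stats::approx(a$energy_kev, a$fwhm_kev, xout = energy, rule = 2)$y
}

#' Apply the Gaussian energy response
#'
#' @param energy true deposited energies, keV.
#' @param response a [detector_response].
#' @return measured energies (keV); uses the current RNG stream.
#' @export
apply_response <- function(energy, response) {
  stopifnot(all(energy > 0))
  energy + stats::rnorm(length(energy), 0, fwhm_at(response, energy) / 2.3548)
}

#' Split events by charge sharing
#'
#' With probability `prob` an event's deposited energy is split (uniform
#' fraction) between its pixel and one uniformly chosen valid 8-neighbor in
#' the same frame; otherwise the event is returned unchanged.  Energies are
#' conserved exactly (the split happens before the energy-response blur).
#'
#' @param events list-mode data frame (`frame`, `module`, `row`, `col`,
#'   `energy_kev`, ...).
#' @param prob sharing probability.
#' @param pixels pixels per module side.
#' @export
simulate_charge_sharing <- function(events, prob, pixels = 80) {
  n <- nrow(events)
  if (n == 0 || prob <= 0) return(events)
  share <- stats::runif(n) < prob
  if (!any(share)) return(events)
  sh <- events[share, , drop = FALSE]
  m <- nrow(sh)
  # choose a neighbor among the valid ones (edge pixels have fewer than 8)
  off <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
               dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  pick <- integer(m)
  ok <- matrix(TRUE, m, 8)
  for (k in 1:8) {
    r <- sh$row + off[k, 1]; c <- sh$col + off[k, 2]
    ok[, k] <- r >= 0 & r < pixels & c >= 0 & c < pixels
  }
  u <- stats::runif(m)
  nvalid <- rowSums(ok)
  kth <- ceiling(u * nvalid)                     # k-th valid neighbor
  cum <- t(apply(ok, 1, cumsum))
  pick <- max.col(cum == kth, ties.method = "first")
  frac <- stats::runif(m)
  a <- sh; b <- sh
  a$energy_kev <- sh$energy_kev * frac
  b$energy_kev <- sh$energy_kev * (1 - frac)
  b$row <- sh$row + off[pick, 1]
  b$col <- sh$col + off[pick, 2]
  out <- rbind(events[!share, , drop = FALSE], a, b)
  out[order(out$frame), , drop = FALSE]
}

## ---- XRF yield --------------------------------------------------------------

# beam entry point: the pencil beam travels along +y at lateral x0, z = 0
.beam_origin <- function(x0) c(x0, -60, 0)

#' Depth-resolved XRF yield along the pencil beam
#'
#' For each depth bin along the beam path through the phantom: incident
#' fluence surviving attenuation, times the element's K-shell photoelectric
#' interaction probability (spectrum bins above the K edge only, with the
#' K-shell fraction given by the absorption jump), times the fluorescence
#' yield and the requested line branching.  Returned per incident beam
#' photon.
#'
#' @param phantom an `xfet_phantom`.
#' @param x0 lateral beam position, mm.
#' @param spectrum a `beam_spectrum`.
#' @param element element symbol.
#' @param line `"Ka"`, `"Kb"` or `"K"` (all K lines).
#' @param depth_step depth bin size along the beam, mm.
#' @return data frame with bin center `y` (mm), bin width, and `yield`
#'   (expected emitted photons per incident photon); zero rows if the beam
#'   misses the phantom, all-zero yield if the element is absent.
#' @export
xrf_yield_per_path <- function(phantom, x0, spectrum, element,
                               line = c("Ka", "Kb", "K"), depth_step = 0.2) {
  line <- match.arg(line)
  O <- matrix(.beam_origin(x0), 1); D <- matrix(c(0, 1, 0), 1)
  b <- phantom$body
  body <- .cyl_interval(O, D, 0, 0, b$radius, b$z_min, b$z_max)
  if (body$len <= 0)
    return(data.frame(y = numeric(), width = numeric(), yield = numeric()))
  tt <- seq(body$t0, body$t1, by = depth_step)
  if (tt[length(tt)] < body$t1) tt <- c(tt, body$t1)
  mid <- (tt[-1] + tt[-length(tt)]) / 2
  dl <- diff(tt)
  nb <- length(mid)
  pts <- cbind(x0, O[1, 2] + mid, 0)
  mats <- lapply(seq_len(nb), function(i) material_at(phantom, pts[i, ]))
  mat_name <- vapply(mats, function(m) if (is.null(m)) "outside" else m$name,
                     character(1))
  umat <- unique(mat_name)
  E <- spectrum$energy_kev
  w <- spectrum$fluence
  # linear attenuation per (unique material, energy)
  mu <- matrix(0, length(umat), length(E))
  for (k in seq_along(umat)) {
    m <- mats[[match(umat[k], mat_name)]]
    if (!is.null(m)) mu[k, ] <- linear_attenuation(m, E)
  }
  imat <- match(mat_name, umat)
  # cumulative optical depth to each bin center (cm)
  od_step <- mu[imat, , drop = FALSE] * dl / 10
  od_mid <- apply(od_step, 2, cumsum) - od_step / 2
  Tmat <- exp(-od_mid)                           # nb x nE transmission
  # element concentration per bin (g/cm^3)
  conc <- vapply(mats, function(m) {
    if (!is.null(m) && !is.null(m$solutes) && element %in% names(m$solutes))
      m$solutes[[element]] / 1000 else 0
  }, numeric(1))
  edge <- k_edge(element)
  above <- E >= edge
  yield <- numeric(nb)
  if (any(above) && any(conc > 0)) {
    tau <- mass_attenuation(element, E[above], "photoelectric")
    J <- jump_factor(element)
    fk <- (J - 1) / J
    exc <- Tmat[, above, drop = FALSE] %*% (w[above] * tau)
    br <- switch(line, Ka = kalpha_fraction(element),
                 Kb = 1 - kalpha_fraction(element), K = 1)
    yield <- conc * (dl / 10) * as.numeric(exc) * fk *
      fluorescence_yield(element) * br
  }
  data.frame(y = pts[, 2], width = dl, yield = yield)
}

## ---- Klein-Nishina ----------------------------------------------------------

# differential KN cross section dsigma/dOmega (cm^2/sr) and total (cm^2)
.kn_diff <- function(E, costh) {
  re2 <- 7.940787e-26
  k <- E / 511
  r <- 1 / (1 + k * (1 - costh))                 # E'/E
  re2 / 2 * r^2 * (r + 1 / r - (1 - costh^2))
}

.kn_total <- function(E) {
  k <- E / 511
  re2 <- 7.940787e-26
  2 * pi * re2 * ((1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k) +
                  log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2)
}

## ---- event assembly helpers -------------------------------------------------

# transport sampled photons (emission point, target pinhole) to detector
# pixels: aperture-disk jitter, exit attenuation, detector absorption,
# projection.  Returns a list-mode fragment without frames.
.transport_to_detector <- function(phantom, geometry, pts, pin_idx, energy,
                                   truth) {
  n <- nrow(pts)
  if (n == 0) return(NULL)
  ph <- geometry$pinholes[pin_idx, , drop = FALSE]
  # jitter across the aperture disk (plane normal to the pinhole axis)
  ax <- cbind(ph$ax, ph$ay, ph$az)
  e1 <- cbind(-ax[, 2], ax[, 1], 0)
  deg <- sqrt(rowSums(e1^2)) < 1e-9
  if (any(deg)) e1[deg, 1] <- 1
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(ax[, 2] * e1[, 3] - ax[, 3] * e1[, 2],
              ax[, 3] * e1[, 1] - ax[, 1] * e1[, 3],
              ax[, 1] * e1[, 2] - ax[, 2] * e1[, 1])
  rr <- geometry$pinhole_diameter / 2 * sqrt(stats::runif(n))
  aa <- stats::runif(n, 0, 2 * pi)
  tx <- ph$cx + rr * (cos(aa) * e1[, 1] + sin(aa) * e2[, 1])
  ty <- ph$cy + rr * (cos(aa) * e1[, 2] + sin(aa) * e2[, 2])
  tz <- ph$cz + rr * (cos(aa) * e1[, 3] + sin(aa) * e2[, 3])
  Dx <- tx - pts[, 1]; Dy <- ty - pts[, 2]; Dz <- tz - pts[, 3]
  dn <- sqrt(Dx^2 + Dy^2 + Dz^2)
  D <- cbind(Dx, Dy, Dz) / dn
  # exit attenuation through the phantom
  surv <- path_transmission(phantom, pts, D, energy)
  # detector photoelectric absorption (1 mm CdTe)
  cdte <- standard_material("cdte")
  eff <- 1 - exp(-mass_attenuation(cdte, energy, "photoelectric") *
                   cdte$density * 0.1)
  keep <- stats::runif(n) < surv * eff
  if (!any(keep)) return(NULL)
  pts <- pts[keep, , drop = FALSE]; D <- D[keep, , drop = FALSE]
  ph <- ph[keep, , drop = FALSE]; energy <- energy[keep]
  truth <- truth[keep]
  # continue the ray to the detector plane of the pinhole's panel
  pr <- geometry$panels[match(ph$panel, geometry$panels$panel), ]
  wn <- D[, 1] * pr$nx + D[, 2] * pr$ny
  pn <- pts[, 1] * pr$nx + pts[, 2] * pr$ny
  td <- (geometry$r_det - pn) / wn
  u <- (pts[, 1] + td * D[, 1]) * pr$tx + (pts[, 2] + td * D[, 2]) * pr$ty
  v <- pts[, 3] + td * D[, 3]
  onp <- is.finite(td) & td > 0 & abs(u) < geometry$half & abs(v) < geometry$half
  if (!any(onp)) return(NULL)
  u <- u[onp]; v <- v[onp]
  pix <- .panel_uv_to_pixel(geometry, u, v)
  mod <- .panel_pixel_to_module(geometry, ph$panel[onp], pix$row, pix$col)
  data.frame(module = mod$module, row = mod$row, col = mod$col,
             energy_kev = energy[onp], truth = truth[onp])
}

#' Simulate one scan position
#'
#' Poisson-samples XRF emissions from the depth-resolved yield profiles of
#' every element present in the phantom fills, emits them isotropically
#' (importance-sampled through the 96 pinhole solid angles), attenuates them
#' along their exit paths, and projects them through the aperture (with
#' aperture-disk blur) onto the detector pixels.  Single-scatter Compton
#' background photons are generated along the beam path from the
#' Klein-Nishina angular/energy distribution by forced detection through the
#' same apertures.  Events receive charge sharing, the Gaussian energy
#' response, and Poisson frame assignment, and are returned sorted by frame.
#'
#' @param phantom an `xfet_phantom`.
#' @param x0 lateral beam position, mm.
#' @param geometry an `xfet_geometry`.
#' @param spectrum a `beam_spectrum`.
#' @param dwell acquisition time, s.
#' @param flux incident beam photons per second through the 1-mm aperture.
#' @param response a [detector_response].
#' @param seed RNG seed (recorded in the metadata).
#' @param compton simulate the Compton background (default TRUE).
#' @param depth_step beam depth bin, mm.
#' @param compton_bin energy bin width for the background sampler, keV.
#' @return a `listmode` object: data frame plus acquisition metadata.
#' @export
simulate_position <- function(phantom, x0, geometry, spectrum, dwell, flux,
                              response = detector_response(), seed = 1,
                              compton = TRUE, depth_step = 0.2,
                              compton_bin = 1) {
  stopifnot(flux > 0, dwell > 0)
  set.seed(seed)
  n_inc <- flux * dwell
  beam_r <- 0.5                                  # 1-mm pencil beam
  frags <- list()
  emitted <- numeric(0)                          # expected K emissions/element

  # --- XRF ---
  elements <- unique(unlist(lapply(phantom$fills, function(f)
    names(f$solutes)[f$solutes > 0])))
  for (el in elements) {
    yl <- xrf_yield_per_path(phantom, x0, spectrum, el, line = "K",
                             depth_step = depth_step)
    if (nrow(yl) == 0 || sum(yl$yield) == 0) next
    emitted[el] <- n_inc * sum(yl$yield)
    lam <- n_inc * yl$yield
    nb <- length(lam)
    pts0 <- cbind(x0, yl$y, 0)
    acc <- .pinhole_acceptance(geometry, pts0)   # nb x 96
    counts <- stats::rpois(length(acc), as.numeric(acc) * lam)
    idx <- which(counts > 0)
    if (!length(idx)) next
    counts <- counts[idx]
    bin <- (idx - 1) %% nb + 1
    pin <- (idx - 1) %/% nb + 1
    bin <- rep(bin, counts); pin <- rep(pin, counts)
    n <- length(bin)
    # exact emission points: uniform in depth bin and beam disk
    rr <- beam_r * sqrt(stats::runif(n)); aa <- stats::runif(n, 0, 2 * pi)
    pts <- cbind(x0 + rr * cos(aa),
                 yl$y[bin] + (stats::runif(n) - 0.5) * yl$width[bin],
                 rr * sin(aa))
    # emission line
    ln <- .xfet$lines[.xfet$lines$element == el, ]
    li <- sample.int(nrow(ln), n, replace = TRUE,
                     prob = ln$rel_intensity)
    fr <- .transport_to_detector(phantom, geometry, pts, pin,
                                 ln$energy_kev[li],
                                 rep(paste0("XRF:", el), n))
    frags <- c(frags, list(fr))
  }

  # --- Compton single scatter (forced detection) ---
  if (compton) {
    O <- matrix(.beam_origin(x0), 1); D <- matrix(c(0, 1, 0), 1)
    b <- phantom$body
    body <- .cyl_interval(O, D, 0, 0, b$radius, b$z_min, b$z_max)
    if (body$len > 0) {
      tt <- seq(body$t0, body$t1, by = depth_step)
      if (tt[length(tt)] < body$t1) tt <- c(tt, body$t1)
      mid <- (tt[-1] + tt[-length(tt)]) / 2
      dl <- diff(tt); nb <- length(mid)
      pts0 <- cbind(x0, O[1, 2] + mid, 0)
      mats <- lapply(seq_len(nb), function(i) material_at(phantom, pts0[i, ]))
      # coarse energy grid
      Eg <- spectrum$energy_kev; wg <- spectrum$fluence
      ce <- seq(min(Eg), max(Eg) + compton_bin, by = compton_bin)
      gi <- findInterval(Eg, ce)
      Ec <- tapply(Eg * wg, gi, sum) / tapply(wg, gi, sum)
      wc <- tapply(wg, gi, sum)
      Ec <- as.numeric(Ec); wc <- as.numeric(wc)
      ok <- is.finite(Ec) & wc > 0; Ec <- Ec[ok]; wc <- wc[ok]
      nE <- length(Ec)
      mu_c <- t(vapply(mats, function(m)
        if (is.null(m)) numeric(nE) else
          mass_attenuation(m, Ec, "incoherent") * m$density, numeric(nE)))
      mu_t <- t(vapply(mats, function(m)
        if (is.null(m)) numeric(nE) else linear_attenuation(m, Ec),
        numeric(nE)))
      od <- apply(mu_t * dl / 10, 2, cumsum) - mu_t * dl / 20
      Tm <- exp(-od)                             # nb x nE
      n_sc <- n_inc * wc[col(Tm)] * Tm * mu_c * dl / 10  # expected scatters
      # per-pinhole angles and solid angles from bin centers
      acc <- .pinhole_acceptance(geometry, pts0) # A cos/(4 pi d2): nb x 96
      ph <- geometry$pinholes
      dx <- outer(pts0[, 1], ph$cx, function(a, b) b - a)
      dy <- outer(pts0[, 2], ph$cy, function(a, b) b - a)
      dz <- outer(pts0[, 3], ph$cz, function(a, b) b - a)
      dd <- sqrt(dx^2 + dy^2 + dz^2)
      costh <- dy / dd                           # beam direction is +y
      lam_tot <- 0
      # lambda(bin, pin, E) = n_sc(bin,E) * KN(E, theta)/sigma(E) * 4*pi*acc
      sig <- .kn_total(Ec)
      counts_all <- NULL
      for (e in seq_len(nE)) {
        kn <- .kn_diff(Ec[e], costh) / sig[e]    # per sr
        lam <- n_sc[, e] * kn * acc * 4 * pi
        cnt <- stats::rpois(length(lam), as.numeric(lam))
        idx <- which(cnt > 0)
        if (!length(idx)) next
        counts_all <- rbind(counts_all,
                            cbind(bin = (idx - 1) %% nb + 1,
                                  pin = (idx - 1) %/% nb + 1,
                                  eidx = e, n = cnt[idx]))
      }
      if (!is.null(counts_all)) {
        bin <- rep(counts_all[, "bin"], counts_all[, "n"])
        pin <- rep(counts_all[, "pin"], counts_all[, "n"])
        eix <- rep(counts_all[, "eidx"], counts_all[, "n"])
        n <- length(bin)
        rr <- beam_r * sqrt(stats::runif(n)); aa <- stats::runif(n, 0, 2 * pi)
        pts <- cbind(x0 + rr * cos(aa),
                     pts0[bin, 2] + (stats::runif(n) - 0.5) * dl[bin],
                     rr * sin(aa))
        # scattered energy from the exact angle to the pinhole center
        ct <- (geometry$pinholes$cy[pin] - pts[, 2]) /
          sqrt((geometry$pinholes$cx[pin] - pts[, 1])^2 +
               (geometry$pinholes$cy[pin] - pts[, 2])^2 +
               (geometry$pinholes$cz[pin] - pts[, 3])^2)
        Esc <- Ec[eix] / (1 + Ec[eix] / 511 * (1 - ct))
        fr <- .transport_to_detector(phantom, geometry, pts, pin, Esc,
                                     rep("Compton", n))
        frags <- c(frags, list(fr))
      }
    }
  }

  ev <- do.call(rbind, frags[!vapply(frags, is.null, logical(1))])
  if (is.null(ev))
    ev <- data.frame(module = integer(), row = integer(), col = integer(),
                     energy_kev = numeric(), truth = character())
  # frames: uniform over the acquisition (Poisson process conditioned on N)
  n_frames <- max(1, ceiling(dwell * response$frame_rate))
  ev$frame <- sample.int(n_frames, nrow(ev), replace = TRUE) - 1L
  ev <- ev[, c("frame", "module", "row", "col", "energy_kev", "truth")]
  ev <- simulate_charge_sharing(ev, response$charge_sharing_prob,
                                geometry$pixels)
  if (nrow(ev)) ev$energy_kev <- apply_response(ev$energy_kev, response)
  ev <- ev[ev$energy_kev > 0, , drop = FALSE]
  ev <- ev[order(ev$frame), , drop = FALSE]
  rownames(ev) <- NULL
  structure(list(events = ev,
                 meta = list(scan_x = x0, dwell = dwell, flux = flux,
                             seed = seed, n_frames = n_frames,
                             geometry = geometry_hash(geometry),
                             compton = compton,
                             emitted = as.list(emitted))),
            class = "listmode")
}

#' @export
print.listmode <- function(x, ...) {
  cat("<listmode>", nrow(x$events), "events at x =", x$meta$scan_x,
      "mm (dwell", x$meta$dwell, "s, seed", x$meta$seed, ")\n")
  if (nrow(x$events)) print(table(x$events$truth))
  invisible(x)
}

#' Simulate a full line-by-line scan
#'
#' Runs [simulate_position] at every position of the scan plan; each position
#' gets its own RNG stream derived from `seed` (seed + position index).
#'
#' @inheritParams simulate_position
#' @param plan a `scan_plan`.
#' @param seed base seed.
#' @param progress print one dot per position.
#' @return list of `listmode` objects, one per scan position.
#' @export
simulate_scan <- function(phantom, plan, geometry, spectrum, flux,
                          response = detector_response(), seed = 1,
                          compton = TRUE, progress = FALSE) {
  out <- vector("list", plan$n_positions)
  for (j in seq_len(plan$n_positions)) {
    out[[j]] <- simulate_position(phantom, plan$positions[j], geometry,
                                  spectrum, plan$dwell, flux, response,
                                  seed = seed + j - 1, compton = compton)
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  out
}

#' Write / read list-mode events as CSV
#'
#' Columns: frame, module, row, col, energy_kev, truth; acquisition metadata
#' goes to a JSON sidecar when `jsonlite` is available.
#'
#' @param lm a `listmode` object.
#' @param file output CSV path.
#' @export
write_listmode_csv <- function(lm, file) {
  utils::write.csv(lm$events, file, row.names = FALSE, quote = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(lm$meta, paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_listmode_csv
#' @export
read_listmode_csv <- function(file) {
  ev <- utils::read.csv(file, stringsAsFactors = FALSE)
  meta <- list()
  sidecar <- paste0(file, ".json")
  if (file.exists(sidecar) && requireNamespace("jsonlite", quietly = TRUE))
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  structure(list(events = ev, meta = meta), class = "listmode")
}
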