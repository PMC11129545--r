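# Dose accounting: exact arithmetic on dose rates, and a simplified
# Monte-Carlo kerma estimator for the pencil-beam irradiation of the phantom,
# with optional low-energy spectrum filtering.

#' Dose per scan position
#' @param rate dose rate, cGy/min (>= 0).
#' @param dwell acquisition time per position, min (>= 0).
#' @return dose in cGy.
#' @export
dose_per_position <- function(rate, dwell) {
  if (rate < 0 || dwell < 0) stop("rate and dwell must be nonnegative",
                                  call. = FALSE)
  rate * dwell
}

#' Total scan dose
#' @param per_position dose per position, cGy.
#' @param n_positions number of scan positions (>= 0).
#' @return total dose in cGy (unrounded; see [dose_report]).
#' @export
total_dose <- function(per_position, n_positions) {
  if (n_positions < 0) stop("n_positions must be nonnegative", call. = FALSE)
  per_position * n_positions
}

#' Dose report
#'
#' Per-position and total dose from a dose rate, dwell and position count;
#' the total is also reported rounded to integer cGy.
#'
#' @param rate cGy/min.
#' @param dwell min per position.
#' @param n_positions scan positions.
#' @param filter_below spectrum filter threshold used for the rate, keV (or
#'   NA).
#' @export
dose_report <- function(rate, dwell, n_positions, filter_below = NA) {
  pp <- dose_per_position(rate, dwell)
  tot <- total_dose(pp, n_positions)
  structure(list(rate_cgy_min = rate, dwell_min = dwell,
                 n_positions = n_positions, per_position_cgy = pp,
                 total_cgy = tot, total_cgy_rounded = round(tot),
                 filter_below_kev = filter_below),
            class = "dose_report")
}

#' @export
print.dose_report <- function(x, ...) {
  cat(sprintf("<dose_report> %.3g cGy/min x %g min = %.3g cGy/position; %d positions -> %.4g cGy (~%d cGy)\n",
              x$rate_cgy_min, x$dwell_min, x$per_position_cgy, x$n_positions,
              x$total_cgy, x$total_cgy_rounded))
  invisible(x)
}

#' Monte-Carlo dose rate to the phantom (kerma approximation)
#'
#' Photons are sampled from the (optionally low-energy-truncated) spectrum
#' and transported along the 1-mm pencil beam through the phantom with
#' photoelectric, Compton and Rayleigh interactions.  Photoelectrons and
#' Compton electrons deposit locally (kerma approximation); Compton-scattered
#' photons are not followed further (single-scatter transport) and Rayleigh
#' scattering continues the photon forward.  The summed deposited energy over
#' the phantom mass, at the given photon flux, gives the dose rate.
#'
#' Filtering semantics: `filter_below` removes spectrum bins strictly below
#' the threshold *and the associated photons*, i.e. the reported rate is for
#' the same tube output with an ideal high-pass filter; the photon rate drops
#' by the filtered fluence fraction.
#'
#' @param spectrum a `beam_spectrum`.
#' @param phantom an `xfet_phantom`.
#' @param flux unfiltered beam photons per second.
#' @param filter_below cutoff in keV, or `NULL` for the unfiltered beam.
#' @param n_histories photon histories (>= 1e4).
#' @param seed RNG seed.
#' @param x0 lateral beam position, mm.
#' @return list with `dose_rate_cgy_min`, its MC standard error, and the
#'   absorbed fraction of the beam energy.
#' @export
mc_dose_rate <- function(spectrum, phantom, flux, filter_below = NULL,
                         n_histories = 1e5, seed = 1, x0 = 0) {
  stopifnot(n_histories >= 1e4, flux > 0)
  set.seed(seed)
  w <- spectrum$fluence
  E <- spectrum$energy_kev
  pass <- if (is.null(filter_below)) rep(TRUE, length(E)) else E >= filter_below
  frac_pass <- sum(w[pass])
  if (frac_pass <= 0) stop("filter removes the entire spectrum", call. = FALSE)
  # phantom mass (body with tubes: PTFE walls and fills replace acrylic)
  b <- phantom$body
  vol_body <- pi * b$radius^2 * (b$z_max - b$z_min) / 1000      # cm^3
  tb <- phantom$tubes
  h <- (tb$z_max - tb$z_min)
  vol_outer <- pi * tb$r_outer^2 * h / 1000
  vol_inner <- pi * tb$r_inner^2 * h / 1000
  mass <- (vol_body - sum(vol_outer)) * b$material$density +
    sum((vol_outer - vol_inner) * phantom$wall_material$density) +
    sum(vol_inner * vapply(phantom$fills, function(f) f$density, numeric(1)))
  if (mass <= 0) stop("phantom has zero mass", call. = FALSE)

  n <- as.integer(n_histories)
  Es <- E[pass][sample.int(sum(pass), n, replace = TRUE, prob = w[pass])]
  # beam entry/exit chords and material structure along the central ray
  O <- .beam_origin(x0)
  seg <- ray_segments(phantom, O, c(0, 1, 0))
  dep <- numeric(n)
  if (nrow(seg)) {
    mats_by_name <- c(stats::setNames(list(b$material), b$material$name),
                      stats::setNames(list(phantom$wall_material),
                                      phantom$wall_material$name),
                      stats::setNames(phantom$fills,
                                      vapply(phantom$fills, function(f) f$name,
                                             character(1))))
    eu <- sort(unique(Es))
    mu_tab <- lapply(mats_by_name, function(m) list(
      tot = linear_attenuation(m, eu),
      pe = mass_attenuation(m, eu, "photoelectric") * m$density,
      inc = mass_attenuation(m, eu, "incoherent") * m$density))
    ei <- match(Es, eu)
    alive <- rep(TRUE, n)
    pos <- rep(seg$entry[1], n)                   # mm along the ray
    for (pass_i in 1:4) {                         # few Rayleigh continuations
      if (!any(alive)) break
      # sample free path through the piecewise-constant material structure
      u <- stats::runif(n)
      tau_target <- -log(u)
      tau_acc <- numeric(n)
      newpos <- rep(Inf, n)
      for (si in seq_len(nrow(seg))) {
        m <- mu_tab[[seg$material[si]]]
        mu <- m$tot[ei]
        lo <- pmax(pos, seg$entry[si]); hi <- seg$exit[si]
        len <- pmax(hi - lo, 0) / 10              # cm
        active <- alive & !is.finite(newpos) & len > 0
        dt <- mu * len
        inside <- active & (tau_acc + dt >= tau_target)
        newpos[inside] <- lo[inside] +
          (tau_target[inside] - tau_acc[inside]) / mu[inside] * 10
        tau_acc[active] <- tau_acc[active] + dt[active]
      }
      escaped <- alive & !is.finite(newpos)
      alive[escaped] <- FALSE
      act <- which(alive)
      if (!length(act)) break
      pos[act] <- newpos[act]
      # interaction type at the site
      si <- findInterval(pos[act], seg$entry)
      si <- pmin(pmax(si, 1), nrow(seg))
      mu_tot <- mu_pe <- mu_inc <- numeric(length(act))
      for (s2 in unique(si)) {
        m <- mu_tab[[seg$material[s2]]]
        sel <- si == s2
        mu_tot[sel] <- m$tot[ei[act][sel]]
        mu_pe[sel] <- m$pe[ei[act][sel]]
        mu_inc[sel] <- m$inc[ei[act][sel]]
      }
      r <- stats::runif(length(act)) * mu_tot
      pe <- r < mu_pe
      comp <- !pe & r < (mu_pe + mu_inc)
      # photoelectric: full local deposition, history ends
      dep[act[pe]] <- dep[act[pe]] + Es[act[pe]]
      alive[act[pe]] <- FALSE
      # Compton: deposit electron energy, scattered photon not followed
      if (any(comp)) {
        ec <- Es[act[comp]]
        # Klein-Nishina angle by rejection sampling
        ct <- numeric(length(ec)); todo <- rep(TRUE, length(ec))
        fmax <- .kn_diff(ec, 1)
        while (any(todo)) {
          idx <- which(todo)
          prop <- stats::runif(length(idx), -1, 1)
          accept <- stats::runif(length(idx)) * fmax[idx] <
            .kn_diff(ec[idx], prop)
          ct[idx[accept]] <- prop[accept]
          todo[idx[accept]] <- FALSE
        }
        esc <- ec / (1 + ec / 511 * (1 - ct))
        dep[act[comp]] <- dep[act[comp]] + (ec - esc)
        alive[act[comp]] <- FALSE
      }
      # Rayleigh: continue forward unchanged (remaining alive photons)
    }
  }
  mean_dep <- mean(dep)                           # keV per beam photon
  se_dep <- stats::sd(dep) / sqrt(n)
  # photons/s after filtering x keV->J, over mass (g -> kg), Gy/s -> cGy/min
  conv <- flux * frac_pass * 1.602176634e-16 / (mass / 1000) * 100 * 60
  list(dose_rate_cgy_min = mean_dep * conv, se = se_dep * conv,
       absorbed_energy_fraction = mean_dep / mean(Es),
       mass_g = mass, filtered_fluence_fraction = frac_pass)
}
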