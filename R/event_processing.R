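# Detector-side processing: per-pixel two-point energy calibration and
# charge-sharing discrimination (CSD), producing clean calibrated spectra.

#' Fit per-pixel two-point energy calibrations
#'
#' Each live pixel's spectrum must show the two calibration photopeaks
#' (59.54 keV Am-241 and 122 keV Co-57 by default).  Peaks are located
#' deterministically as the count-weighted centroid of the highest bin +/- 3
#' bins within each half of the ADC axis (split at the midpoint of the two
#' global maxima); the linear map through the two centroids and the source
#' energies gives the pixel's gain and offset.  Pixels missing a peak (below
#' `min_counts`) are flagged dead and excluded downstream.
#'
#' @param spectra list of per-pixel spectra; each element is a list with
#'   `module`, `row`, `col`, `adc` (bin centers) and `counts`.
#' @param energies the two source energies, keV (ascending).
#' @param min_counts minimum peak height for a peak to count as present.
#' @return a `pixel_calibration`: data frame with module, row, col, gain
#'   (keV/ADC), offset (keV) and a `dead` flag.
#' @export
fit_two_point_calibration <- function(spectra, energies = c(59.54, 122),
                                      min_counts = 10) {
  stopifnot(length(energies) == 2, diff(energies) > 0)
  centroid <- function(adc, counts, win = 3) {
    i <- which.max(counts)
    j <- max(1, i - win):min(length(counts), i + win)
    if (counts[i] < min_counts) return(NA_real_)
    sum(adc[j] * counts[j]) / sum(counts[j])
  }
  rows <- lapply(spectra, function(sp) {
    o <- order(sp$adc)
    adc <- sp$adc[o]; cnt <- sp$counts[o]
    i1 <- which.max(cnt)
    # mask the neighborhood of the first peak to find the second
    cnt2 <- cnt
    cnt2[max(1, i1 - 8):min(length(cnt2), i1 + 8)] <- 0
    i2 <- which.max(cnt2)
    if (cnt[i1] < min_counts || cnt2[i2] < min_counts) {
      return(data.frame(module = sp$module, row = sp$row, col = sp$col,
                        gain = NA_real_, offset = NA_real_, dead = TRUE))
    }
    lo <- min(i1, i2); hi <- max(i1, i2)
    c1 <- centroid(adc, replace(cnt, seq_along(cnt) > (lo + hi) %/% 2, 0))
    c2 <- centroid(adc, replace(cnt, seq_along(cnt) <= (lo + hi) %/% 2, 0))
    if (is.na(c1) || is.na(c2) || c2 <= c1) {
      return(data.frame(module = sp$module, row = sp$row, col = sp$col,
                        gain = NA_real_, offset = NA_real_, dead = TRUE))
    }
    gain <- diff(energies) / (c2 - c1)
    data.frame(module = sp$module, row = sp$row, col = sp$col,
               gain = gain, offset = energies[1] - gain * c1, dead = FALSE)
  })
  structure(do.call(rbind, rows), class = c("pixel_calibration", "data.frame"))
}

#' Convert raw ADC events to energies
#'
#' Applies `E = gain * adc + offset` per pixel; events in dead pixels are
#' dropped.  Events in pixels without a calibration entry raise an error.
#'
#' @param events data frame with `module`, `row`, `col` and `adc`.
#' @param calibration a `pixel_calibration`.
#' @return the events with an `energy_kev` column (ADC column removed).
#' @export
apply_calibration <- function(events, calibration) {
  key <- function(m, r, c) (m * 80 + r) * 80 + c
  i <- match(key(events$module, events$row, events$col),
             key(calibration$module, calibration$row, calibration$col))
  if (anyNA(i))
    stop("events reference pixels with no calibration entry", call. = FALSE)
  dead <- calibration$dead[i]
  ev <- events[!dead, , drop = FALSE]
  i <- i[!dead]
  ev$energy_kev <- calibration$gain[i] * ev$adc + calibration$offset[i]
  ev$adc <- NULL
  ev
}

#' Charge-sharing discrimination filter
#'
#' Within each (frame, module), an event is kept if and only if no other
#' event of that frame and module lies within its 3 x 3 pixel neighborhood
#' (Chebyshev distance <= 1).  All members of a sharing cluster are rejected;
#' kept events are returned unmodified, in the original order.
#'
#' @param events list-mode data frame (`frame`, `module`, `row`, `col`, ...)
#'   or a `listmode` object.
#' @return same type as the input, with only the kept events.
#' @export
csd_filter <- function(events) {
  lm <- NULL
  if (inherits(events, "listmode")) { lm <- events; events <- events$events }
  n <- nrow(events)
  if (n == 0) return(if (is.null(lm)) events else lm)
  # exact integer key per pixel cell; frames*modules*6400 stays < 2^53
  base <- 80L
  cell <- (events$frame * 1000 + events$module) * (base * base) +
    events$row * base + events$col
  u <- sort(unique(cell))
  occ <- tabulate(match(cell, u), nbins = length(u))
  neigh <- numeric(n)
  for (dr in -1:1) for (dc in -1:1) {
    r <- events$row + dr; c <- events$col + dc
    ok <- r >= 0 & r < base & c >= 0 & c < base
    k <- (events$frame * 1000 + events$module) * (base * base) + r * base + c
    m <- match(k, u)
    add <- ifelse(ok & !is.na(m), occ[ifelse(is.na(m), 1, m)], 0)
    neigh <- neigh + add
  }
  keep <- neigh == 1                      # only the event itself in its 3x3
  out <- events[keep, , drop = FALSE]
  if (is.null(lm)) return(out)
  lm$events <- out
  lm
}

#' Accumulate an energy spectrum from events
#'
#' Histogram of event energies on a regular grid; total counts equal the
#' number of in-range events.
#'
#' @param events list-mode data frame or `listmode`.
#' @param bin_width bin width, keV (> 0).
#' @param e_min,e_max spectrum range, keV.
#' @return data frame with bin centers and counts.
#' @export
accumulate_spectrum <- function(events, bin_width = 0.25, e_min = 0,
                                e_max = 150) {
  if (inherits(events, "listmode")) events <- events$events
  stopifnot(bin_width > 0)
  edges <- seq(e_min, e_max, by = bin_width)
  if (edges[length(edges)] < e_max) edges <- c(edges, e_max)
  e <- events$energy_kev
  e <- e[e >= e_min & e <= e_max]
  idx <- pmin(findInterval(e, edges, rightmost.closed = TRUE),
              length(edges) - 1)
  data.frame(energy_kev = (edges[-1] + edges[-length(edges)]) / 2,
             counts = tabulate(idx, nbins = length(edges) - 1))
}
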