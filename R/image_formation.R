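# Image formation: split calibrated, CSD-filtered events into the 96 pinhole
# views, merge them (with the mounting inversions and opposite-panel flips
# handled by exact ray back-projection through each pinhole) into a
# back-projected profile along the beam, collapse over columns, extract net
# XRF per row by windowed linear-background subtraction, and assemble the 2D
# elemental image line by line.

#' Split events into the 96 pinhole views
#'
#' Events are assigned to the pinhole whose subdetector region contains their
#' panel-frame pixel; regions tile each panel, so an event can belong to at
#' most one view.  Events whose energy or pixel fall outside every region
#' (not possible for the reference geometry, whose regions tile the panels)
#' are dropped and counted.
#'
#' @param events list-mode data frame or `listmode` (calibrated, CSD
#'   filtered).
#' @param geometry an `xfet_geometry`.
#' @return a `view_stack`: the events with a `pinhole` column, plus the drop
#'   count.
#' @export
split_views <- function(events, geometry) {
  meta <- NULL
  if (inherits(events, "listmode")) { meta <- events$meta; events <- events$events }
  if (nrow(events) == 0) {
    return(structure(list(events = cbind(events, pinhole = integer(0)),
                          dropped = 0L, meta = meta), class = "view_stack"))
  }
  pp <- .module_pixel_to_panel(geometry, events$module, events$row, events$col)
  ph <- geometry$pinholes
  n_side <- geometry$modules_side * 2
  iu <- pmin(pmax(floor((pp$u + geometry$half) / geometry$region), 0), n_side - 1)
  iv <- pmin(pmax(floor((pp$v + geometry$half) / geometry$region), 0), n_side - 1)
  pin <- pp$panel * n_side^2 + iv * n_side + iu
  ok <- !is.na(pin)
  ev <- events[ok, , drop = FALSE]
  ev$pinhole <- pin[ok]
  structure(list(events = ev, dropped = sum(!ok), meta = meta),
            class = "view_stack")
}

#' @export
print.view_stack <- function(x, ...) {
  cat("<view_stack>", nrow(x$events), "events in",
      length(unique(x$events$pinhole)), "views (", x$dropped, "dropped )\n")
  invisible(x)
}

#' Merge the pinhole views into a back-projected profile
#'
#' Each event's ray (hit pixel through its pinhole center) is traced back to
#' the vertical plane containing the pencil beam; the intersection's beam
#' coordinate (y) indexes the profile row and its axial coordinate (z) the
#' profile column.  This exact inversion applies the module mounting
#' inversions and the opposite-panel view flips automatically (see
#' [view_orientation]) and rescales detector pixels to object millimeters
#' through the 1:2 minification.  Rows bin the beam axis at `row_mm`; counts
#' are conserved exactly (out-of-range rows/columns clamp to the edge bins).
#'
#' @param stack a `view_stack`.
#' @param geometry an `xfet_geometry`.
#' @param scan_x lateral beam position of this acquisition, mm (defaults to
#'   the stack metadata).
#' @param row_mm object-space row size along the beam, mm.
#' @param n_rows number of profile rows (default 20: the 20 mm FOV).
#' @param e_bin,e_min,e_max energy binning of the per-row spectra, keV.
#' @return a `bp_profile`: rows x columns x energy array of counts with bin
#'   annotations.
#' @export
merge_views <- function(stack, geometry, scan_x = NULL, row_mm = 1,
                        n_rows = 20, e_bin = 0.25, e_min = 0, e_max = 150) {
  stopifnot(inherits(stack, "view_stack"))
  if (is.null(scan_x)) scan_x <- stack$meta$scan_x
  if (is.null(scan_x)) stop("scan_x not given and absent from metadata",
                            call. = FALSE)
  ev <- stack$events
  n_cols <- 2 * n_rows                           # axial columns at half pitch
  e_edges <- seq(e_min, e_max, by = e_bin)
  counts <- array(0L, c(n_rows, n_cols, length(e_edges) - 1))
  if (nrow(ev)) {
    bp <- backproject_pixel(geometry, ev$pinhole, ev$module, ev$row, ev$col,
                            plane_x = scan_x)
    ri <- pmin(pmax(floor((bp$y + n_rows * row_mm / 2) / row_mm), 0),
               n_rows - 1) + 1
    ci <- pmin(pmax(floor((bp$z + n_cols * row_mm / 4) / (row_mm / 2)), 0),
               n_cols - 1) + 1
    ei <- pmin(pmax(findInterval(ev$energy_kev, e_edges,
                                 rightmost.closed = TRUE), 1),
               length(e_edges) - 1)
    # accumulate with tabulate on a flattened index (exact integer counts)
    flat <- (ei - 1) * (n_rows * n_cols) + (ci - 1) * n_rows + ri
    tb <- tabulate(flat, nbins = length(counts))
    counts <- array(tb, dim(counts))
  }
  structure(list(counts = counts,
                 row_y = (seq_len(n_rows) - (n_rows + 1) / 2) * row_mm,
                 col_z = (seq_len(n_cols) - (n_cols + 1) / 2) * row_mm / 2,
                 energy_kev = (e_edges[-1] + e_edges[-length(e_edges)]) / 2,
                 scan_x = scan_x),
            class = "bp_profile")
}

#' Collapse a back-projected profile over its columns
#'
#' Sums the axial (column) dimension, preserving rows and energy bins and
#' the total count.
#'
#' @param profile a `bp_profile`.
#' @return matrix (rows x energy bins) with the row/energy annotations as
#'   attributes.
#' @export
collapse_columns <- function(profile) {
  stopifnot(inherits(profile, "bp_profile"))
  m <- apply(profile$counts, c(1, 3), sum)
  attr(m, "row_y") <- profile$row_y
  attr(m, "energy_kev") <- profile$energy_kev
  attr(m, "scan_x") <- profile$scan_x
  m
}

#' Net XRF counts in an energy window over a linear background
#'
#' A window of `window` keV is centered on the emission line; a straight line
#' is least-squares fitted to the flanking sidebands (`sideband` keV on each
#' side) and integrated across the window; the net counts are the window sum
#' minus the integrated background.  The uncertainty combines the Poisson
#' variance of the window counts with the propagated uncertainty of the
#' background fit (Poisson weights on the sideband bins).
#'
#' @param energy_kev spectrum bin centers, keV.
#' @param counts spectrum counts per bin.
#' @param line center of the window (e.g. 42.75 for Gd Kalpha), keV.
#' @param window full window width, keV (default 3).
#' @param sideband sideband width on each side, keV (default 2).
#' @return list with `net`, `sigma`, `window_counts`, `background`.
#' @export
net_xrf <- function(energy_kev, counts, line, window = 3, sideband = 2) {
  inw <- energy_kev >= line - window / 2 & energy_kev <= line + window / 2
  sb <- (energy_kev >= line - window / 2 - sideband &
           energy_kev < line - window / 2) |
        (energy_kev > line + window / 2 &
           energy_kev <= line + window / 2 + sideband)
  if (!any(sb)) stop("empty sidebands", call. = FALSE)
  x <- energy_kev[sb]; y <- counts[sb]
  X <- cbind(1, x)
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  # Poisson propagation through the unweighted LS estimator
  V <- pmax(y, 1)
  cov_beta <- solve(XtX, t(X) %*% (V * X) %*% solve(XtX))
  a <- c(sum(inw), sum(energy_kev[inw]))         # integrates the fit over bins
  bkg <- sum(a * beta)
  var_bkg <- drop(t(a) %*% cov_beta %*% a)
  w <- sum(counts[inw])
  list(net = w - bkg, sigma = sqrt(w + var_bkg),
       window_counts = w, background = bkg)
}

#' Assemble the 2D elemental image from per-position profiles
#'
#' Column j of the image is the net-XRF row vector of scan position j; no
#' attenuation correction is applied.  The background-sigma companion grid is
#' returned alongside.
#'
#' @param profiles list of `bp_profile` objects (or per-row spectra from
#'   [collapse_columns]), one per scan position, in scan order.
#' @param plan the `scan_plan` (positions must match the profiles).
#' @param element element symbol whose Kalpha line defines the window.
#' @param window,sideband see [net_xrf].
#' @return an `xfet_image`: list with `net` and `sigma` matrices (rows x
#'   positions), the element, and the voxel annotations.
#' @export
assemble_image <- function(profiles, plan, element, window = 3, sideband = 2) {
  if (length(profiles) != plan$n_positions)
    stop("expected ", plan$n_positions, " profiles, got ", length(profiles),
         "; missing positions: ",
         paste(setdiff(seq_len(plan$n_positions), seq_along(profiles)),
               collapse = ", "), call. = FALSE)
  line <- line_energy(element, "Ka")
  mats <- lapply(profiles, function(p)
    if (inherits(p, "bp_profile")) collapse_columns(p) else p)
  n_rows <- nrow(mats[[1]])
  net <- sig <- matrix(0, n_rows, plan$n_positions)
  for (j in seq_along(mats)) {
    e <- attr(mats[[j]], "energy_kev")
    for (i in seq_len(n_rows)) {
      r <- net_xrf(e, mats[[j]][i, ], line, window, sideband)
      net[i, j] <- r$net
      sig[i, j] <- r$sigma
    }
  }
  structure(list(net = net, sigma = sig, element = element,
                 row_y = attr(mats[[1]], "row_y"),
                 col_x = plan$positions, window = window,
                 sideband = sideband),
            class = "xfet_image")
}

#' @export
print.xfet_image <- function(x, ...) {
  cat("<xfet_image>", x$element, ":", nrow(x$net), "x", ncol(x$net),
      "voxels,", signif(diff(x$row_y[1:2]), 3), "x",
      signif(diff(x$col_x[1:2]), 3), "mm; total net",
      round(sum(x$net)), "\n")
  invisible(x)
}

#' Run the full processing chain for one simulated scan
#'
#' CSD-filters each position's list mode, splits and merges the views, and
#' assembles the elemental image.
#'
#' @param scan list of `listmode` objects from [simulate_scan].
#' @param geometry an `xfet_geometry`.
#' @param plan the `scan_plan` used.
#' @param element element symbol.
#' @param ... passed to [assemble_image].
#' @export
xfet_image_from_scan <- function(scan, geometry, plan, element, ...) {
  profiles <- lapply(scan, function(lm) {
    merge_views(split_views(csd_filter(lm), geometry), geometry)
  })
  assemble_image(profiles, plan, element, ...)
}

#' Write an image as CSV (and 32-bit TIFF when the tiff package is present)
#'
#' @param image an `xfet_image`.
#' @param file base output path; `.csv` (net), `_sigma.csv`, and `.tif` are
#'   derived from it.
#' @export
write_image <- function(image, file) {
  base <- sub("\\.(csv|tif|tiff)$", "", file)
  utils::write.csv(image$net, paste0(base, ".csv"), row.names = FALSE)
  utils::write.csv(image$sigma, paste0(base, "_sigma.csv"), row.names = FALSE)
  if (requireNamespace("tiff", quietly = TRUE)) {
    m <- image$net
    tiff::writeTIFF((m - min(m)) / max(1e-12, diff(range(m))),
                    paste0(base, ".tif"), bits.per.sample = 32L)
  }
  invisible(file)
}
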