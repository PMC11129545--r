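# Image-quality and concentration metrics: CNR (tube vs phantom-center
# background), per-voxel SNR against the Compton-background sigma, Rose
# detectability, multi-element concentration ratios and linearity.

#' Region of interest
#'
#' A square ROI (5 x 5 voxels by default) centered on an image voxel; an
#' error is raised if it does not fit inside the image.
#'
#' @param row,col center voxel (1-based).
#' @param size side length in voxels (odd).
#' @export
roi <- function(row, col, size = 5) {
  stopifnot(size %% 2 == 1)
  structure(list(row = row, col = col, size = size), class = "xfet_roi")
}

.roi_index <- function(image, r) {
  h <- (r$size - 1) / 2
  rows <- (r$row - h):(r$row + h)
  cols <- (r$col - h):(r$col + h)
  if (min(rows) < 1 || min(cols) < 1 || max(rows) > nrow(image$net) ||
      max(cols) > ncol(image$net))
    stop("ROI extends outside the image", call. = FALSE)
  list(rows = rows, cols = cols)
}

#' ROI nearest to an object-space point
#'
#' Maps an (x, y) object position (mm) to the nearest image voxel and builds
#' a ROI there; used to place tube and background ROIs from the phantom
#' description.
#'
#' @param image an `xfet_image`.
#' @param x,y object-space coordinates, mm (x = scan axis, y = beam axis).
#' @param size ROI side, voxels.
#' @export
roi_at <- function(image, x, y, size = 5) {
  roi(which.min(abs(image$row_y - y)), which.min(abs(image$col_x - x)), size)
}

#' ROI mean and sample standard deviation
#'
#' @param image an `xfet_image`.
#' @param r an ROI from [roi] or [roi_at].
#' @return list with `mean`, `sd` and `n`.
#' @export
roi_stats <- function(image, r) {
  i <- .roi_index(image, r)
  v <- image$net[i$rows, i$cols]
  list(mean = mean(v), sd = stats::sd(as.numeric(v)), n = length(v))
}

#' Contrast-to-noise ratio of a tube ROI
#'
#' (mean net counts in the tube ROI - mean in the background ROI) divided by
#' the standard deviation of the background ROI, the background ROI sitting
#' at the center of the phantom.
#'
#' @param image an `xfet_image`.
#' @param tube_roi,background_roi ROIs.
#' @return the CNR; `NA` (flagged by a warning) when the background SD is 0.
#' @export
cnr <- function(image, tube_roi, background_roi) {
  st <- roi_stats(image, tube_roi)
  sb <- roi_stats(image, background_roi)
  if (sb$sd == 0) {
    warning("background ROI has zero variance; CNR undefined")
    return(NA_real_)
  }
  (st$mean - sb$mean) / sb$sd
}

#' Per-voxel and ROI-mean signal-to-noise ratio
#'
#' SNR is the ratio of net XRF counts to the standard deviation of the
#' Compton background in each voxel (the sigma grid produced by the windowed
#' background subtraction).  Voxels with zero sigma are flagged `NaN`.
#'
#' @param image an `xfet_image` (with its sigma companion grid).
#' @param r optional ROI; when given, the ROI mean of the per-voxel SNRs is
#'   also returned.
#' @return list with the `map` and, if `r` is given, `roi_mean`.
#' @export
snr <- function(image, r = NULL) {
  map <- image$net / image$sigma
  map[image$sigma == 0] <- NaN
  out <- list(map = map)
  if (!is.null(r)) {
    i <- .roi_index(image, r)
    out$roi_mean <- mean(map[i$rows, i$cols])
  }
  out
}

#' Rose-criterion detectability
#'
#' TRUE when CNR >= 3 and mean SNR >= 5 (inclusive thresholds).
#'
#' @param cnr_value contrast-to-noise ratio.
#' @param mean_snr ROI mean signal-to-noise ratio.
#' @param cnr_threshold,snr_threshold detectability thresholds.
#' @export
rose_detectable <- function(cnr_value, mean_snr, cnr_threshold = 3,
                            snr_threshold = 5) {
  !is.na(cnr_value) & !is.na(mean_snr) &
    cnr_value >= cnr_threshold & mean_snr >= snr_threshold
}

#' Per-tube concentration ratio between two element images
#'
#' Ratio of the mean net counts of image A to image B over each tube ROI.
#'
#' @param image_a,image_b `xfet_image` objects of the same shape.
#' @param rois list of tube ROIs.
#' @return numeric vector of ratios (NA where the denominator is zero).
#' @export
concentration_ratio <- function(image_a, image_b, rois) {
  stopifnot(all(dim(image_a$net) == dim(image_b$net)))
  vapply(rois, function(r) {
    a <- roi_stats(image_a, r)$mean
    b <- roi_stats(image_b, r)$mean
    if (b == 0) NA_real_ else a / b
  }, numeric(1))
}

#' Linearity of ROI response with concentration
#'
#' Ordinary least squares of the normalized ROI means (divided by the series
#' maximum) against concentration; returns slope, intercept and R^2.
#' Constant responses are flagged degenerate with R^2 = 0.
#'
#' @param concentrations mg/mL (>= 3 points).
#' @param roi_means mean net ROI counts, same length.
#' @export
linearity <- function(concentrations, roi_means) {
  if (length(concentrations) < 3 || length(roi_means) != length(concentrations))
    stop("need at least 3 matched points", call. = FALSE)
  y <- roi_means / max(roi_means)
  if (stats::var(y) == 0)
    return(list(slope = 0, intercept = y[1], r_squared = 0, degenerate = TRUE))
  fit <- stats::lm(y ~ concentrations)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, degenerate = FALSE)
}

#' Detection report for a phantom study image
#'
#' Computes CNR, ROI-mean SNR and the Rose flag for every metal-bearing tube,
#' with the background ROI at the phantom center.
#'
#' @param image an `xfet_image`.
#' @param phantom the `xfet_phantom` imaged.
#' @param roi_size ROI side, voxels.
#' @return data frame, one row per tube.
#' @export
detection_report <- function(image, phantom, roi_size = 5) {
  bg <- roi_at(image, 0, 0, roi_size)
  tubes <- phantom$tubes
  metal <- vapply(phantom$fills, function(f)
    !is.null(f$solutes) && sum(f$solutes) > 0, logical(1))
  rows <- lapply(which(metal), function(i) {
    tr <- roi_at(image, tubes$x[i], tubes$y[i], roi_size)
    cv <- cnr(image, tr, bg)
    sv <- snr(image, tr)$roi_mean
    data.frame(tube = tubes$label[i],
               concentration = sum(phantom$fills[[i]]$solutes),
               cnr = cv, mean_snr = sv,
               detectable = rose_detectable(cv, sv))
  })
  do.call(rbind, rows)
}
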