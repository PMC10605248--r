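#' Segment the spheroid on a reference slice
#'
#' Otsu intensity thresholding, largest connected component, hole filling.
#' Intended to place measurement ROIs automatically on bright-field spheroid
#' images. If no component exceeds `min_area` the image centre is returned
#' with `found = FALSE`.
#'
#' @param stack a [zstack()].
#' @param reference_slice slice index to segment; default the brightest slice
#'   (maximum pixel value), where a focusing spheroid is most distinct.
#' @param min_area minimum component area in pixels.
#' @return list: `mask` (logical matrix), `centroid` `c(row, col)`,
#'   `area` (pixels), `radius` (equivalent-circle radius), `found` (logical).
#' @export
segment_spheroid <- function(stack, reference_slice = NULL, min_area = 50) {
  stopifnot(inherits(stack, "zstack"))
  if (n_slices(stack) == 0L) stop("empty stack")
  if (is.null(reference_slice))
    reference_slice <- which.max(apply(stack$intensities, 1L, max))
  img <- slice_matrix(stack, reference_slice) / 65535
  side <- dim(img)
  fallback <- list(mask = matrix(FALSE, side[1L], side[2L]),
                   centroid = (side + 1) / 2,
                   area = 0, radius = min(side) / 4, found = FALSE)
  if (diff(range(img)) < .Machine$double.eps) return(fallback)
  thr <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  bw <- img > thr
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw)))
  if (max(lab) == 0L) return(fallback)
  areas <- tabulate(lab[lab > 0L])
  biggest <- which.max(areas)
  if (areas[biggest] < min_area) return(fallback)
  mask <- lab == biggest
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask))) > 0
  idx <- which(mask, arr.ind = TRUE)
  list(mask = mask, centroid = colMeans(idx), area = nrow(idx),
       radius = sqrt(nrow(idx) / pi), found = TRUE)
}

#' Construct a centre/background ROI pair
#'
#' The measurement geometry of the focal-ratio readout: a square ROI over the
#' spheroid centre (maximum intensity is taken there) and a background region
#' of the field around the spheroid (mean intensity is taken there), given as
#' a logical mask. Regions must be non-empty and disjoint.
#'
#' @param center `c(row, col)` centre of the square ROI.
#' @param half_side half-side of the square ROI in pixels.
#' @param background_mask logical matrix marking background pixels.
#' @return list of class `roi_pair`.
#' @export
roi_pair <- function(center, half_side, background_mask) {
  stopifnot(length(center) == 2L, half_side >= 0, is.logical(background_mask))
  if (!any(background_mask)) stop("background ROI is empty")
  rr <- round(center[1L]) + (-half_side:half_side)
  cc <- round(center[2L]) + (-half_side:half_side)
  rr <- rr[rr >= 1L & rr <= nrow(background_mask)]
  cc <- cc[cc >= 1L & cc <= ncol(background_mask)]
  if (length(rr) && length(cc) && any(background_mask[rr, cc]))
    stop("centre and background ROIs overlap")
  structure(list(center = center, half_side = half_side,
                 background_mask = background_mask),
            class = "roi_pair")
}

#' Automatic ROI placement from segmentation
#'
#' Centre square of half-side 10% of the spheroid radius at the segmented
#' centroid; background is the image border band (width `border_frac` of the
#' side) minus a 1.2x dilation of the spheroid (a disk of 1.2x the equivalent
#' radius around the centroid).
#'
#' @param stack a [zstack()].
#' @param reference_slice forwarded to [segment_spheroid()].
#' @param border_frac width of the border band as a fraction of the image
#'   side.
#' @return a [roi_pair()]; attribute `segmentation` holds the
#'   [segment_spheroid()] result (check its `found` flag for the fallback).
#' @export
auto_roi <- function(stack, reference_slice = NULL, border_frac = 0.1) {
  seg <- segment_spheroid(stack, reference_slice)
  side <- dim(stack$intensities)[2:3]
  half <- max(2L, round(0.1 * seg$radius))
  band <- round(border_frac * min(side))
  rows <- matrix(seq_len(side[1L]), side[1L], side[2L])
  cols <- t(matrix(seq_len(side[2L]), side[2L], side[1L]))
  in_band <- rows <= band | rows > side[1L] - band |
    cols <= band | cols > side[2L] - band
  dil <- (rows - seg$centroid[1L])^2 + (cols - seg$centroid[2L])^2 <=
    (1.2 * seg$radius)^2
  bg <- in_band & !dil
  if (!any(bg)) stop("background band is empty; spheroid fills the field")
  rp <- roi_pair(seg$centroid, half, bg)
  attr(rp, "segmentation") <- seg
  rp
}

#' Focal-ratio curve of a z-stack
#'
#' Per slice, the ratio R(z) of the maximum light intensity inside the centre
#' ROI (over the spheroid centre) to the mean intensity of the background
#' region around the spheroid. R(z) well above 1 at some z indicates that the
#' spheroid focuses light.
#'
#' @param stack a [zstack()].
#' @param rois a [roi_pair()]; default [auto_roi()] placement.
#' @return A data frame of class `focal_curve`, ordered by z: `z`, `ratio`,
#'   `max_center`, `mean_background`.
#' @export
focal_ratio_curve <- function(stack, rois = NULL) {
  stopifnot(inherits(stack, "zstack"))
  if (is.null(rois)) rois <- auto_roi(stack)
  side <- dim(stack$intensities)[2:3]
  rr <- round(rois$center[1L]) + (-rois$half_side:rois$half_side)
  cc <- round(rois$center[2L]) + (-rois$half_side:rois$half_side)
  if (min(rr) < 1L || max(rr) > side[1L] || min(cc) < 1L || max(cc) > side[2L])
    stop("centre ROI out of image bounds")
  if (!identical(dim(rois$background_mask), side))
    stop("background mask does not match image dimensions")
  mx <- mb <- numeric(n_slices(stack))
  for (i in seq_len(n_slices(stack))) {
    img <- slice_matrix(stack, i)
    mx[i] <- max(img[rr, cc])
    mb[i] <- mean(img[rois$background_mask])
    if (mb[i] <= 0)
      stop("zero background mean on slice ", i, ": ratio undefined")
  }
  ord <- order(stack$z_positions)
  structure(data.frame(z = stack$z_positions[ord], ratio = (mx / mb)[ord],
                       max_center = mx[ord], mean_background = mb[ord]),
            class = c("focal_curve", "data.frame"))
}

#' Peak summary of a focal-ratio curve
#'
#' The maximum of R(z), the z-position attaining it (ties broken by smallest
#' |z|, i.e. closest to the focus), and a boolean light-focusing call
#' (peak ratio above `1 + margin`).
#'
#' @param curve a `focal_curve` from [focal_ratio_curve()].
#' @param margin focusing-call margin above 1 (default 0.2).
#' @return list of class `focus_summary`: `peak_ratio`, `peak_z`,
#'   `focuses_light`, `margin`.
#' @export
focus_summary <- function(curve, margin = 0.2) {
  if (!nrow(curve)) stop("empty focal curve")
  peak <- max(curve$ratio)
  at <- which(curve$ratio == peak)
  at <- at[which.min(abs(curve$z[at]))]
  structure(list(peak_ratio = peak, peak_z = curve$z[at],
                 focuses_light = peak > 1 + margin, margin = margin),
            class = "focus_summary")
}

#' @export
print.focus_summary <- function(x, ...) {
  cat(sprintf("peak ratio %.3f at z = %g um (%sfocusing, margin %.2f)\n",
              x$peak_ratio, x$peak_z, if (x$focuses_light) "" else "not ",
              x$margin))
  invisible(x)
}

#' Compare focal-ratio curves across conditions
#'
#' Per-condition mean and standard deviation of the peak ratio (and of R(z)
#' per z), plus a Spearman monotone-trend statistic of peak ratio against
#' dose when doses are supplied — the dose-response readout used for
#' cataract-inducing treatments.
#'
#' @param curves named list (one element per condition) of lists of
#'   `focal_curve` objects.
#' @param dose optional numeric vector of doses, one per condition.
#' @param margin forwarded to [focus_summary()].
#' @return list of class `condition_comparison`: `summary` (condition, n,
#'   mean/sd of peak ratio, mean peak z), `curve_summary` (condition, z,
#'   mean/sd of R(z)), `peaks` (per-organoid peak table), `trend`
#'   (Spearman rho and p over all organoids, or NULL without doses).
#' @export
compare_conditions <- function(curves, dose = NULL, margin = 0.2) {
  if (is.null(names(curves)) || any(names(curves) == ""))
    stop("curves must be a named list (one element per condition)")
  if (any(lengths(curves) == 0L)) stop("every condition needs >= 1 curve")
  peaks <- do.call(rbind, lapply(names(curves), function(cond) {
    data.frame(condition = cond,
               peak_ratio = vapply(curves[[cond]], function(cv)
                 focus_summary(cv, margin)$peak_ratio, numeric(1L)),
               peak_z = vapply(curves[[cond]], function(cv)
                 focus_summary(cv, margin)$peak_z, numeric(1L)))
  }))
  summ <- do.call(rbind, lapply(split(peaks, peaks$condition)[names(curves)],
    function(d) data.frame(condition = d$condition[1L], n = nrow(d),
                           mean_peak_ratio = mean(d$peak_ratio),
                           sd_peak_ratio = sd(d$peak_ratio),
                           mean_peak_z = mean(d$peak_z))))
  rownames(summ) <- NULL
  curve_summ <- do.call(rbind, lapply(names(curves), function(cond) {
    zs <- curves[[cond]][[1L]]$z
    mat <- sapply(curves[[cond]], function(cv) cv$ratio)
    mat <- matrix(mat, nrow = length(zs))
    data.frame(condition = cond, z = zs, mean_ratio = rowMeans(mat),
               sd_ratio = apply(mat, 1L, sd))
  }))
  trend <- NULL
  if (!is.null(dose)) {
    if (length(dose) != length(curves))
      stop("dose must have one value per condition")
    dd <- dose[match(peaks$condition, names(curves))]
    ct <- suppressWarnings(cor.test(dd, peaks$peak_ratio, method = "spearman",
                                    exact = FALSE))
    trend <- list(rho = unname(ct$estimate), p_value = ct$p.value)
  }
  structure(list(summary = summ, curve_summary = curve_summ, peaks = peaks,
                 trend = trend),
            class = "condition_comparison")
}
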