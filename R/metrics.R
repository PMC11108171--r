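# Dice evaluation at WSI level and within annotated regions of interest.

#' Dice coefficient of two binary masks
#'
#' 2|A n B| / (|A| + |B|). Both masks empty gives 1.0 by convention (logged
#' nowhere else, so the convention is explicit here); exactly one empty
#' gives 0.0.
#'
#' @param a,b binary `LabelMask` objects or matrices of identical shape.
#' @return value in `[0, 1]`.
#' @export
dice <- function(a, b) {
  a <- mask_data(a) != 0
  b <- mask_data(b) != 0
  if (any(dim(a) != dim(b))) stop("dice: mask shapes differ")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1.0)
  2 * sum(a & b) / (sa + sb)
}

#' Dice within regions of interest
#'
#' Clips both masks to each ROI polygon before computing Dice and summarizes
#' across ROIs as median and inter-quartile range (Q3 - Q1, linear-
#' interpolation quantiles).
#'
#' @param pred,gt binary masks (`LabelMask` or matrix), identical shape.
#' @param rois an `AnnotationSet` (features with role `"roi"` are used) or a
#'   list of N x 2 (x, y) rings in level-0 coordinates.
#' @param downsample factor from level-0 coordinates to the mask grid.
#' @return list with `per_roi` (data.frame: name, dice), `median`, `iqr`, `n`.
#' @export
dice_in_roi <- function(pred, gt, rois, downsample = 1) {
  p <- mask_data(pred); g <- mask_data(gt)
  if (any(dim(p) != dim(g))) stop("dice_in_roi: mask shapes differ")
  if (inherits(rois, "AnnotationSet")) {
    feats <- Filter(function(f) f$role == "roi", rois$features)
    rings <- lapply(feats, function(f) f$rings)
    names <- vapply(feats, function(f) f$name, character(1))
  } else {
    rings <- lapply(rois, function(r) if (is.list(r)) r else list(r))
    names <- paste0("roi_", seq_along(rings))
  }
  if (!length(rings)) stop("dice_in_roi: no ROIs supplied")
  d <- vapply(rings, function(rs) {
    rm <- cpp_rasterize_rings(lapply(rs, function(r) r / downsample),
                              nrow(p), ncol(p)) != 0
    if (!any(rm)) stop("dice_in_roi: ROI falls outside the mask raster")
    dice(p & rm, g & rm)
  }, numeric(1))
  list(per_roi = data.frame(name = names, dice = d),
       median = median(d),
       iqr = unname(diff(quantile(d, c(0.25, 0.75), type = 7))),
       n = length(d))
}

#' Dice of epithelium restricted to the tumor area
#'
#' Both masks are intersected with the tumor-area mask before Dice; an empty
#' tumor area yields 1.0 (both restricted masks empty).
#'
#' @param pred,gt binary epithelium masks.
#' @param tumor_area binary mask of the tumor region.
#' @export
dice_epithelium_within_tumor <- function(pred, gt, tumor_area) {
  tm <- mask_data(tumor_area) != 0
  p <- mask_data(pred) != 0
  g <- mask_data(gt) != 0
  if (any(dim(p) != dim(tm)) || any(dim(g) != dim(tm)))
    stop("dice_epithelium_within_tumor: mask shapes differ")
  dice(p & tm, g & tm)
}
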