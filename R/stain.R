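# Optical-density transform, color deconvolution and thresholding: turns a
# CK8/18-DAB immunohistochemistry image into a binary epithelium label mask.
#
# Stains absorb light multiplicatively, so in optical-density space
# (OD = -log10(I / I0)) their contributions add linearly and can be unmixed
# by inverting a matrix of per-stain absorption unit vectors.

#' Construct a stain matrix for H-DAB deconvolution
#'
#' Rows are unit absorption vectors in OD-RGB space. The defaults are the
#' standard published hematoxylin / DAB vectors; the third row is the
#' normalized cross product of the first two, completing an invertible basis
#' for the residual channel.
#'
#' @param hematoxylin,dab length-3 absorption vectors (normalized internally).
#' @param I0 background (white) intensity, default 255.
#' @return a `StainMatrix` with elements `od` (3 x 3 matrix, rows H, DAB,
#'   residual), `inv` (its inverse) and `I0`.
#' @export
stain_matrix <- function(hematoxylin = c(0.650, 0.704, 0.286),
                         dab = c(0.268, 0.570, 0.776),
                         I0 = 255) {
  stopifnot(length(hematoxylin) == 3, length(dab) == 3, I0 > 0)
  h <- hematoxylin / sqrt(sum(hematoxylin^2))
  d <- dab / sqrt(sum(dab^2))
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  nr <- sqrt(sum(r^2))
  if (nr < 1e-8) stop("stain_matrix: hematoxylin and DAB vectors are collinear")
  M <- rbind(hematoxylin = h, dab = d, residual = r / nr)
  if (abs(det(M)) < 1e-8) stop("stain_matrix: singular stain matrix")
  structure(list(od = M, inv = solve(M), I0 = I0), class = "StainMatrix")
}

#' Optical-density transform
#'
#' OD = -log10(max(I, 1) / I0), per channel. Monotone decreasing in I and
#' zero at background intensity.
#'
#' @param rgb numeric array/matrix of 8-bit intensities.
#' @param I0 background intensity.
#' @return array of the same shape with OD values (>= 0 for I <= I0).
#' @export
od_transform <- function(rgb, I0 = 255) {
  stopifnot(I0 > 0)
  out <- -log10(pmax(rgb, 1) / I0)
  dim(out) <- dim(rgb)
  out
}

#' Unmix per-stain concentrations from an OD image
#'
#' Solves od = c %*% M per pixel via the matrix inverse; negative
#' concentrations are clamped to zero after solving.
#'
#' @param od H x W x 3 array (or N x 3 matrix) of optical densities.
#' @param M a `StainMatrix`.
#' @return same layout with 3 concentration channels (H, DAB, residual).
#' @export
deconvolve <- function(od, M = stain_matrix()) {
  d <- dim(od)
  flat <- if (length(d) == 3) matrix(od, ncol = 3) else od
  conc <- pmax(flat %*% M$inv, 0)
  if (length(d) == 3) dim(conc) <- d
  conc
}

#' Render an RGB image from stain concentrations (Beer-Lambert synthesis)
#'
#' Inverse of [deconvolve()] + [od_transform()]: I = I0 * 10^-(c %*% M).
#'
#' @param conc H x W x 3 array (or N x 3 matrix) of stain concentrations.
#' @param M a `StainMatrix`.
#' @param quantize round to 8-bit integers (default TRUE).
#' @return RGB image with the same layout, values in 0..I0.
#' @export
render_stains <- function(conc, M = stain_matrix(), quantize = TRUE) {
  d <- dim(conc)
  flat <- if (length(d) == 3) matrix(conc, ncol = 3) else conc
  # no upper clamp: the residual stain vector has negative OD components,
  # so synthesis must stay linear in OD space for the round trip to hold
  I <- M$I0 * 10^(-(flat %*% M$od))
  if (quantize) I <- round(I)
  if (length(d) == 3) dim(I) <- d
  I
}

#' Otsu threshold
#'
#' Exhaustively maximizes the between-class variance over `nbins` histogram
#' cuts; returns the cut value (pixels strictly above it are foreground).
#'
#' @param x numeric vector of values.
#' @param nbins number of histogram bins (default 256).
#' @return threshold value.
#' @export
otsu_threshold <- function(x, nbins = 256) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("otsu_threshold: no finite values")
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(lo)
  edges <- seq(lo, hi, length.out = nbins + 1)
  h <- as.numeric(tabulate(pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L),
                                nbins), nbins))
  centers <- (edges[-1] + edges[-(nbins + 1)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * centers)
  tot_w <- w[nbins]; tot_m <- m[nbins]
  w0 <- w[-nbins]; w1 <- tot_w - w0
  mu0 <- m[-nbins] / w0
  mu1 <- (tot_m - m[-nbins]) / w1
  bc <- w0 * w1 * (mu0 - mu1)^2
  bc[!is.finite(bc)] <- -Inf
  edges[which.max(bc) + 1]
}

#' Epithelium mask from a CK8/18-DAB IHC slide
#'
#' Deconvolves the DAB channel, thresholds it (Otsu within the tissue mask by
#' default, or a fixed value), intersects with the tissue mask and removes
#' small objects.
#'
#' @param ihc `SlideImage` of the IHC section (level 0 used).
#' @param tissue binary `LabelMask` (or matrix) aligned to level 0.
#' @param M a `StainMatrix`.
#' @param threshold `"otsu"` or a fixed numeric DAB-concentration cut.
#' @param min_object_px minimum object area in pixels at 1.0 um/px (scaled
#'   by the actual spacing), default 50.
#' @return binary `LabelMask` (`background`/`epithelium`).
#' @export
epithelium_mask_from_ihc <- function(ihc, tissue, M = stain_matrix(),
                                     threshold = "otsu", min_object_px = 50) {
  rgb <- ihc$levels[[1]]
  tis <- mask_data(tissue) != 0
  if (any(dim(tis) != dim(rgb)[1:2]))
    stop("epithelium_mask_from_ihc: tissue mask does not match the slide")
  cls <- c(background = 0L, epithelium = 1L)
  if (!any(tis)) {
    warning("epithelium_mask_from_ihc: empty tissue mask; returning empty mask")
    return(label_mask(matrix(0L, nrow(tis), ncol(tis)), ihc$spacing_um, cls))
  }
  dab <- deconvolve(od_transform(rgb, M$I0), M)[, , 2]
  t <- if (is.numeric(threshold)) threshold else otsu_threshold(dab[tis])
  bin <- (dab > t) & tis
  # drop objects below the configured area (spec'd at 1.0 um/px)
  min_px <- max(1, round(min_object_px * (1.0 / ihc$spacing_um)^2))
  if (min_px > 1 && any(bin)) {
    lab <- cpp_label_components(matrix(as.integer(bin), nrow(bin)), 8L)
    sizes <- tabulate(lab)
    keep <- which(sizes >= min_px)
    bin <- matrix(lab %in% keep, nrow(bin)) & bin
  }
  label_mask(matrix(as.integer(bin), nrow(bin)), ihc$spacing_um, cls)
}
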