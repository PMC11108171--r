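# Tissue-background segmentation with a classical detector (no learned
# model is available in the supported environment): colored (saturated)
# pixels and dark unsaturated pixels are tissue, near-white pixels are glass.

#' Tissue-background segmentation
#'
#' A pixel is tissue when its gray value falls below a near-white cut
#' (everything darker than glass) or its HSV saturation exceeds an Otsu cut
#' (catching bright but stained pixels). The Otsu statistics are computed
#' over non-near-white pixels only, which makes the mask invariant to
#' padding with pure white. The raw mask is then closed with a disk and
#' small interior holes are filled.
#'
#' @param slide a `SlideImage`.
#' @param level 0-based pyramid level to segment.
#' @param near_white gray level at/above which a pixel is glass unless
#'   saturated (default 240).
#' @param close_radius_px disk radius for morphological closing (default 2).
#' @param min_hole_px fill enclosed background holes smaller than this many
#'   pixels (default 256).
#' @return binary `LabelMask` (`background`/`tissue`) aligned to the level.
#' @export
tissue_mask <- function(slide, level = 0, near_white = 240,
                        close_radius_px = 2, min_hole_px = 256) {
  rgb <- slide$levels[[level + 1]]
  mx <- pmax(rgb[, , 1], rgb[, , 2], rgb[, , 3])
  mn <- pmin(rgb[, , 1], rgb[, , 2], rgb[, , 3])
  sat <- (mx - mn) / pmax(mx, 1)
  gray <- (rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3
  cand <- gray < near_white
  cls <- c(background = 0L, tissue = 1L)
  if (!any(cand))
    return(label_mask(matrix(0L, nrow(gray), ncol(gray)),
                      spacing_at(slide, level), cls))
  ts <- otsu_threshold(sat[cand])
  tis <- cand | (sat > ts)
  tis <- matrix(as.integer(tis), nrow(gray))
  if (close_radius_px > 0) {
    offs <- disk_offsets(close_radius_px)
    tis <- cpp_binary_morph(cpp_binary_morph(tis, offs, TRUE), offs, FALSE)
  }
  tis <- fill_small_holes(tis, min_hole_px)
  label_mask(tis, spacing_at(slide, level), cls)
}

# Fill enclosed background components (not touching the border) smaller than
# min_px pixels.
fill_small_holes <- function(bin, min_px) {
  if (min_px <= 0) return(bin)
  comp <- cpp_label_components(matrix(as.integer(bin == 0), nrow(bin)), 4L)
  if (max(comp) == 0) return(bin)
  border <- unique(c(comp[1, ], comp[nrow(comp), ], comp[, 1], comp[, ncol(comp)]))
  sizes <- tabulate(comp)
  fill <- setdiff(which(sizes < min_px), border)
  if (length(fill)) bin[comp %in% fill] <- 1L
  bin
}
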