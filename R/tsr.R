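# Stroma segmentation within the tumor bulk and whole-bulk tumor-stroma
# ratio computation.

#' Segment stroma within the tumor bulk
#'
#' Runs a multi-tissue segmentation model over the slide and keeps the
#' stroma class inside the bulk; everything outside the bulk is background.
#' Passing a `LabelMask`/matrix as `model` is the oracle plumbing path: it
#' is treated as a ready-made stroma mask and simply intersected with the
#' bulk.
#'
#' @param slide a `SlideImage` at the model's spacing.
#' @param bulk binary bulk `LabelMask` or matrix.
#' @param model a `SegModel`, list of `SegModel`s (fold ensemble), or a
#'   binary stroma truth mask.
#' @param tissue optional tissue mask passed to [predict_wsi()].
#' @param stroma_class code of the stroma class in the model output
#'   (default 1).
#' @param window,overlap sliding-window parameters for [predict_wsi()].
#' @return binary stroma `LabelMask` restricted to the bulk.
#' @export
segment_stroma <- function(slide, bulk, model, tissue = NULL,
                           stroma_class = 1L, window = 512, overlap = 128) {
  b <- mask_data(bulk) != 0
  cls <- c(background = 0L, stroma = 1L)
  sp <- if (inherits(bulk, "LabelMask")) bulk$spacing_um else slide$spacing_um
  if (!any(b))
    return(label_mask(matrix(0L, nrow(b), ncol(b)), sp, cls))
  if (inherits(model, "LabelMask") || is.matrix(model)) {
    s <- mask_data(model) != 0
  } else {
    pred <- predict_wsi(model, slide, tissue, window = window, overlap = overlap)
    s <- mask_data(pred$mask) == stroma_class
  }
  if (any(dim(s) != dim(b))) stop("segment_stroma: mask shapes differ")
  label_mask(matrix(as.integer(s & b), nrow(b)), sp, cls)
}

#' Compute the tumor-stroma ratio across the tumor bulk
#'
#' Default formula: TSR = stroma / (stroma + tumor epithelium), both areas
#' measured inside the bulk, so high values mean stroma-rich. Other tissue
#' inside the bulk (lumina, necrosis stand-ins) is excluded from the
#' denominator; the `denominator = "bulk"` variant divides by the whole
#' bulk area instead.
#'
#' @param tumor_epi binary tumor-epithelium mask.
#' @param stroma binary stroma mask.
#' @param bulk binary bulk mask.
#' @param spacing_um micrometers per pixel (taken from `bulk` if a
#'   `LabelMask`).
#' @param denominator `"stroma_epi"` (default) or `"bulk"`.
#' @param slide_id identifier recorded in the report.
#' @param alpha the alpha value used for the bulk, recorded for provenance.
#' @return a `TSRReport`: areas in um^2, `tsr` in `[0, 1]`, formula used,
#'   and md5 provenance hashes of the three masks.
#' @export
compute_tsr <- function(tumor_epi, stroma, bulk, spacing_um = NULL,
                        denominator = c("stroma_epi", "bulk"),
                        slide_id = "slide", alpha = NA_real_) {
  denominator <- match.arg(denominator)
  e <- mask_data(tumor_epi) != 0
  s <- mask_data(stroma) != 0
  b <- mask_data(bulk) != 0
  if (any(dim(e) != dim(b)) || any(dim(s) != dim(b)))
    stop("compute_tsr: misaligned masks")
  if (!any(b)) stop("compute_tsr: empty bulk")
  if (is.null(spacing_um))
    spacing_um <- if (inherits(bulk, "LabelMask")) bulk$spacing_um else 1.0
  px_e <- sum(e & b); px_s <- sum(s & b); px_b <- sum(b)
  denom <- if (denominator == "stroma_epi") px_s + px_e else px_b
  if (denom == 0)
    stop("compute_tsr: undefined TSR (no stroma or tumor epithelium in bulk)")
  a2 <- spacing_um^2
  structure(list(slide_id = slide_id,
                 area_tumor_epithelium = px_e * a2,
                 area_stroma = px_s * a2,
                 area_bulk = px_b * a2,
                 tsr = px_s / denom,
                 denominator = denominator,
                 alpha = alpha,
                 provenance = list(tumor_epi = object_md5(e),
                                   stroma = object_md5(s),
                                   bulk = object_md5(b))),
            class = "TSRReport")
}

#' @export
print.TSRReport <- function(x, ...) {
  cat(sprintf("TSRReport [%s]: TSR = %.3f (%s)\n", x$slide_id, x$tsr,
              x$denominator))
  cat(sprintf("  stroma %.0f um^2, tumor epithelium %.0f um^2, bulk %.0f um^2\n",
              x$area_stroma, x$area_tumor_epithelium, x$area_bulk))
  invisible(x)
}

#' One-row data.frame view of a TSR report (for CSV export)
#' @param report a `TSRReport`.
#' @export
tsr_report_row <- function(report) {
  data.frame(slide_id = report$slide_id, tsr = report$tsr,
             area_stroma = report$area_stroma,
             area_tumor_epithelium = report$area_tumor_epithelium,
             area_bulk = report$area_bulk, denominator = report$denominator,
             alpha = report$alpha, stringsAsFactors = FALSE)
}
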