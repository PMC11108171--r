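# Semantic segmentation: per-pixel multi-class classification with a
# multi-scale filter-bank front end (Gaussian-smoothed intensities and local
# standard deviations over a dyadic scale pyramid) feeding a multinomial
# ridge-logistic head, trained per cross-validation fold and applied to
# whole slides by sliding-window inference with overlap mean-blending and
# fold ensembling.
#
# No deep-learning backend exists in the supported environment, so this is
# the package's stand-in for an encoder-decoder network: the scale pyramid
# plays the encoder (depth = number of dyadic scales), prediction at full
# resolution the decoder. All inference-side contracts (window tiling,
# overlap averaging, ensembling, tissue masking, tie-breaks) are identical
# to what a network backend would use.

#' Segmentation model configuration
#'
#' @param n_classes number of classes (2 or 3).
#' @param depth number of dyadic feature scales (default 5: sigma 1..16 px).
#' @param width features per channel per scale: 1 = smoothed intensity only,
#'   2 = + local standard deviation (default 2). Shrinks the model for
#'   desk-scale tests.
#' @param input_size training tile side in pixels (default 512).
#' @param lambda ridge penalty of the multinomial head (default 1e-3).
#' @param samples_per_class pixels sampled per class per fold (default 2000).
#' @param seed RNG seed for pixel sampling.
#' @return a `SegConfig`.
#' @export
seg_config <- function(n_classes, depth = 5, width = 2, input_size = 512,
                       lambda = 1e-3, samples_per_class = 2000, seed = 1) {
  if (!n_classes %in% c(2L, 3L)) stop("seg_config: n_classes must be 2 or 3")
  if (depth < 1) stop("seg_config: depth must be >= 1")
  if (!width %in% c(1L, 2L)) stop("seg_config: width must be 1 or 2")
  structure(list(n_classes = as.integer(n_classes), depth = as.integer(depth),
                 width = as.integer(width), input_size = as.integer(input_size),
                 lambda = lambda, samples_per_class = as.integer(samples_per_class),
                 seed = as.integer(seed)),
            class = "SegConfig")
}

# H x W x F feature stack for one RGB tile
seg_features <- function(rgb, cfg) {
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  scales <- 2^(seq_len(cfg$depth) - 1)
  nf <- 3 + 3 * cfg$width * cfg$depth
  X <- array(0, c(h, w, nf))
  X[, , 1:3] <- rgb / 255
  i <- 4L
  for (s in scales) {
    mus <- vector("list", 3)
    for (k in 1:3) {
      mus[[k]] <- blur_mat(rgb[, , k] / 255, s)
      X[, , i] <- mus[[k]]
      i <- i + 1L
    }
    if (cfg$width >= 2) {
      for (k in 1:3) {
        ch <- rgb[, , k] / 255
        X[, , i] <- sqrt(pmax(blur_mat(ch * ch, s) - mus[[k]]^2, 0))
        i <- i + 1L
      }
    }
  }
  X
}

#' Train segmentation models, one per cross-validation fold
#'
#' Tiles must carry a `fold` id (patient-level, from [kfold_split()]); fold
#' i's model is fit on all tiles with `fold != i`. Pixels are sampled
#' class-stratified from the training tiles and the multinomial ridge head
#' is fit on standardized features. Deterministic given `cfg$seed`.
#'
#' @param tiles list of `TileSample`s with `fold` set.
#' @param cfg a `SegConfig`.
#' @param classes integer class codes, ascending; defaults to the codes
#'   present in the tile labels (must have length `cfg$n_classes`).
#' @return list of `SegModel`s (one per fold), each recording its fold id,
#'   config, coefficients and train/validation log-loss.
#' @export
train_segnet <- function(tiles, cfg, classes = NULL) {
  folds <- sort(unique(vapply(tiles, function(t) t$fold, integer(1))))
  if (any(is.na(folds))) stop("train_segnet: every tile needs a fold id")
  if (is.null(classes))
    classes <- sort(unique(unlist(lapply(tiles, function(t) unique(as.vector(t$labels))))))
  if (length(classes) != cfg$n_classes)
    stop("train_segnet: found ", length(classes), " classes, config says ",
         cfg$n_classes)
  lapply(folds, function(f) {
    train <- tiles[vapply(tiles, function(t) t$fold != f, logical(1))]
    if (!length(train)) stop("train_segnet: fold ", f, " has no training tiles")
    val <- tiles[vapply(tiles, function(t) t$fold == f, logical(1))]
    xy <- sample_pixels(train, cfg, classes, seed = child_seed(cfg$seed, f))
    mu <- colMeans(xy$x); sg <- pmax(apply(xy$x, 2, sd), 1e-8)
    xs <- sweep(sweep(xy$x, 2, mu), 2, sg, "/")
    fit <- glmnet::glmnet(xs, factor(xy$y, levels = classes),
                          family = "multinomial", alpha = 0,
                          lambda = cfg$lambda, standardize = FALSE)
    co <- stats::coef(fit, s = cfg$lambda)
    W <- vapply(co, function(m) as.numeric(m), numeric(ncol(xs) + 1))
    model <- structure(list(W = W, feat_mean = mu, feat_sd = sg,
                            classes = as.integer(classes), config = cfg,
                            fold = f, train_loss = NA_real_, val_loss = NA_real_),
                       class = "SegModel")
    model$train_loss <- pixel_log_loss(model, xy$x, xy$y)
    if (length(val)) {
      vxy <- sample_pixels(val, cfg, classes, seed = child_seed(cfg$seed, 1000L + f))
      model$val_loss <- pixel_log_loss(model, vxy$x, vxy$y)
    }
    model
  })
}

sample_pixels <- function(tiles, cfg, classes, seed) {
  with_seed(seed, {
    per_tile <- ceiling(cfg$samples_per_class / length(tiles))
    xs <- list(); ys <- list()
    for (t in tiles) {
      X <- seg_features(t$tile, cfg)
      Xf <- matrix(X, ncol = dim(X)[3])
      for (cl in classes) {
        idx <- which(t$labels == cl)
        if (!length(idx)) next
        take <- idx[sample.int(length(idx), min(per_tile, length(idx)))]
        xs[[length(xs) + 1]] <- Xf[take, , drop = FALSE]
        ys[[length(ys) + 1]] <- rep(cl, length(take))
      }
    }
    x <- do.call(rbind, xs); y <- unlist(ys)
    if (length(unique(y)) < length(classes))
      stop("train_segnet: some class has no pixels in the training tiles")
    list(x = x, y = y)
  })
}

pixel_log_loss <- function(model, x, y) {
  p <- softmax_scores(model, x)
  j <- match(y, model$classes)
  -mean(log(pmax(p[cbind(seq_along(j), j)], 1e-12)))
}

softmax_scores <- function(model, x) {
  xs <- sweep(sweep(x, 2, model$feat_mean), 2, model$feat_sd, "/")
  z <- cbind(1, xs) %*% model$W
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean ensemble probability; SegModels sharing a feature config reuse one
# feature stack per patch (the expensive part of inference)
ensemble_probs <- function(models, patch) {
  is_seg <- vapply(models, inherits, logical(1), "SegModel")
  p <- NULL
  add <- function(p, pm) if (is.null(p)) pm else p + pm
  segs <- models[is_seg]
  if (length(segs)) {
    sig <- vapply(segs, function(m)
      paste(m$config$depth, m$config$width), character(1))
    for (s in unique(sig)) {
      grp <- segs[sig == s]
      X <- seg_features(patch, grp[[1]]$config)
      Xf <- matrix(X, ncol = dim(X)[3])
      for (m in grp)
        p <- add(p, array(softmax_scores(m, Xf),
                          c(dim(patch)[1], dim(patch)[2], length(m$classes))))
    }
  }
  for (m in models[!is_seg]) p <- add(p, predict_probs(m, patch))
  p / length(models)
}

#' Per-pixel class probabilities for one RGB patch
#'
#' S3 generic so tests can substitute stub models; the `SegModel` method
#' runs the filter-bank features through the multinomial head.
#'
#' @param model a model object.
#' @param rgb H x W x 3 patch.
#' @return H x W x K probability array (classes in `model$classes` order).
#' @export
predict_probs <- function(model, rgb) UseMethod("predict_probs")

#' @export
predict_probs.SegModel <- function(model, rgb) {
  X <- seg_features(rgb, model$config)
  p <- softmax_scores(model, matrix(X, ncol = dim(X)[3]))
  array(p, c(dim(rgb)[1], dim(rgb)[2], length(model$classes)))
}

#' Sliding-window whole-slide inference with fold ensembling
#'
#' Tiles the slide with `window`-sized patches overlapping by `overlap`
#' pixels; per-pixel probabilities are averaged over all covering windows
#' and over the supplied models (fold ensemble = mean of normalized
#' scores). Pixels outside the tissue mask are forced to the background
#' class (code 0); argmax ties break toward the lower class code.
#'
#' @param models a model or list of models (all sharing `classes`).
#' @param slide a `SlideImage` (level 0 must be at the model's spacing).
#' @param tissue optional binary `LabelMask`.
#' @param window window side in pixels (default 512).
#' @param overlap overlap between adjacent windows in pixels (default 128).
#' @return list: `probs` (H x W x K array), `mask` (argmax `LabelMask`),
#'   `classes`.
#' @export
predict_wsi <- function(models, slide, tissue = NULL, window = 512,
                        overlap = 128) {
  if (!is.list(models) || inherits(models, "SegModel") ||
      !is.null(attr(models, "class"))) models <- list(models)
  classes <- models[[1]]$classes %||% stop("predict_wsi: model lacks classes")
  K <- length(classes)
  dm <- slide_dims(slide, 0)
  H <- dm[1]; W <- dm[2]
  step <- window - overlap
  if (step <= 0) stop("predict_wsi: overlap must be smaller than window")
  origins <- function(total) {
    if (total <= window) return(0L)
    o <- seq(0L, total - window, by = step)
    if (o[length(o)] != total - window) o <- c(o, total - window)
    o
  }
  acc <- array(0, c(H, W, K))
  wt <- matrix(0, H, W)
  for (r0 in origins(H)) for (c0 in origins(W)) {
    patch <- read_region(slide, 0, c(r0, c0), c(window, window))
    p <- ensemble_probs(models, patch)
    rr <- (r0 + 1):min(r0 + window, H)
    cc <- (c0 + 1):min(c0 + window, W)
    acc[rr, cc, ] <- acc[rr, cc, , drop = FALSE] +
      p[seq_along(rr), seq_along(cc), , drop = FALSE]
    wt[rr, cc] <- wt[rr, cc] + 1
  }
  for (k in seq_len(K)) acc[, , k] <- acc[, , k] / wt
  if (!is.null(tissue)) {
    bg <- which(classes == 0L)
    if (length(bg) != 1) stop("predict_wsi: no background class (code 0)")
    out_t <- mask_data(tissue) == 0
    for (k in seq_len(K)) {
      ch <- acc[, , k]
      ch[out_t] <- if (k == bg) 1 else 0
      acc[, , k] <- ch
    }
  }
  lab <- classes[max.col(matrix(acc, ncol = K), ties.method = "first")]
  cls <- classes
  names(cls) <- names(classes) %||% paste0("class_", classes)
  list(probs = acc,
       mask = label_mask(matrix(lab, H, W), slide$spacing_um, cls),
       classes = classes)
}

#' Derive tumor/normal epithelium labels from an epithelium mask and a
#' coarse tumor-bulk annotation
#'
#' Epithelium inside the bulk becomes tumor epithelium, outside becomes
#' normal epithelium, remaining tissue is background.
#'
#' @param epi binary epithelium `LabelMask` or matrix.
#' @param bulk an `AnnotationSet` (rasterized onto the mask grid; requires
#'   `slide`) or an aligned binary mask.
#' @param tissue aligned binary tissue mask (defines the raster extent).
#' @param slide `SlideImage`, only needed when `bulk` is an `AnnotationSet`.
#' @return 3-class `LabelMask`: background 0, normal epithelium 1, tumor
#'   epithelium 2.
#' @export
generate_tumor_epithelium_labels <- function(epi, bulk, tissue, slide = NULL) {
  e <- mask_data(epi) != 0
  if (inherits(bulk, "AnnotationSet")) {
    if (is.null(slide))
      stop("generate_tumor_epithelium_labels: slide required to rasterize bulk")
    b <- mask_data(polygons_to_mask(bulk, slide, 0, roles = "tumor_bulk")) != 0
  } else b <- mask_data(bulk) != 0
  if (any(dim(e) != dim(b)))
    stop("generate_tumor_epithelium_labels: mask shapes differ")
  out <- matrix(0L, nrow(e), ncol(e))
  out[e & !b] <- 1L
  out[e & b] <- 2L
  sp <- if (inherits(epi, "LabelMask")) epi$spacing_um else 1.0
  label_mask(out, sp, c(background = 0L, normal_epithelium = 1L,
                        tumor_epithelium = 2L))
}

#' Serialize a segmentation model to JSON
#' @param model a `SegModel`.
#' @param path output `.json` path.
#' @export
save_segnet <- function(model, path) {
  jsonlite::write_json(list(
    W = model$W, feat_mean = model$feat_mean, feat_sd = model$feat_sd,
    classes = model$classes, fold = model$fold,
    train_loss = model$train_loss, val_loss = model$val_loss,
    config = unclass(model$config)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a segmentation model saved by [save_segnet()]
#' @param path `.json` path.
#' @export
load_segnet <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(seg_config, as.list(j$config))
  structure(list(W = matrix(unlist(j$W), ncol = length(j$classes)),
                 feat_mean = as.numeric(j$feat_mean),
                 feat_sd = as.numeric(j$feat_sd),
                 classes = as.integer(j$classes), config = cfg,
                 fold = j$fold, train_loss = j$train_loss,
                 val_loss = j$val_loss),
            class = "SegModel")
}
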