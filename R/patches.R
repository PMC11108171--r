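# Tile sampling, augmentation and patient-level fold splitting for the
# segmentation networks. Tiles are 512 x 512 at 1.0 um/px by convention
# (both configurable); a tile is admissible when it overlaps the tissue
# mask in at least `tissue_floor` of its pixels.

#' Sample training tiles from a slide
#'
#' Enumerates every admissible origin (tissue overlap >= `tissue_floor`,
#' via an integral image) and draws `n` origins uniformly with replacement.
#' When the slide spacing differs from `spacing_um` by an integer factor the
#' raster is first downsampled by block averaging (labels/tissue by nearest
#' neighbor).
#'
#' @param slide a `SlideImage`.
#' @param labels `LabelMask` aligned to level 0 (class codes become the tile
#'   label rasters).
#' @param tissue binary `LabelMask` aligned to level 0.
#' @param n number of tiles (0 gives an empty list).
#' @param seed RNG seed.
#' @param size tile side in pixels (default 512).
#' @param spacing_um target spacing (default 1.0).
#' @param tissue_floor minimum tissue fraction per tile (default 0.2).
#' @param slide_id identifier recorded on each tile.
#' @return list of `TileSample`: `list(slide_id, origin, tile, labels, fold)`
#'   with `origin` the 0-based (row, col) at the target spacing.
#' @export
sample_tiles <- function(slide, labels, tissue, n, seed = 1, size = 512,
                         spacing_um = 1.0, tissue_floor = 0.2,
                         slide_id = "slide") {
  rgb <- slide$levels[[1]]
  lab <- mask_data(labels)
  tis <- mask_data(tissue) != 0
  f <- spacing_um / slide$spacing_um
  if (abs(f - round(f)) > 1e-9 || f < 1)
    stop("sample_tiles: spacing ratio must be a positive integer (got ", f, ")")
  f <- as.integer(round(f))
  if (f > 1) {
    h <- nrow(lab) %/% f; w <- ncol(lab) %/% f
    nn_r <- (seq_len(h) - 1L) * f + 1L
    nn_c <- (seq_len(w) - 1L) * f + 1L
    out <- array(0L, c(h, w, 3))
    for (k in 1:3) out[, , k] <- as.integer(round(cpp_block_mean(rgb[, , k], f)))
    rgb <- out
    lab <- lab[nn_r, nn_c, drop = FALSE]
    tis <- tis[nn_r, nn_c, drop = FALSE]
  }
  if (n == 0) return(list())
  H <- nrow(tis); W <- ncol(tis)
  if (H < size || W < size)
    stop("sample_tiles: slide '", slide_id, "' smaller than the tile size")
  # integral image -> tissue pixel count of every size x size window
  S <- rbind(0, cbind(0, apply(apply(tis, 2, cumsum), 1, cumsum)))
  S <- t(S)  # S[i+1, j+1] = sum of tis[1..i, 1..j]
  r <- 0:(H - size); c <- 0:(W - size)
  cnt <- S[r + size + 1, c + size + 1, drop = FALSE] -
    S[r + 1, c + size + 1, drop = FALSE] -
    S[r + size + 1, c + 1, drop = FALSE] + S[r + 1, c + 1, drop = FALSE]
  adm <- which(cnt >= tissue_floor * size * size, arr.ind = TRUE)
  if (!nrow(adm))
    stop("sample_tiles: no admissible tile origin on slide '", slide_id, "'")
  picks <- with_seed(seed, adm[sample.int(nrow(adm), n, replace = TRUE), ,
                               drop = FALSE])
  lapply(seq_len(n), function(i) {
    r0 <- picks[i, 1] - 1L; c0 <- picks[i, 2] - 1L
    list(slide_id = slide_id, origin = c(r0, c0),
         tile = rgb[(r0 + 1):(r0 + size), (c0 + 1):(c0 + size), , drop = FALSE],
         labels = lab[(r0 + 1):(r0 + size), (c0 + 1):(c0 + size), drop = FALSE],
         fold = NA_integer_)
  })
}

hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
         ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
         ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
         ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

#' Augment a training tile
#'
#' Each transform is applied independently with probability 0.5: horizontal
#' flip, vertical flip, Gaussian blur (sigma in `blur_sigma`), HSV shifts
#' (up to `hsv_shift` per channel), contrast and brightness scaling (up to
#' +/- `contrast` / `brightness`). Flips are applied identically to the
#' label raster; photometric transforms leave labels untouched.
#'
#' @param t a `TileSample`.
#' @param seed RNG seed (fixes both the transform choices and parameters).
#' @param p per-transform probability (default 0.5).
#' @param blur_sigma range of blur sigma (default c(0.5, 1.5)).
#' @param hsv_shift maximum absolute HSV shift (default 0.05).
#' @param contrast,brightness maximum relative change (default 0.2).
#' @return the augmented `TileSample`.
#' @export
augment <- function(t, seed = 1, p = 0.5, blur_sigma = c(0.5, 1.5),
                    hsv_shift = 0.05, contrast = 0.2, brightness = 0.2) {
  with_seed(seed, {
    tile <- t$tile * 1.0
    lab <- t$labels
    do <- runif(6) < p
    if (do[1]) {  # horizontal flip (mirror columns)
      tile <- tile[, ncol(lab):1, , drop = FALSE]
      lab <- lab[, ncol(lab):1, drop = FALSE]
    }
    if (do[2]) {  # vertical flip
      tile <- tile[nrow(lab):1, , , drop = FALSE]
      lab <- lab[nrow(lab):1, , drop = FALSE]
    }
    if (do[3]) {
      s <- runif(1, blur_sigma[1], blur_sigma[2])
      for (k in 1:3) tile[, , k] <- blur_mat(tile[, , k], s)
    }
    if (do[4]) {
      d <- runif(3, -hsv_shift, hsv_shift)
      hsv <- grDevices::rgb2hsv(rbind(as.vector(tile[, , 1]),
                                      as.vector(tile[, , 2]),
                                      as.vector(tile[, , 3])), maxColorValue = 255)
      rgb <- hsv_to_rgb(hsv[1, ] + d[1], clamp(hsv[2, ] + d[2], 0, 1),
                        clamp(hsv[3, ] + d[3], 0, 1)) * 255
      for (k in 1:3) tile[, , k] <- matrix(rgb[, k], nrow(lab))
    }
    if (do[5]) tile <- (tile - 127.5) * runif(1, 1 - contrast, 1 + contrast) + 127.5
    if (do[6]) tile <- tile * runif(1, 1 - brightness, 1 + brightness)
    t$tile <- array(as.integer(round(clamp(tile, 0, 255))), dim(t$tile))
    t$labels <- lab
    t
  })
}

#' Patient-level k-fold split
#'
#' Folds partition the patients (never slides or tiles); sizes differ by at
#' most one.
#'
#' @param patient_ids character/integer vector of unique patient ids.
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @return list of `k` elements `list(train = ids, val = ids)`.
#' @export
kfold_split <- function(patient_ids, k = 5, seed = 1) {
  patient_ids <- unique(patient_ids)
  n <- length(patient_ids)
  if (k > n) stop("kfold_split: k (", k, ") exceeds the number of patients (", n, ")")
  perm <- with_seed(seed, sample(patient_ids))
  fold <- rep_len(seq_len(k), n)
  lapply(seq_len(k), function(i)
    list(train = sort(perm[fold != i]), val = sort(perm[fold == i])))
}
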