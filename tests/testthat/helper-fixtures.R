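# Shared fixtures, built in code. Heavy synthetic slides are generated once
# per test run and memoised here.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, make) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- make()
  .fixture_env[[key]]
}

# small but fully featured synthetic slide (tumor + normal glands)
fixture_slide <- function(target = 0.6, seed = 101, canvas = 384) {
  memo(sprintf("slide_%g_%d_%d", target, seed, canvas), function()
    generate_slide(slide_recipe(canvas = c(canvas, canvas),
                                target_stroma_frac = target,
                                normal_glands = 10, seed = seed)))
}

# deterministic RGB test raster (not white, not uniform)
toy_rgb <- function(h = 8, w = 8, seed = 1) {
  set.seed(seed)
  array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
}

# square ring (x, y): covers pixel centers rows r0..r1, cols c0..c1 when
# drawn at pixel boundaries
square_ring <- function(c0, r0, c1, r1) {
  cbind(x = c(c0, c1 + 1, c1 + 1, c0), y = c(r0, r0, r1 + 1, r1 + 1))
}

# brute-force point-in-polygon (even-odd; on-edge counts as inside)
pip_oracle <- function(px, py, ring) {
  n <- nrow(ring)
  on_edge <- FALSE
  cross <- 0L
  for (e in seq_len(n)) {
    x1 <- ring[e, 1]; y1 <- ring[e, 2]
    x2 <- ring[e %% n + 1, 1]; y2 <- ring[e %% n + 1, 2]
    d <- abs((x2 - x1) * (py - y1) - (px - x1) * (y2 - y1))
    len2 <- (x2 - x1)^2 + (y2 - y1)^2
    if (len2 > 0 && d < 1e-9 * sqrt(len2)) {
      tproj <- ((px - x1) * (x2 - x1) + (py - y1) * (y2 - y1)) / len2
      if (tproj >= -1e-12 && tproj <= 1 + 1e-12) on_edge <- TRUE
    }
    if ((y1 <= py && y2 > py) || (y2 <= py && y1 > py)) {
      xc <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (px < xc) cross <- cross + 1L
    }
  }
  on_edge || (cross %% 2L == 1L)
}

# ---- acceptance fixtures (shared, generated once per run) -----------------

# five full-scale slides at the generator's stated world (768 px, 1.0 um/px)
acceptance_slides <- function() memo("acc_slides", function() {
  targets <- c(0.3, 0.5, 0.7, 0.9, 0.6)
  lapply(seq_along(targets), function(i)
    generate_slide(slide_recipe(canvas = c(768, 768),
                                target_stroma_frac = targets[i],
                                seed = 200 + i)))
})

# training cohort: 10 patients x 1 slide (512 px), patient-level 5-fold
# split, and the three stand-in networks trained per fold
seg_cohort <- function() memo("seg_cohort", function() {
  n <- 10
  patients <- sprintf("P%02d", seq_len(n))
  targets <- seq(0.35, 0.85, length.out = n)
  slides <- lapply(seq_len(n), function(i)
    generate_slide(slide_recipe(canvas = c(512, 512),
                                target_stroma_frac = targets[i],
                                normal_glands = 10, seed = 300 + i)))
  folds <- kfold_split(patients, k = 5, seed = 1)
  fold_of <- vapply(patients, function(p)
    which(vapply(folds, function(f) p %in% f$val, logical(1))), integer(1))
  prep <- lapply(seq_len(n), function(i) {
    s <- slides[[i]]
    tis <- tissue_mask(s$he)
    em <- epithelium_mask_from_ihc(s$ihc, tis)
    tum <- generate_tumor_epithelium_labels(em, s$bulk, tis, slide = s$he)
    stro <- s$truth$labels$data
    sm <- matrix(0L, nrow(stro), ncol(stro))
    sm[stro == 1L] <- 1L
    sm[stro %in% c(2L, 3L)] <- 2L
    list(tissue = tis, epi = em, tumor = tum,
         stroma = label_mask(sm, s$he$spacing_um,
                             c(background = 0L, stroma = 1L, epithelium = 2L)))
  })
  tiles_for <- function(which_mask) {
    out <- list()
    for (i in seq_len(n)) {
      ts <- sample_tiles(slides[[i]]$he, prep[[i]][[which_mask]],
                         prep[[i]]$tissue, n = 3, seed = 400 + i, size = 256,
                         slide_id = patients[i])
      for (t in ts) { t$fold <- fold_of[i]; out[[length(out) + 1]] <- t }
    }
    out
  }
  cfg2 <- seg_config(2L, depth = 4, width = 2, input_size = 256,
                     samples_per_class = 1500, seed = 11)
  cfg3 <- seg_config(3L, depth = 4, width = 2, input_size = 256,
                     samples_per_class = 1500, seed = 12)
  list(slides = slides, patients = patients, folds = folds,
       fold_of = fold_of, prep = prep,
       epi_models = train_segnet(tiles_for("epi"), cfg2, classes = 0:1),
       tumor_models = train_segnet(tiles_for("tumor"), cfg3, classes = 0:2),
       stroma_models = train_segnet(tiles_for("stroma"), cfg3, classes = 0:2))
})

expect_label_mask <- function(m) {
  expect_s3_class(m, "LabelMask")
  expect_true(all(unique(as.vector(m$data)) %in% m$classes))
}

# brute-force oracle: circumradius of every Delaunay triangle, computed
# independently of the implementation's filter
oracle_keep <- function(pts, tris, alpha) {
  keep <- logical(nrow(tris))
  rmax <- if (alpha == 0) Inf else 1 / alpha
  for (t in seq_len(nrow(tris))) {
    a <- pts[tris[t, 1], ]; b <- pts[tris[t, 2], ]; c <- pts[tris[t, 3], ]
    la <- sqrt(sum((b - c)^2)); lb <- sqrt(sum((a - c)^2)); lc <- sqrt(sum((a - b)^2))
    K <- abs((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])) / 2
    r <- if (K <= 0) Inf else la * lb * lc / (4 * K)
    keep[t] <- r <= rmax
  }
  keep
}

tri_area_sum <- function(pts, tris) {
  if (!nrow(tris)) return(0)
  sum(abs((pts[tris[, 2], 1] - pts[tris[, 1], 1]) *
            (pts[tris[, 3], 2] - pts[tris[, 1], 2]) -
            (pts[tris[, 3], 1] - pts[tris[, 1], 1]) *
            (pts[tris[, 2], 2] - pts[tris[, 1], 2])) / 2)
}

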