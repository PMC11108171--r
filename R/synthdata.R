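# Synthetic paired pseudo-H&E / pseudo-IHC slide generator with exact ground
# truth, plus synthetic patient cohorts.
#
# A slide is a white canvas carrying one roughly circular tissue region of
# textured stroma. Inside the tissue sits a compact tumor blob; tumor
# epithelium is rendered as solid, irregular elliptical nests placed only
# inside the blob (poorly differentiated morphotype), while normal glands
# are ring-shaped (epithelial rim around an empty lumen) and live only
# outside the blob. Because tumor nests are lumen-free, every blob pixel is
# either stroma or tumor epithelium, so the blob's stroma fraction equals
# the tumor-stroma ratio computed from the truth masks. The paired IHC
# image is synthesized through the package's own Beer-Lambert stain model
# (DAB on epithelium, hematoxylin elsewhere), so color deconvolution
# provably recovers the epithelium.

#' Slide recipe
#'
#' @param canvas (h, w) canvas size in pixels.
#' @param spacing_um micrometers per pixel (default 1.0).
#' @param target_stroma_frac target stroma fraction inside the tumor blob,
#'   in `[0, 1]`; gland placement iterates until the realized fraction is
#'   within `tol` of it.
#' @param tumor_radius_frac tumor blob radius as a fraction of min(canvas).
#' @param tissue_radius_frac tissue region radius as a fraction of min(canvas).
#' @param roughness relative amplitude of the blob boundary irregularity.
#' @param tumor_gland_r radius range (px) of tumor epithelium nests.
#' @param tumor_gland_ecc eccentricity range of tumor nests.
#' @param normal_glands number of normal (ring) glands outside the blob.
#' @param normal_gland_r radius range (px) of normal glands.
#' @param lumen_frac lumen radius as a fraction of the gland radius (range).
#' @param noise_sd pixel noise standard deviation in the H&E rendering.
#' @param tol tolerance on the realized stroma fraction (default 0.005).
#' @param seed RNG seed; identical seeds give bit-identical slides.
#' @return a `SlideRecipe`.
#' @export
slide_recipe <- function(canvas = c(768, 768), spacing_um = 1.0,
                         target_stroma_frac = 0.7,
                         tumor_radius_frac = 0.32, tissue_radius_frac = 0.46,
                         roughness = 0.06,
                         tumor_gland_r = c(10, 22), tumor_gland_ecc = c(0, 0.55),
                         normal_glands = 25, normal_gland_r = c(10, 18),
                         lumen_frac = c(0.35, 0.55), noise_sd = 7,
                         tol = 0.005, seed = 1) {
  if (target_stroma_frac < 0 || target_stroma_frac > 1)
    stop("slide_recipe: target_stroma_frac must be in [0, 1]")
  if (any(tumor_gland_r <= 0) || any(normal_gland_r <= 0))
    stop("slide_recipe: gland radii must be positive")
  if (tumor_radius_frac * (1 + roughness) >= 0.5)
    stop("slide_recipe: tumor blob would not fit inside the canvas")
  if (tissue_radius_frac <= tumor_radius_frac)
    stop("slide_recipe: tissue region must contain the tumor blob")
  structure(list(canvas = as.integer(canvas), spacing_um = spacing_um,
                 target_stroma_frac = target_stroma_frac,
                 tumor_radius_frac = tumor_radius_frac,
                 tissue_radius_frac = tissue_radius_frac,
                 roughness = roughness, tumor_gland_r = tumor_gland_r,
                 tumor_gland_ecc = tumor_gland_ecc,
                 normal_glands = normal_glands, normal_gland_r = normal_gland_r,
                 lumen_frac = lumen_frac, noise_sd = noise_sd,
                 tol = tol, seed = as.integer(seed)),
            class = "SlideRecipe")
}

# irregular star-convex blob boundary: radius modulated by low-order
# cosine harmonics, normalized so the relative deviation is exactly `rough`
blob_ring <- function(center, radius, rough, n = 360) {
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  if (rough > 0) {
    kk <- 2:5
    a <- rnorm(length(kk)) / kk
    ph <- runif(length(kk), 0, 2 * pi)
    s <- rowSums(vapply(seq_along(kk),
                        function(i) a[i] * cos(kk[i] * theta + ph[i]),
                        numeric(length(theta))))
    s <- s / max(abs(s), 1e-12) * rough
  } else s <- 0
  r <- radius * (1 + s)
  cbind(x = center[1] + r * cos(theta), y = center[2] + r * sin(theta))
}

# rasterize an ellipse (center cx,cy; semi-axes a,b; rotation th) into mask
# coordinates; returns 0-based (row, col) indices of covered pixel centers
ellipse_pixels <- function(cx, cy, a, b, th, H, W) {
  r0 <- max(0, floor(cy - max(a, b) - 1)); r1 <- min(H - 1, ceiling(cy + max(a, b) + 1))
  c0 <- max(0, floor(cx - max(a, b) - 1)); c1 <- min(W - 1, ceiling(cx + max(a, b) + 1))
  if (r1 < r0 || c1 < c0) return(matrix(integer(0), 0, 2))
  rr <- r0:r1; cc <- c0:c1
  dy <- (rr + 0.5) - cy; dx <- (cc + 0.5) - cx
  X <- outer(dy * 0, dx, "+"); Y <- outer(dy, dx * 0, "+")
  u <- (X * cos(th) + Y * sin(th)) / a
  v <- (-X * sin(th) + Y * cos(th)) / b
  hit <- which(u * u + v * v <= 1, arr.ind = TRUE)
  cbind(rr[hit[, 1]], cc[hit[, 2]])
}

#' Generate a paired pseudo-H&E / pseudo-IHC slide with ground truth
#'
#' @param recipe a `SlideRecipe`.
#' @return list with elements `he`, `ihc` (pixel-aligned `SlideImage`s),
#'   `truth` (list of `LabelMask`: `epithelium`, `tumor_epithelium`,
#'   `stroma`, `tissue`, `tumor_blob`, and a combined multi-class `labels`
#'   mask), `bulk` (`AnnotationSet` with the tumor-bulk polygon),
#'   `realized_stroma_frac`, and `recipe`.
#' @export
generate_slide <- function(recipe) {
  stopifnot(inherits(recipe, "SlideRecipe"))
  with_seed(recipe$seed, {
    H <- recipe$canvas[1]; W <- recipe$canvas[2]
    ctr <- c(W / 2, H / 2)
    R <- recipe$tumor_radius_frac * min(H, W)
    ring <- blob_ring(ctr, R, recipe$roughness)
    blob <- cpp_rasterize_rings(list(ring), H, W)
    tis_ring <- blob_ring(ctr, recipe$tissue_radius_frac * min(H, W),
                          recipe$roughness / 2)
    tissue <- pmax(cpp_rasterize_rings(list(tis_ring), H, W), blob)

    # Solid elliptical nests cannot tile the blob wall-to-wall: a minimal
    # inter-nest stroma rim always survives, so very low stroma targets are
    # geometrically infeasible for the default gland size.
    if (recipe$target_stroma_frac < 0.05)
      stop("generate_slide: target stroma fraction ",
           recipe$target_stroma_frac,
           " is infeasible for the gland geometry (floor 0.05)")
    blob_px <- sum(blob)
    target_epi <- round(blob_px * (1 - recipe$target_stroma_frac))
    tol_px <- max(1, round(recipe$tol * blob_px))
    epi_t <- matrix(0L, H, W)
    epi_px <- 0L

    # invasion front: tumor nests seeded along the blob boundary, so the
    # epithelium reaches the bulk margin all around (infiltrative growth
    # pattern); capped at 60% of the epithelium budget
    r_b <- recipe$tumor_gland_r[1]
    seg <- sqrt(rowSums((ring - ring[c(2:nrow(ring), 1), ])^2))
    perim <- sum(seg)
    n_b <- min(floor(perim / (2.5 * r_b)),
               floor(0.6 * target_epi / (0.5 * pi * r_b^2)))
    if (n_b > 0) {
      arc <- cumsum(seg)
      want <- seq(0, perim, length.out = n_b + 1)[-(n_b + 1)]
      vert <- findInterval(want, c(0, arc), rightmost.closed = TRUE)
      for (v in vert) {
        e <- runif(1, 0, 0.3); th <- runif(1, 0, pi)
        px <- ellipse_pixels(ring[v, 1], ring[v, 2],
                             r_b * (1 + e), r_b * (1 - e), th, H, W)
        if (!nrow(px)) next
        lin <- px[, 1] + 1L + px[, 2] * H
        lin <- lin[blob[lin] != 0 & epi_t[lin] == 0]
        epi_t[lin] <- 1L
        epi_px <- epi_px + length(lin)
      }
    }

    stall <- 0L; iter <- 0L
    while (target_epi - epi_px > tol_px) {
      iter <- iter + 1L
      if (iter > 4000L) break
      deficit <- target_epi - epi_px
      r0 <- runif(1, recipe$tumor_gland_r[1], recipe$tumor_gland_r[2])
      if (pi * r0^2 > 1.05 * deficit) r0 <- max(1.5, sqrt(deficit / pi))
      e <- runif(1, recipe$tumor_gland_ecc[1], recipe$tumor_gland_ecc[2])
      th <- runif(1, 0, pi)
      free_idx <- which(blob != 0 & epi_t == 0)
      if (!length(free_idx)) break
      c_at <- free_idx[sample.int(length(free_idx), 1)]
      cy <- (c_at - 1L) %% H; cx <- (c_at - 1L) %/% H
      px <- ellipse_pixels(cx + 0.5, cy + 0.5,
                           r0 * (1 + e), r0 * (1 - e), th, H, W)
      if (!nrow(px)) next
      lin <- px[, 1] + 1L + px[, 2] * H
      lin <- lin[blob[lin] != 0 & epi_t[lin] == 0]
      if (!length(lin)) {
        stall <- stall + 1L
        if (stall > 100L) break
      } else stall <- 0L
      epi_t[lin] <- 1L
      epi_px <- epi_px + length(lin)
    }
    realized <- 1 - epi_px / blob_px
    if (abs(realized - recipe$target_stroma_frac) > 0.03)
      stop("generate_slide: target stroma fraction ",
           recipe$target_stroma_frac, " infeasible for the gland geometry ",
           "(realized ", round(realized, 3), " after bounded retries)")

    # normal ring glands outside a safety margin around the blob
    epi_n <- matrix(0L, H, W)
    lumen <- matrix(0L, H, W)
    placed <- 0L; tries <- 0L
    tis_idx <- which(tissue != 0 & blob == 0, arr.ind = TRUE)
    while (placed < recipe$normal_glands && tries < recipe$normal_glands * 30L &&
           nrow(tis_idx) > 0) {
      tries <- tries + 1L
      r0 <- runif(1, recipe$normal_gland_r[1], recipe$normal_gland_r[2])
      c_at <- tis_idx[sample.int(nrow(tis_idx), 1), ]
      cx <- c_at[2] - 0.5; cy <- c_at[1] - 0.5
      e <- runif(1, 0, 0.3); th <- runif(1, 0, pi)
      outer_px <- ellipse_pixels(cx, cy, r0 * (1 + e), r0 * (1 - e), th, H, W)
      if (!nrow(outer_px)) next
      lin_o <- outer_px[, 1] + 1L + outer_px[, 2] * H
      # keep glands clear of the tumor blob and inside the tissue
      if (any(blob[lin_o] != 0) || any(tissue[lin_o] == 0)) next
      lf <- runif(1, recipe$lumen_frac[1], recipe$lumen_frac[2])
      inner_px <- ellipse_pixels(cx, cy, r0 * (1 + e) * lf, r0 * (1 - e) * lf,
                                 th, H, W)
      lin_i <- inner_px[, 1] + 1L + inner_px[, 2] * H
      epi_n[setdiff(lin_o, lin_i)] <- 1L
      lumen[lin_i] <- 1L
      placed <- placed + 1L
    }
    lumen[epi_n == 1 | epi_t == 1] <- 0L  # overlapping glands: rim wins
    epithelium <- pmax(epi_t, epi_n)
    stroma <- as.integer(tissue != 0 & epithelium == 0 & lumen == 0)
    dim(stroma) <- c(H, W)

    # ---- H&E rendering ---------------------------------------------------
    base <- list(bg = c(252, 252, 252), stroma = c(235, 162, 192),
                 nepi = c(150, 85, 160), tepi = c(118, 62, 138),
                 lumen = c(248, 246, 248))
    he <- array(0, c(H, W, 3))
    field <- blur_mat(matrix(rnorm(H * W), H, W), 12)
    field <- field / max(abs(field), 1e-12) * 8
    for (k in 1:3) {
      ch <- matrix(base$bg[k], H, W)
      ch[stroma == 1] <- base$stroma[k]
      ch[lumen == 1] <- base$lumen[k]
      ch[epi_n == 1] <- base$nepi[k]
      ch[epi_t == 1] <- base$tepi[k]
      ch <- ch + matrix(rnorm(H * W), H, W) *
        ifelse(tissue != 0, recipe$noise_sd, 1.5) +
        field * (tissue != 0)
      he[, , k] <- clamp(round(ch), 0, 255)
    }

    # ---- IHC rendering through the stain model ---------------------------
    M <- stain_matrix()
    cH <- matrix(0, H, W)
    cH[stroma == 1] <- 0.30
    cH[epithelium == 1] <- 0.35
    cH[lumen == 1] <- 0.05
    cH <- pmax(cH + matrix(rnorm(H * W, 0, 0.02), H, W) * (tissue != 0), 0)
    cD <- matrix(0, H, W)
    cD[epithelium == 1] <- 0.85
    cD <- pmax(cD + matrix(rnorm(H * W, 0, 0.05), H, W) * (tissue != 0), 0)
    conc <- array(0, c(H, W, 3))
    conc[, , 1] <- cH; conc[, , 2] <- cD
    ihc <- render_stains(conc, M, quantize = TRUE)

    sp <- recipe$spacing_um
    bin <- c(background = 0L, foreground = 1L)
    combined <- matrix(0L, H, W)
    combined[stroma == 1] <- 1L
    combined[epi_n == 1] <- 2L
    combined[epi_t == 1] <- 3L
    combined[lumen == 1] <- 4L
    list(
      he = slide_image(he, sp),
      ihc = slide_image(ihc, sp),
      truth = list(
        epithelium = label_mask(epithelium, sp, bin),
        tumor_epithelium = label_mask(epi_t, sp, bin),
        stroma = label_mask(stroma, sp, bin),
        tissue = label_mask(tissue, sp, bin),
        tumor_blob = label_mask(blob, sp, bin),
        labels = label_mask(combined, sp,
                            c(background = 0L, stroma = 1L,
                              normal_epithelium = 2L, tumor_epithelium = 3L,
                              lumen = 4L))),
      bulk = annotation_set(list(list(name = "tumor_bulk", role = "tumor_bulk",
                                      rings = list(ring)))),
      realized_stroma_frac = realized,
      recipe = recipe)
  })
}

#' Cohort recipe
#'
#' Survival follows a proportional-hazards model with exponential baseline:
#' the death hazard of patient i is `baseline_rate * exp(beta * TSR_i)` with
#' TSR_i ~ Uniform(tsr_range); censoring is an independent exponential whose
#' rate is tuned to the requested censoring fraction.
#'
#' @param n_patients cohort size (>= 1).
#' @param baseline_rate exponential baseline hazard in 1/days (default 1/500).
#' @param beta log-hazard per unit TSR (default 2; 0 gives a null cohort).
#' @param censor_rate expected fraction censored, in `[0, 1)` (default 0.3).
#' @param tsr_range range of the true stroma fraction (default c(0.2, 0.95)).
#' @param slide_template a `SlideRecipe` used for every patient's slide
#'   (its target stroma fraction and seed are overridden per patient).
#' @param seed RNG seed.
#' @return a `CohortRecipe`.
#' @export
cohort_recipe <- function(n_patients, baseline_rate = 1 / 500, beta = 2,
                          censor_rate = 0.3, tsr_range = c(0.2, 0.95),
                          slide_template = slide_recipe(), seed = 1) {
  if (n_patients < 1) stop("cohort_recipe: n_patients must be >= 1")
  if (baseline_rate <= 0) stop("cohort_recipe: baseline_rate must be > 0")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("cohort_recipe: censor_rate must be in [0, 1)")
  structure(list(n_patients = as.integer(n_patients),
                 baseline_rate = baseline_rate, beta = beta,
                 censor_rate = censor_rate, tsr_range = tsr_range,
                 slide_template = slide_template, seed = as.integer(seed)),
            class = "CohortRecipe")
}

#' Generate a synthetic patient cohort
#'
#' @param recipe a `CohortRecipe`.
#' @return list with `clinical` (data.frame in the [read_clinical()] layout,
#'   plus the hidden `true_tsr` column), and `slide_recipes` (named list of
#'   per-patient `SlideRecipe`s whose target stroma fraction is the
#'   patient's true TSR).
#' @export
generate_cohort <- function(recipe) {
  stopifnot(inherits(recipe, "CohortRecipe"))
  with_seed(recipe$seed, {
    n <- recipe$n_patients
    tsr <- runif(n, recipe$tsr_range[1], recipe$tsr_range[2])
    rate <- recipe$baseline_rate * exp(recipe$beta * tsr)
    death <- rexp(n, rate)
    if (recipe$censor_rate > 0) {
      # tune the censoring rate mu so that E[P(C < T)] hits the request
      f <- function(lmu) mean(exp(lmu) / (exp(lmu) + rate)) - recipe$censor_rate
      mu <- exp(uniroot(f, c(log(min(rate)) - 12, log(max(rate)) + 12))$root)
      cens <- rexp(n, mu)
    } else cens <- rep(Inf, n)
    event <- death <= cens
    days <- pmax(0L, as.integer(floor(pmin(death, cens))))
    ids <- sprintf("P%04d", seq_len(n))
    clinical <- data.frame(
      patient_id = ids,
      age = as.integer(clamp(round(rnorm(n, 66, 9)), 35, 90)),
      gender = sample(c("male", "female"), n, replace = TRUE),
      vital_status = ifelse(event, "dead", "alive"),
      survival_days = days,
      origin = "pancreas",
      primary_diagnosis = sample(c("ductal_adenocarcinoma", "adenocarcinoma_nos"),
                                 n, replace = TRUE, prob = c(0.8, 0.2)),
      prior_malignancy = sample(c("no", "yes"), n, replace = TRUE,
                                prob = c(0.85, 0.15)),
      slide_ids = paste0(ids, "_S1"),
      true_tsr = tsr,
      stringsAsFactors = FALSE)
    clinical$event <- as.integer(event)
    recipes <- lapply(seq_len(n), function(i) {
      r <- recipe$slide_template
      r$target_stroma_frac <- tsr[i]
      r$seed <- child_seed(recipe$seed, i)
      r
    })
    names(recipes) <- paste0(ids, "_S1")
    list(clinical = clinical, slide_recipes = recipes)
  })
}
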