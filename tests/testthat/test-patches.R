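make_half_tissue <- function(n = 64) {
  # left half tissue, right half glass
  a <- array(255L, c(n, n, 3))
  a[, 1:(n / 2), 1] <- 200L; a[, 1:(n / 2), 2] <- 120L; a[, 1:(n / 2), 3] <- 160L
  tis <- matrix(0L, n, n); tis[, 1:(n / 2)] <- 1L
  lab <- matrix(0L, n, n); lab[1:(n / 2), ] <- 1L
  list(slide = slide_image(a, 1), tissue = label_mask(tis, 1),
       labels = label_mask(lab, 1))
}

test_that("sample_tiles basic contracts", {
  f <- make_half_tissue()
  expect_equal(sample_tiles(f$slide, f$labels, f$tissue, n = 0, size = 16),
               list())
  t1 <- sample_tiles(f$slide, f$labels, f$tissue, n = 5, seed = 3, size = 16)
  t2 <- sample_tiles(f$slide, f$labels, f$tissue, n = 5, seed = 3, size = 16)
  expect_identical(lapply(t1, `[[`, "origin"), lapply(t2, `[[`, "origin"))
  expect_true(all(vapply(t1, function(t) all(dim(t$tile)[1:2] == c(16, 16)),
                         logical(1))))
  expect_true(all(vapply(t1, function(t) all(dim(t$labels) == c(16, 16)),
                         logical(1))))
})

test_that("sampled origins match the exhaustive admissible set", {
  f <- make_half_tissue(64)
  size <- 16
  # brute-force enumeration of admissible origins (tissue fraction >= 0.2)
  adm <- matrix(FALSE, 64 - size + 1, 64 - size + 1)
  tis <- mask_data(f$tissue)
  for (r in 0:(64 - size)) for (c in 0:(64 - size))
    adm[r + 1, c + 1] <- mean(tis[(r + 1):(r + size), (c + 1):(c + size)]) >= 0.2
  tiles <- sample_tiles(f$slide, f$labels, f$tissue, n = 200, seed = 11,
                        size = size)
  for (t in tiles)
    expect_true(adm[t$origin[1] + 1, t$origin[2] + 1])
})

test_that("no admissible origin names the slide in the error", {
  f <- make_half_tissue(32)
  empty_t <- label_mask(matrix(0L, 32, 32), 1)
  expect_error(sample_tiles(f$slide, f$labels, empty_t, n = 1, size = 16,
                            slide_id = "SLIDE_X"), "SLIDE_X")
})

test_that("spacing resampling averages by integer blocks", {
  f <- make_half_tissue(64)
  s05 <- slide_image(f$slide$levels[[1]], 0.5)  # pretend 0.5 um/px
  tl <- sample_tiles(s05, f$labels, f$tissue, n = 1, seed = 1, size = 16,
                     spacing_um = 1.0)
  expect_equal(dim(tl[[1]]$tile)[1:2], c(16, 16))
  expect_error(sample_tiles(slide_image(f$slide$levels[[1]], 0.7), f$labels,
                            f$tissue, n = 1, size = 16), "integer")
})

test_that("flips are involutions and label histograms survive them", {
  f <- make_half_tissue()
  t0 <- sample_tiles(f$slide, f$labels, f$tissue, n = 1, seed = 5, size = 16)[[1]]
  # find a seed that applies both flips and nothing else
  seed_both <- NULL
  for (s in 1:200) {
    d <- with_seed(s, runif(6) < 0.5)
    if (d[1] && d[2] && !any(d[3:6])) { seed_both <- s; break }
  }
  expect_false(is.null(seed_both))
  once <- augment(t0, seed = seed_both)
  twice <- augment(once, seed = seed_both)
  expect_identical(twice$tile, t0$tile)
  expect_identical(twice$labels, t0$labels)
  expect_equal(tabulate(once$labels + 1L, 3), tabulate(t0$labels + 1L, 3))
})

test_that("photometric-only augmentation leaves labels bit-identical", {
  f <- make_half_tissue()
  t0 <- sample_tiles(f$slide, f$labels, f$tissue, n = 1, seed = 6, size = 16)[[1]]
  seed_photo <- NULL
  for (s in 1:400) {
    d <- with_seed(s, runif(6) < 0.5)
    if (!d[1] && !d[2] && any(d[3:6])) { seed_photo <- s; break }
  }
  aug <- augment(t0, seed = seed_photo)
  expect_identical(aug$labels, t0$labels)
  expect_false(identical(aug$tile, t0$tile))
  expect_true(all(aug$tile >= 0 & aug$tile <= 255))
})

test_that("kfold_split partitions patients with balanced sizes", {
  ids <- sprintf("P%02d", 1:10)
  f5 <- kfold_split(ids, k = 5, seed = 1)
  expect_equal(vapply(f5, function(f) length(f$val), integer(1)), rep(2L, 5))
  expect_setequal(unlist(lapply(f5, `[[`, "val")), ids)
  # pairwise disjoint validation folds
  expect_equal(anyDuplicated(unlist(lapply(f5, `[[`, "val"))), 0L)
  # 11 patients, k = 5 -> sizes {3,2,2,2,2}
  f11 <- kfold_split(sprintf("Q%02d", 1:11), k = 5, seed = 2)
  expect_setequal(vapply(f11, function(f) length(f$val), integer(1)),
                  c(3L, 2L, 2L, 2L, 2L))
  expect_error(kfold_split(ids[1:3], k = 5), "exceeds")
})

test_that("no validation patient leaks into its training fold", {
  ids <- sprintf("P%02d", 1:13)
  for (f in kfold_split(ids, k = 5, seed = 3)) {
    expect_length(intersect(f$train, f$val), 0)
    expect_setequal(c(f$train, f$val), ids)
  }
})
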