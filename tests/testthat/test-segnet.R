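# stub model whose probabilities depend on the window's mean intensity:
# makes overlap averaging observable at window seams
local({
  stub <- function(model, rgb) {
    p1 <- matrix(mean(rgb) / 255, dim(rgb)[1], dim(rgb)[2])
    array(c(1 - p1, p1), c(dim(rgb)[1], dim(rgb)[2], 2))
  }
  registerS3method("predict_probs", "stub_model", stub,
                   envir = asNamespace("tsrquant"))
})

stub_model <- function() structure(list(classes = c(0L, 1L)), class = "stub_model")

# tiny labeled tile: class 1 where the red channel is high
toy_tile <- function(n = 32, seed = 1) {
  set.seed(seed)
  lab <- matrix(as.integer(matrix(runif(n * n), n) > 0.5), n)
  a <- array(0L, c(n, n, 3))
  a[, , 1] <- 40L + 180L * lab + sample(-10:10, n * n, TRUE)
  a[, , 2] <- 90L; a[, , 3] <- 120L
  a[, , 1] <- pmax(pmin(a[, , 1], 255L), 0L)
  list(slide_id = "T", origin = c(0L, 0L), tile = a, labels = lab, fold = 1L)
}

test_that("seg_config validates its fields", {
  expect_error(seg_config(4L), "2 or 3")
  expect_error(seg_config(2L, depth = 0), "depth")
  cfg <- seg_config(3L, depth = 2, width = 1)
  expect_s3_class(cfg, "SegConfig")
})

test_that("training smoke: checkpoints serialize and reload exactly", {
  tiles <- list(toy_tile(seed = 1), toy_tile(seed = 2))
  tiles[[2]]$fold <- 2L
  cfg <- seg_config(2L, depth = 2, width = 1, input_size = 32,
                    samples_per_class = 200, seed = 4)
  models <- train_segnet(tiles, cfg, classes = 0:1)
  expect_length(models, 2)
  expect_true(all(is.finite(vapply(models, `[[`, numeric(1), "train_loss"))))
  d <- withr::local_tempdir()
  save_segnet(models[[1]], file.path(d, "m.json"))
  m2 <- load_segnet(file.path(d, "m.json"))
  probe <- toy_tile(seed = 3)$tile
  expect_equal(predict_probs(m2, probe), predict_probs(models[[1]], probe),
               tolerance = 1e-12)
})

test_that("a model overfit on one tile reproduces that tile", {
  t1 <- toy_tile(seed = 5)
  t2 <- toy_tile(seed = 5); t2$fold <- 2L
  cfg <- seg_config(2L, depth = 2, width = 2, input_size = 32,
                    samples_per_class = 400, seed = 4, lambda = 1e-4)
  m <- train_segnet(list(t1, t2), cfg, classes = 0:1)[[2]]
  expect_lt(m$train_loss, 0.3)
  p <- predict_probs(m, t1$tile)
  pred <- (p[, , 2] > 0.5) + 0L
  expect_gt(mean(pred == t1$labels), 0.9)
})

test_that("probabilities are normalized per pixel", {
  t1 <- toy_tile(seed = 6); t2 <- toy_tile(seed = 7); t2$fold <- 2L
  cfg <- seg_config(2L, depth = 2, width = 1, input_size = 32,
                    samples_per_class = 100, seed = 1)
  m <- train_segnet(list(t1, t2), cfg, classes = 0:1)[[1]]
  p <- predict_probs(m, t1$tile)
  expect_true(all(p >= 0))
  expect_equal(apply(p, c(1, 2), sum), matrix(1, 32, 32), tolerance = 1e-5)
})

test_that("an ensemble of identical models equals the single model", {
  s <- slide_image(toy_tile(seed = 8)$tile, 1)
  m <- stub_model()
  one <- predict_wsi(list(m), s, window = 16, overlap = 4)
  three <- predict_wsi(list(m, m, m), s, window = 16, overlap = 4)
  expect_equal(three$probs, one$probs, tolerance = 1e-12)
  expect_identical(three$mask$data, one$mask$data)
})

test_that("stitching is phase-invariant on constant input", {
  a <- array(120L, c(24, 24, 3))
  s <- slide_image(a, 1)
  m <- stub_model()
  p1 <- predict_wsi(m, s, window = 8, overlap = 2)
  p2 <- predict_wsi(m, s, window = 12, overlap = 4)
  expect_equal(p1$probs, p2$probs, tolerance = 1e-12)
  expect_lt(max(abs(p1$probs[, , 2] - 120 / 255)), 1e-12)
})

test_that("overlap averaging equals the brute-force window mean (8x8 toy)", {
  set.seed(33)
  a <- array(sample(0:255, 8 * 8 * 3, TRUE), c(8, 8, 3))
  s <- slide_image(a, 1)
  m <- stub_model()
  got <- predict_wsi(m, s, window = 4, overlap = 2)
  # enumerate all covering windows per pixel, exactly as specified
  origins <- c(0, 2, 4)  # window 4, step 2 on an 8-px side
  acc <- array(0, c(8, 8, 2)); cnt <- matrix(0, 8, 8)
  for (r0 in origins) for (c0 in origins) {
    patch <- a[(r0 + 1):(r0 + 4), (c0 + 1):(c0 + 4), , drop = FALSE]
    p1 <- mean(patch) / 255
    acc[(r0 + 1):(r0 + 4), (c0 + 1):(c0 + 4), 1] <-
      acc[(r0 + 1):(r0 + 4), (c0 + 1):(c0 + 4), 1] + (1 - p1)
    acc[(r0 + 1):(r0 + 4), (c0 + 1):(c0 + 4), 2] <-
      acc[(r0 + 1):(r0 + 4), (c0 + 1):(c0 + 4), 2] + p1
    cnt[(r0 + 1):(r0 + 4), (c0 + 1):(c0 + 4)] <-
      cnt[(r0 + 1):(r0 + 4), (c0 + 1):(c0 + 4)] + 1
  }
  want <- acc / array(cnt, c(8, 8, 2))
  expect_equal(got$probs, want, tolerance = 1e-12)
})

test_that("tissue masking forces background and ties break low", {
  a <- array(127L, c(8, 8, 3))  # stub gives p = (0.502, 0.498): argmax class 0
  s <- slide_image(a, 1)
  tis <- matrix(0L, 8, 8); tis[1:4, ] <- 1L
  out <- predict_wsi(stub_model(), s, label_mask(tis, 1), window = 8, overlap = 2)
  expect_true(all(out$mask$data[5:8, ] == 0L))
  expect_true(all(out$probs[5:8, , 1] == 1))
  # exact tie: half 127, half 128 averages to 127.5, so the stub emits
  # p = (0.5, 0.5) exactly and argmax must pick the lower class code
  a2 <- array(rep(c(127L, 128L), each = 6), c(2, 2, 3))
  tie <- predict_wsi(stub_model(), slide_image(a2, 1), window = 2, overlap = 1)
  expect_true(all(tie$mask$data == 0L))
})

test_that("tumor-epithelium label generation is pure set algebra", {
  epi <- matrix(0L, 4, 4); epi[2, 1:4] <- 1L            # 4 epithelium px
  tis <- matrix(1L, 4, 4)
  bulk0 <- matrix(0L, 4, 4)
  l0 <- generate_tumor_epithelium_labels(epi, bulk0, tis)
  expect_equal(sum(l0$data == 2L), 0)                   # empty bulk: no tumor
  expect_equal(sum(l0$data == 1L), 4)
  bulk_all <- matrix(1L, 4, 4)
  l1 <- generate_tumor_epithelium_labels(epi, bulk_all, tis)
  expect_equal(sum(l1$data == 1L), 0)                   # full bulk: no normal
  expect_equal(sum(l1$data == 2L), 4)
  bulk_half <- matrix(0L, 4, 4); bulk_half[, 1:2] <- 1L
  l2 <- generate_tumor_epithelium_labels(epi, bulk_half, tis)
  expect_equal(sum(l2$data == 2L), 2)                   # checker: 2 tumor
  expect_equal(sum(l2$data == 1L), 2)                   # + 2 normal
})

test_that("ensembling never exceeds the member-wise max probability", {
  set.seed(44)
  t1 <- toy_tile(seed = 9); t2 <- toy_tile(seed = 10); t2$fold <- 2L
  cfg <- seg_config(2L, depth = 2, width = 1, input_size = 32,
                    samples_per_class = 150, seed = 2)
  ms <- train_segnet(list(t1, t2), cfg, classes = 0:1)
  probe <- toy_tile(seed = 11)$tile
  p1 <- predict_probs(ms[[1]], probe)
  p2 <- predict_probs(ms[[2]], probe)
  s <- slide_image(probe, 1)
  ens <- predict_wsi(ms, s, window = 32, overlap = 8)
  expect_true(all(ens$probs <= pmax(p1, p2) + 1e-9))
})
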