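test_that("slide_image enforces pyramid invariants", {
  a <- toy_rgb(16, 12)
  s <- slide_image(a, spacing_um = 1.0)
  expect_equal(n_levels(s), 1)
  expect_equal(slide_dims(s), c(16L, 12L))
  expect_error(slide_image(a, spacing_um = 0), "positive")
  expect_error(slide_image(list(a, a), 1, downsamples = c(1, 0.5)),
               "non-decreasing")
  # level dims must match level-0 dims / downsample
  bad <- list(a, toy_rgb(5, 5))
  expect_error(slide_image(bad, 1, downsamples = c(1, 4)), "inconsistent")
})

test_that("build_pyramid level dims equal level-0 dims %/% factor", {
  a <- toy_rgb(64, 48)
  s <- build_pyramid(a, n_levels = 2, factor = 4, spacing_um = 0.25)
  expect_equal(slide_dims(s, 1), c(16L, 12L))
  expect_equal(s$downsamples, c(1, 4))
  expect_equal(spacing_at(s, 1), 1.0)
})

test_that("slide write/read round trip is pixel-identical at every level", {
  s <- build_pyramid(toy_rgb(32, 32), n_levels = 2, factor = 2)
  d <- withr::local_tempdir()
  # pyramid directory
  write_slide(s, file.path(d, "pyr"))
  s2 <- read_slide(file.path(d, "pyr"))
  expect_identical(s2$levels, s$levels)
  expect_equal(s2$downsamples, s$downsamples)
  # single level PNG + sidecar
  one <- slide_image(toy_rgb(20, 20, seed = 3), 2.0)
  write_slide(one, file.path(d, "one.png"))
  r <- read_slide(file.path(d, "one.png"))
  expect_identical(r$levels[[1]], one$levels[[1]])
  expect_equal(r$spacing_um, 2.0)
})

test_that("read_slide demands a spacing when none is recorded", {
  d <- withr::local_tempdir()
  write_png(toy_rgb(8, 8), file.path(d, "raw.png"))
  expect_error(read_slide(file.path(d, "raw.png")), "spacing")
  s <- read_slide(file.path(d, "raw.png"), spacing_um = 0.25)
  expect_equal(s$spacing_um, 0.25)
  expect_error(read_slide(file.path(d, "nothere.png")), "no such file")
})

test_that("read_region obeys the half-open window and white padding rules", {
  a <- toy_rgb(4, 4)
  s <- slide_image(a, 1)
  expect_identical(read_region(s, 0, c(0, 0), c(4, 4)), s$levels[[1]])
  # fully outside -> all white
  expect_true(all(read_region(s, 0, c(10, 10), c(3, 3)) == 255L))
  # half outside: left half content, right half white (hand-composed)
  p <- read_region(s, 0, c(0, 2), c(4, 4))
  expect_identical(p[, 1:2, ], s$levels[[1]][, 3:4, ])
  expect_true(all(p[, 3:4, ] == 255L))
  expect_error(read_region(s, 0, c(0, 0), c(-1, 4)), "negative")
})

test_that("read_region tiling stitches back to the exact level raster", {
  a <- toy_rgb(10, 14, seed = 7)
  s <- slide_image(a, 1)
  out <- array(0L, dim(a))
  for (r0 in seq(0, 9, by = 5)) for (c0 in seq(0, 13, by = 7))
    out[(r0 + 1):(r0 + 5), (c0 + 1):(c0 + 7), ] <-
      read_region(s, 0, c(r0, c0), c(5, 7))
  expect_identical(out, s$levels[[1]])
})

test_that("polygons_to_mask rasterizes by the pixel-center rule", {
  s <- slide_image(array(255L, c(20, 20, 3)), 1)
  sq <- annotation_set(list(list(name = "a", role = "tumor_bulk",
                                 rings = list(square_ring(0, 0, 9, 9)))))
  m <- polygons_to_mask(sq, s, 0)
  expect_equal(sum(m$data), 100)
  expect_true(all(m$data[1:10, 1:10] == 1L))
  # two disjoint squares sum their areas
  two <- annotation_set(list(
    list(name = "a", role = "roi", rings = list(square_ring(0, 0, 3, 3))),
    list(name = "b", role = "roi", rings = list(square_ring(10, 10, 14, 14)))))
  expect_equal(sum(polygons_to_mask(two, s, 0)$data), 16 + 25)
  # role filter; empty selection is an all-zero mask, not an error
  expect_equal(sum(polygons_to_mask(two, s, 0, roles = "tumor_bulk")$data), 0)
})

test_that("triangle rasterization matches the brute-force oracle", {
  s <- slide_image(array(255L, c(20, 20, 3)), 1)
  tri <- cbind(x = c(2.3, 17.2, 9.1), y = c(3.1, 5.7, 18.4))
  ann <- annotation_set(list(list(name = "t", role = "roi", rings = list(tri))))
  m <- polygons_to_mask(ann, s, 0)
  oracle <- matrix(0L, 20, 20)
  for (r in 0:19) for (c in 0:19)
    oracle[r + 1, c + 1] <- as.integer(pip_oracle(c + 0.5, r + 0.5, tri))
  expect_identical(m$data, oracle)
})

test_that("polygon scaling respects the level downsample", {
  s <- build_pyramid(toy_rgb(40, 40), n_levels = 2, factor = 4)
  sq <- annotation_set(list(list(name = "a", role = "roi",
                                 rings = list(square_ring(0, 0, 19, 19)))))
  m1 <- polygons_to_mask(sq, s, 1)
  expect_equal(sum(m1$data), 25)  # 20x20 level-0 px -> 5x5 at downsample 4
})

test_that("mask -> polygon -> mask round trips exactly for rectangles", {
  m <- matrix(0L, 15, 17)
  m[3:8, 4:11] <- 1L
  m[12:14, 1:2] <- 1L
  rings <- mask_to_polygons(m)
  expect_equal(length(rings), 2)
  s <- slide_image(array(255L, c(15, 17, 3)), 1)
  ann <- annotation_set(lapply(seq_along(rings), function(i)
    list(name = paste0("r", i), role = "other", rings = rings[i])))
  expect_identical(polygons_to_mask(ann, s, 0)$data, m)
})

test_that("annotation GeoJSON round trips and closes rings on write", {
  d <- withr::local_tempdir()
  ann <- annotation_set(list(
    list(name = "bulk", role = "tumor_bulk",
         rings = list(square_ring(1, 1, 6, 6))),
    list(name = "roi1", role = "roi", rings = list(square_ring(0, 0, 2, 2)))))
  f <- file.path(d, "ann.geojson")
  write_annotations(ann, f)
  j <- jsonlite::read_json(f, simplifyVector = FALSE)
  cr <- j$features[[1]]$geometry$coordinates[[1]]
  expect_identical(cr[[1]], cr[[length(cr)]])  # explicitly closed
  back <- read_annotations(f)
  expect_equal(back$features[[1]]$rings[[1]], ann$features[[1]]$rings[[1]],
               ignore_attr = TRUE)
  expect_equal(back$features[[2]]$role, "roi")
})

test_that("annotation_set rejects degenerate rings", {
  expect_error(annotation_set(list(list(name = "x", role = "roi",
    rings = list(cbind(c(0, 1), c(0, 1)))))), "3 vertices")
  expect_error(annotation_set(list(list(name = "x", role = "roi",
    rings = list(cbind(c(0, 1, 2), c(0, 1, 2)))))), "zero-area")
  expect_error(annotation_set(list(list(name = "x", role = "wrong",
    rings = list(square_ring(0, 0, 2, 2))))), "unknown role")
})

test_that("label masks validate codes and round trip through PNG + sidecar", {
  d <- withr::local_tempdir()
  m <- label_mask(matrix(c(0L, 1L, 2L, 1L), 2), 0.5,
                  classes = c(background = 0L, stroma = 1L, epi = 2L))
  f <- file.path(d, "m.png")
  write_mask(m, f)
  back <- read_mask(f)
  expect_identical(back$data, m$data)
  expect_equal(back$spacing_um, 0.5)
  expect_equal(back$classes, m$classes)
  expect_error(label_mask(matrix(5L, 2, 2), 1), "absent from the class table")
})

test_that("read_clinical applies the vital-status rule and validates", {
  d <- withr::local_tempdir()
  f <- file.path(d, "clin.csv")
  df <- data.frame(patient_id = c("P1", "P2"), age = c(70, 61),
                   gender = c("male", NA),
                   vital_status = c("dead", "alive"),
                   days_to_death = c(120, NA),
                   days_to_last_follow_up = c(NA, 400))
  write.csv(df, f, row.names = FALSE)
  r <- read_clinical(f)
  expect_equal(r$survival_days, c(120L, 400L))
  expect_equal(r$event, c(1L, 0L))
  expect_equal(r$gender[2], "unknown")
  # duplicate id errors
  df2 <- df; df2$patient_id <- c("P1", "P1")
  write.csv(df2, f, row.names = FALSE)
  expect_error(read_clinical(f), "duplicate")
  # negative days error
  df3 <- df; df3$days_to_death[1] <- -5
  write.csv(df3, f, row.names = FALSE)
  expect_error(read_clinical(f), "negative")
})
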