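test_that("select_slide keeps the highest-TSR slide with lexicographic ties", {
  df <- data.frame(
    patient_id = c("P1", "P2", "P2", "P3", "P3"),
    slide_id = c("s1", "s2b", "s2a", "s3b", "s3a"),
    tsr = c(0.4, 0.9, 0.4, 0.5, 0.5))
  out <- select_slide(df)
  expect_equal(out$tsr[out$patient_id == "P1"], 0.4)
  expect_equal(out$tsr[out$patient_id == "P2"], 0.9)
  expect_equal(out$slide_id[out$patient_id == "P2"], "s2b")
  # tie 0.5/0.5 -> lexicographically first slide id, flagged
  expect_equal(out$slide_id[out$patient_id == "P3"], "s3a")
  expect_true(out$tie[out$patient_id == "P3"])
})

test_that("horizon labels follow the censoring rule", {
  rec <- data.frame(
    patient_id = c("A", "B", "C", "D"),
    vital_status = c("dead", "alive", "alive", "dead"),
    survival_days = c(100L, 400L, 90L, 400L))
  lab <- make_horizon_labels(rec, 6)
  expect_equal(lab$horizon_days[1], round(30.44 * 6))
  expect_equal(lab$label, c(1L, 0L, NA_integer_, 0L))
  # censored-as-alive switch changes exactly the excluded group
  lab2 <- make_horizon_labels(rec, 6, censored_as_alive = TRUE)
  expect_equal(lab2$label, c(1L, 0L, 0L, 0L))
  changed <- which(!identical(lab$label, lab2$label))
  expect_equal(which(is.na(lab$label)), 3L)
  # all excluded -> error
  allc <- data.frame(patient_id = "X", vital_status = "alive",
                     survival_days = 10L)
  expect_error(make_horizon_labels(allc, 6), "excluded")
})

test_that("cv_auc is 1 for a perfectly separating feature", {
  set.seed(61)
  n <- 100
  d <- data.frame(label = rep(0:1, each = n / 2),
                  tsr = c(runif(n / 2, 0, 0.4), runif(n / 2, 0.6, 1)),
                  age = rnorm(n, 65, 8),
                  gender = sample(c("m", "f"), n, TRUE))
  r <- cv_auc(d, k = 5, seed = 2)
  expect_true(all(r$fold_auc == 1))
  expect_equal(r$mean_auc, 1)
})

test_that("cv_auc stays near 0.5 when labels are independent of features", {
  set.seed(62)
  n <- 500
  d <- data.frame(label = rbinom(n, 1, 0.4),
                  tsr = runif(n), age = rnorm(n, 65, 8),
                  gender = sample(c("m", "f"), n, TRUE))
  r <- cv_auc(d, k = 5, seed = 3)
  expect_gte(r$mean_auc, 0.4)
  expect_lte(r$mean_auc, 0.6)
  expect_length(r$fold_auc, 5)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(63)
  y <- rbinom(80, 1, 0.5)
  s <- rnorm(80) + y
  a1 <- tsrquant:::auc_score(s, y)
  a2 <- tsrquant:::auc_score(exp(2 * s + 1), y)
  expect_equal(a1, a2)
})

test_that("km_estimate matches hand-computed product-limit values", {
  # no censoring, deaths at 1,2,3,4
  k1 <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1), rep("g", 4))
  expect_equal(k1$curves$g$surv, c(0.75, 0.5, 0.25, 0))
  # censored toy: times {6,6,6,7,10}, events {1,1,0,1,0};
  # at t=7 the risk set is {7, 10} (the subject censored at 6 has left),
  # so S(7) = 0.6 * (1 - 1/2) = 0.3
  k2 <- km_estimate(c(6, 6, 6, 7, 10), c(1, 1, 0, 1, 0), rep("g", 5))
  s6 <- k2$curves$g$surv[k2$curves$g$time == 6]
  s7 <- k2$curves$g$surv[k2$curves$g$time == 7]
  expect_equal(s6, 0.6)
  expect_equal(s7, 0.3)
  # survival curve invariants
  expect_true(all(diff(k2$curves$g$surv) <= 0))
  expect_true(all(k2$curves$g$surv >= 0 & k2$curves$g$surv <= 1))
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(64)
  t <- sample(1:50, 30, replace = TRUE)
  k <- km_estimate(t, rep(1, 30), rep("g", 30))
  emp <- vapply(k$curves$g$time, function(u) mean(t > u), numeric(1))
  expect_equal(k$curves$g$surv, emp, tolerance = 1e-12)
})

test_that("identical groups give log-rank chi-square 0 and p = 1", {
  t <- c(5, 10, 15, 20, 25, 5, 10, 15, 20, 25)
  e <- rep(1, 10)
  g <- rep(c("a", "b"), each = 5)
  k <- km_estimate(t, e, g)
  expect_equal(k$chisq, 0, tolerance = 1e-12)
  expect_equal(k$p_value, 1, tolerance = 1e-12)
  expect_error(km_estimate(t, e, factor(g, levels = c("a", "b", "c"))[1:10]),
               NA)  # unused level dropped, no error
})

test_that("tsr_km stratifies at the cohort mean and logs the threshold", {
  set.seed(65)
  d <- data.frame(tsr = runif(40), survival_days = sample(50:500, 40),
                  event = rbinom(40, 1, 0.7))
  k <- tsr_km(d)
  expect_equal(k$threshold, mean(d$tsr))
  expect_named(k$curves, c("high_tsr", "low_tsr"))
  expect_error(tsr_km(data.frame(tsr = rep(0.5, 4),
                                 survival_days = 1:4, event = rep(1, 4))),
               "split")
})
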