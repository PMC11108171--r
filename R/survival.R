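# Survival analysis: horizon classification (logistic regression on TSR +
# clinical covariates with five-fold cross-validated AUC) and Kaplan-Meier
# stratification at the cohort-mean TSR.

DAYS_PER_MONTH <- 30.44  # month -> day conversion used for all horizons

#' Select one TSR per patient (highest-TSR slide)
#'
#' @param reports data.frame with columns `patient_id`, `slide_id`, `tsr`
#'   (one row per slide), or a list of `TSRReport`s plus a `patient_id`
#'   mapping in `patients`.
#' @param patients optional character vector mapping report slides to
#'   patients when `reports` is a list.
#' @return data.frame `patient_id`, `slide_id`, `tsr`, one row per patient;
#'   ties broken by lexicographic slide id (recorded in the `tie` column).
#' @export
select_slide <- function(reports, patients = NULL) {
  if (!is.data.frame(reports)) {
    reports <- do.call(rbind, lapply(reports, tsr_report_row))
    reports$patient_id <- patients
  }
  stopifnot(all(c("patient_id", "slide_id", "tsr") %in% names(reports)))
  out <- do.call(rbind, lapply(split(reports, reports$patient_id), function(d) {
    best <- d$tsr == max(d$tsr)
    tie <- sum(best) > 1
    d <- d[best, , drop = FALSE]
    d <- d[order(d$slide_id), , drop = FALSE][1, , drop = FALSE]
    d$tie <- tie
    d[, c("patient_id", "slide_id", "tsr", "tie")]
  }))
  rownames(out) <- NULL
  out
}

#' Build horizon-classification labels from clinical records
#'
#' Label 1: dead with survival_days <= horizon; label 0: survived past the
#' horizon (dead later, or alive with follow-up beyond it); patients
#' censored (alive) at or before the horizon carry no information about it
#' and are excluded (`NA`) unless `censored_as_alive` is set.
#'
#' @param records clinical data.frame ([read_clinical()] layout: needs
#'   `vital_status`, `survival_days`).
#' @param horizon_months horizon in months; days = round(30.44 x months).
#' @param censored_as_alive label censored-before-horizon patients 0
#'   instead of excluding them (default FALSE).
#' @return the input data.frame with `horizon_days` and `label` (0/1/NA)
#'   columns appended; errors if every patient is excluded.
#' @export
make_horizon_labels <- function(records, horizon_months,
                                censored_as_alive = FALSE) {
  hd <- round(DAYS_PER_MONTH * horizon_months)
  dead <- records$vital_status == "dead"
  label <- ifelse(dead & records$survival_days <= hd, 1L,
                  ifelse(records$survival_days > hd, 0L, NA_integer_))
  if (censored_as_alive) label[is.na(label)] <- 0L
  if (all(is.na(label)))
    stop("make_horizon_labels: every patient is excluded at this horizon")
  records$horizon_days <- hd
  records$label <- label
  records
}

# one-hot encode categorical columns; numeric columns pass through
encode_features <- function(df, cols) {
  mats <- lapply(cols, function(cn) {
    v <- df[[cn]]
    if (is.numeric(v)) {
      m <- matrix(v, ncol = 1); colnames(m) <- cn; m
    } else {
      lv <- sort(unique(as.character(v)))
      if (length(lv) < 2) return(NULL)
      m <- vapply(lv[-1], function(l) as.numeric(v == l), numeric(length(v)))
      m <- matrix(m, nrow = length(v))
      colnames(m) <- paste0(cn, "_", lv[-1]); m
    }
  })
  do.call(cbind, Filter(Negate(is.null), mats))
}

# rank-statistic AUC (equals the Wilcoxon/Mann-Whitney estimator)
auc_score <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Cross-validated AUC of a ridge-logistic horizon classifier
#'
#' Stratified patient-level folds; per fold, feature standardization and the
#' model fit use the training patients only, and AUC is computed on the
#' held-out patients. Reported as per-fold values and mean +/- SD.
#'
#' @param data data.frame from [make_horizon_labels()] (rows with `NA`
#'   labels are dropped), including a `tsr` column.
#' @param features character vector of feature columns
#'   (default `c("tsr", "age", "gender")`); categoricals are one-hot encoded.
#' @param k number of folds (default 5).
#' @param seed RNG seed for the fold split.
#' @param lambda ridge penalty (default 0.01).
#' @return list: `fold_auc`, `mean_auc`, `sd_auc`, `roc` (pooled ROC points),
#'   `n`, `folds`.
#' @export
cv_auc <- function(data, features = c("tsr", "age", "gender"), k = 5,
                   seed = 1, lambda = 0.01) {
  data <- data[!is.na(data$label), , drop = FALSE]
  n <- nrow(data)
  if (length(unique(data$label)) < 2)
    stop("cv_auc: both classes must be present")
  X <- encode_features(data, features)
  y <- data$label
  # stratified fold assignment
  fold <- integer(n)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    perm <- with_seed(child_seed(seed, cl), sample(idx))
    fold[perm] <- rep_len(seq_len(k), length(idx))
  }
  scores <- rep(NA_real_, n)
  fold_auc <- vapply(seq_len(k), function(f) {
    tr <- fold != f; te <- !tr
    if (length(unique(y[tr])) < 2)
      stop("cv_auc: single-class training fold after stratification")
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- pmax(apply(X[tr, , drop = FALSE], 2, sd), 1e-8)
    Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
    fit <- glmnet::glmnet(Xs[tr, , drop = FALSE], y[tr], family = "binomial",
                          alpha = 0, lambda = lambda, standardize = FALSE)
    p <- as.numeric(predict(fit, Xs[te, , drop = FALSE], s = lambda,
                            type = "response"))
    scores[te] <<- p
    auc_score(p, y[te])
  }, numeric(1))
  ord <- order(scores, decreasing = TRUE)
  tpr <- cumsum(y[ord] == 1) / sum(y == 1)
  fpr <- cumsum(y[ord] == 0) / sum(y == 0)
  list(fold_auc = fold_auc, mean_auc = mean(fold_auc), sd_auc = sd(fold_auc),
       roc = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)),
       n = n, folds = fold)
}

#' Kaplan-Meier curves and log-rank test by group
#'
#' Product-limit estimator per group plus the two-group log-rank test
#' (via the survival package). Groups typically come from thresholding the
#' per-patient TSR at the cohort mean.
#'
#' @param times nonnegative survival/censoring times.
#' @param events event indicators (1 = death observed).
#' @param groups group labels (factor/character/logical).
#' @return list: `curves` (one data.frame per group: `time`, `n_risk`,
#'   `n_event`, `surv`), `chisq`, `p_value`, `threshold` (attribute slot
#'   filled by [tsr_km()]).
#' @export
km_estimate <- function(times, events, groups) {
  stopifnot(all(times >= 0), length(times) == length(events),
            length(times) == length(groups))
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 1 || !length(times))
    stop("km_estimate: empty group")
  curves <- lapply(levels(groups), function(g) {
    sel <- groups == g
    fit <- survival::survfit(survival::Surv(times[sel], events[sel]) ~ 1)
    data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
               surv = fit$surv)
  })
  names(curves) <- levels(groups)
  out <- list(curves = curves, chisq = NA_real_, p_value = NA_real_)
  if (nlevels(groups) >= 2) {
    sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
    out$chisq <- sd$chisq
    out$p_value <- pchisq(sd$chisq, df = nlevels(groups) - 1, lower.tail = FALSE)
  }
  out
}

#' TSR-stratified Kaplan-Meier analysis
#'
#' Splits patients into high/low TSR at the cohort mean (the threshold is
#' returned) and runs [km_estimate()].
#'
#' @param data data.frame with `tsr`, `survival_days`, `event`.
#' @param threshold TSR threshold; default the cohort mean.
#' @export
tsr_km <- function(data, threshold = NULL) {
  threshold <- threshold %||% mean(data$tsr)
  grp <- ifelse(data$tsr > threshold, "high_tsr", "low_tsr")
  if (length(unique(grp)) < 2)
    stop("tsr_km: threshold does not split the cohort")
  out <- km_estimate(data$survival_days, data$event, grp)
  out$threshold <- threshold
  out
}
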