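# Horizon-prediction protocol: balance cases and controls by
# down-sampling, split 80/20 stratified by case status, compute each test
# subject's event probability over the horizon from the fitted NHPP,
# classify by threshold and summarize discrimination with ROC/AUC.

#' Down-sample controls to balance cases
#'
#' Keeps every case and samples, uniformly without replacement, exactly
#' as many controls; the common remedy for a rare-event case-control
#' imbalance before supervised evaluation.
#'
#' @param labels named logical (or 0/1) vector: `TRUE` = case (had at
#'   least one event).
#' @param seed integer seed.
#' @return character vector of retained subject ids (all cases plus the
#'   sampled controls).
#' @export
downsample_balance <- function(labels, seed = NULL) {
  stopifnot(!is.null(names(labels)))
  labels <- stats::setNames(as.logical(labels), names(labels))
  cases <- names(labels)[labels]
  controls <- names(labels)[!labels]
  if (length(cases) < 1L) stop("need at least one case")
  if (length(controls) < length(cases))
    stop(sprintf("fewer controls (%d) than cases (%d): cannot balance by down-sampling",
                 length(controls), length(cases)))
  if (!is.null(seed)) set.seed(seed)
  c(cases, sample(controls, length(cases)))
}

#' Stratified train/test split
#'
#' Per case/control group, `floor(train_frac * n_group)` subjects go to
#' the training set and the rest to the test set; the split is seeded,
#' disjoint and exhaustive.
#'
#' @param labels named logical (or 0/1) vector over the balanced set.
#' @param train_frac fraction in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return list with character vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_frac = 0.8, seed = NULL) {
  stopifnot(!is.null(names(labels)), train_frac > 0, train_frac < 1)
  labels <- stats::setNames(as.logical(labels), names(labels))
  if (!is.null(seed)) set.seed(seed)
  train <- character(0)
  for (g in c(TRUE, FALSE)) {
    ids <- names(labels)[labels == g]
    if (length(ids) == 0L) stop("empty case or control group")
    train <- c(train, sample(ids, floor(train_frac * length(ids))))
  }
  list(train = train, test = setdiff(names(labels), train))
}

#' Probability of an event within a horizon
#'
#' `p = 1 - exp(-[Lambda(s + h | x) - Lambda(s | x)])`: the probability
#' of at least one event in the `h` weeks after the prediction start
#' `s` (the first date with complete covariates, on the subject's week
#' axis).
#'
#' @param fit an `nhpp_fit` (or [nhpp_params()]).
#' @param x covariate vector (or `NULL`).
#' @param s prediction start, weeks, >= 0.
#' @param h horizon, weeks, > 0 (26 / 52 / 104 for six months, one year,
#'   two years).
#' @return probability in \[0, 1\].
#' @export
event_probability <- function(fit, x = NULL, s, h) {
  params <- if (inherits(fit, "nhpp_fit")) fit$params else fit
  stopifnot(inherits(params, "nhpp_params"), s >= 0, h > 0)
  1 - exp(-(cumulative_intensity(s + h, x, params) - cumulative_intensity(s, x, params)))
}

#' Observed horizon labels from event windows
#'
#' A subject is labeled positive when at least one event falls in
#' `(s, s + h]` within their window. When the window ends before `s + h`
#' the default labels by the events observed up to window end;
#' `censoring = "exclude"` returns `NA` for those subjects instead.
#'
#' @param windows an [event_windows()].
#' @param s per-subject prediction starts (recycled if scalar), weeks.
#' @param h horizon, weeks.
#' @param censoring `"label_observed"` (default) or `"exclude"`.
#' @return named logical vector (with `NA` for excluded subjects).
#' @export
horizon_labels <- function(windows, s, h, censoring = c("label_observed", "exclude")) {
  censoring <- match.arg(censoring)
  stopifnot(inherits(windows, "event_windows"))
  n <- length(windows$subject_id)
  s <- rep_len(s, n)
  idx <- match(windows$events$subject_id, windows$subject_id)
  hit <- windows$events$t > s[idx] & windows$events$t <= s[idx] + h
  lab <- stats::setNames(rep(FALSE, n), windows$subject_id)
  lab[unique(idx[hit])] <- TRUE
  if (censoring == "exclude") lab[windows$R < s + h & !lab] <- NA
  lab
}

#' Threshold classification summary
#'
#' Predicted positive iff `p > threshold`; returns the confusion counts
#' and the derived rates.
#'
#' @param predictions data frame with columns `p` (probabilities) and
#'   `observed` (logical labels).
#' @param threshold probability threshold in \[0, 1\].
#' @return list with `predicted` (logical), `TP`, `FP`, `TN`, `FN`,
#'   `sensitivity`, `specificity`, `fnr`.
#' @export
classify <- function(predictions, threshold) {
  stopifnot(threshold >= 0, threshold <= 1,
            all(c("p", "observed") %in% names(predictions)))
  pred <- predictions$p > threshold
  obs <- as.logical(predictions$observed)
  TP <- sum(pred & obs); FP <- sum(pred & !obs)
  TN <- sum(!pred & !obs); FN <- sum(!pred & obs)
  list(predicted = pred, TP = TP, FP = FP, TN = TN, FN = FN,
       sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
       specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
       fnr = if (TP + FN > 0) FN / (TP + FN) else NA_real_)
}

#' ROC curve and AUC
#'
#' Sweeps every distinct predicted probability (plus 0/1 sentinels) as a
#' threshold and computes the AUC by the Mann-Whitney rank statistic
#' (ties counted half), which equals the trapezoidal area under the
#' swept curve.
#'
#' @param labels logical (or 0/1) vector; both values must occur.
#' @param probabilities predicted probabilities, same length.
#' @return list with `roc` (data frame: `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(labels, probabilities) {
  labels <- as.logical(labels)
  stopifnot(length(labels) == length(probabilities))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both label values must be present")
  r <- rank(probabilities)  # average ranks: ties counted half
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # sweep from strictest to laxest; ">= threshold" so the curve reaches (1, 1)
  thr <- c(Inf, sort(unique(c(0, 1, probabilities)), decreasing = TRUE))
  tpr <- vapply(thr, function(ct) sum(labels & probabilities >= ct) / n1, numeric(1))
  fpr <- vapply(thr, function(ct) sum(!labels & probabilities >= ct) / n0, numeric(1))
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}
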