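# Descriptive outputs: class-wise baseline tables, coincidence matrices
# between two labelings, and long-format curve exports (trajectories,
# survival).

#' Coincidence matrix between two labelings
#'
#' Entry (a, b) is the fraction of subjects with label `a` in the first
#' labeling that carry label `b` in the second, over the subjects present
#' in both; rows sum to 1. Subjects present in only one labeling are
#' dropped with a count warning.
#'
#' @param labels_a,labels_b named vectors of class labels (rows are the
#'   classes of `labels_a`).
#' @return matrix of row-normalized coincidence rates, with a
#'   `counts` attribute holding the raw contingency table.
#' @export
coincidence_matrix <- function(labels_a, labels_b) {
  stopifnot(!is.null(names(labels_a)), !is.null(names(labels_b)))
  shared <- intersect(names(labels_a), names(labels_b))
  if (length(shared) == 0L) stop("the two labelings share no subjects")
  dropped <- length(labels_a) + length(labels_b) - 2L * length(shared)
  if (dropped > 0L)
    warning(sprintf("%d subject(s) present in only one labeling dropped", dropped))
  tab <- table(A = labels_a[shared], B = labels_b[shared])
  mat <- sweep(unclass(tab), 1, rowSums(tab), "/")
  attr(mat, "counts") <- unclass(tab)
  mat
}

#' Class-wise baseline characteristics table
#'
#' One row per class: size and share, mean +- SD of age at diagnosis and
#' of baseline HbA1c (each subject's first measurement), percentage male,
#' ethnicity percentages, prior-complication and medication percentages,
#' mean measurement count and mean observation period (last measurement
#' time, weeks).
#'
#' @param cohort a [cohort()].
#' @param labels named vector of class labels covering the cohort.
#' @return data frame, one row per class (empty classes give `n = 0`
#'   rows with `NA` summaries).
#' @export
baseline_table <- function(cohort, labels) {
  stopifnot(inherits(cohort, "cohort"))
  sub <- cohort$subjects
  if (!all(sub$subject_id %in% names(labels)))
    stop("labels must cover every subject in the cohort")
  lab <- labels[sub$subject_id]
  mea <- cohort$measurements
  first_idx <- !duplicated(mea$subject_id)
  base_h <- stats::setNames(mea$hba1c[first_idx], mea$subject_id[first_idx])
  n_meas <- table(mea$subject_id)
  obs_per <- tapply(mea$t_weeks, mea$subject_id, max)
  classes <- sort(unique(lab))
  msd <- function(x) if (length(x)) sprintf("%.2f (%.2f)", mean(x, na.rm = TRUE),
                                            stats::sd(x, na.rm = TRUE)) else NA_character_
  pct <- function(x) if (length(x)) 100 * mean(x, na.rm = TRUE) else NA_real_
  rows <- lapply(classes, function(cl) {
    s <- sub[lab == cl, , drop = FALSE]
    ids <- s$subject_id
    out <- data.frame(class = cl, n = nrow(s), pct = 100 * nrow(s) / nrow(sub),
                      age = msd(s$age_at_ddd),
                      baseline_hba1c = msd(base_h[ids]),
                      male_pct = pct(s$sex == "male"))
    for (e in c("Chinese", "Malay", "Indian", "Other"))
      out[[paste0(tolower(e), "_pct")]] <- pct(s$ethnicity == e)
    for (f in paste0("prior_", PRIOR_FLAGS))
      if (f %in% names(s)) out[[paste0(f, "_pct")]] <- pct(s[[f]] == 1)
    for (f in paste0("med_", MED_FLAGS))
      if (f %in% names(s)) out[[paste0(f, "_pct")]] <- pct(s[[f]] == 1)
    out$mean_n_measurements <- if (nrow(s)) mean(n_meas[ids]) else NA_real_
    out$mean_obs_period_weeks <- if (nrow(s)) mean(obs_per[ids]) else NA_real_
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Export fitted curves as long-format CSV
#'
#' For an `lcgm_fit`, writes the class mean trajectories on `grid`; for a
#' named list of survival curves (as returned by
#' [mean_survival_curve()]), writes them stacked. Output columns:
#' `class`, `t_weeks`, `value`.
#'
#' @param object an `lcgm_fit` or a named list of data frames with
#'   columns `t_weeks` and `surv`.
#' @param grid evaluation times (weeks); used for `lcgm_fit` input.
#' @param out_path CSV path.
#' @return the exported data frame, invisibly.
#' @export
export_curves <- function(object, grid = NULL, out_path) {
  if (inherits(object, "lcgm_fit")) {
    stopifnot(!is.null(grid))
    df <- do.call(rbind, lapply(seq_len(object$K), function(k)
      data.frame(class = k, t_weeks = grid,
                 value = predict_trajectory(object, k, grid))))
  } else if (is.list(object)) {
    stopifnot(!is.null(names(object)))
    df <- do.call(rbind, lapply(names(object), function(nm)
      data.frame(class = nm, t_weeks = object[[nm]]$t_weeks,
                 value = object[[nm]]$surv)))
  } else stop("unsupported object for curve export")
  utils::write.csv(df, out_path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
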