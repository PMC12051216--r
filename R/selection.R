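# Iterative joint selection of knot count, knot-placement strategy and
# number of latent classes: alternate (a) BIC over the knot grid at fixed
# K with (b) cross-validated BIC over K at fixed knots, until the triple
# is stable.

#' Subset a cohort by subject id
#'
#' @param x a [cohort()].
#' @param ids subject ids to keep.
#' @return a [cohort()] restricted to `ids`.
#' @export
subset_cohort <- function(x, ids) {
  stopifnot(inherits(x, "cohort"))
  ev <- if (!is.null(x$events)) x$events[x$events$subject_id %in% ids, , drop = FALSE]
  cohort(x$subjects[x$subjects$subject_id %in% ids, , drop = FALSE],
         x$measurements[x$measurements$subject_id %in% ids, , drop = FALSE],
         ev, study_span = x$study_span)
}

#' Marginal mixture log-likelihood of a cohort under a fitted LCGM
#'
#' Sum over subjects of the log mixture density — the held-out likelihood
#' used by the cross-validated selection score.
#'
#' @param fit an `lcgm_fit`.
#' @param cohort a [cohort()].
#' @return scalar log-likelihood.
#' @export
lcgm_loglik <- function(fit, cohort) {
  stopifnot(inherits(fit, "lcgm_fit"))
  dat <- .lcgm_data(cohort, fit$spec)
  .estep(.marg_ll_matrix(dat, fit$beta, fit$sigma_b, fit$sigma_e), fit$pi)$loglik
}

#' Select the number and placement of interior knots at fixed K
#'
#' Fits the LCGM for every (knot count, strategy) pair and returns the
#' BIC argmin; ties go to the smaller knot count, then to equidistant
#' placement (parsimony first).
#'
#' @param cohort a [cohort()].
#' @param K number of classes, held fixed.
#' @param candidates interior knot counts (default 5, 10, ..., 40).
#' @param strategies placement strategies to compare.
#' @param n_starts,seed passed to [fit_lcgm()].
#' @return list with `n_interior`, `strategy`, and `bic_table`
#'   (one row per pair; `NA` BIC for failed fits).
#' @export
select_knots <- function(cohort, K, candidates = seq(5L, 40L, by = 5L),
                         strategies = c("equidistant", "equipotent"),
                         n_starts = 2L, seed = NULL) {
  stopifnot(length(candidates) >= 1L)
  times <- cohort$measurements$t_weeks
  grid <- expand.grid(n_interior = sort(candidates), strategy = strategies,
                      stringsAsFactors = FALSE)
  # candidate order encodes the tie-break: smaller n first, equidistant first
  grid <- grid[order(grid$n_interior, match(grid$strategy, c("equidistant", "equipotent"))), ]
  grid$bic <- NA_real_
  for (r in seq_len(nrow(grid))) {
    fit <- tryCatch({
      sp <- basis_spec(times, grid$n_interior[r], grid$strategy[r])
      fit_lcgm(cohort, K, sp, n_starts = n_starts, seed = seed)
    }, error = function(e) NULL)
    if (!is.null(fit)) grid$bic[r] <- bic(fit)
  }
  if (all(is.na(grid$bic))) stop("knot selection failed: every candidate fit was degenerate")
  best <- which.min(grid$bic)  # first minimum = tie-break order
  rownames(grid) <- NULL
  list(n_interior = grid$n_interior[best], strategy = grid$strategy[best],
       bic_table = grid)
}

#' Cross-validated BIC for a class count
#'
#' Subject-level `n_folds`-fold cross-validation: fit on the training
#' folds, score the held-out fold. The default score is a held-out BIC,
#' `-2 (held-out marginal loglik) + n_params log(n_heldout)`; since
#' `n_params` is constant across folds the ranking over K is driven by
#' the held-out log-likelihood term (`cv_score = "loglik"` drops the
#' penalty entirely). Training-fold fits are warm-started from a
#' full-data fit to cut cost.
#'
#' @param cohort a [cohort()].
#' @param K number of classes.
#' @param spec a [basis_spec()].
#' @param n_folds number of folds (>= 2).
#' @param seed integer seed (fold assignment and fits).
#' @param n_starts EM starts for the full-data warm-start fit.
#' @param cv_score `"bic"` (default) or `"loglik"`.
#' @return mean held-out score across folds (lower is better).
#' @export
cv_bic <- function(cohort, K, spec, n_folds = 10L, seed = NULL, n_starts = 2L,
                   cv_score = c("bic", "loglik")) {
  cv_score <- match.arg(cv_score)
  stopifnot(n_folds >= 2L)
  ids <- cohort$subjects$subject_id
  n <- length(ids)
  if (!is.null(seed)) set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), n))
  if (min(tabulate(fold, n_folds)) < K)
    stop("a fold has fewer subjects than classes; reduce n_folds or K")
  full <- fit_lcgm(cohort, K, spec, n_starts = n_starts, seed = seed)
  scores <- vapply(seq_len(n_folds), function(f) {
    train <- subset_cohort(cohort, ids[fold != f])
    test <- subset_cohort(cohort, ids[fold == f])
    fit <- fit_lcgm(train, K, spec, n_starts = 1L, seed = seed, init = full)
    ll <- lcgm_loglik(fit, test)
    if (cv_score == "bic") -2 * ll + fit$n_params * log(n_subjects(test)) else -2 * ll
  }, numeric(1))
  mean(scores)
}

#' Select the number of latent classes
#'
#' Argmin over `K_range` of the cross-validated BIC (or, with
#' `use_cv = FALSE`, the in-sample BIC); ties go to the smaller K. A K
#' whose fit fails is excluded with a warning.
#'
#' @param cohort a [cohort()].
#' @param spec a [basis_spec()].
#' @param K_range candidate class counts (default 1..10).
#' @param n_folds folds for [cv_bic()].
#' @param seed integer seed.
#' @param n_starts EM starts per fit.
#' @param use_cv cross-validate (default) or use single-fit BIC.
#' @return list with `K` and `cv_table` (K, score per candidate).
#' @export
select_num_classes <- function(cohort, spec, K_range = 1:10, n_folds = 10L,
                               seed = NULL, n_starts = 2L, use_cv = TRUE) {
  stopifnot(length(K_range) >= 1L)
  K_range <- sort(K_range)
  score <- vapply(K_range, function(K) {
    tryCatch({
      if (use_cv) cv_bic(cohort, K, spec, n_folds = n_folds, seed = seed,
                         n_starts = n_starts)
      else bic(fit_lcgm(cohort, K, spec, n_starts = n_starts, seed = seed))
    }, error = function(e) {
      warning(sprintf("K = %d excluded: %s", K, conditionMessage(e)))
      NA_real_
    })
  }, numeric(1))
  if (all(is.na(score))) stop("class-number selection failed for every K")
  tab <- data.frame(K = K_range, score = score)
  list(K = K_range[which.min(score)], cv_table = tab)
}

#' Iterative knot / class-count selection
#'
#' Alternates [select_knots()] at the current class count with
#' [select_num_classes()] at the current knot placement, starting from
#' `K0`, until the (K, knot count, strategy) triple repeats or
#' `max_rounds` is reached.
#'
#' @param cohort a [cohort()].
#' @param K0 initial class count (3 is the conventional coarse
#'   low/moderate/high split of HbA1c levels).
#' @param candidates knot-count grid.
#' @param strategies placement strategies.
#' @param K_range candidate class counts.
#' @param n_folds folds for the class-count step.
#' @param seed integer seed.
#' @param max_rounds maximum alternation rounds.
#' @param n_starts EM starts per fit.
#' @param use_cv cross-validate the class-count step?
#' @return object of class `selection_result`: `chosen_K`,
#'   `chosen_n_interior`, `chosen_strategy`, `stable`, and `trace` (one
#'   entry per round with the BIC tables).
#' @export
iterate_selection <- function(cohort, K0 = 3L, candidates = seq(5L, 40L, by = 5L),
                              strategies = c("equidistant", "equipotent"),
                              K_range = 1:10, n_folds = 10L, seed = NULL,
                              max_rounds = 5L, n_starts = 2L, use_cv = TRUE) {
  stopifnot(K0 %in% K_range)
  K <- K0; trace <- list(); seen <- character(0); stable <- FALSE
  n_int <- NA; strat <- NA
  for (round in seq_len(max_rounds)) {
    ks <- select_knots(cohort, K, candidates, strategies, n_starts = n_starts, seed = seed)
    n_int <- ks$n_interior; strat <- ks$strategy
    sp <- basis_spec(cohort$measurements$t_weeks, n_int, strat)
    kc <- select_num_classes(cohort, sp, K_range, n_folds = n_folds, seed = seed,
                             n_starts = n_starts, use_cv = use_cv)
    K <- kc$K
    trace[[round]] <- list(round = round, K = K, n_interior = n_int,
                           strategy = strat, knot_bic = ks$bic_table,
                           class_score = kc$cv_table)
    key <- paste(K, n_int, strat)
    if (key %in% seen) { stable <- TRUE; break }
    seen <- c(seen, key)
  }
  structure(list(chosen_K = K, chosen_n_interior = n_int, chosen_strategy = strat,
                 stable = stable, trace = trace),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection: K = %d, %d interior knots (%s), %s after %d round(s)\n",
              x$chosen_K, x$chosen_n_interior, x$chosen_strategy,
              if (x$stable) "stable" else "NOT stable", length(x$trace)))
  invisible(x)
}
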