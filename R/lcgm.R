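# Latent class growth model: finite mixture over K classes, each with a
# B-spline mean trajectory B(t) beta_k, a class-specific random intercept
# b_i ~ N(0, sigma_b_k^2) and shared residual noise N(0, sigma_e^2).
# Marginally, subject i under class k is MVN with mean B_i beta_k and
# covariance sigma_b_k^2 J + sigma_e^2 I; the rank-1 structure gives
# O(n_i) likelihood evaluations (Woodbury / matrix determinant lemma).

# Per-subject sufficient statistics for the compound-symmetric marginal
# likelihood and the EM updates: Gram matrices G_i = B_i'B_i (stored as
# n x m^2 rows), B_i'y_i, B_i'1, y_i'y_i, 1'y_i and n_i. Every EM
# iteration then costs O(n m^2) regardless of the number of observations.
.suff_stats <- function(B, y, si, n, t = NULL) {
  m <- ncol(B)
  n_i <- tabulate(si, n)
  B1 <- rowsum(B, si, reorder = TRUE)
  By <- rowsum(B * y, si, reorder = TRUE)
  G <- matrix(0, n, m * m)
  for (j in seq_len(m)) {
    Gj <- rowsum(B * B[, j], si, reorder = TRUE)
    G[, ((j - 1) * m + 1):(j * m)] <- Gj
  }
  out <- list(n = n, m = m, n_i = n_i, B1 = B1, By = By, G = G,
              y1 = rowsum(y, si, reorder = TRUE)[, 1],
              yy = rowsum(y * y, si, reorder = TRUE)[, 1])
  if (!is.null(t)) {  # per-subject features for the k-means start:
    # binned trajectory profile (captures level and shape) + within-subject SD
    ybar <- out$y1 / n_i
    dy <- y - ybar[si]
    s2 <- rowsum(dy * dy, si, reorder = TRUE)[, 1] / pmax(n_i - 1, 1)
    nb <- 5L
    brk <- unique(stats::quantile(t, seq(0, 1, length.out = nb + 1)))
    bin <- if (length(brk) > 2) as.integer(cut(t, brk, include.lowest = TRUE))
           else rep(1L, length(t))
    nbins <- max(bin)
    prof <- matrix(NA_real_, n, nbins)
    sums <- rowsum(cbind(y, 1), si + n * (bin - 1), reorder = FALSE)
    idx <- as.integer(rownames(sums))
    prof[idx] <- sums[, 1] / sums[, 2]
    prof[is.na(prof)] <- ybar[row(prof)[is.na(prof)]]
    out$features <- cbind(prof, sd = sqrt(pmax(s2, 0)))
  }
  out
}

# flatten a cohort's measurements into per-subject sufficient statistics
.lcgm_data <- function(cohort, spec) {
  mea <- cohort$measurements
  ids <- unique(mea$subject_id)
  if (length(setdiff(cohort$subjects$subject_id, ids)))
    stop("every subject needs at least one measurement; missing: ",
         paste(utils::head(setdiff(cohort$subjects$subject_id, ids), 5), collapse = ", "))
  si <- match(mea$subject_id, ids)
  o <- order(si, mea$t_weeks)
  si <- si[o]
  dat <- .suff_stats(basis_matrix(mea$t_weeks[o], spec), mea$hba1c[o], si,
                     length(ids), t = mea$t_weeks[o])
  dat$ids <- ids
  dat$N <- nrow(mea)
  dat
}

# per-subject residual sums under class coefficients beta_k:
# S1_i = sum_j r_ij, S2_i = sum_j r_ij^2, from sufficient statistics
.resid_sums <- function(dat, beta_k) {
  S1 <- dat$y1 - drop(dat$B1 %*% beta_k)
  bb <- as.vector(tcrossprod(beta_k))
  S2 <- dat$yy - 2 * drop(dat$By %*% beta_k) + drop(dat$G %*% bb)
  list(S1 = S1, S2 = pmax(S2, 0))
}

# per-subject marginal log-density for every class; returns n x K matrix
.marg_ll_matrix <- function(dat, beta, sigma_b, sigma_e) {
  K <- ncol(beta)
  n_i <- dat$n_i
  ll <- matrix(0, dat$n, K)
  se2 <- sigma_e^2
  for (k in seq_len(K)) {
    rs <- .resid_sums(dat, beta[, k])
    sb2 <- sigma_b[k]^2
    denom <- se2 + n_i * sb2
    logdet <- (n_i - 1) * log(se2) + log(denom)
    quad <- rs$S2 / se2 - sb2 * rs$S1^2 / (se2 * denom)
    ll[, k] <- -0.5 * (n_i * log(2 * pi) + logdet + quad)
  }
  ll
}

#' Marginal log-likelihood of one series under one class
#'
#' Log-density of an HbA1c series under the class model: multivariate
#' normal with mean `B(t) beta_k` and covariance
#' `sigma_b_k^2 J + sigma_e^2 I` (`J` all-ones). Computed through the
#' rank-1 Woodbury identity, so cost is linear in the series length.
#'
#' @param series data frame (or list) with `t_weeks` and `hba1c`.
#' @param beta_k class coefficient vector, length `spec$m`.
#' @param sigma_b_k class random-intercept SD, >= 0.
#' @param sigma_e residual SD, > 0.
#' @param spec a [basis_spec()].
#' @return scalar log-likelihood.
#' @export
class_marginal_loglik <- function(series, beta_k, sigma_b_k, sigma_e, spec) {
  if (sigma_e <= 0) stop("sigma_e must be > 0")
  t <- series$t_weeks %||% series$times
  y <- series$hba1c %||% series$values
  stopifnot(length(t) == length(y), length(t) >= 1L)
  dat <- .suff_stats(basis_matrix(t, spec), y, rep(1L, length(y)), 1L)
  drop(.marg_ll_matrix(dat, matrix(beta_k, ncol = 1), sigma_b_k, sigma_e))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# responsibilities + total loglik from a class log-density matrix
.estep <- function(ll, pi) {
  lp <- sweep(ll, 2, log(pi), "+")
  mx <- apply(lp, 1, max)
  w <- exp(lp - mx)
  sw <- rowSums(w)
  list(tau = w / sw, loglik = sum(mx + log(sw)))
}

# Split-merge refinement (SMEM-style): EM for mixtures is prone to local
# optima that merge two true classes while splitting another. After the
# best start converges, propose moves that merge the two classes with the
# closest mean trajectories and re-split the class that explains its
# members worst (or has the largest intercept variance); accept a move
# when a short EM run from the proposal beats the current optimum.
.refine_sm <- function(dat, K, best, tol, max_rounds = 3L) {
  if (K < 3L) return(best)
  Gtot <- matrix(colSums(dat$G), dat$m, dat$m)
  fe <- scale(dat$features); fe[!is.finite(fe)] <- 0
  for (round in seq_len(max_rounds)) {
    ll <- .marg_ll_matrix(dat, best$beta, best$sigma_b, best$sigma_e)
    tau <- .estep(ll, best$pi)$tau
    z <- max.col(tau)
    # merge candidates: cheapest pairs by approximate merge cost — curve
    # distance weighted by the harmonic mass pi_a pi_b / (pi_a + pi_b),
    # so near-empty classes merge for free
    pd <- utils::combn(K, 2)
    cost <- apply(pd, 2, function(ab) {
      d <- best$beta[, ab[1]] - best$beta[, ab[2]]
      w <- best$pi[ab[1]] * best$pi[ab[2]] / sum(best$pi[ab])
      w * drop(d %*% Gtot %*% d)
    })
    merge_cands <- lapply(order(cost)[seq_len(min(2L, ncol(pd)))],
                          function(j) pd[, j])
    # split candidates: worst average fit per observation; largest sigma_b
    deficit <- vapply(seq_len(K), function(k) {
      sw <- sum(tau[, k] * dat$n_i)
      if (sw < 1) -Inf else -sum(tau[, k] * ll[, k]) / sw
    }, numeric(1))
    split_cands <- unique(c(which.max(deficit), which.max(best$sigma_b)))
    improved <- FALSE
    for (mc in merge_cands) for (sc in split_cands) {
      if (sc %in% mc) next
      members <- which(z == sc)
      if (length(members) < 4L) next
      km <- tryCatch(stats::kmeans(fe[members, , drop = FALSE], 2L, nstart = 5),
                     error = function(e) NULL)
      if (is.null(km)) next
      tau2 <- tau
      tau2[, mc[1]] <- tau[, mc[1]] + tau[, mc[2]]   # merged pair
      tau2[, mc[2]] <- 1e-3                          # column re-used for the split half
      half <- members[km$cluster == 2L]
      tau2[half, mc[2]] <- tau[half, sc]
      tau2[half, sc] <- 1e-3
      tau2 <- tau2 / rowSums(tau2)
      cand <- .em_run(dat, K, tau2, 60L, tol)
      if (!cand$degenerate && cand$loglik > best$loglik + 1e-6) {
        cont <- .em_run(dat, K, max_iter = 500L, tol = tol, params = cand)
        if (!cont$degenerate && cont$loglik > best$loglik) {
          best <- cont; improved <- TRUE; break
        }
      }
    }
    if (!improved) break
  }
  best
}

# solve tau-weighted normal equations A beta = b with a small relative
# ridge so a class briefly starved of data in some knot span stays solvable
.solve_wls <- function(A, b, ridge = 1e-8) {
  diag(A) <- diag(A) + ridge * max(diag(A), 1)
  solve(A, b)
}

# tau-weighted normal equations from sufficient statistics:
# A = sum_i tau_i G_i, b = sum_i tau_i B_i'(y_i - off_i)
.wls_from_stats <- function(dat, tau_k, off = NULL) {
  A <- matrix(crossprod(dat$G, tau_k), dat$m, dat$m)
  b <- drop(crossprod(dat$By, tau_k))
  if (!is.null(off)) b <- b - drop(crossprod(dat$B1, tau_k * off))
  .solve_wls(A, b)
}

# one EM run from initial responsibilities (or parameters, when
# continuing a short run); returns fitted params or degenerate = TRUE
# when a class empties out
.em_run <- function(dat, K, tau = NULL, max_iter, tol, var_floor = 1e-4,
                    params = NULL) {
  n <- dat$n; N <- dat$N; n_i <- dat$n_i
  if (is.null(params)) {
    # initial coefficients from responsibilities (no random intercept yet)
    beta <- matrix(0, dat$m, K)
    for (k in seq_len(K)) beta[, k] <- .wls_from_stats(dat, tau[, k])
    sigma_b <- rep(0.5, K); sigma_e <- 0.5
    pi <- colMeans(tau)
  } else {
    beta <- params$beta; sigma_b <- params$sigma_b
    sigma_e <- params$sigma_e; pi <- params$pi
  }
  trace <- numeric(0); prev <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    rs <- lapply(seq_len(K), function(k) .resid_sums(dat, beta[, k]))
    se2 <- sigma_e^2; sb2 <- sigma_b^2
    ll <- matrix(0, n, K)
    for (k in seq_len(K)) {
      denom <- se2 + n_i * sb2[k]
      ll[, k] <- -0.5 * (n_i * log(2 * base::pi) + (n_i - 1) * log(se2) + log(denom) +
                         rs[[k]]$S2 / se2 - sb2[k] * rs[[k]]$S1^2 / (se2 * denom))
    }
    es <- .estep(ll, pi)
    tau <- es$tau
    trace <- c(trace, es$loglik)
    if (any(colSums(tau) < 1e-8)) return(list(degenerate = TRUE))
    if (is.finite(prev) && abs(es$loglik - prev) < tol) { converged <- TRUE; break }
    prev <- es$loglik
    # E-step moments of the random intercept given class, at current params
    denom <- outer(n_i, sb2, function(a, b) se2 + a * b)
    S1 <- vapply(rs, `[[`, numeric(n), "S1")
    m_ik <- sweep(S1, 2, sb2, "*") / denom
    v_ik <- se2 * sweep(1 / denom, 2, sb2, "*")
    # M-step
    pi <- colMeans(tau)
    tw <- colSums(tau)
    sigma_b <- sqrt(pmax(colSums(tau * (m_ik^2 + v_ik)) / tw, 0))
    sse <- 0
    for (k in seq_len(K)) {
      beta[, k] <- .wls_from_stats(dat, tau[, k], off = m_ik[, k])
      rsn <- .resid_sums(dat, beta[, k])
      sse <- sse + sum(tau[, k] * (rsn$S2 - 2 * m_ik[, k] * rsn$S1 +
                                   n_i * (m_ik[, k]^2 + v_ik[, k])))
    }
    sigma_e <- max(sqrt(sse / N), var_floor)
  }
  list(degenerate = FALSE, beta = beta, sigma_b = sigma_b, sigma_e = sigma_e,
       pi = pi, loglik = trace[length(trace)], trace = trace,
       converged = converged, n_iter = length(trace))
}

#' Fit the latent class growth model by EM
#'
#' Finite mixture of spline-mean random-intercept models. The E-step
#' computes posterior class responsibilities from the rank-1 marginal
#' likelihood; the M-step updates mixing proportions, class coefficients
#' (responsibility-weighted least squares with the posterior intercept
#' mean as offset, equivalent to generalized least squares under the
#' compound-symmetric covariance) and the variance components in closed
#' form. The log-likelihood is monotone non-decreasing across iterations.
#' Start 1 initializes responsibilities by k-means on per-subject features
#' (mean HbA1c, slope, within-subject SD); remaining starts use random
#' responsibilities. The best final log-likelihood wins. Classes are
#' reported in descending mixing-proportion order (ties by the first
#' coefficient).
#'
#' @param cohort a [cohort()]; every subject needs >= 1 measurement.
#' @param K number of latent classes, >= 1.
#' @param spec a [basis_spec()].
#' @param n_starts number of EM initializations.
#' @param max_iter maximum EM iterations per start.
#' @param tol absolute log-likelihood convergence tolerance; default
#'   `1e-6 * n_subjects`.
#' @param seed integer seed (k-means and random responsibilities).
#' @param init optional `lcgm_fit` with the same K and basis: start 1 is
#'   warm-started from its posterior responsibilities (used by the
#'   cross-validation folds).
#' @param refine run split-merge refinement after the best start
#'   converges (merge the two closest classes, re-split the worst-fitting
#'   one; accept when the likelihood improves). Guards against the local
#'   optima, common at larger K, that merge two true classes.
#' @return object of class `lcgm_fit`: `K`, `spec`, `beta` (`m x K`),
#'   `sigma_b` (length K), `sigma_e`, `pi`, `loglik`, `loglik_trace`,
#'   `n_params`, `converged`, `n_iter`, `n_subjects`, `subject_ids`.
#' @export
fit_lcgm <- function(cohort, K, spec, n_starts = 5L, max_iter = 500L,
                     tol = NULL, seed = NULL, init = NULL, refine = TRUE) {
  stopifnot(inherits(cohort, "cohort"), K >= 1L, inherits(spec, "basis_spec"))
  dat <- .lcgm_data(cohort, spec)
  if (is.null(tol)) tol <- 1e-6 * dat$n
  if (!is.null(seed)) set.seed(seed)
  # starting responsibilities: warm start, then k-means solutions on the
  # per-subject profile features (one fresh k-means local optimum per
  # start — random responsibilities average to near-uniform and reliably
  # merge nearby classes at larger K), plus one random start for diversity
  fe <- scale(dat$features)
  fe[!is.finite(fe)] <- 0
  km_tau <- function(nstart) {
    km <- tryCatch(stats::kmeans(fe, centers = K, nstart = nstart, iter.max = 50),
                   error = function(e) NULL)
    if (is.null(km)) return(NULL)
    tau <- matrix(0.1 / (K - 1), dat$n, K)
    tau[cbind(seq_len(dat$n), km$cluster)] <- 0.9
    tau
  }
  taus <- lapply(seq_len(n_starts), function(s) {
    if (K == 1L) return(matrix(1, dat$n, 1L))
    if (s == 1L && !is.null(init)) {
      stopifnot(inherits(init, "lcgm_fit"), init$K == K)
      return(.estep(.marg_ll_matrix(dat, init$beta, init$sigma_b, init$sigma_e),
                    init$pi)$tau)
    }
    if (s < n_starts || n_starts == 1L) {
      tau <- km_tau(if (s == 1L) 10L else 1L)
      if (!is.null(tau)) return(tau)
    }
    tau <- matrix(stats::rexp(dat$n * K), dat$n, K)
    tau / rowSums(tau)
  })
  # short exploratory runs, then run the best start to convergence
  short <- if (n_starts > 1L) lapply(taus, function(tau)
    .em_run(dat, K, tau, min(60L, max_iter), tol)) else
    list(.em_run(dat, K, taus[[1L]], max_iter, tol))
  ok <- !vapply(short, `[[`, logical(1), "degenerate")
  if (!any(ok)) stop("degenerate fit: every EM start emptied a class")
  best <- short[[which.max(vapply(short, function(r)
    if (r$degenerate) -Inf else r$loglik, numeric(1)))]]
  if (n_starts > 1L && !best$converged) {
    cont <- .em_run(dat, K, max_iter = max_iter, tol = tol, params = best)
    if (!cont$degenerate) best <- cont
  }
  if (refine && K >= 3L) best <- .refine_sm(dat, K, best, tol)
  ord <- order(-best$pi, best$beta[1, ])
  fit <- structure(list(K = K, spec = spec,
                        beta = best$beta[, ord, drop = FALSE],
                        sigma_b = best$sigma_b[ord],
                        sigma_e = best$sigma_e,
                        pi = best$pi[ord],
                        loglik = best$loglik,
                        loglik_trace = best$trace,
                        n_params = K * spec$m + K + 1L + (K - 1L),
                        converged = best$converged,
                        n_iter = best$n_iter,
                        n_subjects = dat$n,
                        subject_ids = dat$ids),
                   class = "lcgm_fit")
  fit
}

#' @export
print.lcgm_fit <- function(x, ...) {
  cat(sprintf("LCGM fit: K = %d, basis dim %d (%s, %d interior knots)\n",
              x$K, x$spec$m, x$spec$strategy, x$spec$n_interior))
  cat(sprintf("  loglik %.2f after %d EM iterations (%sconverged)\n",
              x$loglik, x$n_iter, if (x$converged) "" else "NOT "))
  cat("  pi:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  cat(sprintf("  sigma_e %.3f; sigma_b: %s\n", x$sigma_e,
              paste(sprintf("%.3f", x$sigma_b), collapse = " ")))
  invisible(x)
}

#' Posterior class-membership probabilities
#'
#' Row-normalized posterior probabilities (log-sum-exp stabilized) for
#' every subject of a cohort under a fitted LCGM.
#'
#' @param fit an `lcgm_fit`.
#' @param cohort a [cohort()].
#' @return numeric matrix, subjects x classes, rows summing to 1, with
#'   subject ids as rownames.
#' @export
posterior_probs <- function(fit, cohort) {
  stopifnot(inherits(fit, "lcgm_fit"))
  dat <- .lcgm_data(cohort, fit$spec)
  ll <- .marg_ll_matrix(dat, fit$beta, fit$sigma_b, fit$sigma_e)
  tau <- .estep(ll, fit$pi)$tau
  rownames(tau) <- dat$ids
  tau
}

#' Assign a (possibly unseen) series to a class
#'
#' Posterior argmax for a single HbA1c series; ties go to the lower class
#' index. This is how incoming patients are slotted into a trajectory
#' class from their measurement history.
#'
#' @param fit an `lcgm_fit`.
#' @param series data frame (or list) with `t_weeks` and `hba1c`.
#' @return integer class index in `1..K`.
#' @export
assign_class <- function(fit, series) {
  stopifnot(inherits(fit, "lcgm_fit"))
  t <- series$t_weeks %||% series$times
  y <- series$hba1c %||% series$values
  dat <- .suff_stats(basis_matrix(t, fit$spec), y, rep(1L, length(y)), 1L)
  ll <- .marg_ll_matrix(dat, fit$beta, fit$sigma_b, fit$sigma_e)
  which.max(drop(ll) + log(fit$pi))
}

#' Bayesian Information Criterion of an LCGM fit
#'
#' `-2 loglik + n_params log(n_subjects)` with
#' `n_params = K m + K + 1 + (K - 1)` (class coefficients, class intercept
#' SDs, shared residual SD, free mixing proportions).
#'
#' @param fit an `lcgm_fit`.
#' @param n_subjects sample size for the penalty; defaults to the fitted
#'   cohort's size.
#' @return scalar BIC.
#' @export
bic <- function(fit, n_subjects = fit$n_subjects) {
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  -2 * fit$loglik + fit$n_params * log(n_subjects)
}

#' Fitted class mean trajectory
#'
#' Evaluates `B(times) beta_k` for one class; times beyond the basis
#' boundary are clamped to it.
#'
#' @param fit an `lcgm_fit`.
#' @param class_index class in `1..K`.
#' @param times evaluation times, weeks.
#' @return numeric vector of mean HbA1c values.
#' @export
predict_trajectory <- function(fit, class_index, times) {
  stopifnot(inherits(fit, "lcgm_fit"), class_index >= 1L, class_index <= fit$K)
  drop(basis_matrix(times, fit$spec) %*% fit$beta[, class_index])
}

#' Serialize an LCGM fit to JSON
#'
#' @param fit an `lcgm_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lcgm_json <- function(fit, path) {
  stopifnot(inherits(fit, "lcgm_fit"))
  obj <- list(K = fit$K,
              spec = fit$spec[c("degree", "n_interior", "strategy", "boundary", "interior_knots", "m")],
              beta = fit$beta, sigma_b = fit$sigma_b, sigma_e = fit$sigma_e,
              pi = fit$pi, loglik = fit$loglik, n_params = fit$n_params,
              converged = fit$converged, n_iter = fit$n_iter,
              n_subjects = fit$n_subjects)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read an LCGM fit from JSON
#'
#' @param path file written by [write_lcgm_json()].
#' @return an `lcgm_fit` (without the per-start trace).
#' @export
read_lcgm_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- structure(c(o$spec, list()), class = "basis_spec")
  spec$degree <- as.integer(spec$degree); spec$m <- as.integer(spec$m)
  structure(list(K = o$K, spec = spec, beta = matrix(o$beta, spec$m, o$K),
                 sigma_b = o$sigma_b, sigma_e = o$sigma_e, pi = o$pi,
                 loglik = o$loglik, loglik_trace = NULL, n_params = o$n_params,
                 converged = o$converged, n_iter = o$n_iter,
                 n_subjects = o$n_subjects, subject_ids = NULL),
            class = "lcgm_fit")
}
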