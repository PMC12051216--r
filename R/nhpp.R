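#' Power-law NHPP parameters
#'
#' The recurrent-event model is a nonhomogeneous Poisson process with
#' power-law (Weibull-type) baseline intensity modulated log-linearly by
#' time-fixed covariates:
#' \deqn{\lambda(t \mid x) = (\beta/\eta)(t/\eta)^{\beta-1} \exp(x^T\gamma),}
#' so the cumulative intensity is
#' \eqn{\Lambda(t \mid x) = (t/\eta)^\beta \exp(x^T\gamma)}. `eta` is the
#' scale (weeks), `beta` the dimensionless shape and `gamma` the vector of
#' log hazard ratios. No intercept is included in `gamma`: the scale
#' absorbs the baseline level and an intercept would be unidentified
#' against it.
#'
#' @param eta scale parameter, weeks, > 0.
#' @param beta shape parameter, > 0.
#' @param gamma numeric vector (possibly length 0) of covariate effects on
#'   the log scale.
#' @return object of class `nhpp_params`.
#' @export
nhpp_params <- function(eta, beta, gamma = numeric(0)) {
  stopifnot(is.numeric(eta), length(eta) == 1L, eta > 0,
            is.numeric(beta), length(beta) == 1L, beta > 0,
            is.numeric(gamma), all(is.finite(gamma)))
  structure(list(eta = eta, beta = beta, gamma = gamma), class = "nhpp_params")
}

#' @export
print.nhpp_params <- function(x, ...) {
  cat(sprintf("power-law NHPP: eta = %.4g weeks, beta = %.4g", x$eta, x$beta))
  if (length(x$gamma)) {
    cat(", hazard ratios exp(gamma):\n")
    print(round(exp(x$gamma), 4))
  } else cat(", no covariates\n")
  invisible(x)
}

#' Recurrent-event windows container
#'
#' Holds, for `n` subjects: the observation windows `[L, R]` (weeks on the
#' subject's own time axis), a covariate matrix `X` (`n x p`, may have zero
#' columns) and the observed event times, each strictly inside its
#' subject's window. Events outside the window are unobserved by design
#' and enter no likelihood term.
#'
#' @param subject_id character vector, unique.
#' @param L,R numeric window bounds, `0 <= L < R`.
#' @param X covariate matrix with `length(subject_id)` rows (or `NULL` for
#'   no covariates).
#' @param events data frame with columns `subject_id`, `t` (one row per
#'   event), or `NULL` for none.
#' @return object of class `event_windows`.
#' @export
event_windows <- function(subject_id, L, R, X = NULL, events = NULL) {
  subject_id <- as.character(subject_id)
  n <- length(subject_id)
  stopifnot(!anyDuplicated(subject_id), length(L) == n, length(R) == n,
            all(L >= 0), all(R > L))
  if (is.null(X)) X <- matrix(0, n, 0L)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n)
  rownames(X) <- subject_id
  if (is.null(events)) events <- data.frame(subject_id = character(0), t = numeric(0))
  events <- as.data.frame(events)
  names(events)[1:2] <- c("subject_id", "t")
  events$subject_id <- as.character(events$subject_id)
  idx <- match(events$subject_id, subject_id)
  if (anyNA(idx)) stop("events for unknown subject(s): ",
                       paste(unique(events$subject_id[is.na(idx)]), collapse = ", "))
  bad <- events$t <= L[idx] | events$t > R[idx] | events$t <= 0
  if (any(bad)) stop("event times outside (L, R] for subject(s): ",
                     paste(unique(events$subject_id[bad]), collapse = ", "))
  events <- events[order(idx, events$t), c("subject_id", "t")]
  rownames(events) <- NULL
  structure(list(subject_id = subject_id, L = as.numeric(L), R = as.numeric(R),
                 X = X, events = events),
            class = "event_windows")
}

#' @export
print.event_windows <- function(x, ...) {
  cat(sprintf("event_windows: %d subjects, %d events, %d covariate(s)\n",
              length(x$subject_id), nrow(x$events), ncol(x$X)))
  invisible(x)
}

#' Build event windows from a cohort
#'
#' Extracts the window/event table of a [cohort()] into an
#' [event_windows()] object, optionally attaching a covariate matrix
#' (rows matched to subjects by rowname).
#'
#' @param x a [cohort()] with an `events` table.
#' @param X optional covariate matrix with rownames = subject ids.
#' @return an [event_windows()].
#' @export
as_event_windows <- function(x, X = NULL) {
  stopifnot(inherits(x, "cohort"), !is.null(x$events))
  win <- unique(x$events[, c("subject_id", "L_weeks", "R_weeks")])
  ev <- x$events[!is.na(x$events$t_weeks), c("subject_id", "t_weeks")]
  names(ev) <- c("subject_id", "t")
  if (!is.null(X)) X <- X[win$subject_id, , drop = FALSE]
  event_windows(win$subject_id, win$L_weeks, win$R_weeks, X = X, events = ev)
}

#' Class-indicator covariate matrix
#'
#' Dummy-codes class labels against a reference class (the low stable
#' class in the default configuration), the coding used when hazard
#' ratios of trajectory classes are reported against the reference.
#'
#' @param labels integer class labels in `1..K`, named by subject id.
#' @param K number of classes.
#' @param reference reference class index (column omitted).
#' @return 0/1 matrix with `K - 1` columns named `class<k>`.
#' @export
class_indicators <- function(labels, K, reference = 1L) {
  ks <- setdiff(seq_len(K), reference)
  X <- vapply(ks, function(k) as.numeric(labels == k), numeric(length(labels)))
  X <- matrix(X, nrow = length(labels), dimnames = list(names(labels), paste0("class", ks)))
  X
}

lam_xg <- function(X, gamma) {
  if (length(gamma) == 0L) rep(0, nrow(X)) else drop(X %*% gamma)
}

#' Cumulative intensity of the power-law NHPP
#'
#' \eqn{\Lambda(t \mid x) = (t/\eta)^\beta \exp(x^T\gamma)}; zero at
#' `t = 0` and strictly increasing in `t`.
#'
#' @param t non-negative time(s), weeks.
#' @param x covariate vector (or `NULL`/empty when the model has none).
#' @param params an [nhpp_params()].
#' @return numeric vector of `Lambda(t | x)`.
#' @export
cumulative_intensity <- function(t, x = NULL, params) {
  stopifnot(inherits(params, "nhpp_params"))
  if (any(t < 0)) stop("t must be non-negative")
  xg <- if (length(params$gamma)) sum(x * params$gamma) else 0
  (t / params$eta)^params$beta * exp(xg)
}

# per-subject Lambda(t) for vectorized t with per-subject xg
.Lam <- function(t, eta, beta, xg) (t / eta)^beta * exp(xg)

#' Window-restricted NHPP log-likelihood
#'
#' Only events inside each subject's observation window are recorded, so
#' each subject contributes
#' \eqn{\sum_i \log\lambda(t_i \mid x) - [\Lambda(R \mid x) - \Lambda(L \mid x)]}
#' and the total is the sum over subjects.
#'
#' @param params an [nhpp_params()] with `gamma` conformable to the
#'   windows' covariate columns.
#' @param windows an [event_windows()].
#' @return scalar log-likelihood.
#' @export
window_loglik <- function(params, windows) {
  stopifnot(inherits(params, "nhpp_params"), inherits(windows, "event_windows"))
  p <- ncol(windows$X)
  if (length(params$gamma) != p)
    stop(sprintf("gamma has length %d but windows carry %d covariate(s)", length(params$gamma), p))
  eta <- params$eta; beta <- params$beta
  xg <- lam_xg(windows$X, params$gamma)
  idx <- match(windows$events$subject_id, windows$subject_id)
  te <- windows$events$t
  if (length(te) && beta < 1 && any(te == 0))
    stop("event at t = 0 with beta < 1: intensity diverges (subject ",
         paste(unique(windows$events$subject_id[te == 0]), collapse = ", "), ")")
  ev_term <- if (length(te))
    sum(log(beta) - beta * log(eta) + (beta - 1) * log(te) + xg[idx]) else 0
  gap <- .Lam(windows$R, eta, beta, xg) - .Lam(windows$L, eta, beta, xg)
  ev_term - sum(gap)
}

# negative loglik and gradient on th = (log eta, log beta, gamma); when
# fix_beta is non-NULL th = (log eta, gamma)
.nhpp_obj <- function(windows, fix_beta = NULL) {
  X <- windows$X; p <- ncol(X)
  idx <- match(windows$events$subject_id, windows$subject_id)
  te <- windows$events$t
  n_ev <- length(te)
  sum_log_te <- sum(log(te))
  Xev <- if (p) X[idx, , drop = FALSE] else matrix(0, n_ev, 0L)
  L <- windows$L; R <- windows$R
  unpack <- function(th) {
    if (is.null(fix_beta)) list(eta = exp(th[1]), beta = exp(th[2]), gamma = th[-(1:2)])
    else list(eta = exp(th[1]), beta = fix_beta, gamma = th[-1])
  }
  fn <- function(th) {
    q <- unpack(th)
    xg <- lam_xg(X, q$gamma)
    gap <- .Lam(R, q$eta, q$beta, xg) - .Lam(L, q$eta, q$beta, xg)
    ev <- n_ev * (log(q$beta) - q$beta * log(q$eta)) + (q$beta - 1) * sum_log_te +
      (if (p) sum(xg[idx]) else 0)
    -(ev - sum(gap))
  }
  gr <- function(th) {
    q <- unpack(th)
    xg <- lam_xg(X, q$gamma); exg <- exp(xg)
    PR <- (R / q$eta)^q$beta
    PL <- (L / q$eta)^q$beta
    D <- exg * (PR - PL)
    g_a <- -q$beta * n_ev + q$beta * sum(D)
    out <- numeric(length(th))
    out[1] <- -g_a
    pos <- 2L
    if (is.null(fix_beta)) {
      lR <- log(R / q$eta)
      lL <- ifelse(L > 0, log(L / q$eta), 0)
      dD <- exg * (PR * lR - PL * lL)  # PL = 0 when L = 0
      g_b <- q$beta * (n_ev / q$beta + sum_log_te - n_ev * log(q$eta) - sum(dD))
      out[2] <- -g_b
      pos <- 3L
    }
    if (p) {
      g_g <- colSums(Xev) - drop(t(X) %*% D)
      out[pos:length(th)] <- -g_g
    }
    out
  }
  list(fn = fn, gr = gr, unpack = unpack)
}

#' Fit the window-observed power-law NHPP by maximum likelihood
#'
#' Maximizes [window_loglik()] over `(log eta, log beta, gamma)` (the
#' unconstrained parameterization) by BFGS with analytic gradients, from
#' `n_starts` initializations; the covariance of the estimates is the
#' inverse observed information at the optimum.
#'
#' @param windows an [event_windows()] with at least one event.
#' @param init optional [nhpp_params()] starting value.
#' @param n_starts number of starts (start 1 is `init` or a moment-based
#'   default; the rest are seeded perturbations).
#' @param seed integer seed for the start perturbations.
#' @param fix_beta fix the shape at this value (e.g. `1` for the
#'   homogeneous Poisson process) instead of estimating it.
#' @return object of class `nhpp_fit`: `params`, `vcov` (of
#'   `(log eta[, log beta], gamma)`), `loglik`, `converged`, `n_events`,
#'   `total_exposure` (sum of window lengths, weeks).
#' @export
fit_nhpp <- function(windows, init = NULL, n_starts = 1L, seed = NULL, fix_beta = NULL) {
  stopifnot(inherits(windows, "event_windows"))
  if (nrow(windows$events) == 0L) stop("intensity unidentified: no events observed")
  X <- windows$X
  if (ncol(X)) {
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) {
      dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
      stop("covariate matrix is rank deficient; collinear column(s): ",
           paste(dropped, collapse = ", "))
    }
  }
  obj <- .nhpp_obj(windows, fix_beta)
  p <- ncol(X)
  th0 <- if (!is.null(init)) {
    stopifnot(inherits(init, "nhpp_params"))
    if (is.null(fix_beta)) c(log(init$eta), log(init$beta), init$gamma)
    else c(log(init$eta), init$gamma)
  } else {
    if (is.null(fix_beta)) c(log(stats::median(windows$R)), 0, rep(0, p))
    else c(log(stats::median(windows$R)), rep(0, p))
  }
  if (!is.null(seed)) set.seed(seed)
  starts <- list(th0)
  if (n_starts > 1L) for (s in 2:n_starts)
    starts[[s]] <- th0 + stats::rnorm(length(th0), sd = 0.5)
  best <- NULL
  for (th in starts) {
    op <- stats::optim(th, obj$fn, obj$gr, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-12))
    if (is.null(best) || op$value < best$value) best <- op
  }
  H <- stats::optimHess(best$par, obj$fn, obj$gr)
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, length(best$par), length(best$par)))
  q <- obj$unpack(best$par)
  gn <- colnames(X)
  if (is.null(gn) && p) gn <- paste0("x", seq_len(p))
  names(q$gamma) <- gn
  pn <- if (is.null(fix_beta)) c("log_eta", "log_beta", gn) else c("log_eta", gn)
  dimnames(vc) <- list(pn, pn)
  structure(list(params = nhpp_params(q$eta, q$beta, q$gamma),
                 vcov = vc, loglik = -best$value,
                 converged = best$convergence == 0L,
                 fixed_beta = fix_beta,
                 n_events = nrow(windows$events),
                 total_exposure = sum(windows$R - windows$L)),
            class = "nhpp_fit")
}

#' @export
print.nhpp_fit <- function(x, ...) {
  cat(sprintf("window-observed NHPP fit: loglik %.2f, %d events over %.0f subject-weeks\n",
              x$loglik, x$n_events, x$total_exposure))
  print(x$params)
  invisible(x)
}

#' Hazard-ratio table
#'
#' Exponentiated covariate effects with Wald 95% confidence intervals and
#' two-sided Wald p-values.
#'
#' @param fit an `nhpp_fit`.
#' @param level confidence level (default 0.95).
#' @return data frame with columns `name`, `HR`, `CI_low`, `CI_high`, `p`.
#' @export
hazard_ratios <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "nhpp_fit"))
  g <- fit$params$gamma
  if (!length(g)) return(data.frame(name = character(0), HR = numeric(0),
                                    CI_low = numeric(0), CI_high = numeric(0), p = numeric(0)))
  off <- if (is.null(fit$fixed_beta)) 2L else 1L
  se <- sqrt(diag(fit$vcov)[off + seq_along(g)])
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(name = names(g),
             HR = exp(g),
             CI_low = exp(g - z * se),
             CI_high = exp(g + z * se),
             p = 2 * stats::pnorm(-abs(g / se)),
             row.names = NULL)
}

#' Survival of the first event after window entry
#'
#' Probability of no event in the `t` weeks following the window left
#' bound `L`: \eqn{S(t) = \exp\{-[\Lambda(L+t \mid x) - \Lambda(L \mid x)]\}}.
#'
#' @param params an [nhpp_params()].
#' @param x covariate vector (or `NULL`).
#' @param L window left bound, weeks.
#' @param t elapsed time(s) since `L`, weeks, >= 0.
#' @return survival probabilities, same length as `t`.
#' @export
survival_first_event <- function(params, x = NULL, L, t) {
  stopifnot(inherits(params, "nhpp_params"), all(t >= 0), L >= 0)
  exp(-(cumulative_intensity(L + t, x, params) - cumulative_intensity(L, x, params)))
}

#' Mean first-event survival curve over a set of subjects
#'
#' Pointwise mean over subjects of [survival_first_event()] evaluated with
#' each subject's own covariates and window left bound — the class-wise
#' mean curves when called on one class's subjects at a time.
#'
#' @param fit an `nhpp_fit` (or [nhpp_params()]).
#' @param windows an [event_windows()] for the (non-empty) subject subset.
#' @param time_grid elapsed times since window entry, weeks.
#' @return data frame with columns `t_weeks`, `surv`.
#' @export
mean_survival_curve <- function(fit, windows, time_grid) {
  params <- if (inherits(fit, "nhpp_fit")) fit$params else fit
  stopifnot(inherits(params, "nhpp_params"), inherits(windows, "event_windows"))
  if (length(windows$subject_id) == 0L) stop("empty subject subset")
  xg <- lam_xg(windows$X, params$gamma)
  S <- vapply(time_grid, function(tt) {
    mean(exp(-(.Lam(windows$L + tt, params$eta, params$beta, xg) -
               .Lam(windows$L, params$eta, params$beta, xg))))
  }, numeric(1))
  data.frame(t_weeks = time_grid, surv = S)
}

#' Time-transform residual gaps for one window
#'
#' Under the true model the cumulative-intensity increments between
#' successive events of the full process are iid Exp(1). For a
#' window-observed record the first reference point is the window left
#' bound `L` (pre-window events are unobserved), so the gaps are
#' \eqn{\Lambda(T_1|x)-\Lambda(L|x), \Lambda(T_2|x)-\Lambda(T_1|x), \ldots};
#' the censored remainder \eqn{\Lambda(R|x)-\Lambda(T_{last}|x)} is
#' attached as attribute `"leftover"` (needed for exact pooled
#' diagnostics, see [residual_gaps()]).
#'
#' @param params an [nhpp_params()].
#' @param window list with `L`, `R`, `t` (event times) and optionally `x`.
#' @return numeric vector of gaps with attribute `leftover`.
#' @export
transform_residuals <- function(params, window) {
  stopifnot(inherits(params, "nhpp_params"))
  x <- window$x
  Lt <- cumulative_intensity(c(window$L, window$t, window$R), x, params)
  n <- length(window$t)
  gaps <- diff(Lt[seq_len(n + 1L)])
  attr(gaps, "leftover") <- Lt[n + 2L] - Lt[n + 1L]
  gaps
}

#' Pooled Exp(1) residual diagnostic
#'
#' Pools time-transform residuals across subjects. With `splice = TRUE`
#' (default) subjects' transformed timelines are concatenated end to end:
#' each window's transformed event sequence is a unit-rate Poisson process
#' restricted to an interval of length \eqn{\Lambda(R|x)-\Lambda(L|x)}, so
#' the concatenation is a single unit-rate Poisson process and its
#' inter-event gaps are exactly iid Exp(1) under the true parameters. With
#' `splice = FALSE` the naive within-window gaps are returned; those are
#' biased short by window truncation (mean \eqn{1-(1-e^{-c})/c} for a
#' window of transformed length `c`) and are offered for comparison only.
#'
#' @param params an [nhpp_params()].
#' @param windows an [event_windows()].
#' @param splice concatenate transformed timelines (exact diagnostic)?
#' @return numeric vector of residual gaps.
#' @export
residual_gaps <- function(params, windows, splice = TRUE) {
  stopifnot(inherits(params, "nhpp_params"), inherits(windows, "event_windows"))
  xg <- lam_xg(windows$X, params$gamma)
  idx <- match(windows$events$subject_id, windows$subject_id)
  lam_ev <- .Lam(windows$events$t, params$eta, params$beta, xg[idx]) -
    .Lam(windows$L, params$eta, params$beta, xg)[idx]
  if (!splice) {
    return(unlist(lapply(split(lam_ev, idx), function(v) diff(c(0, sort(v)))), use.names = FALSE))
  }
  clen <- .Lam(windows$R, params$eta, params$beta, xg) -
    .Lam(windows$L, params$eta, params$beta, xg)
  offset <- cumsum(c(0, clen))[seq_along(clen)]
  pts <- sort(offset[idx] + lam_ev)
  diff(c(0, pts))
}

#' Simulate window-observed events from the power-law NHPP
#'
#' Uses the inverse time transform of the Exp(1) property: cumulative
#' Exp(1) draws are mapped through
#' \eqn{\Lambda^{-1}(u \mid x) = \eta\,(u e^{-x^T\gamma})^{1/\beta}},
#' starting from \eqn{\Lambda(L \mid x)} and truncated at `R`.
#'
#' @param params an [nhpp_params()].
#' @param x covariate vector (or `NULL`).
#' @param L,R window bounds, `0 <= L < R`.
#' @param seed optional integer seed.
#' @return numeric vector of event times in `(L, R]` (possibly empty).
#' @export
simulate_events <- function(params, x = NULL, L, R, seed = NULL) {
  stopifnot(inherits(params, "nhpp_params"), L >= 0, R >= L)
  if (!is.null(seed)) set.seed(seed)
  xg <- if (length(params$gamma)) sum(x * params$gamma) else 0
  u0 <- (L / params$eta)^params$beta * exp(xg)
  u_max <- (R / params$eta)^params$beta * exp(xg)
  if (u_max <= u0) return(numeric(0))
  # draw in blocks: expected count + slack
  out <- numeric(0); u <- u0
  repeat {
    k <- max(8L, ceiling(2 * (u_max - u0)))
    draws <- u + cumsum(stats::rexp(k))
    out <- c(out, draws[draws <= u_max])
    if (draws[k] > u_max) break
    u <- draws[k]
  }
  params$eta * (out * exp(-xg))^(1 / params$beta)
}
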