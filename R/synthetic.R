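# Synthetic cohorts with the statistical structure the analysis assumes:
# K latent classes with smooth mean HbA1c trajectories, Gaussian random
# intercepts + residual noise, irregular visit times over 0-2,500 weeks,
# class-conditional covariates, and window-observed recurrent events from
# the power-law NHPP.

#' Trajectory shape primitives
#'
#' Parametric stand-ins for the qualitative class shapes: a stable level,
#' a linear ramp over a span (flat afterwards), an exponential approach
#' from a high start to a floor (sharp decline), and a lightly damped
#' sinusoid (volatility). All take `t` in weeks and return HbA1c %.
#'
#' @param level,start,end,floor HbA1c levels, %.
#' @param span weeks over which the linear ramp runs.
#' @param rate exponential decline rate, per week.
#' @param amplitude sinusoid amplitude, % HbA1c.
#' @param period sinusoid period, weeks.
#' @param damp damping rate of the sinusoid envelope, per week.
#' @return a `trajectory` object (callable description).
#' @name trajectories
NULL

#' @rdname trajectories
#' @export
traj_stable <- function(level)
  structure(list(shape = "stable", level = level), class = "trajectory")

#' @rdname trajectories
#' @export
traj_linear <- function(start, end, span)
  structure(list(shape = "linear", start = start, end = end, span = span),
            class = "trajectory")

#' @rdname trajectories
#' @export
traj_sharp_decline <- function(start, floor, rate)
  structure(list(shape = "sharp_decline", start = start, floor = floor, rate = rate),
            class = "trajectory")

#' @rdname trajectories
#' @export
traj_volatile <- function(level, amplitude, period, damp = 1 / 2500)
  structure(list(shape = "volatile", level = level, amplitude = amplitude,
                 period = period, damp = damp), class = "trajectory")

#' Evaluate a trajectory primitive
#' @param traj a `trajectory` object.
#' @param t times, weeks.
#' @return mean HbA1c values, %.
#' @export
eval_trajectory <- function(traj, t) {
  stopifnot(inherits(traj, "trajectory"))
  switch(traj$shape,
    stable = rep(traj$level, length(t)),
    linear = traj$start + (traj$end - traj$start) * pmin(t, traj$span) / traj$span,
    sharp_decline = traj$floor + (traj$start - traj$floor) * exp(-traj$rate * t),
    volatile = traj$level + traj$amplitude * sin(2 * pi * t / traj$period) * exp(-traj$damp * t),
    stop("unknown trajectory shape: ", traj$shape))
}

#' Synthetic cohort configuration
#'
#' The generative truth: class count and mixing proportions, per-class
#' mean trajectories, variance components, visit process, follow-up and
#' window rules, class-conditional covariate prevalences and the NHPP
#' truth for recurrent events.
#'
#' @param K class count.
#' @param pi mixing proportions, length `K`, summing to 1 (within 1e-12).
#' @param class_trajectories list of `K` `trajectory` objects.
#' @param sigma_b random-intercept SD (%), scalar or per class.
#' @param sigma_e residual SD (%), scalar.
#' @param followup per-subject maximum follow-up, `c(min, max)` weeks
#'   (uniform draw).
#' @param visit_gap inter-measurement gap distribution: exponential with
#'   `mean`, truncated to `[min, max]` weeks (inverse-CDF truncation). A
#'   baseline measurement at t = 0 is always included.
#' @param covariate_prevalences optional list of `K` lists with elements
#'   `age_mean`, `age_sd`, `male`, `ethnicity` (named length-4 vector
#'   summing to 1), `prior` and `med` (named probability vectors).
#' @param nhpp optional list `(eta, beta, gamma)` with `gamma` of length
#'   `K - 1` (log hazard ratios of classes `2..K` vs class 1); when given,
#'   recurrent events are simulated on each subject's window.
#' @param window_rule list with `lookback` (weeks): the window is
#'   `[max(0, followup - lookback), followup]`, mimicking a truncated
#'   covariate-availability period.
#' @param class_names optional class labels.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(K, pi, class_trajectories,
                             sigma_b = 0.2, sigma_e = 0.3,
                             followup = c(150, 2500),
                             visit_gap = list(mean = 26, min = 4, max = 104),
                             covariate_prevalences = NULL,
                             nhpp = NULL,
                             window_rule = list(lookback = 416),
                             class_names = NULL) {
  if (abs(sum(pi) - 1) > 1e-12) stop("pi must sum to 1 (within 1e-12)")
  if (length(pi) != K) stop("pi must have length K")
  if (length(class_trajectories) != K) stop("need one trajectory per class")
  if (any(sigma_b < 0) || sigma_e < 0) stop("SDs must be >= 0")
  if (length(sigma_b) == 1L) sigma_b <- rep(sigma_b, K)
  if (!is.null(covariate_prevalences)) {
    for (cp in covariate_prevalences) {
      pr <- c(cp$male, cp$ethnicity, cp$prior, cp$med)
      if (any(pr < 0 | pr > 1)) stop("covariate prevalences must lie in [0, 1]")
    }
  }
  if (!is.null(nhpp)) {
    stopifnot(nhpp$eta > 0, nhpp$beta > 0, length(nhpp$gamma) == K - 1L)
  }
  structure(list(K = K, pi = pi, class_trajectories = class_trajectories,
                 sigma_b = sigma_b, sigma_e = sigma_e, followup = followup,
                 visit_gap = visit_gap,
                 covariate_prevalences = covariate_prevalences,
                 nhpp = nhpp, window_rule = window_rule,
                 class_names = class_names %||% paste0("class", seq_len(K))),
            class = "synthetic_config")
}

# truncated-exponential visit gaps via inverse CDF
.rgap <- function(n, gap) {
  lo <- stats::pexp(gap$min, 1 / gap$mean)
  hi <- stats::pexp(gap$max, 1 / gap$mean)
  stats::qexp(lo + (hi - lo) * stats::runif(n), 1 / gap$mean)
}

#' Draw class-conditional covariates
#'
#' Bernoulli/categorical draws at the configured class-conditional
#' prevalences (independent given class).
#'
#' @param class_index class in `1..K`.
#' @param config a [synthetic_config()] with `covariate_prevalences`.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return data frame with `age_at_ddd`, `sex`, `ethnicity` and the
#'   `prior_*` / `med_*` flags (0/1).
#' @export
generate_covariates <- function(class_index, config, n = 1L, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"),
            class_index >= 1L, class_index <= config$K)
  if (!is.null(seed)) set.seed(seed)
  cp <- config$covariate_prevalences[[class_index]]
  if (is.null(cp)) stop("config has no covariate prevalences")
  out <- data.frame(
    age_at_ddd = pmax(stats::rnorm(n, cp$age_mean, cp$age_sd), 18),
    sex = ifelse(stats::runif(n) < cp$male, "male", "female"),
    ethnicity = sample(names(cp$ethnicity), n, replace = TRUE, prob = cp$ethnicity))
  for (nm in names(cp$prior))
    out[[paste0("prior_", nm)]] <- as.integer(stats::runif(n) < cp$prior[[nm]])
  for (nm in names(cp$med))
    out[[paste0("med_", nm)]] <- as.integer(stats::runif(n) < cp$med[[nm]])
  out
}

#' Generate a synthetic cohort
#'
#' Per subject: class drawn from `pi`; measurement times are a baseline
#' visit at t = 0 plus truncated-exponential gaps accumulated to the
#' subject's follow-up; HbA1c is class mean + subject intercept
#' `N(0, sigma_b_k)` + residual `N(0, sigma_e)`, clipped to \[3, 25\];
#' covariates from the class-conditional prevalences; recurrent events
#' (when an NHPP truth is configured) simulated on the subject's window
#' with class-indicator covariates. Fully reproducible under `seed`.
#'
#' @param config a [synthetic_config()].
#' @param n number of subjects.
#' @param seed integer seed.
#' @return list with elements `cohort` (a [cohort()]) and `labels`
#'   (named integer vector of true classes).
#' @export
generate_cohort <- function(config, n, seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"), n >= 1L)
  set.seed(seed)
  K <- config$K
  ids <- sprintf("S%06d", seq_len(n))
  cls <- sample.int(K, n, replace = TRUE, prob = config$pi)
  fu <- stats::runif(n, config$followup[1], config$followup[2])
  b <- stats::rnorm(n, 0, config$sigma_b[cls])

  # visit times: t = 0 plus accumulated gaps, truncated at follow-up
  max_gaps <- ceiling(config$followup[2] / config$visit_gap$min)
  mea <- vector("list", n)
  for (i in seq_len(n)) {
    t <- 0
    repeat {
      g <- .rgap(16L, config$visit_gap)
      cand <- t[length(t)] + cumsum(g)
      t <- c(t, cand[cand <= fu[i]])
      if (cand[16L] > fu[i]) break
    }
    mu <- eval_trajectory(config$class_trajectories[[cls[i]]], t)
    y <- pmin(pmax(mu + b[i] + stats::rnorm(length(t), 0, config$sigma_e),
                   HBA1C_RANGE[1]), HBA1C_RANGE[2])
    mea[[i]] <- list(t = t, y = y)
  }
  n_obs <- vapply(mea, function(z) length(z$t), integer(1))
  measurements <- data.frame(
    subject_id = rep(ids, n_obs),
    t_weeks = unlist(lapply(mea, `[[`, "t")),
    hba1c = unlist(lapply(mea, `[[`, "y")))

  if (!is.null(config$covariate_prevalences)) {
    cov_list <- lapply(seq_len(n), function(i) generate_covariates(cls[i], config, 1L))
    covs <- do.call(rbind, cov_list)
  } else {
    covs <- data.frame(age_at_ddd = rep(55, n), sex = "female", ethnicity = "Chinese")
  }
  diagnosis_year <- sample(1990:2018, n, replace = TRUE)
  subjects <- cbind(data.frame(subject_id = ids,
                               diagnosis_year = diagnosis_year,
                               ddd = as.Date(sprintf("%04d-01-01", diagnosis_year)) +
                                 sample.int(365, n, replace = TRUE) - 1L),
                    covs)

  events <- NULL
  if (!is.null(config$nhpp)) {
    L <- pmax(0, fu - config$window_rule$lookback)
    R <- fu
    params <- nhpp_params(config$nhpp$eta, config$nhpp$beta, config$nhpp$gamma)
    lab <- stats::setNames(cls, ids)
    Xc <- class_indicators(lab, K)
    ev <- vector("list", n)
    for (i in seq_len(n)) {
      tt <- simulate_events(params, Xc[i, ], L[i], R[i])
      ev[[i]] <- if (length(tt)) data.frame(subject_id = ids[i], L_weeks = L[i],
                                            R_weeks = R[i], t_weeks = tt)
        else data.frame(subject_id = ids[i], L_weeks = L[i], R_weeks = R[i],
                        t_weeks = NA_real_)
    }
    events <- do.call(rbind, ev)
  }
  list(cohort = cohort(subjects, measurements, events),
       labels = stats::setNames(cls, ids))
}

#' Default 8-class configuration mirroring the published cohort
#'
#' Eight latent classes whose mixing proportions are the published class
#' percentages (renormalized to sum to 1), whose mean trajectories start
#' at the published per-class baseline HbA1c means and follow the
#' described qualitative shapes (stable / ascending / descending / sharp
#' decline / volatile) over 0-2,500 weeks, whose class-conditional
#' covariate prevalences are the published baseline table rates, and
#' whose NHPP truth encodes the published class hazard ratios
#' (reference: the low stable class) with scale 400 weeks and shape 1.3.
#' The volatility amplitude (1.5% HbA1c) is a free choice: no
#' quantitative amplitude is published.
#'
#' @param sigma_b random-intercept SD, % (default 0.2).
#' @param sigma_e residual SD, % (default 0.3).
#' @return a [synthetic_config()].
#' @export
default_paper_config <- function(sigma_b = 0.2, sigma_e = 0.3) {
  cn <- c("LowS", "ModLowA", "ModHighA", "ModLowD", "ModHighD", "ModHighV",
          "HighSD", "HighV")
  pct <- c(22.2, 12.7, 11.5, 17.2, 10.1, 10.1, 8.0, 10.2)
  trajs <- list(
    traj_stable(6.27),
    traj_linear(6.70, 7.40, 1300),
    traj_linear(7.41, 8.60, 1300),
    traj_linear(7.73, 6.70, 1300),
    traj_linear(9.28, 7.20, 1300),
    traj_volatile(8.63, 1.5, 800),
    traj_sharp_decline(11.60, 6.80, 0.025),
    traj_volatile(10.81, 1.5, 1000))
  hr <- c(ModLowA = 0.79, ModHighA = 1.30, ModLowD = 1.17, ModHighD = 1.89,
          ModHighV = 1.94, HighSD = 1.25, HighV = 2.88)
  eth <- c("Chinese", "Malay", "Indian", "Other")
  tab <- list(
    age_mean = c(63.7, 58.3, 55.8, 59.4, 55.1, 51.7, 54.1, 50.2),
    age_sd   = c(12.2, 11.9, 13.0, 12.0, 12.4, 13.5, 12.0, 13.4),
    male     = c(48.9, 50.8, 52.2, 50.6, 52.3, 53.8, 55.2, 58.6) / 100,
    chinese  = c(77.3, 75.1, 68.4, 72.8, 64.4, 58.6, 67.2, 49.3),
    malay    = c(10.9, 11.7, 14.5, 13.0, 17.3, 20.7, 18.4, 27.2),
    indian   = c(8.1, 9.4, 12.5, 10.2, 13.4, 15.0, 9.8, 16.5),
    other    = c(3.7, 3.8, 4.6, 4.0, 4.9, 5.7, 4.6, 7.0),
    cvd = c(25.8, 23.7, 28.4, 26.2, 29.9, 28.0, 22.3, 27.4),
    ihd = c(16.9, 15.9, 18.9, 17.2, 19.1, 18.3, 13.5, 17.3),
    pad = c(1.2, 0.9, 1.6, 1.3, 3.0, 2.6, 1.8, 4.3),
    hs  = c(0.9, 0.6, 0.7, 0.7, 0.6, 0.7, 0.9, 0.6),
    is  = c(6.4, 5.2, 5.8, 6.0, 7.2, 5.8, 6.2, 5.8),
    tia = c(1.6, 1.3, 1.2, 1.2, 1.1, 1.1, 1.0, 0.9),
    af  = c(4.7, 3.4, 3.8, 4.0, 4.0, 3.5, 2.7, 3.3),
    neuropathy = c(1.0, 0.7, 1.3, 1.3, 2.2, 2.3, 1.9, 4.0),
    dpa = c(1.2, 0.8, 1.8, 1.6, 3.4, 3.5, 2.7, 6.3),
    hf  = c(1.2, 1.0, 2.0, 1.6, 2.7, 2.8, 1.3, 3.6),
    acarbose = c(0.5, 1.8, 8.0, 3.8, 10.6, 11.0, 5.6, 7.5),
    metformin = c(30.1, 52.1, 68.2, 66.5, 73.5, 73.4, 80.8, 73.7),
    sulfonylureas = c(9.3, 24.1, 48.8, 37.9, 56.2, 55.9, 56.1, 55.7),
    dpp4i = c(2.8, 4.3, 9.6, 6.2, 11.4, 13.0, 10.6, 12.0),
    sglt2i = c(1.5, 1.7, 2.5, 2.8, 3.4, 2.8, 4.9, 3.9))
  cp <- lapply(seq_along(cn), function(k) {
    e <- c(tab$chinese[k], tab$malay[k], tab$indian[k], tab$other[k])
    list(age_mean = tab$age_mean[k], age_sd = tab$age_sd[k], male = tab$male[k],
         ethnicity = stats::setNames(e / sum(e), eth),
         prior = stats::setNames(
           vapply(PRIOR_FLAGS, function(f) tab[[f]][k] / 100, numeric(1)), PRIOR_FLAGS),
         med = stats::setNames(
           vapply(MED_FLAGS, function(f) tab[[f]][k] / 100, numeric(1)), MED_FLAGS))
  })
  synthetic_config(K = 8L, pi = pct / sum(pct), class_trajectories = trajs,
                   sigma_b = sigma_b, sigma_e = sigma_e,
                   covariate_prevalences = cp,
                   nhpp = list(eta = 400, beta = 1.3, gamma = log(unname(hr))),
                   class_names = cn)
}
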