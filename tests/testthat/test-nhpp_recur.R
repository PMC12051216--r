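test_that("cumulative intensity matches its closed form and quadrature", {
  p <- nhpp_params(100, 2)
  expect_equal(cumulative_intensity(0, NULL, p), 0)
  expect_equal(cumulative_intensity(100, NULL, p), 1)
  expect_error(cumulative_intensity(-1, NULL, p), "non-negative")
  # quadrature oracle over the intensity
  p2 <- nhpp_params(400, 1.3, log(2))
  lam <- function(t) (p2$beta / p2$eta) * (t / p2$eta)^(p2$beta - 1) * exp(p2$gamma)
  for (tt in c(50, 400, 900)) {
    q <- stats::integrate(lam, 0, tt, rel.tol = 1e-10)$value
    expect_equal(cumulative_intensity(tt, 1, p2), q, tolerance = 1e-8)
  }
})

test_that("window loglik reproduces the hand-computed value and is additive", {
  p <- nhpp_params(100, 2)
  w <- event_windows("a", 0, 100, events = data.frame(subject_id = "a", t = c(40, 80)))
  expect_equal(window_loglik(p, w), log(0.008) + log(0.016) - 1, tolerance = 1e-12)
  # no events: minus the Lambda gap
  w0 <- event_windows("b", 20, 80)
  expect_equal(window_loglik(p, w0), -(0.8^2 - 0.2^2), tolerance = 1e-12)
  # duplicating every subject doubles the loglik
  w2 <- event_windows(c("a", "a2"), c(0, 0), c(100, 100),
                      events = data.frame(subject_id = c("a", "a", "a2", "a2"),
                                          t = c(40, 80, 40, 80)))
  expect_equal(window_loglik(p, w2), 2 * window_loglik(p, w), tolerance = 1e-12)
})

test_that("splitting a window into abutting halves leaves the loglik unchanged", {
  p <- nhpp_params(300, 1.4, log(1.5))
  X <- matrix(1, 1, 1, dimnames = list(NULL, "z"))
  w1 <- event_windows("a", 10, 200, X = X,
                      events = data.frame(subject_id = "a", t = c(50, 120, 180)))
  w2 <- event_windows(c("a1", "a2"), c(10, 120), c(120, 200), X = rbind(X, X),
                      events = data.frame(subject_id = c("a1", "a1", "a2"),
                                          t = c(50, 120, 180)))
  expect_equal(window_loglik(p, w1), window_loglik(p, w2), tolerance = 1e-12)
})

test_that("simulated event counts follow the Poisson law of the Lambda gap", {
  p <- nhpp_params(100, 1)
  set.seed(5)
  counts <- vapply(1:10000, function(i) length(simulate_events(p, NULL, 0, 1000)),
                   numeric(1))
  expect_equal(mean(counts), 10, tolerance = 0.012)  # Lambda gap = 10
  # chi-square GOF against Poisson(10), tail-pooled
  brk <- c(-Inf, 4:16, Inf)
  obs <- table(cut(counts, brk))
  pr <- diff(stats::ppois(c(-Inf, 4:16, Inf), 10))
  expect_gt(stats::chisq.test(as.numeric(obs), p = pr)$p.value, 0.01)
  # degenerate window produces nothing
  expect_length(simulate_events(p, NULL, 50, 50), 0L)
})

test_that("time-transform residuals are Exp(1) on the spliced timeline", {
  truth <- nhpp_params(400, 1.3)
  set.seed(7)
  ids <- sprintf("s%04d", 1:2000)
  ev <- do.call(rbind, lapply(ids, function(id) {
    tt <- simulate_events(truth, NULL, 0, 800)
    if (length(tt)) data.frame(subject_id = id, t = tt)
  }))
  w <- event_windows(ids, rep(0, 2000), rep(800, 2000), events = ev)
  g <- residual_gaps(truth, w, splice = TRUE)
  expect_equal(mean(g), 1, tolerance = 0.05)
  expect_gt(stats::ks.test(g, "pexp", 1)$p.value, 0.01)
  # naive within-window pooling is biased short by truncation
  c0 <- (800 / 400)^1.3
  expect_equal(mean(residual_gaps(truth, w, splice = FALSE)),
               1 - (1 - exp(-c0)) / c0, tolerance = 0.05)
})

test_that("per-window residuals follow the definition and the beta = 1 reduction", {
  p <- nhpp_params(200, 1.5, log(2))
  win <- list(L = 20, R = 300, t = c(80, 150), x = 1)
  g <- transform_residuals(p, win)
  Lam <- function(t) (t / 200)^1.5 * 2
  expect_equal(as.numeric(g), c(Lam(80) - Lam(20), Lam(150) - Lam(80)),
               tolerance = 1e-12)
  expect_equal(attr(g, "leftover"), Lam(300) - Lam(150), tolerance = 1e-12)
  # beta = 1: gaps are raw inter-event times scaled by exp(x gamma) / eta
  p1 <- nhpp_params(100, 1, log(3))
  g1 <- transform_residuals(p1, list(L = 0, R = 400, t = c(50, 170), x = 1))
  expect_equal(as.numeric(g1), c(50, 120) / 100 * 3, tolerance = 1e-12)
  # single event: one gap from L
  g2 <- transform_residuals(p1, list(L = 10, R = 100, t = 60, x = 0))
  expect_equal(as.numeric(g2), (60 - 10) / 100, tolerance = 1e-12)
})

test_that("the HPP rate MLE has its closed form at fixed beta = 1", {
  w <- event_windows("a", 0, 300,
                     events = data.frame(subject_id = "a", t = c(50, 150, 250)))
  fit <- fit_nhpp(w, fix_beta = 1)
  expect_equal(fit$params$eta, 300 / 3, tolerance = 1e-6)  # exposure / events
  expect_equal(fit$params$beta, 1)
})

test_that("the MLE recovers simulated parameters within 3 standard errors", {
  truth <- nhpp_params(400, 1.3, log(2))
  w <- sim_binary_windows(2000, truth, prevalence = 0.3, R = 520, seed = 11)
  fit <- fit_nhpp(w, seed = 1)
  expect_true(fit$converged)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(log(fit$params$eta) - log(400)), 3 * se[1])
  expect_lt(abs(log(fit$params$beta) - log(1.3)), 3 * se[2])
  expect_lt(abs(fit$params$gamma - log(2)), 3 * se[3])
  # the MLE is at least as good as the truth on its own data
  expect_gte(fit$loglik, window_loglik(truth, w) - 1e-6)
  # vcov is symmetric positive semi-definite
  expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-8)
  expect_true(all(eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
})

test_that("degenerate inputs are rejected with clear messages", {
  w0 <- event_windows("a", 0, 100)
  expect_error(fit_nhpp(w0), "unidentified")
  X <- cbind(a = c(1, 0, 1), b = c(2, 0, 2))  # b = 2a
  wr <- event_windows(c("x", "y", "z"), rep(0, 3), rep(100, 3), X = X,
                      events = data.frame(subject_id = "x", t = 50))
  expect_error(fit_nhpp(wr), "collinear")
})

test_that("hazard-ratio tables follow Wald arithmetic", {
  fake <- structure(list(params = nhpp_params(400, 1.3, c(grp = log(2))),
                         vcov = diag(c(0.01, 0.01, 0.01)), fixed_beta = NULL),
                    class = "nhpp_fit")
  hr <- hazard_ratios(fake)
  expect_equal(hr$HR, 2, tolerance = 1e-12)
  expect_equal(hr$CI_low, exp(log(2) - 1.96 * 0.1), tolerance = 1e-3)
  expect_equal(hr$CI_high, exp(log(2) + 1.96 * 0.1), tolerance = 1e-3)
  fake$params$gamma <- c(grp = 0)
  hr0 <- hazard_ratios(fake)
  expect_equal(hr0$HR, 1)
  expect_true(hr0$CI_low < 1 && hr0$CI_high > 1)
})

test_that("first-event survival matches closed forms and Kaplan-Meier", {
  p <- nhpp_params(100, 1)
  expect_equal(survival_first_event(p, NULL, 0, 0), 1)
  expect_equal(survival_first_event(p, NULL, 0, 50), exp(-0.5), tolerance = 1e-12)
  skip_if_not_installed("survival")
  truth <- nhpp_params(300, 1.5)
  set.seed(13)
  n <- 20000
  first <- vapply(1:n, function(i) {
    tt <- simulate_events(truth, NULL, 100, 500)
    if (length(tt)) tt[1] - 100 else NA_real_
  }, numeric(1))
  time <- ifelse(is.na(first), 400, first)
  status <- as.numeric(!is.na(first))
  km <- survival::survfit(survival::Surv(time, status) ~ 1)
  for (tt in c(50, 150, 300)) {
    km_s <- summary(km, times = tt)$surv
    expect_equal(survival_first_event(truth, NULL, 100, tt), km_s, tolerance = 0.02)
  }
})

test_that("mean survival curves average subject curves and order by risk", {
  p <- nhpp_params(300, 1.3, log(2))
  X1 <- matrix(0, 1, 1, dimnames = list(NULL, "z"))
  w1 <- event_windows("a", 50, 500, X = X1)
  grid <- c(0, 50, 150)
  single <- mean_survival_curve(p, w1, grid)
  expect_equal(single$surv, survival_first_event(p, 0, 50, grid), tolerance = 1e-12)
  # identical subjects: mean equals the individual curve
  w2 <- event_windows(c("a", "b"), c(50, 50), c(500, 500), X = rbind(X1, X1))
  expect_equal(mean_survival_curve(p, w2, grid)$surv, single$surv, tolerance = 1e-12)
  # higher x gamma -> pointwise lower curve
  whi <- event_windows("c", 50, 500, X = matrix(1, 1, 1, dimnames = list(NULL, "z")))
  expect_true(all(mean_survival_curve(p, whi, grid)$surv[-1] < single$surv[-1]))
  expect_error(mean_survival_curve(p, event_windows(character(0), numeric(0),
                                                    numeric(0)), grid),
               "empty")
})
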