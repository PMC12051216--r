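make_spec <- function(times = 0:100, n = 3) basis_spec(times, n, "equidistant",
                                                       boundary = c(0, 100))

test_that("class marginal loglik matches a dense multivariate-normal evaluation", {
  sp <- make_spec()
  beta_k <- seq(5, 8, length.out = sp$m)
  series <- list(t_weeks = c(10, 45, 80), hba1c = c(6.1, 6.9, 7.4))
  sb <- 0.4; se <- 0.3
  got <- class_marginal_loglik(series, beta_k, sb, se, sp)
  # dense oracle: explicit covariance, base-R solve/determinant
  B <- basis_matrix(series$t_weeks, sp)
  S <- sb^2 * matrix(1, 3, 3) + se^2 * diag(3)
  r <- series$hba1c - drop(B %*% beta_k)
  dense <- -0.5 * (3 * log(2 * pi) + determinant(S)$modulus[1] +
                   drop(r %*% solve(S, r)))
  expect_equal(got, dense, tolerance = 1e-10)
})

test_that("with no random intercept a single observation collapses to a normal density", {
  sp <- make_spec()
  beta_k <- rep(6.5, sp$m)
  got <- class_marginal_loglik(list(t_weeks = 30, hba1c = 7.1), beta_k, 0, 0.5, sp)
  expect_equal(got, dnorm(7.1, 6.5, 0.5, log = TRUE), tolerance = 1e-12)
  # an extra observation exactly on the class mean adds the residual-free constant
  with_extra <- class_marginal_loglik(list(t_weeks = c(30, 60), hba1c = c(7.1, 6.5)),
                                      beta_k, 0, 0.5, sp)
  expect_equal(with_extra - got, -log(0.5 * sqrt(2 * pi)), tolerance = 1e-12)
  expect_error(class_marginal_loglik(list(t_weeks = 30, hba1c = 7), beta_k, 0, 0, sp),
               "sigma_e")
})

test_that("K = 1 reproduces the single-class mixed-model MLE (lme4 oracle)", {
  skip_if_not_installed("lme4")
  set.seed(10)
  cfg <- synthetic_config(K = 1, pi = 1,
                          class_trajectories = list(traj_linear(6.5, 8, 300)),
                          sigma_b = 0.5, sigma_e = 0.3, followup = c(100, 300))
  g <- generate_cohort(cfg, 120, seed = 5)
  sp <- basis_spec(g$cohort$measurements$t_weeks, 3, "equipotent")
  fit <- fit_lcgm(g$cohort, 1, sp, n_starts = 1, seed = 1, tol = 1e-9)
  mea <- g$cohort$measurements
  B <- basis_matrix(mea$t_weeks, sp)
  df <- data.frame(y = mea$hba1c, id = mea$subject_id)
  lfit <- lme4::lmer(y ~ 0 + B + (1 | id), data = df, REML = FALSE)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lfit)), tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(lfit))
  expect_equal(fit$sigma_b, vc$sdcor[vc$grp == "id"], tolerance = 1e-3)
  expect_equal(fit$sigma_e, vc$sdcor[vc$grp == "Residual"], tolerance = 1e-3)
  expect_equal(unname(fit$beta[, 1]), unname(lme4::fixef(lfit)), tolerance = 1e-3)
})

test_that("EM separates well-separated classes and has monotone loglik", {
  g <- generate_cohort(flat_mix_config(c(6, 11), c(0.5, 0.5)), 200, seed = 3)
  sp <- basis_spec(g$cohort$measurements$t_weeks, 3, "equipotent")
  fit <- fit_lcgm(g$cohort, 2, sp, n_starts = 2, seed = 1)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  tau <- posterior_probs(fit, g$cohort)
  expect_equal(rowSums(tau), setNames(rep(1, nrow(tau)), rownames(tau)),
               tolerance = 1e-10)
  pred <- apply(tau, 1, which.max)
  # map fitted classes to truth by the t = 0 level
  lev <- vapply(1:2, function(k) predict_trajectory(fit, k, 0), numeric(1))
  map <- order(lev)  # truth: class 1 low, class 2 high
  agree <- mean(map[pred] == g$labels[rownames(tau)])
  expect_gte(agree, 0.99)
})

test_that("posteriors are degenerate at K = 1 and class order is descending pi", {
  g <- generate_cohort(flat_mix_config(c(6, 11), c(0.8, 0.2)), 150, seed = 6)
  sp <- basis_spec(g$cohort$measurements$t_weeks, 3, "equipotent")
  f1 <- fit_lcgm(g$cohort, 1, sp, n_starts = 1, seed = 1)
  expect_equal(unname(posterior_probs(f1, g$cohort)[, 1]),
               rep(1, n_subjects(g$cohort)))
  f2 <- fit_lcgm(g$cohort, 2, sp, n_starts = 2, seed = 1)
  expect_true(f2$pi[1] >= f2$pi[2])
  expect_equal(f2$pi[1], 0.8, tolerance = 0.05)
})

test_that("assign_class recovers the generating class and breaks ties low", {
  g <- generate_cohort(flat_mix_config(c(6, 11), c(0.5, 0.5)), 150, seed = 8)
  sp <- basis_spec(g$cohort$measurements$t_weeks, 3, "equipotent")
  fit <- fit_lcgm(g$cohort, 2, sp, n_starts = 2, seed = 1)
  hi <- which.max(vapply(1:2, function(k) predict_trajectory(fit, k, 0), numeric(1)))
  got <- assign_class(fit, list(t_weeks = c(0, 50, 100), hba1c = c(11, 11, 11)))
  expect_equal(got, hi)
  # hand-built fit with two identical classes: posterior ties -> lower index
  twin <- fit
  twin$beta[, 2] <- twin$beta[, 1]
  twin$sigma_b <- rep(twin$sigma_b[1], 2)
  twin$pi <- c(0.5, 0.5)
  expect_equal(assign_class(twin, list(t_weeks = 50, hba1c = 7.3)), 1L)
})

test_that("BIC uses the mixture parameter count and the stated formula", {
  sp34 <- basis_spec(0:2500, 30, "equidistant", boundary = c(0, 2500))
  fake <- structure(list(K = 1L, spec = sp34, loglik = -100,
                         n_params = 1L * sp34$m + 1L + 1L + 0L,
                         n_subjects = 100L),
                    class = "lcgm_fit")
  expect_equal(fake$n_params, 36L)
  fake$n_params <- 5L
  expect_equal(bic(fake), 200 + 5 * log(100), tolerance = 1e-12)
  expect_error(bic(fake, 0), "n_subjects")
})

test_that("noise-free data from a representable truth is recovered exactly", {
  cfg <- synthetic_config(K = 1, pi = 1, class_trajectories = list(traj_stable(6.3)),
                          sigma_b = 0, sigma_e = 0, followup = c(100, 300))
  g <- generate_cohort(cfg, 60, seed = 2)
  expect_true(all(g$cohort$measurements$hba1c == 6.3))
  sp <- basis_spec(g$cohort$measurements$t_weeks, 3, "equipotent")
  fit <- fit_lcgm(g$cohort, 1, sp, n_starts = 1, seed = 1)
  tgrid <- seq(0, 300, by = 10)
  expect_equal(predict_trajectory(fit, 1, tgrid), rep(6.3, length(tgrid)),
               tolerance = 5e-4)
})

test_that("an LCGM fit survives JSON serialization", {
  g <- generate_cohort(flat_mix_config(c(6, 11), c(0.5, 0.5)), 80, seed = 9)
  sp <- basis_spec(g$cohort$measurements$t_weeks, 3, "equipotent")
  fit <- fit_lcgm(g$cohort, 2, sp, n_starts = 1, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_lcgm_json(fit, path)
  back <- read_lcgm_json(path)
  expect_equal(back$beta, fit$beta, tolerance = 1e-12)
  expect_equal(back$pi, fit$pi, tolerance = 1e-12)
  expect_equal(predict_trajectory(back, 1, c(0, 50)),
               predict_trajectory(fit, 1, c(0, 50)), tolerance = 1e-10)
})
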