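# Small in-code fixtures shared across test files.

tiny_subjects <- function() {
  data.frame(
    subject_id = c("A", "B", "C"),
    diagnosis_year = c(2010L, 2012L, 2015L),
    ddd = as.Date(c("2010-03-01", "2012-07-15", "2015-01-20")),
    age_at_ddd = c(55.2, 63.0, 48.5),
    sex = c("male", "female", "male"),
    ethnicity = c("Chinese", "Malay", "Indian"),
    prior_cvd = c(0L, 1L, 0L),
    prior_hf = c(0L, 0L, 1L),
    med_metformin = c(1L, 1L, 0L))
}

tiny_cohort <- function() {
  mea <- data.frame(
    subject_id = rep(c("A", "B", "C"), c(3L, 2L, 4L)),
    t_weeks = c(0, 10, 30, 0, 52, 0, 26, 52, 104),
    hba1c = c(6.5, 6.8, 7.0, 8.2, 8.0, 10.5, 9.8, 9.0, 8.5))
  ev <- data.frame(
    subject_id = c("A", "A", "B", "C"),
    L_weeks = c(0, 0, 10, 0),
    R_weeks = c(120, 120, 80, 110),
    t_weeks = c(40, 90, NA, 60))
  cohort(tiny_subjects(), mea, ev)
}

# simulate windows with a single binary covariate from an NHPP truth
sim_binary_windows <- function(n, params, prevalence, L = 0, R = 520, seed = 1) {
  set.seed(seed)
  x <- as.numeric(stats::runif(n) < prevalence)
  ids <- sprintf("W%05d", seq_len(n))
  ev <- vector("list", n)
  for (i in seq_len(n)) {
    tt <- simulate_events(params, x[i], L, R)
    if (length(tt)) ev[[i]] <- data.frame(subject_id = ids[i], t = tt)
  }
  event_windows(ids, rep(L, n), rep(R, n),
                X = matrix(x, ncol = 1, dimnames = list(NULL, "grp")),
                events = do.call(rbind, ev))
}

# well-separated flat-trajectory mixture for recovery tests
flat_mix_config <- function(levels, pi, sigma_b = 0.1, sigma_e = 0.2,
                            followup = c(100, 400)) {
  synthetic_config(K = length(levels), pi = pi,
                   class_trajectories = lapply(levels, traj_stable),
                   sigma_b = sigma_b, sigma_e = sigma_e, followup = followup)
}
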