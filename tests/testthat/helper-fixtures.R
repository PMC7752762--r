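# small cohort configuration for fast tests
small_config <- function(seed = 1, ...) {
  args <- list(n_per_group = c("HLC-F" = 30L, "HLC-M" = 30L,
                               "HLF-F" = 30L, "HLF-M" = 30L),
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(cohort_config, args)
}

# noise-free configuration: deterministic trajectories, full retention
noisefree_config <- function(seed = 1, ...) {
  small_config(seed = seed,
               subject_sd_kg = 0, residual_sd_kg = 0,
               recall_noise_sd_g = 0, adherence_effect_kg = 0,
               retention_prob = 1, dexa_missing_fraction = 0, ...)
}

# printed two-group longitudinal fixture: 6 subjects x 2 visits
lmm_fixture <- function() {
  data.frame(
    id = rep(sprintf("S%d", 1:6), each = 2),
    grp = rep(c("A", "B"), each = 6),
    visit = rep(c("v1", "v2"), 6),
    y = c(5.1, 6.3, 4.8, 5.9, 5.5, 6.1,
          7.2, 8.4, 6.9, 8.1, 7.5, 8.0))
}

fixture_design <- function(d) {
  stats::model.matrix(~ grp + visit, d)
}

# direct generalized-least-squares oracle: dense V built from the variance
# components, beta = (X' Vinv X)^-1 X' Vinv y
gls_oracle <- function(y, X, subject, s2b, s2e) {
  Z <- stats::model.matrix(~ 0 + factor(subject))
  V <- s2e * diag(length(y)) + s2b * tcrossprod(Z)
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  drop(solve(A, t(X) %*% Vi %*% y))
}

# simulate a generic random-intercept longitudinal dataset for
# cross-checking against lme4/lmerTest
sim_longitudinal <- function(seed, n_subj = 60, n_visit = 3,
                             s2b = 4, s2e = 1) {
  set.seed(seed)
  id <- rep(seq_len(n_subj), each = n_visit)
  g <- rep(rep(c("A", "B"), length.out = n_subj), each = n_visit)
  visit <- factor(rep(seq_len(n_visit), n_subj))
  x <- stats::rnorm(n_subj * n_visit)
  b <- stats::rnorm(n_subj, 0, sqrt(s2b))
  y <- 1 + 0.5 * (g == "B") + 0.3 * as.integer(visit) + 0.2 * x +
    b[id] + stats::rnorm(n_subj * n_visit, 0, sqrt(s2e))
  data.frame(id = factor(id), g = g, visit = visit, x = x, y = y)
}

# full-mediation stress scenario: no direct group effect, the entire outcome
# signal flows through the latent adherence trait, and noise sources are kept
# small so WASA is a near-perfect proxy. Baseline weights are homogeneous
# because the DS weight-normalization otherwise injects between-person noise
# that caps the WASA-trait correlation near 0.9
full_mediation_config <- function(seed) {
  small_config(
    seed = seed, adherence_effect_kg = -15,
    true_change_12mo = list(
      weight = c("HLC-F" = -5, "HLC-M" = -5, "HLF-F" = -5, "HLF-M" = -5),
      fat_mass = c("HLC-F" = -3, "HLC-M" = -3, "HLF-F" = -3, "HLF-M" = -3),
      lean_mass = c("HLC-F" = -1, "HLC-M" = -1, "HLF-F" = -1, "HLF-M" = -1)),
    baseline_weight_mean_kg = 95, baseline_weight_sd_kg = 0.5,
    subject_sd_kg = 0.1, residual_sd_kg = 0.1, recall_noise_sd_g = 1,
    time_fraction = c("3" = 1, "6" = 1),  # adherence effect constant over
    retention_prob = 1)                   # months: one WASA slope suffices
}
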