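test_that("REML fixed effects match a direct GLS oracle on the printed fixture", {
  d <- lmm_fixture()
  X <- fixture_design(d)
  fit <- lmm_reml(d$y, X, d$id)
  beta_oracle <- gls_oracle(d$y, X, d$id, fit$sigma2_subject,
                            fit$sigma2_residual)
  expect_equal(unname(fit$beta), unname(beta_oracle), tolerance = 1e-8)
  expect_true(fit$converged)
  expect_gte(fit$sigma2_subject, 0)
  expect_gte(fit$sigma2_residual, 0)
})

test_that("REML objective is locally optimal at the returned components", {
  d <- lmm_fixture()
  X <- fixture_design(d)
  fit <- lmm_reml(d$y, X, d$id)
  obj <- function(s2b, s2e) wasa:::.lmm_neg2_full(fit$pre, s2b, s2e)
  at_opt <- obj(fit$sigma2_subject, fit$sigma2_residual)
  for (f in c(0.9, 0.95, 1.05, 1.1)) {
    expect_gte(obj(fit$sigma2_subject * f, fit$sigma2_residual), at_opt - 1e-8)
    expect_gte(obj(fit$sigma2_subject, fit$sigma2_residual * f), at_opt - 1e-8)
  }
})

test_that("with subject variance fixed at zero the fit is ordinary least squares", {
  d <- lmm_fixture()
  X <- fixture_design(d)
  fit <- lmm_reml(d$y, X, d$id, fix_sigma2_subject = 0)
  ols <- lm(y ~ grp + visit, data = d)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(unname(fit$vcov_beta), unname(vcov(ols)), tolerance = 1e-10)
  cc <- c(0, 1, 0)
  expect_lt(abs(satterthwaite_df(fit, cc) - df.residual(ols)), 0.1)
})

test_that("identical within-subject responses give zero residual variance", {
  y <- c(3, 3, 3, 8, 8, 8)
  id <- rep(c("a", "b"), each = 3)
  X <- matrix(1, 6, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- lmm_reml(y, X, id)
  expect_lt(fit$sigma2_residual, 1e-4)
  # the restricted likelihood is unbounded for exactly-degenerate data; the
  # profiled-REML path converges to sigma2_subject = sum(d_i^2)/(n - p)
  # with d_i the subject-mean deviations from the grand mean (the same
  # limit lme4 returns on this fixture)
  d_i <- c(3, 8) - 5.5
  expect_equal(fit$sigma2_subject, sum(d_i^2) / (6 - 1), tolerance = 1e-3)
  skip_if_not_installed("lme4")
  ref <- suppressWarnings(suppressMessages(
    lme4::lmer(y ~ 1 + (1 | id), data = data.frame(y = y, id = id),
               REML = TRUE)))
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(fit$sigma2_subject, vc$vcov[1], tolerance = 1e-3)
})

test_that("estimates are invariant to row permutation and id relabeling", {
  co <- simulate_cohort(small_config(seed = 19))
  fit1 <- fit_lmm(co$outcomes, co$participants, "weight")
  set.seed(1)
  oc <- co$outcomes[sample(nrow(co$outcomes)), ]
  parts <- co$participants[sample(nrow(co$participants)), ]
  map <- setNames(sprintf("Q%04d", seq_len(nrow(co$participants))),
                  sort(co$participants$participant_id, decreasing = TRUE))
  oc$participant_id <- unname(map[oc$participant_id])
  parts$participant_id <- unname(map[parts$participant_id])
  fit2 <- fit_lmm(oc, parts, "weight")
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-6)
  expect_equal(fit1$sigma2_subject, fit2$sigma2_subject, tolerance = 1e-5)
})

test_that("fit agrees with the lme4/lmerTest reference on a generic dataset", {
  skip_if_not_installed("lmerTest")
  d <- sim_longitudinal(seed = 42)
  X <- model.matrix(~ g + visit + x, d)
  fit <- lmm_reml(d$y, X, d$id)
  ref <- lmerTest::lmer(y ~ g + visit + x + (1 | id), data = d, REML = TRUE)
  expect_equal(unname(fit$beta), unname(lme4::fixef(ref)), tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(fit$sigma2_subject, vc$vcov[1], tolerance = 1e-5)
  expect_equal(fit$sigma2_residual, vc$vcov[2], tolerance = 1e-5)
  # Satterthwaite df for the group contrast
  cc <- c(0, 1, 0, 0, 0)
  ct <- lmerTest::contest1D(ref, cc, ddf = "Satterthwaite")
  expect_equal(satterthwaite_df(fit, cc), ct$df, tolerance = 0.02)
  expect_equal(contrast_test(fit, cc)$p, ct$`Pr(>|t|)`, tolerance = 1e-4)
})

test_that("Satterthwaite df is bounded by the residual df and stable under tiny perturbations", {
  d <- sim_longitudinal(seed = 7, n_subj = 40)
  X <- model.matrix(~ g + visit + x, d)
  fit <- lmm_reml(d$y, X, d$id)
  for (j in seq_along(fit$beta)) {
    cc <- numeric(length(fit$beta)); cc[j] <- 1
    df <- satterthwaite_df(fit, cc)
    expect_gt(df, 1)
    expect_lte(df, fit$df_resid + 0.5)
  }
  # continuity in the variance components
  cc <- c(0, 1, 0, 0, 0)
  fit_pert <- fit
  fit_pert$sigma2_subject <- fit$sigma2_subject * (1 + 1e-7)
  expect_lt(abs(satterthwaite_df(fit, cc) - satterthwaite_df(fit_pert, cc)),
            0.01)
})

test_that("balanced between-subject contrast df matches the subject-means t test", {
  set.seed(11)
  m <- 15; k <- 4
  id <- rep(seq_len(2 * m), each = k)
  g <- rep(c("A", "B"), each = m * k)
  y <- 2 + 0.5 * (g == "B") + rnorm(2 * m, 0, 1.5)[id] +
    rnorm(2 * m * k, 0, 1)
  X <- model.matrix(~ g)
  fit <- lmm_reml(y, X, id)
  df <- satterthwaite_df(fit, c(0, 1))
  expect_lt(abs(df - (2 * m - 2)), 0.5)
})

test_that("participants lacking DEXA are excluded from the default weight model", {
  co <- simulate_cohort(cohort_config(seed = 25))
  fit <- fit_lmm(co$outcomes, co$participants, "weight")
  n_nodexa <- sum(is.na(co$participants$baseline_bodyfat_pct))
  expect_equal(unname(fit$n_excluded["missing_baseline_bodyfat"]) > 0, TRUE)
  fit_all <- fit_lmm(co$outcomes, co$participants, "weight",
                     analysis_set = "all")
  expect_gt(fit_all$n_subjects, fit$n_subjects)
})

test_that("fewer than two groups is an input error", {
  co <- simulate_cohort(small_config(seed = 1))
  one <- co$participants[co$participants$diet == "HLC" &
                           co$participants$sex == "F", ]
  expect_error(fit_lmm(co$outcomes, one, "weight"), "2 diet-sex groups")
})
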