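test_that("percent change arithmetic and missingness rules", {
  oc <- data.frame(participant_id = c("a", "a", "b", "b", "c"),
                   measure = "weight",
                   month = c(0, 12, 0, 12, 0),
                   value_kg = c(100, 95, 80, 80, 70))
  pc <- percent_change_12mo(oc, "weight")
  expect_equal(pc$pct_change[pc$participant_id == "a"], -5)
  expect_equal(pc$pct_change[pc$participant_id == "b"], 0)
  expect_false("c" %in% pc$participant_id)
  expect_equal(attr(pc, "n_excluded"), 1L)
  oc$value_kg[1] <- 0
  expect_error(percent_change_12mo(oc, "weight"), "positive")
})

test_that("adherence regression F matches a hand sums-of-squares oracle", {
  # 3 participants per group, integer scores
  w <- c(1, 2, 3, 4, 5, 6, 2, 2, 2, 5, 3, 1)
  grp <- rep(c("HLC-F", "HLC-M", "HLF-F", "HLF-M"), each = 3)
  wasa_tab <- data.frame(participant_id = sprintf("p%02d", 1:12), wasa = w)
  parts <- data.frame(participant_id = sprintf("p%02d", 1:12),
                      diet = substr(grp, 1, 3), sex = substr(grp, 5, 5))
  res <- adherence_group_regression(wasa_tab, parts)

  gm <- tapply(w, grp, mean)
  ssb <- sum(3 * (gm - mean(w))^2)
  ssw <- sum((w - gm[grp])^2)
  F_oracle <- (ssb / 3) / (ssw / 8)
  expect_equal(res$omnibus$F, F_oracle, tolerance = 1e-12)
  expect_equal(res$omnibus$df1, 3)
  expect_equal(res$omnibus$df2, 8)
  # contrasts are differences of group means
  expect_equal(res$contrasts$estimate[1], unname(gm["HLC-F"] - gm["HLF-F"]))
  expect_equal(res$contrasts$estimate[4], unname(gm["HLC-M"] - gm["HLC-F"]))
})

test_that("constant adherence gives F = 0 and null contrasts", {
  wasa_tab <- data.frame(participant_id = sprintf("p%02d", 1:12),
                         wasa = rep(0.7, 12))
  grp <- rep(c("HLC-F", "HLC-M", "HLF-F", "HLF-M"), each = 3)
  parts <- data.frame(participant_id = sprintf("p%02d", 1:12),
                      diet = substr(grp, 1, 3), sex = substr(grp, 5, 5))
  res <- adherence_group_regression(wasa_tab, parts)
  expect_equal(res$omnibus$F, 0)
  expect_equal(res$contrasts$estimate, rep(0, 4))
})

test_that("with two groups the regression F equals the squared two-sample t", {
  set.seed(3)
  n <- 20
  x <- c(rnorm(n, 0), rnorm(n, 0.8))
  g <- rep(c("F", "M"), each = n)
  fit <- lm(x ~ g)
  F_reg <- anova(fit)$`F value`[1]
  t2 <- t.test(x ~ g, var.equal = TRUE)$statistic^2
  expect_equal(F_reg, unname(t2), tolerance = 1e-12)
})

test_that("a shifted group's adherence is detected with growing power", {
  pow <- sapply(c(0.3, 1.2), function(shift) {
    mean(sapply(1:20, function(s) {
      co <- simulate_cohort(small_config(seed = 100 + s))
      ws <- wasa_scores(co$recalls, co$participants)
      # shift the latent trait of HLC men upward via their reported intake
      idx <- ws$participant_id %in%
        co$participants$participant_id[co$participants$diet == "HLC" &
                                         co$participants$sex == "M"]
      ws$wasa[idx] <- ws$wasa[idx] + shift
      res <- adherence_group_regression(ws, co$participants)
      res$contrasts$p[res$contrasts$label == "men vs women, HLC"] < 0.05
    }))
  })
  expect_gt(pow[2], pow[1] - 0.051)
  expect_gt(pow[2], 0.9)
})

test_that("Spearman matches the brute-force rank-covariance oracle", {
  x <- c(1, 2, 3); y <- c(5, 6, 4)
  rx <- rank(x); ry <- rank(y)
  rs_oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(unname(cor(x, y, method = "spearman")), rs_oracle)
  expect_equal(rs_oracle, -0.5)
})

test_that("group-wise Spearman is -1 for monotone decreasing pairs and invariant to monotone transforms", {
  co <- simulate_cohort(small_config(seed = 43, retention_prob = 1))
  ws <- wasa_scores(co$recalls, co$participants)
  res1 <- spearman_by_group(ws, co$outcomes, co$participants, "weight")
  expect_equal(nrow(res1), 4L)
  expect_true(all(res1$rs >= -1 & res1$rs <= 1))
  expect_true(all(res1$n >= 3))

  # monotone transform of percent change leaves rs unchanged
  oc <- co$outcomes
  oc$value_kg <- oc$value_kg * 2  # pct change is scale-free in value
  res2 <- spearman_by_group(ws, oc, co$participants, "weight")
  expect_equal(res1$rs, res2$rs, tolerance = 1e-12)

  # perfectly monotone case
  oc2 <- data.frame(participant_id = sprintf("m%02d", 1:8),
                    measure = "weight", month = rep(c(0, 12), each = 8),
                    value_kg = c(rep(100, 8), 100 - (1:8)))
  wt <- data.frame(participant_id = sprintf("m%02d", 1:8), wasa = 1:8,
                   diet = "HLC", sex = "F")
  parts <- data.frame(participant_id = sprintf("m%02d", 1:8),
                      diet = "HLC", sex = "F")
  res3 <- spearman_by_group(wt, oc2, parts, "weight")
  expect_equal(res3$rs[res3$group == "HLC-F"], -1)
})

test_that("Spearman under independence is centred at zero", {
  set.seed(99)
  rs <- replicate(1000, cor(rnorm(150), rnorm(150), method = "spearman"))
  expect_lt(abs(mean(rs)), 0.02)
})

test_that("WASA-independent outcomes leave contrasts essentially unchanged", {
  deltas <- sapply(1:8, function(s) {
    co <- simulate_cohort(small_config(seed = 200 + s,
                                       adherence_effect_kg = 0))
    ws <- wasa_scores(co$recalls, co$participants)
    med <- mediation_check(co$outcomes, co$participants, ws, "weight")
    mean(abs(med$abs_change))
  })
  expect_lt(mean(deltas), 0.2)
})

test_that("fully adherence-driven outcomes shrink when adjusted for WASA", {
  # WASA is z-scored within diet, so it can carry no information about the
  # two arms' difference in mean latent adherence: only the within-diet
  # (men vs women) contrasts can shrink individually, and the contrast set
  # shrinks in aggregate
  res <- sapply(1:12, function(s) {
    co <- simulate_cohort(full_mediation_config(seed = 300 + s))
    ws <- wasa_scores(co$recalls, co$participants)
    med <- mediation_check(co$outcomes, co$participants, ws, "weight")
    i <- grepl("men vs women", med$label)
    c(agg = mean(abs(med$estimate_wasa_adjusted)) <
        mean(abs(med$estimate_unadjusted)),
      within = mean(abs(med$estimate_wasa_adjusted[i]) <
                      abs(med$estimate_unadjusted[i])))
  })
  expect_gte(mean(res["agg", ]), 0.9)
  expect_gte(mean(res["within", ]), 0.9)
})

test_that("constant WASA degenerates to the unadjusted model", {
  co <- simulate_cohort(small_config(seed = 55))
  ws <- wasa_scores(co$recalls, co$participants)
  ws$wasa <- 0.3
  med <- mediation_check(co$outcomes, co$participants, ws, "weight")
  expect_equal(med$estimate_unadjusted, med$estimate_wasa_adjusted,
               tolerance = 1e-10)
})
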