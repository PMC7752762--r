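test_that("Kruskal-Wallis reproduces the hand-computed H on {1,2,3} vs {4,5,6}", {
  # H = 12/(N(N+1)) * sum(R_g^2/n_g) - 3(N+1) with no ties:
  # 12/42 * (36/3 + 225/3) - 21 = 3.857142...
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw$H, 3.857143, tolerance = 1e-6)
  expect_equal(kw$df, 1L)
  expect_equal(kw$p, stats::pchisq(kw$H, 1, lower.tail = FALSE))
})

test_that("Kruskal-Wallis is invariant to strictly monotone transforms", {
  set.seed(5)
  x <- rnorm(40)
  g <- rep(letters[1:4], 10)
  k1 <- kruskal_wallis(x, g)
  k2 <- kruskal_wallis(exp(x), g)
  k3 <- kruskal_wallis(x^3, g)
  expect_equal(k1$H, k2$H, tolerance = 1e-12)
  expect_equal(k1$H, k3$H, tolerance = 1e-12)
})

test_that("identical values give H = 0, p = 1; k = 2 equals the Wilcoxon chi-square form", {
  expect_equal(kruskal_wallis(rep(2, 9), rep(c("a", "b", "c"), 3)),
               list(H = 0, df = 2L, p = 1))
  set.seed(6)
  x <- rnorm(30); g <- rep(c("a", "b"), 15)
  kw <- kruskal_wallis(x, g)
  # squared standardized rank-sum statistic on the same ranks
  r <- rank(x); n1 <- 15; n2 <- 15; N <- 30
  W <- sum(r[g == "a"])
  z2 <- (W - n1 * (N + 1) / 2)^2 / (n1 * n2 * (N + 1) / 12)
  expect_equal(kw$H, z2, tolerance = 1e-12)
})

test_that("Dunn-Bonferroni flags agree with a permutation oracle on a 4-group fixture", {
  vals <- c(1.2, 0.8, 1.5, 0.9, 1.1, 1.3,
            1.0, 1.4, 0.7, 1.6, 1.05, 0.95,
            1.25, 0.85, 1.45, 1.15, 0.75, 1.35,
            11.2, 10.8, 11.5, 10.9, 11.1, 11.3)
  g <- rep(c("A", "B", "C", "D"), each = 6)
  res <- dunn_bonferroni(vals, g)
  expect_equal(nrow(res$pairs), 6L)
  with_d <- res$pairs$group1 == "D" | res$pairs$group2 == "D"
  expect_true(all(res$pairs$significant[with_d]))
  expect_false(any(res$pairs$significant[!with_d]))

  # permutation oracle: permute labels, recompute the Dunn z per pair
  r <- rank(vals)
  n <- table(g)
  v0 <- length(vals) * (length(vals) + 1) / 12
  z_of <- function(lab) {
    rbar <- tapply(r, lab, mean)
    cmb <- combn(names(n), 2)
    sapply(seq_len(ncol(cmb)), function(k) {
      a <- cmb[1, k]; b <- cmb[2, k]
      (rbar[[a]] - rbar[[b]]) / sqrt(v0 * (1 / n[[a]] + 1 / n[[b]]))
    })
  }
  z_obs <- z_of(g)
  set.seed(1234)
  B <- 1e4
  exceed <- matrix(FALSE, B, 6)
  for (i in seq_len(B))
    exceed[i, ] <- abs(z_of(sample(g))) >= abs(z_obs) - 1e-12
  p_perm <- pmin((colSums(exceed) + 1) / (B + 1) * 6, 1)
  expect_equal(unname(p_perm < 0.05), res$pairs$significant)
})

test_that("null data give all adjusted p = 1 and 4 groups give 6 pairs", {
  res <- dunn_bonferroni(rep(c(1, 2, 3), 4), rep(letters[1:4], each = 3))
  expect_equal(nrow(res$pairs), 6L)
  expect_true(all(res$pairs$p_adjusted == 1))
})

test_that("Fisher 2x2 enumerates the hypergeometric exactly", {
  res <- fisher_exact_rxc(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
  expect_equal(res$p, 34 / 70, tolerance = 1e-12)
  expect_equal(res$method, "exact")
  # identical rows carry no association
  expect_equal(fisher_exact_rxc(matrix(c(5, 2, 5, 2), 2, byrow = TRUE))$p, 1)
})

test_that("Fisher 2x2 agrees with the classical rule to 1e-12 across tables", {
  set.seed(8)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_rxc(tab)$p, fisher.test(tab)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("zero margins are dropped without changing the p value", {
  tab <- matrix(c(3, 1, 0, 1, 3, 0), 2, byrow = TRUE)  # zero third column
  expect_warning(res <- fisher_exact_rxc(tab), "zero")
  expect_equal(res$p, 34 / 70, tolerance = 1e-12)
  tab2 <- rbind(c(3, 1), c(1, 3), c(0, 0))
  expect_warning(res2 <- fisher_exact_rxc(tab2), "zero")
  expect_equal(res2$p, 34 / 70, tolerance = 1e-12)
})

test_that("large sparse tables fall back to Monte Carlo with a standard error", {
  set.seed(10)
  tab <- matrix(rpois(24, 30), 4, 6)
  res <- fisher_exact_rxc(tab, max_tables = 10)
  expect_equal(res$method, "monte-carlo")
  expect_true(is.finite(res$se) && res$se > 0)
  expect_true(res$p > 0 && res$p <= 1)
})

test_that("endorsement percentages follow the printed-counts rule", {
  counts <- food_attitude_counts()
  lfF <- proportion_endorsing(counts$lowfat_importance$F,
                              counts$lowfat_importance$endorsing)
  lfM <- proportion_endorsing(counts$lowfat_importance$M,
                              counts$lowfat_importance$endorsing)
  expect_equal(sum(counts$lowfat_importance$F), 346L)
  expect_equal(sum(counts$lowfat_importance$M), 263L)
  expect_equal(lfF$display, 58)
  expect_equal(lfM$display, 39)
  expect_equal(lfF$percent, 100 * 202 / 346)
  expect_equal(proportion_endorsing(counts$lowfat_importance$F,
                                    character())$percent, 0)
  expect_error(proportion_endorsing(counts$lowfat_importance$F, "Banana"),
               "unknown category")
})

test_that("group summary table reproduces its percentages from counts", {
  co <- simulate_cohort(small_config(seed = 61))
  parts <- co$participants
  parts$mets <- rep(c("Yes", "No"), length.out = nrow(parts))
  tab <- group_summary_table(parts,
                             continuous = "baseline_weight_kg",
                             categorical = "mets")
  yes_row <- tab[tab$category == "Yes", ]
  n_yes <- sum(parts$mets == "Yes" & parts$diet == "HLC" & parts$sex == "F")
  n_grp <- sum(parts$diet == "HLC" & parts$sex == "F")
  expect_match(yes_row[["HLC-F"]],
               sprintf("%d \\(%.1f%%\\)", n_yes, 100 * n_yes / n_grp))
})
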