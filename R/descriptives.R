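#' Kruskal-Wallis rank test
#'
#' Rank-based omnibus test of identical distributions across groups, with
#' tie correction; p from the chi-square approximation on `k - 1` df.
#' Thin wrapper around [stats::kruskal.test()] returning the pieces the
#' descriptive tables need.
#'
#' @param values numeric vector.
#' @param group_labels grouping vector of the same length.
#' @return list `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, group_labels) {
  g <- factor(group_labels)
  if (nlevels(g) < 2 || any(table(g) == 0))
    stop("need at least 2 non-empty groups", call. = FALSE)
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = nlevels(g) - 1L, p = 1))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Dunn's post-hoc pairwise test with Bonferroni adjustment
#'
#' Rank-based pairwise comparisons following a Kruskal-Wallis test. For
#' groups \eqn{a, b} the statistic is
#' \deqn{z = \frac{\bar R_a - \bar R_b}
#'   {\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum (t^3 - t)}{12(N-1)}\right)
#'     \left(\frac{1}{n_a} + \frac{1}{n_b}\right)}}}
#' with average ranks and the usual tie correction. Two-sided p values are
#' multiplied by the number of pairs (Bonferroni) and capped at 1;
#' significance letters mark, for each group, the set of groups it does
#' *not* differ from at adjusted p < 0.05 (shared letters = not
#' significantly different).
#'
#' @param values numeric vector.
#' @param group_labels grouping vector (at least 3 groups).
#' @param alpha significance level for the letter display.
#' @return list with `pairs` (data frame: `group1`, `group2`, `z`, `p_raw`,
#'   `p_adjusted`, `significant`) and `letters` (named character vector).
#' @export
dunn_bonferroni <- function(values, group_labels, alpha = 0.05) {
  g <- factor(group_labels)
  if (nlevels(g) < 3) stop("Dunn's test needs at least 3 groups", call. = FALSE)
  if (any(table(g) == 0))
    stop("empty group: ", paste(levels(g)[table(g) == 0], collapse = ", "),
         call. = FALSE)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  n <- table(g)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term

  lev <- levels(g)
  cmb <- utils::combn(lev, 2)
  m <- ncol(cmb)
  pairs <- do.call(rbind, lapply(seq_len(m), function(k) {
    a <- cmb[1, k]; b <- cmb[2, k]
    se <- sqrt(v0 * (1 / n[[a]] + 1 / n[[b]]))
    z <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    data.frame(group1 = a, group2 = b, z = z, p_raw = p,
               p_adjusted = min(p * m, 1), stringsAsFactors = FALSE)
  }))
  pairs$significant <- pairs$p_adjusted < alpha

  # letter display: connected components of the "not significantly
  # different" graph get shared letters
  letters_out <- stats::setNames(rep("", length(lev)), lev)
  next_letter <- 1L
  for (k in seq_len(m)) {
    if (!pairs$significant[k]) {
      lab <- letters[next_letter]
      next_letter <- next_letter + 1L
      letters_out[pairs$group1[k]] <- paste0(letters_out[pairs$group1[k]], lab)
      letters_out[pairs$group2[k]] <- paste0(letters_out[pairs$group2[k]], lab)
    }
  }
  list(pairs = pairs, letters = letters_out)
}

# two-sided 2x2 Fisher p by direct hypergeometric enumeration: sum the
# probabilities of all tables (with the observed margins) whose probability
# does not exceed the observed table's
.fisher_2x2 <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  pr <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

#' Fisher's exact test for an r x c contingency table
#'
#' Two-sided exact (Freeman-Halton) test of independence. 2x2 tables are
#' enumerated directly from the hypergeometric distribution (sum of the
#' probabilities of all tables no more probable than the observed one).
#' Larger tables are evaluated exactly while the number of tables with the
#' observed margins is at most `max_tables`; beyond that a Monte Carlo
#' estimate with at least `1e5` sampled tables is returned together with
#' its standard error. Rows or columns whose margin is zero are dropped
#' with a warning (they carry no information about association).
#'
#' @param contingency_table matrix of non-negative integer counts.
#' @param max_tables enumeration budget before switching to Monte Carlo.
#' @param B Monte Carlo sample size (minimum 1e5).
#' @return list `p`, `method` (`"exact"` or `"monte-carlo"`), `se`
#'   (`NA` for exact).
#' @export
fisher_exact_rxc <- function(contingency_table, max_tables = 1e7, B = 1e5) {
  tab <- as.matrix(contingency_table)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers", call. = FALSE)
  zr <- rowSums(tab) == 0; zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warning("dropping ", sum(zr), " zero row(s) and ", sum(zc),
            " zero column(s)", call. = FALSE)
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2)
    return(list(p = 1, method = "exact", se = NA_real_))
  if (nrow(tab) == 2 && ncol(tab) == 2)
    return(list(p = min(.fisher_2x2(tab), 1), method = "exact",
                se = NA_real_))

  # rough upper bound on the number of tables with the observed margins
  n_tab <- prod(pmin(rep(rowSums(tab), ncol(tab) - 1),
                     rep(colSums(tab)[-ncol(tab)], each = nrow(tab))) + 1)
  if (n_tab <= max_tables) {
    p <- stats::fisher.test(tab, workspace = 2e7)$p.value
    return(list(p = min(p, 1), method = "exact", se = NA_real_))
  }
  B <- max(B, 1e5)
  logp_tab <- function(t) sum(lfactorial(rowSums(t))) +
    sum(lfactorial(colSums(t))) - lfactorial(sum(t)) - sum(lfactorial(t))
  lp_obs <- logp_tab(tab)
  draws <- stats::r2dtable(B, rowSums(tab), colSums(tab))
  hits <- vapply(draws, function(t) logp_tab(t) <= lp_obs + 1e-7, logical(1))
  p <- (1 + sum(hits)) / (B + 1)
  list(p = p, method = "monte-carlo", se = sqrt(p * (1 - p) / B))
}

#' Percentage of a group endorsing selected response categories
#'
#' Computes `100 * sum(counts in categories of interest) / n`, with the
#' denominator the group's full randomized n (missing responses stay in the
#' denominator as their own category).
#'
#' @param counts_by_category named integer vector of response counts.
#' @param categories_of_interest character vector of category names to sum.
#' @param denominator total n; defaults to `sum(counts_by_category)`.
#' @return list `percent` (unrounded), `display` (rounded to the nearest
#'   integer), `count`.
#' @export
proportion_endorsing <- function(counts_by_category, categories_of_interest,
                                 denominator = sum(counts_by_category)) {
  unknown <- setdiff(categories_of_interest, names(counts_by_category))
  if (length(unknown))
    stop("unknown category label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cnt <- sum(counts_by_category[categories_of_interest])
  pct <- 100 * cnt / denominator
  list(percent = pct, display = round(pct), count = cnt)
}

#' Baseline descriptive table by diet-sex group
#'
#' Mean (SD) per group with a Kruskal-Wallis omnibus p and Dunn-Bonferroni
#' significance letters for continuous variables; count (percent, over the
#' group's randomized n, missing included as a category) with a Fisher
#' exact p for categorical variables.
#'
#' @param data data frame containing `sex`, `diet` and the variables.
#' @param continuous,categorical character vectors of column names.
#' @return data frame with one row per variable (and per category for
#'   categorical variables).
#' @export
group_summary_table <- function(data, continuous = character(),
                                categorical = character()) {
  data$group <- group_factor(data$diet, data$sex)
  lev <- levels(data$group)
  rows <- list()
  for (v in continuous) {
    x <- data[[v]]
    ok <- !is.na(x)
    kw <- kruskal_wallis(x[ok], data$group[ok])
    letters_v <- tryCatch(dunn_bonferroni(x[ok], data$group[ok])$letters,
                          error = function(e) stats::setNames(rep("", 4), lev))
    cells <- vapply(lev, function(g) {
      xi <- x[data$group == g & ok]
      sprintf("%.1f (±%.1f)%s", mean(xi), stats::sd(xi), letters_v[[g]])
    }, character(1))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, category = "", t(cells),
      p = format.pval(kw$p, digits = 3),
      missing = sum(!ok), stringsAsFactors = FALSE, check.names = FALSE)
  }
  for (v in categorical) {
    x <- addNA(factor(data[[v]]), ifany = TRUE)
    levels(x)[is.na(levels(x))] <- "Missing"
    tab <- table(x, data$group)
    p <- fisher_exact_rxc(t(tab[rownames(tab) != "Missing", , drop = FALSE]))$p
    for (cat_i in rownames(tab)) {
      cells <- vapply(lev, function(g) {
        n_g <- sum(data$group == g)
        sprintf("%d (%.1f%%)", tab[cat_i, g], 100 * tab[cat_i, g] / n_g)
      }, character(1))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, category = cat_i, t(cells),
        p = if (cat_i == rownames(tab)[1]) format.pval(p, digits = 3) else "",
        missing = NA_integer_, stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[3:6] <- lev
  rownames(out) <- NULL
  out
}

#' Printed food-attitude counts by sex
#'
#' The two baseline food-choice items — importance of eating low-fat food
#' on a typical day, and habitual avoidance of refined-carbohydrate foods —
#' as response counts for women (n = 346) and men (n = 263). These printed
#' counts are the input from which the endorsement percentages (58% vs 39%
#' for low-fat importance; 27% vs 18% for carbohydrate avoidance) are
#' computed with [proportion_endorsing()].
#'
#' @return nested list: one element per item, each with integer count
#'   vectors `F` and `M` and the `endorsing` category set.
#' @export
food_attitude_counts <- function() {
  list(
    lowfat_importance = list(
      F = c("Very important" = 45L, "Moderately important" = 157L,
            "A little important" = 107L, "Not at all" = 32L, "Missing" = 5L),
      M = c("Very important" = 23L, "Moderately important" = 79L,
            "A little important" = 115L, "Not at all" = 43L, "Missing" = 3L),
      endorsing = c("Very important", "Moderately important")),
    avoid_refined_carbs = list(
      F = c("Always" = 4L, "Very often" = 43L, "Often" = 48L,
            "Sometimes" = 103L, "Rarely" = 89L, "Never" = 54L, "Missing" = 5L),
      M = c("Always" = 3L, "Very often" = 21L, "Often" = 24L,
            "Sometimes" = 55L, "Rarely" = 97L, "Never" = 59L, "Missing" = 4L),
      endorsing = c("Always", "Very often", "Often")))
}
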