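#' Per-participant percent change in a measure from baseline to month 12
#'
#' `100 * (value_12 - value_0) / value_0` for every participant with both
#' endpoints observed; others are excluded and the count reported via the
#' `n_excluded` attribute.
#'
#' @param outcomes outcome records.
#' @param measure `"weight"`, `"fat_mass"` or `"lean_mass"`.
#' @return data frame `participant_id`, `pct_change`.
#' @export
percent_change_12mo <- function(outcomes,
                                measure = c("weight", "fat_mass", "lean_mass")) {
  measure <- match.arg(measure)
  oc <- outcomes[outcomes$measure == measure, , drop = FALSE]
  v0 <- oc[oc$month == 0, c("participant_id", "value_kg")]
  v12 <- oc[oc$month == 12, c("participant_id", "value_kg")]
  names(v0)[2] <- "value0"; names(v12)[2] <- "value12"
  n_any <- length(unique(oc$participant_id))
  d <- merge(v0, v12, by = "participant_id")
  if (any(d$value0 <= 0))
    stop("baseline value must be positive to form a percent change",
         call. = FALSE)
  out <- data.frame(participant_id = d$participant_id,
                    pct_change = 100 * (d$value12 - d$value0) / d$value0,
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_any - nrow(out)
  out
}

#' Regression of adherence on diet-sex group
#'
#' Ordinary least squares of the WASA score on the 4-level diet-sex group,
#' with the overall F test of any group difference and the four pairwise
#' comparisons of interest (t tests on `n - 4` df, unadjusted for
#' multiplicity), in WASA units.
#'
#' @param wasa a [wasa_scores()] table (or any data frame with
#'   `participant_id`, `wasa`).
#' @param participants participant table with `participant_id`, `sex`,
#'   `diet`.
#' @return list of class `wasa_adherence_model` with elements `omnibus`
#'   (`F`, `df1`, `df2`, `p`), `contrasts` (four rows), `group_means`, `n`.
#' @export
adherence_group_regression <- function(wasa, participants) {
  d <- merge(as.data.frame(wasa)[, c("participant_id", "wasa")],
             participants[, c("participant_id", "sex", "diet")],
             by = "participant_id")
  d <- d[!is.na(d$wasa), , drop = FALSE]
  d$group <- group_factor(d$diet, d$sex)
  counts <- table(d$group)
  if (any(counts < 2))
    stop("group(s) with fewer than 2 WASA scores: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)

  degenerate <- stats::var(d$wasa) == 0
  maybe_quiet <- if (degenerate) suppressWarnings else identity
  fit <- stats::lm(wasa ~ group, data = d)
  an <- maybe_quiet(stats::anova(fit))
  omnibus <- data.frame(F = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
                        p = an$`Pr(>F)`[1])
  if (degenerate) {  # constant scores: no association by definition
    omnibus$F <- 0
    omnibus$p <- 1
  }

  mu <- stats::coef(fit)
  V <- maybe_quiet(stats::vcov(fit))
  lev <- levels(d$group)
  # group-mean rows under treatment coding
  rows <- diag(length(mu)); dimnames(rows) <- list(lev, names(mu))
  rows[, 1] <- 1; rows[1, -1] <- 0
  for (i in 2:length(lev)) rows[i, -c(1, i)] <- 0
  pairs <- list(
    "HLC vs HLF, women" = rows["HLC-F", ] - rows["HLF-F", ],
    "HLC vs HLF, men"   = rows["HLC-M", ] - rows["HLF-M", ],
    "men vs women, HLF" = rows["HLF-M", ] - rows["HLF-F", ],
    "men vs women, HLC" = rows["HLC-M", ] - rows["HLC-F", ])
  df2 <- an$Df[2]
  contrasts <- do.call(rbind, Map(function(cc, lab) {
    est <- sum(cc * mu)
    se <- sqrt(drop(cc %*% V %*% cc))
    tval <- est / se
    qt <- stats::qt(0.975, df2)
    data.frame(label = lab, estimate = est, se = se, df = df2, t = tval,
               p = 2 * stats::pt(abs(tval), df2, lower.tail = FALSE),
               ci_low = est - qt * se, ci_high = est + qt * se,
               stringsAsFactors = FALSE)
  }, pairs, names(pairs)))
  rownames(contrasts) <- NULL

  structure(list(omnibus = omnibus, contrasts = contrasts,
                 group_means = tapply(d$wasa, d$group, mean),
                 n = nrow(d)),
            class = "wasa_adherence_model")
}

#' @export
print.wasa_adherence_model <- function(x, ...) {
  cat("Adherence (WASA) by diet-sex group, n =", x$n, "\n")
  cat(sprintf("  omnibus F(%d, %d) = %.3f, p = %.4g\n",
              x$omnibus$df1, x$omnibus$df2, x$omnibus$F, x$omnibus$p))
  df <- x$contrasts
  df$p <- format.pval(df$p, digits = 3)
  print(df, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Spearman correlation of adherence with 12-month percent change, by group
#'
#' For each diet-sex group and the requested measure, computes the Spearman
#' rank correlation (average ranks for ties) between WASA and the percent
#' change from baseline to month 12, with the t-approximation p value.
#' Participants missing either quantity are excluded.
#'
#' @param wasa a [wasa_scores()] table.
#' @param outcomes outcome records.
#' @param participants participant table.
#' @param measure outcome measure for the percent change.
#' @param exact use the exact permutation p value (only for groups with
#'   `n <= 10`; default uses the t approximation everywhere).
#' @return data frame: `group`, `measure`, `rs`, `p`, `n`. Groups with
#'   fewer than 3 pairs are flagged (`rs` kept when computable, `p` = `NA`).
#' @export
spearman_by_group <- function(wasa, outcomes, participants,
                              measure = c("weight", "fat_mass", "lean_mass"),
                              exact = FALSE) {
  measure <- match.arg(measure)
  pc <- percent_change_12mo(outcomes, measure)
  d <- merge(as.data.frame(wasa)[, c("participant_id", "wasa")], pc,
             by = "participant_id")
  d <- merge(d, participants[, c("participant_id", "sex", "diet")],
             by = "participant_id")
  d <- d[!is.na(d$wasa) & !is.na(d$pct_change), , drop = FALSE]
  d$group <- group_factor(d$diet, d$sex)
  out <- lapply(levels(d$group), function(g) {
    sub <- d[d$group == g, , drop = FALSE]
    n <- nrow(sub)
    if (n < 3)
      return(data.frame(group = g, measure = measure, rs = NA_real_,
                        p = NA_real_, n = n, stringsAsFactors = FALSE))
    ct <- suppressWarnings(stats::cor.test(sub$wasa, sub$pct_change,
                                           method = "spearman",
                                           exact = exact && n <= 10))
    p <- if (exact && n <= 10) ct$p.value else {
      # t approximation with average-rank ties
      rs <- ct$estimate
      tval <- rs * sqrt((n - 2) / (1 - rs^2))
      2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE)
    }
    data.frame(group = g, measure = measure, rs = unname(ct$estimate),
               p = unname(p), n = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Does adjusting for adherence change the group contrasts?
#'
#' Descriptive mediation check: refits the longitudinal change model with
#' WASA as an additional fixed effect and reports the four pairwise 12-month
#' contrasts side by side with the unadjusted ones. Both fits use the same
#' analysis set (participants with a WASA score) so the estimates are
#' comparable. If adherence mediated the group differences, the adjusted
#' estimates would shrink toward zero; similar estimates argue against
#' mediation. No formal indirect-effect test is computed.
#'
#' @param outcomes,participants,wasa as in [fit_lmm()].
#' @param measure outcome measure.
#' @param analysis_set passed to [fit_lmm()].
#' @return data frame of class `wasa_mediation`: per contrast,
#'   `estimate_unadjusted`, `estimate_wasa_adjusted`, `abs_change`,
#'   `rel_change`.
#' @export
mediation_check <- function(outcomes, participants, wasa,
                            measure = c("weight", "fat_mass", "lean_mass"),
                            analysis_set = c("dexa", "all")) {
  measure <- match.arg(measure)
  analysis_set <- match.arg(analysis_set)
  w <- as.data.frame(wasa)
  keep <- w$participant_id[!is.na(w$wasa)]
  parts <- participants[participants$participant_id %in% keep, , drop = FALSE]

  wconst <- stats::var(w$wasa[!is.na(w$wasa)])
  fit0 <- fit_lmm(outcomes, parts, measure, analysis_set = analysis_set)
  fit1 <- if (is.finite(wconst) && wconst > 0)
    fit_lmm(outcomes, parts, measure, wasa = wasa, analysis_set = analysis_set)
  else fit0  # constant WASA is collinear with the intercept; drop the term
  c0 <- pairwise_contrasts(fit0)
  c1 <- pairwise_contrasts(fit1)
  out <- data.frame(label = c0$label, measure = measure,
                    estimate_unadjusted = c0$estimate,
                    estimate_wasa_adjusted = c1$estimate,
                    stringsAsFactors = FALSE)
  out$abs_change <- out$estimate_wasa_adjusted - out$estimate_unadjusted
  out$rel_change <- ifelse(out$estimate_unadjusted != 0,
                           out$abs_change / abs(out$estimate_unadjusted), NA)
  class(out) <- c("wasa_mediation", "data.frame")
  attr(out, "fits") <- list(unadjusted = fit0, adjusted = fit1)
  out
}

#' @export
print.wasa_mediation <- function(x, ...) {
  cat("Mediation check: 12-month contrasts with and without WASA adjustment\n")
  print(as.data.frame(x), digits = 3, row.names = FALSE)
  invisible(x)
}
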