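#' Satterthwaite denominator degrees of freedom for a contrast
#'
#' Approximates the denominator degrees of freedom of the t statistic for a
#' single contrast \eqn{c'\beta} in a fitted random-intercept model by the
#' Satterthwaite method:
#' \deqn{\nu = \frac{2\,[\mathrm{var}(c'\hat\beta)]^2}
#'   {g' \,\Sigma_\theta\, g}, \qquad
#'   g_j = \frac{\partial}{\partial \theta_j}\, c'\,V_\beta(\theta)\,c,}
#' where \eqn{\theta = (\sigma_b^2, \sigma_e^2)} are the variance
#' components, \eqn{\Sigma_\theta} their asymptotic covariance from the REML
#' information matrix, and the gradient is obtained by central differences.
#' When the subject variance is zero (or fixed at zero) the model is
#' ordinary least squares and the degrees of freedom reduce exactly to the
#' residual degrees of freedom \eqn{n - p}.
#'
#' @param fit a `wasa_lmm` fit.
#' @param contrast_vector numeric vector conformable with `coef(fit)`.
#' @return degrees of freedom (real-valued, capped at the residual df).
#' @export
satterthwaite_df <- function(fit, contrast_vector) {
  stopifnot(inherits(fit, "wasa_lmm"))
  cc <- as.numeric(contrast_vector)
  if (length(cc) != length(fit$beta))
    stop("contrast vector has length ", length(cc), ", expected ",
         length(fit$beta), call. = FALSE)
  if (fit$theta_dim == 1L || fit$degenerate)
    return(fit$df_resid)
  var_c <- drop(cc %*% fit$vcov_beta %*% cc)
  th0 <- c(fit$sigma2_subject, fit$sigma2_residual)
  if (any(!is.finite(fit$vcov_theta)))
    stop("singular information for variance components (",
         paste(colnames(fit$vcov_theta), collapse = ", "),
         "); cannot form Satterthwaite df", call. = FALSE)
  fvar <- function(th) {
    parts <- .lmm_parts(fit$pre, th[1] / th[2])
    th[2] * drop(cc %*% chol2inv(parts$R) %*% cc)
  }
  h <- pmax(th0 * 1e-4, 1e-8)
  g <- vapply(1:2, function(j) {
    e <- c(0, 0); e[j] <- h[j]
    (fvar(th0 + e) - fvar(th0 - e)) / (2 * h[j])
  }, numeric(1))
  denom <- drop(g %*% fit$vcov_theta %*% g)
  if (!is.finite(denom) || denom <= 0) return(fit$df_resid)
  min(max(2 * var_c^2 / denom, 1), fit$df_resid)
}

#' Test a single contrast of the fixed effects
#'
#' @param fit a `wasa_lmm` fit.
#' @param contrast_vector numeric vector conformable with `coef(fit)`.
#' @param label optional label carried into the result.
#' @param level confidence level for the interval.
#' @return a one-row data frame: `label`, `estimate`, `se`, `df`, `t`, `p`,
#'   `ci_low`, `ci_high`.
#' @export
contrast_test <- function(fit, contrast_vector, label = "contrast",
                          level = 0.95) {
  cc <- as.numeric(contrast_vector)
  est <- sum(cc * fit$beta)
  se <- sqrt(drop(cc %*% fit$vcov_beta %*% cc))
  df <- satterthwaite_df(fit, cc)
  tval <- if (se > 0) est / se else NA_real_
  p <- if (is.na(tval)) NA_real_ else
    2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  qt <- stats::qt(1 - (1 - level) / 2, df)
  data.frame(label = label, estimate = est, se = se, df = df, t = tval,
             p = p, ci_low = est - qt * se, ci_high = est + qt * se,
             stringsAsFactors = FALSE)
}

#' The four diet-sex pairwise contrasts of adjusted 12-month change
#'
#' Computes the four comparisons of interest for the fitted measure at month
#' 12 — HLC vs HLF within women, HLC vs HLF within men, men vs women within
#' HLF, and men vs women within HLC — as contrasts of the model's adjusted
#' 12-month change (covariates cancel in the difference). Each comes with a
#' Satterthwaite-df t test and 95\% CI; no multiplicity adjustment is
#' applied.
#'
#' @param fit a `wasa_lmm` fit from [fit_lmm()].
#' @param month month at which to compare groups (default 12).
#' @return a data frame of class `wasa_contrasts`, one row per comparison.
#' @examples
#' cohort <- simulate_cohort(cohort_config(seed = 3))
#' fit <- fit_lmm(cohort$outcomes, cohort$participants, "weight")
#' pairwise_contrasts(fit)
#' @export
pairwise_contrasts <- function(fit, month = 12) {
  rows <- lapply(fit$xlevels$group, function(g) .fixef_row(fit, g, month))
  names(rows) <- fit$xlevels$group
  pairs <- list(
    "HLC vs HLF, women" = rows[["HLC-F"]] - rows[["HLF-F"]],
    "HLC vs HLF, men"   = rows[["HLC-M"]] - rows[["HLF-M"]],
    "men vs women, HLF" = rows[["HLF-M"]] - rows[["HLF-F"]],
    "men vs women, HLC" = rows[["HLC-M"]] - rows[["HLC-F"]])
  out <- do.call(rbind, Map(function(cc, lab) contrast_test(fit, cc, lab),
                            pairs, names(pairs)))
  out$measure <- fit$measure %||% NA_character_
  rownames(out) <- NULL
  class(out) <- c("wasa_contrasts", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.wasa_contrasts <- function(x, ...) {
  cat("Pairwise contrasts of adjusted 12-month change",
      if (!all(is.na(x$measure))) paste0("(", x$measure[1], ")"), "\n")
  df <- as.data.frame(x)
  df$p <- format.pval(df$p, digits = 3)
  print(df[, c("label", "estimate", "se", "df", "t", "p",
               "ci_low", "ci_high")], digits = 4, row.names = FALSE)
  invisible(x)
}

#' Omnibus F test of equal adjusted 12-month changes across groups
#'
#' Tests the rank-3 null hypothesis that the four diet-sex groups' adjusted
#' changes at the given month are equal:
#' \eqn{F = (L\hat\beta)'(L V_\beta L')^{-1}(L\hat\beta)/q} with
#' \eqn{q = \mathrm{rank}(L) = 3}. The denominator degrees of freedom use
#' the multi-contrast Satterthwaite combination: eigen-decompose
#' \eqn{L V_\beta L' = P D P'}, compute a Satterthwaite df \eqn{\nu_i} for
#' each eigen-contrast (row of \eqn{P'L}), form
#' \eqn{E = \sum_{\nu_i > 2} \nu_i/(\nu_i - 2)} and set
#' \eqn{\nu_2 = 2E/(E - q)} when \eqn{E > q} (else the residual df).
#'
#' @param fit a `wasa_lmm` fit from [fit_lmm()].
#' @param month month at which groups are compared (default 12).
#' @return a one-row data frame: `F`, `df1`, `df2`, `p`.
#' @export
omnibus_group_test <- function(fit, month = 12) {
  rows <- lapply(fit$xlevels$group, function(g) .fixef_row(fit, g, month))
  ref <- rows[[1]]
  L <- do.call(rbind, lapply(rows[-1], function(r) r - ref))
  lmm_wald_f(fit, L)
}

#' Wald F test of a linear hypothesis with Satterthwaite df
#'
#' @param fit a `wasa_lmm` fit.
#' @param L hypothesis matrix, rows conformable with `coef(fit)`.
#' @return a one-row data frame: `F`, `df1`, `df2`, `p`.
#' @export
lmm_wald_f <- function(fit, L) {
  L <- rbind(L)
  if (qr(L)$rank < nrow(L)) stop("hypothesis matrix is rank deficient",
                                 call. = FALSE)
  q <- nrow(L)
  M <- L %*% fit$vcov_beta %*% t(L)
  Lb <- drop(L %*% fit$beta)
  Fstat <- drop(Lb %*% solve(M, Lb)) / q
  eg <- eigen(M, symmetric = TRUE)
  PtL <- t(eg$vectors) %*% L
  nu <- vapply(seq_len(q), function(i) satterthwaite_df(fit, PtL[i, ]),
               numeric(1))
  E <- sum(ifelse(nu > 2, nu / (nu - 2), 0))
  df2 <- if (E > q) 2 * E / (E - q) else fit$df_resid
  data.frame(F = Fstat, df1 = q, df2 = df2,
             p = stats::pf(Fstat, q, df2, lower.tail = FALSE))
}
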