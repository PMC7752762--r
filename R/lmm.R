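## Random-intercept linear mixed model by profiled REML.
##
## Model: y = X beta + Z b + e, b ~ N(0, sigma2_b I) over subjects,
## e ~ N(0, sigma2_e I). With lambda = sigma2_b / sigma2_e the marginal
## covariance is sigma2_e * (I + lambda Z Z'), block diagonal per subject, so
## every quantity reduces to per-subject sums: for subject i with n_i rows,
## V_i^{-1} = (I - w_i J)/sigma2_e with w_i = lambda/(1 + n_i lambda),
## log|V_i| = n_i log(sigma2_e) + log(1 + n_i lambda). The restricted
## likelihood is profiled over beta and sigma2_e and optimized over
## log(lambda) in one dimension.

# per-lambda building blocks shared by the profiled and full criteria
.lmm_parts <- function(pre, lambda) {
  w <- lambda / (1 + pre$n_i * lambda)
  A <- pre$XtX - crossprod(pre$Tx, w * pre$Tx)        # X' Vinv X * sigma2_e
  b <- pre$Xty - crossprod(pre$Tx, w * pre$ty)        # X' Vinv y * sigma2_e
  R <- chol(A)
  beta <- backsolve(R, backsolve(R, b, transpose = TRUE))
  rss <- max(pre$yty - sum(w * pre$ty^2) - sum(beta * b), 0)
  list(w = w, A = A, R = R, beta = drop(beta), rss = rss,
       logdetA = 2 * sum(log(diag(R))),
       logdetV1 = sum(log1p(pre$n_i * lambda)))       # log|I + lambda ZZ'|
}

# -2 * restricted log-likelihood profiled over beta and sigma2_e
.lmm_neg2_profiled <- function(pre, lambda) {
  parts <- .lmm_parts(pre, lambda)
  s2 <- parts$rss / pre$df_resid
  if (s2 <= 0) return(-Inf)  # exact fit; caller handles the degenerate case
  pre$df_resid * (1 + log(2 * pi * s2)) + parts$logdetV1 + parts$logdetA
}

# -2 * restricted log-likelihood at arbitrary (sigma2_b, sigma2_e)
.lmm_neg2_full <- function(pre, s2b, s2e) {
  if (s2e <= 0 || s2b < 0) return(Inf)
  lambda <- s2b / s2e
  parts <- .lmm_parts(pre, lambda)
  pre$df_resid * log(2 * pi) + pre$df_resid * log(s2e) +
    parts$logdetV1 + parts$logdetA + parts$rss / s2e
}

.lmm_precompute <- function(y, X, subject) {
  subject <- factor(subject)
  Tx <- rowsum(X, subject)
  ty <- drop(rowsum(y, subject))
  n_i <- as.vector(table(subject))
  list(y = y, X = X, subject = subject, Tx = Tx, ty = ty, n_i = n_i,
       XtX = crossprod(X), Xty = drop(crossprod(X, y)), yty = sum(y^2),
       n = length(y), p = ncol(X), df_resid = length(y) - ncol(X))
}

#' Fit a random-intercept linear mixed model by REML
#'
#' Low-level fitter working directly from a response vector, a fixed-effects
#' design matrix and a subject grouping. The restricted likelihood is
#' profiled over the fixed effects and the residual variance and optimized
#' over the single variance ratio \eqn{\lambda = \sigma_b^2/\sigma_e^2}
#' (convergence tolerance 1e-8 on the ratio). Aliased design columns are
#' dropped by pivoted QR, as in [stats::lm()]. The asymptotic covariance of
#' the variance components (`vcov_theta`) is the inverse of the REML
#' information matrix, obtained from a central-difference Hessian of the
#' restricted log-likelihood; when the subject variance is on (or fixed at)
#' the zero boundary the parameter reduces to the residual variance alone
#' and `vcov_theta` uses the exact chi-square form `2 sigma_e^4 / (n - p)`.
#'
#' @param y numeric response.
#' @param X fixed-effects design matrix (with intercept).
#' @param subject grouping factor, one random intercept per level.
#' @param fix_sigma2_subject if non-`NULL`, the subject variance is held at
#'   this value (0 gives the OLS limit) instead of being estimated.
#' @param tol convergence tolerance on the variance ratio.
#' @return an object of class `wasa_lmm`; see [fit_lmm()] for the fields.
#' @export
lmm_reml <- function(y, X, subject, fix_sigma2_subject = NULL, tol = 1e-8) {
  stopifnot(length(y) == nrow(X), length(subject) == length(y))
  ok <- stats::complete.cases(y, X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]; subject <- factor(subject[ok])

  qrX <- qr(X)
  kept <- qrX$pivot[seq_len(qrX$rank)]
  dropped <- colnames(X)[setdiff(seq_len(ncol(X)), kept)]
  X <- X[, sort(kept), drop = FALSE]
  pre <- .lmm_precompute(y, X, subject)
  if (pre$df_resid <= 0) stop("not enough observations to fit the model",
                              call. = FALSE)

  scale_y <- max(stats::var(y), .Machine$double.eps)
  degenerate <- FALSE
  if (!is.null(fix_sigma2_subject) && fix_sigma2_subject == 0) {
    lambda <- 0
    theta_dim <- 1L
    conv <- TRUE
  } else if (!is.null(fix_sigma2_subject)) {
    # hold sigma2_b fixed: optimize sigma2_e only (1-d in log sigma2_e)
    f <- function(ls2e) .lmm_neg2_full(pre, fix_sigma2_subject, exp(ls2e))
    opt <- stats::optimize(f, c(log(scale_y) - 25, log(scale_y) + 10),
                           tol = 1e-10)
    s2e_fixedcase <- exp(opt$minimum)
    lambda <- fix_sigma2_subject / s2e_fixedcase
    theta_dim <- 1L
    conv <- TRUE
  } else {
    f <- function(phi) .lmm_neg2_profiled(pre, exp(phi))
    at0 <- .lmm_neg2_profiled(pre, 0)
    if (!is.finite(at0) && .lmm_parts(pre, 0)$rss / pre$df_resid <= 0) {
      degenerate <- TRUE  # exact fit: zero residual variance
      lambda <- 0
      conv <- TRUE
      theta_dim <- 1L
    } else {
      opt <- stats::optimize(f, c(-20, 16), tol = tol / 10)
      lambda <- if (opt$objective < at0) exp(opt$minimum) else 0
      conv <- is.finite(opt$objective)
      theta_dim <- if (lambda > 1e-7) 2L else 1L
    }
  }

  parts <- .lmm_parts(pre, lambda)
  s2e <- if (!is.null(fix_sigma2_subject) && fix_sigma2_subject > 0)
    s2e_fixedcase else parts$rss / pre$df_resid
  s2b <- if (!is.null(fix_sigma2_subject)) fix_sigma2_subject else lambda * s2e
  beta <- parts$beta
  names(beta) <- colnames(X)
  Ainv <- chol2inv(parts$R)
  vcov_beta <- s2e * Ainv
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))

  ## asymptotic covariance of theta = (sigma2_subject, sigma2_residual)
  if (theta_dim == 2L && !degenerate) {
    h <- pmax(c(s2b, s2e) * 1e-4, 1e-8)
    f2 <- function(th) .lmm_neg2_full(pre, th[1], th[2])
    H <- matrix(0, 2, 2)
    th0 <- c(s2b, s2e)
    for (j in 1:2) for (k in j:2) {
      ej <- ek <- c(0, 0); ej[j] <- h[j]; ek[k] <- h[k]
      H[j, k] <- H[k, j] <-
        (f2(th0 + ej + ek) - f2(th0 + ej - ek) -
           f2(th0 - ej + ek) + f2(th0 - ej - ek)) / (4 * h[j] * h[k])
    }
    info <- H / 2  # information = Hessian of the negative restricted loglik
    vcov_theta <- tryCatch(solve(info), error = function(e) {
      matrix(NA_real_, 2, 2)
    })
  } else {
    vcov_theta <- matrix(0, 2, 2)
    vcov_theta[2, 2] <- if (pre$df_resid > 0) 2 * s2e^2 / pre$df_resid else NA
  }
  dimnames(vcov_theta) <- list(c("sigma2_subject", "sigma2_residual"),
                               c("sigma2_subject", "sigma2_residual"))

  log_reml <- if (degenerate) Inf else -0.5 * .lmm_neg2_full(pre, s2b, s2e)

  structure(list(
    beta = beta, vcov_beta = vcov_beta,
    sigma2_subject = s2b, sigma2_residual = s2e, lambda = lambda,
    vcov_theta = vcov_theta, theta_dim = theta_dim,
    n_obs = pre$n, n_subjects = nlevels(pre$subject),
    rank = pre$p, df_resid = pre$df_resid,
    converged = conv, degenerate = degenerate, log_reml = log_reml,
    dropped_terms = dropped,
    pre = pre, fitted = drop(X %*% beta)
  ), class = "wasa_lmm")
}

#' Fit the longitudinal change model for one body-composition measure
#'
#' Builds the change-from-baseline response for one measure (weight at
#' months 3/6/12; fat or lean mass at months 6/12), assembles the design —
#' diet-sex group (4 cells), month (categorical), their interaction,
#' baseline weight and baseline body-fat percentage as confounders, and
#' optionally WASA as an additional fixed effect for the mediation model —
#' and fits a participant-level random-intercept model by REML via
#' [lmm_reml()]. Incomplete longitudinal data are used as observed,
#' which is valid under a missing-at-random assumption.
#'
#' @param outcomes outcome records (`participant_id`, `measure`, `month`,
#'   `value_kg`).
#' @param participants participant table (`participant_id`, `sex`, `diet`,
#'   `baseline_weight_kg`, `baseline_bodyfat_pct`).
#' @param measure `"weight"`, `"fat_mass"` or `"lean_mass"`.
#' @param wasa optional [wasa_scores()] table; participants without a WASA
#'   are excluded when supplied.
#' @param analysis_set `"dexa"` (default): restrict to participants with a
#'   baseline body-fat measurement so both confounders enter the model;
#'   `"all"`: keep every participant with outcome data and drop the
#'   body-fat covariate instead.
#' @param fix_sigma2_subject passed to [lmm_reml()].
#' @return a `wasa_lmm` fit carrying, in addition to the [lmm_reml()]
#'   fields, the model terms and factor levels needed to form contrasts,
#'   and `n_excluded`, the participants dropped at each exclusion step.
#' @examples
#' cohort <- simulate_cohort(cohort_config(seed = 3))
#' fit <- fit_lmm(cohort$outcomes, cohort$participants, "weight")
#' fit
#' @export
fit_lmm <- function(outcomes, participants,
                    measure = c("weight", "fat_mass", "lean_mass"),
                    wasa = NULL,
                    analysis_set = c("dexa", "all"),
                    fix_sigma2_subject = NULL) {
  measure <- match.arg(measure)
  analysis_set <- match.arg(analysis_set)
  oc <- outcomes[outcomes$measure == measure, , drop = FALSE]
  base <- oc[oc$month == 0, c("participant_id", "value_kg")]
  names(base)[2] <- "value0"
  post <- oc[oc$month != 0, , drop = FALSE]
  d <- merge(post, base, by = "participant_id")
  d$chg <- d$value_kg - d$value0
  d <- merge(d, participants, by = "participant_id")
  d$group <- group_factor(d$diet, d$sex)
  if (nlevels(droplevels(d$group)) < 2)
    stop("need at least 2 diet-sex groups to fit the model", call. = FALSE)
  d$month_f <- factor(d$month)

  n_excluded <- c()
  if (analysis_set == "dexa") {
    drop_bf <- is.na(d$baseline_bodyfat_pct)
    n_excluded["missing_baseline_bodyfat"] <-
      length(unique(d$participant_id[drop_bf]))
    d <- d[!drop_bf, , drop = FALSE]
    rhs <- "group * month_f + baseline_weight_kg + baseline_bodyfat_pct"
  } else {
    rhs <- "group * month_f + baseline_weight_kg"
  }
  if (!is.null(wasa)) {
    d <- merge(d, as.data.frame(wasa)[, c("participant_id", "wasa")],
               by = "participant_id")
    no_w <- is.na(d$wasa)
    n_excluded["missing_wasa"] <- length(unique(d$participant_id[no_w]))
    d <- d[!no_w, , drop = FALSE]
    rhs <- paste(rhs, "+ wasa")
  }
  if (nrow(d) == 0) stop("no rows left after exclusions", call. = FALSE)
  d <- d[order(d$participant_id, d$month), , drop = FALSE]

  form <- stats::as.formula(paste("chg ~", rhs))
  mf <- stats::model.frame(form, data = d)
  X <- stats::model.matrix(form, mf)
  fit <- lmm_reml(stats::model.response(mf), X, d$participant_id,
                  fix_sigma2_subject = fix_sigma2_subject)
  fit$measure <- measure
  fit$months <- sort(unique(d$month))
  fit$terms <- stats::delete.response(stats::terms(mf))
  fit$xlevels <- stats::.getXlevels(stats::terms(mf), mf)
  fit$has_bodyfat <- analysis_set == "dexa"
  fit$has_wasa <- !is.null(wasa)
  fit$covariate_means <- c(
    baseline_weight_kg = mean(d$baseline_weight_kg),
    baseline_bodyfat_pct = if (fit$has_bodyfat) mean(d$baseline_bodyfat_pct) else NA,
    wasa = if (fit$has_wasa) mean(d$wasa) else NA)
  fit$n_excluded <- n_excluded
  fit$call <- match.call()
  fit
}

# design row for one diet-sex group at one month, covariates at their means;
# used to build contrasts in which the covariate entries cancel
.fixef_row <- function(fit, group, month) {
  nd <- data.frame(group = factor(group, levels = fit$xlevels$group),
                   month_f = factor(as.character(month),
                                    levels = fit$xlevels$month_f),
                   baseline_weight_kg = fit$covariate_means[["baseline_weight_kg"]])
  if (fit$has_bodyfat)
    nd$baseline_bodyfat_pct <- fit$covariate_means[["baseline_bodyfat_pct"]]
  if (fit$has_wasa) nd$wasa <- fit$covariate_means[["wasa"]]
  row <- stats::model.matrix(fit$terms, nd)
  row[1, names(fit$beta)]
}

#' @export
print.wasa_lmm <- function(x, ...) {
  cat("Random-intercept linear mixed model (REML)\n")
  if (!is.null(x$measure))
    cat("  measure:", x$measure, " months:",
        paste(x$months, collapse = ", "), "\n")
  cat(sprintf("  n_obs = %d, n_subjects = %d, converged = %s\n",
              x$n_obs, x$n_subjects, x$converged))
  cat(sprintf("  sigma2_subject = %.4g, sigma2_residual = %.4g\n",
              x$sigma2_subject, x$sigma2_residual))
  cat("  fixed effects:\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' @export
coef.wasa_lmm <- function(object, ...) object$beta

#' @export
vcov.wasa_lmm <- function(object, ...) object$vcov_beta

#' @export
logLik.wasa_lmm <- function(object, ...) {
  structure(object$log_reml, df = object$rank + 2, class = "logLik")
}

#' @export
fitted.wasa_lmm <- function(object, ...) object$fitted

#' @export
residuals.wasa_lmm <- function(object, type = c("marginal", "conditional"),
                               ...) {
  type <- match.arg(type)
  r <- object$pre$y - object$fitted
  if (type == "conditional") {
    # subtract the BLUP of the subject intercept
    w <- object$lambda / (1 + object$pre$n_i * object$lambda)
    bhat <- w * drop(rowsum(r, object$pre$subject))
    r <- r - bhat[as.integer(object$pre$subject)]
  }
  r
}

#' @export
summary.wasa_lmm <- function(object, ...) {
  se <- sqrt(diag(object$vcov_beta))
  df <- vapply(seq_along(object$beta), function(j) {
    cc <- numeric(length(object$beta)); cc[j] <- 1
    satterthwaite_df(object, cc)
  }, numeric(1))
  tval <- object$beta / se
  tab <- cbind(Estimate = object$beta, `Std. Error` = se, df = df,
               `t value` = tval,
               `Pr(>|t|)` = 2 * stats::pt(abs(tval), df, lower.tail = FALSE))
  out <- list(fit = object, coefficients = tab)
  class(out) <- "summary.wasa_lmm"
  out
}

#' @export
print.summary.wasa_lmm <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficient tests (Satterthwaite df):\n")
  stats::printCoefmat(x$coefficients, digits = 4, has.Pvalue = TRUE)
  invisible(x)
}
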