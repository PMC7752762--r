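#' Average the restricted macronutrient over a visit's recalls
#'
#' Averages the reported grams of the arm's restricted macronutrient
#' (carbohydrate on HLC, fat on HLF) across the up-to-three 24-hour recall
#' days collected at one participant-month.
#'
#' @param recalls_at_month data frame of recall records for a single
#'   participant-month (columns `carb_g`, `fat_g`; at most 3 rows).
#' @param restricted `"carb"` or `"fat"`.
#' @return mean grams, or `NA` when no recall exists.
#' @export
average_recalls <- function(recalls_at_month, restricted = c("carb", "fat")) {
  restricted <- match.arg(restricted)
  if (is.null(recalls_at_month) || nrow(recalls_at_month) == 0L)
    return(NA_real_)
  if (nrow(recalls_at_month) > 3L)
    stop("at most 3 recall days per participant-month, got ",
         nrow(recalls_at_month), call. = FALSE)
  col <- paste0(restricted, "_g")
  mean(recalls_at_month[[col]])
}

#' Deviation of reported intake from the 20 g goal
#'
#' The restricted-macronutrient goal of the limbo phase is 20 g/day; the
#' deviation is `target - mean`: reporting 50 g yields -30 g. The sign is
#' preserved (no absolute value, no capping), so intake below the goal gives
#' a positive deviation.
#'
#' @param mean_g averaged reported grams (non-negative).
#' @param target_g macronutrient goal in grams; default 20.
#' @return deviation in grams (vectorized; `NA` propagates).
#' @export
deviation_from_target <- function(mean_g, target_g = 20) {
  bad <- !is.na(mean_g) & mean_g < 0
  if (any(bad))
    stop("mean intake must be non-negative, got ",
         paste(mean_g[bad], collapse = ", "), call. = FALSE)
  target_g - mean_g
}

#' Weight-normalized deviation score (DS)
#'
#' Divides the deviation from the 20 g goal by baseline body weight, giving
#' grams of deviation per kg: a -30 g deviation at 60 kg yields DS = -1/2.
#'
#' @param deviation_g deviation in grams.
#' @param baseline_weight_kg baseline weight, strictly positive.
#' @return DS in g/kg (vectorized; `NA` propagates).
#' @export
deviation_score <- function(deviation_g, baseline_weight_kg) {
  bad <- !is.na(baseline_weight_kg) & baseline_weight_kg <= 0
  if (any(bad))
    stop("baseline weight must be positive", call. = FALSE)
  deviation_g / baseline_weight_kg
}

#' Z-score deviation scores within diet-by-month strata
#'
#' Normalizes DS within each (diet, month) stratum by subtracting the
#' stratum mean and dividing by the stratum SD. Strata pool both sexes so
#' that the resulting adherence scale is comparable across diet and sex.
#'
#' @param ds_table data frame with columns `participant_id`, `diet`,
#'   `month`, `ds`.
#' @param sd_convention `"sample"` (n-1 denominator, default) or
#'   `"population"` (n denominator).
#' @return the input with a `z` column added. Strata with fewer than two
#'   non-missing DS or zero SD are flagged with a warning and their `z` set
#'   missing.
#' @export
zscore_within_strata <- function(ds_table,
                                 sd_convention = c("sample", "population")) {
  sd_convention <- match.arg(sd_convention)
  stopifnot(all(c("diet", "month", "ds") %in% names(ds_table)))
  ds_table$z <- NA_real_
  for (key in unique(paste(ds_table$diet, ds_table$month))) {
    idx <- paste(ds_table$diet, ds_table$month) == key
    v <- ds_table$ds[idx]
    ok <- !is.na(v)
    if (sum(ok) < 2L) {
      warning("stratum ", key, ": fewer than 2 deviation scores; z set missing",
              call. = FALSE)
      next
    }
    mu <- mean(v[ok])
    s <- stats::sd(v[ok])
    if (sd_convention == "population")
      s <- s * sqrt((sum(ok) - 1) / sum(ok))
    if (!is.finite(s) || s == 0) {
      warning("stratum ", key, ": zero SD; z set missing", call. = FALSE)
      next
    }
    ds_table$z[idx] <- (v - mu) / s
  }
  ds_table
}

#' Average available z-scores into a WASA score
#'
#' The weight-adjusted standardized adherence (WASA) score is the mean of
#' whichever of the month-3, -6 and -12 z-scored deviation scores are
#' available; it is missing when none are. A score of 0 reflects average
#' adherence relative to all groups; positive scores reflect better-than-
#' average adherence.
#'
#' @param z_by_month numeric vector of up to 3 z values (may contain `NA`).
#' @return list with `wasa` and `n_months_available`.
#' @export
wasa_from_z <- function(z_by_month) {
  ok <- !is.na(z_by_month)
  list(wasa = if (any(ok)) mean(z_by_month[ok]) else NA_real_,
       n_months_available = sum(ok))
}

#' Compute WASA adherence scores for a cohort
#'
#' Runs the full adherence-scoring chain: average each participant-month's
#' recalls of the arm's restricted macronutrient (carbohydrate on HLC, fat
#' on HLF), take the deviation from the 20 g goal, normalize by baseline
#' weight (DS), z-score DS within diet-by-month strata, and average the
#' available post-randomization z-scores (months 3, 6, 12) into one WASA per
#' participant. Baseline (month 0) recalls never enter the score.
#'
#' @param recalls recall records (see [simulate_cohort()] for the schema).
#' @param participants participant table with `participant_id`, `diet`,
#'   `baseline_weight_kg`.
#' @param sd_convention passed to [zscore_within_strata()].
#' @return an object of class `wasa_scores`: a data frame with one row per
#'   participant and columns `participant_id`, `diet`, `sex` (if present),
#'   `ds_3`, `ds_6`, `ds_12`, `z_3`, `z_6`, `z_12`, `wasa`,
#'   `n_months_available`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(seed = 7))
#' ws <- wasa_scores(cohort$recalls, cohort$participants)
#' head(ws)
#' @export
wasa_scores <- function(recalls, participants,
                        sd_convention = c("sample", "population")) {
  sd_convention <- match.arg(sd_convention)
  stopifnot(all(c("participant_id", "month", "carb_g", "fat_g") %in% names(recalls)),
            all(c("participant_id", "diet", "baseline_weight_kg") %in%
                  names(participants)))
  no_wt <- is.na(participants$baseline_weight_kg)
  if (any(no_wt)) {
    warning(sum(no_wt), " participant(s) lack baseline weight; excluded from DS",
            call. = FALSE)
    participants <- participants[!no_wt, , drop = FALSE]
  }

  months <- c(3, 6, 12)
  post <- recalls[recalls$month %in% months, , drop = FALSE]
  post <- merge(post,
                participants[, c("participant_id", "diet", "baseline_weight_kg")],
                by = "participant_id")
  post$restricted_g <- ifelse(post$diet == "HLC", post$carb_g, post$fat_g)

  # per participant-month mean of the restricted macronutrient
  agg <- stats::aggregate(restricted_g ~ participant_id + month + diet +
                            baseline_weight_kg, data = post, FUN = mean)
  agg$deviation_g <- deviation_from_target(agg$restricted_g)
  agg$ds <- deviation_score(agg$deviation_g, agg$baseline_weight_kg)
  agg <- zscore_within_strata(agg, sd_convention = sd_convention)

  out <- participants[, intersect(c("participant_id", "diet", "sex"),
                                  names(participants)), drop = FALSE]
  for (m in months) {
    sub <- agg[agg$month == m, c("participant_id", "ds", "z")]
    names(sub) <- c("participant_id", paste0("ds_", m), paste0("z_", m))
    out <- merge(out, sub, by = "participant_id", all.x = TRUE)
  }
  zmat <- as.matrix(out[, paste0("z_", months)])
  out$n_months_available <- rowSums(!is.na(zmat))
  out$wasa <- ifelse(out$n_months_available > 0, rowMeans(zmat, na.rm = TRUE),
                     NA_real_)
  out <- out[order(out$participant_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("wasa_scores", "data.frame")
  out
}

#' @export
print.wasa_scores <- function(x, ...) {
  cat("WASA adherence scores:", nrow(x), "participants,",
      sum(!is.na(x$wasa)), "with a score\n")
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 3)
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}
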