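#' Configuration for a synthetic diet-trial cohort
#'
#' Builds a validated configuration for [simulate_cohort()]. Defaults emulate
#' a 12-month healthy low-carbohydrate (HLC) vs healthy low-fat (HLF)
#' parallel-group trial with four diet-sex analysis cells: group sizes
#' 179/125/167/138 (HLC-F, HLC-M, HLF-F, HLF-M), sex-specific baseline
#' anthropometrics, visit-wise dropout, a DEXA-unavailable subset, and a
#' latent adherence trait that links reported intake of the restricted
#' macronutrient to 12-month weight change.
#'
#' @param n_per_group named integer vector of randomized counts for the four
#'   diet-sex cells `HLC-F`, `HLC-M`, `HLF-F`, `HLF-M`.
#' @param baseline_weight_mean_kg,baseline_weight_sd_kg named numeric vectors
#'   (one entry per group) of baseline weight moments in kg.
#' @param baseline_bodyfat_mean_pct,baseline_bodyfat_sd_pct named numeric
#'   vectors (one entry per group) of baseline body-fat percentage moments.
#' @param true_change_12mo named list with elements `weight`, `fat_mass`,
#'   `lean_mass`, each a named numeric vector of mean 12-month changes (kg)
#'   per group. Negative values are losses.
#' @param time_fraction named numeric vector giving the fraction of the
#'   12-month change realized at months 3 and 6 (month 12 is always 1).
#' @param adherence_effect_kg shift in 12-month weight change (kg) per SD of
#'   the latent adherence trait; negative values mean more adherent
#'   participants lose more weight. Fat and lean mass receive fixed fractions
#'   (0.7 and 0.3) of this effect so that compartment changes stay consistent
#'   with the weight change.
#' @param intake_location,intake_scale location (g) and per-SD slope (g) of
#'   the reported restricted-macronutrient intake model
#'   `20 + softplus(intake_location - intake_scale * a_i + noise)`.
#' @param recall_noise_sd_g day-to-day reporting noise SD in grams.
#' @param retention_prob probability that a post-baseline visit is attended;
#'   either a single value or a named vector for months 3, 6, 12. Visits are
#'   dropped independently (missing at random given arm and sex).
#' @param dexa_missing_fraction fraction of enrollees (the earliest enrolled)
#'   with no DEXA access: they lack baseline body-fat percentage and all fat-
#'   and lean-mass records.
#' @param subject_sd_kg SD of the per-participant random intercept (kg).
#' @param residual_sd_kg SD of the visit-level measurement error (kg).
#' @param seed master seed; all random substreams derive from it.
#' @return an object of class `cohort_config` (a validated named list).
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_per_group = c("HLC-F" = 179L, "HLC-M" = 125L,
                                          "HLF-F" = 167L, "HLF-M" = 138L),
                          baseline_weight_mean_kg = c("HLC-F" = 88.9, "HLC-M" = 106.8,
                                                      "HLF-F" = 90.7, "HLF-M" = 105.7),
                          baseline_weight_sd_kg = c("HLC-F" = 12.5, "HLC-M" = 13.7,
                                                    "HLF-F" = 11.5, "HLF-M" = 13.9),
                          baseline_bodyfat_mean_pct = c("HLC-F" = 40.4, "HLC-M" = 30.3,
                                                        "HLF-F" = 41.0, "HLF-M" = 29.9),
                          baseline_bodyfat_sd_pct = c("HLC-F" = 4.0, "HLC-M" = 4.7,
                                                      "HLF-F" = 3.9, "HLF-M" = 4.5),
                          true_change_12mo = list(
                            weight    = c("HLC-F" = -5.00, "HLC-M" = -7.32,
                                          "HLF-F" = -5.00, "HLF-M" = -4.34),
                            fat_mass  = c("HLC-F" = -3.50, "HLC-M" = -4.80,
                                          "HLF-F" = -3.50, "HLF-M" = -3.29),
                            lean_mass = c("HLC-F" = -1.30, "HLC-M" = -2.72,
                                          "HLF-F" = -1.30, "HLF-M" = -1.39)),
                          time_fraction = c("3" = 0.6, "6" = 0.85),
                          adherence_effect_kg = -2,
                          intake_location = 80,
                          intake_scale = 30,
                          recall_noise_sd_g = 25,
                          retention_prob = c("3" = 0.90, "6" = 0.81, "12" = 0.79),
                          dexa_missing_fraction = 78 / 609,
                          subject_sd_kg = 4,
                          residual_sd_kg = 2,
                          seed = 1L) {
  groups <- c("HLC-F", "HLC-M", "HLF-F", "HLF-M")
  as_group_vec <- function(x, nm) {
    if (length(x) == 1L) x <- stats::setNames(rep(x, 4L), groups)
    if (is.null(names(x)) && length(x) == 4L) names(x) <- groups
    if (!all(groups %in% names(x)))
      stop("config error: '", nm, "' must be named for all groups ",
           paste(groups, collapse = ", "), call. = FALSE)
    x[groups]
  }
  chk_pos <- function(x, nm) {
    if (any(!is.finite(x)) || any(x <= 0))
      stop("config error: '", nm, "' must be positive and finite", call. = FALSE)
    x
  }
  chk_nonneg <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0))
      stop("config error: '", nm, "' must be non-negative", call. = FALSE)
    x
  }

  n_per_group <- as_group_vec(n_per_group, "n_per_group")
  if (any(n_per_group != round(n_per_group)) || any(n_per_group <= 0))
    stop("config error: 'n_per_group' must be positive integers", call. = FALSE)
  n_per_group <- stats::setNames(as.integer(round(n_per_group)), groups)

  baseline_weight_mean_kg <- chk_pos(as_group_vec(baseline_weight_mean_kg,
                                                  "baseline_weight_mean_kg"),
                                     "baseline_weight_mean_kg")
  baseline_weight_sd_kg <- chk_pos(as_group_vec(baseline_weight_sd_kg,
                                                "baseline_weight_sd_kg"),
                                   "baseline_weight_sd_kg")
  baseline_bodyfat_mean_pct <- as_group_vec(baseline_bodyfat_mean_pct,
                                            "baseline_bodyfat_mean_pct")
  if (any(baseline_bodyfat_mean_pct <= 0) || any(baseline_bodyfat_mean_pct >= 100))
    stop("config error: 'baseline_bodyfat_mean_pct' must lie in (0, 100)",
         call. = FALSE)
  baseline_bodyfat_sd_pct <- chk_pos(as_group_vec(baseline_bodyfat_sd_pct,
                                                  "baseline_bodyfat_sd_pct"),
                                     "baseline_bodyfat_sd_pct")

  if (!is.list(true_change_12mo) ||
      !all(c("weight", "fat_mass", "lean_mass") %in% names(true_change_12mo)))
    stop("config error: 'true_change_12mo' needs elements weight, fat_mass, lean_mass",
         call. = FALSE)
  true_change_12mo <- lapply(true_change_12mo[c("weight", "fat_mass", "lean_mass")],
                             as_group_vec, nm = "true_change_12mo")

  if (length(time_fraction) == 2L && is.null(names(time_fraction)))
    names(time_fraction) <- c("3", "6")
  if (!all(c("3", "6") %in% names(time_fraction)))
    stop("config error: 'time_fraction' must be named for months 3 and 6",
         call. = FALSE)
  time_fraction <- c(time_fraction[c("3", "6")], "12" = 1)

  if (length(retention_prob) == 1L)
    retention_prob <- stats::setNames(rep(retention_prob, 3L), c("3", "6", "12"))
  if (!all(c("3", "6", "12") %in% names(retention_prob)))
    stop("config error: 'retention_prob' must be named for months 3, 6, 12",
         call. = FALSE)
  retention_prob <- retention_prob[c("3", "6", "12")]
  if (any(retention_prob <= 0) || any(retention_prob > 1))
    stop("config error: 'retention_prob' must lie in (0, 1]", call. = FALSE)

  if (!is.finite(dexa_missing_fraction) ||
      dexa_missing_fraction < 0 || dexa_missing_fraction >= 1)
    stop("config error: 'dexa_missing_fraction' must lie in [0, 1)", call. = FALSE)

  chk_nonneg(recall_noise_sd_g, "recall_noise_sd_g")
  chk_nonneg(subject_sd_kg, "subject_sd_kg")
  chk_nonneg(residual_sd_kg, "residual_sd_kg")
  chk_nonneg(intake_scale, "intake_scale")
  if (!is.finite(adherence_effect_kg))
    stop("config error: 'adherence_effect_kg' must be finite", call. = FALSE)
  if (!is.finite(seed) || seed != round(seed))
    stop("config error: 'seed' must be an integer", call. = FALSE)

  structure(list(
    n_per_group = n_per_group,
    baseline_weight_mean_kg = baseline_weight_mean_kg,
    baseline_weight_sd_kg = baseline_weight_sd_kg,
    baseline_bodyfat_mean_pct = baseline_bodyfat_mean_pct,
    baseline_bodyfat_sd_pct = baseline_bodyfat_sd_pct,
    true_change_12mo = true_change_12mo,
    time_fraction = time_fraction,
    adherence_effect_kg = adherence_effect_kg,
    intake_location = intake_location,
    intake_scale = intake_scale,
    recall_noise_sd_g = recall_noise_sd_g,
    retention_prob = retention_prob,
    dexa_missing_fraction = dexa_missing_fraction,
    subject_sd_kg = subject_sd_kg,
    residual_sd_kg = residual_sd_kg,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic diet-trial cohort configuration\n")
  cat("  groups:            ",
      paste(sprintf("%s n=%d", names(x$n_per_group), x$n_per_group),
            collapse = ", "), "\n")
  cat("  retention (3/6/12):", paste(x$retention_prob, collapse = "/"), "\n")
  cat("  DEXA-missing:      ", sprintf("%.1f%%", 100 * x$dexa_missing_fraction), "\n")
  cat("  adherence effect:  ", x$adherence_effect_kg, "kg / SD\n")
  cat("  seed:              ", x$seed, "\n")
  invisible(x)
}

# fractions of the per-SD adherence effect on weight that flow into the fat
# and lean compartments (they sum to 1 so compartments stay consistent)
.adherence_split <- c(weight = 1, fat_mass = 0.7, lean_mass = 0.3)

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# derive a substream seed from the master seed; keeps every component
# regenerable on its own while staying inside the 32-bit integer range
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483587) + 1L
}

#' Simulate a synthetic diet-trial cohort
#'
#' Generates participants, longitudinal outcomes and 24-hour dietary recall
#' records with the statistical structure a sex-stratified low-carbohydrate
#' vs low-fat trial analysis assumes. The outcome trajectory for participant
#' \eqn{i} in group \eqn{g} at month \eqn{t} is
#' \deqn{y_{it} = \mathrm{baseline}_i + f(t)\,(\Delta_g + e\,a_i) + b_i +
#'   \epsilon_{it}}
#' with \eqn{f(0)=0}, \eqn{f(12)=1}, \eqn{f(3)}, \eqn{f(6)} from
#' `time_fraction`, latent adherence \eqn{a_i \sim N(0,1)}, random intercept
#' \eqn{b_i \sim N(0, \sigma_b^2)} and visit noise
#' \eqn{\epsilon_{it} \sim N(0, \sigma_e^2)}. Reported grams of the
#' restricted macronutrient (carbohydrate on HLC, fat on HLF) decrease with
#' \eqn{a_i} and never fall below the 20 g/day goal:
#' `20 + softplus(location - scale * a_i + noise)`. Post-baseline visits are
#' dropped independently with probability `1 - retention_prob`, and the first
#' `floor(dexa_missing_fraction * N)` enrollees lack baseline body-fat and
#' all fat/lean-mass records (no DEXA access).
#'
#' @param config a [cohort_config()] object.
#' @return an object of class `diet_cohort`: a list with data frames
#'   `participants` (`participant_id`, `sex`, `diet`, `baseline_weight_kg`,
#'   `baseline_bodyfat_pct`), `outcomes` (`participant_id`, `measure`,
#'   `month`, `value_kg`), `recalls` (`participant_id`, `month`, `day_index`,
#'   `carb_g`, `fat_g`, `protein_g`, `energy_kcal`), plus `truth`, a data
#'   frame with the latent adherence trait. `truth` is simulation-internal
#'   and is never written by [write_cohort()].
#' @examples
#' cohort <- simulate_cohort(cohort_config(seed = 42))
#' nrow(cohort$participants)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    config <- do.call(cohort_config, as.list(config))
  groups <- names(config$n_per_group)
  n_tot <- sum(config$n_per_group)

  ## participants ------------------------------------------------------------
  set.seed(substream_seed(config$seed, 1L))
  grp <- rep(groups, config$n_per_group)
  # enrollment order: shuffle so the early-enrollee DEXA gap cuts across groups
  enroll <- sample.int(n_tot)
  grp <- grp[order(enroll)]
  diet <- substr(grp, 1, 3)
  sex <- substr(grp, 5, 5)
  id <- sprintf("P%04d", seq_len(n_tot))

  w0 <- stats::rnorm(n_tot, config$baseline_weight_mean_kg[grp],
                     config$baseline_weight_sd_kg[grp])
  w0 <- pmax(w0, 40)
  bf0 <- stats::rnorm(n_tot, config$baseline_bodyfat_mean_pct[grp],
                      config$baseline_bodyfat_sd_pct[grp])
  bf0 <- pmin(pmax(bf0, 5), 60)
  a <- stats::rnorm(n_tot)

  n_nodexa <- floor(config$dexa_missing_fraction * n_tot)
  has_dexa <- rep(TRUE, n_tot)
  if (n_nodexa > 0) has_dexa[seq_len(n_nodexa)] <- FALSE
  bf_rec <- ifelse(has_dexa, bf0, NA_real_)

  participants <- data.frame(
    participant_id = id, sex = sex, diet = diet,
    baseline_weight_kg = w0, baseline_bodyfat_pct = bf_rec,
    stringsAsFactors = FALSE)

  ## visit attendance (shared by outcomes and recalls at that visit) ---------
  set.seed(substream_seed(config$seed, 2L))
  attend <- matrix(TRUE, n_tot, 4, dimnames = list(NULL, c("0", "3", "6", "12")))
  for (m in c("3", "6", "12"))
    attend[, m] <- stats::runif(n_tot) < config$retention_prob[m]

  ## outcomes ----------------------------------------------------------------
  fat0 <- bf0 / 100 * w0
  lean0 <- 0.95 * (w0 - fat0)  # remainder after bone mineral etc.
  base_by_measure <- list(weight = w0, fat_mass = fat0, lean_mass = lean0)
  months_by_measure <- list(weight = c(0, 3, 6, 12),
                            fat_mass = c(0, 6, 12), lean_mass = c(0, 6, 12))
  f_of <- c("0" = 0, config$time_fraction)

  # the subject intercept and visit noise are drawn once (for weight) and
  # flow into the fat/lean compartments with the same 0.7/0.3 split as the
  # adherence effect; the splits sum to 1, so fat + lean < weight holds by
  # construction at every shared visit
  set.seed(substream_seed(config$seed, 10L))
  b_w <- stats::rnorm(n_tot, 0, config$subject_sd_kg)
  eps_w <- sapply(c("0", "3", "6", "12"), function(m)
    stats::rnorm(n_tot, 0, config$residual_sd_kg))
  out_list <- list()
  for (meas in names(base_by_measure)) {
    split <- .adherence_split[[meas]]
    delta <- config$true_change_12mo[[meas]][grp] +
      split * config$adherence_effect_kg * a
    keep_i <- if (meas == "weight") rep(TRUE, n_tot) else has_dexa
    for (m in months_by_measure[[meas]]) {
      mm <- as.character(m)
      val <- base_by_measure[[meas]] + f_of[mm] * delta +
        split * (b_w + eps_w[, mm])
      sel <- keep_i & attend[, mm]
      if (any(sel))
        out_list[[length(out_list) + 1L]] <- data.frame(
          participant_id = id[sel], measure = meas, month = m,
          value_kg = pmax(val[sel], 1), stringsAsFactors = FALSE)
    }
  }
  outcomes <- do.call(rbind, out_list)
  outcomes <- outcomes[order(outcomes$participant_id, outcomes$measure,
                             outcomes$month), , drop = FALSE]
  rownames(outcomes) <- NULL

  ## dietary recalls ---------------------------------------------------------
  set.seed(substream_seed(config$seed, 30L))
  rec_list <- list()
  n_days <- 3L
  for (m in c(0, 3, 6, 12)) {
    mm <- as.character(m)
    sel <- which(attend[, mm])
    for (d in seq_len(n_days)) {
      ns <- length(sel)
      if (m == 0) {
        # pre-randomization habitual intake, common to both arms
        carb <- pmax(stats::rnorm(ns, 240, 80), 0)
        fatg <- pmax(stats::rnorm(ns, 90, 33), 0)
      } else {
        restricted <- 20 + softplus(config$intake_location -
                                      config$intake_scale * a[sel] +
                                      stats::rnorm(ns, 0, config$recall_noise_sd_g))
        other <- pmax(stats::rnorm(ns, 85, 25), 0)
        is_hlc <- diet[sel] == "HLC"
        carb <- ifelse(is_hlc, restricted, 20 + softplus(160 + stats::rnorm(ns, 0, 40)))
        fatg <- ifelse(is_hlc, other, restricted)
      }
      prot <- pmax(stats::rnorm(ns, 95, 28), 0)
      rec_list[[length(rec_list) + 1L]] <- data.frame(
        participant_id = id[sel], month = m, day_index = d,
        carb_g = carb[seq_len(ns)], fat_g = fatg[seq_len(ns)],
        protein_g = prot,
        energy_kcal = 4 * (carb + prot) + 9 * fatg,
        stringsAsFactors = FALSE)
    }
  }
  recalls <- do.call(rbind, rec_list)
  recalls <- recalls[order(recalls$participant_id, recalls$month,
                           recalls$day_index), , drop = FALSE]
  rownames(recalls) <- NULL

  structure(list(
    participants = participants,
    outcomes = outcomes,
    recalls = recalls,
    truth = data.frame(participant_id = id, group = grp,
                       latent_adherence = a, stringsAsFactors = FALSE),
    config = config
  ), class = "diet_cohort")
}

#' @export
print.diet_cohort <- function(x, ...) {
  tab <- table(paste(x$participants$diet, x$participants$sex, sep = "-"))
  cat("Synthetic diet-trial cohort:", nrow(x$participants), "participants\n")
  cat("  ", paste(sprintf("%s n=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  outcome records:", nrow(x$outcomes),
      " recall records:", nrow(x$recalls), "\n")
  invisible(x)
}

#' Write a cohort's analysis-facing tables to CSV
#'
#' Writes `participants.csv`, `outcomes.csv` and `recalls.csv`. The latent
#' adherence trait (`truth`) is simulation-internal and is deliberately never
#' written: analysis code must work from observable data only.
#'
#' @param cohort a `diet_cohort` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "diet_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("participants.csv", "outcomes.csv", "recalls.csv"))
  utils::write.csv(cohort$participants, paths[1], row.names = FALSE)
  utils::write.csv(cohort$outcomes, paths[2], row.names = FALSE)
  utils::write.csv(cohort$recalls, paths[3], row.names = FALSE)
  invisible(paths)
}

# diet-sex group factor with the four analysis cells in canonical order
group_factor <- function(diet, sex) {
  factor(paste(diet, sex, sep = "-"),
         levels = c("HLC-F", "HLC-M", "HLF-F", "HLF-M"))
}
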