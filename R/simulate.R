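# Published calibration constants for the synthetic-cohort generator:
# risk-group survival profiles (percent surviving at 3/6/12/24 months) and
# group sizes from the validation analysis, covariate marginals from the
# validation-cohort characteristics table, and multivariable hazard ratios.

.default_profiles <- list(
  low          = list(percent = c(94.4, 77.8, 61.1, 55.6), tail_median = 27),
  intermediate = list(percent = c(67.7, 48.7, 31.2, 16.0), tail_median = NULL),
  high         = list(percent = c(39.1, 22.1,  9.0,  3.0), tail_median = NULL)
)

.default_group_sizes <- c(low = 18L, intermediate = 133L, high = 205L)

.default_freqs <- list(
  sex          = c(male = 0.632, female = 0.368),
  age_band     = c("<=64" = 0.489, ">=65" = 0.511),
  kps_band     = c("10-60" = 0.528, "70-80" = 0.281, "90-100" = 0.185),
  ecog_band    = c("0-2" = 0.565, "3-4" = 0.435),
  growth_class = c(slow = 0.124, moderate = 0.124, rapid = 0.753),
  visceral     = c(none = 0.118, nodular = 0.697, disseminated = 0.185),
  lab_category = c(normal = 0.090, abnormal = 0.652, critical = 0.258),
  prior_chemo  = c(no = 0.410, yes = 0.590),
  multiple_bone_mets = c(no = 0.242, yes = 0.758)
)

# Hazard ratios (reference level = 1) used by covariate_effect mode.
.default_hazard_ratios <- list(
  sex          = c(male = 0.479, female = 1),
  kps_band     = c("10-60" = 1.796, "70-80" = 1.479, "90-100" = 1),
  ecog_band    = c("0-2" = 0.690, "3-4" = 1),
  lab_category = c(normal = 0.312, abnormal = 0.697, critical = 1),
  growth_class = c(slow = 0.278, moderate = 0.708, rapid = 1),
  visceral     = c(none = 0.428, nodular = 0.753, disseminated = 1)
)

#' Configuration for the synthetic cohort generator
#'
#' Three modes. \code{replica_validation}: the scorable cohort -- fixed
#' risk-group sizes, survival drawn from per-group piecewise-exponential
#' models calibrated to the published survival profiles, covariates decoded
#' from component scores drawn uniformly among the combinations compatible
#' with each group. \code{replica_entire}: additionally appends
#' \code{n_nonscorable} patients with at least one missing score component
#' (lab panels blanked first, then visceral status, echoing the observed
#' missingness pattern). \code{covariate_effect}: covariates drawn
#' independently at the published marginal frequencies and event times from
#' a proportional-hazards model with the published hazard ratios on an
#' exponential baseline -- the mode used for parameter-recovery checks.
#'
#' @param mode One of \code{"replica_validation"}, \code{"replica_entire"},
#'   \code{"covariate_effect"}.
#' @param seed Mandatory integer seed; all randomness flows through it.
#' @param n Cohort size for \code{covariate_effect} mode (default 5000).
#' @param group_sizes Named integer vector (low/intermediate/high) for
#'   replica modes.
#' @param profiles Per-group survival profiles: list of
#'   \code{list(percent, tail_median)} at \code{profile_times}.
#' @param profile_times Reporting times of the profiles (months).
#' @param covariate_freqs Marginal level frequencies for covariate
#'   sampling.
#' @param hazard_ratios Per-factor hazard ratios for
#'   \code{covariate_effect} mode (reference level 1).
#' @param baseline_median Median survival (months) of the reference
#'   patient in \code{covariate_effect} mode; baseline is exponential.
#' @param censor_range Administrative censoring horizon, drawn uniformly
#'   per patient (months).
#' @param n_nonscorable Extra non-scorable patients in
#'   \code{replica_entire} mode.
#' @param n_missing_labs Of the non-scorable patients, how many are
#'   non-scorable because the lab panel is absent (the remainder lack
#'   visceral status).
#' @return An object of class \code{cohort_config}.
#' @export
cohort_config <- function(mode = c("replica_validation", "replica_entire",
                                   "covariate_effect"),
                          seed,
                          n = 5000L,
                          group_sizes = .default_group_sizes,
                          profiles = .default_profiles,
                          profile_times = c(3, 6, 12, 24),
                          covariate_freqs = .default_freqs,
                          hazard_ratios = .default_hazard_ratios,
                          baseline_median = 2,
                          censor_range = c(24, 137),
                          n_nonscorable = 260L,
                          n_missing_labs = 244L) {
  mode <- match.arg(mode)
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("cohort_config: a seed is mandatory")
  }
  if (any(group_sizes <= 0) ||
      !identical(sort(names(group_sizes)),
                 sort(c("low", "intermediate", "high")))) {
    stop("group_sizes must be positive and named low/intermediate/high")
  }
  for (f in covariate_freqs) {
    if (any(f < 0 | f > 1)) stop("covariate frequencies must be in [0, 1]")
  }
  if (n_missing_labs > n_nonscorable) {
    stop("n_missing_labs cannot exceed n_nonscorable")
  }
  structure(list(mode = mode, seed = as.integer(seed), n = as.integer(n),
                 group_sizes = group_sizes, profiles = profiles,
                 profile_times = profile_times,
                 covariate_freqs = covariate_freqs,
                 hazard_ratios = hazard_ratios,
                 baseline_median = baseline_median,
                 censor_range = censor_range,
                 n_nonscorable = as.integer(n_nonscorable),
                 n_missing_labs = as.integer(n_missing_labs)),
            class = "cohort_config")
}

# All 3*3*3*2*2*2 = 216 component combinations with totals and groups.
component_combinations <- function() {
  g <- expand.grid(primary = c(0L, 2L, 3L), visceral = 0:2, lab = 0:2,
                   ecog = 0:1, chemo = 0:1, mult = 0:1,
                   KEEP.OUT.ATTRS = FALSE)
  g$total <- rowSums(g)
  g$risk_group <- assign_risk_group(g$total)
  g
}

# Decode sampled component points into concrete covariate values that
# re-score to exactly those points. The joint distribution of sites and
# lab values within a component level is unpublished; the weights below
# are a documented stand-in skewed toward the common primaries.
.site_weights <- list(
  slow = c(breast = 0.60, prostate = 0.30, thyroid = 0.05,
           multiple_myeloma = 0.03, lymphoma = 0.02),
  moderate = c(renal_cell = 0.50, ovarian = 0.20, endometrial = 0.10,
               sarcoma = 0.10, other = 0.10),
  rapid = c(lung = 0.60, colorectal = 0.10, hepatocellular = 0.08,
            gastric = 0.05, pancreatic = 0.05, head_and_neck = 0.05,
            esophageal = 0.03, unknown_origin = 0.04)
)

.sample_level <- function(n, freqs) {
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

# Lab panel values consistent with a lab category (vectorized over n).
.decode_labs <- function(category) {
  n <- length(category)
  labs <- data.frame(
    crp = runif(n, 0.02, 0.35), ldh = runif(n, 120, 240),
    albumin = runif(n, 3.8, 4.8), platelets = round(runif(n, 150e3, 350e3)),
    calcium = runif(n, 8.6, 9.6), bilirubin = runif(n, 0.2, 1.0)
  )
  abn <- category == "abnormal"
  labs$crp[abn] <- runif(sum(abn), 0.5, 8)
  crit <- category == "critical"
  labs$platelets[crit] <- round(runif(sum(crit), 30e3, 95e3))
  labs$crp[crit] <- runif(sum(crit), 0.02, 6)
  labs
}

# KPS loosely coupled to the ECOG band so that both marginals stay close
# to the published frequencies while avoiding grossly discordant pairs.
.decode_kps <- function(ecog) {
  n <- length(ecog)
  band <- character(n)
  hi <- ecog >= 3
  band[hi] <- "10-60"
  band[!hi] <- sample(c("10-60", "70-80", "90-100"), sum(!hi),
                      replace = TRUE, prob = c(0.17, 0.50, 0.33))
  .kps_from_band(band)
}

.kps_from_band <- function(band) {
  vapply(band, function(b) {
    switch(b,
           "10-60" = sample(seq(10L, 60L, 10L), 1L),
           "70-80" = sample(c(70L, 80L), 1L),
           "90-100" = sample(c(90L, 100L), 1L))
  }, integer(1), USE.NAMES = FALSE)
}

.decode_ecog <- function(pts) {
  n <- length(pts)
  out <- integer(n)
  lo <- pts == 0L
  out[lo] <- sample(0:2, sum(lo), replace = TRUE, prob = c(0.2, 0.4, 0.4))
  out[!lo] <- sample(3:4, sum(!lo), replace = TRUE, prob = c(0.7, 0.3))
  out
}

.decode_site <- function(growth_class) {
  vapply(growth_class, function(g) {
    w <- .site_weights[[g]]
    sample(names(w), 1L, prob = w)
  }, character(1), USE.NAMES = FALSE)
}

.decode_age <- function(band) {
  vapply(band, function(b) {
    if (b == "<=64") sample(35:64, 1L) else sample(65:89, 1L)
  }, integer(1), USE.NAMES = FALSE)
}

# Build the patient-table data.frame shared by all modes.
.assemble_table <- function(id, sex, age, kps, ecog, site, visceral,
                            chemo, mult, labs, surv, event) {
  n <- length(id)
  rt_start <- as.Date("2004-01-01") +
    sample(0:3651, n, replace = TRUE)          # accrual window, ~10 years
  lab_date <- rt_start - sample(0:45, n, replace = TRUE)
  lab_date[is.na(labs$crp) & is.na(labs$platelets)] <- NA
  data.frame(
    patient_id = id, sex = sex, age_years = age, kps = kps, ecog = ecog,
    primary_site = site, visceral = visceral, prior_chemo = chemo,
    multiple_bone_mets = mult,
    crp = labs$crp, ldh = labs$ldh, albumin = labs$albumin,
    platelets = labs$platelets, calcium = labs$calcium,
    bilirubin = labs$bilirubin,
    lab_date = lab_date, rt_start = rt_start,
    survival_months = round(surv, 4), event = event,
    stringsAsFactors = FALSE
  )
}

.growth_from_pts <- c(`0` = "slow", `2` = "moderate", `3` = "rapid")
.visc_from_pts <- c(`0` = "none", `1` = "nodular", `2` = "disseminated")
.lab_from_pts <- c(`0` = "normal", `1` = "abnormal", `2` = "critical")
.yn_from_pts <- c(`0` = "no", `1` = "yes")

#' Simulate a synthetic cohort
#'
#' Generates a seeded synthetic patient table on the documented CSV schema
#' (see [read_patient_table()]). See [cohort_config()] for the three modes
#' and their calibration. Replica modes draw survival by inverse transform
#' from per-group piecewise-exponential models calibrated to the published
#' risk-group survival profiles, then apply administrative censoring with
#' a per-patient horizon uniform on \code{censor_range}; covariates are
#' decoded from component scores so that re-scoring reproduces each
#' patient's intended risk group exactly.
#'
#' @param config A [cohort_config()].
#' @return A \code{data.frame} on the patient-table schema, with attribute
#'   \code{config}.
#' @examples
#' cohort <- simulate_cohort(cohort_config("replica_validation", seed = 1))
#' nrow(cohort)  # 356
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  switch(config$mode,
         replica_validation = .simulate_replica(config, entire = FALSE),
         replica_entire = .simulate_replica(config, entire = TRUE),
         covariate_effect = .simulate_covariate_effect(config))
}

.group_segments <- function(config) {
  lapply(config$profiles, function(p) {
    calibrate_piecewise_hazards(p$percent, times = config$profile_times,
                                tail_median = p$tail_median)
  })
}

.simulate_replica <- function(config, entire) {
  combos <- component_combinations()
  segs <- .group_segments(config)
  groups <- c("low", "intermediate", "high")

  rows <- lapply(groups, function(g) {
    n_g <- config$group_sizes[[g]]
    pool <- combos[combos$risk_group == g, , drop = FALSE]
    pool[sample(nrow(pool), n_g, replace = TRUE), , drop = FALSE]
  })
  combo <- do.call(rbind, rows)
  group_of <- rep(groups, times = config$group_sizes[groups])
  n <- nrow(combo)

  latent <- numeric(n)
  for (g in groups) {
    idx <- group_of == g
    latent[idx] <- piecewise_quantile(segs[[g]], runif(sum(idx)))
  }
  horizon <- runif(n, config$censor_range[1], config$censor_range[2])
  surv <- pmin(latent, horizon)
  event <- ifelse(latent <= horizon, "died", "censored")

  sex <- .sample_level(n, config$covariate_freqs$sex)
  age <- .decode_age(.sample_level(n, config$covariate_freqs$age_band))
  ecog <- .decode_ecog(combo$ecog)
  kps <- .decode_kps(ecog)
  site <- .decode_site(.growth_from_pts[as.character(combo$primary)])
  visceral <- unname(.visc_from_pts[as.character(combo$visceral)])
  labs <- .decode_labs(.lab_from_pts[as.character(combo$lab)])
  chemo <- unname(.yn_from_pts[as.character(combo$chemo)])
  mult <- unname(.yn_from_pts[as.character(combo$mult)])

  tab <- .assemble_table(sprintf("P%04d", seq_len(n)), sex, age, kps, ecog,
                         site, visceral, chemo, mult, labs, surv, event)

  if (entire) {
    m <- config$n_nonscorable
    pool <- combos[sample(nrow(combos), m, replace = TRUE), , drop = FALSE]
    g_of <- pool$risk_group
    latent2 <- numeric(m)
    for (g in groups) {
      idx <- g_of == g
      if (any(idx)) latent2[idx] <- piecewise_quantile(segs[[g]],
                                                       runif(sum(idx)))
    }
    horizon2 <- runif(m, config$censor_range[1], config$censor_range[2])
    surv2 <- pmin(latent2, horizon2)
    event2 <- ifelse(latent2 <= horizon2, "died", "censored")

    sex2 <- .sample_level(m, config$covariate_freqs$sex)
    age2 <- .decode_age(.sample_level(m, config$covariate_freqs$age_band))
    ecog2 <- .decode_ecog(pool$ecog)
    kps2 <- .decode_kps(ecog2)
    site2 <- .decode_site(.growth_from_pts[as.character(pool$primary)])
    visc2 <- unname(.visc_from_pts[as.character(pool$visceral)])
    labs2 <- .decode_labs(.lab_from_pts[as.character(pool$lab)])
    chemo2 <- unname(.yn_from_pts[as.character(pool$chemo)])
    mult2 <- unname(.yn_from_pts[as.character(pool$mult)])

    # Missingness pattern: lab panels blanked first, then visceral status.
    k_lab <- min(config$n_missing_labs, m)
    labs2[seq_len(k_lab), ] <- NA_real_
    if (k_lab < m) visc2[(k_lab + 1L):m] <- NA_character_

    tab2 <- .assemble_table(sprintf("N%04d", seq_len(m)), sex2, age2, kps2,
                            ecog2, site2, visc2, chemo2, mult2, labs2,
                            surv2, event2)
    tab <- rbind(tab, tab2)
  }
  attr(tab, "config") <- config
  tab
}

.simulate_covariate_effect <- function(config) {
  n <- config$n
  hr <- config$hazard_ratios
  fr <- config$covariate_freqs

  lev <- list(
    sex = .sample_level(n, fr$sex),
    kps_band = .sample_level(n, fr$kps_band),
    ecog_band = .sample_level(n, fr$ecog_band),
    lab_category = .sample_level(n, fr$lab_category),
    growth_class = .sample_level(n, fr$growth_class),
    visceral = .sample_level(n, fr$visceral)
  )
  eta <- Reduce(`+`, lapply(names(lev), function(f) {
    log(unname(hr[[f]][lev[[f]]]))
  }))
  rate0 <- log(2) / config$baseline_median
  latent <- rexp(n, rate0 * exp(eta))
  horizon <- runif(n, config$censor_range[1], config$censor_range[2])
  surv <- pmin(latent, horizon)
  event <- ifelse(latent <= horizon, "died", "censored")

  ecog <- ifelse(lev$ecog_band == "0-2",
                 sample(0:2, n, replace = TRUE, prob = c(0.2, 0.4, 0.4)),
                 sample(3:4, n, replace = TRUE, prob = c(0.7, 0.3)))
  tab <- .assemble_table(
    sprintf("C%05d", seq_len(n)),
    lev$sex,
    .decode_age(.sample_level(n, fr$age_band)),
    .kps_from_band(lev$kps_band),
    ecog,
    .decode_site(lev$growth_class),
    lev$visceral,
    .sample_level(n, fr$prior_chemo),
    .sample_level(n, fr$multiple_bone_mets),
    .decode_labs(lev$lab_category),
    surv, event
  )
  attr(tab, "config") <- config
  tab
}
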