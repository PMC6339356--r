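# Canonical level orders of the analysis factors (on the augmented cohort).
.factor_levels <- list(
  sex = c("male", "female"),
  age_band = c("<=64", ">=65"),
  kps_band = c("10-60", "70-80", "90-100"),
  ecog_band = c("0-2", "3-4"),
  lesion_group = c("lung", "breast", "prostate", "others"),
  growth_class = c("slow", "moderate", "rapid"),
  visceral = c("none", "nodular", "disseminated"),
  lab_category = c("normal", "abnormal", "critical"),
  prior_chemo = c("no", "yes"),
  multiple_bone_mets = c("no", "yes"),
  risk_group = c("low", "intermediate", "high")
)

#' Default analysis factors
#'
#' The univariate screening factors: display name mapped to the column of
#' the augmented cohort ([augment_cohort()]) holding the categorization.
#'
#' @return Named character vector (display name -> column).
#' @export
default_factors <- function() {
  c("Gender" = "sex", "Age" = "age_band", "KPS" = "kps_band",
    "ECOG PS" = "ecog_band", "Primary lesion" = "lesion_group",
    "Primary characteristics" = "growth_class",
    "Visceral metastases" = "visceral", "Laboratory data" = "lab_category",
    "Previous chemotherapy" = "prior_chemo",
    "Multiple bone metastases" = "multiple_bone_mets",
    "Katagiri score" = "risk_group")
}

# Convert one patient-table row to a patient_record.
.record_from_row <- function(row) {
  md <- if (is.na(row$lab_date)) NULL else as.Date(row$lab_date)
  patient_record(
    patient_id = row$patient_id, sex = row$sex, age_years = row$age_years,
    kps = row$kps, ecog = row$ecog, primary_site = row$primary_site,
    visceral = row$visceral, prior_chemo = row$prior_chemo,
    multiple_bone_mets = row$multiple_bone_mets,
    labs = lab_panel(crp = row$crp, ldh = row$ldh, albumin = row$albumin,
                     platelets = row$platelets, calcium = row$calcium,
                     bilirubin = row$bilirubin, measured_on = md),
    rt_start = row$rt_start, survival_months = row$survival_months,
    event = row$event
  )
}

#' Score every patient of a cohort table
#'
#' Applies [katagiri_score()] row-wise to a patient table (the CSV schema
#' of [read_patient_table()]).
#'
#' @param cohort Patient-table \code{data.frame}.
#' @param vocabulary Site vocabulary (see [site_vocabulary()]).
#' @param lab_window_days Lab validity window before radiotherapy start.
#' @return \code{data.frame}: one row per patient with the six component
#'   points, \code{total}, \code{risk_group}, \code{scorable},
#'   \code{missing_components} (comma-separated), \code{lab_category},
#'   \code{growth_class} and \code{recommendation}.
#' @export
score_cohort <- function(cohort, vocabulary = site_vocabulary(),
                         lab_window_days = 61L) {
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0L)
  res <- lapply(seq_len(nrow(cohort)), function(i) {
    r <- katagiri_score(.record_from_row(cohort[i, , drop = FALSE]),
                        vocabulary, lab_window_days)
    data.frame(
      patient_id = r$patient_id, primary_pts = r$primary_pts,
      visceral_pts = r$visceral_pts, lab_pts = r$lab_pts,
      ecog_pts = r$ecog_pts, chemo_pts = r$chemo_pts,
      multiplicity_pts = r$multiplicity_pts, total = r$total,
      risk_group = r$risk_group, scorable = r$scorable,
      missing_components = paste(r$missing_components, collapse = ","),
      lab_category = r$lab_category,
      growth_class = if (is.na(r$growth_class)) NA_character_
                     else r$growth_class,
      recommendation = r$recommendation,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

#' Augment a cohort with derived analysis columns
#'
#' Adds the score results ([score_cohort()]) and the univariate banding
#' columns: \code{age_band} (<=64 / >=65), \code{kps_band}
#' (10-60 / 70-80 / 90-100), \code{ecog_band} (0-2 / 3-4),
#' \code{lesion_group} (lung / breast / prostate / others). An
#' \code{undetermined} lab category becomes \code{NA} in
#' \code{lab_category} (it is missing data for factor analyses).
#'
#' @inheritParams score_cohort
#' @return The cohort with the derived columns appended.
#' @export
augment_cohort <- function(cohort, vocabulary = site_vocabulary(),
                           lab_window_days = 61L) {
  sc <- score_cohort(cohort, vocabulary, lab_window_days)
  stopifnot(identical(sc$patient_id, cohort$patient_id))
  out <- cbind(cohort, sc[, setdiff(names(sc), "patient_id")])
  out$lab_category[out$lab_category == "undetermined"] <- NA_character_
  out$age_band <- ifelse(is.na(out$age_years), NA_character_,
                         ifelse(out$age_years <= 64, "<=64", ">=65"))
  out$kps_band <- ifelse(is.na(out$kps), NA_character_,
                         ifelse(out$kps <= 60, "10-60",
                                ifelse(out$kps <= 80, "70-80", "90-100")))
  out$ecog_band <- ifelse(is.na(out$ecog), NA_character_,
                          ifelse(out$ecog <= 2, "0-2", "3-4"))
  out$lesion_group <- ifelse(is.na(out$primary_site), NA_character_,
                             ifelse(out$primary_site %in%
                                      c("lung", "breast", "prostate"),
                                    out$primary_site, "others"))
  out
}

#' Split a cohort into scorable and non-scorable patients
#'
#' @inheritParams score_cohort
#' @return List: \code{scorable} (augmented rows with a complete score)
#'   and \code{exclusion_log} (\code{patient_id} and
#'   \code{missing_components} of every excluded patient).
#' @export
filter_scorable <- function(cohort, vocabulary = site_vocabulary(),
                            lab_window_days = 61L) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    stop("filter_scorable: empty cohort")
  }
  aug <- augment_cohort(cohort, vocabulary, lab_window_days)
  list(
    scorable = aug[aug$scorable, , drop = FALSE],
    exclusion_log = aug[!aug$scorable,
                        c("patient_id", "missing_components"),
                        drop = FALSE]
  )
}

#' Cohort characteristics table
#'
#' Counts and percentages per factor level. Percentages use the whole
#' cohort as denominator, so a factor with missing values sums to less
#' than 100 percent; zero-count levels are retained.
#'
#' @param aug Augmented cohort ([augment_cohort()]).
#' @param factors Named character vector (display name -> column), default
#'   [default_factors()].
#' @return \code{data.frame}: \code{variable}, \code{level}, \code{n},
#'   \code{percent}.
#' @export
characteristics_table <- function(aug, factors = default_factors()) {
  denom <- nrow(aug)
  rows <- lapply(seq_along(factors), function(i) {
    col <- factors[[i]]
    levs <- .factor_levels[[col]]
    if (is.null(levs)) levs <- sort(unique(stats::na.omit(aug[[col]])))
    n <- vapply(levs, function(l) sum(aug[[col]] == l, na.rm = TRUE),
                numeric(1))
    data.frame(variable = names(factors)[i], level = levs, n = as.integer(n),
               percent = round(100 * n / denom, 1),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Univariate survival screening
#'
#' For each factor: Kaplan-Meier median survival per level and a k-group
#' log-rank p-value. Patients missing a factor are excluded from that
#' factor's analysis only. A factor collapsing to fewer than two non-empty
#' levels is flagged (\code{NA} p-value) and not tested.
#'
#' @inheritParams characteristics_table
#' @return \code{data.frame}: \code{variable}, \code{level}, \code{n},
#'   \code{median_months} (exact; \code{Inf} = not reached),
#'   \code{median_display} (integer-rounded), \code{p_value} (repeated
#'   across the factor's rows).
#' @export
univariate_analysis <- function(aug, factors = default_factors()) {
  rows <- lapply(seq_along(factors), function(i) {
    col <- factors[[i]]
    keep <- !is.na(aug[[col]])
    sub <- aug[keep, , drop = FALSE]
    levs <- .factor_levels[[col]]
    if (is.null(levs)) levs <- sort(unique(sub[[col]]))
    levs <- levs[levs %in% sub[[col]]]
    med <- vapply(levs, function(l) {
      km_median(km_estimate(sub$survival_months[sub[[col]] == l],
                            sub$event[sub[[col]] == l]))
    }, numeric(1))
    n <- vapply(levs, function(l) sum(sub[[col]] == l), numeric(1))
    p <- if (length(levs) >= 2L) {
      logrank_test(sub$survival_months, sub$event,
                   factor(sub[[col]], levels = levs))$p_value
    } else NA_real_
    data.frame(variable = names(factors)[i], level = levs,
               n = as.integer(n), median_months = med,
               median_display = ifelse(is.infinite(med), NA, round(med)),
               p_value = p, stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Default multivariable model specifications
#'
#' Sex and ECOG performance status are fitted in separate models (they
#' proxy overlapping information in this setting); a combined model is
#' also reported but marked non-canonical. Reference levels follow the
#' usual clinical-table convention: woman, KPS 90-100, ECOG 3-4, critical
#' labs, rapid growth, disseminated visceral metastases.
#'
#' @return List of model specs: \code{name}, \code{canonical}, and
#'   \code{covariates} -- a named character vector mapping factor column
#'   to its reference level.
#' @export
default_covariate_specs <- function() {
  ref <- c(kps_band = "90-100", lab_category = "critical",
           growth_class = "rapid", visceral = "disseminated")
  list(
    with_ecog = list(name = "with ECOG PS", canonical = TRUE,
                     covariates = c(ref, ecog_band = "3-4")),
    with_sex = list(name = "with sex", canonical = TRUE,
                    covariates = c(sex = "female", ref)),
    combined = list(name = "combined (non-canonical)", canonical = FALSE,
                    covariates = c(sex = "female", ref, ecog_band = "3-4"))
  )
}

# Expand factors to a 0/1 design matrix against declared reference levels.
.build_design <- function(aug, covariates) {
  cols <- lapply(names(covariates), function(f) {
    ref <- covariates[[f]]
    levs <- .factor_levels[[f]]
    if (!ref %in% levs) stop("reference level '", ref,
                             "' not a level of ", f)
    non_ref <- setdiff(levs, ref)
    m <- vapply(non_ref, function(l) as.numeric(aug[[f]] == l),
                numeric(nrow(aug)))
    m <- matrix(m, nrow = nrow(aug),
                dimnames = list(NULL, paste0(f, ":", non_ref)))
    m
  })
  do.call(cbind, cols)
}

#' Multivariable Cox analysis
#'
#' Fits the configured Cox models ([cox_fit()]) on listwise-complete
#' patients (per model) and reports hazard ratios, 95 percent confidence
#' intervals and Wald p-values per non-reference level; reference levels
#' print HR = 1.000 with no interval.
#'
#' @inheritParams characteristics_table
#' @param specs Model specifications, default [default_covariate_specs()].
#' @param ties Tie handling passed to [cox_fit()].
#' @return Named list, one element per model: \code{table}
#'   (\code{data.frame} with \code{variable}, \code{level}, \code{hr},
#'   \code{lower95}, \code{upper95}, \code{p_value}, \code{reference}),
#'   \code{fit} (the \code{cox_model}), \code{n_used}, \code{canonical};
#'   on rank deficiency or separation a \code{diagnostic} message replaces
#'   the coefficients.
#' @export
multivariate_analysis <- function(aug, specs = default_covariate_specs(),
                                  ties = "breslow") {
  lapply(specs, function(spec) {
    fac <- names(spec$covariates)
    keep <- rowSums(is.na(aug[, fac, drop = FALSE])) == 0L
    sub <- aug[keep, , drop = FALSE]
    X <- .build_design(sub, spec$covariates)
    fit <- tryCatch(cox_fit(sub$survival_months, sub$event, X, ties = ties),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      return(list(name = spec$name, canonical = spec$canonical,
                  n_used = nrow(sub), diagnostic = conditionMessage(fit)))
    }
    rows <- lapply(fac, function(f) {
      ref <- spec$covariates[[f]]
      levs <- .factor_levels[[f]]
      out <- data.frame(variable = f, level = levs, hr = NA_real_,
                        lower95 = NA_real_, upper95 = NA_real_,
                        p_value = NA_real_,
                        reference = levs == ref,
                        stringsAsFactors = FALSE)
      out$hr[out$reference] <- 1
      for (l in setdiff(levs, ref)) {
        key <- paste0(f, ":", l)
        j <- out$level == l
        out$hr[j] <- fit$hazard_ratios[[key]]
        out$lower95[j] <- fit$ci95[key, "lower"]
        out$upper95[j] <- fit$ci95[key, "upper"]
        out$p_value[j] <- fit$p_values[[key]]
      }
      out
    })
    tab <- do.call(rbind, rows)
    diagnostic <- if (fit$monotone) {
      "monotone likelihood (possible perfect separation)"
    } else if (!fit$converged) "did not converge" else NULL
    list(name = spec$name, canonical = spec$canonical, table = tab,
         fit = fit, n_used = nrow(sub), diagnostic = diagnostic)
  })
}

#' Risk-group survival validation
#'
#' Per Katagiri risk group: patient count, Kaplan-Meier median survival,
#' and survival percentages at the reporting times (step-function
#' evaluation, one decimal); across groups, the k-group log-rank test.
#' Also emits plot-ready Kaplan-Meier step coordinates per group.
#'
#' @param aug Augmented, scorable cohort (see [filter_scorable()]).
#' @param times Reporting times in months (default 3, 6, 12, 24).
#' @return List of class \code{validation_report}: \code{table}
#'   (per-group \code{n}, \code{median_months}, \code{median_display},
#'   one \code{surv_pct_<t>} column per time), \code{logrank}
#'   (\code{logrank_result} or \code{NULL} when fewer than two non-empty
#'   groups), \code{km_curves} (\code{data.frame}: group, time, surv,
#'   n_risk), \code{absent_groups}.
#' @export
risk_group_validation <- function(aug, times = c(3, 6, 12, 24)) {
  stopifnot(all(aug$scorable))
  groups <- .factor_levels$risk_group
  present <- groups[groups %in% aug$risk_group]
  absent <- setdiff(groups, present)

  per_group <- lapply(present, function(g) {
    sub <- aug[aug$risk_group == g, , drop = FALSE]
    curve <- km_estimate(sub$survival_months, sub$event)
    med <- km_median(curve)
    pct <- round(100 * survival_probability_at(curve, times), 1)
    row <- data.frame(risk_group = g, n = nrow(sub), median_months = med,
                      median_display = if (is.infinite(med)) NA
                                       else round(med),
                      stringsAsFactors = FALSE)
    for (k in seq_along(times)) {
      row[[paste0("surv_pct_", times[k])]] <- pct[k]
    }
    coords <- km_step_coords(curve)
    coords$group <- g
    list(row = row, coords = coords)
  })

  lr <- if (length(present) >= 2L) {
    sub <- aug[aug$risk_group %in% present, , drop = FALSE]
    logrank_test(sub$survival_months, sub$event,
                 factor(sub$risk_group, levels = present))
  } else NULL

  structure(list(
    table = do.call(rbind, lapply(per_group, `[[`, "row")),
    logrank = lr,
    km_curves = do.call(rbind, lapply(per_group, `[[`, "coords")),
    absent_groups = absent,
    times = times
  ), class = "validation_report")
}

#' Run the full validation pipeline
#'
#' Scores the cohort, excludes non-scorable patients from score-based
#' analyses, and builds the four report tables: cohort characteristics,
#' univariate screening, multivariable Cox models, and the risk-group
#' survival validation. No multiplicity adjustment is applied; the number
#' of tests performed is recorded in the report footer.
#'
#' @param cohort Patient-table \code{data.frame}.
#' @param times Survival-rate reporting times (months).
#' @param specs Multivariable model specifications.
#' @param factors Univariate factor set.
#' @return List of class \code{katagiri_report}: \code{n_total},
#'   \code{n_scorable}, \code{exclusion_log}, \code{characteristics},
#'   \code{univariate}, \code{multivariate}, \code{validation},
#'   \code{follow_up} (median follow-up among survivors), \code{n_tests}.
#' @export
run_validation <- function(cohort, times = c(3, 6, 12, 24),
                           specs = default_covariate_specs(),
                           factors = default_factors()) {
  fs <- filter_scorable(cohort)
  aug_all <- augment_cohort(cohort)
  sc <- fs$scorable

  uni <- univariate_analysis(sc, factors)
  multi <- multivariate_analysis(sc, specs)
  val <- risk_group_validation(sc, times)

  n_tests <- sum(!is.na(unique(uni[, c("variable", "p_value")])$p_value)) +
    sum(vapply(multi, function(m) {
      if (is.null(m$table)) 0L else sum(!m$table$reference)
    }, integer(1))) + as.integer(!is.null(val$logrank))

  structure(list(
    n_total = nrow(cohort), n_scorable = nrow(sc),
    exclusion_log = fs$exclusion_log,
    characteristics = characteristics_table(sc, factors),
    characteristics_entire = characteristics_table(aug_all, factors),
    univariate = uni, multivariate = multi, validation = val,
    follow_up = suppressWarnings(
      median_follow_up_survivors(sc$survival_months, sc$event)),
    n_tests = n_tests
  ), class = "katagiri_report")
}

#' @export
print.validation_report <- function(x, ...) {
  print(x$table, row.names = FALSE)
  if (!is.null(x$logrank)) {
    cat(sprintf("log-rank across groups: chi-square = %.2f, p = %s\n",
                x$logrank$chi_square,
                format.pval(x$logrank$p_value, digits = 3)))
  }
  if (length(x$absent_groups)) {
    cat("absent risk groups:", paste(x$absent_groups, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.katagiri_report <- function(x, ...) {
  cat(sprintf("Cohort: %d patients, %d scorable (%d excluded)\n",
              x$n_total, x$n_scorable, x$n_total - x$n_scorable))
  cat("\nRisk-group validation:\n")
  print(x$validation)
  cat(sprintf("\n%d hypothesis tests performed; no multiplicity adjustment.\n",
              x$n_tests))
  invisible(x)
}
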