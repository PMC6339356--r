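#' Primary-site growth-class vocabulary
#'
#' Returns the mapping from primary-site codes to growth classes
#' (\code{slow}/\code{moderate}/\code{rapid}). The default vocabulary is
#' shipped as a tab-separated file (\code{inst/extdata/site_vocabulary.tsv})
#' so that users can copy and edit it; pass \code{path} to load an edited
#' version. Lung cancer is always rapid and breast/prostate always slow in
#' this modified scheme -- there is no subcategorization by targeted-agent
#' use or hormone sensitivity.
#'
#' @param path Optional path to an alternative two-column TSV
#'   (\code{site}, \code{growth_class}).
#' @return Named character vector: names are site codes, values growth
#'   classes.
#' @export
site_vocabulary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "site_vocabulary.tsv",
                        package = "katagiri", mustWork = TRUE)
  }
  tab <- read.csv(path, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE)
  if (!all(c("site", "growth_class") %in% names(tab))) {
    stop("site vocabulary needs columns 'site' and 'growth_class'")
  }
  bad <- setdiff(unique(tab$growth_class), c("slow", "moderate", "rapid"))
  if (length(bad)) stop("unknown growth class(es): ",
                        paste(bad, collapse = ", "))
  setNames(tab$growth_class, tab$site)
}

#' Classify a primary tumor site into a growth class
#'
#' Slow-growth: breast, prostate, thyroid, multiple myeloma, malignant
#' lymphoma. Moderate: renal cell, endometrial, ovarian, sarcoma, and the
#' explicit catch-all \code{"other"}. Rapid: lung, colorectal, gastric,
#' pancreatic, head and neck, esophageal, other urological, melanoma,
#' hepatocellular, gall bladder, cervical, and \code{"unknown_origin"}.
#'
#' An unrecognized site code raises an error: callers must map unlisted
#' sites to \code{"other"} deliberately, never silently.
#'
#' @param primary_site Site code (see [site_vocabulary()]).
#' @param vocabulary Optional vocabulary override.
#' @return \code{"slow"}, \code{"moderate"} or \code{"rapid"}.
#' @examples
#' classify_primary_growth("breast")          # slow
#' classify_primary_growth("renal_cell")      # moderate
#' classify_primary_growth("unknown_origin")  # rapid
#' @export
classify_primary_growth <- function(primary_site,
                                    vocabulary = site_vocabulary()) {
  if (length(primary_site) != 1L || is.na(primary_site)) {
    stop("classify_primary_growth: a single non-missing site code required")
  }
  key <- tolower(trimws(primary_site))
  if (!key %in% names(vocabulary)) {
    stop("classify_primary_growth: unrecognized site code '", primary_site,
         "'; map it to 'other' explicitly if that is intended")
  }
  unname(vocabulary[[key]])
}

#' Construct a patient record
#'
#' One row of the analysis: demographics, performance status, tumor and
#' metastasis descriptors, laboratory panel, radiotherapy start date and
#' survival outcome. Every prognostic field may be missing (\code{NA});
#' missingness makes the score non-scorable, it is not an error.
#'
#' @param patient_id Identifier (coerced to character).
#' @param sex \code{"male"} or \code{"female"}.
#' @param age_years Age in whole years.
#' @param kps Karnofsky Performance Status, one of 10, 20, ..., 100.
#' @param ecog ECOG performance status, 0--4.
#' @param primary_site Site code (see [site_vocabulary()]).
#' @param visceral \code{"none"}, \code{"nodular"} or
#'   \code{"disseminated"} (pleural/peritoneal/leptomeningeal spread).
#' @param prior_chemo \code{"yes"} or \code{"no"}.
#' @param multiple_bone_mets \code{"yes"} or \code{"no"}.
#' @param labs A [lab_panel()].
#' @param rt_start Radiotherapy start date.
#' @param survival_months Follow-up from \code{rt_start}, months, >= 0.
#' @param event \code{"died"} or \code{"censored"}.
#' @return An object of class \code{patient_record}.
#' @export
patient_record <- function(patient_id, sex = NA, age_years = NA,
                           kps = NA, ecog = NA, primary_site = NA,
                           visceral = NA, prior_chemo = NA,
                           multiple_bone_mets = NA,
                           labs = lab_panel(), rt_start = NA,
                           survival_months, event) {
  chk_level <- function(x, levels, what) {
    if (!is.na(x) && !x %in% levels) {
      stop("patient_record: ", what, " must be one of ",
           paste(levels, collapse = "/"), " or NA, got '", x, "'")
    }
    x
  }
  if (!is.na(kps) && !kps %in% seq(10L, 100L, by = 10L)) {
    stop("patient_record: kps must be one of 10,20,...,100")
  }
  if (!is.na(ecog) && !ecog %in% 0:4) {
    stop("patient_record: ecog must be in 0..4")
  }
  if (is.na(survival_months) || survival_months < 0) {
    stop("patient_record: survival_months must be >= 0")
  }
  event <- match.arg(event, c("died", "censored"))
  structure(list(
    patient_id = as.character(patient_id),
    sex = chk_level(sex, c("male", "female"), "sex"),
    age_years = if (is.na(age_years)) NA_integer_ else as.integer(age_years),
    kps = if (is.na(kps)) NA_integer_ else as.integer(kps),
    ecog = if (is.na(ecog)) NA_integer_ else as.integer(ecog),
    primary_site = if (is.na(primary_site)) NA_character_
                   else tolower(trimws(primary_site)),
    visceral = chk_level(visceral, c("none", "nodular", "disseminated"),
                         "visceral"),
    prior_chemo = chk_level(prior_chemo, c("yes", "no"), "prior_chemo"),
    multiple_bone_mets = chk_level(multiple_bone_mets, c("yes", "no"),
                                   "multiple_bone_mets"),
    labs = labs,
    rt_start = if (is.na(rt_start[1])) as.Date(NA) else as.Date(rt_start),
    survival_months = as.numeric(survival_months),
    event = event
  ), class = "patient_record")
}

# Point values of the six score components (worst level -> most points).
.component_points <- list(
  primary      = c(slow = 0L, moderate = 2L, rapid = 3L),
  visceral     = c(none = 0L, nodular = 1L, disseminated = 2L),
  lab          = c(normal = 0L, abnormal = 1L, critical = 2L),
  ecog         = c(`0-2` = 0L, `3-4` = 1L),
  chemo        = c(no = 0L, yes = 1L),
  multiplicity = c(no = 0L, yes = 1L)
)

#' Component points of the Katagiri score for one patient
#'
#' Maps each of the six prognostic factors to its point value: primary
#' growth class slow/moderate/rapid = 0/2/3, visceral metastases
#' none/nodular/disseminated = 0/1/2, laboratory category
#' normal/abnormal/critical = 0/1/2, ECOG 0--2 / 3--4 = 0/1, previous
#' chemotherapy no/yes = 0/1, multiple skeletal metastases no/yes = 0/1.
#' A factor that is absent (or a lab panel that is \code{undetermined})
#' is listed in \code{missing_components}; the result is scorable only
#' when all six resolve.
#'
#' @param record A [patient_record()].
#' @param vocabulary Site vocabulary override for growth classification.
#' @param lab_window_days Lab validity window before \code{rt_start}.
#' @return An object of class \code{katagiri_result} with fields
#'   \code{primary_pts}, \code{visceral_pts}, \code{lab_pts},
#'   \code{ecog_pts}, \code{chemo_pts}, \code{multiplicity_pts},
#'   \code{total}, \code{risk_group}, \code{scorable},
#'   \code{missing_components}, \code{lab_category}, \code{growth_class}.
#' @export
component_scores <- function(record, vocabulary = site_vocabulary(),
                             lab_window_days = 61L) {
  stopifnot(inherits(record, "patient_record"))
  missing_components <- character(0)

  growth <- NA_character_
  if (is.na(record$primary_site)) {
    missing_components <- c(missing_components, "primary")
  } else {
    growth <- classify_primary_growth(record$primary_site, vocabulary)
  }
  primary_pts <- if (is.na(growth)) NA_integer_
                 else .component_points$primary[[growth]]

  visceral_pts <- if (is.na(record$visceral)) {
    missing_components <- c(missing_components, "visceral")
    NA_integer_
  } else .component_points$visceral[[record$visceral]]

  lab_cat <- categorize_labs(record$labs, rt_start = record$rt_start,
                             window_days = lab_window_days)
  lab_pts <- if (lab_cat == "undetermined") {
    missing_components <- c(missing_components, "lab")
    NA_integer_
  } else .component_points$lab[[lab_cat]]

  ecog_pts <- if (is.na(record$ecog)) {
    missing_components <- c(missing_components, "ecog")
    NA_integer_
  } else if (record$ecog <= 2L) 0L else 1L

  chemo_pts <- if (is.na(record$prior_chemo)) {
    missing_components <- c(missing_components, "chemo")
    NA_integer_
  } else .component_points$chemo[[record$prior_chemo]]

  multiplicity_pts <- if (is.na(record$multiple_bone_mets)) {
    missing_components <- c(missing_components, "multiplicity")
    NA_integer_
  } else .component_points$multiplicity[[record$multiple_bone_mets]]

  scorable <- length(missing_components) == 0L
  total <- if (scorable) {
    primary_pts + visceral_pts + lab_pts + ecog_pts + chemo_pts +
      multiplicity_pts
  } else NA_integer_

  structure(list(
    patient_id = record$patient_id,
    primary_pts = primary_pts, visceral_pts = visceral_pts,
    lab_pts = lab_pts, ecog_pts = ecog_pts, chemo_pts = chemo_pts,
    multiplicity_pts = multiplicity_pts,
    total = total,
    risk_group = if (scorable) assign_risk_group(total) else NA_character_,
    scorable = scorable,
    missing_components = missing_components,
    lab_category = lab_cat,
    growth_class = growth
  ), class = "katagiri_result")
}

#' Total Katagiri score
#'
#' Sum of the six component points, an integer between 0 and 10. Calling
#' this on a non-scorable result is an error naming the missing
#' components.
#'
#' @param result A \code{katagiri_result} from [component_scores()].
#' @return Integer total in 0--10.
#' @export
total_score <- function(result) {
  stopifnot(inherits(result, "katagiri_result"))
  if (!result$scorable) {
    stop("total_score: patient not scorable; missing component(s): ",
         paste(result$missing_components, collapse = ", "))
  }
  result$total
}

#' Risk group for a total score
#'
#' Scores 0--3 are low-risk, 4--6 intermediate-risk, 7--10 high-risk.
#'
#' @param total Integer total score in 0--10 (vectorized).
#' @return Character vector of \code{"low"}, \code{"intermediate"},
#'   \code{"high"}.
#' @examples
#' assign_risk_group(c(3, 4, 7))
#' @export
assign_risk_group <- function(total) {
  if (any(is.na(total)) || any(total < 0 | total > 10) ||
      any(total != as.integer(total))) {
    stop("assign_risk_group: total must be an integer in [0, 10]")
  }
  ifelse(total <= 3, "low", ifelse(total <= 6, "intermediate", "high"))
}

#' Dose-fractionation recommendation for a risk group
#'
#' High-risk patients (expected survival around 2 months) are recommended
#' single-fraction palliative radiotherapy (e.g. 8 Gy in 1 fraction) for
#' pain or metastatic spinal cord compression; low- and intermediate-risk
#' patients multi-fraction schedules (e.g. 20 Gy in 5 or 30 Gy in 10
#' fractions). The caveat field reminds the reader that patient preference
#' and systemic-therapy priority also enter the decision.
#'
#' @param risk_group \code{"low"}, \code{"intermediate"} or \code{"high"}.
#' @return A list with \code{risk_group}, \code{schedule},
#'   \code{example_regimens} and \code{caveat}.
#' @export
recommend_fractionation <- function(risk_group) {
  risk_group <- match.arg(risk_group, c("low", "intermediate", "high"))
  if (risk_group == "high") {
    list(risk_group = risk_group,
         schedule = "single-fraction",
         example_regimens = "8 Gy x 1",
         caveat = paste("Consider patient preference and systemic-therapy",
                        "priority; single fraction favored for short",
                        "expected survival (pain/MSCC palliation)."))
  } else {
    list(risk_group = risk_group,
         schedule = "multi-fraction",
         example_regimens = "20 Gy / 5 fx or 30 Gy / 10 fx",
         caveat = paste("Consider patient preference and systemic-therapy",
                        "priority; longer courses reduce retreatment in",
                        "patients expected to survive them."))
  }
}

#' Score a single patient
#'
#' Convenience wrapper: [component_scores()] plus a fractionation
#' recommendation when scorable.
#'
#' @inheritParams component_scores
#' @return A \code{katagiri_result} with an added \code{recommendation}
#'   field (\code{NULL} when non-scorable).
#' @export
katagiri_score <- function(record, vocabulary = site_vocabulary(),
                           lab_window_days = 61L) {
  res <- component_scores(record, vocabulary, lab_window_days)
  res$recommendation <- if (res$scorable) {
    recommend_fractionation(res$risk_group)$schedule
  } else NA_character_
  res
}

#' @export
print.katagiri_result <- function(x, ...) {
  if (x$scorable) {
    cat(sprintf("Katagiri score for %s: %d (%s risk)\n", x$patient_id,
                x$total, x$risk_group))
    cat(sprintf("  components: primary=%d visceral=%d lab=%d ecog=%d chemo=%d mult=%d\n",
                x$primary_pts, x$visceral_pts, x$lab_pts, x$ecog_pts,
                x$chemo_pts, x$multiplicity_pts))
  } else {
    cat(sprintf("Katagiri score for %s: not scorable (missing: %s)\n",
                x$patient_id, paste(x$missing_components, collapse = ", ")))
  }
  invisible(x)
}
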