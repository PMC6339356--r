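# Patient-table CSV schema and value alias maps.

.patient_columns <- c("patient_id", "sex", "age_years", "kps", "ecog",
                      "primary_site", "visceral", "prior_chemo",
                      "multiple_bone_mets", "crp", "ldh", "albumin",
                      "platelets", "calcium", "bilirubin", "lab_date",
                      "rt_start", "survival_months", "event")

.aliases <- list(
  sex = c(m = "male", male = "male", man = "male", men = "male",
          f = "female", female = "female", woman = "female",
          women = "female"),
  visceral = c(no = "none", none = "none", nodular = "nodular",
               disseminated = "disseminated"),
  yesno = c(y = "yes", yes = "yes", `1` = "yes", `true` = "yes",
            n = "no", no = "no", `0` = "no", `false` = "no"),
  event = c(died = "died", dead = "died", death = "died", deceased = "died",
            `1` = "died", censored = "censored", alive = "censored",
            `0` = "censored")
)

.normalize_levels <- function(x, map, col, problems, lines) {
  x <- tolower(trimws(as.character(x)))
  x[x == ""] <- NA_character_
  known <- is.na(x) | x %in% names(map)
  for (i in which(!known)) {
    problems$add(lines[i], paste0("unrecognized ", col, " value '",
                                  x[i], "'"))
    x[i] <- NA_character_
  }
  out <- unname(map[x])
  out[is.na(x)] <- NA_character_
  out
}

#' Read a patient cohort table
#'
#' Reads the documented CSV schema (columns \code{patient_id, sex,
#' age_years, kps, ecog, primary_site, visceral, prior_chemo,
#' multiple_bone_mets, crp, ldh, albumin, platelets, calcium, bilirubin,
#' lab_date, rt_start, survival_months, event}). Empty cells are missing.
#' Dates are ISO-8601. Categorical values are normalized through a
#' documented alias map (e.g. \code{"M"} -> \code{male}, \code{"alive"}
#' -> \code{censored}). Platelets are absolute counts per microlitre; a
#' platelets column whose header carries a thousands unit (e.g.
#' \code{platelets_x10^3_uL}, any header containing \code{10^3} or
#' \code{10e3}) is converted to absolute counts.
#'
#' Malformed values are collected, not fatal: the affected cell becomes
#' missing and the problem is recorded (line number and issue) in the
#' \code{problems} attribute of the result. An unknown or missing column
#' is an error.
#'
#' @param path CSV file path.
#' @return Patient-table \code{data.frame}; attribute \code{problems} is a
#'   \code{data.frame(line, issue)} of row-level parse problems.
#' @export
read_patient_table <- function(path) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  strip.white = TRUE)
  nm <- names(raw)

  # platelets unit variant in the header
  plt_k <- grepl("platelets", nm) & grepl("10\\^?e?3", nm)
  if (any(plt_k)) nm[plt_k] <- "platelets"
  plt_in_thousands <- any(plt_k)
  names(raw) <- nm

  unknown <- setdiff(nm, .patient_columns)
  if (length(unknown)) {
    stop("read_patient_table: unknown column(s): ",
         paste(unknown, collapse = ", "))
  }
  absent <- setdiff(.patient_columns, nm)
  if (length(absent)) {
    stop("read_patient_table: missing column(s): ",
         paste(absent, collapse = ", "))
  }

  probs <- new.env()
  probs$tab <- data.frame(line = integer(0), issue = character(0))
  probs$add <- function(line, issue) {
    probs$tab <- rbind(probs$tab, data.frame(line = line, issue = issue))
  }
  lines <- seq_len(nrow(raw)) + 1L   # header is line 1

  num <- function(col) {
    x <- raw[[col]]
    x[x == ""] <- NA
    out <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(out)
    for (i in which(bad)) {
      probs$add(lines[i], paste0("unparseable number in ", col, ": '",
                                 x[i], "'"))
    }
    out
  }
  dat <- function(col) {
    x <- raw[[col]]
    x[x == ""] <- NA
    out <- as.Date(rep(NA_character_, length(x)))
    ok <- !is.na(x)
    parsed <- suppressWarnings(as.Date(x[ok], format = "%Y-%m-%d"))
    bad <- is.na(parsed)
    for (i in which(ok)[bad]) {
      probs$add(lines[i], paste0("unparseable ISO-8601 date in ", col,
                                 ": '", raw[[col]][i], "'"))
    }
    out[ok] <- parsed
    out
  }

  out <- data.frame(
    patient_id = raw$patient_id,
    sex = .normalize_levels(raw$sex, .aliases$sex, "sex", probs, lines),
    age_years = num("age_years"), kps = num("kps"), ecog = num("ecog"),
    primary_site = {
      s <- tolower(trimws(raw$primary_site)); s[s == ""] <- NA; s
    },
    visceral = .normalize_levels(raw$visceral, .aliases$visceral,
                                 "visceral", probs, lines),
    prior_chemo = .normalize_levels(raw$prior_chemo, .aliases$yesno,
                                    "prior_chemo", probs, lines),
    multiple_bone_mets = .normalize_levels(raw$multiple_bone_mets,
                                           .aliases$yesno,
                                           "multiple_bone_mets", probs,
                                           lines),
    crp = num("crp"), ldh = num("ldh"), albumin = num("albumin"),
    platelets = num("platelets"), calcium = num("calcium"),
    bilirubin = num("bilirubin"),
    lab_date = dat("lab_date"), rt_start = dat("rt_start"),
    survival_months = num("survival_months"),
    event = .normalize_levels(raw$event, .aliases$event, "event", probs,
                              lines),
    stringsAsFactors = FALSE
  )
  if (plt_in_thousands) out$platelets <- out$platelets * 1000

  bad_surv <- is.na(out$survival_months) | out$survival_months < 0 |
    is.na(out$event)
  for (i in which(bad_surv)) {
    probs$add(lines[i], "invalid or missing survival_months/event")
  }
  if (any(bad_surv)) out <- out[!bad_surv, , drop = FALSE]

  if (nrow(probs$tab)) {
    message("read_patient_table: ", nrow(probs$tab),
            " row-level problem(s); see attr(x, 'problems')")
  }
  attr(out, "problems") <- probs$tab
  out
}

#' Write a patient cohort table
#'
#' Inverse of [read_patient_table()]: missing values become empty cells,
#' dates ISO-8601. Read-write-read round-trips are lossless for every
#' field including missingness.
#'
#' @param cohort Patient-table \code{data.frame}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_patient_table <- function(cohort, path) {
  stopifnot(all(.patient_columns %in% names(cohort)))
  out <- cohort[, .patient_columns]
  out$lab_date <- format(out$lab_date, "%Y-%m-%d")
  out$rt_start <- format(out$rt_start, "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write per-patient score output
#'
#' @param scores Output of [score_cohort()].
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_score_table <- function(scores, path) {
  write.csv(scores, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write validation report files
#'
#' Writes the report of [run_validation()] to a directory:
#' \code{table2.csv} (characteristics), \code{table3.csv} (univariate),
#' \code{table4.csv} (multivariable models, stacked), \code{table5.csv}
#' (risk-group validation), \code{km_curves.csv} (step coordinates) and
#' \code{report.json} (machine-readable twin). Display rounding follows
#' clinical-table convention: medians to integer months, percentages to
#' one decimal, hazard ratios to three decimals; exact values are kept in
#' \code{report.json}.
#'
#' @param report A \code{katagiri_report}.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "katagiri_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(x) file.path(dir, x)

  write.csv(report$characteristics, f("table2.csv"), row.names = FALSE,
            na = "")

  uni <- report$univariate
  uni$median_months <- ifelse(is.infinite(uni$median_months),
                              "not reached",
                              format(round(uni$median_months, 2)))
  uni$p_value <- signif(uni$p_value, 3)
  write.csv(uni, f("table3.csv"), row.names = FALSE, na = "")

  multi <- do.call(rbind, lapply(names(report$multivariate), function(nm) {
    m <- report$multivariate[[nm]]
    if (is.null(m$table)) return(NULL)
    cbind(model = m$name, canonical = m$canonical,
          within(m$table, {
            hr <- round(hr, 3); lower95 <- round(lower95, 3)
            upper95 <- round(upper95, 3); p_value <- signif(p_value, 3)
          }))
  }))
  write.csv(multi, f("table4.csv"), row.names = FALSE, na = "")

  tab5 <- report$validation$table
  tab5$median_months <- ifelse(is.infinite(tab5$median_months),
                               "not reached",
                               format(round(tab5$median_months, 2)))
  if (!is.null(report$validation$logrank)) {
    tab5$logrank_p <- signif(report$validation$logrank$p_value, 3)
  }
  write.csv(tab5, f("table5.csv"), row.names = FALSE, na = "")

  km <- report$validation$km_curves[, c("group", "time", "surv", "n_risk")]
  write.csv(km, f("km_curves.csv"), row.names = FALSE)

  json <- list(
    n_total = report$n_total, n_scorable = report$n_scorable,
    follow_up_median_survivors = report$follow_up,
    n_tests = report$n_tests,
    characteristics = report$characteristics,
    univariate = report$univariate,
    multivariate = lapply(report$multivariate, function(m) {
      m[c("name", "canonical", "table", "n_used", "diagnostic")]
    }),
    validation = list(
      table = report$validation$table,
      logrank = if (!is.null(report$validation$logrank)) {
        report$validation$logrank[c("chi_square", "df", "p_value")]
      },
      absent_groups = report$validation$absent_groups
    ),
    exclusions = report$exclusion_log
  )
  jsonlite::write_json(json, f("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(file.path(dir, c("table2.csv", "table3.csv", "table4.csv",
                             "table5.csv", "km_curves.csv", "report.json")))
}
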