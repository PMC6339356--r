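#' Laboratory panel for Katagiri lab categorization
#'
#' Bundles the six analytes the score inspects. Any analyte may be missing
#' (\code{NA}); a missing analyte is never treated as zero.
#'
#' @param crp C-reactive protein, mg/dL.
#' @param ldh Lactate dehydrogenase, IU/L.
#' @param albumin Serum albumin, g/dL.
#' @param platelets Platelet count, per microlitre (absolute count,
#'   e.g. 250000, not thousands).
#' @param calcium Serum calcium, mg/dL (uncorrected; correction for albumin
#'   is applied internally, see [corrected_calcium()]).
#' @param bilirubin Total bilirubin, mg/dL.
#' @param measured_on Measurement date(s): a single \code{Date} applying to
#'   the whole panel, or a named \code{Date} vector with one entry per
#'   analyte. \code{NULL} means undated (always considered current).
#' @return An object of class \code{lab_panel}.
#' @examples
#' lab_panel(crp = 0.2, ldh = 180, albumin = 4.1,
#'           platelets = 250000, calcium = 9.2, bilirubin = 0.5)
#' @export
lab_panel <- function(crp = NA_real_, ldh = NA_real_, albumin = NA_real_,
                      platelets = NA_real_, calcium = NA_real_,
                      bilirubin = NA_real_, measured_on = NULL) {
  vals <- list(crp = crp, ldh = ldh, albumin = albumin,
               platelets = platelets, calcium = calcium,
               bilirubin = bilirubin)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (length(v) != 1L || (!is.na(v) && (!is.numeric(v) || v < 0))) {
      stop("lab_panel: '", nm, "' must be a single non-negative number or NA")
    }
    vals[[nm]] <- as.numeric(v)
  }
  if (!is.null(measured_on)) {
    measured_on <- as.Date(measured_on)
    if (length(measured_on) > 1L &&
        !all(names(measured_on) %in% names(vals))) {
      stop("lab_panel: per-analyte 'measured_on' must be named after analytes")
    }
  }
  structure(c(vals, list(measured_on = measured_on)), class = "lab_panel")
}

#' Albumin-corrected serum calcium (Payne formula)
#'
#' Corrects measured calcium upward when albumin is below 4.0 g/dL:
#' \code{corrected = calcium + 0.8 * (4.0 - albumin)}. No downward
#' correction is applied for albumin above 4.0, so the result is never
#' below the measured value. When albumin is missing the measured calcium
#' is returned unchanged, annotated with attribute \code{uncorrected = TRUE}.
#'
#' @param calcium Measured serum calcium, mg/dL (> 0).
#' @param albumin Serum albumin, g/dL (> 0), or \code{NA}.
#' @return Corrected calcium in mg/dL.
#' @examples
#' corrected_calcium(10.0, 4.0)  # 10.0 -- identity at the pivot
#' corrected_calcium(9.0, 3.0)   # 9.8
#' @export
corrected_calcium <- function(calcium, albumin) {
  if (is.na(calcium) || calcium <= 0) {
    stop("corrected_calcium: calcium must be present and > 0")
  }
  if (is.na(albumin)) {
    return(structure(calcium, uncorrected = TRUE))
  }
  if (albumin <= 0) stop("corrected_calcium: albumin must be > 0")
  if (albumin < 4.0) calcium + 0.8 * (4.0 - albumin) else calcium
}

# Threshold table. Tiering mirrors whether a derangement is immediately
# life-threatening: abnormal-tier analytes raise the lab category to
# "abnormal", critical-tier analytes to "critical" (worst tier wins).
.lab_thresholds <- list(
  abnormal = list(
    crp       = function(v) v >= 0.4,     # mg/dL
    ldh       = function(v) v >= 250,     # IU/L
    albumin   = function(v) v < 3.7       # g/dL
  ),
  critical = list(
    platelets = function(v) v < 100000,   # per uL
    calcium   = function(v) v >= 10.3,    # mg/dL, after albumin correction
    bilirubin = function(v) v >= 1.4      # mg/dL
  )
)

# Mask out analytes measured outside [rt_start - window_days, rt_start].
# Undated analytes are kept. Returns the panel with stale values set to NA.
.apply_lab_window <- function(panel, rt_start, window_days = 61L) {
  if (is.null(rt_start) || is.null(panel$measured_on)) return(panel)
  rt_start <- as.Date(rt_start)
  analytes <- c("crp", "ldh", "albumin", "platelets", "calcium", "bilirubin")
  dates <- panel$measured_on
  for (nm in analytes) {
    d <- if (length(dates) == 1L && is.null(names(dates))) dates else dates[nm]
    if (length(d) == 0L || is.na(d)) next
    if (d > rt_start || d < rt_start - window_days) panel[[nm]] <- NA_real_
  }
  panel
}

#' Categorize a laboratory panel
#'
#' Assigns the panel one of four categories. \code{critical} if any
#' critical-tier analyte (platelets < 100,000/uL, corrected calcium
#' >= 10.3 mg/dL, bilirubin >= 1.4 mg/dL) crosses its threshold;
#' otherwise \code{abnormal} if any abnormal-tier analyte (CRP >= 0.4
#' mg/dL, LDH >= 250 IU/L, albumin < 3.7 g/dL) crosses; otherwise
#' \code{normal} only when all six analytes are present and within limits;
#' otherwise \code{undetermined} (a valid category -- it makes the score
#' non-scorable, it is not an error).
#'
#' Calcium is compared after albumin correction ([corrected_calcium()]);
#' if albumin is missing the measured calcium is compared as-is. When
#' \code{rt_start} is supplied and the panel carries measurement dates,
#' only values dated within \code{window_days} days before \code{rt_start}
#' are used; older values count as missing.
#'
#' @param panel A [lab_panel()].
#' @param rt_start Radiotherapy start date (optional; enables the validity
#'   window).
#' @param window_days Width of the validity window in days (default 61,
#'   about two months).
#' @return One of \code{"normal"}, \code{"abnormal"}, \code{"critical"},
#'   \code{"undetermined"}.
#' @export
categorize_labs <- function(panel, rt_start = NULL, window_days = 61L) {
  stopifnot(inherits(panel, "lab_panel"))
  panel <- .apply_lab_window(panel, rt_start, window_days)

  eff_calcium <- panel$calcium
  if (!is.na(eff_calcium)) {
    eff_calcium <- as.numeric(corrected_calcium(panel$calcium,
                                                panel$albumin))
  }
  vals <- list(crp = panel$crp, ldh = panel$ldh, albumin = panel$albumin,
               platelets = panel$platelets, calcium = eff_calcium,
               bilirubin = panel$bilirubin)

  crossed <- function(tier) {
    any(vapply(names(tier), function(nm) {
      v <- vals[[nm]]
      !is.na(v) && tier[[nm]](v)
    }, logical(1)))
  }

  if (crossed(.lab_thresholds$critical)) return("critical")
  if (crossed(.lab_thresholds$abnormal)) return("abnormal")
  if (all(!vapply(vals, is.na, logical(1)))) return("normal")
  "undetermined"
}
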