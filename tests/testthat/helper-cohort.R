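# Shared fixture builders. Everything is generated in code at test time.

# A fully favorable, fully observed patient (score 0) whose fields can be
# overridden one at a time.
make_record <- function(...) {
  override <- list(...)
  defaults <- list(
    patient_id = "T1", sex = "female", age_years = 55, kps = 90, ecog = 0,
    primary_site = "breast", visceral = "none", prior_chemo = "no",
    multiple_bone_mets = "no",
    labs = normal_panel(),
    rt_start = as.Date("2010-06-01"),
    survival_months = 12, event = "censored"
  )
  defaults[names(override)] <- override
  do.call(patient_record, defaults)
}

normal_panel <- function(...) {
  override <- list(...)
  defaults <- list(crp = 0.1, ldh = 180, albumin = 4.2, platelets = 250000,
                   calcium = 9.2, bilirubin = 0.5,
                   measured_on = as.Date("2010-05-20"))
  defaults[names(override)] <- override
  do.call(lab_panel, defaults)
}

# Minimal complete patient-table data.frame (vectorized over arguments).
make_cohort_df <- function(n = 4, survival_months = seq_len(n),
                           event = rep("died", n), ...) {
  override <- list(...)
  df <- data.frame(
    patient_id = sprintf("T%02d", seq_len(n)),
    sex = rep("female", n), age_years = rep(55, n), kps = rep(90, n),
    ecog = rep(0, n), primary_site = rep("breast", n),
    visceral = rep("none", n), prior_chemo = rep("no", n),
    multiple_bone_mets = rep("no", n),
    crp = rep(0.1, n), ldh = rep(180, n), albumin = rep(4.2, n),
    platelets = rep(250000, n), calcium = rep(9.2, n),
    bilirubin = rep(0.5, n),
    lab_date = rep(as.Date("2010-05-20"), n),
    rt_start = rep(as.Date("2010-06-01"), n),
    survival_months = survival_months, event = event,
    stringsAsFactors = FALSE
  )
  for (nm in names(override)) df[[nm]] <- override[[nm]]
  df
}

# Independent enumeration of all component combinations, built from the
# point values stated in the scoring rules (not from package internals).
enumerate_components_oracle <- function() {
  g <- expand.grid(primary = c(0, 2, 3), visceral = c(0, 1, 2),
                   lab = c(0, 1, 2), ecog = c(0, 1), chemo = c(0, 1),
                   mult = c(0, 1))
  g$total <- g$primary + g$visceral + g$lab + g$ecog + g$chemo + g$mult
  g
}

# Decode a component-point combination into a concrete patient record
# (deterministic representative per level).
record_from_points <- function(primary, visceral, lab, ecog, chemo, mult) {
  site <- c(`0` = "breast", `2` = "renal_cell", `3` = "lung")[[
    as.character(primary)]]
  visc <- c(`0` = "none", `1` = "nodular", `2` = "disseminated")[[
    as.character(visceral)]]
  labs <- switch(as.character(lab),
                 `0` = normal_panel(),
                 `1` = normal_panel(crp = 1.2),
                 `2` = normal_panel(platelets = 80000))
  make_record(primary_site = site, visceral = visc, labs = labs,
              ecog = if (ecog == 0) 1 else 3,
              prior_chemo = if (chemo == 0) "no" else "yes",
              multiple_bone_mets = if (mult == 0) "no" else "yes")
}
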