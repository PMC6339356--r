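test_that("primary growth classification follows the site vocabulary", {
  expect_equal(classify_primary_growth("breast"), "slow")
  expect_equal(classify_primary_growth("prostate"), "slow")
  expect_equal(classify_primary_growth("renal_cell"), "moderate")
  expect_equal(classify_primary_growth("lung"), "rapid")
  expect_equal(classify_primary_growth("unknown_origin"), "rapid")
  expect_equal(classify_primary_growth("other"), "moderate")
  expect_error(classify_primary_growth("meningioma"), "unrecognized")
  expect_error(classify_primary_growth(NA_character_))
})

test_that("component points match the scoring rules", {
  worst <- component_scores(record_from_points(3, 2, 2, 1, 1, 1))
  expect_equal(
    unlist(worst[c("primary_pts", "visceral_pts", "lab_pts", "ecog_pts",
                   "chemo_pts", "multiplicity_pts")], use.names = FALSE),
    c(3L, 2L, 2L, 1L, 1L, 1L))
  expect_equal(worst$total, 10L)

  best <- component_scores(make_record())
  expect_equal(best$total, 0L)
  expect_true(best$scorable)
  expect_equal(total_score(best), 0L)
  expect_equal(total_score(worst), 10L)
})

test_that("a hand-summed mixed case totals 7", {
  # rapid (3) + nodular (1) + abnormal (1) + ECOG 0-2 (0) + chemo (1) +
  # multiple (1) = 7
  r <- make_record(primary_site = "lung", visceral = "nodular",
                   labs = normal_panel(crp = 1.2), ecog = 1,
                   prior_chemo = "yes", multiple_bone_mets = "yes")
  expect_equal(total_score(component_scores(r)), 7L)
})

test_that("any missing factor makes the patient non-scorable", {
  r <- component_scores(make_record(visceral = NA))
  expect_false(r$scorable)
  expect_equal(r$missing_components, "visceral")
  expect_true(is.na(r$total))
  expect_true(is.na(r$risk_group))
  expect_error(total_score(r), "visceral")

  r2 <- component_scores(make_record(labs = lab_panel(crp = 0.1),
                                     ecog = NA))
  expect_setequal(r2$missing_components, c("lab", "ecog"))
})

test_that("risk groups partition 0-10 at the 3/4 and 6/7 boundaries", {
  expect_equal(assign_risk_group(0:10),
               c(rep("low", 4), rep("intermediate", 3), rep("high", 4)))
  expect_equal(assign_risk_group(3), "low")
  expect_equal(assign_risk_group(4), "intermediate")
  expect_equal(assign_risk_group(6), "intermediate")
  expect_equal(assign_risk_group(7), "high")
  expect_error(assign_risk_group(11), "0, 10")
  expect_error(assign_risk_group(-1), "0, 10")
  expect_error(assign_risk_group(2.5), "integer")
})

test_that("all 216 component combinations match an independent hand sum", {
  oracle <- enumerate_components_oracle()
  expect_equal(nrow(oracle), 216L)
  expect_equal(min(oracle$total), 0)
  expect_equal(max(oracle$total), 10)
  totals <- integer(nrow(oracle))
  for (i in seq_len(nrow(oracle))) {
    r <- record_from_points(oracle$primary[i], oracle$visceral[i],
                            oracle$lab[i], oracle$ecog[i],
                            oracle$chemo[i], oracle$mult[i])
    totals[i] <- total_score(component_scores(r))
  }
  expect_equal(totals, oracle$total)
  # every total maps to exactly one risk group and all totals occur
  expect_setequal(unique(totals), 0:10)
})

test_that("worsening any single component never lowers score or risk", {
  rank_group <- c(low = 1L, intermediate = 2L, high = 3L)
  base <- list(primary = 0, visceral = 0, lab = 0, ecog = 0, chemo = 0,
               mult = 0)
  worse_levels <- list(primary = c(2, 3), visceral = c(1, 2), lab = c(1, 2),
                       ecog = 1, chemo = 1, mult = 1)
  score_of <- function(pts) {
    r <- record_from_points(pts$primary, pts$visceral, pts$lab, pts$ecog,
                            pts$chemo, pts$mult)
    res <- component_scores(r)
    c(total = res$total, rank = rank_group[[res$risk_group]])
  }
  # from several starting points, bump one component at a time
  starts <- list(base,
                 list(primary = 2, visceral = 1, lab = 1, ecog = 0,
                      chemo = 1, mult = 0),
                 list(primary = 3, visceral = 1, lab = 1, ecog = 1,
                      chemo = 0, mult = 1))
  for (s in starts) {
    ref <- score_of(s)
    for (comp in names(worse_levels)) {
      for (w in worse_levels[[comp]]) {
        if (w <= s[[comp]]) next
        bumped <- s; bumped[[comp]] <- w
        got <- score_of(bumped)
        expect_gte(got["total"], ref["total"])
        expect_gte(got["rank"], ref["rank"])
      }
    }
  }
})

test_that("fractionation recommendation maps risk to schedule", {
  expect_equal(recommend_fractionation("high")$schedule, "single-fraction")
  expect_equal(recommend_fractionation("low")$schedule, "multi-fraction")
  expect_equal(recommend_fractionation("intermediate")$schedule,
               "multi-fraction")
  expect_match(recommend_fractionation("high")$caveat, "preference")
  expect_error(recommend_fractionation("none"))
})

test_that("katagiri_score attaches a recommendation when scorable", {
  r <- katagiri_score(record_from_points(3, 2, 2, 1, 1, 1))
  expect_equal(r$recommendation, "single-fraction")
  r2 <- katagiri_score(make_record(visceral = NA))
  expect_true(is.na(r2$recommendation))
})
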