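test_that("the index reproduces its worked examples and zero/negative behaviour", {
  expect_identical(hti(145, 2), 75)
  expect_identical(hti(130, 4), 50)
  expect_identical(hti(120, 7), 0)
  expect_identical(hti(110, 0), -10)
  # vectorised
  expect_equal(hti(c(145, 130, 120, 110), c(2, 4, 7, 0)), c(75, 50, 0, -10))
  # SBP of 120 annihilates the product for every medication count
  expect_equal(hti(rep(120, 21), 0:20), rep(0, 21))
})

test_that("the index is affine in SBP with slope n_meds + offset, monotone in meds with a sign flip at the reference", {
  for (n in c(0, 1, 3, 7)) {
    s <- seq(100, 220, by = 7.5)
    scores <- hti(s, rep(n, length(s)))
    slopes <- diff(scores) / diff(s)
    expect_equal(slopes, rep(n + 1, length(slopes)))
  }
  above <- hti(rep(150, 6), 0:5)   # SBP above reference: increasing in meds
  expect_true(all(diff(above) > 0))
  below <- hti(rep(110, 6), 0:5)   # below reference: decreasing in meds
  expect_true(all(diff(below) < 0))
})

test_that("blood-pressure components are extracted correctly", {
  expect_equal(bp_component_value(120, 80, "mean_arterial"), 80 + 40 / 3)
  expect_equal(bp_component_value(120, 80, "pulse_pressure"), 40)
  expect_equal(bp_component_value(185.3, 91.1, "systolic"), 185.3)
  expect_equal(bp_component_value(185.3, 91.1, "diastolic"), 91.1)
  expect_error(bp_component_value(120, 80, "wedge"), "component")
})

test_that("variant index definitions use the component value at ideal 120/80 as reference", {
  expect_equal(hti(120, 3, hti_definition(bp_component = "diastolic"), dbp = 80), 0)
  expect_equal(hti(120, 3, hti_definition(bp_component = "mean_arterial"), dbp = 80), 0)
  expect_equal(hti(120, 3, hti_definition(bp_component = "pulse_pressure"), dbp = 80), 0)
  # pulse pressure 60 at 2 meds: (60 - 40) * 3
  expect_equal(hti(150, 2, hti_definition(bp_component = "pulse_pressure"), dbp = 90), 60)
})

test_that("invalid measures and definitions are rejected with the field named", {
  expect_error(hti(145, -1), "n_meds")
  expect_error(hti(145, 1.5), "n_meds")
  expect_error(hti(NaN, 1), "sbp")
  expect_error(hti(80, 1, dbp = 95), "sbp")
  expect_error(hti(145, 1, dbp = -5), "dbp")
  expect_error(hti_definition(med_offset = 0), "med_offset")
  expect_error(hti_definition(bp_reference = -10), "bp_reference")
  expect_error(hti(145, 2, hti_definition(bp_component = "diastolic")), "dbp")
})

test_that("the treated-BP comparator adds exactly 10 mmHg iff any drug is prescribed", {
  expect_equal(gwas_score(145, 2), 155)
  expect_equal(gwas_score(145, 0), 145)
  expect_equal(gwas_score(145, 5), 155)  # supplement does not scale with count
  grid <- expand.grid(sbp = c(110, 120, 145, 190), n = 0:6)
  supp <- gwas_score(grid$sbp, grid$n) - grid$sbp
  expect_true(all(supp %in% c(0, 10)))
  expect_equal(supp == 10, grid$n >= 1)
})

test_that("change scores equal baseline minus discharge for every field", {
  coh <- make_cohort(145, 85, 2, 130, 80, 4)
  cs <- change_scores(coh)
  expect_equal(cs$d_hti, 75 - 50)
  expect_equal(cs$d_sbp, 15)
  expect_equal(cs$d_dbp, 5)
  expect_equal(cs$d_meds, -2)
  # identical timepoints: all zero
  same <- make_cohort(150, 90, 3, 150, 90, 3)
  expect_true(all(unlist(change_scores(same)[-1]) == 0))
  # hand arithmetic: (185-120)*4 - (185-120)*5 = 260 - 325
  coh2 <- make_cohort(185, 91, 3, 185, 91, 4)
  expect_equal(change_scores(coh2)$d_hti, -65)
})

test_that("change scores are antisymmetric under swapping baseline and discharge", {
  for (seed in 1:5) {
    coh <- random_cohort(20, seed)
    swapped <- make_cohort(coh$sbp_discharge, coh$dbp_discharge,
                           coh$meds_discharge, coh$sbp_baseline,
                           coh$dbp_baseline, coh$meds_baseline,
                           ids = coh$patient_id)
    a <- change_scores(coh)
    b <- change_scores(swapped)
    for (cl in c("d_sbp", "d_dbp", "d_meds", "d_hti", "d_gwas")) {
      expect_equal(a[[cl]], -b[[cl]])
    }
  }
})

test_that("summary-level scoring matches the index formula applied to cohort means", {
  expect_equal(hti_from_summary(150, 2.1), 93)
  expect_equal(hti_from_summary(120, 5), 0)
  expect_error(hti_from_summary(150, -1), "meds_mean")
  expect_error(
    hti_from_summary(150, 2, hti_definition(bp_component = "diastolic")),
    "systolic")
})
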