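test_that("Calvert dosing and whole-vial pricing follow the formulas", {
  expect_equal(carboplatin_dose(5, 70), 475)
  expect_equal(carboplatin_dose(0, 70), 0)
  expect_equal(carboplatin_dose(5, 0), 125)
  expect_error(carboplatin_dose(-1, 70))

  expect_equal(drug_admin_cost(1200, 600, 1844.26), 3688.52)
  expect_equal(drug_admin_cost(0, 600, 1844.26), 0)
  # pemetrexed 500 mg/m2 x 1.72 m2 = 860 mg -> 9 whole 100 mg vials
  expect_equal(drug_admin_cost(500 * 1.72, 100, 330.23), 9 * 330.23)
  expect_error(drug_admin_cost(-5, 600, 1), "non-negative")
})

test_that("on-treatment cycle costs follow the regimen schedule", {
  econ <- default_economics()
  # induction, all non-squamous: sugemalimab + carboplatin + pemetrexed
  econ0 <- econ; econ0$squamous_fraction <- 0
  expect_equal(oncycle_cost("sugemalimab", 0, econ0),
               3688.52 + 5 * 13.39 + 9 * 330.23)
  # placebo maintenance, all squamous: no drug at all
  econ1 <- econ; econ1$squamous_fraction <- 1
  expect_equal(oncycle_cost("placebo", 10, econ1), 0)
  # beyond the 35-cycle treatment cap the drug cost is zero for any arm
  expect_equal(oncycle_cost("sugemalimab", 35, econ), 0)
  expect_equal(oncycle_cost("placebo", 40, econ), 0)
  econ_bad <- econ
  econ_bad$squamous_fraction <- 1.4
  expect_error(oncycle_cost("sugemalimab", 0, econ_bad),
               "squamous_fraction")
})

test_that("post-progression cost is the mix expectation plus follow-up", {
  econ <- default_economics()
  bsc_only <- c(docetaxel = 0, crossover = 0, bsc = 1)
  expect_equal(progression_cost_per_cycle(bsc_only, econ), 320.84 + 199.55)
  doc_only <- c(docetaxel = 1, crossover = 0, bsc = 0)
  # docetaxel 75 mg/m2 x 1.72 = 129 mg -> 7 x 20 mg vials
  expect_equal(progression_cost_per_cycle(doc_only, econ),
               7 * 96.65 + 199.55)
  expect_gt(progression_cost_per_cycle(doc_only, econ),
            progression_cost_per_cycle(bsc_only, econ))
  zero <- econ
  zero$prices[] <- lapply(zero$prices, function(x) 0)
  zero$per_cycle[] <- lapply(zero$per_cycle, function(x) 0)
  expect_equal(progression_cost_per_cycle(doc_only, zero), 0)
  expect_error(progression_cost_per_cycle(
    c(docetaxel = 0.6, crossover = 0.6, bsc = 0.2), econ), "summing")
})

test_that("SAE burden is the published cost plus a one-cycle disutility", {
  econ <- default_economics()
  cyc_yr <- 21 / 30.4375 / 12
  b <- sae_burden(econ$sae_prob$sugemalimab, econ$disutility,
                  econ$sae_cost$sugemalimab, cyc_yr)
  hand <- (0.325 * 0.20 + 0.016 * 0.12 + 0.003 * 0.06 + 0.006 * 0.10 +
             0.009 * 0.07 + 0.009 * 0.07) * cyc_yr
  expect_equal(b$one_off_qaly_loss, hand)
  expect_equal(b$one_off_cost, 23.57)
  # linear in the probabilities; zero probabilities keep the printed cost
  b2 <- sae_burden(2 * econ$sae_prob$placebo, econ$disutility,
                   econ$sae_cost$placebo, cyc_yr)
  b1 <- sae_burden(econ$sae_prob$placebo, econ$disutility,
                   econ$sae_cost$placebo, cyc_yr)
  expect_equal(b2$one_off_qaly_loss, 2 * b1$one_off_qaly_loss)
  b0 <- sae_burden(0 * econ$sae_prob$placebo, econ$disutility,
                   econ$sae_cost$placebo, cyc_yr)
  expect_equal(b0$one_off_qaly_loss, 0)
  expect_equal(b0$one_off_cost, 23.81)
})

test_that("arm costs decompose exactly and respond monotonically to prices", {
  res <- run_arm(arm_definition("sugemalimab"))
  expect_equal(sum(res$cost_breakdown), res$total_cost, tolerance = 1e-9)
  expect_true(all(res$cost_breakdown >= 0))
  expect_setequal(names(res$cost_breakdown),
                  c("immunotherapy", "chemotherapy", "hospital", "followup",
                    "subsequent", "sae"))
  # raising any single price never lowers the arm total
  set.seed(14)
  for (nm in names(default_economics()$prices)) {
    econ_hi <- default_economics()
    econ_hi$prices[[nm]] <- econ_hi$prices[[nm]] * runif(1, 1.1, 2)
    for (arm in c("sugemalimab", "placebo")) {
      expect_gte(run_arm(arm_definition(arm, econ_hi))$total_cost,
                 run_arm(arm_definition(arm))$total_cost)
    }
  }
})

test_that("zeroing the sugemalimab price removes exactly the immunotherapy
           component", {
  base <- run_arm(arm_definition("sugemalimab"))
  econ0 <- default_economics()
  econ0$prices$sugemalimab_600mg <- 0
  free <- run_arm(arm_definition("sugemalimab", econ0))
  expect_equal(base$total_cost - free$total_cost,
               base$cost_breakdown[["immunotherapy"]], tolerance = 1e-9)
  expect_equal(free$cost_breakdown[["immunotherapy"]], 0)
  # the other components are untouched
  keep <- setdiff(names(base$cost_breakdown), "immunotherapy")
  expect_equal(base$cost_breakdown[keep], free$cost_breakdown[keep])
})
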