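test_that("discount factors follow the annual-rate closed forms", {
  expect_equal(discount_factor(c(0, 3, 7.5), 0), rep(1, 3))
  expect_equal(discount_factor(1, 0.05), 1 / 1.05)
  expect_equal(discount_factor(10, 0.05), 1.05^-10)
  expect_equal(discount_factor(0.5, 0.05, "annual"), 1)
  expect_equal(discount_factor(1.5, 0.05, "annual"), 1 / 1.05)
  expect_error(discount_factor(1, -0.01), "non-negative")
  expect_error(discount_factor(-1, 0.05), "non-negative")
})

test_that("state occupancy conserves probability and starts in PFS", {
  crv <- published_curves()
  tr <- state_occupancy(crv$sugemalimab$pfs, crv$sugemalimab$os,
                        model_settings())
  expect_equal(tr$p_pfs[1], 1)
  expect_equal(tr$p_pd[1], 0)
  expect_equal(tr$p_death[1], 0)
  expect_lt(max(abs(tr$p_pfs + tr$p_pd + tr$p_death - 1)), 1e-12)
  expect_true(all(diff(tr$p_death) >= -1e-12))
  expect_true(all(tr$discount > 0 & tr$discount <= 1))
  expect_true(all(diff(tr$discount) <= 1e-15))
  # horizon bookkeeping: widths tile exactly ten years
  expect_equal(sum(tr$width_months), 120)
})

test_that("PFS is clamped to OS when extrapolated curves cross", {
  pfs <- surv_dist("exponential", rate = 0.01)   # slower than OS
  os <- surv_dist("exponential", rate = 0.10)
  tr <- state_occupancy(pfs, os, model_settings(horizon_years = 5))
  expect_true(all(tr$p_pfs <= 1 - tr$p_death + 1e-15))
  expect_true(all(tr$p_pd >= 0))
  expect_equal(max(tr$p_pd), 0)                  # fully clamped here
})

test_that("accrual is a discounted occupancy-weighted sum with one-offs", {
  tr <- toy_trace()
  expect_equal(accrue(tr, 0, 0), 0)
  expect_equal(accrue(tr, 1, 0), 1.5)            # 1*1 + 0.5*1
  expect_equal(accrue(tr, 1, 1), 2)              # both states valued
  expect_equal(accrue(tr, 0, 0, one_off = c("1" = 10)), 10)
  # linear in values
  expect_equal(accrue(tr, 4, 2), 4 * accrue(tr, 1, 0) + 2 * accrue(tr, 0, 1))
  bad <- tr; bad$p_pfs[1] <- -0.2
  expect_error(accrue(bad, 1, 1), "negative")
})

test_that("a costless perfect-utility arm yields zero cost and QALY = LY", {
  econ <- default_economics()
  econ$prices[] <- lapply(econ$prices, function(x) 0)
  econ$per_cycle[] <- lapply(econ$per_cycle, function(x) 0)
  econ$sae_cost[] <- lapply(econ$sae_cost, function(x) 0)
  econ$sae_prob <- lapply(econ$sae_prob, function(p) p * 0)
  econ$utility <- c(pfs = 1, pd = 1)
  sett <- model_settings(discount_rate_annual = 0)
  res <- run_arm(arm_definition("sugemalimab", econ), sett)
  expect_equal(res$total_cost, 0)
  expect_equal(res$qaly, res$ly, tolerance = 1e-12)
})

test_that("doubling every cost input doubles total cost, by component", {
  econ <- default_economics()
  econ2 <- econ
  econ2$prices[] <- lapply(econ$prices, function(x) 2 * x)
  econ2$per_cycle[] <- lapply(econ$per_cycle, function(x) 2 * x)
  econ2$sae_cost[] <- lapply(econ$sae_cost, function(x) 2 * x)
  r1 <- run_arm(arm_definition("placebo", econ))
  r2 <- run_arm(arm_definition("placebo", econ2))
  expect_equal(r2$total_cost, 2 * r1$total_cost, tolerance = 1e-12)
  expect_equal(r2$cost_breakdown, 2 * r1$cost_breakdown, tolerance = 1e-12)
  expect_equal(r1$total_cost, sum(r1$cost_breakdown))
})

test_that("discounting can only shrink totals and QALY never exceeds LY", {
  for (arm in c("sugemalimab", "placebo")) {
    r5 <- run_arm(arm_definition(arm), model_settings())
    r0 <- run_arm(arm_definition(arm),
                  model_settings(discount_rate_annual = 0))
    expect_lte(r5$total_cost, r0$total_cost)
    expect_lte(r5$ly, r0$ly)
    expect_lte(r5$qaly, r5$ly)
  }
})

test_that("ICER handles ratio, dominance and undefined cases", {
  mk <- function(cost, qaly)
    structure(list(arm = "x", total_cost = cost, ly = qaly, qaly = qaly),
              class = "cea_arm")
  same <- icer(mk(100, 1), mk(100, 1))
  expect_equal(same$status, "undefined")
  expect_true(is.na(same$icer))
  dom <- icer(mk(90, 1.2), mk(100, 1))
  expect_equal(dom$status, "dominant")
  dtd <- icer(mk(120, 0.8), mk(100, 1))
  expect_equal(dtd$status, "dominated")
  ratio <- icer(mk(166666.63, 1.59), mk(100000, 1))
  expect_equal(ratio$status, "icer")
  expect_equal(ratio$icer, 66666.63 / 0.59)
  # invariant to component bundling: only the totals matter
  expect_equal(icer(mk(150, 1.5), mk(100, 1))$icer,
               icer(mk(50 + 100, 1.5), mk(70 + 30, 1))$icer)
})

test_that("the deterministic comparison is reproducible and well-formed", {
  r1 <- run_cea()
  r2 <- run_cea()
  expect_identical(summary(r1), summary(r2))
  s <- summary(r1)
  expect_equal(nrow(s), 2)
  expect_true(all(s$qaly <= s$ly))
  expect_equal(r1$incremental$status, "icer")
  expect_output(print(r1), "not cost-effective")
})
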