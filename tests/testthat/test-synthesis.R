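test_that("trial simulation is seeded, ordered and reproducible", {
  des <- trial_design(n_per_arm = c(sugemalimab = 100L, placebo = 50L))
  set.seed(123); a <- simulate_trial(des)
  set.seed(123); b <- simulate_trial(des)
  expect_identical(a, b)
  expect_equal(nrow(a), 2 * 150)

  # within a patient, observed PFS never exceeds observed OS
  for (arm in c("sugemalimab", "placebo")) {
    pfs <- a[a$arm == arm & a$endpoint == "pfs", ]
    os <- a[a$arm == arm & a$endpoint == "os", ]
    expect_true(all(pfs$time_months <= os$time_months + 1e-12))
  }
})

test_that("simulated survival converges to the generating curve", {
  set.seed(9)
  crv <- published_curves()
  des <- trial_design(n_per_arm = c(placebo = 10000L),
                      accrual_months = 0, max_followup_months = 1e5,
                      arm_curves = crv["placebo"])
  ipd <- simulate_trial(des)
  os <- ipd[ipd$endpoint == "os", ]
  expect_equal(mean(os$event), 1)       # no censoring at this cutoff
  grid <- seq(0.5, 120, by = 0.5)
  emp <- vapply(grid, function(t) mean(os$time_months > t), 0)
  ks <- max(abs(emp - surv_prob(crv$placebo$os, grid)))
  expect_lt(ks, 0.03)

  # K-M median of a large minimally censored sample hits the scale
  des2 <- trial_design(n_per_arm = c(placebo = 5000L), accrual_months = 0,
                       max_followup_months = 200,
                       arm_curves = crv["placebo"])
  pfs <- simulate_trial(des2)
  pfs <- pfs[pfs$endpoint == "pfs", ]
  sf <- survival::survfit(survival::Surv(pfs$time_months, pfs$event) ~ 1)
  med <- summary(sf)$table[["median"]]
  # PFS is min(progression, death); with OS median far above, the K-M
  # median sits just under the log-logistic scale 5.3347
  expect_equal(med, 5.3347, tolerance = 0.5 / 5.3347)
})

test_that("an immediate data cutoff censors essentially everyone", {
  set.seed(4)
  des <- trial_design(n_per_arm = c(placebo = 200L), accrual_months = 0,
                      max_followup_months = 0.01,
                      arm_curves = published_curves()["placebo"])
  ipd <- simulate_trial(des)
  expect_lt(mean(ipd$event), 0.05)
})

test_that("a single digitized drop reconstructs events then censoring", {
  curve <- structure(list(
    points = data.frame(time_months = c(0, 5, 10),
                        survival = c(1, 0.5, 0.5)),
    risk_table = data.frame(time_months = c(0, 10), n_risk = c(10, 5))),
    class = "digitized_curve")
  rec <- reconstruct_ipd(curve)
  expect_equal(sum(rec$event == 1), 5)
  expect_equal(unique(rec$time_months[rec$event == 1]), 5)
  expect_equal(sum(rec$event == 0), 5)
  expect_equal(unique(rec$time_months[rec$event == 0]), 10)
})

test_that("digitize -> reconstruct round-trips the Kaplan-Meier curve", {
  set.seed(21)
  crv <- published_curves()
  des <- trial_design(n_per_arm = c(sugemalimab = 300L),
                      accrual_months = 12, max_followup_months = 30,
                      arm_curves = crv["sugemalimab"])
  ipd <- simulate_trial(des)
  s_at <- function(km, tt) vapply(tt, function(x) {
    i <- findInterval(x, km$time)
    if (i == 0) 1 else km$surv[i]
  }, 0)
  for (ep in c("pfs", "os")) {
    d <- ipd[ipd$endpoint == ep, ]
    grid <- seq(0, max(d$time_months), length.out = 40)
    dig <- digitize_km(d$time_months, d$event, grid = grid)
    rec <- reconstruct_ipd(dig)
    expect_lte(nrow(rec), 300)
    km0 <- survival::survfit(survival::Surv(d$time_months, d$event) ~ 1)
    km1 <- survival::survfit(survival::Surv(rec$time_months, rec$event) ~ 1)
    expect_true(all(diff(km1$surv) <= 1e-12))
    expect_lt(max(abs(s_at(km0, grid) - s_at(km1, grid))), 0.02)
  }
})

test_that("reconstruction degrades gracefully without a risk table", {
  set.seed(33)
  d <- censored_sample(150, surv_dist("weibull", shape = 1.2, scale = 10),
                       0.2)
  dig <- digitize_km(d$time, d$event)
  dig$risk_table <- NULL
  expect_error(reconstruct_ipd(dig), "n0")
  rec <- reconstruct_ipd(dig, n0 = 150)
  km <- survival::survfit(survival::Surv(rec$time_months, rec$event) ~ 1)
  expect_true(all(diff(km$surv) <= 1e-12))
  expect_lte(sum(rec$event), 150)
})

test_that("an inconsistent risk table is rejected", {
  curve <- structure(list(
    points = data.frame(time_months = c(0, 5), survival = c(1, 0.6)),
    risk_table = data.frame(time_months = c(0, 5), n_risk = c(10, 12))),
    class = "digitized_curve")
  expect_error(reconstruct_ipd(curve), "non-increasing")
})
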