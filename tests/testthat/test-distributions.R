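test_that("closed-form survival functions honour their medians and limits", {
  ll <- surv_dist("loglogistic", shape = 1.6637, scale = 9.3549)
  expect_equal(surv_prob(ll, 9.3549), 0.5, tolerance = 1e-12)
  expect_equal(surv_prob(ll, 0), 1)

  ln <- surv_dist("lognormal", meanlog = 2.8289, sdlog = 0.9785)
  expect_equal(surv_prob(ln, exp(2.8289)), 0.5, tolerance = 1e-12)
  expect_equal(surv_prob(ln, 0), 1)

  # cure plateaus: mixture levels at pi, non-mixture at pi as S0 -> 0
  mc <- surv_dist("mixture_cure", cure = 0.2,
                  base = surv_dist("exponential", rate = 0.3))
  nm <- surv_dist("nonmixture_cure", cure = 0.2,
                  base = surv_dist("exponential", rate = 0.3))
  expect_equal(surv_prob(mc, 1e6), 0.2, tolerance = 1e-9)
  expect_equal(surv_prob(nm, 1e6), 0.2, tolerance = 1e-9)
  expect_equal(surv_plateau(mc), 0.2)
  expect_equal(surv_plateau(nm), 0.2)

  # pi = 0 reproduces the base family exactly
  mc0 <- surv_dist("mixture_cure", cure = 0,
                   base = surv_dist("weibull", shape = 1.3, scale = 8))
  tt <- c(0, 0.5, 2, 11, 40)
  expect_equal(surv_prob(mc0, tt),
               surv_prob(surv_dist("weibull", shape = 1.3, scale = 8), tt))
})

test_that("every family yields a valid non-increasing survival curve", {
  set.seed(202)
  tt <- sort(c(0, runif(60, 0, 60)))
  specs <- list()
  for (i in 1:8) {
    specs <- c(specs, list(
      surv_dist("exponential", rate = runif(1, 0.01, 1)),
      surv_dist("weibull", shape = runif(1, 0.3, 3),
                scale = runif(1, 1, 40)),
      surv_dist("gompertz", shape = runif(1, -0.2, 0.3),
                rate = runif(1, 0.01, 0.5)),
      surv_dist("loglogistic", shape = runif(1, 0.3, 3),
                scale = runif(1, 1, 40)),
      surv_dist("lognormal", meanlog = runif(1, 0, 3.5),
                sdlog = runif(1, 0.2, 2)),
      surv_dist("mixture_cure", cure = runif(1),
                base = surv_dist("weibull", shape = runif(1, 0.5, 2),
                                 scale = runif(1, 2, 30)))))
  }
  for (sp in specs) {
    s <- surv_prob(sp, tt)
    expect_equal(s[1], 1)
    expect_true(all(s >= 0 & s <= 1))
    expect_true(all(diff(s) <= 1e-12))
  }
})

test_that("parameter-domain and time-domain violations are rejected", {
  expect_error(surv_dist("loglogistic", shape = 1.5, scale = -2),
               "positive")
  expect_error(surv_dist("mixture_cure", cure = 1.2,
                         base = surv_dist("exponential", rate = 1)),
               "cure fraction")
  expect_error(surv_prob(surv_dist("exponential", rate = 1), -1),
               "non-negative")
  expect_error(surv_dist_rp(gamma = c(1, 1, 1), knots = c(0, 2, 1)),
               "increasing")
})

test_that("quantile functions invert the survival functions", {
  set.seed(7)
  specs <- list(
    surv_dist("loglogistic", shape = 1.9645, scale = 5.3347),
    surv_dist("lognormal", meanlog = 2.8289, sdlog = 0.9785),
    surv_dist("gompertz", shape = 0.05, rate = 0.03),
    surv_dist("nonmixture_cure", cure = 0.15,
              base = surv_dist("weibull", shape = 1.2, scale = 10)))
  for (sp in specs) {
    p <- runif(20, max(surv_plateau(sp) + 0.01, 0.01), 0.99)
    expect_equal(surv_prob(sp, surv_quantile(sp, p)), p, tolerance = 1e-6)
  }
  # below an improper plateau there is no finite quantile
  mc <- surv_dist("mixture_cure", cure = 0.3,
                  base = surv_dist("exponential", rate = 1))
  expect_identical(surv_quantile(mc, 0.2), Inf)
})

test_that("restricted mean survival matches closed forms and a fine grid", {
  ex <- surv_dist("exponential", rate = 0.1)
  expect_equal(rmst(ex, Inf), 10, tolerance = 1e-6)
  expect_equal(rmst(ex, 0), 0)
  h <- c(12, 60)
  expect_true(all(diff(vapply(h, function(x) rmst(ex, x), 0)) > 0))

  # published sugemalimab OS curve vs an independent trapezoid oracle
  g <- 1.3722; l <- 24.9818
  grid <- seq(0, 120, length.out = 1e6 + 1)
  s <- 1 / (1 + (grid / l)^g)
  oracle <- sum((s[-1] + s[-length(s)]) / 2) * (120 / 1e6)
  mine <- rmst(surv_dist("loglogistic", shape = g, scale = l), 120)
  expect_equal(mine, oracle, tolerance = 0.005)
  expect_lt(mine, 120)
})

test_that("the spline evaluator reproduces flexsurv's spline survival", {
  set.seed(31)
  d <- censored_sample(400, surv_dist("lognormal", meanlog = 2.8, sdlog = 1),
                       0.3)
  fs <- flexsurv::flexsurvspline(survival::Surv(d$time, d$event) ~ 1,
                                 k = 1, scale = "hazard")
  sp <- surv_dist_rp(unname(fs$coefficients), unname(fs$knots))
  tt <- c(0.5, 2, 8, 20, 45)
  expect_equal(surv_prob(sp, tt),
               flexsurv::psurvspline(tt, gamma = fs$coefficients,
                                     knots = fs$knots, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(surv_prob(sp, 0), 1)
})
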