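# shared fixtures: published best-fit curves and a small toy trace

published_curves <- function() default_curves()

# hand-built occupancy trace (2 cycles, no discounting) for accrual checks
toy_trace <- function() {
  tr <- data.frame(cycle = 0:1, t_months = c(0, 1), width_months = c(1, 1),
                   t_eval = c(0, 1),
                   p_pfs = c(1, 0.5), p_pd = c(0, 0.5), p_death = c(0, 0),
                   discount = c(1, 1))
  class(tr) <- c("occupancy_trace", "data.frame")
  tr
}

# draw right-censored data from a distribution with a given censoring
# fraction (administrative censoring at a fixed quantile)
censored_sample <- function(n, dist, cens_frac) {
  t <- surv_rand(n, dist)
  if (cens_frac <= 0) return(data.frame(time = t, event = rep(1L, n)))
  cutoff <- unname(stats::quantile(t, 1 - cens_frac))
  data.frame(time = pmin(t, cutoff), event = as.integer(t <= cutoff))
}
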