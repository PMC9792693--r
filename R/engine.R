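#' Model run settings
#'
#' Global settings of the partitioned survival model: 21-day cycles, a
#' 10-year horizon, 5% annual discounting of costs and utilities, and the
#' Chinese willingness-to-pay threshold of 3x 2021 per-capita GDP.
#'
#' Discounting defaults to discrete annual steps,
#' \eqn{(1+r)^{-\lfloor t \rfloor}} with `t` in years — the convention of
#' cycle-tree software, under which the deterministic base case reproduces
#' the published tables most closely — with continuous compounding
#' \eqn{(1+r)^{-t}} available via `discounting = "continuous"`.
#'
#' @param cycle_days Model cycle length in days (21, the administration
#'   cycle).
#' @param horizon_years Time horizon in years.
#' @param discount_rate_annual Annual discount rate for costs and QALYs/LYs.
#' @param half_cycle_correction Evaluate state membership at cycle midpoints
#'   instead of cycle starts.
#' @param discounting `"annual"` (discrete yearly steps, default) or
#'   `"continuous"`.
#' @param wtp_per_qaly Willingness-to-pay threshold, USD per QALY.
#' @param days_per_month Calendar convention converting cycle days to the
#'   month scale of the survival curves (365.25/12).
#' @return An object of class `model_settings`.
#' @export
model_settings <- function(cycle_days = 21,
                           horizon_years = 10,
                           discount_rate_annual = 0.05,
                           half_cycle_correction = FALSE,
                           discounting = c("annual", "continuous"),
                           wtp_per_qaly = 36203.88,
                           days_per_month = 30.4375) {
  discounting <- match.arg(discounting)
  stopifnot(cycle_days > 0, horizon_years > 0,
            discount_rate_annual >= 0, discount_rate_annual <= 1)
  structure(list(cycle_days = cycle_days, horizon_years = horizon_years,
                 discount_rate_annual = discount_rate_annual,
                 half_cycle_correction = isTRUE(half_cycle_correction),
                 discounting = discounting, wtp_per_qaly = wtp_per_qaly,
                 days_per_month = days_per_month,
                 cycle_months = cycle_days / days_per_month),
            class = "model_settings")
}

#' Discount factor at a point in time
#'
#' \eqn{(1+r)^{-t}} with `t` in years (continuous compounding) or
#' \eqn{(1+r)^{-\lfloor t \rfloor}} (discrete annual steps).
#'
#' @param t_years Non-negative times in years.
#' @param rate Annual discount rate (>= 0).
#' @param discounting `"continuous"` or `"annual"`.
#' @return Discount factors in (0, 1].
#' @examples
#' discount_factor(1, 0.05)             # 1/1.05
#' discount_factor(0.5, 0.05, "annual") # 1: still within the first year
#' @export
discount_factor <- function(t_years, rate,
                            discounting = c("continuous", "annual")) {
  discounting <- match.arg(discounting)
  if (rate < 0) stop("discount rate must be non-negative", call. = FALSE)
  if (any(t_years < 0)) stop("times must be non-negative", call. = FALSE)
  expo <- if (discounting == "annual") floor(t_years) else t_years
  (1 + rate)^(-expo)
}

#' Per-cycle state occupancy of the three-state PartSA model
#'
#' Partitioned survival: at each cycle time `t`,
#' \eqn{p_{PFS} = \min(S_{PFS}(t), S_{OS}(t))},
#' \eqn{p_{death} = 1 - S_{OS}(t)} and \eqn{p_{PD}} is the remainder
#' (clamped at 0 where extrapolated curves cross). Membership is evaluated
#' at cycle starts, or midpoints under half-cycle correction; the final
#' cycle is truncated at the horizon.
#'
#' @param pfs,os [surv_dist()] objects for progression-free and overall
#'   survival (times in months).
#' @param settings A [model_settings()] object.
#' @return A data frame of class `occupancy_trace` with columns `cycle`,
#'   `t_months` (cycle start), `width_months`, `t_eval` (evaluation time),
#'   `p_pfs`, `p_pd`, `p_death`, `discount`. Rows sum to 1 to within 1e-12.
#' @export
state_occupancy <- function(pfs, os, settings = model_settings()) {
  stopifnot(inherits(pfs, "surv_dist"), inherits(os, "surv_dist"),
            inherits(settings, "model_settings"))
  horizon_m <- settings$horizon_years * 12
  cm <- settings$cycle_months
  n <- ceiling(horizon_m / cm)
  t0 <- (seq_len(n) - 1) * cm
  w <- rep(cm, n)
  w[n] <- horizon_m - t0[n]
  t_eval <- if (settings$half_cycle_correction) t0 + w / 2 else t0
  s_pfs <- surv_prob(pfs, t_eval)
  s_os <- surv_prob(os, t_eval)
  p_pfs <- pmin(s_pfs, s_os)
  trace <- data.frame(cycle = seq_len(n) - 1L, t_months = t0,
                      width_months = w, t_eval = t_eval,
                      p_pfs = p_pfs, p_pd = s_os - p_pfs,
                      p_death = 1 - s_os,
                      discount = discount_factor(t_eval / 12,
                                                 settings$discount_rate_annual,
                                                 settings$discounting))
  class(trace) <- c("occupancy_trace", "data.frame")
  trace
}

#' Accrue a discounted total over an occupancy trace
#'
#' \deqn{\sum_k d_k (p_{PFS,k} v_{PFS,k} + p_{PD,k} v_{PD,k})
#'       + \sum_j d_{k_j} o_j}
#' where `d` is the per-cycle discount factor and `o` are one-off values
#' attached to specific cycles (e.g. the SAE cost and disutility deducted in
#' the first cycle). Linear in all values.
#'
#' @param trace An [state_occupancy()] trace.
#' @param pfs_values,pd_values Per-cycle values for the PFS and PD states;
#'   scalars are recycled.
#' @param one_off Named numeric vector of one-off values, names = cycle
#'   indices (0-based).
#' @return The discounted total (scalar).
#' @export
accrue <- function(trace, pfs_values, pd_values, one_off = NULL) {
  stopifnot(inherits(trace, "occupancy_trace"))
  if (any(trace$p_pfs < -1e-12 | trace$p_pd < -1e-12 | trace$p_death < -1e-12))
    stop("invalid trace: negative state probabilities", call. = FALSE)
  n <- nrow(trace)
  pfs_values <- rep_len(pfs_values, n)
  pd_values <- rep_len(pd_values, n)
  total <- sum(trace$discount * (trace$p_pfs * pfs_values +
                                 trace$p_pd * pd_values))
  if (length(one_off)) {
    idx <- as.integer(names(one_off)) + 1L
    stopifnot(all(idx >= 1L & idx <= n))
    total <- total + sum(trace$discount[idx] * one_off)
  }
  total
}

#' Run one strategy arm of the cost-utility model
#'
#' Composes [state_occupancy()], the arm's valuation streams
#' ([arm_definition()]) and [accrue()] into discounted totals: cost (with a
#' component breakdown), life-years and QALYs.
#'
#' @param arm An [arm_definition()].
#' @param settings A [model_settings()].
#' @param trace Optional precomputed [state_occupancy()] trace (the PSA
#'   reuses one trace across draws since survival parameters are fixed
#'   there).
#' @return An object of class `cea_arm`: list with `arm`, `total_cost`,
#'   `ly`, `qaly`, `cost_breakdown` (sums to `total_cost`), `trace`.
#' @export
run_arm <- function(arm, settings = model_settings(), trace = NULL) {
  stopifnot(inherits(arm, "arm_definition"),
            inherits(settings, "model_settings"))
  if (is.null(trace))
    trace <- state_occupancy(arm$pfs, arm$os, settings)
  streams <- valuation_streams(arm, settings, n_cycles = nrow(trace))

  wy <- trace$width_months / 12
  ly <- accrue(trace, wy, wy)
  qaly <- accrue(trace, arm$utility[["pfs"]] * wy, arm$utility[["pd"]] * wy,
                 one_off = c("0" = -streams$sae_qaly_loss))

  breakdown <- vapply(names(streams$pfs_components), function(comp) {
    accrue(trace, streams$pfs_components[[comp]],
           streams$pd_components[[comp]])
  }, numeric(1))
  breakdown[["sae"]] <- accrue(trace, 0, 0,
                               one_off = c("0" = streams$sae_cost))
  structure(list(arm = arm$label, total_cost = sum(breakdown), ly = ly,
                 qaly = qaly, cost_breakdown = breakdown, trace = trace),
            class = "cea_arm")
}

#' Incremental cost-effectiveness ratio
#'
#' Computed from unrounded per-arm totals. When the intervention is cheaper
#' and more effective (or the reverse) the comparison is labelled
#' dominant/dominated instead of reporting a ratio; a zero QALY difference
#' is flagged undefined.
#'
#' @param intervention,comparator `cea_arm` results from [run_arm()].
#' @return List with `delta_cost`, `delta_qaly`, `icer` (NA unless status is
#'   `"icer"`), `status` (one of `"icer"`, `"dominant"`, `"dominated"`,
#'   `"undefined"`).
#' @export
icer <- function(intervention, comparator) {
  dc <- intervention$total_cost - comparator$total_cost
  dq <- intervention$qaly - comparator$qaly
  if (dq == 0) {
    status <- "undefined"; ratio <- NA_real_
  } else if (dc <= 0 && dq > 0) {
    status <- "dominant"; ratio <- NA_real_
  } else if (dc >= 0 && dq < 0) {
    status <- "dominated"; ratio <- NA_real_
  } else {
    status <- "icer"; ratio <- dc / dq
  }
  list(delta_cost = dc, delta_qaly = dq, icer = ratio, status = status)
}

#' Run the full deterministic cost-utility comparison
#'
#' The model's main entry point: builds both strategy arms from an economics
#' configuration and survival curves, runs the partitioned survival model,
#' and returns per-arm discounted totals with the incremental comparison.
#'
#' @param economics Economics configuration, see [default_economics()].
#' @param settings A [model_settings()].
#' @param curves Per-arm survival curves, see [default_curves()];
#'   named list `arm -> list(pfs = , os = )`.
#' @param intervention,comparator Arm names (must match `curves` and the
#'   economics config).
#' @return An object of class `cea` with per-arm results (`arms`), the
#'   incremental comparison (`incremental`), and the inputs used. Methods:
#'   `print()`, `summary()`, `plot()` (occupancy traces).
#' @examples
#' res <- run_cea()
#' res
#' @export
run_cea <- function(economics = default_economics(),
                    settings = model_settings(),
                    curves = default_curves(),
                    intervention = "sugemalimab", comparator = "placebo") {
  arms <- list()
  for (a in c(intervention, comparator)) {
    def <- arm_definition(a, economics, curves[[a]])
    arms[[a]] <- run_arm(def, settings)
  }
  structure(list(arms = arms,
                 incremental = icer(arms[[intervention]], arms[[comparator]]),
                 intervention = intervention, comparator = comparator,
                 economics = economics, settings = settings, curves = curves),
            class = "cea")
}

#' @export
print.cea_arm <- function(x, ...) {
  cat(sprintf("<cea_arm> %s: cost %.2f USD | %.3f LY | %.3f QALY\n",
              x$arm, x$total_cost, x$ly, x$qaly))
  invisible(x)
}

#' @export
print.cea <- function(x, ...) {
  cat("Partitioned survival cost-utility analysis\n")
  for (a in x$arms)
    cat(sprintf("  %-12s cost %10.2f USD | %5.2f LY | %5.2f QALY\n",
                a$arm, a$total_cost, a$ly, a$qaly))
  inc <- x$incremental
  if (inc$status == "icer") {
    cat(sprintf("  incremental: %.2f USD, %.4f QALY -> ICER %.2f USD/QALY\n",
                inc$delta_cost, inc$delta_qaly, inc$icer))
    verdict <- if (inc$icer > x$settings$wtp_per_qaly) "not cost-effective"
               else "cost-effective"
    cat(sprintf("  vs WTP %.2f USD/QALY: %s\n", x$settings$wtp_per_qaly,
                verdict))
  } else {
    cat("  incremental status:", inc$status, "\n")
  }
  invisible(x)
}

#' @export
summary.cea <- function(object, ...) {
  arms <- object$arms
  df <- data.frame(
    arm = vapply(arms, `[[`, "", "arm"),
    cost = vapply(arms, `[[`, 0, "total_cost"),
    ly = vapply(arms, `[[`, 0, "ly"),
    qaly = vapply(arms, `[[`, 0, "qaly"))
  rownames(df) <- NULL
  inc <- object$incremental
  attr(df, "incremental") <- inc
  df
}

#' @export
plot.cea <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, length(x$arms)))
  on.exit(graphics::par(old))
  for (a in x$arms) {
    tr <- a$trace
    graphics::matplot(tr$t_months, cbind(tr$p_pfs, tr$p_pd, tr$p_death),
                      type = "l", lty = 1, lwd = 2,
                      col = c("forestgreen", "orange", "grey30"),
                      xlab = "Months", ylab = "State probability",
                      main = a$arm, ...)
    graphics::legend("right", c("PFS", "PD", "Death"), lty = 1, lwd = 2,
                     col = c("forestgreen", "orange", "grey30"), bty = "n")
  }
  invisible(x)
}
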