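#' Define a two-arm synthetic trial
#'
#' Describes a GEMSTONE-302-like randomized trial: per-arm sample sizes,
#' uniform accrual, a common administrative data cutoff, and per-arm PFS/OS
#' distributions. Defaults emulate the source trial's scale and maturity:
#' 2:1 randomization (320 vs 160), accrual over 12 months, cutoff at 30
#' months, and the published best-fit curves of [default_curves()].
#'
#' @param n_per_arm Named integer vector of patients per arm.
#' @param accrual_months Length of the uniform accrual window.
#' @param max_followup_months Administrative cutoff, measured from study
#'   start; a patient accrued at `a` is censored at `max_followup_months - a`.
#' @param arm_curves Named list (one element per arm) of lists with `pfs`
#'   and `os` [surv_dist()] objects.
#' @return An object of class `trial_design`.
#' @seealso [simulate_trial()]
#' @export
trial_design <- function(n_per_arm = c(sugemalimab = 320L, placebo = 160L),
                         accrual_months = 12,
                         max_followup_months = 30,
                         arm_curves = default_curves()) {
  stopifnot(all(n_per_arm >= 2), max_followup_months > 0,
            accrual_months >= 0,
            all(names(n_per_arm) %in% names(arm_curves)))
  for (a in names(n_per_arm)) {
    stopifnot(inherits(arm_curves[[a]]$pfs, "surv_dist"),
              inherits(arm_curves[[a]]$os, "surv_dist"))
  }
  structure(list(n_per_arm = n_per_arm, accrual_months = accrual_months,
                 max_followup_months = max_followup_months,
                 arm_curves = arm_curves[names(n_per_arm)]),
            class = "trial_design")
}

#' Simulate patient-level PFS and OS data for a two-arm trial
#'
#' Draws, per patient, a progression time and a death time whose marginals
#' follow the arm's PFS and OS distributions. The two endpoints are coupled
#' comonotonically (one shared uniform drives both quantile functions);
#' draws with death before the raw progression time are resolved by
#' redrawing the death uniform (bounded retries), and the PFS endpoint is
#' the earlier of progression and death, so PFS \eqn{\le} OS always holds.
#' Censoring is purely administrative: uniform accrual with a common data
#' cutoff. Only the marginal survival functions matter to the downstream
#' partitioned survival model; the coupling only shapes the joint law.
#'
#' @param design A [trial_design()].
#' @param max_retries Retries per patient for the OS >= PFS constraint.
#' @return A data frame of pseudo-IPD with columns `arm`, `endpoint`
#'   (`"pfs"`/`"os"`), `time_months` (> 0) and `event` (1 = event,
#'   0 = censored). Reproducible under [set.seed()].
#' @examples
#' set.seed(42)
#' ipd <- simulate_trial(trial_design())
#' table(ipd$arm, ipd$endpoint)
#' @export
simulate_trial <- function(design, max_retries = 1000L) {
  stopifnot(inherits(design, "trial_design"))
  out <- list()
  for (arm in names(design$n_per_arm)) {
    n <- design$n_per_arm[[arm]]
    d_pfs <- design$arm_curves[[arm]]$pfs
    d_os <- design$arm_curves[[arm]]$os
    u <- stats::runif(n)
    t_prog <- surv_quantile(d_pfs, u)
    t_os <- surv_quantile(d_os, u)
    bad <- which(t_os < t_prog)
    tries <- 0L
    while (length(bad) && tries < max_retries) {
      t_os[bad] <- surv_quantile(d_os, stats::runif(length(bad)))
      bad <- bad[t_os[bad] < t_prog[bad]]
      tries <- tries + 1L
    }
    if (length(bad))
      stop("could not couple OS >= PFS after ", max_retries, " retries",
           call. = FALSE)
    accrual <- stats::runif(n, 0, design$accrual_months)
    cens <- pmax(design$max_followup_months - accrual, 1e-6)
    t_pfs <- pmin(t_prog, t_os)    # PFS event = progression or death
    out[[arm]] <- rbind(
      data.frame(arm = arm, endpoint = "pfs",
                 time_months = pmin(t_pfs, cens),
                 event = as.integer(t_pfs <= cens)),
      data.frame(arm = arm, endpoint = "os",
                 time_months = pmin(t_os, cens),
                 event = as.integer(t_os <= cens)))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier step function of pseudo-IPD
#'
#' Thin wrapper over [survival::survfit] returning the step function as a
#' data frame (time, survival, n.risk).
#' @param time,event Right-censored observations.
#' @return Data frame with columns `time_months`, `survival`, `n_risk`.
#' @export
km_curve <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time_months = sf$time, survival = sf$surv, n_risk = sf$n.risk)
}

#' Sample a Kaplan-Meier curve on a digitization grid
#'
#' Emulates the output of curve digitization software: the KM step function
#' evaluated at a fixed grid of times, plus a numbers-at-risk table.
#'
#' @param time,event Right-censored observations.
#' @param grid Times at which to read off the curve (default 0.25-month
#'   spacing, finer than one model cycle).
#' @param risk_times Times at which numbers at risk are tabulated.
#' @return A list of class `digitized_curve` with `points`
#'   (`time_months`, `survival`) and `risk_table` (`time_months`, `n_risk`).
#' @export
digitize_km <- function(time, event,
                        grid = seq(0, max(time), by = 0.25),
                        risk_times = seq(0, max(time), by = 6)) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  surv_at <- function(tt) {
    vapply(tt, function(x) {
      i <- findInterval(x, sf$time)
      if (i == 0) 1 else sf$surv[i]
    }, numeric(1))
  }
  nrisk_at <- function(tt) {
    vapply(tt, function(x) sum(time >= x), numeric(1))
  }
  structure(list(points = data.frame(time_months = grid,
                                     survival = surv_at(grid)),
                 risk_table = data.frame(time_months = risk_times,
                                         n_risk = nrisk_at(risk_times))),
            class = "digitized_curve")
}

#' Reconstruct pseudo individual patient data from a digitized KM curve
#'
#' Guyot-style inversion of a published Kaplan-Meier curve: within each
#' numbers-at-risk interval, censoring is spread uniformly and the censored
#' count is chosen so that the implied number at risk at the start of the
#' next interval matches the published risk table, while events at each
#' digitized point are recovered from the drop in the KM product. Patients
#' still at risk after the last digitized point are censored there. Without
#' a risk table, an initial cohort size must be supplied and no censoring is
#' assumed before the end of follow-up.
#'
#' @param curve A `digitized_curve` (see [digitize_km()]), or a data frame
#'   with columns `time_months` and `survival`.
#' @param n0 Initial number at risk; required when `curve` carries no risk
#'   table.
#' @return Data frame with columns `time_months` and `event` — pseudo-IPD
#'   whose KM estimate tracks the digitized points.
#' @references Guyot P., Ades A.E., Ouwens M.J., Welton N.J. (2012).
#'   Enhanced secondary analysis of survival data: reconstructing the data
#'   from published Kaplan-Meier survival curves. BMC Med Res Methodol 12:9.
#' @export
reconstruct_ipd <- function(curve, n0 = NULL) {
  if (is.data.frame(curve))
    curve <- structure(list(points = curve, risk_table = NULL),
                       class = "digitized_curve")
  pts <- curve$points
  stopifnot(all(c("time_months", "survival") %in% names(pts)))
  pts <- pts[order(pts$time_months), ]
  if (any(pts$survival <= 0 | pts$survival > 1))
    stop("digitized survival must lie in (0, 1]", call. = FALSE)
  pts$survival <- cummin(pts$survival)  # enforce monotone non-increasing

  risk <- curve$risk_table
  if (is.null(risk) || !nrow(risk)) {
    if (is.null(n0)) stop("need n0 when no risk table is given", call. = FALSE)
    risk <- data.frame(time_months = pts$time_months[1], n_risk = n0)
  }
  if (any(diff(risk$n_risk) > 0))
    stop("risk table counts must be non-increasing", call. = FALSE)

  J <- nrow(pts)
  bounds <- c(risk$time_months, Inf)
  # interval index of each digitized point
  iv <- findInterval(pts$time_months, bounds, left.open = FALSE)
  iv[iv < 1] <- 1L

  ev_t <- numeric(0); cn_t <- numeric(0)
  n_hat <- risk$n_risk[1]
  km_prod <- 1
  for (i in seq_len(nrow(risk))) {
    jj <- which(iv == i)
    if (!length(jj)) next
    t_lo <- min(pts$time_months[jj])
    t_hi <- max(pts$time_months[jj])
    n_target <- if (i < nrow(risk)) risk$n_risk[i + 1] else NA_real_
    best <- NULL
    # choose the censored count in this interval to hit the next published
    # number at risk; last interval assumes administrative censoring only
    nc_max <- if (is.na(n_target)) 0L else max(0L, n_hat - 0L)
    cand <- if (is.na(n_target)) 0L else 0:nc_max
    for (nc in cand) {
      state <- .km_walk(pts$survival[jj], n_hat, km_prod, nc,
                        pts$time_months[jj], t_lo, t_hi)
      miss <- if (is.na(n_target)) 0 else abs(state$n_end - n_target)
      if (is.null(best) || miss < best$miss) {
        best <- c(state, list(miss = miss, nc = nc))
        if (miss == 0) break
      }
    }
    ev_t <- c(ev_t, best$ev_t)
    cn_t <- c(cn_t, best$cn_t)
    n_hat <- best$n_end
    km_prod <- best$km_end
    if (n_hat <= 0) break
  }
  # anyone left is administratively censored at the final digitized time
  if (n_hat > 0) cn_t <- c(cn_t, rep(max(pts$time_months), n_hat))
  out <- rbind(data.frame(time_months = ev_t, event = 1L),
               data.frame(time_months = cn_t, event = 0L))
  out <- out[out$time_months > 0 | out$event == 1L, ]
  out[order(out$time_months), , drop = FALSE]
}

# walk the digitized points of one risk-table interval with nc censorings
# spread uniformly; returns event/censor times and end state
.km_walk <- function(surv, n_start, km_start, nc, times, t_lo, t_hi) {
  J <- length(surv)
  # censoring times at interval quantiles
  c_times <- if (nc > 0) t_lo + (seq_len(nc) - 0.5) / nc * (t_hi - t_lo)
             else numeric(0)
  # censors allocated to the sub-interval ending at each digitized point
  c_alloc <- if (nc > 0)
    tabulate(findInterval(c_times, times, left.open = TRUE) + 1L, J)
  else integer(J)
  n_hat <- n_start; km <- km_start
  ev_t <- numeric(0); d_tot <- 0
  for (j in seq_len(J)) {
    d_j <- if (km > 0 && n_hat > 0)
      round(n_hat * (1 - surv[j] / km)) else 0
    d_j <- max(0, min(d_j, n_hat))
    if (d_j > 0) {
      km <- km * (1 - d_j / n_hat)
      ev_t <- c(ev_t, rep(times[j], d_j))
    }
    n_hat <- n_hat - d_j - c_alloc[j]
    if (n_hat < 0) { c_alloc[j] <- c_alloc[j] + n_hat; n_hat <- 0 }
    d_tot <- d_tot + d_j
  }
  list(ev_t = ev_t,
       cn_t = if (nc > 0) rep(times, c_alloc) else numeric(0),
       n_end = n_hat, km_end = km)
}

#' @export
print.trial_design <- function(x, ...) {
  cat("<trial_design>\n")
  for (a in names(x$n_per_arm))
    cat(sprintf("  %s: n = %d (PFS %s, OS %s)\n", a, x$n_per_arm[[a]],
                x$arm_curves[[a]]$pfs$family, x$arm_curves[[a]]$os$family))
  cat(sprintf("  accrual %.3g mo, cutoff %.3g mo\n",
              x$accrual_months, x$max_followup_months))
  invisible(x)
}
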