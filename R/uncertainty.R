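#' Sensitivity-analysis parameter table
#'
#' One row per uncertain input: its location in the configuration (a dotted
#' path), base value, one-way range, sampling distribution and role.
#' Ranges follow the study conventions: the intervention drug price varies
#' from 50% of list price up to list price, the discount rate over 0-8%,
#' utilities/disutilities and adverse-event probabilities over their
#' published ranges, and all remaining inputs +-20% of base. Costs are
#' sampled from gamma distributions and probabilities, utilities and
#' disutility magnitudes from beta distributions in the probabilistic
#' analysis; the discount rate and histology split are varied one-way only
#' (`dist = "fixed"`).
#'
#' Disutility rows carry the magnitude `|d|`; the applied value is negated.
#'
#' @return Data frame with columns `name`, `path`, `base`, `low`, `high`,
#'   `dist` (gamma/beta/fixed), `role` (cost/probability/utility/
#'   disutility/rate).
#' @export
parameter_table <- function() {
  row <- function(name, path, base, low, high, dist, role)
    data.frame(name = name, path = path, base = base, low = low,
               high = high, dist = dist, role = role)
  rbind(
    row("Price of sugemalimab (600 mg)", "prices.sugemalimab_600mg",
        1844.26, 922.13, 1844.26, "gamma", "cost"),
    row("Price of carboplatin (100 mg)", "prices.carboplatin_100mg",
        13.39, 10.71, 16.06, "gamma", "cost"),
    row("Price of pemetrexed (100 mg)", "prices.pemetrexed_100mg",
        330.23, 264.18, 396.27, "gamma", "cost"),
    row("Price of paclitaxel (30 mg)", "prices.paclitaxel_30mg",
        51.39, 41.12, 61.67, "gamma", "cost"),
    row("Price of docetaxel (20 mg)", "prices.docetaxel_20mg",
        96.65, 77.32, 115.97, "gamma", "cost"),
    row("Hospital management per cycle", "per_cycle.hospital",
        72.43, 57.94, 86.91, "gamma", "cost"),
    row("Follow-up per cycle", "per_cycle.followup",
        199.55, 159.64, 239.46, "gamma", "cost"),
    row("SAE cost, sugemalimab group", "sae_cost.sugemalimab",
        23.57, 18.86, 28.28, "gamma", "cost"),
    row("SAE cost, placebo group", "sae_cost.placebo",
        23.81, 19.05, 28.57, "gamma", "cost"),
    row("Best supportive care per cycle", "per_cycle.bsc",
        320.84, 256.67, 385.01, "gamma", "cost"),
    row("P(neutropenia), sugemalimab", "sae_prob.sugemalimab.neutropenia",
        0.3250, 0.2600, 0.3900, "beta", "probability"),
    row("P(nausea/vomiting), sugemalimab",
        "sae_prob.sugemalimab.nausea_vomiting",
        0.0160, 0.0128, 0.0192, "beta", "probability"),
    row("P(alopecia), sugemalimab", "sae_prob.sugemalimab.alopecia",
        0.0030, 0.0024, 0.0036, "beta", "probability"),
    row("P(rash), sugemalimab", "sae_prob.sugemalimab.rash",
        0.0060, 0.0048, 0.0072, "beta", "probability"),
    row("P(fatigue), sugemalimab", "sae_prob.sugemalimab.fatigue",
        0.0090, 0.0072, 0.1080, "beta", "probability"),
    row("P(diarrhoea), sugemalimab", "sae_prob.sugemalimab.diarrhoea",
        0.0090, 0.0072, 0.1080, "beta", "probability"),
    row("P(neutropenia), placebo", "sae_prob.placebo.neutropenia",
        0.3330, 0.2664, 0.3996, "beta", "probability"),
    row("P(nausea/vomiting), placebo", "sae_prob.placebo.nausea_vomiting",
        0.0250, 0.0200, 0.0300, "beta", "probability"),
    row("P(fatigue), placebo", "sae_prob.placebo.fatigue",
        0.0060, 0.0048, 0.0072, "beta", "probability"),
    row("Utility of PFS", "utility.pfs",
        0.804, 0.536, 0.840, "beta", "utility"),
    row("Utility of PD", "utility.pd",
        0.321, 0.031, 0.473, "beta", "utility"),
    row("Disutility of neutropenia", "disutility.neutropenia",
        0.20, 0.15, 0.50, "beta", "disutility"),
    row("Disutility of nausea/vomiting", "disutility.nausea_vomiting",
        0.12, 0.06, 0.29, "beta", "disutility"),
    row("Disutility of alopecia", "disutility.alopecia",
        0.06, 0.06, 0.26, "beta", "disutility"),
    row("Disutility of rash", "disutility.rash",
        0.10, 0.10, 0.19, "beta", "disutility"),
    row("Disutility of fatigue", "disutility.fatigue",
        0.07, 0.07, 0.49, "beta", "disutility"),
    row("Disutility of diarrhoea", "disutility.diarrhoea",
        0.07, 0.06, 0.35, "beta", "disutility"),
    row("Squamous histology fraction", "squamous_fraction",
        0.40, 0.32, 0.48, "fixed", "probability"),
    row("Annual discount rate", "settings.discount_rate_annual",
        0.05, 0.00, 0.08, "fixed", "rate"))
}

# set a value in a nested list by dotted path
set_by_path <- function(x, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  rec <- function(node, keys) {
    if (length(keys) == 1L) {
      node[[keys]] <- value
      return(node)
    }
    node[[keys[1]]] <- rec(node[[keys[1]]], keys[-1])
    node
  }
  rec(x, keys)
}

# apply one parameter excursion; disutility rows carry magnitudes
apply_parameter <- function(economics, settings, row, value) {
  value <- unname(value)
  if (row$role == "disutility") value <- -abs(value)
  if (startsWith(row$path, "settings.")) {
    settings[[sub("^settings\\.", "", row$path)]] <- value
  } else {
    economics <- set_by_path(economics, row$path, value)
  }
  list(economics = economics, settings = settings)
}

.cea_icer <- function(economics, settings, curves, intervention, comparator) {
  res <- run_cea(economics, settings, curves, intervention, comparator)
  res$incremental$icer
}

#' One-way (deterministic) sensitivity analysis
#'
#' Reruns the deterministic model with each parameter in turn at its lower
#' and upper bound, all others held at base, and tabulates the resulting
#' ICERs. Entries are sorted by descending bar width for tornado plotting;
#' a model failure at an excursion is recorded as `NA` for that bound, not
#' raised.
#'
#' @inheritParams run_cea
#' @param params Parameter table, see [parameter_table()].
#' @return Data frame of class `cea_owsa` with columns `name`, `low`,
#'   `high`, `icer_low`, `icer_high`, `width`, sorted by `width`
#'   (descending); the base-case ICER is in `attr(, "base_icer")`.
#'   `plot()` draws the tornado diagram.
#' @export
owsa <- function(economics = default_economics(),
                 settings = model_settings(),
                 curves = default_curves(),
                 params = parameter_table(),
                 intervention = "sugemalimab", comparator = "placebo") {
  base_icer <- .cea_icer(economics, settings, curves, intervention,
                         comparator)
  one <- function(row, value) {
    tryCatch({
      mod <- apply_parameter(economics, settings, row, value)
      .cea_icer(mod$economics, mod$settings, curves, intervention,
                comparator)
    }, error = function(e) NA_real_)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(params)), function(i) {
    row <- params[i, ]
    il <- one(row, row$low); ih <- one(row, row$high)
    data.frame(name = row$name, low = row$low, high = row$high,
               icer_low = il, icer_high = ih,
               width = abs(ih - il))
  }))
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_icer
  class(out) <- c("cea_owsa", "data.frame")
  out
}

#' @export
plot.cea_owsa <- function(x, n_top = 12, ...) {
  d <- x[seq_len(min(n_top, nrow(x))), ]
  d <- d[nrow(d):1, ]
  base <- attr(x, "base_icer")
  lo <- pmin(d$icer_low, d$icer_high)
  hi <- pmax(d$icer_low, d$icer_high)
  old <- graphics::par(mar = c(4, 16, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(NULL, xlim = range(c(lo, hi, base), finite = TRUE),
                 ylim = c(0.5, nrow(d) + 0.5), yaxt = "n",
                 xlab = "ICER (USD/QALY)", ylab = "",
                 main = "One-way sensitivity analysis", ...)
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$name, las = 1,
                 cex.axis = 0.7)
  graphics::rect(lo, seq_len(nrow(d)) - 0.35, hi, seq_len(nrow(d)) + 0.35,
                 col = "steelblue", border = NA)
  graphics::abline(v = base, lty = 2)
  invisible(x)
}

#' Sample parameter vectors for probabilistic sensitivity analysis
#'
#' Second-order Monte Carlo draws: gamma for costs and beta for
#' probabilities, utilities and disutility magnitudes, each moment-matched
#' to mean = base value and sd = (high - low)/3.92 (the range read as a 95%
#' interval). A beta sd that is infeasible for the mean is clipped with a
#' warning; `dist = "fixed"` rows are kept at base. Draws are reproducible
#' under [set.seed()].
#'
#' @param params Parameter table ([parameter_table()]).
#' @param n Number of draws.
#' @return An `n` x `nrow(params)` matrix, columns named by parameter path.
#' @export
draw_parameters <- function(params, n) {
  stopifnot(n >= 1)
  draws <- matrix(NA_real_, n, nrow(params),
                  dimnames = list(NULL, params$path))
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    sd <- (p$high - p$low) / 3.92
    draws[, i] <- if (p$dist == "fixed" || sd == 0) {
      rep(p$base, n)
    } else if (p$dist == "gamma") {
      stats::rgamma(n, shape = p$base^2 / sd^2, rate = p$base / sd^2)
    } else if (p$dist == "beta") {
      m <- p$base
      sd_max <- sqrt(m * (1 - m))
      if (sd >= sd_max) {
        warning("sd clipped to feasible value for beta parameter '",
                p$name, "'", call. = FALSE)
        sd <- 0.95 * sd_max
      }
      v <- m * (1 - m) / sd^2 - 1
      stats::rbeta(n, m * v, (1 - m) * v)
    } else stop("unknown distribution: ", p$dist, call. = FALSE)
  }
  draws
}

#' Probabilistic sensitivity analysis
#'
#' Runs the model under `n` second-order Monte Carlo parameter draws
#' ([draw_parameters()]); survival-curve parameters are held fixed (the
#' published input table lists no sampling distribution for them), so the
#' occupancy traces are computed once and reused.
#'
#' @inheritParams owsa
#' @param n Number of draws (study convention: 1000).
#' @return Object of class `cea_psa`: `samples` (per-draw costs, QALYs and
#'   increments), `draws` (the parameter matrix), `wtp`. `plot()` draws the
#'   incremental cost-effectiveness scatter; see [ceac()].
#' @export
psa <- function(economics = default_economics(),
                settings = model_settings(),
                curves = default_curves(),
                params = parameter_table(), n = 1000,
                intervention = "sugemalimab", comparator = "placebo") {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  draws <- draw_parameters(params, n)
  # enforce the state-utility ordering u_pd <= u_pfs (independent beta
  # draws cross in a fraction ~2e-4 of samples); the PD utility of an
  # offending draw is resampled, leaving the PFS marginal untouched
  i_pfs <- match("utility.pfs", params$path)
  i_pd <- match("utility.pd", params$path)
  if (!is.na(i_pfs) && !is.na(i_pd)) {
    for (guard in 1:100) {
      bad <- which(draws[, i_pd] > draws[, i_pfs])
      if (!length(bad)) break
      draws[bad, i_pd] <- draw_parameters(params[i_pd, ],
                                          length(bad))[, 1]
    }
    draws[, i_pd] <- pmin(draws[, i_pd], draws[, i_pfs])
  }
  arms <- c(intervention, comparator)
  traces <- lapply(arms, function(a)
    state_occupancy(curves[[a]]$pfs, curves[[a]]$os, settings))
  names(traces) <- arms
  sampled <- params$dist != "fixed"
  samples <- vapply(seq_len(n), function(j) {
    econ_j <- economics
    for (i in which(sampled)) {
      econ_j <- apply_parameter(econ_j, settings, params[i, ],
                                draws[j, i])$economics
    }
    res <- vapply(arms, function(a) {
      r <- run_arm(arm_definition(a, econ_j, curves[[a]]), settings,
                   trace = traces[[a]])
      c(r$total_cost, r$qaly)
    }, numeric(2))
    c(cost_int = res[1, 1], qaly_int = res[2, 1],
      cost_comp = res[1, 2], qaly_comp = res[2, 2])
  }, numeric(4))
  samples <- as.data.frame(t(samples))
  samples$draw <- seq_len(n)
  samples$delta_cost <- samples$cost_int - samples$cost_comp
  samples$delta_qaly <- samples$qaly_int - samples$qaly_comp
  structure(list(samples = samples, draws = draws,
                 wtp = settings$wtp_per_qaly,
                 intervention = intervention, comparator = comparator),
            class = "cea_psa")
}

#' @export
print.cea_psa <- function(x, ...) {
  s <- x$samples
  cat(sprintf("PSA with %d draws: mean dCost %.2f USD, mean dQALY %.4f\n",
              nrow(s), mean(s$delta_cost), mean(s$delta_qaly)))
  cat(sprintf("P(cost-effective at WTP %.2f) = %.3f\n", x$wtp,
              mean(x$wtp * s$delta_qaly - s$delta_cost > 0)))
  invisible(x)
}

#' @export
plot.cea_psa <- function(x, ...) {
  s <- x$samples
  graphics::plot(s$delta_qaly, s$delta_cost, pch = 16, cex = 0.5,
                 col = grDevices::adjustcolor("steelblue", 0.6),
                 xlab = "Incremental QALYs", ylab = "Incremental cost (USD)",
                 main = "Incremental cost-effectiveness scatter", ...)
  graphics::abline(0, x$wtp, lty = 2)
  graphics::abline(h = 0, v = 0, col = "grey70")
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with
#' positive net monetary benefit, \eqn{w \Delta QALY - \Delta cost > 0}.
#' Monotone non-decreasing in `w` whenever all draws gain QALYs.
#'
#' @param x A `cea_psa` object.
#' @param wtp_grid Willingness-to-pay grid (USD/QALY); the default spans 0
#'   to 400,000 in 2,000-USD steps.
#' @return Data frame of class `cea_ceac` with columns `wtp` and
#'   `probability`; `plot()` draws the curve.
#' @export
ceac <- function(x, wtp_grid = seq(0, 4e5, by = 2000)) {
  stopifnot(inherits(x, "cea_psa"))
  s <- x$samples
  pr <- vapply(wtp_grid,
               function(w) mean(w * s$delta_qaly - s$delta_cost > 0),
               numeric(1))
  structure(data.frame(wtp = wtp_grid, probability = pr),
            class = c("cea_ceac", "data.frame"))
}

#' @export
plot.cea_ceac <- function(x, ...) {
  graphics::plot(x$wtp, x$probability, type = "l", lwd = 2,
                 ylim = c(0, 1), xlab = "Willingness to pay (USD/QALY)",
                 ylab = "P(cost-effective)",
                 main = "Cost-effectiveness acceptability curve", ...)
  invisible(x)
}

#' Scenario analyses
#'
#' Reruns the deterministic base case under the study's scenarios:
#' intervention drug price reduced by 70% and 90% (the price factor scales
#' the sugemalimab vial price, hence first-line and crossover use,
#' linearly); 5- and 20-year horizons; and, optionally, alternative OS
#' extrapolations (mixture cure, non-mixture cure, Royston-Parmar spline)
#' supplied as fitted distributions per arm.
#'
#' @inheritParams owsa
#' @param price_factors Multipliers applied to the sugemalimab vial price
#'   (besides the base case).
#' @param horizons_years Alternative horizons (besides the base case).
#' @param os_alternatives Named list of scenarios, each a named list
#'   `arm -> surv_dist` replacing the OS curve of each arm.
#' @return Data frame of class `cea_scenarios`: one row per scenario and
#'   arm with discounted cost, LY, QALY and the scenario's incremental
#'   cost, QALY and ICER on the intervention row.
#' @export
run_scenarios <- function(economics = default_economics(),
                          settings = model_settings(),
                          curves = default_curves(),
                          price_factors = c(0.3, 0.1),
                          horizons_years = c(5, 20),
                          os_alternatives = NULL,
                          intervention = "sugemalimab",
                          comparator = "placebo") {
  run1 <- function(label, econ, sett, crv) {
    res <- run_cea(econ, sett, crv, intervention, comparator)
    s <- summary(res)
    inc <- res$incremental
    s$scenario <- label
    s$delta_cost <- c(inc$delta_cost, NA)
    s$delta_qaly <- c(inc$delta_qaly, NA)
    s$icer <- c(inc$icer, NA)
    s[, c("scenario", "arm", "cost", "ly", "qaly",
          "delta_cost", "delta_qaly", "icer")]
  }
  out <- list(run1("base", economics, settings, curves))
  for (f in price_factors) {
    econ_f <- economics
    econ_f$prices$sugemalimab_600mg <- econ_f$prices$sugemalimab_600mg * f
    out[[length(out) + 1]] <-
      run1(sprintf("price_x%.2f", f), econ_f, settings, curves)
  }
  for (h in horizons_years) {
    sett_h <- settings
    sett_h$horizon_years <- h
    out[[length(out) + 1]] <-
      run1(sprintf("horizon_%gy", h), economics, sett_h, curves)
  }
  for (nm in names(os_alternatives)) {
    crv <- curves
    for (a in names(os_alternatives[[nm]]))
      crv[[a]]$os <- os_alternatives[[nm]][[a]]
    out[[length(out) + 1]] <- run1(nm, economics, settings, crv)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("cea_scenarios", "data.frame")
  out
}
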