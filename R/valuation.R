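#' Default economic inputs
#'
#' The base-case economic configuration of the evaluation, from the Chinese
#' health-system perspective (USD; 1 USD = 6.71 CNY at the study's
#' conversion): per-vial drug prices, per-cycle management costs, one-off
#' serious-adverse-event (grade >= 3, incidence >= 10%) costs and
#' probabilities with their disutilities, health-state utilities, the
#' post-progression treatment mix of each arm, and the dosing assumptions
#' (body surface area 1.72 m2, GFR 70 ml/min, carboplatin by the Calvert
#' formula).
#'
#' @details The squamous/non-squamous histology split used to weight the
#'   chemotherapy backbone (paclitaxel vs pemetrexed) is not a published
#'   input; `squamous_fraction = 0.4` approximates the trial population and
#'   is swept in the one-way sensitivity analysis. Post-progression costs
#'   (docetaxel 75 mg/m2 q3w, crossover sugemalimab 1200 mg, or best
#'   supportive care, each plus follow-up) are applied to every cycle of PD
#'   occupancy; `pd_crossover_cap_cycles` optionally stops the crossover
#'   drug component after a fixed number of model cycles.
#'
#' @return A nested list of class `cea_economics`.
#' @export
default_economics <- function() {
  structure(list(
    prices = list(
      sugemalimab_600mg = 1844.26,
      carboplatin_100mg = 13.39,
      pemetrexed_100mg  = 330.23,
      paclitaxel_30mg   = 51.39,
      docetaxel_20mg    = 96.65),
    per_cycle = list(
      hospital = 72.43,
      followup = 199.55,
      bsc      = 320.84),
    sae_cost = list(sugemalimab = 23.57, placebo = 23.81),
    sae_prob = list(
      sugemalimab = c(neutropenia = 0.3250, nausea_vomiting = 0.0160,
                      alopecia = 0.0030, rash = 0.0060, fatigue = 0.0090,
                      diarrhoea = 0.0090),
      placebo = c(neutropenia = 0.3330, nausea_vomiting = 0.0250,
                  fatigue = 0.0060)),
    disutility = c(neutropenia = -0.20, nausea_vomiting = -0.12,
                   alopecia = -0.06, rash = -0.10, fatigue = -0.07,
                   diarrhoea = -0.07),
    utility = c(pfs = 0.804, pd = 0.321),
    subsequent = list(
      sugemalimab = c(docetaxel = 0.531, crossover = 0.056, bsc = 0.413),
      placebo     = c(docetaxel = 0.251, crossover = 0.277, bsc = 0.472)),
    dosing = list(
      bsa_m2 = 1.72, gfr_ml_min = 70, carboplatin_auc = 5,
      pemetrexed_mg_per_m2 = 500, paclitaxel_mg_per_m2 = 175,
      docetaxel_mg_per_m2 = 75, sugemalimab_mg = 1200,
      induction_cycles = 4L, max_treatment_cycles = 35L),
    squamous_fraction = 0.4,
    pd_crossover_cap_cycles = NULL),
    class = "cea_economics")
}

#' Default survival curves of the two strategy arms
#'
#' The published best-fitting extrapolations, by AIC/BIC, of the trial's
#' Kaplan-Meier curves (times in months): log-logistic PFS and OS in the
#' sugemalimab arm, log-logistic PFS and log-normal OS in the placebo arm.
#' The log-logistic scale is the median (9.35 months approximates the
#' trial's 9.0-month median PFS); the log-normal parameters are
#' meanlog/sdlog, median \eqn{e^{2.8289} \approx 16.9} months against the
#' trial's 17.7.
#'
#' @return Named list `arm -> list(pfs, os)` of [surv_dist()] objects.
#' @export
default_curves <- function() {
  list(
    sugemalimab = list(
      pfs = surv_dist("loglogistic", shape = 1.6637, scale = 9.3549),
      os  = surv_dist("loglogistic", shape = 1.3722, scale = 24.9818)),
    placebo = list(
      pfs = surv_dist("loglogistic", shape = 1.9645, scale = 5.3347),
      os  = surv_dist("lognormal", meanlog = 2.8289, sdlog = 0.9785)))
}

#' Carboplatin dose by the Calvert formula
#'
#' dose (mg) = AUC x (GFR + 25).
#'
#' @param auc Target area under the curve (mg/mL/min).
#' @param gfr Glomerular filtration rate (ml/min).
#' @return Dose in mg.
#' @examples
#' carboplatin_dose(5, 70)  # 475 mg
#' @export
carboplatin_dose <- function(auc, gfr) {
  stopifnot(auc >= 0, gfr >= 0)
  auc * (gfr + 25)
}

#' Drug acquisition cost under a whole-vial policy
#'
#' Vials cannot be shared: the administered dose is rounded up to whole
#' vials, `ceiling(dose/vial) x price`. This reproduces the published
#' per-cycle immunotherapy acquisition cost of 2 x 1844.26 = 3688.52 USD
#' for the 1200 mg dose in 600 mg vials.
#'
#' @param dose_mg Administered dose (mg), >= 0.
#' @param vial_mg Vial size (mg), > 0.
#' @param vial_price Price per vial (USD).
#' @return Acquisition cost in USD.
#' @export
drug_admin_cost <- function(dose_mg, vial_mg, vial_price) {
  if (any(dose_mg < 0)) stop("dose must be non-negative", call. = FALSE)
  stopifnot(vial_mg > 0)
  ceiling(dose_mg / vial_mg) * vial_price
}

# per-cycle acquisition costs of each agent at the configured dosing
.agent_costs <- function(econ) {
  d <- econ$dosing; p <- econ$prices
  list(
    sugemalimab = drug_admin_cost(d$sugemalimab_mg, 600,
                                  p$sugemalimab_600mg),
    carboplatin = drug_admin_cost(
      carboplatin_dose(d$carboplatin_auc, d$gfr_ml_min), 100,
      p$carboplatin_100mg),
    pemetrexed = drug_admin_cost(d$pemetrexed_mg_per_m2 * d$bsa_m2, 100,
                                 p$pemetrexed_100mg),
    paclitaxel = drug_admin_cost(d$paclitaxel_mg_per_m2 * d$bsa_m2, 30,
                                 p$paclitaxel_30mg),
    docetaxel = drug_admin_cost(d$docetaxel_mg_per_m2 * d$bsa_m2, 20,
                                p$docetaxel_20mg))
}

#' On-treatment drug cost of one model cycle
#'
#' First-line regimen cost by cycle index (0-based): induction cycles
#' (first 4) carry the platinum doublet (carboplatin plus a
#' histology-weighted mix of paclitaxel for squamous and pemetrexed for
#' non-squamous disease) on top of sugemalimab (intervention arm only);
#' maintenance cycles (up to the 35-cycle treatment cap) carry sugemalimab
#' (intervention) and pemetrexed for the non-squamous fraction (both arms);
#' beyond the cap the drug cost is zero.
#'
#' @param arm `"sugemalimab"` or `"placebo"`.
#' @param cycle_index 0-based cycle number(s).
#' @param econ Economics configuration ([default_economics()]).
#' @return Drug cost in USD per cycle (vector along `cycle_index`).
#' @export
oncycle_cost <- function(arm, cycle_index, econ = default_economics()) {
  arm <- match.arg(arm, c("sugemalimab", "placebo"))
  stopifnot(all(cycle_index >= 0))
  sq <- econ$squamous_fraction
  if (sq < 0 || sq > 1)
    stop("squamous_fraction must lie in [0, 1]", call. = FALSE)
  ac <- .agent_costs(econ)
  induction <- cycle_index < econ$dosing$induction_cycles
  on_trt <- cycle_index < econ$dosing$max_treatment_cycles
  chemo <- ifelse(induction,
                  ac$carboplatin + sq * ac$paclitaxel +
                    (1 - sq) * ac$pemetrexed,
                  (1 - sq) * ac$pemetrexed)
  immuno <- if (arm == "sugemalimab") ac$sugemalimab else 0
  ifelse(on_trt, immuno + chemo, 0)
}

#' Expected post-progression cost per cycle
#'
#' Expectation over the arm's subsequent-treatment mix of docetaxel
#' (75 mg/m2 q3w), crossover sugemalimab (1200 mg q3w) and best supportive
#' care, each plus the per-cycle follow-up cost; applied to every cycle of
#' PD occupancy.
#'
#' @param mix Named fractions `c(docetaxel=, crossover=, bsc=)` summing
#'   to 1 (+-0.01).
#' @param econ Economics configuration.
#' @return Cost in USD per PD cycle.
#' @export
progression_cost_per_cycle <- function(mix, econ = default_economics()) {
  stopifnot(all(c("docetaxel", "crossover", "bsc") %in% names(mix)))
  if (any(mix < 0 | mix > 1) || abs(sum(mix) - 1) > 0.01)
    stop("subsequent-treatment mix must be fractions summing to 1",
         call. = FALSE)
  ac <- .agent_costs(econ)
  unname(mix[["docetaxel"]] * ac$docetaxel +
         mix[["crossover"]] * ac$sugemalimab +
         mix[["bsc"]] * econ$per_cycle$bsc +
         econ$per_cycle$followup)
}

#' One-off serious-adverse-event burden of an arm
#'
#' The SAE cost is the arm's published aggregate management cost; the QALY
#' loss is \eqn{\sum_i p_i |d_i|} scaled by one cycle length in years (the
#' disutility is carried for one model cycle), both applied in the model's
#' first cycle.
#'
#' @param probs Named per-event probabilities (grade >= 3 SAEs).
#' @param disutility Named disutilities (<= 0); matched to `probs` by name.
#' @param cost_one_off Aggregate SAE management cost (USD).
#' @param cycle_years One model cycle expressed in years.
#' @return List with `one_off_cost` and `one_off_qaly_loss` (>= 0, to be
#'   deducted).
#' @export
sae_burden <- function(probs, disutility, cost_one_off, cycle_years) {
  stopifnot(all(probs >= 0 & probs <= 1), all(disutility <= 0),
            cycle_years > 0)
  d <- disutility[names(probs)]
  if (anyNA(d))
    stop("missing disutility for: ",
         paste(names(probs)[is.na(d)], collapse = ", "), call. = FALSE)
  list(one_off_cost = cost_one_off,
       one_off_qaly_loss = sum(probs * abs(d)) * cycle_years)
}

#' Define one strategy arm
#'
#' Bundles the survival curves, utilities, dosing/price configuration and
#' SAE profile of one arm into the object consumed by [run_arm()].
#'
#' @param label Arm name, `"sugemalimab"` or `"placebo"`.
#' @param econ Economics configuration ([default_economics()]).
#' @param curves List with `pfs` and `os` [surv_dist()] objects.
#' @return Object of class `arm_definition`.
#' @export
arm_definition <- function(label, econ = default_economics(),
                           curves = default_curves()[[label]]) {
  label <- match.arg(label, c("sugemalimab", "placebo"))
  stopifnot(inherits(curves$pfs, "surv_dist"),
            inherits(curves$os, "surv_dist"))
  u <- econ$utility
  if (u[["pd"]] < 0 || u[["pd"]] > u[["pfs"]] || u[["pfs"]] > 1)
    stop("utilities must satisfy 0 <= u_pd <= u_pfs <= 1", call. = FALSE)
  structure(list(label = label, pfs = curves$pfs, os = curves$os,
                 utility = u, economics = econ),
            class = "arm_definition")
}

# Per-cycle cost component streams of an arm: named list of vectors for the
# PFS and PD states plus the one-off SAE burden. Components: immunotherapy
# (first-line + crossover sugemalimab), chemotherapy, hospital, followup,
# subsequent (docetaxel + BSC), sae.
valuation_streams <- function(arm, settings, n_cycles) {
  econ <- arm$economics
  k <- seq_len(n_cycles) - 1L
  ac <- .agent_costs(econ)
  sq <- econ$squamous_fraction
  induction <- k < econ$dosing$induction_cycles
  on_trt <- k < econ$dosing$max_treatment_cycles

  chemo <- ifelse(on_trt,
                  ifelse(induction,
                         ac$carboplatin + sq * ac$paclitaxel +
                           (1 - sq) * ac$pemetrexed,
                         (1 - sq) * ac$pemetrexed),
                  0)
  immuno_pfs <- if (arm$label == "sugemalimab")
    ifelse(on_trt, ac$sugemalimab, 0) else rep(0, n_cycles)

  mix <- econ$subsequent[[arm$label]]
  if (abs(sum(mix) - 1) > 0.01)
    stop("subsequent-treatment mix must sum to 1", call. = FALSE)
  xover_on <- if (is.null(econ$pd_crossover_cap_cycles)) rep(TRUE, n_cycles)
              else k < econ$pd_crossover_cap_cycles
  immuno_pd <- mix[["crossover"]] * ac$sugemalimab * xover_on
  subseq_pd <- mix[["docetaxel"]] * ac$docetaxel +
    mix[["bsc"]] * econ$per_cycle$bsc

  zero <- rep(0, n_cycles)
  pfs_components <- list(
    immunotherapy = immuno_pfs,
    chemotherapy = chemo,
    hospital = ifelse(on_trt, econ$per_cycle$hospital, 0),
    followup = ifelse(on_trt, econ$per_cycle$followup, 0),
    subsequent = zero)
  pd_components <- list(
    immunotherapy = immuno_pd,
    chemotherapy = zero,
    hospital = zero,
    followup = rep(econ$per_cycle$followup, n_cycles),
    subsequent = rep(subseq_pd, n_cycles))

  sae <- sae_burden(econ$sae_prob[[arm$label]], econ$disutility,
                    econ$sae_cost[[arm$label]],
                    settings$cycle_months / 12)
  list(pfs_components = pfs_components, pd_components = pd_components,
       sae_cost = sae$one_off_cost, sae_qaly_loss = sae$one_off_qaly_loss)
}
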