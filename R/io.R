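#' Read and write pseudo-IPD event tables
#'
#' Pseudo individual patient data are exchanged as plain CSV with columns
#' `time_months` (positive), `event` (1 = event, 0 = censored) and,
#' optionally, `arm` and `endpoint`.
#'
#' @param path CSV file path.
#' @param ipd Data frame as returned by [simulate_trial()] or
#'   [reconstruct_ipd()].
#' @return `read_ipd()` returns the validated data frame.
#' @export
read_ipd <- function(path) {
  ipd <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_months", "event")
  miss <- setdiff(need, names(ipd))
  if (length(miss))
    stop("malformed IPD file '", path, "': missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(ipd$time_months) | ipd$time_months <= 0 |
                 !(ipd$event %in% c(0, 1)))
  if (length(bad))
    stop("malformed IPD file '", path, "': invalid values at data line(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  ipd
}

#' @rdname read_ipd
#' @export
write_ipd <- function(ipd, path) {
  utils::write.csv(ipd, path, row.names = FALSE)
  invisible(path)
}

#' Read a digitized Kaplan-Meier curve
#'
#' @param points_path CSV with columns `time_months,survival`.
#' @param risk_path Optional CSV with columns `time_months,n_risk`.
#' @return A `digitized_curve` object (see [digitize_km()]).
#' @export
read_digitized <- function(points_path, risk_path = NULL) {
  pts <- utils::read.csv(points_path)
  stopifnot(all(c("time_months", "survival") %in% names(pts)))
  risk <- if (!is.null(risk_path)) {
    r <- utils::read.csv(risk_path)
    stopifnot(all(c("time_months", "n_risk") %in% names(r)))
    r
  }
  structure(list(points = pts, risk_table = risk),
            class = "digitized_curve")
}

#' Serialize a fitted survival model to YAML
#'
#' Writes family, parameter vector, log-likelihood and AIC/BIC; the
#' round-trip through [read_parsurv()] restores a [surv_dist()] plus fit
#' statistics.
#'
#' @param fit A `parsurv` object ([fit_parsurv()]) or a list of them.
#' @param path Output YAML file.
#' @export
write_parsurv <- function(fit, path) {
  as_rec <- function(f) {
    d <- f$dist
    rec <- list(family = d$family,
                loglik = f$loglik, aic = f$aic, bic = f$bic,
                n = f$n, n_events = f$n_events, converged = f$converged)
    if (d$family == "royston_parmar") {
      rec$gamma <- as.numeric(d$pars$gamma)
      rec$knots <- as.numeric(d$pars$knots)
    } else {
      rec$params <- as.list(d$pars)
      if (!is.null(d$base))
        rec$base <- list(family = d$base$family,
                         params = as.list(d$base$pars))
    }
    rec
  }
  recs <- if (inherits(fit, "parsurv")) as_rec(fit) else lapply(fit, as_rec)
  yaml::write_yaml(recs, path, precision = 15)
  invisible(path)
}

#' @rdname write_parsurv
#' @export
read_parsurv <- function(path) {
  rec <- yaml::read_yaml(path)
  from_rec <- function(r) {
    dist <- if (r$family == "royston_parmar") {
      surv_dist_rp(unlist(r$gamma), unlist(r$knots))
    } else if (!is.null(r$base)) {
      surv_dist(r$family, cure = r$params$cure,
                base = do.call(surv_dist,
                               c(list(r$base$family), r$base$params)))
    } else {
      do.call(surv_dist, c(list(r$family), r$params))
    }
    structure(list(dist = dist, loglik = r$loglik, npars = n_pars(dist),
                   aic = r$aic, bic = r$bic, n = r$n,
                   n_events = r$n_events, converged = r$converged,
                   family = r$family, time = NULL, event = NULL),
              class = "parsurv")
  }
  if (!is.null(rec$family)) from_rec(rec) else lapply(rec, from_rec)
}

#' Load an economics configuration from YAML
#'
#' Reads a config mirroring [default_economics()] (sections `prices`,
#' `per_cycle`, `sae_cost`, `sae_prob`, `disutility`, `utility`,
#' `subsequent`, `dosing`, `squamous_fraction`) and validates it against
#' the default structure; missing entries fall back to defaults.
#'
#' @param path YAML file (see `system.file("extdata", "base_config.yaml",
#'   package = "partsacea")` for the packaged base case).
#' @return A `cea_economics` list.
#' @export
load_economics <- function(path) {
  cfg <- yaml::read_yaml(path)
  econ <- default_economics()
  for (sec in names(cfg)) {
    if (!sec %in% names(econ))
      stop("unknown config section: ", sec, call. = FALSE)
    if (is.list(econ[[sec]])) {
      for (k in names(cfg[[sec]])) {
        val <- cfg[[sec]][[k]]
        econ[[sec]][[k]] <- if (is.list(val)) {
          v <- unlist(val)
          stats::setNames(as.numeric(v), names(v))
        } else val
      }
    } else {
      econ[[sec]] <- if (is.list(cfg[[sec]])) unlist(cfg[[sec]])
                     else cfg[[sec]]
    }
  }
  # coerce named sections stored as lists back to named vectors
  for (nm in c("utility", "disutility"))
    econ[[nm]] <- stats::setNames(as.numeric(unlist(econ[[nm]])),
                                  names(unlist(econ[[nm]])))
  for (a in names(econ$sae_prob))
    econ$sae_prob[[a]] <- stats::setNames(
      as.numeric(unlist(econ$sae_prob[[a]])),
      names(unlist(econ$sae_prob[[a]])))
  for (a in names(econ$subsequent)) {
    v <- stats::setNames(as.numeric(unlist(econ$subsequent[[a]])),
                         names(unlist(econ$subsequent[[a]])))
    if (abs(sum(v) - 1) > 0.01)
      stop("subsequent mix for arm '", a, "' must sum to 1", call. = FALSE)
    econ$subsequent[[a]] <- v
  }
  class(econ) <- "cea_economics"
  econ
}

#' Write the standard analysis output files
#'
#' Writes the deterministic base case (`base_case.csv`), tornado table
#' (`tornado.csv`), PSA samples (`psa_samples.csv`), acceptability curve
#' (`ceac.csv`) and scenario table (`scenarios.csv`) for whichever result
#' objects are supplied.
#'
#' @param dir Output directory (created if needed).
#' @param cea,owsa,psa,ceac,scenarios Optional result objects from
#'   [run_cea()], [owsa()], [psa()], [ceac()], [run_scenarios()].
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(dir, cea = NULL, owsa = NULL, psa = NULL,
                          ceac = NULL, scenarios = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(df, file) {
    p <- file.path(dir, file)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  if (!is.null(cea)) paths <- c(paths, put(summary(cea), "base_case.csv"))
  if (!is.null(owsa)) paths <- c(paths, put(as.data.frame(owsa),
                                            "tornado.csv"))
  if (!is.null(psa))
    paths <- c(paths, put(psa$samples[, c("draw", "delta_cost",
                                          "delta_qaly")],
                          "psa_samples.csv"))
  if (!is.null(ceac)) paths <- c(paths, put(as.data.frame(ceac), "ceac.csv"))
  if (!is.null(scenarios)) paths <- c(paths, put(as.data.frame(scenarios),
                                                 "scenarios.csv"))
  invisible(paths)
}
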