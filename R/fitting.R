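#' Fit a parametric survival distribution to right-censored data
#'
#' Maximum-likelihood estimation of any [surv_dist()] family on
#' right-censored event times, maximizing
#' \deqn{\ell = \sum_{events} \ln f(t_i) + \sum_{censored} \ln S(t_i).}
#' Positive parameters are optimized on the log scale and cure fractions on
#' the logit scale (quasi-Newton BFGS, numeric gradients), with
#' method-of-moments style starting values, so convergence is reproducible
#' for a given data set. The Royston-Parmar spline family is fitted via
#' [flexsurv::flexsurvspline] (proportional-hazards scale) and its
#' coefficients and knots stored in the same `surv_dist` form.
#'
#' @param time Positive observation times (months).
#' @param event Event indicator: 1 = event (death/progression), 0 = censored.
#' @param family Distribution family (see [surv_dist()]).
#' @param data Optional data frame in which `time` and `event` are looked up
#'   as column names.
#' @param cure_base Base family for the cure models (default `"weibull"`).
#' @param rp_knots Number of internal knots for the Royston-Parmar spline
#'   (default 1, placed at the median log event time; boundaries at the
#'   extreme event times).
#'
#' @return An object of class `parsurv` with components `dist` (the fitted
#'   [surv_dist()]), `loglik`, `npars`, `aic`, `bic`, `n`, `n_events`,
#'   `converged`, plus the data used. Supports `print()`, `summary()`,
#'   `coef()`, `logLik()`, `AIC()`, `BIC()`, `predict()`, `simulate()` and
#'   `plot()`.
#'
#' @details AIC is \eqn{2k - 2\ell} and BIC \eqn{k\ln n - 2\ell} with
#'   \eqn{k} the number of free parameters and \eqn{n} the number of
#'   observations. Non-convergence is flagged in the returned object and by
#'   `print()`, never silently dropped. All-censored input is an error: the
#'   likelihood has no interior maximum.
#' @examples
#' set.seed(1)
#' t <- rexp(400, 0.1)
#' f <- fit_parsurv(t, rep(1, 400), "exponential")
#' coef(f)          # close to rate = 0.1
#' AIC(f)
#' @export
fit_parsurv <- function(time, event, family, data = NULL,
                        cure_base = "weibull", rp_knots = 1L) {
  if (!is.null(data)) {
    time <- data[[deparse(substitute(time))]] %||% time
    event <- data[[deparse(substitute(event))]] %||% event
  }
  stopifnot(length(time) == length(event))
  keep <- is.finite(time) & is.finite(event)
  time <- time[keep]; event <- as.integer(event[keep] > 0)
  if (any(time <= 0)) stop("observation times must be positive", call. = FALSE)
  if (sum(event) < 2)
    stop("degenerate data: need at least 2 events to fit", call. = FALSE)

  if (family == "royston_parmar")
    return(.fit_rp(time, event, rp_knots))

  tr <- .fit_transform(family, cure_base)
  nll <- function(theta) {
    # extreme excursions of the line search can overflow the d* functions;
    # they are fenced off with a large penalty
    ll <- suppressWarnings(tryCatch({
      d <- tr$make(tr$from(theta))
      sum(event * log(pmax(surv_dens(d, time), 1e-300)) +
          (1 - event) * log(pmax(surv_prob(d, time), 1e-300)))
    }, error = function(e) NA_real_))
    if (!is.finite(ll)) 1e10 else -ll
  }
  theta0 <- tr$to(.fit_start(family, time, event, cure_base))
  opt <- stats::optim(theta0, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  dist <- tr$make(tr$from(opt$par))
  k <- n_pars(dist)
  ll <- -opt$value
  n <- length(time)
  structure(list(dist = dist, loglik = ll, npars = k,
                 aic = 2 * k - 2 * ll, bic = k * log(n) - 2 * ll,
                 n = n, n_events = sum(event),
                 converged = opt$convergence == 0 && is.finite(ll),
                 family = family, time = time, event = event),
            class = "parsurv")
}

# parameter transforms: natural -> unconstrained ('to') and back ('from'),
# plus a constructor 'make' from the natural vector
.fit_transform <- function(family, cure_base = "weibull") {
  logit <- function(p) log(p / (1 - p))
  expit <- function(x) 1 / (1 + exp(-x))
  switch(family,
    exponential = list(
      to = log, from = exp,
      make = function(p) surv_dist("exponential", rate = p[1])),
    weibull = list(
      to = log, from = exp,
      make = function(p) surv_dist("weibull", shape = p[1], scale = p[2])),
    gompertz = list(
      to = function(p) c(p[1], log(p[2])),
      from = function(x) c(x[1], exp(x[2])),
      make = function(p) surv_dist("gompertz", shape = p[1], rate = p[2])),
    loglogistic = list(
      to = log, from = exp,
      make = function(p) surv_dist("loglogistic", shape = p[1], scale = p[2])),
    lognormal = list(
      to = function(p) c(p[1], log(p[2])),
      from = function(x) c(x[1], exp(x[2])),
      make = function(p) surv_dist("lognormal", meanlog = p[1], sdlog = p[2])),
    mixture_cure = ,
    nonmixture_cure = {
      base_tr <- .fit_transform(cure_base)
      list(
        to = function(p) c(logit(min(max(p[1], 1e-6), 1 - 1e-6)),
                           base_tr$to(p[-1])),
        from = function(x) c(expit(x[1]), base_tr$from(x[-1])),
        make = function(p) surv_dist(family, cure = p[1],
                                     base = base_tr$make(p[-1])))
    },
    stop("unsupported family: ", family, call. = FALSE))
}

# fixed, data-driven starting values (method-of-moments flavour)
.fit_start <- function(family, time, event, cure_base = "weibull") {
  rate0 <- sum(event) / sum(time)
  med0 <- stats::median(time[event == 1])
  switch(family,
    exponential = rate0,
    weibull     = c(1, 1 / rate0),
    gompertz    = c(1e-3, rate0),
    loglogistic = c(1.2, med0),
    lognormal   = c(mean(log(time)), max(stats::sd(log(time)), 0.2)),
    mixture_cure = ,
    nonmixture_cure = c(0.1, .fit_start(cure_base, time, event)))
}

.fit_rp <- function(time, event, rp_knots) {
  fs <- flexsurv::flexsurvspline(survival::Surv(time, event) ~ 1,
                                 k = rp_knots, scale = "hazard")
  dist <- surv_dist_rp(gamma = unname(fs$coefficients),
                       knots = unname(fs$knots))
  k <- length(fs$coefficients)
  ll <- fs$loglik
  n <- length(time)
  structure(list(dist = dist, loglik = ll, npars = k,
                 aic = 2 * k - 2 * ll, bic = k * log(n) - 2 * ll,
                 n = n, n_events = sum(event), converged = TRUE,
                 family = "royston_parmar", time = time, event = event),
            class = "parsurv")
}

#' Fit several candidate families to the same data
#'
#' @inheritParams fit_parsurv
#' @param families Character vector of families to try (defaults to the five
#'   standard parametric families).
#' @return A named list of `parsurv` fits (non-fatal failures are dropped
#'   with a warning).
#' @export
fit_candidates <- function(time, event,
                           families = c("exponential", "weibull", "gompertz",
                                        "loglogistic", "lognormal"), ...) {
  fits <- list()
  for (fam in families) {
    f <- tryCatch(fit_parsurv(time, event, fam, ...),
                  error = function(e) {
                    warning("fit failed for ", fam, ": ", conditionMessage(e),
                            call. = FALSE)
                    NULL
                  })
    if (!is.null(f)) fits[[fam]] <- f
  }
  fits
}

#' Select the best-fitting distribution by information criteria
#'
#' Among converged fits, returns the one with the lowest AIC; ties are
#' broken by lowest BIC, then by fewest parameters.
#'
#' @param fits A list of `parsurv` objects (e.g. from [fit_candidates()]).
#' @return The selected `parsurv` fit.
#' @export
select_best <- function(fits) {
  if (inherits(fits, "parsurv")) fits <- list(fits)
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(fits)) stop("no converged fits to select from", call. = FALSE)
  ord <- order(vapply(fits, `[[`, 0, "aic"),
               vapply(fits, `[[`, 0, "bic"),
               vapply(fits, function(f) as.numeric(f$npars), 0))
  fits[[ord[1L]]]
}

#' @export
print.parsurv <- function(x, ...) {
  cat("Parametric survival fit (", x$family, "), n = ", x$n, ", events = ",
      x$n_events, "\n", sep = "")
  print(x$dist)
  cat(sprintf("  logLik %.3f | AIC %.3f | BIC %.3f\n", x$loglik, x$aic, x$bic))
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
summary.parsurv <- function(object, times = NULL, ...) {
  if (is.null(times))
    times <- pretty(c(0, max(object$time)), 10)
  data.frame(time = times, survival = surv_prob(object$dist, times))
}

#' @export
coef.parsurv <- function(object, ...) {
  if (object$family == "royston_parmar") object$dist$pars$gamma
  else if (grepl("cure", object$family))
    c(cure = unname(object$dist$pars[["cure"]]), object$dist$base$pars)
  else object$dist$pars
}

#' @export
logLik.parsurv <- function(object, ...) {
  structure(object$loglik, df = object$npars, nobs = object$n,
            class = "logLik")
}

#' @export
predict.parsurv <- function(object, times, type = c("survival", "rmst"),
                            ...) {
  type <- match.arg(type)
  switch(type,
    survival = surv_prob(object$dist, times),
    rmst = vapply(times, function(h) rmst(object$dist, h), numeric(1)))
}

#' @export
simulate.parsurv <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  surv_rand(nsim, object$dist)
}

#' @export
plot.parsurv <- function(x, xmax = NULL, km = TRUE, ...) {
  xmax <- xmax %||% max(x$time) * 1.5
  tt <- seq(0, xmax, length.out = 400)
  plot(tt, surv_prob(x$dist, tt), type = "l", lwd = 2, col = "firebrick",
       xlab = "Time (months)", ylab = "Survival", ylim = c(0, 1), ...)
  if (km && !is.null(x$time)) {
    sf <- survival::survfit(survival::Surv(x$time, x$event) ~ 1)
    lines(sf, conf.int = FALSE, col = "grey40")
  }
  invisible(x)
}
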