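#' Parametric survival distribution specifications
#'
#' `surv_dist()` builds a survival distribution object: one of the five
#' standard parametric families used for Kaplan-Meier extrapolation, a
#' mixture or non-mixture cure model wrapped around a base family, or a
#' Royston-Parmar natural cubic spline on the log cumulative hazard.
#'
#' Parameterizations:
#' \describe{
#'   \item{exponential}{`rate` > 0; \eqn{S(t) = e^{-rate \cdot t}}.}
#'   \item{weibull}{`shape`, `scale` > 0 (as [stats::pweibull]).}
#'   \item{gompertz}{`shape` (any sign), `rate` > 0; hazard
#'     \eqn{rate \cdot e^{shape \cdot t}}. A negative shape gives an improper
#'     distribution with survival plateau \eqn{e^{rate/shape}}; this is
#'     permitted (finite-horizon extrapolation) but flagged by `print()`.}
#'   \item{loglogistic}{`shape`, `scale` > 0;
#'     \eqn{S(t) = 1 / (1 + (t/scale)^{shape})}, so the median equals `scale`.}
#'   \item{lognormal}{`meanlog`, `sdlog` (> 0);
#'     \eqn{S(t) = 1 - \Phi((\ln t - meanlog)/sdlog)}.}
#'   \item{mixture_cure}{`cure` in \[0,1\] plus a `base` distribution;
#'     \eqn{S(t) = \pi + (1-\pi) S_0(t)}.}
#'   \item{nonmixture_cure}{`cure` in (0,1\] plus `base`;
#'     \eqn{S(t) = \pi^{1 - S_0(t)}}.}
#'   \item{royston_parmar}{`gamma` (spline coefficients) and `knots`
#'     (strictly increasing, on log time, boundaries included);
#'     \eqn{\ln H(t) = s(\ln t; \gamma)} with a natural cubic spline `s`.}
#' }
#'
#' Times are in months throughout the package.
#'
#' @param family Character, one of `"exponential"`, `"weibull"`, `"gompertz"`,
#'   `"loglogistic"`, `"lognormal"`, `"mixture_cure"`, `"nonmixture_cure"`,
#'   `"royston_parmar"`.
#' @param ... Named numeric parameters for the family (see Details).
#' @param base A `surv_dist` object, required by the cure families.
#'
#' @return An object of class `surv_dist`.
#' @examples
#' d <- surv_dist("loglogistic", shape = 1.6637, scale = 9.3549)
#' surv_prob(d, c(0, 9.3549))   # 1 and 0.5: the median equals the scale
#' rmst(d, 120)                 # restricted mean survival over 10 years
#' @seealso [surv_prob()], [surv_quantile()], [rmst()], [fit_parsurv()]
#' @export
surv_dist <- function(family, ..., base = NULL) {
  family <- match.arg(family, c("exponential", "weibull", "gompertz",
                                "loglogistic", "lognormal", "mixture_cure",
                                "nonmixture_cure", "royston_parmar"))
  if (family == "royston_parmar") {
    dots <- list(...)
    return(surv_dist_rp(dots$gamma, dots$knots))
  }
  pars <- c(...)
  if (length(pars) && is.null(names(pars)))
    names(pars) <- .dist_par_names(family)[seq_along(pars)]

  obj <- structure(list(family = family, pars = pars, base = base),
                   class = "surv_dist")
  validate_surv_dist(obj)
  obj
}

.dist_par_names <- function(family) {
  switch(family,
    exponential     = "rate",
    weibull         = c("shape", "scale"),
    gompertz        = c("shape", "rate"),
    loglogistic     = c("shape", "scale"),
    lognormal       = c("meanlog", "sdlog"),
    mixture_cure    = "cure",
    nonmixture_cure = "cure",
    royston_parmar  = NULL)
}

validate_surv_dist <- function(x) {
  stopifnot(inherits(x, "surv_dist"))
  p <- x$pars
  need <- function(nm) {
    if (!all(nm %in% names(p)))
      stop("family '", x$family, "' requires parameters: ",
           paste(nm, collapse = ", "), call. = FALSE)
  }
  pos <- function(nm) {
    if (any(!is.finite(p[nm])) || any(p[nm] <= 0))
      stop("parameter(s) ", paste(nm, collapse = ", "),
           " must be strictly positive for family '", x$family, "'",
           call. = FALSE)
  }
  switch(x$family,
    exponential = { need("rate"); pos("rate") },
    weibull     = { need(c("shape", "scale")); pos(c("shape", "scale")) },
    gompertz    = { need(c("shape", "rate")); pos("rate") },
    loglogistic = { need(c("shape", "scale")); pos(c("shape", "scale")) },
    lognormal   = { need(c("meanlog", "sdlog")); pos("sdlog") },
    mixture_cure = ,
    nonmixture_cure = {
      need("cure")
      if (p[["cure"]] < 0 || p[["cure"]] > 1)
        stop("cure fraction must lie in [0, 1]", call. = FALSE)
      if (!inherits(x$base, "surv_dist"))
        stop("cure families require a 'base' surv_dist", call. = FALSE)
      validate_surv_dist(x$base)
    },
    royston_parmar = {
      if (!is.list(x$pars) || is.null(x$pars$gamma) || is.null(x$pars$knots))
        stop("royston_parmar needs list pars with 'gamma' and 'knots'",
             call. = FALSE)
      if (any(diff(x$pars$knots) <= 0))
        stop("knot locations must be strictly increasing", call. = FALSE)
    })
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a Royston-Parmar spline distribution
#'
#' Convenience wrapper: stores spline coefficients and knots (on log time)
#' as a `surv_dist` of family `"royston_parmar"` on the proportional-hazards
#' scale, \eqn{\ln H(t) = s(\ln t)}.
#'
#' @param gamma Numeric vector of spline coefficients (length =
#'   number of knots).
#' @param knots Strictly increasing numeric vector of knot locations on log
#'   time, boundary knots included.
#' @return A `surv_dist` object.
#' @export
surv_dist_rp <- function(gamma, knots) {
  stopifnot(is.numeric(gamma), is.numeric(knots), length(knots) >= 2,
            length(gamma) == length(knots))
  if (any(diff(knots) <= 0))
    stop("knot locations must be strictly increasing", call. = FALSE)
  structure(list(family = "royston_parmar",
                 pars = list(gamma = gamma, knots = knots), base = NULL),
            class = "surv_dist")
}

# Natural cubic spline basis of Royston & Parmar on x = log(t).
# Columns: 1, x, v_1(x), ..., v_m(x) for the m internal knots.
rp_basis <- function(x, knots) {
  kmin <- knots[1L]; kmax <- knots[length(knots)]
  out <- cbind(1, x)
  if (length(knots) > 2) {
    for (kj in knots[-c(1L, length(knots))]) {
      lam <- (kmax - kj) / (kmax - kmin)
      out <- cbind(out,
                   pmax(x - kj, 0)^3 - lam * pmax(x - kmin, 0)^3 -
                     (1 - lam) * pmax(x - kmax, 0)^3)
    }
  }
  out
}

#' Survival, density, quantile and random generation for `surv_dist`
#'
#' `surv_prob()` evaluates \eqn{S(t)}; `surv_dens()` the density
#' \eqn{f(t) = -S'(t)}; `surv_quantile()` inverts the survival function
#' (returns the time `t` with \eqn{S(t) = p}, `Inf` below an improper
#' plateau); `surv_rand()` draws event times by inversion.
#'
#' @param dist A [surv_dist()] object.
#' @param t Non-negative times (months).
#' @param p Survival probabilities in (0, 1\].
#' @param n Number of draws.
#' @return Numeric vector.
#' @export
surv_prob <- function(dist, t) {
  validate_surv_dist(dist)
  if (any(t < 0)) stop("times must be non-negative", call. = FALSE)
  p <- dist$pars
  s <- switch(dist$family,
    exponential = exp(-p[["rate"]] * t),
    weibull     = stats::pweibull(t, p[["shape"]], p[["scale"]],
                                  lower.tail = FALSE),
    gompertz    = {
      a <- p[["shape"]]; b <- p[["rate"]]
      if (abs(a) < 1e-12) exp(-b * t) else exp(-b / a * (exp(a * t) - 1))
    },
    loglogistic = 1 / (1 + (t / p[["scale"]])^p[["shape"]]),
    lognormal   = ifelse(t <= 0, 1,
                         stats::pnorm((log(pmax(t, .Machine$double.xmin)) -
                                       p[["meanlog"]]) / p[["sdlog"]],
                                      lower.tail = FALSE)),
    mixture_cure = p[["cure"]] + (1 - p[["cure"]]) * surv_prob(dist$base, t),
    nonmixture_cure = {
      pi0 <- max(p[["cure"]], .Machine$double.xmin)
      pi0^(1 - surv_prob(dist$base, t))
    },
    royston_parmar = {
      g <- dist$pars$gamma; k <- dist$pars$knots
      out <- numeric(length(t))
      pos <- t > 0
      out[!pos] <- 1
      if (any(pos)) {
        eta <- drop(rp_basis(log(t[pos]), k) %*% g)
        out[pos] <- exp(-exp(eta))
      }
      out
    })
  pmin(pmax(s, 0), 1)
}

#' @rdname surv_prob
#' @export
surv_dens <- function(dist, t) {
  validate_surv_dist(dist)
  if (any(t < 0)) stop("times must be non-negative", call. = FALSE)
  p <- dist$pars
  switch(dist$family,
    exponential = stats::dexp(t, p[["rate"]]),
    weibull     = stats::dweibull(t, p[["shape"]], p[["scale"]]),
    gompertz    = {
      a <- p[["shape"]]; b <- p[["rate"]]
      b * exp(a * t) * surv_prob(dist, t)
    },
    loglogistic = {
      g <- p[["shape"]]; l <- p[["scale"]]
      tt <- pmax(t, .Machine$double.xmin)
      (g / l) * (tt / l)^(g - 1) / (1 + (tt / l)^g)^2
    },
    lognormal   = stats::dlnorm(t, p[["meanlog"]], p[["sdlog"]]),
    mixture_cure = (1 - p[["cure"]]) * surv_dens(dist$base, t),
    nonmixture_cure = {
      pi0 <- min(max(p[["cure"]], .Machine$double.xmin), 1 - 1e-15)
      -log(pi0) * surv_dens(dist$base, t) * surv_prob(dist, t)
    },
    royston_parmar = {
      g <- dist$pars$gamma; k <- dist$pars$knots
      tt <- pmax(t, .Machine$double.xmin)
      x <- log(tt)
      eta <- drop(rp_basis(x, k) %*% g)
      deta <- drop(rp_basis_deriv(x, k) %*% g)
      h <- pmax(deta, 0) * exp(eta) / tt   # hazard; deta >= 0 where monotone
      h * exp(-exp(eta))
    })
}

# d/dx of the Royston-Parmar basis
rp_basis_deriv <- function(x, knots) {
  kmin <- knots[1L]; kmax <- knots[length(knots)]
  out <- cbind(0, rep(1, length(x)))
  if (length(knots) > 2) {
    for (kj in knots[-c(1L, length(knots))]) {
      lam <- (kmax - kj) / (kmax - kmin)
      out <- cbind(out,
                   3 * pmax(x - kj, 0)^2 - 3 * lam * pmax(x - kmin, 0)^2 -
                     3 * (1 - lam) * pmax(x - kmax, 0)^2)
    }
  }
  out
}

#' @rdname surv_prob
#' @export
surv_quantile <- function(dist, p) {
  validate_surv_dist(dist)
  if (any(p <= 0 | p > 1)) stop("p must lie in (0, 1]", call. = FALSE)
  pr <- dist$pars
  vapply(p, function(pp) {
    switch(dist$family,
      exponential = -log(pp) / pr[["rate"]],
      weibull     = stats::qweibull(pp, pr[["shape"]], pr[["scale"]],
                                    lower.tail = FALSE),
      gompertz    = {
        a <- pr[["shape"]]; b <- pr[["rate"]]
        if (abs(a) < 1e-12) return(-log(pp) / b)
        arg <- 1 - a * log(pp) / b
        if (arg <= 0) Inf else log(arg) / a
      },
      loglogistic = pr[["scale"]] * ((1 - pp) / pp)^(1 / pr[["shape"]]),
      lognormal   = exp(stats::qnorm(pp, lower.tail = FALSE) * pr[["sdlog"]] +
                        pr[["meanlog"]]),
      mixture_cure = {
        if (pp <= pr[["cure"]]) Inf
        else surv_quantile(dist$base,
                           (pp - pr[["cure"]]) / (1 - pr[["cure"]]))
      },
      nonmixture_cure = {
        pi0 <- pr[["cure"]]
        if (pi0 >= 1 || pp <= pi0) return(Inf)
        s0 <- 1 - log(pp) / log(max(pi0, .Machine$double.xmin))
        if (s0 <= 0) Inf else surv_quantile(dist$base, min(s0, 1))
      },
      royston_parmar = {
        f <- function(lt) surv_prob(dist, exp(lt)) - pp
        lo <- -20; hi <- 20
        if (f(hi) > 0) return(Inf)
        exp(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root)
      })
  }, numeric(1))
}

#' @rdname surv_prob
#' @export
surv_rand <- function(n, dist) {
  surv_quantile(dist, stats::runif(n))
}

#' Restricted mean survival time
#'
#' Integrates \eqn{S(t)} from 0 to `horizon` by adaptive quadrature
#' ([stats::integrate]); the restricted mean is bounded by the horizon and
#' increasing in it.
#'
#' @param dist A [surv_dist()] object.
#' @param horizon Upper limit of integration, months (`Inf` allowed for
#'   proper distributions).
#' @return Restricted mean survival in months.
#' @export
rmst <- function(dist, horizon) {
  stopifnot(is.numeric(horizon), length(horizon) == 1, horizon >= 0)
  if (horizon == 0) return(0)
  stats::integrate(function(t) surv_prob(dist, t), 0, horizon,
                   rel.tol = 1e-9, subdivisions = 2000L)$value
}

#' Survival plateau of an improper distribution
#'
#' Cure models (and Gompertz with negative shape) level off at a positive
#' survival fraction; returns that limit, 0 for proper distributions.
#' @param dist A [surv_dist()] object.
#' @return The limiting survival probability as \eqn{t \to \infty}.
#' @export
surv_plateau <- function(dist) {
  p <- dist$pars
  switch(dist$family,
    mixture_cure    = unname(p[["cure"]]) +
      (1 - unname(p[["cure"]])) * surv_plateau(dist$base),
    nonmixture_cure = unname(p[["cure"]])^(1 - surv_plateau(dist$base)),
    gompertz        = if (p[["shape"]] < 0)
      exp(unname(p[["rate"]] / p[["shape"]])) else 0,
    0)
}

#' @export
print.surv_dist <- function(x, ...) {
  cat("<surv_dist> family:", x$family, "\n")
  if (x$family == "royston_parmar") {
    cat("  gamma:", paste(signif(x$pars$gamma, 5), collapse = ", "), "\n")
    cat("  knots (log t):", paste(signif(x$pars$knots, 5), collapse = ", "),
        "\n")
  } else {
    cat(" ", paste(names(x$pars), signif(x$pars, 6), sep = " = ",
                   collapse = ", "), "\n")
    if (!is.null(x$base)) {
      cat("  base: "); print(x$base)
    }
  }
  pl <- surv_plateau(x)
  if (pl > 0)
    cat("  note: improper survival, plateau at S =", signif(pl, 4), "\n")
  invisible(x)
}

# number of free parameters of a specification
n_pars <- function(dist) {
  switch(dist$family,
    mixture_cure    = ,
    nonmixture_cure = 1L + n_pars(dist$base),
    royston_parmar  = length(dist$pars$gamma),
    length(dist$pars))
}
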