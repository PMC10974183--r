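#' Two-parameter concentration-response curve parameters
#'
#' Container for the parameters of a two-parameter concentration-response
#' model. Two families are supported:
#'
#' * `"weibull"`: \eqn{E = 1 - \exp(-\exp(\alpha + \beta \log_{10} x))},
#'   where `alpha` is the (dimensionless) location parameter and `beta` the
#'   slope on the log10 concentration axis.
#' * `"hill"`: \eqn{E = \alpha x / (\beta + x)}, where `alpha` is the
#'   maximum effect (a fraction in (0, 1]) and `beta` the EC50 in mol/L.
#'
#' @param family `"weibull"` or `"hill"`.
#' @param alpha Location (Weibull) or maximum effect (Hill).
#' @param beta Slope (Weibull, nonzero) or EC50 in mol/L (Hill, positive).
#' @return An object of class `curve_params`.
#' @examples
#' curve_params("weibull", alpha = 2, beta = 1.5)
#' curve_params("hill", alpha = 1, beta = 1e-4)
#' @export
curve_params <- function(family = c("weibull", "hill"), alpha, beta) {
  family <- match.arg(family)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha))
    stop("'alpha' must be a single finite number", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta))
    stop("'beta' must be a single finite number", call. = FALSE)
  if (family == "hill") {
    if (beta <= 0) stop("Hill 'beta' (EC50) must be > 0", call. = FALSE)
    if (alpha <= 0 || alpha > 1)
      stop("Hill 'alpha' (maximum effect) must lie in (0, 1]", call. = FALSE)
  } else {
    if (beta == 0) stop("Weibull 'beta' (slope) must be nonzero", call. = FALSE)
  }
  structure(list(family = family, alpha = as.numeric(alpha),
                 beta = as.numeric(beta)),
            class = "curve_params")
}

#' @export
print.curve_params <- function(x, ...) {
  cat(sprintf("<curve_params> %s: alpha = %.6g, beta = %.6g\n",
              x$family, x$alpha, x$beta))
  invisible(x)
}

check_conc <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop("concentrations must be finite and strictly positive (mol/L)",
         call. = FALSE)
  x
}

#' Evaluate a Weibull concentration-response curve
#'
#' Effect \eqn{E = 1 - \exp(-\exp(\alpha + \beta \log_{10} x))}; strictly
#' increasing in `x` when `beta > 0`, with values in (0, 1).
#'
#' @param params A `curve_params` with `family = "weibull"`.
#' @param x Concentration(s), mol/L, strictly positive.
#' @return Effect fraction(s) in (0, 1).
#' @examples
#' weibull_effect(curve_params("weibull", 0, 1), 1) # 1 - exp(-1)
#' @export
weibull_effect <- function(params, x) {
  stopifnot(inherits(params, "curve_params"))
  if (params$family != "weibull") stop("'params' is not a Weibull curve", call. = FALSE)
  check_conc(x)
  1 - exp(-exp(params$alpha + params$beta * log10(x)))
}

#' Evaluate a Hill concentration-response curve
#'
#' Effect \eqn{E = \alpha x / (\beta + x)}: half-maximal at `x = beta`,
#' approaching the ceiling `alpha` as `x` grows.
#'
#' @param params A `curve_params` with `family = "hill"`.
#' @param x Concentration(s), mol/L, strictly positive.
#' @return Effect fraction(s) in (0, alpha).
#' @examples
#' hill_effect(curve_params("hill", 1, 1e-4), 1e-4) # 0.5
#' @export
hill_effect <- function(params, x) {
  stopifnot(inherits(params, "curve_params"))
  if (params$family != "hill") stop("'params' is not a Hill curve", call. = FALSE)
  check_conc(x)
  params$alpha * x / (params$beta + x)
}

#' Evaluate a fitted curve of either family
#'
#' @param params A `curve_params` object.
#' @param x Concentration(s), mol/L.
#' @return Effect fraction(s).
#' @export
curve_effect <- function(params, x) {
  switch(params$family,
         weibull = weibull_effect(params, x),
         hill = hill_effect(params, x))
}

#' Maximum attainable effect of a curve
#'
#' 1 for Weibull (asymptotically), `alpha` for Hill.
#'
#' @param params A `curve_params` object.
#' @return Supremum of the effect over concentrations.
#' @export
curve_max_effect <- function(params) {
  if (params$family == "hill") params$alpha else 1
}

#' Invert a concentration-response curve
#'
#' Closed-form inversion: for Weibull,
#' \eqn{x = 10^{(\ln(-\ln(1 - E)) - \alpha)/\beta}}; for Hill,
#' \eqn{x = \beta E / (\alpha - E)}. The effect level must lie strictly
#' inside the curve's attainable range.
#'
#' @param params A `curve_params` object.
#' @param effect Effect fraction(s): in (0, 1) for Weibull, (0, alpha) for Hill.
#' @return Concentration(s) in mol/L producing `effect`.
#' @examples
#' invert_curve(curve_params("hill", 1, 5e-5), 0.5) # the EC50, 5e-5
#' @export
invert_curve <- function(params, effect) {
  stopifnot(inherits(params, "curve_params"))
  if (!is.numeric(effect) || any(!is.finite(effect)))
    stop("'effect' must be finite", call. = FALSE)
  if (params$family == "weibull") {
    if (any(effect <= 0 | effect >= 1))
      stop("Weibull inversion requires 0 < effect < 1", call. = FALSE)
    10^((log(-log(1 - effect)) - params$alpha) / params$beta)
  } else {
    if (any(effect <= 0 | effect >= params$alpha))
      stop(sprintf("Hill inversion requires 0 < effect < alpha (= %g)",
                   params$alpha), call. = FALSE)
    params$beta * effect / (params$alpha - effect)
  }
}

#' Negative log10 effect concentration
#'
#' `pec(ec)` returns \eqn{-\log_{10}(\mathrm{EC})} for an effect
#' concentration in mol/L; larger values mean higher potency. Values are
#' conventionally reported to 2 decimals (`round(pec(ec), 2)`), but full
#' precision is returned.
#'
#' @param ec Effect concentration(s), mol/L, strictly positive.
#' @return Dimensionless pEC value(s).
#' @examples
#' round(pec(1.18e-4), 2) # 3.93
#' @export
pec <- function(ec) {
  if (!is.numeric(ec) || any(!is.finite(ec)) || any(ec <= 0))
    stop("'ec' must be finite and > 0 (mol/L)", call. = FALSE)
  -log10(ec)
}

#' Convert mass concentration to molar concentration
#'
#' @param mass_conc Mass concentration(s) in g/L, > 0.
#' @param molar_mass Molar mass in g/mol, > 0.
#' @return Molar concentration(s) in mol/L.
#' @examples
#' mass_to_molar(27.1e-6, 349) # 7.77e-8 to 3 significant figures
#' @export
mass_to_molar <- function(mass_conc, molar_mass) {
  if (!is.numeric(mass_conc) || any(!is.finite(mass_conc)) || any(mass_conc <= 0))
    stop("'mass_conc' must be finite and > 0 (g/L)", call. = FALSE)
  if (!is.numeric(molar_mass) || any(!is.finite(molar_mass)) || any(molar_mass <= 0))
    stop("'molar_mass' must be finite and > 0 (g/mol)", call. = FALSE)
  mass_conc / molar_mass
}
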