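#' Fixed-ratio mixture ray
#'
#' A mixture ray holds the components of a fixed concentration ratio
#' mixture: each component's concentration-response curve (a [curve_params]
#' or a fitted [fit_curve()] result) and its fraction of the total mixture
#' molar concentration, so that \eqn{c_i = p_i c_{mix}} along the ray.
#'
#' Fractions may be given directly as molar fractions (`fraction_type =
#' "molar"`, the default) or as toxic-unit fractions (`"toxic_unit"`): equal
#' toxic-unit shares at the 50% effect level correspond to molar fractions
#' proportional to \eqn{p_i^{TU} \cdot EC_{50,i}}, and the constructor
#' performs that conversion.
#'
#' @param components List of `curve_params` or `crc_fit` objects (length
#'   >= 1; a single component is a valid degenerate ray).
#' @param fractions Numeric vector of the same length, each in (0, 1],
#'   summing to 1 (within 1e-12).
#' @param ids Component identifiers; defaults to names of `components` or
#'   `comp1`, `comp2`, ...
#' @param molar_mass Optional numeric vector of molar masses (g/mol).
#' @param fraction_type `"molar"` or `"toxic_unit"`.
#' @return An object of class `mixture_ray`.
#' @examples
#' amp <- curve_params("weibull", 2, 1.5)
#' czo <- curve_params("weibull", 1.8, 1.5)
#' mixture_ray(list(AMP = amp, CZO = czo), c(0.2, 0.8))
#' @export
mixture_ray <- function(components, fractions, ids = NULL, molar_mass = NULL,
                        fraction_type = c("molar", "toxic_unit")) {
  fraction_type <- match.arg(fraction_type)
  if (inherits(components, "curve_params") || inherits(components, "crc_fit"))
    components <- list(components)
  params <- lapply(components, function(cmp) {
    if (inherits(cmp, "crc_fit")) cmp$params
    else if (inherits(cmp, "curve_params")) cmp
    else stop("components must be curve_params or crc_fit objects",
              call. = FALSE)
  })
  m <- length(params)
  if (m < 1L) stop("at least one component is required", call. = FALSE)
  if (is.null(ids)) ids <- names(components)
  if (is.null(ids) || any(!nzchar(ids))) ids <- paste0("comp", seq_len(m))
  if (anyDuplicated(ids)) stop("component ids must be unique", call. = FALSE)
  if (!is.numeric(fractions) || length(fractions) != m)
    stop("'fractions' must be numeric, one per component", call. = FALSE)
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-12)
    stop("fractions must sum to 1 (within 1e-12)", call. = FALSE)
  if (fraction_type == "toxic_unit") {
    ec50 <- vapply(params, function(p) invert_curve(p, 0.5), numeric(1))
    fractions <- fractions * ec50 / sum(fractions * ec50)
  }
  if (!is.null(molar_mass) && length(molar_mass) != m)
    stop("'molar_mass' must have one entry per component", call. = FALSE)
  structure(list(ids = ids, params = params,
                 fractions = as.numeric(fractions),
                 molar_mass = molar_mass),
            class = "mixture_ray")
}

#' @export
print.mixture_ray <- function(x, ...) {
  cat(sprintf("<mixture_ray> %d component(s)\n", length(x$ids)))
  for (i in seq_along(x$ids))
    cat(sprintf("  %s: p = %.4g, %s(alpha = %.4g, beta = %.4g)\n",
                x$ids[i], x$fractions[i], x$params[[i]]$family,
                x$params[[i]]$alpha, x$params[[i]]$beta))
  invisible(x)
}

#' Mixture effect concentration under concentration addition
#'
#' Concentration addition (CA) states \eqn{\sum_i c_i / EC_{x,i} = 1} at the
#' mixture concentration producing effect `x`. Along a fixed-ratio ray with
#' \eqn{c_i = p_i c_{mix}} this gives the weighted harmonic mean
#' \eqn{EC_{x,CA} = 1 / \sum_i (p_i / EC_{x,i})}.
#'
#' @param ray A [mixture_ray].
#' @param x Effect level in (0, 1); every component curve must attain it.
#' @return The CA-predicted mixture effect concentration, mol/L.
#' @examples
#' amp <- curve_params("hill", 1, 1.18e-4)
#' czo <- curve_params("hill", 1, 1.99e-4)
#' ec_ca(mixture_ray(list(AMP = amp, CZO = czo), c(0.2, 0.8)), 0.5)
#' @export
ec_ca <- function(ray, x) {
  stopifnot(inherits(ray, "mixture_ray"))
  if (length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1)
    stop("effect level must lie in (0, 1)", call. = FALSE)
  ec_i <- mapply(function(p, id) {
    if (x >= curve_max_effect(p))
      stop(sprintf("component '%s' cannot attain effect %g (ceiling %g)",
                   id, x, curve_max_effect(p)), call. = FALSE)
    invert_curve(p, x)
  }, ray$params, ray$ids)
  1 / sum(ray$fractions / ec_i)
}

#' Mixture effect under independent action
#'
#' Independent action (IA) combines component effects as survival
#' probabilities: \eqn{E(c_{mix}) = 1 - \prod_i (1 - E_i(p_i c_{mix}))},
#' each component evaluated at its share of the total concentration.
#'
#' @param ray A [mixture_ray].
#' @param c_mix Total mixture concentration(s), mol/L, > 0.
#' @return Effect fraction(s).
#' @export
ia_effect <- function(ray, c_mix) {
  stopifnot(inherits(ray, "mixture_ray"))
  check_conc(c_mix)
  surv <- rep(1, length(c_mix))
  for (i in seq_along(ray$params))
    surv <- surv * (1 - curve_effect(ray$params[[i]], ray$fractions[i] * c_mix))
  1 - surv
}

ia_max_effect <- function(ray) {
  1 - prod(1 - vapply(ray$params, curve_max_effect, numeric(1)))
}

#' Mixture effect concentration under independent action
#'
#' Numerically inverts [ia_effect()]: brackets the root by geometric
#' expansion (factor 10) around an initial guess, then bisects on the log
#' concentration scale until the bracket's relative width falls below
#' `rel_tol`.
#'
#' @param ray A [mixture_ray].
#' @param x Effect level in (0, supremum of the IA curve).
#' @param rel_tol Relative concentration tolerance (default 1e-10).
#' @return The IA-predicted mixture effect concentration, mol/L.
#' @export
ec_ia <- function(ray, x, rel_tol = 1e-10) {
  stopifnot(inherits(ray, "mixture_ray"))
  if (length(x) != 1L || !is.finite(x) || x <= 0)
    stop("effect level must be a single value in (0, 1)", call. = FALSE)
  if (x >= ia_max_effect(ray))
    stop(sprintf("effect %g is unattainable under IA (supremum %g)",
                 x, ia_max_effect(ray)), call. = FALSE)
  # initial scale: smallest component EC at min(x, half its ceiling)
  guess <- min(vapply(seq_along(ray$params), function(i) {
    p <- ray$params[[i]]
    xe <- min(x, curve_max_effect(p) / 2)
    invert_curve(p, xe) / ray$fractions[i]
  }, numeric(1)))
  lo <- hi <- guess
  while (ia_effect(ray, lo) >= x) lo <- lo / 10
  while (ia_effect(ray, hi) <= x) hi <- hi * 10
  while (hi / lo - 1 > rel_tol) {
    mid <- sqrt(lo * hi)
    if (ia_effect(ray, mid) < x) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Mixture effect at a concentration under concentration addition
#'
#' Solves the CA relation for the effect level whose predicted mixture
#' effect concentration equals `c_mix` (monotone root-find over the effect
#' level). Concentrations below/above the attainable range return 0 / the
#' CA ceiling.
#'
#' @param ray A [mixture_ray].
#' @param c_mix Total mixture concentration(s), mol/L, > 0.
#' @return Effect fraction(s) predicted by CA.
#' @export
ca_effect <- function(ray, c_mix) {
  stopifnot(inherits(ray, "mixture_ray"))
  check_conc(c_mix)
  x_max <- min(vapply(ray$params, curve_max_effect, numeric(1)))
  x_lo <- 1e-12
  x_hi <- x_max * (1 - 1e-12)
  vapply(c_mix, function(cc) {
    if (ec_ca(ray, x_lo) >= cc) return(0)
    if (ec_ca(ray, x_hi) <= cc) return(x_max)
    stats::uniroot(function(x) ec_ca(ray, x) - cc,
                   lower = x_lo, upper = x_hi, tol = 1e-14)$root
  }, numeric(1))
}

#' Predicted mixture concentration-response curves
#'
#' Evaluates the CA- and IA-predicted mixture effects over a concentration
#' grid, suitable for overlaying on observed mixture data.
#'
#' @param ray A [mixture_ray].
#' @param conc_grid Strictly positive, sorted concentrations (mol/L).
#' @return data.frame with columns `concentration`, `effect_ca`,
#'   `effect_ia`; both effect columns are nondecreasing.
#' @export
predicted_crcs <- function(ray, conc_grid) {
  check_conc(conc_grid)
  if (is.unsorted(conc_grid))
    stop("'conc_grid' must be sorted increasingly", call. = FALSE)
  data.frame(concentration = conc_grid,
             effect_ca = ca_effect(ray, conc_grid),
             effect_ia = ia_effect(ray, conc_grid))
}

#' Design a fixed-ratio geometric dilution series
#'
#' Builds the exposure design used on the plates: total mixture
#' concentrations form a geometric series `top_conc * dilution^k`,
#' `k = 0 .. n_levels - 1`, and each component's concentration is its fixed
#' fraction of the total.
#'
#' @param top_conc Highest total concentration, mol/L.
#' @param n_levels Number of concentration levels (>= 1).
#' @param dilution Dilution factor in (0, 1) between successive levels.
#' @param fractions Component fractions summing to 1 (single `1` for an
#'   individual compound).
#' @param ids Optional component names for the per-component columns.
#' @return data.frame with `level`, `c_total`, and one concentration column
#'   per component.
#' @examples
#' design_ray(1e-4, 3, 0.4, c(AMP = 0.2, CZO = 0.8))
#' @export
design_ray <- function(top_conc, n_levels, dilution, fractions, ids = NULL) {
  check_conc(top_conc)
  if (length(n_levels) != 1L || n_levels < 1L || n_levels != round(n_levels))
    stop("'n_levels' must be a positive integer", call. = FALSE)
  if (length(dilution) != 1L || !is.finite(dilution) ||
      dilution <= 0 || dilution >= 1)
    stop("'dilution' must lie strictly between 0 and 1", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-12)
    stop("fractions must sum to 1", call. = FALSE)
  if (is.null(ids)) ids <- names(fractions)
  if (is.null(ids)) ids <- paste0("comp", seq_along(fractions))
  c_total <- top_conc * dilution^(seq_len(n_levels) - 1)
  out <- data.frame(level = seq_len(n_levels), c_total = c_total)
  for (i in seq_along(fractions)) out[[ids[i]]] <- fractions[i] * c_total
  out
}
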