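#' Mixture deviation ratio
#'
#' MDR is the ratio of the reference-model-predicted mixture effect
#' concentration (CA or IA) to the observed one:
#' \eqn{MDR = EC_{x,pred} / EC_{x,obs}}.
#'
#' @param ec_pred Predicted effect concentration, mol/L, > 0.
#' @param ec_obs Observed effect concentration, mol/L, > 0.
#' @return The MDR (dimensionless).
#' @examples
#' mdr(2e-4, 1e-4) # 2
#' @export
mdr <- function(ec_pred, ec_obs) {
  if (any(!is.finite(ec_pred)) || any(ec_pred <= 0) ||
      any(!is.finite(ec_obs)) || any(ec_obs <= 0))
    stop("effect concentrations must be finite and > 0", call. = FALSE)
  ec_pred / ec_obs
}

#' Confidence bounds of the mixture deviation ratio
#'
#' The 95% observed confidence interval of the observed effect
#' concentration maps onto the MDR scale as
#' \eqn{MDR_{lower} = EC_{x,low} / EC_{x,obs}} and
#' \eqn{MDR_{upper} = EC_{x,up} / EC_{x,obs}}.
#'
#' @param ec_obs_low Lower 95% OCI bound of the observed EC, mol/L.
#' @param ec_obs_up Upper 95% OCI bound, mol/L.
#' @param ec_obs Observed effect concentration, mol/L; the ordering
#'   `ec_obs_low <= ec_obs <= ec_obs_up` is required.
#' @return Named numeric vector `c(mdr_lower, mdr_upper)`.
#' @export
mdr_bounds <- function(ec_obs_low, ec_obs_up, ec_obs) {
  if (any(!is.finite(c(ec_obs_low, ec_obs_up, ec_obs))) ||
      any(c(ec_obs_low, ec_obs_up, ec_obs) <= 0))
    stop("effect concentrations must be finite and > 0", call. = FALSE)
  if (ec_obs_low > ec_obs || ec_obs > ec_obs_up)
    stop("ordering ec_obs_low <= ec_obs <= ec_obs_up violated", call. = FALSE)
  c(mdr_lower = ec_obs_low / ec_obs, mdr_upper = ec_obs_up / ec_obs)
}

#' Classify a mixture interaction from the MDR and its bounds
#'
#' `mdr > mdr_upper` is synergism, `mdr < mdr_lower` antagonism, and a
#' value within the bounds (boundary equality included) is additive.
#'
#' @param mdr The mixture deviation ratio.
#' @param mdr_lower,mdr_upper Its 95% confidence bounds
#'   (`mdr_lower <= mdr_upper`).
#' @return `"additive"`, `"synergism"` or `"antagonism"`.
#' @examples
#' classify_mdr(2.0, 0.8, 1.3) # synergism
#' @export
classify_mdr <- function(mdr, mdr_lower, mdr_upper) {
  if (any(!is.finite(c(mdr, mdr_lower, mdr_upper))))
    stop("'mdr' and its bounds must be finite", call. = FALSE)
  if (mdr_lower > mdr_upper)
    stop("'mdr_lower' must not exceed 'mdr_upper'", call. = FALSE)
  if (mdr > mdr_upper) "synergism"
  else if (mdr < mdr_lower) "antagonism"
  else "additive"
}

#' Dose reduction index
#'
#' The fold-reduction in a component's dose achievable inside the mixture
#' at equal effect: \eqn{DRI_i = EC_{x,i} / (p_i \cdot EC_{x,mix})}, where
#' \eqn{EC_{x,i}} is the component's single-compound effect concentration
#' and \eqn{p_i EC_{x,mix}} its dose within the mixture at the mixture's
#' effect concentration.
#'
#' @param ec_x_single Component's single-compound EC at effect level x, mol/L.
#' @param p_i Component's fraction of the total mixture concentration, (0, 1].
#' @param ec_x_mix Mixture EC at the same effect level, mol/L.
#' @return The DRI (> 0; 1 means no reduction).
#' @examples
#' dri(1.18e-4, 0.20, 3.89e-5) # about 15.2
#' @export
dri <- function(ec_x_single, p_i, ec_x_mix) {
  if (any(!is.finite(c(ec_x_single, p_i, ec_x_mix))) ||
      any(c(ec_x_single, ec_x_mix) <= 0))
    stop("effect concentrations must be finite and > 0", call. = FALSE)
  if (any(p_i <= 0 | p_i > 1))
    stop("'p_i' must lie in (0, 1]", call. = FALSE)
  ec_x_single / (p_i * ec_x_mix)
}

#' Assess mixture interactions along a ray
#'
#' The full interaction workflow: fits the observed mixture
#' concentration-response curve (all requested families, best model
#' selected), computes the observed effect concentration and its 95%
#' bootstrap OCI at each requested effect level, the CA- and IA-predicted
#' effect concentrations from the component curves, the MDR with its
#' bounds and classification against both reference models, and the dose
#' reduction index of every component. Deterministic given `seed`.
#'
#' @param ray A [mixture_ray] whose components carry fitted (or known)
#'   single-compound curves.
#' @param mix_data Effect table observed along the ray (total mixture
#'   concentration vs effect).
#' @param x_levels Effect levels to assess (default 0.10, 0.25, 0.50).
#' @param n_boot Bootstrap resamples for the OCI (default 1000).
#' @param seed Integer seed.
#' @param families Curve families to try on the mixture data.
#' @return An object of class `mixture_assessment`: list with `fit` (the
#'   selected mixture `crc_fit`), `assessment` (data.frame: `effect_level`,
#'   `reference`, `ec_obs`, `ec_obs_low`, `ec_obs_up`, `ec_pred`, `mdr`,
#'   `mdr_lower`, `mdr_upper`, `label`), `dri` (data.frame: `effect_level`,
#'   `component`, `dri`) and `seed`.
#' @export
assess_mixture <- function(ray, mix_data, x_levels = c(0.10, 0.25, 0.50),
                           n_boot = 1000L, seed = 1L,
                           families = c("weibull", "hill")) {
  stopifnot(inherits(ray, "mixture_ray"))
  fits <- lapply(families, function(fam) fit_curve(mix_data, fam))
  fit <- select_model(fits)
  if (n_boot > 0L) fit <- boot_refit(fit, n_boot = n_boot, seed = seed)
  rows <- list()
  dri_rows <- list()
  for (x in x_levels) {
    est <- ec_with_oci(fit, x = x, n_boot = n_boot, seed = seed)
    preds <- c(CA = ec_ca(ray, x), IA = ec_ia(ray, x))
    for (ref in names(preds)) {
      if (n_boot > 0L) {
        b <- mdr_bounds(est$ec_low, est$ec_up, est$ec)
      } else {
        b <- c(mdr_lower = NA_real_, mdr_upper = NA_real_)
      }
      m <- mdr(preds[[ref]], est$ec)
      lab <- if (n_boot > 0L) classify_mdr(m, b[["mdr_lower"]], b[["mdr_upper"]])
             else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        effect_level = x, reference = ref,
        ec_obs = est$ec, ec_obs_low = est$ec_low, ec_obs_up = est$ec_up,
        ec_pred = preds[[ref]], mdr = m,
        mdr_lower = b[["mdr_lower"]], mdr_upper = b[["mdr_upper"]],
        label = lab, stringsAsFactors = FALSE)
    }
    for (i in seq_along(ray$ids)) {
      p <- ray$params[[i]]
      d <- if (x < curve_max_effect(p))
        dri(invert_curve(p, x), ray$fractions[i], est$ec) else NA_real_
      dri_rows[[length(dri_rows) + 1L]] <- data.frame(
        effect_level = x, component = ray$ids[i], dri = d,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(fit = fit,
                 assessment = do.call(rbind, rows),
                 dri = do.call(rbind, dri_rows),
                 seed = as.integer(seed)),
            class = "mixture_assessment")
}

#' @export
print.mixture_assessment <- function(x, ...) {
  cat("<mixture_assessment>\n")
  cat(sprintf("mixture fit: %s (R2 = %.4f, RMSE = %.4g)\n",
              x$fit$params$family, x$fit$r_squared, x$fit$rmse))
  print(x$assessment, row.names = FALSE, digits = 4)
  cat("dose reduction indices:\n")
  print(x$dri, row.names = FALSE, digits = 4)
  invisible(x)
}
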