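#' Validate an effect table
#'
#' An effect table is a data.frame with columns `concentration` (mol/L,
#' strictly positive), `effect` (fraction; may be negative under hormesis or
#' exceed neither bound clipping is applied), and optionally `replicate`.
#'
#' @param data A data.frame.
#' @param min_rows Minimum number of rows required.
#' @return The validated data.frame (with a `replicate` column added if
#'   absent), invisibly usable downstream.
#' @keywords internal
as_effect_table <- function(data, min_rows = 3L) {
  if (!is.data.frame(data))
    stop("effect data must be a data.frame", call. = FALSE)
  need <- c("concentration", "effect")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("effect data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(data) < min_rows)
    stop(sprintf("at least %d observations are required", min_rows),
         call. = FALSE)
  check_conc(data$concentration)
  if (!is.numeric(data$effect) || any(!is.finite(data$effect)))
    stop("'effect' must be finite numeric", call. = FALSE)
  if (length(unique(data$concentration)) < 2L)
    stop("at least 2 distinct concentrations are required", call. = FALSE)
  if (is.null(data$replicate)) data$replicate <- seq_len(nrow(data))
  data
}

start_values <- function(data, family) {
  x <- data$concentration
  e <- data$effect
  if (family == "weibull") {
    ec <- pmin(pmax(e, 1e-3), 1 - 1e-3)
    interior <- e > 1e-3 & e < 1 - 1e-3
    use <- if (sum(interior) >= 2) interior else rep(TRUE, length(e))
    z <- log(-log(1 - ec[use]))
    co <- stats::coef(stats::lm(z ~ log10(x[use])))
    beta0 <- unname(co[2]); alpha0 <- unname(co[1])
    if (!is.finite(beta0) || abs(beta0) < 1e-8) beta0 <- 1
    if (!is.finite(alpha0)) alpha0 <- -beta0 * log10(stats::median(x))
    c(alpha = alpha0, beta = beta0)
  } else {
    alpha0 <- min(max(max(e), 0.05), 1)
    beta0 <- x[which.min(abs(e - alpha0 / 2))]
    c(alpha = alpha0, beta = beta0)
  }
}

model_fun <- function(family) {
  if (family == "weibull") {
    function(p, x) 1 - exp(-exp(p[1] + p[2] * log10(x)))
  } else {
    function(p, x) p[1] * x / (p[2] + x)
  }
}

#' Fit a two-parameter concentration-response curve
#'
#' Ordinary least squares via Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]). Starting values: for Weibull, a linearised
#' regression of \eqn{\ln(-\ln(1-E))} on \eqn{\log_{10} x} over interior
#' effect points; for Hill, the maximum observed effect (clipped to (0, 1])
#' and the concentration nearest half-maximum. Effects outside \[0, 1\]
#' (hormesis) are not clipped before fitting.
#'
#' @param data Effect table: data.frame with `concentration`, `effect`, and
#'   optionally `replicate` columns; >= 3 rows over >= 2 distinct
#'   concentrations.
#' @param family `"weibull"` or `"hill"`.
#' @return An object of class `crc_fit`: list with `params`
#'   ([curve_params]), `r_squared` (`NA` when the observed effects have zero
#'   variance), `rmse` (denominator `n`, not `n - p`), `n_points`,
#'   `converged`, `data`, `bootstrap_params` (empty until
#'   [ec_with_oci()]/[boot_refit()] is used) and `seed`.
#' @examples
#' tr <- curve_params("weibull", 2, 1.5)
#' d <- data.frame(concentration = 10^seq(-5, -2, length.out = 7))
#' d$effect <- weibull_effect(tr, d$concentration)
#' fit_curve(d, "weibull")
#' @export
fit_curve <- function(data, family = c("weibull", "hill")) {
  family <- match.arg(family)
  data <- as_effect_table(data)
  x <- data$concentration
  e <- data$effect
  f <- model_fun(family)
  p0 <- start_values(data, family)
  lower <- if (family == "hill") c(1e-9, 1e-300) else c(-Inf, -Inf)
  upper <- if (family == "hill") c(1, Inf) else c(Inf, Inf)
  p0 <- pmin(pmax(p0, lower), upper)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                       fn = function(p) e - f(p, x),
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(err) NULL)
  converged <- !is.null(fit) && fit$info %in% 1:4
  p <- if (is.null(fit)) p0 else fit$par
  params <- tryCatch(curve_params(family, p[1], p[2]),
                     error = function(err) NULL)
  if (is.null(params)) {
    params <- curve_params(family, p0[1], p0[2])
    converged <- FALSE
  }
  res <- e - f(c(params$alpha, params$beta), x)
  ss_res <- sum(res^2)
  ss_tot <- sum((e - mean(e))^2)
  structure(list(
    params = params,
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    rmse = sqrt(ss_res / length(e)),
    n_points = length(e),
    converged = converged,
    data = data,
    bootstrap_params = list(),
    seed = NA_integer_
  ), class = "crc_fit")
}

#' @export
print.crc_fit <- function(x, ...) {
  cat(sprintf("<crc_fit> %s: alpha = %.6g, beta = %.6g | R2 = %s, RMSE = %.4g, n = %d%s\n",
              x$params$family, x$params$alpha, x$params$beta,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared)),
              x$rmse, x$n_points,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Select the best concentration-response fit
#'
#' Chooses the fit with the maximum determination coefficient R2;
#' ties within `1e-6` are broken by minimum RMSE, remaining ties by family
#' order (Weibull before Hill). Non-converged fits are discarded first.
#'
#' @param fits A list of `crc_fit` objects (or a single one).
#' @return The selected `crc_fit`.
#' @export
select_model <- function(fits) {
  if (inherits(fits, "crc_fit")) fits <- list(fits)
  if (!length(fits)) stop("no fits supplied", call. = FALSE)
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  fits <- fits[ok]
  if (!length(fits)) stop("no converged fits to select from", call. = FALSE)
  r2 <- vapply(fits, function(f) ifelse(is.na(f$r_squared), -Inf, f$r_squared),
               numeric(1))
  cand <- which(r2 >= max(r2) - 1e-6)
  if (length(cand) > 1) {
    rmse <- vapply(fits[cand], function(f) f$rmse, numeric(1))
    cand <- cand[rmse <= min(rmse) + 1e-12]
  }
  if (length(cand) > 1) {
    fam <- vapply(fits[cand], function(f) f$params$family, character(1))
    cand <- cand[order(match(fam, c("weibull", "hill")))][1]
  }
  fits[[cand[1]]]
}

#' Bootstrap refits of a concentration-response curve
#'
#' Nonparametric bootstrap: replicate observations are resampled with
#' replacement within each concentration, the curve refit (same family,
#' started at the point estimates), and the refitted parameters collected.
#' Because plate assays carry very few replicates per concentration
#' (typically 3), plain resampling underestimates the replicate variance
#' by the factor (n-1)/n; resampling therefore uses the bootknife scheme
#' (Hesterberg 2004): within each concentration one randomly chosen
#' replicate is deleted and n values are then drawn with replacement from
#' the remaining n-1, which makes the resampled variance unbiased.
#' Deterministic given `seed`.
#'
#' @param fit A `crc_fit`.
#' @param data Effect table; defaults to the data stored in `fit`.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return `fit` with `bootstrap_params` filled (a list of [curve_params];
#'   failed refits are dropped) and `seed` recorded.
#' @export
boot_refit <- function(fit, data = fit$data, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(fit, "crc_fit"))
  data <- as_effect_table(data)
  family <- fit$params$family
  f <- model_fun(family)
  lower <- if (family == "hill") c(1e-9, 1e-300) else c(-Inf, -Inf)
  upper <- if (family == "hill") c(1, Inf) else c(Inf, Inf)
  p_hat <- c(fit$params$alpha, fit$params$beta)
  groups <- split(seq_len(nrow(data)), data$concentration)
  set.seed(seed)
  boots <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(groups, function(g) {
      n <- length(g)
      if (n > 1L) g <- g[-sample.int(n, 1L)]
      g[sample.int(length(g), n, replace = TRUE)]
    }), use.names = FALSE)
    xb <- data$concentration[idx]
    eb <- data$effect[idx]
    fb <- tryCatch(
      minpack.lm::nls.lm(par = p_hat, lower = lower, upper = upper,
                         fn = function(p) eb - f(p, xb),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(err) NULL)
    if (!is.null(fb) && fb$info %in% 1:4) {
      pb <- tryCatch(curve_params(family, fb$par[1], fb$par[2]),
                     error = function(err) NULL)
      boots[[b]] <- pb
    }
  }
  fit$bootstrap_params <- Filter(Negate(is.null), boots)
  fit$seed <- as.integer(seed)
  fit$n_boot <- as.integer(n_boot)
  fit
}

#' Effect concentration with 95% observed confidence interval
#'
#' The point estimate inverts the fitted curve at effect level `x`
#' ([invert_curve()]). The 95% observed confidence interval (OCI) is the
#' 2.5th/97.5th percentile of the effect concentration over `n_boot`
#' nonparametric bootstrap resamples (replicates resampled within
#' concentration, curve refit, inverted). `n_boot = 0` returns the point
#' estimate with absent (`NA`) bounds.
#'
#' @param fit A `crc_fit` (bootstrap replicates are computed here unless
#'   already present with the same `n_boot`/`seed`).
#' @param data Effect table; defaults to the data stored in `fit`.
#' @param x Effect level, a fraction in (0, attainable maximum).
#' @param n_boot Number of bootstrap resamples (>= 2, or 0 for no bounds).
#' @param seed Integer seed; same seed gives bit-identical results.
#' @return An object of class `ec_estimate`: list with `effect_level`,
#'   `ec`, `ec_low`, `ec_up`, `n_boot`, `n_failed`, `seed`.
#' @export
ec_with_oci <- function(fit, data = fit$data, x = 0.5, n_boot = 1000L,
                        seed = 1L) {
  stopifnot(inherits(fit, "crc_fit"))
  if (length(x) != 1L || !is.finite(x) || x <= 0 || x >= curve_max_effect(fit$params))
    stop(sprintf("effect level must lie in (0, %g) for this curve",
                 curve_max_effect(fit$params)), call. = FALSE)
  ec <- invert_curve(fit$params, x)
  if (n_boot == 0L) {
    return(structure(list(effect_level = x, ec = ec, ec_low = NA_real_,
                          ec_up = NA_real_, n_boot = 0L, n_failed = 0L,
                          seed = as.integer(seed)),
                     class = "ec_estimate"))
  }
  if (n_boot < 2L) stop("'n_boot' must be 0 or >= 2", call. = FALSE)
  if (!identical(fit$seed, as.integer(seed)) ||
      !identical(fit$n_boot, as.integer(n_boot)))
    fit <- boot_refit(fit, data, n_boot = n_boot, seed = seed)
  ecs <- vapply(fit$bootstrap_params, function(p) {
    if (x >= curve_max_effect(p)) return(NA_real_)
    invert_curve(p, x)
  }, numeric(1))
  n_failed <- n_boot - sum(is.finite(ecs))
  qs <- stats::quantile(ecs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(effect_level = x, ec = ec, ec_low = qs[1], ec_up = qs[2],
                 n_boot = as.integer(n_boot), n_failed = as.integer(n_failed),
                 seed = as.integer(seed)),
            class = "ec_estimate")
}

#' @export
print.ec_estimate <- function(x, ...) {
  cat(sprintf("<ec_estimate> EC%g = %.4g mol/L", 100 * x$effect_level, x$ec))
  if (is.finite(x$ec_low))
    cat(sprintf(" [95%% OCI %.4g, %.4g; %d bootstraps]",
                x$ec_low, x$ec_up, x$n_boot))
  cat("\n")
  invisible(x)
}
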