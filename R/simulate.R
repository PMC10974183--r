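#' Weibull parameters with a prescribed EC50 and slope
#'
#' Convenience constructor: returns the Weibull curve whose 50% effect
#' concentration equals `ec50` and whose log10-concentration slope is
#' `slope` (\eqn{\alpha = \ln(\ln 2) - \beta \log_{10} EC_{50}}).
#'
#' @param ec50 Target EC50, mol/L.
#' @param slope Slope parameter (default 2, a typical sigmoid steepness
#'   for single-class toxicants on algae).
#' @return A [curve_params] of family `"weibull"`.
#' @export
weibull_from_ec50 <- function(ec50, slope = 2) {
  check_conc(ec50)
  curve_params("weibull", alpha = log(log(2)) - slope * log10(ec50),
               beta = slope)
}

#' Define a simulation scenario
#'
#' Describes a synthetic algal growth-inhibition experiment: the true
#' concentration-response curve(s), the mixture ratio and interaction
#' truth, the plate design (geometric dilution series with replicates),
#' the optical-density noise, and the control growth. Defaults mirror the
#' emulated bench design: 7 concentrations at dilution factor 0.4,
#' triplicates, OD read at 0 h and 96 h, control growing from OD 0.1 to
#' 0.5, and Gaussian instrument noise with SD 0.01 on the OD scale.
#'
#' @param truth A [curve_params] (single compound) or list of
#'   `curve_params` (mixture components, optionally named).
#' @param fractions Molar fractions of the mixture ray (required when
#'   `truth` is a list of length > 1).
#' @param interaction `"CA"`, `"IA"`, or a positive number `s`
#'   interpreted as a potency-shift synergy factor on the CA surface (the
#'   true mixture effect at total concentration c is the CA effect at
#'   `s * c`; `s = 1` reduces to CA, `s > 1` is synergy, `s < 1`
#'   antagonism).
#' @param top_conc Highest (total) concentration, mol/L.
#' @param n_levels,dilution,replicates Plate design (defaults 7, 0.4, 3).
#' @param noise_sd Gaussian SD added to endpoint OD readings.
#' @param od_00,od_0i Control OD at 0 h and at the endpoint.
#' @param seed Integer seed.
#' @return An object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(truth, fractions = NULL, interaction = "CA",
                                top_conc, n_levels = 7L, dilution = 0.4,
                                replicates = 3L, noise_sd = 0.01,
                                od_00 = 0.1, od_0i = 0.5, seed = 1L) {
  if (inherits(truth, "curve_params")) truth <- list(truth)
  if (!length(truth) || !all(vapply(truth, inherits, logical(1), "curve_params")))
    stop("'truth' must be curve_params or a list of them", call. = FALSE)
  if (length(truth) > 1L) {
    if (is.null(fractions))
      stop("'fractions' required for multi-component truth", call. = FALSE)
  } else if (is.null(fractions)) fractions <- 1
  if (is.numeric(interaction)) {
    if (length(interaction) != 1L || !is.finite(interaction) || interaction <= 0)
      stop("numeric 'interaction' (synergy factor s) must be > 0", call. = FALSE)
  } else if (!interaction %in% c("CA", "IA")) {
    stop("'interaction' must be \"CA\", \"IA\", or a synergy factor s > 0",
         call. = FALSE)
  }
  check_conc(top_conc)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (od_0i <= od_00) stop("control must grow: od_0i > od_00", call. = FALSE)
  structure(list(truth = truth, fractions = fractions,
                 interaction = interaction, top_conc = top_conc,
                 n_levels = as.integer(n_levels), dilution = dilution,
                 replicates = as.integer(replicates), noise_sd = noise_sd,
                 od_00 = od_00, od_0i = od_0i, seed = as.integer(seed)),
            class = "simulation_scenario")
}

scenario_ray <- function(scenario) {
  mixture_ray(scenario$truth, scenario$fractions)
}

truth_effect <- function(scenario, conc) {
  if (length(scenario$truth) == 1L && !is.numeric(scenario$interaction))
    return(curve_effect(scenario$truth[[1]], conc))
  ray <- scenario_ray(scenario)
  if (identical(scenario$interaction, "IA")) ia_effect(ray, conc)
  else if (identical(scenario$interaction, "CA")) ca_effect(ray, conc)
  else ca_effect(ray, scenario$interaction * conc)
}

od_table_from_effects <- function(scenario, treatment, conc, effects) {
  reps <- scenario$replicates
  growth <- scenario$od_0i - scenario$od_00
  rows <- expand.grid(replicate = seq_len(reps),
                      i = seq_along(conc), KEEP.OUT.ATTRS = FALSE)
  n_tr <- nrow(rows)
  eps <- stats::rnorm(n_tr, 0, scenario$noise_sd)
  od_t96 <- scenario$od_00 + (1 - effects[rows$i]) * growth + eps
  ctrl_t96 <- rep(scenario$od_0i, reps)
  out <- data.frame(
    treatment = c(rep(treatment, n_tr), rep("control", reps)),
    concentration_mol_per_L = c(conc[rows$i], rep(0, reps)),
    replicate = c(rows$replicate, seq_len(reps)),
    od_t0 = scenario$od_00,
    od_t96 = c(od_t96, ctrl_t96),
    stringsAsFactors = FALSE)
  n_clip <- sum(out$od_t96 < 0)
  if (n_clip > 0) {
    warning(sprintf("%d simulated OD value(s) clipped at 0", n_clip),
            call. = FALSE)
    out$od_t96 <- pmax(out$od_t96, 0)
  }
  attr(out, "n_clipped") <- n_clip
  out
}

#' Simulate a single-compound growth-inhibition plate
#'
#' Inverts the growth-inhibition formula: for each concentration and
#' replicate the endpoint OD is set so the implied inhibition equals the
#' truth curve's effect, then Gaussian instrument noise is added
#' (`od_t96 = od_00 + (1 - E(c)) * (od_0i - od_00) + eps`). Control rows
#' are emitted at their nominal ODs (the noise model lives on the
#' treatment endpoint readings). Deterministic given the scenario seed.
#'
#' @param scenario A [simulation_scenario] with a single truth curve.
#' @param treatment Label for the treatment rows.
#' @return data.frame with columns `treatment`, `concentration_mol_per_L`,
#'   `replicate`, `od_t0`, `od_t96` (control rows have concentration 0);
#'   attribute `n_clipped` counts negative ODs clipped at 0.
#' @export
simulate_single <- function(scenario, treatment = "treatment") {
  stopifnot(inherits(scenario, "simulation_scenario"))
  if (length(scenario$truth) != 1L)
    stop("simulate_single() needs a single-component scenario", call. = FALSE)
  set.seed(scenario$seed)
  conc <- scenario$top_conc * scenario$dilution^(seq_len(scenario$n_levels) - 1)
  effects <- curve_effect(scenario$truth[[1]], conc)
  od_table_from_effects(scenario, treatment, conc, effects)
}

#' Simulate a fixed-ratio mixture plate
#'
#' As [simulate_single()], but the true effect at each total concentration
#' comes from the scenario's interaction truth: the CA surface, the IA
#' surface, or the CA surface with its potency multiplied by the synergy
#' factor `s` (so the expected MDR against CA is `s`).
#'
#' @param scenario A [simulation_scenario] (multi-component, or
#'   single-component as a degenerate ray).
#' @param treatment Label for the treatment rows.
#' @return data.frame in the same layout as [simulate_single()].
#' @export
simulate_mixture <- function(scenario, treatment = "mixture") {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(scenario$seed)
  conc <- scenario$top_conc * scenario$dilution^(seq_len(scenario$n_levels) - 1)
  effects <- truth_effect(scenario, conc)
  od_table_from_effects(scenario, treatment, conc, effects)
}

#' Simulate a biomarker absorbance table
#'
#' Generates raw spectrophotometric records whose derived indices respond
#' linearly to the truth effect: each index takes the value
#' `base * (1 - slope * E(c))`, absorbances are back-computed by inverting
#' the pigment and TBARS formulas exactly, and Gaussian noise (`noise_sd`)
#' is added to the absorbances. Kit-derived activities (`gsh`, `tp`,
#' `cat`, `sod`) are emitted directly as values with the same relative
#' noise on their scale. Control rows (concentration 0) are included.
#'
#' @param scenario A [simulation_scenario].
#' @param slopes Named numeric vector of response slopes per index
#'   (subset of `chla`, `chlb`, `car`, `mda`, `gsh`, `tp`, `cat`, `sod`);
#'   positive slope = the index decreases with effect.
#' @param base Named numeric vector of control (baseline) index values.
#' @param M,N TBARS dilution factor and cell density used for the MDA
#'   back-computation.
#' @return data.frame with `treatment`, `concentration`, `replicate`,
#'   absorbance columns and activity columns, ready for
#'   [biomarker_panel()].
#' @export
simulate_biomarkers <- function(scenario,
                                slopes = c(chla = 0.8, chlb = 0.5,
                                           car = 0.4, mda = -0.6,
                                           gsh = -0.3, tp = 0.4,
                                           cat = -0.2, sod = 0.3),
                                base = c(chla = 2, chlb = 1, car = 0.8,
                                         mda = 2e-9, gsh = 50, tp = 100,
                                         cat = 10, sod = 40),
                                M = 1, N = 1e6) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(scenario$seed + 1L)
  sl <- stats::setNames(rep(0, length(base)), names(base))
  sl[intersect(names(slopes), names(base))] <-
    slopes[intersect(names(slopes), names(base))]
  slopes <- sl
  conc <- scenario$top_conc * scenario$dilution^(seq_len(scenario$n_levels) - 1)
  effects <- truth_effect(scenario, conc)
  conc_all <- c(conc, 0)
  eff_all <- c(effects, 0)
  treat <- c(rep("mixture", length(conc)), "control")
  rows <- list()
  for (i in seq_along(conc_all)) {
    for (r in seq_len(scenario$replicates)) {
      target <- base * (1 - slopes[names(base)] * eff_all[i])
      # invert Chla/Chlb for od665/od649, then Car for od470
      a649 <- (13.59 * target[["chlb"]] + 7.32 * target[["chla"]]) /
        (13.59 * 24.96 - 6.88 * 7.32)
      a665 <- (target[["chla"]] + 6.88 * a649) / 13.59
      a470 <- (245 * target[["car"]] + 2.05 * a665 + 114.8 * a649) / 1000
      a450 <- 0.05
      a600 <- 0.02
      a532 <- (target[["mda"]] * 1000 * N / M + 0.56 * a450) / 6.45 + a600
      noise <- stats::rnorm(6, 0, scenario$noise_sd)
      act_noise <- stats::rnorm(4, 0, scenario$noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        treatment = treat[i], concentration = conc_all[i], replicate = r,
        od470 = max(a470 + noise[1], 0), od649 = max(a649 + noise[2], 0),
        od665 = max(a665 + noise[3], 0), od450 = max(a450 + noise[4], 0),
        od532 = max(a532 + noise[5], 0), od600 = max(a600 + noise[6], 0),
        M = M, N = N,
        gsh = target[["gsh"]] * (1 + act_noise[1]),
        tp = target[["tp"]] * (1 + act_noise[2]),
        cat = target[["cat"]] * (1 + act_noise[3]),
        sod = target[["sod"]] * (1 + act_noise[4]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
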