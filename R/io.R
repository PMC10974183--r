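#' Read an optical-density plate table
#'
#' Reads a CSV with columns `treatment`, `concentration_mol_per_L`,
#' `replicate`, `od_t0`, `od_t96`. Control rows have
#' `treatment == "control"` (concentration 0) and are required: growth
#' inhibition is computed for every treatment row against the mean control
#' growth. Malformed rows are rejected with their file line numbers.
#'
#' @param path Path to the CSV file (or a data.frame in the same layout).
#' @return list with `effects` (effect table: `treatment`,
#'   `concentration`, `effect`, `replicate`), `controls` (the control
#'   rows) and `control_growth` (mean control OD delta).
#' @export
read_od_table <- function(path) {
  raw <- if (is.data.frame(path)) path
         else utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("treatment", "concentration_mol_per_L", "replicate",
            "od_t0", "od_t96")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("OD table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  numcols <- c("concentration_mol_per_L", "od_t0", "od_t96")
  bad <- rep(FALSE, nrow(raw))
  for (cc in numcols) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- bad | !is.finite(v)
    raw[[cc]] <- v
  }
  is_ctrl <- raw$treatment == "control"
  bad <- bad | (!is_ctrl & raw$concentration_mol_per_L <= 0)
  if (any(bad))
    stop("malformed OD row(s) at file line(s): ",
         paste(which(bad) + 1L, collapse = ", "), call. = FALSE)
  controls <- raw[is_ctrl, , drop = FALSE]
  if (!nrow(controls))
    stop("no control rows (treatment == \"control\") found", call. = FALSE)
  growth <- mean(controls$od_t96 - controls$od_t0)
  if (growth <= 0)
    stop("control must grow: mean(od_t96 - od_t0) must be > 0", call. = FALSE)
  tr <- raw[!is_ctrl, , drop = FALSE]
  eff <- growth_inhibition(tr$od_t0, tr$od_t96,
                           od_00 = 0, od_0i = growth)
  if (any(eff < 0))
    warning(sprintf("%d observation(s) show growth stimulation (negative inhibition)",
                    sum(eff < 0)), call. = FALSE)
  list(effects = data.frame(treatment = tr$treatment,
                            concentration = tr$concentration_mol_per_L,
                            effect = eff, replicate = tr$replicate,
                            stringsAsFactors = FALSE),
       controls = controls,
       control_growth = growth)
}

#' Write an optical-density plate table
#'
#' @param od data.frame as produced by [simulate_single()] /
#'   [simulate_mixture()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_od_table <- function(od, path) {
  utils::write.csv(od, path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' YAML configuration for [run_pipeline()]. Expected top-level fields:
#' `compounds` (list of `id`, `molar_mass`, `od_file`), `mixture`
#' (`od_file`, `fractions` named by compound id, optional `fraction_type`),
#' `effect_levels`, `families`, `n_boot`, `seed`, optional `biomarker_file`
#' and `out_dir`. Concentrations in all files are mol/L; mass-based inputs
#' must be pre-converted with [mass_to_molar()].
#'
#' @param path Path to a YAML file.
#' @return The configuration as a named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$compounds) || !length(cfg$compounds))
    stop("config must list at least one compound", call. = FALSE)
  if (!is.null(cfg$mixture)) {
    fr <- unlist(cfg$mixture$fractions)
    if (abs(sum(fr) - 1) > 1e-12)
      stop("mixture fractions must sum to 1", call. = FALSE)
  }
  if (is.null(cfg$seed) &&
      (is.null(cfg$n_boot) || cfg$n_boot > 0))
    stop("a seed is required when bootstrap stages are requested", call. = FALSE)
  cfg
}

fit_compound <- function(effects, families, n_boot, seed, label) {
  fits <- lapply(families, function(fam) fit_curve(effects, fam))
  sel <- select_model(fits)
  message(sprintf("[fit] %s: selected %s (R2 = %.4f, RMSE = %.4g) from %d candidate(s)",
                  label, sel$params$family, sel$r_squared, sel$rmse,
                  length(fits)))
  sel
}

#' Run the end-to-end mixture toxicity pipeline
#'
#' Orchestrates the whole analysis: reads per-compound and mixture OD
#' tables, fits and selects single-compound curves, reports pEC50s with
#' bootstrap OCIs, builds the fixed-ratio ray, predicts CA/IA, assesses
#' MDR interactions and DRIs, optionally summarises a biomarker table into
#' a panel with its Pearson correlation matrix, and writes a
#' machine-readable `report.json` plus tidy CSVs (`fits.csv`,
#' `assessment.csv`, `dri.csv`, and `panel.csv`/`correlation.csv` when
#' biomarkers are supplied). Fully deterministic given the configured
#' seed.
#'
#' @param config Configuration list (see [read_run_config()]) or a path to
#'   a YAML file.
#' @return The report, invisibly (a named list mirroring `report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  families <- config$families %||% c("weibull", "hill")
  n_boot <- as.integer(config$n_boot %||% 1000L)
  seed <- as.integer(config$seed %||% 1L)
  x_levels <- as.numeric(config$effect_levels %||% c(0.10, 0.25, 0.50))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  compounds <- list()
  for (cmp in config$compounds) {
    od <- read_od_table(cmp$od_file %||% cmp$od)
    message(sprintf("[read] %s: %d treatment rows, %d control rows, seed %d",
                    cmp$id, nrow(od$effects), nrow(od$controls), seed))
    fit <- fit_compound(od$effects, families, n_boot, seed, cmp$id)
    est <- ec_with_oci(fit, x = 0.5, n_boot = n_boot, seed = seed)
    compounds[[cmp$id]] <- list(
      id = cmp$id, molar_mass = cmp$molar_mass, fit = fit, ec50 = est,
      record = list(id = cmp$id, family = fit$params$family,
                    alpha = fit$params$alpha, beta = fit$params$beta,
                    r_squared = fit$r_squared, rmse = fit$rmse,
                    n_points = fit$n_points,
                    ec50 = est$ec, ec50_low = est$ec_low, ec50_up = est$ec_up,
                    pec50 = round(pec(est$ec), 2)))
  }

  report <- list(
    seed = seed, n_boot = n_boot, effect_levels = x_levels,
    families = families,
    package_version = as.character(utils::packageVersion("raytox")),
    compounds = lapply(compounds, `[[`, "record"))
  fits_df <- do.call(rbind, lapply(compounds, function(cm)
    as.data.frame(cm$record, stringsAsFactors = FALSE)))

  assessment <- NULL
  if (!is.null(config$mixture)) {
    fr <- unlist(config$mixture$fractions)
    ids <- names(fr)
    if (is.null(ids)) ids <- names(compounds)
    ray <- mixture_ray(lapply(compounds[ids], `[[`, "fit"), as.numeric(fr),
                       ids = ids,
                       fraction_type = config$mixture$fraction_type %||% "molar")
    mix_od <- read_od_table(config$mixture$od_file %||% config$mixture$od)
    message(sprintf("[mixture] %d treatment rows; fractions %s",
                    nrow(mix_od$effects),
                    paste(sprintf("%s=%.2f", ids, fr), collapse = ", ")))
    assessment <- assess_mixture(ray, mix_od$effects, x_levels = x_levels,
                                 n_boot = n_boot, seed = seed,
                                 families = families)
    mix_est <- ec_with_oci(assessment$fit, x = 0.5, n_boot = n_boot,
                           seed = seed)
    report$mixture <- list(
      fractions = as.list(stats::setNames(as.numeric(fr), ids)),
      family = assessment$fit$params$family,
      alpha = assessment$fit$params$alpha,
      beta = assessment$fit$params$beta,
      r_squared = assessment$fit$r_squared,
      rmse = assessment$fit$rmse,
      ec50 = mix_est$ec, ec50_low = mix_est$ec_low, ec50_up = mix_est$ec_up,
      pec50 = round(pec(mix_est$ec), 2))
    report$assessment <- assessment$assessment
    report$dri <- assessment$dri
    for (i in seq_len(nrow(assessment$assessment))) {
      a <- assessment$assessment[i, ]
      message(sprintf("[assess] x = %.2f %s: MDR = %.3f [%.3f, %.3f] -> %s",
                      a$effect_level, a$reference, a$mdr, a$mdr_lower,
                      a$mdr_upper, a$label))
    }
  }

  panel <- NULL
  if (!is.null(config$biomarker_file)) {
    raw <- utils::read.csv(config$biomarker_file, stringsAsFactors = FALSE)
    panel <- biomarker_panel(raw)
    rel_cols <- paste0(panel$indices, "_rel")
    keep <- panel$panel$treatment != "control"
    cor_mat <- correlation_panel(panel$panel[keep, rel_cols, drop = FALSE])
    report$biomarkers <- list(indices = panel$indices)
    message(sprintf("[biomarkers] %d indices over %d treatment points",
                    length(panel$indices), sum(keep)))
  }

  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    utils::write.csv(fits_df, file.path(out_dir, "fits.csv"),
                     row.names = FALSE)
    if (!is.null(assessment)) {
      utils::write.csv(assessment$assessment,
                       file.path(out_dir, "assessment.csv"), row.names = FALSE)
      utils::write.csv(assessment$dri, file.path(out_dir, "dri.csv"),
                       row.names = FALSE)
    }
    if (!is.null(panel)) {
      utils::write.csv(panel$panel, file.path(out_dir, "panel.csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(cor_mat),
                       file.path(out_dir, "correlation.csv"))
    }
    message(sprintf("[write] report bundle in %s", out_dir))
  }
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
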