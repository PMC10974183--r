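#' Growth inhibition from optical densities
#'
#' The 96 h algal growth-inhibition ratio compares the optical density
#' increase of a treatment with that of the control:
#' \eqn{I = 1 - (OD_{ti} - OD_{t0}) / (OD_{0i} - OD_{00})}.
#' 0 means growth equal to control, 1 means no growth, negative values
#' indicate growth stimulation (hormesis). Because only the within-arm
#' deltas enter, a constant blank offset added to both readings of an arm
#' cancels.
#'
#' @param od_t0,od_ti Treatment optical densities at 0 h and the endpoint.
#' @param od_00,od_0i Control optical densities at 0 h and the endpoint;
#'   the control must grow (`od_0i > od_00`).
#' @return Inhibition fraction(s).
#' @examples
#' growth_inhibition(0.1, 0.3, 0.1, 0.5) # 0.5
#' @export
growth_inhibition <- function(od_t0, od_ti, od_00, od_0i) {
  if (any(!is.finite(c(od_t0, od_ti, od_00, od_0i))))
    stop("optical densities must be finite", call. = FALSE)
  if (any(od_0i - od_00 <= 0))
    stop("control must grow (od_0i > od_00) for inhibition to be defined",
         call. = FALSE)
  1 - (od_ti - od_t0) / (od_0i - od_00)
}

#' Malondialdehyde content from TBARS absorbances
#'
#' \eqn{MDA = [6.45 (OD_{532} - OD_{600}) - 0.56\, OD_{450}] \cdot M /
#' (1000 N)}, with `M` the dilution factor and `N` the algal cell count per
#' millilitre. Units are those native to the formula (per-cell scale);
#' pathological absorbance combinations can yield negative values, which
#' are reported, not clipped.
#'
#' @param od450,od532,od600 Absorbances at 450, 532 and 600 nm (>= 0).
#' @param M Dilution factor, > 0.
#' @param N Algal cells per mL, > 0.
#' @return MDA content.
#' @export
mda_content <- function(od450, od532, od600, M = 1, N) {
  if (any(!is.finite(c(od450, od532, od600))) ||
      any(c(od450, od532, od600) < 0))
    stop("absorbances must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(M)) || any(M <= 0))
    stop("dilution factor 'M' must be > 0", call. = FALSE)
  if (any(!is.finite(N)) || any(N <= 0))
    stop("cell density 'N' must be > 0", call. = FALSE)
  (6.45 * (od532 - od600) - 0.56 * od450) * M / (1000 * N)
}

#' Photosynthetic pigment content from extract absorbances
#'
#' Ethanol-extract spectrophotometry:
#' \eqn{Chla = 13.59\, OD_{665} - 6.88\, OD_{649}},
#' \eqn{Chlb = 24.96\, OD_{649} - 7.32\, OD_{665}},
#' \eqn{Car = (1000\, OD_{470} - 2.05\, OD_{665} - 114.8\, OD_{649}) / 245}.
#' Values are in the formulas' native concentration units (ug/mL scale).
#'
#' @param od470,od649,od665 Absorbances at 470, 649 and 665 nm (>= 0).
#' @return data.frame with columns `chla`, `chlb`, `car`.
#' @examples
#' pigments(0.4, 0.2, 0.5)
#' @export
pigments <- function(od470, od649, od665) {
  if (any(!is.finite(c(od470, od649, od665))) ||
      any(c(od470, od649, od665) < 0))
    stop("absorbances must be finite and >= 0", call. = FALSE)
  data.frame(
    chla = 13.59 * od665 - 6.88 * od649,
    chlb = 24.96 * od649 - 7.32 * od665,
    car = (1000 * od470 - 2.05 * od665 - 114.8 * od649) / 245)
}

#' Relative change of an index versus control
#'
#' Inhibition-positive convention: \eqn{100 (control - treatment)/control}.
#' Positive values mean the index is suppressed relative to control,
#' negative values mean stimulation.
#'
#' @param treatment Treatment value(s).
#' @param control Control value (nonzero).
#' @return Percent relative change.
#' @examples
#' relative_change(0, 2) # 100: full inhibition
#' relative_change(3, 2) # -50: stimulation
#' @export
relative_change <- function(treatment, control) {
  if (any(!is.finite(c(treatment, control))))
    stop("values must be finite", call. = FALSE)
  if (any(control == 0))
    stop("control value must be nonzero", call. = FALSE)
  100 * (control - treatment) / control
}

#' Pearson correlation panel of biomarker indices
#'
#' Pairwise Pearson correlations of biochemical indices across
#' concentration points, as displayed in biomarker correlation heat maps.
#' Indices with zero variance get `NA` against every partner.
#'
#' @param panel data.frame of index values, one row per concentration
#'   point (>= 3 rows), one column per index (non-numeric columns are
#'   dropped).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_panel <- function(panel) {
  if (!is.data.frame(panel) && !is.matrix(panel))
    stop("'panel' must be a data.frame or matrix", call. = FALSE)
  panel <- as.data.frame(panel)
  panel <- panel[vapply(panel, is.numeric, logical(1))]
  if (!ncol(panel)) stop("no numeric index columns in 'panel'", call. = FALSE)
  if (nrow(panel) < 3)
    stop("at least 3 concentration points are required", call. = FALSE)
  r <- suppressWarnings(stats::cor(panel, method = "pearson"))
  ok <- vapply(panel, function(v) stats::sd(v) > 0, logical(1))
  diag(r)[ok] <- 1
  diag(r)[!ok] <- NA_real_
  r
}

#' Summarise a raw biomarker table into a per-treatment panel
#'
#' Computes the derived endpoints (pigments from 470/649/665 nm
#' absorbances, MDA from the TBARS triplet when present), averages
#' replicates within each treatment/concentration, and appends the
#' relative change of every index versus the control rows
#' (`treatment == "control"`), in the inhibition-positive convention.
#' Replicate dispersion is reported as the standard deviation.
#'
#' @param raw data.frame with columns `treatment`, `concentration`,
#'   `replicate`, absorbance columns (`od470`, `od649`, `od665`, and
#'   optionally `od450`, `od532`, `od600`, `M`, `N`), plus any
#'   already-computed activity columns (e.g. `gsh`, `tp`, `cat`, `sod`).
#' @return list with `panel` (means per treatment/concentration, one column
#'   per index plus `<index>_rel` relative changes and `<index>_sd`
#'   dispersions) and `indices` (the index column names).
#' @export
biomarker_panel <- function(raw) {
  if (!is.data.frame(raw) || !all(c("treatment", "concentration") %in% names(raw)))
    stop("'raw' must have 'treatment' and 'concentration' columns", call. = FALSE)
  if (!any(raw$treatment == "control"))
    stop("no control rows (treatment == \"control\") found", call. = FALSE)
  derived <- raw
  if (all(c("od470", "od649", "od665") %in% names(raw))) {
    pg <- pigments(raw$od470, raw$od649, raw$od665)
    derived <- cbind(derived, pg)
  }
  if (all(c("od450", "od532", "od600", "N") %in% names(raw))) {
    M <- if ("M" %in% names(raw)) raw$M else 1
    derived$mda <- mda_content(raw$od450, raw$od532, raw$od600, M, raw$N)
  }
  skip <- c("treatment", "concentration", "replicate",
            "od470", "od649", "od665", "od450", "od532", "od600", "M", "N")
  indices <- setdiff(names(derived)[vapply(derived, is.numeric, logical(1))],
                     skip)
  if (!length(indices)) stop("no index columns to summarise", call. = FALSE)
  agg <- function(fun) {
    out <- stats::aggregate(derived[indices], by = list(
      treatment = derived$treatment, concentration = derived$concentration),
      FUN = fun)
    out[order(out$treatment != "control", out$concentration), , drop = FALSE]
  }
  means <- agg(mean)
  sds <- agg(stats::sd)
  ctrl <- means[means$treatment == "control", indices, drop = FALSE]
  ctrl <- vapply(ctrl, mean, numeric(1))
  panel <- means
  for (idx in indices) {
    panel[[paste0(idx, "_sd")]] <- sds[[idx]]
    panel[[paste0(idx, "_rel")]] <- relative_change(means[[idx]], ctrl[[idx]])
  }
  list(panel = panel, indices = indices)
}
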