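---
title: "Mixture toxicity analysis with raytox: models, design choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture toxicity analysis with raytox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raytox)
```

## The problem

Antibiotics reach surface waters as mixtures, and green algae such as
*Selenastrum capricornutum* sit at the base of the aquatic food web. The
standard bench design for quantifying mixture toxicity is the fixed
concentration ratio ray: the components are combined at a constant molar
ratio and the total concentration is diluted geometrically, giving a
one-dimensional "ray" through the mixture concentration space. Growth
inhibition after 96 h is read off optical densities, a
concentration-response curve (CRC) is fitted, and the observed mixture
potency is compared with what the two classical reference models predict
from the single-compound curves:

* **Concentration addition (CA)** treats the components as dilutions of one
  another: at the mixture concentration producing effect $x$,
  $\sum_i c_i / EC_{x,i} = 1$. Along a ray with molar fractions $p_i$
  (so $c_i = p_i\,c_{mix}$) this has the closed form
  $EC_{x,CA} = 1 / \sum_i (p_i / EC_{x,i})$, a fraction-weighted harmonic
  mean of the single-compound effect concentrations.
* **Independent action (IA)** multiplies survival probabilities:
  $E(c_{mix}) = 1 - \prod_i \bigl(1 - E_i(p_i\,c_{mix})\bigr)$.

Deviation from a reference model is quantified by the **mixture deviation
ratio** $MDR = EC_{x,pred} / EC_{x,obs}$, compared against the bounds
obtained by mapping the 95% observed confidence interval (OCI) of
$EC_{x,obs}$ onto the MDR scale: an MDR above the upper bound is
synergism, below the lower bound antagonism, and anything in between (the
bounds included) additive. The **dose reduction index**
$DRI_i = EC_{x,i} / (p_i\,EC_{x,mix})$ expresses how many-fold less of
component $i$ achieves the same effect inside the mixture.

## Concentration-response models

Two two-parameter families are fitted:

* Weibull: $E = 1 - \exp(-\exp(\alpha + \beta \log_{10} x))$, with
  location $\alpha$ and slope $\beta$ (dimensionless; $x$ in mol/L).
* Hill: $E = \alpha x / (\beta + x)$, with maximum effect
  $\alpha \in (0, 1]$ and EC50 $\beta$ (mol/L).

Both are monotone, so effect concentrations invert in closed form
(`invert_curve()`), which the CA prediction and the MDR need. The better
family is chosen by maximum $R^2$; ties within $10^{-6}$ fall back to
minimum RMSE, then to Weibull first (`select_model()`). RMSE uses
denominator $n$ rather than $n - p$, the commonest convention in the
mixture-toxicology literature; users comparing with $n - p$ tools should
rescale. $R^2$ is computed about the mean observed effect, and a
zero-variance response reports `NA` rather than a misleading 1.

Fitting is ordinary least squares via Levenberg–Marquardt
(`minpack.lm::nls.lm`) with box constraints keeping the Hill ceiling in
$(0, 1]$ and its EC50 positive. Starting values matter more than the
optimizer here: the Weibull start comes from a linearised regression of
$\ln(-\ln(1-E))$ on $\log_{10} x$ over interior effect points, the Hill
start from the maximum observed effect and the concentration nearest
half-maximum. These avoid the flat local solutions that plague naive
starts on sigmoid data. Observed effects are *not* clipped to $[0, 1]$
before fitting: hormesis (negative inhibition at low doses) is real
signal, and clipping biases the slope.

## Effect concentrations and their confidence intervals

The 95% OCI of an effect concentration is obtained by a nonparametric
percentile bootstrap: replicates are resampled within each concentration,
the curve refitted (same family, started at the point estimates), the
refit inverted at the requested effect level, and the 2.5th/97.5th
percentiles taken (default 1000 resamples; everything is deterministic
given a seed). This needs no distributional assumption and reflects
exactly the replicate scatter the plates produced.

One refinement is required at bench-realistic replicate counts. Plain
with-replacement resampling of $n$ values underestimates their variance by
the factor $(n-1)/n$ — at triplicates, a third. Measured on simulated
plates (triplicate, 7 levels, OD noise SD 0.02), the plain percentile
interval covered the true EC50 in only about 80% of runs. `raytox`
therefore uses the bootknife scheme (Hesterberg 2004): within each
concentration one randomly chosen replicate is deleted and $n$ values are
drawn with replacement from the remaining $n - 1$, which makes the
resampled variance unbiased and raises measured coverage to about 89%.
The interval remains approximate — small-sample percentile intervals are
inherently a little narrow — which is worth remembering when an MDR sits
close to a bound.

## Interaction assessment

`assess_mixture()` runs the whole chain at one or more effect levels
(defaults 0.10, 0.25, 0.50; headline classifications are conventionally
quoted at 0.50): fit the observed mixture CRC, compute $EC_{x,obs}$ with
its OCI, compute $EC_{x,CA}$ and $EC_{x,IA}$ from the component curves,
form the MDR and its bounds for both references, classify, and attach the
DRIs. Both reference models are always reported side by side rather than
privileging one. An MDR exactly equal to a bound is classified additive:
the strict inequalities of the classification rule leave equality
undefined, and the conservative reading avoids declaring an interaction
on a tie. The DRI uses the standard dose-reduction definition above; it
is computed against the *observed* mixture effect concentration.

Ratio semantics: the ray's fractions are molar fractions of the total
mixture concentration ($c_i = p_i\,c_{mix}$). A `toxic_unit` switch on
`mixture_ray()` instead interprets the supplied numbers as toxic-unit
shares at the 50% level and converts them (molar fraction proportional to
$p_i^{TU} EC_{50,i}$), since "equivalent-effect" ratios are common in ray
designs and published reports are not always explicit about which was
used.

## The synthetic-data generator

No raw plate data ship with the package, so `simulate_single()` /
`simulate_mixture()` generate them from a declared truth. The generator
inverts the growth-inhibition formula
$I = 1 - (OD_{ti} - OD_{t0}) / (OD_{0i} - OD_{00})$: the endpoint OD of
each treatment replicate is set so its implied inhibition equals the
truth curve's effect, then Gaussian noise is added on the OD scale —
measurement error lives on the instrument, not on the derived effect.
Control rows are emitted at their nominal ODs; the observation model
places the noise on the treatment endpoint readings. Defaults emulate the
bench design: 7 concentrations at dilution factor 0.4, triplicates,
control growing from OD 0.1 to 0.5 (arbitrary but fixed), noise SD 0.01
(about 2.5% of the control growth delta; replicate-level scatter is
rarely published, so this is a judgment call, exposed as a parameter).
Negative simulated ODs are clipped at zero with a warning (rare at the
defaults).

Mixture truths: `"CA"`, `"IA"`, or a positive potency-shift factor $s$
applied to the CA surface (the true effect at $c$ is the CA effect at
$s c$). The $s$ parameterisation is chosen because it maps directly onto
the expected MDR — an $s$-fold shift produces $MDR_{CA} \approx s$ — so
recovery tests are self-calibrating. Default truth curves in the test
suite are equal-slope Weibulls (slope 2) carrying the study compounds'
EC50s; equal slopes make the CA surface of Weibull components *exactly*
Weibull again, so the noise-free pipeline is the identity on pEC50 and
MDR rather than merely close, and any end-to-end discrepancy is a defect,
not an approximation artifact. Classification-recovery simulations build
the ray from the components' truth curves and put noise on the mixture
plate only: the MDR/OCI rule conditions on the component curves, and this
isolates the observation uncertainty that the OCI actually models.

What the generator does **not** emulate: mechanistic algal growth (no
logistic dynamics, light or nutrient limitation), hormesis-shaped truth
curves (noise can produce negative inhibition, but the truth is
monotone), non-Gaussian or heteroscedastic instrument error, and
between-plate batch effects. Passing recovery tests therefore show the
statistical machinery is correct under its own assumptions — not that
real plates satisfy those assumptions.

`simulate_biomarkers()` produces raw absorbance tables whose derived
indices (chlorophyll a/b, carotenoids via the ethanol-extract equations;
MDA via the TBARS equation; kit activities directly) respond linearly to
the truth effect, by exactly inverting the endpoint formulas and adding
absorbance-scale noise — enough structure to exercise
`biomarker_panel()` and `correlation_panel()` end to end.

## Numerical choices

* IA inversion (`ec_ia()`): geometric bracket expansion (factor 10) from
  a component-based initial guess, then bisection on the log scale to
  relative tolerance $10^{-10}$. Derivative-based root finding is avoided
  because CRC slopes vanish at extreme effects.
* CA effect at a concentration (`ca_effect()`): monotone root-find over
  the effect level with `uniroot` at tolerance $10^{-14}$; concentrations
  outside the attainable range return 0 or the CA ceiling (the smallest
  component ceiling) rather than erroring, so predicted CRC grids are
  total.
* A Hill ceiling $\alpha < 1$ truncates attainable effects; requesting an
  effect level at or above a component's ceiling raises a domain error
  naming the component instead of extrapolating.
* Bootstrap resamples that fail to refit or cannot attain the requested
  effect level are dropped (and counted) rather than imputed.
* pEC50s are reported rounded to 2 decimals by convention; all internal
  arithmetic keeps full precision.

## Problem sizes used in the shipped checks

The package's own validation uses deliberately modest simulation sizes
chosen to give stable Monte Carlo answers: parameter recovery over 100
seeds, OCI coverage over 40 plates at 200 resamples, classification
recovery over 50 seeds per scenario at 500 resamples, and IA-inversion
oracle comparisons against $10^6$-point grids on 20 random rays. At these
sizes the measured rates (e.g. about 89% OCI coverage, 84% additive
recovery under an exact-CA truth, 100% synergism recovery under a 4-fold
potency shift at x = 0.5) are reproducible to within a few percentage
points across seed choices.

## Known limitations

* Only two-parameter CRC families are provided; no floor/ceiling
  log-logistic variants, Box–Cox transforms, or weighted least squares.
* The MDR framework ignores the uncertainty of the *predicted* effect
  concentration (it conditions on the component curves); its false-call
  rate is therefore somewhat above nominal when component curves are
  themselves noisy.
* Percentile bootstrap intervals at triplicate designs remain slightly
  anti-conservative even with the bootknife correction.
* The DRI definition here is the standard dose-reduction form; published
  DRI values computed with unstated conventions may not be comparable.
* Isobolograms, Loewe interaction surfaces and response-surface
  (Bliss-regression) methods are out of scope.
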