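# shared fixtures, all built in code

# noise-free effect table from a truth curve over a 7-point dilution series
exact_table <- function(params, top = 1e-3, n = 7, dilution = 0.4,
                        replicates = 1) {
  conc <- rep(top * dilution^(seq_len(n) - 1), each = replicates)
  data.frame(concentration = conc,
             effect = curve_effect(params, conc),
             replicate = rep(seq_len(replicates), times = n))
}

# random in-domain curve parameters
random_params <- function(family) {
  if (family == "weibull") {
    curve_params("weibull", alpha = stats::runif(1, -2, 8),
                 beta = stats::runif(1, 0.5, 4))
  } else {
    curve_params("hill", alpha = stats::runif(1, 0.4, 1),
                 beta = 10^stats::runif(1, -6, -3))
  }
}

random_ray <- function(m = 2) {
  fams <- sample(c("weibull", "hill"), m, replace = TRUE)
  p <- stats::runif(m)
  mixture_ray(lapply(fams, random_params), p / sum(p))
}

# the two study compounds as equal-slope Weibull truths with the reported
# potencies (EC50 1.18e-4 and 1.99e-4 mol/L)
amp_truth <- function() weibull_from_ec50(1.18e-4)
czo_truth <- function() weibull_from_ec50(1.99e-4)

study_ray <- function() {
  mixture_ray(list(AMP = amp_truth(), CZO = czo_truth()), c(0.2, 0.8))
}
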