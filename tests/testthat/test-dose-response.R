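test_that("weibull and hill effects match their closed forms", {
  w <- curve_params("weibull", 0, 1)
  expect_equal(weibull_effect(w, 1), 1 - exp(-1))
  expect_lt(weibull_effect(w, 1e-30), 1e-10) # effect -> 0 as x -> 0+
  w2 <- curve_params("weibull", 2, 1.5)
  expect_equal(weibull_effect(w2, 1e-4),
               1 - exp(-exp(2 + 1.5 * log10(1e-4))))

  h <- curve_params("hill", 1, 1e-4)
  expect_equal(hill_effect(h, 1e-4), 0.5) # half-maximal at x = beta
  h2 <- curve_params("hill", 0.8, 1e-5)
  expect_equal(hill_effect(h2, 1e5), 0.8, tolerance = 1e-9) # ceiling alpha
  expect_equal(hill_effect(curve_params("hill", 1, 2e-4), 1e-4), 1 / 3)

  expect_error(weibull_effect(w, 0), "positive")
  expect_error(hill_effect(h, -1), "positive")
})

test_that("both families are strictly increasing in concentration", {
  set.seed(42)
  for (i in 1:100) {
    fam <- if (i %% 2) "weibull" else "hill"
    p <- random_params(fam)
    x <- 10^seq(-8, -1, length.out = 50)
    e <- curve_effect(p, x)
    expect_true(all(diff(e) >= 0))
    # strictly increasing wherever the effect has not saturated in floating
    # point (the weibull reaches 1 - eps below machine precision)
    interior <- e > 1e-15 & e < 1 - 1e-12
    expect_true(all(diff(e[interior]) > 0))
  }
})

test_that("invert_curve round-trips through the effect functions", {
  expect_equal(invert_curve(curve_params("weibull", 0, 1), 1 - exp(-1)), 1)
  expect_equal(invert_curve(curve_params("hill", 1, 5e-5), 0.5), 5e-5)

  # bisection oracle for the weibull median
  w <- curve_params("weibull", 2, 1.5)
  lo <- 1e-12; hi <- 1
  while (hi / lo - 1 > 1e-14) {
    mid <- sqrt(lo * hi)
    if (weibull_effect(w, mid) < 0.5) lo <- mid else hi <- mid
  }
  expect_equal(invert_curve(w, 0.5), sqrt(lo * hi), tolerance = 1e-12)

  set.seed(7)
  for (i in 1:1000) {
    p <- random_params(if (i %% 2) "weibull" else "hill")
    e <- stats::runif(1, 1e-4, curve_max_effect(p) - 1e-4)
    expect_equal(curve_effect(p, invert_curve(p, e)), e, tolerance = 1e-10)
  }

  expect_error(invert_curve(curve_params("weibull", 0, 1), 1), "0 < effect < 1")
  expect_error(invert_curve(curve_params("hill", 0.8, 1e-4), 0.9), "alpha")
})

test_that("fitting noise-free data recovers the generating parameters", {
  for (fam in c("weibull", "hill")) {
    truth <- if (fam == "weibull") curve_params("weibull", 2, 1.5)
             else curve_params("hill", 0.9, 5e-5)
    d <- exact_table(truth, top = if (fam == "weibull") 0.1 else 1e-3)
    fit <- fit_curve(d, fam)
    expect_true(fit$converged)
    expect_equal(fit$params$alpha, truth$alpha, tolerance = 1e-6)
    expect_equal(fit$params$beta, truth$beta, tolerance = 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-10)
    expect_lt(fit$rmse, 1e-8)
  }
})

test_that("fit_curve validates its input and flags degenerate data", {
  expect_error(fit_curve(data.frame(concentration = 1, effect = 0.5), "hill"),
               "at least 3")
  expect_error(fit_curve(data.frame(concentration = c(1, 1, 1),
                                    effect = c(0.1, 0.2, 0.3)), "hill"),
               "distinct")
  flat <- data.frame(concentration = c(1e-5, 1e-4, 1e-3),
                     effect = c(0.5, 0.5, 0.5))
  expect_true(is.na(fit_curve(flat, "weibull")$r_squared))
})

test_that("fit recovers pEC50 from noisy synthetic data", {
  truth <- amp_truth()
  sc <- simulation_scenario(truth, top_conc = 8e-4, noise_sd = 0.02,
                            seed = 3L)
  tab <- suppressWarnings(read_od_table(simulate_single(sc)))
  fit <- select_model(list(fit_curve(tab$effects, "weibull"),
                           fit_curve(tab$effects, "hill")))
  expect_equal(pec(invert_curve(fit$params, 0.5)), pec(1.18e-4),
               tolerance = 0.1 / pec(1.18e-4))
})

test_that("select_model prefers R2, then RMSE, then family order", {
  d <- exact_table(curve_params("weibull", 2, 1.5), top = 0.1)
  fw <- fit_curve(d, "weibull")
  fh <- fit_curve(d, "hill")
  expect_identical(select_model(list(fh, fw))$params$family, "weibull")
  expect_identical(select_model(list(fw))$params$family, "weibull")

  # synthetic tie: identical R2 within tolerance, RMSE decides
  a <- fw; a$r_squared <- 0.99; a$rmse <- 0.03
  b <- fh; b$r_squared <- 0.99; b$rmse <- 0.02
  expect_identical(select_model(list(a, b))$params$family, "hill")
  # full tie: weibull first
  b$rmse <- 0.03
  expect_identical(select_model(list(b, a))$params$family, "weibull")
  expect_error(select_model(list()), "no fits")
})

test_that("bootstrap OCI is degenerate on noise-free data and seeded", {
  d <- exact_table(curve_params("weibull", 2, 1.5), top = 0.1,
                   replicates = 3)
  fit <- fit_curve(d, "weibull")
  est <- ec_with_oci(fit, x = 0.5, n_boot = 50, seed = 1)
  expect_equal(est$ec_low, est$ec)
  expect_equal(est$ec_up, est$ec)

  sc <- simulation_scenario(amp_truth(), top_conc = 8e-4, noise_sd = 0.02,
                            seed = 5L)
  tab <- suppressWarnings(read_od_table(simulate_single(sc)))
  f <- fit_curve(tab$effects, "weibull")
  e1 <- ec_with_oci(f, x = 0.5, n_boot = 100, seed = 9)
  e2 <- ec_with_oci(f, x = 0.5, n_boot = 100, seed = 9)
  expect_identical(e1, e2)
  expect_true(e1$ec_low < e1$ec && e1$ec < e1$ec_up)

  e0 <- ec_with_oci(f, x = 0.5, n_boot = 0)
  expect_true(is.na(e0$ec_low) && is.na(e0$ec_up))
  expect_error(ec_with_oci(f, x = 1.2, n_boot = 0), "effect level")
})

test_that("bootstrap OCI covers the true EC50 at roughly nominal rate", {
  truth <- amp_truth()
  ec_true <- invert_curve(truth, 0.5)
  hits <- vapply(1:40, function(seed) {
    sc <- simulation_scenario(truth, top_conc = 8e-4, noise_sd = 0.02,
                              seed = seed)
    tab <- suppressWarnings(read_od_table(simulate_single(sc)))
    f <- fit_curve(tab$effects, "weibull")
    est <- ec_with_oci(f, x = 0.5, n_boot = 200, seed = seed)
    est$ec_low <= ec_true && ec_true <= est$ec_up
  }, logical(1))
  expect_gte(mean(hits), 0.75)
})

test_that("pec and mass_to_molar implement the reporting conventions", {
  expect_equal(round(pec(1.18e-4), 2), 3.93)
  expect_equal(round(pec(1.99e-4), 2), 3.70)
  expect_equal(pec(1e-5), 5)
  expect_error(pec(0), "> 0")

  expect_equal(signif(mass_to_molar(27.1e-6, 349), 3), 7.77e-8)
  expect_equal(mass_to_molar(349, 349), 1)
  expect_error(mass_to_molar(-1, 349), "> 0")

  # exact pEC50 identity through the hill EC50 parameter
  b <- 3.7e-5
  expect_identical(pec(invert_curve(curve_params("hill", 1, b), 0.5)),
                   -log10(b))
})
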