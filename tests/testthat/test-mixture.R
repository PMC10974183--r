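test_that("ec_ca is the fraction-weighted harmonic mean of component ECs", {
  same <- curve_params("hill", 1, 1e-4)
  ray <- mixture_ray(list(same, same), c(0.3, 0.7))
  expect_equal(ec_ca(ray, 0.5), 1e-4)

  # direct arithmetic on the reported study EC50s
  ray2 <- mixture_ray(list(curve_params("hill", 1, 1.18e-4),
                           curve_params("hill", 1, 1.99e-4)), c(0.2, 0.8))
  expect_equal(ec_ca(ray2, 0.5),
               1 / (0.2 / 1.18e-4 + 0.8 / 1.99e-4))
  expect_equal(ec_ca(ray2, 0.5), 1.750e-4, tolerance = 1e-3)

  single <- mixture_ray(list(amp_truth()), 1)
  expect_equal(ec_ca(single, 0.3), invert_curve(amp_truth(), 0.3))

  # component ceiling below x is a named domain error
  capped <- mixture_ray(list(AMP = amp_truth(),
                             low = curve_params("hill", 0.4, 1e-4)),
                        c(0.5, 0.5))
  expect_error(ec_ca(capped, 0.5), "low")
})

test_that("ec_ca respects the harmonic-mean bound and degenerate identity", {
  set.seed(11)
  for (i in 1:25) {
    ray <- random_ray(m = sample(2:3, 1))
    x <- stats::runif(1, 0.05,
                      min(vapply(ray$params, curve_max_effect, numeric(1))) - 0.05)
    ec_i <- vapply(ray$params, invert_curve, numeric(1), effect = x)
    expect_gte(ec_ca(ray, x), min(ec_i))
    expect_lte(ec_ca(ray, x), max(ec_i))
  }
  p <- curve_params("weibull", 1.2, 2)
  ray_eq <- mixture_ray(list(p, p, p), c(0.2, 0.3, 0.5))
  for (x in c(0.05, 0.3, 0.7, 0.95))
    expect_equal(ec_ca(ray_eq, x), invert_curve(p, x), tolerance = 1e-12)
})

test_that("ia_effect multiplies survival fractions", {
  # two components each at 50% at their share -> 0.75
  p <- curve_params("hill", 1, 1e-4)
  ray <- mixture_ray(list(p, p), c(0.5, 0.5))
  expect_equal(ia_effect(ray, 2e-4), 0.75)
  # grid monotonicity and IA >= largest single-component effect
  set.seed(13)
  for (i in 1:10) {
    ray <- random_ray()
    grid <- 10^seq(-8, -2, length.out = 40)
    e <- ia_effect(ray, grid)
    expect_true(all(diff(e) >= -1e-12))
    singles <- sapply(seq_along(ray$params), function(j)
      curve_effect(ray$params[[j]], ray$fractions[j] * grid))
    expect_true(all(e >= apply(singles, 1, max) - 1e-12))
  }
})

test_that("ec_ia inverts the IA surface", {
  single <- mixture_ray(list(czo_truth()), 1)
  expect_equal(ec_ia(single, 0.5), invert_curve(czo_truth(), 0.5),
               tolerance = 1e-9)
  set.seed(17)
  for (i in 1:10) {
    ray <- random_ray()
    sup <- 1 - prod(1 - vapply(ray$params, curve_max_effect, numeric(1)))
    x <- stats::runif(1, 0.1, min(0.9, sup - 0.05))
    ec <- ec_ia(ray, x)
    expect_equal(ia_effect(ray, ec), x, tolerance = 1e-9)
  }
  low <- mixture_ray(list(curve_params("hill", 0.3, 1e-4),
                          curve_params("hill", 0.3, 1e-4)), c(0.5, 0.5))
  expect_error(ec_ia(low, 0.6), "unattainable")
})

test_that("ec_ia agrees with a dense grid-search oracle", {
  set.seed(19)
  for (i in 1:20) {
    ray <- random_ray()
    xmax <- 1 - prod(1 - vapply(ray$params, curve_max_effect, numeric(1)))
    x <- stats::runif(1, 0.1, min(0.9, xmax - 0.05))
    ec <- ec_ia(ray, x)
    grid <- 10^seq(log10(ec) - 2, log10(ec) + 2, length.out = 1e6)
    oracle <- grid[which.max(ia_effect(ray, grid) >= x)]
    step <- grid[2] / grid[1]
    expect_lte(max(ec / oracle, oracle / ec), step)
  }
})

test_that("predicted_crcs columns are consistent and nondecreasing", {
  ray <- study_ray()
  grid <- 10^seq(-8, -2.5, length.out = 60)
  crc <- predicted_crcs(ray, grid)
  expect_true(all(diff(crc$effect_ca) >= -1e-12))
  expect_true(all(diff(crc$effect_ia) >= -1e-12))
  expect_lt(crc$effect_ca[1], 1e-3)
  expect_lt(crc$effect_ia[1], 1e-3)

  # identical components: CA curve equals the single-compound curve
  p <- amp_truth()
  ray_eq <- mixture_ray(list(p, p), c(0.4, 0.6))
  crc_eq <- predicted_crcs(ray_eq, grid)
  expect_equal(crc_eq$effect_ca, curve_effect(p, grid), tolerance = 1e-8)

  # spot-check E_CA against bisection on the CA relation
  cc <- 1.5e-4
  lo <- 1e-9; hi <- 1 - 1e-9
  while (hi - lo > 1e-13) {
    mid <- (lo + hi) / 2
    if (ec_ca(ray, mid) < cc) lo <- mid else hi <- mid
  }
  expect_equal(ca_effect(ray, cc), (lo + hi) / 2, tolerance = 1e-8)
})

test_that("design_ray builds the geometric fixed-ratio series", {
  d <- design_ray(1e-4, 3, 0.4, c(AMP = 0.2, CZO = 0.8))
  expect_equal(d$c_total, c(1e-4, 4e-5, 1.6e-5))
  expect_equal(d$AMP, c(2e-5, 8e-6, 3.2e-6))
  expect_equal(design_ray(5e-5, 1, 0.4, 1)$c_total, 5e-5)
  d7 <- design_ray(2.73e-4, 7, 0.4, 1)
  expect_equal(d7$c_total[7], 2.73e-4 * 0.4^6)
  expect_error(design_ray(1e-4, 3, 1.2, 1), "dilution")
  expect_error(design_ray(1e-4, 3, 0.4, c(0.5, 0.4)), "sum to 1")
})

test_that("mixture_ray validates fractions and supports toxic-unit ratios", {
  expect_error(mixture_ray(list(amp_truth(), czo_truth()), c(0.5, 0.6)),
               "sum to 1")
  expect_error(mixture_ray(list(amp_truth(), czo_truth()), c(1.2, -0.2)),
               "\\(0, 1\\]")
  # equal toxic units at EC50 -> molar fractions proportional to the EC50s
  tu <- mixture_ray(list(AMP = amp_truth(), CZO = czo_truth()), c(0.5, 0.5),
                    fraction_type = "toxic_unit")
  ec50s <- c(invert_curve(amp_truth(), 0.5), invert_curve(czo_truth(), 0.5))
  expect_equal(tu$fractions, ec50s / sum(ec50s))
})
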