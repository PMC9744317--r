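# Path model: equation-level estimation, mediation decomposition, nested
# confounding, cluster bootstrap.

test_that("fit_equation reproduces exact and oracle solutions", {
  # y identical to x: unit slope, no residual variance
  d <- data.frame(y = 1:10 / 3, x = 1:10 / 3, cl = rep(1:5, each = 2))
  f <- fit_equation(d, "y", "x", "cl")
  expect_equal(unname(f$coefficients["x"]), 1, tolerance = 1e-12)
  expect_lt(var(f$residuals), 1e-20)

  # normal-equations oracle on random data
  set.seed(301)
  n <- 80
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
  d2 <- data.frame(y = rnorm(n), X, cl = rep(1:20, each = 4))
  f2 <- fit_equation(d2, "y", paste0("x", 1:4), "cl")
  expect_equal(unname(f2$coefficients), unname(ols_oracle(d2$y, X)),
               tolerance = 1e-10)

  expect_error(fit_equation(cbind(d2, x5 = d2$x1), "y",
                            c(paste0("x", 1:4), "x5"), "cl"),
               "rank-deficient")
  d3 <- d2; d3$cl <- seq_len(n)
  expect_error(fit_equation(d3, "y", "x1", "cl"), "singleton")
})

test_that("cluster-robust covariance matches a hand-assembled sandwich", {
  set.seed(302)
  n <- 12
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("x1", "x2")))
  cl <- rep(1:3, each = 4)
  d <- data.frame(y = rnorm(n), X, cl = cl)
  f <- fit_equation(d, "y", c("x1", "x2"), "cl")
  expect_equal(unname(f$vcov), unname(sandwich_oracle(d$y, X, cl)),
               tolerance = 1e-12)
  # independent cross-check against the sandwich package's estimator
  lmf <- lm(y ~ x1 + x2, d)
  expect_equal(unname(f$vcov),
               unname(sandwich::vcovCL(lmf, cluster = cl, type = "HC1")),
               tolerance = 1e-10)
})

test_that("total effect equals direct plus indirect under common controls", {
  for (s in c(31, 32)) {
    pr <- prepare_cohort(simulate_cohort(small_config(s)))
    fit <- fit_path_model(pr, path_spec(control_placement = "common"))
    dec <- decompose_effects(fit)
    expect_equal(dec$total, dec$reduced_form, tolerance = 1e-8)
  }
})

test_that("an orthogonalized noise mediator leaves other coefficients untouched", {
  pr <- prepare_cohort(simulate_cohort(small_config(33)))
  spec <- path_spec()
  other <- cbind(1, as.matrix(pr[c(spec$focal, spec$mediators[c("school", "leisure")],
                                   spec$controls)]))
  noise <- rnorm(nrow(pr))
  pr$pgs <- standardize(as.numeric(noise - other %*% qr.coef(qr(other), noise)))
  ns <- fit_nested_suite(pr, spec)
  expect_equal(ns$M3$b[["school"]], ns$M1$b[["school"]], tolerance = 1e-10)
  expect_equal(ns$M3$b[["leisure"]], ns$M1$b[["leisure"]], tolerance = 1e-10)
  expect_equal(ns$M3$direct, ns$M1$direct, tolerance = 1e-10)
})

test_that("no genetic confounding appears without a shared genetic cause", {
  pr <- prepare_cohort(simulate_cohort(
    scenario_config("no_rge", n_households = 1500, n_loci = 80, seed = 34)))
  ns <- fit_nested_suite(pr)
  # involvement coefficients barely move from M1 to M3
  shift <- abs(ns$M3$b[["school"]] - ns$M1$b[["school"]])
  expect_lt(shift, 3 * ns$M1$equations$outcome$se[["school_inv"]])
})

test_that("decomposition arithmetic follows the product-of-coefficients rule", {
  expect_equal(round(proportion_mediated(0.065, 0.303), 2), 21.45)
  expect_equal(round(proportion_mediated(0.007, 0.303), 1), 2.3)
  expect_equal(round(proportion_mediated(0.004, 0.303), 1), 1.3)
  expect_equal(proportion_mediated(0, 0.3), 0)
  expect_error(proportion_mediated(0.1, 0), "non-zero")

  expect_equal(round(confounding_percent(0.056, 0.050), 1), 10.7)
  expect_equal(round(confounding_percent(0.220, 0.219), 1), 0.5)
  expect_equal(confounding_percent(0.37, 0.37), 0)
  expect_error(confounding_percent(0, 0.1), "undefined")
})

test_that("proportions and percentages are invariant to affine input rescaling", {
  pr <- prepare_cohort(simulate_cohort(small_config(35)))
  ns1 <- fit_nested_suite(pr)
  dec1 <- decompose_effects(ns1$M3)
  # rescale raw inputs; prepare_cohort re-standardizes, so results must agree
  raw <- simulate_cohort(small_config(35))
  raw$pgs <- 3.7 * raw$pgs - 2
  raw$age <- raw$age / 10
  pr2 <- prepare_cohort(raw)
  ns2 <- fit_nested_suite(pr2)
  dec2 <- decompose_effects(ns2$M3)
  expect_equal(dec1$proportion_mediated, dec2$proportion_mediated,
               tolerance = 1e-8)
  expect_equal(ns1$confounding$percent_reduction,
               ns2$confounding$percent_reduction, tolerance = 1e-8)
})

test_that("cluster bootstrap is deterministic and degenerate-safe", {
  set.seed(303)
  d <- clustered_slope_data(120)
  b1 <- cluster_bootstrap(d, slope_stat, B = 200, seed = 77)
  b2 <- cluster_bootstrap(d, slope_stat, B = 200, seed = 77)
  expect_identical(b1$ci, b2$ci)
  b3 <- cluster_bootstrap(d, slope_stat, B = 200, seed = 78)
  expect_false(identical(b1$ci, b3$ci))

  const <- cluster_bootstrap(d, function(x) 1.5, B = 200, seed = 1)
  expect_equal(unname(const$ci["lower", 1]), 1.5)
  expect_equal(unname(const$ci["upper", 1]), 1.5)

  expect_error(cluster_bootstrap(d, slope_stat, B = 200), "seed")
  expect_error(cluster_bootstrap(d, slope_stat, B = 50, seed = 1), "at least 200")
})

test_that("bootstrap percentile intervals attain nominal coverage", {
  set.seed(304)
  true_slope <- 0.5
  covered <- logical(500)
  for (r in seq_len(500)) {
    d <- clustered_slope_data(200, slope = true_slope)
    ci <- cluster_bootstrap(d, slope_stat, B = 200, seed = r)$ci
    covered[r] <- ci["lower", 1] <= true_slope && true_slope <= ci["upper", 1]
  }
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})

test_that("indirect-effect intervals cover zero under the no-mediation null", {
  # null calibration across replicates, scaled down: the bootstrap interval
  # for the PGS indirect effect should cover 0 about 95% of the time
  set.seed(305)
  covered <- logical(40)
  for (r in seq_len(40)) {
    pr <- prepare_cohort(simulate_cohort(
      scenario_config("null", n_households = 250, n_loci = 40, seed = 4000 + r)))
    stat <- function(d) {
      a <- fit_equation(d, "pgs", c("father_edu", paste0("PC", 1:10)),
                        "household_id")$coefficients[["father_edu"]]
      b <- fit_equation(d, "child_edu",
                        c("father_edu", "school_inv", "leisure_inv", "pgs"),
                        "household_id")$coefficients[["pgs"]]
      a * b
    }
    ci <- cluster_bootstrap(pr, stat, B = 200, seed = r)$ci
    covered[r] <- ci["lower", 1] <= 0 && 0 <= ci["upper", 1]
  }
  expect_gte(mean(covered), 0.85)
})
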