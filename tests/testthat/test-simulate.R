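# Generator: config validation, Mendelian transmission, PGS, PCs,
# phenotype structure, determinism.

test_that("config validation rejects degenerate settings", {
  expect_error(sim_config(allele_freq_range = c(1 - 1e-16, 1 - 1e-16)),
               "strictly inside")
  expect_error(sim_config(allele_freq_range = c(0.9, 0.1)), "ordered")
  expect_error(sim_config(assortative_rho = 1), "assortative_rho")
  expect_error(sim_config(sibling_fraction = 1.2), "sibling_fraction")
  expect_error(sim_config(resid_child_edu_sd = 0), "residual SDs")
  expect_error(sim_config(stratification = TRUE, strat_divergence = 0.5,
                          allele_freq_range = c(0.1, 0.9)),
               "stay inside")
  # zero-width range away from the boundary is fine
  expect_s3_class(sim_config(allele_freq_range = c(0.5, 0.5)), "sim_config")
})

test_that("mean dosage per locus is twice the allele frequency", {
  set.seed(101)
  par <- simulate_parents(small_config(1, n_households = 1500,
                                       allele_freq_range = c(0.5, 0.5)))
  doses <- rbind(par$father_dosage, par$mother_dosage)
  expect_true(all(doses %in% 0:2))
  per_locus <- colMeans(doses)
  expect_lt(max(abs(per_locus - 1)), 0.07)      # ~5 MC SEs at n = 3,000
  expect_lt(abs(mean(per_locus) - 1), 0.01)
})

test_that("rank coupling achieves the target spousal correlation", {
  set.seed(102)
  p0 <- simulate_parents(small_config(1, n_households = 5000,
                                      assortative_rho = 0))
  r0 <- cor(p0$father_edu_latent, p0$mother_edu_latent)
  expect_lt(abs(r0), 2.5 / sqrt(5000))          # CI covers 0

  p5 <- simulate_parents(small_config(1, n_households = 5000,
                                      assortative_rho = 0.5))
  r5 <- cor(p5$father_edu_latent, p5$mother_edu_latent)
  expect_lt(abs(r5 - 0.5), 0.05)
})

test_that("transmission is Mendelian: certainty, sibling correlation, midparent mean", {
  cfg <- small_config(1, n_households = 300, n_loci = 10, sibling_fraction = 0)
  set.seed(103)
  par <- simulate_parents(cfg)
  # force homozygous parents at locus 1 (dosage 2) and locus 2 (dosage 0)
  par$father_dosage[, 1] <- 2L; par$mother_dosage[, 1] <- 2L
  par$father_dosage[, 2] <- 0L; par$mother_dosage[, 2] <- 0L
  kids <- mate_and_transmit(par, cfg)
  expect_true(all(kids$dosage[, 1] == 2L))
  expect_true(all(kids$dosage[, 2] == 0L))

  # unpaired parents rejected
  broken <- par; broken$mother_dosage <- broken$mother_dosage[-1, ]
  expect_error(mate_and_transmit(broken, cfg), "unpaired")

  # per-locus sibling dosage correlation ~ 1/2 under random mating
  cfg2 <- sim_config(n_households = 5000, sibling_fraction = 1, n_loci = 150,
                     assortative_rho = 0, seed = 1)
  set.seed(104)
  par2 <- simulate_parents(cfg2)
  kids2 <- mate_and_transmit(par2, cfg2)
  first <- kids2$dosage[kids2$birth_order == 1, ]
  second <- kids2$dosage[kids2$birth_order == 2, ]
  sib_cor <- vapply(seq_len(ncol(first)),
                    function(l) cor(first[, l], second[, l]), numeric(1))
  expect_lt(abs(mean(sib_cor) - 0.5), 0.03)

  # fair transmission: child PGS is midparent-unbiased
  pgs_child <- compute_pgs(kids2$dosage, par2$pgs_weights)
  midparent <- (compute_pgs(par2$father_dosage, par2$pgs_weights) +
                compute_pgs(par2$mother_dosage, par2$pgs_weights)) / 2
  diff <- pgs_child - midparent[kids2$household_id]
  ci <- t.test(diff)$conf.int
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("polygenic scores follow the weighted-sum contract", {
  d <- matrix(c(2L, 1L, 0L, 2L), 2, 2)
  expect_equal(compute_pgs(d, c(0, 0)), c(0, 0))
  expect_equal(compute_pgs(matrix(2L, 1, 1), 1), 2)
  expect_error(compute_pgs(d, c(1, 2, 3)), "mismatch")
  expect_equal(sd(compute_pgs(d, c(1, -1), scaling = "zscore")), 1)

  # Var(PGS) = sum_l 2 p (1-p) w^2 under HWE and linkage equilibrium
  set.seed(105)
  L <- 80; p <- runif(L, 0.2, 0.8); w <- rnorm(L)
  dose <- sapply(p, function(pp) rbinom(10000, 2, pp))
  v <- var(compute_pgs(dose, w))
  expect_lt(abs(v / sum(2 * p * (1 - p) * w^2) - 1), 0.05)
})

test_that("genetic PCs are centered, ordered, and detect structure only when present", {
  set.seed(106)
  dose <- sapply(runif(40, 0.2, 0.8), function(pp) rbinom(300, 2, pp))
  expect_equal(ncol(compute_genetic_pcs(dose, 0)), 0)
  expect_error(compute_genetic_pcs(dose, 200), "rank")
  pcs <- compute_genetic_pcs(dose, 5)
  expect_lt(max(abs(colMeans(pcs))), 1e-10)

  # homogeneous population: PC1 unrelated to a structureless phenotype
  co <- simulate_cohort(small_config(7, n_households = 800))
  expect_lt(abs(cor(co$PC1, recode_child_education(co$child_edu_label))),
            2.5 / sqrt(nrow(co)))

  # two-subpopulation mode: PC1 separates the labels almost perfectly
  co2 <- simulate_cohort(small_scenario("stratified_null", 7,
                                        n_households = 600))
  expect_gt(abs(cor(co2$PC1, co2$subpop)), 0.9)
})

test_that("cohorts are seed-deterministic and respect scale ranges", {
  cfg <- small_config(9, n_households = 150, n_loci = 40)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  expect_false(identical(simulate_cohort(cfg),
                         simulate_cohort(small_config(10, n_households = 150,
                                                      n_loci = 40))))

  for (scen in c("passive", "evocative", "null")) {
    co <- simulate_cohort(small_scenario(scen, 3))
    school <- rowSums(co[paste0("father_school_", 1:3)])
    leisure <- rowSums(co[paste0("father_leisure_", 1:5)])
    expect_true(all(school %in% 0:3))
    expect_true(all(leisure %in% 0:5))
    expect_true(all(co$mother_school %in% 0:3))
    expect_true(all(co$mother_leisure %in% 0:5))
  }

  # sibling bookkeeping: the configured fraction of households has 2 children
  co <- simulate_cohort(small_config(4, n_households = 1000,
                                     sibling_fraction = 0.25))
  sizes <- table(co$household_id)
  expect_equal(sum(sizes == 2), 250)
  expect_true(all(sizes <= 2))
})

test_that("phenotypes are pure noise when all structural effects are zero", {
  co <- simulate_cohort(scenario_config("null", n_households = 1200,
                                        n_loci = 60, seed = 12))
  yrs <- recode_child_education(co$child_edu_label)
  ct <- cor.test(yrs, co$pgs)
  expect_true(ct$conf.int[1] < 0 && ct$conf.int[2] > 0)
})

test_that("passive and evocative modes leave their fingerprints", {
  # passive: between-family association without a within-family one
  pr <- prepare_cohort(simulate_cohort(
    scenario_config("passive", n_households = 2000, n_loci = 100, seed = 21,
                    sibling_fraction = 0.2)))
  bf <- between_family_rge(pr)
  wf <- within_family_rge(pr)
  expect_gt(bf$beta[bf$scale == "school"] /
            bf$se[bf$scale == "school"], 2)
  expect_true(wf$ci_lower[wf$scale == "school"] < 0 &&
              wf$ci_upper[wf$scale == "school"] > 0)

  # evocative: the child-driven path survives family differencing
  pr2 <- prepare_cohort(simulate_cohort(
    scenario_config("evocative", n_households = 2000, n_loci = 100, seed = 22,
                    sibling_fraction = 0.2)))
  wf2 <- within_family_rge(pr2)
  expect_gt(wf2$ci_lower[wf2$scale == "school"], 0)
})

test_that("PC adjustment removes stratification-induced PGS inflation", {
  pr <- prepare_cohort(simulate_cohort(
    scenario_config("stratified_null", n_households = 1500, n_loci = 100,
                    seed = 23)))
  naive <- fit_equation(pr, "child_edu", "pgs", "household_id")
  adj <- fit_equation(pr, "child_edu", c("pgs", paste0("PC", 1:10)),
                      "household_id")
  z_naive <- naive$coefficients["pgs"] / naive$se["pgs"]
  z_adj <- adj$coefficients["pgs"] / adj$se["pgs"]
  expect_gt(abs(z_naive), 3)
  expect_lt(abs(z_adj), 2.5)
})

test_that("cohort tables round-trip through the delimited writer", {
  co <- simulate_cohort(small_config(5, n_households = 60, n_loci = 20))
  path <- tempfile(fileext = ".tsv")
  write_cohort(co, path)
  back <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(co))
  expect_equal(back$pgs, co$pgs, tolerance = 1e-12)
  meta <- jsonlite::fromJSON(paste0(path, ".meta.json"))
  expect_equal(meta$seed, 5)
  unlink(c(path, paste0(path, ".meta.json")))
})
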