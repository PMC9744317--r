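# Family-structured cohort simulator: genotypes, Mendelian transmission,
# polygenic scores, ancestry PCs, and phenotypes with switchable passive /
# evocative gene-environment correlation, assortative mating and
# two-subpopulation stratification.

# Year values and canonical labels used when the generator discretizes the
# latent education score into survey response categories.
.parent_edu_levels <- data.frame(
  years = c(0L, 8L, 10L, 12L, 14L, 16L, 18L),
  label = c("never went to school",
            "8th grade or less",
            "more than eighth grade, but did not graduate from high school",
            "high school graduate",
            "went to college, but did not graduate",
            "graduated from a college or university",
            "professional training beyond a four-year college or university"),
  stringsAsFactors = FALSE
)
# cumulative probabilities of the categories on the latent N(0,1) scale,
# chosen so the marginal mean lands near 13.5 years
.parent_edu_cum <- c(0.002, 0.020, 0.100, 0.420, 0.680, 0.910)

.child_edu_levels <- data.frame(
  years = c(8L, 10L, 12L, 13L, 14L, 16L, 17L, 18L, 19L, 20L),
  label = c("8th grade or less",
            "some high school",
            "high school graduate",
            "some vocational/technical training",
            "some college",
            "completed college",
            "some graduate school",
            "completed a master's degree",
            "some graduate training beyond a master's degree",
            "completed a doctoral degree"),
  stringsAsFactors = FALSE
)
.child_edu_cum <- c(0.010, 0.050, 0.230, 0.290, 0.530, 0.780, 0.830, 0.930, 0.970)

.discretize_edu <- function(latent, levels, cum) {
  idx <- findInterval(latent, stats::qnorm(cum)) + 1L
  levels$label[idx]
}

#' Simulation configuration
#'
#' Build and validate the configuration of the family-cohort generator.  The
#' defaults describe the reference scenario the package's analyses are
#' calibrated against: 4,000 households of which 10% contribute a sibling
#' pair, 200 independent loci, moderate assortative mating, passive
#' gene-environment correlation (father's polygenic score raises his
#' involvement) and no evocative path.
#'
#' Effect sizes on involvement items are on the logit scale; effects on the
#' latent (standardized) education scores are in SD units.
#'
#' @param n_households Number of households (one father, one mother, 1-2
#'   genotyped children each).
#' @param sibling_fraction Proportion of households contributing exactly two
#'   children.
#' @param n_loci Number of independent biallelic loci.
#' @param allele_freq_range Interval strictly inside (0, 1) from which base
#'   allele frequencies are drawn (may be zero-width away from the
#'   boundaries).
#' @param pgs_weight_sd SD of the Gaussian per-locus additive weights.
#' @param b_parent_pgs_edu Effect of a parent's standardized PGS on their
#'   latent education.
#' @param assortative_rho Target spousal correlation (in `[0, 1)`) of latent
#'   education, achieved by rank-based coupling.
#' @param b_father_edu_school,b_father_edu_leisure Logit effect of father's
#'   latent education on each school / leisure involvement item.
#' @param b_passive_school,b_passive_leisure Logit effect of the *father's*
#'   PGS on involvement items (passive rGE).
#' @param b_evocative_school,b_evocative_leisure Logit effect of the
#'   *child's* PGS on involvement items (evocative/active rGE).
#' @param b_father_edu_child,b_mother_edu_child Direct effects of parental
#'   latent education on the child's latent education.
#' @param b_pgs_child Effect of the child's standardized PGS on their latent
#'   education.
#' @param b_school_child,b_leisure_child Effect per involvement item count
#'   (centered) on the child's latent education.
#' @param b_mother_edu_minv Logit effect of mother's latent education on her
#'   involvement items.
#' @param b_mother_school_child,b_mother_leisure_child Effects of mother's
#'   involvement counts on the child's latent education.
#' @param b_female_child,b_father_resident_child Control-variable effects on
#'   the child's latent education.
#' @param stratification Logical; two-subpopulation mode.
#' @param strat_divergence Absolute allele-frequency difference between the
#'   two subpopulations at every locus.
#' @param strat_edu_shift Total latent-education shift between the two
#'   subpopulations (split symmetrically).
#' @param household_intercept_sd SD of the household intercept on the
#'   child-education equation.
#' @param involvement_hh_sd SD of the household intercept on the involvement
#'   item logits.
#' @param resid_parent_edu_sd,resid_child_edu_sd Residual SDs of the latent
#'   education equations.
#' @param n_pcs Number of genetic principal components carried in the
#'   cohort table.
#' @param seed Integer seed; identical config and seed give a byte-identical
#'   cohort.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()], [scenario_config()]
#' @export
sim_config <- function(n_households = 4000,
                       sibling_fraction = 0.10,
                       n_loci = 200,
                       allele_freq_range = c(0.1, 0.9),
                       pgs_weight_sd = 1,
                       b_parent_pgs_edu = 0.4,
                       assortative_rho = 0.3,
                       b_father_edu_school = 0.30,
                       b_father_edu_leisure = 0.25,
                       b_passive_school = 0.25,
                       b_passive_leisure = 0.15,
                       b_evocative_school = 0,
                       b_evocative_leisure = 0,
                       b_father_edu_child = 0.18,
                       b_mother_edu_child = 0.15,
                       b_pgs_child = 0.25,
                       b_school_child = 0.05,
                       b_leisure_child = 0.03,
                       b_mother_edu_minv = 0.30,
                       b_mother_school_child = 0.02,
                       b_mother_leisure_child = 0.02,
                       b_female_child = 0.10,
                       b_father_resident_child = 0.10,
                       stratification = FALSE,
                       strat_divergence = 0.2,
                       strat_edu_shift = 0.5,
                       household_intercept_sd = 0.2,
                       involvement_hh_sd = 0.4,
                       resid_parent_edu_sd = sqrt(1 - 0.4^2),
                       resid_child_edu_sd = 0.8,
                       n_pcs = 10,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config A `sim_config` object to validate.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with(config, {
    if (!is.numeric(n_households) || n_households < 1)
      stop("n_households must be a positive count")
    if (sibling_fraction < 0 || sibling_fraction > 1)
      stop("sibling_fraction must be in [0, 1]")
    if (n_loci < 1) stop("n_loci must be a positive count")
    if (length(allele_freq_range) != 2 || any(!is.finite(allele_freq_range)))
      stop("allele_freq_range must be two finite numbers")
    lo <- allele_freq_range[1]; hi <- allele_freq_range[2]
    if (lo > hi) stop("allele_freq_range must be ordered")
    if (lo <= 0.001 || hi >= 0.999)
      stop("allele_freq_range must lie strictly inside (0, 1); ",
           "boundary or degenerate frequencies are rejected")
    if (stratification) {
      if (strat_divergence <= 0 || strat_divergence >= 1)
        stop("strat_divergence must be in (0, 1)")
      if (lo - strat_divergence / 2 <= 0 || hi + strat_divergence / 2 >= 1)
        stop("allele_freq_range +/- strat_divergence/2 must stay inside (0, 1)")
    }
    if (assortative_rho < 0 || assortative_rho >= 1)
      stop("assortative_rho must be in [0, 1)")
    effs <- c(b_parent_pgs_edu, b_father_edu_school, b_father_edu_leisure,
              b_passive_school, b_passive_leisure, b_evocative_school,
              b_evocative_leisure, b_father_edu_child, b_mother_edu_child,
              b_pgs_child, b_school_child, b_leisure_child, b_mother_edu_minv,
              b_mother_school_child, b_mother_leisure_child,
              b_female_child, b_father_resident_child)
    if (any(!is.finite(effs))) stop("all effect sizes must be finite")
    if (household_intercept_sd < 0 || involvement_hh_sd < 0)
      stop("household intercept SDs must be >= 0")
    if (resid_parent_edu_sd <= 0 || resid_child_edu_sd <= 0)
      stop("residual SDs must be > 0")
    if (n_pcs < 0) stop("n_pcs must be >= 0")
    if (length(seed) != 1 || is.na(seed)) stop("seed is mandatory")
  })
  invisible(config)
}

#' Named demonstration scenarios
#'
#' Preset configurations for the hypotheses the package's analyses are
#' designed to discriminate:
#' \describe{
#'   \item{passive}{the reference scenario (the defaults): father's PGS
#'     raises his involvement, no evocative path.}
#'   \item{evocative}{the child's PGS elicits father involvement; no
#'     passive path.}
#'   \item{no_rge}{mediation paths present but neither rGE path.}
#'   \item{null}{all structural paths zero (pure noise phenotypes).}
#'   \item{stratified_null}{two-subpopulation stratification shifts both
#'     allele frequencies and education, but no phenotypic PGS effect:
#'     any PGS-education association is spurious.}
#' }
#'
#' @param name Scenario name.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
scenario_config <- function(name = c("passive", "evocative", "no_rge",
                                     "null", "stratified_null"),
                            ...) {
  name <- match.arg(name)
  over <- list(...)
  base <- switch(name,
    passive = list(),
    evocative = list(b_passive_school = 0, b_passive_leisure = 0,
                     b_evocative_school = 0.30, b_evocative_leisure = 0.30),
    no_rge = list(b_passive_school = 0, b_passive_leisure = 0,
                  b_evocative_school = 0, b_evocative_leisure = 0),
    null = list(b_parent_pgs_edu = 0, b_father_edu_school = 0,
                b_father_edu_leisure = 0, b_passive_school = 0,
                b_passive_leisure = 0, b_evocative_school = 0,
                b_evocative_leisure = 0, b_father_edu_child = 0,
                b_mother_edu_child = 0, b_pgs_child = 0,
                b_school_child = 0, b_leisure_child = 0,
                b_mother_school_child = 0, b_mother_leisure_child = 0,
                b_female_child = 0, b_father_resident_child = 0,
                assortative_rho = 0),
    stratified_null = list(b_parent_pgs_edu = 0, b_passive_school = 0,
                           b_passive_leisure = 0, b_evocative_school = 0,
                           b_evocative_leisure = 0, b_pgs_child = 0,
                           stratification = TRUE,
                           allele_freq_range = c(0.2, 0.8))
  )
  base[names(over)] <- over
  do.call(sim_config, base)
}

.draw_genotypes <- function(n, p) {
  # n persons x length(p) loci, dosages Binomial(2, p_l)
  L <- length(p)
  matrix(stats::rbinom(n * L, 2L, rep(p, each = n)), nrow = n, ncol = L)
}

#' Simulate the parent generation
#'
#' Draws paired parental genotypes, polygenic scores and latent education
#' scores.  Under two-subpopulation stratification each household belongs to
#' one subpopulation and both spouses' genotypes are drawn from its allele
#' frequencies.  Spouses are coupled by ranks so that the realized spousal
#' correlation of latent education approximates `assortative_rho`.
#'
#' @param config A [sim_config()].
#' @return A list of class `parent_panel` with father/mother dosage
#'   matrices, allele frequencies, PGS weights, standardized parental PGS,
#'   latent education scores and subpopulation labels.
#' @export
simulate_parents <- function(config) {
  validate_sim_config(config)
  n <- config$n_households
  L <- config$n_loci
  rng <- config$allele_freq_range
  p_base <- stats::runif(L, rng[1], rng[2])
  weights <- stats::rnorm(L, 0, config$pgs_weight_sd)

  if (config$stratification) {
    subpop <- rep_len(c(1L, 2L), n)
    sign_l <- sample(c(-1, 1), L, replace = TRUE)
    d <- config$strat_divergence / 2
    p1 <- p_base + sign_l * d
    p2 <- p_base - sign_l * d
    dose_f <- matrix(0L, n, L); dose_m <- matrix(0L, n, L)
    for (s in 1:2) {
      idx <- which(subpop == s)
      ps <- if (s == 1) p1 else p2
      dose_f[idx, ] <- .draw_genotypes(length(idx), ps)
      dose_m[idx, ] <- .draw_genotypes(length(idx), ps)
    }
  } else {
    subpop <- NULL
    dose_f <- .draw_genotypes(n, p_base)
    dose_m <- .draw_genotypes(n, p_base)
  }

  pgs_f <- compute_pgs(dose_f, weights)
  pgs_m <- compute_pgs(dose_m, weights)
  mu <- mean(c(pgs_f, pgs_m)); sdv <- stats::sd(c(pgs_f, pgs_m))
  pgs_f_z <- (pgs_f - mu) / sdv
  pgs_m_z <- (pgs_m - mu) / sdv

  shift <- if (config$stratification)
    ifelse(subpop == 1L, 1, -1) * config$strat_edu_shift / 2 else 0
  edu_f <- config$b_parent_pgs_edu * pgs_f_z + shift +
    stats::rnorm(n, 0, config$resid_parent_edu_sd)
  edu_m_raw <- config$b_parent_pgs_edu * pgs_m_z + shift +
    stats::rnorm(n, 0, config$resid_parent_edu_sd)

  # assortative mating: within each subpopulation, re-pair mothers so that
  # mother latent education ranks follow a noisy copy of the father's
  perm <- seq_len(n)
  strata <- if (is.null(subpop)) list(seq_len(n)) else split(seq_len(n), subpop)
  rho <- config$assortative_rho
  for (idx in strata) {
    zf <- as.numeric(scale(edu_f[idx]))
    target <- rho * zf + sqrt(1 - rho^2) * stats::rnorm(length(idx))
    # mother (within stratum) sorted by latent education, matched to the
    # rank of the father's target score
    perm[idx] <- idx[order(edu_m_raw[idx])][rank(target, ties.method = "first")]
  }
  dose_m <- dose_m[perm, , drop = FALSE]
  pgs_m_z <- pgs_m_z[perm]
  edu_m <- edu_m_raw[perm]

  structure(list(
    n_households = n,
    father_dosage = dose_f, mother_dosage = dose_m,
    allele_freq = p_base, pgs_weights = weights,
    father_pgs_z = pgs_f_z, mother_pgs_z = pgs_m_z,
    father_edu_latent = edu_f, mother_edu_latent = edu_m,
    subpop = subpop, config = config
  ), class = "parent_panel")
}

#' Mendelian transmission to children
#'
#' Each child receives, independently at every locus, one allele drawn
#' uniformly from each parent's two alleles (a Binomial(1, dosage/2) draw
#' per parent), so sibling genotypes are conditionally independent given the
#' parents.  A `sibling_fraction` share of households receives exactly two
#' children.
#'
#' @param parents A `parent_panel` from [simulate_parents()].
#' @param config The same [sim_config()].
#' @return A list of class `child_panel` with the child dosage matrix,
#'   `household_id`, `person_id`, and a `sibling` flag.
#' @export
mate_and_transmit <- function(parents, config) {
  stopifnot(inherits(parents, "parent_panel"))
  n <- parents$n_households
  if (nrow(parents$father_dosage) != n || nrow(parents$mother_dosage) != n)
    stop("unpaired parent rows: father and mother panels must both have one row per household")
  n_sib <- round(config$sibling_fraction * n)
  sib_households <- sort(sample.int(n, n_sib))
  hh_of_child <- c(seq_len(n), sib_households)          # first-borns then seconds
  ord <- order(hh_of_child)
  hh_of_child <- hh_of_child[ord]
  nc <- length(hh_of_child)
  L <- config$n_loci

  Fd <- parents$father_dosage[hh_of_child, , drop = FALSE]
  Md <- parents$mother_dosage[hh_of_child, , drop = FALSE]
  from_f <- matrix(stats::rbinom(nc * L, 1L, Fd / 2), nc, L)
  from_m <- matrix(stats::rbinom(nc * L, 1L, Md / 2), nc, L)
  dosage <- from_f + from_m

  birth_order <- stats::ave(hh_of_child, hh_of_child, FUN = seq_along)
  structure(list(
    dosage = dosage,
    household_id = hh_of_child,
    birth_order = birth_order,
    person_id = sprintf("H%06d_C%d", hh_of_child, birth_order),
    sibling = hh_of_child %in% sib_households,
    config = config
  ), class = "child_panel")
}

#' Polygenic score from a dosage matrix
#'
#' Raw score is the weighted allele-dosage sum `sum_l w_l d_l`; `"zscore"`
#' standardizes within the supplied panel.
#'
#' @param dosage Person x locus dosage matrix (values 0/1/2).
#' @param weights Per-locus additive weights, length `ncol(dosage)`.
#' @param scaling `"none"` (raw) or `"zscore"`.
#' @return Numeric vector of scores, one per row.
#' @export
compute_pgs <- function(dosage, weights, scaling = c("none", "zscore")) {
  scaling <- match.arg(scaling)
  dosage <- as.matrix(dosage)
  if (length(weights) != ncol(dosage))
    stop(sprintf("weight/locus length mismatch: %d weights for %d loci",
                 length(weights), ncol(dosage)))
  score <- as.numeric(dosage %*% weights)
  if (scaling == "zscore") score <- standardize(score)
  score
}

#' Genetic principal components
#'
#' Columns of the dosage matrix are centered at twice the sample allele
#' frequency and scaled by `sqrt(2 p (1 - p))` before eigendecomposition;
#' zero-variance loci are dropped.  Component scores have mean zero and are
#' ordered by decreasing eigenvalue.
#'
#' @param dosage Person x locus dosage matrix.
#' @param k Number of components (0 gives an empty block).
#' @return n x k matrix of PC scores with columns `PC1..PCk`.
#' @export
compute_genetic_pcs <- function(dosage, k) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  if (k == 0) return(matrix(numeric(0), n, 0))
  p_hat <- colMeans(dosage) / 2
  keep <- p_hat > 0 & p_hat < 1
  X <- dosage[, keep, drop = FALSE]
  p <- p_hat[keep]
  if (k > min(n, ncol(X)))
    stop("k exceeds the available rank of the genotype matrix")
  Xs <- sweep(X, 2, 2 * p)
  Xs <- sweep(Xs, 2, sqrt(2 * p * (1 - p)), "/")
  eg <- eigen(crossprod(Xs) / n, symmetric = TRUE)
  scores <- Xs %*% eg$vectors[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

.bernoulli_items <- function(n_items, linpred, prefix) {
  n <- length(linpred)
  items <- matrix(stats::rbinom(n * n_items, 1L,
                                rep(stats::plogis(linpred), n_items)),
                  n, n_items)
  colnames(items) <- paste0(prefix, seq_len(n_items))
  items
}

# item intercepts set so marginal item means land near the reference
# sample's scale means (school 1.16/3, leisure 1.44/5; mother 1.32/3, 2.08/5)
.item_intercepts <- c(father_school = -0.46, father_leisure = -0.90,
                      mother_school = -0.24, mother_leisure = -0.34)

#' Simulate phenotypes onto a genotyped family cohort
#'
#' Generates parental education category labels (latent score thresholded
#' onto the survey categories), father involvement items as
#' Bernoulli-logistic draws with optional passive (father-PGS) and
#' evocative (child-PGS) paths, mother involvement scale counts, controls,
#' and the child's education label from a linear latent equation with a
#' Gaussian household intercept.
#'
#' @param parents `parent_panel` from [simulate_parents()].
#' @param children `child_panel` from [mate_and_transmit()].
#' @param config The same [sim_config()].
#' @return A `cohort_table` data frame (one row per child) with household
#'   and person identifiers, education labels, involvement items, mother
#'   involvement counts, standardized PGS, genetic PCs and controls.  The
#'   generative latent variables are attached as `attr(, "truth")`.
#' @export
simulate_phenotypes <- function(parents, children, config) {
  stopifnot(inherits(parents, "parent_panel"), inherits(children, "child_panel"))
  hh <- children$household_id
  nc <- length(hh)
  n <- parents$n_households

  pgs_raw <- compute_pgs(children$dosage, parents$pgs_weights)
  pgs_z <- standardize(pgs_raw)
  pcs <- compute_genetic_pcs(children$dosage, config$n_pcs)

  edu_f <- parents$father_edu_latent[hh]
  edu_m <- parents$mother_edu_latent[hh]
  f_pgs <- parents$father_pgs_z[hh]

  u_inv <- stats::rnorm(n, 0, config$involvement_hh_sd)[hh]
  lp_school <- .item_intercepts["father_school"] +
    config$b_father_edu_school * edu_f +
    config$b_passive_school * f_pgs +
    config$b_evocative_school * pgs_z + u_inv
  lp_leisure <- .item_intercepts["father_leisure"] +
    config$b_father_edu_leisure * edu_f +
    config$b_passive_leisure * f_pgs +
    config$b_evocative_leisure * pgs_z + u_inv
  school_items <- .bernoulli_items(3, lp_school, "father_school_")
  leisure_items <- .bernoulli_items(5, lp_leisure, "father_leisure_")
  school <- rowSums(school_items)
  leisure <- rowSums(leisure_items)

  u_minv <- stats::rnorm(n, 0, config$involvement_hh_sd)[hh]
  m_school <- rowSums(.bernoulli_items(
    3, .item_intercepts["mother_school"] +
      config$b_mother_edu_minv * edu_m + u_minv, "ms"))
  m_leisure <- rowSums(.bernoulli_items(
    5, .item_intercepts["mother_leisure"] +
      config$b_mother_edu_minv * edu_m + u_minv, "ml"))

  age <- pmin(pmax(stats::rnorm(nc, 16, 1.7), 12), 21)
  female <- stats::rbinom(nc, 1L, 0.5)
  father_resident <- stats::rbinom(n, 1L, 0.75)[hh]
  mother_resident <- stats::rbinom(n, 1L, 0.91)[hh]
  enrolled <- stats::rbinom(nc, 1L, 0.08)

  shift <- if (config$stratification)
    ifelse(parents$subpop[hh] == 1L, 1, -1) * config$strat_edu_shift / 2 else 0
  u_edu <- stats::rnorm(n, 0, config$household_intercept_sd)[hh]
  edu_c <- config$b_father_edu_child * edu_f +
    config$b_mother_edu_child * edu_m +
    config$b_school_child * (school - mean(school)) +
    config$b_leisure_child * (leisure - mean(leisure)) +
    config$b_pgs_child * pgs_z +
    config$b_mother_school_child * (m_school - mean(m_school)) +
    config$b_mother_leisure_child * (m_leisure - mean(m_leisure)) +
    config$b_female_child * (female - 0.5) +
    config$b_father_resident_child * (father_resident - 0.75) +
    shift + u_edu + stats::rnorm(nc, 0, config$resid_child_edu_sd)

  out <- data.frame(
    household_id = hh,
    person_id = children$person_id,
    sibling = children$sibling,
    child_edu_label = .discretize_edu(edu_c, .child_edu_levels, .child_edu_cum),
    father_edu_label = .discretize_edu(edu_f, .parent_edu_levels, .parent_edu_cum),
    mother_edu_label = .discretize_edu(edu_m, .parent_edu_levels, .parent_edu_cum),
    school_items, leisure_items,
    mother_school = m_school, mother_leisure = m_leisure,
    pgs = pgs_z,
    age = age, female = female,
    father_resident = father_resident, mother_resident = mother_resident,
    enrolled = enrolled,
    stringsAsFactors = FALSE
  )
  if (config$n_pcs > 0) out <- cbind(out, as.data.frame(pcs))
  if (config$stratification) out$subpop <- parents$subpop[hh]

  attr(out, "truth") <- data.frame(
    father_edu_latent = edu_f, mother_edu_latent = edu_m,
    father_pgs_z = f_pgs, child_edu_latent = edu_c,
    child_pgs_raw = pgs_raw
  )
  attr(out, "config") <- config
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Simulate a complete family cohort
#'
#' Runs the full generative chain (parents, Mendelian transmission,
#' polygenic scores, genetic PCs, phenotypes) behind the single seed in the
#' configuration.  Identical configuration and seed give a byte-identical
#' cohort.
#'
#' @param config A [sim_config()] or [scenario_config()].
#' @return A `cohort_table` data frame; see [simulate_phenotypes()].
#' @examples
#' cfg <- sim_config(n_households = 200, n_loci = 50, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' table(cohort$sibling)
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  parents <- simulate_parents(config)
  children <- mate_and_transmit(parents, config)
  simulate_phenotypes(parents, children, config)
}

#' @export
print.cohort_table <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Simulated family cohort: %d children in %d households (%d sibling pairs)\n",
              nrow(x), length(unique(x$household_id)), sum(x$sibling) %/% 2))
  if (!is.null(cfg))
    cat(sprintf("  loci: %d, seed: %s, stratified: %s\n",
                cfg$n_loci, format(cfg$seed), cfg$stratification))
  NextMethod()
}

#' Write a cohort table to a delimited text file
#'
#' Tab-delimited UTF-8 with a header row; the seed and scenario parameters
#' travel in a sidecar JSON metadata file next to the table.
#'
#' @param cohort A `cohort_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t",
                     row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  cfg <- attr(cohort, "config")
  if (!is.null(cfg)) {
    meta <- unclass(cfg)
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
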