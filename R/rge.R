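# Gene-environment correlation three ways: residual-based correlated
# effects, between-family random-intercept association with PC control,
# within-family sibling-difference correlation.

#' Fisher-z confidence interval for a Pearson correlation
#'
#' @param r Correlation estimate.
#' @param n Number of observation pairs (must exceed 3).
#' @param conf Confidence level.
#' @return Numeric vector `c(lower, upper)`.
#' @export
fisher_z_ci <- function(r, n, conf = 0.95) {
  if (n <= 3) stop("Fisher-z interval needs n > 3")
  z <- atanh(r)
  half <- stats::qnorm(1 - (1 - conf) / 2) / sqrt(n - 3)
  tanh(c(lower = z - half, upper = z + half))
}

#' Two-level random-intercept linear model by REML
#'
#' Fits `y = X b + u_g + e` with `u_g ~ N(0, sigma_b^2)` and
#' `e ~ N(0, sigma_e^2)` by restricted maximum likelihood, profiling the
#' fixed effects and residual variance and optimizing the single variance
#' ratio `psi = sigma_b^2 / sigma_e^2` numerically to high precision.  A
#' boundary estimate (`sigma_b^2 = 0`) is allowed and flagged.
#'
#' @param y Numeric response.
#' @param X Numeric design matrix (an intercept column is added).
#' @param groups Grouping factor (e.g. household); at least 2 groups.
#' @param tol Convergence tolerance on the variance ratio.
#' @return Object of class `ri_fit`: `coefficients`, `se`, `vcov`,
#'   `sigma_b2`, `sigma_e2`, `icc`, `psi`, `reml_loglik`, `boundary`, `n`,
#'   `n_groups`, and the per-observation `fitted` and conditional
#'   `residuals` (fixed part minus the BLUP of the group intercept).
#' @export
fit_random_intercept <- function(y, X, groups, tol = 1e-10) {
  X <- as.matrix(X)
  if (ncol(X) > 0 && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  X <- if (ncol(X) > 0) cbind(`(Intercept)` = 1, X) else
    matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  n <- length(y)
  if (nrow(X) != n || length(groups) != n) stop("dimension mismatch")
  if (anyNA(y) || anyNA(X)) stop("missing values not supported")
  g <- factor(groups)
  G <- nlevels(g)
  if (G < 2) stop("need at least 2 groups")
  p <- ncol(X)

  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)
  S <- rowsum(X, g)                 # G x p group sums of X
  t_g <- rowsum(y, g)[, 1]          # group sums of y
  n_g <- tabulate(g)

  # REML criterion (-2 log restricted likelihood, up to an additive
  # constant) as a function of psi, with sigma_e^2 profiled out
  crit <- function(psi) {
    c_g <- psi / (1 + n_g * psi)
    A <- XtX - crossprod(S, c_g * S)
    u <- Xty - crossprod(S, c_g * t_g)
    R <- chol(A)
    beta <- backsolve(R, backsolve(R, u, transpose = TRUE))
    q <- yty - sum(c_g * t_g^2) - sum(u * beta)
    s2 <- q / (n - p)
    val <- (n - p) * log(s2) + sum(log1p(n_g * psi)) + 2 * sum(log(diag(R)))
    list(value = val, beta = beta, s2 = s2, A = A)
  }
  f <- function(psi) crit(psi)$value

  # analytic derivative of the REML criterion in psi, used to polish the
  # golden-section minimum to near machine precision
  score <- function(psi) {
    c_g <- psi / (1 + n_g * psi)
    cp_g <- 1 / (1 + n_g * psi)^2
    A <- XtX - crossprod(S, c_g * S)
    u <- Xty - crossprod(S, c_g * t_g)
    R <- chol(A)
    beta <- backsolve(R, backsolve(R, u, transpose = TRUE))
    q <- yty - sum(c_g * t_g^2) - sum(u * beta)
    du <- -crossprod(S, cp_g * t_g)
    dq <- -sum(cp_g * t_g^2) - (2 * sum(du * beta) +
                                  sum(beta * (crossprod(S, cp_g * S) %*% beta)))
    W <- backsolve(R, t(S), transpose = TRUE)      # R^-T S'
    dlogdet <- -sum(cp_g * colSums(W^2))
    (n - p) * dq / q + sum(n_g / (1 + n_g * psi)) + dlogdet
  }

  # bracket the minimum, then polish
  upper <- 2
  while (f(upper * 2) < f(upper) && upper < 1e6) upper <- upper * 2
  opt <- stats::optimize(f, c(0, upper * 2), tol = tol)
  psi <- opt$minimum
  boundary <- FALSE
  if (f(0) <= opt$objective) {
    psi <- 0; boundary <- TRUE
  } else {
    lo <- psi / 2; hi <- psi * 2 + 1e-12
    if (score(lo) < 0 && score(hi) > 0) {
      psi <- stats::uniroot(score, c(lo, hi), tol = 1e-14)$root
    }
    if (psi < 1e-10 && f(0) <= f(psi)) { psi <- 0; boundary <- TRUE }
  }
  fit <- crit(psi)

  beta <- drop(fit$beta)
  names(beta) <- colnames(X)
  Vb <- fit$s2 * chol2inv(chol(fit$A))
  dimnames(Vb) <- list(colnames(X), colnames(X))
  sigma_e2 <- fit$s2
  sigma_b2 <- psi * sigma_e2

  fixed <- drop(X %*% beta)
  raw <- y - fixed
  blup <- (n_g * psi / (1 + n_g * psi)) * (rowsum(raw, g)[, 1] / n_g)
  cond_resid <- raw - blup[as.integer(g)]

  structure(list(coefficients = beta, se = sqrt(diag(Vb)), vcov = Vb,
                 sigma_b2 = sigma_b2, sigma_e2 = sigma_e2,
                 icc = sigma_b2 / (sigma_b2 + sigma_e2), psi = psi,
                 reml_loglik = -0.5 * (fit$value + (n - p) * (1 + log(2 * pi))),
                 boundary = boundary, n = n, n_groups = G,
                 fitted = fixed + blup[as.integer(g)],
                 residuals = cond_resid),
            class = "ri_fit")
}

#' @export
coef.ri_fit <- function(object, ...) object$coefficients

#' @export
residuals.ri_fit <- function(object, ...) object$residuals

#' @export
fitted.ri_fit <- function(object, ...) object$fitted

#' @export
print.ri_fit <- function(x, ...) {
  cat(sprintf("Random-intercept model (REML): n = %d, groups = %d\n",
              x$n, x$n_groups))
  print(round(cbind(Estimate = x$coefficients, SE = x$se), 4))
  cat(sprintf("sigma_b^2 = %.5f, sigma_e^2 = %.5f, ICC = %.4f%s\n",
              x$sigma_b2, x$sigma_e2, x$icc,
              if (x$boundary) " (boundary)" else ""))
  invisible(x)
}

.rge_controls_default <- c("mother_edu", "mother_school_inv",
                           "mother_leisure_inv", "father_resident",
                           "mother_resident", "age", "female", "enrolled")

#' Correlated effects of the polygenic score and father involvement
#'
#' Three-stage residual analysis.  Stage 1 regresses the child's years of
#' education on both parents' education, the genetic PCs and all control
#' variables in a household random-intercept model and takes the
#' individual-level (conditional) residuals.  Stage 2 regresses those
#' residuals separately on the PGS and on each involvement scale.  Stage 3
#' reports the Pearson correlation between the stage-2 fitted values of the
#' PGS model and each involvement model, with Fisher-z intervals.  Because
#' the stage-2 fits are single-predictor regressions, the statistic equals
#' the correlation between the PGS and the involvement scale up to the sign
#' of the product of the two slopes.
#'
#' @param data Prepared analysis data frame (see [prepare_cohort()]).
#' @param outcome,parents_edu,pgs Column names.
#' @param scales Named character vector of involvement scale columns.
#' @param controls,pcs Control and PC column names for the stage-1 model.
#' @param cluster Household id column.
#' @param conf Confidence level.
#' @return Data frame with one row per involvement scale: `estimate`,
#'   `ci_lower`, `ci_upper`, `n`, and a `degenerate` flag set when a
#'   stage-2 slope is exactly zero (correlation undefined).
#' @export
correlated_effects <- function(data,
                               outcome = "child_edu",
                               parents_edu = c("father_edu", "mother_edu"),
                               pgs = "pgs",
                               scales = c(school = "school_inv",
                                          leisure = "leisure_inv"),
                               controls = .rge_controls_default,
                               pcs = paste0("PC", 1:10),
                               cluster = "household_id",
                               conf = 0.95) {
  Xcols <- unique(c(parents_edu, pcs, controls))
  miss <- setdiff(c(outcome, Xcols, pgs, unname(scales), cluster), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  base <- fit_random_intercept(data[[outcome]], as.matrix(data[Xcols]),
                               data[[cluster]])
  r <- base$residuals

  stage2 <- function(x) stats::lm.fit(cbind(1, x), r)
  m_pgs <- stage2(data[[pgs]])
  out <- lapply(names(scales), function(nm) {
    m_inv <- stage2(data[[unname(scales[nm])]])
    s1 <- m_pgs$coefficients[2]; s2 <- m_inv$coefficients[2]
    if (s1 == 0 || s2 == 0)
      return(data.frame(scale = nm, estimate = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, n = length(r), degenerate = TRUE))
    rho <- stats::cor(m_pgs$fitted.values, m_inv$fitted.values)
    ci <- fisher_z_ci(rho, length(r), conf)
    data.frame(scale = nm, estimate = rho, ci_lower = ci[1], ci_upper = ci[2],
               n = length(r), degenerate = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Between-family gene-environment correlation
#'
#' For each father-involvement scale, fits a household random-intercept
#' model of the (z-scored) scale on the (z-scored) PGS controlling for the
#' genetic PCs, and reports the standardized PGS coefficient with a Wald
#' interval.
#'
#' @inheritParams correlated_effects
#' @return Data frame: one row per scale with `beta`, `se`, `ci_lower`,
#'   `ci_upper`, `icc`, `n`, `n_families`.
#' @export
between_family_rge <- function(data,
                               pgs = "pgs",
                               scales = c(school = "school_inv",
                                          leisure = "leisure_inv"),
                               pcs = paste0("PC", 1:10),
                               cluster = "household_id",
                               conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  pgs_z <- standardize(data[[pgs]])
  X <- cbind(pgs = pgs_z, as.matrix(data[pcs]))
  out <- lapply(names(scales), function(nm) {
    fit <- fit_random_intercept(standardize(data[[unname(scales[nm])]]),
                                X, data[[cluster]])
    b <- unname(fit$coefficients["pgs"]); se <- unname(fit$se["pgs"])
    data.frame(scale = nm, beta = b, se = se,
               ci_lower = b - z * se, ci_upper = b + z * se,
               icc = fit$icc, boundary = fit$boundary, n = fit$n,
               n_families = fit$n_groups)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Within-family (sibling-difference) gene-environment correlation
#'
#' Restricts to households contributing a complete sibling pair (first pair
#' by person id when more exist), forms within-pair differences of the PGS
#' and of each involvement scale with sibling order fixed by ascending
#' person id (the correlation is order-invariant), and reports the Pearson
#' correlation of the differences with a Fisher-z interval, plus the slope
#' of the difference regression.  Siblings share ancestry, so no PC
#' adjustment is applied.
#'
#' @inheritParams correlated_effects
#' @param person_id Person identifier column used to fix sibling order.
#' @return Data frame: one row per scale with `estimate` (correlation),
#'   `ci_lower`, `ci_upper`, `slope`, `n_pairs`.
#' @export
within_family_rge <- function(data,
                              pgs = "pgs",
                              scales = c(school = "school_inv",
                                         leisure = "leisure_inv"),
                              cluster = "household_id",
                              person_id = "person_id",
                              conf = 0.95) {
  used <- c(pgs, unname(scales))
  complete <- stats::complete.cases(data[used])
  d <- data[complete, , drop = FALSE]
  d <- d[order(d[[cluster]], d[[person_id]]), , drop = FALSE]
  counts <- table(d[[cluster]])
  multi <- names(counts)[counts >= 2]
  d <- d[d[[cluster]] %in% multi, , drop = FALSE]
  # first pair per household by ascending person id
  ord_in_hh <- stats::ave(seq_len(nrow(d)), d[[cluster]], FUN = seq_along)
  d <- d[ord_in_hh <= 2, , drop = FALSE]
  first <- d[seq(1, nrow(d), by = 2), , drop = FALSE]
  second <- d[seq(2, nrow(d), by = 2), , drop = FALSE]
  n_pairs <- nrow(first)
  if (n_pairs < 3) stop("within-family analysis needs at least 3 complete sibling pairs")

  d_pgs <- first[[pgs]] - second[[pgs]]
  if (stats::var(d_pgs) == 0) stop("zero variance in the PGS differences")
  out <- lapply(names(scales), function(nm) {
    d_inv <- first[[unname(scales[nm])]] - second[[unname(scales[nm])]]
    if (stats::var(d_inv) == 0)
      stop("zero variance in the ", nm, " involvement differences")
    rho <- stats::cor(d_pgs, d_inv)
    ci <- fisher_z_ci(rho, n_pairs, conf)
    slope <- stats::cov(d_inv, d_pgs) / stats::var(d_pgs)
    data.frame(scale = nm, estimate = rho, ci_lower = ci[1], ci_upper = ci[2],
               slope = slope, n_pairs = n_pairs)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Combined gene-environment correlation report
#'
#' Assembles the correlated-effects, between-family and within-family
#' estimates for both involvement scales into one table (the machine twin
#' of a three-panel correlation table), with sample sizes.
#'
#' @inheritParams correlated_effects
#' @param min_pairs Minimum number of sibling pairs required before the
#'   within-family panel is attempted; below it the panel is reported as
#'   missing rather than zero.
#' @return Object of class `rge_report`.
#' @export
rge_report <- function(data,
                       pgs = "pgs",
                       scales = c(school = "school_inv",
                                  leisure = "leisure_inv"),
                       controls = .rge_controls_default,
                       pcs = paste0("PC", 1:10),
                       cluster = "household_id",
                       conf = 0.95,
                       min_pairs = 3) {
  ce <- correlated_effects(data, pgs = pgs, scales = scales,
                           controls = controls, pcs = pcs,
                           cluster = cluster, conf = conf)
  bf <- between_family_rge(data, pgs = pgs, scales = scales, pcs = pcs,
                           cluster = cluster, conf = conf)
  n_sib_hh <- sum(table(data[[cluster]]) >= 2)
  wf <- if (n_sib_hh >= min_pairs) {
    within_family_rge(data, pgs = pgs, scales = scales, cluster = cluster,
                      conf = conf)
  } else {
    data.frame(scale = names(scales), estimate = NA_real_,
               ci_lower = NA_real_, ci_upper = NA_real_,
               slope = NA_real_, n_pairs = n_sib_hh)
  }
  tab <- data.frame(
    scale = names(scales),
    correlated_effects = ce$estimate,
    ce_lower = ce$ci_lower, ce_upper = ce$ci_upper,
    between_beta = bf$beta,
    bf_lower = bf$ci_lower, bf_upper = bf$ci_upper,
    within_corr = wf$estimate,
    wf_lower = wf$ci_lower, wf_upper = wf$ci_upper
  )
  structure(list(table = tab, correlated_effects = ce, between_family = bf,
                 within_family = wf,
                 n_individuals = nrow(data),
                 n_families = length(unique(data[[cluster]])),
                 n_pairs = wf$n_pairs[1]),
            class = "rge_report")
}

#' @export
print.rge_report <- function(x, digits = 3, ...) {
  cat("Gene-environment correlation between the education PGS and father involvement\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("N individuals = %d, N families = %d, N sibling pairs = %s\n",
              x$n_individuals, x$n_families,
              ifelse(is.na(x$n_pairs), "none", as.character(x$n_pairs))))
  invisible(x)
}
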