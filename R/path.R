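# Recursive linear path model: per-equation least squares with
# household-cluster-robust covariance, indirect effects via coefficient
# products, nested-model genetic/social confounding, cluster bootstrap.

#' Path model specification
#'
#' Variable roles for the recursive path system.  The defaults name the
#' columns produced by [prepare_cohort()]: father's years of education is
#' the focal predictor, the two father-involvement scales and the child's
#' polygenic score are the mediators, and the control set (mother's
#' education and involvement, residence indicators, age, sex, enrolment)
#' enters the child-education equation.  Genetic PCs sit on the equation for
#' the PGS mediator.
#'
#' `control_placement = "outcome"` (default) mirrors the applied analysis:
#' controls in the outcome equation only, PCs in the PGS equation only.
#' `"common"` puts the full control + PC set in every equation (and the
#' reduced form), which makes the total-effect identity
#' `total = direct + sum(indirect)` exact.
#'
#' @param outcome,focal Column names of the outcome and focal predictor.
#' @param mediators Named character vector of mediator columns.
#' @param controls Character vector of control columns.
#' @param pcs Character vector of genetic PC columns.
#' @param cluster Household identifier column.
#' @param control_placement `"outcome"` or `"common"`.
#' @return An object of class `path_spec`.
#' @export
path_spec <- function(outcome = "child_edu",
                      focal = "father_edu",
                      mediators = c(school = "school_inv",
                                    leisure = "leisure_inv",
                                    pgs = "pgs"),
                      controls = c("mother_edu", "mother_school_inv",
                                   "mother_leisure_inv", "father_resident",
                                   "mother_resident", "age", "female",
                                   "enrolled"),
                      pcs = paste0("PC", 1:10),
                      cluster = "household_id",
                      control_placement = c("outcome", "common")) {
  control_placement <- match.arg(control_placement)
  if (is.null(names(mediators)) || any(names(mediators) == ""))
    stop("mediators must be a named character vector")
  structure(list(outcome = outcome, focal = focal, mediators = mediators,
                 controls = controls, pcs = pcs, cluster = cluster,
                 control_placement = control_placement),
            class = "path_spec")
}

#' Least-squares fit with household-cluster-robust covariance
#'
#' Ordinary least squares (with intercept) plus the CR1 cluster-robust
#' sandwich covariance
#' `c * (X'X)^{-1} (sum_g X_g' e_g e_g' X_g) (X'X)^{-1}` with the
#' small-sample factor `c = G/(G-1) * (n-1)/(n-k)`, clusters grouped by
#' household.
#'
#' @param data Data frame with no missing values in the used columns.
#' @param outcome Outcome column name.
#' @param predictors Character vector of predictor column names.
#' @param cluster Cluster id column name.
#' @return An object of class `eq_fit` with elements `coefficients`,
#'   `vcov`, `se`, `residuals`, `fitted`, `n`, `n_clusters`, `outcome`,
#'   `predictors`.
#' @export
fit_equation <- function(data, outcome, predictors, cluster) {
  miss <- setdiff(c(outcome, predictors, cluster), names(data))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  y <- data[[outcome]]
  X <- cbind(`(Intercept)` = 1, as.matrix(data[predictors]))
  if (anyNA(y) || anyNA(X)) stop("fit_equation does not accept missing values")
  cl <- data[[cluster]]
  n <- length(y); k <- ncol(X)
  if (n < k) stop("fewer observations than parameters")
  g <- length(unique(cl))
  if (g < 2) stop("need at least 2 clusters")
  if (g == n && n > 2)
    stop("all clusters are singletons; cluster-robust inference is not meaningful here")

  qrX <- qr(X)
  if (qrX$rank < k)
    stop("rank-deficient design in equation for ", outcome)
  beta <- qr.coef(qrX, y)
  fitted <- as.numeric(X %*% beta)
  e <- y - fitted

  Xe <- X * e
  # sum over clusters of (X_g' e_g)(X_g' e_g)'
  S <- rowsum(Xe, group = cl)
  meat <- crossprod(S)
  bread <- chol2inv(qr.R(qrX))        # (X'X)^{-1}
  adj <- g / (g - 1) * (n - 1) / (n - k)
  V <- adj * bread %*% meat %*% bread
  dimnames(V) <- list(colnames(X), colnames(X))

  structure(list(coefficients = beta, vcov = V, se = sqrt(diag(V)),
                 residuals = e, fitted = fitted, n = n, n_clusters = g,
                 outcome = outcome, predictors = predictors),
            class = "eq_fit")
}

#' @export
coef.eq_fit <- function(object, ...) object$coefficients

#' @export
vcov.eq_fit <- function(object, ...) object$vcov

#' @export
residuals.eq_fit <- function(object, ...) object$residuals

#' @export
fitted.eq_fit <- function(object, ...) object$fitted

#' @export
print.eq_fit <- function(x, ...) {
  cat(sprintf("Equation: %s ~ %s  (n = %d, clusters = %d)\n",
              x$outcome, paste(x$predictors, collapse = " + "),
              x$n, x$n_clusters))
  tab <- cbind(Estimate = x$coefficients, `Cluster SE` = x$se)
  print(round(tab, 4))
  invisible(x)
}

.spec_rhs <- function(spec, eq) {
  common <- if (spec$control_placement == "common")
    unique(c(spec$controls, spec$pcs)) else character(0)
  switch(eq,
    mediator = unique(c(spec$focal, common)),
    pgs = unique(c(spec$focal, spec$pcs, common)),
    outcome = unique(c(spec$focal, unname(spec$mediators),
                       if (spec$control_placement == "outcome") spec$controls else common)),
    reduced = unique(c(spec$focal,
                       if (spec$control_placement == "outcome") spec$controls else common))
  )
}

#' Fit the recursive path model
#'
#' One least-squares equation per mediator (the focal predictor, plus
#' genetic PCs for the PGS mediator) and the outcome equation (focal
#' predictor, all mediators, controls), each with household-cluster-robust
#' covariance, plus the reduced-form regression of the outcome on the focal
#' predictor used for the total effect.
#'
#' @param data Prepared analysis data frame (see [prepare_cohort()]), all
#'   variables standardized.
#' @param spec A [path_spec()].
#' @return An object of class `path_fit`: equations (`eq_fit`s), the spec,
#'   and the a-path/b-path coefficients per mediator.
#' @export
fit_path_model <- function(data, spec = path_spec()) {
  stopifnot(inherits(spec, "path_spec"))
  eqs <- list()
  for (m in names(spec$mediators)) {
    rhs <- .spec_rhs(spec, if (m == "pgs") "pgs" else "mediator")
    eqs[[m]] <- fit_equation(data, spec$mediators[[m]], rhs, spec$cluster)
  }
  eqs$outcome <- fit_equation(data, spec$outcome, .spec_rhs(spec, "outcome"),
                              spec$cluster)
  eqs$reduced <- fit_equation(data, spec$outcome, .spec_rhs(spec, "reduced"),
                              spec$cluster)

  a <- vapply(names(spec$mediators), function(m)
    unname(eqs[[m]]$coefficients[spec$focal]), numeric(1))
  a_se <- vapply(names(spec$mediators), function(m)
    unname(eqs[[m]]$se[spec$focal]), numeric(1))
  b <- vapply(spec$mediators, function(v)
    unname(eqs$outcome$coefficients[v]), numeric(1))
  b_se <- vapply(spec$mediators, function(v)
    unname(eqs$outcome$se[v]), numeric(1))
  names(b) <- names(b_se) <- names(spec$mediators)

  structure(list(equations = eqs, spec = spec,
                 a = a, a_se = a_se, b = b, b_se = b_se,
                 direct = unname(eqs$outcome$coefficients[spec$focal]),
                 direct_se = unname(eqs$outcome$se[spec$focal]),
                 reduced_form = unname(eqs$reduced$coefficients[spec$focal]),
                 reduced_form_se = unname(eqs$reduced$se[spec$focal]),
                 n = eqs$outcome$n, n_clusters = eqs$outcome$n_clusters),
            class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf("Recursive path model: %s on %s via %s\n",
              x$spec$outcome, x$spec$focal,
              paste(names(x$spec$mediators), collapse = ", ")))
  cat(sprintf("n = %d children in %d households\n", x$n, x$n_clusters))
  cat(sprintf("direct effect %.4f (SE %.4f); reduced-form total %.4f (SE %.4f)\n",
              x$direct, x$direct_se, x$reduced_form, x$reduced_form_se))
  invisible(x)
}

#' @export
summary.path_fit <- function(object, ...) {
  structure(list(fit = object, decomposition = decompose_effects(object)),
            class = "summary.path_fit")
}

#' @export
print.summary.path_fit <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$decomposition)
  invisible(x)
}

#' @export
coef.path_fit <- function(object, ...) {
  lapply(object$equations, stats::coef)
}

#' Mediation decomposition
#'
#' Indirect effect per mediator is the product of the a-path (focal
#' predictor on the mediator) and the b-path (mediator on the outcome);
#' `total = direct + sum(indirect)`; proportion mediated is
#' `100 * indirect / total`.  Approximate SEs for the products use the
#' delta (Sobel) formula; [cluster_bootstrap()] gives resampling intervals.
#'
#' @param fit A [fit_path_model()] result.
#' @param conf Confidence level for the normal-theory intervals.
#' @return An object of class `mediation`: a table with the total, direct
#'   and per-mediator indirect effects, SEs, CIs and proportions mediated.
#' @export
decompose_effects <- function(fit, conf = 0.95) {
  stopifnot(inherits(fit, "path_fit"))
  indirect <- fit$a * fit$b
  ind_se <- sqrt(fit$a^2 * fit$b_se^2 + fit$b^2 * fit$a_se^2)
  total <- fit$direct + sum(indirect)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  prop <- if (total == 0) rep(NA_real_, length(indirect)) else
    proportion_mediated(indirect, total)
  tab <- data.frame(
    effect = c("total", "direct", paste0("indirect_", names(indirect))),
    estimate = c(total, fit$direct, indirect),
    se = c(NA, fit$direct_se, ind_se),
    ci_lower = c(NA, fit$direct - z * fit$direct_se, indirect - z * ind_se),
    ci_upper = c(NA, fit$direct + z * fit$direct_se, indirect + z * ind_se),
    pct_of_total = c(NA, if (total == 0) NA else 100 * fit$direct / total, prop),
    row.names = NULL
  )
  structure(list(table = tab, total = total, direct = fit$direct,
                 indirect = indirect, proportion_mediated = prop,
                 reduced_form = fit$reduced_form,
                 total_undefined = total == 0),
            class = "mediation")
}

#' Proportion of a total effect mediated
#'
#' `100 * indirect / total`, in percent.
#'
#' @param indirect Indirect effect(s) (a-path times b-path).
#' @param total Total effect.
#' @return Percentage(s).
#' @examples
#' proportion_mediated(0.065, 0.303)  # 21.45
#' @export
proportion_mediated <- function(indirect, total) {
  if (length(total) != 1 || total == 0)
    stop("total effect must be a single non-zero value")
  100 * indirect / total
}

#' @export
print.mediation <- function(x, digits = 4, ...) {
  cat("Mediation decomposition (standardized coefficients)\n")
  tab <- x$table
  tab$estimate <- round(tab$estimate, digits)
  tab$pct_of_total <- round(tab$pct_of_total, 2)
  print(tab, row.names = FALSE)
  cat(sprintf("reduced-form total effect: %.4f\n", x$reduced_form))
  invisible(x)
}

#' @describeIn decompose_effects Bar chart of the direct and per-mediator
#'   indirect effects with their normal-theory intervals.
#' @param x A `mediation` object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.mediation <- function(x, ...) {
  tab <- x$table[x$table$effect != "total", ]
  mid <- graphics::barplot(tab$estimate, names.arg = sub("indirect_", "", tab$effect),
                           ylab = "standardized effect",
                           ylim = range(0, tab$ci_lower, tab$ci_upper,
                                        na.rm = TRUE) * 1.1, ...)
  ok <- !is.na(tab$ci_lower)
  graphics::arrows(mid[ok], tab$ci_lower[ok], mid[ok], tab$ci_upper[ok],
                   angle = 90, code = 3, length = 0.05)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Nested path models and confounding decomposition
#'
#' Fits three nested models: M1 with the involvement mediators only, M2
#' with the PGS mediator only, M3 with all mediators, with identical
#' control handling.  Genetic confounding of an involvement coefficient is
#' its percent reduction from M1 to M3 (outcome equation); social
#' confounding of the PGS coefficient is its percent reduction from M2 to
#' M3.
#'
#' @param data Prepared analysis data frame.
#' @param spec A [path_spec()] naming all three mediators.
#' @return Object of class `nested_suite`: the three `path_fit`s and a
#'   confounding comparison table.
#' @export
fit_nested_suite <- function(data, spec = path_spec()) {
  med <- spec$mediators
  if (!all(c("school", "leisure", "pgs") %in% names(med)))
    stop("spec must name 'school', 'leisure' and 'pgs' mediators")
  sub_spec <- function(keep) {
    s <- spec; s$mediators <- med[keep]; s
  }
  m1 <- fit_path_model(data, sub_spec(c("school", "leisure")))
  m2 <- fit_path_model(data, sub_spec("pgs"))
  m3 <- fit_path_model(data, spec)

  comp <- data.frame(
    label = c("genetic_school", "genetic_leisure", "social_pgs"),
    coefficient = c(med[["school"]], med[["leisure"]], med[["pgs"]]),
    before = c(m1$b[["school"]], m1$b[["leisure"]], m2$b[["pgs"]]),
    after = c(m3$b[["school"]], m3$b[["leisure"]], m3$b[["pgs"]]),
    stringsAsFactors = FALSE
  )
  comp$percent_reduction <- ifelse(
    comp$before == 0, NA_real_,
    confounding_percent(comp$before, comp$after))
  structure(list(M1 = m1, M2 = m2, M3 = m3, confounding = comp),
            class = "nested_suite")
}

#' @export
print.nested_suite <- function(x, ...) {
  cat("Nested path models: M1 involvement mediators, M2 PGS mediator, M3 both\n")
  tab <- x$confounding
  tab$before <- round(tab$before, 4)
  tab$after <- round(tab$after, 4)
  tab$percent_reduction <- round(tab$percent_reduction, 1)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Percent attenuation of a coefficient across nested models
#'
#' `100 * (before - after) / before`; undefined (error) when `before` is 0.
#' Values are returned unrounded; display at one decimal.
#'
#' @param before Coefficient in the smaller model.
#' @param after Coefficient after adding the competing mediator block.
#' @return Percent reduction(s).
#' @examples
#' confounding_percent(0.056, 0.050)  # 10.71 -> "10.7%"
#' @export
confounding_percent <- function(before, after) {
  if (any(before == 0)) stop("percent reduction undefined when the base coefficient is 0")
  100 * (before - after) / before
}

#' Cluster bootstrap
#'
#' Resamples households (clusters) with replacement and recomputes an
#' arbitrary statistic of the data, giving percentile confidence intervals
#' and a bootstrap SE.  A resample on which the statistic fails or is not
#' finite is redrawn (the count is reported).
#'
#' @param data Data frame.
#' @param statistic Function `data -> numeric vector` (possibly named).
#' @param cluster Cluster id column name.
#' @param B Number of bootstrap resamples (>= 200).
#' @param seed Integer seed (mandatory; same seed gives identical intervals).
#' @param conf Confidence level.
#' @return List with `estimate`, `se`, `ci` (matrix with lower/upper rows),
#'   `B`, and `n_redrawn`.
#' @export
cluster_bootstrap <- function(data, statistic, cluster = "household_id",
                              B = 1000, seed, conf = 0.95) {
  if (missing(seed)) stop("seed is mandatory for cluster_bootstrap")
  if (B < 200) stop("B must be at least 200")
  idx_by_cl <- split(seq_len(nrow(data)), data[[cluster]])
  G <- length(idx_by_cl)
  est <- statistic(data)
  p <- length(est)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  out <- matrix(NA_real_, B, p)
  n_redrawn <- 0L
  b <- 1L
  while (b <= B) {
    rows <- unlist(idx_by_cl[sample.int(G, G, replace = TRUE)],
                   use.names = FALSE)
    val <- tryCatch(statistic(data[rows, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(val) || length(val) != p || any(!is.finite(val))) {
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 10 * B) stop("statistic failed on too many resamples")
      next
    }
    out[b, ] <- val
    b <- b + 1L
  }
  alpha <- (1 - conf) / 2
  ci <- apply(out, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE, type = 7)
  ci <- matrix(ci, nrow = 2)
  dimnames(ci) <- list(c("lower", "upper"), names(est))
  list(estimate = est, se = apply(out, 2, stats::sd), ci = ci,
       B = B, n_redrawn = n_redrawn)
}
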