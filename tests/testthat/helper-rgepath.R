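# Shared fixtures: small, fast simulation configs and hand-rolled oracles.

small_config <- function(seed, ...) {
  args <- list(n_households = 400, n_loci = 60, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

small_scenario <- function(name, seed, ...) {
  scenario_config(name, n_households = 400, n_loci = 60, seed = seed, ...)
}

# independent OLS oracle: solve the normal equations directly
ols_oracle <- function(y, X) {
  X1 <- cbind(1, X)
  drop(solve(crossprod(X1), crossprod(X1, y)))
}

# independent CR1 sandwich oracle assembled cluster by cluster
sandwich_oracle <- function(y, X, cl) {
  X1 <- cbind(1, X)
  n <- nrow(X1); k <- ncol(X1)
  beta <- solve(crossprod(X1), crossprod(X1, y))
  e <- y - X1 %*% beta
  meat <- matrix(0, k, k)
  for (g in unique(cl)) {
    i <- which(cl == g)
    sg <- t(X1[i, , drop = FALSE]) %*% e[i]
    meat <- meat + sg %*% t(sg)
  }
  G <- length(unique(cl))
  bread <- solve(crossprod(X1))
  G / (G - 1) * (n - 1) / (n - k) * bread %*% meat %*% bread
}

# simple clustered regression data for bootstrap checks
clustered_slope_data <- function(n_clusters, slope = 0.5) {
  sizes <- sample(1:2, n_clusters, replace = TRUE)
  g <- rep(seq_len(n_clusters), sizes)
  n <- length(g)
  x <- rnorm(n)
  y <- slope * x + rnorm(n_clusters, 0, 0.5)[g] + rnorm(n)
  data.frame(y = y, x = x, household_id = g)
}

slope_stat <- function(d) {
  unname(stats::cov(d$x, d$y) / stats::var(d$x))
}
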