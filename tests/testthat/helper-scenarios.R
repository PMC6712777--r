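# Shared fixtures: everything is generated in code, nothing on disk.

# Small scenario for fast unit tests: 2 regions x 6 districts x 8 cells.
tiny_scenario <- function(...) {
  selection_scenario(districts_per_region = rep(6L, 2), ...)
}

tiny_population <- function(seed = 1, ...) {
  generate_population(tiny_scenario(...), seed)
}

# Default correctly-specified design for a scenario: intercept + cell size +
# the truly predictive auxiliary columns.
truth_design <- function(scenario) {
  model_design(c("cell_size",
                 scenario$aux_labels[seq_len(scenario$n_predictive)]))
}

# Balanced one-way random-intercept layout with known closed-form REML.
balanced_oneway <- function(m, n_per, mu = 5, psi = 4, sigma2 = 1,
                            seed = 1) {
  set.seed(seed)
  g <- factor(rep(seq_len(m), each = n_per))
  y <- mu + rnorm(m, 0, sqrt(psi))[g] + rnorm(m * n_per, 0, sqrt(sigma2))
  X <- matrix(1, m * n_per, 1, dimnames = list(NULL, "(Intercept)"))
  list(y = y, X = X, Z = X, g = g, m = m, n_per = n_per)
}

# ANOVA closed-form REML estimators for the balanced one-way layout.
oneway_closed_form <- function(d) {
  gm <- tapply(d$y, d$g, mean)
  msw <- sum((d$y - gm[d$g])^2) / (d$m * (d$n_per - 1))
  msb <- d$n_per * sum((gm - mean(d$y))^2) / (d$m - 1)
  list(sigma2 = msw, psi = max(0, (msb - msw) / d$n_per))
}

# Random mixed-model instance plus the brute-force dense GLS/BLUP solution
# (independent oracle: explicit V inversion, no shared code path).
random_gls_instance <- function(seed, n_max = 200, p_max = 6, q_max = 2) {
  set.seed(seed)
  n <- sample(20:n_max, 1)
  D <- sample(2:8, 1)
  p <- sample(2:p_max, 1)
  q <- sample(1:q_max, 1)
  repeat {
    g <- factor(sample(seq_len(D), n, replace = TRUE))
    if (nlevels(droplevels(g)) == D) break
  }
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1)))
  Z <- matrix(rnorm(n * q), n)
  colnames(Z) <- paste0("z", seq_len(q))
  A <- matrix(rnorm(q * q), q)
  psi <- crossprod(A) + 0.1 * diag(q)
  sigma2 <- runif(1, 0.5, 3)
  y <- rnorm(n)
  list(y = y, X = X, Z = Z, g = g, psi = psi, sigma2 = sigma2,
       n = n, D = D, q = q)
}

dense_gls_blup <- function(inst) {
  with(inst, {
    Zfull <- matrix(0, n, D * q)
    lv <- levels(g)
    for (d in seq_len(D)) {
      rows <- g == lv[d]
      Zfull[rows, ((d - 1) * q + 1):(d * q)] <- Z[rows, , drop = FALSE]
    }
    Psi_big <- kronecker(diag(D), psi)
    V <- Zfull %*% Psi_big %*% t(Zfull) + sigma2 * diag(n)
    Vi <- solve(V)
    beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    b <- Psi_big %*% t(Zfull) %*% Vi %*% (y - X %*% beta)
    list(beta = unname(drop(beta)), b = matrix(drop(b), D, q, byrow = TRUE))
  })
}
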