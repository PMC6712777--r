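test_that("design matrices carry the block structure of the region model", {
  sc <- selection_scenario(districts_per_region = 3L)
  pop <- generate_population(sc, 51)
  des <- model_design(c("cell_size", "age_group", "sex",
                        sc$aux_labels[1:2]))
  dm <- build_design_matrices(pop, des, "member")
  # random intercept: Z is a single column of ones, blocks = districts
  expect_equal(ncol(dm$Z), 1)
  expect_true(all(dm$Z == 1))
  expect_equal(nlevels(dm$districts), 3)
  # intercept first, then cell size, then 3 age dummies + sex dummy + aux
  expect_equal(colnames(dm$X)[1], "(Intercept)")
  expect_equal(ncol(dm$X), 1 + 1 + 3 + 1 + 2)
  expect_equal(qr(dm$X)$rank, ncol(dm$X))

  # the member build drops member-free cells and the index map tracks them
  pop2 <- tibble::as_tibble(pop)
  pop2$n_member[5] <- 0
  pop2$y_member[5] <- 0
  dm2 <- build_design_matrices(validate_cell_table(pop2), des, "member")
  expect_equal(nrow(dm2$X), nrow(pop) - 1)
  expect_false(any(dm2$index$cell == pop2$cell[5] &
                     dm2$index$district == pop2$district[5]))
  # the national build keeps all cells
  dn <- build_design_matrices(validate_cell_table(pop2), des, "national")
  expect_equal(nrow(dn$X), nrow(pop))
})

test_that("collinear fixed effects are reported by name", {
  pop <- tibble::as_tibble(tiny_population(52))
  pop$mem_COPY_main <- pop$mem_E11_secondary
  pop$nat_COPY_main <- pop$nat_E11_secondary
  des <- model_design(c("cell_size", "E11_secondary", "COPY_main"))
  expect_error(
    build_design_matrices(validate_cell_table(pop), des, "member"),
    "COPY_main"
  )
})

test_that("REML matches the closed-form ANOVA estimators on balanced data", {
  d <- balanced_oneway(5, 4, seed = 61)
  fit <- fit_region_reml(d$y, d$X, d$Z, d$g)
  cf <- oneway_closed_form(d)
  expect_equal(fit$sigma2, cf$sigma2, tolerance = 1e-6)
  expect_equal(fit$psi[1, 1], cf$psi, tolerance = 1e-6)
  # the GLS estimate of the mean in the balanced case is the grand mean
  expect_equal(unname(fit$beta[1]), mean(d$y), tolerance = 1e-8)
})

test_that("REML agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  set.seed(62)
  D <- 10; C <- 8; n <- D * C
  X <- cbind(1, rnorm(n), runif(n, 0, 5))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  g <- factor(rep(seq_len(D), each = C))
  y <- drop(X %*% c(2, 1.5, -0.7)) + rnorm(D, 0, 1.5)[g] + rnorm(n)
  fit <- fit_region_reml(y, X, matrix(1, n, 1), g)
  df <- data.frame(y = y, x1 = X[, 2], x2 = X[, 3], g = g)
  ref <- lme4::lmer(y ~ x1 + x2 + (1 | g), data = df, REML = TRUE)
  expect_equal(unname(fit$beta), unname(lme4::fixef(ref)), tolerance = 1e-6)
  expect_equal(fit$sigma2, stats::sigma(ref)^2, tolerance = 1e-6)
  expect_equal(fit$psi[1, 1], as.numeric(lme4::VarCorr(ref)$g),
               tolerance = 1e-5)
  expect_equal(fit$reml_loglik, as.numeric(stats::logLik(ref)),
               tolerance = 1e-8)
  expect_equal(unname(fit$b[, 1]), lme4::ranef(ref)$g[, 1], tolerance = 1e-6)
})

test_that("gls_blup reduces to OLS when shrinkage demands it", {
  set.seed(63)
  n <- 40
  X <- cbind(1, rnorm(n)); colnames(X) <- c("(Intercept)", "x")
  Z <- matrix(1, n, 1)
  g <- factor(rep(1:5, each = 8))
  y <- rnorm(n)
  ols <- unname(stats::lm.fit(X, y)$coefficients)
  # Psi = 0: random effects vanish
  r0 <- gls_blup(y, X, Z, g, psi = matrix(0, 1, 1), sigma2 = 2)
  expect_equal(unname(r0$beta), ols, tolerance = 1e-10)
  expect_true(all(r0$b == 0))
  # V proportional to the identity: GLS equals OLS for any sigma2
  expect_equal(unname(gls_blup(y, X, matrix(0, n, 1), g,
                               psi = matrix(1, 1, 1),
                               sigma2 = 7)$beta),
               ols, tolerance = 1e-10)
  expect_error(gls_blup(y, X, Z, g, matrix(1, 1, 1), sigma2 = 0),
               "sigma2 > 0")
})

test_that("gls_blup matches brute-force dense inversion", {
  for (seed in 71:80) {
    inst <- random_gls_instance(seed)
    got <- gls_blup(inst$y, inst$X, inst$Z, inst$g, inst$psi, inst$sigma2)
    want <- dense_gls_blup(inst)
    expect_equal(unname(got$beta), want$beta, tolerance = 1e-10)
    expect_equal(unname(got$b), unname(want$b), tolerance = 1e-8)
  }
})

test_that("fits are invariant to row order and fixed-effect basis", {
  sc <- tiny_scenario()
  pop <- generate_population(sc, 53)
  dm <- build_design_matrices(pop[pop$region == 1, ], truth_design(sc),
                              "member")
  fit <- fit_region_reml(dm$y, dm$X, dm$Z, dm$districts)

  # row permutation
  set.seed(1)
  ord <- sample(length(dm$y))
  fit_p <- fit_region_reml(dm$y[ord], dm$X[ord, ], dm$Z[ord, , drop = FALSE],
                           dm$districts[ord])
  expect_equal(fit_p$beta, fit$beta, tolerance = 1e-8)
  expect_equal(fit_p$sigma2, fit$sigma2, tolerance = 1e-8)
  expect_equal(fit_p$psi, fit$psi, tolerance = 1e-8)

  # full-rank reparameterization of X leaves the REML criterion unchanged
  set.seed(2)
  P <- ncol(dm$X)
  repeat {
    Tm <- matrix(rnorm(P * P), P)
    if (abs(det(Tm)) > 0.1) break
  }
  XT <- dm$X %*% Tm
  colnames(XT) <- colnames(dm$X)
  fit_t <- fit_region_reml(dm$y, XT, dm$Z, dm$districts)
  # the restricted likelihood shifts by the log-Jacobian of the basis change
  # and is otherwise unchanged; variance estimates and fits are invariant
  expect_equal(fit_t$reml_loglik + log(abs(det(Tm))), fit$reml_loglik,
               tolerance = 1e-6)
  expect_equal(fit_t$sigma2, fit$sigma2, tolerance = 1e-4)
  expect_equal(fit_t$psi[1, 1], fit$psi[1, 1], tolerance = 1e-3)
  expect_equal(fit_t$fitted, fit$fitted, tolerance = 1e-4)
})

test_that("strong random effects with tiny noise interpolate the data", {
  set.seed(64)
  n <- 6
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  g <- factor(seq_len(n)) # one row per district
  y <- rnorm(n, 10, 3)
  r <- gls_blup(y, X, X, g, psi = matrix(1e8, 1, 1), sigma2 = 1e-6)
  expect_equal(r$fitted, y, tolerance = 1e-8)
})

test_that("model comparison reports LR test and penalised criterion", {
  sc <- tiny_scenario()
  pop <- generate_population(sc, 54)
  rows <- pop[pop$region == 1, ]
  des_s <- model_design(c("cell_size", sc$aux_labels[1:3]))
  dm_s <- build_design_matrices(rows, des_s, "member")
  fit_s <- fit_region_reml(dm_s$y, dm_s$X, dm_s$Z, dm_s$districts)

  # identical designs: zero LR statistic, identical criterion
  cmp0 <- compare_fits(fit_s, fit_s)
  expect_equal(cmp0$lr_stat, 0)
  expect_equal(cmp0$df, 0)
  expect_equal(cmp0$caic_bic_small, cmp0$caic_bic_large)

  # nested comparison with one extra (noise) fixed effect
  des_l <- model_design(c("cell_size", sc$aux_labels[1:4]))
  dm_l <- build_design_matrices(rows, des_l, "member")
  fit_l <- fit_region_reml(dm_l$y, dm_l$X, dm_l$Z, dm_l$districts)
  cmp <- compare_fits(fit_s, fit_l)
  expect_equal(cmp$df, 1)
  expect_gte(cmp$lr_stat, -1e-6)
  expect_true(cmp$preferred %in% c("small", "large"))

  # non-nested designs refuse the LR branch
  des_o <- model_design(c("cell_size", sc$aux_labels[4:6]))
  dm_o <- build_design_matrices(rows, des_o, "member")
  fit_o <- fit_region_reml(dm_o$y, dm_o$X, dm_o$Z, dm_o$districts)
  expect_error(compare_fits(fit_o, fit_l), "not nested")
})

test_that("effective degrees of freedom collapse to P without random effects", {
  # data generated with no district effect: psi_hat hits the boundary and
  # the hat matrix reduces to the OLS projection
  set.seed(65)
  n <- 120
  X <- cbind(1, rnorm(n)); colnames(X) <- c("(Intercept)", "x")
  g <- factor(rep(1:12, each = 10))
  y <- drop(X %*% c(1, 2)) + rnorm(n)
  fit <- fit_region_reml(y, X, matrix(1, n, 1), g)
  expect_lt(fit$psi[1, 1], 0.2)
  expect_lt(fit$edf, ncol(X) + 2)
  expect_gte(fit$edf, ncol(X) - 1e-8)
})

test_that("the BIC penalty rejects noise predictors more often than AIC", {
  # small Monte-Carlo: add one pure-noise column; count how often each
  # penalty still prefers the smaller model
  sc <- tiny_scenario()
  reps <- 40
  pick_small <- matrix(NA, reps, 2,
                       dimnames = list(NULL, c("bic_pen", "aic_pen")))
  for (i in seq_len(reps)) {
    pop <- generate_population(sc, 600 + i)
    rows <- pop[pop$region == 1, ]
    dm_s <- build_design_matrices(rows, truth_design(sc), "member")
    fit_s <- fit_region_reml(dm_s$y, dm_s$X, dm_s$Z, dm_s$districts)
    des_l <- model_design(c("cell_size", sc$aux_labels[c(1:3, 8)]))
    dm_l <- build_design_matrices(rows, des_l, "member")
    fit_l <- fit_region_reml(dm_l$y, dm_l$X, dm_l$Z, dm_l$districts)
    n <- fit_s$n
    pick_small[i, "bic_pen"] <- fit_s$caic_bic < fit_l$caic_bic
    aic_s <- -2 * fit_s$cond_loglik + 2 * fit_s$edf
    aic_l <- -2 * fit_l$cond_loglik + 2 * fit_l$edf
    pick_small[i, "aic_pen"] <- aic_s < aic_l
  }
  rate_bic <- mean(pick_small[, "bic_pen"])
  rate_aic <- mean(pick_small[, "aic_pen"])
  expect_gt(rate_bic, 0.5)
  expect_gte(rate_bic, rate_aic)
})
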