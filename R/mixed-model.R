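#' Declare a region-wise mixed-model design
#'
#' A design names the fixed-effect and random-effect columns of the
#' region-wise linear mixed model
#' \deqn{y_{rd} = X_{rd}\beta_r + Z_{rd} b_{rd} + e_{rd},}
#' with district random effects \eqn{b_{rd} \sim N(0, \Psi)} and cell errors
#' \eqn{e_{rd} \sim N(0, \sigma_r^2 I)}. Column tokens may be
#' `"(Intercept)"`, `"cell_size"` (the member or national cell population,
#' depending on which side the design is built for), `"age_group"` and
#' `"sex"` (expanded to indicator columns), or any auxiliary diagnosis label
#' of the cell table. The same token list is used to build the member-side
#' matrices (for fitting) and the national-side matrices (for benchmark
#' prediction), which enforces the matched-variable requirement.
#'
#' @param fixed Ordered character vector of fixed-effect tokens; an intercept
#'   is prepended if absent.
#' @param random Random-effect tokens on the district level (default:
#'   intercept only).
#' @param region_partition Optional named vector mapping geographic region
#'   ids to model regions, allowing territories to be merged when a region
#'   alone has too few cells for the requested complexity. Default: identity.
#' @return An object of class `model_design`.
#' @export
#' @examples
#' model_design(c("cell_size", "E11_secondary"))
model_design <- function(fixed, random = "(Intercept)",
                         region_partition = NULL) {
  fixed <- unique(c("(Intercept)", fixed))
  if (length(random) < 1) {
    stop("at least one random-effect column is required", call. = FALSE)
  }
  bad <- setdiff(random, c(fixed, "(Intercept)"))
  if (length(bad) > 0) {
    stop("random columns must be drawn from the fixed columns or the ",
         "intercept: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(fixed = fixed, random = unique(random),
         region_partition = region_partition),
    class = "model_design"
  )
}

model_region_of <- function(design, region) {
  part <- design$region_partition
  if (is.null(part)) return(as.character(region))
  out <- part[as.character(region)]
  if (anyNA(out)) {
    stop("region_partition does not cover region(s): ",
         paste(unique(region[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  as.character(out)
}

# Expand design tokens into numeric columns for a set of cell rows.
expand_columns <- function(rows, tokens, population) {
  aux <- aux_labels(rows)
  prefix <- if (population == "member") "mem_" else "nat_"
  size_col <- if (population == "member") "n_member" else "n_national"
  cols <- list()
  for (tok in tokens) {
    if (tok == "(Intercept)") {
      cols[["(Intercept)"]] <- rep(1, nrow(rows))
    } else if (tok == "cell_size") {
      cols[["cell_size"]] <- rows[[size_col]]
    } else if (tok == "age_group") {
      lv <- levels(rows$age_group)
      for (l in lv[-1]) {
        cols[[paste0("age_group", l)]] <- as.numeric(rows$age_group == l)
      }
    } else if (tok == "sex") {
      lv <- levels(rows$sex)
      for (l in lv[-1]) {
        cols[[paste0("sex", l)]] <- as.numeric(rows$sex == l)
      }
    } else if (tok %in% aux) {
      cols[[tok]] <- rows[[paste0(prefix, tok)]]
    } else {
      stop("unknown design column: ", tok, call. = FALSE)
    }
  }
  do.call(cbind, cols)
}

#' Build model matrices for one model region
#'
#' Constructs the response, fixed-effect matrix `X` and random-effect matrix
#' `Z` for the rows of a single model region. The member build keeps only
#' cells with members (`n_member > 0`) and returns the member diseased counts
#' as `y`; the national build keeps all cells and returns no response. `Z`
#' holds the per-row random-effect covariates; its block-diagonal district
#' structure is carried by the `districts` factor.
#'
#' @param rows Cell rows of one model region.
#' @param design A [model_design()].
#' @param population `"member"` or `"national"`.
#' @param response Column holding the member-build response (default the
#'   member diseased count; the proxy cross-validation substitutes a member
#'   diagnosis-count column here).
#' @return List with `y` (member build only), `X`, `Z`, `districts` (factor
#'   `region/district`), and `index` (tibble mapping rows to cells).
#' @export
build_design_matrices <- function(rows, design,
                                  population = c("member", "national"),
                                  response = "y_member") {
  population <- match.arg(population)
  stopifnot(inherits(design, "model_design"))
  if (population == "member") {
    rows <- dplyr::filter(rows, .data$n_member > 0)
  }
  if (nrow(rows) == 0) {
    stop("no usable cells for the ", population, " design", call. = FALSE)
  }
  X <- expand_columns(rows, design$fixed, population)
  Z <- expand_columns(rows, design$random, population)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient fixed-effect matrix; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  list(
    y = if (population == "member") as.double(rows[[response]]) else NULL,
    X = X,
    Z = Z,
    districts = factor(paste(rows$region, rows$district, sep = "/")),
    index = dplyr::select(rows, dplyr::all_of(CELL_INDEX_COLS))
  )
}

# --- profiled REML -----------------------------------------------------------
#
# The error variance is profiled out: with Psi = sigma2 * Psi*, write
# V = sigma2 * W, W = I + Z Psi* Z'. Psi* is parameterised by the
# log-Cholesky factor L (Psi* = L L', log-scale diagonal), so the optimiser
# runs unconstrained while Psi stays positive semidefinite. All linear
# algebra runs district block by district block through the Q x Q capacitance
# matrix A_d = I_Q + K_d'K_d, K_d = Z_d L, which keeps evaluations cheap even
# with many districts.

theta_to_L <- function(theta, q) {
  L <- matrix(0, q, q)
  L[lower.tri(L, diag = TRUE)] <- theta
  diag(L) <- exp(diag(L))
  L
}

split_blocks <- function(M, districts) {
  lapply(split(seq_along(districts), districts), function(i) {
    M[i, , drop = FALSE]
  })
}

# Precompute the per-fit context: sufficient statistics that do not depend
# on the variance parameters. The single-random-effect case (the default
# district random intercept) gets a fully vectorised path via rowsum();
# higher Q falls back to district-block lists.
make_reml_ctx <- function(y, X, Z, districts) {
  districts <- droplevels(as.factor(districts))
  g <- as.integer(districts)
  ctx <- list(
    y = y, X = X, Z = Z, g = g, levels = levels(districts),
    n = length(y), p = ncol(X), q = ncol(Z), D = nlevels(districts),
    XtX = crossprod(X), Xty = crossprod(X, y), yty = sum(y^2)
  )
  if (ctx$q == 1) {
    z <- Z[, 1]
    ctx$z <- z
    ctx$zX <- rowsum(z * X, g)      # D x P
    ctx$zy <- drop(rowsum(z * y, g))
    ctx$ztz <- drop(rowsum(z^2, g))
  } else {
    ctx$Xb <- split_blocks(X, districts)
    ctx$Zb <- split_blocks(Z, districts)
    ctx$yb <- split(y, districts)
  }
  ctx
}

# Sufficient statistics of the profiled REML criterion at a given
# log-Cholesky factor L of Psi/sigma2. Returns -2 * restricted
# log-likelihood and the pieces needed to finish the fit.
reml_pieces <- function(L, ctx) {
  n <- ctx$n; p <- ctx$p; q <- ctx$q
  if (q == 1) {
    l2 <- L[1, 1]^2
    A <- 1 + l2 * ctx$ztz
    scaled <- ctx$zX * sqrt(l2 / A)
    XtWiX <- ctx$XtX - crossprod(scaled)
    XtWiy <- ctx$Xty - colSums(ctx$zX * (l2 * ctx$zy / A))
    ytWiy <- ctx$yty - sum(l2 * ctx$zy^2 / A)
    logdetW <- sum(log(A))
    extra <- list(A = A, l2 = l2)
  } else {
    XtWiX <- matrix(0, p, p)
    XtWiy <- numeric(p)
    ytWiy <- 0
    logdetW <- 0
    blocks <- vector("list", length(ctx$Xb))
    for (d in seq_along(ctx$Xb)) {
      X_d <- ctx$Xb[[d]]; y_d <- ctx$yb[[d]]; K_d <- ctx$Zb[[d]] %*% L
      A <- diag(q) + crossprod(K_d)
      cA <- chol(A)
      KtX <- crossprod(K_d, X_d)
      Kty <- crossprod(K_d, y_d)
      AiKtX <- backsolve(cA, forwardsolve(t(cA), KtX))
      AiKty <- backsolve(cA, forwardsolve(t(cA), Kty))
      XtWiX <- XtWiX + crossprod(X_d) - crossprod(KtX, AiKtX)
      XtWiy <- XtWiy + crossprod(X_d, y_d) - crossprod(KtX, AiKty)
      ytWiy <- ytWiy + sum(y_d^2) - sum(Kty * AiKty)
      logdetW <- logdetW + 2 * sum(log(diag(cA)))
      blocks[[d]] <- list(K = K_d, AiKtX = AiKtX, AiKty = AiKty, cA = cA,
                          KtX = KtX)
    }
    extra <- list(blocks = blocks)
  }
  cX <- tryCatch(chol(XtWiX), error = function(e) NULL)
  if (is.null(cX)) {
    return(list(obj = .Machine$double.xmax))
  }
  beta <- backsolve(cX, forwardsolve(t(cX), XtWiy))
  rss <- max(ytWiy - sum(beta * XtWiy), 0)
  sigma2 <- rss / (n - p)
  obj <- if (sigma2 <= 0) {
    -Inf # exact interpolation; handled by the caller
  } else {
    logdetW + 2 * sum(log(diag(cX))) +
      (n - p) * (log(sigma2) + 1 + log(2 * pi))
  }
  c(list(obj = obj, beta = drop(beta), sigma2 = sigma2, logdetW = logdetW,
         logdetXtWiX = 2 * sum(log(diag(cX))), XtWiX = XtWiX,
         cX = cX), extra)
}

# BLUPs, fitted values and hat-matrix trace at a given L / pieces pair.
reml_finish <- function(L, ctx, pieces, beta) {
  q <- ctx$q
  psi_star <- tcrossprod(L)
  G <- chol2inv(pieces$cX)
  b <- matrix(0, ctx$D, q, dimnames = list(ctx$levels, colnames(ctx$Z)))
  if (q == 1) {
    r <- ctx$y - drop(ctx$X %*% beta)
    zr <- drop(rowsum(ctx$z * r, ctx$g))
    b[, 1] <- psi_star[1, 1] * zr / pieces$A
    fitted <- drop(ctx$X %*% beta) + ctx$z * unname(b[ctx$g, 1])
    tr_smooth <- sum(pieces$l2 * ctx$ztz / pieces$A)
    MtM <- crossprod(ctx$zX * sqrt(pieces$l2) / pieces$A)
  } else {
    fitted <- numeric(ctx$n)
    row_of <- split(seq_along(ctx$g), ctx$g)
    tr_smooth <- 0
    MtM <- matrix(0, ctx$p, ctx$p)
    for (d in seq_along(ctx$Xb)) {
      bl <- pieces$blocks[[d]]
      r_d <- ctx$yb[[d]] - ctx$Xb[[d]] %*% beta
      Wir <- r_d - bl$K %*% (bl$AiKty - bl$AiKtX %*% beta)
      b[d, ] <- psi_star %*% crossprod(ctx$Zb[[d]], Wir)
      fitted[row_of[[d]]] <- ctx$Xb[[d]] %*% beta + ctx$Zb[[d]] %*% b[d, ]
      KtK <- crossprod(bl$K)
      AiKtK <- backsolve(bl$cA, forwardsolve(t(bl$cA), KtK))
      tr_smooth <- tr_smooth + sum(diag(KtK)) - sum(KtK * t(AiKtK))
      M_d <- bl$KtX - KtK %*% bl$AiKtX
      MtM <- MtM + crossprod(M_d)
    }
  }
  list(b = b, fitted = fitted, edf = ctx$p + tr_smooth - sum(G * MtM))
}

#' Fit one region sub-model by restricted maximum likelihood
#'
#' Maximises the REML criterion of the region model over the variance
#' parameters (district random-effect covariance `Psi` and error variance
#' `sigma2`), then evaluates the generalized-least-squares fixed effects and
#' the best linear unbiased predictors of the district random effects at the
#' estimates,
#' \deqn{\hat\beta = (X'V^{-1}X)^{-1} X'V^{-1} y, \qquad
#'       \hat b = \Psi Z' V^{-1} (y - X\hat\beta),}
#' with \eqn{V = Z\Psi Z' + \sigma^2 I}. The error variance is profiled out
#' of the criterion and `Psi` is parameterised through its log-Cholesky
#' factor; with a single random effect the profiled criterion is optimised by
#' one-dimensional search, otherwise by BFGS with three deterministic
#' restarts. The marginal (unrestricted) log-likelihood at the same variance
#' estimates, the conditional log-likelihood given the predicted random
#' effects, the effective degrees of freedom (trace of the hat matrix mapping
#' `y` to `X b̂eta + Z b̂`), and the BIC-penalised conditional criterion
#' `caic_bic = -2 * cond_loglik + log(n) * edf` are returned alongside.
#'
#' @param y Response vector (member diseased counts).
#' @param X Fixed-effect matrix (`P` columns, intercept first).
#' @param Z Random-effect covariate matrix (`Q` columns); its block-diagonal
#'   structure over districts is given by `districts`.
#' @param districts Factor assigning each row to its district.
#' @param region Optional region id stored in the result.
#' @param control List: `maxit`, `reltol`, and the 1-D search bounds
#'   `lower`/`upper` on the log scale of `Psi*/sigma2`.
#' @return An object of class `region_fit`.
#' @export
fit_region_reml <- function(y, X, Z, districts, region = NA,
                            control = list()) {
  ctrl <- utils::modifyList(
    list(maxit = 500L, reltol = 1e-10, lower = -13, upper = 8), control
  )
  X <- as.matrix(X); Z <- as.matrix(Z)
  n <- length(y); p <- ncol(X); q <- ncol(Z)
  n_theta <- q * (q + 1) / 2
  if (n < p + n_theta + 2) {
    stop("too few cells to fit the region model (", n, " rows for ",
         p + n_theta + 1, " parameters)", call. = FALSE)
  }
  ctx <- make_reml_ctx(y, X, Z, districts)

  # exact-interpolation guard: an OLS fit with (numerically) zero residuals
  # pins all variance components at the boundary
  ols <- stats::lm.fit(X, y)
  if (max(abs(ols$residuals)) < 1e-10 * (1 + max(abs(y)))) {
    return(new_region_fit(
      region = region, beta = stats::setNames(ols$coefficients, colnames(X)),
      b = matrix(0, ctx$D, q, dimnames = list(ctx$levels, colnames(Z))),
      psi = matrix(0, q, q, dimnames = list(colnames(Z), colnames(Z))),
      sigma2 = 0, reml_loglik = NA_real_, ml_loglik = NA_real_,
      cond_loglik = NA_real_, edf = p, caic_bic = NA_real_,
      converged = TRUE, n = n, fitted = drop(X %*% ols$coefficients),
      columns = list(fixed = colnames(X), random = colnames(Z)),
      boundary = TRUE
    ))
  }

  objective <- function(theta) {
    reml_pieces(theta_to_L(theta, q), ctx)$obj
  }

  if (q == 1) {
    opt <- stats::optimize(objective, c(ctrl$lower, ctrl$upper), tol = 1e-9)
    theta_hat <- opt$minimum
    # compare with the Psi = 0 boundary (OLS limit of the criterion)
    obj0 <- objective(-60)
    if (obj0 <= opt$objective) theta_hat <- -60
    converged <- TRUE
  } else {
    starts <- list(rep(0, n_theta), rep(-2, n_theta), rep(1, n_theta))
    best <- NULL
    converged <- FALSE
    for (s in starts) {
      o <- stats::optim(s, objective, method = "BFGS",
                        control = list(maxit = ctrl$maxit,
                                       reltol = ctrl$reltol))
      if (is.null(best) || o$value < best$value) best <- o
      if (o$convergence == 0) {
        converged <- TRUE
        if (o$value <= best$value) best <- o
        break
      }
    }
    if (!converged) pa_warn("REML optimisation did not converge in region %s",
                            as.character(region))
    theta_hat <- best$par
  }

  L <- theta_to_L(theta_hat, q)
  pieces <- reml_pieces(L, ctx)
  beta <- stats::setNames(pieces$beta, colnames(X))
  sigma2 <- pieces$sigma2
  psi <- sigma2 * tcrossprod(L)
  dimnames(psi) <- list(colnames(Z), colnames(Z))
  fin <- reml_finish(L, ctx, pieces, beta)

  reml_ll <- -0.5 * pieces$obj
  ml_ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + pieces$logdetW +
                     (n - p))
  cond_ll <- sum(stats::dnorm(y, fin$fitted, sqrt(sigma2), log = TRUE))

  new_region_fit(
    region = region, beta = beta, b = fin$b, psi = psi, sigma2 = sigma2,
    reml_loglik = reml_ll, ml_loglik = ml_ll, cond_loglik = cond_ll,
    edf = fin$edf, caic_bic = -2 * cond_ll + log(n) * fin$edf,
    converged = converged, n = n, fitted = fin$fitted,
    columns = list(fixed = colnames(X), random = colnames(Z)),
    boundary = all(abs(psi) < 1e-12)
  )
}

new_region_fit <- function(region, beta, b, psi, sigma2, reml_loglik,
                           ml_loglik, cond_loglik, edf, caic_bic, converged,
                           n, fitted, columns, boundary) {
  structure(
    list(region = region, beta = beta, b = b, psi = psi, sigma2 = sigma2,
         reml_loglik = reml_loglik, ml_loglik = ml_loglik,
         cond_loglik = cond_loglik, edf = edf, caic_bic = caic_bic,
         converged = converged, n = n, fitted = fitted, columns = columns,
         boundary = boundary),
    class = "region_fit"
  )
}

#' @export
print.region_fit <- function(x, ...) {
  cat(sprintf("<region_fit %s>  n = %d cells, %s\n", x$region, x$n,
              if (x$converged) "converged" else "NOT converged"))
  cat("  fixed effects:\n")
  print(round(x$beta, 6))
  cat(sprintf("  sigma2 = %.4f, psi[1,1] = %.4f, edf = %.2f\n",
              x$sigma2, x$psi[1, 1], x$edf))
  invisible(x)
}

#' Explicit GLS/BLUP estimates at given variance parameters
#'
#' Evaluates the generalized-least-squares fixed-effect estimator and the
#' best linear unbiased predictor of the district random effects,
#' \deqn{\hat\beta = (X'V^{-1}X)^{-1}X'V^{-1}y, \qquad
#'       \hat b_d = \Psi Z_d' V_d^{-1}(y_d - X_d\hat\beta),}
#' at user-supplied `psi` and `sigma2`, without estimating them. The
#' computation runs through the district-blocked Cholesky factorisation used
#' by [fit_region_reml()] and agrees with the dense-matrix formulas to high
#' relative accuracy.
#'
#' @inheritParams fit_region_reml
#' @param psi Random-effect covariance (`Q x Q`, positive semidefinite).
#' @param sigma2 Error variance, strictly positive.
#' @return List with `beta`, `b` (one row per district) and `fitted`.
#' @export
gls_blup <- function(y, X, Z, districts, psi, sigma2) {
  if (!is.numeric(sigma2) || sigma2 <= 0) {
    stop("gls_blup requires sigma2 > 0", call. = FALSE)
  }
  X <- as.matrix(X); Z <- as.matrix(Z)
  psi <- as.matrix(psi)
  q <- ncol(Z)
  stopifnot(nrow(psi) == q, ncol(psi) == q)
  ev <- eigen(psi / sigma2, symmetric = TRUE)
  if (any(ev$values < -1e-10)) {
    stop("psi must be positive semidefinite", call. = FALSE)
  }
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), q)
  ctx <- make_reml_ctx(y, X, Z, districts)
  pieces <- reml_pieces(L, ctx)
  beta <- stats::setNames(pieces$beta, colnames(X))
  fin <- reml_finish(L, ctx, pieces, beta)
  list(beta = beta, b = fin$b, fitted = fin$fitted)
}

#' Fit the region-wise prevalence model on member data
#'
#' Splits the cell table into model regions (after applying the design's
#' region partition), builds the member-side design of every region and fits
#' each sub-model by [fit_region_reml()].
#'
#' @param records A [cell_table].
#' @param design A [model_design()].
#' @param control Passed to [fit_region_reml()].
#' @return An object of class `prevalence_fit`: a list of `region_fit`
#'   objects keyed by model region, plus the design.
#' @export
fit_prevalence_model <- function(records, design, control = list()) {
  records <- validate_cell_table(records)
  mr <- model_region_of(design, records$region)
  fits <- lapply(split(seq_len(nrow(records)), mr), function(i) {
    rows <- records[i, ]
    dm <- build_design_matrices(rows, design, "member")
    fit_region_reml(dm$y, dm$X, dm$Z, dm$districts,
                    region = mr[i][1], control = control)
  })
  pa_log("fitted %d region sub-models on %d member cells",
         length(fits), sum(records$n_member > 0))
  structure(list(fits = fits, design = design), class = "prevalence_fit")
}

#' @export
print.prevalence_fit <- function(x, ...) {
  cat(sprintf("<prevalence_fit>  %d region sub-models, design: %s\n",
              length(x$fits), paste(x$design$fixed, collapse = " + ")))
  invisible(x)
}

#' Compare two nested region fits
#'
#' Carries out the two comparisons used for model choice: a likelihood-ratio
#' test on the marginal (ML) log-likelihoods with a chi-square reference on
#' the difference in fixed-effect dimension, and the BIC-penalised
#' conditional criterion `caic_bic` of each fit (lower preferred). The
#' likelihood-ratio branch requires the smaller fit's fixed effects to be
#' nested in the larger fit's and the same response rows; the criterion
#' comparison is reported regardless.
#'
#' @param fit_small,fit_large `region_fit` objects.
#' @return A tibble with one row per comparison aspect.
#' @export
compare_fits <- function(fit_small, fit_large) {
  stopifnot(inherits(fit_small, "region_fit"), inherits(fit_large, "region_fit"))
  caic <- tibble::tibble(
    model = c("small", "large"),
    edf = c(fit_small$edf, fit_large$edf),
    caic_bic = c(fit_small$caic_bic, fit_large$caic_bic)
  )
  preferred <- caic$model[which.min(caic$caic_bic)]
  nested <- all(fit_small$columns$fixed %in% fit_large$columns$fixed)
  if (!nested) {
    stop("fixed effects of fit_small are not nested in fit_large; ",
         "likelihood-ratio comparison undefined (caic_bic of the fits: ",
         paste(signif(caic$caic_bic, 6), collapse = ", "), ")",
         call. = FALSE)
  }
  if (fit_small$n != fit_large$n) {
    stop("fits use different numbers of rows", call. = FALSE)
  }
  df <- length(fit_large$beta) - length(fit_small$beta)
  lr <- 2 * (fit_large$ml_loglik - fit_small$ml_loglik)
  tibble::tibble(
    lr_stat = lr,
    df = df,
    p_value = if (df > 0) stats::pchisq(lr, df, lower.tail = FALSE)
              else NA_real_,
    caic_bic_small = fit_small$caic_bic,
    caic_bic_large = fit_large$caic_bic,
    preferred = preferred
  )
}
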