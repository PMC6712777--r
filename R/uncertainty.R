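#' Semiparametric bootstrap confidence intervals
#'
#' Constructs percentile confidence intervals for cell-level aggregates of
#' the benchmark-adjusted prevalence by resampling the *estimated* random
#' effects and residuals of each region sub-model:
#'
#' 1. centre the predicted district random effects and the cell residuals of
#'    the member fit within each region,
#' 2. reflate both pools so their empirical second moments match the REML
#'    estimates exactly (`Psi_hat` for the random effects, `sigma2_hat` for
#'    the residuals),
#' 3. draw, for every replicate, district random-effect vectors and cell
#'    residuals independently with replacement from the reflated pools
#'    (within region, matching the region-specific error variance),
#' 4. rebuild the member response `y* = X b̂eta + Z b* + e*`, refit the full
#'    region-wise model on `y*`, and
#' 5. recompute the national benchmark predictions and the target aggregates.
#'
#' Intervals are the empirical `alpha/2` and `1 - alpha/2` percentiles over
#' replicates — no normality of the predictions is presupposed. Replicates
#' whose refit does not converge are dropped and logged; if more than 10% of
#' replicates drop, the summary is flagged invalid.
#'
#' @param object A [fit_prevalence_model()] result.
#' @param records The [cell_table] the model was fitted on.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; the resampling is reproducible bit for bit.
#' @param alpha Nominal error level of the intervals (default 0.05).
#' @param targets Aggregation levels to summarise (subset of
#'   `c("national", "region", "district", "age_group", "sex")`).
#' @param clamp Clamp replicate cell predictions into `[0, n_national]`.
#' @return An object of class `boot_summary`: a tibble of targets with
#'   `point`, `ci_low`, `ci_high`, plus the replicate values as attribute
#'   `"replicates"` (matrix `B_kept x n_targets`).
#' @export
bootstrap_prevalence <- function(object, records, B = 1000, seed = 1L,
                                 alpha = 0.05, targets = "national",
                                 clamp = TRUE) {
  stopifnot(inherits(object, "prevalence_fit"), B >= 2)
  targets <- match.arg(targets,
                       c("national", "region", "district", "age_group",
                         "sex"), several.ok = TRUE)
  records <- validate_cell_table(records)
  design <- object$design
  mr <- model_region_of(design, records$region)
  set.seed(split_seed(seed, "bootstrap"))

  # per-region precomputation: member matrices, reflated pools, national
  # matrices and district lookup
  regions <- lapply(split(seq_len(nrow(records)), mr), function(i) {
    rows <- records[i, ]
    fit <- object$fits[[model_region_of(design, rows$region[1])]]
    dm <- build_design_matrices(rows, design, "member")
    dn <- build_design_matrices(rows, design, "national")
    resid <- dm$y - fit$fitted
    prep <- list(
      fit = fit, rows_idx = i,
      Xm = dm$X, Zm = dm$Z, dm_districts = dm$districts,
      Xn = dn$X, Zn = dn$Z,
      dn_keys = as.character(dn$districts),
      mean_fit = drop(dm$X %*% fit$beta),
      b_pool = reflate_pool(fit$b, fit$psi),
      e_pool = reflate_resid(resid, fit$sigma2)
    )
    prep$d_levels <- rownames(fit$b)
    prep$Zb_map <- match(as.character(dm$districts), prep$d_levels)
    prep
  })

  # target group index over the full cell grid
  groups <- target_groups(records, targets)
  n_nat <- records$n_national

  predict_cells <- function(fits_by_region) {
    y_hat <- numeric(nrow(records))
    for (rg in regions) {
      fit <- fits_by_region[[model_region_of(design, records$region[rg$rows_idx][1])]]
      b_rows <- fit$b[match(rg$dn_keys, rownames(fit$b)), , drop = FALSE]
      b_rows[is.na(b_rows[, 1]), ] <- 0
      y <- drop(rg$Xn %*% fit$beta) + rowSums(rg$Zn * b_rows)
      y_hat[rg$rows_idx] <- y
    }
    if (clamp) y_hat <- clamp(y_hat, 0, n_nat)
    y_hat
  }
  agg <- function(y_hat) {
    vapply(groups, function(g) {
      sum(y_hat[g$rows]) / sum(n_nat[g$rows])
    }, numeric(1))
  }

  point <- agg(predict_cells(object$fits))

  reps <- matrix(NA_real_, B, length(groups),
                 dimnames = list(NULL, names(groups)))
  dropped <- 0L
  for (b in seq_len(B)) {
    fits_b <- list()
    ok <- TRUE
    for (key in names(object$fits)) {
      rg <- regions[[key]]
      D <- length(rg$d_levels)
      b_star <- rg$b_pool[sample.int(nrow(rg$b_pool), D, replace = TRUE), ,
                          drop = FALSE]
      rownames(b_star) <- rg$d_levels
      e_star <- rg$e_pool[sample.int(length(rg$e_pool), length(rg$e_pool),
                                     replace = TRUE)]
      y_star <- rg$mean_fit + rowSums(rg$Zm * b_star[rg$Zb_map, , drop = FALSE]) +
        e_star
      fit_b <- tryCatch(
        fit_region_reml(y_star, rg$Xm, rg$Zm, rg$dm_districts,
                        region = rg$fit$region),
        error = function(e) NULL
      )
      if (is.null(fit_b) || !fit_b$converged) {
        ok <- FALSE
        break
      }
      fits_b[[key]] <- fit_b
    }
    if (!ok) {
      dropped <- dropped + 1L
      next
    }
    reps[b, ] <- agg(predict_cells(fits_b))
  }
  reps <- reps[stats::complete.cases(reps), , drop = FALSE]
  invalid <- dropped > 0.1 * B
  if (dropped > 0) {
    pa_warn("dropped %d of %d bootstrap replicates (refit non-convergence)%s",
            dropped, B, if (invalid) "; summary flagged invalid" else "")
  }

  qs <- apply(reps, 2, stats::quantile, probs = c(alpha / 2, 1 - alpha / 2),
              names = FALSE, type = 7)
  summary <- tibble::tibble(
    level = vapply(groups, `[[`, "", "level"),
    group = names(groups),
    point = unname(point),
    ci_low = unname(qs[1, ]),
    ci_high = unname(qs[2, ])
  )
  structure(
    list(B = B, B_kept = nrow(reps), alpha = alpha, summary = summary,
         invalid = invalid),
    replicates = reps,
    class = "boot_summary"
  )
}

# Centre a pool of predicted random effects and rescale it so that its
# empirical second-moment matrix equals psi exactly.
reflate_pool <- function(b, psi) {
  b <- as.matrix(b)
  centred <- sweep(b, 2, colMeans(b))
  if (all(abs(psi) < 1e-14) || all(abs(centred) < 1e-14)) {
    return(matrix(0, nrow(b), ncol(b)))
  }
  S <- crossprod(centred) / nrow(b)
  cS <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(cS)) return(matrix(0, nrow(b), ncol(b)))
  ev <- eigen(psi, symmetric = TRUE)
  Cp <- diag(sqrt(pmax(ev$values, 0)), ncol(b)) %*% t(ev$vectors)
  out <- centred %*% solve(cS) %*% Cp
  dimnames(out) <- dimnames(b)
  out
}

reflate_resid <- function(r, sigma2) {
  centred <- r - mean(r)
  m2 <- mean(centred^2)
  if (sigma2 <= 0 || m2 <= 0) return(rep(0, length(r)))
  centred * sqrt(sigma2 / m2)
}

target_groups <- function(records, targets) {
  out <- list()
  for (lv in targets) {
    key <- switch(lv,
      national = rep("national", nrow(records)),
      region = paste0("region ", records$region),
      district = paste0("district ", records$region, "/", records$district),
      age_group = paste0("age_group ", records$age_group),
      sex = paste0("sex ", records$sex)
    )
    for (g in unique(key)) {
      out[[g]] <- list(level = lv, rows = which(key == g))
    }
  }
  out
}

#' @export
print.boot_summary <- function(x, ...) {
  cat(sprintf("<boot_summary>  B = %d (%d kept), alpha = %.3f%s\n", x$B,
              x$B_kept, x$alpha, if (x$invalid) "  [INVALID]" else ""))
  print(x$summary)
  invisible(x)
}
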