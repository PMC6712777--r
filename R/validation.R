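#' Monte-Carlo validation of the benchmark adjustment
#'
#' Repeats, for every scenario in a grid, the full estimation pipeline on
#' freshly generated synthetic populations and scores the benchmark-adjusted
#' national and district prevalence estimates against the generative truth,
#' side by side with the naive demographically scaled baseline. This is the
#' in-silico analogue of resampling member populations under scenarios that
#' mimic structural morbidity differences: if the adjusted estimates are
#' unbiased in expectation, inferring prevalence from inpatient diagnosis
#' frequencies is valid under that scenario.
#'
#' The estimation path never touches `y_national_true`; the truth is read
#' only when scoring.
#'
#' @param scenarios A [selection_scenario()] or a list of them (e.g. from
#'   [make_scenario_grid()]).
#' @param reps Replicates per scenario (`>= 2`).
#' @param seed Integer seed; replicate seeds are derived deterministically.
#' @param design Optional [model_design()]; default: intercept + cell size +
#'   the scenario's predictive auxiliary columns (the correctly specified
#'   design).
#' @param select If `TRUE`, run region-wise correlation selection on every
#'   replicate and use the elected columns instead of the scenario truth.
#' @param top_k,p_sel Selection parameters when `select = TRUE`; `p_sel`
#'   defaults to the scenario's number of predictive columns.
#' @param bootstrap_B If non-`NULL`, additionally run the semiparametric
#'   bootstrap with this many replicates on every Monte-Carlo run and report
#'   the empirical coverage of the nominal `1 - alpha` interval for the
#'   national prevalence.
#' @param alpha Interval level used for the coverage study.
#' @return A `validation_report` tibble with one row per scenario: mean bias,
#'   relative bias (percent), RMSE of the national prevalence estimate,
#'   district-level RMSE, the same for the naive baseline, coverage (if
#'   requested), replicate count and seed. Replicate-level results are
#'   attached as attribute `"replicates"`.
#' @export
monte_carlo_validation <- function(scenarios, reps, seed = 1L, design = NULL,
                                   select = FALSE, top_k = 10, p_sel = NULL,
                                   bootstrap_B = NULL, alpha = 0.05) {
  stopifnot(reps >= 2)
  if (inherits(scenarios, "selection_scenario")) scenarios <- list(scenarios)
  rep_rows <- list()
  for (s in seq_along(scenarios)) {
    sc <- scenarios[[s]]
    stopifnot(inherits(sc, "selection_scenario"))
    for (i in seq_len(reps)) {
      row <- tryCatch(
        mc_one_replicate(sc, split_seed(seed, "mc", s, i), design, select,
                         top_k, p_sel, bootstrap_B, alpha),
        error = function(e) tibble::tibble(failed = TRUE,
                                           error = conditionMessage(e))
      )
      row$scenario <- s
      row$rep <- i
      rep_rows[[length(rep_rows) + 1]] <- row
    }
  }
  rep_tbl <- dplyr::bind_rows(rep_rows)
  if (!"failed" %in% names(rep_tbl)) rep_tbl$failed <- FALSE
  rep_tbl$failed[is.na(rep_tbl$failed)] <- FALSE
  n_failed <- sum(rep_tbl$failed)
  if (n_failed > 0.1 * nrow(rep_tbl)) {
    stop("more than 10% of Monte-Carlo replicates failed (", n_failed, "/",
         nrow(rep_tbl), "); first error: ",
         rep_tbl$error[rep_tbl$failed][1], call. = FALSE)
  }
  ok <- rep_tbl[!rep_tbl$failed, ]
  report <- ok |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(
      reps = dplyr::n(),
      truth = mean(.data$truth),
      mean_bias = mean(.data$estimate - .data$truth),
      rel_bias_pct = 100 * mean(.data$estimate - .data$truth) /
        mean(.data$truth),
      rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
      mc_se = stats::sd(.data$estimate - .data$truth) / sqrt(dplyr::n()),
      naive_mean_bias = mean(.data$naive - .data$truth),
      naive_rel_bias_pct = 100 * mean(.data$naive - .data$truth) /
        mean(.data$truth),
      naive_rmse = sqrt(mean((.data$naive - .data$truth)^2)),
      naive_mc_se = stats::sd(.data$naive - .data$truth) / sqrt(dplyr::n()),
      district_rmse = mean(.data$district_rmse),
      coverage = if (all(is.na(.data$covered))) NA_real_
                 else mean(.data$covered, na.rm = TRUE),
      n_failed = n_failed,
      .groups = "drop"
    ) |>
    dplyr::mutate(seed = seed)
  attr(report, "replicates") <- rep_tbl
  class(report) <- c("validation_report", class(report))
  report
}

mc_one_replicate <- function(sc, rep_seed, design, select, top_k, p_sel,
                             bootstrap_B, alpha) {
  pop <- generate_population(sc, rep_seed)
  truth <- attr(pop, "truth")
  if (is.null(design)) {
    pred_cols <- sc$aux_labels[seq_len(sc$n_predictive)]
    design <- model_design(c("cell_size", pred_cols))
  }
  if (select) {
    rk <- rank_predictors_by_region(pop)
    el <- elect_predictors(rk, top_k = top_k,
                           p_sel = p_sel %||% sc$n_predictive)
    design <- model_design(c("cell_size", el$elected),
                           random = design$random,
                           region_partition = design$region_partition)
  }
  fit <- fit_prevalence_model(pop, design)
  tab <- predict_prevalence(fit, pop)
  nat <- aggregate_prevalence(tab, "national")
  dst <- aggregate_prevalence(tab, "district")
  truth_dst <- tibble::as_tibble(pop) |>
    dplyr::group_by(.data$region, .data$district) |>
    dplyr::summarise(p_true = sum(.data$y_national_true) /
                       sum(.data$n_national), .groups = "drop")
  dcmp <- dplyr::left_join(dst, truth_dst, by = c("region", "district"))
  covered <- NA
  if (!is.null(bootstrap_B)) {
    bs <- bootstrap_prevalence(fit, pop, B = bootstrap_B,
                               seed = split_seed(rep_seed, "ci"),
                               alpha = alpha, targets = "national")
    covered <- bs$summary$ci_low[1] <= truth$national_prevalence &&
      truth$national_prevalence <= bs$summary$ci_high[1]
  }
  tibble::tibble(
    truth = truth$national_prevalence,
    estimate = nat$prevalence,
    naive = nat$naive_prevalence,
    district_rmse = sqrt(mean((dcmp$prevalence - dcmp$p_true)^2)),
    covered = covered,
    failed = FALSE,
    error = NA_character_
  )
}

#' Cross-validation with a hospital-observed proxy endpoint
#'
#' Checks the extrapolation step on an endpoint that — unlike the disease
#' prevalence — is known in *both* populations: an inpatient diagnosis
#' frequency. The member count of `proxy` is treated as the endogenous
#' variable, the region-wise model is fitted on member data with the
#' remaining design predictors, the fit is extrapolated with the national
#' auxiliary benchmarks, and the predicted national total of the proxy is
#' compared to its known national total. A relative error near zero supports
#' the validity of the benchmark extrapolation; a clearly nonzero error
#' signals member/national distortions the auxiliary data cannot explain.
#'
#' @param records A [cell_table].
#' @param proxy Auxiliary diagnosis code used as proxy endpoint; must not be
#'   among the design predictors.
#' @param design A [model_design()] whose fixed columns exclude `proxy`.
#' @return An object of class `proxy_validation`: overall relative error,
#'   per-region errors, and the totals.
#' @export
cross_validation_proxy <- function(records, proxy, design) {
  records <- validate_cell_table(records)
  if (!proxy %in% aux_labels(records)) {
    stop("proxy column ", proxy, " not present in the auxiliary data",
         call. = FALSE)
  }
  if (proxy %in% design$fixed) {
    stop("proxy column ", proxy, " must not be among the design predictors",
         call. = FALSE)
  }
  mr <- model_region_of(design, records$region)
  per_region <- purrr::imap(split(seq_len(nrow(records)), mr), function(i, key) {
    rows <- records[i, ]
    dm <- build_design_matrices(rows, design, "member",
                                response = paste0("mem_", proxy))
    fit <- fit_region_reml(dm$y, dm$X, dm$Z, dm$districts, region = key)
    dn <- build_design_matrices(rows, design, "national")
    b_rows <- fit$b[match(as.character(dn$districts), rownames(fit$b)), ,
                    drop = FALSE]
    b_rows[is.na(b_rows[, 1]), ] <- 0
    y_hat <- drop(dn$X %*% fit$beta) + rowSums(dn$Z * b_rows)
    tibble::tibble(
      region = key,
      predicted_total = sum(y_hat),
      known_total = sum(rows[[paste0("nat_", proxy)]]),
      relative_error = (sum(y_hat) - sum(rows[[paste0("nat_", proxy)]])) /
        sum(rows[[paste0("nat_", proxy)]])
    )
  })
  per_region <- dplyr::bind_rows(per_region)
  overall <- (sum(per_region$predicted_total) - sum(per_region$known_total)) /
    sum(per_region$known_total)
  structure(
    list(proxy = proxy,
         relative_error = overall,
         predicted_total = sum(per_region$predicted_total),
         known_total = sum(per_region$known_total),
         per_region = per_region),
    class = "proxy_validation"
  )
}

#' @export
print.proxy_validation <- function(x, ...) {
  cat(sprintf("<proxy_validation %s>  relative error %.4g (predicted %.1f, known %.1f)\n",
              x$proxy, x$relative_error, x$predicted_total, x$known_total))
  invisible(x)
}
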