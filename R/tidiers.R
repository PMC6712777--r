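#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a region fit
#'
#' @param x A `region_fit`.
#' @param effects `"fixed"` returns one row per fixed-effect term,
#'   `"random"` one row per district and random-effect column.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.region_fit <- function(x, effects = c("fixed", "random"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") {
    tibble::tibble(region = x$region, term = names(x$beta),
                   estimate = unname(x$beta))
  } else {
    tibble::as_tibble(x$b, rownames = "district_key") |>
      tidyr::pivot_longer(-"district_key", names_to = "term",
                          values_to = "estimate") |>
      dplyr::mutate(region = x$region, .before = 1)
  }
}

#' @export
glance.region_fit <- function(x, ...) {
  tibble::tibble(
    region = x$region, n_cells_used = x$n,
    sigma2 = x$sigma2, psi_11 = x$psi[1, 1],
    reml_loglik = x$reml_loglik, ml_loglik = x$ml_loglik,
    edf = x$edf, caic_bic = x$caic_bic,
    converged = x$converged, boundary = x$boundary
  )
}

#' @export
tidy.prevalence_fit <- function(x, effects = "fixed", ...) {
  purrr::map_dfr(x$fits, tidy, effects = effects)
}

#' @export
glance.prevalence_fit <- function(x, ...) {
  purrr::map_dfr(x$fits, glance)
}

#' @export
tidy.boot_summary <- function(x, ...) {
  x$summary
}

#' @export
glance.boot_summary <- function(x, ...) {
  tibble::tibble(B = x$B, B_kept = x$B_kept, alpha = x$alpha,
                 invalid = x$invalid)
}

#' @export
tidy.selection_result <- function(x, ...) {
  dplyr::mutate(x$election_counts,
                elected = .data$label %in% x$elected)
}

#' @export
tidy.validation_report <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Plot the distribution of district-level prevalence adjustments
#'
#' @param object A `prevalence_table` from [predict_prevalence()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prevalence_table <- function(object, ...) {
  adj <- aggregate_prevalence(object, "district")
  ggplot2::ggplot(adj, ggplot2::aes(x = .data$relative_adjustment)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "relative prevalence adjustment [%]",
      y = "districts",
      title = "Member-to-national prevalence adjustment by district"
    )
}

#' Plot bootstrap intervals
#'
#' @param object A `boot_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.boot_summary <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$group, y = .data$point)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "prevalence",
                  title = sprintf("Percentile bootstrap, B = %d, %d%% intervals",
                                  object$B, round(100 * (1 - object$alpha))))
}

#' Plot a Monte-Carlo validation report
#'
#' Shows the relative bias of the benchmark-adjusted estimator against the
#' naive scaled baseline, per scenario, with 3 Monte-Carlo standard errors.
#'
#' @param object A `validation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.validation_report <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    dplyr::transmute(
      scenario = factor(.data$scenario),
      adjusted = .data$rel_bias_pct,
      naive = .data$naive_rel_bias_pct,
      se_adjusted = 100 * 3 * .data$mc_se / .data$truth,
      se_naive = 100 * 3 * .data$naive_mc_se / .data$truth
    ) |>
    tidyr::pivot_longer(c("adjusted", "naive"), names_to = "estimator",
                        values_to = "rel_bias") |>
    dplyr::mutate(se = ifelse(.data$estimator == "adjusted",
                              .data$se_adjusted, .data$se_naive))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$scenario, y = .data$rel_bias,
                                     colour = .data$estimator)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$rel_bias - .data$se,
                                          ymax = .data$rel_bias + .data$se),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(y = "relative bias of national prevalence [%]",
                  title = "Monte-Carlo validation: adjusted vs naive estimator")
}
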