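#' Naive demographically scaled baseline estimate
#'
#' Scales the member diseased count of every cell by the demographic scaling
#' factor `n_national / n_member`. Under fund-specific selectivity this
#' baseline is biased — members differ from the national population in
#' morbidity, not only in demographic composition — which is exactly the
#' problem the benchmark adjustment addresses. Cells without members have no
#' defined baseline and are flagged.
#'
#' @param records A [cell_table].
#' @return Tibble with the cell index, `naive_count`, `naive_prevalence`
#'   and `flag_undefined`.
#' @export
#' @examples
#' # N = 100, 50 members of whom 5 diseased: scaled count 10
naive_scaled_estimate <- function(records) {
  records <- validate_cell_table(records)
  tibble::as_tibble(records) |>
    dplyr::transmute(
      dplyr::across(dplyr::all_of(CELL_INDEX_COLS)),
      naive_count = ifelse(.data$n_member > 0,
                           .data$n_national / .data$n_member * .data$y_member,
                           NA_real_),
      naive_prevalence = .data$naive_count / .data$n_national,
      flag_undefined = .data$n_member == 0
    )
}

#' Benchmark prediction of national cell prevalence
#'
#' Applies the member-fitted region sub-models to the national auxiliary
#' benchmarks: for every cell,
#' \deqn{\hat y_{rd}^c = x_{rd}^{c\prime}\hat\beta_r + z_{rd}^{c\prime}\hat b_{rd},}
#' where `x` and `z` are built from the *national* population columns of the
#' same design that was fitted on the member side. Districts without any
#' member cell are predicted from the fixed effects alone (`b = 0`) and
#' flagged; this is what allows prevalence estimates for cells with zero
#' members. Raw predictions are retained in `y_hat_raw`; the reported
#' `y_hat` is clamped to `[0, n_national]` and clamped cells are flagged and
#' counted in the log.
#'
#' @param object A [fit_prevalence_model()] result.
#' @param records The [cell_table] to predict for (all cells, including
#'   member-free ones).
#' @param clamp Clamp predictions into `[0, n_national]` (default). Turn off
#'   when the response is a case count that may legitimately exceed the cell
#'   population, as in the proxy cross-validation.
#' @return A `prevalence_table` tibble with one row per cell: predictions,
#'   prevalence proportions, the naive baseline, member prevalence, the
#'   relative adjustment in percent, and flags.
#' @export
predict_prevalence <- function(object, records, clamp = TRUE) {
  stopifnot(inherits(object, "prevalence_fit"))
  records <- validate_cell_table(records)
  design <- object$design
  mr <- model_region_of(design, records$region)
  parts <- lapply(split(seq_len(nrow(records)), mr), function(i) {
    rows <- records[i, ]
    key <- mr[i][1]
    fit <- object$fits[[key]]
    if (is.null(fit)) {
      stop("no fitted sub-model for model region ", key, call. = FALSE)
    }
    dm <- build_design_matrices(rows, design, "national")
    if (!identical(colnames(dm$X), fit$columns$fixed)) {
      stop("column mismatch between member and national designs: ",
           paste(symdiff <- union(setdiff(colnames(dm$X), fit$columns$fixed),
                                  setdiff(fit$columns$fixed, colnames(dm$X))),
                 collapse = ", "), call. = FALSE)
    }
    dk <- as.character(dm$districts)
    b_rows <- fit$b[match(dk, rownames(fit$b)), , drop = FALSE]
    no_b <- is.na(b_rows[, 1])
    b_rows[no_b, ] <- 0
    y_raw <- drop(dm$X %*% fit$beta) + rowSums(dm$Z * b_rows)
    tibble::tibble(.row = i, y_hat_raw = y_raw,
                   flag_no_member_district = no_b)
  })
  pred <- dplyr::arrange(dplyr::bind_rows(parts), .data$.row)

  out <- tibble::as_tibble(records) |>
    dplyr::select(dplyr::all_of(c(CELL_INDEX_COLS,
                                  "n_national", "n_member", "y_member")))
  out$y_hat_raw <- pred$y_hat_raw
  out$y_hat <- if (clamp) clamp(pred$y_hat_raw, 0, out$n_national) else
    pred$y_hat_raw
  out$prevalence <- out$y_hat / out$n_national
  nv <- naive_scaled_estimate(records)
  out$naive_count <- nv$naive_count
  out$member_prevalence <- ifelse(out$n_member > 0,
                                  out$y_member / out$n_member, NA_real_)
  out$relative_adjustment <- relative_adjustment(
    out$member_prevalence, out$prevalence, quiet = TRUE
  )
  out$flag_zero_member <- out$n_member == 0
  out$flag_no_member_district <- pred$flag_no_member_district
  out$flag_clamped <- clamp & (pred$y_hat_raw < 0 |
                                 pred$y_hat_raw > out$n_national)
  n_cl <- sum(out$flag_clamped)
  if (n_cl > 0) pa_log("clamped %d of %d cell predictions", n_cl, nrow(out))
  class(out) <- c("prevalence_table", class(out))
  out
}

#' Aggregate a prevalence table
#'
#' Sums predicted and observed counts over the requested partition and
#' recomputes prevalence as summed diseased count over summed population.
#' Aggregation is exactly additive: any nesting of partitions yields the
#' same totals.
#'
#' @param table A `prevalence_table`.
#' @param level One of `"district"`, `"region"`, `"age_group"`, `"sex"`,
#'   `"national"`.
#' @return Tibble with group keys, summed counts, prevalence proportions,
#'   the member prevalence and the relative adjustment in percent.
#' @export
aggregate_prevalence <- function(table,
                                 level = c("national", "region", "district",
                                           "age_group", "sex")) {
  level <- match.arg(level)
  keys <- switch(level,
    national = character(0),
    region = "region",
    district = c("region", "district"),
    age_group = "age_group",
    sex = "sex"
  )
  tibble::as_tibble(table) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_national = sum(.data$n_national),
      n_member = sum(.data$n_member),
      y_hat = sum(.data$y_hat),
      y_member = sum(.data$y_member),
      naive_count = sum(.data$naive_count, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      level = level,
      prevalence = .data$y_hat / .data$n_national,
      naive_prevalence = .data$naive_count / .data$n_national,
      member_prevalence = ifelse(.data$n_member > 0,
                                 .data$y_member / .data$n_member, NA_real_),
      relative_adjustment = relative_adjustment(
        .data$member_prevalence, .data$prevalence, quiet = TRUE
      )
    ) |>
    dplyr::relocate("level")
}

#' Relative prevalence adjustment in percent
#'
#' The signed percentage by which the benchmark-adjusted estimate moves away
#' from the member prevalence: `100 * (estimate - member) / member`. A
#' negative value means the member population is sicker than the national
#' population, as for the fund studied in the motivating application.
#'
#' @param member_prevalence Member prevalence proportion(s), `> 0`.
#' @param estimate Adjusted prevalence proportion(s).
#' @param quiet Suppress the warning for undefined entries.
#' @return Numeric vector of signed percentages; `NA` where the member
#'   prevalence is zero or missing.
#' @export
#' @examples
#' relative_adjustment(0.10, 0.08) # -20
relative_adjustment <- function(member_prevalence, estimate, quiet = FALSE) {
  out <- ifelse(!is.na(member_prevalence) & member_prevalence > 0,
                100 * (estimate - member_prevalence) / member_prevalence,
                NA_real_)
  if (!quiet && anyNA(out)) {
    pa_warn("relative adjustment undefined for %d entr%s (member prevalence 0)",
            sum(is.na(out)), if (sum(is.na(out)) == 1) "y" else "ies")
  }
  out
}
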