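#' Region-wise correlation ranking of auxiliary predictors
#'
#' For every region, computes the Pearson correlation between the member
#' prevalence proportion (`y_member / n_member`) and the member per-capita
#' rate of each candidate diagnosis (`mem_<code> / n_member`) over the
#' region's cells, and ranks candidates by descending absolute correlation.
#' Rates rather than raw counts are used so that cell size does not induce
#' spurious correlation. Cells without members are excluded; a region needs
#' at least three usable cells. A candidate with zero variance within a
#' region receives correlation 0 with a logged warning.
#'
#' @param records A [cell_table].
#' @param candidates Candidate diagnosis codes; default: all auxiliary
#'   columns.
#' @return Tibble with `region`, `label`, `correlation`, `rank` (1 = best
#'   within region; ties broken by label for determinism).
#' @export
rank_predictors_by_region <- function(records, candidates = NULL) {
  records <- validate_cell_table(records)
  candidates <- candidates %||% aux_labels(records)
  missing <- setdiff(candidates, aux_labels(records))
  if (length(missing) > 0) {
    stop("candidate column(s) not present in the member auxiliary data: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  per_region <- split(seq_len(nrow(records)), records$region)
  out <- purrr::imap(per_region, function(i, reg) {
    rows <- records[i, ]
    rows <- rows[rows$n_member > 0, ]
    if (nrow(rows) < 3) {
      stop("region ", reg, " has fewer than 3 usable cells", call. = FALSE)
    }
    prev <- rows$y_member / rows$n_member
    cors <- vapply(candidates, function(lab) {
      rate <- rows[[paste0("mem_", lab)]] / rows$n_member
      if (stats::sd(rate) == 0 || stats::sd(prev) == 0) {
        pa_warn("zero-variance candidate %s in region %s; correlation set to 0",
                lab, reg)
        return(0)
      }
      stats::cor(prev, rate)
    }, numeric(1))
    tibble::tibble(region = rows$region[1], label = candidates,
                   correlation = unname(cors)) |>
      dplyr::arrange(dplyr::desc(abs(.data$correlation)), .data$label) |>
      dplyr::mutate(rank = dplyr::row_number())
  })
  dplyr::bind_rows(out)
}

#' Elect predictors across regions
#'
#' Counts, for every candidate, the number of regions in which it reaches
#' that region's top `top_k` by absolute correlation, and elects the `p_sel`
#' most frequently chosen candidates. Ties in election counts are broken by
#' mean absolute correlation across regions, then by lexicographic label, so
#' the election is deterministic and auditable.
#'
#' @param rankings Output of [rank_predictors_by_region()].
#' @param top_k Region-level shortlist size (default 10).
#' @param p_sel Number of predictors to elect (default 10).
#' @return An object of class `selection_result` with elements `elected`
#'   (ordered character vector), `election_counts` (tibble), and the input
#'   `rankings`.
#' @export
elect_predictors <- function(rankings, top_k = 10, p_sel = 10) {
  stopifnot(top_k >= 1, p_sel >= 1)
  n_cand <- length(unique(rankings$label))
  if (p_sel > n_cand) {
    stop("p_sel (", p_sel, ") exceeds the number of candidates (", n_cand,
         ")", call. = FALSE)
  }
  counts <- rankings |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      elections = sum(.data$rank <= top_k),
      mean_abs_correlation = mean(abs(.data$correlation)),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$elections),
                   dplyr::desc(.data$mean_abs_correlation), .data$label)
  structure(
    list(elected = counts$label[seq_len(p_sel)],
         election_counts = counts,
         rankings = rankings),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> elected predictors:\n  ",
      paste(x$elected, collapse = ", "), "\n", sep = "")
  invisible(x)
}
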