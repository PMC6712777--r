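#' Cell-level data model
#'
#' The estimation unit throughout the package is the *cell*: the cross of an
#' administrative district, an age group and sex. A cell table is a tibble
#' with one row per cell and the columns
#'
#' * `region`, `district`: integer ids; districts are numbered within their
#'   region (`1..D_r`), every district belongs to exactly one region,
#' * `cell`: integer id encoding the (age group, sex) pair,
#' * `age_group` (ordered factor), `sex` (factor `female`/`male`),
#' * `n_national`: persons in the cell in the national population,
#' * `n_member`: persons in the cell that are members of the insurance fund,
#' * `y_member`: diseased members in the cell,
#' * `y_national_true`: diseased persons in the national population — known
#'   for synthetic populations only, `NA` otherwise,
#' * one pair of auxiliary columns per diagnosis code: `mem_<code>` (member
#'   inpatient case counts) and `nat_<code>` (national case counts). The two
#'   sets must carry identical codes: whatever predictor set is isolated in
#'   the member records must be available as a national benchmark too.
#'
#' The cell grid is dense: every district carries the complete set of
#' `n_age_groups * 2` cells. Missing member data is encoded as
#' `n_member = 0`, never by an absent row.
#'
#' @name cell_table
NULL

CELL_INDEX_COLS <- c("region", "district", "cell", "age_group", "sex")
CELL_COUNT_COLS <- c("n_national", "n_member", "y_member", "y_national_true")

#' Extract the auxiliary diagnosis labels of a cell table
#'
#' @param records A cell table.
#' @return Character vector of diagnosis codes present as matched
#'   `mem_<code>` / `nat_<code>` column pairs, in column order.
#' @export
aux_labels <- function(records) {
  mem <- sub("^mem_", "", grep("^mem_", names(records), value = TRUE))
  nat <- sub("^nat_", "", grep("^nat_", names(records), value = TRUE))
  if (!setequal(mem, nat)) {
    stop("auxiliary columns are not matched between member and national ",
         "data; unmatched: ",
         paste(union(setdiff(mem, nat), setdiff(nat, mem)), collapse = ", "),
         call. = FALSE)
  }
  mem
}

#' Build a dense cell grid
#'
#' Crosses regions, districts, age groups and sexes into the complete cell
#' index. With the German dimensions (402 districts, 4 age groups, both
#' sexes) this yields 3216 cells.
#'
#' @param districts_per_region Integer vector: number of districts in each
#'   region (its length is the number of regions).
#' @param age_labels Ordered age-group labels (coarsest first).
#' @param sex_labels Sex labels, default `c("female", "male")`.
#' @return Tibble with the index columns of [cell_table].
#' @export
#' @examples
#' nrow(make_cell_grid(rep(25L, 16), default_age_labels(4))) # not 3216: toy
make_cell_grid <- function(districts_per_region,
                           age_labels = default_age_labels(4),
                           sex_labels = default_sex_labels()) {
  stopifnot(length(districts_per_region) >= 1, all(districts_per_region >= 1))
  regions <- seq_along(districts_per_region)
  idx <- tidyr::expand_grid(
    region = regions
  ) |>
    dplyr::mutate(n_d = districts_per_region[.data$region]) |>
    tidyr::uncount(.data$n_d, .id = "district")
  cells <- tidyr::expand_grid(
    age_group = factor(age_labels, levels = age_labels, ordered = TRUE),
    sex = factor(sex_labels, levels = sex_labels)
  ) |>
    dplyr::mutate(cell = dplyr::row_number())
  tidyr::expand_grid(idx, cells) |>
    dplyr::select("region", "district", "cell", "age_group", "sex")
}

#' Validate a cell table
#'
#' Checks the cell-table invariants: required columns, matched auxiliary
#' column pairs, a dense duplicate-free cell grid, and the count orderings
#' `n_member <= n_national`, `y_member <= n_member`, and (where known)
#' `y_member <= y_national_true <= n_national`.
#'
#' @param records A candidate cell table.
#' @return The validated table, invisibly classed as `cell_table`.
#' @export
validate_cell_table <- function(records) {
  needed <- c(CELL_INDEX_COLS, "n_national", "n_member", "y_member")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    stop("cell table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"y_national_true" %in% names(records)) {
    records$y_national_true <- NA_real_
  }
  labs <- aux_labels(records)

  cell_id <- function(df) {
    paste(df$region, df$district, df$cell, sep = "/")
  }
  dup <- duplicated(cell_id(records))
  if (any(dup)) {
    stop("duplicate cell index: ", cell_id(records)[dup][1], call. = FALSE)
  }
  # dense grid: every (region, district) carries the full cell set
  n_cells <- length(unique(records$cell))
  per_district <- dplyr::count(records, .data$region, .data$district)
  bad <- per_district$n != n_cells
  if (any(bad)) {
    stop("incomplete cell grid in region ", per_district$region[bad][1],
         ", district ", per_district$district[bad][1], call. = FALSE)
  }

  fail <- function(cond, what) {
    if (any(cond, na.rm = TRUE)) {
      i <- which(cond)[1]
      stop("invariant violation (", what, ") at cell ",
           cell_id(records)[i], call. = FALSE)
    }
  }
  fail(records$n_national < 0, "n_national >= 0")
  fail(records$n_member > records$n_national, "n_member <= n_national")
  fail(records$y_member > records$n_member, "y_member <= n_member")
  fail(records$y_national_true > records$n_national,
       "y_national_true <= n_national")
  fail(records$y_national_true < records$y_member,
       "y_national_true >= y_member")

  out <- tibble::as_tibble(records)
  class(out) <- c("cell_table", class(out))
  attr(out, "aux_labels") <- labs
  invisible(out)
}

#' Read a cell table from CSV
#'
#' Reads a comma-separated, UTF-8 cell table with a mandatory header row and
#' validates all cell invariants. Auxiliary diagnosis columns are recognised
#' by the `mem_` / `nat_` prefixes.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector renaming file columns to the
#'   canonical names, e.g. `c(n_national = "pop_total")`: names are canonical,
#'   values are the column names found in the file.
#' @return A validated [cell_table] tibble.
#' @export
read_cell_table <- function(path, schema = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    absent <- setdiff(unname(schema), names(raw))
    if (length(absent) > 0) {
      stop("schema names column(s) not present in file: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    raw <- dplyr::rename(raw, !!!rlang::set_names(schema, names(schema)))
  }
  if ("age_group" %in% names(raw) && !is.factor(raw$age_group)) {
    lv <- unique(raw$age_group)
    raw$age_group <- factor(raw$age_group, levels = lv, ordered = TRUE)
  }
  if ("sex" %in% names(raw) && !is.factor(raw$sex)) {
    raw$sex <- factor(raw$sex, levels = unique(raw$sex))
  }
  out <- validate_cell_table(raw)
  pa_log("read %d cells (%d regions, %d aux columns) from %s",
         nrow(out), length(unique(out$region)),
         length(aux_labels(out)), path)
  out
}

#' Write a cell table to CSV
#'
#' @param records A [cell_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(records, path) {
  readr::write_csv(tibble::as_tibble(records), path, progress = FALSE)
  invisible(path)
}

#' Write a prevalence table and aggregate companions to CSV
#'
#' Writes the per-cell prevalence table to `path` and, for every requested
#' aggregation level, a companion file `<stem>_<level>.csv` next to it.
#' Values round-trip through [readr::read_csv()] at full double precision.
#'
#' @param table A prevalence table as returned by [predict_prevalence()].
#' @param path Output path of the cell-level file.
#' @param levels Aggregation levels for companion files (subset of
#'   `c("district", "region", "age_group", "sex", "national")`), or `NULL`.
#' @return Named character vector of files written, invisibly.
#' @export
write_prevalence_table <- function(table, path, levels = NULL) {
  readr::write_csv(tibble::as_tibble(table), path, progress = FALSE)
  written <- c(cell = path)
  stem <- sub("\\.csv$", "", path)
  for (lv in levels) {
    p <- paste0(stem, "_", lv, ".csv")
    readr::write_csv(aggregate_prevalence(table, lv), p, progress = FALSE)
    written[lv] <- p
  }
  pa_log("wrote prevalence tables: %s", paste(written, collapse = ", "))
  invisible(written)
}
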