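#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML file with the sections
#' `seed` (integer, mandatory), `output_dir`, `stages` (any of `generate`,
#' `select`, `fit`, `estimate`, `bootstrap`, `validate`), `input` (path to an
#' existing cell table CSV) *or* `scenario` (arguments of
#' [selection_scenario()]), `design` (`fixed`, `random`; the token
#' `"<elected>"` in `fixed` is replaced by the columns elected in the
#' `select` stage), `selection` (`top_k`, `p_sel`), `bootstrap` (`B`,
#' `alpha`, `targets`), and `validate` (`reps`, optionally `axis` and
#' `values` for a scenario grid).
#'
#' @param path Path to a YAML configuration file.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) {
    stop("config parse error: missing section 'seed'", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$output_dir <- cfg$output_dir %||% "prevadjust-run"
  cfg$stages <- cfg$stages %||%
    c("generate", "select", "fit", "estimate", "bootstrap")
  bad <- setdiff(cfg$stages, c("generate", "select", "fit", "estimate",
                               "bootstrap", "validate"))
  if (length(bad) > 0) {
    stop("config parse error: unknown stage(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

config_scenario <- function(cfg) {
  args <- cfg$scenario %||% list()
  if (!is.null(args$districts_per_region)) {
    args$districts_per_region <- as.integer(unlist(args$districts_per_region))
  }
  do.call(selection_scenario, args)
}

config_design <- function(cfg, elected = NULL) {
  d <- cfg$design
  if (is.null(d) || is.null(d$fixed)) {
    stop("config parse error: missing section 'design' (fixed columns)",
         call. = FALSE)
  }
  fixed <- unlist(d$fixed)
  if ("<elected>" %in% fixed) {
    if (is.null(elected)) {
      stop("design uses '<elected>' but the select stage did not run",
           call. = FALSE)
    }
    fixed <- c(setdiff(fixed, "<elected>"), elected)
  }
  model_design(fixed, random = unlist(d$random %||% "(Intercept)"))
}

#' Run the estimation pipeline from a configuration
#'
#' Executes the requested stages in order — `generate` (or read the input
#' cell table), `select`, `fit`, `estimate`, `bootstrap`, `validate` — and
#' writes every artifact as CSV into the configured output directory,
#' together with a `run_metadata.json` sidecar holding the seed and a hash
#' of the configuration. Rerunning with an identical configuration
#' reproduces all numeric outputs exactly. On stage failure a `FAILED`
#' marker naming the stage is left next to the partial artifacts and the
#' error is rethrown.
#'
#' @param config A `run_config` from [read_run_config()], or a path to one.
#' @param stages Optional stage subset overriding the config.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config, stages = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stages <- stages %||% config$stages
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old_opt <- options(prevadjust.verbose = isTRUE(config$verbose))
  on.exit(options(old_opt), add = TRUE)
  artifacts <- list()
  current_stage <- NA_character_

  run <- function() {
    records <- NULL
    elected <- NULL
    fit <- NULL
    tab <- NULL

    if ("generate" %in% stages) {
      current_stage <<- "generate"
      sc <- config_scenario(config)
      records <- generate_population(sc, config$seed)
      p <- file.path(out_dir, "population.csv")
      write_cell_table(records, p)
      artifacts$population <<- p
    } else if (!is.null(config$input)) {
      records <- read_cell_table(config$input)
    }

    if ("select" %in% stages) {
      current_stage <<- "select"
      if (is.null(records)) stop("select stage needs a cell table")
      sel <- config$selection %||% list()
      rk <- rank_predictors_by_region(records)
      el <- elect_predictors(rk, top_k = sel$top_k %||% 10,
                             p_sel = sel$p_sel %||% 10)
      elected <- el$elected
      p <- file.path(out_dir, "selection.csv")
      readr::write_csv(tidy(el), p, progress = FALSE)
      artifacts$selection <<- p
    }

    if (any(c("fit", "estimate", "bootstrap") %in% stages)) {
      current_stage <<- "fit"
      if (is.null(records)) stop("fit stage needs a cell table")
      design <- config_design(config, elected)
      fit <- fit_prevalence_model(records, design)
      p <- file.path(out_dir, "fit_summary.csv")
      readr::write_csv(glance(fit), p, progress = FALSE)
      artifacts$fit_summary <<- p
    }

    if ("estimate" %in% stages) {
      current_stage <<- "estimate"
      tab <- predict_prevalence(fit, records)
      written <- write_prevalence_table(
        tab, file.path(out_dir, "prevalence.csv"),
        levels = c("district", "region", "age_group", "sex", "national")
      )
      artifacts$prevalence <<- written
    }

    if ("bootstrap" %in% stages) {
      current_stage <<- "bootstrap"
      bs_cfg <- config$bootstrap %||% list()
      bs <- bootstrap_prevalence(
        fit, records,
        B = bs_cfg$B %||% 1000,
        seed = split_seed(config$seed, "bootstrap-stage"),
        alpha = bs_cfg$alpha %||% 0.05,
        targets = unlist(bs_cfg$targets %||% "national")
      )
      p <- file.path(out_dir, "bootstrap_ci.csv")
      readr::write_csv(bs$summary, p, progress = FALSE)
      artifacts$bootstrap <<- p
    }

    if ("validate" %in% stages) {
      current_stage <<- "validate"
      v <- config$validate %||% list()
      base <- config_scenario(config)
      grid <- if (!is.null(v$axis)) {
        make_scenario_grid(base, v$axis, v$values)
      } else {
        list(base)
      }
      rep_design <- tryCatch(config_design(config, elected),
                             error = function(e) NULL)
      vr <- monte_carlo_validation(grid, reps = v$reps %||% 10,
                                   seed = split_seed(config$seed, "validate"),
                                   design = rep_design)
      p <- file.path(out_dir, "validation.csv")
      readr::write_csv(tibble::as_tibble(vr), p, progress = FALSE)
      artifacts$validation <<- p
    }
  }

  status <- tryCatch({
    run()
    0L
  }, error = function(e) {
    writeLines(
      c(paste("stage:", current_stage), paste("error:", conditionMessage(e))),
      file.path(out_dir, "FAILED")
    )
    stop("pipeline failed in stage '", current_stage, "': ",
         conditionMessage(e), call. = FALSE)
  })

  meta <- list(
    seed = config$seed,
    stages = stages,
    config_hash = rlang::hash(unclass(config)),
    artifacts = artifacts
  )
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  pa_log("pipeline finished (%d artifacts) in %s", length(artifacts), out_dir)
  invisible(c(artifacts, list(status = status, metadata = meta)))
}
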