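#' Define a synthetic selection scenario
#'
#' A scenario is the generative truth behind a synthetic national population
#' with an informatively selected insurance-member subpopulation. It fixes
#'
#' * the hierarchy (regions, districts per region, age groups, sexes),
#' * the outcome model: expected diseased count per cell
#'   `mu = beta_size * N + sum_j beta_aux[j] * x_j + b_d`, with district
#'   random intercepts `b_d ~ N(0, psi)` shared between the member and the
#'   national outcome and an extra cell-level Gaussian disturbance with
#'   region-specific variance `sigma2`,
#' * the auxiliary-count model: per-cell Poisson counts for each diagnosis
#'   code, with an age/sex morbidity profile and a district-level latent
#'   morbidity score that loads on the predictive columns only,
#' * the membership mechanism: a cell-level propensity on the logit scale
#'   (intercept + age + sex terms). Diagnosis counts and diseased persons of
#'   members are binomial thinnings of the national counts; `gamma_morbidity`
#'   shifts the thinning odds of everything morbidity-related, which makes
#'   members sicker per capita than the national population *through the
#'   auxiliary variables* — the identifying equality of conditional
#'   expectations still holds and the benchmark adjustment can succeed,
#' * the violation switch: with `informative_beyond_aux = TRUE`, diseased
#'   members are additionally enriched by `gamma_residual` on the log scale
#'   beyond what the auxiliary counts explain; the identifying assumption
#'   then fails by construction and the adjustment is expected to be biased.
#'
#' With all selectivity coefficients zero the member population is a simple
#' random subsample of every cell.
#'
#' @param districts_per_region Integer vector, one entry per region.
#' @param n_age_groups Number of age groups (cells per district =
#'   `2 * n_age_groups`).
#' @param pop_cell_mean Mean national persons per cell.
#' @param age_pop_weights Relative population sizes of the age groups.
#' @param n_aux,n_predictive Number of auxiliary diagnosis columns and how
#'   many of them truly enter the outcome model (the first `n_predictive`).
#' @param aux_rate_base Baseline per-capita inpatient case rate per column.
#' @param aux_age_profile Log-scale age morbidity profile of the predictive
#'   columns (centred internally so the mean rate stays `aux_rate_base`).
#' @param aux_sex_effect Log-scale male effect on predictive column rates.
#' @param aux_profile_sd SD of the random log-scale age/sex profiles of the
#'   non-predictive (noise) columns.
#' @param aux_district_sd SD of the district latent morbidity score loading
#'   on predictive columns.
#' @param prevalence_base Disease probability carried by the cell-size
#'   covariate (the `beta_size` coefficient).
#' @param prevalence_aux Total disease probability carried by the predictive
#'   auxiliary columns at their baseline rates; divided equally over them to
#'   form `beta_aux`.
#' @param region_beta_scale Per-region multiplier on `beta_aux` (length =
#'   number of regions), making the fixed effects region-specific.
#' @param psi Variance of the district random intercept (count scale).
#' @param sigma2 Extra cell-level error variance, recycled over regions.
#' @param membership_rate Baseline member share of a cell.
#' @param gamma_age,gamma_sex Demographic selectivity: log-odds shifts of the
#'   membership propensity by age group and for males.
#' @param gamma_morbidity Morbidity selectivity: log-odds shift applied to
#'   the thinning of diagnosis counts and diseased persons.
#' @param gamma_residual Residual-morbidity selectivity used only when
#'   `informative_beyond_aux = TRUE`.
#' @param informative_beyond_aux Logical: if `TRUE`, membership is
#'   informative for disease status beyond the auxiliary data.
#' @param binomial_outcome Logical: draw realized diseased counts binomially
#'   with mean equal to the linear predictor (default), or map the linear
#'   predictor deterministically to a rounded count.
#' @param noise_seed Integer folded into every seed used by the generator.
#' @return An object of class `selection_scenario`.
#' @seealso [generate_population()], [make_scenario_grid()]
#' @export
selection_scenario <- function(districts_per_region = rep(12L, 4),
                               n_age_groups = 4,
                               pop_cell_mean = 2000,
                               age_pop_weights = NULL,
                               n_aux = 10,
                               n_predictive = 3,
                               aux_rate_base = 0.05,
                               aux_age_profile = NULL,
                               aux_sex_effect = 0.15,
                               aux_profile_sd = 0.2,
                               aux_district_sd = 0.3,
                               prevalence_base = 0.03,
                               prevalence_aux = 0.05,
                               region_beta_scale = NULL,
                               psi = 64,
                               sigma2 = 225,
                               membership_rate = 0.30,
                               gamma_age = NULL,
                               gamma_sex = -0.05,
                               gamma_morbidity = 0.6,
                               gamma_residual = 0.4,
                               informative_beyond_aux = FALSE,
                               binomial_outcome = TRUE,
                               noise_seed = 1L) {
  R <- length(districts_per_region)
  stopifnot(R >= 1, all(districts_per_region >= 1), n_age_groups >= 1,
            n_aux >= 1, n_predictive >= 0, n_predictive <= n_aux,
            pop_cell_mean > 0, aux_rate_base > 0)
  psi <- as.matrix(psi)
  if (nrow(psi) != ncol(psi) || any(psi != t(psi)) ||
      any(eigen(psi, symmetric = TRUE, only.values = TRUE)$values < -1e-10)) {
    stop("psi must be a symmetric positive-semidefinite matrix", call. = FALSE)
  }
  sigma2 <- rep_len(sigma2, R)
  if (any(sigma2 < 0)) stop("sigma2 must be nonnegative", call. = FALSE)
  if (membership_rate <= 0 || membership_rate >= 1) {
    stop("membership_rate must lie strictly in (0, 1)", call. = FALSE)
  }
  age_pop_weights <- age_pop_weights %||%
    seq(1.4, 0.7, length.out = n_age_groups)
  aux_age_profile <- aux_age_profile %||%
    seq(-1.2, 1.1, length.out = n_age_groups)
  gamma_age <- gamma_age %||% seq(-0.15, 0.25, length.out = n_age_groups)
  stopifnot(length(age_pop_weights) == n_age_groups,
            length(aux_age_profile) == n_age_groups,
            length(gamma_age) == n_age_groups)
  region_beta_scale <- region_beta_scale %||% rep(1, R)
  stopifnot(length(region_beta_scale) == R)

  # ICD-3-style labels: the printed comorbidity set first, synthetic codes after
  icd <- c("E11_secondary", "E78_secondary", "E87_secondary", "G81_secondary",
           "I10_secondary", "I48_main", "I63_main", "K29_secondary",
           "M16_main", "T81_secondary")
  labels <- if (n_aux <= length(icd)) icd[seq_len(n_aux)] else {
    c(icd, sprintf("N%02d_main", seq_len(n_aux - length(icd))))
  }

  beta_aux <- if (n_predictive > 0) {
    rep(prevalence_aux / (n_predictive * aux_rate_base), n_predictive)
  } else {
    numeric(0)
  }

  structure(
    list(
      districts_per_region = as.integer(districts_per_region),
      n_age_groups = as.integer(n_age_groups),
      age_labels = default_age_labels(n_age_groups),
      pop_cell_mean = pop_cell_mean,
      age_pop_weights = age_pop_weights,
      n_aux = as.integer(n_aux),
      n_predictive = as.integer(n_predictive),
      aux_labels = labels,
      aux_rate_base = aux_rate_base,
      aux_age_profile = aux_age_profile,
      aux_sex_effect = aux_sex_effect,
      aux_profile_sd = aux_profile_sd,
      aux_district_sd = aux_district_sd,
      beta_size = prevalence_base,
      beta_aux = beta_aux,
      region_beta_scale = region_beta_scale,
      psi = psi,
      sigma2 = sigma2,
      membership_rate = membership_rate,
      gamma_age = gamma_age,
      gamma_sex = gamma_sex,
      gamma_morbidity = gamma_morbidity,
      gamma_residual = gamma_residual,
      informative_beyond_aux = isTRUE(informative_beyond_aux),
      binomial_outcome = isTRUE(binomial_outcome),
      noise_seed = as.integer(noise_seed)
    ),
    class = "selection_scenario"
  )
}

#' @export
print.selection_scenario <- function(x, ...) {
  cat("<selection_scenario>\n")
  cat(sprintf("  %d regions, %d districts, %d cells\n",
              length(x$districts_per_region), sum(x$districts_per_region),
              sum(x$districts_per_region) * x$n_age_groups * 2L))
  cat(sprintf("  %d auxiliary columns (%d predictive)\n",
              x$n_aux, x$n_predictive))
  cat(sprintf("  membership %.2f, gamma_morbidity %.2f, beyond-aux: %s\n",
              x$membership_rate, x$gamma_morbidity,
              x$informative_beyond_aux))
  invisible(x)
}

#' Generate a synthetic population from a scenario
#'
#' Draws one national population with its member subpopulation, cell by cell:
#' national cell sizes (Poisson around the scenario's population pyramid),
#' national auxiliary diagnosis counts (Poisson), district random intercepts
#' `b_d ~ N(0, psi)` shared between the member and the national outcome,
#' realized national diseased counts with mean equal to the outcome linear
#' predictor, and member quantities by binomial thinning of the national
#' ones: persons at the cell propensity, morbidity-related counts (diagnosis
#' counts and diseased persons) at odds shifted by `gamma_morbidity`.
#' Diseased members are drawn from the realized national diseased count with
#' a thinning probability that makes the member conditional expectation equal
#' the member linear predictor — so the identifying assumption of the
#' benchmark adjustment holds by construction unless
#' `informative_beyond_aux = TRUE`.
#'
#' Identical `(scenario, seed)` pairs reproduce the population bit for bit.
#'
#' @param scenario A [selection_scenario()].
#' @param seed Integer seed.
#' @return A validated [cell_table] with `y_national_true` filled; the
#'   generative truth (coefficients, random effects, realized national
#'   prevalence) is attached as attribute `"truth"`.
#' @export
generate_population <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "selection_scenario"))
  sc <- scenario
  set.seed(split_seed(seed, sc$noise_seed, "population"))

  grid <- make_cell_grid(sc$districts_per_region, sc$age_labels)
  n <- nrow(grid)
  age_i <- as.integer(grid$age_group)
  male <- as.integer(grid$sex == "male")
  district_key <- paste(grid$region, grid$district, sep = "/")
  districts <- unique(district_key)
  d_idx <- match(district_key, districts)
  d_region <- grid$region[!duplicated(district_key)]

  # national cell sizes
  N <- pmax(1L, stats::rpois(n, sc$pop_cell_mean * sc$age_pop_weights[age_i]))
  if (any(N == 0)) stop("scenario produced an empty national cell",
                        call. = FALSE)

  # district-level draws: outcome random intercept and latent aux morbidity
  b_d <- as.vector(stats::rnorm(length(districts), 0, sqrt(sc$psi[1, 1])))
  v_d <- stats::rnorm(length(districts), 0, sc$aux_district_sd)

  # auxiliary log-rate profiles; noise columns get their own random profiles
  P <- sc$n_aux
  log_rate <- matrix(log(sc$aux_rate_base), n, P)
  centre <- function(prof_age, prof_sex) {
    # centre so that the population-averaged rate multiplier is 1
    m <- mean(exp(rep(prof_age, each = 2) + prof_sex * rep(0:1, sc$n_age_groups)))
    list(age = prof_age - log(m), sex = prof_sex)
  }
  for (j in seq_len(P)) {
    if (j <= sc$n_predictive) {
      pr <- centre(sc$aux_age_profile, sc$aux_sex_effect)
      load <- 1
    } else {
      pr <- centre(stats::rnorm(sc$n_age_groups, 0, sc$aux_profile_sd),
                   stats::rnorm(1, 0, sc$aux_profile_sd))
      load <- 0
    }
    log_rate[, j] <- log_rate[, j] + pr$age[age_i] + pr$sex * male +
      load * v_d[d_idx]
  }
  x_nat <- matrix(stats::rpois(n * P, N * exp(log_rate)), n, P)
  colnames(x_nat) <- sc$aux_labels

  # outcome: expected diseased count, region-specific aux coefficients
  beta_mat <- outer(sc$beta_aux, sc$region_beta_scale) # n_pred x R
  aux_part <- if (sc$n_predictive > 0) {
    rowSums(x_nat[, seq_len(sc$n_predictive), drop = FALSE] *
              t(beta_mat)[grid$region, , drop = FALSE])
  } else {
    rep(0, n)
  }
  mu <- sc$beta_size * N + aux_part + b_d[d_idx]
  e <- stats::rnorm(n, 0, sqrt(sc$sigma2[grid$region]))
  p_nat <- clamp((mu + e) / N, 0, 1)
  y_nat <- if (sc$binomial_outcome) {
    stats::rbinom(n, N, p_nat)
  } else {
    round(clamp(mu + e, 0, N))
  }

  # membership propensity (cell level) and morbidity-shifted thinning odds
  eta <- stats::qlogis(sc$membership_rate) + sc$gamma_age[age_i] +
    sc$gamma_sex * male
  pi_cell <- stats::plogis(eta)
  pi_morb <- stats::plogis(eta + sc$gamma_morbidity)
  if (any(!is.finite(pi_cell)) || any(pi_cell <= 0) || any(pi_cell >= 1)) {
    stop("membership propensity outside (0, 1)", call. = FALSE)
  }
  n_mem <- stats::rbinom(n, N, pi_cell)
  x_mem <- matrix(stats::rbinom(n * P, x_nat, rep(pi_morb, P)), n, P)
  colnames(x_mem) <- sc$aux_labels

  # member diseased: thinning of the realized national diseased count whose
  # expectation equals the member-side linear predictor
  aux_part_mem <- if (sc$n_predictive > 0) {
    rowSums(x_mem[, seq_len(sc$n_predictive), drop = FALSE] *
              t(beta_mat)[grid$region, , drop = FALSE])
  } else {
    rep(0, n)
  }
  mu_mem <- sc$beta_size * n_mem + aux_part_mem + b_d[d_idx]
  denom <- N * p_nat
  ratio <- ifelse(denom > 0, mu_mem / denom, 0)
  if (sc$informative_beyond_aux) ratio <- ratio * exp(sc$gamma_residual)
  ratio <- clamp(ratio, 0, 1)
  y_mem <- if (sc$binomial_outcome) {
    stats::rbinom(n, y_nat, ratio)
  } else {
    round(clamp(mu_mem, 0, pmin(n_mem, y_nat)))
  }
  y_mem <- pmin(y_mem, n_mem)

  out <- dplyr::bind_cols(
    grid,
    tibble::tibble(
      n_national = as.double(N),
      n_member = as.double(n_mem),
      y_member = as.double(y_mem),
      y_national_true = as.double(y_nat)
    ),
    tibble::as_tibble(`colnames<-`(x_mem, paste0("mem_", sc$aux_labels))),
    tibble::as_tibble(`colnames<-`(x_nat, paste0("nat_", sc$aux_labels)))
  )
  out <- validate_cell_table(out)
  attr(out, "truth") <- list(
    beta_size = sc$beta_size,
    beta_aux = beta_mat,
    psi = sc$psi,
    sigma2 = sc$sigma2,
    random_effects = tibble::tibble(
      region = d_region,
      district = grid$district[!duplicated(district_key)],
      b = b_d
    ),
    national_prevalence = sum(y_nat) / sum(N)
  )
  pa_log("generated population: %d cells, national prevalence %.4f",
         n, sum(y_nat) / sum(N))
  out
}

#' Vary one scenario parameter over a grid
#'
#' Returns one scenario per value of `axis`, all else equal, with
#' deterministically offset `noise_seed`s so scenarios stay independent.
#'
#' @param base A [selection_scenario()].
#' @param axis Name of a scenario parameter.
#' @param values Values to substitute (list or vector; may be empty).
#' @return List of `selection_scenario` objects.
#' @export
#' @examples
#' grid <- make_scenario_grid(selection_scenario(), "gamma_morbidity",
#'                            c(0, 0.5, 1))
#' length(grid)
make_scenario_grid <- function(base, axis, values) {
  stopifnot(inherits(base, "selection_scenario"))
  if (!axis %in% names(base)) {
    stop("unknown scenario axis: ", axis, call. = FALSE)
  }
  values <- as.list(values)
  purrr::imap(values, function(v, i) {
    sc <- base
    sc[[axis]] <- if (axis == "psi") as.matrix(v) else v
    sc$noise_seed <- split_seed(base$noise_seed, "grid", i)
    sc
  })
}
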