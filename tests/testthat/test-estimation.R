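test_that("the naive baseline is the demographic scaling of member counts", {
  pop <- tibble::as_tibble(tiny_population(81))
  pop$n_national[1] <- 100; pop$n_member[1] <- 50; pop$y_member[1] <- 5
  pop$n_member[2] <- pop$n_national[2] # full coverage
  pop$y_member[2] <- min(pop$y_member[2], pop$n_member[2])
  pop$n_member[3] <- 0; pop$y_member[3] <- 0
  pop$y_national_true[1] <- 50 # keep the edited cell coherent
  nv <- naive_scaled_estimate(validate_cell_table(pop))
  expect_equal(nv$naive_count[1], 10)
  expect_equal(nv$naive_count[2], pop$y_member[2])
  expect_true(is.na(nv$naive_count[3]))
  expect_true(nv$flag_undefined[3])
})

test_that("benchmark prediction returns member fit when populations coincide", {
  # national data identical to member data: the two-step estimator must
  # reproduce the member fitted values, hence the member prevalence
  sc <- tiny_scenario()
  pop <- tibble::as_tibble(generate_population(sc, 82))
  pop$n_national <- pop$n_member
  pop$y_national_true <- pop$y_member
  for (lab in aux_labels(validate_cell_table(pop))) {
    pop[[paste0("nat_", lab)]] <- pop[[paste0("mem_", lab)]]
  }
  pop <- validate_cell_table(pop)
  fit <- fit_prevalence_model(pop, truth_design(sc))
  tab <- predict_prevalence(fit, pop)
  fitted_member <- unlist(lapply(fit$fits, `[[`, "fitted"), use.names = FALSE)
  expect_equal(sort(tab$y_hat_raw), sort(fitted_member), tolerance = 1e-10)
  expect_false(any(tab$flag_clamped))
  nat <- aggregate_prevalence(tab, "national")
  expect_equal(nat$prevalence,
               sum(fitted_member) / sum(pop$n_member), tolerance = 1e-10)
})

test_that("aggregation is exactly additive along any partition", {
  sc <- tiny_scenario()
  pop <- generate_population(sc, 83)
  fit <- fit_prevalence_model(pop, truth_design(sc))
  tab <- predict_prevalence(fit, pop)
  nat <- aggregate_prevalence(tab, "national")
  via_district <- aggregate_prevalence(tab, "district")
  via_age <- aggregate_prevalence(tab, "age_group")
  expect_equal(nat$prevalence,
               sum(via_district$y_hat) / sum(via_district$n_national),
               tolerance = 1e-12)
  expect_equal(nat$prevalence,
               sum(via_age$y_hat) / sum(via_age$n_national),
               tolerance = 1e-12)
  expect_equal(sum(via_district$y_hat), sum(tab$y_hat), tolerance = 1e-12)
  # two-cell arithmetic: (8 of 100) + (4 of 100) pool to 6%
  two <- tab[1:2, ]
  two$y_hat <- c(8, 4); two$n_national <- c(100, 100)
  expect_equal(aggregate_prevalence(two, "national")$prevalence, 0.06)
})

test_that("relative adjustment is the signed percent change from member prevalence", {
  expect_equal(relative_adjustment(0.10, 0.10), 0)
  expect_equal(relative_adjustment(0.10, 0.08), -20)
  expect_warning(out <- relative_adjustment(0, 0.08), "undefined")
  expect_true(is.na(out))
  # planted morbidity selectivity: members sicker, so adjustments are negative
  sc <- tiny_scenario()
  pop <- generate_population(sc, 84)
  fit <- fit_prevalence_model(pop, truth_design(sc))
  adj <- aggregate_prevalence(predict_prevalence(fit, pop), "district")
  expect_lt(mean(adj$relative_adjustment), 0)
})

test_that("cells and districts without members still receive predictions", {
  sc <- tiny_scenario()
  pop <- tibble::as_tibble(generate_population(sc, 85))
  # empty one whole district and one extra cell elsewhere
  d1 <- pop$region == 1 & pop$district == 2
  pop$n_member[d1] <- 0; pop$y_member[d1] <- 0
  pop$n_member[which(!d1)[1]] <- 0; pop$y_member[which(!d1)[1]] <- 0
  pop <- validate_cell_table(pop)
  fit <- fit_prevalence_model(pop, truth_design(sc))
  tab <- predict_prevalence(fit, pop)
  expect_equal(nrow(tab), nrow(pop))
  expect_false(any(is.na(tab$y_hat)))
  expect_true(all(tab$flag_no_member_district[d1]))
  expect_true(all(tab$flag_zero_member[d1]))
  expect_true(tab$flag_zero_member[which(!d1)[1]])
  # a member-free cell inside a surviving district still borrows its b-hat
  expect_false(tab$flag_no_member_district[which(!d1)[1]])
  expect_true(all(tab$y_hat >= 0 & tab$y_hat <= tab$n_national))
})

test_that("out-of-range raw predictions are clamped and flagged", {
  sc <- tiny_scenario()
  pop <- generate_population(sc, 86)
  fit <- fit_prevalence_model(pop, truth_design(sc))
  # inflate one region's coefficients so raw predictions overshoot
  fit$fits[[1]]$beta["cell_size"] <- 10
  tab <- predict_prevalence(fit, pop)
  expect_true(any(tab$flag_clamped))
  expect_true(all(tab$y_hat >= 0 & tab$y_hat <= tab$n_national))
  expect_true(any(tab$y_hat_raw > tab$n_national))
  # raw values are preserved unclamped on request
  raw <- predict_prevalence(fit, pop, clamp = FALSE)
  expect_true(any(raw$y_hat > raw$n_national))
})

test_that("estimation never reads the national truth", {
  sc <- tiny_scenario()
  pop <- tibble::as_tibble(generate_population(sc, 87))
  blind <- pop
  blind$y_national_true <- NA_real_
  f1 <- fit_prevalence_model(validate_cell_table(pop), truth_design(sc))
  f2 <- fit_prevalence_model(validate_cell_table(blind), truth_design(sc))
  t1 <- predict_prevalence(f1, validate_cell_table(pop))
  t2 <- predict_prevalence(f2, validate_cell_table(blind))
  expect_identical(t1$y_hat, t2$y_hat)
  expect_identical(t1$prevalence, t2$prevalence)
})
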