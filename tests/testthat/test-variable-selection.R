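test_that("a rescaled copy of the prevalence ranks first, at any scale", {
  pop <- tibble::as_tibble(tiny_population(41))
  # plant a candidate whose per-capita rate is proportional to prevalence
  pop$mem_PLANT_main <- 3 * pop$y_member
  pop$nat_PLANT_main <- 3 * pop$y_national_true
  rk <- rank_predictors_by_region(validate_cell_table(pop))
  top <- dplyr::filter(rk, rank == 1)
  expect_true(all(top$label == "PLANT_main"))
  expect_true(all(abs(top$correlation - 1) < 1e-12))

  # scale invariance: multiplying a candidate by a positive constant leaves
  # every ranking unchanged
  pop2 <- pop
  lab <- aux_labels(validate_cell_table(pop))[2]
  pop2[[paste0("mem_", lab)]] <- 7 * pop2[[paste0("mem_", lab)]]
  pop2[[paste0("nat_", lab)]] <- 7 * pop2[[paste0("nat_", lab)]]
  rk2 <- rank_predictors_by_region(validate_cell_table(pop2))
  expect_equal(rk2$rank, rk$rank)
  expect_equal(rk2$label, rk$label)
})

test_that("a permutation-destroyed copy of prevalence carries no signal", {
  pop <- tibble::as_tibble(tiny_population(42))
  set.seed(99)
  rate <- pop$y_member / pop$n_member
  nat_rate <- pop$y_national_true / pop$n_national
  cors <- replicate(100, {
    shuffled <- pop
    ord <- sample(nrow(pop))
    # destroy the signal in the per-capita rate, not in the raw count, so
    # no spurious correlation re-enters through the shared denominator
    shuffled$mem_SHUF_main <- rate[ord] * pop$n_member
    shuffled$nat_SHUF_main <- nat_rate[ord] * pop$n_national
    rk <- rank_predictors_by_region(validate_cell_table(shuffled))
    c(mean(abs(rk$correlation[rk$label == "SHUF_main"])),
      mean(rk$rank[rk$label == "SHUF_main"]))
  })
  expect_lt(mean(cors[1, ]), 0.25)
  # and it sits in the bottom half of the ranking on average
  n_cand <- length(aux_labels(validate_cell_table(pop))) + 1
  expect_gt(mean(cors[2, ]), n_cand / 2)
})

test_that("election counts top-k appearances across regions", {
  pop <- tiny_population(43)
  rk <- rank_predictors_by_region(pop)
  el <- elect_predictors(rk, top_k = 3, p_sel = 3)
  expect_length(el$elected, 3)
  expect_true(all(el$elected %in% aux_labels(pop)))
  counts <- el$election_counts
  expect_true(all(counts$elections <= length(unique(pop$region))))

  # single region: elected equals that region's top p_sel
  one <- validate_cell_table(tibble::as_tibble(pop)[pop$region == 1, ])
  rk1 <- rank_predictors_by_region(one)
  el1 <- elect_predictors(rk1, top_k = 5, p_sel = 5)
  expect_equal(el1$elected,
               dplyr::arrange(rk1, rank)$label[1:5])

  # a candidate ranked first everywhere is elected first
  planted <- tibble::as_tibble(pop)
  planted$mem_AAA_main <- 2 * planted$y_member
  planted$nat_AAA_main <- 2 * planted$y_national_true
  elp <- elect_predictors(
    rank_predictors_by_region(validate_cell_table(planted)),
    top_k = 3, p_sel = 3
  )
  expect_equal(elp$elected[1], "AAA_main")
  expect_equal(
    elp$election_counts$elections[elp$election_counts$label == "AAA_main"],
    length(unique(pop$region))
  )
})

test_that("election ties break by mean correlation, then label", {
  pop <- tibble::as_tibble(tiny_population(44))
  # two exact duplicates of the prevalence: identical correlations, so the
  # election count and mean |correlation| tie and the label decides
  pop$mem_TIEB_main <- 2 * pop$y_member
  pop$nat_TIEB_main <- 2 * pop$y_national_true
  pop$mem_TIEA_main <- 4 * pop$y_member
  pop$nat_TIEA_main <- 4 * pop$y_national_true
  el <- elect_predictors(rank_predictors_by_region(validate_cell_table(pop)),
                         top_k = 3, p_sel = 2)
  expect_equal(el$elected, c("TIEA_main", "TIEB_main"))
})

test_that("degenerate inputs are handled as specified", {
  pop <- tibble::as_tibble(tiny_population(45))
  # zero-variance candidate (constant per-capita rate): correlation 0 plus
  # a warning
  pop$mem_FLAT_main <- 2 * pop$n_member
  pop$nat_FLAT_main <- 2 * pop$n_national
  w <- testthat::capture_warnings(
    rk <- rank_predictors_by_region(validate_cell_table(pop))
  )
  expect_true(any(grepl("zero-variance", w))) # warned once per region
  expect_true(all(rk$correlation[rk$label == "FLAT_main"] == 0))

  # a region with fewer than 3 usable cells fails
  crippled <- tibble::as_tibble(tiny_population(46))
  in_r1 <- crippled$region == 1
  crippled$n_member[in_r1] <- 0
  crippled$y_member[in_r1] <- 0
  crippled$n_member[which(in_r1)[1:2]] <- 50
  expect_error(rank_predictors_by_region(validate_cell_table(crippled)),
               "fewer than 3")

  # p_sel larger than the candidate pool fails
  rk2 <- rank_predictors_by_region(tiny_population(47))
  expect_error(elect_predictors(rk2, top_k = 3, p_sel = 99), "exceeds")

  # unknown candidate name fails
  expect_error(rank_predictors_by_region(tiny_population(48), "NOPE_main"),
               "NOPE_main")
})

test_that("planted predictors win the election under a clear signal", {
  sc <- selection_scenario(districts_per_region = rep(10L, 4),
                           n_aux = 30, n_predictive = 3)
  planted <- sc$aux_labels[1:3]
  hits <- vapply(1:25, function(i) {
    pop <- generate_population(sc, i)
    el <- elect_predictors(rank_predictors_by_region(pop),
                           top_k = 3, p_sel = 3)
    all(planted %in% el$elected)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
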