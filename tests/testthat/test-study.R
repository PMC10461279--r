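make_library <- function() {
  memo("library12", make_cohort(12, p_incline15 = 0.5, p_large = 0.5,
                                n_test = 3, seed = 31, grid = small_grid()))
}

test_that("atlas groups honour filters, size and determinism", {
  coh <- make_library()
  sp <- group_spec(3, incline_filter = 15, seed = 2, label = "g15")
  grp <- build_group(coh, sp)
  expect_length(grp, 3)
  expect_true(all(vapply(grp, function(cs) cs$incline_deg == 15,
                         logical(1))))
  grp2 <- build_group(coh, sp)
  expect_identical(vapply(grp, function(cs) cs$case_id, character(1)),
                   vapply(grp2, function(cs) cs$case_id, character(1)))
  expect_error(build_group(coh, group_spec(50)), "insufficient")
})

test_that("test-role cases never enter atlas groups", {
  coh <- make_library()
  test_ids <- tidy(coh)$case_id[tidy(coh)$role == "test"]
  for (seed in 1:5) {
    grp <- build_group(coh, group_spec(6, seed = seed))
    expect_length(intersect(
      vapply(grp, function(cs) cs$case_id, character(1)), test_ids), 0)
  }
})

test_that("match policies select matching and non-matching test cases", {
  coh <- make_library()
  meta <- tidy(coh)
  inc_avail <- meta$incline_deg[meta$role == "test"]
  sp_m <- group_spec(2, incline_filter = inc_avail[1],
                     match_policy = "MTC", seed = 3)
  tc <- select_test_cases(coh, sp_m, sum(inc_avail == inc_avail[1]))
  expect_true(all(vapply(tc, function(cs)
    cs$incline_deg == inc_avail[1], logical(1))))
  # NMTC from a 15-degree group must be scanned at 20 degrees
  sp_n <- group_spec(2, incline_filter = 15, match_policy = "NMTC",
                     seed = 3)
  n_avail <- sum(inc_avail == 20)
  if (n_avail > 0) {
    tn <- select_test_cases(coh, sp_n, n_avail)
    expect_true(all(vapply(tn, function(cs) cs$incline_deg == 20,
                           logical(1))))
  }
  expect_error(select_test_cases(coh, sp_m, 50), "unsatisfiable")
})

test_that("evaluation bookkeeping covers every group, case and structure", {
  coh <- make_library()
  grp <- build_group(coh, group_spec(3, seed = 4, label = "A"))
  grp2 <- build_group(coh, group_spec(4, seed = 5, label = "B"))
  tc <- select_test_cases(coh, group_spec(3, seed = 4), 2)
  ev <- run_evaluation(list(A = grp, B = grp2), tc,
                       params = list(mode = "pseudo"))
  n_struct <- length(tc[[1]]$structures$masks)
  expect_equal(nrow(ev), 2 * 2 * n_struct)
  expect_setequal(unique(ev$group_label), c("A", "B"))
})

test_that("evaluating unperturbed copies is the pipeline's null case", {
  coh <- make_library()
  tc <- select_test_cases(coh, group_spec(3, seed = 4), 2)
  ev <- run_evaluation("identity", tc, params = list(mode = "pseudo"))
  expect_true(all(ev$jaccard == 1))
  expect_true(all(abs(as.matrix(ev[, var_cols()])) < 1e-12))
  ev2 <- apply_cdv_exclusion(ev)
  expect_equal(nrow(suppressWarnings(flag_clinical(ev2))), 0)
})

test_that("pseudo-AS translations yield closed-form variants", {
  coh <- make_library()
  tc <- select_test_cases(coh, group_spec(3, seed = 4), 1)
  t_cm <- c(1.2, 0, 0.6)
  ev <- run_evaluation(
    "shifted", tc,
    params = list(mode = "pseudo", centre_mode = "reference",
                  perturbation = perturbation_spec(translation_cm = t_cm)))
  for (ax in 1:3) {
    for (mm in c("min", "max")) {
      col <- paste0("var_", mm, "_", c("x", "y", "z")[ax])
      expect_true(all(abs(ev[[col]] - (-t_cm[ax])) <= 0.6 + 1e-9),
                  info = col)
    }
  }
})

test_that("CDV exclusion removes low-overlap and routine-TPS structures", {
  base <- tibble::tibble(
    group_label = "g", case_id = rep(c("c1", "c2"), each = 5),
    structure = rep(c("Breast", "IMN", "Interpectoral", "Heart", "Lung"),
                    2),
    jaccard = rep(c(0.9, 0.42, 0.5, 0.95, 0.97), 2),
    dice = NA_real_, volume_cm3 = 100,
    var_min_x = 0.4, var_max_x = 0, var_min_y = -0.5, var_max_y = 0,
    var_min_z = 0, var_max_z = 0,
    cdv_excluded = FALSE, exclusion_reason = NA_character_
  )
  class(base) <- c("atlaseval_evaluation", class(base))
  out <- apply_cdv_exclusion(base)
  reasons <- unique(out[out$cdv_excluded, c("structure",
                                            "exclusion_reason")])
  expect_setequal(reasons$structure, c("IMN", "Heart", "Lung"))
  expect_equal(
    unique(out$exclusion_reason[out$structure == "IMN"]), "low-overlap")
  expect_equal(
    unique(out$exclusion_reason[out$structure == "Heart"]),
    "routine-TPS structure")
  # structure at exactly the cut is retained (strict comparison)
  expect_false(any(out$cdv_excluded[out$structure == "Interpectoral"]))
  expect_true(all(is.na(out$var_min_x[out$cdv_excluded])))
  expect_true(all(out$var_min_x_raw[out$cdv_excluded] == 0.4))
})

test_that("aggregation computes sample statistics and respects classes", {
  tb <- tibble::tibble(
    group_label = rep("g", 4), case_id = c("a", "b", "a", "b"),
    structure = c("Breast", "Breast", "IMN", "IMN"),
    jaccard = c(0.2, 0.4, 0.6, 0.6), dice = NA_real_, volume_cm3 = 1,
    var_min_x = c(0.2, 0.4, NA, NA), var_max_x = 0, var_min_y = 0,
    var_max_y = 0, var_min_z = 0, var_max_z = 0,
    cdv_excluded = FALSE, exclusion_reason = NA_character_
  )
  class(tb) <- c("atlaseval_evaluation", class(tb))
  s <- aggregate_evaluation(tb)
  breast <- s$by_structure_group[
    s$by_structure_group$structure == "Breast", ]
  expect_equal(breast$jsc_mean, 0.3)
  expect_equal(breast$jsc_sd, sd(c(0.2, 0.4)))
  expect_equal(breast$var_min_x_mean, 0.3)
  expect_setequal(s$by_size_class$size_class, c("larger", "smaller"))
  # row order does not matter
  s2 <- aggregate_evaluation(tb[sample(nrow(tb)), ])
  expect_equal(dplyr::arrange(s$by_structure_group, structure),
               dplyr::arrange(s2$by_structure_group, structure))
})

test_that("one-way ANOVA matches textbook sums of squares", {
  a <- anova_oneway(list(c(1, 2), c(3, 4)))
  expect_equal(a$statistic, 8)
  expect_equal(a$ss_between, 4)
  expect_equal(a$ss_within, 1)
  expect_equal(anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))$statistic, 0)
  deg <- anova_oneway(list(c(2, 2), c(2, 2)))
  expect_equal(deg$statistic, 0)
  expect_equal(deg$p.value, 1)
  expect_error(anova_oneway(list(c(1, 2))), "two groups")
})

test_that("ANOVA agrees with a brute-force oracle on random inputs", {
  withr::with_seed(17, {
    for (i in 1:50) {
      k <- sample(2:4, 1)
      groups <- lapply(seq_len(k), function(j) rnorm(sample(3:6, 1)))
      got <- anova_oneway(groups)$statistic
      expect_equal(got, brute_force_anova_f(groups), tolerance = 1e-10)
    }
  })
})

test_that("tidy and glance summarise ANOVA fits", {
  a <- anova_oneway(list(c(1, 2), c(3, 4)))
  td <- tidy(a)
  expect_equal(td$term, c("between", "within"))
  expect_equal(td$statistic[1], 8)
  expect_equal(glance(a)$p.value, a$p.value)
})

test_that("adjusted R-squared behaves across fit qualities", {
  x <- 1:20
  expect_equal(adjusted_r2(x, 2 * x + 3 + rnorm(20, 0, 1e-8)), 1,
               tolerance = 1e-6)
  withr::with_seed(23, {
    vals <- replicate(40, adjusted_r2(rnorm(3), rnorm(3)))
    expect_true(any(vals < 0))
    big <- adjusted_r2(rnorm(500), rnorm(500))
    expect_lt(abs(big), 0.1)
  })
  expect_error(adjusted_r2(rep(1, 5), rnorm(5)), "constant")
  expect_error(adjusted_r2(1:2, 1:2), "at least 3")
})

test_that("clinical flagging applies the rule set to published variants", {
  het <- dplyr::filter(published_variants(), group == "Heterogeneous")
  flags <- flag_clinical(het)
  rules <- default_relevance_rules()
  expect_equal(nrow(flags), nrow(rules))
  expect_setequal(paste(flags$structure, flags$direction),
                  paste(rules$structure, rules$direction))
  # a sky-high threshold flags nothing, including directions outside the
  # rule list however large their variant
  expect_equal(nrow(flag_clinical(het, default_relevance_rules(10))), 0)
  expect_error(default_relevance_rules(0), "> 0")
})

test_that("flag rules on excluded structures warn and are skipped", {
  het <- dplyr::filter(published_variants(), group == "Heterogeneous")
  het$excluded <- het$structure == "Breast"
  expect_warning(flags <- flag_clinical(het), "skipping")
  expect_false("Breast" %in% flags$structure)
})
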