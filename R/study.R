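#' Atlas group specification
#'
#' Describes how an atlas group is drawn from the case library: its size,
#' optional incline and separation-class filters, the test-case match
#' policy, and a seed for reproducible sampling.
#'
#' @param size Number of atlases (>= 1).
#' @param incline_filter `15`, `20` or `"any"`.
#' @param separation_filter `"small"`, `"large"` or `"any"`.
#' @param match_policy `"MTC"` (test cases match the group filters),
#'   `"NMTC"` (test cases deliberately violate at least one filter) or
#'   `"none"`.
#' @param seed Integer sampling seed.
#' @param label Group label used in result tables.
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(size, incline_filter = "any",
                       separation_filter = "any",
                       match_policy = c("none", "MTC", "NMTC"),
                       seed = 1L, label = NULL) {
  match_policy <- match.arg(match_policy)
  if (size < 1) abort("group size must be >= 1")
  if (!identical(incline_filter, "any") &&
      !incline_filter %in% c(15, 20, "15", "20"))
    abort("`incline_filter` must be 15, 20 or 'any'")
  if (!separation_filter %in% c("small", "large", "any"))
    abort("`separation_filter` must be 'small', 'large' or 'any'")
  if (is.null(label))
    label <- paste0(
      ifelse(identical(incline_filter, "any"), "", paste0(incline_filter,
                                                          "deg-")),
      ifelse(separation_filter == "any", "", paste0(separation_filter,
                                                    "-")),
      "n", size)
  structure(
    list(size = as.integer(size), incline_filter = incline_filter,
         separation_filter = separation_filter,
         match_policy = match_policy, seed = as.integer(seed),
         label = label),
    class = "group_spec"
  )
}

case_matches <- function(case, spec) {
  ok <- TRUE
  if (!identical(spec$incline_filter, "any"))
    ok <- ok && case$incline_deg == as.numeric(spec$incline_filter)
  if (spec$separation_filter != "any")
    ok <- ok && case$separation_class == spec$separation_filter
  ok
}

#' Draw an atlas group from a case library
#'
#' Seeded sampling without replacement of exactly `spec$size` atlas-role
#' cases matching the spec's filters.  Test-role cases are never
#' eligible, so a designated test case can never appear in a group used
#' to segment it.
#'
#' @param library A `case_cohort` or list of `case_record`s.
#' @param spec A [group_spec()].
#' @return A list of `case_record`s with attribute `label`.
#' @export
build_group <- function(library, spec) {
  cases <- if (inherits(library, "case_cohort")) library$cases else library
  eligible <- Filter(function(cs) cs$role == "atlas" &&
                       case_matches(cs, spec), cases)
  if (length(eligible) < spec$size)
    abort(sprintf(
      "insufficient eligible atlases: need %d, found %d", spec$size,
      length(eligible)))
  pick <- with_local_seed(spec$seed,
                          sample.int(length(eligible), spec$size))
  out <- eligible[sort(pick)]
  attr(out, "label") <- spec$label
  out
}

#' Select test cases under a match policy
#'
#' `MTC` selects test-role cases satisfying the group's filters; `NMTC`
#' selects test-role cases violating at least one filter; `none` selects
#' unrestricted test-role cases.  Selection is seeded by the spec.
#'
#' @inheritParams build_group
#' @param n Number of test cases required.
#' @return A list of `case_record`s.
#' @export
select_test_cases <- function(library, spec, n) {
  cases <- if (inherits(library, "case_cohort")) library$cases else library
  tests <- Filter(function(cs) cs$role == "test", cases)
  keep <- switch(
    spec$match_policy,
    MTC = Filter(function(cs) case_matches(cs, spec), tests),
    NMTC = Filter(function(cs) !case_matches(cs, spec), tests),
    none = tests
  )
  if (length(keep) < n)
    abort(sprintf(
      "match policy %s unsatisfiable: need %d test cases, found %d",
      spec$match_policy, n, length(keep)))
  pick <- with_local_seed(derive_seed(spec$seed, 999L),
                          sample.int(length(keep), n))
  keep[sort(pick)]
}

#' Run an evaluation of auto-segmentations against references
#'
#' For each (atlas group, test case) pair, produces an auto-segmentation
#' and compares it with the test case's reference structures: the
#' Jaccard overlap and the six centroid distance variants per structure.
#' Two generation modes are available: `"mas"` runs the full multi-atlas
#' pipeline via [auto_segment()]; `"pseudo"` replaces the segmenter with
#' a controlled perturbation of the reference structures
#' ([perturb()]), giving auto-segmentations whose expected metrics are
#' known in closed form.
#'
#' @param groups Named list of atlas groups (as from [build_group()]);
#'   labels are taken from the list names or group attributes.  In
#'   `"pseudo"` mode a plain character vector of labels is also accepted.
#' @param test_cases List of test `case_record`s.
#' @param params List of controls: `mode` (`"mas"` or `"pseudo"`),
#'   `policy` ([fusion_policy()]), `mas` (params for [auto_segment()]),
#'   `perturbation` (a [perturbation_spec()] or function
#'   `(case, group_label) -> perturbation_spec` for pseudo mode),
#'   `centre_mode` and `decimals` for the metrics.
#' @return An `atlaseval_evaluation` tibble: one row per (group, case,
#'   structure) with `group_label`, `case_id`, `structure`, `jaccard`,
#'   `dice`, `volume_cm3`, `var_*` columns, `cdv_excluded`,
#'   `exclusion_reason`.
#' @export
run_evaluation <- function(groups, test_cases, params = list()) {
  p <- modifyList(
    list(mode = "pseudo", policy = fusion_policy(), mas = list(),
         perturbation = perturbation_spec(), centre_mode = "own",
         decimals = 1),
    params
  )
  if (is.character(groups)) {
    stopifnot(p$mode == "pseudo")
    groups <- setNames(vector("list", length(groups)), groups)
  }
  labels <- names(groups)
  if (is.null(labels))
    labels <- vapply(groups, function(g) attr(g, "label") %||% NA_character_,
                     character(1))
  if (any(is.na(labels) | !nzchar(labels)))
    abort("every group must carry a label")

  rows <- list()
  for (gi in seq_along(groups)) {
    grp <- groups[[gi]]
    for (case in test_cases) {
      as_set <- if (p$mode == "mas") {
        auto_segment(case, grp, policy = p$policy, params = p$mas)
      } else {
        spec <- if (is.function(p$perturbation))
          p$perturbation(case, labels[gi]) else p$perturbation
        perturb(case$structures, spec)
      }
      tab <- evaluate_pairs(case$structures, as_set,
                            centre_mode = p$centre_mode,
                            decimals = p$decimals)
      tab <- dplyr::mutate(tab, group_label = labels[gi],
                           case_id = case$case_id, .before = 1)
      rows[[length(rows) + 1L]] <- tab
    }
  }
  out <- dplyr::bind_rows(rows)
  out$cdv_excluded <- FALSE
  out$exclusion_reason <- NA_character_
  class(out) <- c("atlaseval_evaluation", class(out))
  attr(out, "centre_mode") <- p$centre_mode
  attr(out, "decimals") <- p$decimals
  out
}

#' Exclude centroid distance variants for unreliable structures
#'
#' Marks the variant columns as excluded (set to `NA` with a
#' machine-readable reason, raw values kept in `var_*_raw` columns) for
#' any structure whose mean Jaccard falls strictly below `jsc_cut`
#' (reason `"low-overlap"`), and unconditionally for the heart and lung
#' (reason `"routine-TPS structure"`), which treatment planning systems
#' contour successfully on their own.  A structure at exactly the cut is
#' retained.
#'
#' @param table An `atlaseval_evaluation` tibble.
#' @param jsc_cut Mean-Jaccard threshold (default 0.5).
#' @return The table with exclusions applied.
#' @export
apply_cdv_exclusion <- function(table, jsc_cut = 0.5) {
  mean_jsc <- dplyr::summarise(
    dplyr::group_by(table, .data$structure),
    mean_jsc = mean(.data$jaccard), .groups = "drop")
  low <- mean_jsc$structure[mean_jsc$mean_jsc < jsc_cut]
  var_cols <- paste0("var_", direction_names())
  for (vc in var_cols) table[[paste0(vc, "_raw")]] <- table[[vc]]
  excl_low <- table$structure %in% low
  excl_tps <- table$structure %in% c("Heart", "Lung")
  table$cdv_excluded <- excl_low | excl_tps
  table$exclusion_reason <- dplyr::case_when(
    excl_tps ~ "routine-TPS structure",
    excl_low ~ "low-overlap",
    TRUE ~ NA_character_
  )
  for (vc in var_cols) table[[vc]][table$cdv_excluded] <- NA_real_
  table
}

#' Summarise an evaluation table
#'
#' Descriptive statistics of the Jaccard overlap and centroid distance
#' variants: arithmetic means and sample standard deviations (n - 1
#' denominator), by structure and group, by group, and by structure size
#' class (larger structures being breast, heart, lung and level 1
#' nodes).  Raw values are retained; the print method rounds to the
#' table's reporting precision.
#'
#' @param table An `atlaseval_evaluation` tibble.
#' @return A list of tibbles (`by_structure_group`, `by_group`,
#'   `by_size_class`, `overall`) of class `atlaseval_summary`.
#' @export
aggregate_evaluation <- function(table) {
  if (nrow(table) == 0) abort("empty evaluation table")
  var_cols <- paste0("var_", direction_names())
  summarise_block <- function(tbl, by = character()) {
    dplyr::summarise(
      dplyr::group_by(tbl, dplyr::across(dplyr::all_of(by))),
      n = dplyr::n(),
      jsc_mean = mean(.data$jaccard), jsc_sd = sd(.data$jaccard),
      dplyr::across(dplyr::all_of(var_cols),
                    list(mean = ~mean(.x, na.rm = TRUE),
                         sd = ~sd(.x, na.rm = TRUE))),
      .groups = "drop")
  }
  tbl <- dplyr::mutate(
    table,
    size_class = ifelse(.data$structure %in% larger_structures(),
                        "larger", "smaller"))
  out <- list(
    by_structure_group = summarise_block(tbl, c("structure",
                                                "group_label")),
    by_group = summarise_block(tbl, "group_label"),
    by_size_class = summarise_block(tbl, "size_class"),
    overall = summarise_block(tbl)
  )
  structure(out, class = "atlaseval_summary",
            decimals = attr(table, "decimals") %||% 1)
}

#' @export
print.atlaseval_summary <- function(x, ...) {
  dec <- attr(x, "decimals") %||% 1
  cat("<atlaseval_summary>\n")
  for (nm in names(x)) {
    cat("--", nm, "--\n")
    print(dplyr::mutate(x[[nm]],
                        dplyr::across(dplyr::where(is.numeric),
                                      ~round(.x, dec + 1))))
  }
  invisible(x)
}

#' Mean centroid distance variants per structure and direction
#'
#' Collapses an evaluation table to the mean variant (cm) per structure,
#' group and direction, in long format; excluded rows contribute `NA`.
#'
#' @param table An `atlaseval_evaluation` tibble.
#' @return A tibble with `structure`, `group`, `direction`,
#'   `variant_cm`, `excluded`.
#' @export
cdv_means <- function(table) {
  var_cols <- paste0("var_", direction_names())
  long <- tidyr::pivot_longer(
    dplyr::select(table, dplyr::all_of(c("group_label", "structure",
                                         "cdv_excluded", var_cols))),
    cols = dplyr::all_of(var_cols), names_to = "direction",
    names_prefix = "var_", values_to = "variant_cm")
  dplyr::summarise(
    dplyr::group_by(long, group = .data$group_label, .data$structure,
                    .data$direction),
    variant_cm = mean(.data$variant_cm),
    excluded = any(.data$cdv_excluded),
    .groups = "drop")
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: the ratio of between-group to
#' within-group mean squares, with an upper-tail p-value from the F
#' distribution (equal-variance form, via [stats::oneway.test()]).
#' Degenerate input where all values are identical is reported as F = 0,
#' p = 1 by convention.
#'
#' @param values Either a list of numeric group samples, or a numeric
#'   vector accompanied by `groups`.
#' @param groups Group membership vector when `values` is a numeric
#'   vector.
#' @return A `oneway_anova` object: list with `statistic` (F), `p.value`,
#'   `df_between`, `df_within`, `ss_between`, `ss_within`, `n`.
#' @export
anova_oneway <- function(values, groups = NULL) {
  if (is.list(values) && is.null(groups)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2) abort("need at least two groups")
  if (length(values) - 1 < 2) abort("need at least two total degrees of freedom")

  gm <- tapply(values, groups, mean)
  ssb <- sum(tapply(values, groups, length) * (gm - mean(values))^2)
  ssw <- sum((values - gm[groups])^2)
  dfb <- nlevels(groups) - 1L
  dfw <- length(values) - nlevels(groups)

  if (ssb < 1e-24 && ssw < 1e-24) {
    f <- 0; p <- 1
  } else if (ssw < 1e-24) {
    f <- Inf; p <- 0
  } else {
    ow <- oneway.test(values ~ groups, var.equal = TRUE)
    f <- unname(ow$statistic); p <- unname(ow$p.value)
  }
  structure(
    list(statistic = f, p.value = p, df_between = dfb, df_within = dfw,
         ss_between = ssb, ss_within = ssw, n = length(values)),
    class = "oneway_anova"
  )
}

#' @export
print.oneway_anova <- function(x, ...) {
  cat(sprintf("<oneway_anova> F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$statistic, x$p.value))
  invisible(x)
}

#' @rdname anova_oneway
#' @param x A `oneway_anova` object.
#' @param ... Unused.
#' @export
tidy.oneway_anova <- function(x, ...) {
  tibble(
    term = c("between", "within"),
    df = c(x$df_between, x$df_within),
    sumsq = c(x$ss_between, x$ss_within),
    meansq = c(x$ss_between / x$df_between, x$ss_within / x$df_within),
    statistic = c(x$statistic, NA_real_),
    p.value = c(x$p.value, NA_real_)
  )
}

#' @rdname anova_oneway
#' @export
glance.oneway_anova <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value,
         df_between = x$df_between, df_within = x$df_within, n = x$n)
}

#' Adjusted R-squared of a univariate linear fit
#'
#' Ordinary least squares of `y` on `x`;
#' `adjusted R^2 = 1 - (1 - R^2)(n - 1)/(n - 2)`, which can be negative
#' for uninformative predictors.
#'
#' @param x Predictor values (not constant, length >= 3).
#' @param y Responses.
#' @return Adjusted coefficient of determination (scalar).
#' @export
adjusted_r2 <- function(x, y) {
  if (length(x) < 3) abort("need at least 3 points")
  if (sd(x) < 1e-24) abort("`x` must not be constant")
  summary(lm(y ~ x))$adj.r.squared
}

#' Default clinical-relevance rules for directional variants
#'
#' The structure/direction pairs whose auto-segmentation variation is
#' reviewed before radiotherapy planning: the medial and posterior
#' aspects of the breast, the posterior aspect of the level 1 and level 2
#' nodes, the lateral aspect of the level 3 nodes, the medial and lateral
#' aspects of the level 4 nodes, and the medial, posterior and anterior
#' aspects of the brachial plexus.  The default magnitude threshold is
#' 0.3 cm, the smallest variant treated as requiring editing.
#'
#' @param threshold_cm Magnitude cut applied to mean variants (cm, > 0).
#' @return A tibble of rules: `structure`, `direction`, `threshold_cm`.
#' @export
default_relevance_rules <- function(threshold_cm = 0.3) {
  if (threshold_cm <= 0) abort("`threshold_cm` must be > 0")
  tibble(
    structure = c("Breast", "Breast", "Level1", "Level2", "Level3",
                  "Level4", "Level4", "BrachialPlexus", "BrachialPlexus",
                  "BrachialPlexus"),
    direction = c("min_x", "min_y", "min_y", "min_y", "max_x",
                  "min_x", "max_x", "min_x", "min_y", "max_y"),
    threshold_cm = threshold_cm
  )
}

#' Flag clinically relevant directional variants
#'
#' A (structure, direction) location is flagged when it appears in the
#' rule set and the magnitude of its mean variant meets or exceeds the
#' rule's threshold.  Rules referring to structures whose variants are
#' excluded (or absent) are skipped with a warning.
#'
#' @param x An `atlaseval_evaluation` table, or a long tibble with
#'   columns `structure`, `direction` and `variant_cm` (one mean variant
#'   per row, e.g. [published_variants()] filtered to one group).
#' @param rules A rule tibble as from [default_relevance_rules()].
#' @return A tibble of flagged locations: `structure`, `direction`,
#'   `variant_cm`, `threshold_cm` (plus `group` when present).
#' @export
flag_clinical <- function(x, rules = default_relevance_rules()) {
  means <- if (inherits(x, "atlaseval_evaluation")) cdv_means(x) else
    as_tibble(x)
  if (!all(c("structure", "direction", "variant_cm") %in% names(means)))
    abort("`x` must provide structure, direction and variant_cm")
  if (!"excluded" %in% names(means)) means$excluded <- FALSE

  hit <- dplyr::inner_join(means, rules, by = c("structure", "direction"))
  bad <- dplyr::filter(hit, .data$excluded | is.na(.data$variant_cm))
  if (nrow(bad) > 0) {
    warn(paste0("skipping rules for excluded structure(s): ",
                paste(unique(bad$structure), collapse = ", ")))
    hit <- dplyr::filter(hit, !.data$excluded, !is.na(.data$variant_cm))
  }
  out <- dplyr::filter(hit, abs(.data$variant_cm) >=
                         .data$threshold_cm - 1e-9)
  dplyr::select(out, -dplyr::any_of("excluded"))
}
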