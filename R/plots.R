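#' Plot Jaccard overlap by structure and atlas group
#'
#' Boxplots of per-case Jaccard scores per structure, coloured by atlas
#' group, structures ordered by reference volume (largest first) as in
#' volume-sorted overlap summaries.
#'
#' @param object An `atlaseval_evaluation` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.atlaseval_evaluation <- function(object, ...) {
  ord <- dplyr::arrange(
    dplyr::summarise(dplyr::group_by(object, .data$structure),
                     v = mean(.data$volume_cm3), .groups = "drop"),
    dplyr::desc(.data$v))
  df <- dplyr::mutate(
    object, structure = factor(.data$structure, levels = ord$structure))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$structure, y = .data$jaccard,
                                   fill = .data$group_label)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "Jaccard similarity coefficient",
                  fill = "Atlas group") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Heatmap of mean centroid distance variants
#'
#' Structure-by-direction tile map of mean variants (cm), diverging
#' colour scale centred at zero; excluded structures are left blank.
#'
#' @param table An `atlaseval_evaluation` tibble, or a long tibble with
#'   `structure`, `direction`, `variant_cm`.
#' @return A ggplot object.
#' @export
plot_cdv <- function(table) {
  means <- if (inherits(table, "atlaseval_evaluation")) cdv_means(table)
    else as_tibble(table)
  means$direction <- factor(means$direction, levels = direction_names(),
                            labels = paste0(direction_labels(), "\n",
                                            direction_names()))
  ggplot2::ggplot(means,
                  ggplot2::aes(x = .data$direction, y = .data$structure,
                               fill = .data$variant_cm)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  na.value = "grey95") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Variant (cm)") +
    ggplot2::theme_minimal() +
    (if ("group" %in% names(means) && length(unique(means$group)) > 1)
      ggplot2::facet_wrap(~group) else NULL)
}

#' @rdname run_evaluation
#' @param x An `atlaseval_evaluation` tibble.
#' @param ... Unused.
#' @export
tidy.atlaseval_evaluation <- function(x, ...) {
  var_cols <- paste0("var_", direction_names())
  tidyr::pivot_longer(
    dplyr::select(x, dplyr::all_of(c("group_label", "case_id", "structure",
                                     "jaccard", var_cols))),
    cols = dplyr::all_of(var_cols), names_to = "direction",
    names_prefix = "var_", values_to = "variant_cm")
}

#' @rdname run_evaluation
#' @export
glance.atlaseval_evaluation <- function(x, ...) {
  var_cols <- paste0("var_", direction_names())
  vmat <- as.matrix(x[, var_cols])
  tibble(
    n_rows = nrow(x),
    n_groups = length(unique(x$group_label)),
    n_cases = length(unique(x$case_id)),
    jsc_mean = mean(x$jaccard), jsc_sd = sd(x$jaccard),
    cdv_mean = mean(vmat, na.rm = TRUE),
    n_excluded = sum(x$cdv_excluded)
  )
}
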