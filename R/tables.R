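#' Published mean directional extents for the heterogeneous atlas group
#'
#' Transcription of the published per-structure summary for
#' auto-segmentations built from the heterogeneous (randomly mixed) atlas
#' group: the mean reference and auto-segmentation extent (cm) in each of
#' the six directions, together with the printed variant.  The printed
#' variant is the mean of per-case variants, so for a few cells it
#' differs by 0.1 cm (one rounding unit) from the difference of the two
#' printed means; the difference-of-means route is exact for the
#' internally consistent cells.
#'
#' @return A tibble with columns `structure`, `direction` (`min_x` ..
#'   `max_z`), `ref_mean_cm`, `as_mean_cm`, `printed_variant_cm`.
#' @export
published_extents <- function() {
  dn <- direction_names()
  row <- function(structure, ref, as_, printed) {
    tibble(structure = structure, direction = dn, ref_mean_cm = ref,
           as_mean_cm = as_, printed_variant_cm = printed)
  }
  dplyr::bind_rows(
    row("Breast",
        c(0.9, 16.1, -2.1, 8.4, -9.4, 6.5),
        c(2.0, 16.1, -1.5, 8.5, -8.2, 7.6),
        c(-1.2, 0.0, -0.7, -0.1, -1.2, -1.1)),
    row("Level1",
        c(9.1, 14.3, -3.3, 2.3, -11.0, -3.8),
        c(9.7, 14.0, -2.1, 2.1, -11.7, -4.5),
        c(-0.6, 0.3, -1.2, 0.1, 0.8, 0.8)),
    row("Level2",
        c(6.4, 10.6, -1.0, 3.7, -12.8, -6.7),
        c(6.8, 10.4, -0.6, 3.4, -12.9, -6.9),
        c(-0.4, 0.2, -0.4, 0.3, 0.1, 0.2)),
    row("Level3",
        c(3.2, 8.8, -0.1, 4.3, -12.8, -9.4),
        c(3.8, 8.1, -0.3, 4.1, -13.1, -9.4),
        c(-0.6, 0.7, 0.2, 0.2, 0.3, 0.0)),
    row("Level4",
        c(1.2, 6.0, 0.2, 4.2, -13.2, -10.6),
        c(1.5, 6.5, 0.7, 4.1, -13.4, -10.7),
        c(-0.3, -0.5, -0.5, 0.2, 0.2, 0.1)),
    row("BrachialPlexus",
        c(-0.2, 10.7, -1.1, 4.2, -12.7, -4.0),
        c(3.3, 10.7, -0.3, 2.0, -15.3, -11.1),
        c(-3.5, 0.0, -0.9, 2.2, 2.6, 7.1)),
    row("HumeralHead",
        c(11.1, 15.7, -3.7, 1.1, -15.8, -12.4),
        c(11.1, 15.9, -3.5, 1.5, -16.1, -12.3),
        c(0.0, -0.2, -0.2, -0.4, 0.3, -0.1))
  )
}

#' Published centroid distance variants across atlas groups
#'
#' Transcription of the published per-structure variant summary (cm) for
#' the three reported atlas groups: large-separation atlases with
#' matching test cases (`Large MTC`), 15-degree atlases with
#' deliberately non-matching (20-degree) test cases (`15deg NMTC`), and
#' the heterogeneous mixed group.
#'
#' @return A tibble with columns `structure`, `group`, `direction`,
#'   `variant_cm`.
#' @export
published_variants <- function() {
  dn <- direction_names()
  row <- function(structure, group, v) {
    tibble(structure = structure, group = group, direction = dn,
           variant_cm = v)
  }
  dplyr::bind_rows(
    row("Breast", "Large MTC", c(0.2, 0.1, -0.9, 0.0, -0.2, -0.3)),
    row("Breast", "15deg NMTC", c(0.5, 0.2, -0.7, 0.0, 0.1, -0.6)),
    row("Breast", "Heterogeneous", c(-1.2, 0.0, -0.7, -0.1, -1.2, -1.1)),
    row("Level1", "Large MTC", c(-0.1, 0.4, -0.1, 0.2, 0.3, -0.2)),
    row("Level1", "15deg NMTC", c(-0.1, 0.4, -0.8, 0.0, 0.1, -0.9)),
    row("Level1", "Heterogeneous", c(-0.6, 0.3, -1.2, 0.1, 0.8, 0.8)),
    row("Level2", "Large MTC", c(0.1, 0.6, -0.4, 0.5, 0.2, 0.3)),
    row("Level2", "15deg NMTC", c(-0.4, 1.4, -0.8, 0.8, -0.1, 2.0)),
    row("Level2", "Heterogeneous", c(-0.4, 0.2, -0.4, 0.3, 0.1, 0.2)),
    row("Level3", "Large MTC", c(-0.1, 0.6, -0.7, 0.1, 0.1, -0.4)),
    row("Level3", "15deg NMTC", c(-0.2, 0.6, -1.0, 0.2, 0.0, -0.2)),
    row("Level3", "Heterogeneous", c(-0.6, 0.7, 0.2, 0.2, 0.3, 0.0)),
    row("Level4", "Large MTC", c(0.4, 0.4, -0.6, 0.2, 0.2, -0.8)),
    row("Level4", "15deg NMTC", c(0.1, 0.5, -0.7, 0.2, 0.4, -0.5)),
    row("Level4", "Heterogeneous", c(-0.3, -0.5, -0.5, 0.2, 0.2, 0.1)),
    row("Level3_4", "Large MTC", c(0.0, 0.7, -0.7, 0.3, 0.3, -0.4)),
    row("Level3_4", "15deg NMTC", c(0.0, 0.7, -1.0, 0.3, 0.4, -0.2)),
    row("Level1_4", "Large MTC", c(0.0, 0.4, -0.4, 0.1, 0.6, 0.1)),
    row("Level1_4", "15deg NMTC", c(0.0, 0.4, -1.0, 0.4, 0.5, -0.1)),
    row("BrachialPlexus", "Large MTC", c(-0.8, 3.2, -0.6, 0.9, -0.7, 0.7)),
    row("BrachialPlexus", "15deg NMTC", c(-1.4, 2.3, -0.9, 0.4, -0.2, 0.5)),
    row("BrachialPlexus", "Heterogeneous",
        c(-3.5, 0.0, -0.9, 2.2, 2.6, 7.1)),
    row("HumeralHead", "Large MTC", c(-0.1, 0.1, -0.1, 0.0, 0.4, 0.0)),
    row("HumeralHead", "15deg NMTC", c(-0.3, -0.1, 0.0, -0.1, 0.7, 0.0)),
    row("HumeralHead", "Heterogeneous", c(0.0, -0.2, -0.2, -0.4, 0.3, -0.1))
  )
}
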