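direction_names <- function() {
  c("min_x", "max_x", "min_y", "max_y", "min_z", "max_z")
}

#' Anatomical labels of the six directional components
#'
#' Maps the per-axis minima/maxima onto the anatomy implied by the grid
#' convention: `min_x` medial, `max_x` lateral, `min_y` posterior,
#' `max_y` anterior, `min_z` superior, `max_z` inferior.
#'
#' @return Named character vector keyed by direction.
#' @export
direction_labels <- function() {
  c(min_x = "medial", max_x = "lateral", min_y = "posterior",
    max_y = "anterior", min_z = "superior", max_z = "inferior")
}

#' Jaccard and Dice overlap of two binary masks
#'
#' The Jaccard similarity coefficient (JSC) is the intersection over the
#' union of the two voxel sets; 1 indicates complete overlap.  The Dice
#' coefficient is computed jointly via `D = 2J / (1 + J)`.  Two empty
#' masks are defined as identical (JSC 1); an empty versus a non-empty
#' mask gives 0.
#'
#' @param a,b Binary 3D masks on the same grid.
#' @return An `overlap_score`: list with `jaccard` and `dice`.
#' @export
#' @examples
#' m <- array(FALSE, c(4, 4, 4)); m[1:2, 1:2, 1:2] <- TRUE
#' jaccard(m, m)$jaccard
jaccard <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    abort("masks are defined on different grids")
  a <- as.logical(a); b <- as.logical(b)
  inter <- sum(a & b)
  uni <- sum(a | b)
  j <- if (uni == 0) 1 else inter / uni
  structure(list(jaccard = j, dice = 2 * j / (1 + j)),
            class = "overlap_score")
}

#' @export
print.overlap_score <- function(x, ...) {
  cat(sprintf("<overlap_score> JSC %.4f, DSC %.4f\n", x$jaccard, x$dice))
  invisible(x)
}

#' Convert a Dice coefficient to a Jaccard coefficient
#'
#' `J = D / (2 - D)`; e.g. a Dice of 0.8 corresponds to a Jaccard of
#' 0.667 (0.7 at one decimal).
#'
#' @param d Dice fraction in `[0, 1]`.
#' @return Jaccard fraction.
#' @export
dice_to_jaccard <- function(d) {
  if (any(d < 0 | d > 1)) abort("Dice values must lie in [0, 1]")
  d / (2 - d)
}

#' Convert a Jaccard coefficient to a Dice coefficient
#'
#' Inverse of [dice_to_jaccard()]: `D = 2J / (1 + J)`.
#'
#' @param j Jaccard fraction in `[0, 1]`.
#' @return Dice fraction.
#' @export
jaccard_to_dice <- function(j) {
  if (any(j < 0 | j > 1)) abort("Jaccard values must lie in [0, 1]")
  2 * j / (1 + j)
}

#' Centroid of a binary mask in physical coordinates
#'
#' Unweighted mean of the occupied voxel-centre coordinates, in cm.
#'
#' @param mask Non-empty binary 3D mask.
#' @param grid The [voxel_grid()] the mask lives on.
#' @return Numeric length-3 centroid (cm).
#' @export
mask_centroid <- function(mask, grid) {
  idx <- which(as.logical(mask))
  if (length(idx) == 0) abort("centroid of an empty mask is undefined")
  d <- grid$dim
  i <- (idx - 1) %% d[1]
  j <- ((idx - 1) %/% d[1]) %% d[2]
  k <- (idx - 1) %/% (d[1] * d[2])
  grid$origin_cm + c(mean(i), mean(j), mean(k)) * grid$spacing_mm / 10
}

#' Directional extents of a structure
#'
#' The signed physical coordinates (cm, voxel centres) of the extreme
#' occupied voxels along each axis: the most medial, lateral, posterior,
#' anterior, superior and inferior extent of the structure under the
#' fixed axis convention.
#'
#' @inheritParams mask_centroid
#' @return A named numeric vector of class `directional_extents` with
#'   components `min_x`, `max_x`, `min_y`, `max_y`, `min_z`, `max_z`.
#' @export
directional_extents <- function(mask, grid) {
  idx <- which(as.logical(mask))
  if (length(idx) == 0) abort("extents of an empty mask are undefined")
  d <- grid$dim
  i <- (idx - 1) %% d[1]
  j <- ((idx - 1) %/% d[1]) %% d[2]
  k <- (idx - 1) %/% (d[1] * d[2])
  sp <- grid$spacing_mm / 10
  o <- grid$origin_cm
  structure(
    c(min_x = o[1] + min(i) * sp[1], max_x = o[1] + max(i) * sp[1],
      min_y = o[2] + min(j) * sp[2], max_y = o[2] + max(j) * sp[2],
      min_z = o[3] + min(k) * sp[3], max_z = o[3] + max(k) * sp[3]),
    class = "directional_extents"
  )
}

#' Signed centroid distances of a structure
#'
#' For each of the six directions, the extent coordinate minus the centre
#' coordinate on the matching axis (signed, cm).  With
#' `centre_mode = "own"` the centre is the structure's own centroid; with
#' `centre_mode = "reference"` a supplied reference centre is used, which
#' makes the distances sensitive to whole-structure displacement.
#'
#' @param ext A [directional_extents()] vector.
#' @param centre Length-3 centre point (cm).
#' @param centre_mode `"own"` or `"reference"`; recorded on the result so
#'   that only like-for-like distances are differenced.
#' @return A named numeric vector of class `centroid_distances` with a
#'   `centre_mode` attribute.
#' @export
centroid_distances <- function(ext, centre, centre_mode = c("own",
                                                            "reference")) {
  centre_mode <- match.arg(centre_mode)
  stopifnot(length(centre) == 3L)
  d <- c(
    min_x = ext[["min_x"]] - centre[1], max_x = ext[["max_x"]] - centre[1],
    min_y = ext[["min_y"]] - centre[2], max_y = ext[["max_y"]] - centre[2],
    min_z = ext[["min_z"]] - centre[3], max_z = ext[["max_z"]] - centre[3]
  )
  structure(d, centre_mode = centre_mode, class = "centroid_distances")
}

#' Centroid distance variants (reference minus test)
#'
#' The per-direction difference between reference and auto-segmentation
#' centroid distances, in cm.  The reference-minus-test orientation is
#' the one that reproduces published per-structure variant tables (e.g. a
#' level 2 medial reference distance of 6.4 cm against a test distance of
#' 6.8 cm gives a variant of -0.4).  Raw values are retained; rounded
#' values at `decimals` places are reported alongside.
#'
#' @param ref,test [centroid_distances()] with matching `centre_mode`.
#' @param structure Optional structure name carried on the record.
#' @param decimals Reporting precision in decimal places.
#' @return A `cdv_record`: list with `structure`, `variants` (rounded),
#'   `raw`, `decimals`, `centre_mode`.
#' @export
cdv <- function(ref, test, structure = NA_character_, decimals = 1) {
  if (!identical(attr(ref, "centre_mode"), attr(test, "centre_mode")))
    abort("centre_mode mismatch between reference and test distances")
  raw <- setNames(as.numeric(unclass(ref) - unclass(test)),
                  direction_names())
  structure(
    list(structure = structure, variants = round(raw, decimals),
         raw = raw, decimals = decimals,
         centre_mode = attr(ref, "centre_mode")),
    class = "cdv_record"
  )
}

#' @export
print.cdv_record <- function(x, ...) {
  cat(sprintf("<cdv_record> %s (centre: %s), cm\n",
              ifelse(is.na(x$structure), "(unnamed)", x$structure),
              x$centre_mode))
  print(x$variants)
  invisible(x)
}

#' Centroid distance variants from mean directional extents
#'
#' Convenience route used with published summary tables: when reference
#' and test distances share one centre the centre cancels and the variant
#' reduces to the difference of directional extents.  Accepts two
#' named vectors of per-direction extent means (cm).
#'
#' @param ref_ext,test_ext Named numeric vectors with components
#'   `min_x` .. `max_z` (cm).
#' @inheritParams cdv
#' @return A `cdv_record` (centre mode `"reference"`).
#' @export
cdv_from_extents <- function(ref_ext, test_ext, structure = NA_character_,
                             decimals = 1) {
  dn <- direction_names()
  r <- centroid_distances(structure(as.numeric(ref_ext[dn]), names = dn),
                          c(0, 0, 0), "reference")
  t <- centroid_distances(structure(as.numeric(test_ext[dn]), names = dn),
                          c(0, 0, 0), "reference")
  cdv(r, t, structure = structure, decimals = decimals)
}

#' Classify variants as under- or over-contouring
#'
#' Direction-aware reading of signed variants (reference minus test): in
#' a min direction (medial, posterior, superior) a negative variant means
#' the auto-segmentation stops short of the reference boundary
#' (under-contouring) and a positive variant overshoots it
#' (over-contouring); in a max direction (lateral, anterior, inferior)
#' the signs swap.  Magnitudes below the dead band are labelled `none`.
#'
#' @param record A `cdv_record`.
#' @param dead_band_cm Magnitude below which a variant is treated as no
#'   variation (default 0.05 cm, half the 0.1 cm reporting precision).
#' @return Named character vector over the six directions with values
#'   `"under"`, `"over"` or `"none"`.
#' @export
classify_variant <- function(record, dead_band_cm = 0.05) {
  stopifnot(inherits(record, "cdv_record"))
  v <- record$raw
  if (any(!is.finite(v))) abort("variants must be finite")
  out <- rep("none", 6)
  names(out) <- direction_names()
  mins <- c("min_x", "min_y", "min_z")
  for (dnm in names(out)) {
    if (abs(v[[dnm]]) < dead_band_cm) next
    if (dnm %in% mins) {
      out[[dnm]] <- if (v[[dnm]] < 0) "under" else "over"
    } else {
      out[[dnm]] <- if (v[[dnm]] > 0) "under" else "over"
    }
  }
  out
}

#' Compare a test structure set against a reference
#'
#' Batch metric computation: for every structure present in both sets,
#' the Jaccard/Dice overlap, reference volume, and the six centroid
#' distance variants.
#'
#' @param ref,test [structure_set()] objects on the same grid.
#' @param centre_mode Centre used for centroid distances: the structure's
#'   own centroid (`"own"`) or the reference structure's centroid for
#'   both (`"reference"`).
#' @param decimals Reporting precision for variants.
#' @return A tibble with one row per structure: `structure`, `jaccard`,
#'   `dice`, `volume_cm3`, and `var_min_x` .. `var_max_z` (cm, raw).
#' @export
evaluate_pairs <- function(ref, test, centre_mode = c("own", "reference"),
                           decimals = 1) {
  stopifnot(inherits(ref, "structure_set"), inherits(test, "structure_set"))
  stop_if_grid_mismatch(ref$grid, test$grid)
  centre_mode <- match.arg(centre_mode)
  common <- intersect(names(ref$masks), names(test$masks))
  vox <- grid_voxel_cm3(ref$grid)
  rows <- lapply(common, function(nm) {
    rm_ <- ref$masks[[nm]]; tm_ <- test$masks[[nm]]
    ov <- jaccard(rm_, tm_)
    vars <- rep(NA_real_, 6)
    if (any(rm_) && any(tm_)) {
      c_ref <- mask_centroid(rm_, ref$grid)
      c_test <- if (centre_mode == "own") mask_centroid(tm_, test$grid)
                else c_ref
      rd <- centroid_distances(directional_extents(rm_, ref$grid), c_ref,
                               centre_mode)
      td <- centroid_distances(directional_extents(tm_, test$grid), c_test,
                               centre_mode)
      vars <- cdv(rd, td, structure = nm, decimals = decimals)$raw
    }
    tibble(
      structure = nm, jaccard = ov$jaccard, dice = ov$dice,
      volume_cm3 = sum(rm_) * vox,
      var_min_x = vars[[1]], var_max_x = vars[[2]],
      var_min_y = vars[[3]], var_max_y = vars[[4]],
      var_min_z = vars[[5]], var_max_z = vars[[6]]
    )
  })
  dplyr::bind_rows(rows)
}
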