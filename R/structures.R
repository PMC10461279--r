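#' Controlled vocabulary of structure names
#'
#' The structures contoured for breast and loco-regional nodal
#' radiotherapy planning: breast CTV, axillary nodal levels 1-4 and the
#' combined CTVs (levels 3 & 4, levels 1-4), interpectoral and internal
#' mammary nodes, brachial plexus, humeral head, heart and lung.
#'
#' @return Character vector of valid structure names.
#' @export
structure_names <- function() {
  c("Breast", "Level1", "Level2", "Level3", "Level4", "Level3_4",
    "Level1_4", "Interpectoral", "IMN", "BrachialPlexus", "HumeralHead",
    "Heart", "Lung")
}

#' Structures the study treats as "larger"
#'
#' Breast, heart, lung and the level 1 nodes; used when aggregating
#' overlap scores by structure size class.
#'
#' @return Character vector.
#' @export
larger_structures <- function() c("Breast", "Heart", "Lung", "Level1")

#' Bundle binary structure masks on a shared grid
#'
#' @param grid A [voxel_grid()].
#' @param masks Named list of logical (or 0/1) 3D arrays conforming to
#'   `grid`; names must come from [structure_names()].
#'
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(grid, masks) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (length(masks) == 0 || is.null(names(masks)) ||
      any(!nzchar(names(masks))))
    abort("`masks` must be a non-empty named list")
  bad <- setdiff(names(masks), structure_names())
  if (length(bad))
    abort(paste0("unknown structure name(s): ", paste(bad, collapse = ", ")))
  masks <- lapply(masks, function(m) {
    if (!identical(dim(m), as.integer(grid$dim)) &&
        !identical(dim(m), grid$dim))
      abort("mask dimensions do not match the grid")
    storage.mode(m) <- "logical"
    m
  })
  structure(list(grid = grid, masks = masks), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d structures on %d x %d x %d grid\n",
              length(x$masks), x$grid$dim[1], x$grid$dim[2], x$grid$dim[3]))
  vox <- vapply(x$masks, sum, numeric(1))
  for (nm in names(x$masks))
    cat(sprintf("  %-15s %8d voxels\n", nm, as.integer(vox[[nm]])))
  invisible(x)
}

#' Add combined nodal clinical target volumes
#'
#' Builds `Level3_4` (union of levels 3 and 4) and `Level1_4` (union of
#' levels 1-4) as voxelwise unions of the individual nodal levels, as done
#' when combined CTVs are used during planning.
#'
#' @param ss A [structure_set()] containing `Level1`..`Level4`.
#' @return The structure set with `Level3_4` and `Level1_4` masks added
#'   (replaced if present).
#' @export
combine_nodes <- function(ss) {
  stopifnot(inherits(ss, "structure_set"))
  need <- paste0("Level", 1:4)
  missing <- setdiff(need, names(ss$masks))
  if (length(missing))
    abort(paste0("missing nodal levels: ", paste(missing, collapse = ", ")))
  ss$masks$Level3_4 <- ss$masks$Level3 | ss$masks$Level4
  ss$masks$Level1_4 <- ss$masks$Level1 | ss$masks$Level2 |
    ss$masks$Level3 | ss$masks$Level4
  ss
}

#' Structure volumes in cubic centimetres
#'
#' @param ss A [structure_set()].
#' @return A tibble with columns `structure` and `volume_cm3`.
#' @export
structure_volumes <- function(ss) {
  stopifnot(inherits(ss, "structure_set"))
  vox <- grid_voxel_cm3(ss$grid)
  tibble(
    structure = names(ss$masks),
    volume_cm3 = unname(vapply(ss$masks, function(m) sum(m) * vox,
                               numeric(1)))
  )
}
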