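#' Write a case to NIfTI volumes with a JSON sidecar
#'
#' File layout (all inside `dir`): `<id>_intensity.nii.gz` (CT-proxy),
#' `<id>_body.nii.gz` (body mask), one `<id>_mask_<Structure>.nii.gz`
#' per structure (unsigned 8-bit, 0/1), and `<id>_meta.json` with the
#' grid (dim, spacing in mm, origin in cm), case metadata and the
#' structure list.  Voxel spacings are also stored in each NIfTI header.
#'
#' @param case A `case_record`.
#' @param dir Output directory (created if needed).
#' @return The sidecar path, invisibly.
#' @export
write_case <- function(case, dir) {
  stopifnot(inherits(case, "case_record"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- case$case_id
  g <- case$grid

  as_nii <- function(arr, datatype) {
    attr(arr, "pixdim") <- g$spacing_mm
    RNifti::asNifti(arr, datatype = datatype)
  }
  RNifti::writeNifti(as_nii(case$intensity * 1, "float"),
                     file.path(dir, paste0(id, "_intensity.nii.gz")))
  RNifti::writeNifti(as_nii(case$body + 0L, "uint8"),
                     file.path(dir, paste0(id, "_body.nii.gz")))
  for (nm in names(case$structures$masks))
    RNifti::writeNifti(
      as_nii(case$structures$masks[[nm]] + 0L, "uint8"),
      file.path(dir, paste0(id, "_mask_", nm, ".nii.gz")))

  meta <- list(
    case_id = id,
    grid = list(dim = g$dim, spacing_mm = g$spacing_mm,
                origin_cm = g$origin_cm),
    incline_deg = case$incline_deg,
    separation_cm = case$separation_cm,
    separation_class = case$separation_class,
    role = case$role,
    seed = case$seed,
    structures = names(case$structures$masks)
  )
  sidecar <- file.path(dir, paste0(id, "_meta.json"))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(sidecar)
}

#' Read a case written by [write_case()]
#'
#' Validates the layout: structure names must belong to the controlled
#' vocabulary, every volume must agree with the sidecar grid (dimensions
#' and header spacing), and label data must be binary.
#'
#' @param dir Directory containing the case files.
#' @param case_id Case identifier.
#' @return A `case_record`.
#' @export
read_case <- function(dir, case_id) {
  sidecar <- file.path(dir, paste0(case_id, "_meta.json"))
  if (!file.exists(sidecar))
    abort(paste0("no sidecar found for case '", case_id, "'"))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  grid <- voxel_grid(meta$grid$dim, meta$grid$spacing_mm,
                     meta$grid$origin_cm)

  bad <- setdiff(meta$structures, structure_names())
  if (length(bad))
    abort(paste0("unknown structure name(s) in sidecar: ",
                 paste(bad, collapse = ", ")))

  read_vol <- function(path) {
    img <- RNifti::readNifti(path)
    arr <- array(as.numeric(img), dim = dim(img))
    if (!identical(as.integer(dim(arr)), grid$dim))
      abort(paste0("grid mismatch: ", basename(path),
                   " does not match the sidecar dimensions"))
    pd <- RNifti::pixdim(img)[1:3]
    if (any(abs(pd - grid$spacing_mm) > 1e-4))
      abort(paste0("spacing mismatch: ", basename(path),
                   " disagrees with the sidecar grid"))
    arr
  }
  read_mask <- function(path) {
    arr <- read_vol(path)
    if (!all(arr %in% c(0, 1)))
      abort(paste0("non-binary label data in ", basename(path)))
    array(arr > 0.5, dim = grid$dim)
  }

  intensity <- read_vol(file.path(dir, paste0(case_id, "_intensity.nii.gz")))
  body <- read_mask(file.path(dir, paste0(case_id, "_body.nii.gz")))
  masks <- lapply(meta$structures, function(nm)
    read_mask(file.path(dir, paste0(case_id, "_mask_", nm, ".nii.gz"))))
  names(masks) <- meta$structures

  structure(
    list(case_id = case_id, intensity = intensity, body = body,
         structures = structure_set(grid, masks), grid = grid,
         incline_deg = meta$incline_deg,
         separation_cm = meta$separation_cm,
         separation_class = meta$separation_class, role = meta$role,
         seed = meta$seed),
    class = "case_record"
  )
}

#' Write a whole cohort
#'
#' One subdirectory of case files plus `cohort.json` recording the
#' master seed, separation cut and per-case metadata.
#'
#' @param cohort A `case_cohort`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "case_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (case in cohort$cases) write_case(case, file.path(dir, "cases"))
  jsonlite::write_json(
    list(seed = cohort$seed, separation_cut_cm = cohort$separation_cut_cm,
         meta = cohort$meta),
    file.path(dir, "cohort.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `cohort.json` and `cases/`.
#' @return A `case_cohort`.
#' @export
read_cohort <- function(dir) {
  manifest <- file.path(dir, "cohort.json")
  if (!file.exists(manifest))
    abort(paste0("no cohort manifest at ", manifest))
  info <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  meta <- as_tibble(info$meta)
  cases <- lapply(meta$case_id, function(id)
    read_case(file.path(dir, "cases"), id))
  names(cases) <- meta$case_id
  structure(
    list(cases = cases, meta = meta, seed = info$seed,
         separation_cut_cm = info$separation_cut_cm),
    class = "case_cohort"
  )
}

#' Write an auto-segmentation with provenance
#'
#' Parallel layout to [write_case()]: per-structure mask files named
#' `<case>_as_<group>_mask_<Structure>.nii.gz` plus a JSON sidecar with
#' the atlas ids and a hash of the parameters used.
#'
#' @param as_set A [structure_set()] (e.g. from [auto_segment()]).
#' @param case_id,group_label Identifiers for the file names.
#' @param dir Output directory.
#' @param provenance List stored verbatim in the sidecar (e.g. atlas
#'   ids, parameter hash).
#' @return The sidecar path, invisibly.
#' @export
write_autoseg <- function(as_set, case_id, group_label, dir,
                          provenance = list()) {
  stopifnot(inherits(as_set, "structure_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- paste0(case_id, "_as_", group_label)
  g <- as_set$grid
  for (nm in names(as_set$masks)) {
    arr <- as_set$masks[[nm]] + 0L
    attr(arr, "pixdim") <- g$spacing_mm
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "uint8"),
                       file.path(dir, paste0(stem, "_mask_", nm,
                                             ".nii.gz")))
  }
  meta <- c(list(
    case_id = case_id, group_label = group_label,
    grid = list(dim = g$dim, spacing_mm = g$spacing_mm,
                origin_cm = g$origin_cm),
    structures = names(as_set$masks),
    atlas_ids = attr(as_set, "atlas_ids")
  ), provenance)
  sidecar <- file.path(dir, paste0(stem, "_meta.json"))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(sidecar)
}

#' Read an auto-segmentation written by [write_autoseg()]
#'
#' @inheritParams write_autoseg
#' @param dir Directory containing the files.
#' @return A [structure_set()] with attribute `atlas_ids`.
#' @export
read_autoseg <- function(dir, case_id, group_label) {
  stem <- paste0(case_id, "_as_", group_label)
  sidecar <- file.path(dir, paste0(stem, "_meta.json"))
  if (!file.exists(sidecar))
    abort(paste0("no auto-segmentation sidecar at ", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  grid <- voxel_grid(meta$grid$dim, meta$grid$spacing_mm,
                     meta$grid$origin_cm)
  masks <- lapply(meta$structures, function(nm) {
    img <- RNifti::readNifti(file.path(dir, paste0(stem, "_mask_", nm,
                                                   ".nii.gz")))
    array(as.numeric(img) > 0.5, dim = grid$dim)
  })
  names(masks) <- meta$structures
  out <- structure_set(grid, masks)
  attr(out, "atlas_ids") <- meta$atlas_ids
  out
}

# CSV with a unit-declaring comment header; read back with
# read_results_csv()
write_results_csv <- function(df, path, units_note) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", units_note), con)
  utils::write.csv(df, con, row.names = FALSE)
}

read_results_csv <- function(path) {
  as_tibble(utils::read.csv(path, comment.char = "#",
                            stringsAsFactors = FALSE))
}
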