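#' Voxel grid with physical spacing and anatomical axis convention
#'
#' A `voxel_grid` describes the sampling lattice shared by an intensity
#' volume and its structure masks: voxel counts per axis, voxel spacing in
#' millimetres, and the physical coordinate (in centimetres) of the centre
#' of the first voxel.  The anatomical convention is fixed: +x runs
#' medial-to-lateral, +y posterior-to-anterior, and +z superior-to-inferior,
#' so per-axis minima/maxima correspond to the medial, lateral, posterior,
#' anterior, superior and inferior extents of a structure.
#'
#' @param dim Integer vector of length 3, voxel counts per axis (each >= 1).
#' @param spacing_mm Numeric vector of length 3, voxel spacing in mm
#'   (each > 0).
#' @param origin_cm Numeric vector of length 3, physical coordinate (cm) of
#'   the first voxel centre.
#'
#' @return An object of class `voxel_grid`.
#' @export
#' @examples
#' g <- voxel_grid(c(96, 96, 96), spacing_mm = c(2.5, 2.5, 2.5))
#' grid_axis_coords(g, 1)[1:4]
voxel_grid <- function(dim, spacing_mm, origin_cm = c(0, 0, 0)) {
  dim <- as.integer(dim)
  spacing_mm <- as.numeric(spacing_mm)
  origin_cm <- as.numeric(origin_cm)
  if (length(dim) != 3L || any(is.na(dim)) || any(dim < 1L))
    abort("`dim` must be 3 positive voxel counts")
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    abort("`spacing_mm` must be 3 positive spacings")
  if (length(origin_cm) != 3L || any(!is.finite(origin_cm)))
    abort("`origin_cm` must be 3 finite coordinates")
  structure(
    list(dim = dim, spacing_mm = spacing_mm, origin_cm = origin_cm),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf(
    "<voxel_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm, origin (%g, %g, %g) cm\n",
    x$dim[1], x$dim[2], x$dim[3],
    x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
    x$origin_cm[1], x$origin_cm[2], x$origin_cm[3]
  ))
  invisible(x)
}

#' Physical voxel-centre coordinates along one axis
#'
#' @param grid A [voxel_grid()].
#' @param axis Axis index 1 (x), 2 (y) or 3 (z).
#' @return Numeric vector of voxel-centre coordinates in cm.
#' @export
grid_axis_coords <- function(grid, axis) {
  stopifnot(inherits(grid, "voxel_grid"), axis %in% 1:3)
  grid$origin_cm[axis] +
    (seq_len(grid$dim[axis]) - 1) * grid$spacing_mm[axis] / 10
}

#' World-coordinate arrays for every voxel centre
#'
#' @param grid A [voxel_grid()].
#' @return A list with 3D arrays `x`, `y`, `z` of coordinates in cm.
#' @export
grid_world <- function(grid) {
  xs <- grid_axis_coords(grid, 1)
  ys <- grid_axis_coords(grid, 2)
  zs <- grid_axis_coords(grid, 3)
  d <- grid$dim
  list(
    x = array(rep(xs, times = d[2] * d[3]), dim = d),
    y = array(rep(rep(ys, each = d[1]), times = d[3]), dim = d),
    z = array(rep(zs, each = d[1] * d[2]), dim = d)
  )
}

grid_center_cm <- function(grid) {
  grid$origin_cm + (grid$dim - 1) * grid$spacing_mm / 20
}

grid_extent_cm <- function(grid) {
  # physical span covered by voxel centres, per axis
  (grid$dim - 1) * grid$spacing_mm / 10
}

grid_voxel_cm3 <- function(grid) prod(grid$spacing_mm / 10)

#' Test whether two grids are compatible
#'
#' Grids are compatible when dimensions, spacings and origins agree to
#' within a small tolerance.
#'
#' @param a,b [voxel_grid()] objects.
#' @param tol Numeric tolerance (cm / mm as appropriate).
#' @return Logical scalar.
#' @export
grid_compatible <- function(a, b, tol = 1e-6) {
  identical(a$dim, b$dim) &&
    all(abs(a$spacing_mm - b$spacing_mm) < tol) &&
    all(abs(a$origin_cm - b$origin_cm) < tol)
}

stop_if_grid_mismatch <- function(a, b) {
  if (!grid_compatible(a, b))
    abort("volumes are defined on different grids")
  invisible(TRUE)
}

# world-cm pull affine (q_w = A_w p_w + t_w) -> 0-based index affine
affine_world_to_index <- function(grid, A_w, t_w) {
  sp <- grid$spacing_mm / 10
  o <- grid$origin_cm
  A_i <- diag(1 / sp) %*% A_w %*% diag(sp)
  t_i <- (A_w %*% o + t_w - o) / sp
  list(A = A_i, t = as.numeric(t_i))
}

#' Rotation matrix from per-axis angles
#'
#' Composes rotations about the anatomical axes as `Rz %*% Ry %*% Rx`,
#' angles in degrees.
#'
#' @param angles_deg Numeric vector of length 3 (rotations about x, y, z).
#' @return A 3x3 rotation matrix.
#' @keywords internal
rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Gaussian smoothing of a 3D volume
#'
#' Separable Gaussian filter with replicated edges.
#'
#' @param vol 3D numeric array.
#' @param sigma_voxels Standard deviation in voxels; `<= 0` returns the
#'   input unchanged.
#' @return Smoothed array of the same dimensions.
#' @export
smooth_volume <- function(vol, sigma_voxels) {
  d <- dim(vol)
  stopifnot(length(d) == 3L)
  out <- cpp_smooth3d(as.numeric(vol), as.integer(d), sigma_voxels)
  array(out, dim = d)
}
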