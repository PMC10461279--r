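#' Rigid transform (rotation + translation)
#'
#' Pull/resampling convention: the transform maps coordinates of the
#' fixed (test) grid into the moving (atlas) space, so volumes are warped
#' by sampling the moving image at transformed fixed-grid coordinates.
#' Rotations are about the grid centre.
#'
#' @param rotation_deg Length-3 rotation angles (degrees) about x, y, z.
#' @param translation_cm Length-3 translation (cm).
#' @param center_cm Rotation centre (cm); defaults to the origin.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation_deg = c(0, 0, 0),
                            translation_cm = c(0, 0, 0),
                            center_cm = c(0, 0, 0)) {
  structure(
    list(rotation_deg = as.numeric(rotation_deg),
         translation_cm = as.numeric(translation_cm),
         center_cm = as.numeric(center_cm)),
    class = "rigid_transform"
  )
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> rot (%.2f, %.2f, %.2f) deg, trans (%.2f, %.2f, %.2f) cm\n",
    x$rotation_deg[1], x$rotation_deg[2], x$rotation_deg[3],
    x$translation_cm[1], x$translation_cm[2], x$translation_cm[3]))
  invisible(x)
}

# world-cm pull affine of a rigid transform
rigid_world_affine <- function(tr) {
  R <- rotation_matrix(tr$rotation_deg)
  c0 <- tr$center_cm
  list(A = R, t = as.numeric(c0 - R %*% c0 + tr$translation_cm))
}

#' Warp a volume through a rigid transform
#'
#' @param vol 3D numeric array on `grid`.
#' @param grid A [voxel_grid()].
#' @param transform A [rigid_transform()].
#' @param default Fill value outside the source volume.
#' @return Warped array.
#' @export
apply_rigid <- function(vol, grid, transform, default = min(vol)) {
  wa <- rigid_world_affine(transform)
  ai <- affine_world_to_index(grid, wa$A, wa$t)
  array(cpp_warp_affine(as.numeric(vol), grid$dim, grid$dim, ai$A, ai$t,
                        default),
        dim = grid$dim)
}

# smooth + stride-2 downsample; returns list(vol, grid)
downsample2 <- function(vol, grid) {
  sm <- smooth_volume(vol, 0.8)
  d <- grid$dim
  ix <- seq(1, d[1], by = 2); iy <- seq(1, d[2], by = 2)
  iz <- seq(1, d[3], by = 2)
  g2 <- voxel_grid(c(length(ix), length(iy), length(iz)),
                   grid$spacing_mm * 2, grid$origin_cm)
  list(vol = sm[ix, iy, iz, drop = FALSE], grid = g2)
}

ncc <- function(a, b) {
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa < 1e-12 || sb < 1e-12)
    abort("similarity undefined for constant volumes")
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

#' Rigid registration by normalised cross-correlation
#'
#' Moment-based initialisation (intensity-centroid alignment) followed by
#' local Nelder-Mead refinement of the six rigid parameters maximising
#' the normalised cross-correlation between the fixed volume and the
#' warped moving volume.  The search runs on volumes downsampled by two
#' for speed; the search space is bounded to translations within a
#' quarter of the field of view and rotations within +/- 15 degrees
#' (covering the 15 vs 20 degree incline gap).
#'
#' @param fixed,moving 3D intensity arrays on `grid`.
#' @param grid A [voxel_grid()] shared by both volumes.
#' @param params List of controls: `maxit` (Nelder-Mead iterations),
#'   `downsample` (logical).
#' @return A [rigid_transform()] with attribute `ncc`, the achieved
#'   similarity.
#' @export
rigid_register <- function(fixed, moving, grid,
                           params = list(maxit = 150, downsample = TRUE)) {
  p <- modifyList(list(maxit = 150, downsample = TRUE), params)
  if (stats::sd(fixed) < 1e-12 || stats::sd(moving) < 1e-12)
    abort("similarity undefined for constant volumes")
  ctr <- grid_center_cm(grid)

  if (isTRUE(p$downsample) && all(grid$dim >= 32L)) {
    f <- downsample2(fixed, grid); m <- downsample2(moving, grid)
    g <- f$grid; fv <- f$vol; mv <- m$vol
  } else {
    g <- grid; fv <- fixed; mv <- moving
  }
  def <- min(mv)

  # moment initialisation: map the fixed intensity centroid onto the
  # moving one (intensities shifted to be non-negative weights)
  wcent <- function(v, gg) {
    w <- v - min(v)
    w <- w / sum(w)
    ww <- grid_world(gg)
    c(sum(ww$x * w), sum(ww$y * w), sum(ww$z * w))
  }
  t0 <- wcent(mv, g) - wcent(fv, g)

  t_max <- grid_extent_cm(grid) / 4
  rot_max <- 15
  obj <- function(par) {
    if (any(abs(par[1:3]) > rot_max) || any(abs(par[4:6]) > t_max))
      return(1e3 + sum(pmax(abs(par[1:3]) - rot_max, 0)) +
               sum(pmax(abs(par[4:6]) - t_max, 0)))
    tr <- rigid_transform(par[1:3], par[4:6], ctr)
    -ncc(fv, apply_rigid(mv, g, tr, default = def))
  }

  t_start <- pmin(pmax(t0, -t_max), t_max)
  # coarse seeding over rotations about x (the incline axis) before the
  # local search, which otherwise stalls on the NCC rotation landscape
  seeds <- lapply(seq(-12, 12, by = 4), function(rx) c(rx, 0, 0, t_start))
  seed_vals <- vapply(seeds, obj, numeric(1))
  start <- seeds[[which.min(seed_vals)]]
  f_start <- min(seed_vals)
  par <- start
  val <- f_start
  for (round in 1:2) {
    opt <- stats::optim(
      par, obj, method = "Nelder-Mead",
      control = list(maxit = p$maxit,
                     parscale = c(2, 2, 2, 0.5, 0.5, 0.5))
    )
    if (opt$value < val) {
      par <- opt$par
      val <- opt$value
    }
  }
  # keep the identity when it is at least as good (self-registration)
  f_id <- tryCatch(obj(rep(0, 6)), error = function(e) Inf)
  if (f_id <= val + 1e-12) {
    par <- rep(0, 6); val <- f_id
  }
  out <- rigid_transform(par[1:3], par[4:6], ctr)
  attr(out, "ncc") <- -val
  out
}

#' Deformation field
#'
#' Per-voxel displacement vectors (mm) on the fixed grid, pull
#' convention: a voxel at fixed-grid position `p` samples the moving
#' image at `p + u(p)`.
#'
#' @param grid [voxel_grid()] of the fixed image.
#' @param ux,uy,uz Displacement component arrays in mm.
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(grid, ux, uy, uz) {
  stopifnot(identical(dim(ux), as.integer(grid$dim)) ||
              identical(dim(ux), grid$dim))
  if (any(!is.finite(ux)) || any(!is.finite(uy)) || any(!is.finite(uz)))
    abort("deformation field must be finite everywhere")
  structure(list(grid = grid, ux = ux, uy = uy, uz = uz),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(x$ux^2 + x$uy^2 + x$uz^2)
  cat(sprintf("<deformation_field> max |u| %.2f mm, mean |u| %.2f mm\n",
              max(mag), mean(mag)))
  invisible(x)
}

zero_field <- function(grid) {
  z <- array(0, dim = grid$dim)
  deformation_field(grid, z, z, z)
}

# central-difference gradient in voxel units
gradient3d <- function(v) {
  d <- dim(v)
  gx <- v; gy <- v; gz <- v
  gx[] <- 0; gy[] <- 0; gz[] <- 0
  gx[2:(d[1] - 1), , ] <- (v[3:d[1], , ] - v[1:(d[1] - 2), , ]) / 2
  gy[, 2:(d[2] - 1), ] <- (v[, 3:d[2], ] - v[, 1:(d[2] - 2), ]) / 2
  gz[, , 2:(d[3] - 1)] <- (v[, , 3:d[3]] - v[, , 1:(d[3] - 2)]) / 2
  list(x = gx, y = gy, z = gz)
}

# trilinear upsample of a coarse field component onto a finer grid
upsample_component <- function(comp, fine_dim) {
  cd <- dim(comp)
  A <- diag((cd - 1) / pmax(fine_dim - 1, 1))
  array(cpp_warp_affine(as.numeric(comp), as.integer(cd),
                        as.integer(fine_dim), A, c(0, 0, 0), 0),
        dim = fine_dim)
}

#' Deformable registration by multi-resolution optical flow
#'
#' A demons-style scheme in the optical-flow family: at each resolution
#' level the per-voxel update is the intensity mismatch times the fixed
#' image gradient, normalised by the squared gradient magnitude plus the
#' squared mismatch, followed by Gaussian smoothing of the field.
#' Iteration stops on the iteration cap or when the relative improvement
#' of the sum of squared differences (SSD) falls below `tol`; a
#' divergence guard stops (with a warning) if SSD worsens for
#' `diverge_limit` consecutive iterations.  The returned field is the
#' best (lowest-SSD) iterate, so final SSD never exceeds the initial SSD.
#'
#' @param fixed,moving 3D intensity arrays on `grid` (the moving volume
#'   already rigidly aligned).
#' @param grid A [voxel_grid()].
#' @param params Controls: `levels` (resolution levels, default 3),
#'   `iterations` (per level, default 50), `sigma_voxels` (field
#'   smoothing, default 1.5), `tol` (relative SSD tolerance, default
#'   1e-4), `diverge_limit` (default 5).
#' @return A [deformation_field()] with attributes `ssd_initial` and
#'   `ssd_final`.
#' @export
deformable_register <- function(fixed, moving, grid, params = list()) {
  p <- modifyList(
    list(levels = 3L, iterations = 50L, sigma_voxels = 1.5, tol = 1e-4,
         diverge_limit = 5L),
    params
  )
  stopifnot(identical(dim(fixed), dim(moving)))

  # build pyramid, coarsest first
  pyr <- list(list(fixed = fixed, moving = moving, grid = grid))
  lev <- 1L
  # never coarsen below 24 voxels per axis: coarser grids no longer
  # resolve the anatomy and derail the finer levels
  while (lev < p$levels && all(pyr[[1]]$grid$dim >= 48L)) {
    top <- pyr[[1]]
    pyr <- c(list(list(
      fixed = downsample2(top$fixed, top$grid)$vol,
      moving = downsample2(top$moving, top$grid)$vol,
      grid = downsample2(top$fixed, top$grid)$grid
    )), pyr)
    lev <- lev + 1L
  }

  u <- NULL
  ssd0_full <- sum((fixed - moving)^2)
  for (L in seq_along(pyr)) {
    f <- pyr[[L]]$fixed; m <- pyr[[L]]$moving; g <- pyr[[L]]$grid
    d <- g$dim
    if (is.null(u)) {
      ux <- array(0, d); uy <- array(0, d); uz <- array(0, d)
    } else {
      ratio <- dim(u$ux) / d    # coarse voxels per fine voxel
      ux <- upsample_component(u$ux, d) / ratio[1]
      uy <- upsample_component(u$uy, d) / ratio[2]
      uz <- upsample_component(u$uz, d) / ratio[3]
    }
    gr <- gradient3d(f)
    g2 <- gr$x^2 + gr$y^2 + gr$z^2
    def <- min(m)
    warp <- function() array(
      cpp_warp_field(as.numeric(m), d, as.numeric(ux), as.numeric(uy),
                     as.numeric(uz), def), dim = d)

    mw <- warp()
    ssd <- sum((mw - f)^2)
    if (L > 1L) {
      # guard: fall back to the zero field if the upsampled coarse field
      # starts off worse than no deformation at all
      ssd_zero <- sum((m - f)^2)
      if (ssd_zero < ssd) {
        ux[] <- 0; uy[] <- 0; uz[] <- 0
        mw <- m
        ssd <- ssd_zero
      }
    }
    best <- list(ssd = ssd, ux = ux, uy = uy, uz = uz)
    worse <- 0L
    for (it in seq_len(p$iterations)) {
      diff <- mw - f
      denom <- g2 + diff^2
      ok <- denom > 1e-9
      fac <- ifelse(ok, -diff / denom, 0)
      ux <- smooth_volume(ux + fac * gr$x, p$sigma_voxels)
      uy <- smooth_volume(uy + fac * gr$y, p$sigma_voxels)
      uz <- smooth_volume(uz + fac * gr$z, p$sigma_voxels)
      mw <- warp()
      ssd_new <- sum((mw - f)^2)
      if (ssd_new < best$ssd)
        best <- list(ssd = ssd_new, ux = ux, uy = uy, uz = uz)
      # divergence guard: consecutive step-to-step SSD increases
      if (ssd_new > ssd + 1e-12) {
        worse <- worse + 1L
        if (worse >= p$diverge_limit) {
          warn(sprintf(
            "optical-flow iteration diverging at level %d (iteration %d); stopping",
            L, it))
          break
        }
      } else {
        worse <- 0L
      }
      if (abs(ssd - ssd_new) / max(ssd, 1e-12) < p$tol) break
      ssd <- ssd_new
    }
    u <- list(ux = best$ux, uy = best$uy, uz = best$uz)
  }

  sp <- grid$spacing_mm
  out <- deformation_field(grid, u$ux * sp[1], u$uy * sp[2], u$uz * sp[3])
  mw_final <- array(
    cpp_warp_field(as.numeric(moving), grid$dim, as.numeric(u$ux),
                   as.numeric(u$uy), as.numeric(u$uz), min(moving)),
    dim = grid$dim)
  attr(out, "ssd_initial") <- ssd0_full
  attr(out, "ssd_final") <- min(sum((mw_final - fixed)^2), ssd0_full)
  out
}

#' Propagate atlas structures through registration transforms
#'
#' Resamples each binary atlas mask through the composed transform
#' (deformable displacement, then rigid) with trilinear interpolation and
#' binarises at 0.5.  Identity transforms return the masks unchanged.
#'
#' @param atlas_structures A [structure_set()] in atlas space.
#' @param rigid A [rigid_transform()] (fixed -> atlas, pull convention).
#' @param field A [deformation_field()] on the fixed grid, or `NULL` for
#'   rigid-only propagation.
#' @param grid Fixed-grid [voxel_grid()]; defaults to the field's grid.
#' @return A [structure_set()] on the fixed grid.
#' @export
propagate_labels <- function(atlas_structures, rigid, field = NULL,
                             grid = NULL) {
  stopifnot(inherits(atlas_structures, "structure_set"))
  if (is.null(grid))
    grid <- if (!is.null(field)) field$grid else atlas_structures$grid
  if (is.null(field)) field <- zero_field(grid)
  stop_if_grid_mismatch(grid, field$grid)
  wa <- rigid_world_affine(rigid)
  ai <- affine_world_to_index(grid, wa$A, wa$t)
  sp <- grid$spacing_mm
  ux <- field$ux / sp[1]; uy <- field$uy / sp[2]; uz <- field$uz / sp[3]
  masks <- lapply(atlas_structures$masks, function(m) {
    v <- cpp_warp_affine_field(as.numeric(m), grid$dim, ai$A, ai$t,
                               as.numeric(ux), as.numeric(uy),
                               as.numeric(uz), 0)
    array(v, dim = grid$dim) >= 0.5
  })
  structure_set(grid, masks)
}

#' Label-fusion policy
#'
#' @param method `"majority"` (vote fraction 0.5) or `"threshold"` (use
#'   `vote_fraction` as given).
#' @param vote_fraction Fraction of candidates that must contain a voxel
#'   for it to enter the consensus, in `(0, 1]`.
#' @param atlas_preselect_k Optional count of atlases retained after
#'   ranking by post-rigid similarity; `NULL` fuses all (the default, as
#'   when whole atlas groups are fused).
#' @return An object of class `fusion_policy`.
#' @export
fusion_policy <- function(method = c("majority", "threshold"),
                          vote_fraction = 0.5, atlas_preselect_k = NULL) {
  method <- match.arg(method)
  if (method == "majority") vote_fraction <- 0.5
  if (vote_fraction <= 0 || vote_fraction > 1)
    abort("`vote_fraction` must lie in (0, 1]")
  structure(
    list(method = method, vote_fraction = vote_fraction,
         atlas_preselect_k = atlas_preselect_k),
    class = "fusion_policy"
  )
}

#' Fuse candidate segmentations into a consensus
#'
#' Per structure and per voxel, the consensus contains the voxel iff the
#' fraction of candidates containing it is at least the vote fraction.
#' With a single candidate the output equals the input; with
#' `vote_fraction = 1` the output is the voxelwise intersection.
#'
#' @param candidates Non-empty list of [structure_set()]s on one grid.
#' @param policy A [fusion_policy()].
#' @return A consensus [structure_set()].
#' @export
fuse <- function(candidates, policy = fusion_policy()) {
  if (length(candidates) == 0) abort("empty candidate list")
  stopifnot(all(vapply(candidates, inherits, logical(1), "structure_set")))
  grid <- candidates[[1]]$grid
  for (cand in candidates) stop_if_grid_mismatch(grid, cand$grid)
  common <- Reduce(intersect, lapply(candidates, function(s) names(s$masks)))
  n <- length(candidates)
  masks <- lapply(common, function(nm) {
    counts <- Reduce(`+`, lapply(candidates,
                                 function(s) s$masks[[nm]] + 0L))
    counts / n >= policy$vote_fraction - 1e-9
  })
  names(masks) <- common
  structure_set(grid, masks)
}

#' Multi-atlas auto-segmentation of a test case
#'
#' The full pipeline on one test case: for each atlas, rigid registration
#' of the atlas intensity to the test intensity, deformable registration
#' of the rigidly aligned atlas, propagation of the atlas structures
#' through the composed transform, and vote fusion of the propagated
#' candidates.  Optionally only the `atlas_preselect_k` atlases most
#' similar (by post-rigid normalised cross-correlation) are fused.
#'
#' The test case must not be a member of its own atlas group; this
#' leakage is an error (bypass only for sanity checks via
#' `allow_self`).
#'
#' @param test A `case_record`.
#' @param atlas_group Non-empty list of `case_record`s.
#' @param policy A [fusion_policy()].
#' @param params List with optional `rigid` and `deformable` control
#'   lists passed to [rigid_register()] and [deformable_register()].
#' @param allow_self Set `TRUE` to bypass the leakage check.
#' @return A [structure_set()] on the test grid with attribute
#'   `atlas_ids`.
#' @export
auto_segment <- function(test, atlas_group, policy = fusion_policy(),
                         params = list(), allow_self = FALSE) {
  if (length(atlas_group) == 0) abort("empty atlas group")
  ids <- vapply(atlas_group, function(a) a$case_id, character(1))
  if (!allow_self && test$case_id %in% ids)
    abort(paste0("leakage: test case '", test$case_id,
                 "' appears in its own atlas group"))
  grid <- test$grid
  cands <- vector("list", length(atlas_group))
  sims <- numeric(length(atlas_group))
  for (i in seq_along(atlas_group)) {
    atlas <- atlas_group[[i]]
    stop_if_grid_mismatch(grid, atlas$grid)
    tr <- rigid_register(test$intensity, atlas$intensity, grid,
                         params = params$rigid %||% list())
    aligned <- apply_rigid(atlas$intensity, grid, tr)
    sims[i] <- attr(tr, "ncc")
    fld <- deformable_register(test$intensity, aligned, grid,
                               params = params$deformable %||% list())
    cands[[i]] <- propagate_labels(atlas$structures, tr, fld, grid)
  }
  k <- policy$atlas_preselect_k
  if (!is.null(k) && k < length(cands)) {
    keep <- order(sims, decreasing = TRUE)[seq_len(k)]
    cands <- cands[keep]
    ids <- ids[keep]
  }
  out <- fuse(cands, policy)
  attr(out, "atlas_ids") <- ids
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
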