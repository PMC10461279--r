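#' Default phantom grid
#'
#' 96 x 96 x 96 voxels at 2.5 mm isotropic spacing: small enough for
#' minutes-scale registration on one CPU, fine enough that 0.1 cm
#' reporting precision is resolvable.  The origin places x = 0 at the
#' medial edge, y = 0 near the chest wall and z = 0 mid-thorax.
#'
#' @return A [voxel_grid()].
#' @export
default_grid <- function() {
  voxel_grid(c(96, 96, 96), spacing_mm = c(2.5, 2.5, 2.5),
             origin_cm = c(0, -12, -16))
}

# evaluate code under a seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a per-case seed from a master seed
#'
#' A stated counter scheme (multiplicative congruential step modulo
#' 2^31 - 1) so that cohorts can be extended case-by-case without
#' reshuffling earlier cases.
#'
#' @param master Integer master seed.
#' @param index Positive case counter.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  m <- 2147483647
  s <- (abs(as.numeric(master)) %% m) + 1
  v <- (s * 48271 + as.numeric(index) * 16807) %% m
  as.integer(if (v == 0) 1 else v)
}

ellipsoid_mask <- function(w, centre, semi) {
  ((w$x - centre[1]) / semi[1])^2 +
    ((w$y - centre[2]) / semi[2])^2 +
    ((w$z - centre[3]) / semi[3])^2 <= 1
}

# tube of given radius around a polyline (matrix of xyz rows)
tube_mask <- function(w, pts, radius) {
  out <- array(FALSE, dim = dim(w$x))
  for (s in seq_len(nrow(pts) - 1)) {
    p0 <- pts[s, ]; p1 <- pts[s + 1, ]
    d <- p1 - p0
    len2 <- sum(d^2)
    t <- ((w$x - p0[1]) * d[1] + (w$y - p0[2]) * d[2] +
            (w$z - p0[3]) * d[3]) / len2
    t[t < 0] <- 0
    t[t > 1] <- 1
    dist2 <- (w$x - (p0[1] + t * d[1]))^2 +
      (w$y - (p0[2] + t * d[2]))^2 +
      (w$z - (p0[3] + t * d[3]))^2
    out <- out | (dist2 <= radius^2)
  }
  out
}

#' Generate one synthetic thorax case
#'
#' Builds a parametric thorax phantom: a chest-wall shell whose lateral
#' width scales with the chest-wall separation, a half-ellipsoid breast
#' CTV, axillary nodal levels 1-4 as a contiguous ellipsoid chain running
#' from superior-medial (level 4) to inferior-lateral (level 1),
#' interpectoral and internal mammary nodes, a thin-tube brachial plexus,
#' a spherical humeral head, an ellipsoidal heart and a lung blob.  The
#' breast-board incline is applied as a rotation of the whole anatomy
#' about the x (medial-lateral) axis.  Structure positions and sizes
#' receive small seeded jitter so no two cases are identical; identical
#' `(parameters, seed)` reproduce the case bit for bit.
#'
#' @param case_id Case identifier.
#' @param incline_deg Breast-board incline, 15 or 20 (degrees).
#' @param separation_cm Chest-wall separation (distance between medial and
#'   lateral skin markers), in cm.
#' @param separation_class `"small"` or `"large"`; recorded metadata,
#'   normally assigned by [make_cohort()] from its separation cut.
#' @param role `"atlas"` or `"test"`.
#' @param grid A [voxel_grid()].
#' @param seed Integer seed for the case's jitter and intensity texture.
#' @param jitter_sd_cm Standard deviation (cm) of the per-structure
#'   placement jitter.
#'
#' @return A `case_record`: list with `case_id`, `intensity` (CT-proxy
#'   array), `body` (logical body mask), `structures`
#'   ([structure_set()]), `grid`, `incline_deg`, `separation_cm`,
#'   `separation_class`, `role` and `seed`.
#' @export
#' @examples
#' case <- make_phantom(grid = voxel_grid(c(48, 48, 48), rep(5, 3),
#'                                        c(0, -12, -16)), seed = 7)
#' structure_volumes(case$structures)
make_phantom <- function(case_id = "case001", incline_deg = 15,
                         separation_cm = 20, separation_class = "large",
                         role = "atlas", grid = default_grid(), seed = 1L,
                         jitter_sd_cm = 0.25) {
  if (!incline_deg %in% c(15, 20))
    abort("unsupported incline: must be 15 or 20 degrees")
  if (!separation_class %in% c("small", "large"))
    abort("`separation_class` must be 'small' or 'large'")
  ext <- grid_extent_cm(grid)
  if (ext[1] < separation_cm + 1.2 || ext[2] < 18 || ext[3] < 18)
    abort("grid too small to contain anatomy")

  with_local_seed(seed, {
    jit <- function(n = 3) rnorm(n, 0, jitter_sd_cm)
    szf <- function() exp(rnorm(1, 0, 0.04))

    w <- grid_world(grid)
    ctr <- grid_center_cm(grid)

    # anatomy-space coordinates: inverse-rotate the world about the x axis
    th <- -incline_deg * pi / 180
    dy <- w$y - ctr[2]; dz <- w$z - ctr[3]
    wr <- list(
      x = w$x,
      y = ctr[2] + cos(th) * dy - sin(th) * dz,
      z = ctr[3] + sin(th) * dy + cos(th) * dz
    )

    s <- separation_cm
    u <- s / 20                     # lateral scale factor
    cx <- 0.6 + s / 2               # chest mid-line (lateral centre)

    # chest-wall shell: elliptic cylinder spanning z, lateral semi-axis s/2
    ebody <- ((wr$x - cx) / (s / 2))^2 + ((wr$y + 2) / 8.5)^2
    body <- ebody <= 1

    masks <- list()
    masks$Breast <- ellipsoid_mask(
      wr, c(cx, 2.3, -1) + jit(), c(0.42 * s, 3.2, 7.6) * szf()
    ) & (wr$y > -0.8)
    masks$Heart <- ellipsoid_mask(
      wr, c(cx - 0.18 * s, 0.3, 3.5) + jit(), c(3.9, 3.4, 4.0) * szf()
    )
    masks$Lung <- ellipsoid_mask(
      wr, c(cx, -3.6, -4) + jit(), c(0.37 * s, 4.4, 9.0) * szf()
    )
    # nodal chain, level 4 superior-medial -> level 1 inferior-lateral
    masks$Level4 <- ellipsoid_mask(
      wr, c(3.6 * u, 2.2, -11.9) + jit(), c(2.4 * u, 2.0, 1.3) * szf()
    )
    masks$Level3 <- ellipsoid_mask(
      wr, c(6.0 * u, 2.1, -11.1) + jit(), c(2.8 * u, 2.2, 1.7) * szf()
    )
    masks$Level2 <- ellipsoid_mask(
      wr, c(8.5 * u, 1.4, -9.8) + jit(), c(2.1 * u, 2.3, 3.0) * szf()
    )
    masks$Level1 <- ellipsoid_mask(
      wr, c(11.7 * u, -0.5, -7.4) + jit(), c(2.6 * u, 2.8, 3.6) * szf()
    )
    masks$Interpectoral <- ellipsoid_mask(
      wr, c(8.5 * u, 3.6, -9.5) + jit(), c(1.2 * u, 1.0, 1.5) * szf()
    )
    masks$IMN <- ellipsoid_mask(
      wr, c(3.0 * u, 1.8, -4) + jit(), c(0.9, 0.9, 4.0) * szf()
    )
    bp_jit <- jit()
    masks$BrachialPlexus <- tube_mask(
      wr,
      rbind(c(2.5 * u, 0.5, -14.3), c(8 * u, 1.6, -13.0),
            c(13 * u, 0.5, -11.5)) +
        matrix(bp_jit, 3, 3, byrow = TRUE),
      radius = 0.5
    )
    masks$HumeralHead <- ellipsoid_mask(
      wr, c(15.3 * u, 0.4, -13.8) + jit(), rep(2.1 * szf(), 3)
    )

    # anatomical containment: structures live inside the body shell
    masks <- lapply(masks, function(m) m & body)
    empty <- names(masks)[!vapply(masks, any, logical(1))]
    if (length(empty))
      abort(paste0("grid too small to contain anatomy: empty structure(s) ",
                   paste(empty, collapse = ", ")))

    ss <- combine_nodes(structure_set(grid, masks))

    # CT-proxy intensities: tissue classes plus rib-like bands and smooth
    # seeded texture so registration has gradients to work with
    intensity <- array(-1000, dim = grid$dim)
    intensity[body] <- 20
    intensity[ss$masks$Lung] <- -750
    intensity[ss$masks$Breast] <- -80
    intensity[ss$masks$Heart] <- 45
    for (nm in c("Level1", "Level2", "Level3", "Level4", "Interpectoral",
                 "IMN"))
      intensity[ss$masks[[nm]]] <- 60
    intensity[ss$masks$BrachialPlexus] <- 80
    ribs <- body & (ebody > 0.78) & (sin(2 * pi * wr$z / 2.5) > 0.35)
    intensity[ribs] <- 350
    intensity[ss$masks$HumeralHead] <- 400
    tex <- smooth_volume(array(rnorm(prod(grid$dim)), dim = grid$dim), 2)
    intensity <- intensity + body * (12 / max(sd(tex), 1e-9)) * tex

    structure(
      list(case_id = case_id, intensity = intensity, body = body,
           structures = ss, grid = grid, incline_deg = incline_deg,
           separation_cm = separation_cm,
           separation_class = separation_class, role = role, seed = seed),
      class = "case_record"
    )
  })
}

#' @export
print.case_record <- function(x, ...) {
  cat(sprintf(
    "<case_record> %s: incline %g deg, separation %.1f cm (%s), role %s\n",
    x$case_id, x$incline_deg, x$separation_cm, x$separation_class, x$role))
  invisible(x)
}

#' Generate a seeded cohort of synthetic cases
#'
#' Emulates a library of radiotherapy planning CTs: `n` phantom cases with
#' a requested mix of breast-board inclines (15/20 degrees) and chest-wall
#' separation classes.  The realised counts match the requested
#' proportions to within integer rounding; separations are drawn uniformly
#' on either side of the separation cut.  A subset of cases is designated
#' as test cases, the rest as template atlases.
#'
#' @param n Number of cases (>= 1).
#' @param p_incline15 Proportion of cases scanned at 15 degrees.
#' @param p_large Proportion of cases with large chest-wall separation.
#' @param n_test Number of cases given the test role.
#' @param seed Master seed; per-case seeds are derived with
#'   [derive_seed()].
#' @param grid A [voxel_grid()] shared by all cases.
#' @param separation_cut_cm Separation (cm) separating the small and large
#'   classes.
#' @param separation_range_cm Length-2 range (cm) separations are drawn
#'   from.
#' @param jitter_sd_cm Per-structure placement jitter passed to
#'   [make_phantom()].
#'
#' @return A `case_cohort`: list with `cases` (named list of
#'   `case_record`s), `meta` (tibble of per-case metadata), `seed` and
#'   `separation_cut_cm`.
#' @export
make_cohort <- function(n, p_incline15 = 0.5, p_large = 0.5,
                        n_test = max(1L, round(0.1 * n)), seed = 1L,
                        grid = default_grid(), separation_cut_cm = 19,
                        separation_range_cm = c(16, 22),
                        jitter_sd_cm = 0.25) {
  if (n < 1) abort("`n` must be >= 1")
  if (p_incline15 < 0 || p_incline15 > 1 || p_large < 0 || p_large > 1)
    abort("infeasible mix: proportions must lie in [0, 1]")
  if (n_test >= n)
    abort("infeasible mix: `n_test` must leave at least one atlas case")
  if (separation_cut_cm <= separation_range_cm[1] ||
      separation_cut_cm >= separation_range_cm[2])
    abort("infeasible mix: separation cut outside the separation range")

  n15 <- round(n * p_incline15)
  n_large <- round(n * p_large)

  with_local_seed(derive_seed(seed, 0L), {
    incline <- sample(c(rep(15, n15), rep(20, n - n15)))
    cls <- sample(c(rep("large", n_large), rep("small", n - n_large)))
    sep <- ifelse(
      cls == "large",
      runif(n, separation_cut_cm + 0.1, separation_range_cm[2]),
      runif(n, separation_range_cm[1], separation_cut_cm - 0.1)
    )
    role <- rep("atlas", n)
    role[sample.int(n, n_test)] <- "test"
    list(incline = incline, cls = cls, sep = sep, role = role)
  }) -> mix

  ids <- sprintf("case%03d", seq_len(n))
  cases <- lapply(seq_len(n), function(i) {
    make_phantom(
      case_id = ids[i], incline_deg = mix$incline[i],
      separation_cm = mix$sep[i], separation_class = mix$cls[i],
      role = mix$role[i], grid = grid, seed = derive_seed(seed, i),
      jitter_sd_cm = jitter_sd_cm
    )
  })
  names(cases) <- ids

  meta <- tibble(
    case_id = ids,
    incline_deg = mix$incline,
    separation_cm = mix$sep,
    separation_class = mix$cls,
    role = mix$role,
    seed = vapply(seq_len(n), function(i) derive_seed(seed, i), integer(1))
  )
  structure(
    list(cases = cases, meta = meta, seed = seed,
         separation_cut_cm = separation_cut_cm),
    class = "case_cohort"
  )
}

#' @export
print.case_cohort <- function(x, ...) {
  cat(sprintf("<case_cohort> %d cases (%d test), master seed %d\n",
              nrow(x$meta), sum(x$meta$role == "test"), x$seed))
  invisible(x)
}

#' @rdname make_cohort
#' @param x A `case_cohort`.
#' @param ... Unused.
#' @export
tidy.case_cohort <- function(x, ...) x$meta
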