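test_that("jaccard matches hand-counted configurations", {
  a <- array(FALSE, c(4, 4, 4)); a[1:2, 1:2, 1:2] <- TRUE
  expect_equal(jaccard(a, a)$jaccard, 1)
  b <- array(FALSE, c(4, 4, 4)); b[3:4, 3:4, 3:4] <- TRUE
  expect_equal(jaccard(a, b)$jaccard, 0)
  # two 2x2x2 cubes sharing a 1x2x2 slab: 4 / 12
  c2 <- array(FALSE, c(4, 4, 4)); c2[2:3, 1:2, 1:2] <- TRUE
  expect_equal(jaccard(a, c2)$jaccard, 4 / 12)
  expect_equal(jaccard(c2, a)$jaccard, jaccard(a, c2)$jaccard)
})

test_that("empty-mask conventions are as documented", {
  e <- array(FALSE, c(3, 3, 3))
  m <- e; m[1, 1, 1] <- TRUE
  expect_equal(jaccard(e, e)$jaccard, 1)
  expect_equal(jaccard(e, m)$jaccard, 0)
  expect_error(jaccard(e, array(FALSE, c(4, 4, 4))), "different grids")
})

test_that("jaccard agrees with a brute-force voxel-count oracle", {
  withr::with_seed(71, {
    for (rep in 1:25) {
      a <- random_mask(); b <- random_mask()
      expect_equal(jaccard(a, b)$jaccard, brute_force_jaccard(a, b),
                   tolerance = 1e-12)
    }
  })
})

test_that("Dice and Jaccard interconvert and round-trip", {
  expect_equal(dice_to_jaccard(0.8), 2 / 3, tolerance = 1e-12)
  expect_equal(round(dice_to_jaccard(0.8), 1), 0.7)
  expect_equal(dice_to_jaccard(1), 1)
  expect_equal(dice_to_jaccard(0), 0)
  grid_vals <- seq(0, 1, by = 0.01)
  expect_equal(jaccard_to_dice(dice_to_jaccard(grid_vals)), grid_vals,
               tolerance = 1e-14)
  expect_equal(dice_to_jaccard(jaccard_to_dice(grid_vals)), grid_vals,
               tolerance = 1e-14)
  expect_error(dice_to_jaccard(1.2), "\\[0, 1\\]")
})

test_that("overlap score keeps dice and jaccard consistent", {
  ss <- fixture_case()$structures
  ov <- jaccard(ss$masks$Heart, ss$masks$Lung)
  expect_equal(ov$jaccard, ov$dice / (2 - ov$dice), tolerance = 1e-12)
  expect_lte(ov$jaccard, ov$dice)
})

test_that("centroid is the mean occupied voxel-centre coordinate", {
  g <- voxel_grid(c(8, 8, 8), rep(10, 3), c(0, 0, 0))
  m <- array(FALSE, c(8, 8, 8)); m[3, 4, 5] <- TRUE
  expect_equal(mask_centroid(m, g), c(2, 3, 4))
  m2 <- m; m2[4, 4, 5] <- TRUE   # voxels at x = 2 and x = 3 cm
  expect_equal(mask_centroid(m2, g)[1], 2.5)
  s <- sphere_mask(g, c(3.5, 3.5, 3.5), 2)
  expect_equal(mask_centroid(s, g), rep(3.5, 3), tolerance = 0.5)
  expect_error(mask_centroid(array(FALSE, c(8, 8, 8)), g), "empty")
})

test_that("directional extents recover constructed boxes", {
  g <- voxel_grid(c(10, 10, 10), rep(5, 3), c(0, -2, 1))
  m <- array(FALSE, c(10, 10, 10)); m[2, 3, 4] <- TRUE
  e <- directional_extents(m, g)
  expect_equal(unname(e[c("min_x", "max_x")]), c(0.5, 0.5))
  expect_equal(unname(e[c("min_y", "max_y")]), c(-1, -1))
  box <- box_mask(g, c(0.5, -1.5, 1.5), c(2.0, 0.5, 3.0))
  eb <- directional_extents(box, g)
  expect_equal(unname(eb), c(0.5, 2.0, -1.5, 0.5, 1.5, 3.0))
  expect_error(directional_extents(array(FALSE, dim = g$dim), g), "empty")
})

test_that("extents are translation-equivariant", {
  g <- fixture_case()$grid
  m <- fixture_case()$structures$masks$Heart
  shifted <- perturb(structure_set(g, list(Heart = m)),
                     perturbation_spec(translation_cm = c(0.6, 0, 0)))
  e0 <- directional_extents(m, g)
  e1 <- directional_extents(shifted$masks$Heart, g)
  expect_equal(e1[["min_x"]], e0[["min_x"]] + 0.6)
  expect_equal(e1[["max_x"]], e0[["max_x"]] + 0.6)
  expect_equal(e1[["min_y"]], e0[["min_y"]])
})

test_that("centroid distances are signed extent-to-centre offsets", {
  g <- voxel_grid(c(17, 17, 17), rep(5, 3), c(-4, -4, -4))
  box <- box_mask(g, c(-2, -1, -1), c(2, 1, 1))  # centred at origin
  e <- directional_extents(box, g)
  d <- centroid_distances(e, mask_centroid(box, g), "own")
  expect_equal(d[["min_x"]], -2, tolerance = 1e-9)
  expect_equal(d[["max_x"]], 2, tolerance = 1e-9)
  d2 <- centroid_distances(e, c(e[["min_x"]], 0, 0), "reference")
  expect_equal(d2[["min_x"]], 0)
  s <- sphere_mask(g, c(0, 0, 0), 1.6)
  ds <- centroid_distances(directional_extents(s, g),
                           mask_centroid(s, g), "own")
  expect_true(all(abs(abs(unname(ds)) - 1.6) <= 0.25 + 1e-9))
})

test_that("cdv is zero on identity and recovers translations", {
  g <- fixture_case()$grid
  m <- fixture_case()$structures$masks$Level1
  c0 <- mask_centroid(m, g)
  d0 <- centroid_distances(directional_extents(m, g), c0, "own")
  z <- cdv(d0, d0, structure = "Level1")
  expect_equal(unname(z$raw), rep(0, 6))
  expect_equal(unname(z$variants), rep(0, 6))

  t_cm <- c(1.2, -0.6, 0.6)    # whole voxels at 6 mm
  sh <- perturb(structure_set(g, list(Level1 = m)),
                perturbation_spec(translation_cm = t_cm))$masks$Level1
  # reference-centre mode: each min/max variant equals -t on its axis
  dr <- centroid_distances(directional_extents(m, g), c0, "reference")
  dt <- centroid_distances(directional_extents(sh, g), c0, "reference")
  v <- cdv(dr, dt)$raw
  expect_equal(unname(v), -rep(t_cm, each = 2), tolerance = 1e-9)
  # own-centre mode: a pure shift cancels
  dto <- centroid_distances(directional_extents(sh, g),
                            mask_centroid(sh, g), "own")
  do_ <- centroid_distances(directional_extents(m, g), c0, "own")
  expect_true(all(abs(cdv(do_, dto)$raw) < 1e-9))
  expect_error(cdv(dr, dto), "centre_mode mismatch")
})

test_that("rounded variants stay within half a reporting unit of raw", {
  withr::with_seed(5, {
    for (i in 1:20) {
      raw <- runif(6, -3, 3)
      dn <- c("min_x", "max_x", "min_y", "max_y", "min_z", "max_z")
      r <- centroid_distances(setNames(raw, dn), c(0, 0, 0), "reference")
      z <- centroid_distances(setNames(rep(0, 6), dn), c(0, 0, 0),
                              "reference")
      rec <- cdv(r, z)
      expect_true(all(abs(rec$variants - rec$raw) <= 0.05 + 1e-12))
    }
  })
})

test_that("variant classification is direction-aware", {
  g <- voxel_grid(c(21, 21, 21), rep(5, 3), c(-5, -5, -5))
  outer_box <- box_mask(g, c(-4, -4, -4), c(4, 4, 4))
  inner_box <- box_mask(g, c(-2.5, -2.5, -2.5), c(2.5, 2.5, 2.5))
  cen <- c(0, 0, 0)
  d_out <- centroid_distances(directional_extents(outer_box, g), cen,
                              "reference")
  d_in <- centroid_distances(directional_extents(inner_box, g), cen,
                             "reference")
  # AS strictly contained in the reference: under-contoured on every side
  expect_equal(unname(classify_variant(cdv(d_out, d_in))), rep("under", 6))
  # AS strictly containing the reference: over-contoured on every side
  expect_equal(unname(classify_variant(cdv(d_in, d_out))), rep("over", 6))
  expect_equal(unname(classify_variant(cdv(d_out, d_out))), rep("none", 6))
})

test_that("evaluate_pairs reports identity and volumes", {
  case <- fixture_case()
  tab <- evaluate_pairs(case$structures, case$structures)
  expect_equal(nrow(tab), length(case$structures$masks))
  expect_true(all(tab$jaccard == 1))
  expect_true(all(abs(as.matrix(tab[, var_cols()])) < 1e-12))
  vol <- structure_volumes(case$structures)
  expect_equal(tab$volume_cm3, vol$volume_cm3[match(tab$structure,
                                                    vol$structure)])
})
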