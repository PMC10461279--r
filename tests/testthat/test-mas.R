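test_that("self-registration returns the identity transform", {
  case <- fixture_case_mid()
  tr <- rigid_register(case$intensity, case$intensity, case$grid)
  expect_true(all(abs(tr$translation_cm) < 0.25))   # half a voxel
  expect_true(all(abs(tr$rotation_deg) < 0.5))
})

test_that("rigid registration recovers known shifts and rotations", {
  case <- fixture_case_mid()
  g <- case$grid
  ctr <- g$origin_cm + (g$dim - 1) * g$spacing_mm / 20
  # content shifted +1 cm in x (pull by -1 produces the shifted volume)
  mv <- apply_rigid(case$intensity, g,
                    rigid_transform(c(0, 0, 0), c(-1, 0, 0), ctr))
  tr <- rigid_register(case$intensity, mv, g)
  expect_lt(abs(tr$translation_cm[1] - 1), 0.5)     # within one voxel
  expect_lt(max(abs(tr$translation_cm[2:3])), 0.5)
  # content rotated 5 degrees about x
  mv2 <- apply_rigid(case$intensity, g,
                     rigid_transform(c(-5, 0, 0), c(0, 0, 0), ctr))
  tr2 <- rigid_register(case$intensity, mv2, g)
  expect_lt(abs(tr2$rotation_deg[1] - 5), 1)
})

test_that("constant volumes make the similarity undefined", {
  flat <- array(1, c(32, 32, 32))
  g <- voxel_grid(c(32, 32, 32), rep(5, 3))
  expect_error(rigid_register(flat, flat, g), "undefined")
})

test_that("deformable registration is a fixed point on identical images", {
  case <- fixture_case()
  fld <- deformable_register(case$intensity, case$intensity, case$grid,
                             params = list(iterations = 10))
  mag_vox <- sqrt(fld$ux^2 + fld$uy^2 + fld$uz^2) / 6
  expect_lt(max(mag_vox), 0.1)
})

test_that("deformable registration recovers a known blob displacement", {
  g <- mid_grid()
  w <- grid_world(g)
  blob <- function(cx) 100 * exp(-(((w$x - cx) / 3)^2 +
                                     ((w$y + 2) / 3)^2 +
                                     ((w$z + 4) / 3)^2))
  f <- blob(12)
  m <- blob(11)    # displaced 2 voxels (1 cm) in x
  fld <- suppressWarnings(
    deformable_register(f, m, g, params = list(iterations = 100)))
  core <- blob(12) > 30
  mean_ux_vox <- mean(fld$ux[core]) / 5
  expect_lt(abs(mean_ux_vox - (-2)), 0.5)
  expect_lte(attr(fld, "ssd_final"), attr(fld, "ssd_initial"))
})

test_that("deformable registration never worsens the SSD it reports", {
  a <- fixture_case()
  b <- make_phantom(grid = small_grid(), seed = 77, separation_cm = 21)
  fld <- suppressWarnings(
    deformable_register(a$intensity, b$intensity, small_grid(),
                        params = list(iterations = 20)))
  expect_lte(attr(fld, "ssd_final"), attr(fld, "ssd_initial"))
  expect_true(all(is.finite(fld$ux)))
})

test_that("label propagation under identity transforms is the identity", {
  ss <- fixture_case()$structures
  out <- propagate_labels(ss, rigid_transform(), NULL, ss$grid)
  expect_identical(out$masks, ss$masks)
})

test_that("label propagation shifts masks by whole voxels exactly", {
  case <- fixture_case()
  g <- case$grid
  ctr <- g$origin_cm + (g$dim - 1) * g$spacing_mm / 20
  out <- propagate_labels(case$structures,
                          rigid_transform(c(0, 0, 0), c(1.2, 0, 0), ctr),
                          NULL, g)
  m <- case$structures$masks$Heart
  d <- dim(m)
  shifted <- array(FALSE, d)
  shifted[1:(d[1] - 2), , ] <- m[3:d[1], , ]
  expect_identical(out$masks$Heart, shifted)
})

test_that("fractional shifts keep propagated volumes within 15%", {
  g <- voxel_grid(c(24, 24, 24), rep(5, 3), c(0, 0, 0))
  s <- sphere_mask(g, c(5.75, 5.75, 5.75), 2.6)
  ss <- structure_set(g, list(Heart = s))
  ctr <- g$origin_cm + (g$dim - 1) * g$spacing_mm / 20
  out <- propagate_labels(ss, rigid_transform(c(0, 0, 0), c(0.25, 0, 0),
                                              ctr), NULL, g)
  expect_lt(abs(sum(out$masks$Heart) - sum(s)) / sum(s), 0.15)
})

test_that("fusion implements the vote-fraction rule on all patterns", {
  g <- voxel_grid(c(2, 2, 2), rep(5, 3))
  mk <- function(on) {
    m <- array(FALSE, c(2, 2, 2)); if (on) m[1, 1, 1] <- TRUE
    structure_set(g, list(Heart = m))
  }
  for (pattern in 0:7) {
    bits <- as.logical(intToBits(pattern)[1:3])
    cands <- lapply(bits, mk)
    got <- fuse(cands, fusion_policy(vote_fraction = 0.5))
    expect_equal(got$masks$Heart[1, 1, 1], sum(bits) / 3 >= 0.5,
                 info = paste("pattern", pattern))
    inter <- fuse(cands, fusion_policy("threshold", vote_fraction = 1))
    expect_equal(inter$masks$Heart[1, 1, 1], all(bits))
  }
})

test_that("fusion is permutation-invariant and handles edge cases", {
  ss <- fixture_case()$structures
  p1 <- perturb(ss, perturbation_spec(translation_cm = c(0.6, 0, 0)))
  p2 <- perturb(ss, perturbation_spec(translation_cm = c(0, 0.6, 0)))
  a <- fuse(list(ss, p1, p2))
  b <- fuse(list(p2, ss, p1))
  expect_identical(a$masks, b$masks)
  single <- fuse(list(ss))
  expect_identical(single$masks, ss$masks)
  three_same <- fuse(list(ss, ss, ss))
  expect_identical(three_same$masks, ss$masks)
  expect_error(fuse(list()), "empty")
  expect_error(fusion_policy("threshold", vote_fraction = 0), "\\(0, 1\\]")
})

test_that("auto-segmentation refuses leaking test cases into the group", {
  case <- fixture_case()
  expect_error(auto_segment(case, list(case)), "leakage")
  other <- make_phantom(case_id = "fix99", grid = small_grid(), seed = 88)
  expect_error(suppressWarnings(
    auto_segment(case, list(other),
                 params = list(rigid = list(maxit = 20),
                               deformable = list(iterations = 5)))), NA)
})

test_that("a self-atlas under a different id recovers the references", {
  case <- fixture_case()
  twin <- case
  twin$case_id <- "twin01"
  as_set <- suppressWarnings(auto_segment(case, list(twin)))
  for (nm in c("Breast", "Heart", "Lung", "Level1"))
    expect_gt(jaccard(case$structures$masks[[nm]],
                      as_set$masks[[nm]])$jaccard, 0.95)
})

test_that("a grossly mismatched atlas is outvoted by two concordant ones", {
  case <- fixture_case()
  near1 <- case; near1$case_id <- "n1"
  near2 <- case; near2$case_id <- "n2"
  # mismatched candidate: heavily displaced copy of the structures
  off <- perturb(case$structures,
                 perturbation_spec(translation_cm = c(3, 2.4, 0)))
  cands <- list(propagate_labels(near1$structures, rigid_transform(),
                                 NULL, case$grid),
                propagate_labels(near2$structures, rigid_transform(),
                                 NULL, case$grid),
                off)
  fz <- fuse(cands, fusion_policy(vote_fraction = 0.5))
  agree <- mean(fz$masks$Breast == case$structures$masks$Breast)
  expect_gte(agree, 0.95)
  expect_equal(fz$masks$Heart, case$structures$masks$Heart)
})

test_that("mean overlap does not degrade as atlas noise decreases", {
  case <- fixture_case()
  jsc_at_noise <- function(sd) {
    pert <- perturbation_spec(boundary_noise_sd_cm = sd, seed = 13)
    as_set <- perturb(case$structures, pert)
    mean(evaluate_pairs(case$structures, as_set)$jaccard)
  }
  j <- vapply(c(0.8, 0.3, 0), jsc_at_noise, numeric(1))
  expect_true(all(diff(j) >= -1e-9))
  expect_equal(j[3], 1)
})
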