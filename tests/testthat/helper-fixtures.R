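# Shared fixtures are generated in code and memoised per test run; grids
# are kept coarse so the whole suite stays fast.

small_grid <- function() voxel_grid(c(40, 40, 40), rep(6, 3), c(0, -12, -15))
mid_grid <- function() voxel_grid(c(48, 48, 48), rep(5, 3), c(0, -12, -16))

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

fixture_case <- function() {
  memo("case_small", make_phantom(case_id = "fix01", grid = small_grid(),
                                  seed = 41, separation_cm = 19))
}

fixture_case_mid <- function() {
  memo("case_mid", make_phantom(case_id = "fix02", grid = mid_grid(),
                                seed = 42, separation_cm = 20))
}

# independent overlap oracle: explicit voxel loop, no set arithmetic
brute_force_jaccard <- function(a, b) {
  inter <- 0L
  uni <- 0L
  for (i in seq_len(dim(a)[1]))
    for (j in seq_len(dim(a)[2]))
      for (k in seq_len(dim(a)[3])) {
        ina <- isTRUE(a[i, j, k]); inb <- isTRUE(b[i, j, k])
        if (ina && inb) inter <- inter + 1L
        if (ina || inb) uni <- uni + 1L
      }
  if (uni == 0L) 1 else inter / uni
}

random_mask <- function(d = c(8, 8, 8), p = 0.3) {
  array(runif(prod(d)) < p, dim = d)
}

# brute-force one-way ANOVA from textbook sums of squares
brute_force_anova_f <- function(groups) {
  all_v <- unlist(groups)
  gmean <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gmean)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(all_v) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

box_mask <- function(grid, lo, hi) {
  w <- grid_world(grid)
  w$x >= lo[1] & w$x <= hi[1] & w$y >= lo[2] & w$y <= hi[2] &
    w$z >= lo[3] & w$z <= hi[3]
}

sphere_mask <- function(grid, centre, radius) {
  w <- grid_world(grid)
  (w$x - centre[1])^2 + (w$y - centre[2])^2 + (w$z - centre[3])^2 <=
    radius^2
}

var_cols <- function() paste0("var_", c("min_x", "max_x", "min_y",
                                        "max_y", "min_z", "max_z"))
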