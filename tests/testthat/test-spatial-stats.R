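test_that("distance map is exact for axis-aligned walls and on the mask", {
  sp <- voxel_spacing(150, 150, 300)
  mask <- array(FALSE, c(16, 8, 6))
  mask[1, , ] <- TRUE  # full x = 0 wall
  dm <- capillary_distance_map(mask, sp)
  expect_equal(dm$values[11, 4, 3], 10 * 0.15)  # 10 voxel steps at dx = 150 nm
  expect_true(all(dm$values[mask] == 0))
  expect_error(capillary_distance_map(array(FALSE, c(4, 4, 4)), sp), "empty")
})

test_that("distance map matches the O(N^2) brute-force oracle", {
  sp <- voxel_spacing(150, 150, 300)
  set.seed(31)
  for (rep in 1:3) {
    mask <- array(stats::runif(20^3) < 0.02, c(20, 20, 20))
    if (!any(mask)) mask[7, 3, 11] <- TRUE
    dm <- capillary_distance_map(mask, sp)
    bf <- bf_distance_map(mask, c(0.15, 0.15, 0.3))
    expect_lt(max(abs(dm$values - bf)), 1e-6)
  }
})

test_that("distance map translates with the mask and shrinks under dilation", {
  sp <- voxel_spacing(200, 200, 400)
  mask <- array(FALSE, c(14, 14, 10))
  mask[4:5, 6:7, 4:5] <- TRUE
  dm <- capillary_distance_map(mask, sp)
  shifted <- array(FALSE, c(14, 14, 10))
  shifted[7:8, 6:7, 4:5] <- TRUE
  dm_s <- capillary_distance_map(shifted, sp)
  expect_equal(dm_s$values[4:14, , ], dm$values[1:11, , ])

  dil <- mask
  dil[3:6, 5:8, 3:6] <- TRUE
  dm_d <- capillary_distance_map(dil, sp)
  expect_true(all(dm_d$values <= dm$values + 1e-12))
})

test_that("structure distances report surface and centroid proximity", {
  sp <- voxel_spacing(150, 150, 300)
  mask <- array(FALSE, c(20, 10, 8))
  mask[1, , ] <- TRUE
  dm <- capillary_distance_map(mask, sp)
  st <- array(FALSE, c(20, 10, 8))
  st[2:4, 4:6, 3:5] <- TRUE          # adjacent to the wall
  sd_ <- structure_distance(st, dm)
  expect_equal(sd_$min_um, 0.15)     # one inter-centre step
  expect_gt(sd_$centroid_um, sd_$min_um)
  expect_warning(structure_distance(mask, dm), "overlaps")
  expect_error(structure_distance(array(FALSE, c(20, 10, 8)), dm), "empty")
})

test_that("cylinder-capillary scene distances match the analytic geometry", {
  cfg <- scene_config(dims = c(96, 96, 48), spacing = voxel_spacing(300, 300, 400),
                      n_cells = 8, cell_radius_mean = 2, cell_radius_sd = 0.2,
                      mito_per_cell = c(0, 0),
                      capillary = capillary_spec(c(4, 0, 9.6), c(4, 28.8, 9.6), 2),
                      seed = 33)
  sc <- generate_scene(cfg)
  cap_mask <- array(sc$labels$labels == sc$model$capillary_label,
                    dim = cfg$dims)
  dm <- capillary_distance_map(cap_mask, cfg$spacing)
  vox_diag <- sqrt(sum((unname(unclass(cfg$spacing)) * 1e-3)^2))
  for (i in seq_len(nrow(sc$truth))) {
    fam <- c(sc$truth$cell_label[i], sc$truth$nucleus_label[i])
    m <- array(sc$labels$labels %in% fam, dim = cfg$dims)
    sd_ <- structure_distance(m, dm)
    # analytic: centre-to-axis distance minus capillary radius minus the
    # cell's extent toward the capillary, bounded by its semi-axis range
    lower <- sc$truth$dist_capillary_um[i] - sc$truth$semi_a_um[i] - vox_diag
    upper <- sc$truth$dist_capillary_um[i] - sc$truth$semi_c_um[i] + vox_diag
    expect_gte(sd_$min_um, max(lower, 0))
    expect_lte(sd_$min_um, max(upper, vox_diag))
  }
})

test_that("spearman rho matches the closed form and base R on no-tie data", {
  r <- spearman_test(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(r$rho, 0.8)   # 1 - 6*4/(5*24)
  expect_equal(r$rho, spearman_closed_form(1:5, c(2, 1, 4, 3, 5)))

  set.seed(35)
  for (n in c(6, 8, 20)) {
    x <- rnorm(n); y <- rnorm(n)
    mine <- spearman_test(x, y)
    expect_equal(mine$rho, spearman_closed_form(x, y), tolerance = 1e-12)
    ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = n <= 9))
    expect_equal(mine$rho, unname(ct$estimate), tolerance = 1e-12)
    if (n > 9) {
      # both use the t-approximation above the exact-enumeration range
      expect_equal(mine$p_value, ct$p.value, tolerance = 1e-10)
    }
  }

  y <- -(1:6)
  expect_equal(spearman_test(1:6, y)$rho, -1)
  r1 <- spearman_test(1:7, (1:7)^3)
  expect_equal(r1$rho, 1)
  expect_equal(r1$p_value, 2 / factorial(7))  # both extreme orderings
})

test_that("exact permutation p-values agree with full enumeration semantics", {
  x <- c(3, 1, 4, 1, 5)
  y <- c(2, 7, 1, 8, 2)   # ties in both
  r <- spearman_test(x, y)
  # independent re-enumeration
  perms <- sbfmorph:::all_permutations(5)
  rx <- rank(x); ry <- rank(y)
  rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
  expect_equal(r$p_value, mean(abs(rhos) >= abs(r$rho) - 1e-12))
})

test_that("spearman is symmetric and monotone-transform invariant", {
  set.seed(36)
  x <- rnorm(15); y <- rnorm(15)
  a <- spearman_test(x, y)
  expect_equal(a$rho, spearman_test(y, x)$rho)
  expect_equal(a$p_value, spearman_test(y, x)$p_value)
  b <- spearman_test(exp(x), y)
  expect_equal(a$rho, b$rho)
  expect_equal(spearman_test(x, 2 * y + 5)$rho, a$rho)
  expect_error(spearman_test(rep(1, 5), 1:5), "constant")
  expect_error(spearman_test(1:2, 2:3), "at least 3")
})

test_that("the report joins per-cell data and runs the full correlation panel", {
  cfg <- scene_config(dims = c(128, 128, 48), spacing = voxel_spacing(300, 300, 400),
                      n_cells = 21, cell_radius_mean = 2, cell_radius_sd = 0.25,
                      mito_per_cell = c(5, 8), size_distance_beta = 0.5,
                      interior_only = TRUE,
                      capillary = capillary_spec(c(3, 0, 9.6), c(3, 38.4, 9.6), 2),
                      seed = 37)
  sc <- generate_scene(cfg)
  res <- analyze_scene(sc$labels, sc$segments, ray = ray_params(radius_um = 3))
  expect_equal(nrow(res$cells), 21)
  expect_equal(nrow(res$correlations), 11)   # 6 volumetric + 5 distance
  expect_equal(sum(grepl("^distance", res$correlations$var_x)), 5)
  # size gradient: cell volume anticorrelates with capillary distance
  rho_cd <- res$correlations$rho[
    res$correlations$var_x == "distance_to_capillary" &
      res$correlations$var_y == "cell"]
  expect_lt(rho_cd, 0)
  # composition invariants hold in the joined table
  expect_equal(res$cells$cytoplasm_volume_um3,
               res$cells$cell_volume_um3 - res$cells$nucleus_volume_um3)
  expect_true(all(res$cells$mito_total_volume_um3 <=
                    res$cells$cytoplasm_volume_um3))
})

test_that("null scenes rarely flag the distance correlation as significant", {
  hits <- sapply(1:10, function(s) {
    cfg <- scene_config(dims = c(96, 96, 48),
                        spacing = voxel_spacing(300, 300, 400),
                        n_cells = 15, cell_radius_mean = 1.8,
                        cell_radius_sd = 0.25, mito_per_cell = c(0, 0),
                        size_distance_beta = 0, interior_only = TRUE,
                        capillary = capillary_spec(c(3, 0, 9.6),
                                                   c(3, 28.8, 9.6), 1.5),
                        seed = 500 + s)
    sc <- generate_scene(cfg)
    vol <- (4 / 3) * pi * sc$truth$semi_a_um * sc$truth$semi_b_um *
      sc$truth$semi_c_um
    spearman_test(vol, sc$truth$dist_capillary_um)$significant
  })
  expect_lte(mean(hits), 0.1)
})
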