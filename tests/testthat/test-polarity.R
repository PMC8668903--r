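axis_obj <- function(centroid, direction, id = 1L) {
  structure(list(label_id = id, centroid = centroid,
                 direction = direction / sqrt(sum(direction^2)),
                 eigenvalues = c(3, 1, 1), ambiguous = FALSE),
            class = "principal_axis")
}

sp_iso <- voxel_spacing(100, 100, 100)

test_that("ray footprint follows the radial falloff exactly", {
  dims <- c(21, 21, 21)
  # axis along x through the centre of voxel row iy=11, iz=11
  ax <- axis_obj(c(1.05, 1.05, 1.05), c(1, 0, 0))
  rp <- ray_params(radius_um = 0.5, threshold = 1)
  fp <- ray_footprint(ax, rp, dims, sp_iso)
  # voxel centres on the axis line get exactly 1
  expect_true(all(fp[, 11, 11] == 1))
  expect_equal(fp[5, 11, 11 + 2], 1 - 0.2 / 0.5)  # d = 2 voxels * 0.1 um
  expect_equal(fp[5, 11 + 2, 11], 1 - 0.2 / 0.5)
  # beyond the radius the footprint is zero (d = 5 voxels = radius)
  expect_true(all(fp[, 11 + 5, 11] == 0))
  expect_true(all(fp[, , 11 + 6] == 0))

  # point reflection through the centroid leaves the footprint unchanged
  expect_equal(fp, fp[dims[1]:1, dims[2]:1, dims[3]:1])
})

test_that("footprints match a brute-force point-line distance over the grid", {
  dims <- c(12, 10, 8)
  sp <- voxel_spacing(150, 150, 300)
  ax <- axis_obj(c(0.9, 0.75, 1.2), c(2, 1, 1))
  rp <- ray_params(radius_um = 1, threshold = 1)
  fp <- ray_footprint(ax, rp, dims, sp)
  cen <- expand.grid(x = (1:12 - 0.5) * 0.15, y = (1:10 - 0.5) * 0.15,
                     z = (1:8 - 0.5) * 0.3)
  a <- ax$direction
  bf <- apply(as.matrix(cen), 1, function(p) {
    r <- p - ax$centroid
    d <- sqrt(max(sum(r^2) - sum(r * a)^2, 0))
    if (d >= 1) 0 else 1 - d / 1
  })
  expect_equal(as.vector(fp), bf, tolerance = 1e-12)
})

test_that("a custom falloff profile is honoured", {
  dims <- c(15, 15, 15)
  ax <- axis_obj(c(0.75, 0.75, 0.75), c(0, 0, 1))
  rp <- ray_params(radius_um = 0.45,
                   falloff = function(d) pmax(1 - (d / 0.45)^2, 0))
  fp <- ray_footprint(ax, rp, dims, sp_iso)
  expect_true(all(fp[8, 8, ] == 1))               # the axis column
  expect_equal(fp[9, 8, 8], 1 - (0.1 / 0.45)^2)   # quadratic profile at 0.1 um
  expect_true(all(fp[13, 8, ] == 0))              # d = 0.5 um >= radius
})

test_that("accumulation is additive, order-invariant and bounded by n cells", {
  dims <- c(16, 16, 16)
  rp <- ray_params(radius_um = 0.4, threshold = 1)
  f1 <- ray_footprint(axis_obj(c(0.8, 0.8, 0.8), c(1, 0, 0)), rp, dims, sp_iso)
  f2 <- ray_footprint(axis_obj(c(0.8, 0.8, 0.8), c(0, 1, 0)), rp, dims, sp_iso)
  f3 <- ray_footprint(axis_obj(c(0.4, 0.4, 0.4), c(0, 0, 1)), rp, dims, sp_iso)
  m123 <- accumulate_rays(list(f1, f2, f3))
  m321 <- accumulate_rays(list(f3, f2, f1))
  expect_equal(m123, m321)
  expect_equal(m123, f1 + accumulate_rays(list(f2, f3)))
  expect_lte(max(m123), 3)
  # collinear axes double up on the shared line (0.75 = centre of voxel 8)
  g1 <- ray_footprint(axis_obj(c(0.75, 0.75, 0.2), c(0, 0, 1)), rp, dims, sp_iso)
  g2 <- ray_footprint(axis_obj(c(0.75, 0.75, 1.4), c(0, 0, 1)), rp, dims, sp_iso)
  expect_true(all(accumulate_rays(list(g1, g2))[8, 8, ] == 2))
  expect_error(accumulate_rays(list(f1, array(0, c(4, 4, 4)))), "mismatch")
})

test_that("hotspot extraction thresholds strictly and keeps the largest blob", {
  map <- array(0, c(10, 10, 4))
  expect_false(any(extract_hotspot(map, 3.5)))
  map[2:3, 2:3, 2] <- 3.5           # exactly at threshold: excluded (strict)
  expect_false(any(extract_hotspot(map, 3.5)))
  map[2:3, 2:3, 2] <- 4             # blob of 4
  map[6:8, 6:8, 2:3] <- 4           # blob of 18 -> the main region
  hs <- extract_hotspot(map, 3.5)
  expect_equal(sum(hs), 18)
  expect_true(all(hs[6:8, 6:8, 2:3]))
  # diagonal contact merges under 26-connectivity
  map2 <- array(0, c(6, 6, 6))
  map2[2, 2, 2] <- 4
  map2[3, 3, 3] <- 4
  expect_equal(sum(extract_hotspot(map2, 3.5)), 2)
})

test_that("polarized classification requires the ray to reach the hotspot", {
  dims <- c(16, 16, 16)
  rp <- ray_params(radius_um = 0.25, threshold = 1)
  hits <- ray_footprint(axis_obj(c(0.75, 0.75, 0.75), c(1, 0, 0), 5L),
                        rp, dims, sp_iso)
  misses <- ray_footprint(axis_obj(c(0.8, 1.2, 1.2), c(1, 0, 0), 9L),
                          rp, dims, sp_iso)
  hotspot <- array(FALSE, dims)
  hotspot[8, 8, 8] <- TRUE   # voxel centre on cell 5's axis line
  ids <- classify_polarized(list(`5` = hits, `9` = misses), hotspot)
  expect_equal(ids, 5L)
  empty <- array(FALSE, dims)
  expect_equal(classify_polarized(list(`5` = hits), empty), integer(0))
})

test_that("isotropic sparse scenes rarely clear the accumulation threshold", {
  # with 20 isotropic cells and a scene-scaled radius, chance alignment of
  # more than 3.5 cells' worth of rays at one voxel is uncommon
  exceed <- sapply(1:10, function(s) {
    cfg <- scene_config(dims = c(96, 96, 48),
                        spacing = voxel_spacing(400, 400, 400),
                        n_cells = 20, cell_radius_mean = 2,
                        cell_radius_sd = 0.3, mito_per_cell = c(0, 0),
                        orientation = orientation_isotropic(), seed = 100 + s)
    sc <- generate_scene(cfg)
    map <- accumulate_rays(lapply(truth_axes(sc), ray_footprint,
                                  params = ray_params(radius_um = 3),
                                  dims = cfg$dims, spacing = cfg$spacing))
    max(map) > 3.5
  })
  expect_lte(mean(exceed), 0.2)
})
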