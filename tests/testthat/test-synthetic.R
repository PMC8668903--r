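small_cfg <- function(...) {
  args <- utils::modifyList(
    list(dims = c(64, 64, 32), spacing = voxel_spacing(300, 300, 400),
         n_cells = 6, cell_radius_mean = 2, cell_radius_sd = 0.3,
         mito_per_cell = c(3, 5)),
    list(...))
  do.call(scene_config, args)
}

test_that("scene generation is deterministic and degenerate configs work", {
  cfg <- small_cfg(seed = 7)
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(s1$labels$labels, s2$labels$labels)
  expect_identical(s1$truth, s2$truth)

  # n_cells = 0, no capillary -> all-background volume, empty table
  s0 <- generate_scene(small_cfg(n_cells = 0, seed = 1))
  expect_true(all(s0$labels$labels == 0L))
  expect_equal(nrow(s0$segments), 0)
  expect_equal(nrow(s0$truth), 0)

  # impossible packing errors with advice
  expect_error(
    generate_scene(scene_config(dims = c(24, 24, 16),
                                spacing = voxel_spacing(300, 300, 400),
                                n_cells = 50, cell_radius_mean = 3,
                                max_attempts = 20, seed = 1)),
    "reduce n_cells")
})

test_that("generated scenes satisfy containment and disjointness voxel-wise", {
  cfg <- small_cfg(seed = 11,
                   capillary = capillary_spec(c(2, 0, 6.4), c(2, 19.2, 6.4), 1.5))
  sc <- generate_scene(cfg)
  labs <- sc$labels$labels
  segs <- sc$segments
  sp_um <- unname(unclass(cfg$spacing)) * 1e-3
  expect_true(validate_segmentation(sc$labels, segs))

  cen <- list(x = (seq_len(cfg$dims[1]) - 0.5) * sp_um[1],
              y = (seq_len(cfg$dims[2]) - 0.5) * sp_um[2],
              z = (seq_len(cfg$dims[3]) - 0.5) * sp_um[3])
  for (i in seq_len(nrow(sc$truth))) {
    tr <- sc$truth[i, ]
    fam <- c(tr$cell_label, tr$nucleus_label,
             segs$label_id[!is.na(segs$parent_id) &
                             segs$parent_id == tr$cell_label])
    idx <- which(array(labs %in% fam, dim = cfg$dims), arr.ind = TRUE)
    pts <- cbind(cen$x[idx[, 1]] - tr$centre_x_um,
                 cen$y[idx[, 2]] - tr$centre_y_um,
                 cen$z[idx[, 3]] - tr$centre_z_um)
    u <- c(tr$axis_x, tr$axis_y, tr$axis_z)
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w1 <- c(u[2] * ref[3] - u[3] * ref[2], u[3] * ref[1] - u[1] * ref[3],
            u[1] * ref[2] - u[2] * ref[1])
    w1 <- w1 / sqrt(sum(w1^2))
    w2 <- c(u[2] * w1[3] - u[3] * w1[2], u[3] * w1[1] - u[1] * w1[3],
            u[1] * w1[2] - u[2] * w1[1])
    el <- (pts %*% u / tr$semi_a_um)^2 + (pts %*% w1 / tr$semi_b_um)^2 +
      (pts %*% w2 / tr$semi_c_um)^2
    # every voxel of the cell family lies inside the true ellipsoid
    expect_true(all(el <= 1 + 1e-9))
    # nucleus voxels inside the concentric nucleus ellipsoid
    nidx <- idx[labs[idx] == tr$nucleus_label, , drop = FALSE]
    if (nrow(nidx)) {
      npts <- cbind(cen$x[nidx[, 1]] - tr$centre_x_um,
                    cen$y[nidx[, 2]] - tr$centre_y_um,
                    cen$z[nidx[, 3]] - tr$centre_z_um)
      f <- cfg$nucleus_volume_fraction^(1 / 3)
      nel <- (npts %*% u / (f * tr$semi_a_um))^2 +
        (npts %*% w1 / (f * tr$semi_b_um))^2 +
        (npts %*% w2 / (f * tr$semi_c_um))^2
      expect_true(all(nel <= 1 + 1e-9))
    }
  }
  # mitochondria never carry nucleus or background voxels: mito labels were
  # painted only over their cell's cytoplasm, so classes partition the family
  mito_ids <- segs$label_id[segs$class == "mitochondrion"]
  expect_true(length(mito_ids) > 0)
  # capillary voxels lie within the tube radius of its axis
  cap_idx <- which(array(labs == sc$model$capillary_label, dim = cfg$dims),
                   arr.ind = TRUE)
  cap <- cfg$capillary
  ab <- cap$p1 - cap$p0
  pts <- cbind(cen$x[cap_idx[, 1]], cen$y[cap_idx[, 2]], cen$z[cap_idx[, 3]])
  tpar <- pmin(pmax(((pts[, 1] - cap$p0[1]) * ab[1] +
                       (pts[, 2] - cap$p0[2]) * ab[2] +
                       (pts[, 3] - cap$p0[3]) * ab[3]) / sum(ab^2), 0), 1)
  dd <- sqrt((pts[, 1] - cap$p0[1] - tpar * ab[1])^2 +
               (pts[, 2] - cap$p0[2] - tpar * ab[2])^2 +
               (pts[, 3] - cap$p0[3] - tpar * ab[3])^2)
  expect_true(all(dd <= cap$radius_um + 1e-9))
})

test_that("plane-aligned axes at sigma 0 lie exactly in the plane", {
  cfg <- small_cfg(n_cells = 12, seed = 5, mito_per_cell = c(0, 0),
                   orientation = orientation_plane(c(0, 0, 1), sigma_deg = 0))
  sc <- generate_scene(cfg)
  expect_equal(nrow(sc$truth), 12)
  expect_true(all(abs(sc$truth$axis_z) < 1e-12))
})

test_that("hotspot truth axes pass through the hotspot point at sigma 0", {
  cfg <- small_cfg(n_cells = 10, seed = 9, mito_per_cell = c(0, 0),
                   orientation = orientation_hotspot(fraction = 0.4,
                                                     sigma_deg = 0))
  sc <- generate_scene(cfg)
  expect_equal(sum(sc$truth$polarized), 4L)
  hp <- sc$model$hotspot_point
  miss <- sapply(seq_len(nrow(sc$truth)), function(i) {
    c0 <- c(sc$truth$centre_x_um[i], sc$truth$centre_y_um[i],
            sc$truth$centre_z_um[i])
    a <- c(sc$truth$axis_x[i], sc$truth$axis_y[i], sc$truth$axis_z[i])
    r <- hp - c0
    sqrt(max(sum(r^2) - sum(r * a)^2, 0))  # point-line distance
  })
  expect_true(all(miss[sc$truth$polarized] < 1e-9))
  expect_true(all(miss[!sc$truth$polarized] > 0.5))
})

test_that("plane-aligned inclination share matches the wrapped-normal mass", {
  sigma <- 17
  cfg <- scene_config(dims = c(128, 128, 48),
                      spacing = voxel_spacing(300, 300, 400),
                      n_cells = 220, cell_radius_mean = 1.2,
                      cell_radius_sd = 0.15, mito_per_cell = c(0, 0),
                      orientation = orientation_plane(c(0, 0, 1), sigma),
                      seed = 21)
  sc <- generate_scene(cfg)
  inc <- asin(pmin(abs(sc$truth$axis_z), 1)) * 180 / pi
  share <- mean(inc <= 20)
  mass <- 2 * stats::pnorm(20 / sigma) - 1
  n <- nrow(sc$truth)
  expect_gte(n, 200)
  expect_lt(abs(share - mass), 3 * sqrt(mass * (1 - mass) / n))
})

test_that("size-distance coupling gives a negative volume-distance trend", {
  cfg <- scene_config(dims = c(96, 96, 48),
                      spacing = voxel_spacing(300, 300, 400),
                      n_cells = 25, cell_radius_mean = 2, cell_radius_sd = 0.2,
                      mito_per_cell = c(0, 0), size_distance_beta = 0.5,
                      capillary = capillary_spec(c(3, 0, 9.6), c(3, 28.8, 9.6), 2),
                      seed = 13)
  sc <- generate_scene(cfg)
  vol <- (4 / 3) * pi * sc$truth$semi_a_um * sc$truth$semi_b_um *
    sc$truth$semi_c_um
  res <- spearman_test(vol, sc$truth$dist_capillary_um)
  expect_lt(res$rho, 0)
})

test_that("EM rendering is reproducible, class-faithful and records jitter", {
  cfg <- small_cfg(seed = 15)
  sc <- generate_scene(cfg)
  em0 <- render_em_like(sc, noise_sd = 0, jitter_px = 0, seed = 2)
  # background exactly at its base grey; structures displaced from it
  bg <- sc$labels$labels == 0L
  expect_true(all(em0$values[bg] == 40))
  for (cls in c("nucleus", "cell", "mitochondrion")) {
    ids <- sc$segments$label_id[sc$segments$class == cls]
    m <- array(sc$labels$labels %in% ids, dim = cfg$dims)
    expect_gt(mean(em0$values[m]), 40 + 20)
  }
  # different noise seeds, identical geometry (same label volume rendered)
  em1 <- render_em_like(sc, noise_sd = 5, jitter_px = 0, seed = 3)
  em2 <- render_em_like(sc, noise_sd = 5, jitter_px = 0, seed = 4)
  expect_false(identical(em1$values, em2$values))
  expect_identical(render_em_like(sc, 5, 0, 3)$values, em1$values)

  # jittered slices equal the unjittered render shifted by the recorded offset
  emj <- render_em_like(sc, noise_sd = 0, jitter_px = 2, seed = 2)
  jit <- attr(emj, "jitter")
  expect_equal(nrow(jit), cfg$dims[3])
  expect_true(all(abs(jit$ox) <= 2 & abs(jit$oy) <= 2))
  iz <- which(jit$ox != 0 | jit$oy != 0)[1]
  ox <- jit$ox[iz]; oy <- jit$oy[iz]
  xs <- (1 + abs(ox)):(cfg$dims[1] - abs(ox))
  ys <- (1 + abs(oy)):(cfg$dims[2] - abs(oy))
  expect_identical(emj$values[xs, ys, iz], em0$values[xs - ox, ys - oy, iz])
})

test_that("sparse annotation keeps exactly the stride slices", {
  sp <- voxel_spacing(150, 150, 300)
  labs <- array(1L, c(4, 4, 30))
  vol <- label_volume(labs, sp)
  sa <- sparse_annotation(vol, 10)
  kept <- which(apply(sa$labels, 3, function(m) any(m != 0L))) - 1L
  expect_equal(kept, c(0L, 10L, 20L))

  two <- sparse_annotation(label_volume(array(1L, c(4, 4, 2)), sp), 2)
  expect_true(all(two$labels[, , 1] == 1L))
  expect_true(all(two$labels[, , 2] == 0L))

  big <- sparse_annotation(label_volume(array(1L, c(4, 4, 5)), sp), 6)
  kept_big <- which(apply(big$labels, 3, function(m) any(m != 0L)))
  expect_equal(kept_big, 1L)

  expect_error(sparse_annotation(vol, 1), "at least 2")
})
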