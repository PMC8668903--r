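# Independent oracles and fixture builders used across the suite.

# O(N^2) brute-force anisotropic distance map (voxel centres, micrometres)
bf_distance_map <- function(mask, spacing_um) {
  dims <- dim(mask)
  grid <- expand.grid(x = (seq_len(dims[1]) - 0.5) * spacing_um[1],
                      y = (seq_len(dims[2]) - 0.5) * spacing_um[2],
                      z = (seq_len(dims[3]) - 0.5) * spacing_um[3])
  src <- as.matrix(grid[as.vector(mask), , drop = FALSE])
  out <- apply(as.matrix(grid), 1, function(p) {
    sqrt(min((src[, 1] - p[1])^2 + (src[, 2] - p[2])^2 + (src[, 3] - p[3])^2))
  })
  array(out, dim = dims)
}

# minimum of the axial least-squares objective over a 1-degree grid of unit
# normals (half sphere suffices: the objective is sign-invariant)
grid_search_objective <- function(A, step_deg = 1) {
  th <- seq(0, 90, by = step_deg) * pi / 180
  ph <- seq(0, 359, by = step_deg) * pi / 180
  g <- expand.grid(th = th, ph = ph)
  N <- rbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
  min(colSums((t(A %*% N))^2))
}

# brute-force covariance accumulation + characteristic-polynomial eigenvalues
bf_cov_eigenvalues <- function(pts) {
  n <- nrow(pts)
  mu <- colSums(pts) / n
  C <- matrix(0, 3, 3)
  for (i in seq_len(n)) {
    d <- pts[i, ] - mu
    C <- C + outer(d, d)
  }
  C <- C / n
  c2 <- sum(diag(C))
  c1 <- (C[1, 1] * C[2, 2] - C[1, 2]^2) +
    (C[1, 1] * C[3, 3] - C[1, 3]^2) +
    (C[2, 2] * C[3, 3] - C[2, 3]^2)
  c0 <- det(C)
  # p(l) = l^3 - c2 l^2 + c1 l - c0
  roots <- polyroot(c(-c0, c1, -c2, 1))
  sort(Re(roots), decreasing = TRUE)
}

# closed-form no-ties Spearman rho
spearman_closed_form <- function(x, y) {
  n <- length(x)
  1 - 6 * sum((rank(x) - rank(y))^2) / (n * (n^2 - 1))
}

# smooth random texture matrix
smooth_texture <- function(nx, ny, passes = 6, amplitude = 50) {
  m <- matrix(stats::rnorm(nx * ny), nx, ny)
  for (i in seq_len(passes)) {
    n <- nrow(m); p <- ncol(m)
    m <- (m + m[c(1, 1:(n - 1)), ] + m[c(2:n, n), ] +
            m[, c(1, 1:(p - 1))] + m[, c(2:p, p)]) / 5
  }
  m * amplitude
}

# textured stack of a disk translating (vx, vy) px per slice, with labels
make_disk_stack <- function(nx = 96, ny = 96, nz = 30, r = 18,
                            vx = 1, vy = 0.8, seed = 5) {
  set.seed(seed)
  sp <- voxel_spacing(150, 150, 300)
  bgtex <- smooth_texture(nx, ny)
  fgtex <- smooth_texture(nx, ny)
  vals <- array(0, c(nx, ny, nz))
  labs <- array(0L, c(nx, ny, nz))
  X <- matrix(seq_len(nx), nx, ny)
  Y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  for (iz in seq_len(nz)) {
    cx <- 30 + vx * (iz - 1)
    cy <- 30 + vy * (iz - 1)
    disk <- (X - cx)^2 + (Y - cy)^2 <= r^2
    sl <- 100 + bgtex
    sl[disk] <- 170 + fgtex[disk]
    vals[, , iz] <- sl
    lab <- matrix(0L, nx, ny)
    lab[disk] <- 1L
    labs[, , iz] <- lab
  }
  list(stack = intensity_stack(pmin(pmax(vals, 0), 255), sp),
       labels = label_volume(labs, sp))
}

# principal_axis objects straight from a scene's ground truth
truth_axes <- function(scene) {
  tr <- scene$truth
  lapply(seq_len(nrow(tr)), function(i) {
    structure(list(label_id = tr$cell_label[i],
                   centroid = c(tr$centre_x_um[i], tr$centre_y_um[i],
                                tr$centre_z_um[i]),
                   direction = c(tr$axis_x[i], tr$axis_y[i], tr$axis_z[i]),
                   eigenvalues = c(3, 1, 1), ambiguous = FALSE),
              class = "principal_axis")
  })
}

# measured PCA axes (cell mask including organelles) for every cell in a
# scene; cells clipped to fewer than 4 voxels have no measurable axis and
# are dropped
measured_axes <- function(scene, ids = scene$truth$cell_label) {
  axes <- lapply(ids, function(id) {
    m <- array(scene$labels$labels %in% c(
      id,
      scene$segments$label_id[!is.na(scene$segments$parent_id) &
                                scene$segments$parent_id == id]),
      dim = scene$labels$dims)
    if (sum(m) < 4) return(NULL)
    principal_axis(m, scene$labels$spacing, id)
  })
  axes[!vapply(axes, is.null, logical(1))]
}

angle_between_deg <- function(a, b) {
  acos(min(abs(sum(a * b)), 1)) * 180 / pi
}

# small voxelized ellipsoid mask for morphometry/orientation tests
ellipsoid_mask <- function(dims, spacing, centre_um, semi_um, axis = c(1, 0, 0)) {
  sp_um <- unname(unclass(spacing)) * 1e-3
  u <- axis / sqrt(sum(axis^2))
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w1 <- c(u[2] * ref[3] - u[3] * ref[2],
          u[3] * ref[1] - u[1] * ref[3],
          u[1] * ref[2] - u[2] * ref[1])
  w1 <- w1 / sqrt(sum(w1^2))
  w2 <- c(u[2] * w1[3] - u[3] * w1[2],
          u[3] * w1[1] - u[1] * w1[3],
          u[1] * w1[2] - u[2] * w1[1])
  xs <- (seq_len(dims[1]) - 0.5) * sp_um[1] - centre_um[1]
  ys <- (seq_len(dims[2]) - 0.5) * sp_um[2] - centre_um[2]
  zs <- (seq_len(dims[3]) - 0.5) * sp_um[3] - centre_um[3]
  X <- array(rep(xs, times = dims[2] * dims[3]), dim = dims)
  Y <- array(rep(rep(ys, each = dims[1]), times = dims[3]), dim = dims)
  Z <- array(rep(zs, each = dims[1] * dims[2]), dim = dims)
  qu <- X * u[1] + Y * u[2] + Z * u[3]
  qv <- X * w1[1] + Y * w1[2] + Z * w1[3]
  qw <- X * w2[1] + Y * w2[2] + Z * w2[3]
  (qu / semi_um[1])^2 + (qv / semi_um[2])^2 + (qw / semi_um[3])^2 <= 1
}

# 6-connected erosion: voxels whose six face neighbours are all in the mask
# (out-of-bounds counts as outside)
erode6 <- function(m) {
  d <- dim(m)
  shifted <- function(s) {
    r <- array(FALSE, d)
    xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
    okx <- xs - s[1] >= 1 & xs - s[1] <= d[1]
    oky <- ys - s[2] >= 1 & ys - s[2] <= d[2]
    okz <- zs - s[3] >= 1 & zs - s[3] <= d[3]
    r[xs[okx], ys[oky], zs[okz]] <-
      m[xs[okx] - s[1], ys[oky] - s[2], zs[okz] - s[3]]
    r
  }
  out <- m
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
    out <- out & shifted(s)
  }
  out
}
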