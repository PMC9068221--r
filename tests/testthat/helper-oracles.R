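# Pure-R brute-force oracles, independent of the compiled kernels: every
# voxel center of the grid is tested against the closed-form capsule /
# distance definitions.

# world coordinates of every voxel center, n x 3
all_voxel_centers <- function(vol) {
  d <- dim(vol$labels)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

# squared distance from points (n x 3) to the segment [a, a + len*u]
oracle_seg_dist2 <- function(pts, a, u, len) {
  b <- a + len * u
  v <- b - a
  vv <- sum(v^2)
  w <- sweep(pts, 2, a, "-")
  t <- if (vv > 0) pmin(pmax((w %*% v) / vv, 0), 1) else rep(0, nrow(pts))
  dx <- w - outer(as.numeric(t), v)
  rowSums(dx^2)
}

# exhaustive voxel-center capsule membership (the rasterization oracle)
oracle_capsule_voxels <- function(vol, tip, axis, len, radius) {
  d <- dim(vol$labels)
  pts <- all_voxel_centers(vol)
  inside <- oracle_seg_dist2(pts, tip, axis, len) <= radius^2
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))[inside, , drop = FALSE]
  idx[order(idx[, 3], idx[, 2], idx[, 1]), , drop = FALSE]
}

# feasibility oracle: no forbidden voxel center inside the capsule
oracle_corridor_ok <- function(vol, scheme, tip, axis, len, radius) {
  forb <- which(vol$labels == scheme$non_surgical, arr.ind = TRUE)
  if (nrow(forb) == 0L) return(TRUE)
  pts <- sweep(sweep(forb - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
  all(oracle_seg_dist2(pts, tip, axis, len) > radius^2)
}

# exact min distance from the axis segment to any forbidden voxel center
oracle_min_forbidden_dist <- function(vol, scheme, tip, axis, len) {
  forb <- which(vol$labels == scheme$non_surgical, arr.ind = TRUE)
  if (nrow(forb) == 0L) return(Inf)
  pts <- sweep(sweep(forb - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
  sqrt(min(oracle_seg_dist2(pts, tip, axis, len)))
}

# exhaustive nearest-forbidden distance at every voxel center
oracle_clearance <- function(vol, scheme) {
  d <- dim(vol$labels)
  forb <- which(vol$labels == scheme$non_surgical, arr.ind = TRUE)
  out <- array(Inf, dim = d)
  if (nrow(forb) == 0L) return(out)
  fp <- sweep(sweep(forb - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
  pts <- all_voxel_centers(vol)
  for (r in seq_len(nrow(pts))) {
    dx <- sweep(fp, 2, pts[r, ], "-")
    out[r] <- sqrt(min(rowSums(dx^2)))
  }
  out
}

# a corridor row in the layout pose_corridors() produces
corridor_row <- function(tip, axis, len, radius) {
  axis <- axis / sqrt(sum(axis^2))
  tibble::tibble(rx = NA_real_, ry = NA_real_, rz = NA_real_,
                 spin = 0, depth = 0,
                 axis_x = axis[1], axis_y = axis[2], axis_z = axis[3],
                 tip_x = tip[1], tip_y = tip[2], tip_z = tip[3],
                 length = len, radius = radius, in_bounds = TRUE)
}

# seeded random corridors with tips inside the volume
random_corridors <- function(vol, n, radius, seed) {
  set.seed(seed)
  box <- list(lo = vol$origin, hi = vol$origin + (dim(vol$labels) - 1) * vol$spacing)
  rows <- lapply(seq_len(n), function(i) {
    tip <- box$lo + runif(3) * (box$hi - box$lo)
    ax <- rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    len <- runif(1, 2, sum(box$hi - box$lo))
    corridor_row(tip, ax, len, radius)
  })
  dplyr::bind_rows(rows)
}

# small channel fixture used across tests: block 8 mm thick, target 2 voxels
channel_fixture <- function(channel_width, spacing, jitter = 0, seed = 1L,
                            obstacle_specs = list()) {
  tr_n <- 2 * ceiling((channel_width / 2 + 3) / spacing)
  ylen <- ceiling((channel_width / 2 + 2 + 8 + 4) / spacing)
  spec <- phantom_spec(shape = c(tr_n, ylen, tr_n), spacing = spacing,
                       channel_width = channel_width, block_extent = 8,
                       target_extent = max(1, 2 * spacing),
                       obstacle_specs = obstacle_specs,
                       jitter = jitter, seed = seed)
  if (length(obstacle_specs)) generate_skull_phantom(spec) else generate_channel_phantom(spec)
}

# coarse grid keeping materialized sweeps small
coarse_grid <- function(rot_step = 45, spin_step = 180, travel_step = 5,
                        travel_range = 15) {
  search_grid(rot_step = rot_step, spin_step = spin_step,
              travel_step = travel_step, travel_range = travel_range)
}
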