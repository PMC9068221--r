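#' Microdrill tool specification
#'
#' Geometry of the surgical microdrill and the rules for automatic size
#' adaptation.  The corridor swept by the drill is modeled as a capsule
#' (cylinder with hemispherical caps, matching a diamond burr head) of
#' radius `head_diameter / 2`.
#'
#' @param head_diameter Drill head diameter in mm (> 0).  A conventional
#'   endoscopic microdrill is 2.9 mm.
#' @param shaft_diameter Shaft diameter in mm; defaults to the head
#'   diameter, giving a uniform capsule.
#' @param min_diameter Smallest diameter (mm) the adaptation loop may try.
#' @param decrement Size reduction step (mm) used when no feasible path
#'   exists at the current diameter; default 0.5.
#' @return An object of class `tool_spec`.
#' @examples
#' tool_spec(2.9)
#' @export
tool_spec <- function(head_diameter, shaft_diameter = head_diameter,
                      min_diameter = 1, decrement = 0.5) {
  if (!is.numeric(head_diameter) || head_diameter <= 0) stop("`head_diameter` must be > 0")
  if (shaft_diameter <= 0) stop("`shaft_diameter` must be > 0")
  if (min_diameter <= 0) stop("`min_diameter` must be > 0")
  if (decrement <= 0) stop("`decrement` must be > 0")
  structure(list(head_diameter = as.numeric(head_diameter),
                 shaft_diameter = as.numeric(shaft_diameter),
                 min_diameter = as.numeric(min_diameter),
                 decrement = as.numeric(decrement)),
            class = "tool_spec")
}

#' @export
print.tool_spec <- function(x, ...) {
  cat(sprintf("<tool_spec> head %.2f mm, shaft %.2f mm, floor %.2f mm, step -%.2f mm\n",
              x$head_diameter, x$shaft_diameter, x$min_diameter, x$decrement))
  invisible(x)
}

#' Five-degree-of-freedom search grid
#'
#' Discretization of the corridor's five degrees of freedom: rotations about
#' the world x, y, z axes, spin about the corridor's own major axis, and
#' travel along that axis.  Each range must be an exact integer multiple of
#' its step.  Rotations lie on the half-open centered grid
#' `[-range/2, +range/2)`, spin on `[0, range)` and travel on `[0, range)`,
#' so the number of poses is exactly
#' `(rot_range/rot_step)^3 * (spin_range/spin_step) * (travel_range/travel_step)`.
#'
#' The defaults (5 deg steps over 180 deg rotations and 360 deg spin, 1 mm
#' steps over 15 mm travel) give 36^3 * 72 * 15 = 50,388,480 poses.
#'
#' @param rot_step,rot_range Step and total range (degrees) for each of the
#'   three world-axis rotations.
#' @param spin_step,spin_range Step and total range (degrees) for spin about
#'   the corridor axis.
#' @param travel_step,travel_range Step and total range (mm) for travel
#'   along the corridor axis.
#' @return An object of class `search_grid`.
#' @examples
#' n_poses(search_grid())           # 50388480
#' n_poses(search_grid(rot_step = 15, spin_step = 30, travel_step = 5))
#' @export
search_grid <- function(rot_step = 5, rot_range = 180,
                        spin_step = 5, spin_range = 360,
                        travel_step = 1, travel_range = 15) {
  g <- list(rot_step = rot_step, rot_range = rot_range,
            spin_step = spin_step, spin_range = spin_range,
            travel_step = travel_step, travel_range = travel_range)
  for (nm in names(g)) {
    if (!is.numeric(g[[nm]]) || length(g[[nm]]) != 1L || g[[nm]] <= 0) {
      stop(sprintf("`%s` must be a single positive number", nm))
    }
  }
  check_div <- function(range, step, what) {
    k <- range / step
    if (abs(k - round(k)) > 1e-9) {
      stop(sprintf("%s range (%g) is not an integer multiple of its step (%g)",
                   what, range, step))
    }
    as.integer(round(k))
  }
  g$n_rot <- check_div(rot_range, rot_step, "rotation")
  g$n_spin <- check_div(spin_range, spin_step, "spin")
  g$n_travel <- check_div(travel_range, travel_step, "travel")
  structure(g, class = "search_grid")
}

#' @export
print.search_grid <- function(x, ...) {
  cat(sprintf(paste0("<search_grid> rot %g deg / %g deg (x3), spin %g deg / %g deg, ",
                     "travel %g mm / %g mm: %s poses\n"),
              x$rot_step, x$rot_range, x$spin_step, x$spin_range,
              x$travel_step, x$travel_range, format(n_poses(x), big.mark = ",")))
  invisible(x)
}

#' Number of poses in a search grid
#'
#' Closed-form pose count
#' `(rot_range/rot_step)^3 * (spin_range/spin_step) * (travel_range/travel_step)`.
#' [enumerate_poses()] materializes exactly this many rows.
#'
#' @param grid A [search_grid()].
#' @return A double (counts can exceed the integer range).
#' @export
n_poses <- function(grid) {
  stopifnot(inherits(grid, "search_grid"))
  as.numeric(grid$n_rot)^3 * grid$n_spin * grid$n_travel
}

grid_rot_values <- function(grid) -grid$rot_range / 2 + (seq_len(grid$n_rot) - 1) * grid$rot_step
grid_spin_values <- function(grid) (seq_len(grid$n_spin) - 1) * grid$spin_step
grid_depth_values <- function(grid) (seq_len(grid$n_travel) - 1) * grid$travel_step

#' Enumerate every pose of a search grid
#'
#' Materializes the full Cartesian product of the five pose coordinates in
#' deterministic lexicographic order (`rx`, `ry`, `rz`, `spin`, `depth`).
#' A pose has exactly five degrees of freedom: three world-axis rotations
#' (degrees), spin about the corridor axis (degrees) and travel depth (mm).
#'
#' Intended for small and coarse grids; the default grid has 5.04e7 rows and
#' should be counted with [n_poses()] instead of materialized.
#'
#' @param grid A [search_grid()].
#' @return A tibble with columns `rx`, `ry`, `rz`, `spin`, `depth`.
#' @examples
#' enumerate_poses(search_grid(rot_step = 90, spin_step = 180, travel_step = 15))
#' @export
enumerate_poses <- function(grid) {
  stopifnot(inherits(grid, "search_grid"))
  if (n_poses(grid) > 5e6) {
    stop("grid has more than 5e6 poses; use n_poses() or search_paths() instead of materializing")
  }
  tidyr::expand_grid(rx = grid_rot_values(grid),
                     ry = grid_rot_values(grid),
                     rz = grid_rot_values(grid),
                     spin = grid_spin_values(grid),
                     depth = grid_depth_values(grid))
}

#' Target anchor: contact point and canonical approach axis
#'
#' The anchor fixes the zero pose: `point` is the centroid of the
#' target-labeled voxel centers (world mm) and `outward` is the canonical
#' corridor axis at zero rotation, pointing from the target toward the
#' entry.  By default `outward` is the anatomical-anterior axis (+y under
#' the RAS convention), i.e. the trans-nasal approach direction.
#'
#' @param vol A [label_volume()].
#' @param scheme A [label_scheme()].
#' @param outward Length-3 direction of the zero-pose axis; normalized
#'   internally.
#' @return An object of class `anchor` with elements `point` and `outward`.
#' @export
target_anchor <- function(vol, scheme = label_scheme(), outward = c(0, 1, 0)) {
  assert_volume(vol)
  assert_scheme(scheme)
  idx <- which(vol$labels == scheme$target, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty target label: no voxels carry the target value")
  pts <- sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
  anchor(point = colMeans(pts), outward = outward)
}

#' @rdname target_anchor
#' @param point World mm coordinates of the target contact point.
#' @export
anchor <- function(point, outward = c(0, 1, 0)) {
  point <- as.numeric(point)
  outward <- as.numeric(outward)
  if (length(point) != 3L || any(!is.finite(point))) stop("`point` must be 3 finite values")
  nrm <- sqrt(sum(outward^2))
  if (length(outward) != 3L || !is.finite(nrm) || nrm == 0) stop("`outward` must be a nonzero 3-vector")
  structure(list(point = point, outward = outward / nrm), class = "anchor")
}

#' @export
print.anchor <- function(x, ...) {
  cat(sprintf("<anchor> point (%s) mm, outward (%s)\n",
              paste(signif(x$point, 5), collapse = ", "),
              paste(signif(x$outward, 4), collapse = ", ")))
  invisible(x)
}

# Apply the extrinsic rotation Rz(rz) %*% Ry(ry) %*% Rx(rx) to one vector,
# vectorized over rows of (rx, ry, rz) in degrees.  Returns an n x 3 matrix
# of unit vectors.
rotate_outward <- function(rx, ry, rz, outward) {
  d2r <- pi / 180
  cx <- cos(rx * d2r); sx <- sin(rx * d2r)
  cy <- cos(ry * d2r); sy <- sin(ry * d2r)
  cz <- cos(rz * d2r); sz <- sin(rz * d2r)
  v1 <- outward[1]; v2 <- outward[2]; v3 <- outward[3]
  # Rx
  x1 <- v1
  y1 <- cx * v2 - sx * v3
  z1 <- sx * v2 + cx * v3
  # Ry
  x2 <- cy * x1 + sy * z1
  y2 <- y1
  z2 <- -sy * x1 + cy * z1
  # Rz
  x3 <- cz * x2 - sz * y2
  y3 <- sz * x2 + cz * y2
  z3 <- z2
  cbind(x3, y3, z3, deparse.level = 0)
}

# Distance from an interior point to the volume's physical bounding-box exit
# along direction `axes` (rows).  Returns NA for points outside the box.
ray_box_exit <- function(tips, axes, vol) {
  box <- volume_box(vol)
  n <- nrow(tips)
  tmin <- rep(Inf, n)
  inside <- rep(TRUE, n)
  for (a in 1:3) {
    inside <- inside & tips[, a] >= box$lo[a] - 1e-9 & tips[, a] <= box$hi[a] + 1e-9
    pos <- axes[, a] > 1e-12
    neg <- axes[, a] < -1e-12
    t_a <- rep(Inf, n)
    t_a[pos] <- (box$hi[a] - tips[pos, a]) / axes[pos, a]
    t_a[neg] <- (box$lo[a] - tips[neg, a]) / axes[neg, a]
    tmin <- pmin(tmin, t_a)
  }
  tmin[!inside] <- NA_real_
  tmin
}

#' Realize poses as corridors in world coordinates
#'
#' Turns each discretized pose into the capsule geometry it realizes.  The
#' corridor axis is the anchor's outward direction rotated by the extrinsic
#' rotations `Rz(rz) %*% Ry(ry) %*% Rx(rx)` (fixed world axes, in that
#' composition order); the tip sits `depth` mm from the anchor point along
#' the axis (depth retracts the tip away from the target, toward the entry);
#' the corridor extends from the tip along the axis to the volume's
#' physical bounding-box exit.  Spin is recorded but does not change the
#' geometry of a circular cross-section.
#'
#' @param poses A tibble/data frame with columns `rx`, `ry`, `rz`, `spin`,
#'   `depth` (see [enumerate_poses()]).
#' @param anchor An [anchor()].
#' @param tool A [tool_spec()].
#' @param vol A [label_volume()] fixing the physical bounds.
#' @param on_oob What to do when a pose puts the tip outside the volume:
#'   `"flag"` (default) marks the row with `in_bounds = FALSE`, `"error"`
#'   fails with "tip out of volume".
#' @return The input tibble with added columns `axis_x/y/z` (unit vector),
#'   `tip_x/y/z` (mm), `length` (mm), `radius` (mm) and `in_bounds`.
#' @export
pose_corridors <- function(poses, anchor, tool, vol, on_oob = c("flag", "error")) {
  on_oob <- match.arg(on_oob)
  stopifnot(inherits(anchor, "anchor"), inherits(tool, "tool_spec"))
  assert_volume(vol)
  poses <- as_tibble(poses)
  need <- c("rx", "ry", "rz", "spin", "depth")
  if (!all(need %in% names(poses))) {
    stop("`poses` must have columns rx, ry, rz, spin, depth")
  }
  axes <- rotate_outward(poses$rx, poses$ry, poses$rz, anchor$outward)
  tips <- cbind(anchor$point[1] + poses$depth * axes[, 1],
                anchor$point[2] + poses$depth * axes[, 2],
                anchor$point[3] + poses$depth * axes[, 3])
  len <- ray_box_exit(tips, axes, vol)
  oob <- is.na(len)
  if (any(oob) && on_oob == "error") stop("tip out of volume")
  dplyr::mutate(poses,
                axis_x = axes[, 1], axis_y = axes[, 2], axis_z = axes[, 3],
                tip_x = tips[, 1], tip_y = tips[, 2], tip_z = tips[, 3],
                length = len,
                radius = tool$head_diameter / 2,
                in_bounds = !oob)
}

#' Rasterize one corridor into voxel indices
#'
#' Returns exactly the voxels whose centers lie within `radius` mm of the
#' corridor's axis segment (capsule membership, closed `<=` convention).
#'
#' @param vol A [label_volume()].
#' @param corridor A one-row tibble from [pose_corridors()], or any list
#'   with `tip_x/y/z`, `axis_x/y/z`, `length`, `radius`.
#' @return A tibble of 1-based voxel indices `i`, `j`, `k`, ordered by
#'   `k`, then `j`, then `i`.  May be empty for sub-voxel radii that miss
#'   every center.
#' @export
rasterize_corridor <- function(vol, corridor) {
  assert_volume(vol)
  cr <- as.list(corridor)
  if (isFALSE(cr$in_bounds[1]) || is.na(cr$length[1])) stop("tip out of volume")
  idx <- rasterize_capsule_cpp(dim(vol$labels), vol$spacing, vol$origin,
                               c(cr$tip_x[1], cr$tip_y[1], cr$tip_z[1]),
                               c(cr$axis_x[1], cr$axis_y[1], cr$axis_z[1]),
                               cr$length[1], cr$radius[1])
  tibble(i = idx[, 1], j = idx[, 2], k = idx[, 3])
}
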