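#' Clearance map: distance to the nearest forbidden voxel
#'
#' Exact Euclidean distance transform (anisotropy-aware, in mm) from every
#' voxel center to the nearest non-surgical voxel center.  Zero exactly on
#' forbidden voxels; `Inf` everywhere when the volume has no forbidden
#' voxels.  The map is 1-Lipschitz in world coordinates and is used as a
#' conservative prefilter during feasibility checking; it never decides a
#' pose on its own.
#'
#' @param vol A [label_volume()].
#' @param scheme A [label_scheme()].
#' @return A numeric 3D array of class `clearance_map` (mm), with the
#'   volume's spacing and origin attached as attributes.
#' @export
clearance_map <- function(vol, scheme = label_scheme()) {
  assert_volume(vol)
  forb <- forbidden_mask(vol, scheme)
  d <- dim(vol$labels)
  if (!any(forb)) {
    cm <- array(Inf, dim = d)
  } else {
    cm <- array(edt3d_cpp(forb, d, vol$spacing), dim = d)
  }
  structure(cm, spacing = vol$spacing, origin = vol$origin,
            class = c("clearance_map", class(cm)))
}

# Feasibility of a batch of corridors (rows of `corridors`).  Out-of-bounds
# rows come back FALSE.  method "fast" must agree with "bruteforce" on every
# pose; "bruteforce" is the reference: rasterize, then look for any
# forbidden voxel in the capsule.
check_corridor_rows <- function(vol, corridors, scheme, cmap = NULL,
                                method = c("fast", "bruteforce")) {
  method <- match.arg(method)
  n <- nrow(corridors)
  ok <- corridors$in_bounds & !is.na(corridors$length)
  out <- logical(n)
  if (!any(ok)) return(out)
  forb <- forbidden_mask(vol, scheme)
  if (!any(forb)) {
    out[ok] <- TRUE
    return(out)
  }
  if (method == "fast") {
    if (is.null(cmap)) cmap <- clearance_map(vol, scheme)
    cm <- as.numeric(cmap)
    cm[!is.finite(cm)] <- 1e12
    out[ok] <- check_corridors_cpp(
      as.matrix(corridors[ok, c("tip_x", "tip_y", "tip_z")]),
      as.matrix(corridors[ok, c("axis_x", "axis_y", "axis_z")]),
      corridors$length[ok], corridors$radius[1],
      cm, forb, dim(vol$labels), vol$spacing, vol$origin)
  } else {
    rows <- which(ok)
    for (r in rows) {
      vox <- rasterize_corridor(vol, corridors[r, ])
      if (nrow(vox) == 0L) {
        out[r] <- TRUE
      } else {
        lab <- vol$labels[cbind(vox$i, vox$j, vox$k)]
        out[r] <- !any(lab == scheme$non_surgical)
      }
    }
  }
  out
}

#' Check corridors for collision with non-surgical tissue
#'
#' A corridor is feasible iff no non-surgical voxel center lies within the
#' capsule, i.e. every voxel of the corridor is in the surgical space, in
#' air, or on the target.  `method = "bruteforce"` rasterizes the capsule
#' and inspects the labels (the reference rule); `method = "fast"` reaches
#' the same answer for every pose through a clearance-map prefilter with
#' exact local resolution of ambiguous segments.
#'
#' @param corridors Output of [pose_corridors()].
#' @param vol A [label_volume()].
#' @param scheme A [label_scheme()].
#' @param method `"fast"` (default) or `"bruteforce"`; results are
#'   identical, only runtime differs.
#' @param cmap Optional precomputed [clearance_map()] (fast method only).
#' @return The corridors tibble with a logical `feasible` column added.
#'   Out-of-bounds corridors are infeasible.
#' @export
check_corridors <- function(corridors, vol, scheme = label_scheme(),
                            method = c("fast", "bruteforce"), cmap = NULL) {
  method <- match.arg(method)
  assert_volume(vol)
  assert_scheme(scheme)
  dplyr::mutate(as_tibble(corridors),
                feasible = check_corridor_rows(vol, corridors, scheme,
                                               cmap = cmap, method = method))
}

#' Exhaustive feasible-path search over a pose grid
#'
#' Enumerates every pose of the grid, realizes its corridor and tests it for
#' collision with non-surgical voxels.  Spin does not change the capsule of
#' a circular tool, so feasibility is computed once per unique
#' `(rx, ry, rz, depth)` combination and replicated across spin values
#' (`spin_cache = FALSE` checks every pose individually; the counts and the
#' feasible set are identical, only runtime differs).  Results are fully
#' deterministic, with feasible poses listed in lexicographic
#' `(rx, ry, rz, spin, depth)` order.
#'
#' @param vol A [label_volume()].
#' @param tool A [tool_spec()].
#' @param grid A [search_grid()].
#' @param scheme A [label_scheme()].
#' @param anchor An [anchor()]; computed from the target label via
#'   [target_anchor()] when omitted.
#' @param method Collision test used for every pose, `"fast"` or
#'   `"bruteforce"` (see [check_corridors()]).
#' @param spin_cache Reuse each unique-geometry verdict across spin values
#'   (default `TRUE`); provably result-identical for circular tools.
#' @return A `feasibility_result` object: pose counts, feasible fraction,
#'   the feasible-pose tibble, the tool diameter used and the adaptation
#'   trace (a single diameter here; see [adapt_tool_size()]).
#' @examples
#' ph <- generate_channel_phantom(phantom_spec(
#'   shape = c(24, 36, 24), spacing = 0.5, channel_width = 6,
#'   block_extent = 8))
#' res <- search_paths(ph, tool_spec(2.9),
#'                     search_grid(rot_step = 60, spin_step = 180,
#'                                 travel_step = 5, travel_range = 5))
#' glance(res)
#' @export
search_paths <- function(vol, tool, grid, scheme = label_scheme(),
                         anchor = target_anchor(vol, scheme),
                         method = c("fast", "bruteforce"),
                         spin_cache = TRUE) {
  method <- match.arg(method)
  assert_volume(vol)
  stopifnot(inherits(tool, "tool_spec"), inherits(grid, "search_grid"),
            inherits(anchor, "anchor"))
  box <- volume_box(vol)
  if (any(anchor$point < box$lo) || any(anchor$point > box$hi)) {
    stop("anchor outside volume")
  }

  rot <- grid_rot_values(grid)
  spin <- grid_spin_values(grid)
  depth <- grid_depth_values(grid)

  # unique capsule geometries: spin is redundant for a circular tool
  geoms <- tidyr::expand_grid(rx = rot, ry = rot, rz = rot, depth = depth)
  geoms$spin <- 0
  corr <- pose_corridors(geoms[c("rx", "ry", "rz", "spin", "depth")],
                         anchor, tool, vol, on_oob = "flag")
  cmap <- if (method == "fast") clearance_map(vol, scheme) else NULL
  if (spin_cache) {
    geom_ok <- check_corridor_rows(vol, corr, scheme, cmap = cmap, method = method)
  } else {
    all_poses <- tidyr::expand_grid(rx = rot, ry = rot, rz = rot,
                                    spin = spin, depth = depth)
    corr_all <- pose_corridors(all_poses, anchor, tool, vol, on_oob = "flag")
    ok_all <- check_corridor_rows(vol, corr_all, scheme, cmap = cmap, method = method)
    # collapse back to unique geometries (all spins agree by construction)
    geom_ok <- ok_all[all_poses$spin == spin[1]]
  }

  n_total <- n_poses(grid)
  n_feasible <- as.numeric(sum(geom_ok)) * grid$n_spin
  feasible_geoms <- geoms[geom_ok, c("rx", "ry", "rz", "depth")]
  feasible_poses <- tidyr::expand_grid(feasible_geoms, spin = spin)
  feasible_poses <- dplyr::arrange(
    feasible_poses[c("rx", "ry", "rz", "spin", "depth")],
    .data$rx, .data$ry, .data$rz, .data$spin, .data$depth)

  new_feasibility_result(
    grid = grid, tool = tool, scheme = scheme, anchor = anchor,
    tool_diameter_used = tool$head_diameter,
    n_poses_total = n_total, n_feasible = n_feasible,
    feasible_poses = feasible_poses,
    adaptation_trace = tool$head_diameter)
}

new_feasibility_result <- function(grid, tool, scheme, anchor,
                                   tool_diameter_used, n_poses_total,
                                   n_feasible, feasible_poses,
                                   adaptation_trace) {
  structure(list(grid = grid, tool = tool, scheme = scheme, anchor = anchor,
                 tool_diameter_used = tool_diameter_used,
                 n_poses_total = n_poses_total,
                 n_feasible = n_feasible,
                 feasible_fraction = n_feasible / n_poses_total,
                 feasible_poses = feasible_poses,
                 adaptation_trace = adaptation_trace,
                 feasible = n_feasible > 0),
            class = "feasibility_result")
}

#' @export
print.feasibility_result <- function(x, ...) {
  cat(sprintf("<feasibility_result> drill %.2f mm: %s / %s poses feasible (%.4g%%)\n",
              x$tool_diameter_used,
              format(x$n_feasible, big.mark = ","),
              format(x$n_poses_total, big.mark = ","),
              100 * x$feasible_fraction))
  if (length(x$adaptation_trace) > 1) {
    cat("  adaptation trace (mm):", paste(x$adaptation_trace, collapse = " -> "), "\n")
  }
  if (!x$feasible) cat("  no feasible surgical path\n")
  invisible(x)
}

#' Automatic microdrill size adaptation
#'
#' Runs [search_paths()] at the tool's head diameter; while no feasible path
#' exists and the next smaller diameter is still at or above the floor
#' (`min_diameter`), the diameter is reduced by `decrement` (default 0.5 mm)
#' and the search repeats.  Returns the first feasible result, carrying the
#' full trace of attempted diameters; if the floor is reached without
#' feasibility the last (empty) result is returned with `feasible = FALSE`.
#'
#' @inheritParams search_paths
#' @return A `feasibility_result` whose `adaptation_trace` lists every
#'   attempted diameter (strictly decreasing by `decrement`).
#' @export
adapt_tool_size <- function(vol, tool, grid, scheme = label_scheme(),
                            anchor = target_anchor(vol, scheme),
                            method = c("fast", "bruteforce")) {
  method <- match.arg(method)
  stopifnot(inherits(tool, "tool_spec"))
  trace <- numeric(0)
  d <- tool$head_diameter
  repeat {
    trace <- c(trace, d)
    t_d <- tool_spec(d, shaft_diameter = d, min_diameter = tool$min_diameter,
                     decrement = tool$decrement)
    res <- search_paths(vol, t_d, grid, scheme = scheme, anchor = anchor,
                        method = method)
    if (res$feasible || (d - tool$decrement) < tool$min_diameter - 1e-9) break
    d <- d - tool$decrement
  }
  res$adaptation_trace <- trace
  res
}

#' Rank feasible paths by wall clearance
#'
#' Orders the feasible poses by decreasing clearance: the minimal distance
#' from the corridor axis to any non-surgical voxel center, minus the
#' corridor radius (so clearance is the extra margin in mm before the
#' corridor would graze forbidden tissue).  Ties are broken by smaller
#' angular deviation of the corridor axis from the canonical outward
#' direction, then by lexicographic pose order.  The candidate set is the
#' surface of the forbidden region (centers with a non-forbidden
#' 6-neighbor), which carries the nearest forbidden center for any corridor
#' that stays clear of the region's interior.
#'
#' @param result A `feasibility_result` from [search_paths()] or
#'   [adapt_tool_size()].
#' @param vol The [label_volume()] the result was computed on.
#' @return A tibble of feasible poses with `clearance_mm` and `angle_deg`
#'   columns, best path first; empty when no path is feasible.
#' @export
rank_paths <- function(result, vol) {
  stopifnot(inherits(result, "feasibility_result"))
  assert_volume(vol)
  poses <- result$feasible_poses
  if (nrow(poses) == 0L) {
    return(tibble(rx = numeric(0), ry = numeric(0), rz = numeric(0),
                  spin = numeric(0), depth = numeric(0),
                  clearance_mm = numeric(0), angle_deg = numeric(0)))
  }
  tool <- tool_spec(result$tool_diameter_used,
                    min_diameter = result$tool$min_diameter,
                    decrement = result$tool$decrement)
  geoms <- dplyr::distinct(poses[c("rx", "ry", "rz", "depth")])
  geoms$spin <- 0
  corr <- pose_corridors(geoms[c("rx", "ry", "rz", "spin", "depth")],
                         result$anchor, tool, vol, on_oob = "flag")
  pts <- forbidden_surface_points(vol, result$scheme)
  if (nrow(pts) == 0L) {
    dmin <- rep(Inf, nrow(corr))
  } else {
    dmin <- min_seg_dist_cpp(
      as.matrix(corr[c("tip_x", "tip_y", "tip_z")]),
      as.matrix(corr[c("axis_x", "axis_y", "axis_z")]),
      corr$length, pts)
  }
  geoms$clearance_mm <- dmin - tool$head_diameter / 2
  dots <- corr$axis_x * result$anchor$outward[1] +
    corr$axis_y * result$anchor$outward[2] +
    corr$axis_z * result$anchor$outward[3]
  geoms$angle_deg <- acos(pmin(pmax(dots, -1), 1)) * 180 / pi
  out <- dplyr::left_join(poses, geoms[c("rx", "ry", "rz", "depth",
                                         "clearance_mm", "angle_deg")],
                          by = c("rx", "ry", "rz", "depth"))
  dplyr::arrange(out, dplyr::desc(.data$clearance_mm), .data$angle_deg,
                 .data$rx, .data$ry, .data$rz, .data$spin, .data$depth)
}

# world coordinates of forbidden voxel centers on the surface of the
# forbidden region (6-connectivity; grid-edge forbidden voxels count)
forbidden_surface_points <- function(vol, scheme) {
  forb <- forbidden_mask(vol, scheme)
  d <- dim(forb)
  if (!any(forb)) return(matrix(numeric(0), ncol = 3))
  interior <- array(TRUE, dim = d)
  shift_and <- function(m, a, s) {
    out <- array(FALSE, dim = d)
    src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    if (s > 0) { dst[[a]] <- 2:d[a]; src[[a]] <- 1:(d[a] - 1) }
    else { dst[[a]] <- 1:(d[a] - 1); src[[a]] <- 2:d[a] }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (a in 1:3) for (s in c(-1, 1)) interior <- interior & shift_and(forb, a, s)
  surf <- forb & !interior
  idx <- which(surf, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}
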