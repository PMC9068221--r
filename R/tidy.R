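#' Tidy a feasibility result
#'
#' Returns the feasible poses as a tibble, one row per pose, in
#' deterministic lexicographic order.
#'
#' @param x A `feasibility_result`.
#' @param ... Unused.
#' @return A tibble with columns `rx`, `ry`, `rz`, `spin`, `depth`.
#' @export
tidy.feasibility_result <- function(x, ...) {
  as_tibble(x$feasible_poses)
}

#' One-row summary of a feasibility result
#'
#' @param x A `feasibility_result`.
#' @param ... Unused.
#' @return A one-row tibble: `tool_diameter_used`, `n_poses_total`,
#'   `n_feasible`, `feasible_fraction`, `n_adaptation_steps`, `feasible`.
#' @export
glance.feasibility_result <- function(x, ...) {
  tibble(tool_diameter_used = x$tool_diameter_used,
         n_poses_total = x$n_poses_total,
         n_feasible = x$n_feasible,
         feasible_fraction = x$feasible_fraction,
         n_adaptation_steps = length(x$adaptation_trace),
         feasible = x$feasible)
}

#' Plot the angular map of feasible corridors
#'
#' Heat map of feasible-pose counts over the (rx, ry) rotation plane,
#' summed over rz, spin and depth: a quick view of which approach
#' directions admit a collision-free corridor.
#'
#' @param object A `feasibility_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.feasibility_result <- function(object, ...) {
  poses <- tidy(object)
  if (nrow(poses) == 0L) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "no feasible path") +
             ggplot2::theme_void())
  }
  counts <- dplyr::count(poses, .data$rx, .data$ry)
  ggplot2::ggplot(counts, ggplot2::aes(.data$rx, .data$ry, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "feasible\nposes") +
    ggplot2::labs(x = "rotation about x (deg)", y = "rotation about y (deg)",
                  title = sprintf("Feasible corridors, drill %.1f mm",
                                  object$tool_diameter_used)) +
    ggplot2::theme_minimal()
}

#' Plot a drill-diameter feasibility sweep
#'
#' Feasible-path fraction against microdrill diameter, the curve used to
#' judge which drill sizes can reach the target in a given anatomy.
#'
#' @param object A `feasibility_sweep` from [sweep_diameters()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.feasibility_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$diameter, .data$feasible_fraction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "microdrill diameter (mm)", y = "feasible fraction of poses") +
    ggplot2::theme_minimal()
}

#' Plot one transverse slice of a label volume
#'
#' Tile plot of a single slice with the four semantic roles colored the way
#' segmentation overlays are usually shown (surgical space green,
#' non-surgical red, target yellow).
#'
#' @param vol A [label_volume()].
#' @param slice Slice index along `axis`; defaults to the middle slice.
#' @param axis Axis perpendicular to the slice: `"x"`, `"y"` or `"z"`.
#' @param scheme A [label_scheme()].
#' @return A ggplot object.
#' @export
plot_slice <- function(vol, slice = NULL, axis = "z", scheme = label_scheme()) {
  assert_volume(vol)
  ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  d <- dim(vol$labels)
  if (is.null(slice)) slice <- ceiling(d[ax] / 2)
  m <- slice_along(vol$labels, ax, slice)
  tr <- setdiff(1:3, ax)
  df <- tidyr::expand_grid(a = seq_len(dim(m)[1]), b = seq_len(dim(m)[2]))
  df$label <- m[cbind(df$a, df$b)]
  role <- setNames(c("air", "surgical", "non-surgical", "target"),
                   c(scheme$air, scheme$surgical, scheme$non_surgical, scheme$target))
  df$role <- factor(role[as.character(df$label)],
                    levels = c("air", "surgical", "non-surgical", "target"))
  axn <- c("x", "y", "z")
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b, fill = .data$role)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(air = "grey90", surgical = "#2e7d32",
                                          `non-surgical` = "#c62828",
                                          target = "#f9a825"),
                               drop = FALSE) +
    ggplot2::coord_fixed(ratio = vol$spacing[tr[2]] / vol$spacing[tr[1]]) +
    ggplot2::labs(x = sprintf("%s (voxel)", axn[tr[1]]),
                  y = sprintf("%s (voxel)", axn[tr[2]]),
                  title = sprintf("slice %d along %s", slice, axn[ax])) +
    ggplot2::theme_minimal()
}
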