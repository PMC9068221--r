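#' Write a feasibility result as a JSON report
#'
#' Serializes a `feasibility_result` with stable key order and no
#' timestamps, so re-running an identical configuration yields a
#' byte-identical report.  Angles are in degrees, lengths in mm.
#'
#' @param result A `feasibility_result`.
#' @param path Output file path.
#' @param ranked Optional ranked pose tibble from [rank_paths()]; when
#'   given, poses are written in ranked order with their clearance.
#' @return `path`, invisibly.
#' @seealso [read_report()]
#' @export
write_report <- function(result, path, ranked = NULL) {
  stopifnot(inherits(result, "feasibility_result"))
  g <- result$grid
  poses <- if (!is.null(ranked)) ranked else result$feasible_poses
  payload <- list(
    config = list(
      grid = list(rot_step = g$rot_step, rot_range = g$rot_range,
                  spin_step = g$spin_step, spin_range = g$spin_range,
                  travel_step = g$travel_step, travel_range = g$travel_range),
      tool = list(head_diameter = result$tool$head_diameter,
                  shaft_diameter = result$tool$shaft_diameter,
                  min_diameter = result$tool$min_diameter,
                  decrement = result$tool$decrement),
      scheme = list(air = result$scheme$air, surgical = result$scheme$surgical,
                    non_surgical = result$scheme$non_surgical,
                    target = result$scheme$target),
      anchor = list(point = result$anchor$point, outward = result$anchor$outward)
    ),
    tool_diameter_used = result$tool_diameter_used,
    n_poses_total = result$n_poses_total,
    n_feasible = result$n_feasible,
    feasible_fraction = result$feasible_fraction,
    adaptation_trace = as.numeric(result$adaptation_trace),
    feasible = result$feasible,
    poses = as.data.frame(poses)
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           dataframe = "columns", pretty = TRUE)
  writeLines(json, path, sep = "\n")
  invisible(path)
}

#' Read a feasibility report back into a result object
#'
#' Inverse of [write_report()]: reconstructs a `feasibility_result` whose
#' counts, fraction, trace and pose set equal the original's.
#'
#' @param path Path to a JSON report written by [write_report()].
#' @return A `feasibility_result`.
#' @export
read_report <- function(path) {
  p <- jsonlite::fromJSON(path)
  g <- p$config$grid
  tl <- p$config$tool
  sc <- p$config$scheme
  poses <- as_tibble(as.data.frame(p$poses))
  if (nrow(poses) == 0L) {
    poses <- tibble(rx = numeric(0), ry = numeric(0), rz = numeric(0),
                    spin = numeric(0), depth = numeric(0))
  }
  res <- new_feasibility_result(
    grid = search_grid(g$rot_step, g$rot_range, g$spin_step, g$spin_range,
                       g$travel_step, g$travel_range),
    tool = tool_spec(tl$head_diameter, tl$shaft_diameter, tl$min_diameter,
                     tl$decrement),
    scheme = label_scheme(sc$air, sc$surgical, sc$non_surgical, sc$target),
    anchor = anchor(p$config$anchor$point, p$config$anchor$outward),
    tool_diameter_used = p$tool_diameter_used,
    n_poses_total = p$n_poses_total,
    n_feasible = p$n_feasible,
    feasible_poses = poses[intersect(c("rx", "ry", "rz", "spin", "depth"),
                                     names(poses))],
    adaptation_trace = p$adaptation_trace)
  res
}

#' Export the union of feasible corridors as an overlay volume
#'
#' Writes a binary label volume on the input grid marking every voxel swept
#' by at least one feasible corridor (optionally only the top-ranked `k`).
#' Zero feasible poses give an all-zero overlay.
#'
#' @param result A `feasibility_result`.
#' @param vol The [label_volume()] the result was computed on.
#' @param path Output path (`.nii`, `.nii.gz` or `.nrrd`); `NULL` skips
#'   writing and just returns the overlay volume.
#' @param top_k Number of ranked paths to include; `Inf` (default) exports
#'   the union over all feasible poses.
#' @return The overlay [label_volume()] (labels 0/1), invisibly when
#'   written to file.
#' @export
export_path_mask <- function(result, vol, path = NULL, top_k = Inf) {
  stopifnot(inherits(result, "feasibility_result"))
  assert_volume(vol)
  mask <- array(0L, dim = dim(vol$labels))
  poses <- result$feasible_poses
  if (nrow(poses) > 0L) {
    geoms <- dplyr::distinct(poses[c("rx", "ry", "rz", "depth")])
    if (is.finite(top_k)) {
      ranked <- rank_paths(result, vol)
      geoms <- utils::head(dplyr::distinct(ranked[c("rx", "ry", "rz", "depth")]),
                           top_k)
    }
    geoms$spin <- 0
    tool <- tool_spec(result$tool_diameter_used)
    corr <- pose_corridors(geoms[c("rx", "ry", "rz", "spin", "depth")],
                           result$anchor, tool, vol, on_oob = "flag")
    for (r in seq_len(nrow(corr))) {
      vox <- rasterize_corridor(vol, corr[r, ])
      if (nrow(vox)) mask[cbind(vox$i, vox$j, vox$k)] <- 1L
    }
  }
  overlay <- label_volume(mask, spacing = vol$spacing, origin = vol$origin,
                          orientation = vol$orientation)
  if (!is.null(path)) {
    write_labelmap(overlay, path)
    return(invisible(overlay))
  }
  overlay
}

#' Feasibility sweep over microdrill diameters
#'
#' Runs [search_paths()] at each diameter and tabulates the feasible-path
#' count and fraction, the drill-size curve used to compare species or
#' candidate tools.
#'
#' @inheritParams search_paths
#' @param diameters Numeric vector of head diameters (mm) to test.
#' @return A tibble with columns `diameter`, `n_feasible`, `n_poses_total`,
#'   `feasible_fraction`; class `feasibility_sweep`.
#' @export
sweep_diameters <- function(vol, diameters, grid, scheme = label_scheme(),
                            anchor = target_anchor(vol, scheme),
                            method = c("fast", "bruteforce")) {
  method <- match.arg(method)
  rows <- lapply(diameters, function(d) {
    res <- search_paths(vol, tool_spec(d), grid, scheme = scheme,
                        anchor = anchor, method = method)
    tibble(diameter = d, n_feasible = res$n_feasible,
           n_poses_total = res$n_poses_total,
           feasible_fraction = res$feasible_fraction)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("feasibility_sweep", class(out))
  out
}

# ---- flat configuration files ---------------------------------------------

#' Read a flat `key = value` plan configuration
#'
#' Parses the plain-text configuration format used by the command-line
#' driver: one `key = value` pair per line, `#` comments, degrees and mm
#' throughout.  Unknown keys are an error.  Recognized keys: `input`,
#' `output_dir`, `head_diameter`, `shaft_diameter`, `min_diameter`,
#' `decrement`, `rot_step`, `rot_range`, `spin_step`, `spin_range`,
#' `travel_step`, `travel_range`, `label_air`, `label_surgical`,
#' `label_non_surgical`, `label_target`, `adapt`, `resample`,
#' `target_spacing`, `export_overlay`, `top_k`, `outward`.
#'
#' @param path Path to the configuration file.
#' @param overrides Named list applied on top of the file values (used by
#'   the CLI's flag overrides).
#' @return A named list of class `plan_config`.
#' @export
read_plan_config <- function(path, overrides = list()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop(sprintf("cannot parse config line: '%s'", lines[bad][1]))
  cfg <- setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, "", 1L))
  plan_config(utils::modifyList(cfg, overrides))
}

#' @rdname read_plan_config
#' @param cfg Named list of raw configuration values.
#' @export
plan_config <- function(cfg = list()) {
  known_num <- c("head_diameter", "shaft_diameter", "min_diameter", "decrement",
                 "rot_step", "rot_range", "spin_step", "spin_range",
                 "travel_step", "travel_range", "target_spacing", "top_k",
                 "label_air", "label_surgical", "label_non_surgical",
                 "label_target")
  known_chr <- c("input", "output_dir", "outward")
  known_lgl <- c("adapt", "resample", "export_overlay")
  unknown <- setdiff(names(cfg), c(known_num, known_chr, known_lgl))
  if (length(unknown)) stop(sprintf("unknown config key(s): %s",
                                    paste(unknown, collapse = ", ")))
  for (k in intersect(names(cfg), known_num)) cfg[[k]] <- as.numeric(cfg[[k]])
  for (k in intersect(names(cfg), known_lgl)) {
    cfg[[k]] <- tolower(as.character(cfg[[k]])) %in% c("true", "1", "yes", "on")
  }
  defaults <- list(head_diameter = 2.9, min_diameter = 1, decrement = 0.5,
                   rot_step = 5, rot_range = 180, spin_step = 5,
                   spin_range = 360, travel_step = 1, travel_range = 15,
                   label_air = 0, label_surgical = 1, label_non_surgical = 2,
                   label_target = 3, adapt = TRUE, resample = TRUE,
                   export_overlay = FALSE, top_k = Inf, outward = "0,1,0",
                   output_dir = ".")
  cfg <- utils::modifyList(defaults, cfg)
  if (is.null(cfg$shaft_diameter)) cfg$shaft_diameter <- cfg$head_diameter
  structure(cfg, class = "plan_config")
}

#' Run a full surgical-path plan
#'
#' End-to-end driver: load the label volume, validate it against the
#' scheme, resample to an isotropic grid, locate the target anchor, search
#' (with automatic drill-size adaptation if enabled), rank the feasible
#' paths, and write the JSON report plus optional corridor overlay into the
#' output directory.
#'
#' @param cfg A `plan_config` (see [read_plan_config()]), or a named list
#'   accepted by [plan_config()].
#' @param vol Optional preloaded [label_volume()]; when given, `cfg$input`
#'   is not read.
#' @return A list with elements `result` (the `feasibility_result`),
#'   `ranked` (the ranked pose tibble), `report` (path of the written JSON)
#'   and `status` (0 when at least one feasible path exists, 2 when
#'   infeasible at the floor diameter).
#' @export
run_plan <- function(cfg, vol = NULL) {
  if (!inherits(cfg, "plan_config")) cfg <- plan_config(cfg)
  scheme <- label_scheme(cfg$label_air, cfg$label_surgical,
                         cfg$label_non_surgical, cfg$label_target)
  if (is.null(vol)) {
    if (is.null(cfg$input)) stop("config must name an `input` volume")
    vol <- read_labelmap(cfg$input, scheme)
  }
  if (isTRUE(cfg$resample)) {
    t <- if (!is.null(cfg$target_spacing)) cfg$target_spacing else min(vol$spacing)
    vol <- resample_isotropic(vol, t)
  }
  outward <- as.numeric(strsplit(cfg$outward, ",")[[1]])
  anc <- target_anchor(vol, scheme, outward = outward)
  tool <- tool_spec(cfg$head_diameter, cfg$shaft_diameter, cfg$min_diameter,
                    cfg$decrement)
  grid <- search_grid(cfg$rot_step, cfg$rot_range, cfg$spin_step,
                      cfg$spin_range, cfg$travel_step, cfg$travel_range)
  res <- if (isTRUE(cfg$adapt)) {
    adapt_tool_size(vol, tool, grid, scheme = scheme, anchor = anc)
  } else {
    search_paths(vol, tool, grid, scheme = scheme, anchor = anc)
  }
  ranked <- rank_paths(res, vol)
  if (!dir.exists(cfg$output_dir)) dir.create(cfg$output_dir, recursive = TRUE)
  report_path <- file.path(cfg$output_dir, "plan_report.json")
  write_report(res, report_path, ranked = ranked)
  if (isTRUE(cfg$export_overlay)) {
    export_path_mask(res, vol, file.path(cfg$output_dir, "feasible_corridors.nii.gz"),
                     top_k = cfg$top_k)
  }
  list(result = res, ranked = ranked, report = report_path,
       status = if (res$feasible) 0L else 2L)
}
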