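#' Synthetic skull-phantom specification
#'
#' Parameters of the analytic segmented-skull phantoms used to exercise the
#' planner without CT data.  A phantom is a solid non-surgical block pierced
#' by a straight open channel (the surrogate trans-sphenoidal corridor) that
#' terminates in a marked target slab, surrounded by open air, optionally
#' with additional non-surgical obstacle bodies (orbit pair, anterior slab).
#' Every voxel is classified analytically by its center (closed-form solid
#' membership), so each fixture has an exact geometric oracle; optional
#' seeded jitter roughens the channel wall after classification.
#'
#' @param shape Integer length-3 grid dimensions.  Even transverse
#'   dimensions put the channel axis midway between voxel centers, which
#'   keeps the discretized channel width symmetric.
#' @param spacing Voxel size in mm; scalar (isotropic) or length-3.
#' @param channel_width Open channel diameter in mm (e.g. 13 for a
#'   goat-like sphenoid corridor, 2.5 for a macaque-like one).
#' @param channel_axis Grid axis the channel runs along: `"x"`, `"y"`
#'   (default, the anatomical anterior axis) or `"z"`.
#' @param block_extent Thickness of the non-surgical block along the
#'   channel axis, mm.  Defaults to 18 so the block outlasts the default
#'   15 mm travel range.
#' @param target_extent Length of the target slab at the channel's far
#'   (posterior) end, mm.
#' @param posterior_margin Extent of the posterior compartment behind the
#'   block, mm: solid bone enclosing a blind cavity (see `cavity_depth`).
#' @param cavity_depth Depth (mm) of the blind canal-like recess carved
#'   into the posterior bone directly behind the target slab, coaxial with
#'   the channel.  It gives the capsule's hemispherical tip cap room at
#'   target contact without opening a through-route out of the back of the
#'   volume.  Defaults to `channel_width / 2 + 1.5` so drills up to roughly
#'   the channel width keep tip clearance; must leave at least one voxel of
#'   bone behind it (`cavity_depth < posterior_margin`).
#' @param obstacle_specs List of obstacle bodies for
#'   [generate_skull_phantom()]; each element is a list with `type`
#'   (`"box"` or `"ellipsoid"`), `center` (world mm) and `half`
#'   (half-extents mm).
#' @param jitter Amplitude (mm) of seeded random roughening of the channel
#'   wall; 0 gives the exact analytic geometry.
#' @param seed Integer seed for the jitter; the same spec and seed always
#'   produce a voxel-identical phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, spacing, channel_width, channel_axis = "y",
                         block_extent = 18, target_extent = 1,
                         posterior_margin = channel_width / 2 + 2,
                         cavity_depth = channel_width / 2 + 1.5,
                         obstacle_specs = list(),
                         jitter = 0, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L)) stop("`shape` must be 3 dimensions >= 4")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("`spacing` must be positive")
  ax <- match(match.arg(channel_axis, c("x", "y", "z")), c("x", "y", "z"))
  if (channel_width <= 0) stop("`channel_width` must be > 0")
  tr <- setdiff(1:3, ax)
  if (channel_width >= min((shape[tr] - 1) * spacing[tr])) {
    stop("channel wider than block: `channel_width` must be smaller than the transverse extent")
  }
  if (target_extent <= 0) stop("`target_extent` must be > 0")
  if (block_extent <= target_extent) stop("`block_extent` must exceed `target_extent`")
  extent_ax <- shape[ax] * spacing[ax]
  if (posterior_margin + block_extent >= extent_ax) {
    stop("target would fall outside grid: block + margin exceed the volume extent")
  }
  if (cavity_depth < 0) stop("`cavity_depth` must be >= 0")
  if (cavity_depth >= posterior_margin) {
    stop("`cavity_depth` must leave bone behind it: increase `posterior_margin`")
  }
  if (jitter < 0) stop("`jitter` must be >= 0")
  structure(list(shape = shape, spacing = spacing,
                 channel_width = as.numeric(channel_width), channel_axis = ax,
                 block_extent = as.numeric(block_extent),
                 target_extent = as.numeric(target_extent),
                 posterior_margin = as.numeric(posterior_margin),
                 cavity_depth = as.numeric(cavity_depth),
                 obstacle_specs = obstacle_specs,
                 jitter = as.numeric(jitter), seed = as.integer(seed)),
            class = "phantom_spec")
}

# run expr with a local RNG state so package code never disturbs the
# caller's random stream
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a straight-channel phantom
#'
#' Builds the basic fixture: a non-surgical block spanning the transverse
#' extent of the volume, pierced along the channel axis by a straight open
#' channel of the requested width (labeled surgical space) whose posterior
#' end is a target slab.  Behind the block lies solid posterior bone with a
#' blind canal-like recess behind the target (so the drill's hemispherical
#' tip has room at contact but no path leads out of the back); anterior of
#' the block is the open air vestibule.  Deterministic given the spec's
#' seed.
#'
#' @param spec A [phantom_spec()].
#' @param scheme A [label_scheme()] giving the integer labels to emit.
#' @return A [label_volume()].
#' @examples
#' ph <- generate_channel_phantom(phantom_spec(
#'   shape = c(24, 36, 24), spacing = 0.5, channel_width = 5,
#'   block_extent = 8))
#' table(ph$labels)
#' @export
generate_channel_phantom <- function(spec, scheme = label_scheme()) {
  stopifnot(inherits(spec, "phantom_spec"))
  assert_scheme(scheme)
  d <- spec$shape
  sp <- spec$spacing
  ax <- spec$channel_axis
  tr <- setdiff(1:3, ax)

  # world coordinates per axis (origin at 0; voxel-center convention)
  w <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * sp[a])
  center_tr <- vapply(tr, function(a) (d[a] - 1) * sp[a] / 2, numeric(1))

  a_lo <- -sp[ax] / 2                       # physical start of the volume
  y0 <- a_lo + spec$posterior_margin        # block posterior face
  y1 <- y0 + spec$block_extent              # block anterior face

  in_block_1d <- w[[ax]] >= y0 & w[[ax]] < y1
  in_target_1d <- w[[ax]] >= y0 & w[[ax]] < y0 + spec$target_extent
  in_post_1d <- w[[ax]] < y0                # posterior bone compartment
  in_cavity_1d <- w[[ax]] >= y0 - spec$cavity_depth & w[[ax]] < y0

  # transverse radial distance from the channel axis, as a 2D field
  r2d <- outer((w[[tr[1]]] - center_tr[1])^2, (w[[tr[2]]] - center_tr[2])^2, "+")
  rad <- sqrt(r2d)

  half_w <- spec$channel_width / 2
  if (spec$jitter > 0) {
    thresh <- with_local_seed(spec$seed, {
      eps <- array(stats::runif(length(rad) * sum(in_block_1d),
                                -spec$jitter, spec$jitter),
                   dim = c(dim(rad), sum(in_block_1d)))
      eps + half_w
    })
  }

  labels <- array(scheme$air, dim = d)
  # posterior bone with the blind recess behind the target (analytic wall,
  # never jittered: the recess is a clearance pocket, not a corridor wall)
  for (j in which(in_post_1d)) {
    open <- if (in_cavity_1d[j]) rad <= half_w else rad < 0
    slice <- ifelse(open, scheme$surgical, scheme$non_surgical)
    labels <- assign_slice(labels, ax, j, slice)
  }
  blk_idx <- which(in_block_1d)
  jslice <- 0L
  for (j in blk_idx) {
    jslice <- jslice + 1L
    th <- if (spec$jitter > 0) thresh[, , jslice] else half_w
    open <- rad <= th
    slice <- ifelse(open,
                    if (in_target_1d[j]) scheme$target else scheme$surgical,
                    scheme$non_surgical)
    labels <- assign_slice(labels, ax, j, slice)
  }
  label_volume(labels, spacing = sp, origin = c(0, 0, 0))
}

# write a 2D transverse slice into the 3D label array along axis `ax`
assign_slice <- function(labels, ax, j, slice) {
  if (ax == 1L) labels[j, , ] <- slice
  else if (ax == 2L) labels[, j, ] <- slice
  else labels[, , j] <- slice
  labels
}

#' Generate a skull phantom with obstacle bodies
#'
#' The channel phantom of [generate_channel_phantom()] plus the spec's
#' obstacle bodies (e.g. an orbit pair flanking the corridor, or an anterior
#' slab blocking it), each labeled non-surgical.  Obstacles overwrite air
#' and surgical-space voxels but never the target; it is an error if an
#' obstacle erases the entire channel.
#'
#' @inheritParams generate_channel_phantom
#' @return A [label_volume()].
#' @export
generate_skull_phantom <- function(spec, scheme = label_scheme()) {
  vol <- generate_channel_phantom(spec, scheme)
  if (length(spec$obstacle_specs) == 0L) return(vol)
  d <- spec$shape
  w <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * spec$spacing[a])
  labels <- vol$labels
  for (ob in spec$obstacle_specs) {
    type <- ob$type %||% "box"
    ctr <- as.numeric(ob$center)
    half <- as.numeric(ob$half)
    stopifnot(length(ctr) == 3L, length(half) == 3L, all(half > 0))
    inside_1d <- lapply(1:3, function(a) abs(w[[a]] - ctr[a]) <= half[a])
    if (type == "box") {
      member <- outer(outer(inside_1d[[1]], inside_1d[[2]], "&"), inside_1d[[3]], "&")
    } else if (type == "ellipsoid") {
      q <- lapply(1:3, function(a) ((w[[a]] - ctr[a]) / half[a])^2)
      member <- outer(outer(q[[1]], q[[2]], "+"), q[[3]], "+") <= 1
    } else {
      stop(sprintf("unknown obstacle type '%s'", type))
    }
    overwrite <- member & labels != scheme$target
    labels[overwrite] <- scheme$non_surgical
  }
  if (!any(labels == scheme$surgical)) {
    stop("obstacle erases the entire channel: no surgical-space voxels remain")
  }
  label_volume(labels, spacing = vol$spacing, origin = vol$origin)
}

#' Measure the open channel width of a phantom
#'
#' Instrumental check on generated fixtures: at the mid-channel transverse
#' cross-section, the inscribed-disc diameter is twice the largest in-plane
#' distance from a surgical-space voxel center to the nearest non-surgical
#' voxel center, plus one in-plane voxel (the nearest forbidden center sits
#' about half a voxel beyond the wall surface on each side).  Recovers the
#' generator's `channel_width` to within about one voxel.
#'
#' @param vol A [label_volume()] containing a channel.
#' @param scheme A [label_scheme()].
#' @param channel_axis Axis the channel runs along (`"x"`, `"y"` or `"z"`).
#' @return Channel width in mm.
#' @export
measure_channel_width <- function(vol, scheme = label_scheme(), channel_axis = "y") {
  assert_volume(vol)
  ax <- match(match.arg(channel_axis, c("x", "y", "z")), c("x", "y", "z"))
  tr <- setdiff(1:3, ax)
  surg <- vol$labels == scheme$surgical
  if (!any(surg)) stop("no channel: volume has no surgical-space voxels")
  forb <- vol$labels == scheme$non_surgical
  slice_has <- function(m, j) {
    s <- slice_along(m, ax, j)
    any(s)
  }
  d <- dim(vol$labels)
  cand <- which(vapply(seq_len(d[ax]), function(j) {
    slice_has(surg, j) && slice_has(forb, j)
  }, logical(1)))
  if (length(cand) == 0L) stop("no channel: no cross-section holds both channel and wall")
  j <- cand[ceiling(length(cand) / 2)]
  fs <- slice_along(forb, ax, j)
  ss <- slice_along(surg, ax, j)
  d2 <- dim(fs)
  dist <- array(edt3d_cpp(array(fs, dim = c(d2, 1L)), c(d2, 1L),
                          c(vol$spacing[tr], 1)), dim = d2)
  2 * max(dist[ss]) + mean(vol$spacing[tr])
}

slice_along <- function(m, ax, j) {
  if (ax == 1L) m[j, , ]
  else if (ax == 2L) m[, j, ]
  else m[, , j]
}

#' Phantom presets mirroring the planner's study species
#'
#' Ready-made [phantom_spec()]s for the four fixture families used
#' throughout the tests and documentation:
#'
#' * `"goat"` — a wide (13 mm) trans-sphenoidal channel at 0.65 mm voxels;
#'   a conventional 2.9 mm microdrill passes easily.
#' * `"macaque"` — a narrow (2.5 mm) channel; a 2.9 mm drill cannot pass
#'   and size adaptation must drop to 2.4 mm.  Sampled at 0.25 mm voxels so
#'   the 0.4 mm interference is resolvable on the grid.
#' * `"blocked"` — the goat geometry with an anterior slab fully crossing
#'   the corridor (a frontal-cortex-like obstruction); no path is feasible
#'   at any pose.
#' * `"orbit"` — the goat geometry flanked by a pair of orbit-like boxes
#'   placed clear of every corridor that threads the channel.
#'
#' @param name Preset name.
#' @param shape Optional override of the grid dimensions.
#' @param jitter,seed Passed to [phantom_spec()].
#' @return A [phantom_spec()].
#' @examples
#' ph <- generate_skull_phantom(phantom_preset("goat"))
#' measure_channel_width(ph)
#' @export
phantom_preset <- function(name = c("goat", "macaque", "blocked", "orbit"),
                           shape = NULL, jitter = 0, seed = 1L) {
  name <- match.arg(name)
  base <- switch(name,
    goat = ,
    blocked = ,
    orbit = list(shape = c(48L, 64L, 40L), spacing = 0.65, channel_width = 13,
                 block_extent = 18, target_extent = 1.3, posterior_margin = 9.1),
    macaque = list(shape = c(40L, 104L, 40L), spacing = 0.25, channel_width = 2.5,
                   block_extent = 18, target_extent = 1, posterior_margin = 3.25)
  )
  if (!is.null(shape)) base$shape <- shape
  sp <- base$spacing
  dims <- base$shape
  y1 <- -sp / 2 + base$posterior_margin + base$block_extent
  ymax <- dims[2] * sp
  cx <- (dims[1] - 1) * sp / 2
  cz <- (dims[3] - 1) * sp / 2
  obstacles <- switch(name,
    blocked = list(list(type = "box",
                        center = c(cx, y1 + 3, cz),
                        half = c(dims[1] * sp, 1, dims[3] * sp))),
    orbit = {
      off <- base$channel_width / 2 + 1.45 + 4 + 2.5   # clear of threaded corridors
      vest_mid <- min(y1 + 6, (y1 + ymax) / 2)
      list(
        list(type = "ellipsoid", center = c(cx - off, vest_mid, cz), half = c(2.5, 3, 3)),
        list(type = "ellipsoid", center = c(cx + off, vest_mid, cz), half = c(2.5, 3, 3))
      )
    },
    list()
  )
  phantom_spec(shape = base$shape, spacing = base$spacing,
               channel_width = base$channel_width, channel_axis = "y",
               block_extent = base$block_extent,
               target_extent = base$target_extent,
               posterior_margin = base$posterior_margin,
               obstacle_specs = obstacles, jitter = jitter, seed = seed)
}
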