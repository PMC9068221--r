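test_that("pose counts follow the closed-form product, checked by materialization", {
  cases <- list(
    list(g = search_grid(rot_step = 45, spin_step = 90, travel_step = 5), n = 4^3 * 4 * 3),
    list(g = search_grid(rot_step = 15, spin_step = 30, travel_step = 5), n = 12^3 * 12 * 3),
    list(g = search_grid(rot_step = 60, spin_step = 360, travel_step = 15), n = 3^3),
    list(g = search_grid(rot_step = 180, rot_range = 180, spin_step = 360,
                         travel_step = 15), n = 1)
  )
  for (cs in cases) {
    expect_equal(n_poses(cs$g), cs$n)
    expect_equal(nrow(enumerate_poses(cs$g)), cs$n)
  }
})

test_that("a grid whose ranges equal its steps contains only the zero pose", {
  g <- search_grid(rot_step = 180, rot_range = 180, spin_step = 360,
                   spin_range = 360, travel_step = 15, travel_range = 15)
  p <- enumerate_poses(g)
  expect_equal(nrow(p), 1)
  # centered half-open rotation grid starts at -range/2
  expect_equal(unname(unlist(p[1, ])), c(-90, -90, -90, 0, 0))
})

test_that("ranges that are not multiples of their steps are rejected", {
  expect_error(search_grid(rot_step = 7), "not an integer multiple")
  expect_error(search_grid(travel_step = 4), "not an integer multiple")
})

test_that("pose enumeration is lexicographic in (rx, ry, rz, spin, depth)", {
  p <- enumerate_poses(search_grid(rot_step = 90, spin_step = 180, travel_step = 5))
  key <- order(p$rx, p$ry, p$rz, p$spin, p$depth)
  expect_identical(key, seq_len(nrow(p)))
  # half-open intervals: max rotation stays strictly below +range/2
  expect_lt(max(p$rx), 90)
  expect_gte(min(p$rx), -90)
  expect_lt(max(p$spin), 360)
  expect_lt(max(p$depth), 15)
})

test_that("the target anchor is the centroid of target voxel centers", {
  arr <- array(0L, c(12, 12, 12))
  arr[6, 8, 4] <- 3L
  vol <- label_volume(arr, spacing = c(2, 2.5, 10), origin = c(0, 0, -10))
  a <- target_anchor(vol)
  expect_equal(a$point, c(10, 17.5, 20))

  arr2 <- array(0L, c(8, 8, 8))
  arr2[3, 3, 3] <- 3L
  arr2[3, 3, 5] <- 3L
  vol2 <- label_volume(arr2, spacing = c(1, 1, 1))
  expect_equal(target_anchor(vol2)$point, c(2, 2, 3))

  expect_error(target_anchor(label_volume(array(0L, c(4, 4, 4)), c(1, 1, 1))),
               "empty target")
})

test_that("the phantom target slab centroid sits on the channel axis", {
  ph <- channel_fixture(5, 0.5)
  a <- target_anchor(ph)
  sch <- label_scheme()
  idx <- which(ph$labels == sch$target, arr.ind = TRUE)
  pts <- sweep(sweep(idx - 1, 2, ph$spacing, "*"), 2, ph$origin, "+")
  expect_equal(a$point, unname(colMeans(pts)))
  d <- dim(ph$labels)
  expect_equal(a$point[c(1, 3)],
               c((d[1] - 1) * ph$spacing[1] / 2, (d[3] - 1) * ph$spacing[3] / 2),
               tolerance = 1e-9)
})

test_that("pose-to-corridor geometry follows the documented conventions", {
  vol <- label_volume(array(0L, c(40, 40, 40)), spacing = c(1, 1, 1))
  anc <- anchor(c(19.5, 10, 19.5), outward = c(0, 1, 0))
  tool <- tool_spec(2.9)

  zero <- pose_corridors(tibble::tibble(rx = 0, ry = 0, rz = 0, spin = 0, depth = 0),
                         anc, tool, vol)
  expect_equal(c(zero$axis_x, zero$axis_y, zero$axis_z), anc$outward)
  expect_equal(c(zero$tip_x, zero$tip_y, zero$tip_z), anc$point)
  expect_equal(zero$radius, 1.45)
  # corridor runs to the +y face of the physical box (hi = 39 + half voxel)
  expect_equal(zero$length, 39.5 - 10)

  quarter <- pose_corridors(tibble::tibble(rx = 0, ry = 0, rz = 90, spin = 0, depth = 0),
                            anc, tool, vol)
  expect_equal(c(quarter$axis_x, quarter$axis_y, quarter$axis_z), c(-1, 0, 0),
               tolerance = 1e-12)

  deep <- pose_corridors(tibble::tibble(rx = 0, ry = 0, rz = 0, spin = 0, depth = 5),
                         anc, tool, vol)
  expect_equal(c(deep$tip_x, deep$tip_y, deep$tip_z), anc$point + 5 * anc$outward)

  # axes stay unit-norm over a sweep of poses
  p <- enumerate_poses(search_grid(rot_step = 15, spin_step = 360, travel_step = 15))
  cr <- pose_corridors(p, anc, tool, vol)
  nrm <- sqrt(cr$axis_x^2 + cr$axis_y^2 + cr$axis_z^2)
  expect_lt(max(abs(nrm - 1)), 1e-9)
})

test_that("poses that lift the tip outside the volume are flagged or error", {
  vol <- label_volume(array(0L, c(10, 10, 10)), spacing = c(1, 1, 1))
  anc <- anchor(c(4.5, 8, 4.5), outward = c(0, 1, 0))
  p <- tibble::tibble(rx = 0, ry = 0, rz = 0, spin = 0, depth = 5)
  flagged <- pose_corridors(p, anc, tool_spec(1), vol)
  expect_false(flagged$in_bounds)
  expect_error(pose_corridors(p, anc, tool_spec(1), vol, on_oob = "error"),
               "tip out of volume")
})

test_that("capsule rasterization matches the exhaustive voxel-center oracle", {
  vol <- label_volume(array(0L, c(9, 9, 9)), spacing = c(1, 1, 1))

  # on-axis segment, radius 0.5: only the five on-axis centers qualify
  cr <- corridor_row(c(0, 0, 0), c(0, 0, 1), 4, 0.5)
  vox <- rasterize_corridor(vol, cr)
  expect_equal(nrow(vox), 5)
  expect_equal(vox$i, rep(1, 5))
  expect_equal(vox$k, 1:5)

  # radius 1 adds the 4-neighborhood at each level; compare to the oracle
  cr2 <- corridor_row(c(0, 0, 0), c(0, 0, 1), 4, 1)
  vox2 <- as.matrix(rasterize_corridor(vol, cr2))
  expect_equal(unname(vox2), unname(oracle_capsule_voxels(vol, c(0, 0, 0), c(0, 0, 1), 4, 1)))

  # radius too small to reach any off-lattice center: empty set
  cr3 <- corridor_row(c(0.5, 0.5, 0.5), c(0, 0, 1), 4, 0.2)
  expect_equal(nrow(rasterize_corridor(vol, cr3)), 0)
})

test_that("rasterization equals the oracle for random oblique capsules", {
  vol <- label_volume(array(0L, c(14, 12, 10)), spacing = c(0.7, 1, 1.3),
                      origin = c(-2, 0, 1))
  corrs <- random_corridors(vol, 12, radius = 1.6, seed = 42)
  for (r in seq_len(nrow(corrs))) {
    cr <- corrs[r, ]
    got <- as.matrix(rasterize_corridor(vol, cr))
    want <- oracle_capsule_voxels(vol, c(cr$tip_x, cr$tip_y, cr$tip_z),
                                  c(cr$axis_x, cr$axis_y, cr$axis_z),
                                  cr$length, cr$radius)
    expect_equal(unname(got), unname(want))
  }
})

test_that("capsule membership is monotone in radius", {
  vol <- label_volume(array(0L, c(12, 12, 12)), spacing = c(1, 1, 1))
  cr <- function(r) corridor_row(c(3.2, 2.1, 4.7), c(1, 2, 0.5), 8, r)
  key <- function(v) paste(v$i, v$j, v$k)
  prev <- character(0)
  for (r in c(0.4, 0.9, 1.7, 2.6)) {
    cur <- key(rasterize_corridor(vol, cr(r)))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})
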