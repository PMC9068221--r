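test_that("phantom generation is deterministic under a fixed seed", {
  spec <- phantom_spec(shape = c(24, 40, 24), spacing = 0.5, channel_width = 5,
                       block_extent = 8, jitter = 0.4, seed = 99)
  a <- generate_channel_phantom(spec)
  b <- generate_channel_phantom(spec)
  expect_identical(a$labels, b$labels)
})

test_that("distinct seeds differ only in jittered channel-boundary voxels", {
  mk <- function(seed, jitter) generate_channel_phantom(
    phantom_spec(shape = c(24, 40, 24), spacing = 0.5, channel_width = 5,
                 block_extent = 8, jitter = jitter, seed = seed))
  a <- mk(1, 0.4)
  b <- mk(2, 0.4)
  delta <- which(a$labels != b$labels, arr.ind = TRUE)
  expect_gt(nrow(delta), 0)
  # every differing voxel lies within `jitter` of the analytic channel wall
  ctr <- (dim(a$labels)[c(1, 3)] - 1) * a$spacing[c(1, 3)] / 2
  r <- sqrt(((delta[, 1] - 1) * a$spacing[1] - ctr[1])^2 +
            ((delta[, 3] - 1) * a$spacing[3] - ctr[2])^2)
  expect_true(all(abs(r - 2.5) <= 0.4 + 1e-9))

  # jitter 0 reproduces the analytic geometry regardless of seed
  expect_identical(mk(1, 0)$labels, mk(2, 0)$labels)
})

test_that("every voxel carries exactly one of the four role labels", {
  for (nm in c("goat", "macaque", "blocked", "orbit")) {
    ph <- generate_skull_phantom(phantom_preset(nm))
    expect_true(all(ph$labels %in% 0:3), label = nm)
    expect_gt(sum(ph$labels == 3L), 0)   # target present for planning
    expect_gt(sum(ph$labels == 1L), 0)
  }
})

test_that("the measured channel width recovers the requested width", {
  for (case in list(c(1.5, 0.25), c(2.5, 0.25), c(5, 0.5), c(13, 0.65))) {
    ph <- channel_fixture(case[1], case[2])
    got <- measure_channel_width(ph)
    expect_lt(abs(got - case[1]), case[2] + 1e-9,
              label = sprintf("width %.1f at %.2f mm voxels (got %.3f)",
                              case[1], case[2], got))
  }
})

test_that("the measured width is stable under isotropic resampling", {
  spec <- phantom_spec(shape = c(28, 40, 28), spacing = c(0.5, 1, 0.5),
                       channel_width = 6, block_extent = 8)
  ph <- generate_channel_phantom(spec)
  iso <- resample_isotropic(ph, 0.5)
  expect_lt(abs(measure_channel_width(ph) - measure_channel_width(iso)), 0.5 + 1e-9)
})

test_that("width measurement rejects volumes without a channel", {
  expect_error(measure_channel_width(label_volume(array(0L, c(6, 6, 6)), c(1, 1, 1))),
               "no channel")
})

test_that("obstacle-free skull phantoms reduce to channel phantoms", {
  spec <- phantom_spec(shape = c(24, 40, 24), spacing = 0.5, channel_width = 5,
                       block_extent = 8)
  expect_identical(generate_skull_phantom(spec)$labels,
                   generate_channel_phantom(spec)$labels)
})

test_that("an obstacle that swallows the whole channel is an error", {
  spec <- phantom_spec(shape = c(24, 40, 24), spacing = 0.5, channel_width = 5,
                       block_extent = 8,
                       obstacle_specs = list(list(type = "box",
                                                  center = c(5.75, 10, 5.75),
                                                  half = c(50, 50, 50))))
  expect_error(generate_skull_phantom(spec), "erases the entire channel")
})

test_that("a slab across the vestibule blocks every surgical path", {
  blk <- generate_skull_phantom(phantom_preset("blocked"))
  res <- search_paths(blk, tool_spec(2.9),
                      coarse_grid(rot_step = 45, spin_step = 180,
                                  travel_step = 5, travel_range = 5))
  expect_equal(res$n_feasible, 0)
})

test_that("well-cleared lateral orbits leave the feasible count unchanged", {
  gr <- coarse_grid(rot_step = 45, spin_step = 180, travel_step = 5,
                    travel_range = 5)
  base <- search_paths(generate_skull_phantom(phantom_preset("goat")),
                       tool_spec(2.9), gr)
  orb <- search_paths(generate_skull_phantom(phantom_preset("orbit")),
                      tool_spec(2.9), gr)
  expect_equal(orb$n_feasible, base$n_feasible)
  expect_identical(tidy(orb), tidy(base))
})

test_that("feasibility flips from present to absent across the channel width", {
  # transition window no wider than two voxels around the channel width
  s <- 0.5
  ph <- channel_fixture(5, s)
  gr <- coarse_grid(rot_step = 90, spin_step = 360, travel_step = 5,
                    travel_range = 5)
  below <- search_paths(ph, tool_spec(5 - 2 * s), gr)
  above <- search_paths(ph, tool_spec(5 + 2 * s), gr)
  expect_gt(below$n_feasible, 0)
  expect_equal(above$n_feasible, 0)
})
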