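test_that("unbranched tree generation is seeded and stays in bounds", {
  spec <- phantom_spec(shape = c(64, 64, 64), n_trees = 1, branch_prob = 0,
                       seed = 7)
  tr1 <- generate_tree(spec)
  tr2 <- generate_tree(spec)
  expect_identical(tr1, tr2)
  expect_length(tr1$polylines, 1)
  expect_equal(tree_bifurcations(tr1), 0)
})

test_that("branching walk produces a large in-bounds tree", {
  spec <- phantom_spec(shape = c(160, 160, 160), n_trees = 1,
                       branch_prob = 0.2, step_len_um = 4, n_steps = 200,
                       tortuosity = 0.12, seed = 3)
  tr <- generate_tree(spec)
  pts <- do.call(rbind, lapply(tr$polylines, `[[`, "pts"))
  expect_gte(nrow(pts), 200)
  expect_true(all(pts >= 0 & pts <= rep(spec$shape - 1, each = nrow(pts))))
  # radii never increase from root to tip within a polyline
  for (pl in tr$polylines)
    expect_true(all(diff(pl$radius_um) <= 0))
  expect_gt(tree_bifurcations(tr), 0)
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(shape = c(16, 64, 64)), "shape")
  expect_error(phantom_spec(n_trees = 0), "n_trees")
  expect_error(phantom_spec(intensity_large = 100, intensity_small = 150),
               "intensity")
  expect_error(phantom_spec(radius_range_um = c(0.2, 10)), "radius")
})

test_that("rasterized solid cylinder matches its analytic volume", {
  spec <- phantom_spec(shape = c(64, 64, 64), n_trees = 1, psf_sigma_um = 0,
                       seed = 1)
  tr <- straight_tree(spec, c(5, 32, 32), c(54, 32, 32), radius_um = 3)
  ras <- rasterize(tr, spec)
  analytic <- pi * 3^2 * 50
  expect_lt(abs(sum(ras$truth$voxels) - analytic) / analytic, 0.15)
  expect_true(all(ras$truth$voxels %in% c(0L, 1L)))
})

test_that("hollow vessels have dark lumens and bright walls", {
  spec <- phantom_spec(shape = c(64, 64, 64), n_trees = 1, psf_sigma_um = 0.7,
                       seed = 1)
  tr <- straight_tree(spec, c(5, 32, 32), c(58, 32, 32), radius_um = 10)
  ras <- rasterize(tr, spec)
  img <- ras$image$voxels
  axis_vals <- img[20:40, 32, 32]
  shell <- img[20:40, 32 + 9, 32]  # one voxel inside the r=10 wall
  expect_lt(mean(axis_vals), mean(shell))
  # truth includes the lumen
  expect_equal(ras$truth$voxels[30, 32, 32], 1L)
})

test_that("solid-vessel foreground is inside the truth mask", {
  spec <- phantom_spec(shape = c(64, 64, 64), n_trees = 1, psf_sigma_um = 0,
                       seed = 2)
  tr <- straight_tree(spec, c(10, 20, 20), c(50, 40, 44), radius_um = 3)
  ras <- rasterize(tr, spec)
  fg <- ras$image$voxels > (spec$intensity_small - spec$background_mean) / 2
  expect_true(all(ras$truth$voxels[fg] == 1L))
})

test_that("corrupt adds exactly the requested isolated speckles", {
  spec <- phantom_spec(shape = c(64, 64, 64), n_trees = 1, n_speckles = 5,
                       background_sd = 0, seed = 9)
  truth <- tube_mask(c(64, 64, 64), c(10, 32, 32), c(54, 32, 32), 4)
  img <- volume_stack(array(0, c(64, 64, 64)))
  co <- corrupt(img, spec, truth = truth, seed = 9)
  expect_equal(co$n_speckles_placed, 5L)
  bright <- array(as.integer(co$image$voxels > spec$intensity_small - 1),
                  dim(truth))
  lab <- bfs_label_oracle(bright, 26)
  expect_equal(max(lab), 5L)
  expect_true(all(truth[bright == 1L] == 0L))
})

test_that("corrupt with no noise and no speckles is a constant offset", {
  spec <- phantom_spec(shape = c(64, 64, 64), background_sd = 0,
                       n_speckles = 0, seed = 4)
  img <- volume_stack(array(10, c(64, 64, 64)))
  co <- corrupt(img, spec, seed = 4)
  expect_equal(co$image$voxels,
               array(10 + spec$background_mean, c(64, 64, 64)))
  co2 <- corrupt(img, spec, seed = 4)
  expect_identical(co$image$voxels, co2$image$voxels)
})

test_that("whole phantom generation is bit-reproducible and connected", {
  spec <- phantom_spec(shape = c(64, 64, 64), n_trees = 1, n_speckles = 3,
                       seed = 21)
  p1 <- generate_phantom(spec)
  p2 <- generate_phantom(spec)
  expect_identical(p1$image$voxels, p2$image$voxels)
  expect_identical(p1$truth$voxels, p2$truth$voxels)
  # one tree -> one 26-connected truth component
  lab <- label_components_3d(p1$truth$voxels, 26L)
  expect_equal(max(lab), 1L)
})

test_that("dataset splits are disjoint, exhaustive and reproducible", {
  spec <- phantom_spec(shape = c(64, 64, 64), n_trees = 2, seed = 5)
  ds <- make_dataset(spec, n_blocks = 20, block_shape = c(32, 32, 32),
                     seed = 5)
  counts <- table(ds$manifest$split)
  expect_equal(as.integer(counts[c("train", "val", "test")]), c(14L, 3L, 3L))
  ds2 <- make_dataset(spec, n_blocks = 20, block_shape = c(32, 32, 32),
                      seed = 5)
  expect_identical(ds$manifest, ds2$manifest)
  # background-only datasets have empty truths
  dsbg <- make_dataset(spec, n_blocks = 6, block_shape = c(32, 32, 32),
                       seed = 5, background_fraction = 1)
  expect_true(all(vapply(dsbg$blocks, function(b) sum(b$truth) == 0,
                         logical(1))))
})

test_that("dataset writing produces stacks and a manifest", {
  spec <- phantom_spec(shape = c(64, 64, 64), n_trees = 1, seed = 6)
  ds <- make_dataset(spec, n_blocks = 2, block_shape = c(32, 32, 32),
                     seed = 6, background_fraction = 0)
  dir <- withr::local_tempdir()
  write_phantom_dataset(ds, dir)
  man <- read.table(file.path(dir, "manifest.tsv"), header = TRUE)
  expect_equal(nrow(man), 2)
  v <- read_stack(man$truth[1])
  expect_true(all(v$voxels %in% c(0L, 255L)))
  expect_equal(dim(v$voxels), c(32, 32, 32))
})
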