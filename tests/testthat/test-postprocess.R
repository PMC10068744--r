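test_that("a foreground annulus is filled to a disk", {
  m <- array(0L, c(1, 9, 9))
  m[1, 3:7, 3:7] <- 1L
  m[1, 4:6, 4:6] <- 0L
  f <- fill_holes_planewise(m, passes = 1)
  expect_equal(sum(f), 25)
  expect_true(all(f >= m))
})

test_that("an open C-shaped region stays unfilled", {
  m <- array(0L, c(1, 9, 9))
  m[1, 3:7, 3] <- 1L; m[1, 3, 3:7] <- 1L; m[1, 7, 3:7] <- 1L  # open C
  expect_identical(fill_holes_planewise(m), m)
})

test_that("plane-wise filling closes tube lumens a 3D fill cannot", {
  # hollow axis-aligned tube open at both z-ends: its cavity is
  # 3D-connected to the volume border, so a 3D fill would leave it
  d <- c(24, 17, 17)
  outer <- tube_mask(d, c(1, 9, 9), c(24, 9, 9), 6)
  inner <- tube_mask(d, c(1, 9, 9), c(24, 9, 9), 3.2)
  shell <- array(as.integer(outer & !inner), d)
  # a single 3D fill keeps every background component that touches the
  # volume border; the lumen reaches the open z-faces, so it survives
  bg <- array(as.integer(shell == 0L), d)
  lab <- bfs_label_oracle(bg, 6)
  border_labs <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                          lab[, , c(1, d[3])]))
  fill3d <- shell
  fill3d[bg == 1L & !(lab %in% setdiff(border_labs, 0L))] <- 1L
  expect_identical(fill3d, shell)  # the 3D fill does nothing here
  filled <- fill_holes_planewise(shell)
  expect_true(all(filled[outer == 1L] == 1L))
  expect_identical(filled, fill_planewise_oracle(shell))
})

test_that("a hollow sphere shell becomes a solid ball", {
  d <- c(19, 19, 19)
  ctr <- c(10, 10, 10)
  dist <- array(0, d)
  for (x in 1:19) for (y in 1:19) for (z in 1:19)
    dist[z, y, x] <- sqrt(sum((c(z, y, x) - ctr)^2))
  shell <- array(as.integer(dist <= 7 & dist >= 5), d)
  ball <- array(as.integer(dist <= 7), d)
  filled <- fill_holes_planewise(shell)
  expect_identical(filled, ball)
  expect_identical(filled, fill_planewise_oracle(shell))
})

test_that("small-component removal follows the strictly-below rule", {
  m <- array(0L, c(20, 20, 20))
  m[1:5, 1, 1] <- 1L                       # size 5
  m[10:14, 1:10, 1:10] <- 1L               # size 500
  r <- remove_small_components(m, min_size = 100)
  expect_equal(sum(r), 500)
  expect_true(all(r <= m))
  # a component of exactly min_size survives
  expect_equal(sum(remove_small_components(m, min_size = 5)), 505)
  expect_identical(remove_small_components(m, 0), m)
})

test_that("component removal agrees with a BFS labeling oracle", {
  set.seed(11)
  for (i in 1:6) {
    m <- array(as.integer(runif(32^3) > 0.7), c(32, 32, 32))
    min_size <- sample(c(2, 5, 20), 1)
    fast <- remove_small_components(m, min_size)
    lab <- bfs_label_oracle(m, 26)
    sizes <- tabulate(lab[lab > 0])
    slow <- array(0L, dim(m))
    slow[lab > 0 & sizes[pmax(lab, 1L)] >= min_size] <- 1L
    expect_identical(fast, slow)
    # idempotence
    expect_identical(remove_small_components(fast, min_size), fast)
  }
})

test_that("filling converges after the six standard passes on vessel masks", {
  spec <- phantom_spec(shape = c(48, 48, 48), n_trees = 2,
                       radius_range_um = c(2, 12), seed = 33)
  truth <- generate_phantom(spec)$truth$voxels
  f2 <- fill_holes_planewise(truth, passes = 2)
  f3 <- fill_holes_planewise(truth, passes = 3)
  expect_identical(f2, f3)
  d <- c(19, 19, 19); ctr <- c(10, 10, 10)
  dist <- array(0, d)
  for (x in 1:19) for (y in 1:19) for (z in 1:19)
    dist[z, y, x] <- sqrt(sum((c(z, y, x) - ctr)^2))
  shell <- array(as.integer(dist <= 7 & dist >= 5), d)
  expect_identical(fill_holes_planewise(shell, passes = 2),
                   fill_holes_planewise(shell, passes = 3))
})

test_that("fill-then-remove differs from remove-then-fill on a thin shell", {
  d <- c(19, 19, 19)
  ctr <- c(10, 10, 10)
  dist <- array(0, d)
  for (x in 1:19) for (y in 1:19) for (z in 1:19)
    dist[z, y, x] <- sqrt(sum((c(z, y, x) - ctr)^2))
  shell <- array(as.integer(dist <= 6 & dist >= 5), d)
  n_shell <- sum(shell)
  n_ball <- sum(dist <= 6)
  min_size <- n_shell + 1  # shell alone is below threshold, filled ball is not
  expect_lt(min_size, n_ball)
  fill_first <- remove_small_components(fill_holes_planewise(shell), min_size)
  remove_first <- fill_holes_planewise(remove_small_components(shell, min_size))
  expect_gt(sum(fill_first), 0)
  expect_equal(sum(remove_first), 0)
  expect_equal(sum(postprocess_mask(shell, min_size = min_size)), n_ball)
})

test_that("both operations are shift-equivariant away from borders", {
  m <- array(0L, c(20, 20, 20))
  m[5:9, 5:9, 5:9] <- 1L; m[6:8, 6:8, 6:8] <- 0L; m[12, 12, 12] <- 1L
  shift <- function(a, s) {
    out <- array(0L, dim(a))
    out[(1 + s[1]):20, (1 + s[2]):20, (1 + s[3]):20] <-
      a[1:(20 - s[1]), 1:(20 - s[2]), 1:(20 - s[3])]
    out
  }
  s <- c(2, 3, 1)
  expect_identical(fill_holes_planewise(shift(m, s)),
                   shift(fill_holes_planewise(m), s))
  expect_identical(remove_small_components(shift(m, s), 10),
                   shift(remove_small_components(m, 10), s))
})
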