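flat_cylinder <- function(d, zlo, zhi, c0, r) {
  m <- array(0L, d)
  for (x in 1:d[3]) for (y in 1:d[2])
    if ((y - c0)^2 + (x - c0)^2 <= r^2) m[zlo:zhi, y, x] <- 1L
  m
}

test_that("a straight cylinder thins to a single full-length path", {
  m <- flat_cylinder(c(64, 15, 15), 3, 62, 8, 3)  # axial length 60
  sk <- skeletonize(m)
  deg <- tabulate(c(sk$edges[, 1], sk$edges[, 2]), nbins = nrow(sk$nodes))
  expect_equal(sum(deg == 1), 2)        # a simple path
  expect_lte(max(deg), 2)
  expect_lte(abs(nrow(sk$nodes) - 60), 2)
  # skeleton is inside the mask
  lin <- sk$nodes$z + 64 * (sk$nodes$y + 15 * sk$nodes$x) + 1
  expect_true(all(m[lin] == 1L))
  # topology preservation: one component each
  expect_equal(length(unique(connectivity_domains(sk))), 1)
})

test_that("length recovery: within 5% axis-aligned, 10% at 45 degrees", {
  m <- flat_cylinder(c(64, 15, 15), 3, 62, 8, 3)
  len <- morphometry(skeletonize(m))$total_length_mm * 1000
  expect_lt(abs(len - 59) / 59, 0.05)
  ob <- tube_mask(c(50, 50, 15), c(4, 4, 8), c(46, 46, 8), 3)
  oblen <- morphometry(skeletonize(ob))$total_length_mm * 1000
  expect_lt(abs(oblen - sqrt(2) * 42) / (sqrt(2) * 42), 0.10)
})

test_that("two disjoint tubes give two ordered connectivity domains", {
  t1 <- tube_mask(c(40, 30, 15), c(3, 8, 8), c(38, 8, 8), 3)
  t2 <- tube_mask(c(40, 30, 15), c(10, 22, 8), c(20, 22, 8), 2)
  sk <- skeletonize(array(pmax(t1, t2), c(40, 30, 15)))
  dom <- connectivity_domains(sk)
  expect_equal(length(unique(dom)), 2)
  expect_gt(sum(dom == 1), sum(dom == 2))  # domain 1 is the larger
  # matches a brute-force graph traversal on the skeleton's edges
  n <- nrow(sk$nodes)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_len(nrow(sk$edges))) {
    u <- sk$edges[k, 1]; v <- sk$edges[k, 2]
    adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
  }
  seen <- integer(n); comp <- 0
  for (i in seq_len(n)) {
    if (seen[i] != 0) next
    comp <- comp + 1
    queue <- i; seen[i] <- comp
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) if (seen[v] == 0) { seen[v] <- comp; queue <- c(queue, v) }
    }
  }
  expect_equal(comp, 2)
  # same partition (up to relabeling)
  expect_equal(length(unique(paste(dom, seen))), 2)
  expect_equal(morphometry(skeletonize(array(0L, c(32, 32, 32))))$n_connectivity_domains, 0)
})

test_that("distance-transform radii recover cylinder radii within 0.5 voxel", {
  for (r in c(2, 3, 4, 6, 10)) {
    dd <- c(40, 2 * r + 9, 2 * r + 9); c0 <- (2 * r + 10) / 2
    tm <- tube_mask(dd, c(3, c0, c0), c(38, c0, c0), r)
    sk <- estimate_radii(tm, skeletonize(tm))
    interior <- sk$nodes$z > 8 & sk$nodes$z < 30
    expect_lt(mean(abs(sk$nodes$radius_um[interior] - r)), 0.5)
  }
  # 1-voxel line: all radii at most 1 voxel
  line <- array(0L, c(20, 9, 9)); line[3:18, 5, 5] <- 1L
  skl <- estimate_radii(line, skeletonize(line))
  expect_true(all(skl$nodes$radius_um <= 1 + 1e-9))
  # radii scale linearly with voxel size
  sk2 <- estimate_radii(line, skeletonize(line), voxel_size_um = 2)
  expect_equal(sk2$nodes$radius_um, 2 * skl$nodes$radius_um)
  expect_error(estimate_radii(array(0L, c(20, 9, 9)), skl), "outside mask")
})

test_that("morphometry reports densities, bifurcations and histogram", {
  line <- array(0L, c(100, 11, 11)); line[1:100, 6, 6] <- 1L
  sk <- estimate_radii(line, skeletonize(line))
  region <- array(1L, c(100, 100, 100))  # 100^3 um^3
  mo <- morphometry(sk, region_mask = region)
  expect_lt(abs(mo$length_density_mm_per_mm3 - 100) / 100, 0.05)
  expect_equal(mo$n_bifurcations, 0L)
  expect_equal(sum(mo$radius_histogram), nrow(sk$nodes))
  expect_error(morphometry(sk, region_mask = array(0L, c(4, 4, 4))), "empty")
  # Y-junction: exactly one bifurcation, one domain
  dy <- c(40, 40, 15)
  ym <- array(pmax(tube_mask(dy, c(4, 20, 8), c(20, 20, 8), 3),
                   tube_mask(dy, c(20, 20, 8), c(36, 10, 8), 3),
                   tube_mask(dy, c(20, 20, 8), c(36, 30, 8), 3)), dy)
  moy <- morphometry(skeletonize(ym))
  expect_equal(moy$n_bifurcations, 1L)
  expect_equal(moy$n_connectivity_domains, 1L)
  # empty skeleton: zero totals
  mo0 <- morphometry(skeletonize(array(0L, c(32, 32, 32))))
  expect_equal(mo0$total_length_mm, 0)
  expect_equal(mo0$n_bifurcations, 0L)
})

test_that("SWC export is well-formed and round-trips", {
  t1 <- tube_mask(c(40, 30, 15), c(3, 8, 8), c(38, 8, 8), 3)
  t2 <- tube_mask(c(40, 30, 15), c(10, 22, 8), c(20, 22, 8), 2)
  mask <- array(pmax(t1, t2), c(40, 30, 15))
  sk <- estimate_radii(mask, skeletonize(mask, voxel_size_um = c(1, 1, 1)))
  f <- withr::local_tempfile(fileext = ".swc")
  export_swc(sk, f)
  df <- read_swc(f)
  expect_equal(nrow(df), nrow(sk$nodes))
  expect_equal(df$type, rep(7, nrow(df)))
  expect_equal(sum(df$parent == -1), 2)  # one root per domain
  # every parent id precedes its child
  nonroot <- df$parent != -1
  expect_true(all(df$parent[nonroot] < df$id[nonroot]))
  # positions and radii round trip (as unordered sets, in um)
  got <- df[order(df$z, df$y, df$x), c("x", "y", "z", "radius")]
  want <- data.frame(x = sk$nodes$x, y = sk$nodes$y, z = sk$nodes$z,
                     radius = sk$nodes$radius_um)
  want <- want[order(want$z, want$y, want$x), ]
  expect_equal(unname(as.matrix(got)), unname(as.matrix(want)),
               tolerance = 1e-3)
})

test_that("cycles are broken for SWC but kept in the skeleton graph", {
  # a square loop of tubes
  d <- c(30, 30, 9)
  loop <- array(pmax(tube_mask(d, c(5, 5, 5), c(25, 5, 5), 2),
                     tube_mask(d, c(25, 5, 5), c(25, 25, 5), 2),
                     tube_mask(d, c(25, 25, 5), c(5, 25, 5), 2),
                     tube_mask(d, c(5, 25, 5), c(5, 5, 5), 2)), d)
  sk <- skeletonize(loop)
  n <- nrow(sk$nodes)
  expect_gte(nrow(sk$edges), n)  # at least one cycle
  f <- withr::local_tempfile(fileext = ".swc")
  export_swc(sk, f)
  header <- readLines(f, n = 1)
  expect_match(header, "[1-9][0-9]* cycle edge")
  df <- read_swc(f)
  expect_equal(nrow(df), n)  # all nodes exported despite the cycle
})
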