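test_that("TIFF stack round trip preserves voxels exactly", {
  set.seed(1)
  vox <- array(sample(0:255, 64 * 32 * 16, replace = TRUE), c(64, 32, 16))
  d1 <- withr::local_tempdir()
  write_stack(volume_stack(vox), d1, compress = TRUE)
  expect_length(list.files(d1, pattern = "\\.tif$"), 64)
  back <- read_stack(d1)
  expect_equal(back$voxels, vox, ignore_attr = TRUE)
  expect_equal(dim(back$voxels), c(64, 32, 16))
})

test_that("binary masks round trip as 8-bit 0/255", {
  m <- array(0L, c(8, 8, 8)); m[3:5, 3:5, 3:5] <- 1L
  d <- withr::local_tempdir()
  write_stack(m, d)
  back <- read_stack(d)
  expect_setequal(unique(as.vector(back$voxels)), c(0L, 255L))
})

test_that("mixed slice shapes raise an error naming the file", {
  d <- withr::local_tempdir()
  tiff::writeTIFF(matrix(0, 8, 8), file.path(d, "img_0000.tif"))
  tiff::writeTIFF(matrix(0, 8, 9), file.path(d, "img_0001.tif"))
  expect_error(read_stack(d), "img_0001")
  expect_error(read_stack(withr::local_tempdir()), "no TIFF")
})

test_that("resampling pools images and majority-votes masks", {
  v <- volume_stack(array(5, c(8, 8, 8)), 1)
  expect_equal(resample(v, 1)$voxels, v$voxels)
  r2 <- resample(v, 2, kind = "image")
  expect_true(all(r2$voxels == 5))
  expect_equal(r2$voxel_size_um, c(2, 2, 2))
  # 8^3 checkerboard -> uniform mid-value under factor-2 mean pooling
  idx <- expand.grid(z = 1:8, y = 1:8, x = 1:8)
  cb <- array(as.numeric((idx$z + idx$y + idx$x) %% 2), c(8, 8, 8))
  rc <- resample(volume_stack(cb), 2, kind = "image")
  expect_true(all(abs(rc$voxels - 0.5) < 1e-12))
  expect_error(resample(v, 1.5), "factor")
})

test_that("block planning follows the stride-and-clamp rule", {
  g <- plan_blocks(c(512, 512, 512), 192, 32)
  expect_equal(nrow(g$blocks), 27)
  expect_setequal(unique(g$blocks$z), c(0, 160, 320))
  g1 <- plan_blocks(c(192, 192, 192), 192, 32)
  expect_equal(nrow(g1$blocks), 1)
  expect_equal(unlist(g1$blocks[1, c("z", "y", "x")]), c(z = 0, y = 0, x = 0))
  g2 <- plan_blocks(c(200, 512, 512), 192, 32)
  expect_setequal(unique(g2$blocks$z), c(0, 8))
  # origins sorted z, then y, then x and unique
  key <- with(g$blocks, order(z, y, x))
  expect_equal(key, seq_len(27))
})

test_that("extraction conserves voxels and duplicates overlaps", {
  set.seed(2)
  vox <- array(sample(0:255, 72^3, replace = TRUE), c(72, 72, 72))
  g <- plan_blocks(dim(vox), 48, 16)
  blocks <- extract_blocks(vox, g)
  expect_equal(sum(vapply(blocks, function(b) length(b$block), numeric(1))),
               nrow(g$blocks) * prod(g$block_shape))
  # a voxel in the overlap of the first two z-blocks appears in both
  b1 <- blocks[[1]]; b2 <- blocks[[which(vapply(blocks, function(b)
    b$spec$z == 24 && b$spec$y == 0 && b$spec$x == 0, logical(1)))]]
  expect_equal(b1$block[40, 5, 5], vox[40, 5, 5])
  expect_equal(b2$block[40 - 24, 5, 5], vox[40, 5, 5])
})

test_that("coordinate record round trips", {
  g <- plan_blocks(c(512, 512, 512), 192, 32)
  f <- withr::local_tempfile()
  write_block_coords(g, f)
  lines <- readLines(f)
  expect_equal(sum(!startsWith(lines, "#")), 27)
  g2 <- read_block_coords(f)
  expect_equal(g2$blocks, g$blocks)
  expect_equal(g2$volume_shape, g$volume_shape)
  expect_equal(g2$overlap, g$overlap)
})

test_that("extract-then-fuse is the identity on binary volumes", {
  set.seed(3)
  for (shape in list(c(48, 48, 48), c(50, 61, 72), c(40, 90, 33))) {
    m <- array(as.integer(runif(prod(shape)) > 0.6), shape)
    g <- plan_blocks(shape, 48, 16)
    fused <- fuse_blocks(extract_blocks(m, g), g)
    expect_identical(fused$voxels, m)
  }
})

test_that("fusion ORs overlaps and ignores processing order", {
  m <- array(0L, c(40, 72, 72))
  m[10, 30, 30] <- 1L
  g <- plan_blocks(dim(m), 48, 16)  # one block per axis except y/x
  blocks <- extract_blocks(m, g)
  # flip the overlap voxel to 0 in one covering block only: OR must keep 1
  overlap_blocks <- which(vapply(blocks, function(b)
    b$spec$y <= 29 && b$spec$y + 48 > 29, logical(1)))
  blocks2 <- blocks
  blocks2[[overlap_blocks[1]]]$block[] <- 0L
  fused <- fuse_blocks(blocks2, g)
  if (length(overlap_blocks) > 1) expect_equal(fused$voxels[10, 30, 30], 1L)
  expect_identical(fuse_blocks(rev(blocks), g)$voxels,
                   fuse_blocks(blocks, g)$voxels)
  expect_error(fuse_blocks(blocks[-1], g), "missing block")
})

test_that("section planning covers all slices with the requested halo", {
  s1 <- plan_sections(100, 1)
  expect_equal(nrow(s1), 1)
  expect_equal(c(s1$z0, s1$z1), c(0, 100))
  s4 <- plan_sections(100, 4, halo = 32)
  expect_equal(nrow(s4), 4)
  expect_equal(s4$core0[1], 0)
  expect_equal(s4$core1[4], 100)
  for (i in 1:3) expect_gte(s4$z1[i] - s4$z0[i + 1], 32)
  covered <- sort(unique(unlist(lapply(seq_len(4), function(i)
    seq(s4$core0[i], s4$core1[i] - 1)))))
  expect_equal(covered, 0:99)
  expect_identical(s4, plan_sections(100, 4, halo = 32))
  expect_equal(nrow(plan_sections(3, 8)), 3)
})

test_that("blockwise pointwise prediction equals whole-volume prediction", {
  set.seed(4)
  img <- array(runif(60 * 50 * 44, 0, 255), c(60, 50, 44))
  thr <- function(b) array(as.integer(b > 128), dim(b))
  g <- plan_blocks(dim(img), 32, 8)
  pred <- lapply(extract_blocks(img, g), function(b)
    list(spec = b$spec, block = thr(b$block)))
  expect_identical(fuse_blocks(pred, g)$voxels, thr(img))
})
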