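# Volume I/O, resampling, overlapped blocking and OR fusion.
#
# Volumes are 3D arrays indexed (z, y, x); slice z of a stack is the z-th
# TIFF file in lexicographic filename order.  All block coordinates are
# 0-based with half-open extents.

#' Construct a volume stack
#'
#' A `volume_stack` is a 3D scalar array indexed `(z, y, x)` together with
#' its voxel size in micrometres.  It is the universal currency of the
#' pipeline: images, probability maps and binary masks are all carried in
#' this container.
#'
#' @param voxels 3D numeric or integer array, dimension `(z, y, x)`.
#' @param voxel_size_um voxel size in micrometres, scalar (isotropic) or
#'   `(z, y, x)` triple.
#' @return An object of class `volume_stack`.
#' @export
volume_stack <- function(voxels, voxel_size_um = c(1, 1, 1)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3) stop("voxels must be a 3D array")
  structure(list(voxels = voxels,
                 voxel_size_um = as_triple(voxel_size_um, "voxel_size_um")),
            class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume_stack> %d x %d x %d (z,y,x), voxel %s um, range [%g, %g]\n",
              d[1], d[2], d[3],
              paste(signif(x$voxel_size_um, 3), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.volume_stack <- function(x) dim(x$voxels)

#' Read a volume from a directory of 2D TIFF slices
#'
#' Slices are assembled in lexicographic filename order; file `z` becomes
#' slice `z` of the `(z, y, x)` array.  All slices must share one shape.
#'
#' @param dir_path directory containing one 2D TIFF per z-slice.
#' @param voxel_size_um voxel size metadata to attach (not read from TIFF
#'   tags).
#' @return A [volume_stack()] with integer sample values (0..255 or
#'   0..65535).
#' @export
read_stack <- function(dir_path, voxel_size_um = c(1, 1, 1)) {
  files <- sort(list.files(dir_path, pattern = "\\.tiff?$", ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0)
    stop("no TIFF slices found in ", dir_path)
  slices <- vector("list", length(files))
  shp <- NULL
  for (i in seq_along(files)) {
    m <- tiff::readTIFF(files[i], as.is = TRUE)
    if (is.array(m) && length(dim(m)) == 3) m <- m[, , 1]
    if (is.null(shp)) shp <- dim(m)
    if (!identical(dim(m), shp))
      stop("slice shape mismatch in ", basename(files[i]),
           ": expected ", paste(shp, collapse = "x"),
           ", got ", paste(dim(m), collapse = "x"))
    slices[[i]] <- m
  }
  vox <- array(0, c(length(files), shp[1], shp[2]))
  for (i in seq_along(slices)) vox[i, , ] <- slices[[i]]
  storage.mode(vox) <- "integer"
  volume_stack(vox, voxel_size_um)
}

#' Write a volume as a directory of 2D TIFF slices
#'
#' One TIFF per z-slice, named `img_0000.tif`, `img_0001.tif`, ...
#' Binary masks (values within \{0, 1\} or \{0, 255\}) are written as 8-bit
#' \{0, 255\}; images are written 8- or 16-bit according to their range.
#'
#' @param volume a [volume_stack()] or bare 3D array.
#' @param dir_path output directory (created if missing).
#' @param compress use LZW lossless compression.
#' @param prefix slice filename prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_stack <- function(volume, dir_path, compress = TRUE, prefix = "img_") {
  vox <- voxels_of(volume)
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  vals <- range(vox)
  is_mask <- all(as.vector(vox) %in% c(0, 1)) || all(as.vector(vox) %in% c(0, 255))
  if (is_mask) {
    vox <- array(ifelse(vox != 0, 255L, 0L), dim(vox))
    bits <- 8L
  } else {
    bits <- if (vals[2] <= 255) 8L else 16L
  }
  scale <- 2^bits - 1
  comp <- if (compress) "LZW" else "none"
  nz <- dim(vox)[1]
  files <- character(nz)
  for (z in seq_len(nz)) {
    f <- file.path(dir_path, sprintf("%s%04d.tif", prefix, z - 1))
    m <- pmin(pmax(vox[z, , ], 0), scale) / scale
    tiff::writeTIFF(m, f, bits.per.sample = bits, compression = comp)
    files[z] <- f
  }
  invisible(files)
}

#' Resample a volume by integer factors
#'
#' Images are block-mean pooled; binary masks take a majority vote with
#' ties resolved to foreground.  The voxel size is multiplied by the
#' factor.
#'
#' @param volume a [volume_stack()] or 3D array.
#' @param factor integer downsampling factor, scalar or `(z, y, x)` triple.
#' @param kind `"auto"` detects binary masks; or force `"image"` / `"mask"`.
#' @return A [volume_stack()].
#' @export
resample <- function(volume, factor, kind = c("auto", "image", "mask")) {
  kind <- match.arg(kind)
  f <- as_triple(factor, "factor")
  if (any(f != round(f)) || any(f < 1))
    stop("unsupported resampling factor: integer factors >= 1 required")
  f <- as.integer(f)
  vox <- voxels_of(volume)
  vs <- vsize_of(volume)
  if (kind == "auto")
    kind <- if (all(as.vector(vox) %in% c(0, 1, 255))) "mask" else "image"
  x4 <- array(as.double(vox), c(dim(vox), 1L))
  pooled <- pool_mean_fwd(x4, f)
  out <- array(pooled, dim(pooled)[1:3])
  if (kind == "mask") {
    mx <- max(vox)
    out <- array(as.integer(out >= mx / 2), dim(out))  # majority, ties -> fg
  }
  volume_stack(out, vs * f)
}

#' Plan an overlapped block decomposition
#'
#' Splits a volume into fixed-size blocks with a fixed overlap between
#' neighbours.  Per axis, origins advance by `block - overlap`; a final
#' block that would overrun is clamped to end exactly at the volume edge
#' (gaining extra overlap).  If an axis is shorter than the block size a
#' single block at origin 0 is planned and extraction zero-pads.
#'
#' @param volume_shape `(z, y, x)` voxel counts.
#' @param block_shape block edge length, scalar or triple (default 192).
#' @param overlap minimum overlap between neighbouring blocks (default 32).
#' @return A `block_grid` with a `blocks` data frame (0-based origins).
#' @export
plan_blocks <- function(volume_shape, block_shape = 192, overlap = 32) {
  B <- as.integer(as_triple(block_shape, "block_shape"))
  O <- as.integer(as_triple(overlap, "overlap"))
  if (any(B <= O) || any(O < 0)) stop("need block_shape > overlap >= 0")
  volume_shape <- as.integer(volume_shape)
  axis_origins <- function(dim, b, o) {
    if (dim <= b) return(0L)
    s <- b - o
    org <- seq(0L, dim - b, by = s)
    if (org[length(org)] != dim - b) org <- c(org, dim - b)
    org
  }
  oz <- axis_origins(volume_shape[1], B[1], O[1])
  oy <- axis_origins(volume_shape[2], B[2], O[2])
  ox <- axis_origins(volume_shape[3], B[3], O[3])
  g <- expand.grid(x = ox, y = oy, z = oz)[, 3:1]  # sorted z, then y, then x
  g <- g[order(g$z, g$y, g$x), , drop = FALSE]
  blocks <- data.frame(index = seq_len(nrow(g)) - 1L,
                       z = g$z, y = g$y, x = g$x,
                       bz = B[1], by = B[2], bx = B[3])
  rownames(blocks) <- NULL
  structure(list(volume_shape = volume_shape, block_shape = B,
                 overlap = O, blocks = blocks),
            class = "block_grid")
}

#' @export
print.block_grid <- function(x, ...) {
  cat(sprintf("<block_grid> volume %s, block %s, overlap %s, %d blocks\n",
              paste(x$volume_shape, collapse = "x"),
              paste(x$block_shape, collapse = "x"),
              paste(x$overlap, collapse = "x"), nrow(x$blocks)))
  invisible(x)
}

#' Extract the planned blocks from a volume
#'
#' Blocks are copied out half-open; axes shorter than the block size are
#' zero-padded up to the block shape (the valid extent is recoverable from
#' the grid, and [fuse_blocks()] trims it before fusing).
#'
#' @param volume a [volume_stack()] or 3D array matching the grid.
#' @param grid a [plan_blocks()] result for this volume's shape.
#' @return List of `list(spec = <row of grid$blocks>, block = <array>)`.
#' @export
extract_blocks <- function(volume, grid) {
  vox <- voxels_of(volume)
  if (!identical(as.integer(dim(vox)), grid$volume_shape))
    stop("volume shape ", paste(dim(vox), collapse = "x"),
         " does not match grid ", paste(grid$volume_shape, collapse = "x"))
  B <- grid$block_shape
  d <- dim(vox)
  lapply(seq_len(nrow(grid$blocks)), function(i) {
    s <- grid$blocks[i, ]
    ez <- min(s$z + B[1], d[1]); ey <- min(s$y + B[2], d[2])
    ex <- min(s$x + B[3], d[3])
    blk <- array(0, B)
    blk[seq_len(ez - s$z), seq_len(ey - s$y), seq_len(ex - s$x)] <-
      vox[(s$z + 1):ez, (s$y + 1):ey, (s$x + 1):ex]
    list(spec = s, block = blk)
  })
}

#' Write the block coordinate record
#'
#' Plain text, one line per block:
#' `index<TAB>z<TAB>y<TAB>x<TAB>bz<TAB>by<TAB>bx`, with `#` header lines
#' carrying the volume shape, block shape and overlap so the grid can be
#' reconstructed.
#'
#' @param grid a `block_grid`.
#' @param path output text file.
#' @export
write_block_coords <- function(grid, path) {
  hdr <- c(sprintf("# volume\t%s", paste(grid$volume_shape, collapse = "\t")),
           sprintf("# block\t%s", paste(grid$block_shape, collapse = "\t")),
           sprintf("# overlap\t%s", paste(grid$overlap, collapse = "\t")),
           "# index\tz\ty\tx\tbz\tby\tbx")
  body <- apply(grid$blocks, 1, function(r) paste(r, collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a block coordinate record back into a grid
#'
#' @param path a file written by [write_block_coords()].
#' @return A `block_grid` identical to the one written.
#' @export
read_block_coords <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  getv <- function(key) {
    l <- hdr[startsWith(hdr, paste0("# ", key))]
    as.integer(strsplit(l, "\t")[[1]][-1])
  }
  body <- lines[!startsWith(lines, "#")]
  m <- do.call(rbind, lapply(strsplit(body, "\t"), as.integer))
  blocks <- data.frame(index = m[, 1], z = m[, 2], y = m[, 3], x = m[, 4],
                       bz = m[, 5], by = m[, 6], bx = m[, 7])
  structure(list(volume_shape = getv("volume"), block_shape = getv("block"),
                 overlap = getv("overlap"), blocks = blocks),
            class = "block_grid")
}

#' Fuse segmented blocks back into a whole binary volume
#'
#' Blocks are placed at their recorded origins; voxels covered by several
#' blocks combine with logical OR.  Padding added by [extract_blocks()] for
#' short axes is trimmed first so it can never leak foreground.
#'
#' @param blocks list as produced by [extract_blocks()] (each element
#'   `list(spec, block)` with a binary block).
#' @param grid the `block_grid` the blocks were extracted with.
#' @return A binary [volume_stack()] (values 0/1) of the full volume shape.
#' @export
fuse_blocks <- function(blocks, grid) {
  need <- grid$blocks$index
  have <- vapply(blocks, function(b) as.integer(b$spec$index), integer(1))
  missing_idx <- setdiff(need, have)
  if (length(missing_idx) > 0)
    stop("fusion incomplete; missing block indices: ",
         paste(missing_idx, collapse = ", "))
  d <- grid$volume_shape
  out <- array(0L, d)
  B <- grid$block_shape
  for (b in blocks) {
    s <- b$spec
    blk <- as_binary_array(b$block)
    ez <- min(s$z + B[1], d[1]); ey <- min(s$y + B[2], d[2])
    ex <- min(s$x + B[3], d[3])
    sub <- blk[seq_len(ez - s$z), seq_len(ey - s$y), seq_len(ex - s$x),
               drop = FALSE]
    cur <- out[(s$z + 1):ez, (s$y + 1):ey, (s$x + 1):ex]
    out[(s$z + 1):ez, (s$y + 1):ey, (s$x + 1):ex] <- pmax(cur, sub)
  }
  volume_stack(out)
}

#' Plan overlapped z-sections for parallel workers
#'
#' Divides `[0, n_slices)` into near-equal contiguous core ranges, one per
#' worker, each extended by a halo on both sides.  Consecutive extended
#' sections therefore share at least `halo` slices.
#'
#' @param n_slices number of z-slices.
#' @param n_workers requested worker count (>= 1).
#' @param halo halo width in slices.
#' @return Data frame with 0-based half-open columns `z0, z1` (halo-extended
#'   read range) and `core0, core1` (owned write range).
#' @export
plan_sections <- function(n_slices, n_workers, halo = 0) {
  if (n_workers < 1) stop("n_workers must be >= 1")
  k <- max(1L, min(as.integer(n_workers), as.integer(n_slices)))
  bounds <- round(seq(0, n_slices, length.out = k + 1))
  data.frame(z0 = pmax(0, bounds[-(k + 1)] - halo),
             z1 = pmin(n_slices, bounds[-1] + halo),
             core0 = bounds[-(k + 1)], core1 = bounds[-1])
}
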