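# End-to-end orchestration: blocking -> block prediction -> OR fusion ->
# morphological clean-up, with a deterministic parallel worker contract.
#
# Parallelism is a map over independent work items (blocks, sections) whose
# results are merged in deterministic item order, so the output is
# bit-identical for any worker count.

#' Pipeline configuration
#'
#' @param input_dir directory of input TIFF slices (or `NULL` when a
#'   volume is passed in memory).
#' @param output_dir directory for the segmented TIFF slices.
#' @param checkpoint path to a [save_checkpoint()] file.
#' @param block_shape block edge (default 192).
#' @param overlap block overlap (default 32).
#' @param resample_factor integer pre-resampling factor (default 1).
#' @param threshold binarization threshold.
#' @param min_component small-component removal threshold (voxels).
#' @param skip_fill,skip_remove post-processing stage toggles.
#' @param n_workers parallel workers for block prediction.
#' @param block_dir optional directory caching predicted blocks; an
#'   existing complete block file is not recomputed (crash-restart
#'   safety).
#' @param seed seed recorded in the manifest (prediction itself is
#'   deterministic).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, output_dir = NULL,
                            checkpoint = NULL, block_shape = 192,
                            overlap = 32, resample_factor = 1,
                            threshold = 0.5, min_component = 100,
                            skip_fill = FALSE, skip_remove = FALSE,
                            n_workers = 1, block_dir = NULL, seed = 1) {
  B <- as_triple(block_shape); O <- as_triple(overlap)
  if (any(B <= O)) stop("block_shape must exceed overlap")
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 checkpoint = checkpoint, block_shape = B, overlap = O,
                 resample_factor = resample_factor, threshold = threshold,
                 min_component = min_component, skip_fill = skip_fill,
                 skip_remove = skip_remove, n_workers = as.integer(n_workers),
                 block_dir = block_dir, seed = seed),
            class = "pipeline_config")
}

# deterministic parallel map: results in item order for any worker count
worker_map <- function(items, fn, n_workers) {
  if (n_workers <= 1 || length(items) <= 1) return(lapply(items, fn))
  parallel::mclapply(items, fn, mc.cores = n_workers, mc.preschedule = TRUE)
}

block_cache_path <- function(dir, index) {
  file.path(dir, sprintf("block_%05d.tif", index))
}

write_block_tiff <- function(block, path) {
  pages <- lapply(seq_len(dim(block)[1]), function(z)
    ifelse(block[z, , ] != 0, 1, 0))
  tmp <- paste0(path, ".tmp")
  tiff::writeTIFF(pages, tmp, bits.per.sample = 8L, compression = "LZW")
  file.rename(tmp, path)  # content-complete or absent
}

read_block_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  out <- array(0L, c(length(pages), dim(pages[[1]])))
  for (z in seq_along(pages)) out[z, , ] <- as.integer(pages[[z]] != 0)
  out
}

#' Segment a whole volume blockwise
#'
#' The three-stage flow: plan overlapped blocks, predict each block with
#' the network (or any predictor), fuse with voxelwise OR, then plane-wise
#' hole filling and small-component removal.  Output is written as LZW
#' TIFF slices when `cfg$output_dir` is set.  The result is bit-identical
#' for any `n_workers >= 1`.
#'
#' @param cfg a [pipeline_config()].
#' @param volume optional in-memory [volume_stack()] (otherwise read from
#'   `cfg$input_dir`).
#' @param predictor optional function `(block array) -> binary block`
#'   overriding the checkpointed network (e.g. a global threshold).
#' @return `list(mask = <binary volume_stack>, manifest = <list>)`.
#' @export
segment_volume <- function(cfg, volume = NULL, predictor = NULL) {
  t0 <- Sys.time()
  if (is.null(volume)) {
    if (is.null(cfg$input_dir) || !dir.exists(cfg$input_dir))
      stop("[read] input stack directory not found: ", cfg$input_dir)
    volume <- read_stack(cfg$input_dir)
  }
  if (is.null(predictor)) {
    if (is.null(cfg$checkpoint) || !file.exists(cfg$checkpoint))
      stop("[predict] checkpoint not found: ", cfg$checkpoint)
    net <- load_checkpoint(cfg$checkpoint)
    predictor <- function(block) predict_block(net, block, cfg$threshold)
  }
  if (any(cfg$resample_factor != 1))
    volume <- resample(volume, cfg$resample_factor, kind = "image")

  vox <- voxels_of(volume)
  grid <- plan_blocks(dim(vox), cfg$block_shape, cfg$overlap)
  if (!is.null(cfg$block_dir))
    dir.create(cfg$block_dir, showWarnings = FALSE, recursive = TRUE)

  # blocks are sliced out lazily inside each worker so only one block per
  # worker is materialized at a time (the full volume is shared)
  slice_block <- function(i) {
    s <- grid$blocks[i, ]
    B <- grid$block_shape
    d <- dim(vox)
    ez <- min(s$z + B[1], d[1]); ey <- min(s$y + B[2], d[2])
    ex <- min(s$x + B[3], d[3])
    blk <- array(0, B)
    blk[seq_len(ez - s$z), seq_len(ey - s$y), seq_len(ex - s$x)] <-
      vox[(s$z + 1):ez, (s$y + 1):ey, (s$x + 1):ex]
    blk
  }
  t1 <- Sys.time()
  if (cfg$n_workers > 1) gc(FALSE)  # trim the heap forked workers inherit
  predicted <- worker_map(seq_len(nrow(grid$blocks)), function(i) {
    spec <- grid$blocks[i, ]
    if (!is.null(cfg$block_dir)) {
      pth <- block_cache_path(cfg$block_dir, spec$index)
      if (file.exists(pth))
        return(list(spec = spec, block = read_block_tiff(pth)))
      out <- predictor(slice_block(i))
      write_block_tiff(out, pth)
      return(list(spec = spec, block = out))
    }
    list(spec = spec, block = predictor(slice_block(i)))
  }, cfg$n_workers)

  t2 <- Sys.time()
  fused <- fuse_blocks(predicted, grid)
  removed_before <- sum(fused$voxels)
  mask <- postprocess_mask(fused$voxels, min_size = cfg$min_component,
                           skip_fill = cfg$skip_fill,
                           skip_remove = cfg$skip_remove)
  t3 <- Sys.time()

  out <- volume_stack(mask, vsize_of(volume))
  if (!is.null(cfg$output_dir))
    write_stack(out, cfg$output_dir, compress = TRUE)
  manifest <- list(
    n_blocks = nrow(grid$blocks),
    volume_shape = dim(voxels_of(volume)),
    block_shape = grid$block_shape, overlap = grid$overlap,
    threshold = cfg$threshold, min_component = cfg$min_component,
    skip_fill = cfg$skip_fill, skip_remove = cfg$skip_remove,
    n_workers = cfg$n_workers, seed = cfg$seed,
    connectivity = 26,
    foreground_voxels_fused = removed_before,
    foreground_voxels_final = sum(mask),
    timing_s = list(read = as.numeric(t1 - t0, units = "secs"),
                    predict = as.numeric(t2 - t1, units = "secs"),
                    postprocess = as.numeric(t3 - t2, units = "secs")))
  if (!is.null(cfg$output_dir)) {
    write_block_coords(grid, file.path(cfg$output_dir, "blocks.txt"))
    jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(mask = out, manifest = manifest)
}

#' Evaluate a prediction and analyze its vasculature
#'
#' Chains the full evaluation suite (precision, recall, Dice, Jaccard,
#' clDice, Hausdorff distance) with skeleton-based morphometry of the
#' prediction.
#'
#' @param pred,truth binary volumes or stack directories.
#' @param voxel_size_um voxel size for morphometry.
#' @param metrics_csv,report_json optional output paths.
#' @return `list(metrics = <one-row data frame>, morphometry)`.
#' @export
run_experiment <- function(pred, truth, voxel_size_um = c(1, 1, 1),
                           metrics_csv = NULL, report_json = NULL) {
  if (is.character(pred)) pred <- read_stack(pred)
  if (is.character(truth)) truth <- read_stack(truth)
  met <- evaluate_segmentation(pred, truth)
  sk <- skeletonize(as_binary_array(pred), voxel_size_um)
  sk <- if (nrow(sk$nodes) > 0)
    estimate_radii(as_binary_array(pred), sk, voxel_size_um) else sk
  mor <- morphometry(sk, voxel_size_um = voxel_size_um)
  if (!is.null(metrics_csv)) write.csv(met, metrics_csv, row.names = FALSE)
  if (!is.null(report_json))
    jsonlite::write_json(unclass(mor), report_json, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  list(metrics = met, morphometry = mor)
}
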