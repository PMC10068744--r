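# Synthetic vascular phantoms with known ground truth.
#
# The generator emulates the appearance of a fluorescence vessel channel in
# which endothelial cells of the vessel wall carry the label: large vessels
# appear as bright hollow tubes with a dark central lumen, capillaries as
# dim solid tubes, over a diffuse background with isolated fluorescent
# specks.  Geometry is a seeded random walk with probabilistic symmetric
# bifurcation; ground truth is the filled tube (lumen included).

#' Specification of a synthetic vascular phantom
#'
#' Encodes the full generative description of a phantom volume: tree
#' geometry, tube appearance, background noise and speckle model.  Large
#' vessels (radius at or above `hollow_radius_um`) are rendered wall-only at
#' `intensity_large`; thinner vessels are rendered solid at
#' `intensity_small`.  Intensities are on an 8-bit scale.
#'
#' @param shape volume shape `(z, y, x)` in voxels, each >= 32.
#' @param voxel_size_um isotropic voxel size in micrometres.
#' @param n_trees number of vessel trees (>= 1).
#' @param radius_range_um `(min, max)` vessel radius in micrometres.
#' @param hollow_radius_um radius at and above which a vessel is rendered
#'   wall-only.
#' @param wall_thickness_um wall shell thickness of hollow vessels.
#' @param branch_prob per-step probability of a symmetric bifurcation.
#' @param step_len_um centerline step length.
#' @param tortuosity standard deviation of the per-step direction
#'   perturbation (radians-like, applied per component).
#' @param n_steps maximum number of centerline steps per branch.
#' @param intensity_large,intensity_small mean foreground intensity of
#'   hollow walls and of solid (capillary) tubes; must satisfy
#'   `intensity_large > intensity_small > background_mean`.
#' @param background_mean,background_sd additive Gaussian background.
#' @param n_speckles count of isolated noise blobs added by [corrupt()].
#' @param speckle_size_range `(min, max)` voxel count of a speckle blob.
#' @param psf_sigma_um Gaussian blur scale emulating the optical PSF.
#' @param seed integer seed; identical seeds give bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64),
                         voxel_size_um = 1.0,
                         n_trees = 3,
                         radius_range_um = c(2.0, 20.0),
                         hollow_radius_um = 6.0,
                         wall_thickness_um = 2.0,
                         branch_prob = 0.04,
                         step_len_um = 2.0,
                         tortuosity = 0.18,
                         n_steps = 120,
                         intensity_large = 200,
                         intensity_small = 120,
                         background_mean = 40,
                         background_sd = 10,
                         n_speckles = 20,
                         speckle_size_range = c(3, 15),
                         psf_sigma_um = 0.7,
                         seed = NULL) {
  shape <- as.integer(as_triple(shape, "shape"))
  if (any(shape < 32)) stop("invalid phantom spec: shape must be >= 32 per axis")
  if (n_trees < 1) stop("invalid phantom spec: n_trees must be >= 1")
  if (!(intensity_large > intensity_small && intensity_small > background_mean))
    stop("invalid phantom spec: need intensity_large > intensity_small > background_mean")
  if (radius_range_um[1] < voxel_size_um)
    stop("invalid phantom spec: minimum radius below one voxel")
  if (radius_range_um[1] > radius_range_um[2])
    stop("invalid phantom spec: radius_range_um must be increasing")
  structure(list(shape = shape, voxel_size_um = voxel_size_um,
                 n_trees = as.integer(n_trees),
                 radius_range_um = radius_range_um,
                 hollow_radius_um = hollow_radius_um,
                 wall_thickness_um = wall_thickness_um,
                 branch_prob = branch_prob, step_len_um = step_len_um,
                 tortuosity = tortuosity, n_steps = as.integer(n_steps),
                 intensity_large = intensity_large,
                 intensity_small = intensity_small,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 n_speckles = as.integer(n_speckles),
                 speckle_size_range = speckle_size_range,
                 psf_sigma_um = psf_sigma_um, seed = seed),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s voxels @ %g um, %d tree(s), radii %g-%g um\n",
              paste(x$shape, collapse = "x"), x$voxel_size_um, x$n_trees,
              x$radius_range_um[1], x$radius_range_um[2]))
  invisible(x)
}

unit_vec <- function(v) v / sqrt(sum(v^2))

random_unit <- function() unit_vec(rnorm(3))

# a random unit vector perpendicular to d
perp_vec <- function(d) {
  p <- rnorm(3)
  p <- p - sum(p * d) * d
  if (sqrt(sum(p^2)) < 1e-8) p <- c(d[2], -d[1], 0)
  unit_vec(p)
}

#' Generate one random vessel tree
#'
#' Centerlines follow a seeded random walk with Gaussian direction
#' perturbation; at each step a symmetric bifurcation occurs with
#' probability `branch_prob`, with child radii scaled by `2^(-1/3)`
#' (Murray-law-like taper).  The root radius is drawn from the upper half of
#' `radius_range_um`.  All node positions lie inside the volume bounds, and
#' radii never increase from root to tip.
#'
#' @param spec a [phantom_spec()].
#' @param seed optional seed overriding `spec$seed`.
#' @return An object of class `vessel_tree`: a list of polylines, each
#'   `list(pts = <n x 3 matrix of (z,y,x) voxel coords>, radius_um = <n>,
#'   parent = c(polyline, point) or NA)`.
#' @export
generate_tree <- function(spec, seed = spec$seed) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  local_seed(seed, {
    d <- spec$shape
    vs <- spec$voxel_size_um
    step <- spec$step_len_um / vs
    rmin <- spec$radius_range_um[1]
    rmid <- mean(spec$radius_range_um)
    polylines <- list()
    for (attempt in seq_len(30)) {
      r0 <- runif(1, rmid, spec$radius_range_um[2])
      # start away from the border so the walk has room to grow
      m <- pmax(2, d %/% 8)
      start <- c(runif(1, m[1], d[1] - 1 - m[1]),
                 runif(1, m[2], d[2] - 1 - m[2]),
                 runif(1, m[3], d[3] - 1 - m[3]))
      # queue of branches to grow: (start point, direction, radius, parent)
      queue <- list(list(p = start, dir = random_unit(), r = r0, parent = NA))
    while (length(queue) > 0) {
      br <- queue[[1]]
      queue <- queue[-1]
      pts <- matrix(br$p, ncol = 3)
      radii <- br$r
      p <- br$p
      dirv <- br$dir
      for (s in seq_len(spec$n_steps)) {
        dirv <- unit_vec(dirv + rnorm(3, sd = spec$tortuosity))
        pn <- p + dirv * step
        if (any(pn < 1) || any(pn > d - 2)) break
        p <- pn
        pts <- rbind(pts, p)
        radii <- c(radii, br$r)
        if (runif(1) < spec$branch_prob && length(polylines) < 64) {
          rc <- br$r * 2^(-1 / 3)
          if (rc >= rmin) {
            ref <- c(length(polylines) + 1, nrow(pts))
            ax <- perp_vec(dirv)
            ang <- runif(2, 0.4, 0.8)  # ~23-46 degrees off the parent
            d1 <- unit_vec(cos(ang[1]) * dirv + sin(ang[1]) * ax)
            d2 <- unit_vec(cos(ang[2]) * dirv - sin(ang[2]) * ax)
            queue <- c(queue, list(list(p = p, dir = d2, r = rc, parent = ref)))
            dirv <- d1
            br$r <- rc
            # continue current branch as the first child (radius shrinks)
          }
        }
      }
      if (nrow(pts) >= 2)
        polylines[[length(polylines) + 1]] <-
          list(pts = unname(pts), radius_um = radii, parent = br$parent)
      }
      if (length(polylines) > 0) break
    }
    if (length(polylines) == 0)
      stop("degenerate phantom spec: no tree could be grown")
    structure(list(polylines = polylines, shape = d,
                   voxel_size_um = vs), class = "vessel_tree")
  })
}

#' Number of bifurcations recorded in a tree
#' @param tree a `vessel_tree`.
#' @return Count of child polylines (each marks one bifurcation).
#' @export
tree_bifurcations <- function(tree) {
  sum(vapply(tree$polylines, function(p) !anyNA(p$parent), logical(1)))
}

#' Rasterize vessel trees into an image and ground-truth pair
#'
#' The truth mask is the union of filled tubes (lumen included).  In the
#' image, vessels with radius at or above `hollow_radius_um` are rendered
#' wall-only: an annulus of `wall_thickness_um` at `intensity_large`, with
#' the lumen left at the background level so it is indistinguishable from
#' background, as under wall-only endothelial labeling.  Thinner vessels
#' are solid tubes at `intensity_small`.  The signal image is then blurred
#' with a Gaussian of `psf_sigma_um`.  The returned image holds the signal
#' above a zero background; [corrupt()] adds the background offset, noise
#' and speckles.
#'
#' @param trees a `vessel_tree` or list of them.
#' @param spec the [phantom_spec()] they were generated from.
#' @return `list(image = <volume_stack, numeric>, truth = <volume_stack,
#'   binary 0/1>)`.
#' @export
rasterize <- function(trees, spec) {
  if (inherits(trees, "vessel_tree")) trees <- list(trees)
  d <- spec$shape
  vs <- spec$voxel_size_um
  solid <- array(0L, d); wallv <- array(0L, d); lumen <- array(0L, d)
  for (tree in trees) {
    for (pl in tree$polylines) {
      r_vox <- pl$radius_um / vs
      hollow <- pl$radius_um[1] >= spec$hollow_radius_um
      rasterize_path(pl$pts, r_vox, hollow, spec$wall_thickness_um / vs,
                     solid, wallv, lumen)
    }
  }
  truth <- array(as.integer(solid | wallv | lumen), d)
  img <- array(0, d)
  img[solid == 1L & wallv == 0L] <- spec$intensity_small - spec$background_mean
  img[wallv == 1L] <- spec$intensity_large - spec$background_mean
  # lumen voxels stay at 0 (background level)
  sig <- spec$psf_sigma_um / vs
  if (sig > 0) img <- gaussian_blur3d(img, rep(sig, 3))
  list(image = volume_stack(img, rep(vs, 3)),
       truth = volume_stack(truth, rep(vs, 3)))
}

# grow one connected speckle blob of `size` voxels starting at `start`
grow_speckle <- function(start, size, d) {
  pts <- matrix(start, ncol = 3)
  for (i in seq_len(size - 1)) {
    base <- pts[sample(nrow(pts), 1), ]
    off <- sample(c(-1L, 0L, 1L), 3, replace = TRUE)
    cand <- base + off
    if (any(cand < 1) || any(cand > d)) next
    pts <- unique(rbind(pts, cand))
    if (nrow(pts) >= size) break
  }
  pts
}

#' Corrupt a clean phantom image with background noise and speckles
#'
#' Adds the constant background offset plus Gaussian noise, then injects
#' `n_speckles` isolated bright blobs (connected clumps at the capillary
#' intensity) placed so that neither they nor their 1-voxel border touches
#' the true vessel mask or each other.  Output is clipped to `[0, 255]`.
#'
#' @param image clean signal image from [rasterize()].
#' @param spec the [phantom_spec()].
#' @param truth the ground-truth mask speckles must avoid (binary volume);
#'   `NULL` allows speckles anywhere.
#' @param seed seed for noise and speckle placement.
#' @return `list(image = <volume_stack>, n_speckles_placed = <int>)`.
#'   A warning reports any shortfall after bounded placement retries.
#' @export
corrupt <- function(image, spec, truth = NULL, seed = spec$seed) {
  vox <- voxels_of(image)
  if (!identical(as.integer(dim(vox)), spec$shape))
    stop("image shape does not match spec")
  d <- dim(vox)
  local_seed(seed, {
    out <- vox + spec$background_mean
    if (spec$background_sd > 0)
      out <- out + array(rnorm(length(out), 0, spec$background_sd), d)
    avoid <- if (is.null(truth)) array(0L, d) else as_binary_array(truth)
    placed <- 0L
    if (spec$n_speckles > 0) {
      for (i in seq_len(spec$n_speckles)) {
        ok <- FALSE
        for (try in seq_len(60)) {
          size <- sample(spec$speckle_size_range[1]:spec$speckle_size_range[2], 1)
          start <- c(sample(2:(d[1] - 1), 1), sample(2:(d[2] - 1), 1),
                     sample(2:(d[3] - 1), 1))
          pts <- grow_speckle(start, size, d)
          # reject if blob or its 1-voxel border touches avoid-mask
          clear <- TRUE
          for (j in seq_len(nrow(pts))) {
            z <- pts[j, 1]; y <- pts[j, 2]; x <- pts[j, 3]
            zr <- max(1, z - 1):min(d[1], z + 1)
            yr <- max(1, y - 1):min(d[2], y + 1)
            xr <- max(1, x - 1):min(d[3], x + 1)
            if (any(avoid[zr, yr, xr] != 0)) { clear <- FALSE; break }
          }
          if (!clear) next
          for (j in seq_len(nrow(pts))) {
            out[pts[j, 1], pts[j, 2], pts[j, 3]] <-
              spec$intensity_small + spec$background_mean / 2
            avoid[pts[j, 1], pts[j, 2], pts[j, 3]] <- 1L
          }
          placed <- placed + 1L
          ok <- TRUE
          break
        }
        if (!ok) break
      }
      if (placed < spec$n_speckles)
        warning(sprintf("placed %d of %d speckles (placement retries exhausted)",
                        placed, spec$n_speckles))
    }
    out <- pmin(pmax(out, 0), 255)
    list(image = volume_stack(array(out, d), rep(spec$voxel_size_um, 3)),
         n_speckles_placed = placed)
  })
}

#' Generate a complete phantom volume
#'
#' Convenience wrapper: grows `spec$n_trees` trees, rasterizes them and
#' corrupts the image.
#'
#' @param spec a [phantom_spec()].
#' @param seed seed; defaults to `spec$seed`.
#' @return `list(image, truth, trees, n_speckles_placed)`.
#' @export
generate_phantom <- function(spec, seed = spec$seed) {
  local_seed(seed, {
    trees <- lapply(seq_len(spec$n_trees), function(i)
      generate_tree(spec, seed = NULL))
    ras <- rasterize(trees, spec)
    cor <- corrupt(ras$image, spec, truth = ras$truth, seed = NULL)
    list(image = cor$image, truth = ras$truth, trees = trees,
         n_speckles_placed = cor$n_speckles_placed)
  })
}

#' Build a partitioned block dataset from phantom volumes
#'
#' Randomly crops `n_blocks` blocks from freshly generated phantom volumes
#' and partitions them into train/validation/test splits.  A configurable
#' fraction of the blocks contain background only (noise and speckles, no
#' vessels).
#'
#' @param spec a [phantom_spec()]; `spec$shape` must contain `block_shape`.
#' @param n_blocks number of blocks (>= 1).
#' @param block_shape cropped block shape, scalar or triple.
#' @param split fractions for (train, validation, test); must sum to 1.
#' @param seed seed controlling phantom generation, cropping and the split.
#' @param background_fraction fraction of blocks containing background only
#'   (default 47/179).
#' @param crops_per_volume how many blocks to crop from each generated
#'   phantom volume.
#' @return An object of class `phantom_dataset`: `list(blocks, manifest)`
#'   where `blocks` is a list of `list(id, image, truth, split)` and
#'   `manifest` a data frame (block id, split, background flag).
#' @export
make_dataset <- function(spec, n_blocks, block_shape = c(64, 64, 64),
                         split = c(0.7, 0.15, 0.15), seed = spec$seed,
                         background_fraction = 47 / 179,
                         crops_per_volume = 4) {
  if (n_blocks < 1) stop("n_blocks must be >= 1")
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  bs <- as.integer(as_triple(block_shape, "block_shape"))
  if (any(bs > spec$shape))
    stop("invalid spec: block_shape larger than phantom shape")
  local_seed(seed, {
    n_bg <- round(background_fraction * n_blocks)
    n_fg <- n_blocks - n_bg
    blocks <- vector("list", n_blocks)
    bi <- 0
    while (bi < n_fg) {
      ph <- generate_phantom(spec, seed = NULL)
      img <- ph$image$voxels; tru <- ph$truth$voxels
      d <- spec$shape
      for (k in seq_len(crops_per_volume)) {
        if (bi >= n_fg) break
        for (try in seq_len(20)) {
          o <- c(sample(0:(d[1] - bs[1]), 1), sample(0:(d[2] - bs[2]), 1),
                 sample(0:(d[3] - bs[3]), 1))
          tb <- tru[(o[1] + 1):(o[1] + bs[1]), (o[2] + 1):(o[2] + bs[2]),
                    (o[3] + 1):(o[3] + bs[3])]
          if (sum(tb) > 0 || try == 20) {
            ib <- img[(o[1] + 1):(o[1] + bs[1]), (o[2] + 1):(o[2] + bs[2]),
                      (o[3] + 1):(o[3] + bs[3])]
            bi <- bi + 1
            blocks[[bi]] <- list(id = as.integer(bi), image = ib, truth = tb,
                                 background = FALSE)
            break
          }
        }
      }
    }
    if (n_bg > 0) {
      bg_spec <- spec
      bg_spec$shape <- bs
      class(bg_spec) <- "phantom_spec"
      for (k in seq_len(n_bg)) {
        empty <- volume_stack(array(0, bs), rep(spec$voxel_size_um, 3))
        cor <- corrupt(empty, bg_spec, truth = NULL, seed = NULL)
        bi <- bi + 1
        blocks[[bi]] <- list(id = as.integer(bi), image = cor$image$voxels,
                             truth = array(0L, bs), background = TRUE)
      }
    }
    # disjoint exhaustive split by rounded cumulative fractions
    ord <- sample(n_blocks)
    cuts <- diff(c(0, round(cumsum(split) * n_blocks)))
    labels <- rep(c("train", "val", "test"), times = cuts)
    for (i in seq_len(n_blocks)) blocks[[ord[i]]]$split <- labels[i]
    manifest <- data.frame(
      id = vapply(blocks, `[[`, integer(1), "id"),
      split = vapply(blocks, `[[`, character(1), "split"),
      background = vapply(blocks, `[[`, logical(1), "background"))
    structure(list(blocks = blocks, manifest = manifest, spec = spec,
                   block_shape = bs), class = "phantom_dataset")
  })
}

#' Write a phantom dataset as TIFF slice stacks with a manifest
#'
#' Each block's image and truth go to numbered slice-stack directories
#' (`block_0001/image`, `block_0001/truth`); the manifest is a plain-text
#' table (block id, split, paths).
#'
#' @param dataset a [make_dataset()] result.
#' @param dir output directory.
#' @return Invisibly, the manifest path.
#' @export
write_phantom_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(dataset$blocks, function(b) {
    bdir <- file.path(dir, sprintf("block_%04d", b$id))
    write_stack(round(b$image), file.path(bdir, "image"), compress = TRUE)
    write_stack(b$truth, file.path(bdir, "truth"), compress = TRUE)
    data.frame(id = b$id, split = b$split,
               image = file.path(bdir, "image"),
               truth = file.path(bdir, "truth"))
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.tsv")
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
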