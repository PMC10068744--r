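# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.  All stochastic operations in the package route
# their randomness through this so no global state leaks.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

as_triple <- function(x, what = "value") {
  if (length(x) == 1) x <- rep(x, 3)
  if (length(x) != 3) stop(what, " must have length 1 or 3")
  x
}

# Min-max normalization of an image block to [0, 1]; constant blocks map to 0.
normalize_block <- function(x, eps = 1e-6) {
  lo <- min(x)
  hi <- max(x)
  if (hi - lo < eps) return(array(0, dim(x)))
  (x - lo) / (hi - lo)
}

relu <- function(x) relu_fwd(x)

sigmoid <- function(x) 1 / (1 + exp(-x))

# binarize any 0/1, logical or 0/255 array to integer 0/1
as_binary_array <- function(x) {
  v <- if (inherits(x, "volume_stack")) x$voxels else x
  v <- as.array(v)
  u <- unique(as.vector(v))
  if (!all(u %in% c(0, 1, 255, TRUE, FALSE)))
    stop("mask is not binary (values outside {0, 1, 255})")
  out <- array(as.integer(v != 0), dim(v))
  out
}

voxels_of <- function(x) if (inherits(x, "volume_stack")) x$voxels else as.array(x)

vsize_of <- function(x, default = c(1, 1, 1)) {
  if (inherits(x, "volume_stack")) x$voxel_size_um else default
}
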