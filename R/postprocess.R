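# Morphological post-processing of fused segmentations.
#
# Wall-only labeling leaves a closed cavity in the middle of large vessels.
# A 3D hole fill cannot close a lumen that reaches the volume border
# through an open tube end, but slice-wise 2D filling can: every interior
# cross-section of a tube is a closed annulus.  Hence hole filling runs
# plane-wise over the three slice families.

#' Plane-wise 2D hole filling
#'
#' Applies 2D hole filling over every slice of the x-y, then x-z, then y-z
#' plane families, and repeats the triple once more (six passes in total).
#' One 2D fill converts to foreground every background region of a slice
#' that is not 4-connected to the slice border.  The output is a superset
#' of the input.
#'
#' @param mask binary volume (array or [volume_stack()]; values 0/1 or
#'   0/255).
#' @param passes number of passes over the three plane families
#'   (default 2, i.e. six 2D fills).
#' @return Binary integer array with lumens filled.
#' @export
fill_holes_planewise <- function(mask, passes = 2) {
  m <- as_binary_array(mask)
  for (p in seq_len(passes))
    for (axis in 0:2)
      m <- fill_holes_slices(m, axis)
  m
}

#' Remove small connected components
#'
#' Labels 3D connected components (default 26-connectivity) and deletes
#' every component whose voxel count is strictly below `min_size`; a
#' component of exactly `min_size` voxels is kept.  The output is a subset
#' of the input.
#'
#' @param mask binary volume.
#' @param min_size voxel-count threshold (default 100).
#' @param connectivity 26 (default) or 6.
#' @return Binary integer array.
#' @export
remove_small_components <- function(mask, min_size = 100, connectivity = 26) {
  m <- as_binary_array(mask)
  if (min_size <= 0) return(m)
  lab <- label_components_3d(m, as.integer(connectivity))
  n <- max(lab)
  if (n == 0) return(m)
  sizes <- tabulate(lab[lab > 0], nbins = n)
  keep <- sizes >= min_size
  out <- array(0L, dim(m))
  out[lab > 0 & keep[pmax(lab, 1L)]] <- 1L
  out
}

#' Full morphological clean-up: fill lumens, then drop isolated specks
#'
#' Filling runs first: it can merge wall fragments of one vessel above the
#' size threshold, which removal-first could delete.
#'
#' @param mask binary volume.
#' @param min_size component-size threshold for removal.
#' @param skip_fill,skip_remove stage toggles.
#' @param connectivity component connectivity for removal.
#' @return Binary integer array.
#' @export
postprocess_mask <- function(mask, min_size = 100, skip_fill = FALSE,
                             skip_remove = FALSE, connectivity = 26) {
  m <- as_binary_array(mask)
  if (!skip_fill) m <- fill_holes_planewise(m)
  if (!skip_remove) m <- remove_small_components(m, min_size, connectivity)
  m
}
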