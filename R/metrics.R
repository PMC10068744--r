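# Voxel-overlap metrics, centerline Dice and Hausdorff distance.

#' Confusion counts between a prediction and ground truth
#' @param pred,truth equal-shape binary volumes.
#' @return `list(TP, FP, FN, TN)`.
#' @export
confusion_counts <- function(pred, truth) {
  p <- as_binary_array(pred)
  t <- as_binary_array(truth)
  if (!identical(dim(p), dim(t))) stop("shape mismatch between pred and truth")
  tp <- sum(p & t)
  list(TP = tp, FP = sum(p) - tp, FN = sum(t) - tp,
       TN = length(p) - sum(p | t))
}

#' Voxel-overlap segmentation metrics
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, Dice `2TP/(2TP+FP+FN)` and
#' Jaccard `TP/(TP+FP+FN)`.  If both masks are empty all four metrics are
#' 1; if exactly one is empty they are 0.
#'
#' @param pred,truth equal-shape binary volumes.
#' @return `list(precision, recall, dice, jaccard)`.
#' @export
overlap_metrics <- function(pred, truth) {
  cc <- confusion_counts(pred, truth)
  np <- cc$TP + cc$FP
  nt <- cc$TP + cc$FN
  if (np == 0 && nt == 0)
    return(list(precision = 1, recall = 1, dice = 1, jaccard = 1))
  if (np == 0 || nt == 0)
    return(list(precision = 0, recall = 0, dice = 0, jaccard = 0))
  list(precision = cc$TP / np, recall = cc$TP / nt,
       dice = 2 * cc$TP / (2 * cc$TP + cc$FP + cc$FN),
       jaccard = cc$TP / (cc$TP + cc$FP + cc$FN))
}

#' Centerline Dice (clDice)
#'
#' Topology precision is the fraction of the prediction's skeleton inside
#' the truth mask; topology sensitivity the fraction of the truth's
#' skeleton inside the prediction.  clDice is their harmonic mean.  A
#' centerline miss is penalized much harder than a wall-thickness error,
#' which makes the metric sensitive to broken or spurious branches.
#'
#' @param pred,truth equal-shape binary volumes.
#' @return Scalar in `[0, 1]`.
#' @export
cl_dice <- function(pred, truth) {
  p <- as_binary_array(pred)
  t <- as_binary_array(truth)
  if (!identical(dim(p), dim(t))) stop("shape mismatch between pred and truth")
  if (sum(p) == 0 && sum(t) == 0) return(1)
  if (sum(p) == 0 || sum(t) == 0) return(0)
  sp <- skeletonize3d(p)
  st <- skeletonize3d(t)
  tprec <- if (sum(sp) == 0) 0 else sum(sp & t) / sum(sp)
  tsens <- if (sum(st) == 0) 0 else sum(st & p) / sum(st)
  if (tprec + tsens == 0) return(0)
  2 * tprec * tsens / (tprec + tsens)
}

surface_voxels <- function(m) {
  d <- dim(m)
  pad <- array(0L, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  interior <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  array(as.integer(m & !interior), d)
}

#' Hausdorff distance between two binary masks
#'
#' The symmetric maximum over both directions of the maximum Euclidean
#' distance from a surface voxel of one mask to the nearest surface voxel
#' of the other, computed via distance transforms, in voxel units.
#' `percentile < 1` gives the robust percentile variant (e.g. 0.95 for
#' HD95).
#'
#' @param pred,truth equal-shape non-empty binary volumes.
#' @param percentile 1 for the exact maximum (default), or a quantile in
#'   (0, 1).
#' @return Scalar distance in voxels.
#' @export
hausdorff_distance <- function(pred, truth, percentile = 1) {
  p <- as_binary_array(pred)
  t <- as_binary_array(truth)
  if (!identical(dim(p), dim(t))) stop("shape mismatch between pred and truth")
  if (sum(p) == 0 || sum(t) == 0)
    stop("Hausdorff distance undefined for an empty mask")
  sp <- surface_voxels(p)
  st <- surface_voxels(t)
  dt_t <- edt_from_seeds(st, c(1, 1, 1))
  dt_p <- edt_from_seeds(sp, c(1, 1, 1))
  da <- dt_t[sp == 1L]
  db <- dt_p[st == 1L]
  if (percentile >= 1) max(max(da), max(db))
  else max(quantile(da, percentile, names = FALSE),
           quantile(db, percentile, names = FALSE))
}

#' All segmentation metrics as one row
#'
#' Computes precision, recall, Dice, Jaccard, clDice and Hausdorff
#' distance for a prediction/truth pair.
#'
#' @param pred,truth equal-shape binary volumes.
#' @param hd_percentile passed to [hausdorff_distance()].
#' @return A one-row data frame.
#' @export
evaluate_segmentation <- function(pred, truth, hd_percentile = 1) {
  om <- overlap_metrics(pred, truth)
  hd <- if (sum(as_binary_array(pred)) == 0 || sum(as_binary_array(truth)) == 0)
    NA_real_ else hausdorff_distance(pred, truth, hd_percentile)
  data.frame(precision = om$precision, recall = om$recall, dice = om$dice,
             jaccard = om$jaccard, cldice = cl_dice(pred, truth), hd = hd)
}
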