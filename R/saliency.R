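#' Gradient class-saliency map for one volume
#'
#' Computes the gradient of the pre-sigmoid class score with respect to every
#' input voxel in a single back-propagation pass (network in evaluation
#' mode: dropout off, batch norm on running statistics), takes its absolute
#' value, and min-max normalizes within the brain mask.  Because the model
#' has a single logit, female- and male-targeted gradients have identical
#' magnitude.
#'
#' The pre-sigmoid score is used as the class score to avoid vanishing
#' gradients from sigmoid saturation.
#'
#' @param model A trained `sfcn_model`.
#' @param vol Input `volume3d`.
#' @param mask Logical brain mask (defaults to `vol != 0`).
#' @param normalize Min-max normalize in-mask to [0, 1] (default TRUE).
#' @return A `volume3d` saliency map (0 outside the mask) with attribute
#'   `normalization` ("minmax" or "raw").
#' @export
gradient_saliency <- function(model, vol, mask = NULL, normalize = TRUE) {
  if (is.null(mask)) mask <- bare_array(vol) != 0
  X <- batch_matrix(list(vol))
  fw <- sfcn_forward(model, X, 1L, training = FALSE, keep_cache = TRUE)
  bw <- sfcn_backward(model, fw$cache, 1, training = FALSE)
  g <- abs(bw$dX[, 1])
  if (!all(is.finite(g))) stop("non-finite saliency gradients")
  s <- array(g, dim(vol))
  s[!mask] <- 0
  out <- vol3d(s, voxel_mm(vol))
  attr(out, "normalization") <- "raw"
  if (normalize) out <- minmax_mask(out, mask)
  out
}

minmax_mask <- function(map, mask) {
  v <- bare_array(map)
  inm <- v[mask]
  rng <- range(inm)
  if (diff(rng) < 1e-30) stop_degenerate("constant saliency within mask")
  out <- array(0, dim(v))
  out[mask] <- (inm - rng[1]) / diff(rng)
  out <- vol3d(out, voxel_mm(map))
  attr(out, "normalization") <- "minmax"
  out
}

#' Average saliency maps
#'
#' Voxelwise mean of template-space maps, optionally min-max re-normalized
#' over the mask so downstream figures and region scoring operate on [0, 1].
#'
#' @param maps Non-empty list of `volume3d` maps on a common grid.
#' @param mask Logical mask for re-normalization (defaults to union of
#'   nonzero voxels).
#' @param renormalize Re-normalize the mean map (default TRUE).
#' @return A `volume3d`.
#' @export
average_maps <- function(maps, mask = NULL, renormalize = TRUE) {
  if (!length(maps)) stop_degenerate("no maps to average")
  d <- dim(maps[[1]])
  acc <- array(0, d)
  for (m in maps) {
    stopifnot(identical(dim(m), d))
    acc <- acc + bare_array(m)
  }
  avg <- vol3d(acc / length(maps), voxel_mm(maps[[1]]))
  if (is.null(mask)) mask <- bare_array(avg) != 0
  if (renormalize) avg <- minmax_mask(avg, mask)
  avg
}

#' Per-sex average maps over correctly classified subjects
#'
#' Restricts averaging to correctly classified subjects of each sex, the
#' convention used for the per-sex maps and the composite sex differences
#' map.
#'
#' @param maps Named list of saliency maps keyed by `subject_id`.
#' @param preds Prediction table covering those subjects.
#' @param renormalize Re-normalize each average (default TRUE).
#' @return List with `map_F` and `map_M` (`NULL`, with a warning, when a sex
#'   has no correctly classified subjects).
#' @export
sexwise_average <- function(maps, preds, renormalize = TRUE) {
  correct <- preds[preds$pred == preds$true, ]
  out <- list(map_F = NULL, map_M = NULL)
  for (sx in c("F", "M")) {
    ids <- intersect(correct$subject_id[correct$true == sx], names(maps))
    if (!length(ids)) {
      warning("no correctly classified subjects of sex ", sx)
      next
    }
    out[[paste0("map_", sx)]] <- average_maps(maps[ids],
                                              renormalize = renormalize)
  }
  out
}

#' Spearman correlation between two maps
#'
#' Rank correlation (average ranks for ties) over in-mask voxels; used to
#' compare female- and male-derived average saliency maps.
#'
#' @param mapA,mapB `volume3d` maps on the same grid.
#' @param mask Logical mask.
#' @return Spearman's rho (`NA` with a warning for a constant map).
#' @export
spearman_maps <- function(mapA, mapB, mask) {
  stopifnot(identical(dim(mapA), dim(mapB)), sum(mask) > 1)
  a <- bare_array(mapA)[mask]
  b <- bare_array(mapB)[mask]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant map: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b, method = "spearman")
}
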