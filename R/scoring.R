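#' Region-level saliency scores
#'
#' For every atlas region (background label 0 is never scored): `n_voxels`,
#' `saliency_score` -- the proportion of the region's voxels with saliency
#' strictly greater than `tau` (default 0.1) -- and `mean_saliency`, the mean
#' over all the region's voxels (sub-threshold voxels included).  Regions
#' with zero voxels are dropped with a warning.
#'
#' @param map A min-max normalized saliency `volume3d`.
#' @param atlas A `brain_atlas` on the same grid.
#' @param tau Saliency threshold (strict `>`).
#' @return Data frame `region_id`, `name`, `n_voxels`, `saliency_score`,
#'   `mean_saliency` (one row per region).
#' @export
region_scores <- function(map, atlas, tau = 0.1) {
  stopifnot(inherits(atlas, "brain_atlas"))
  if (!identical(dim(map), dim(atlas$labels)))
    stop("saliency map and atlas grids differ")
  v <- bare_array(map)
  ids <- as.integer(names(atlas$names))
  rows <- lapply(ids, function(id) {
    inr <- atlas$labels == id
    nv <- sum(inr)
    if (nv == 0) return(NULL)
    data.frame(region_id = id, name = unname(atlas$names[as.character(id)]),
               n_voxels = nv,
               saliency_score = sum(v[inr] > tau) / nv,
               mean_saliency = mean(v[inr]),
               stringsAsFactors = FALSE)
  })
  drop <- vapply(rows, is.null, TRUE)
  if (any(drop))
    warning(sum(drop), " empty region(s) excluded from scoring")
  do.call(rbind, rows[!drop])
}

#' Weighted saliency scores
#'
#' Min-max normalizes the per-region mean saliencies across regions (the
#' region with the largest mean gets `norm_mean` 1, the smallest 0) and
#' multiplies by the saliency score.  When all regions share the same mean,
#' normalization is degenerate; `norm_mean` is then defined as 1 for all
#' regions, with a warning.
#'
#' @param table Output of [region_scores()].
#' @return The table with `norm_mean` and `weighted_score` columns added.
#' @export
weighted_scores <- function(table) {
  stopifnot(nrow(table) >= 1)
  rng <- range(table$mean_saliency)
  if (diff(rng) < 1e-15) {
    warning("all regions have equal mean saliency; norm_mean set to 1")
    table$norm_mean <- 1
  } else {
    table$norm_mean <- (table$mean_saliency - rng[1]) / diff(rng)
  }
  table$weighted_score <- table$saliency_score * table$norm_mean
  table
}

#' Top-k regions by weighted saliency score
#'
#' Descending `weighted_score`; ties broken by `saliency_score`, then by
#' `region_id` (stable).
#'
#' @param table Output of [weighted_scores()].
#' @param k Number of regions to return (1 <= k <= nrow).
#' @return The top `k` rows, ranked.
#' @export
top_k <- function(table, k = 10L) {
  if (k <= 0) stop("k must be positive")
  stopifnot(k <= nrow(table), "weighted_score" %in% names(table))
  ord <- order(-table$weighted_score, -table$saliency_score, table$region_id)
  out <- table[ord[seq_len(k)], ]
  rownames(out) <- NULL
  out
}
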