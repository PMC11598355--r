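#' Rank-based TIV tertiles
#'
#' Splits TIV values into three near-equal groups (low, medium, high) by
#' rank, ties broken by stable input order.  Group sizes differ by at most
#' one, with larger groups first (211 values give 71/70/70).
#'
#' @param tivs Numeric TIV values in ml (>= 3 finite values).
#' @return List with `assignment` (integer 1-3 per input), `ranges` (3x2
#'   matrix of min/max per tertile) and `sizes`.
#' @export
tiv_tertiles <- function(tivs) {
  if (sum(is.finite(tivs)) < 3) stop_degenerate("need at least 3 finite TIVs")
  n <- length(tivs)
  sizes <- rep(n %/% 3L, 3L)
  extra <- n %% 3L
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ord <- order(tivs)  # stable for ties
  assignment <- integer(n)
  assignment[ord] <- rep(1:3, times = sizes)
  ranges <- t(vapply(1:3, function(k) range(tivs[assignment == k]), numeric(2)))
  colnames(ranges) <- c("lo", "hi")
  list(assignment = assignment, ranges = ranges, sizes = sizes)
}

#' Per-tertile classification performance
#'
#' Joins predictions to TIVs, splits into TIV tertiles and reports per-sex
#' recall ("female/male accuracy") and balanced accuracy per tertile,
#' mirroring quantile-wise bias tables.  A tertile missing one sex gets `NA`
#' for that recall and for balanced accuracy.
#'
#' @param preds Prediction table.
#' @param tivs TIV in ml, aligned with `preds` rows.
#' @return Data frame: tertile, tiv_lo, tiv_hi, n, recall_f, recall_m,
#'   balanced_accuracy.
#' @export
tertile_performance <- function(preds, tivs) {
  stopifnot(nrow(preds) == length(tivs))
  tt <- tiv_tertiles(tivs)
  rows <- lapply(1:3, function(k) {
    sub <- preds[tt$assignment == k, ]
    m <- compute_metrics(sub)
    data.frame(tertile = c("first", "second", "third")[k],
               tiv_lo = tt$ranges[k, "lo"], tiv_hi = tt$ranges[k, "hi"],
               n = nrow(sub), recall_f = m$recall_f, recall_m = m$recall_m,
               balanced_accuracy = m$balanced_accuracy,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Scott's bandwidth (as used by multivariate KDE implementations):
# sigma * n^(-1/5)
scott_bw <- function(x) stats::sd(x) * length(x)^(-1 / 5)

#' KDE overlap interval of female and male TIV distributions
#'
#' Gaussian kernel-density estimates are computed per sex on a shared dense
#' grid; each sex's support is the set of grid points where its density is
#' at least `threshold` times its own maximum (excluding the low-density
#' tails); the overlap interval is the intersection of the convex hulls of
#' the two supports.  An empty intersection yields an empty interval, not an
#' error.
#'
#' @param tiv_female,tiv_male TIV samples in ml (>= 5 each).
#' @param threshold Relative density threshold (default 0.2).
#' @param n_grid Number of grid points (default 512).
#' @param bw_f,bw_m Kernel bandwidths in ml (default Scott's rule per sex).
#' @return List `lo`, `hi` (NA when empty), `empty`, `threshold`,
#'   `bandwidth_f`, `bandwidth_m`, `grid_step`.
#' @export
kde_overlap <- function(tiv_female, tiv_male, threshold = 0.2, n_grid = 512L,
                        bw_f = scott_bw(tiv_female),
                        bw_m = scott_bw(tiv_male)) {
  stopifnot(length(tiv_female) >= 5, length(tiv_male) >= 5,
            threshold > 0, threshold <= 1)
  h <- max(bw_f, bw_m)
  lo <- min(tiv_female, tiv_male) - 3 * h
  hi <- max(tiv_female, tiv_male) + 3 * h
  grid <- seq(lo, hi, length.out = n_grid)
  df <- stats::density(tiv_female, bw = bw_f, kernel = "gaussian",
                       from = lo, to = hi, n = n_grid)$y
  dm <- stats::density(tiv_male, bw = bw_m, kernel = "gaussian",
                       from = lo, to = hi, n = n_grid)$y
  sup_f <- which(df >= threshold * max(df))
  sup_m <- which(dm >= threshold * max(dm))
  # convex hulls of the supports, then intersect
  a <- max(grid[min(sup_f)], grid[min(sup_m)])
  b <- min(grid[max(sup_f)], grid[max(sup_m)])
  empty <- a > b
  if (any(diff(sup_f) > 1) || any(diff(sup_m) > 1))
    message("kde_overlap: multimodal thresholded support; using convex hulls")
  list(lo = if (empty) NA_real_ else a, hi = if (empty) NA_real_ else b,
       empty = empty, threshold = threshold,
       bandwidth_f = bw_f, bandwidth_m = bw_m,
       grid_step = diff(grid[1:2]))
}

#' Balanced correctly-classified subset within the overlap interval
#'
#' Keeps correctly classified subjects whose TIV lies in `[lo, hi]`, then
#' down-samples the larger sex uniformly at random (seeded) so both sexes
#' contribute equally -- the subset used for the composite sex differences
#' map.
#'
#' @param preds Prediction table.
#' @param tivs TIV in ml aligned with `preds`.
#' @param interval Result of [kde_overlap()] (or any list with `lo`, `hi`).
#' @param seed Integer seed for the down-sampling.
#' @return Character vector of subject ids (empty, with a warning, when a
#'   sex is absent after filtering).
#' @export
balanced_correct_subset <- function(preds, tivs, interval, seed = 1L) {
  if (isTRUE(interval$empty) || is.na(interval$lo))
    stop("overlap interval is empty")
  keep <- preds$pred == preds$true & tivs >= interval$lo & tivs <= interval$hi
  sub <- preds[keep, ]
  ids_f <- sub$subject_id[sub$true == "F"]
  ids_m <- sub$subject_id[sub$true == "M"]
  if (!length(ids_f) || !length(ids_m)) {
    warning("one sex has no correctly classified subjects in the interval")
    return(character(0))
  }
  k <- min(length(ids_f), length(ids_m))
  set.seed(derive_seed(seed, "balanced_subset"))
  if (length(ids_f) > k) ids_f <- sample(ids_f, k)
  if (length(ids_m) > k) ids_m <- sample(ids_m, k)
  c(ids_f, ids_m)
}
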