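#' Build a toy brain parcellation
#'
#' Places `n_regions` disjoint spherical regions inside a conservative
#' ellipsoidal brain envelope on the template grid, standing in for an
#' anatomical parcellation such as CerebrA.  Label 0 is background; labels
#' `1..n_regions` are named `region_1..region_n`.
#'
#' Regions are confined to `envelope_frac` of the template half-extent so
#' that they fall inside the brain mask of even the smallest simulated
#' subject; see the phantom generator for the envelope geometry.
#'
#' @param grid_shape Integer length-3 template grid (voxels per axis).
#' @param n_regions Number of regions (>= 2).
#' @param seed Integer seed; placement is deterministic given the seed.
#' @param voxel_mm Voxel spacing in mm.
#' @param radius Region radius in voxels (default scales with the grid).
#' @param envelope_frac Fraction of the brain envelope semi-axes within which
#'   region centres must lie.
#' @return A `brain_atlas`: list with `labels` (integer 3D array), `names`
#'   (named character vector), `voxel_mm`.
#' @export
make_atlas <- function(grid_shape, n_regions, seed,
                       voxel_mm = c(1, 1, 1),
                       radius = max(2L, round(min(grid_shape) / 16)),
                       envelope_frac = 0.55) {
  grid_shape <- as.integer(grid_shape)
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 16L),
            n_regions >= 2L, radius >= 1)
  set.seed(derive_seed(seed, "atlas"))
  centre <- (grid_shape - 1) / 2
  semi <- envelope_frac * brain_shape_frac() * (grid_shape / 2 - 1)
  centres <- matrix(NA_real_, n_regions, 3)
  placed <- 0L
  for (attempt in seq_len(5000L)) {
    cand <- centre + (runif(3) * 2 - 1) * pmax(semi - radius, 0)
    u <- (cand - centre) / pmax(semi - radius, 1e-9)
    if (sum(u^2) > 1) next
    if (placed > 0L) {
      dists <- sqrt(colSums((t(centres[seq_len(placed), , drop = FALSE]) - cand)^2))
      if (any(dists < 2 * radius + 1)) next
    }
    placed <- placed + 1L
    centres[placed, ] <- cand
    if (placed == n_regions) break
  }
  if (placed < n_regions)
    stop(sprintf("could not place %d disjoint regions of radius %g inside the brain envelope",
                 n_regions, radius))
  ax <- seq_len(grid_shape[1]) - 1
  ay <- seq_len(grid_shape[2]) - 1
  az <- seq_len(grid_shape[3]) - 1
  labels <- array(0L, grid_shape)
  for (r in seq_len(n_regions)) {
    cx <- centres[r, ]
    d2 <- outer(outer((ax - cx[1])^2, (ay - cx[2])^2, `+`), (az - cx[3])^2, `+`)
    labels[d2 <= radius^2] <- r
  }
  nm <- paste0("region_", seq_len(n_regions))
  names(nm) <- seq_len(n_regions)
  structure(list(labels = labels, names = nm, voxel_mm = as.numeric(voxel_mm)),
            class = "brain_atlas")
}

#' @export
print.brain_atlas <- function(x, ...) {
  cat(sprintf("<brain_atlas %s, %d regions>\n",
              paste(dim(x$labels), collapse = "x"), length(x$names)))
  invisible(x)
}

#' Voxel counts per atlas region
#'
#' @param atlas A `brain_atlas`.
#' @return Named integer vector of voxel counts, one entry per region label.
#' @export
atlas_region_sizes <- function(atlas) {
  tab <- table(factor(atlas$labels[atlas$labels > 0], levels = names(atlas$names)))
  stats::setNames(as.integer(tab), names(atlas$names))
}

# anisotropy of the phantom brain: left-right, anterior-posterior,
# inferior-superior proportions of an adult brain, roughly
brain_shape_frac <- function() c(0.82, 0.95, 0.80)
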