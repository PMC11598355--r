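#' Z-score intensity normalization within a brain mask
#'
#' Subtracts the within-mask mean and divides by the within-mask population
#' standard deviation; voxels outside the mask are set to 0.  The normalized
#' volume has in-mask mean 0 and SD 1.
#'
#' @param vol A `volume3d`.
#' @param mask Logical array of the same shape (the brain mask).
#' @return Normalized `volume3d`.
#' @export
zscore_normalize <- function(vol, mask) {
  stopifnot(identical(dim(vol), dim(mask)))
  v <- bare_array(vol)
  inm <- v[mask]
  if (!length(inm)) stop_degenerate("mask is empty")
  mu <- mean(inm)
  sdv <- sqrt(mean((inm - mu)^2))  # population SD
  if (sdv < 1e-12) stop_degenerate("zero within-mask intensity variance")
  out <- array(0, dim(v))
  out[mask] <- (inm - mu) / sdv
  vol3d(out, voxel_mm(vol))
}

#' Mask-based total intracranial volume
#'
#' TIV in ml = (number of mask voxels) x (voxel volume in mm^3) / 1000.
#'
#' @param mask Logical or 0/1 array.
#' @param voxel_mm Voxel spacing in mm (scalar or length 3).
#' @return TIV in ml.
#' @export
estimate_tiv <- function(mask, voxel_mm) {
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  n <- sum(mask != 0)
  if (n == 0) stop_degenerate("empty mask")
  n * prod(voxel_mm) / 1000
}

#' Rigid (6-DOF) transforms
#'
#' A rigid transform is three rotations (degrees, applied as Rz Ry Rx about
#' the volume centre) plus three translations (mm): `T(p) = R p + t` in
#' centred physical coordinates.  Rigid alignment preserves individual brain
#' volume, which is why it is the registration of choice when TIV must not
#' be altered.
#'
#' @param rotations Length-3 rotations in degrees (rx, ry, rz).
#' @param translations Length-3 translations in mm (tx, ty, tz).
#' @return A `rigid_transform`.
#' @export
rigid_transform <- function(rotations = c(0, 0, 0), translations = c(0, 0, 0)) {
  stopifnot(length(rotations) == 3L, length(translations) == 3L,
            all(is.finite(c(rotations, translations))))
  structure(list(rotations = as.numeric(rotations),
                 translations = as.numeric(translations)),
            class = "rigid_transform")
}

rot_matrix <- function(deg) {
  a <- deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  rz %*% ry %*% rx
}

euler_from_rot <- function(R) {
  ry <- -asin(max(-1, min(1, R[3, 1])))
  rx <- atan2(R[3, 2], R[3, 3])
  rz <- atan2(R[2, 1], R[1, 1])
  c(rx, ry, rz) * 180 / pi
}

#' @rdname rigid_transform
#' @param t,t1,t2 `rigid_transform` objects.
#' @export
invert_transform <- function(t) {
  R <- rot_matrix(t$rotations)
  rigid_transform(euler_from_rot(t(R)), as.numeric(-t(R) %*% t$translations))
}

#' @rdname rigid_transform
#' @export
compose_transform <- function(t2, t1) {
  # returns the transform applying t1 first, then t2
  R1 <- rot_matrix(t1$rotations); R2 <- rot_matrix(t2$rotations)
  rigid_transform(euler_from_rot(R2 %*% R1),
                  as.numeric(R2 %*% t1$translations + t2$translations))
}

#' Resample a volume under a rigid transform
#'
#' The output volume at physical point p equals the input at `T^(-1)(p)`,
#' i.e. the input moved by the transform.  Trilinear interpolation by
#' default, background fill 0.
#'
#' @param vol A `volume3d`.
#' @param transform A `rigid_transform`.
#' @param target_shape Output grid (defaults to the input grid).
#' @param target_voxel_mm Output spacing (defaults to the input spacing).
#' @param method "trilinear" or "nearest".
#' @return Resampled `volume3d`.
#' @export
resample <- function(vol, transform = rigid_transform(),
                     target_shape = dim(vol),
                     target_voxel_mm = voxel_mm(vol),
                     method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  if (length(target_voxel_mm) == 1L) target_voxel_mm <- rep(target_voxel_mm, 3L)
  out <- cpp_resample_rigid(as.numeric(bare_array(vol)), dim(vol),
                            voxel_mm(vol), as.integer(target_shape),
                            as.numeric(target_voxel_mm),
                            transform$rotations, transform$translations,
                            method == "nearest")
  vol3d(array(out, target_shape), target_voxel_mm)
}

#' Rigid registration by multi-resolution derivative-free search
#'
#' Finds the 6-DOF transform minimizing the mean squared intensity
#' difference between the moving volume (after resampling onto the fixed
#' grid) and the fixed volume, using a 3-level mean-pooled pyramid and
#' Nelder-Mead search at each level.  `resample(moving, transform)` then
#' approximates `fixed`.
#'
#' @param moving,fixed `volume3d` objects sharing an intensity convention.
#' @param levels Number of pyramid levels (coarsest = factor 2^(levels-1)).
#' @param maxit Nelder-Mead iteration cap per level.
#' @param init Optional initial `rigid_transform`.
#' @return A `rigid_transform` with attributes `mse` (final cost) and
#'   `converged`.
#' @export
rigid_register <- function(moving, fixed, levels = 3L, maxit = 600L,
                           init = rigid_transform()) {
  pyr_m <- list(moving); pyr_f <- list(fixed)
  for (l in seq_len(levels - 1L)) {
    if (any(dim(pyr_m[[l]]) %/% 2L < 8L)) break
    pyr_m[[l + 1L]] <- downsample2(pyr_m[[l]])
    pyr_f[[l + 1L]] <- downsample2(pyr_f[[l]])
  }
  par <- c(init$rotations, init$translations)
  conv <- 0L; val <- NA_real_
  for (l in rev(seq_along(pyr_m))) {
    mv <- pyr_m[[l]]; fx <- pyr_f[[l]]
    fxa <- bare_array(fx)
    cost <- function(p) {
      r <- cpp_resample_rigid(as.numeric(bare_array(mv)), dim(mv),
                              voxel_mm(mv), dim(fx), voxel_mm(fx),
                              p[1:3], p[4:6], FALSE)
      mean((r - fxa)^2)
    }
    opt <- optim(par, cost, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-10,
                                parscale = c(2, 2, 2, 2, 2, 2)))
    par <- opt$par; conv <- opt$convergence; val <- opt$value
  }
  out <- rigid_transform(par[1:3], par[4:6])
  attr(out, "mse") <- val
  attr(out, "converged") <- conv == 0L
  if (conv != 0L)
    warning("rigid_register: iteration cap reached; returning best-so-far transform")
  out
}

#' Stratified train/validation/test split
#'
#' Partitions a cohort into train/val/test within strata defined by
#' sex x site x field, using largest-remainder rounding per stratum followed
#' by a deterministic global correction so the overall totals equal the
#' largest-remainder rounding of `n * fractions`.  Assignment within a
#' stratum is a seeded random permutation.
#'
#' @param cohort Data frame with columns `subject_id`, `sex`, `site`,
#'   `field`.
#' @param fractions Length-3 split fractions summing to 1 (train, val, test).
#' @param seed Integer seed.
#' @param strata Character columns defining the strata.
#' @return Data frame `subject_id`, `split` (train/val/test), `stratum`.
#' @export
stratified_split <- function(cohort, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                             strata = c("sex", "site", "field")) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, all(fractions >= 0))
  miss <- setdiff(c("subject_id", strata), names(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  n <- nrow(cohort)
  splits <- c("train", "val", "test")
  key <- do.call(paste, c(unname(cohort[strata]), sep = "|"))
  global <- largest_remainder(n * fractions, n)
  groups <- split(seq_len(n), key)
  small <- vapply(groups, length, 1L) < sum(fractions > 0)
  if (any(small))
    warning(sprintf("%d stratum/strata smaller than the number of splits; best-effort assignment",
                    sum(small)))
  alloc <- t(vapply(groups, function(ix)
    largest_remainder(length(ix) * fractions, length(ix)), numeric(3)))
  # global correction: move single allocations between splits, preferring the
  # stratum whose quota is most under-served for the receiving split
  quota <- vapply(groups, length, 1L) %o% fractions
  for (k in seq_len(3L)) {
    while (sum(alloc[, k]) > global[k]) {
      under <- which(colSums(alloc) < global)[1]
      cand <- which(alloc[, k] > 0)
      pick <- cand[order(alloc[cand, k] - quota[cand, k],
                         decreasing = TRUE)][1]
      alloc[pick, k] <- alloc[pick, k] - 1
      alloc[pick, under] <- alloc[pick, under] + 1
    }
  }
  set.seed(derive_seed(seed, "split"))
  assign <- character(n)
  for (g in seq_along(groups)) {
    ix <- groups[[g]][sample.int(length(groups[[g]]))]
    assign[ix] <- rep(splits, times = alloc[g, ])
  }
  data.frame(subject_id = cohort$subject_id, split = assign, stratum = key,
             stringsAsFactors = FALSE)
}

# integer allocation by largest remainder, constrained to sum to `total`
largest_remainder <- function(quota, total) {
  base <- floor(quota)
  rem <- quota - base
  need <- round(total - sum(base))
  if (need > 0) {
    extra <- order(rem, decreasing = TRUE)[seq_len(need)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
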