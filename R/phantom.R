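#' Configuration for the synthetic phantom cohort
#'
#' Defines the statistical structure of the simulated study population: a
#' near-balanced sex ratio, a sex difference in total intracranial volume
#' (females on average 10-15% smaller, default deficit 0.125), optional
#' planted regional intensity effects carried by one sex, and site/field
#' covariates assigned independently of sex.
#'
#' The default grid is a desk-scale template (48 voxels per axis at 3 mm)
#' with TIV means rescaled proportionally so phantom brains fit the grid;
#' a full-scale 193x229x193 grid at 1 mm remains configurable.
#'
#' @param n_subjects Number of subjects (>= 0).
#' @param female_fraction Proportion of females (default 0.53, the pooled
#'   multi-site value).
#' @param tiv_mean_male Mean male TIV in ml on this grid scale.
#' @param tiv_deficit_female Proportional female TIV deficit (default 0.125).
#' @param tiv_sd TIV standard deviation in ml (per sex; normal truncated at
#'   +/- 3 SD).
#' @param effect_regions Integer atlas labels carrying the planted regional
#'   effect (may be empty).
#' @param effect_size Additive intensity delta applied inside
#'   `effect_regions` for subjects of `effect_sex` (arbitrary units on the
#'   0-1 tissue intensity scale).
#' @param effect_sex Which sex carries the regional effect ("M" or "F").
#' @param noise_sd Gaussian intensity noise SD inside the brain mask.
#' @param grid_shape Template grid, voxels per axis (>= 16 each).
#' @param voxel_mm Voxel spacing in mm (scalar or length 3).
#' @param age_range Inclusive integer age bounds.
#' @param site_probs Named marginal distribution of sites (scanner vendors).
#' @param field_probs Named marginal distribution of field strengths (tesla).
#' @param seed Integer seed governing all randomness of the generator.
#' @return A validated `phantom_config` list.
#' @export
phantom_config <- function(n_subjects = 200L,
                           female_fraction = 0.53,
                           tiv_mean_male = 800,
                           tiv_deficit_female = 0.125,
                           tiv_sd = 60,
                           effect_regions = integer(0),
                           effect_size = 0,
                           effect_sex = "M",
                           noise_sd = 0.1,
                           grid_shape = c(48L, 48L, 48L),
                           voxel_mm = 3,
                           age_range = c(18L, 95L),
                           site_probs = c(GE = 0.11, Philips = 0.08, Siemens = 0.81),
                           field_probs = c(`1.5` = 0.21, `3` = 0.79),
                           seed = 1L) {
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  cfg <- list(n_subjects = as.integer(n_subjects),
              female_fraction = female_fraction,
              tiv_mean_male = tiv_mean_male,
              tiv_deficit_female = tiv_deficit_female,
              tiv_sd = tiv_sd,
              effect_regions = as.integer(effect_regions),
              effect_size = effect_size,
              effect_sex = effect_sex,
              noise_sd = noise_sd,
              grid_shape = as.integer(grid_shape),
              voxel_mm = as.numeric(voxel_mm),
              age_range = as.integer(age_range),
              site_probs = site_probs,
              field_probs = field_probs,
              seed = as.integer(seed))
  errs <- validate_phantom_config(cfg)
  if (length(errs)) stop(paste(errs, collapse = "; "))
  class(cfg) <- "phantom_config"
  cfg
}

validate_phantom_config <- function(cfg) {
  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(cfg$n_subjects >= 0L, "n_subjects must be >= 0")
  chk(cfg$female_fraction >= 0 && cfg$female_fraction <= 1,
      "female_fraction must be in [0, 1]")
  chk(cfg$tiv_deficit_female >= 0 && cfg$tiv_deficit_female < 1,
      "tiv_deficit_female must be in [0, 1)")
  chk(cfg$tiv_mean_male > 0, "tiv_mean_male must be positive")
  chk(cfg$tiv_sd >= 0, "tiv_sd must be non-negative")
  chk(all(cfg$grid_shape >= 16L), "grid_shape must be >= 16 voxels per axis")
  chk(all(cfg$voxel_mm > 0), "voxel_mm must be positive")
  chk(cfg$noise_sd >= 0, "noise_sd must be non-negative")
  chk(cfg$effect_sex %in% c("F", "M"), "effect_sex must be 'F' or 'M'")
  chk(abs(sum(cfg$site_probs) - 1) < 1e-8, "site_probs must sum to 1")
  chk(abs(sum(cfg$field_probs) - 1) < 1e-8, "field_probs must sum to 1")
  chk(diff(cfg$age_range) >= 0, "age_range must be non-decreasing")
  errs
}

# coordinate grids (voxel index units, 0-based) for a template shape;
# returned as three arrays broadcastable by outer sums
squared_axes <- function(grid_shape, centre, semi_mm, voxel_mm) {
  ax <- ((seq_len(grid_shape[1]) - 1 - centre[1]) * voxel_mm[1] / semi_mm[1])^2
  ay <- ((seq_len(grid_shape[2]) - 1 - centre[2]) * voxel_mm[2] / semi_mm[2])^2
  az <- ((seq_len(grid_shape[3]) - 1 - centre[3]) * voxel_mm[3] / semi_mm[3])^2
  outer(outer(ax, ay, `+`), az, `+`)
}

# ellipsoid mask with semi-axes scale*shape_frac (mm), centred on the grid
ellipsoid_rho2 <- function(grid_shape, voxel_mm, scale_mm) {
  semi <- scale_mm * brain_shape_frac()
  centre <- (grid_shape - 1) / 2
  squared_axes(grid_shape, centre, semi, voxel_mm)
}

# unit-scale quadratic form, cached per grid: ellipsoid_rho2(gs, vx, s)
# equals rho2_unit / s^2, so the scale matching a voxel-count target is a
# kth-smallest lookup rather than a search
.bsm_grid_cache <- new.env(parent = emptyenv())

rho2_unit <- function(grid_shape, voxel_mm) {
  key <- paste(c(grid_shape, signif(voxel_mm, 10)), collapse = "|")
  if (is.null(.bsm_grid_cache[[key]]))
    .bsm_grid_cache[[key]] <- ellipsoid_rho2(grid_shape, voxel_mm, 1)
  .bsm_grid_cache[[key]]
}

#' Generate one brain phantom
#'
#' Builds a brain-extracted synthetic volume: a smooth ellipsoidal "brain"
#' whose mask volume matches `tiv_target` (within voxelisation error), with
#' three concentric tissue-like intensity bands (white matter core, grey
#' matter shell, CSF rim), Gaussian intensity noise inside the mask, and --
#' for subjects of the effect-carrying sex -- an additive intensity shift
#' inside the configured atlas regions.  Background is exactly 0.
#'
#' Randomness (the noise field) is drawn from the current R RNG state; seed
#' upstream for reproducibility.
#'
#' @param sex "F" or "M".
#' @param tiv_target Target mask volume in ml (> 0).
#' @param atlas A `brain_atlas` on the same grid.
#' @param config A `phantom_config`.
#' @return List with `volume` (`volume3d`) and `mask` (logical 3D array).
#' @export
make_phantom <- function(sex, tiv_target, atlas, config) {
  stopifnot(tiv_target > 0, inherits(atlas, "brain_atlas"))
  gs <- config$grid_shape
  vx <- config$voxel_mm
  voxvol <- prod(vx)
  target_vox <- tiv_target * 1000 / voxvol
  k <- max(1L, round(target_vox))
  r2 <- rho2_unit(gs, vx)
  if (k >= length(r2))
    stop(sprintf("tiv_target %.0f ml does not fit the %s grid",
                 tiv_target, paste(gs, collapse = "x")))
  # scale whose ellipsoid contains exactly the k voxels closest to centre
  s2 <- sort(as.vector(r2), partial = k)[k]
  s <- sqrt(s2)
  max_semi_mm <- (gs / 2 - 1) * vx / brain_shape_frac()
  if (s > min(max_semi_mm))
    stop(sprintf("tiv_target %.0f ml does not fit the %s grid",
                 tiv_target, paste(gs, collapse = "x")))
  mask <- r2 <= s2
  if (abs(sum(mask) - target_vox) / target_vox > 0.02)
    stop("phantom mask volume deviates more than 2% from tiv_target")
  rho <- sqrt(pmin(r2 / s2, 1))
  intens <- array(0, gs)
  intens[mask] <- ifelse(rho[mask] < 0.62, 0.9,
                         ifelse(rho[mask] < 0.88, 0.6, 0.35))
  if (length(config$effect_regions) && config$effect_size != 0 &&
      sex == config$effect_sex) {
    hit <- mask & (atlas$labels %in% config$effect_regions)
    intens[hit] <- intens[hit] + config$effect_size
  }
  if (config$noise_sd > 0)
    intens[mask] <- intens[mask] + rnorm(sum(mask), 0, config$noise_sd)
  list(volume = vol3d(intens, vx), mask = mask)
}

#' Generate a synthetic cohort
#'
#' Draws per-subject metadata (sex at the configured fraction, uniform ages,
#' site and field strength independent of sex) and a per-sex truncated-normal
#' TIV (female mean = male mean x (1 - deficit), truncation at +/- 3 SD),
#' then builds one phantom per subject.  Fully reproducible from
#' `config$seed`.
#'
#' @param config A `phantom_config`.
#' @param atlas A `brain_atlas` on `config$grid_shape`.
#' @param dir Optional output directory; when given, each phantom is written
#'   as `<subject_id>.nii.gz` plus `<subject_id>_mask.nii.gz` and the table
#'   gains a `path` column.  When `NULL`, volumes are returned in memory.
#' @param volumes When `FALSE`, only the metadata table is generated (useful
#'   for demographic/splitting studies); the table is identical to the one a
#'   full run would produce.
#' @return List with `cohort` (data.frame: subject_id, sex, age, site, field,
#'   tiv_ml[, path]), and -- when `dir` is `NULL` -- `volumes` and `masks`
#'   lists keyed by subject id.
#' @export
generate_cohort <- function(config, atlas, dir = NULL, volumes = TRUE) {
  stopifnot(inherits(config, "phantom_config"), inherits(atlas, "brain_atlas"))
  if (!identical(dim(atlas$labels), as.integer(config$grid_shape)))
    stop("atlas grid does not match config grid_shape")
  n <- config$n_subjects
  if (n < 0L) stop("n_subjects must be >= 0")
  empty <- data.frame(subject_id = character(0), sex = character(0),
                      age = integer(0), site = character(0),
                      field = numeric(0), tiv_ml = numeric(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(list(cohort = empty, volumes = list(), masks = list()))

  set.seed(derive_seed(config$seed, "cohort"))
  n_f <- round(n * config$female_fraction)
  sex <- sample(c(rep("F", n_f), rep("M", n - n_f)))
  age <- sample(seq(config$age_range[1], config$age_range[2]), n, replace = TRUE)
  site <- sample(names(config$site_probs), n, replace = TRUE,
                 prob = config$site_probs)
  field <- as.numeric(sample(names(config$field_probs), n, replace = TRUE,
                             prob = config$field_probs))
  mu <- ifelse(sex == "F",
               config$tiv_mean_male * (1 - config$tiv_deficit_female),
               config$tiv_mean_male)
  tiv <- rtruncnorm3(n, mu, config$tiv_sd)
  id <- sprintf("sub-%04d", seq_len(n))
  cohort <- data.frame(subject_id = id, sex = sex, age = age, site = site,
                       field = field, tiv_ml = tiv, stringsAsFactors = FALSE)
  if (!volumes) return(list(cohort = cohort))
  volumes <- list(); masks <- list()
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(derive_seed(config$seed, "phantoms"))
  for (i in seq_len(n)) {
    ph <- make_phantom(sex[i], tiv[i], atlas, config)
    if (is.null(dir)) {
      volumes[[id[i]]] <- ph$volume
      masks[[id[i]]] <- ph$mask
    } else {
      write_volume(ph$volume, file.path(dir, paste0(id[i], ".nii.gz")))
      write_volume(vol3d(array(as.numeric(ph$mask), config$grid_shape),
                         config$voxel_mm),
                   file.path(dir, paste0(id[i], "_mask.nii.gz")))
    }
  }
  if (!is.null(dir)) {
    cohort$path <- file.path(dir, paste0(id, ".nii.gz"))
    write.csv(cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
    return(list(cohort = cohort))
  }
  list(cohort = cohort, volumes = volumes, masks = masks)
}

# normal draws truncated at +/- 3 SD (resampling)
rtruncnorm3 <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  bad <- abs(x - mean) > 3 * sd
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean[bad], sd)
    bad <- abs(x - mean) > 3 * sd
  }
  x
}
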