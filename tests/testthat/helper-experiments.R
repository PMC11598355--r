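# Shared desk-scale experiments, memoized so several test files can reuse
# the same trained models instead of retraining.

.exp_cache <- new.env(parent = emptyenv())

desk_channels <- c(4, 8, 8, 16, 16, 8)

# Planted-regional-effect condition: no TIV deficit, two effect regions.
# Full pipeline (training, saliency, composite map, region scoring).
effect_runs <- function(seeds = c(101L, 102L, 103L)) {
  key <- "effect"
  if (!is.null(.exp_cache[[key]])) return(.exp_cache[[key]])
  runs <- lapply(seeds, function(seed) {
    cfg <- run_config(
      phantom = list(n_subjects = 200L, tiv_deficit_female = 0,
                     effect_regions = c(1L, 2L), effect_size = 0.2),
      train = list(epochs = 10L, aug_prob = 0),
      channels = desk_channels, n_regions = 6L, k = 3L, seed = seed)
    out <- file.path(tempdir(), paste0("bsm_effect_", seed))
    res <- suppressWarnings(run_all(cfg, out))
    list(seed = seed, metrics = res$metrics, top = res$top,
         table = res$region_table, composite = res$composite,
         atlas = res$atlas, spearman = res$spearman, overlap = res$overlap,
         tertiles = res$tertiles)
  })
  .exp_cache[[key]] <- runs
  runs
}

# TIV-only condition: volumetric deficit is the sole sex signal.  Runs the
# pipeline stages by hand (no saliency needed), trains to convergence on
# half the cohort and audits tertile performance on the pooled held-out
# val+test subjects, so the extreme tertiles carry stable per-sex counts.
tiv_runs <- function(seeds = c(201L, 202L, 203L)) {
  key <- "tiv"
  if (!is.null(.exp_cache[[key]])) return(.exp_cache[[key]])
  runs <- lapply(seeds, function(seed) {
    pcfg <- phantom_config(n_subjects = 600L, tiv_deficit_female = 0.125,
                           effect_size = 0, seed = derive_seed(seed, "phantom"))
    atlas <- make_atlas(pcfg$grid_shape, 2L, seed = seed,
                        voxel_mm = pcfg$voxel_mm)
    sim <- generate_cohort(pcfg, atlas)
    co <- sim$cohort
    for (id in co$subject_id) {
      co$tiv_ml[co$subject_id == id] <- estimate_tiv(sim$masks[[id]],
                                                     pcfg$voxel_mm)
      sim$volumes[[id]] <- zscore_normalize(sim$volumes[[id]],
                                            sim$masks[[id]])
    }
    sim$masks <- NULL
    spl <- suppressWarnings(
      stratified_split(co, c(0.5, 0.25, 0.25),
                       seed = derive_seed(seed, "split")))
    ix <- split(co$subject_id, spl$split[match(co$subject_id, spl$subject_id)])
    lab <- function(ids) as.integer(co$sex[match(ids, co$subject_id)] == "M")
    model <- sfcn_init(build_sfcn(pcfg$grid_shape, desk_channels),
                       seed = derive_seed(seed, "init"))
    fit <- train_sfcn(model, sim$volumes[ix$train], lab(ix$train),
                      sim$volumes[ix$val], lab(ix$val),
                      train_config(epochs = 10L,
                                   seed = derive_seed(seed, "sgd")))
    held <- c(ix$val, ix$test)
    prob <- sfcn_predict(fit$model, sim$volumes[held])
    preds <- prediction_table(held, prob, co$sex[match(held, co$subject_id)])
    tivs <- co$tiv_ml[match(held, co$subject_id)]
    list(seed = seed, preds = preds, tivs = tivs,
         tertiles = tertile_performance(preds, tivs),
         metrics = compute_metrics(preds))
  })
  .exp_cache[[key]] <- runs
  runs
}

# Central finite-difference check of the saliency gradient at sampled
# voxels.  Voxels where the network is locally non-smooth (a ReLU or
# max-pool kink inside the probe interval, detected by disagreement of FD
# estimates at two step sizes) are excluded; at least `min_smooth` must
# remain and every smooth voxel must match to 1e-3 relative.
expect_fd_match <- function(model, x, ix, min_smooth = 12L) {
  X <- matrix(as.numeric(x), ncol = 1)
  raw <- gradient_saliency(model, x, mask = array(TRUE, dim(x)),
                           normalize = FALSE)
  logit_at <- function(X) brainsexmap:::sfcn_forward(model, X, 1L)$logits
  fd_at <- function(i, eps) {
    Xp <- X; Xp[i] <- Xp[i] + eps
    Xm <- X; Xm[i] <- Xm[i] - eps
    (logit_at(Xp) - logit_at(Xm)) / (2 * eps)
  }
  n_smooth <- 0L
  for (i in ix) {
    f1 <- fd_at(i, 1e-4)
    f2 <- fd_at(i, 2e-4)
    scale <- max(abs(f1), abs(f2), 1e-8)
    if (abs(f1 - f2) > 1e-3 * scale) next  # kink inside probe interval
    n_smooth <- n_smooth + 1L
    testthat::expect_lt(abs(as.numeric(raw)[i] - abs(f1)),
                        1e-3 * max(abs(f1), 1e-8))
  }
  testthat::expect_gte(n_smooth, min_smooth)
}

# small metadata-only cohort for split/demographics tests
meta_cohort <- function(n, seed = 1L, female_fraction = 0.53) {
  cfg <- phantom_config(n_subjects = n, female_fraction = female_fraction,
                        seed = seed)
  atlas <- tiny_atlas()
  generate_cohort(cfg, atlas, volumes = FALSE)$cohort
}

tiny_atlas <- function(seed = 1L) {
  if (is.null(.exp_cache$tiny_atlas))
    .exp_cache$tiny_atlas <- make_atlas(c(48L, 48L, 48L), 4L, seed = seed,
                                        voxel_mm = 3)
  .exp_cache$tiny_atlas
}

# coarse config for cheap phantom construction in unit tests
coarse_config <- function(...) {
  phantom_config(grid_shape = c(24L, 24L, 24L), voxel_mm = 6,
                 tiv_mean_male = 600, tiv_sd = 40, ...)
}

coarse_atlas <- function(seed = 5L) {
  if (is.null(.exp_cache$coarse_atlas))
    .exp_cache$coarse_atlas <- make_atlas(c(24L, 24L, 24L), 2L, seed = seed,
                                          voxel_mm = 6)
  .exp_cache$coarse_atlas
}
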