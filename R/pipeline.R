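#' Assemble a full-run configuration
#'
#' Bundles the phantom-cohort settings, training protocol and analysis
#' settings under a single global seed.  Stage seeds are derived
#' deterministically from the global seed and the stage name, so stages can
#' be re-run in isolation.
#'
#' @param phantom Named list of [phantom_config()] overrides.
#' @param train Named list of [train_config()] overrides.
#' @param channels Six channel widths for the classifier.
#' @param n_regions Number of toy-atlas regions.
#' @param tau Region saliency threshold.
#' @param density_threshold KDE overlap threshold.
#' @param k Top-k regions to report.
#' @param register Rigidly register each phantom to the cohort template
#'   before training (phantoms are generated in a common space, so this
#'   defaults to FALSE).
#' @param split_fractions Train/val/test fractions.
#' @param seed Global integer seed.
#' @return A validated `run_config`.
#' @export
run_config <- function(phantom = list(), train = list(),
                       channels = c(8, 16, 16, 32, 32, 16),
                       n_regions = 6L, tau = 0.1, density_threshold = 0.2,
                       k = 3L, register = FALSE,
                       split_fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  phantom$seed <- derive_seed(seed, "phantom")
  train$seed <- derive_seed(seed, "sgd")
  cfg <- list(phantom = do.call(phantom_config, phantom),
              train = do.call(train_config, train),
              channels = as.integer(channels),
              n_regions = as.integer(n_regions),
              tau = tau, density_threshold = density_threshold,
              k = as.integer(k), register = isTRUE(register),
              split_fractions = split_fractions,
              seed = as.integer(seed))
  errs <- validate_run_config(cfg)
  if (length(errs)) stop(paste(errs, collapse = "; "))
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  errs <- c(errs, validate_phantom_config(cfg$phantom))
  chk(length(cfg$channels) == 6L && all(cfg$channels >= 1),
      "channels must be six positive widths")
  chk(cfg$n_regions >= 2, "n_regions must be >= 2")
  chk(cfg$tau > 0 && cfg$tau < 1, "tau must be in (0, 1)")
  chk(cfg$density_threshold > 0 && cfg$density_threshold <= 1,
      "density_threshold must be in (0, 1]")
  chk(cfg$k >= 1, "k must be >= 1")
  chk(abs(sum(cfg$split_fractions) - 1) < 1e-8,
      sprintf("split_fractions sum to %.3f, expected 1",
              sum(cfg$split_fractions)))
  chk(cfg$train$lr0 > 0, "lr0 must be positive")
  errs
}

#' Load and validate a run configuration from JSON
#'
#' All invariant violations are aggregated into a single error report rather
#' than failing on the first.
#'
#' @param path JSON file with (optional) `phantom`, `train` and analysis
#'   fields as accepted by [run_config()].
#' @return A `run_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- raw[intersect(names(raw),
                        setdiff(names(formals(run_config)), c("phantom", "train")))]
  args$phantom <- as.list(raw$phantom)
  args$train <- as.list(raw$train)
  tryCatch(do.call(run_config, args),
           error = function(e) stop("invalid config: ", conditionMessage(e)))
}

#' Run the full experiment
#'
#' Simulate a phantom cohort, preprocess (z-score, mask TIV, optional rigid
#' registration), split, train the classifier, evaluate globally and by
#' subgroup, audit TIV bias (tertile table + KDE overlap), build per-sex and
#' composite saliency maps from correctly classified subjects (composite
#' from the TIV-balanced subset), and score atlas regions.  All artifacts are
#' written under `out_dir`; identical config + seed reproduces identical
#' tables and maps.
#'
#' @param config A `run_config`.
#' @param out_dir Writable output directory.
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the main in-memory results (cohort, split,
#'   metrics, tertiles, overlap, region table, manifest).
#' @export
run_all <- function(config, out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- "simulate"
  res <- tryCatch({
    say("[simulate] n=%d", config$phantom$n_subjects)
    atlas <- make_atlas(config$phantom$grid_shape, config$n_regions,
                        seed = derive_seed(config$seed, "atlas_stage"),
                        voxel_mm = config$phantom$voxel_mm)
    sim <- generate_cohort(config$phantom, atlas)
    cohort <- sim$cohort
    write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)

    stage <- "preprocess"
    say("[preprocess] z-score + TIV")
    template <- NULL
    vols <- sim$volumes
    for (id in cohort$subject_id) {
      v <- vols[[id]]; m <- sim$masks[[id]]
      if (config$register) {
        if (is.null(template)) template <- v
        else {
          tr <- rigid_register(v, template)
          v <- resample(v, tr)
          m <- bare_array(resample(vol3d(array(as.numeric(m), dim(m)),
                                         voxel_mm(v)), tr)) >= 0.5
        }
      }
      cohort$tiv_ml[cohort$subject_id == id] <-
        estimate_tiv(m, config$phantom$voxel_mm)
      vols[[id]] <- zscore_normalize(v, m)
    }

    stage <- "split"
    spl <- stratified_split(cohort, config$split_fractions,
                            seed = derive_seed(config$seed, "split_stage"))
    write.csv(spl, file.path(out_dir, "split.csv"), row.names = FALSE)
    ix <- split(cohort$subject_id,
                spl$split[match(cohort$subject_id, spl$subject_id)])
    lab <- function(ids) as.integer(cohort$sex[match(ids, cohort$subject_id)] == "M")

    stage <- "train"
    say("[train] %d train / %d val", length(ix$train), length(ix$val))
    spec <- build_sfcn(config$phantom$grid_shape, config$channels)
    model0 <- sfcn_init(spec, seed = derive_seed(config$seed, "init_stage"))
    fit <- train_sfcn(model0, vols[ix$train], lab(ix$train),
                      vols[ix$val], lab(ix$val), config$train,
                      verbose = verbose)
    jsonlite::write_json(list(history = fit$history,
                              selected_epoch = fit$selected_epoch),
                         file.path(out_dir, "history.json"),
                         dataframe = "columns", auto_unbox = TRUE, digits = NA)
    saveRDS(fit$model, file.path(out_dir, "model.rds"))

    stage <- "evaluate"
    test_ids <- ix$test
    prob <- sfcn_predict(fit$model, vols[test_ids], config$train$batch_size)
    preds <- prediction_table(test_ids, prob,
                              cohort$sex[match(test_ids, cohort$subject_id)])
    write.csv(preds, file.path(out_dir, "predictions.csv"), row.names = FALSE)
    metrics <- compute_metrics(preds)
    subgroups <- subgroup_report(preds, cohort)
    jsonlite::write_json(list(global = metrics, subgroups = subgroups),
                         file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    say("[evaluate] test acc %.3f bal acc %.3f", metrics$accuracy,
        metrics$balanced_accuracy)

    stage <- "tiv_audit"
    tivs <- cohort$tiv_ml[match(test_ids, cohort$subject_id)]
    tert <- tertile_performance(preds, tivs)
    write.csv(tert, file.path(out_dir, "tertiles.csv"), row.names = FALSE)
    sex_t <- cohort$sex[match(test_ids, cohort$subject_id)]
    overlap <- kde_overlap(tivs[sex_t == "F"], tivs[sex_t == "M"],
                           threshold = config$density_threshold)
    jsonlite::write_json(overlap, file.path(out_dir, "rtiv.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")

    stage <- "saliency"
    say("[saliency] %d test maps", length(test_ids))
    maps <- lapply(stats::setNames(test_ids, test_ids), function(id)
      gradient_saliency(fit$model, vols[[id]], mask = sim$masks[[id]]))
    sal_dir <- file.path(out_dir, "saliency")
    dir.create(sal_dir, showWarnings = FALSE)
    for (id in test_ids)
      write_volume(maps[[id]], file.path(sal_dir, paste0(id, ".nii.gz")))
    sexmaps <- sexwise_average(maps, preds)
    if (!is.null(sexmaps$map_F))
      write_volume(sexmaps$map_F, file.path(out_dir, "map_F.nii.gz"))
    if (!is.null(sexmaps$map_M))
      write_volume(sexmaps$map_M, file.path(out_dir, "map_M.nii.gz"))
    rho <- if (!is.null(sexmaps$map_F) && !is.null(sexmaps$map_M))
      spearman_maps(sexmaps$map_F, sexmaps$map_M,
                    bare_array(sexmaps$map_F) != 0 |
                      bare_array(sexmaps$map_M) != 0) else NA_real_
    subset_ids <- if (!isTRUE(overlap$empty))
      balanced_correct_subset(preds, tivs, overlap,
                              seed = derive_seed(config$seed, "subset")) else
      character(0)
    comp_ids <- if (length(subset_ids)) subset_ids else
      preds$subject_id[preds$pred == preds$true]
    composite <- average_maps(maps[comp_ids])
    write_volume(composite, file.path(out_dir, "sex_differences_map.nii.gz"))

    stage <- "score"
    table <- weighted_scores(region_scores(composite, atlas, tau = config$tau))
    write.csv(table, file.path(out_dir, "region_scores.csv"), row.names = FALSE)
    top <- top_k(table, min(config$k, nrow(table)))
    jsonlite::write_json(top[, c("name", "weighted_score")],
                         file.path(out_dir, "topk.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)

    manifest <- list(config_hash = config_hash(config),
                     seed = config$seed,
                     n_subjects = config$phantom$n_subjects,
                     grid = config$phantom$grid_shape,
                     channels = config$channels,
                     selected_epoch = fit$selected_epoch,
                     test_accuracy = metrics$accuracy,
                     test_balanced_accuracy = metrics$balanced_accuracy,
                     spearman_f_vs_m = rho,
                     n_balanced_subset = length(subset_ids),
                     r_tiv = overlap[c("lo", "hi")],
                     package_version = as.character(utils::packageVersion("brainsexmap")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    list(cohort = cohort, split = spl, metrics = metrics,
         subgroups = subgroups, tertiles = tert, overlap = overlap,
         spearman = rho, region_table = table, top = top,
         manifest = manifest, predictions = preds, composite = composite,
         atlas = atlas, sexmaps = sexmaps)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}
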