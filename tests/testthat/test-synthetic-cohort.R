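test_that("atlas regions are disjoint, named, inside the envelope, and deterministic", {
  a1 <- make_atlas(c(32, 32, 32), 2L, seed = 1)
  expect_setequal(unique(as.vector(a1$labels)), c(0L, 1L, 2L))
  a2 <- make_atlas(c(32, 32, 32), 2L, seed = 1)
  expect_identical(a1$labels, a2$labels)
  a3 <- make_atlas(c(32, 32, 32), 4L, seed = 3)
  # brute-force voxel count per label: spheres of the default radius
  r <- max(2L, round(32 / 16))
  min_vox <- sum(outer(outer((-r:r)^2, (-r:r)^2, `+`), (-r:r)^2, `+`) <= r^2) / 2
  sizes <- atlas_region_sizes(a3)
  expect_length(sizes, 4L)
  expect_true(all(sizes >= min_vox))
  # disjoint by construction: total labelled voxels equals sum of per-label counts
  expect_identical(sum(a3$labels > 0), sum(sizes))
})

test_that("atlas placement fails cleanly when regions cannot fit", {
  expect_error(make_atlas(c(16, 16, 16), 50L, seed = 1, radius = 4),
               "could not place")
})

test_that("empty cohort yields an empty table and no volumes", {
  out <- generate_cohort(phantom_config(n_subjects = 0L), tiny_atlas())
  expect_identical(nrow(out$cohort), 0L)
  expect_length(out$volumes, 0L)
})

test_that("female TIV deficit is reproduced within the generator's own sampling error", {
  cfg <- phantom_config(n_subjects = 400L, tiv_deficit_female = 0.125,
                        seed = 7L)
  co <- generate_cohort(cfg, tiny_atlas(), volumes = FALSE)$cohort
  ratio <- mean(co$tiv_ml[co$sex == "F"]) / mean(co$tiv_ml[co$sex == "M"])
  # Monte-Carlo oracle: the ratio distribution under fresh truncated-normal
  # draws at the same per-sex sample sizes
  n_f <- sum(co$sex == "F"); n_m <- sum(co$sex == "M")
  draw <- function(n, mu) {
    x <- rnorm(n, mu, cfg$tiv_sd)
    while (any(bad <- abs(x - mu) > 3 * cfg$tiv_sd))
      x[bad] <- rnorm(sum(bad), mu, cfg$tiv_sd)
    x
  }
  set.seed(424242)
  sims <- replicate(500, mean(draw(n_f, cfg$tiv_mean_male * 0.875)) /
                           mean(draw(n_m, cfg$tiv_mean_male)))
  ci <- quantile(sims, c(0.025, 0.975))
  expect_gt(ratio, ci[1])
  expect_lt(ratio, ci[2])
})

test_that("pooled-demographics cohort is 53% female after rounding", {
  co <- meta_cohort(2110L, seed = 9L, female_fraction = 1115 / 2110)
  expect_equal(sum(co$sex == "F"), 1115)
  expect_equal(round(100 * mean(co$sex == "F")), 53)
})

test_that("phantom mask matches its TIV target and stays inside the grid", {
  atlas <- make_atlas(c(64, 64, 64), 2L, seed = 2, voxel_mm = 3)
  cfg <- phantom_config(grid_shape = c(64, 64, 64), voxel_mm = 3,
                        tiv_mean_male = 1200, tiv_sd = 60)
  set.seed(1)
  ph <- make_phantom("M", 1200, atlas, cfg)
  tiv <- estimate_tiv(ph$mask, 3)
  expect_lt(abs(tiv - 1200) / 1200, 0.02)
  # containment: no mask voxel on the grid boundary
  expect_false(any(ph$mask[c(1, 64), , ]) || any(ph$mask[, c(1, 64), ]) ||
                 any(ph$mask[, , c(1, 64)]))
  # background exactly zero
  expect_true(all(ph$volume[!ph$mask] == 0))
})

test_that("oversized TIV targets raise a sizing error", {
  expect_error(make_phantom("M", 5000, coarse_atlas(), coarse_config()),
               "does not fit")
})

test_that("mask-volume fidelity holds across a sampled cohort", {
  cfg <- coarse_config(n_subjects = 20L, seed = 3L)
  sim <- generate_cohort(cfg, coarse_atlas())
  for (id in sim$cohort$subject_id) {
    target <- sim$cohort$tiv_ml[sim$cohort$subject_id == id]
    got <- estimate_tiv(sim$masks[[id]], cfg$voxel_mm)
    expect_lt(abs(got - target) / target, 0.02)
  }
})

test_that("with no planted effect, region intensities differ between sexes only by noise", {
  # 50 male/female pairs at identical TIV: two-sample t-test on mean
  # intensity inside region 1 should be non-significant
  atlas <- coarse_atlas()
  cfg <- coarse_config(effect_regions = 1L, effect_size = 0)
  set.seed(11)
  reg <- atlas$labels == 1L
  m_means <- f_means <- numeric(50)
  for (i in 1:50) {
    m_means[i] <- mean(make_phantom("M", 600, atlas, cfg)$volume[reg])
    f_means[i] <- mean(make_phantom("F", 600, atlas, cfg)$volume[reg])
  }
  expect_gt(t.test(m_means, f_means)$p.value, 0.01)
  # and with an effect, the same comparison separates clearly
  cfg2 <- coarse_config(effect_regions = 1L, effect_size = 0.2)
  set.seed(11)
  m2 <- replicate(20, mean(make_phantom("M", 600, atlas, cfg2)$volume[reg]))
  f2 <- replicate(20, mean(make_phantom("F", 600, atlas, cfg2)$volume[reg]))
  expect_lt(t.test(m2, f2)$p.value, 1e-6)
})

test_that("cohort generation is bit-identical for a fixed seed", {
  cfg <- coarse_config(n_subjects = 6L, seed = 21L)
  s1 <- generate_cohort(cfg, coarse_atlas())
  s2 <- generate_cohort(cfg, coarse_atlas())
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$volumes, s2$volumes)
})

test_that("with zero deficit, TIV distributions are exchangeable between sexes", {
  set.seed(99)
  pvals <- vapply(1:20, function(i) {
    co <- generate_cohort(phantom_config(n_subjects = 120L,
                                         tiv_deficit_female = 0,
                                         seed = 1000L + i),
                          tiny_atlas(), volumes = FALSE)$cohort
    suppressWarnings(ks.test(co$tiv_ml[co$sex == "F"],
                             co$tiv_ml[co$sex == "M"])$p.value)
  }, numeric(1))
  # p-values behave like draws from a uniform: KS against U(0,1)
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
  expect_gt(mean(pvals), 0.2)
})

test_that("cohort volumes round-trip through NIfTI with spacing preserved", {
  dir <- withr::local_tempdir()
  cfg <- coarse_config(n_subjects = 2L, seed = 4L)
  out <- generate_cohort(cfg, coarse_atlas(), dir = dir)
  expect_true(all(file.exists(out$cohort$path)))
  v <- read_volume(out$cohort$path[1])
  expect_equal(voxel_mm(v), c(6, 6, 6))
  m <- read_volume(file.path(dir, paste0(out$cohort$subject_id[1],
                                         "_mask.nii.gz")))
  expect_equal(estimate_tiv(bare_mask <- (as.array(m) > 0.5), c(6, 6, 6)),
               out$cohort$tiv_ml[1], tolerance = 0.02)
})
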