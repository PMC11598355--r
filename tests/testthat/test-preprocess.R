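test_that("z-scoring yields in-mask mean 0 and SD 1, zero background", {
  set.seed(2)
  ph <- make_phantom("F", 600, coarse_atlas(), coarse_config())
  z <- zscore_normalize(ph$volume, ph$mask)
  inm <- as.numeric(z)[ph$mask]
  expect_equal(mean(inm), 0, tolerance = 1e-6)
  expect_equal(sqrt(mean(inm^2)), 1, tolerance = 1e-6)
  expect_true(all(as.numeric(z)[!ph$mask] == 0))
  # idempotence
  z2 <- zscore_normalize(z, ph$mask)
  expect_equal(as.numeric(z2), as.numeric(z), tolerance = 1e-6)
})

test_that("z-scoring rejects constant volumes and honours the two-point case", {
  v <- vol3d(array(5, c(4, 4, 4)))
  m <- array(TRUE, c(4, 4, 4))
  expect_error(zscore_normalize(v, m), class = "bsm_degenerate_input")
  v2 <- vol3d(array(0, c(4, 4, 4)))
  v2[1, 1, 1] <- 1; v2[2, 1, 1] <- 3
  m2 <- array(FALSE, c(4, 4, 4)); m2[1:2, 1, 1] <- TRUE
  z <- zscore_normalize(v2, m2)
  expect_equal(as.numeric(z[1:2, 1, 1]), c(-1, 1))
})

test_that("TIV is voxel count times voxel volume over 1000", {
  expect_equal(estimate_tiv(array(TRUE, c(100, 100, 100)), 1), 1000)
  m <- array(FALSE, c(10, 10, 10)); m[1:500] <- TRUE
  expect_equal(estimate_tiv(m, c(2, 1, 1)), 1.0)
  expect_error(estimate_tiv(array(FALSE, c(4, 4, 4)), 1),
               class = "bsm_degenerate_input")
})

test_that("resampling honours identity, inversion round-trips, and lattice shifts", {
  set.seed(3)
  ph <- make_phantom("M", 600, coarse_atlas(), coarse_config())
  v <- ph$volume
  expect_equal(as.numeric(resample(v, rigid_transform())), as.numeric(v),
               tolerance = 1e-12)
  # round trip on smooth (band-limited) content, where interpolation error
  # is well defined: a broad Gaussian blob
  d2 <- outer(outer((1:24 - 12.5)^2, (1:24 - 12.5)^2, `+`), (1:24 - 12.5)^2, `+`)
  smooth <- vol3d(exp(-d2 / 72), c(6, 6, 6))
  t1 <- rigid_transform(rotations = c(4, -3, 2), translations = c(5, -4, 3))
  back <- resample(resample(smooth, t1), invert_transform(t1))
  core <- d2 <= 64  # away from the field-of-view edge
  expect_lt(mean(abs(back[core] - smooth[core])) / sd(smooth[core]), 0.05)
  # integer-voxel translation, nearest neighbour: exact shift
  sh <- resample(v, rigid_transform(translations = c(6, 0, 0)),
                 method = "nearest")  # +1 voxel at 6 mm spacing
  expect_equal(as.numeric(sh[2:24, , ]), as.numeric(v[1:23, , ]))
})

test_that("transform composition and inversion are consistent", {
  t1 <- rigid_transform(c(3, -2, 5), c(2, 1, -4))
  t2 <- rigid_transform(c(-1, 4, 2), c(-3, 2, 1))
  c12 <- compose_transform(t2, t1)
  ident <- compose_transform(invert_transform(c12), c12)
  expect_equal(ident$rotations, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(ident$translations, c(0, 0, 0), tolerance = 1e-10)
})

test_that("registration recovers identity, planted translations and rotations", {
  set.seed(4)
  cfg <- phantom_config(noise_sd = 0.02)
  atlas <- tiny_atlas()
  ph <- make_phantom("M", 800, atlas, cfg)
  fixed <- ph$volume
  t0 <- suppressWarnings(rigid_register(fixed, fixed))
  expect_lt(max(abs(t0$rotations)), 0.1)
  expect_lt(max(abs(t0$translations)), 0.1 * 3)  # 0.1 voxel at 3 mm
  # known translation of (3, -2, 1) voxels = (9, -6, 3) mm
  tr <- rigid_transform(translations = c(9, -6, 3))
  moved <- resample(fixed, tr)
  rec <- suppressWarnings(rigid_register(moved, fixed))
  # registering moved onto fixed recovers the inverse transform
  expect_lt(max(abs(rec$translations - c(-9, 6, -3))), 0.5 * 3)
  # known rotation of 5 degrees about one axis
  rot <- rigid_transform(rotations = c(0, 5, 0))
  movedr <- resample(fixed, rot)
  recr <- suppressWarnings(rigid_register(movedr, fixed))
  expect_lt(abs(recr$rotations[2] - (-5)), 1)
  # rigid invariance of volume: mask TIV changes < 2% under the recovered map
  mask <- ph$mask
  remask <- resample(vol3d(array(as.numeric(mask), dim(mask)), voxel_mm(fixed)),
                     tr)
  tiv0 <- estimate_tiv(mask, voxel_mm(fixed))
  tiv1 <- estimate_tiv(as.numeric(remask) >= 0.5, voxel_mm(fixed))
  expect_lt(abs(tiv1 - tiv0) / tiv0, 0.02)
})

test_that("stratified split reproduces the pooled-cohort arithmetic and is stable", {
  co <- meta_cohort(2110L, seed = 5L, female_fraction = 1115 / 2110)
  s <- suppressWarnings(stratified_split(co, c(0.8, 0.1, 0.1), seed = 2))
  expect_equal(unname(table(s$split)[c("train", "val", "test")]),
               c(1688L, 211L, 211L), ignore_attr = TRUE)
  s2 <- suppressWarnings(stratified_split(co, c(0.8, 0.1, 0.1), seed = 2))
  expect_identical(s, s2)
  # different seed: same totals, proportions per stratum within +/- 1
  s3 <- suppressWarnings(stratified_split(co, c(0.8, 0.1, 0.1), seed = 3))
  expect_equal(table(s3$split), table(s$split))
  tab2 <- table(s$stratum, s$split)
  tab3 <- table(s3$stratum, s3$split)
  expect_true(all(abs(tab2 - tab3) <= 1))
})

test_that("split handles exact fractions and small strata", {
  co <- data.frame(subject_id = sprintf("s%02d", 1:10),
                   sex = "F", site = "A", field = 3)
  s <- stratified_split(co, c(0.8, 0.1, 0.1), seed = 1)
  expect_equal(unname(table(s$split)[c("train", "val", "test")]),
               c(8L, 1L, 1L), ignore_attr = TRUE)
  expect_warning(
    stratified_split(data.frame(subject_id = c("a", "b"), sex = c("F", "M"),
                                site = "A", field = 3),
                     c(0.8, 0.1, 0.1), seed = 1),
    "best-effort")
})

test_that("per-stratum allocations follow largest-remainder rounding", {
  co <- data.frame(subject_id = sprintf("s%03d", 1:100),
                   sex = rep(c("F", "M"), each = 50),
                   site = rep(c("A", "B"), times = 50), field = 3)
  s <- stratified_split(co, c(0.8, 0.1, 0.1), seed = 7)
  tab <- table(s$stratum, s$split)
  # 4 strata of 25: quotas (20, 2.5, 2.5); every allocation within 1 of quota
  for (st in rownames(tab)) {
    expect_equal(unname(tab[st, "train"]), 20)
    expect_true(all(abs(tab[st, c("val", "test")] - 2.5) <= 0.5))
  }
  expect_equal(unname(colSums(tab)[c("train", "val", "test")]),
               c(80, 10, 10), ignore_attr = TRUE)
})
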