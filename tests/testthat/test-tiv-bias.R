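test_that("tertile sizes follow the near-equal rank split", {
  expect_equal(tiv_tertiles(seq_len(210))$sizes, c(70L, 70L, 70L))
  t211 <- tiv_tertiles(rnorm(211, 1500, 100))
  expect_equal(t211$sizes, c(71L, 70L, 70L))
  t3 <- tiv_tertiles(c(2, 1, 3))
  expect_equal(t3$assignment, c(2L, 1L, 3L))
  expect_error(tiv_tertiles(c(1, 2)), class = "bsm_degenerate_input")
})

test_that("tertile assignment matches a sort-and-slice oracle and ranges are ordered", {
  set.seed(8)
  x <- rnorm(211, 1500, 120)
  tt <- tiv_tertiles(x)
  ord <- order(x)
  oracle <- integer(211)
  oracle[ord] <- rep(1:3, times = c(71, 70, 70))
  expect_equal(tt$assignment, oracle)
  expect_true(all(diff(as.vector(t(tt$ranges))) >= 0))
  # union of tertiles is the full sample
  expect_equal(sort(table(tt$assignment)), sort(c(`1` = 71, `2` = 70, `3` = 70)),
               ignore_attr = TRUE)
})

test_that("a perfect classifier scores 1.0 in every tertile and rows aggregate to the global confusion", {
  set.seed(12)
  n <- 90
  true <- sample(c("F", "M"), n, replace = TRUE)
  tivs <- rnorm(n, 1500, 100)
  perfect <- prediction_table(sprintf("s%d", 1:n),
                              ifelse(true == "M", 0.9, 0.1), true)
  tp <- tertile_performance(perfect, tivs)
  expect_equal(tp$balanced_accuracy, rep(1, 3))
  # aggregation: per-tertile confusions sum to the global one
  noisy <- prediction_table(sprintf("s%d", 1:n), runif(n), true)
  tt <- tiv_tertiles(tivs)
  agg <- Reduce(`+`, lapply(1:3, function(k)
    confusion(noisy[tt$assignment == k, ])))
  expect_equal(agg, confusion(noisy))
})

test_that("a tertile missing one sex yields NA recalls, flagged not zero", {
  true <- c(rep("F", 10), rep("M", 20))
  tivs <- c(seq(1000, 1090, by = 10), seq(1200, 1390, by = 10))
  preds <- prediction_table(sprintf("s%d", 1:30),
                            ifelse(true == "M", 0.9, 0.1), true)
  tp <- tertile_performance(preds, tivs)
  expect_true(is.na(tp$recall_m[1]))   # lowest tertile is all female
  expect_true(is.na(tp$balanced_accuracy[1]))
  expect_false(is.na(tp$recall_f[1]))
})

test_that("KDE overlap equals a dense-grid brute-force evaluation", {
  set.seed(15)
  f <- rnorm(105, 1300, 60)
  m <- rnorm(105, 1500, 60)
  ov <- kde_overlap(f, m, threshold = 0.2)
  # brute force: evaluate both Gaussian KDEs directly on a fine grid
  bw_f <- sd(f) * length(f)^(-1 / 5)
  bw_m <- sd(m) * length(m)^(-1 / 5)
  grid <- seq(min(c(f, m)) - 3 * max(bw_f, bw_m),
              max(c(f, m)) + 3 * max(bw_f, bw_m), length.out = 4096)
  kde <- function(x, bw) vapply(grid, function(g)
    mean(dnorm(g, x, bw)), numeric(1))
  df <- kde(f, bw_f); dm <- kde(m, bw_m)
  sf <- range(grid[df >= 0.2 * max(df)])
  sm <- range(grid[dm >= 0.2 * max(dm)])
  lo <- max(sf[1], sm[1]); hi <- min(sf[2], sm[2])
  expect_lt(abs(ov$lo - lo), ov$grid_step + diff(grid[1:2]))
  expect_lt(abs(ov$hi - hi), ov$grid_step + diff(grid[1:2]))
  expect_false(ov$empty)
})

test_that("identical samples give their own thresholded support; disjoint samples give empty overlap", {
  set.seed(16)
  x <- rnorm(50, 1400, 80)
  ov <- kde_overlap(x, x)
  d <- density(x, bw = sd(x) * 50^(-1 / 5), from = ov$lo - 1, to = ov$hi + 1,
               n = 512)
  expect_equal(ov$bandwidth_f, ov$bandwidth_m)
  # support endpoints have density >= threshold * max on the shared grid
  dd <- density(x, bw = ov$bandwidth_f,
                from = min(x) - 3 * ov$bandwidth_f,
                to = max(x) + 3 * ov$bandwidth_f, n = 512)
  sup <- range(dd$x[dd$y >= 0.2 * max(dd$y)])
  expect_equal(c(ov$lo, ov$hi), sup, tolerance = 2 * ov$grid_step)
  far <- kde_overlap(rnorm(50, 1000, 10), rnorm(50, 2000, 10))
  expect_true(far$empty)
  expect_true(is.na(far$lo))
})

test_that("raising the density threshold never widens the interval", {
  set.seed(19)
  f <- rnorm(80, 1350, 70); m <- rnorm(80, 1480, 70)
  prev <- kde_overlap(f, m, threshold = 0.1)
  for (th in c(0.2, 0.4, 0.6)) {
    cur <- kde_overlap(f, m, threshold = th)
    if (cur$empty) break
    expect_gte(cur$lo, prev$lo - 1e-9)
    expect_lte(cur$hi, prev$hi + 1e-9)
    prev <- cur
  }
})

test_that("balanced subset keeps all when already balanced and down-samples reproducibly", {
  true <- c(rep("F", 5), rep("M", 5))
  preds <- prediction_table(sprintf("s%d", 1:10),
                            ifelse(true == "M", 0.9, 0.1), true)
  tivs <- rep(1500, 10)
  iv <- list(lo = 1400, hi = 1600, empty = FALSE)
  expect_setequal(balanced_correct_subset(preds, tivs, iv, seed = 1),
                  preds$subject_id)
  # 10 F vs 6 M correct in range: 6 + 6, seeded draw reproducible
  true2 <- c(rep("F", 10), rep("M", 6))
  preds2 <- prediction_table(sprintf("t%d", 1:16),
                             ifelse(true2 == "M", 0.9, 0.1), true2)
  tivs2 <- rep(1500, 16)
  s1 <- balanced_correct_subset(preds2, tivs2, iv, seed = 7)
  s2 <- balanced_correct_subset(preds2, tivs2, iv, seed = 7)
  expect_identical(s1, s2)
  expect_equal(sum(s1 %in% preds2$subject_id[true2 == "F"]), 6)
  expect_length(s1, 12)
  # no males in range: empty with a warning
  preds3 <- preds2[true2 == "F", ]
  expect_warning(out <- balanced_correct_subset(preds3, rep(1500, 10), iv),
                 "no correctly classified")
  expect_length(out, 0)
})

test_that("TIV-only cohorts reproduce the published tertile asymmetry pattern", {
  for (run in tiv_runs()) {
    tt <- run$tertiles
    expect_gt(tt$recall_f[1], tt$recall_m[1])  # females favoured at low TIV
    expect_gt(tt$recall_m[3], tt$recall_f[3])  # males favoured at high TIV
    gaps <- abs(tt$recall_f - tt$recall_m)
    expect_lt(gaps[2], gaps[1])                # middle tertile most balanced
    expect_lt(gaps[2], gaps[3])
  }
})
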