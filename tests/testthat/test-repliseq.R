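make_reads <- function(chrom, mids, w = 100L) {
  intervals(chrom, pmax(0L, mids - w %/% 2L), mids + w %/% 2L)
}

test_that("windowed_counts assigns reads to midpoint-containing windows", {
  g <- random_genome(1, 200000, seed = 300)
  empty <- intervals(character(0), integer(0), integer(0))
  fc <- windowed_counts(list(S1 = empty, S2 = empty, S3 = empty, S4 = empty,
                             async = empty), g)
  expect_true(all(fc$counts == 0))

  one <- make_reads("chr1", 75000L)
  fc <- windowed_counts(list(S1 = one, S2 = empty, S3 = empty, S4 = empty,
                             async = empty), g)
  hit <- which(fc$counts[, "S1"] == 1)
  expect_true(all(fc$windows$start[hit] <= 75000 &
                    fc$windows$end[hit] > 75000))
  expect_lte(length(hit), 50000 / 10000)
  expect_gte(length(hit), 1)
  expect_error(windowed_counts(list(S1 = one, S2 = empty, S3 = empty,
                                    S4 = empty, async = empty), g,
                               window = 100, step = 200), "step")
})

test_that("windowed_counts equals the counting oracle on random reads", {
  g <- random_genome(2, 150000, seed = 310)
  set.seed(311)
  for (trial in 1:5) {
    n <- 2000
    ch <- sample(c("chr1", "chr2"), n, replace = TRUE)
    mids <- sample.int(149000, n)
    reads <- make_reads(ch, mids)
    empty <- intervals(character(0), integer(0), integer(0))
    fc <- windowed_counts(list(S1 = reads, S2 = empty, S3 = empty,
                               S4 = empty, async = reads), g)
    mid_r <- (reads$start + reads$end) %/% 2L
    expect_equal(unname(fc$counts[, "S1"]),
                 oracle_window_counts(reads$chrom, mid_r, fc$windows))
  }
})

test_that("normalization is proportionality- and scale-invariant, standardization exact", {
  g <- random_genome(1, 2e6, seed = 320)
  win <- genome_windows(g)
  set.seed(321)
  async <- stats::rpois(nrow(win), 100) + 1L
  cnt <- cbind(S1 = 3L * async, S2 = stats::rpois(nrow(win), 80),
               S3 = stats::rpois(nrow(win), 80) + 1L,
               S4 = stats::rpois(nrow(win), 80) + 1L)
  fc <- fraction_counts(win, cnt, async)
  prof <- normalize_standardize_smooth(fc)
  # S1 proportional to async -> constant normalized track, ~0 standardized
  expect_lt(stats::sd(prof$normalized[prof$mask, "S1"]), 1e-12)
  expect_true(all(abs(prof$standardized[prof$mask, "S1"]) < 1e-6))
  # centered and standardized to tolerance 1e-6 before smoothing
  for (f in c("S2", "S3", "S4")) {
    expect_lt(abs(mean(prof$standardized[prof$mask, f])), 1e-6)
    expect_lt(abs(stats::sd(prof$standardized[prof$mask, f]) - 1), 1e-6)
  }
  # global rescaling of one fraction leaves its standardized track unchanged
  fc10 <- fraction_counts(win, cbind(S1 = cnt[, 1], S2 = 10L * cnt[, 2],
                                     S3 = cnt[, 3], S4 = cnt[, 4]), async)
  prof10 <- normalize_standardize_smooth(fc10)
  expect_equal(prof10$standardized[, "S2"], prof$standardized[, "S2"],
               tolerance = 1e-9)
  # zero-async windows are masked
  async2 <- async
  async2[5] <- 0L
  prof2 <- normalize_standardize_smooth(fraction_counts(win, cnt, async2))
  expect_false(prof2$mask[5])
  expect_true(is.na(prof2$smoothed[5, "S1"]))
})

test_that("a planted step timing landscape keeps its sign after smoothing", {
  g <- random_genome(1, 2e6, seed = 330)
  win <- genome_windows(g)
  left <- win$midpoint < 1e6
  signs <- vapply(1:100, function(s) {
    set.seed(400 + s)
    n <- nrow(win)
    s1 <- stats::rpois(n, ifelse(left, 120, 40))
    s4 <- stats::rpois(n, ifelse(left, 40, 120))
    s2 <- stats::rpois(n, 80)
    s3 <- stats::rpois(n, 80)
    async <- stats::rpois(n, 120) + 1L
    prof <- normalize_standardize_smooth(
      fraction_counts(win, cbind(S1 = s1, S2 = s2, S3 = s3, S4 = s4), async))
    sm <- prof$smoothed[, "S1"]
    mean(sm[left & prof$mask]) > mean(sm[!left & prof$mask])
  }, logical(1))
  expect_equal(sum(signs), 100)
})

test_that("weighted-average combination applies the printed coefficients", {
  expect_identical(wa_combine(1, 0, 0, 0), 0.750)
  expect_identical(wa_combine(0, 0, 0, 1), 0.250)
  expect_equal(wa_combine(0, 1, 0, 0), 0.583)
  expect_equal(wa_combine(0, 0, 1, 0), 0.417)
  expect_equal(wa_combine(1, 1, 1, 1), 2.000)
  # linearity and early-shift monotonicity
  set.seed(340)
  x <- matrix(stats::rnorm(40), 10, 4)
  expect_equal(wa_combine(2 * x[, 1], 2 * x[, 2], 2 * x[, 3], 2 * x[, 4]),
               2 * wa_combine(x[, 1], x[, 2], x[, 3], x[, 4]))
  shifted <- wa_combine(x[, 1] + 0.5, x[, 2], x[, 3], x[, 4] - 0.5)
  expect_true(all(shifted > wa_combine(x[, 1], x[, 2], x[, 3], x[, 4])))
})

test_that("rt_shift arithmetic, antisymmetry and linearity", {
  same <- c(25, 25, 25, 25)
  expect_equal(rt_shift(same, same)$rt_shift, 0)
  r <- rt_shift(c(40, 30, 20, 10), c(25, 25, 25, 25))
  expect_equal(r$delta_e, 15)
  expect_equal(r$delta_l, -20)
  expect_equal(r$rt_shift, 35)
  # antisymmetry
  r2 <- rt_shift(c(25, 25, 25, 25), c(40, 30, 20, 10))
  expect_equal(r2$rt_shift, -r$rt_shift)
  # moving 5 points from S4 to S1 raises the shift by exactly 10
  base <- c(20, 30, 25, 25)
  moved <- c(25, 30, 25, 20)
  expect_equal(rt_shift(moved, same)$rt_shift -
                 rt_shift(base, same)$rt_shift, 10)
  expect_error(rt_shift(c(10, 10, 10, 10), same), "sum to 100")
  expect_error(rt_shift(c(110, -10, 0, 0), same), "non-negative")
})

test_that("origin_strength matches the counting oracle", {
  ori <- intervals("chr1", 1000, 2000)
  reads <- make_reads("chr1", as.integer(seq(1050, 1950, length.out = 100)))
  expect_equal(origin_strength(ori, reads), 0.1)
  empty <- intervals(character(0), integer(0), integer(0))
  expect_equal(origin_strength(ori, empty), 0)

  g <- random_genome(2, 80000, seed = 350)
  set.seed(351)
  for (trial in 1:200) {
    n_ori <- sample(2:10, 1)
    origins <- random_intervals(n_ori, g, max_width = 800, seed = 5000 + trial)
    reads <- make_reads(sample(c("chr1", "chr2"), 300, TRUE),
                        sample.int(79000, 300))
    got <- origin_strength(origins, reads)
    expect_equal(got, oracle_strength(origins, reads))
    # invariance to ordering
    perm <- sample(nrow(origins))
    expect_equal(origin_strength(origins[perm, ], reads), got[perm])
  }
})

test_that("strong_origins matches the sort-and-slice oracle with ties", {
  g <- random_genome(1, 50000, seed = 360)
  origins <- random_intervals(100, g, max_width = 300, seed = 361)
  set.seed(362)
  st <- stats::runif(100)
  sel <- strong_origins(origins, st)
  expect_equal(nrow(sel), 25)
  expect_setequal(sel$name, origins$name[oracle_strong(st, 0.75)])
  # all ties selected
  st_eq <- rep(1, 100)
  expect_equal(nrow(strong_origins(origins, st_eq)), 100)
  for (trial in 1:200) {
    st_r <- sample(1:10, 100, replace = TRUE) / 10
    sel <- strong_origins(origins, st_r, quantile = 0.75)
    expect_setequal(sel$name, origins$name[oracle_strong(st_r, 0.75)])
  }
})

test_that("stratify_strength groups, CIs and degenerate cases", {
  g <- random_genome(1, 100000, seed = 370)
  origins <- random_intervals(40, g, max_width = 400, seed = 371)
  motifs <- random_intervals(60, g, max_width = 25, seed = 372,
                             stranded = TRUE)
  cl <- cluster_pg4(motifs)
  cgis <- random_intervals(6, g, max_width = 1500, seed = 373)
  st <- rep(0.5, 40)
  out <- stratify_strength(origins, st, cl, cgis, genome = g)
  expect_equal(sum(out$groups$n), 40)
  expect_true(all(abs(out$groups$mean - 0.5) < 1e-12))
  ok <- out$groups$ci_defined
  expect_true(all(out$groups$ci_hi[ok] - out$groups$ci_lo[ok] < 1e-9))
  expect_true(all(is.na(out$groups$ci_lo[!ok])))
})

test_that("per-cluster strength effect is recovered within the CI", {
  sim <- simulate_sns_reads(simulate_origins_and_marks(
    simulate_genome_with_motifs(small_sim_config(seed = 380))))
  tr <- sim$truth$origins
  est <- origin_strength(sim$origins, sim$sns_reads)
  fit <- stats::lm(est ~ n_clustered + n_monomeric + cgi, data =
                     tibble::tibble(est = est, n_clustered = tr$n_clustered,
                                    n_monomeric = tr$n_monomeric,
                                    cgi = tr$cgi))
  # Poisson noise scales with strength: use a robust (HC3) interval
  ci <- lmtest::coefci(fit, vcov. = sandwich::vcovHC(fit, type = "HC3"))
  beta <- sim$truth$config$strength$per_clustered
  expect_true(ci["n_clustered", 1] <= beta && beta <= ci["n_clustered", 2])
})
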