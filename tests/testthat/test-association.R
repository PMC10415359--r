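test_that("overlap_flags respects the extended-anchor boundary geometry", {
  g <- as_genome(c(chr1 = strrep("A", 10000)))
  seg <- intervals("chr1", 3000, 3001)
  near <- intervals("chr1", 4999, 5000)   # peaks 1999 bp apart
  far <- intervals("chr1", 5001, 5002)    # peaks 2001 bp apart
  expect_equal(overlap_flags(seg, near, flank = 1000, genome = g), 1L)
  expect_equal(overlap_flags(seg, far, flank = 1000, genome = g), 0L)
})

test_that("overlap_flags equals the all-pairs oracle on random sets", {
  g <- random_genome(2, 50000, seed = 130)
  segs <- random_intervals(1000, g, max_width = 300, seed = 131)
  feats <- random_intervals(200, g, max_width = 300, seed = 132)
  flank <- 500
  got <- overlap_flags(segs, feats, flank = flank, genome = g)
  ext_s <- extend_around_point(segs, flank, g)
  ext_f <- extend_around_point(feats, flank, g)
  expect_equal(got, oracle_overlap_flags(ext_s, ext_f))
})

test_that("strand-aware origin flags use the correct side per strand", {
  g <- as_genome(c(chr1 = strrep("A", 10000)))
  ori <- intervals("chr1", 5000, 5001)  # peak at 5000
  plus_up <- intervals("chr1", 4790, 4810, strand = "+")
  plus_down <- intervals("chr1", 5190, 5210, strand = "+")
  minus_down <- intervals("chr1", 5190, 5210, strand = "-")
  f1 <- strand_aware_origin_pg4_flags(ori, plus_up, flank = 1000, genome = g)
  expect_equal(f1$flag, 1L)
  expect_equal(f1$plus_upstream, 1L)
  expect_equal(f1$minus_downstream, 0L)
  f2 <- strand_aware_origin_pg4_flags(ori, plus_down, flank = 1000, genome = g)
  expect_equal(f2$flag, 0L)
  f3 <- strand_aware_origin_pg4_flags(ori, minus_down, flank = 1000, genome = g)
  expect_equal(f3$flag, 1L)
  expect_equal(f3$minus_downstream, 1L)
  un <- intervals("chr1", 100, 120, strand = ".")
  expect_error(strand_aware_origin_pg4_flags(ori, un), "stranded")
})

test_that("logistic enrichment equals the closed-form 2x2 odds ratio", {
  e <- logistic_enrichment(rep(c(1, 0), c(30, 20)), rep(c(1, 0), c(15, 35)))
  expect_equal(e$log_or, log(3.5), tolerance = 1e-8)
  expect_equal(e$se, sqrt(1/30 + 1/20 + 1/15 + 1/35), tolerance = 1e-8)
  expect_false(e$continuity_corrected)

  set.seed(140)
  for (trial in 1:300) {
    cnt <- sample(1:120, 4, replace = TRUE)
    e <- logistic_enrichment(rep(c(1, 0), cnt[1:2]), rep(c(1, 0), cnt[3:4]))
    want <- oracle_logor(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(e$log_or, want$log_or, tolerance = 1e-6)
    expect_equal(e$se, want$se, tolerance = 1e-6)
  }
})

test_that("balanced designs give logOR exactly zero", {
  e <- logistic_enrichment(rep(c(1, 0), c(120, 80)), rep(c(1, 0), c(120, 80)))
  expect_equal(e$log_or, 0, tolerance = 1e-10)
})

test_that("label swap negates logOR and scaling both classes preserves it", {
  r <- rep(c(1, 0), c(40, 25))
  n <- rep(c(1, 0), c(12, 53))
  e <- logistic_enrichment(r, n)
  expect_equal(logistic_enrichment(n, r)$log_or, -e$log_or, tolerance = 1e-8)
  expect_equal(logistic_enrichment(rep(r, 3), rep(n, 5))$log_or, e$log_or,
               tolerance = 1e-8)
})

test_that("zero cells trigger the Haldane-Anscombe correction", {
  e <- logistic_enrichment(rep(1, 20), rep(c(1, 0), c(5, 15)))
  expect_true(e$continuity_corrected)
  expect_true(is.finite(e$log_or) && is.finite(e$se))
  expect_error(logistic_enrichment(integer(0), c(0, 1)), "non-empty")
  expect_error(logistic_enrichment(c(0, 2), c(0, 1)), "0/1")
})

test_that("Wald interval covers planted logOR across effect sizes", {
  set.seed(150)
  n <- 400
  for (L in c(0, 0.5, 1.0, 1.5)) {
    p0 <- 0.15
    p1 <- stats::plogis(L + stats::qlogis(p0))
    cover <- vapply(1:200, function(i) {
      rf <- stats::rbinom(n, 1, p1)
      nf <- stats::rbinom(n, 1, p0)
      e <- logistic_enrichment(rf, nf)
      e$log_or - 1.96 * e$se <= L && L <= e$log_or + 1.96 * e$se
    }, logical(1))
    expect_gte(mean(cover), 0.90)
  }
})

test_that("estimated logOR is monotone in the planted real-class probability", {
  set.seed(160)
  p0 <- 0.2
  grid <- c(0.2, 0.3, 0.4, 0.55, 0.7)
  means <- vapply(grid, function(p1)
    mean(vapply(1:100, function(i)
      logistic_enrichment(stats::rbinom(300, 1, p1),
                          stats::rbinom(300, 1, p0))$log_or,
      numeric(1))), numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("enrichment_table drops unmatched pairs and supports the pG4-conditional filter", {
  sim <- simulate_origins_and_marks(
    simulate_genome_with_motifs(small_sim_config(seed = 170)))
  g <- sim$genome
  det <- detect_pg4(g)
  cl <- cluster_pg4(det)
  rnd <- sample_matched_random(sim$origins, g, seed = 171)
  tab <- enrichment_table(sim$origins, rnd,
                          list(clustered = cl$clusters,
                               monomeric = cl$monomers),
                          genome = g)
  expect_equal(nrow(tab), 2)
  n_real <- nrow(sim$origins) - length(rnd$unmatched)
  expect_equal(unname(tab$a + tab$b), rep(n_real, 2))
  expect_equal(unname(tab$c + tab$d), rep(nrow(rnd$segments), 2))
  # conditional variant restricted to pG4-bearing segments
  cond <- enrichment_table(sim$origins, rnd,
                           list(clustered = cl$clusters),
                           genome = g, require_pg4 = det)
  expect_lte(cond$a + cond$b, n_real)
})
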