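test_that("detect_pg4 finds the minimal canonical motif on either strand", {
  core <- "GGGTGGGTGGGTGGG"
  g <- as_genome(c(chr1 = paste0(strrep("A", 50), core, strrep("A", 50))))
  m <- detect_pg4(g)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(50, 65))
  expect_equal(m$strand, "+")
  expect_equal(m$n_tracts, 4L)

  rc <- "CCCACCCACCCACCC"
  g2 <- as_genome(c(chr1 = paste0(strrep("A", 50), rc, strrep("A", 50))))
  m2 <- detect_pg4(g2)
  expect_equal(nrow(m2), 1)
  expect_equal(c(m2$start, m2$end), c(50, 65))
  expect_equal(m2$strand, "-")
})

test_that("detect_pg4 matches the independent regex oracle on random sequences", {
  for (trial in 1:100) {
    g <- random_genome(1, 10000, gc = 0.5, seed = 2000 + trial)
    got <- detect_pg4(g)
    want <- oracle_detect_pg4(g)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$strand, want$strand)
  }
})

test_that("detect_pg4 is symmetric under reverse complement of the genome", {
  g <- random_genome(1, 100000, gc = 0.6, seed = 31)
  L <- unname(genome_lengths(g))
  m <- detect_pg4(g)
  expect_gt(nrow(m), 0)
  grc <- as_genome(c(chr1 = as.character(
    Biostrings::reverseComplement(g[[1]]))))
  mrc <- detect_pg4(grc)
  # swap strands and mirror coordinates of the revcomp detection
  mirrored <- data.frame(start = L - mrc$end, end = L - mrc$start,
                         strand = ifelse(mrc$strand == "+", "-", "+"))
  mirrored <- mirrored[order(mirrored$start, mirrored$end, mirrored$strand), ]
  orig <- m[order(m$start, m$end, m$strand), ]
  expect_equal(orig$start, mirrored$start)
  expect_equal(orig$end, mirrored$end)
  expect_equal(orig$strand, mirrored$strand)
})

test_that("detect_pg4 validates parameters", {
  g <- random_genome(1, 1000, seed = 1)
  expect_error(detect_pg4(g, loop_min = 5, loop_max = 2), "loop")
  expect_error(detect_pg4(g, tract_len = 1), "tract_len")
})

test_that("cluster_pg4 applies the size and same-strand rules directly", {
  two_plus <- intervals("chr1", c(100, 165), c(115, 180), strand = "+")
  cl <- cluster_pg4(two_plus, max_gap = 100)
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$k, 2L)
  expect_equal(nrow(cl$monomers), 0)

  opp <- intervals("chr1", c(100, 165), c(115, 180), strand = c("+", "-"))
  cl2 <- cluster_pg4(opp, max_gap = 100)
  expect_equal(nrow(cl2$clusters), 0)
  expect_equal(nrow(cl2$monomers), 2)

  far <- intervals("chr1", c(100, 300), c(115, 315), strand = "+")
  expect_equal(nrow(cluster_pg4(far, max_gap = 100)$clusters), 0)
  # boundary: gap exactly 100 clusters by default, not with strict = TRUE
  edge <- intervals("chr1", c(100, 215), c(115, 230), strand = "+")
  expect_equal(nrow(cluster_pg4(edge, max_gap = 100)$clusters), 1)
  expect_equal(nrow(cluster_pg4(edge, max_gap = 100,
                                strict = TRUE)$clusters), 0)
})

test_that("cluster_pg4 partition matches the connected-components oracle", {
  g <- random_genome(2, 5000, seed = 40)
  for (trial in 1:300) {
    n <- sample(2:25, 1)
    motifs <- random_intervals(n, g, max_width = 30,
                               seed = 3000 + trial, stranded = TRUE)
    gap <- sample(c(20L, 50L, 100L), 1)
    cl <- cluster_pg4(motifs, max_gap = gap)
    want <- oracle_cluster_partition(cl$motifs, gap)
    expect_equal(cl$motifs$category, want)
    # partition completeness
    expect_equal(nrow(cl$monomers) + sum(cl$clusters$k) +
                   sum(cl$oversize$k), n)
  }
})

test_that("oversize runs are excluded from both categories but reported", {
  starts <- seq(0, by = 50, length.out = 8)
  x <- intervals("chr1", starts, starts + 20, strand = "+")
  cl <- cluster_pg4(x, max_gap = 100, max_k = 6)
  expect_equal(nrow(cl$clusters), 0)
  expect_equal(nrow(cl$monomers), 0)
  expect_equal(cl$oversize$k, 8L)
  expect_equal(unname(cl$fractions["oversize"]), 1)
})

test_that("cluster spans contain no same-strand non-member motif", {
  g <- random_genome(1, 20000, gc = 0.5, seed = 55)
  m <- detect_pg4(g)
  extra <- random_intervals(60, g, max_width = 25, seed = 56, stranded = TRUE)
  all_m <- rbind(m[, c("chrom", "start", "end", "name", "score", "strand")],
                 extra)
  all_m$name <- paste0("m", seq_len(nrow(all_m)))
  cl <- cluster_pg4(all_m)
  for (i in seq_len(nrow(cl$clusters))) {
    members <- strsplit(cl$clusters$members[i], ",")[[1]]
    inside <- all_m$strand == cl$clusters$strand[i] &
      all_m$chrom == cl$clusters$chrom[i] &
      all_m$start >= cl$clusters$start[i] &
      all_m$end <= cl$clusters$end[i]
    expect_true(all(all_m$name[inside] %in% members))
  }
})

test_that("planted motifs are recovered and classified from simulated genomes", {
  sim <- simulate_genome_with_motifs(small_sim_config(seed = 77))
  det <- detect_pg4(sim$genome)
  hit <- overlap_flags(sim$truth$motifs, det, flank = NULL)
  expect_gte(mean(hit), 0.95)
  # every detection is either planted or a chance match confirmed by the oracle
  want <- oracle_detect_pg4(sim$genome)
  expect_equal(nrow(det), nrow(want))
  expect_equal(det$start, want$start)
  # planted clusters are recovered as clusters
  cl <- cluster_pg4(det)
  got <- overlap_flags(sim$truth$clusters, cl$clusters, flank = NULL)
  expect_gte(mean(got), 0.9)
})
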