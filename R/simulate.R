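#' Simulation configuration
#'
#' Defaults define the package's standard synthetic study conditions: a
#' 5 x 2-Mb genome at 40% GC carrying planted canonical pG4 motifs
#' (monomers and same-strand clusters of 2-6 with intra-cluster gaps of
#' 1-100 bp), GC-elevated CGI blocks, replication origins whose placement
#' near clustered/monomeric pG4s realizes configured log-odds ratios,
#' NFR and H2A.Z marks with configured co-occurrence, Poisson SNS reads
#' whose rate follows an additive strength model, and Repli-seq fraction
#' counts over a smooth timing landscape with a planted local advance.
#'
#' @param n_chroms,chrom_length Genome shape (default 5 x 2e6 bp).
#' @param base_gc Background GC fraction (default 0.40).
#' @param gc_gradient Linear GC change from chromosome start to end
#'   (default 0; e.g. 0.1 ramps GC from base_gc - 0.05 to base_gc + 0.05).
#' @param monomer_rate,cluster_rate Planted monomeric motifs and clusters
#'   per Mb per chromosome (defaults 40 and 10).
#' @param cluster_size_probs Distribution of cluster sizes 2..6.
#' @param gap_range Intra-cluster gap range in bp (default `c(1, 100)`).
#' @param tract_len,loop_min,loop_max,n_tracts Planted motif geometry
#'   (defaults match [detect_pg4()]).
#' @param n_cgis,cgi_width,cgi_gc CpG-island blocks: count, width, GC.
#' @param n_origins,origin_width Origin count and width (defaults 400, 300).
#' @param log_or_clustered,log_or_monomeric Target log-odds ratios of the
#'   origin association with clustered and monomeric pG4s (defaults 1.5 and
#'   0.5); placement probabilities are solved analytically from these.
#' @param flank Anchor extension used for association geometry (1000 bp).
#' @param strength Additive origin-strength model (reads/bp): `baseline`,
#'   `per_clustered`, `per_monomeric`, `cgi`.
#' @param sns_background_rate Background SNS reads per bp (default 0.002).
#' @param read_width Simulated read width in bp (default 100).
#' @param nfr_frac Probability that an origin-associated cluster gets an
#'   NFR planted on its 5' side (default 0.7).
#' @param nfr_width,nfr_offset NFR width and offset range from the cluster
#'   edge, bp.
#' @param n_background_nfr,n_background_h2az Uniformly placed background
#'   marks.
#' @param h2az_frac Probability that a planted pG4 entity (monomer or
#'   cluster, origin-associated or not) gets a flanking H2A.Z peak
#'   (default 0.3).
#' @param h2az_width,h2az_offset H2A.Z peak width and offset range, bp.
#' @param repliseq List: `window`, `step` (bp), `depth` (expected reads per
#'   window per fraction), `n_domains` (timing waves per chromosome),
#'   `sigma` (fraction-assignment spread), `advance` (percentage points of
#'   locus late-fraction mass moved to S1 in the "with" condition),
#'   `locus_width` (bp).
#' @param seed Integer root seed (< 2^31 - 10; stage seeds are derived by
#'   small offsets).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 5L, chrom_length = 2e6, base_gc = 0.40,
                       gc_gradient = 0,
                       monomer_rate = 40, cluster_rate = 10,
                       cluster_size_probs = c(`2` = 0.50, `3` = 0.25,
                                              `4` = 0.12, `5` = 0.08,
                                              `6` = 0.05),
                       gap_range = c(1L, 100L),
                       tract_len = 3L, loop_min = 1L, loop_max = 7L,
                       n_tracts = 4L,
                       n_cgis = 60L, cgi_width = 1500L, cgi_gc = 0.65,
                       n_origins = 400L, origin_width = 300L,
                       log_or_clustered = 1.5, log_or_monomeric = 0.5,
                       flank = 1000L,
                       strength = list(baseline = 0.02, per_clustered = 0.03,
                                       per_monomeric = 0.005, cgi = 0.02),
                       sns_background_rate = 0.002, read_width = 100L,
                       nfr_frac = 0.7, nfr_width = 300L,
                       nfr_offset = c(100L, 400L),
                       n_background_nfr = 50L, n_background_h2az = 100L,
                       h2az_frac = 0.3, h2az_width = 200L,
                       h2az_offset = c(200L, 800L),
                       repliseq = list(window = 50000L, step = 10000L,
                                       depth = 30, n_domains = 3,
                                       sigma = 0.8, advance = 20,
                                       locus_width = 30000L),
                       seed = 1L) {
  stopifnot(n_chroms >= 1, chrom_length >= 1e4,
            base_gc > 0, base_gc < 1,
            monomer_rate >= 0, cluster_rate >= 0,
            abs(sum(cluster_size_probs) - 1) < 1e-8,
            gap_range[1] >= 1, gap_range[2] >= gap_range[1],
            n_origins >= 1, origin_width >= 2,
            nfr_frac >= 0, nfr_frac <= 1, h2az_frac >= 0, h2az_frac <= 1,
            abs(seed) < 2^31 - 10)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# logit-scale helpers linking placement probabilities to the target logOR
# against a background hit probability b.
implied_log_or <- function(q, b) stats::qlogis(q + (1 - q) * b) -
  stats::qlogis(b)

placement_prob_for_log_or <- function(log_or, b) {
  if (log_or < 0) stop("directed placement supports log_or >= 0 only")
  p1 <- stats::plogis(log_or + stats::qlogis(b))
  (p1 - b) / (1 - b)
}

# Draw one canonical motif sequence on the plus strand.
.make_motif_seq <- function(cfg) {
  k <- cfg$n_tracts
  loops <- sample(seq.int(cfg$loop_min, cfg$loop_max), k - 1L, replace = TRUE)
  tract <- strrep("G", cfg$tract_len)
  parts <- character(2L * k - 1L)
  parts[seq(1, 2 * k - 1, by = 2)] <- tract
  # loop letters exclude G (no tract extension) and C (no pC4-side runs)
  parts[seq(2, 2 * k - 2, by = 2)] <- vapply(loops, function(n)
    paste(sample(c("A", "T"), n, replace = TRUE), collapse = ""),
    character(1))
  paste(parts, collapse = "")
}

#' Simulate a genome with planted pG4 motifs and CGI blocks
#'
#' Background bases are drawn independently per position from the
#' configured GC content (with optional linear gradient); CGI blocks are
#' GC-elevated; canonical pG4 motifs matching the detector's pattern are
#' planted at random non-overlapping positions, as isolated monomers and as
#' same-strand clusters with gaps drawn from the configured range. Planted
#' entities are separated from each other by more than the clustering gap
#' so categories remain unambiguous, and flanked by A/T so tract boundaries
#' are exact. Deterministic for a fixed seed.
#'
#' @param cfg A [sim_config()] object.
#' @return A list with `genome` (a `DNAStringSet`) and `truth` (list with
#'   `motifs`, `clusters`, `cgis` interval tibbles and the config).
#' @export
simulate_genome_with_motifs <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  L <- as.integer(cfg$chrom_length)
  pad <- 150L
  motif_rows <- list()
  cluster_rows <- list()
  cgi_rows <- list()
  seqs <- character(cfg$n_chroms)
  names(seqs) <- chroms
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    gc_vec <- rep(cfg$base_gc, L)
    if (cfg$gc_gradient != 0)
      gc_vec <- cfg$base_gc + cfg$gc_gradient *
        (seq_len(L) / L - 0.5)
    # CGI blocks (uniform share per chromosome), GC elevated
    n_cgi <- as.integer(round(cfg$n_cgis / cfg$n_chroms))
    occ_s <- integer(0)
    occ_e <- integer(0)
    for (j in seq_len(n_cgi)) {
      for (att in 1:200) {
        s <- sample.int(L - cfg$cgi_width, 1L) - 1L
        cs <- max(0L, s - pad)
        ce <- min(L, s + cfg$cgi_width + pad)
        if (!any(occ_s < ce & occ_e > cs)) break
      }
      occ_s <- c(occ_s, cs)
      occ_e <- c(occ_e, ce)
      gc_vec[(s + 1):(s + cfg$cgi_width)] <- cfg$cgi_gc
      cgi_rows[[length(cgi_rows) + 1L]] <-
        tibble::tibble(chrom = ch, start = s, end = s + as.integer(cfg$cgi_width))
    }
    gc_vec <- pmin(pmax(gc_vec, 0.01), 0.99)
    u1 <- stats::runif(L) < gc_vec
    u2 <- stats::runif(L) < 0.5
    base <- c("A", "T", "C", "G")[1L + u2 + 2L * u1]
    # plant entities: monomers and clusters
    mb <- L / 1e6
    n_mono <- stats::rpois(1, cfg$monomer_rate * mb)
    n_clus <- stats::rpois(1, cfg$cluster_rate * mb)
    ent <- c(rep("monomer", n_mono), rep("cluster", n_clus))
    for (e in seq_along(ent)) {
      strand <- sample(c("+", "-"), 1L)
      if (ent[e] == "monomer") {
        motif_seqs <- .make_motif_seq(cfg)
        gaps <- integer(0)
      } else {
        k <- sample(2:6, 1L, prob = cfg$cluster_size_probs)
        motif_seqs <- vapply(seq_len(k), function(i) .make_motif_seq(cfg),
                             character(1))
        gaps <- sample(seq.int(cfg$gap_range[1], cfg$gap_range[2]),
                       length(motif_seqs) - 1L, replace = TRUE)
      }
      gap_seqs <- vapply(gaps, function(n)
        paste(sample(c("A", "T"), n, replace = TRUE), collapse = ""),
        character(1))
      body <- motif_seqs[1]
      offs <- 0L
      ends <- nchar(motif_seqs[1])
      for (j in seq_along(gap_seqs)) {
        body <- paste0(body, gap_seqs[j], motif_seqs[j + 1])
        offs <- c(offs, nchar(body) - nchar(motif_seqs[j + 1]))
        ends <- c(ends, nchar(body))
      }
      if (strand == "-") {
        lb <- nchar(body)
        body <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(body)))
        new_start <- lb - ends
        new_end <- lb - offs
        o <- order(new_start)
        offs <- new_start[o]
        ends <- new_end[o]
      }
      full <- paste0(sample(c("A", "T"), 1L), body, sample(c("A", "T"), 1L))
      le <- nchar(full)
      placed <- FALSE
      for (att in 1:300) {
        s <- sample.int(L - le, 1L) - 1L
        cs <- max(0L, s - pad)
        ce <- min(L, s + le + pad)
        if (!any(occ_s < ce & occ_e > cs)) {
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("planting density infeasible for genome size")
      occ_s <- c(occ_s, cs)
      occ_e <- c(occ_e, ce)
      base[(s + 1L):(s + le)] <- strsplit(full, "", fixed = TRUE)[[1]]
      m_start <- s + 1L + offs   # +1 for the pad base, 0-based
      m_end <- s + 1L + ends
      motif_rows[[length(motif_rows) + 1L]] <- tibble::tibble(
        chrom = ch, start = as.integer(m_start), end = as.integer(m_end),
        strand = strand, planted = ent[e],
        entity = paste0(ch, "_e", e))
      if (ent[e] == "cluster")
        cluster_rows[[length(cluster_rows) + 1L]] <- tibble::tibble(
          chrom = ch, start = as.integer(min(m_start)),
          end = as.integer(max(m_end)), strand = strand,
          k = length(motif_seqs), entity = paste0(ch, "_e", e))
    }
    seqs[ch] <- paste(base, collapse = "")
  }
  motifs <- if (length(motif_rows))
    sort_intervals(as_intervals(do.call(rbind, motif_rows)))
  else {
    z <- intervals(character(0), integer(0), integer(0))
    z$planted <- character(0); z$entity <- character(0); z
  }
  clusters <- if (length(cluster_rows))
    sort_intervals(as_intervals(do.call(rbind, cluster_rows)))
  else {
    z <- intervals(character(0), integer(0), integer(0))
    z$k <- integer(0); z$entity <- character(0); z
  }
  cgis <- if (length(cgi_rows))
    sort_intervals(as_intervals(do.call(rbind, cgi_rows)))
  else intervals(character(0), integer(0), integer(0))
  genome <- as_genome(seqs)
  list(genome = genome,
       truth = list(motifs = motifs, clusters = clusters, cgis = cgis,
                    config = cfg))
}

#' Simulate origins, NFR and H2A.Z marks with configured associations
#'
#' Origins are placed adjacent to clustered pG4s with probability `q_c`,
#' adjacent to monomeric pG4s with probability `q_m`, and uniformly
#' elsewhere, with `q_c`/`q_m` solved analytically so that the origin
#' versus random-segment association realizes the configured target
#' log-odds ratios given the genome's background hit probabilities.
#' Placement is oriented (plus-strand cluster: origin on the 3' side), so
#' the strand-aware association holds by construction. A configured
#' fraction of origin-associated clusters receives an NFR on its 5' side
#' (the asymmetric nucleosome-free pattern); H2A.Z peaks are placed near
#' planted pG4 entities independently of origin status. True per-origin
#' strengths follow the additive strength model.
#'
#' @param sim Output of [simulate_genome_with_motifs()].
#' @return `sim` with added elements `origins`, `nfr`, `h2az` (interval
#'   tibbles) and an augmented `truth` (placement modes, true strengths,
#'   target and background probabilities, true log-odds ratios).
#' @export
simulate_origins_and_marks <- function(sim) {
  cfg <- sim$truth$config
  set.seed(cfg$seed + 1L)
  genome <- sim$genome
  len <- genome_lengths(genome)
  total <- sum(len)
  f <- as.integer(cfg$flank)
  w <- as.integer(cfg$origin_width)
  truth <- sim$truth
  hit_cov <- function(anchors_tbl) {
    if (!nrow(anchors_tbl)) return(1e-9)
    a <- anchor_point(anchors_tbl)
    m <- merge_intervals(intervals(anchors_tbl$chrom,
                                   pmax(0L, a - 2L * f + 1L),
                                   pmin(len[anchors_tbl$chrom], a + 2L * f)))
    sum(m$end - m$start) / total
  }
  b_c <- hit_cov(truth$clusters)
  mono_motifs <- truth$motifs[truth$motifs$planted == "monomer", ]
  b_m <- hit_cov(mono_motifs)
  q_c <- max(0, placement_prob_for_log_or(cfg$log_or_clustered, b_c))
  q_m <- max(0, placement_prob_for_log_or(cfg$log_or_monomeric, b_m))
  if (q_c + q_m > 1) stop("inconsistent placement probabilities (q_c + q_m > 1)")
  modes <- sample(c("clustered", "monomeric", "background"), cfg$n_origins,
                  replace = TRUE, prob = c(q_c, q_m, 1 - q_c - q_m))
  prep <- function(tbl) list(
    chrom = tbl$chrom, anchor = anchor_point(tbl),
    half_span = (tbl$end - tbl$start + 1L) %/% 2L,
    side = ifelse(tbl$strand == "+", 1L, -1L))
  pc <- prep(truth$clusters)
  pmn <- prep(mono_motifs)
  place_near <- function(pp) {
    i <- sample.int(length(pp$anchor), 1L)
    d_min <- pp$half_span[i] + w %/% 2L + 20L
    d_max <- max(d_min, 2L * f - 200L)
    d <- if (d_max > d_min) sample.int(d_max - d_min, 1L) + d_min else d_min
    m <- pp$anchor[i] + pp$side[i] * d
    if (m - w %/% 2L < 0 || m + w %/% 2L > len[[pp$chrom[i]]])
      m <- pp$anchor[i] - pp$side[i] * d
    list(ch = pp$chrom[i], m = m)
  }
  o_ch <- character(cfg$n_origins)
  o_m <- integer(cfg$n_origins)
  for (i in seq_len(cfg$n_origins)) {
    if (modes[i] == "clustered" && length(pc$anchor)) {
      pm <- place_near(pc)
    } else if (modes[i] == "monomeric" && length(pmn$anchor)) {
      pm <- place_near(pmn)
    } else {
      modes[i] <- "background"
      ch <- sample(names(len), 1L, prob = len)
      pm <- list(ch = ch, m = sample.int(len[[ch]] - w, 1L) - 1L + w %/% 2L)
    }
    o_ch[i] <- pm$ch
    o_m[i] <- as.integer(pm$m)
  }
  origins <- as_intervals(tibble::tibble(
    chrom = o_ch, start = pmax(0L, o_m - w %/% 2L),
    end = pmin(as.integer(len[o_ch]), o_m + w %/% 2L)), genome = genome)
  origins$name <- paste0("ori", seq_len(nrow(origins)))
  origins$strand <- "."
  # true strengths from planted pG4 content and CGI status
  ext <- extend_around_point(origins, f, genome)
  n_c <- interval_overlap_counts(ext, truth$clusters)
  n_m <- interval_overlap_counts(ext, mono_motifs)
  in_cgi <- interval_overlaps_any(origins, truth$cgis)
  strength <- cfg$strength$baseline + cfg$strength$per_clustered * n_c +
    cfg$strength$per_monomeric * n_m + cfg$strength$cgi * in_cgi
  origins$score <- strength
  # origin-associated clusters: any origin anchor within 2f of cluster anchor
  cl <- truth$clusters
  nfr <- list()
  h2az <- list()
  if (nrow(cl)) {
    assoc <- overlap_flags(cl, origins, flank = f, genome = genome) == 1L
    for (i in which(assoc)) {
      if (stats::runif(1) > cfg$nfr_frac) next
      off <- sample.int(cfg$nfr_offset[2] - cfg$nfr_offset[1], 1L) +
        cfg$nfr_offset[1]
      if (cl$strand[i] == "+") {
        e <- cl$start[i] - off
        s <- e - cfg$nfr_width
      } else {
        s <- cl$end[i] + off
        e <- s + cfg$nfr_width
      }
      if (s < 0 || e > len[[cl$chrom[i]]]) next
      nfr[[length(nfr) + 1L]] <- tibble::tibble(chrom = cl$chrom[i],
                                                start = as.integer(s),
                                                end = as.integer(e))
    }
  }
  ent_idx <- split(seq_len(nrow(truth$motifs)), truth$motifs$entity)
  for (ix in ent_idx) {
    if (stats::runif(1) > cfg$h2az_frac) next
    a <- (min(truth$motifs$start[ix]) + max(truth$motifs$end[ix])) %/% 2L
    off <- sample.int(cfg$h2az_offset[2] - cfg$h2az_offset[1], 1L) +
      cfg$h2az_offset[1]
    side <- sample(c(-1L, 1L), 1L)
    s <- a + side * off - cfg$h2az_width %/% 2L
    ech <- truth$motifs$chrom[ix[1]]
    if (s < 0 || s + cfg$h2az_width > len[[ech]]) next
    h2az[[length(h2az) + 1L]] <- tibble::tibble(
      chrom = ech, start = as.integer(s),
      end = as.integer(s + cfg$h2az_width))
  }
  unif_marks <- function(n, width) {
    ch <- sample(names(len), n, replace = TRUE, prob = len)
    s <- vapply(ch, function(cc) sample.int(len[[cc]] - width, 1L) - 1L,
                integer(1))
    tibble::tibble(chrom = ch, start = s, end = s + as.integer(width))
  }
  nfr_tbl <- do.call(rbind, c(nfr, list(unif_marks(cfg$n_background_nfr,
                                                   cfg$nfr_width))))
  h2az_tbl <- do.call(rbind, c(h2az, list(unif_marks(cfg$n_background_h2az,
                                                     cfg$h2az_width))))
  nfr_tbl <- sort_intervals(as_intervals(nfr_tbl, genome = genome))
  h2az_tbl <- sort_intervals(as_intervals(h2az_tbl, genome = genome))
  nfr_tbl$name <- paste0("nfr", seq_len(nrow(nfr_tbl)))
  h2az_tbl$name <- paste0("h2az", seq_len(nrow(h2az_tbl)))
  truth$origins <- tibble::tibble(origins[, c("chrom", "start", "end", "name")],
                                  mode = modes, strength = strength,
                                  n_clustered = n_c, n_monomeric = n_m,
                                  cgi = in_cgi)
  truth$background_p <- c(clustered = b_c, monomeric = b_m)
  truth$placement_q <- c(clustered = q_c, monomeric = q_m)
  truth$true_log_or <- c(
    clustered = implied_log_or(q_c, b_c),
    monomeric = implied_log_or(q_m, b_m))
  sim$origins <- origins
  sim$nfr <- nfr_tbl
  sim$h2az <- h2az_tbl
  sim$truth <- truth
  sim
}

#' Simulate SNS reads from true origin strengths
#'
#' Per origin, `Poisson(strength x length)` reads with midpoints uniform
#' within the origin; background reads are Poisson-uniform over the genome
#' at the configured rate.
#'
#' @param sim Output of [simulate_origins_and_marks()].
#' @return `sim` with an added `sns_reads` interval tibble.
#' @export
simulate_sns_reads <- function(sim) {
  cfg <- sim$truth$config
  set.seed(cfg$seed + 2L)
  len <- genome_lengths(sim$genome)
  rw <- as.integer(cfg$read_width)
  tr <- sim$truth$origins
  ow <- tr$end - tr$start
  n_per <- stats::rpois(nrow(tr), tr$strength * ow)
  idx <- rep.int(seq_len(nrow(tr)), n_per)
  ori_mid <- tr$start[idx] +
    floor(stats::runif(length(idx)) * ow[idx])
  n_bg <- stats::rpois(1, cfg$sns_background_rate * sum(len))
  bg_ch <- character(0)
  bg_m <- integer(0)
  if (n_bg > 0) {
    bg_ch <- sample(names(len), n_bg, replace = TRUE, prob = len)
    bg_m <- floor(stats::runif(n_bg) * (len[bg_ch] - 1))
  }
  all <- tibble::tibble(chrom = c(tr$chrom[idx], bg_ch),
                        midpoint = as.integer(c(ori_mid, bg_m)))
  reads <- tibble::tibble(chrom = all$chrom,
                          start = pmax(0L, as.integer(all$midpoint - rw %/% 2L)),
                          end = as.integer(all$midpoint + rw %/% 2L))
  reads$end <- pmin(reads$end, as.integer(len[reads$chrom]))
  reads <- sort_intervals(as_intervals(reads, genome = sim$genome))
  reads$name <- paste0("sns", seq_len(nrow(reads)))
  sim$sns_reads <- reads
  sim
}

# Timing landscape in [0, 1] (1 = early) along a chromosome.
.timing_u <- function(midpoint, chrom_len, chrom_index, n_domains) {
  phase <- 2 * pi * chrom_index / 7
  0.5 + 0.5 * sin(2 * pi * n_domains * midpoint / chrom_len + phase)
}

# S1..S4 probabilities for a timing value u.
.fraction_probs <- function(u, sigma) {
  mu <- 1 + 3 * (1 - u)
  p <- vapply(1:4, function(f) exp(-(f - mu)^2 / (2 * sigma^2)), numeric(length(u)))
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  p / rowSums(p)
}

#' Simulate Repli-seq fraction counts with a planted local RT advance
#'
#' Windows follow a smooth early/late timing landscape per chromosome; each
#' window's reads are split multinomially over S1-S4 according to its
#' timing, and the asynchronous sample is Poisson-uniform. Two conditions
#' are generated: "without", and "with", in which the configured percentage
#' of the locus's late-fraction (S3+S4) probability mass is moved to S1 —
#' by the RT-shift formula the expected shift is twice the configured
#' advance. The locus defaults to the latest-replicating stretch of chr1.
#'
#' @param sim A simulation list containing `genome` and `truth` (only the
#'   config and genome are used), or the output of previous stages.
#' @return `sim` with an added `repliseq` element: list with `with` and
#'   `without` (`fraction_counts`), `locus` (interval tibble) and
#'   `expected_rt_shift`.
#' @export
simulate_repliseq_counts <- function(sim) {
  cfg <- sim$truth$config
  rs <- cfg$repliseq
  set.seed(cfg$seed + 3L)
  len <- genome_lengths(sim$genome)
  win <- genome_windows(sim$genome, rs$window, rs$step)
  ci <- match(win$chrom, names(len))
  u <- .timing_u(win$midpoint, len[win$chrom], ci, rs$n_domains)
  probs <- .fraction_probs(u, rs$sigma)
  # locus: latest windows on chr1
  i1 <- which(win$chrom == names(len)[1])
  center <- win$midpoint[i1[which.min(u[i1])]]
  locus <- tibble::tibble(chrom = names(len)[1],
                          start = max(0L, as.integer(center - rs$locus_width %/% 2)),
                          end = as.integer(center + rs$locus_width %/% 2))
  at_locus <- win$chrom == locus$chrom & win$midpoint >= locus$start &
    win$midpoint < locus$end
  a <- rs$advance / 100
  probs_with <- probs
  late <- probs[, 3] + probs[, 4]
  if (any(at_locus & late < a + 0.01))
    stop("locus not late enough for the configured advance")
  sc <- ifelse(at_locus, (late - a) / late, 1)
  probs_with[, 3] <- probs[, 3] * sc
  probs_with[, 4] <- probs[, 4] * sc
  probs_with[, 1] <- probs[, 1] + ifelse(at_locus, a, 0)
  draw <- function(pmat) {
    n <- stats::rpois(nrow(win), rs$depth * 4)
    cnt <- matrix(0L, nrow(win), 4, dimnames = list(NULL, paste0("S", 1:4)))
    pos <- which(n > 0)
    for (i in pos) cnt[i, ] <- stats::rmultinom(1, n[i], pmat[i, ])
    fraction_counts(win, cnt, stats::rpois(nrow(win), rs$depth * 4),
                    rs$window, rs$step)
  }
  sim$repliseq <- list(without = draw(probs), with = draw(probs_with),
                       locus = locus,
                       expected_rt_shift = 2 * rs$advance,
                       timing_u = u)
  sim
}

#' Run the whole synthetic-data generator
#'
#' Chains [simulate_genome_with_motifs()], [simulate_origins_and_marks()],
#' [simulate_sns_reads()] and [simulate_repliseq_counts()].
#'
#' @param cfg A [sim_config()] object.
#' @return The full simulation list with genome, all feature sets, reads,
#'   Repli-seq counts and ground truth.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  sim <- simulate_genome_with_motifs(cfg)
  sim <- simulate_origins_and_marks(sim)
  sim <- simulate_sns_reads(sim)
  simulate_repliseq_counts(sim)
}

#' Audit a simulation for internal consistency
#'
#' Checks that every emitted interval lies within the generated genome,
#' that truth tables and emitted features agree, and that planted motif
#' sequences match the detector's pattern on their strand.
#'
#' @param sim A simulation list.
#' @return `TRUE` invisibly; stops with a message on any inconsistency.
#' @export
audit_simulation <- function(sim) {
  genome <- sim$genome
  cfg <- sim$truth$config
  for (nm in c("origins", "nfr", "h2az", "sns_reads")) {
    if (!is.null(sim[[nm]])) as_intervals(sim[[nm]], genome = genome)
  }
  as_intervals(sim$truth$motifs, genome = genome)
  as_intervals(sim$truth$clusters, genome = genome)
  as_intervals(sim$truth$cgis, genome = genome)
  pat <- sprintf("^G{%d,}(?:[ACGT]{%d,%d}G{%d,}){%d}$",
                 cfg$tract_len, cfg$loop_min, cfg$loop_max, cfg$tract_len,
                 cfg$n_tracts - 1L)
  sq <- interval_seq(genome, sim$truth$motifs, stranded = TRUE)
  if (!all(grepl(pat, sq, perl = TRUE)))
    stop("planted motif sequence does not match the detector pattern")
  if (!is.null(sim$truth$origins) &&
      !identical(nrow(sim$truth$origins), nrow(sim$origins)))
    stop("origin truth table and emitted origins disagree")
  invisible(TRUE)
}

#' Write all simulation outputs to a directory
#'
#' Emits FASTA, per-class BED6, read BEDs, the truth tables (JSON) and the
#' configuration (YAML).
#'
#' @param sim A simulation list.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- character(0)
  fa <- file.path(dir, "genome.fa")
  write_fasta(sim$genome, fa)
  p <- c(p, fa)
  beds <- list(motifs = sim$truth$motifs, clusters = sim$truth$clusters,
               cgis = sim$truth$cgis, origins = sim$origins, nfr = sim$nfr,
               h2az = sim$h2az, sns_reads = sim$sns_reads)
  for (nm in names(beds)) {
    if (is.null(beds[[nm]])) next
    f <- file.path(dir, paste0(nm, ".bed"))
    write_bed(as_intervals(beds[[nm]]), f)
    p <- c(p, f)
  }
  tf <- file.path(dir, "truth.json")
  tr <- sim$truth
  tr$config <- NULL
  jsonlite::write_json(tr, tf, dataframe = "columns", digits = NA)
  p <- c(p, tf)
  cf <- file.path(dir, "config.yaml")
  cfg <- sim$truth$config
  yaml::write_yaml(lapply(unclass(cfg), function(x)
    if (is.numeric(x) || is.character(x) || is.logical(x) || is.list(x)) x
    else as.character(x)), cf)
  p <- c(p, cf)
  invisible(p)
}
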