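# Independent brute-force oracles used to validate the fast implementations.
# These deliberately use naive algorithms (all-pairs loops, union-find,
# character counting, closed forms) and a different regex engine.

# Transitive-closure interval merging: union any two intervals whose gap
# (max start - min end; negative when overlapping) is <= max_gap, repeat to
# fixed point via union-find.
oracle_merge <- function(x, max_gap, stranded = FALSE) {
  n <- nrow(x)
  if (!n) return(x[0, c("chrom", "start", "end")])
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  grp <- if (stranded) x$strand else rep(".", n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (x$chrom[i] != x$chrom[j] || grp[i] != grp[j]) next
    gap <- max(x$start[i], x$start[j]) - min(x$end[i], x$end[j])
    if (gap <= max_gap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  comp <- split(seq_len(n), root)
  out <- do.call(rbind, lapply(comp, function(ix)
    data.frame(chrom = x$chrom[ix[1]], start = min(x$start[ix]),
               end = max(x$end[ix]), strand = grp[ix[1]],
               n_members = length(ix))))
  out[order(out$chrom, out$start, out$end, out$strand), ]
}

# Character-counting GC oracle.
oracle_gc <- function(genome, x) {
  seqs <- as.character(genome)
  vapply(seq_len(nrow(x)), function(i) {
    s <- strsplit(substring(seqs[[x$chrom[i]]], x$start[i] + 1, x$end[i]),
                  "")[[1]]
    acgt <- sum(s %in% c("A", "C", "G", "T"))
    if (acgt == 0) NA_real_ else sum(s %in% c("G", "C")) / acgt
  }, numeric(1))
}

# All-pairs overlap flags on already-extended half-open intervals.
oracle_overlap_flags <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    hit <- any(b$chrom == a$chrom[i] & b$start < a$end[i] &
                 b$end > a$start[i])
    as.integer(hit)
  }, integer(1))
}

# Closed-form 2x2 odds-ratio oracle.
oracle_logor <- function(a, b, c, d) {
  list(log_or = log(a * d / (b * c)), se = sqrt(1/a + 1/b + 1/c + 1/d))
}

# pG4 regex oracle using the ICU engine (stringr) on the forward sequence
# and on the reverse complement, with independent coordinate mapping.
oracle_detect_pg4 <- function(genome, tract_len = 3, loop_min = 1,
                              loop_max = 7, n_tracts = 4) {
  pat <- sprintf("G{%d,}(?:[ACGT]{%d,%d}G{%d,}){%d}",
                 tract_len, loop_min, loop_max, tract_len, n_tracts - 1)
  revcomp <- function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  seqs <- as.character(genome)
  out <- list()
  for (ch in names(seqs)) {
    L <- nchar(seqs[[ch]])
    m <- stringr::str_locate_all(seqs[[ch]], pat)[[1]]
    if (nrow(m))
      out[[length(out) + 1]] <- data.frame(chrom = ch, start = m[, 1] - 1,
                                           end = m[, 2], strand = "+")
    m <- stringr::str_locate_all(revcomp(seqs[[ch]]), pat)[[1]]
    if (nrow(m))
      out[[length(out) + 1]] <- data.frame(chrom = ch, start = L - m[, 2],
                                           end = L - m[, 1] + 1, strand = "-")
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  out <- do.call(rbind, out)
  out[order(out$chrom, out$start, out$end, out$strand), ]
}

# Connected components of the per-strand gap graph (edges: gap <= max_gap).
oracle_cluster_partition <- function(motifs, max_gap, min_k = 2, max_k = 6) {
  n <- nrow(motifs)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(max(0, n - 1))) for (j in (i + 1):n) {
    if (motifs$chrom[i] != motifs$chrom[j] ||
        motifs$strand[i] != motifs$strand[j]) next
    gap <- max(motifs$start[i], motifs$start[j]) -
      min(motifs$end[i], motifs$end[j])
    if (gap <= max_gap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  sizes <- table(root)
  k <- as.integer(sizes[as.character(root)])
  ifelse(k == 1, "monomeric",
         ifelse(k >= min_k & k <= max_k, "clustered", "oversize"))
}

# Counting oracle for windowed read-midpoint counts.
oracle_window_counts <- function(chrom, mid, windows) {
  vapply(seq_len(nrow(windows)), function(i)
    sum(chrom == windows$chrom[i] & mid >= windows$start[i] &
          mid < windows$end[i]), integer(1))
}

# Counting oracle for origin strengths.
oracle_strength <- function(origins, reads) {
  mid <- (reads$start + reads$end) %/% 2
  vapply(seq_len(nrow(origins)), function(i) {
    n <- sum(reads$chrom == origins$chrom[i] & mid >= origins$start[i] &
               mid < origins$end[i])
    n / (origins$end[i] - origins$start[i])
  }, numeric(1))
}

# Sort-and-slice oracle for strong-origin selection (ties at the threshold
# all included).
oracle_strong <- function(strengths, q) {
  thr <- stats::quantile(strengths, q, names = FALSE)
  which(strengths >= thr)
}
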