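#' Detect potential G-quadruplex motifs (pG4s) on both strands
#'
#' Scans every chromosome for the canonical pG4 pattern
#' `G{tract_len,} (loop G{tract_len,}) x (n_tracts - 1)` with loop lengths
#' in `[loop_min, loop_max]`. The plus strand is scanned directly; the minus
#' strand is scanned on the reverse complement (so minus-strand motifs are
#' C-rich on the reference, "pC4s") and reported at reference coordinates.
#' Matches within a strand are leftmost-greedy and non-overlapping in that
#' strand's 5'-to-3' direction; the two strands are scanned independently,
#' so overlapping plus/minus motifs are both kept. N bases never occur
#' inside a motif.
#'
#' @param genome A genome (`DNAStringSet` or named character vector).
#' @param tract_len Minimum G-run length (>= 2; default 3, the classical
#'   quadparser rule).
#' @param loop_min,loop_max Loop length bounds in bp (defaults 1 and 7).
#' @param n_tracts Number of G-runs (default 4).
#' @return An interval tibble of motifs with strand `+`/`-` and an
#'   `n_tracts` column (number of G-runs of at least `tract_len`, counted on
#'   the motif strand; also mirrored in `score`).
#' @export
detect_pg4 <- function(genome, tract_len = 3L, loop_min = 1L, loop_max = 7L,
                       n_tracts = 4L) {
  genome <- as_genome(genome)
  if (tract_len < 2) stop("tract_len must be >= 2")
  if (loop_min < 1 || loop_max < loop_min)
    stop("need 1 <= loop_min <= loop_max")
  if (n_tracts < 2) stop("n_tracts must be >= 2")
  pat <- sprintf("G{%d,}(?:[ACGT]{%d,%d}G{%d,}){%d}",
                 tract_len, loop_min, loop_max, tract_len, n_tracts - 1L)
  seqs <- as.character(genome)
  res <- list()
  for (ch in names(seqs)) {
    fwd <- seqs[[ch]]
    L <- nchar(fwd)
    m <- gregexpr(pat, fwd, perl = TRUE)[[1]]
    if (m[1] != -1L) {
      s0 <- as.integer(m) - 1L
      w <- attr(m, "match.length")
      res[[length(res) + 1L]] <- tibble::tibble(
        chrom = ch, start = s0, end = s0 + w, strand = "+",
        motif_seq = substring(fwd, s0 + 1L, s0 + w))
    }
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(fwd)))
    m <- gregexpr(pat, rc, perl = TRUE)[[1]]
    if (m[1] != -1L) {
      s0 <- as.integer(m) - 1L
      w <- attr(m, "match.length")
      res[[length(res) + 1L]] <- tibble::tibble(
        chrom = ch, start = L - (s0 + w), end = L - s0, strand = "-",
        motif_seq = substring(rc, s0 + 1L, s0 + w))
    }
  }
  if (!length(res)) {
    out <- intervals(character(0), integer(0), integer(0))
    out$n_tracts <- integer(0)
    return(out)
  }
  out <- do.call(rbind, res)
  run_pat <- sprintf("G{%d,}", tract_len)
  out$n_tracts <- vapply(gregexpr(run_pat, out$motif_seq, perl = TRUE),
                         function(m) if (m[1] == -1L) 0L else length(m),
                         integer(1))
  out$motif_seq <- NULL
  out$score <- as.numeric(out$n_tracts)
  out <- sort_intervals(as_intervals(out, genome = genome))
  out$name <- paste0("pG4_", seq_len(nrow(out)))
  out
}

#' Classify pG4 motifs into monomeric, clustered and oversize runs
#'
#' Same-strand motifs are chained transitively whenever consecutive gaps
#' (next start minus previous end) are at most `max_gap` (or strictly below
#' it with `strict = TRUE`). Runs of size 1 are monomers; runs of size
#' `min_k` to `max_k` are clusters; larger runs are "oversize" and excluded
#' from both categories but reported so they can be reassigned. Opposite
#' strands never merge.
#'
#' @param motifs A stranded interval table of pG4 motifs (strand `+`/`-`).
#' @param max_gap Maximum gap in bp between consecutive same-strand motifs
#'   (default 100).
#' @param min_k,max_k Cluster size bounds (defaults 2 and 6).
#' @param strict Use `gap < max_gap` instead of `gap <= max_gap`.
#' @return An object of class `pg4_clusters`: a list with
#'   \describe{
#'     \item{motifs}{the input motifs with `run_id` and `category` columns
#'       (`monomeric`, `clustered`, `oversize`);}
#'     \item{clusters}{one row per cluster: span interval, strand, size `k`
#'       (in `score`), and comma-separated member names;}
#'     \item{monomers}{the monomeric motifs;}
#'     \item{oversize}{spans of runs larger than `max_k`;}
#'     \item{fractions}{motif-level fractions of the three categories.}
#'   }
#' @export
cluster_pg4 <- function(motifs, max_gap = 100L, min_k = 2L, max_k = 6L,
                        strict = FALSE) {
  if (max_gap < 0) stop("max_gap must be >= 0")
  if (min_k < 1 || max_k < min_k) stop("need 1 <= min_k <= max_k")
  motifs <- as_intervals(motifs)
  if (nrow(motifs) && !all(motifs$strand %in% c("+", "-")))
    stop("pG4 motifs must carry explicit '+' or '-' strands")
  ord <- order(motifs$strand, motifs$chrom, motifs$start, motifs$end)
  xs <- motifs[ord, ]
  n <- nrow(xs)
  run_id <- integer(n)
  cur <- 0L; cur_end <- -1L
  for (i in seq_len(n)) {
    gap_ok <- if (strict) xs$start[i] - cur_end < max_gap
              else xs$start[i] - cur_end <= max_gap
    if (i == 1L || xs$strand[i] != xs$strand[i - 1L] ||
        xs$chrom[i] != xs$chrom[i - 1L] || !gap_ok) {
      cur <- cur + 1L
      cur_end <- xs$end[i]
    } else cur_end <- max(cur_end, xs$end[i])
    run_id[i] <- cur
  }
  k <- tabulate(run_id)
  category <- ifelse(k == 1L, "monomeric",
                     ifelse(k <= max_k & k >= min_k, "clustered", "oversize"))
  xs$run_id <- run_id
  xs$category <- category[run_id]
  span <- function(ids) {
    first <- !duplicated(run_id) & run_id %in% ids
    tibble::tibble(
      chrom = xs$chrom[first],
      start = as.integer(tapply(xs$start, run_id, min)[as.character(ids)]),
      end = as.integer(tapply(xs$end, run_id, max)[as.character(ids)]),
      name = paste0("run", ids),
      score = as.numeric(k[ids]),
      strand = xs$strand[first],
      k = k[ids],
      members = vapply(ids, function(r)
        paste(xs$name[run_id == r], collapse = ","), character(1)))
  }
  cl_ids <- which(k >= min_k & k <= max_k & k > 1L)
  ov_ids <- which(k > max_k)
  clusters <- if (length(cl_ids)) sort_intervals(span(cl_ids)) else
    span(integer(0))
  oversize <- if (length(ov_ids)) sort_intervals(span(ov_ids)) else
    span(integer(0))
  if (length(cl_ids)) clusters$name <- paste0("cluster", seq_len(nrow(clusters)))
  monomers <- sort_intervals(xs[xs$category == "monomeric",
                                setdiff(names(xs), c("run_id", "category"))])
  fr <- c(monomeric = sum(xs$category == "monomeric"),
          clustered = sum(xs$category == "clustered"),
          oversize = sum(xs$category == "oversize"))
  fractions <- if (n) fr / n else fr * NA_real_
  structure(list(motifs = xs,
                 clusters = clusters, monomers = monomers,
                 oversize = oversize, fractions = fractions,
                 params = list(max_gap = max_gap, min_k = min_k,
                               max_k = max_k, strict = strict)),
            class = "pg4_clusters")
}

#' @export
print.pg4_clusters <- function(x, ...) {
  cat("pG4 classification:", nrow(x$motifs), "motifs;",
      nrow(x$clusters), "clusters;", nrow(x$monomers), "monomers;",
      nrow(x$oversize), "oversize runs\n")
  cat("fractions: monomeric", round(x$fractions["monomeric"], 3),
      "/ clustered", round(x$fractions["clustered"], 3),
      "/ oversize", round(x$fractions["oversize"], 3), "\n")
  invisible(x)
}
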