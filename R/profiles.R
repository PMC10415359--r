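#' Anchored sliding-window coverage profile
#'
#' Aggregate meta-profile of a signal set (reads, motifs, peaks) around the
#' anchor points of a set of anchors: for each anchor and each sliding
#' window position (width `window`, step `step`, covering `[-span, span)`
#' around the anchor), counts the signal intervals intersecting the window
#' by at least 1 bp, then averages across anchors. A signal item
#' intersecting two overlapping windows contributes to both (feature
#' counting, not per-bp pileup). The number of offsets is
#' `floor((2 span - window) / step) + 1` (199 for the 1000/20/10 defaults).
#'
#' Windows extending beyond chromosome ends (when a genome is supplied) are
#' clipped out of the average: those anchor/offset cells are dropped and the
#' per-offset denominator adjusted, unless `drop_clipped = TRUE`, in which
#' case anchors with any clipped window are removed entirely.
#'
#' @param anchors Non-empty interval table of anchors.
#' @param signal Interval table of signal items on the same genome.
#' @param span Half-width of the profiled region in bp (default 1000).
#' @param window Window width in bp (default 20).
#' @param step Window step in bp (default 10; must be <= window).
#' @param anchor_mode `"first"` (5' end on the anchor's strand, the default
#'   for motif-anchored profiles) or `"midpoint"`.
#' @param orient_by_strand Mirror offsets of minus-strand anchors before
#'   averaging, so negative offsets always mean 5' of the anchor.
#' @param genome Optional genome for end clipping.
#' @param drop_clipped Drop anchors whose span exceeds chromosome bounds
#'   instead of adjusting denominators.
#' @return A tibble with columns `offset` (window centre relative to the
#'   anchor), `mean`, `se` and `n` (anchors contributing at that offset).
#' @export
coverage_profile <- function(anchors, signal, span = 1000L, window = 20L,
                             step = 10L,
                             anchor_mode = c("first", "midpoint"),
                             orient_by_strand = FALSE, genome = NULL,
                             drop_clipped = FALSE) {
  anchor_mode <- match.arg(anchor_mode)
  if (window <= 0 || step <= 0 || step > window || span < window)
    stop("need window > 0, 0 < step <= window, span >= window")
  anchors <- as_intervals(anchors, genome = genome)
  if (!nrow(anchors)) stop("anchor set must be non-empty")
  signal <- as_intervals(signal, genome = genome)
  p <- anchor_point(anchors, anchor_mode)
  wstarts <- seq.int(-span, span - window, by = step)
  n_off <- length(wstarts)
  n_anc <- nrow(anchors)
  counts <- matrix(0L, n_anc, n_off)
  valid <- matrix(TRUE, n_anc, n_off)
  len <- if (!is.null(genome)) genome_lengths(genome) else NULL
  for (ch in unique(anchors$chrom)) {
    ia <- which(anchors$chrom == ch)
    abs_start <- rep(p[ia], each = n_off) + rep(wstarts, length(ia))
    abs_end <- abs_start + window
    ok <- abs_start >= 0
    if (!is.null(len)) ok <- ok & abs_end <= len[[ch]]
    valid[ia, ] <- matrix(ok, length(ia), n_off, byrow = TRUE)
    js <- which(signal$chrom == ch)
    cnt <- integer(length(abs_start))
    if (length(js) && any(ok)) {
      h <- IRanges::findOverlaps(
        IRanges::IRanges(abs_start[ok] + 1L, abs_end[ok]),
        IRanges::IRanges(signal$start[js] + 1L, signal$end[js]))
      cnt[which(ok)] <- tabulate(S4Vectors::queryHits(h), nbins = sum(ok))
    }
    counts[ia, ] <- matrix(cnt, length(ia), n_off, byrow = TRUE)
  }
  if (orient_by_strand) {
    neg <- which(anchors$strand == "-")
    if (length(neg)) {
      counts[neg, ] <- counts[neg, n_off:1, drop = FALSE]
      valid[neg, ] <- valid[neg, n_off:1, drop = FALSE]
    }
  }
  if (drop_clipped) {
    keep <- rowSums(!valid) == 0
    if (!any(keep)) stop("all anchors clipped")
    counts <- counts[keep, , drop = FALSE]
    valid <- valid[keep, , drop = FALSE]
  }
  cm <- counts
  cm[!valid] <- NA_real_
  n <- colSums(valid)
  mu <- colMeans(cm, na.rm = TRUE)
  sdv <- apply(cm, 2, stats::sd, na.rm = TRUE)
  se <- ifelse(n > 1, sdv / sqrt(n), NA_real_)
  tibble::tibble(offset = wstarts + window / 2, mean = mu, se = se, n = n)
}
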