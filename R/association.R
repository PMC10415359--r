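#' Flag segments overlapping a feature set after anchor extension
#'
#' Both segments and features are extended by `flank` bp around their anchor
#' points (see [extend_around_point()]); a segment is flagged 1 when its
#' extended interval intersects at least one extended feature by at least
#' 1 bp.
#'
#' @param segments,features Interval tables on the same genome.
#' @param flank Extension in bp on each side of the anchor (default 1000).
#'   Use `flank = NULL` to flag raw-interval overlaps without extension.
#' @param genome Optional genome for clipping at chromosome ends.
#' @param anchor Anchor mode (default `"midpoint"`).
#' @return Integer vector of 0/1 flags, one per segment.
#' @export
overlap_flags <- function(segments, features, flank = 1000L, genome = NULL,
                          anchor = "midpoint") {
  segments <- as_intervals(segments, genome = genome)
  features <- as_intervals(features, genome = genome)
  if (!is.null(flank)) {
    segments <- extend_around_point(segments, flank, genome, anchor)
    features <- extend_around_point(features, flank, genome, anchor)
  }
  as.integer(interval_overlaps_any(segments, features))
}

#' Strand-aware origin/pG4 association flags
#'
#' Implements the oriented variant of the origin association: per origin
#' peak `p` (the anchor point), the flag is 1 when a plus-strand pG4
#' overlaps the upstream window `[p - flank, p)` (in reference orientation)
#' or a minus-strand pG4 (a pC4 on the reference) overlaps the downstream
#' window `[p, p + flank)`. The two components are also returned separately.
#'
#' @param origins Interval table of origin peaks.
#' @param motifs Stranded interval table of pG4 motifs.
#' @param flank Window size in bp on each side of the peak (default 1000).
#' @param genome Optional genome for clipping.
#' @param anchor Origin anchor mode (default `"midpoint"`).
#' @return A tibble with columns `flag`, `plus_upstream`,
#'   `minus_downstream` (0/1), one row per origin.
#' @export
strand_aware_origin_pg4_flags <- function(origins, motifs, flank = 1000L,
                                          genome = NULL, anchor = "midpoint") {
  origins <- as_intervals(origins, genome = genome)
  motifs <- as_intervals(motifs, genome = genome)
  if (nrow(motifs) && any(!motifs$strand %in% c("+", "-")))
    stop("all pG4 motifs must be stranded (+/-)")
  p <- anchor_point(origins, anchor)
  up <- tibble::tibble(chrom = origins$chrom,
                       start = pmax(0L, p - as.integer(flank)),
                       end = p)
  dn <- tibble::tibble(chrom = origins$chrom, start = p,
                       end = p + as.integer(flank))
  if (!is.null(genome)) {
    len <- genome_lengths(genome)
    dn$end <- pmin(dn$end, as.integer(len[dn$chrom]))
  }
  valid_up <- up$start < up$end
  valid_dn <- dn$start < dn$end
  plus_up <- integer(nrow(origins))
  minus_dn <- integer(nrow(origins))
  plus <- motifs[motifs$strand == "+", ]
  minus <- motifs[motifs$strand == "-", ]
  if (any(valid_up) && nrow(plus))
    plus_up[valid_up] <- as.integer(
      interval_overlaps_any(as_intervals(up[valid_up, ]), plus))
  if (any(valid_dn) && nrow(minus))
    minus_dn[valid_dn] <- as.integer(
      interval_overlaps_any(as_intervals(dn[valid_dn, ]), minus))
  tibble::tibble(flag = as.integer(plus_up | minus_dn),
                 plus_upstream = plus_up, minus_downstream = minus_dn)
}

#' Logistic-regression enrichment of real versus matched random segments
#'
#' Fits `class ~ flag` by maximum likelihood (binomial GLM), where class is
#' 1 for real segments and 0 for random segments. With a single binary
#' covariate the flag coefficient is the log-odds ratio
#' `ln(a d / (b c))` of the 2x2 table (a = real & flagged, b = real & not,
#' c = random & flagged, d = random & not), with standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)`. `logOR = 0` means the feature is equally
#' associated in real and random segments; `logOR > 0` means stronger
#' association in the real class. Significance is a two-sided Wald test.
#' Any zero cell triggers the Haldane-Anscombe correction (+0.5 on all
#' cells), flagged in the result.
#'
#' @param real_flags,random_flags Non-empty 0/1 vectors for the real and
#'   random segment classes.
#' @return An object of class `enrichment_result`: list with `counts`
#'   (named a, b, c, d), `log_or`, `se`, `wald_z`, `p_value`,
#'   `continuity_corrected`.
#' @export
logistic_enrichment <- function(real_flags, random_flags) {
  if (!length(real_flags) || !length(random_flags))
    stop("both flag vectors must be non-empty (need both classes)")
  if (!all(c(real_flags, random_flags) %in% c(0L, 1L)))
    stop("flags must be 0/1")
  a <- sum(real_flags == 1)
  b <- sum(real_flags == 0)
  c_ <- sum(random_flags == 1)
  d <- sum(random_flags == 0)
  counts <- c(a = a, b = b, c = c_, d = d)
  corrected <- any(counts == 0)
  if (corrected) {
    cc <- counts + 0.5
    log_or <- log(cc["a"] * cc["d"] / (cc["b"] * cc["c"]))
    se <- sqrt(sum(1 / cc))
  } else {
    df <- data.frame(class = c(1, 1, 0, 0), flag = c(1, 0, 1, 0),
                     wt = as.numeric(counts))
    fit <- stats::glm(class ~ flag, family = stats::binomial(),
                      weights = wt, data = df,
                      control = stats::glm.control(epsilon = 1e-12))
    log_or <- unname(stats::coef(fit)["flag"])
    se <- sqrt(sum(1 / counts))
  }
  z <- unname(log_or / se)
  structure(list(counts = counts, log_or = unname(log_or), se = unname(se),
                 wald_z = z,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 continuity_corrected = corrected),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment: logOR = %.4f (se %.4f), Wald z = %.3f, p = %.3g%s\n",
    x$log_or, x$se, x$wald_z, x$p_value,
    if (x$continuity_corrected) " [Haldane-Anscombe corrected]" else ""))
  cat("counts: a =", x$counts["a"], "b =", x$counts["b"],
      "c =", x$counts["c"], "d =", x$counts["d"], "\n")
  invisible(x)
}

#' Per-feature-class enrichment table
#'
#' Computes overlap flags and logistic enrichment for each feature class
#' against a paired matched random set. Features of the real set whose
#' random matches failed are dropped together with their (absent) random
#' partners, preserving the paired design. With `require_pg4`, both real
#' and random segments are first restricted to segments flagged for any pG4
#' motif, giving the conditional comparisons (among pG4-bearing segments,
#' is the association towards the clustered or the monomeric form?).
#'
#' @param real Interval table of real segments (e.g. origins).
#' @param random A `matched_random` object paired to `real`, or an interval
#'   table of random segments.
#' @param feature_sets Named list of interval tables, one per feature class.
#' @param flank Anchor extension in bp (default 1000).
#' @param genome Optional genome for clipping.
#' @param adjust Multiple-testing adjustment passed to [stats::p.adjust()]
#'   (default `"none"`; the Wald p-values are reported raw).
#' @param require_pg4 Optional interval table of pG4 motifs; when given,
#'   the comparison is restricted to segments carrying any pG4.
#' @return A tibble with one row per feature class: counts a-d, `log_or`,
#'   `se`, `wald_z`, `p_value`, `p_adj`, `continuity_corrected`.
#' @export
enrichment_table <- function(real, random, feature_sets, flank = 1000L,
                             genome = NULL, adjust = "none",
                             require_pg4 = NULL) {
  real <- as_intervals(real, genome = genome)
  if (inherits(random, "matched_random")) {
    if (length(random$unmatched))
      real <- real[-random$unmatched, ]
    random <- random$segments
  }
  random <- as_intervals(random, genome = genome)
  if (!is.null(require_pg4)) {
    keep_r <- overlap_flags(real, require_pg4, flank, genome) == 1L
    keep_n <- overlap_flags(random, require_pg4, flank, genome) == 1L
    real <- real[keep_r, ]
    random <- random[keep_n, ]
  }
  rows <- lapply(names(feature_sets), function(cls) {
    fr <- overlap_flags(real, feature_sets[[cls]], flank, genome)
    fn <- overlap_flags(random, feature_sets[[cls]], flank, genome)
    e <- logistic_enrichment(fr, fn)
    tibble::tibble(feature = cls, a = e$counts["a"], b = e$counts["b"],
                   c = e$counts["c"], d = e$counts["d"], log_or = e$log_or,
                   se = e$se, wald_z = e$wald_z, p_value = e$p_value,
                   continuity_corrected = e$continuity_corrected)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = adjust)
  out
}
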