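#' Genome sliding-window grid
#'
#' Windows of width `window` every `step` bp per chromosome. Trailing
#' partial windows are kept with their true (clipped) width.
#'
#' @param genome A genome, or a named vector of chromosome lengths.
#' @param window Window width in bp (default 50000).
#' @param step Window step in bp (default 10000; must be <= window).
#' @return A tibble with `chrom`, `start`, `end`, `midpoint`.
#' @export
genome_windows <- function(genome, window = 50000L, step = 10000L) {
  if (step > window) stop("step must be <= window")
  len <- if (is.numeric(genome)) genome else genome_lengths(genome)
  rows <- lapply(names(len), function(ch) {
    starts <- seq.int(0L, max(0L, len[[ch]] - 1L), by = step)
    starts <- starts[starts < len[[ch]]]
    tibble::tibble(chrom = ch, start = as.integer(starts),
                   end = as.integer(pmin(starts + window, len[[ch]])))
  })
  out <- do.call(rbind, rows)
  out$midpoint <- (out$start + out$end) %/% 2L
  out
}

#' Windowed read counts for Repli-seq fractions
#'
#' Counts reads per sliding genome window, assigning each read to every
#' window containing its midpoint. Builds the four S-phase fraction tracks
#' (S1 early to S4 late) plus the asynchronous control sample.
#'
#' @param reads Named list of interval tables with elements `S1`, `S2`,
#'   `S3`, `S4` and `async`.
#' @param genome A genome (or named length vector).
#' @param window,step Window geometry in bp (defaults 50000 and 10000).
#' @return An object of class `fraction_counts`: list with `windows` (the
#'   grid tibble), `counts` (matrix windows x S1..S4) and `async` (vector).
#' @export
windowed_counts <- function(reads, genome, window = 50000L, step = 10000L) {
  need <- c("S1", "S2", "S3", "S4", "async")
  if (!all(need %in% names(reads)))
    stop("reads must be a named list with S1, S2, S3, S4 and async")
  win <- genome_windows(genome, window, step)
  wtab <- as_intervals(win[, c("chrom", "start", "end")])
  count_one <- function(x) {
    x <- as_intervals(x)
    point_in_interval_counts(wtab, x$chrom, (x$start + x$end) %/% 2L)
  }
  cnt <- vapply(reads[c("S1", "S2", "S3", "S4")], count_one,
                integer(nrow(win)))
  structure(list(windows = win, counts = cnt,
                 async = count_one(reads$async),
                 window = window, step = step),
            class = "fraction_counts")
}

#' Assemble fraction counts from precomputed tracks
#'
#' @param windows A window tibble (see [genome_windows()]).
#' @param counts Matrix of per-window counts with columns S1..S4.
#' @param async Vector of asynchronous-sample counts per window.
#' @param window,step Window geometry the grid was built with.
#' @return A `fraction_counts` object.
#' @export
fraction_counts <- function(windows, counts, async, window = 50000L,
                            step = 10000L) {
  counts <- as.matrix(counts)
  colnames(counts) <- c("S1", "S2", "S3", "S4")
  stopifnot(nrow(windows) == nrow(counts), length(async) == nrow(counts),
            all(counts >= 0), all(async >= 0))
  if (!"midpoint" %in% names(windows))
    windows$midpoint <- (windows$start + windows$end) %/% 2L
  structure(list(windows = tibble::as_tibble(windows), counts = counts,
                 async = async, window = window, step = step),
            class = "fraction_counts")
}

#' Normalize, standardize and spline-smooth Repli-seq fraction tracks
#'
#' Per fraction f and window w, the normalized enrichment is
#' `(c_f(w) / sum_w c_f) / (a(w) / sum_w a)` where `a` is the asynchronous
#' coverage: this corrects both global (library size) and local (coverage)
#' variation. Windows with zero asynchronous coverage are masked. Each
#' normalized track is then centred and scaled to unit standard deviation
#' over unmasked windows, and finally smoothed per chromosome with a cubic
#' smoothing spline ([stats::smooth.spline()]) against window midpoints.
#'
#' @param fc A `fraction_counts` object.
#' @param spar Smoothing parameter for `smooth.spline`; `NULL` (default)
#'   selects it per chromosome by generalized cross-validation.
#' @return An object of class `rt_profile`: list with `windows`, `mask`
#'   (TRUE = usable window), and windows-by-fraction matrices `normalized`,
#'   `standardized`, `smoothed` (NA at masked windows).
#' @export
normalize_standardize_smooth <- function(fc, spar = NULL) {
  stopifnot(inherits(fc, "fraction_counts"))
  a <- fc$async
  if (all(a == 0)) stop("asynchronous counts are all zero")
  mask <- a > 0
  if (!any(mask)) stop("all windows masked")
  a_rel <- a / sum(a)
  norm <- std <- smo <- matrix(NA_real_, nrow(fc$counts), 4,
                               dimnames = list(NULL, colnames(fc$counts)))
  for (f in 1:4) {
    cf <- fc$counts[, f]
    if (sum(cf) == 0) stop("fraction ", colnames(fc$counts)[f],
                           " has zero total counts")
    r <- (cf / sum(cf)) / a_rel
    r[!mask] <- NA_real_
    norm[, f] <- r
    mu <- mean(r[mask])
    sdv <- stats::sd(r[mask])
    if (sdv == 0) sdv <- 1
    std[, f] <- (r - mu) / sdv
  }
  for (ch in unique(fc$windows$chrom)) {
    i <- which(fc$windows$chrom == ch & mask)
    if (length(i) < 4) {
      smo[i, ] <- std[i, ]
      next
    }
    x <- fc$windows$midpoint[i]
    for (f in 1:4) {
      fit <- if (is.null(spar))
        stats::smooth.spline(x, std[i, f], cv = FALSE)
      else stats::smooth.spline(x, std[i, f], spar = spar)
      smo[i, f] <- stats::predict(fit, x)$y
    }
  }
  structure(list(windows = fc$windows, mask = mask, normalized = norm,
                 standardized = std, smoothed = smo, spar = spar),
            class = "rt_profile")
}

#' Weighted-average combination of four S-phase fraction values
#'
#' The single-track replication-timing summary
#' `WA = 0.750 S1 + 0.583 S2 + 0.417 S3 + 0.250 S4`. An increase in WA
#' indicates earlier replication timing. Vectorized over windows.
#'
#' @param s1,s2,s3,s4 Standardized enrichment values of fractions S1..S4.
#' @return Numeric vector of WA values.
#' @export
wa_combine <- function(s1, s2, s3, s4) {
  0.750 * s1 + 0.583 * s2 + 0.417 * s3 + 0.250 * s4
}

#' Weighted-average replication-timing track of a profile
#'
#' @param profile An `rt_profile` object with all four fraction tracks.
#' @param use_smoothed Combine the smoothed tracks (default) or the raw
#'   standardized tracks.
#' @return Numeric vector of WA per window (NA at masked windows).
#' @export
weighted_average_rt <- function(profile, use_smoothed = TRUE) {
  stopifnot(inherits(profile, "rt_profile"))
  m <- if (use_smoothed) profile$smoothed else profile$standardized
  if (ncol(m) != 4 || any(!c("S1", "S2", "S3", "S4") %in% colnames(m)))
    stop("profile must carry all four fraction tracks")
  wa_combine(m[, "S1"], m[, "S2"], m[, "S3"], m[, "S4"])
}

#' Replication-timing shift between two conditions
#'
#' From locus-level percentage distributions of nascent-strand signal over
#' the four S-phase fractions (each summing to 100):
#' `deltaL = (S3 + S4)_with - (S3 + S4)_without`,
#' `deltaE = S1_with - S1_without`, and
#' `RT shift = -deltaL + deltaE` (percentage points; positive = replication
#' advanced to earlier S phase).
#'
#' @param percent_with,percent_without Length-4 non-negative vectors of
#'   percentages (S1, S2, S3, S4) summing to 100 (tolerance 1e-6).
#' @return A list of class `rt_shift_result` with `delta_e`, `delta_l`,
#'   `rt_shift`.
#' @export
rt_shift <- function(percent_with, percent_without) {
  check <- function(v, nm) {
    if (length(v) != 4 || any(is.na(v)) || any(v < 0))
      stop(nm, " must be a non-negative length-4 percentage vector")
    if (abs(sum(v) - 100) > 1e-6)
      stop(nm, " must sum to 100 (got ", sum(v), ")")
  }
  check(percent_with, "percent_with")
  check(percent_without, "percent_without")
  delta_l <- (percent_with[3] + percent_with[4]) -
    (percent_without[3] + percent_without[4])
  delta_e <- percent_with[1] - percent_without[1]
  structure(list(delta_e = unname(delta_e), delta_l = unname(delta_l),
                 rt_shift = unname(-delta_l + delta_e)),
            class = "rt_shift_result")
}

#' @export
print.rt_shift_result <- function(x, ...) {
  cat(sprintf("RT shift = %.2f (deltaE = %.2f, deltaL = %.2f); %s\n",
              x$rt_shift, x$delta_e, x$delta_l,
              if (x$rt_shift > 0) "earlier" else if (x$rt_shift < 0)
                "later" else "unchanged"))
  invisible(x)
}

#' Locus percentage vector over the four S-phase fractions
#'
#' Sums fraction counts over the windows whose midpoint falls inside the
#' locus and converts to percentages (summing to 100). This is the input
#' contract of [rt_shift()].
#'
#' @param fc A `fraction_counts` object.
#' @param locus A single-row interval table (or list with `chrom`, `start`,
#'   `end`).
#' @return Named numeric length-4 vector of percentages.
#' @export
rt_percent_vectors <- function(fc, locus) {
  stopifnot(inherits(fc, "fraction_counts"))
  i <- which(fc$windows$chrom == locus$chrom[1] &
               fc$windows$midpoint >= locus$start[1] &
               fc$windows$midpoint < locus$end[1])
  if (!length(i)) stop("no window midpoint falls inside the locus")
  tot <- colSums(fc$counts[i, , drop = FALSE])
  if (sum(tot) == 0) stop("no reads at the locus")
  100 * tot / sum(tot)
}

#' Origin strength from SNS reads
#'
#' Strength of origin i = (number of reads whose midpoint lies within the
#' origin) / origin length, in reads per bp.
#'
#' @param origins Interval table of origins (non-degenerate).
#' @param sns_reads Interval table of SNS reads.
#' @return Numeric vector of strengths, one per origin.
#' @export
origin_strength <- function(origins, sns_reads) {
  origins <- as_intervals(origins)
  if (nrow(origins) && any(origins$end - origins$start <= 0))
    stop("zero-length origin")
  sns_reads <- as_intervals(sns_reads)
  n <- point_in_interval_counts(origins, sns_reads$chrom,
                                (sns_reads$start + sns_reads$end) %/% 2L)
  n / (origins$end - origins$start)
}

#' Select strong origins by strength quantile
#'
#' Origins with strength at or above the given quantile of the strength
#' distribution (default 0.75, i.e. the top 25% most active origins). Ties
#' at the threshold are all included.
#'
#' @param origins Interval table of origins.
#' @param strengths Numeric vector of strengths (see [origin_strength()]).
#' @param quantile Strength quantile threshold (default 0.75).
#' @return The selected origins, with a `strength` column.
#' @export
strong_origins <- function(origins, strengths, quantile = 0.75) {
  origins <- as_intervals(origins)
  stopifnot(length(strengths) == nrow(origins))
  thr <- stats::quantile(strengths, quantile, names = FALSE)
  out <- origins[strengths >= thr, ]
  out$strength <- strengths[strengths >= thr]
  out
}

#' Stratify origin strength by CGI status and pG4 content
#'
#' Assigns each origin to CGI or non-CGI by direct overlap, counts the
#' monomeric and clustered pG4s within its extended span (anchor +/- flank;
#' counts at or above `max_count` are binned as `"max_count+"`), and
#' reports each group's mean strength with a two-sided 95% Student-t
#' confidence interval. Groups with a single origin have an undefined CI
#' (NA, flagged by `ci_defined`).
#'
#' @param origins Interval table of origins.
#' @param strengths Numeric vector of per-origin strengths.
#' @param clusters A `pg4_clusters` object (see [cluster_pg4()]).
#' @param cgis Interval table of CpG islands.
#' @param flank Extension of the origin span in bp for pG4 counting
#'   (default 1000).
#' @param max_count Cap for the count bins (default 3).
#' @param genome Optional genome for clipping.
#' @return A list with `origins` (per-origin tibble: `cgi`, `n_monomeric`,
#'   `n_clustered`, `strength`) and `groups` (per-group tibble: `cgi`,
#'   `n_monomeric`, `n_clustered`, `n`, `mean`, `ci_lo`, `ci_hi`,
#'   `ci_defined`).
#' @export
stratify_strength <- function(origins, strengths, clusters, cgis,
                              flank = 1000L, max_count = 3L, genome = NULL) {
  origins <- as_intervals(origins, genome = genome)
  stopifnot(inherits(clusters, "pg4_clusters"),
            length(strengths) == nrow(origins))
  ext <- extend_around_point(origins, flank, genome)
  cap <- function(n) {
    lv <- c(as.character(0:(max_count - 1)), paste0(max_count, "+"))
    factor(ifelse(n >= max_count, paste0(max_count, "+"), as.character(n)),
           levels = lv)
  }
  n_mono <- interval_overlap_counts(ext, clusters$monomers)
  n_clus <- interval_overlap_counts(ext, clusters$clusters)
  cgi <- interval_overlaps_any(origins, as_intervals(cgis))
  per <- tibble::tibble(name = origins$name, cgi = cgi,
                        n_monomeric = cap(n_mono), n_clustered = cap(n_clus),
                        strength = strengths)
  key <- interaction(per$cgi, per$n_monomeric, per$n_clustered, drop = TRUE)
  groups <- do.call(rbind, lapply(levels(key), function(kk) {
    s <- per$strength[key == kk]
    n <- length(s)
    m <- mean(s)
    half <- if (n >= 2) stats::qt(0.975, n - 1) * stats::sd(s) / sqrt(n)
            else NA_real_
    row <- per[key == kk, ][1, c("cgi", "n_monomeric", "n_clustered")]
    tibble::tibble(row, n = n, mean = m, ci_lo = m - half, ci_hi = m + half,
                   ci_defined = n >= 2)
  }))
  list(origins = per, groups = groups)
}
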