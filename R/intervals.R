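#' Build or validate an interval table
#'
#' Interval tables are the package's lingua franca: tibbles with columns
#' `chrom`, `start`, `end` (0-based half-open, BED convention), and
#' optionally `name`, `score`, `strand` (one of `+`, `-`, `.`). Missing
#' optional columns are filled with defaults. Invariants enforced:
#' `0 <= start < end`, and `end <=` chromosome length when a genome is
#' supplied.
#'
#' @param x A data frame with at least `chrom`, `start`, `end`.
#' @param genome Optional genome; when given, intervals are validated
#'   against chromosome bounds and names.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (plus any extra columns of `x`).
#' @export
as_intervals <- function(x, genome = NULL) {
  if (!is.data.frame(x)) stop("intervals must be a data frame")
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing interval columns: ", paste(miss, collapse = ", "))
  x <- tibble::as_tibble(x)
  x$chrom <- as.character(x$chrom)
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  if (!"name" %in% names(x)) x$name <- if (nrow(x)) paste0("iv", seq_len(nrow(x))) else character(0)
  if (!"score" %in% names(x)) x$score <- rep(0, nrow(x))
  if (!"strand" %in% names(x)) x$strand <- rep(".", nrow(x))
  if (nrow(x)) {
    if (anyNA(x$start) || anyNA(x$end)) stop("non-integer interval coordinates")
    bad <- which(x$start < 0L | x$start >= x$end)
    if (length(bad))
      stop("invalid interval (need 0 <= start < end) at row ", bad[1])
    if (!all(x$strand %in% c("+", "-", ".")))
      stop("strand must be one of '+', '-', '.'")
    if (!is.null(genome)) {
      len <- genome_lengths(genome)
      unknown <- setdiff(unique(x$chrom), names(len))
      if (length(unknown)) stop("chromosome not in genome: ", unknown[1])
      oob <- which(x$end > len[x$chrom])
      if (length(oob))
        stop("interval exceeds chromosome bounds at row ", oob[1])
    }
  }
  x[, c("name", "score", "strand")] <- x[, c("name", "score", "strand")]
  x[, unique(c(need, "name", "score", "strand", names(x)))]
}

#' Construct an interval table from vectors
#'
#' @param chrom,start,end,name,score,strand Field vectors (recycled).
#' @param genome Optional genome for bounds validation.
#' @return An interval tibble.
#' @export
intervals <- function(chrom, start, end, name = NULL, score = 0,
                      strand = ".", genome = NULL) {
  df <- tibble::tibble(chrom = as.character(chrom), start = as.integer(start),
                       end = as.integer(end), score = score, strand = strand)
  if (!is.null(name)) df$name <- name
  as_intervals(df, genome = genome)
}

#' Sort an interval table
#'
#' Deterministic order: chromosome (lexical), start, end, strand.
#'
#' @param x An interval table.
#' @return The sorted table.
#' @export
sort_intervals <- function(x) {
  x <- as_intervals(x)
  x[order(x$chrom, x$start, x$end, x$strand), ]
}

#' Read a BED3/BED6 file
#'
#' Tab-separated, headerless BED. Column 6 (strand) defaults to `"."` when
#' absent. Malformed lines (non-integer coordinates, `start >= end`) raise a
#' parse error naming the offending line; out-of-bounds records against a
#' supplied genome raise a validation error.
#'
#' @param path Path to the BED file.
#' @param genome Optional genome for bounds validation.
#' @return An interval tibble (empty for an empty file).
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(intervals(character(0), integer(0), integer(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) stop("BED parse error: fewer than 3 fields at line ",
                        which(nf < 3)[1], " of ", path)
  get <- function(k, default) vapply(fields, function(f)
    if (length(f) >= k) f[k] else default, character(1))
  start <- suppressWarnings(as.integer(get(2, NA)))
  end <- suppressWarnings(as.integer(get(3, NA)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad))
    stop("BED parse error: bad coordinates at line ", bad[1], " of ", path)
  df <- tibble::tibble(
    chrom = get(1, NA_character_),
    start = start, end = end,
    name = get(4, "."),
    score = suppressWarnings(as.numeric(get(5, "0"))),
    strand = get(6, "."))
  df$score[is.na(df$score)] <- 0
  as_intervals(df, genome = genome)
}

#' Write an interval table as BED6
#'
#' @param x An interval table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  x <- as_intervals(x)
  df <- data.frame(x$chrom, x$start, x$end, x$name,
                   format(x$score, trim = TRUE, scientific = FALSE), x$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a bedGraph track
#'
#' @param x A data frame with columns `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(x)))
  keep <- !is.na(x$value)
  df <- data.frame(x$chrom, x$start, x$end,
                   format(x$value, trim = TRUE, scientific = FALSE))[keep, ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge intervals separated by at most a gap
#'
#' Replaces maximal runs of intervals in which consecutive members (in
#' sorted order) are separated by `gap <= max_gap` (gap = next start minus
#' previous end; overlapping intervals have negative gap) with their span,
#' mirroring `bedtools merge -d`. With `stranded = TRUE`, merging happens
#' within each strand separately. Output is sorted and carries the member
#' count of each merged interval in `n_members` (also mirrored in `score`).
#'
#' @param x An interval table.
#' @param max_gap Maximum gap in bp (>= 0) across which to merge.
#' @param stranded Merge within strands separately.
#' @return A sorted interval tibble with an `n_members` column.
#' @export
merge_intervals <- function(x, max_gap = 0L, stranded = FALSE) {
  if (max_gap < 0) stop("max_gap must be >= 0")
  x <- as_intervals(x)
  if (!nrow(x)) {
    out <- x
    out$n_members <- integer(0)
    return(out)
  }
  grp <- if (stranded) x$strand else rep(".", nrow(x))
  ord <- order(grp, x$chrom, x$start, x$end)
  xs <- x[ord, ]
  gs <- grp[ord]
  n <- nrow(xs)
  # new run whenever group/chrom changes or gap to running max end > max_gap
  run_id <- integer(n)
  cur <- 0L
  cur_end <- -1L
  for (i in seq_len(n)) {
    if (i == 1L || gs[i] != gs[i - 1L] || xs$chrom[i] != xs$chrom[i - 1L] ||
        xs$start[i] > cur_end + max_gap) {
      cur <- cur + 1L
      cur_end <- xs$end[i]
    } else {
      cur_end <- max(cur_end, xs$end[i])
    }
    run_id[i] <- cur
  }
  starts <- tapply(xs$start, run_id, min)
  ends <- tapply(xs$end, run_id, max)
  first <- !duplicated(run_id)
  out <- tibble::tibble(
    chrom = xs$chrom[first],
    start = as.integer(starts),
    end = as.integer(ends),
    name = paste0("merged", seq_along(starts)),
    score = as.numeric(tabulate(run_id)),
    strand = if (stranded) gs[first] else rep(".", sum(first)),
    n_members = tabulate(run_id))
  sort_intervals(out)
}

#' Anchor point of intervals
#'
#' The reference point used for extension and profiling. `"midpoint"` is
#' `floor((start + end) / 2)`; `"first"` is the 5' end on the interval's
#' strand (`start` for `+` or unstranded, `end - 1` for `-`); `"start"` is
#' always the reference start.
#'
#' @param x An interval table.
#' @param mode One of `"midpoint"`, `"first"`, `"start"`.
#' @return Integer vector of anchor positions (0-based).
#' @export
anchor_point <- function(x, mode = c("midpoint", "first", "start")) {
  mode <- match.arg(mode)
  x <- as_intervals(x)
  switch(mode,
    midpoint = as.integer((x$start + x$end) %/% 2L),
    start = x$start,
    first = ifelse(x$strand == "-", x$end - 1L, x$start))
}

#' Extend intervals around their anchor point
#'
#' Returns `[p - flank, p + flank)` around each interval's anchor point `p`,
#' clipped to chromosome bounds when a genome is supplied. Strand and
#' metadata are preserved.
#'
#' @param x An interval table.
#' @param flank Flank in bp (> 0) on each side of the anchor.
#' @param genome Optional genome for clipping at chromosome ends.
#' @param anchor Anchor mode, see [anchor_point()].
#' @return An interval tibble of extended segments.
#' @export
extend_around_point <- function(x, flank, genome = NULL,
                                anchor = c("midpoint", "first", "start")) {
  if (flank <= 0) stop("flank must be > 0")
  x <- as_intervals(x, genome = genome)
  p <- anchor_point(x, match.arg(anchor))
  out <- x
  out$start <- pmax(0L, p - as.integer(flank))
  out$end <- p + as.integer(flank)
  if (!is.null(genome)) {
    len <- genome_lengths(genome)
    out$end <- pmin(out$end, as.integer(len[out$chrom]))
  }
  out
}

# ---- internal overlap machinery (IRanges behind the tibble surface) ----

.ir <- function(x) IRanges::IRanges(start = x$start + 1L, end = x$end)

# All overlapping pairs between two interval tables (>= minoverlap bp).
# Returns a data.frame with columns query, subject (row indices).
interval_overlap_pairs <- function(a, b, minoverlap = 1L) {
  q <- integer(0); s <- integer(0)
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    h <- IRanges::findOverlaps(.ir(a[ia, ]), .ir(b[ib, ]),
                               minoverlap = minoverlap)
    q <- c(q, ia[S4Vectors::queryHits(h)])
    s <- c(s, ib[S4Vectors::subjectHits(h)])
  }
  data.frame(query = q, subject = s)
}

# Logical: does each interval of a overlap any interval of b?
interval_overlaps_any <- function(a, b, minoverlap = 1L) {
  out <- logical(nrow(a))
  if (!nrow(a) || !nrow(b)) return(out)
  h <- interval_overlap_pairs(a, b, minoverlap)
  out[unique(h$query)] <- TRUE
  out
}

# Count of b-intervals overlapping each a-interval.
interval_overlap_counts <- function(a, b, minoverlap = 1L) {
  if (!nrow(a) || !nrow(b)) return(integer(nrow(a)))
  h <- interval_overlap_pairs(a, b, minoverlap)
  tabulate(h$query, nbins = nrow(a))
}

# Count of positions (0-based) falling inside each interval of a.
point_in_interval_counts <- function(a, chrom, pos) {
  out <- integer(nrow(a))
  for (ch in intersect(unique(a$chrom), unique(chrom))) {
    ia <- which(a$chrom == ch)
    p <- pos[chrom == ch]
    h <- IRanges::findOverlaps(IRanges::IRanges(p + 1L, width = 1L),
                               .ir(a[ia, ]))
    out[ia] <- out[ia] + tabulate(S4Vectors::subjectHits(h),
                                  nbins = length(ia))
  }
  out
}
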