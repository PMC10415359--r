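#' Read a genome from a FASTA file
#'
#' Reads a multi-record, possibly line-wrapped FASTA file into a
#' [Biostrings::DNAStringSet], uppercases the sequences and checks that the
#' alphabet is restricted to A, C, G, T and N and that record names are
#' unique. The returned object is the genome container used throughout the
#' package.
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet`, one entry per chromosome.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  as_genome(stats::setNames(toupper(as.character(g)), names(g)))
}

#' Write a genome to a FASTA file
#'
#' @param genome A `DNAStringSet` (or named character vector of sequences).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(genome, path, width = width)
  invisible(path)
}

#' Coerce to the genome container
#'
#' Validates and converts a named character vector (or `DNAStringSet`) of
#' chromosome sequences into the package's genome container. Sequences must
#' use only the alphabet A, C, G, T, N and chromosome names must be unique
#' and non-empty.
#'
#' @param x Named character vector of sequences, or a `DNAStringSet`.
#' @return A named `DNAStringSet`.
#' @export
as_genome <- function(x) {
  if (is(x, "DNAStringSet")) return(x)   # validated at construction
  if (!is.character(x) || is.null(names(x)) || any(!nzchar(names(x))))
    stop("genome must be a named character vector or DNAStringSet")
  if (anyDuplicated(names(x))) stop("duplicate chromosome names in genome")
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad))
    stop("genome alphabet restricted to {A,C,G,T,N}; offending chromosome: ",
         names(x)[bad][1])
  Biostrings::DNAStringSet(x)
}

#' Chromosome lengths of a genome
#'
#' @param genome A genome (`DNAStringSet`).
#' @return Named integer vector of chromosome lengths in bp.
#' @export
genome_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

#' Precompute a cumulative GC index for fast repeated lookups
#'
#' For each chromosome, stores cumulative counts of G/C and of non-N bases,
#' giving O(1) GC-fraction computation for arbitrary intervals. Pass the
#' result to [gc_fraction()] or [sample_matched_random()] when querying the
#' same genome many times.
#'
#' @param genome A genome (`DNAStringSet`).
#' @return An opaque index object of class `gc_index`.
#' @export
gc_index <- function(genome) {
  seqs <- as.character(genome)
  idx <- lapply(seqs, function(s) {
    r <- charToRaw(s)
    is_gc <- r == charToRaw("G") | r == charToRaw("C")
    is_n <- r == charToRaw("N")
    list(gc = c(0, cumsum(as.integer(is_gc))),
         acgt = c(0, cumsum(as.integer(!is_n))))
  })
  structure(idx, class = "gc_index")
}

#' GC fraction of genomic intervals
#'
#' Computes (G + C) / (A + C + G + T) for each interval; N bases are excluded
#' from the denominator. Intervals composed entirely of N return `NA`.
#'
#' @param genome A genome (`DNAStringSet`).
#' @param x An interval table (see [as_intervals()]).
#' @param index Optional precomputed index from `gc_index()`; computing it
#'   once is much faster when calling repeatedly on the same genome.
#' @return Numeric vector of GC fractions in `[0, 1]` (NA for all-N
#'   intervals).
#' @export
gc_fraction <- function(genome, x, index = NULL) {
  x <- as_intervals(x, genome = genome)
  if (is.null(index)) index <- gc_index(genome)
  out <- numeric(nrow(x))
  for (ch in unique(x$chrom)) {
    i <- which(x$chrom == ch)
    ci <- index[[ch]]
    if (is.null(ci)) stop("chromosome not in genome: ", ch)
    gc <- ci$gc[x$end[i] + 1L] - ci$gc[x$start[i] + 1L]
    nn <- ci$acgt[x$end[i] + 1L] - ci$acgt[x$start[i] + 1L]
    out[i] <- ifelse(nn == 0L, NA_real_, gc / nn)
  }
  out
}

#' GC bin of a GC fraction
#'
#' Maps a GC fraction to its bin index under bins of the given width on
#' `[0, 1]` (bin `floor(gc / width)`, with the top edge folded into the
#' last bin). This is the binning used by [sample_matched_random()].
#'
#' @param gc Numeric vector of GC fractions.
#' @param width Bin width as a fraction.
#' @return Integer vector of 0-based bin indices (NA propagates).
#' @export
gc_bin <- function(gc, width) {
  pmin(as.integer(floor(gc / width)),
       as.integer(ceiling(1 / width)) - 1L)
}

#' Extract interval sequences from a genome
#'
#' @param genome A genome (`DNAStringSet`).
#' @param x An interval table. Minus-strand intervals are reverse
#'   complemented when `stranded = TRUE`.
#' @param stranded Return the 5'-to-3' sequence of the interval's strand.
#' @return Character vector of sequences.
#' @export
interval_seq <- function(genome, x, stranded = FALSE) {
  x <- as_intervals(x, genome = genome)
  seqs <- as.character(genome)
  out <- substring(seqs[x$chrom], x$start + 1L, x$end)
  if (stranded && "strand" %in% names(x)) {
    neg <- which(x$strand == "-")
    if (length(neg))
      out[neg] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(out[neg])))
  }
  unname(out)
}
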