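#' Sample random genomic segments matched on length and GC content
#'
#' For each feature, draws `samples_per_feature` random segments of exactly
#' the feature's length whose GC fraction falls in the feature's GC bin
#' (bins of width `gc_bin_width` on `[0, 1]`), by rejection sampling of
#' uniform positions over the genome. Sampling is paired: each random
#' segment inherits one feature's length and GC bin, which makes the random
#' set reproduce the feature length multiset and per-bin GC counts exactly.
#' Features whose bin cannot be matched within `max_attempts` candidate
#' draws are reported in `unmatched` and contribute no segments (drop them
#' from the paired real set downstream). All-N features (undefined GC) are
#' treated as unmatched.
#'
#' Randomness is fully deterministic for a fixed `seed`: each feature uses
#' its own RNG stream derived from the root seed and the feature index, so
#' appending features does not perturb earlier draws.
#'
#' @param features Non-empty interval table within genome bounds.
#' @param genome A genome (`DNAStringSet`).
#' @param samples_per_feature Random segments per feature (>= 1).
#' @param gc_bin_width GC bin width as a fraction (default 0.02).
#' @param max_attempts Candidate positions tried per required segment before
#'   declaring the feature unmatched (default 2000).
#' @param seed Integer root seed.
#' @param exclude Optional interval table of regions barred from sampling
#'   (segments must not overlap it by any bp).
#' @param index Optional precomputed [gc_index()] of `genome` (computing it
#'   once is much faster when sampling repeatedly on the same genome).
#' @return An object of class `matched_random`: list with `segments` (an
#'   interval tibble with `feature_id`, `feature_name` and `gc_bin`
#'   columns), `unmatched` (feature row indices), and `params`.
#' @export
sample_matched_random <- function(features, genome, samples_per_feature = 1L,
                                  gc_bin_width = 0.02, max_attempts = 2000L,
                                  seed = 1L, exclude = NULL, index = NULL) {
  genome <- as_genome(genome)
  features <- as_intervals(features, genome = genome)
  if (!nrow(features)) stop("feature set must be non-empty")
  if (gc_bin_width <= 0 || gc_bin_width > 1)
    stop("gc_bin_width must be in (0, 1]")
  if (samples_per_feature < 1) stop("samples_per_feature must be >= 1")
  if (max_attempts < 1) stop("max_attempts must be >= 1")
  len <- genome_lengths(genome)
  widths <- features$end - features$start
  if (max(widths) > max(len)) stop("genome shorter than longest feature")
  idx <- if (is.null(index)) gc_index(genome) else index
  feat_gc <- gc_fraction(genome, features, index = idx)
  bin_of <- function(gc) gc_bin(gc, gc_bin_width)
  feat_bin <- bin_of(feat_gc)
  excl <- if (!is.null(exclude)) merge_intervals(as_intervals(exclude)) else NULL
  chroms <- names(len)
  cap <- nrow(features) * samples_per_feature
  acc_ch <- character(cap)
  acc_st <- integer(cap)
  acc_id <- integer(cap)
  n_acc <- 0L
  unmatched <- integer(0)
  batch <- 64L
  for (i in seq_len(nrow(features))) {
    set.seed((as.integer(seed) %% 1000003L) * 2011L + i)
    w <- widths[i]
    ok_chr <- chroms[len >= w]
    avail <- len[ok_chr] - w + 1
    got <- 0L; tried <- 0L
    if (!is.na(feat_bin[i])) {
      while (got < samples_per_feature && tried < max_attempts) {
        nb <- min(batch, max_attempts - tried)
        tried <- tried + nb
        ch <- sample(ok_chr, nb, replace = TRUE, prob = avail)
        st <- as.integer(floor(stats::runif(nb) * avail[ch]))
        en <- st + w
        gc <- numeric(nb)
        nn <- numeric(nb)
        for (cc in unique(ch)) {
          j <- which(ch == cc)
          ci <- idx[[cc]]
          gc[j] <- ci$gc[en[j] + 1L] - ci$gc[st[j] + 1L]
          nn[j] <- ci$acgt[en[j] + 1L] - ci$acgt[st[j] + 1L]
        }
        cand_gc <- ifelse(nn == 0, NA_real_, gc / nn)
        keep <- which(!is.na(cand_gc) & bin_of(cand_gc) == feat_bin[i])
        if (length(keep) && !is.null(excl)) {
          cand <- intervals(ch[keep], st[keep], en[keep])
          keep <- keep[!interval_overlaps_any(cand, excl)]
        }
        for (j in keep) {
          if (got >= samples_per_feature) break
          got <- got + 1L
          acc_ch[n_acc + got] <- ch[j]
          acc_st[n_acc + got] <- st[j]
          acc_id[n_acc + got] <- i
        }
      }
    }
    if (got < samples_per_feature) unmatched <- c(unmatched, i)
    else n_acc <- n_acc + samples_per_feature
  }
  take <- seq_len(n_acc)
  segs <- tibble::tibble(chrom = acc_ch[take], start = acc_st[take],
                         end = acc_st[take] + widths[acc_id[take]],
                         feature_id = acc_id[take])
  segs <- as_intervals(segs, genome = genome)
  segs$name <- if (nrow(segs)) paste0("rand", seq_len(nrow(segs))) else character(0)
  segs$feature_name <- features$name[segs$feature_id]
  segs$gc_bin <- feat_bin[segs$feature_id]
  structure(list(segments = segs, unmatched = unmatched,
                 params = list(samples_per_feature = samples_per_feature,
                               gc_bin_width = gc_bin_width,
                               max_attempts = max_attempts, seed = seed,
                               exclude = !is.null(excl))),
            class = "matched_random")
}

#' @export
print.matched_random <- function(x, ...) {
  cat("matched random segments:", nrow(x$segments), "segments;",
      length(x$unmatched), "unmatched features; gc_bin_width =",
      x$params$gc_bin_width, "\n")
  invisible(x)
}

#' Write a matched random set to disk
#'
#' Emits the segments as BED6, the per-segment provenance as TSV and the
#' sampler configuration as a JSON sidecar.
#'
#' @param x A `matched_random` object.
#' @param prefix Output path prefix (writes `<prefix>.bed`,
#'   `<prefix>_provenance.tsv`, `<prefix>_config.json`).
#' @return Invisibly, the vector of paths written.
#' @export
write_matched_random <- function(x, prefix) {
  stopifnot(inherits(x, "matched_random"))
  paths <- c(bed = paste0(prefix, ".bed"),
             prov = paste0(prefix, "_provenance.tsv"),
             cfg = paste0(prefix, "_config.json"))
  write_bed(x$segments, paths["bed"])
  utils::write.table(
    x$segments[, c("name", "feature_id", "feature_name", "gc_bin")],
    paths["prov"], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(x$params, paths["cfg"], auto_unbox = TRUE)
  invisible(paths)
}
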