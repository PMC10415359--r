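# Programmatic fixtures: everything is generated in code at test time.

random_genome <- function(n_chroms = 2, len = 10000, gc = 0.4, seed = 1) {
  set.seed(seed)
  seqs <- vapply(seq_len(n_chroms), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = ""), character(1))
  as_genome(stats::setNames(seqs, paste0("chr", seq_len(n_chroms))))
}

random_intervals <- function(n, genome, max_width = 200, seed = 1,
                             stranded = FALSE) {
  set.seed(seed)
  len <- genome_lengths(genome)
  ch <- sample(names(len), n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  s <- vapply(seq_len(n), function(i)
    sample.int(len[[ch[i]]] - w[i], 1) - 1L, integer(1))
  intervals(ch, s, s + w,
            strand = if (stranded) sample(c("+", "-"), n, TRUE) else ".",
            genome = genome)
}

# Small-genome simulation config used by most integration tests.
small_sim_config <- function(seed = 1, ...) {
  sim_config(n_chroms = 2L, chrom_length = 400000L, n_origins = 80L,
             n_cgis = 10L, seed = seed, ...)
}
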