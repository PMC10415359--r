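#' Default pipeline configuration
#'
#' Parameters default to the analysis' standard values: clustering gap 100
#' bp and cluster sizes 2-6, 1-kb anchor extension, coverage windows of 20
#' bp stepped by 10 bp over +/-1 kb, Repli-seq windows of 50 kb at 10-kb
#' intervals, strong-origin quantile 0.75, and one matched random segment
#' per feature in 2% GC bins.
#'
#' @param simulate A [sim_config()] object (synthetic input), or `NULL`
#'   when real input paths are given.
#' @param inputs Named list of input paths (`genome` FASTA plus BED files
#'   `motifs`, `origins`, `nfr`, `h2az`, `cgis`, `sns_reads`); ignored when
#'   `simulate` is set.
#' @param detector,cluster,sampler,enrich,profile,timing Stage parameter
#'   lists; unset entries keep their defaults.
#' @param seed Integer seed for all randomness.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = sim_config(), inputs = NULL,
                            detector = list(), cluster = list(),
                            sampler = list(), enrich = list(),
                            profile = list(), timing = list(), seed = 1L) {
  merge_defaults <- function(user, def) utils::modifyList(def, user)
  cfg <- list(
    simulate = simulate,
    inputs = inputs,
    detector = merge_defaults(detector, list(tract_len = 3L, loop_min = 1L,
                                             loop_max = 7L, n_tracts = 4L)),
    cluster = merge_defaults(cluster, list(max_gap = 100L, min_k = 2L,
                                           max_k = 6L, strict = FALSE)),
    sampler = merge_defaults(sampler, list(samples_per_feature = 1L,
                                           gc_bin_width = 0.02,
                                           max_attempts = 2000L)),
    enrich = merge_defaults(enrich, list(flank = 1000L, adjust = "none")),
    profile = merge_defaults(profile, list(span = 1000L, window = 20L,
                                           step = 10L)),
    timing = merge_defaults(timing, list(window = 50000L, step = 10000L,
                                         spar = NULL,
                                         strong_quantile = 0.75)),
    seed = as.integer(seed))
  if (is.null(simulate) && is.null(inputs))
    stop("either a simulate block or input paths are required")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; top-level keys mirror the arguments of
#'   [pipeline_config()], with `simulate: true` (defaults), a parameter
#'   map, or absent when `inputs` paths are given.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  simulate <- NULL
  if (!is.null(y$simulate)) {
    simulate <- if (isTRUE(y$simulate)) sim_config()
    else do.call(sim_config, y$simulate)
  }
  pipeline_config(simulate = simulate, inputs = y$inputs,
                  detector = y$detector %||% list(),
                  cluster = y$cluster %||% list(),
                  sampler = y$sampler %||% list(),
                  enrich = y$enrich %||% list(),
                  profile = y$profile %||% list(),
                  timing = y$timing %||% list(),
                  seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — simulate (or load inputs),
#' detect pG4s, classify clusters, sample matched random segments, compute
#' enrichments (including the strand-aware origin/pG4 association), build
#' coverage profiles, score and stratify origin strength, and process
#' Repli-seq timing — writing every stage output plus a machine-readable
#' JSON report of the statistics and output checksums. Deterministic for a
#' fixed config and seed.
#'
#' @param config A `pipeline_config` object (or path to a YAML config).
#' @param outdir Output directory.
#' @return The report, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = list(seed = config$seed))
  outputs <- character(0)
  emit_bed <- function(x, nm) {
    f <- file.path(outdir, paste0(nm, ".bed"))
    write_bed(as_intervals(x), f)
    outputs <<- c(outputs, f)
  }
  emit_tsv <- function(x, nm) {
    f <- file.path(outdir, paste0(nm, ".tsv"))
    utils::write.table(x, f, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, f)
  }
  # --- stage: inputs ---
  if (!is.null(config$simulate)) {
    scfg <- config$simulate
    scfg$seed <- config$seed
    sim <- simulate_dataset(scfg)
    audit_simulation(sim)
    genome <- sim$genome
    origins <- sim$origins
    nfr <- sim$nfr
    h2az <- sim$h2az
    cgis <- sim$truth$cgis
    sns <- sim$sns_reads
    repli <- sim$repliseq
    report$truth <- list(true_log_or = as.list(sim$truth$true_log_or),
                         expected_rt_shift = repli$expected_rt_shift)
    outputs <- c(outputs, write_simulation(sim, file.path(outdir, "sim")))
  } else {
    inp <- config$inputs
    genome <- read_fasta(inp$genome)
    origins <- read_bed(inp$origins, genome)
    nfr <- if (!is.null(inp$nfr)) read_bed(inp$nfr, genome)
    h2az <- if (!is.null(inp$h2az)) read_bed(inp$h2az, genome)
    cgis <- if (!is.null(inp$cgis)) read_bed(inp$cgis, genome)
    sns <- if (!is.null(inp$sns_reads)) read_bed(inp$sns_reads, genome)
    repli <- NULL
  }
  # --- stage: detect + cluster ---
  motifs <- if (!is.null(config$inputs$motifs))
    read_bed(config$inputs$motifs, genome)
  else do.call(detect_pg4, c(list(genome), config$detector))
  emit_bed(motifs, "pg4_motifs")
  cl <- do.call(cluster_pg4, c(list(motifs), config$cluster))
  emit_bed(cl$clusters, "pg4_clusters")
  emit_bed(cl$monomers, "pg4_monomers")
  if (nrow(cl$oversize)) emit_bed(cl$oversize, "pg4_oversize")
  emit_tsv(data.frame(category = names(cl$fractions),
                      fraction = as.numeric(cl$fractions)),
           "pg4_category_fractions")
  report$pg4 <- list(n_motifs = nrow(cl$motifs),
                     fractions = as.list(cl$fractions))
  # --- stage: matched random ---
  rnd <- sample_matched_random(
    origins, genome,
    samples_per_feature = config$sampler$samples_per_feature,
    gc_bin_width = config$sampler$gc_bin_width,
    max_attempts = config$sampler$max_attempts,
    seed = config$seed)
  outputs <- c(outputs, write_matched_random(rnd, file.path(outdir, "random")))
  report$random <- list(n_segments = nrow(rnd$segments),
                        n_unmatched = length(rnd$unmatched))
  # --- stage: enrichment ---
  feature_sets <- list(pg4_monomeric = cl$monomers,
                       pg4_clustered = cl$clusters)
  if (!is.null(nfr)) feature_sets$nfr <- nfr
  if (!is.null(h2az)) feature_sets$h2az <- h2az
  if (!is.null(cgis)) feature_sets$cgi <- cgis
  enr <- enrichment_table(origins, rnd, feature_sets,
                          flank = config$enrich$flank, genome = genome,
                          adjust = config$enrich$adjust)
  emit_tsv(enr, "enrichment")
  report$enrichment <- lapply(seq_len(nrow(enr)), function(i)
    list(feature = enr$feature[i], log_or = enr$log_or[i], se = enr$se[i],
         p_value = enr$p_value[i]))
  saw <- strand_aware_origin_pg4_flags(origins, motifs,
                                       flank = config$enrich$flank,
                                       genome = genome)
  report$strand_aware <- list(frac_flagged = mean(saw$flag),
                              frac_plus_upstream = mean(saw$plus_upstream),
                              frac_minus_downstream = mean(saw$minus_downstream))
  # --- stage: profiles ---
  if (!is.null(nfr) && nrow(cl$clusters)) {
    prof <- coverage_profile(cl$clusters, nfr,
                             span = config$profile$span,
                             window = config$profile$window,
                             step = config$profile$step,
                             anchor_mode = "first",
                             orient_by_strand = TRUE, genome = genome)
    emit_tsv(prof, "profile_nfr_around_clusters")
  }
  # --- stage: origin strength ---
  if (!is.null(sns)) {
    strengths <- origin_strength(origins, sns)
    tb <- origins
    tb$strength <- strengths
    emit_tsv(tb[, c("chrom", "start", "end", "name", "strength")],
             "origin_strength")
    so <- strong_origins(origins, strengths,
                         quantile = config$timing$strong_quantile)
    emit_bed(so, "strong_origins")
    if (!is.null(cgis)) {
      st <- stratify_strength(origins, strengths, cl, cgis,
                              flank = config$enrich$flank, genome = genome)
      emit_tsv(st$groups, "strength_groups")
    }
    report$strength <- list(n_strong = nrow(so),
                            mean_strength = mean(strengths))
  }
  # --- stage: replication timing ---
  if (!is.null(repli)) {
    prof_rt <- normalize_standardize_smooth(repli$without,
                                            spar = config$timing$spar)
    wa <- weighted_average_rt(prof_rt)
    bg <- tibble::tibble(chrom = prof_rt$windows$chrom,
                         start = prof_rt$windows$start,
                         end = prof_rt$windows$end, value = wa)
    f <- file.path(outdir, "rt_wa.bedgraph")
    write_bedgraph(bg, f)
    outputs <- c(outputs, f)
    pv_with <- rt_percent_vectors(repli$with, repli$locus)
    pv_without <- rt_percent_vectors(repli$without, repli$locus)
    shift <- rt_shift(pv_with, pv_without)
    emit_tsv(data.frame(delta_e = shift$delta_e, delta_l = shift$delta_l,
                        rt_shift = shift$rt_shift), "rt_shift")
    report$rt <- list(delta_e = shift$delta_e, delta_l = shift$delta_l,
                      rt_shift = shift$rt_shift)
  }
  report$outputs <- lapply(sort(outputs), function(f)
    list(path = basename(f), md5 = unname(tools::md5sum(f))))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
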