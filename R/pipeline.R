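# End-to-end orchestration: the chromatin stage chain on user data, and the
# fully synthetic run with truth scoring and a reproducible results directory.

#' Run the chromatin analysis chain
#'
#' Tiling, counting, input normalization, moderated-t differential windows,
#' region merging and genomic-context annotation, in one call.
#'
#' @param reads read tibble (`contig`, `start`, `end`, `strand`, `mapq`,
#'   `sample`).
#' @param samples sample sheet (`sample`, `condition`, `mark`; `"input"` rows
#'   mark background samples).
#' @param annotation a `genome_annotation`.
#' @param width,spacing window grid (defaults 100/50).
#' @param extension,mapq_min read handling (defaults 250 and 20).
#' @param input_width input expansion (default 5000).
#' @param q_max,delta_min region thresholds (defaults 0.01 and 3).
#' @param conditions length-2 character; first = positive direction.
#' @return list with `windows`, `enrichment`, `stats`, `regions`,
#'   `region_annotation`.
#' @export
run_chromatin <- function(reads, samples, annotation,
                          width = 100, spacing = 50,
                          extension = 250, mapq_min = 20, input_width = 5000,
                          q_max = 0.01, delta_min = 3, conditions = NULL) {
  missing_ctg <- setdiff(unique(reads$contig), names(annotation$contig_lengths))
  if (length(missing_ctg) > 0) {
    abort(paste("read contigs absent from annotation:",
                paste(missing_ctg, collapse = ", ")))
  }
  windows <- tile_windows(annotation$contig_lengths, width, spacing)
  enrichment <- chip_enrichment(reads, samples, windows,
                                extension = extension, mapq_min = mapq_min,
                                input_width = input_width)
  stats <- diff_windows(enrichment, conditions = conditions)
  regions <- call_differential_regions(stats, q_max = q_max,
                                       delta_min = delta_min)
  region_annotation <- if (nrow(regions) > 0 &&
                           nrow(annotation$transcripts) > 0) {
    regions %>%
      classify_regions(annotation) %>%
      distance_to_nearest_tss(annotation)
  } else {
    regions
  }
  list(windows = windows, enrichment = enrichment, stats = stats,
       regions = regions, region_annotation = region_annotation)
}

#' @noRd
score_spike_recovery <- function(regions, spikes) {
  if (nrow(spikes) == 0) {
    return(list(recall = NA_real_, n_false = nrow(regions),
                n_recovered = 0L, n_spikes = 0L))
  }
  if (nrow(regions) == 0) {
    return(list(recall = 0, n_false = 0L, n_recovered = 0L,
                n_spikes = nrow(spikes)))
  }
  ov <- GenomicRanges::findOverlaps(as_granges0(spikes), as_granges0(regions),
                                    ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  same <- spikes$mark[qi] == regions$mark[si] &
    spikes$condition[qi] == regions$direction[si]
  recovered <- unique(qi[same])
  true_region <- unique(si[same])
  list(recall = length(recovered) / nrow(spikes),
       n_false = nrow(regions) - length(true_region),
       n_recovered = length(recovered), n_spikes = nrow(spikes))
}

#' Run a complete synthetic study end to end
#'
#' Generates a synthetic two-caste study, writes its inputs in standard
#' formats (GFF3, BED, FASTA, TSV, MEME, JSON truth), runs every analysis
#' stage, scores recovery against the truth table and writes all stage
#' outputs plus a manifest with file checksums. Identical config and seed
#' reproduce every output byte for byte.
#'
#' @param config a `synth_config`.
#' @param out_dir results directory (created; existing files overwritten).
#' @param seed optional master-seed override.
#' @param n_perm permutations for the enrichment tests (default 1000).
#' @return (invisibly) a list with all stage results and `report`, the
#'   truth-comparison summary.
#' @export
run_synthetic <- function(config = synth_config(), out_dir, seed = NULL,
                          n_perm = 1000) {
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- simulate_caste_study(config)
  ann <- study$annotation
  conds <- config$conditions

  # -- write generated inputs
  write_annotation_gff3(ann, file.path(out_dir, "annotation.gff3"))
  write_reads_bed(study$reads, file.path(out_dir, "reads.bed"))
  write_tsv_plain(study$expression, file.path(out_dir, "expression.tsv"))
  write_tsv_plain(study$methylation, file.path(out_dir, "methylation.tsv"))
  write_fasta(study$sequences, file.path(out_dir, "contigs.fa"))
  write_meme(study$motif, file.path(out_dir, "motif.meme"))
  jsonlite::write_json(study$truth, file.path(out_dir, "truth.json"),
                       digits = NA, pretty = TRUE)
  cfg_out <- config[setdiff(names(config), "contig_lengths")]
  class(cfg_out) <- NULL
  jsonlite::write_json(cfg_out, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # -- chromatin chain
  chrom <- run_chromatin(study$reads, study$samples, ann,
                         conditions = conds)
  write_tsv_plain(chrom$stats, file.path(out_dir, "window_stats.tsv"))
  write_regions_bed(chrom$regions, file.path(out_dir, "regions.bed"))
  write_tsv_plain(chrom$region_annotation,
                  file.path(out_dir, "region_annotation.tsv"))
  profile <- tss_metagene_profile(chrom$enrichment, ann)
  write_tsv_plain(profile, file.path(out_dir, "tss_metagene.tsv"))
  gene_marks <- mark_genes(chrom$enrichment, ann)
  write_tsv_plain(gene_marks, file.path(out_dir, "gene_marks.tsv"))

  # -- expression
  de <- lrt_de(study$expression, conditions = conds)
  write_tsv_plain(de, file.path(out_dir, "de.tsv"))
  mds <- mds_samples(study$expression)
  write_tsv_plain(mds, file.path(out_dir, "mds.tsv"))
  corr <- chromatin_expression_correlation(chrom$regions, de, ann,
                                           conditions = conds)
  write_tsv_plain(corr, file.path(out_dir, "chromatin_expression_corr.tsv"))
  combos <- expression_by_mark_combination(gene_marks, study$expression,
                                           seed = config$seed)
  write_tsv_plain(combos, file.path(out_dir, "mark_combinations.tsv"))

  # -- methylation and permutation enrichment
  dmps <- call_dmps(study$methylation)
  write_tsv_plain(dmps, file.path(out_dir, "dmps.tsv"))
  dmp_sites <- dmps[dmps$dmp, c("contig", "pos")]
  k36_regions <- chrom$regions[chrom$regions$mark == "H3K36me3", , drop = FALSE]
  dmp_perm <- if (nrow(dmp_sites) > 0 && nrow(k36_regions) > 0) {
    overlap_permutation_test(dmp_sites, k36_regions, config$contig_lengths,
                             n_perm = n_perm,
                             seed = derive_seed(config$seed, "dmp_perm"))
  } else NULL

  de_genes <- unique(de$gene_id[de$q <= 0.01])
  ra <- chrom$region_annotation
  peak_genes <- if (nrow(ra) > 0 && "location_class" %in% names(ra)) {
    intronic_k27 <- ra[ra$mark == "H3K27ac" &
                         ra$location_class == "intronic", , drop = FALSE]
    if (nrow(intronic_k27) > 0) {
      ov <- GenomicRanges::findOverlaps(as_granges0(intronic_k27),
                                        as_granges0(ann$genes),
                                        ignore.strand = TRUE)
      unique(ann$genes$gene_id[S4Vectors::subjectHits(ov)])
    } else character(0)
  } else character(0)
  gene_perm <- if (length(de_genes) > 0 && length(peak_genes) > 0) {
    gene_set_peak_permutation(de_genes, peak_genes, ann$genes$gene_id,
                              n_perm = n_perm,
                              seed = derive_seed(config$seed, "gene_perm"))
  } else NULL

  perm_out <- list(
    dmp_by_h3k36me3 = if (!is.null(dmp_perm)) unclass(tidy(dmp_perm)) else NULL,
    de_genes_by_intronic_h3k27ac =
      if (!is.null(gene_perm)) unclass(tidy(gene_perm)) else NULL
  )
  jsonlite::write_json(perm_out, file.path(out_dir, "permutation_tests.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # -- motif analysis on called H3K27ac regions
  k27_regions <- chrom$regions[chrom$regions$mark == "H3K27ac", , drop = FALSE]
  motif_res <- NULL; curve <- NULL
  if (nrow(k27_regions) >= 10) {
    peaks5k <- extend_peaks(k27_regions, 5000, config$contig_lengths)
    region_seqs <- vapply(seq_len(nrow(peaks5k)), function(i) {
      substr(study$sequences[[peaks5k$contig[i]]],
             peaks5k$start[i] + 1, peaks5k$end[i])
    }, character(1))
    names(region_seqs) <- peaks5k$peak_id
    hits <- scan_regions(region_seqs, study$motif)
    motif_res <- central_enrichment(hits, region_width = 5000)
    curve <- motif_probability_curve(hits, region_width = 5000)
    write_tsv_plain(hits, file.path(out_dir, "motif_hits.tsv"))
    write_tsv_plain(motif_res, file.path(out_dir, "motif_central.tsv"))
    write_tsv_plain(curve, file.path(out_dir, "motif_curve.tsv"))
  }

  # -- truth comparison
  spike_score <- score_spike_recovery(chrom$regions, study$truth$spikes)
  de_truth <- study$truth$de_transcripts
  strong <- de_truth$transcript_id[abs(de_truth$true_logfc) >= 1]
  de_called <- de$transcript_id[de$q <= 0.01]
  dmp_truth_key <- paste(study$truth$dmps$contig, study$truth$dmps$pos)
  dmp_called_key <- paste(dmp_sites$contig, dmp_sites$pos)
  report <- list(
    spike_recall = spike_score$recall,
    spike_false_regions = spike_score$n_false,
    n_regions = nrow(chrom$regions),
    de_recall = if (length(strong)) mean(strong %in% de_called) else NA,
    de_precision = if (length(de_called))
      mean(de_called %in% de_truth$transcript_id) else NA,
    n_de_called = length(de_called),
    dmp_recall = if (length(dmp_truth_key))
      mean(dmp_truth_key %in% dmp_called_key) else NA,
    dmp_precision = if (length(dmp_called_key))
      mean(dmp_called_key %in% dmp_truth_key) else NA,
    dmp_fold_enrichment = if (!is.null(dmp_perm)) dmp_perm$fold_enrichment else NA,
    dmp_perm_p = if (!is.null(dmp_perm)) dmp_perm$p_emp else NA,
    gene_perm_fold = if (!is.null(gene_perm)) gene_perm$fold_enrichment else NA,
    gene_perm_p = if (!is.null(gene_perm)) gene_perm$p_emp else NA,
    motif_p_adj = if (!is.null(motif_res)) motif_res$p_adj else NA
  )
  jsonlite::write_json(report, file.path(out_dir, "truth_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "castechrom",
    version = as.character(utils::packageVersion("castechrom")),
    seed = config$seed,
    files = as.list(setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(study = study, chromatin = chrom, de = de, mds = mds,
                 correlation = corr, combinations = combos, dmps = dmps,
                 dmp_perm = dmp_perm, gene_perm = gene_perm,
                 motif = motif_res, motif_curve = curve,
                 profile = profile, report = report))
}
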