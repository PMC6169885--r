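# Synthetic-data generator: structure, determinism, truth-table completeness.

test_that("annotation generation honors counts and determinism", {
  cfg <- synth_config(n_genes = 10, exons_per_gene = 3, seed = 4)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann$genes), 10)
  expect_equal(nrow(ann$exons), 30)
  expect_equal(nrow(ann_introns(ann)), 20)
  # genes do not overlap
  gr <- GenomicRanges::reduce(
    GenomicRanges::GRanges(ann$genes$contig,
                           IRanges::IRanges(ann$genes$start + 1,
                                            ann$genes$end)),
    ignore.strand = TRUE)
  expect_equal(length(gr), nrow(ann$genes))

  # empty case
  ann0 <- generate_annotation(synth_config(n_genes = 0, seed = 4))
  expect_equal(nrow(ann0$genes), 0)

  # byte-identical GFF3 under the same seed
  f1 <- tempfile(fileext = ".gff3"); f2 <- tempfile(fileext = ".gff3")
  write_annotation_gff3(generate_annotation(cfg), f1)
  write_annotation_gff3(generate_annotation(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))

  # contig too short
  expect_error(generate_annotation(synth_config(contig_length = 3000,
                                                n_genes = 50, seed = 1)),
               "too short")
})

test_that("GFF3 round trip preserves the gene models", {
  cfg <- synth_config(n_genes = 8, seed = 14)
  ann <- generate_annotation(cfg)
  f <- tempfile(fileext = ".gff3")
  write_annotation_gff3(ann, f)
  back <- read_annotation_gff3(f, contig_lengths = cfg$contig_lengths)
  expect_equal(dplyr::arrange(back$genes, gene_id),
               dplyr::arrange(ann$genes, gene_id))
  expect_equal(nrow(back$exons), nrow(ann$exons))
  expect_setequal(ann_tss(back)$pos, ann_tss(ann)$pos)
})

test_that("read generation scales with library size and respects spike folds", {
  cfg1 <- synth_config(seed = 8, library_size = 50000, n_genes = 10,
                       n_spikes_per_condition = 6)
  ann <- generate_annotation(cfg1)
  r1 <- generate_chip_reads(ann, cfg1)
  cfg2 <- synth_config(seed = 8, library_size = 100000, n_genes = 10,
                       n_spikes_per_condition = 6)
  r2 <- generate_chip_reads(generate_annotation(cfg2), cfg2)
  n1 <- nrow(r1$reads[r1$reads$sample == "H3K4me3_W_1", ])
  n2 <- nrow(r2$reads[r2$reads$sample == "H3K4me3_W_1", ])
  expect_equal(n2 / n1, 2, tolerance = 0.05)

  # spiked windows are more enriched in the spiked condition
  enr <- chip_enrichment(r1$reads, r1$samples, tile_windows(cfg1$contig_lengths))
  sp <- r1$spikes[r1$spikes$condition == "W" & r1$spikes$mark == "H3K4me3", ]
  mid <- (enr$start + enr$end) / 2
  in_spike <- rep(FALSE, nrow(enr))
  for (i in seq_len(nrow(sp))) {
    in_spike <- in_spike | (enr$contig == sp$contig[i] & mid >= sp$start[i] &
                              mid < sp$end[i])
  }
  w_mean <- rowMeans(as.matrix(enr[, c("H3K4me3_W_1", "H3K4me3_W_2")]))
  q_mean <- rowMeans(as.matrix(enr[, c("H3K4me3_Q_1", "H3K4me3_Q_2")]))
  expect_gt(mean(w_mean[in_spike]), mean(q_mean[in_spike]) + 3)

  expect_error(generate_chip_reads(ann, cfg1,
    spikes = tibble::tibble(mark = "H3K4me3", condition = "W", contig = "ctg1",
                            start = 0L, end = 100L, fold = -1)),
    "positive")
})

test_that("flat configuration yields statistically uniform window counts", {
  rejected <- vapply(1:8, function(s) {
    cfg <- synth_config(seed = s, tss_enrichment_fold = 1, gene_body_fold = 1,
                        n_spikes_per_condition = 0, n_genes = 10)
    ann <- generate_annotation(cfg)
    enr <- generate_window_counts(ann, cfg)
    cnt <- attr(enr, "counts")[, "H3K4me3_W_1"]
    # chi-square goodness of fit against a common mean
    stat <- sum((cnt - mean(cnt))^2 / mean(cnt))
    pchisq(stat, df = length(cnt) - 1, lower.tail = FALSE) < 0.01
  }, logical(1))
  expect_gte(mean(!rejected), 0.75)
})

test_that("expression generator recovers planted log fold changes", {
  cfg <- synth_config(seed = 23, expression_effect = 1, chromatin_coupling = 0)
  ann <- generate_annotation(cfg)
  spikes <- generate_spike_regions(ann, cfg)
  ex <- generate_expression(ann, cfg, spikes)
  expect_gt(nrow(ex$truth), 0)
  samples <- attr(ex$expression, "samples")
  w <- samples$sample[samples$condition == "W"]
  q <- samples$sample[samples$condition == "Q"]
  est <- rowMeans(as.matrix(ex$expression[, w])) -
    rowMeans(as.matrix(ex$expression[, q]))
  idx <- match(ex$truth$transcript_id, ex$expression$transcript_id)
  # estimated LogFC tracks the planted +-1 within the n=4 sampling error
  expect_equal(est[idx], ex$truth$true_logfc, tolerance = 0.6)
  expect_gt(cor(est[idx], ex$truth$true_logfc), 0.8)

  # null: no planted effect, LogFC centered at zero
  cfg0 <- synth_config(seed = 23, de_fraction = 0, chromatin_coupling = 0)
  ex0 <- generate_expression(generate_annotation(cfg0), cfg0, NULL)
  expect_equal(nrow(ex0$truth), 0)
  s0 <- attr(ex0$expression, "samples")
  est0 <- rowMeans(as.matrix(ex0$expression[, s0$sample[s0$condition == "W"]])) -
    rowMeans(as.matrix(ex0$expression[, s0$sample[s0$condition == "Q"]]))
  expect_lt(abs(mean(est0)), 0.1)

  # determinism
  ex_again <- generate_expression(ann, cfg, spikes)
  expect_equal(ex$expression, ex_again$expression)
})

test_that("truth table is complete and refers to existing objects", {
  cfg <- synth_config(seed = 31)
  study <- simulate_caste_study(cfg)
  tr <- study$truth
  expect_equal(nrow(tr$spikes), 2 * cfg$n_spikes_per_condition)
  expect_true(all(tr$spikes$contig %in% names(cfg$contig_lengths)))
  expect_true(all(tr$de_transcripts$transcript_id %in%
                    study$expression$transcript_id))
  meth_key <- paste(study$methylation$contig, study$methylation$pos)
  expect_true(all(paste(tr$dmps$contig, tr$dmps$pos) %in% meth_key))
  expect_true(all(tr$motif_sites$region_id %in%
                    seq_len(nrow(study$motif_regions))))
  # planted motif sites actually contain the consensus
  cons <- pwm_consensus(study$motif)
  for (i in seq_len(min(5, nrow(tr$motif_sites)))) {
    s <- tr$motif_sites[i, ]
    expect_equal(substr(study$sequences[[s$contig]], s$start + 1,
                        s$start + nchar(cons)), cons)
  }
})

test_that("motif planting laws behave as specified", {
  cfg <- synth_config(seed = 43)
  seqs <- generate_sequences(cfg)
  p <- default_motif()
  # no regions chosen: sequences unchanged
  none <- plant_motifs(seqs, tibble::tibble(contig = character(),
                                            start = integer(),
                                            end = integer()), p)
  expect_identical(none$sequences, seqs)
  # centered planting puts every offset at zero
  regions <- tibble::tibble(contig = "ctg1",
                            start = as.integer(seq(2000, 40000, by = 4000)))
  regions$end <- regions$start + 1000L
  centered <- plant_motifs(seqs, regions, p, offset_law = "center", seed = 2)
  expect_true(all(centered$sites$offset == 0))
  expect_equal(nrow(centered$sites), nrow(regions))
})
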