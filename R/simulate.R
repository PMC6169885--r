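# Synthetic two-caste study generator with a machine-readable truth table.
#
# The generator emulates the statistical structure the analysis assumes:
# near-uniform input coverage, TSS-proximal enrichment for H3K4me3/H3K27ac,
# gene-body enrichment for H3K36me3, condition-specific spiked windows,
# expression shifts correlated with spiked active marks, caste-differential
# CpG methylation, and motif instances planted in peak-centered sequence.
# Every planted effect is recorded so recovery can be scored exactly.

#' Configuration for a synthetic two-caste study
#'
#' Defaults describe a miniature but statistically faithful study: two 150-kb
#' contigs, 40 genes of 3 exons, 2 ChIP replicates and 4 RNA-seq replicates
#' per caste (the replicate design of the study layout this emulates), 1.5e5
#' reads per ChIP sample (about 0.5 background reads per bp), spikes at 8-fold over background.
#'
#' @param n_contigs,contig_length genome shape (bp).
#' @param n_genes,exons_per_gene,exon_width,intron_width gene models.
#' @param n_replicates ChIP replicates per condition (default 2).
#' @param n_rna_replicates RNA-seq replicates per condition (default 4).
#' @param library_size reads per ChIP sample.
#' @param input_library_size reads per input sample (default: same depth as
#'   ChIP; the relative input depth is a free parameter of the design).
#' @param tss_enrichment_fold enrichment of H3K4me3/H3K27ac at TSSs over
#'   background (1 = flat).
#' @param gene_body_fold enrichment of H3K36me3 over gene bodies.
#' @param spike_regions tibble `mark`, `condition`, `contig`, `start`, `end`,
#'   `fold`, or `NULL` to place `n_spikes_per_condition` automatically.
#' @param n_spikes_per_condition,spike_fold,spike_width automatic spike
#'   placement; H3K27ac spikes are placed inside introns (the candidate
#'   enhancer signature), others anywhere free.
#' @param expression_effect log2 expression shift of differential transcripts.
#' @param de_fraction fraction of transcripts with a planted expression shift.
#' @param chromatin_coupling expression boost (in log2 units per log2 spike
#'   fold) for genes overlapping a spiked active-mark region, creating the
#'   recoverable chromatin-expression correlation.
#' @param expr_d0,expr_s0_sq scaled-inverse-chi-square hyperparameters for
#'   per-transcript log2 abundance variances (so the empirical-Bayes prior is
#'   itself recoverable).
#' @param n_cpg,dmp_fraction,meth_coverage methylation table shape.
#' @param nb_dispersion gamma-mixing over-dispersion for read counts
#'   (0 = pure Poisson, the default).
#' @param conditions caste labels (default `c("W", "Q")`).
#' @param seed master seed; every stage derives its own stream from it.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_contigs = 2, contig_length = 150000,
                         n_genes = 40, exons_per_gene = 3,
                         exon_width = 200, intron_width = 500,
                         n_replicates = 2, n_rna_replicates = 4,
                         library_size = 150000,
                         input_library_size = library_size,
                         tss_enrichment_fold = 6, gene_body_fold = 3.5,
                         spike_regions = NULL,
                         n_spikes_per_condition = 20, spike_fold = 8,
                         spike_width = 600,
                         expression_effect = 2, de_fraction = 0.15,
                         chromatin_coupling = 0.5,
                         expr_d0 = 10, expr_s0_sq = 0.09,
                         n_cpg = 2000, dmp_fraction = 0.05,
                         meth_coverage = 30,
                         nb_dispersion = 0,
                         conditions = c("W", "Q"),
                         seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_contigs", "contig_length", "exon_width", "intron_width",
              "n_replicates", "n_rna_replicates", "library_size",
              "input_library_size", "n_cpg", "meth_coverage")
  for (f in counts) if (cfg[[f]] <= 0) abort(sprintf("`%s` must be positive", f))
  if (n_genes < 0 || exons_per_gene < 1) abort("invalid gene-model parameters")
  if (dmp_fraction < 0 || dmp_fraction > 1) abort("`dmp_fraction` must lie in [0, 1]")
  if (de_fraction < 0 || de_fraction > 1) abort("`de_fraction` must lie in [0, 1]")
  if (tss_enrichment_fold < 1 || gene_body_fold < 1) {
    abort("enrichment folds must be >= 1")
  }
  if (spike_fold <= 0) abort("spike fold must be positive")
  if (length(conditions) != 2) abort("exactly two conditions required")
  cfg$contig_lengths <- setNames(rep(contig_length, n_contigs),
                                 paste0("ctg", seq_len(n_contigs)))
  if (!is.null(spike_regions)) {
    check_interval_tbl(spike_regions, "spike_regions")
    if (any(spike_regions$fold <= 0)) abort("spike fold must be positive")
    too_long <- spike_regions$end > cfg$contig_lengths[spike_regions$contig]
    if (any(is.na(too_long)) || any(too_long)) {
      abort("spike intervals must lie within the configured contigs")
    }
  }
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "<synth_config> %d x %.0f bp contigs, %d genes, %d+%d reps/caste, seed %d\n",
    x$n_contigs, x$contig_length, x$n_genes, x$n_replicates,
    x$n_rna_replicates, x$seed))
  invisible(x)
}

#' Generate non-overlapping gene models
#'
#' Genes are laid out round-robin across contigs in equal slots with a
#' seed-deterministic jitter, one transcript per gene, `exons_per_gene`
#' equal-width exons separated by introns. Strands are assigned at random.
#'
#' @param config a `synth_config`.
#' @return a `genome_annotation`.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cl <- config$contig_lengths
  if (config$n_genes == 0) {
    empty <- tibble(contig = character(), start = integer(), end = integer(),
                    strand = character())
    return(genome_annotation(
      mutate(empty, gene_id = character(), .before = 1),
      mutate(empty, transcript_id = character(), gene_id = character(), .before = 1),
      mutate(empty, transcript_id = character(), gene_id = character(), .before = 1),
      cl))
  }
  span <- config$exons_per_gene * config$exon_width +
    (config$exons_per_gene - 1) * config$intron_width
  ctg_of_gene <- rep(names(cl), length.out = config$n_genes)
  genes_per_ctg <- table(factor(ctg_of_gene, levels = names(cl)))
  slot <- floor(config$contig_length / pmax(1, as.numeric(genes_per_ctg)))
  names(slot) <- names(cl)
  if (any(slot[as.numeric(genes_per_ctg) > 0] < span + 100)) {
    abort("contigs too short for the requested number of genes")
  }

  with_seed(derive_seed(config$seed, "annotation"), {
    rows <- purrr::map_dfr(names(cl), function(ctg) {
      idx <- which(ctg_of_gene == ctg)
      if (length(idx) == 0) return(NULL)
      s <- slot[ctg]
      jitter <- floor(runif(length(idx)) * (s - span - 50))
      start <- (seq_along(idx) - 1) * s + 25 + jitter
      tibble(gene_id = sprintf("g%03d", idx), contig = ctg,
             start = as.integer(start), end = as.integer(start + span),
             strand = sample(c("+", "-"), length(idx), replace = TRUE))
    })
  })
  rows <- arrange(rows, .data$gene_id)
  tx <- rows %>%
    mutate(transcript_id = paste0(.data$gene_id, ".t1"), .before = 1) %>%
    select("transcript_id", "gene_id", "contig", "start", "end", "strand")
  exons <- tx %>%
    tidyr::expand_grid(exon = seq_len(config$exons_per_gene)) %>%
    mutate(
      ex_start = .data$start +
        (.data$exon - 1) * (config$exon_width + config$intron_width),
      ex_end = .data$ex_start + config$exon_width
    ) %>%
    select("transcript_id", "gene_id", "contig",
           start = "ex_start", end = "ex_end", "strand")
  genome_annotation(rows, tx, exons, cl)
}

#' Place spike regions automatically
#'
#' `n_spikes_per_condition` regions per condition in total, split as evenly
#' as possible across the spiked marks (H3K27ac takes any remainder):
#' H3K27ac spikes sit inside introns (the intronic-enhancer signature; they
#' are placed first), H3K4me3 and H3K36me3 spikes anywhere free of other
#' spikes. Regions never overlap each other.
#'
#' @param annotation a `genome_annotation`.
#' @param config a `synth_config`.
#' @param marks marks to spike (default all three).
#' @return spike tibble `mark`, `condition`, `contig`, `start`, `end`, `fold`.
#' @export
generate_spike_regions <- function(annotation, config,
                                   marks = c("H3K4me3", "H3K27ac", "H3K36me3")) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(config$spike_regions)) return(as_tibble(config$spike_regions))
  empty <- tibble(mark = character(), condition = character(),
                  contig = character(), start = integer(), end = integer(),
                  fold = numeric())
  if (config$n_spikes_per_condition == 0) return(empty)
  cl <- config$contig_lengths
  introns <- ann_introns(annotation)
  genes <- annotation$genes
  taken <- tibble(contig = character(), start = numeric(), end = numeric())

  overlaps_taken <- function(ctg, s, e) {
    any(taken$contig == ctg & taken$start < e & taken$end > s)
  }
  draw_in <- function(pool, width) {
    for (try in seq_len(500)) {
      row <- pool[sample.int(nrow(pool), 1), ]
      w <- min(width, row$end - row$start)
      if (w < 100) next
      s <- row$start + floor(runif(1) * (row$end - row$start - w + 1))
      if (!overlaps_taken(row$contig, s, s + w)) {
        taken <<- bind_rows(taken, tibble(contig = row$contig, start = s,
                                          end = s + w))
        return(tibble(contig = row$contig, start = s, end = s + w))
      }
    }
    abort("could not place spike regions without overlap; reduce their number")
  }
  genome_pool <- tibble(contig = names(cl), start = 0, end = unname(cl))

  with_seed(derive_seed(config$seed, "spikes"), {
    ordered_marks <- c(intersect("H3K27ac", marks),
                       setdiff(marks, "H3K27ac"))
    n_per_mark <- rep(floor(config$n_spikes_per_condition / length(marks)),
                      length(ordered_marks))
    extra <- config$n_spikes_per_condition - sum(n_per_mark)
    if (extra > 0) n_per_mark[seq_len(extra)] <- n_per_mark[seq_len(extra)] + 1
    names(n_per_mark) <- ordered_marks
    out <- purrr::map_dfr(ordered_marks, function(mk) {
      pool <- switch(mk,
        H3K27ac = if (nrow(introns)) introns else genome_pool,
        genome_pool)
      purrr::map_dfr(config$conditions, function(cond) {
        purrr::map_dfr(seq_len(n_per_mark[[mk]]), function(i) {
          mutate(draw_in(pool, config$spike_width), mark = mk,
                 condition = cond, fold = config$spike_fold, .before = 1)
        })
      })
    })
  })
  if (nrow(out) == 0) return(empty)
  select(out, "mark", "condition", "contig", "start", "end", "fold")
}

#' @noRd
sample_positions <- function(n, contig_lengths) {
  probs <- contig_lengths / sum(contig_lengths)
  ctg <- sample(names(contig_lengths), n, replace = TRUE, prob = probs)
  tibble(contig = ctg, pos = floor(runif(n) * unname(contig_lengths[ctg])))
}

#' @noRd
centers_to_reads <- function(centers, contig_lengths, read_length = 75,
                             coverage_half = 125) {
  n <- nrow(centers)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  start <- ifelse(strand == "+", centers$pos - coverage_half,
                  centers$pos + coverage_half - read_length)
  len <- unname(contig_lengths[centers$contig])
  start <- pmin(pmax(start, 0), len - read_length)
  mapq <- sample(c(60L, 10L), n, replace = TRUE, prob = c(0.97, 0.03))
  tibble(contig = centers$contig, start = as.integer(start),
         end = as.integer(start + read_length), strand = strand, mapq = mapq)
}

#' @noRd
rpois_od <- function(n, lambda, dispersion) {
  if (dispersion <= 0) return(rpois(n, lambda))
  rpois(n, lambda * stats::rgamma(n, shape = 1 / dispersion,
                                  scale = dispersion))
}

#' Generate ChIP and input reads with spiked differential windows
#'
#' Input samples are near-uniform; H3K4me3/H3K27ac read density peaks around
#' TSSs (fragment centers Gaussian, sd 250 bp), H3K36me3 density is elevated
#' across gene bodies, and spike regions receive condition-specific extra
#' reads calibrated so their enrichment over input approaches the spike fold.
#' Reads are 75-bp single-end with strand and mapping quality (a small
#' fraction below the default quality filter, to exercise it).
#'
#' @param annotation a `genome_annotation`.
#' @param config a `synth_config`.
#' @param spikes spike tibble, or `NULL` for [generate_spike_regions()]
#'   (pass a zero-row tibble for a spike-free null study).
#' @return list with `reads` (tibble `contig`, `start`, `end`, `strand`,
#'   `mapq`, `sample`), `samples` (sample sheet) and `spikes` (the truth).
#' @export
generate_chip_reads <- function(annotation, config, spikes = NULL) {
  stopifnot(inherits(config, "synth_config"))
  cl <- config$contig_lengths
  genome <- sum(cl)
  spikes <- spikes %||% generate_spike_regions(annotation, config)
  if (nrow(spikes) > 0 && any(spikes$fold <= 0)) abort("spike fold must be positive")
  tss <- ann_tss(annotation)
  genes <- annotation$genes
  marks <- c("H3K4me3", "H3K27ac", "H3K36me3")

  samples <- bind_rows(
    tidyr::expand_grid(mark = marks, condition = config$conditions,
                       replicate = seq_len(config$n_replicates)),
    tibble(mark = "input", condition = config$conditions, replicate = 1L)
  ) %>%
    mutate(sample = paste(.data$mark, .data$condition, .data$replicate,
                          sep = "_"))

  gene_bp <- sum(genes$end - genes$start)

  one_sample <- function(mark, condition, sample_id, stream) {
    with_seed(derive_seed(config$seed, stream), {
      if (mark == "input") {
        centers <- sample_positions(rpois(1, config$input_library_size), cl)
        return(mutate(centers_to_reads(centers, cl), sample = sample_id))
      }
      lib <- config$library_size
      # feature read fraction solved so the realized window enrichment at the
      # feature (after footprint smoothing and library-composition division)
      # equals the configured fold; capped by what the genome composition
      # allows
      S <- 100 + 250 - 1  # default counting footprint the generator calibrates to
      if (mark %in% c("H3K4me3", "H3K27ac")) {
        fold <- config$tss_enrichment_fold
        k <- 2 * stats::pnorm(S / 2, 0, 150) - 1
        coef <- if (nrow(tss) > 0) k * genome / (nrow(tss) * S) else 1
      } else {
        fold <- config$gene_body_fold
        coef <- if (gene_bp > 0) genome / gene_bp else 1
      }
      phi <- if (coef > 1) (fold - 1) / (coef - 1) else 0
      phi <- min(max(phi, 0), 0.95)
      n_bg <- rpois(1, lib * (1 - phi))
      n_feat <- rpois(1, lib * phi)
      bg <- sample_positions(n_bg, cl)
      feat <- NULL
      if (n_feat > 0) {
        if (mark %in% c("H3K4me3", "H3K27ac")) {
          pick <- sample.int(nrow(tss), n_feat, replace = TRUE)
          feat <- tibble(contig = tss$contig[pick],
                         pos = round(tss$pos[pick] + rnorm(n_feat, 0, 150)))
        } else {
          w <- genes$end - genes$start
          pick <- sample.int(nrow(genes), n_feat, replace = TRUE, prob = w)
          feat <- tibble(contig = genes$contig[pick],
                         pos = genes$start[pick] +
                           floor(runif(n_feat) * w[pick]))
        }
        feat$pos <- pmin(pmax(feat$pos, 0), unname(cl[feat$contig]) - 1)
      }
      sp <- spikes[spikes$mark == mark & spikes$condition == condition, ,
                   drop = FALSE]
      extra <- NULL
      if (nrow(sp) > 0) {
        lam <- (sp$fold - 1) * (lib / genome) * (sp$end - sp$start)
        n_extra <- rpois(nrow(sp), lam)
        extra <- purrr::map_dfr(seq_len(nrow(sp)), function(i) {
          if (n_extra[i] == 0) return(NULL)
          tibble(contig = sp$contig[i],
                 pos = sp$start[i] +
                   floor(runif(n_extra[i]) * (sp$end[i] - sp$start[i])))
        })
      }
      centers <- bind_rows(bg, feat, extra)
      mutate(centers_to_reads(centers, cl), sample = sample_id)
    })
  }

  reads <- purrr::pmap_dfr(samples, function(mark, condition, replicate, sample) {
    one_sample(mark, condition, sample, paste0("reads_", sample))
  })
  list(reads = reads,
       samples = select(samples, "sample", "condition", "mark", "replicate"),
       spikes = spikes)
}

#' Generate window counts directly (fast mode)
#'
#' Skips read-level simulation: per-window Poisson counts whose expectations
#' follow the same background/TSS/gene-body/spike intensity model as
#' [generate_chip_reads()], pushed straight through the normalization
#' equation. Intended for calibration studies that need many independent
#' runs (e.g. null false-positive rates).
#'
#' @param annotation a `genome_annotation`.
#' @param config a `synth_config`.
#' @param windows grid from [tile_windows()]; defaults to the standard
#'   100/50 grid over the configured contigs.
#' @param spikes spike tibble (zero-row for a null study); default automatic.
#' @param marks marks to simulate (default all three).
#' @param extension,input_width effective read extension and input expansion
#'   used to set expected counts (defaults 250 and 5000).
#' @return an enrichment tibble with the same shape and attributes as
#'   [chip_enrichment()] output.
#' @export
generate_window_counts <- function(annotation, config, windows = NULL,
                                   spikes = NULL,
                                   marks = c("H3K4me3", "H3K27ac", "H3K36me3"),
                                   extension = 250, input_width = 5000) {
  stopifnot(inherits(config, "synth_config"))
  cl <- config$contig_lengths
  genome <- sum(cl)
  windows <- windows %||% tile_windows(cl)
  spikes <- spikes %||% generate_spike_regions(annotation, config)
  width <- attr(windows, "width") %||% 100
  tss <- ann_tss(annotation)
  genes <- annotation$genes
  mid <- (windows$start + windows$end) / 2

  nearest_tss_dist <- rep(Inf, nrow(windows))
  if (nrow(tss) > 0) {
    for (ctg in names(cl)) {
      wi <- which(windows$contig == ctg)
      tp <- sort(tss$pos[tss$contig == ctg])
      if (length(tp) == 0 || length(wi) == 0) next
      j <- findInterval(mid[wi], tp)
      lo <- ifelse(j >= 1, abs(mid[wi] - tp[pmax(j, 1)]), Inf)
      hi <- ifelse(j < length(tp), abs(tp[pmin(j + 1, length(tp))] - mid[wi]), Inf)
      nearest_tss_dist[wi] <- pmin(lo, hi)
    }
  }
  in_gene <- rep(FALSE, nrow(windows))
  if (nrow(genes) > 0) {
    ov <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(windows$contig, IRanges::IRanges(mid + 1, mid + 1)),
      as_granges0(genes), ignore.strand = TRUE)
    in_gene[unique(S4Vectors::queryHits(ov))] <- TRUE
  }

  profile_for <- function(mark, condition) {
    if (mark %in% c("H3K4me3", "H3K27ac")) {
      f <- 1 + (config$tss_enrichment_fold - 1) *
        exp(-nearest_tss_dist^2 / (2 * 300^2))
    } else {
      f <- ifelse(in_gene, config$gene_body_fold, 1)
    }
    sp <- spikes[spikes$mark == mark & spikes$condition == condition, ,
                 drop = FALSE]
    if (nrow(sp) > 0) {
      for (i in seq_len(nrow(sp))) {
        hit <- windows$contig == sp$contig[i] & mid >= sp$start[i] &
          mid < sp$end[i]
        f[hit] <- f[hit] + (sp$fold[i] - 1)
      }
    }
    f
  }

  samples <- bind_rows(
    tidyr::expand_grid(mark = marks, condition = config$conditions,
                       replicate = seq_len(config$n_replicates)),
    tibble(mark = "input", condition = config$conditions, replicate = 1L)
  ) %>%
    mutate(sample = paste(.data$mark, .data$condition, .data$replicate,
                          sep = "_"))

  span <- width + extension - 1
  bg_per_bp <- config$library_size / genome
  exp_w <- expand_windows(windows, input_width, cl)
  keep <- !exp_w$removed
  out <- windows[keep, c("window_id", "contig", "start", "end")]
  chip_ids <- samples$sample[samples$mark != "input"]
  count_mat <- matrix(NA_integer_, nrow = sum(keep), ncol = length(chip_ids),
                      dimnames = list(NULL, chip_ids))
  n_reads <- c()

  with_seed(derive_seed(config$seed, "fast_counts"), {
    input_counts <- list()
    span_ratio <- span / (input_width + extension - 1)
    for (cond in config$conditions) {
      lam <- (config$input_library_size / genome) * (input_width + extension - 1)
      input_counts[[cond]] <- rpois_od(sum(keep), lam, config$nb_dispersion) *
        span_ratio
      n_reads[paste0("input_", cond, "_1")] <- config$input_library_size
    }
    for (i in which(samples$mark != "input")) {
      mk <- samples$mark[i]; cond <- samples$condition[i]
      f <- profile_for(mk, cond)[keep]
      lam <- bg_per_bp * span * f
      cnt <- rpois_od(sum(keep), lam, config$nb_dispersion)
      count_mat[, samples$sample[i]] <- cnt
      n_reads[samples$sample[i]] <- config$library_size
      out[[samples$sample[i]]] <- normalize_to_input(
        cnt, config$library_size, input_counts[[cond]],
        config$input_library_size)
    }
  })
  attr(out, "samples") <- samples[samples$mark != "input", , drop = FALSE]
  attr(out, "n_reads") <- n_reads
  attr(out, "removed") <- windows$window_id[!keep]
  attr(out, "counts") <- count_mat
  attr(out, "width") <- width
  attr(out, "spacing") <- attr(windows, "spacing")
  attr(out, "contig_lengths") <- cl
  out
}

#' Generate a log2 expression matrix with planted effects
#'
#' Baseline abundances are uniform on log2 [4, 10]; per-transcript noise SDs
#' are drawn from a scaled inverse-chi-square (so downstream variance
#' shrinkage has a true prior to recover). A `de_fraction` of transcripts get
#' `expression_effect` added in one condition (random sign); genes overlapping
#' a spiked active-mark region additionally get a coupled boost in the spiked
#' condition, which creates the chromatin-expression correlation.
#'
#' @param annotation a `genome_annotation`.
#' @param config a `synth_config`.
#' @param spikes spike tibble (or `NULL` for none).
#' @return list with `expression` (tibble `transcript_id`, `gene_id`, sample
#'   columns; attribute `samples`) and `truth` (tibble `transcript_id`,
#'   `true_logfc`, positive = higher in the first condition).
#' @export
generate_expression <- function(annotation, config, spikes = NULL) {
  stopifnot(inherits(config, "synth_config"))
  tx <- annotation$transcripts
  n_tx <- nrow(tx)
  conds <- config$conditions
  samples <- tidyr::expand_grid(condition = conds,
                                replicate = seq_len(config$n_rna_replicates)) %>%
    mutate(sample = paste("rna", .data$condition, .data$replicate, sep = "_"))

  coupled <- tibble(gene_id = character(), boost = numeric())
  if (!is.null(spikes) && nrow(spikes) > 0 && n_tx > 0) {
    ov <- GenomicRanges::findOverlaps(as_granges0(spikes),
                                      as_granges0(annotation$genes),
                                      ignore.strand = TRUE)
    coupled <- tibble(
      gene_id = annotation$genes$gene_id[S4Vectors::subjectHits(ov)],
      condition = spikes$condition[S4Vectors::queryHits(ov)],
      fold = spikes$fold[S4Vectors::queryHits(ov)]
    ) %>%
      mutate(boost = config$chromatin_coupling * log2(.data$fold) *
               if_else(.data$condition == conds[1], 1, -1)) %>%
      group_by(.data$gene_id) %>%
      summarise(boost = sum(.data$boost), .groups = "drop")
  }

  with_seed(derive_seed(config$seed, "expression"), {
    mu <- runif(n_tx, 4, 10)
    sd_tx <- sqrt(config$expr_s0_sq * config$expr_d0 /
                    rchisq(n_tx, df = config$expr_d0))
    n_de <- round(config$de_fraction * n_tx)
    de_idx <- if (n_de > 0) sample.int(n_tx, n_de) else integer(0)
    effect <- numeric(n_tx)
    effect[de_idx] <- config$expression_effect *
      sample(c(1, -1), n_de, replace = TRUE)
    boost <- coupled$boost[match(tx$gene_id, coupled$gene_id)]
    boost[is.na(boost)] <- 0
    true_logfc <- effect + boost

    out <- tibble(transcript_id = tx$transcript_id, gene_id = tx$gene_id)
    for (i in seq_len(nrow(samples))) {
      shift <- if (samples$condition[i] == conds[1]) true_logfc / 2 else -true_logfc / 2
      out[[samples$sample[i]]] <- mu + shift + rnorm(n_tx, 0, sd_tx)
    }
  })
  attr(out, "samples") <- select(samples, "sample", "condition")
  truth <- tibble(transcript_id = tx$transcript_id,
                  true_logfc = true_logfc)[true_logfc != 0, , drop = FALSE]
  list(expression = out, truth = truth)
}

#' Generate a per-CpG methylation count table
#'
#' CpG positions are uniform over the genome (optionally concentrated inside
#' supplied intervals for a `dmp_fraction` of sites); counts are binomial at
#' Poisson coverage. Differential sites get methylation proportions 0.8 vs
#' 0.1 (direction random); all other sites share a common baseline per site.
#'
#' @param annotation a `genome_annotation` (for contig lengths).
#' @param config a `synth_config`.
#' @param dmp_in_regions optional interval tibble; planted DMPs are placed
#'   inside these regions (e.g. to emulate enrichment of DMPs in a mark).
#' @return list with `methylation` (tibble `contig`, `pos`, `meth_a`, `cov_a`,
#'   `meth_b`, `cov_b`; condition a = first configured condition) and `truth`
#'   (tibble `contig`, `pos` of planted DMPs).
#' @export
generate_methylation <- function(annotation, config, dmp_in_regions = NULL) {
  stopifnot(inherits(config, "synth_config"))
  cl <- config$contig_lengths
  n <- config$n_cpg
  with_seed(derive_seed(config$seed, "methylation"), {
    sites <- sample_positions(n, cl)
    n_dmp <- round(config$dmp_fraction * n)
    is_dmp <- rep(FALSE, n)
    if (n_dmp > 0) {
      idx <- sample.int(n, n_dmp)
      is_dmp[idx] <- TRUE
      if (!is.null(dmp_in_regions) && nrow(dmp_in_regions) > 0) {
        w <- dmp_in_regions$end - dmp_in_regions$start
        pick <- sample.int(nrow(dmp_in_regions), n_dmp, replace = TRUE, prob = w)
        sites$contig[idx] <- dmp_in_regions$contig[pick]
        sites$pos[idx] <- dmp_in_regions$start[pick] +
          floor(runif(n_dmp) * w[pick])
      }
    }
    base_p <- runif(n, 0.05, 0.3)
    flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
    p_a <- ifelse(is_dmp, ifelse(flip, 0.8, 0.1), base_p)
    p_b <- ifelse(is_dmp, ifelse(flip, 0.1, 0.8), base_p)
    cov_a <- rpois(n, config$meth_coverage)
    cov_b <- rpois(n, config$meth_coverage)
    meth <- tibble(
      contig = sites$contig, pos = sites$pos,
      meth_a = rbinom(n, cov_a, p_a), cov_a = cov_a,
      meth_b = rbinom(n, cov_b, p_b), cov_b = cov_b
    ) %>% arrange(.data$contig, .data$pos)
  })
  truth <- tibble(contig = sites$contig[is_dmp], pos = sites$pos[is_dmp])
  list(methylation = meth, truth = arrange(truth, .data$contig, .data$pos))
}

#' Generate random genome sequence
#'
#' @param config a `synth_config`.
#' @return named character vector, one string per contig.
#' @export
generate_sequences <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cl <- config$contig_lengths
  with_seed(derive_seed(config$seed, "sequences"), {
    out <- vapply(names(cl), function(ctg) {
      paste(sample(c("A", "C", "G", "T"), cl[[ctg]], replace = TRUE),
            collapse = "")
    }, character(1))
  })
  out
}

#' Default planted motif
#'
#' An 8-bp PWM with 0.91 probability on its consensus `TGACGTCA` at every
#' position (informative enough that planted copies dominate random matches).
#' @return a `pwm`.
#' @export
default_motif <- function() {
  cons <- c("T", "G", "A", "C", "G", "T", "C", "A")
  mat <- matrix(0.03, nrow = length(cons), ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(cons)) mat[i, cons[i]] <- 0.91
  pwm("synthetic_TGACGTCA", mat)
}

#' Plant motif instances into genome sequence
#'
#' Writes the PWM consensus into each chosen region at an offset from the
#' region center drawn from `offset_law`: `"center"` (offset 0),
#' `"bimodal"` (+- `shift` bp, emulating motif enrichment flanking peaks) or
#' `"uniform"`.
#'
#' @param sequences named character vector of contig sequences.
#' @param regions interval tibble of (typically fixed-width) target regions.
#' @param pwm a `pwm`.
#' @param offset_law placement law.
#' @param shift bimodal shift in bp (default 500).
#' @param seed integer seed.
#' @return list with `sequences` (modified) and `sites` (tibble `region_id`,
#'   `contig`, `start`, `offset`).
#' @export
plant_motifs <- function(sequences, regions, pwm,
                         offset_law = c("center", "bimodal", "uniform"),
                         shift = 500, seed = 1L) {
  offset_law <- match.arg(offset_law)
  if (nrow(regions) == 0) {
    return(list(sequences = sequences,
                sites = tibble(region_id = integer(), contig = character(),
                               start = integer(), offset = numeric())))
  }
  check_interval_tbl(regions, "regions")
  cons <- pwm_consensus(pwm)
  L <- nchar(cons)
  half <- floor((regions$end - regions$start) / 2)
  with_seed(derive_seed(seed, "plant_motifs"), {
    offset <- switch(offset_law,
      center = rep(0, nrow(regions)),
      bimodal = sample(c(-shift, shift), nrow(regions), replace = TRUE),
      uniform = floor(runif(nrow(regions), -half + L, half - L))
    )
  })
  centers <- floor((regions$start + regions$end) / 2)
  site_start <- centers + offset - floor(L / 2)
  sites <- tibble(region_id = seq_len(nrow(regions)),
                  contig = regions$contig,
                  start = as.integer(site_start), offset = offset)
  for (i in seq_len(nrow(sites))) {
    s <- sites$start[i]
    substr(sequences[[sites$contig[i]]], s + 1, s + L) <- cons
  }
  list(sequences = sequences, sites = sites)
}

#' Simulate a complete two-caste study
#'
#' Runs every generator and assembles the truth table.
#'
#' @param config a `synth_config`.
#' @param spikes spike tibble override (`NULL` = automatic; zero-row tibble =
#'   null study).
#' @param motif_offset_law placement law for planted motifs in extended
#'   H3K27ac spike windows (default `"center"`).
#' @return list with `annotation`, `reads`, `samples`, `expression`,
#'   `methylation`, `sequences`, `motif`, `motif_regions` and `truth` (list
#'   `spikes`, `de_transcripts`, `dmps`, `motif_sites`).
#' @export
simulate_caste_study <- function(config = synth_config(), spikes = NULL,
                                 motif_offset_law = "center") {
  annotation <- generate_annotation(config)
  spikes <- spikes %||% generate_spike_regions(annotation, config)
  chip <- generate_chip_reads(annotation, config, spikes)
  expr <- generate_expression(annotation, config, spikes)
  k36 <- spikes[spikes$mark == "H3K36me3", , drop = FALSE]
  meth <- generate_methylation(annotation, config,
                               dmp_in_regions = if (nrow(k36)) k36 else NULL)
  seqs <- generate_sequences(config)

  k27 <- spikes[spikes$mark == "H3K27ac", , drop = FALSE]
  motif_regions <- extend_peaks(k27, total_width = 5000,
                                contig_lengths = config$contig_lengths)
  mot <- default_motif()
  planted <- plant_motifs(seqs, motif_regions, mot,
                          offset_law = motif_offset_law,
                          seed = derive_seed(config$seed, "motif_seed"))

  list(
    config = config,
    annotation = annotation,
    reads = chip$reads,
    samples = chip$samples,
    expression = expr$expression,
    methylation = meth$methylation,
    sequences = planted$sequences,
    motif = mot,
    motif_regions = motif_regions,
    truth = list(
      spikes = spikes,
      de_transcripts = expr$truth,
      dmps = meth$truth,
      motif_sites = planted$sites
    )
  )
}
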