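# Shared fixtures and independent oracles, all built in code.

# A small hand-written annotation on one 50-kb contig: three genes with known
# structure (g1 +, two exons; g2 -, two exons; g3 +, single exon).
tiny_annotation <- function() {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    contig = "chrT",
    start = c(1000L, 10000L, 30000L),
    end = c(3000L, 12000L, 30500L),
    strand = c("+", "-", "+")
  )
  tx <- dplyr::mutate(genes,
                      transcript_id = paste0(gene_id, ".t1"), .before = 1)
  exons <- tibble::tibble(
    transcript_id = c("g1.t1", "g1.t1", "g2.t1", "g2.t1", "g3.t1"),
    gene_id = c("g1", "g1", "g2", "g2", "g3"),
    contig = "chrT",
    start = c(1000L, 2500L, 10000L, 11500L, 30000L),
    end = c(1500L, 3000L, 10500L, 12000L, 30500L),
    strand = c("+", "+", "-", "-", "+")
  )
  genome_annotation(genes, tx[, c("transcript_id", "gene_id", "contig",
                                  "start", "end", "strand")],
                    exons, c(chrT = 50000))
}

# Brute-force per-read, per-window overlap counting oracle.
brute_force_counts <- function(reads, windows, extension, mapq_min,
                               contig_lengths) {
  reads <- reads[reads$mapq >= mapq_min, , drop = FALSE]
  counts <- integer(nrow(windows))
  for (i in seq_len(nrow(reads))) {
    len <- contig_lengths[[reads$contig[i]]]
    if (reads$strand[i] == "-") {
      s <- max(0, reads$end[i] - extension); e <- reads$end[i]
    } else {
      s <- reads$start[i]; e <- min(len, reads$start[i] + extension)
    }
    for (j in seq_len(nrow(windows))) {
      if (windows$contig[j] == reads$contig[i] &&
          s < windows$end[j] && e > windows$start[j]) {
        counts[j] <- counts[j] + 1L
      }
    }
  }
  counts
}

# Brute-force BH definition: q_i = min over {j : p_(j) >= p_i} of m p_(j) / j.
brute_force_bh <- function(p) {
  m <- length(p)
  ps <- sort(p)
  q <- vapply(p, function(pi) {
    js <- which(ps >= pi - 1e-15)
    min(1, min(m * ps[js] / js))
  }, numeric(1))
  q
}

# Exhaustive two-sided Fisher oracle: enumerate all tables with the observed
# margins and sum hypergeometric probabilities <= that of the observed table.
enumerate_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  as <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(as, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Small null enrichment matrix built directly from Poisson counts, bypassing
# the generator, for targeted moderated-t checks.
null_enrichment <- function(n_windows = 500, mean_count = 100, seed = 1) {
  set.seed(seed)
  samples <- tibble::tibble(
    sample = c("m_W_1", "m_W_2", "m_Q_1", "m_Q_2"),
    condition = c("W", "W", "Q", "Q"),
    mark = "m"
  )
  out <- tibble::tibble(
    window_id = seq_len(n_windows), contig = "chrT",
    start = (seq_len(n_windows) - 1) * 50L,
    end = (seq_len(n_windows) - 1) * 50L + 100L
  )
  cb <- rpois(n_windows, mean_count * 15) / 15
  for (id in samples$sample) {
    out[[id]] <- normalize_to_input(rpois(n_windows, mean_count), 1e6, cb, 1e6)
  }
  attr(out, "samples") <- samples
  attr(out, "spacing") <- 50
  attr(out, "width") <- 100
  out
}
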