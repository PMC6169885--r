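# DMP calling and permutation overlap-enrichment tests.

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The two-sided p-value is the total probability, under the hypergeometric
#' null with fixed margins, of all tables whose point probability does not
#' exceed that of the observed table. An empty margin gives p = 1.
#'
#' @param a,b,c,d non-negative integer cells, rows = groups, columns =
#'   outcome (e.g. methylated / unmethylated).
#' @return two-sided p-value.
#' @examples
#' fisher_exact_2x2(5, 0, 0, 5)
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("cells must be non-negative integers")
  }
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) return(1)
  min(1, fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value)
}

#' Call differentially methylated positions
#'
#' Per CpG site, a Fisher's exact test on methylated vs unmethylated counts
#' between the two conditions; BH adjustment across all tested sites; a site
#' is a DMP when its adjusted p falls below `alpha`. Sites with zero coverage
#' in either condition are excluded from testing.
#'
#' @param methylation tibble with columns `contig`, `pos`, `meth_a`, `cov_a`,
#'   `meth_b`, `cov_b` (counts for the two conditions).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return the tested sites with `prop_a`, `prop_b`, `p`, `q`, `dmp` columns
#'   added; excluded zero-coverage sites are dropped (count kept in the
#'   `n_excluded` attribute).
#' @export
call_dmps <- function(methylation, alpha = 0.05) {
  need <- c("contig", "pos", "meth_a", "cov_a", "meth_b", "cov_b")
  if (!all(need %in% names(methylation))) {
    abort(paste("`methylation` needs columns", paste(need, collapse = ", ")))
  }
  m <- as_tibble(methylation)
  if (any(m$meth_a > m$cov_a | m$meth_b > m$cov_b)) {
    abort("methylated counts cannot exceed coverage")
  }
  testable <- m$cov_a > 0 & m$cov_b > 0
  excluded <- sum(!testable)
  m <- m[testable, , drop = FALSE]
  p <- vapply(seq_len(nrow(m)), function(i) {
    fisher_exact_2x2(m$meth_a[i], m$cov_a[i] - m$meth_a[i],
                     m$meth_b[i], m$cov_b[i] - m$meth_b[i])
  }, numeric(1))
  out <- m %>% mutate(
    prop_a = .data$meth_a / .data$cov_a,
    prop_b = .data$meth_b / .data$cov_b,
    p = p, q = bh_adjust(p), dmp = .data$q < alpha
  )
  attr(out, "n_excluded") <- excluded
  out
}

#' @noRd
new_perm_test <- function(observed, null_values, n_perm, seed,
                          alternative, extra = list()) {
  k <- switch(alternative,
              enrichment = sum(null_values >= observed),
              depletion = sum(null_values <= observed))
  structure(
    c(list(
      observed = observed,
      null_values = null_values,
      fold_enrichment = if (mean(null_values) > 0)
        observed / mean(null_values) else NA_real_,
      p_emp = (1 + k) / (n_perm + 1),
      n_perm = n_perm, seed = seed, alternative = alternative
    ), extra),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "<perm_test> observed = %g, null mean = %.3g, fold enrichment = %.3g, p_emp = %.4g (%s, %d permutations)\n",
    x$observed, mean(x$null_values), x$fold_enrichment, x$p_emp,
    x$alternative, x$n_perm))
  invisible(x)
}

#' Permutation test for point-feature overlap with regions
#'
#' The observed statistic is the number of point features (e.g. DMPs) falling
#' inside the regions (e.g. differential histone-mark regions). The null is
#' built by re-placing each region uniformly at random within its own contig,
#' preserving its length (`mode = "relocate"`), or by re-drawing the feature
#' positions uniformly (`mode = "shuffle_features"`). Fold enrichment is the
#' observed count over the null mean; the empirical p carries a +1 pseudocount
#' so it is never zero and bottoms out at `1/(n_perm + 1)`.
#'
#' @param features tibble `contig`, `pos` (0-based positions).
#' @param regions interval tibble `contig`, `start`, `end`.
#' @param contig_lengths named contig lengths.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @param mode null scheme: `"relocate"` (default) or `"shuffle_features"`.
#' @return a `perm_test` object (see [tidy.perm_test()]).
#' @export
overlap_permutation_test <- function(features, regions, contig_lengths,
                                     n_perm = 1000, seed = 1L,
                                     mode = c("relocate", "shuffle_features")) {
  mode <- match.arg(mode)
  check_interval_tbl(regions, "regions")
  check_contig_lengths(contig_lengths)
  widths <- regions$end - regions$start
  if (any(widths > contig_lengths[regions$contig])) {
    abort("a region is longer than its contig")
  }

  count_inside <- function(feat, regs) {
    if (nrow(feat) == 0 || nrow(regs) == 0) return(0L)
    total <- 0L
    for (ctg in unique(feat$contig)) {
      f <- feat$pos[feat$contig == ctg]
      r <- regs[regs$contig == ctg, , drop = FALSE]
      if (nrow(r) == 0) next
      # count features with start <= pos < end over possibly overlapping regions
      red <- IRanges::reduce(IRanges::IRanges(r$start + 1, r$end))
      total <- total + sum(IRanges::countOverlaps(
        IRanges::IRanges(f + 1, f + 1), red) > 0)
    }
    as.integer(total)
  }

  observed <- count_inside(features, regions)
  null_values <- integer(n_perm)
  with_seed(derive_seed(seed, paste0("overlap_perm_", mode)), {
    for (b in seq_len(n_perm)) {
      if (mode == "relocate") {
        max_start <- unname(contig_lengths[regions$contig]) - widths
        new_start <- floor(runif(nrow(regions)) * (max_start + 1))
        perm_regions <- tibble(contig = regions$contig, start = new_start,
                               end = new_start + widths)
        null_values[b] <- count_inside(features, perm_regions)
      } else {
        probs <- contig_lengths / sum(contig_lengths)
        ctg <- sample(names(contig_lengths), nrow(features),
                      replace = TRUE, prob = probs)
        pos <- floor(runif(nrow(features)) * unname(contig_lengths[ctg]))
        null_values[b] <- count_inside(tibble(contig = ctg, pos = pos), regions)
      }
    }
  })
  new_perm_test(observed, null_values, n_perm, seed, "enrichment",
                extra = list(mode = mode))
}

#' Permutation test for gene-set overlap with peak-bearing genes
#'
#' Tests whether a gene set (e.g. differentially expressed genes) contains
#' more genes with an intronic peak than expected: the observed statistic is
#' the intersection size, and the null redraws an equal-size gene set from the
#' universe without replacement, 1000 times by default. Depletion can be
#' tested with `alternative = "depletion"` (left tail, fold < 1).
#'
#' @param de_genes character vector, subset of `all_genes`.
#' @param peak_genes character vector of genes carrying at least one
#'   qualifying peak.
#' @param all_genes gene universe.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param alternative `"enrichment"` (default) or `"depletion"`.
#' @return a `perm_test` object.
#' @export
gene_set_peak_permutation <- function(de_genes, peak_genes, all_genes,
                                      n_perm = 1000, seed = 1L,
                                      alternative = c("enrichment", "depletion")) {
  alternative <- match.arg(alternative)
  if (!all(de_genes %in% all_genes)) abort("`de_genes` must be a subset of `all_genes`")
  if (length(de_genes) > length(all_genes)) {
    abort("gene set larger than the universe")
  }
  peak <- unique(peak_genes)
  observed <- length(intersect(unique(de_genes), peak))
  k <- length(unique(de_genes))
  is_peak <- all_genes %in% peak
  null_values <- integer(n_perm)
  with_seed(derive_seed(seed, "gene_set_perm"), {
    for (b in seq_len(n_perm)) {
      null_values[b] <- sum(is_peak[sample.int(length(all_genes), k)])
    }
  })
  new_perm_test(observed, null_values, n_perm, seed, alternative)
}
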