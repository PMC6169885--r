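# Differential expression (Gaussian likelihood-ratio test), sample MDS,
# Spearman correlation and the mark-combination expression analysis.
#
# Abundances are modelled on the log2 scale. The LRT compares a full model
# with a condition mean shift against a reduced grand-mean model per
# transcript; this keeps the full-vs-reduced inferential structure of
# bootstrap-based transcript DE tools without their pseudoalignment
# dependency.

#' Sample sheet of an expression tibble
#' @noRd
expr_samples <- function(expression) {
  s <- attr(expression, "samples")
  if (is.null(s)) abort("expression tibble lacks its `samples` attribute")
  s
}

#' Likelihood-ratio differential expression between two conditions
#'
#' Per transcript, fits Gaussian models on log2 abundance: full (one mean per
#' condition) vs reduced (grand mean), and reports the likelihood-ratio
#' statistic `n * ln(RSS_reduced / RSS_full)`. P-values use the exact
#' finite-sample form of the same comparison: the LR statistic is a monotone
#' function of the F statistic `(RSS_reduced - RSS_full) / (RSS_full / (n -
#' 2))`, whose null distribution at Gaussian noise is F(1, n - 2) exactly, so
#' null p-values are uniform even at small replicate numbers where the
#' chi-square(1) asymptotic reference is anticonservative. P-values are
#' BH-adjusted. `logfc` is `mean(first condition) - mean(second)`, so a
#' positive value means higher expression in the first condition.
#'
#' @param expression tibble with `transcript_id`, `gene_id` and one column per
#'   sample; attribute `samples` (tibble `sample`, `condition`).
#' @param conditions length-2 character fixing the direction; defaults to
#'   order of appearance.
#' @param var_floor small value added to both RSS so transcripts with zero
#'   within-group variance do not produce infinite statistics (default 1e-8).
#' @return tibble `transcript_id`, `gene_id`, `logfc`, `lrt_stat`, `p`, `q`.
#' @export
lrt_de <- function(expression, conditions = NULL, var_floor = 1e-8) {
  samples <- expr_samples(expression)
  conditions <- conditions %||% unique(samples$condition)
  if (length(conditions) != 2) abort("exactly two conditions required")
  i1 <- samples$sample[samples$condition == conditions[1]]
  i2 <- samples$sample[samples$condition == conditions[2]]
  if (length(i1) < 2 || length(i2) < 2) abort("need >= 2 samples per condition")
  x1 <- as.matrix(expression[, i1, drop = FALSE])
  x2 <- as.matrix(expression[, i2, drop = FALSE])
  n <- ncol(x1) + ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  grand <- (rowSums(x1) + rowSums(x2)) / n
  rss_full <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  rss_red <- rowSums((x1 - grand)^2) + rowSums((x2 - grand)^2)
  if (all(rss_full <= 0)) {
    abort("zero within-group variance everywhere; add a noise floor to the abundances")
  }
  stat <- n * log((rss_red + var_floor) / (rss_full + var_floor))
  stat <- pmax(stat, 0)
  fstat <- pmax(rss_red - rss_full, 0) / ((rss_full + var_floor) / (n - 2))
  p <- stats::pf(fstat, 1, n - 2, lower.tail = FALSE)
  tibble(
    transcript_id = expression$transcript_id, gene_id = expression$gene_id,
    logfc = m1 - m2, lrt_stat = stat, p = p, q = bh_adjust(p)
  )
}

#' Classical multidimensional scaling of samples
#'
#' Torgerson MDS on Euclidean distances between samples' log2 abundance
#' profiles. Axis orientation is arbitrary; only relative configuration is
#' meaningful.
#'
#' @param expression expression tibble (see [lrt_de()]).
#' @param k number of dimensions (default 2).
#' @return tibble `sample`, `condition`, `dim1` ... `dimk`.
#' @export
mds_samples <- function(expression, k = 2) {
  samples <- expr_samples(expression)
  if (nrow(samples) < 3) abort("need at least three samples for MDS")
  x <- t(as.matrix(expression[, samples$sample, drop = FALSE]))
  d <- dist(x)
  coords <- cmdscale(d, k = k, add = FALSE)
  if (ncol(coords) < k) {  # degenerate configurations embed in fewer dims
    coords <- cbind(coords, matrix(0, nrow(coords), k - ncol(coords)))
  }
  out <- tibble(sample = samples$sample, condition = samples$condition)
  for (j in seq_len(k)) out[[paste0("dim", j)]] <- coords[, j]
  out
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties; two-sided p from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y paired numeric vectors, `n >= 3` finite pairs.
#' @return tibble `rho`, `p`, `n`, `flagged` (`TRUE` when rho is undefined,
#'   e.g. a constant vector).
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need at least three finite pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(rho = NA_real_, p = NA_real_, n = n, flagged = TRUE))
  }
  rho <- cor(x, y, method = "spearman")
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  tibble(rho = rho, p = p, n = n, flagged = FALSE)
}

#' Correlate chromatin differences with expression differences
#'
#' Each differential region is assigned to every gene whose span it overlaps;
#' each (region, gene) pair contributes the region's signed enrichment
#' difference and the gene's expression log fold change (mean over its
#' transcripts). Spearman correlation is computed per mark.
#'
#' @param regions differential regions from [call_differential_regions()].
#' @param de DE results from [lrt_de()].
#' @param annotation a `genome_annotation`.
#' @param conditions length-2 character; the first condition is the positive
#'   direction on both axes.
#' @return tibble `mark`, `rho`, `p`, `n`, `flagged` (one row per mark with
#'   >= 3 pairs; marks with fewer pairs are flagged with `NA` statistics).
#' @export
chromatin_expression_correlation <- function(regions, de, annotation,
                                             conditions = NULL) {
  conditions <- conditions %||% c("W", "Q")
  gene_fc <- de %>%
    group_by(.data$gene_id) %>%
    summarise(logfc = mean(.data$logfc), .groups = "drop")
  if (nrow(regions) == 0) {
    return(tibble(mark = character(), rho = numeric(), p = numeric(),
                  n = integer(), flagged = logical()))
  }
  hits <- GenomicRanges::findOverlaps(as_granges0(regions),
                                      as_granges0(annotation$genes),
                                      ignore.strand = TRUE)
  pairs <- tibble(
    mark = regions$mark[S4Vectors::queryHits(hits)],
    delta = regions$max_abs_delta[S4Vectors::queryHits(hits)] *
      if_else(regions$direction[S4Vectors::queryHits(hits)] == conditions[1],
              1, -1),
    gene_id = annotation$genes$gene_id[S4Vectors::subjectHits(hits)]
  ) %>%
    left_join(gene_fc, by = "gene_id")

  purrr::map_dfr(unique(regions$mark), function(mk) {
    sub <- filter(pairs, .data$mark == mk, is.finite(.data$logfc))
    if (nrow(sub) < 3) {
      return(tibble(mark = mk, rho = NA_real_, p = NA_real_,
                    n = nrow(sub), flagged = TRUE))
    }
    mutate(spearman_cor(sub$delta, sub$logfc), mark = mk, .before = 1)
  })
}

#' Expression distributions by histone-mark combination
#'
#' Genes are grouped by their combination of marks (from [mark_genes()]); for
#' each non-empty combination the member genes' expression is compared to an
#' equal-size random background sample of genes by a two-sided Wilcoxon
#' rank-sum test, and p-values are BH-adjusted across combinations.
#'
#' @param gene_marks tibble from [mark_genes()] (`gene_id` + one logical
#'   column per mark).
#' @param expression expression tibble; gene expression is the mean log2
#'   abundance over its transcripts and samples.
#' @param seed integer seed controlling the background draws.
#' @return tibble `combination`, `n`, `median_expr`, `median_background`, `p`,
#'   `q` plus list-columns `expr` and `background` with the raw values.
#' @export
expression_by_mark_combination <- function(gene_marks, expression, seed = 1L) {
  mark_cols <- setdiff(names(gene_marks), "gene_id")
  sample_cols <- setdiff(names(expression), c("transcript_id", "gene_id"))
  gene_expr <- expression %>%
    mutate(expr = rowMeans(across(dplyr::all_of(sample_cols)))) %>%
    group_by(.data$gene_id) %>%
    summarise(expr = mean(.data$expr), .groups = "drop")
  gm <- left_join(gene_marks, gene_expr, by = "gene_id") %>%
    filter(is.finite(.data$expr))
  combo <- apply(as.matrix(gm[, mark_cols]), 1, function(r) {
    if (!any(r)) "unmarked" else paste(mark_cols[r], collapse = "+")
  })
  gm$combination <- combo

  with_seed(derive_seed(seed, "mark_combination_background"), {
    res <- purrr::map_dfr(sort(unique(combo)), function(cb) {
      vals <- gm$expr[gm$combination == cb]
      bg <- sample(gm$expr, length(vals), replace = FALSE)
      p <- if (length(vals) >= 2) {
        suppressWarnings(wilcox.test(vals, bg, exact = FALSE)$p.value)
      } else NA_real_
      tibble(combination = cb, n = length(vals),
             median_expr = median(vals), median_background = median(bg),
             p = p, expr = list(vals), background = list(bg))
    })
    res
  }) -> res
  ok <- !is.na(res$p)
  res$q <- NA_real_
  res$q[ok] <- bh_adjust(res$p[ok])
  select(res, "combination", "n", "median_expr", "median_background",
         "p", "q", "expr", "background")
}
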