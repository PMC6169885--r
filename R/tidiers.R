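# broom-style tidiers for the package's fitted objects.

#' Tidy a permutation test
#'
#' @param x a `perm_test`.
#' @param ... unused.
#' @return one-row tibble `observed`, `null_mean`, `fold_enrichment`,
#'   `p_emp`, `n_perm`, `alternative`.
#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble(observed = x$observed, null_mean = mean(x$null_values),
         fold_enrichment = x$fold_enrichment, p_emp = x$p_emp,
         n_perm = x$n_perm, alternative = x$alternative)
}

#' @rdname tidy.perm_test
#' @method glance perm_test
#' @export
glance.perm_test <- function(x, ...) tidy(x)

#' Tidy an empirical-Bayes variance prior
#'
#' @param x an `ebayes_prior`.
#' @param ... unused.
#' @return one-row tibble `d0`, `s0_sq`.
#' @method tidy ebayes_prior
#' @export
tidy.ebayes_prior <- function(x, ...) tibble(d0 = x$d0, s0_sq = x$s0_sq)

#' @rdname tidy.ebayes_prior
#' @method glance ebayes_prior
#' @export
glance.ebayes_prior <- function(x, ...) tidy(x)

#' Tidy a genome annotation into a feature table
#'
#' @param x a `genome_annotation`.
#' @param ... unused.
#' @return tibble of gene, transcript and exon features.
#' @method tidy genome_annotation
#' @export
tidy.genome_annotation <- function(x, ...) {
  bind_rows(
    mutate(x$genes, type = "gene", feature_id = .data$gene_id),
    mutate(x$transcripts, type = "transcript", feature_id = .data$transcript_id),
    mutate(x$exons, type = "exon", feature_id = NA_character_)
  ) %>%
    select("feature_id", "type", dplyr::everything())
}

#' @rdname tidy.genome_annotation
#' @method glance genome_annotation
#' @export
glance.genome_annotation <- function(x, ...) {
  tibble(n_contigs = length(x$contig_lengths),
         genome_bp = sum(x$contig_lengths),
         n_genes = nrow(x$genes), n_transcripts = nrow(x$transcripts),
         n_exons = nrow(x$exons))
}
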