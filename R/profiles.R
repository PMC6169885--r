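# TSS metagene profiles and threefold gene marking.

#' Average enrichment around transcription start sites
#'
#' For every TSS in the annotation, windows whose midpoints fall within
#' `flank` bp are collected; their signed offsets (window midpoint minus TSS,
#' flipped on minus-strand transcripts so negative always means upstream of
#' transcription) are binned at the grid spacing and the mean enrichment per
#' bin is returned per sample. Replicate profiles are kept separate so
#' replicate agreement can be inspected; average over replicates downstream if
#' a single curve per mark is wanted.
#'
#' @param enrichment enrichment tibble from [chip_enrichment()].
#' @param annotation a `genome_annotation`.
#' @param flank half-width of the profiled region in bp (default 2000).
#' @return tibble `offset` (bin center, bp), `sample`, `condition`, `mark`,
#'   `nc` (mean enrichment), `n` (windows averaged).
#' @export
tss_metagene_profile <- function(enrichment, annotation, flank = 2000) {
  samples <- attr(enrichment, "samples")
  spacing <- attr(enrichment, "spacing") %||% 50
  tss <- ann_tss(annotation)
  if (nrow(tss) == 0) abort("annotation contains no transcripts")

  mid <- (enrichment$start + enrichment$end) / 2
  win_gr <- GenomicRanges::GRanges(enrichment$contig,
                                   IRanges::IRanges(mid + 1, mid + 1))
  tss_gr <- GenomicRanges::GRanges(tss$contig,
                                   IRanges::IRanges(pmax(1, tss$pos + 1 - flank),
                                                    tss$pos + 1 + flank))
  hits <- GenomicRanges::findOverlaps(tss_gr, win_gr)
  ti <- S4Vectors::queryHits(hits)
  wi <- S4Vectors::subjectHits(hits)
  off <- mid[wi] - tss$pos[ti]
  off <- ifelse(tss$strand[ti] == "-", -off, off)
  bin <- floor(off / spacing) * spacing + spacing / 2

  nc_cols <- samples$sample
  long <- purrr::map_dfr(nc_cols, function(id) {
    tibble(offset = bin, nc = enrichment[[id]][wi], sample = id)
  })
  long %>%
    group_by(.data$sample, .data$offset) %>%
    summarise(nc = mean(.data$nc, na.rm = TRUE), n = dplyr::n(),
              .groups = "drop") %>%
    left_join(select(samples, "sample", "condition", "mark"), by = "sample") %>%
    select("offset", "sample", "condition", "mark", "nc", "n") %>%
    arrange(.data$mark, .data$sample, .data$offset)
}

#' Mark genes by threefold enrichment over input
#'
#' A gene carries a histone mark if at least one window overlapping its span
#' has a replicate-mean enrichment above `fold_threshold` (default 3, the
#' "greater than threefold over input" rule) in at least one condition.
#'
#' @param enrichment enrichment tibble from [chip_enrichment()].
#' @param annotation a `genome_annotation`.
#' @param fold_threshold enrichment cutoff (default 3).
#' @param by_condition if `TRUE`, return one row per gene/condition with a
#'   logical column per mark; the default collapses over conditions.
#' @return tibble with `gene_id` and one logical column per mark.
#' @export
mark_genes <- function(enrichment, annotation, fold_threshold = 3,
                       by_condition = FALSE) {
  samples <- attr(enrichment, "samples")
  genes <- annotation$genes
  if (nrow(genes) == 0) return(tibble(gene_id = character()))

  hits <- GenomicRanges::findOverlaps(
    as_granges0(genes), as_granges0(enrichment), minoverlap = 1L)
  gi <- S4Vectors::queryHits(hits)
  wi <- S4Vectors::subjectHits(hits)

  combos <- distinct(samples, .data$mark, .data$condition)
  marked <- purrr::pmap_dfr(combos, function(mark, condition) {
    ids <- samples$sample[samples$mark == mark & samples$condition == condition]
    m <- rowMeans(as.matrix(enrichment[, ids, drop = FALSE]))
    over <- m[wi] > fold_threshold
    tibble(gene_id = genes$gene_id[gi][over], mark = mark,
           condition = condition) %>% distinct()
  })

  all_marks <- unique(samples$mark)
  skeleton <- if (by_condition) {
    tidyr::expand_grid(gene_id = genes$gene_id,
                       condition = unique(samples$condition))
  } else {
    tibble(gene_id = genes$gene_id)
  }
  if (!by_condition) marked <- distinct(marked, .data$gene_id, .data$mark)
  marked$flag <- TRUE
  wide <- marked %>%
    tidyr::pivot_wider(names_from = "mark", values_from = "flag",
                       values_fill = FALSE)
  for (m in setdiff(all_marks, names(wide))) wide[[m]] <- FALSE
  out <- left_join(skeleton, wide,
                   by = intersect(names(skeleton), names(wide)))
  out %>% mutate(across(dplyr::all_of(all_marks), ~ !is.na(.x) & .x))
}
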