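# Genomic context of differential regions: TSS distance, exon/intron class,
# and distance-binned expression profiles.

#' Signed distance from regions to the nearest TSS
#'
#' Distance is measured from the region midpoint to the nearest transcription
#' start site over all transcripts on the same contig. The sign follows the
#' transcript's direction of transcription: negative means the region lies
#' upstream of the TSS, so minus-strand distances are flipped. Equidistant
#' ties go to the lexicographically smaller gene id.
#'
#' @param regions interval tibble (`contig`, `start`, `end`).
#' @param annotation a `genome_annotation` with at least one transcript.
#' @return `regions` with `nearest_gene`, `nearest_transcript` and
#'   `tss_distance` (bp, signed) columns added; `NA` when the region's contig
#'   has no TSS.
#' @export
distance_to_nearest_tss <- function(regions, annotation) {
  check_interval_tbl(regions, "regions")
  tss <- ann_tss(annotation)
  if (nrow(tss) == 0) abort("annotation contains no transcripts")
  mid <- (regions$start + regions$end) / 2

  pick <- function(i) {
    cand <- tss[tss$contig == regions$contig[i], , drop = FALSE]
    if (nrow(cand) == 0) {
      return(tibble(nearest_gene = NA_character_,
                    nearest_transcript = NA_character_,
                    tss_distance = NA_real_))
    }
    d_abs <- abs(mid[i] - cand$pos)
    best <- which(d_abs == min(d_abs))
    best <- best[order(cand$gene_id[best], cand$transcript_id[best])][1]
    d <- mid[i] - cand$pos[best]
    if (cand$strand[best] == "-") d <- -d
    tibble(nearest_gene = cand$gene_id[best],
           nearest_transcript = cand$transcript_id[best],
           tss_distance = d)
  }
  bind_cols(as_tibble(regions), purrr::map_dfr(seq_len(nrow(regions)), pick))
}

#' Classify regions as intergenic, exonic or intronic
#'
#' A region overlapping no gene span is intergenic. Otherwise the intragenic
#' bases are split into exonic (overlap with any exon) and intronic; the
#' majority wins, with exonic winning exact ties.
#'
#' @param regions interval tibble.
#' @param annotation a `genome_annotation` with exon structure.
#' @return `regions` with `location_class` plus the base tallies
#'   `bases_exonic` and `bases_intronic` added.
#' @export
classify_regions <- function(regions, annotation) {
  check_interval_tbl(regions, "regions")
  out <- as_tibble(regions)
  if (nrow(out) == 0) {
    out$location_class <- character()
    out$bases_exonic <- integer()
    out$bases_intronic <- integer()
    return(out)
  }
  reg_gr <- as_granges0(out)
  GenomicRanges::strand(reg_gr) <- "*"
  gene_gr <- GenomicRanges::reduce(as_granges0(annotation$genes),
                                   ignore.strand = TRUE)
  exon_gr <- GenomicRanges::reduce(as_granges0(annotation$exons),
                                   ignore.strand = TRUE)

  overlap_bases <- function(query, subject) {
    if (length(subject) == 0) return(integer(length(query)))
    ov <- GenomicRanges::findOverlaps(query, subject)
    w <- GenomicRanges::width(IRanges::pintersect(
      query[S4Vectors::queryHits(ov)], subject[S4Vectors::subjectHits(ov)]))
    as.integer(tapply(w, factor(S4Vectors::queryHits(ov),
                                levels = seq_along(query)), sum,
                      default = 0L))
  }
  genic <- overlap_bases(reg_gr, gene_gr)
  # exonic bases counted only where they fall inside gene spans
  exonic <- overlap_bases(reg_gr, GenomicRanges::intersect(exon_gr, gene_gr,
                                                           ignore.strand = TRUE))
  intronic <- genic - exonic
  out$location_class <- dplyr::case_when(
    genic == 0 ~ "intergenic",
    exonic >= intronic ~ "exonic",
    TRUE ~ "intronic"
  )
  out$bases_exonic <- exonic
  out$bases_intronic <- pmax(intronic, 0L)
  out
}

#' Mean expression by distance from the nearest region
#'
#' Assigns every gene its distance to the nearest region (gene span to region
#' midpoint; zero when a region midpoint falls inside the gene), bins genes by
#' that distance and returns the mean gene-level expression per bin. Genes
#' farther than `max_distance` collect in a single overflow bin. Distances are
#' binned by region midpoint.
#'
#' @param regions interval tibble (at least one row).
#' @param annotation a `genome_annotation`.
#' @param expression expression tibble (`transcript_id`, `gene_id`, sample
#'   columns); gene expression is the mean log2 abundance over transcripts and
#'   samples.
#' @param bin_width bin width in bp (default 10000).
#' @param max_distance distances at or beyond this collapse into the overflow
#'   bin (default 20 bins).
#' @return tibble `bin_start`, `bin_end` (`Inf` for overflow), `mean_expr`, `n`.
#' @export
distance_expression_profile <- function(regions, annotation, expression,
                                        bin_width = 10000,
                                        max_distance = 20 * bin_width) {
  check_interval_tbl(regions, "regions")
  if (nrow(regions) == 0) abort("`regions` must contain at least one region")
  genes <- annotation$genes
  sample_cols <- setdiff(names(expression),
                         c("transcript_id", "gene_id"))
  gene_expr <- expression %>%
    mutate(expr = rowMeans(across(dplyr::all_of(sample_cols)))) %>%
    group_by(.data$gene_id) %>%
    summarise(expr = mean(.data$expr), .groups = "drop")

  mid <- floor((regions$start + regions$end) / 2)
  mid_gr <- GenomicRanges::GRanges(regions$contig,
                                   IRanges::IRanges(mid + 1, mid + 1))
  gene_gr <- as_granges0(genes)
  GenomicRanges::strand(gene_gr) <- "*"
  near <- GenomicRanges::distanceToNearest(gene_gr, mid_gr)
  dist <- rep(NA_real_, nrow(genes))
  dist[S4Vectors::queryHits(near)] <- S4Vectors::mcols(near)$distance

  tb <- tibble(gene_id = genes$gene_id, dist = dist) %>%
    filter(!is.na(.data$dist)) %>%
    left_join(gene_expr, by = "gene_id") %>%
    mutate(
      bin_start = if_else(.data$dist >= max_distance, max_distance,
                          floor(.data$dist / bin_width) * bin_width),
      bin_end = if_else(.data$dist >= max_distance, Inf,
                        .data$bin_start + bin_width)
    )
  tb %>%
    group_by(.data$bin_start, .data$bin_end) %>%
    summarise(mean_expr = mean(.data$expr), n = dplyr::n(), .groups = "drop") %>%
    arrange(.data$bin_start)
}
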