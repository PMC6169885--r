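# Gene-model container and GFF3 I/O.
#
# An annotation is a plain list of tibbles (genes, transcripts, exons) plus
# the contig lengths, class "genome_annotation". All coordinates 0-based
# half-open; GFF3's 1-based closed convention is converted at the boundary by
# rtracklayer.

#' Assemble a genome annotation object
#'
#' @param genes tibble `gene_id`, `contig`, `start`, `end`, `strand`.
#' @param transcripts tibble `transcript_id`, `gene_id`, `contig`, `start`,
#'   `end`, `strand`.
#' @param exons tibble `transcript_id`, `gene_id`, `contig`, `start`, `end`,
#'   `strand`.
#' @param contig_lengths named vector of contig lengths (bp).
#' @return a `genome_annotation` list.
#' @export
genome_annotation <- function(genes, transcripts, exons, contig_lengths) {
  check_contig_lengths(contig_lengths)
  if (nrow(genes) > 0) check_interval_tbl(genes, "genes")
  structure(
    list(genes = as_tibble(genes), transcripts = as_tibble(transcripts),
         exons = as_tibble(exons), contig_lengths = contig_lengths),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf(
    "<genome_annotation> %d contigs (%.0f bp), %d genes, %d transcripts, %d exons\n",
    length(x$contig_lengths), sum(x$contig_lengths),
    nrow(x$genes), nrow(x$transcripts), nrow(x$exons)))
  invisible(x)
}

#' Transcription start sites of an annotation
#'
#' One row per transcript; the TSS of a minus-strand transcript is the last
#' base of its span (0-based position `end - 1`).
#' @param annotation a `genome_annotation`.
#' @return tibble `transcript_id`, `gene_id`, `contig`, `pos`, `strand`.
#' @export
ann_tss <- function(annotation) {
  tx <- annotation$transcripts
  tibble(
    transcript_id = tx$transcript_id, gene_id = tx$gene_id,
    contig = tx$contig,
    pos = ifelse(tx$strand == "-", tx$end - 1L, tx$start),
    strand = tx$strand
  )
}

#' Introns of an annotation
#'
#' Gaps between consecutive exons of each transcript.
#' @param annotation a `genome_annotation`.
#' @return tibble `transcript_id`, `gene_id`, `contig`, `start`, `end`, `strand`.
#' @export
ann_introns <- function(annotation) {
  ex <- annotation$exons
  if (nrow(ex) == 0) {
    return(tibble(transcript_id = character(), gene_id = character(),
                  contig = character(), start = integer(), end = integer(),
                  strand = character()))
  }
  ex %>%
    arrange(.data$transcript_id, .data$start) %>%
    group_by(.data$transcript_id, .data$gene_id, .data$contig, .data$strand) %>%
    dplyr::reframe(intron_start = head(.data$end, -1),
                   intron_end = tail(.data$start, -1)) %>%
    filter(.data$intron_end > .data$intron_start) %>%
    select("transcript_id", "gene_id", "contig",
           start = "intron_start", end = "intron_end", "strand")
}

#' Write an annotation as GFF3
#'
#' @param annotation a `genome_annotation`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  feats <- bind_rows(
    annotation$genes %>%
      mutate(type = "gene", ID = .data$gene_id, Parent = NA_character_),
    annotation$transcripts %>%
      mutate(type = "mRNA", ID = .data$transcript_id, Parent = .data$gene_id),
    annotation$exons %>%
      group_by(.data$transcript_id) %>%
      mutate(ID = paste0(.data$transcript_id, ".e", row_number())) %>%
      ungroup() %>%
      mutate(type = "exon", Parent = .data$transcript_id)
  )
  gr <- as_granges0(feats, annotation$contig_lengths)
  S4Vectors::mcols(gr)$type <- feats$type
  S4Vectors::mcols(gr)$ID <- feats$ID
  S4Vectors::mcols(gr)$Parent <- feats$Parent
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 annotation
#'
#' Gene/mRNA/exon features are assembled into a [genome_annotation()];
#' coordinates are converted to the package's 0-based half-open convention.
#' Contig lengths are taken from `##sequence-region` directives when present,
#' otherwise from the rightmost feature per contig.
#'
#' @param path GFF3 file.
#' @param contig_lengths optional named vector overriding lengths from the file.
#' @return a `genome_annotation`.
#' @export
read_annotation_gff3 <- function(path, contig_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  tb <- granges_to_tbl(gr)
  tb$type <- as.character(S4Vectors::mcols(gr)$type)
  tb$ID <- as.character(S4Vectors::mcols(gr)$ID)
  parent <- S4Vectors::mcols(gr)$Parent
  tb$Parent <- vapply(as.list(parent), function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))

  genes <- tb %>% filter(.data$type == "gene") %>%
    mutate(gene_id = .data$ID) %>%
    select("gene_id", "contig", "start", "end", "strand")
  tx <- tb %>% filter(.data$type %in% c("mRNA", "transcript")) %>%
    mutate(transcript_id = .data$ID, gene_id = .data$Parent) %>%
    select("transcript_id", "gene_id", "contig", "start", "end", "strand")
  exons <- tb %>% filter(.data$type == "exon") %>%
    mutate(transcript_id = .data$Parent) %>%
    left_join(select(tx, "transcript_id", "gene_id"), by = "transcript_id") %>%
    select("transcript_id", "gene_id", "contig", "start", "end", "strand")

  if (is.null(contig_lengths)) {
    sl <- GenomeInfoDb::seqlengths(gr)
    if (all(is.na(sl))) {
      sl <- tapply(tb$end, tb$contig, max)
    }
    contig_lengths <- setNames(as.numeric(sl), names(sl))
  }
  genome_annotation(genes, tx, exons, contig_lengths)
}
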