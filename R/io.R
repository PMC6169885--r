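# Standard-format I/O. BED and GFF3 go through rtracklayer (coordinates
# converted to/from the package's 0-based half-open convention), FASTA through
# Biostrings, tables through plain TSV.

#' Write reads as BED6
#'
#' One line per read: name = sample id, score = mapping quality.
#' @param reads tibble `contig`, `start`, `end`, `strand`, `mapq`, `sample`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  gr <- as_granges0(reads)
  S4Vectors::mcols(gr)$name <- reads$sample
  S4Vectors::mcols(gr)$score <- reads$mapq
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read reads from BED6
#'
#' @param path BED file with name = sample id, score = mapping quality.
#' @return tibble `contig`, `start`, `end`, `strand`, `mapq`, `sample`.
#' @export
read_reads_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- granges_to_tbl(gr)
  out$mapq <- as.integer(S4Vectors::mcols(gr)$score)
  out$sample <- as.character(S4Vectors::mcols(gr)$name)
  out
}

#' Write differential regions as BED
#'
#' Name field is `mark:direction`, score is `-10 log10(q)` capped at 1000.
#' @param regions tibble from [call_differential_regions()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  if (nrow(regions) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- as_granges0(regions)
  S4Vectors::mcols(gr)$name <- paste0(regions$mark, ":", regions$direction)
  S4Vectors::mcols(gr)$score <- pmin(1000, round(-10 * log10(pmax(regions$best_q, 1e-100))))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write contig sequences as FASTA
#' @param sequences named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read contig sequences from FASTA
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @noRd
write_tsv_plain <- function(x, path) {
  x <- x[, !vapply(x, is.list, logical(1)), drop = FALSE]
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @noRd
read_tsv_plain <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE))
}
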