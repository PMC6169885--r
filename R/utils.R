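# Internal helpers shared across modules.
#
# Coordinates are 0-based half-open ([start, end)) in every tibble the package
# exposes, matching BED. GRanges (1-based closed) are used only transiently for
# interval arithmetic; these two helpers are the single conversion point.

#' Convert an interval tibble to GRanges
#'
#' @param x tibble with columns `contig`, `start`, `end` (0-based half-open)
#'   and optionally `strand`.
#' @param contig_lengths optional named vector of contig lengths (bp) used to
#'   set seqlengths.
#' @return a `GRanges` (1-based closed coordinates).
#' @keywords internal
#' @noRd
as_granges0 <- function(x, contig_lengths = NULL) {
  strand <- if ("strand" %in% names(x)) {
    s <- as.character(x$strand)
    s[!s %in% c("+", "-")] <- "*"
    s
  } else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(x$contig),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
  if (!is.null(contig_lengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(contig_lengths)
    GenomeInfoDb::seqlengths(gr) <- unname(contig_lengths)
  }
  gr
}

#' @noRd
granges_to_tbl <- function(gr) {
  tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Derive a reproducible per-component seed from a master seed
#'
#' Each stochastic stage draws from its own stream so that adding a stage never
#' perturbs the draws of another. Streams are derived by hashing the stage name
#' onto the master seed; the result stays inside the 32-bit integer range.
#' @noRd
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483587)
}

#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' @noRd
check_interval_tbl <- function(x, what = "intervals") {
  need <- c("contig", "start", "end")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    abort(sprintf("`%s` must be a data frame with columns contig, start, end", what))
  }
  if (nrow(x) > 0 && any(x$start < 0 | x$end <= x$start)) {
    abort(sprintf("`%s` must satisfy 0 <= start < end", what))
  }
  invisible(x)
}

#' @noRd
check_contig_lengths <- function(contig_lengths) {
  if (is.null(names(contig_lengths)) || any(names(contig_lengths) == "") ||
      anyDuplicated(names(contig_lengths)) || any(contig_lengths <= 0)) {
    abort("`contig_lengths` must be a named vector of positive lengths with unique names")
  }
  invisible(contig_lengths)
}
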