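#' Tile contigs into overlapping windows
#'
#' Builds the sliding-window grid the whole chromatin analysis operates on:
#' windows of `width` bp every `spacing` bp, starting at position 0 of each
#' contig. With the defaults (width 100, spacing 50) each interior window
#' overlaps exactly two other windows. A final window that would extend past
#' the contig end is dropped, so every window has full width.
#'
#' @param contig_lengths named numeric vector of contig lengths in bp.
#' @param width window width in bp (default 100).
#' @param spacing distance between consecutive window starts in bp
#'   (default 50). A spacing larger than the width leaves uncovered gaps and
#'   triggers a warning.
#'
#' @return A tibble with columns `window_id`, `contig`, `start`, `end`
#'   (0-based half-open), ordered by contig then start.
#' @examples
#' tile_windows(c(chr1 = 200))
#' @export
tile_windows <- function(contig_lengths, width = 100, spacing = 50) {
  check_contig_lengths(contig_lengths)
  if (width <= 0 || spacing <= 0) abort("`width` and `spacing` must be positive")
  if (spacing > width) warn("spacing > width leaves gaps between windows")
  width <- as.integer(width)
  spacing <- as.integer(spacing)
  per_contig <- purrr::map2(names(contig_lengths), as.numeric(contig_lengths),
    function(ctg, len) {
      n <- if (len >= width) floor((len - width) / spacing) + 1 else 0
      if (n == 0) return(NULL)
      start <- as.integer(seq(0L, by = spacing, length.out = n))
      tibble(contig = ctg, start = start, end = start + width)
    })
  out <- bind_rows(per_contig)
  if (nrow(out) == 0) {
    return(tibble(window_id = integer(), contig = character(),
                  start = integer(), end = integer()))
  }
  out <- mutate(out, window_id = row_number(), .before = 1)
  attr(out, "width") <- width
  attr(out, "spacing") <- spacing
  attr(out, "contig_lengths") <- contig_lengths
  out
}

#' Symmetrically expand windows for input counting
#'
#' Input (background) coverage is counted in windows symmetrically expanded to
#' `target_width` bp (default 5000, i.e. +-2450 bp around a 100-bp window) so
#' the background rate is estimated from a broad local neighbourhood. Windows
#' whose expansion would cross a contig boundary cannot be expanded and are
#' flagged `removed`; downstream they are excluded from the enrichment matrix.
#'
#' @param windows window tibble from [tile_windows()].
#' @param target_width expanded width in bp (default 5000); must be at least
#'   the window width.
#' @param contig_lengths named vector of contig lengths; defaults to the
#'   attribute stored by [tile_windows()].
#'
#' @return The input tibble with `exp_start`, `exp_end` and logical `removed`
#'   columns added. Removed windows have `NA` expanded coordinates.
#' @export
expand_windows <- function(windows, target_width = 5000, contig_lengths = NULL) {
  check_interval_tbl(windows, "windows")
  contig_lengths <- contig_lengths %||% attr(windows, "contig_lengths")
  check_contig_lengths(contig_lengths)
  w <- windows$end - windows$start
  if (any(target_width < w)) abort("`target_width` must be >= window width")
  flank <- (target_width - w) / 2
  exp_start <- windows$start - floor(flank)
  exp_end <- windows$end + ceiling(flank)
  len <- unname(contig_lengths[windows$contig])
  removed <- exp_start < 0 | exp_end > len
  out <- mutate(windows,
    exp_start = ifelse(removed, NA_real_, exp_start),
    exp_end = ifelse(removed, NA_real_, exp_end),
    removed = removed
  )
  attr(out, "contig_lengths") <- contig_lengths
  out
}

#' Extend reads from their 5' ends
#'
#' Single-end reads are extended to `extension` bp from the 5' end in the
#' direction of the strand (the fragment-length surrogate), truncated at
#' contig edges.
#' @noRd
extend_reads <- function(reads, extension, contig_lengths) {
  len <- unname(contig_lengths[reads$contig])
  minus <- reads$strand == "-"
  start <- ifelse(minus, reads$end - extension, reads$start)
  end <- ifelse(minus, reads$end, reads$start + extension)
  tibble(contig = reads$contig,
         start = pmax(0, start),
         end = pmin(len, end))
}

#' Count extended reads into windows
#'
#' Reads with mapping quality below `mapq_min` are discarded; duplicates (reads
#' at identical positions) are kept. Each retained read is extended to
#' `extension` bp from its 5' end in the strand direction, and increments every
#' window its extended interval overlaps by at least one base -- with an
#' overlapping tiling a single read is counted in several windows by design.
#'
#' @param reads tibble with columns `contig`, `start`, `end` (0-based
#'   half-open), `strand` (`+`/`-`), `mapq`. Rows with missing coordinates are
#'   skipped and their number reported as the `n_skipped` attribute.
#' @param windows window tibble from [tile_windows()] (or the expanded
#'   coordinates of [expand_windows()] when `use_expanded = TRUE`).
#' @param extension read extension length in bp (default 250).
#' @param mapq_min minimum mapping quality (default 20); reads strictly below
#'   it are not counted.
#' @param contig_lengths named contig lengths; defaults to the grid attribute.
#' @param use_expanded count into the `exp_start`/`exp_end` coordinates
#'   (input-style counting). Removed windows get `NA` counts.
#'
#' @return tibble `window_id`, `count`, with attributes `n_total` (number of
#'   retained reads, the library-size denominator of the enrichment equation)
#'   and `n_skipped`.
#' @export
count_reads <- function(reads, windows, extension = 250, mapq_min = 20,
                        contig_lengths = NULL, use_expanded = FALSE) {
  contig_lengths <- contig_lengths %||% attr(windows, "contig_lengths")
  check_contig_lengths(contig_lengths)
  bad <- !complete.cases(reads[, c("contig", "start", "end")]) |
    reads$end <= reads$start
  n_skipped <- sum(bad)
  reads <- reads[!bad, , drop = FALSE]
  keep <- reads$mapq >= mapq_min
  reads <- reads[keep, , drop = FALSE]
  n_total <- nrow(reads)

  if (use_expanded) {
    if (!all(c("exp_start", "exp_end", "removed") %in% names(windows))) {
      abort("`use_expanded = TRUE` needs windows from expand_windows()")
    }
    tgt <- windows[!windows$removed, c("contig", "exp_start", "exp_end")]
    names(tgt) <- c("contig", "start", "end")
    ids <- windows$window_id[!windows$removed]
  } else {
    tgt <- windows[, c("contig", "start", "end")]
    ids <- windows$window_id
  }

  counts <- rep(NA_integer_, nrow(windows))
  if (nrow(tgt) > 0) {
    if (n_total > 0) {
      ext <- extend_reads(reads, extension, contig_lengths)
      ext <- ext[ext$end > ext$start, , drop = FALSE]
      hits <- GenomicRanges::countOverlaps(
        as_granges0(tgt), as_granges0(ext), minoverlap = 1L
      )
    } else {
      hits <- integer(nrow(tgt))
    }
    counts[match(ids, windows$window_id)] <- hits
  }
  out <- tibble(window_id = windows$window_id, count = counts)
  attr(out, "n_total") <- n_total
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Normalize ChIP window counts to input
#'
#' The normalized enrichment of window i is the ChIP count rate divided by the
#' input (background) count rate:
#' \deqn{NC_i = \frac{C_i \, N_b}{C_b \, N_i}}
#' where \eqn{C_i} is the window count in the ChIP sample, \eqn{N_i} its total
#' retained reads, \eqn{C_b} the count in the expanded input window and
#' \eqn{N_b} the input's total reads. NC is invariant to rescaling all four
#' quantities by a common factor. Zero input counts are replaced by
#' `pseudocount` so enrichment stays finite while the ordering of windows is
#' preserved.
#'
#' @param c_i,n_i ChIP window counts and total ChIP reads.
#' @param c_b,n_b input window counts and total input reads.
#' @param pseudocount value substituted for zero `c_b` (default 0.5).
#' @return numeric vector of enrichments, `NA` where `c_b` is `NA`.
#' @examples
#' normalize_to_input(30, 1e6, 10, 1e6) # 3.0
#' @export
normalize_to_input <- function(c_i, n_i, c_b, n_b, pseudocount = 0.5) {
  if (any(n_i <= 0) || any(n_b <= 0)) abort("library sizes must be positive")
  if (any(c_i < 0, na.rm = TRUE) || any(c_b < 0, na.rm = TRUE)) {
    abort("counts must be non-negative")
  }
  c_b <- ifelse(!is.na(c_b) & c_b == 0, pseudocount, c_b)
  (c_i * n_b) / (c_b * n_i)
}

#' Build the per-window, per-sample enrichment matrix
#'
#' Runs the full counting/normalization chain: ChIP reads counted into the
#' window grid, input reads counted into the same windows expanded to
#' `input_width` bp, and each ChIP sample normalized to its condition's input
#' by the enrichment equation (see [normalize_to_input()]). Windows that could
#' not be expanded are removed from the matrix; their ids are kept in the
#' `removed` attribute so row bookkeeping stays auditable.
#'
#' @param reads tibble of aligned reads with columns `contig`, `start`, `end`,
#'   `strand`, `mapq`, `sample`.
#' @param samples sample sheet: tibble with `sample`, `condition`, `mark`
#'   (`"input"` marks background samples). Each ChIP sample is normalized to
#'   the input of its own condition, or to the single input if only one exists.
#' @param windows grid from [tile_windows()].
#' @param extension,mapq_min see [count_reads()].
#' @param input_width expanded width for input counting (default 5000).
#' @param width_normalize rescale the expanded input count to the window's
#'   effective footprint (`(width + extension - 1) / (input_width + extension
#'   - 1)`) before the enrichment equation, so an unenriched window has
#'   enrichment near 1 and "threefold over input" means what it says
#'   (default `TRUE`). With `FALSE` the raw expanded count enters the
#'   equation unscaled.
#' @param pseudocount zero-input replacement (default 0.5).
#' @param contig_lengths named contig lengths; defaults to the grid attribute.
#'
#' @return tibble with `window_id`, `contig`, `start`, `end` and one `NC`
#'   column per ChIP sample (named by sample id). Attributes: `samples` (sample
#'   sheet restricted to ChIP samples), `n_reads` (named library sizes incl.
#'   inputs), `removed` (window ids dropped), `counts` (raw ChIP count matrix).
#' @export
chip_enrichment <- function(reads, samples, windows,
                            extension = 250, mapq_min = 20,
                            input_width = 5000, width_normalize = TRUE,
                            pseudocount = 0.5, contig_lengths = NULL) {
  contig_lengths <- contig_lengths %||% attr(windows, "contig_lengths")
  check_contig_lengths(contig_lengths)
  stopifnot(all(c("sample", "condition", "mark") %in% names(samples)))
  input_samples <- samples$sample[samples$mark == "input"]
  chip_samples <- samples$sample[samples$mark != "input"]
  if (length(input_samples) == 0) abort("no input sample in `samples`")

  exp_w <- expand_windows(windows, input_width, contig_lengths)
  keep <- !exp_w$removed
  width <- attr(windows, "width") %||% round(mean(windows$end - windows$start))
  span_ratio <- if (width_normalize) {
    (width + extension - 1) / (input_width + extension - 1)
  } else 1

  count_one <- function(id, expanded) {
    count_reads(reads[reads$sample == id, , drop = FALSE],
                if (expanded) exp_w else windows,
                extension = extension, mapq_min = mapq_min,
                contig_lengths = contig_lengths, use_expanded = expanded)
  }
  chip_counts <- lapply(setNames(chip_samples, chip_samples), count_one,
                        expanded = FALSE)
  input_counts <- lapply(setNames(input_samples, input_samples), count_one,
                         expanded = TRUE)
  n_reads <- vapply(c(chip_counts, input_counts), attr, numeric(1), "n_total")

  pick_input <- function(chip_id) {
    cond <- samples$condition[samples$sample == chip_id]
    cand <- samples$sample[samples$mark == "input" & samples$condition == cond]
    if (length(cand) == 0) cand <- input_samples
    cand[1]
  }

  out <- windows[keep, c("window_id", "contig", "start", "end")]
  count_mat <- matrix(NA_integer_, nrow = sum(keep), ncol = length(chip_samples),
                      dimnames = list(NULL, chip_samples))
  for (id in chip_samples) {
    inp <- pick_input(id)
    ci <- chip_counts[[id]]$count[keep]
    cb <- input_counts[[inp]]$count[keep] * span_ratio
    count_mat[, id] <- ci
    out[[id]] <- normalize_to_input(ci, n_reads[[id]], cb, n_reads[[inp]],
                                    pseudocount = pseudocount)
  }
  attr(out, "samples") <- samples[samples$mark != "input", , drop = FALSE]
  attr(out, "n_reads") <- n_reads
  attr(out, "removed") <- windows$window_id[!keep]
  attr(out, "counts") <- count_mat
  attr(out, "width") <- attr(windows, "width")
  attr(out, "spacing") <- attr(windows, "spacing")
  attr(out, "contig_lengths") <- contig_lengths
  out
}
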