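# PWM scanning and central motif enrichment on peak-centered windows.
#
# Peaks are first replaced by fixed-width windows (default 5 kbp) centered on
# the peak midpoint; the best log-odds site per window is located on both
# strands; central enrichment asks whether best sites concentrate near offset
# 0 more than a uniform placement would allow (binomial test over a ladder of
# central half-widths, Bonferroni-corrected for the ladder).

#' Construct a position weight matrix
#'
#' @param id motif identifier.
#' @param mat numeric matrix, positions x 4, columns A, C, G, T; rows must sum
#'   to 1. Zero probabilities are floored at 1e-3 and rows renormalized so
#'   log-odds scores stay finite.
#' @param background length-4 base frequencies (default uniform).
#' @return a `pwm` object.
#' @export
pwm <- function(id, mat, background = rep(0.25, 4)) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4) abort("`mat` must have 4 columns (A, C, G, T)")
  if (any(abs(rowSums(mat) - 1) > 1e-6)) abort("PWM rows must sum to 1")
  if (abs(sum(background) - 1) > 1e-6) abort("background must sum to 1")
  mat[mat < 1e-3] <- 1e-3
  mat <- mat / rowSums(mat)
  colnames(mat) <- c("A", "C", "G", "T")
  structure(list(id = id, mat = mat, background = setNames(background, colnames(mat))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, width %d, consensus %s\n",
              x$id, nrow(x$mat), pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM
#' @param x a `pwm`.
#' @return character scalar.
#' @export
pwm_consensus <- function(x) {
  paste(colnames(x$mat)[apply(x$mat, 1, which.max)], collapse = "")
}

#' Reverse complement of a PWM
#' @noRd
pwm_revcomp <- function(x) {
  m <- x$mat[rev(seq_len(nrow(x$mat))), c("T", "G", "C", "A"), drop = FALSE]
  colnames(m) <- c("A", "C", "G", "T")
  pwm(x$id, m, x$background)
}

#' Read motifs in MEME minimal format
#'
#' Parses the minimal motif text format (MEME version header, optional
#' background line, `MOTIF` blocks with letter-probability matrices).
#'
#' @param path motif file.
#' @return named list of `pwm` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    toks <- strsplit(trimws(lines[bg_i[1] + 1]), "\\s+")[[1]]
    vals <- as.numeric(toks[seq(2, length(toks), by = 2)])
    if (length(vals) == 4 && !any(is.na(vals))) bg <- vals
  }
  motif_i <- grep("^MOTIF", lines)
  out <- list()
  for (mi in motif_i) {
    id <- strsplit(trimws(lines[mi]), "\\s+")[[1]][2]
    li <- grep("^letter-probability matrix", lines[mi:length(lines)])[1] + mi - 1
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[li]))
    rows <- lines[(li + 1):(li + w)]
    mat <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
    out[[id]] <- pwm(id, mat, bg)
  }
  out
}

#' Write motifs in MEME minimal format
#'
#' @param pwms a `pwm` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       nrow(p$mat)), con)
    writeLines(apply(p$mat, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")),
               con)
    writeLines("", con)
  }
  invisible(path)
}

#' Replace peaks by fixed-width midpoint-centered windows
#'
#' @param peaks interval tibble.
#' @param total_width width of the centered window in bp (default 5000).
#' @param contig_lengths named contig lengths; peaks whose centered window
#'   would cross a contig boundary are dropped (their count is kept in the
#'   `n_dropped` attribute).
#' @return tibble `contig`, `start`, `end`, `peak_id` of fixed-width windows.
#' @export
extend_peaks <- function(peaks, total_width = 5000, contig_lengths) {
  check_interval_tbl(peaks, "peaks")
  check_contig_lengths(contig_lengths)
  mid <- floor((peaks$start + peaks$end) / 2)
  start <- mid - floor(total_width / 2)
  end <- start + total_width
  keep <- start >= 0 & end <= unname(contig_lengths[peaks$contig])
  out <- tibble(contig = peaks$contig[keep], start = start[keep],
                end = end[keep],
                peak_id = paste0("peak_", which(keep)))
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "total_width") <- total_width
  out
}

#' @noRd
encode_bases <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
}

#' @noRd
scan_scores_one_strand <- function(idx, lo) {
  L <- nrow(lo)
  n <- length(idx) - L + 1
  if (n < 1) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(L)) {
    contrib <- unname(lo[j, ])[idx[j:(j + n - 1)]]
    contrib[is.na(contrib)] <- 0  # ambiguous base: background scores cancel
    s <- s + contrib
  }
  s
}

#' Best motif site in a sequence
#'
#' Scores every offset on both strands with the log2-odds
#' `log2(P(word | pwm) / P(word | background))` and returns the best site, or
#' no row when the best score falls below `threshold`. Ties are broken toward
#' the smallest absolute offset from the sequence center, then the + strand.
#'
#' @param seq character scalar (A/C/G/T; other letters score as background).
#' @param pwm a `pwm`.
#' @param threshold minimum score in bits (default 0).
#' @return tibble with zero or one row: `offset` (bp of the site center from
#'   the sequence center, signed), `strand`, `score`.
#' @export
scan_best_site <- function(seq, pwm, threshold = 0) {
  L <- nrow(pwm$mat)
  if (nchar(seq) < L) abort("sequence shorter than the motif")
  lo <- log2(pwm$mat / matrix(pwm$background, nrow = L, ncol = 4, byrow = TRUE))
  lo_rc <- {
    rc <- pwm_revcomp(pwm)
    log2(rc$mat / matrix(rc$background, nrow = L, ncol = 4, byrow = TRUE))
  }
  idx <- encode_bases(seq)
  fwd <- scan_scores_one_strand(idx, lo)
  rev_ <- scan_scores_one_strand(idx, lo_rc)
  n <- length(fwd)
  center <- nchar(seq) / 2
  offsets <- (seq_len(n) - 1) + L / 2 - center
  cand <- tibble(
    offset = c(offsets, offsets),
    strand = rep(c("+", "-"), each = n),
    score = c(fwd, rev_)
  )
  best_score <- max(cand$score)
  if (best_score < threshold) {
    return(tibble(offset = numeric(), strand = character(), score = numeric()))
  }
  # ties detected with a numerical tolerance: summation order must not
  # decide which of two equally scoring sites wins
  cand %>%
    filter(.data$score >= best_score - 1e-9) %>%
    arrange(abs(.data$offset), .data$strand) %>%
    slice(1) %>%
    mutate(score = best_score)
}

#' Best sites across a set of region sequences
#'
#' @param region_seqs named character vector of equal-width region sequences
#'   (e.g. extracted under [extend_peaks()] windows).
#' @param pwm a `pwm`.
#' @param threshold minimum score in bits (default 0).
#' @return tibble `region`, `offset`, `strand`, `score`; regions without a
#'   qualifying site are absent (total region count in attribute `n_regions`).
#' @export
scan_regions <- function(region_seqs, pwm, threshold = 0) {
  out <- purrr::imap_dfr(region_seqs, function(s, nm) {
    h <- scan_best_site(s, pwm, threshold)
    if (nrow(h) == 0) return(NULL)
    mutate(h, region = nm, .before = 1)
  })
  if (nrow(out) == 0) {
    out <- tibble(region = character(), offset = numeric(),
                  strand = character(), score = numeric())
  }
  attr(out, "n_regions") <- length(region_seqs)
  attr(out, "motif_id") <- pwm$id
  attr(out, "motif_length") <- nrow(pwm$mat)
  out
}

#' Central enrichment of best motif sites
#'
#' For each candidate central half-width w, counts best sites with
#' `|offset| <= w` and compares the count to a binomial null in which a best
#' site is equally likely at any of the possible site positions. The smallest
#' p over the ladder is reported after Bonferroni correction for the number of
#' candidates tested.
#'
#' @param hits tibble from [scan_regions()].
#' @param region_width width of the scanned regions in bp.
#' @param motif_length motif width in bp (default taken from `hits`).
#' @param n_regions number of scanned regions (default from `hits`).
#' @param half_widths candidate central half-widths in bp.
#' @return one-row tibble `motif`, `best_half_width`, `n_central`, `n_hits`,
#'   `p`, `p_adj`, `fraction_central`; the per-candidate table is attached as
#'   attribute `ladder`.
#' @export
central_enrichment <- function(hits, region_width,
                               motif_length = attr(hits, "motif_length"),
                               n_regions = attr(hits, "n_regions"),
                               half_widths = c(50, 100, 250, 500, 1000, 2450)) {
  if (nrow(hits) == 0) {
    return(tibble(motif = attr(hits, "motif_id") %||% NA_character_,
                  best_half_width = NA_real_, n_central = NA_integer_,
                  n_hits = 0L, p = NA_real_, p_adj = NA_real_,
                  fraction_central = NA_real_))
  }
  if (nrow(hits) < 10) {
    warn("fewer than 10 regions with hits; central enrichment is unreliable")
  }
  n_pos <- region_width - motif_length + 1
  ladder <- purrr::map_dfr(half_widths, function(w) {
    k <- sum(abs(hits$offset) <= w)
    pr <- min(2 * w + 1, n_pos) / n_pos
    tibble(half_width = w, n_central = k, prob = pr,
           p = pbinom(k - 1, nrow(hits), pr, lower.tail = FALSE))
  })
  best <- ladder[which.min(ladder$p), ]
  out <- tibble(
    motif = attr(hits, "motif_id") %||% NA_character_,
    best_half_width = best$half_width,
    n_central = best$n_central,
    n_hits = nrow(hits),
    p = best$p,
    p_adj = min(1, best$p * length(half_widths)),
    fraction_central = best$n_central / n_regions
  )
  attr(out, "ladder") <- ladder
  out
}

#' Motif probability curve around region centers
#'
#' Fraction of regions whose best site center falls in each signed-offset bin.
#' Regions without a qualifying site contribute to the denominator only, so
#' the curve sums to the fraction of regions with a hit.
#'
#' @param hits tibble from [scan_regions()].
#' @param region_width width of the scanned regions in bp (sets the bin grid).
#' @param n_regions number of scanned regions (default from `hits`).
#' @param bin_width bin width in bp (default 100).
#' @return tibble `offset` (bin center, bp), `probability`, `n`.
#' @export
motif_probability_curve <- function(hits, region_width,
                                    n_regions = attr(hits, "n_regions"),
                                    bin_width = 100) {
  half <- region_width / 2
  breaks <- seq(-half, half, by = bin_width)
  centers <- head(breaks, -1) + bin_width / 2
  counts <- integer(length(centers))
  if (nrow(hits) > 0) {
    b <- findInterval(hits$offset, breaks, rightmost.closed = TRUE)
    b <- b[b >= 1 & b <= length(centers)]
    tab <- table(b)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  tibble(offset = centers, probability = counts / n_regions, n = counts)
}
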