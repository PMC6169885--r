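# PWM construction, MEME round trip, scanning, central enrichment, curves.

test_that("pwm validates and floors zero probabilities", {
  mat <- matrix(c(1, 0, 0, 0,
                  0, 0, 0, 1), nrow = 2, byrow = TRUE)
  p <- pwm("toy", mat)
  expect_s3_class(p, "pwm")
  expect_true(all(p$mat > 0))
  expect_equal(rowSums(p$mat), c(1, 1))
  expect_equal(pwm_consensus(p), "AT")
  expect_error(pwm("bad", matrix(0.3, 2, 4)), "sum to 1")
})

test_that("MEME minimal format round-trips", {
  p <- default_motif()
  tmp <- tempfile(fileext = ".meme")
  write_meme(p, tmp)
  back <- read_meme(tmp)
  expect_equal(names(back), p$id)
  expect_equal(back[[1]]$mat, p$mat, tolerance = 1e-5)
})

test_that("consensus scores 2 bits per position against uniform background", {
  mat <- matrix(0, 6, 4); colnames(mat) <- c("A", "C", "G", "T")
  cons <- c(1, 3, 2, 4, 1, 2)  # ACGTAC... indices into ACGT
  for (i in 1:6) mat[i, cons[i]] <- 1
  p <- pwm("sharp", mat)
  seqchars <- c("A", "C", "G", "T")[cons]
  flank <- strrep("A", 20)
  s <- paste0(flank, paste(seqchars, collapse = ""), flank)
  hit <- scan_best_site(s, p)
  # probabilities floored at 1e-3 then renormalized, so per-position bits are
  # log2(p_max/0.25) rather than exactly 2
  expect_equal(hit$score, 6 * log2((1 - 3e-3) / 0.25), tolerance = 0.02)
  expect_equal(hit$strand, "+")
})

test_that("scanning is strand symmetric", {
  p <- default_motif()
  set.seed(61)
  s <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  h1 <- scan_best_site(s, p, threshold = -Inf)
  h2 <- scan_best_site(rc, p, threshold = -Inf)
  expect_equal(h1$score, h2$score, tolerance = 1e-9)
})

test_that("best site matches a brute-force scan oracle", {
  p <- default_motif()
  L <- nrow(p$mat)
  lo <- log2(p$mat / 0.25)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  brute_best <- function(s) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch) - L + 1
    best <- -Inf; best_off <- NA; best_strand <- NA
    for (i in seq_len(n)) {
      word <- ch[i:(i + L - 1)]
      sc_f <- sum(vapply(seq_len(L), function(j) lo[j, word[j]], numeric(1)))
      word_rc <- rev(unname(comp[word]))
      sc_r <- sum(vapply(seq_len(L), function(j) lo[j, word_rc[j]], numeric(1)))
      for (sc in list(c(sc_f, 1), c(sc_r, 2))) {
        off <- (i - 1) + L / 2 - nchar(s) / 2
        better <- sc[1] > best + 1e-12 ||
          (abs(sc[1] - best) <= 1e-12 && abs(off) < abs(best_off) - 1e-12)
        if (better) {
          best <- sc[1]; best_off <- off
          best_strand <- c("+", "-")[sc[2]]
        }
      }
    }
    list(score = best, offset = best_off)
  }
  set.seed(62)
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    got <- scan_best_site(s, p, threshold = -Inf)
    want <- brute_best(s)
    expect_equal(got$score, want$score, tolerance = 1e-9)
    expect_equal(abs(got$offset), abs(want$offset))
  }
})

test_that("peak extension centers fixed-width windows and drops edge peaks", {
  cl <- c(c1 = 50000)
  peaks <- tibble::tibble(contig = "c1",
                          start = c(10000L, 800L, 20000L),
                          end = c(10100L, 1200L, 20100L))
  ext <- extend_peaks(peaks, 5000, cl)
  expect_equal(nrow(ext), 2)
  expect_equal(attr(ext, "n_dropped"), 1)
  expect_equal(c(ext$start[1], ext$end[1]), c(7550, 12550))
  expect_true(all(ext$end - ext$start == 5000))
  # identity width keeps the midpoint
  same <- extend_peaks(peaks[1, ], 100, cl)
  expect_equal(c(same$start, same$end), c(10000, 10100))
})

test_that("central enrichment detects planted central sites and not uniform ones", {
  p <- default_motif()
  cons <- pwm_consensus(p)
  make_regions <- function(offsets, n = 40, width = 2000, seed = 1) {
    set.seed(seed)
    vapply(seq_len(n), function(i) {
      s <- paste(sample(c("A", "C", "G", "T"), width, TRUE), collapse = "")
      if (!is.na(offsets[i])) {
        at <- width / 2 + offsets[i] - nchar(cons) / 2
        substr(s, at + 1, at + nchar(cons)) <- cons
      }
      s
    }, character(1))
  }
  # 60% of regions carry a central site (within +-250)
  offs <- ifelse(seq_len(40) <= 24, round(runif(40, -250, 250)), NA)
  seqs <- make_regions(offs, seed = 3)
  names(seqs) <- paste0("r", 1:40)
  hits <- scan_regions(seqs, p)
  res <- central_enrichment(hits, region_width = 2000,
                            half_widths = c(50, 100, 250, 500))
  expect_lt(res$p_adj, 0.01)

  # uniform offsets: rarely significant
  sig <- vapply(1:10, function(sd) {
    set.seed(sd)
    offs <- round(runif(40, -950, 950))
    seqs <- make_regions(offs, seed = sd + 100)
    names(seqs) <- paste0("r", 1:40)
    hits <- scan_regions(seqs, p)
    central_enrichment(hits, region_width = 2000,
                       half_widths = c(50, 100, 250, 500))$p_adj < 0.05
  }, logical(1))
  expect_gte(mean(!sig), 0.9)
})

test_that("motif probability curve mass equals the hit fraction", {
  p <- default_motif()
  set.seed(71)
  seqs <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = ""),
    character(1))
  names(seqs) <- paste0("r", 1:20)
  hits <- scan_regions(seqs, p, threshold = 0)
  curve <- motif_probability_curve(hits, region_width = 1000)
  expect_equal(sum(curve$probability), nrow(hits) / 20, tolerance = 1e-12)

  # all sites at offset zero concentrate in the central bin
  cons <- pwm_consensus(p)
  central <- vapply(1:15, function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
    at <- 500 - nchar(cons) / 2
    substr(s, at + 1, at + nchar(cons)) <- cons
    s
  }, character(1))
  names(central) <- paste0("c", 1:15)
  ch <- scan_regions(central, p)
  cc <- motif_probability_curve(ch, region_width = 1000)
  expect_equal(cc$offset[which.max(cc$probability)], 50, tolerance = 100)

  # no hits: all-zero curve
  empty <- scan_regions(setNames(strrep("A", 500), "r1"), p, threshold = 50)
  zc <- motif_probability_curve(empty, region_width = 500, n_regions = 1)
  expect_true(all(zc$probability == 0))
})

test_that("bimodal planted offsets produce flanking modes", {
  cfg <- synth_config(seed = 99)
  seqs <- generate_sequences(cfg)
  regions <- tibble::tibble(contig = "ctg1",
                            start = as.integer(seq(5000, 120000, by = 5000)))
  regions$end <- regions$start + 2000L
  p <- default_motif()
  planted <- plant_motifs(seqs, regions, p, offset_law = "bimodal",
                          shift = 500, seed = 5)
  region_seqs <- vapply(seq_len(nrow(regions)), function(i)
    substr(planted$sequences[[regions$contig[i]]], regions$start[i] + 1,
           regions$end[i]), character(1))
  names(region_seqs) <- paste0("r", seq_len(nrow(regions)))
  hits <- scan_regions(region_seqs, p)
  curve <- motif_probability_curve(hits, region_width = 2000, bin_width = 200)
  top2 <- curve$offset[order(-curve$probability)][1:2]
  expect_setequal(sign(top2), c(-1, 1))
  expect_true(all(abs(abs(top2) - 500) <= 200))
})
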