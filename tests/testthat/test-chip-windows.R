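# Window tiling, read counting, input expansion and the enrichment equation.

test_that("tiling enumerates the expected windows", {
  w <- tile_windows(c(chr1 = 200), width = 100, spacing = 50)
  expect_equal(w$start, c(0, 50, 100))
  expect_equal(w$end, c(100, 150, 200))

  # count formula: floor((L - width)/spacing) + 1 for L >= width
  for (L in c(100, 149, 150, 1000, 12345)) {
    w <- tile_windows(c(c1 = L), 100, 50)
    expect_equal(nrow(w), floor((L - 100) / 50) + 1)
    expect_true(all(w$end <= L))
  }

  # contig shorter than a window yields no windows
  expect_equal(nrow(tile_windows(c(c1 = 80), 100, 50)), 0)
  expect_warning(tile_windows(c(c1 = 1000), 100, 200), "gaps")
})

test_that("every interior window overlaps exactly two others at spacing = width/2", {
  w <- tile_windows(c(c1 = 5000), 100, 50)
  gr <- GenomicRanges::GRanges(w$contig, IRanges::IRanges(w$start + 1, w$end))
  ov <- GenomicRanges::countOverlaps(gr, gr) - 1L
  interior <- seq(2, nrow(w) - 1)
  expect_true(all(ov[interior] == 2))
})

test_that("window expansion follows the +-2450 rule and flags edge windows", {
  w <- tibble::tibble(window_id = 1:3, contig = "c1",
                      start = c(10000L, 0L, 47600L),
                      end = c(10100L, 100L, 47700L))
  e <- expand_windows(w, 5000, c(c1 = 50000))
  expect_equal(e$exp_start[1], 7550)
  expect_equal(e$exp_end[1], 12550)
  expect_equal(e$exp_end[1] - e$exp_start[1], 5000)
  expect_true(e$removed[2])   # cannot expand left
  expect_true(e$removed[3])   # cannot expand right
  # identity when target equals width
  e0 <- expand_windows(w[1, ], 100, c(c1 = 50000))
  expect_equal(e0$exp_start, 10000)
  expect_equal(e0$exp_end, 10100)
  expect_error(expand_windows(w, 50, c(c1 = 50000)), "target_width")
})

test_that("read counting matches a brute-force overlap enumeration", {
  cl <- c(c1 = 10000, c2 = 8000)
  grid <- tile_windows(cl, 100, 50)
  set.seed(11)
  n <- 400
  ctg <- sample(names(cl), n, replace = TRUE)
  start <- floor(runif(n) * (cl[ctg] - 75))
  reads <- tibble::tibble(contig = ctg, start = as.integer(start),
                          end = as.integer(start + 75),
                          strand = sample(c("+", "-"), n, TRUE),
                          mapq = sample(c(60L, 30L, 19L, 5L), n, TRUE))
  got <- count_reads(reads, grid, extension = 250, mapq_min = 20)
  want <- brute_force_counts(reads, grid, 250, 20, cl)
  expect_equal(got$count, want)
  expect_equal(attr(got, "n_total"), sum(reads$mapq >= 20))
})

test_that("mapq filter and duplicate handling follow the counting rules", {
  grid <- tile_windows(c(c1 = 200), 100, 50)
  read <- tibble::tibble(contig = "c1", start = 0L, end = 75L,
                         strand = "+", mapq = 19L)
  expect_equal(sum(count_reads(read, grid)$count), 0)

  # one plus-strand read at 0 extended to 250 covers every window of the
  # 200-bp contig: [0,100), [50,150), [100,200)
  read$mapq <- 20L
  cnt <- count_reads(read, grid)
  expect_equal(cnt$count, c(1, 1, 1))
  # duplicates both counted
  dup <- dplyr::bind_rows(read, read)
  expect_equal(count_reads(dup, grid)$count, c(2, 2, 2))

  # a window fully beyond the extended interval is not incremented
  far <- tile_windows(c(c1 = 400), 100, 50)
  cnt_far <- count_reads(read, far)
  expect_equal(cnt_far$count, as.integer(far$start < 250))
})

test_that("minus-strand reads extend from their 5' end leftwards", {
  grid <- tile_windows(c(c1 = 600), 100, 50)
  read <- tibble::tibble(contig = "c1", start = 425L, end = 500L,
                         strand = "-", mapq = 60L)
  cnt <- count_reads(read, grid, extension = 250)
  # extended interval is [250, 500)
  covered <- grid$start < 500 & grid$end > 250
  expect_equal(cnt$count, as.integer(covered))
})

test_that("enrichment equation matches closed forms and is scale invariant", {
  expect_equal(normalize_to_input(30, 1e6, 10, 1e6), 3.0)
  expect_equal(normalize_to_input(10, 1e6, 10, 2e6), 2.0)
  set.seed(3)
  n <- 1e5
  ci <- rpois(n, 50); cb <- rpois(n, 40) + 1
  ni <- 2e6; nb <- 3e6
  nc <- normalize_to_input(ci, ni, cb, nb)
  expect_equal(nc, (ci / ni) / (cb / nb))
  for (const in c(0.5, 2, 17)) {
    expect_equal(normalize_to_input(ci * const, ni * const,
                                    cb * const, nb * const), nc)
  }
  # zero input count handled by pseudocount, stays finite and positive
  expect_equal(normalize_to_input(5, 1e6, 0, 1e6), 5 / 0.5)
  expect_error(normalize_to_input(1, 0, 1, 1), "positive")
})

test_that("removed windows are excluded from the matrix but accounted for", {
  cl <- c(c1 = 20000)
  grid <- tile_windows(cl, 100, 50)
  set.seed(5)
  n <- 2000
  start <- floor(runif(n) * (cl - 75))
  reads <- dplyr::bind_rows(
    tibble::tibble(contig = "c1", start = as.integer(start),
                   end = as.integer(start + 75),
                   strand = "+", mapq = 60L, sample = "m_W_1"),
    tibble::tibble(contig = "c1", start = as.integer(rev(start)),
                   end = as.integer(rev(start) + 75),
                   strand = "-", mapq = 60L, sample = "m_W_2"),
    tibble::tibble(contig = "c1", start = as.integer(start),
                   end = as.integer(start + 75),
                   strand = "+", mapq = 60L, sample = "m_Q_1"),
    tibble::tibble(contig = "c1", start = as.integer(start + 3),
                   end = as.integer(start + 78),
                   strand = "+", mapq = 60L, sample = "m_Q_2"),
    tibble::tibble(contig = "c1", start = as.integer(start),
                   end = as.integer(start + 75),
                   strand = "+", mapq = 60L, sample = "input_W_1")
  )
  samples <- tibble::tibble(
    sample = c("m_W_1", "m_W_2", "m_Q_1", "m_Q_2", "input_W_1"),
    condition = c("W", "W", "Q", "Q", "W"),
    mark = c("m", "m", "m", "m", "input")
  )
  enr <- chip_enrichment(reads, samples, grid, contig_lengths = cl)
  expect_equal(nrow(enr) + length(attr(enr, "removed")), nrow(grid))
  expect_true(all(is.finite(enr$m_W_1)))
  expect_true(all(enr$m_W_1 >= 0))
})
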