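# Gaussian LRT differential expression, MDS, Spearman and mark combinations.

make_expr <- function(mat, conds) {
  out <- tibble::tibble(
    transcript_id = paste0("t", seq_len(nrow(mat))),
    gene_id = paste0("g", seq_len(nrow(mat)))
  )
  for (j in seq_len(ncol(mat))) out[[paste0("s", j)]] <- mat[, j]
  attr(out, "samples") <- tibble::tibble(
    sample = paste0("s", seq_len(ncol(mat))), condition = conds)
  out
}

test_that("LRT is zero for identical group means and detects planted shifts", {
  conds <- rep(c("W", "Q"), each = 4)
  flat <- make_expr(matrix(rep(c(1, 2, 3, 4), 2), nrow = 1), conds)
  res <- lrt_de(flat, conditions = c("W", "Q"))
  expect_equal(res$lrt_stat, 0)
  expect_equal(res$p, 1)
  expect_equal(res$logfc, 0)

  # power experiment: every transcript carries the planted logfc 2 at sd 0.5,
  # so the BH threshold sits near alpha and per-transcript power is the
  # noncentral-F tail P(F(1,6; ncp = (2 / (0.5 sqrt(1/2)))^2) > crit)
  set.seed(41)
  n <- 300
  base <- matrix(rnorm(n * 8, 6, 0.5), nrow = n)
  base[, 1:4] <- base[, 1:4] + 2
  res <- lrt_de(make_expr(base, conds), conditions = c("W", "Q"))
  expect_gte(mean(res$q <= 0.01), 0.9)
  expect_equal(mean(res$logfc), 2, tolerance = 0.1)
  expect_true(all(res$q >= res$p))

  # mixed null/effect: false positives among the null transcripts stay rare
  set.seed(42)
  mix <- matrix(rnorm(n * 8, 6, 0.5), nrow = n)
  mix[1:50, 1:4] <- mix[1:50, 1:4] + 2
  resm <- lrt_de(make_expr(mix, conds), conditions = c("W", "Q"))
  expect_lte(mean(resm$q[51:n] <= 0.01), 0.02)
  expect_gt(mean(resm$q[1:50] <= 0.01), mean(resm$q[51:n] <= 0.01))
})

test_that("LRT null p-values are approximately uniform and shift-invariant", {
  conds <- rep(c("W", "Q"), each = 4)
  rejections <- vapply(1:10, function(s) {
    set.seed(s)
    x <- matrix(rnorm(500 * 8), nrow = 500)
    res <- lrt_de(make_expr(x, conds), conditions = c("W", "Q"))
    suppressWarnings(stats::ks.test(res$p, "punif")$p.value) < 0.01
  }, logical(1))
  expect_lte(mean(rejections), 0.2)

  set.seed(2)
  x <- matrix(rnorm(50 * 8), nrow = 50)
  r1 <- lrt_de(make_expr(x, conds), conditions = c("W", "Q"))
  r2 <- lrt_de(make_expr(x + 100, conds), conditions = c("W", "Q"))
  expect_equal(r1$lrt_stat, r2$lrt_stat, tolerance = 1e-6)
})

test_that("classical MDS preserves structure", {
  conds <- rep(c("W", "Q"), each = 3)
  set.seed(5)
  x <- matrix(rnorm(100 * 6), nrow = 100)
  x[, 1:3] <- x[, 1:3] + 3   # condition shift
  mds <- mds_samples(make_expr(x, conds))
  expect_equal(nrow(mds), 6)
  # embedded distances approximate input distances for well-separated groups
  cw <- colMeans(as.matrix(mds[mds$condition == "W", c("dim1", "dim2")]))
  cq <- colMeans(as.matrix(mds[mds$condition == "Q", c("dim1", "dim2")]))
  between <- sqrt(sum((cw - cq)^2))
  within <- max(sqrt((mds$dim1 - ifelse(mds$condition == "W", cw[1], cq[1]))^2 +
                     (mds$dim2 - ifelse(mds$condition == "W", cw[2], cq[2]))^2))
  expect_gt(between, within)

  # identical samples get identical coordinates
  y <- matrix(rnorm(20), nrow = 5)
  y <- cbind(y, y[, 1])
  m2 <- mds_samples(make_expr(y, c("A", "A", "B", "B", "A")))
  expect_equal(unname(unlist(m2[1, c("dim1", "dim2")])),
               unname(unlist(m2[5, c("dim1", "dim2")])), tolerance = 1e-8)
})

test_that("Spearman correlation handles ranks, ties and degenerate input", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)
  r <- spearman_cor(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(r$rho, 0.8)  # sum d^2 = 4 -> 1 - 24/120
  ref <- suppressWarnings(cor.test(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5),
                                   method = "spearman"))
  expect_equal(r$rho, unname(ref$estimate))
  # monotone-transform invariance
  set.seed(8)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(spearman_cor(x, y)$rho, spearman_cor(exp(x), y^3 + y)$rho)
  expect_true(spearman_cor(rep(1, 10), 1:10)$flagged)
  expect_error(spearman_cor(1, 2), "three")
})

test_that("chromatin-expression correlation recovers coupled effects", {
  cfg <- synth_config(seed = 13)
  ann <- generate_annotation(cfg)
  spikes <- generate_spike_regions(ann, cfg)
  expr <- generate_expression(ann, cfg, spikes)
  de <- lrt_de(expr$expression, conditions = cfg$conditions)
  # regions = the true spikes with their directions
  regions <- dplyr::mutate(spikes, direction = condition,
                           max_abs_delta = fold - 1, best_q = 1e-6,
                           n_windows = 5L)
  corr <- chromatin_expression_correlation(regions, de, ann,
                                           conditions = cfg$conditions)
  k27 <- corr[corr$mark == "H3K27ac", ]
  expect_false(k27$flagged)
  expect_gt(k27$rho, 0.3)
  expect_lt(k27$p, 0.05)

  # fewer than three pairs is flagged, not tested
  one <- regions[1, ]
  corr1 <- chromatin_expression_correlation(one, de, ann,
                                            conditions = cfg$conditions)
  expect_true(all(corr1$flagged | corr1$n >= 3))
})

test_that("mark-combination expression test finds a planted boost and is reproducible", {
  set.seed(77)
  n <- 400
  marks <- tibble::tibble(
    gene_id = paste0("g", 1:n),
    H3K4me3 = runif(n) < 0.5,
    H3K27ac = runif(n) < 0.5,
    H3K36me3 = runif(n) < 0.5
  )
  expr_val <- rnorm(n, 5)
  boost <- marks$H3K4me3 & marks$H3K36me3 & !marks$H3K27ac
  expr_val[boost] <- expr_val[boost] + 2
  expr <- tibble::tibble(transcript_id = paste0("t", 1:n),
                         gene_id = paste0("g", 1:n),
                         s1 = expr_val, s2 = expr_val)
  res <- expression_by_mark_combination(marks, expr, seed = 3)
  target <- res[res$combination == "H3K4me3+H3K36me3", ]
  expect_lt(target$p, 0.05)
  res_again <- expression_by_mark_combination(marks, expr, seed = 3)
  expect_equal(res$p, res_again$p)
  expect_equal(res$background, res_again$background)
})
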