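# Empirical-Bayes moderated t differential window calling.
#
# The per-window two-sample t is underpowered at 2 replicates per condition,
# so window variances are shrunk toward a prior (d0, s0^2) estimated from the
# marginal scaled-F distribution of all window variances (closed-form moment
# estimator on log variances). The moderated t then has d0 + d_g degrees of
# freedom.

#' Invert the trigamma function
#'
#' Newton iteration on 1/trigamma, monotone and stable for x > 0.
#' @param x positive values.
#' @return y with `trigamma(y) == x`.
#' @keywords internal
#' @export
trigamma_inverse <- function(x) {
  y <- rep(NA_real_, length(x))
  y[x > 1e7] <- 1 / sqrt(x[x > 1e7])
  y[x < 1e-6] <- 1 / x[x < 1e-6]
  todo <- is.na(y) & is.finite(x) & x > 0
  yy <- 0.5 + 1 / x[todo]
  for (i in seq_len(50)) {
    tri <- trigamma(yy)
    dif <- tri * (1 - tri / x[todo]) / psigamma(yy, deriv = 2)
    yy <- yy + dif
    if (max(-dif / yy) < 1e-8) break
  }
  y[todo] <- yy
  y
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits the marginal distribution of residual sample variances
#' \eqn{s_g^2 \sim s_0^2 F(d_g, d_0)} by matching moments of
#' \eqn{z_g = \log s_g^2}: the excess spread of z over the sampling
#' contribution `trigamma(d_g/2)` identifies the prior degrees of freedom
#' `d0`, and the corrected mean identifies the prior variance `s0_sq`. When
#' the observed spread does not exceed the sampling contribution the variances
#' are consistent with a single common value and `d0 = Inf`.
#'
#' @param s2 vector of residual sample variances (finite, positive values are
#'   used; at least two required).
#' @param df residual degrees of freedom, scalar or vector matching `s2`.
#' @return an `ebayes_prior` list with elements `d0` and `s0_sq`.
#' @export
estimate_ebayes_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  s2 <- s2[ok]
  df_v <- if (length(df) == 1) rep(df, length(s2)) else df[ok]
  if (length(s2) < 2) abort("need at least two finite positive variances")
  z <- log(s2)
  e <- z - digamma(df_v / 2) + log(df_v / 2)
  evar <- var(e) - mean(trigamma(df_v / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # spread no larger than pure sampling noise: variances share one value,
    # best estimated by their mean
    d0 <- Inf
    s0_sq <- mean(s2)
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "ebayes_prior")
}

#' @export
print.ebayes_prior <- function(x, ...) {
  cat(sprintf("<ebayes_prior> d0 = %.4g, s0_sq = %.4g\n", x$d0, x$s0_sq))
  invisible(x)
}

#' Moderated two-sample t-statistics
#'
#' Equal-variance two-sample t per row of a value matrix, with the pooled
#' residual variance replaced by its posterior under the prior:
#' `s_tilde_sq = (d0 * s0_sq + d_g * s_g_sq) / (d0 + d_g)`. Two-sided p-values
#' come from a t distribution on `d0 + d_g` degrees of freedom (the normal
#' limit when `d0` is infinite). With `prior = NULL` a prior is estimated from
#' the rows themselves; a prior with `d0 = 0` weight reduces to the ordinary t.
#'
#' @param x numeric matrix, rows = features (windows), columns = samples.
#' @param condition character/factor of length `ncol(x)` with exactly two
#'   levels; the difference is `mean(first level) - mean(second level)`.
#' @param prior an `ebayes_prior`, or `NULL` to estimate it from `x`.
#' @param conditions optional length-2 vector fixing which level is first.
#' @return tibble with `delta`, `s_g_sq`, `d_g`, `s_tilde_sq`, `t_mod`, `p`;
#'   the prior used is attached as attribute `prior`.
#' @export
moderated_t_test <- function(x, condition, prior = NULL, conditions = NULL) {
  x <- as.matrix(x)
  condition <- as.character(condition)
  conditions <- conditions %||% unique(condition)
  if (length(conditions) != 2 || !all(condition %in% conditions)) {
    abort("`condition` must take exactly the two values in `conditions`")
  }
  i1 <- which(condition == conditions[1])
  i2 <- which(condition == conditions[2])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2 || n2 < 2) abort("need >= 2 samples per condition")
  d_g <- n1 + n2 - 2

  m1 <- rowMeans(x[, i1, drop = FALSE])
  m2 <- rowMeans(x[, i2, drop = FALSE])
  ss1 <- rowSums((x[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, i2, drop = FALSE] - m2)^2)
  s_g_sq <- (ss1 + ss2) / d_g

  if (is.null(prior)) prior <- estimate_ebayes_prior(s_g_sq, d_g)
  d0 <- prior$d0; s0_sq <- prior$s0_sq
  s_tilde_sq <- if (is.infinite(d0)) rep(s0_sq, length(s_g_sq)) else {
    (d0 * s0_sq + d_g * s_g_sq) / (d0 + d_g)
  }
  u <- sqrt(1 / n1 + 1 / n2)
  delta <- m1 - m2
  t_mod <- delta / (u * sqrt(s_tilde_sq))
  p <- 2 * pt(-abs(t_mod), df = d0 + d_g)
  out <- tibble(delta = delta, s_g_sq = s_g_sq, d_g = d_g,
                s_tilde_sq = s_tilde_sq, t_mod = t_mod, p = p)
  attr(out, "prior") <- prior
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, order-preserving on
#' the input.
#' @param p p-values in `[0, 1]`.
#' @return adjusted p-values (q-values) of the same length.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-window differential statistics between two conditions
#'
#' For each mark, computes the replicate-mean enrichment difference
#' (first condition minus second; positive = higher in the first), fits the
#' moderated t on `log2(NC + 0.5)` (variance-stabilized scale), and BH-adjusts
#' p-values within the mark. The raw-scale difference `delta` is the effect
#' filtered by the threefold rule; `delta_log2` is the scale the test ran on.
#'
#' @param enrichment enrichment tibble from [chip_enrichment()].
#' @param conditions length-2 character; the first is the "positive" direction
#'   (default the order of appearance in the sample sheet).
#' @param marks subset of marks to test (default all non-input marks).
#' @return tibble `window_id`, `contig`, `start`, `end`, `mark`, `delta`,
#'   `delta_log2`, `s_g_sq`, `d_g`, `s_tilde_sq`, `t_mod`, `p`, `q`; per-mark
#'   priors in attribute `priors`.
#' @export
diff_windows <- function(enrichment, conditions = NULL, marks = NULL) {
  samples <- attr(enrichment, "samples")
  conditions <- conditions %||% unique(samples$condition)
  marks <- marks %||% unique(samples$mark)
  priors <- list()
  out <- purrr::map_dfr(marks, function(mk) {
    sub <- samples[samples$mark == mk, , drop = FALSE]
    nc <- as.matrix(enrichment[, sub$sample, drop = FALSE])
    raw <- moderated_t_test(nc, sub$condition, prior = NULL,
                            conditions = conditions)
    st <- moderated_t_test(log2(nc + 0.5), sub$condition, prior = NULL,
                           conditions = conditions)
    priors[[mk]] <<- attr(st, "prior")
    tibble(
      window_id = enrichment$window_id, contig = enrichment$contig,
      start = enrichment$start, end = enrichment$end, mark = mk,
      delta = raw$delta, delta_log2 = st$delta,
      s_g_sq = st$s_g_sq, d_g = st$d_g, s_tilde_sq = st$s_tilde_sq,
      t_mod = st$t_mod, p = st$p, q = bh_adjust(st$p)
    )
  })
  attr(out, "priors") <- priors
  attr(out, "conditions") <- conditions
  out
}

#' Merge significant windows into unique differential regions
#'
#' Windows passing both the significance filter (`q <= q_max`) and the effect
#' filter (`|delta| > delta_min`, on the raw enrichment scale) are merged into
#' maximal runs: windows of the same mark and direction that overlap or abut
#' by at least one base become one region. Direction is the condition with the
#' higher enrichment.
#'
#' @param stats window statistics from [diff_windows()].
#' @param q_max adjusted-p cutoff (default 0.01).
#' @param delta_min enrichment-difference cutoff (default 3).
#' @param conditions length-2 character giving the direction labels; defaults
#'   to the attribute stored by [diff_windows()].
#' @return tibble `contig`, `start`, `end`, `mark`, `direction`, `best_q`,
#'   `max_abs_delta`, `n_windows`, sorted by mark then position.
#' @export
call_differential_regions <- function(stats, q_max = 0.01, delta_min = 3,
                                      conditions = NULL) {
  conditions <- conditions %||% attr(stats, "conditions") %||% c("W", "Q")
  sig <- filter(stats, .data$q <= q_max, abs(.data$delta) > delta_min)
  empty <- tibble(contig = character(), start = integer(), end = integer(),
                  mark = character(), direction = character(),
                  best_q = numeric(), max_abs_delta = numeric(),
                  n_windows = integer())
  if (nrow(sig) == 0) return(empty)
  sig <- mutate(sig, direction = if_else(.data$delta > 0,
                                         conditions[1], conditions[2]))
  out <- sig %>%
    group_by(.data$mark, .data$direction) %>%
    dplyr::group_modify(function(d, key) {
      gr <- as_granges0(d)
      red <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
      ov <- GenomicRanges::findOverlaps(gr, red)
      ri <- S4Vectors::subjectHits(ov)
      tb <- granges_to_tbl(red)
      tibble(
        contig = tb$contig, start = tb$start, end = tb$end,
        best_q = as.numeric(tapply(d$q, ri, min)),
        max_abs_delta = as.numeric(tapply(abs(d$delta), ri, max)),
        n_windows = as.integer(tapply(ri, ri, length))
      )
    }) %>%
    ungroup() %>%
    select("contig", "start", "end", "mark", "direction",
           "best_q", "max_abs_delta", "n_windows") %>%
    arrange(.data$mark, .data$contig, .data$start)
  out
}
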