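#' Pair two cohorts' proportion series on a common period grid
#'
#' Inner-joins the health-care-worker and general-population proportion
#' series on `period_start`; periods present in only one cohort are
#' dropped with a message.
#'
#' @param hcw,gen Proportion tibbles (e.g. from [aggregate_proportions()])
#'   with columns `period_start` and `proportion`, one row per period and
#'   sharing the same granularity.
#' @return Tibble `period_start`, `x` (HCW proportion), `y` (general
#'   proportion), periods unique and ordered.
#' @export
build_paired_series <- function(hcw, gen) {
  stopifnot(all(c("period_start", "proportion") %in% names(hcw)),
            all(c("period_start", "proportion") %in% names(gen)))
  if (anyDuplicated(hcw$period_start) || anyDuplicated(gen$period_start))
    stop("one row per period required; filter to a single stratum first")
  j <- dplyr::inner_join(
    tibble(period_start = hcw$period_start, x = hcw$proportion),
    tibble(period_start = gen$period_start, y = gen$proportion),
    by = "period_start")
  n_drop <- nrow(hcw) + nrow(gen) - 2 * nrow(j)
  if (nrow(j) == 0) stop("no overlapping periods between the two cohorts")
  if (n_drop > 0) message(n_drop, " unpaired period(s) dropped")
  j[order(j$period_start), ]
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Zero differences are removed (Wilcoxon's method), absolute differences
#' are ranked with midranks for ties, and `W` is the sum of the ranks of
#' the positive differences. For `n_effective <= 25` the two-sided p-value
#' is exact, computed from the full distribution of `W` over all `2^n`
#' sign assignments (conditional on the observed tie pattern); for larger
#' `n` a normal approximation with tie correction and continuity
#' correction is used. Per-cohort medians and IQRs are reported alongside.
#'
#' @param pairs A paired series from [build_paired_series()] (columns `x`,
#'   `y`), or use `x`/`y` directly.
#' @param x,y Alternative interface: two numeric vectors of equal length.
#' @param exact_max Largest `n_effective` for which the exact distribution
#'   is enumerated (default 25).
#' @return An object of class `wilcoxon_result`: `W`, `n_pairs`,
#'   `n_effective`, `p_value`, `method` (`"exact"`,
#'   `"normal-approximation"` or `"degenerate"`), `summary_x`, `summary_y`
#'   (median/IQR tibbles). All differences zero yields the degenerate
#'   method with `p_value = NA` and a warning; fewer than 6 effective
#'   pairs triggers a low-power warning.
#' @export
wilcoxon_signed_rank <- function(pairs = NULL, x = NULL, y = NULL,
                                 exact_max = 25) {
  if (!is.null(pairs)) {
    stopifnot(all(c("x", "y") %in% names(pairs)))
    x <- pairs$x; y <- pairs$y
  }
  stopifnot(length(x) == length(y), !anyNA(x), !anyNA(y))
  d <- x - y
  nz <- d != 0
  n_eff <- sum(nz)
  sx <- summarize_median_iqr(x)
  sy <- summarize_median_iqr(y)
  if (n_eff == 0) {
    warning("all paired differences are zero: degenerate test")
    return(new_wilcoxon_result(NA_real_, length(d), 0L, NA_real_,
                               "degenerate", sx, sy))
  }
  if (n_eff < 6) warning("fewer than 6 effective pairs: low-power result")
  dd <- d[nz]
  r <- rank(abs(dd))            # midranks
  W <- sum(r[dd > 0])
  r2 <- as.integer(round(2 * r))  # doubled ranks are exact integers
  W2 <- sum(r2[dd > 0])
  if (n_eff <= exact_max) {
    counts <- signed_rank_counts(r2)
    # counts[s + 1] = number of sign assignments with doubled statistic s
    total <- 2^n_eff
    p_le <- sum(counts[seq_len(W2 + 1)]) / total
    p_ge <- sum(counts[seq(W2 + 1, length(counts))]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n_eff * (n_eff + 1) / 4
    ties <- table(r)
    sig2 <- n_eff * (n_eff + 1) * (2 * n_eff + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal-approximation"
  }
  new_wilcoxon_result(W, length(d), n_eff, p, method, sx, sy)
}

# exact distribution of the doubled signed-rank statistic by convolution of
# the generating function over ranks: equivalent to enumerating all 2^n
# sign assignments, but in O(n * max_sum) integer counts
signed_rank_counts <- function(r2) {
  s_max <- sum(r2)
  counts <- numeric(s_max + 1)
  counts[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), counts[seq_len(s_max + 1 - r)])
    counts <- counts + shifted
  }
  counts
}

new_wilcoxon_result <- function(W, n_pairs, n_eff, p, method, sx, sy) {
  structure(list(W = W, n_pairs = n_pairs, n_effective = n_eff,
                 p_value = p, method = method,
                 summary_x = sx, summary_y = sy),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat("Wilcoxon matched-pairs signed-rank test\n")
  cat(sprintf("  W = %s on %d effective pairs (of %d), p = %s [%s]\n",
              format(x$W), x$n_effective, x$n_pairs,
              format.pval(x$p_value, digits = 3), x$method))
  cat(sprintf("  cohort x: median %.4g (IQR %.4g-%.4g)\n",
              x$summary_x$median, x$summary_x$q25, x$summary_x$q75))
  cat(sprintf("  cohort y: median %.4g (IQR %.4g-%.4g)\n",
              x$summary_y$median, x$summary_y$q25, x$summary_y$q75))
  invisible(x)
}

#' Median and interquartile range of a series
#'
#' Quartiles use the linear-interpolation convention between order
#' statistics (R's default quantile type 7).
#'
#' @param x Nonempty numeric vector.
#' @return Tibble `median`, `q25`, `q75`.
#' @export
summarize_median_iqr <- function(x) {
  stopifnot(length(x) >= 1, !anyNA(x))
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble(median = q[2], q25 = q[1], q75 = q[3])
}
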