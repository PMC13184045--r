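#' Percent change of a paired measurement
#'
#' 100 * (CE - AC) / AC, the per-unit primitive behind every intra-patient and
#' intra-lesion change statistic. Vectorised. Note this is not antisymmetric
#' under exchanging the two arms: percent_change(a, b) != -percent_change(b, a)
#' in general, because the baseline changes.
#'
#' @param value_ac baseline (AC-CT reconstruction) value, > 0.
#' @param value_ce comparison (CE-CT reconstruction) value.
#' @return percent change(s).
#' @export
percent_change <- function(value_ac, value_ce) {
  if (any(!(value_ac > 0))) stop("baseline (AC) values must be positive", call. = FALSE)
  100 * (value_ce - value_ac) / value_ac
}

#' Robust distribution summary of a sample
#'
#' Median, unscaled MAD (median absolute deviation about the median, no
#' 1.4826 consistency factor unless `mad_scaled`), quartiles by linear
#' interpolation (type 7), IQR, and box-plot whiskers at Q1 - 1.5 IQR /
#' Q3 + 1.5 IQR clamped to the data range.
#'
#' @param x numeric sample, n >= 1.
#' @param mad_scaled apply the 1.4826 normal-consistency factor (default no).
#' @return one-row data.frame: n, median, mad, q1, q3, iqr, whisker_low,
#'   whisker_high.
#' @export
distribution_summary <- function(x, mad_scaled = FALSE) {
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  bx <- box_stats(x)
  md <- bx$median
  mad <- stats::median(abs(x - md))
  if (mad_scaled) mad <- mad * 1.4826
  data.frame(
    n = length(x), median = md, mad = mad, q1 = bx$q1, q3 = bx$q3,
    iqr = bx$q3 - bx$q1, whisker_low = bx$whisker_low, whisker_high = bx$whisker_high
  )
}

#' Paired AC/CE cohort summary
#'
#' Builds the per-arm distribution summaries plus the change summary for a set
#' of paired records: median intra-unit percent change, the count of strict
#' increases, and the Wilcoxon signed-rank p-value for the chosen alternative.
#'
#' @param value_ac,value_ce paired vectors (same length, AC > 0).
#' @param alternative passed to [wilcoxon_signed_rank()]; default `"greater"`
#'   (the one-sided increase test).
#' @param method Wilcoxon method: `"auto"` (exact when feasible, i.e. at most
#'   30 nonzero untied differences, else normal approximation), `"exact"`, or
#'   `"normal"`.
#' @param mad_scaled see [distribution_summary()].
#' @return list: `per_arm` (two-row data.frame, recon AC/CE), `change`
#'   (one-row data.frame with n, n_increase, median_percent_change, q1/q3 of
#'   changes, wilcoxon_p).
#' @export
paired_summary <- function(value_ac, value_ce, alternative = "greater",
                           method = c("auto", "exact", "normal"), mad_scaled = FALSE) {
  if (length(value_ac) != length(value_ce)) stop("unpaired input lengths", call. = FALSE)
  if (length(value_ac) == 0L) stop("empty input", call. = FALSE)
  method <- match.arg(method)
  chg <- percent_change(value_ac, value_ce)
  per_arm <- rbind(
    cbind(recon = "AC", distribution_summary(value_ac, mad_scaled)),
    cbind(recon = "CE", distribution_summary(value_ce, mad_scaled))
  )
  d <- value_ce - value_ac
  if (method == "auto") {
    dn <- d[d != 0]
    method <- if (length(dn) > 0 && length(dn) <= 30 && !anyDuplicated(abs(dn))) {
      "exact"
    } else {
      "normal"
    }
  }
  p <- if (all(d == 0)) NA_real_ else {
    wilcoxon_signed_rank(d, alternative = alternative, method = method)
  }
  qs <- stats::quantile(chg, c(0.25, 0.75), names = FALSE, type = 7)
  change <- data.frame(
    n = length(chg), n_increase = sum(chg > 0),
    median_percent_change = stats::median(chg),
    q1_percent_change = qs[1], q3_percent_change = qs[2],
    wilcoxon_p = p
  )
  list(per_arm = per_arm, change = change)
}

#' Wilcoxon signed-rank test
#'
#' Classical signed-rank test on paired differences. Zero differences are
#' dropped before ranking. The exact method computes the null distribution of
#' the positive-rank sum W+ over all 2^n equiprobable sign assignments (via
#' the standard count-polynomial recursion, identical to full enumeration) and
#' requires untied absolute differences; the normal method uses the Gaussian
#' approximation with tie-corrected variance and continuity correction,
#' average ranks for ties.
#'
#' @param d numeric vector of paired differences.
#' @param alternative `"greater"` (location shift > 0), `"less"`, `"two.sided"`.
#' @param method `"exact"` or `"normal"`.
#' @return p-value.
#' @export
wilcoxon_signed_rank <- function(d, alternative = c("greater", "less", "two.sided"),
                                 method = c("exact", "normal")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero", call. = FALSE)
  a <- abs(d)
  r <- rank(a)
  w <- sum(r[d > 0])
  if (method == "exact") {
    if (anyDuplicated(a)) {
      stop("exact method requires no ties in |d|; use method = 'normal'", call. = FALSE)
    }
    # counts[k + 1] = number of sign assignments with W+ = k
    counts <- signrank_counts(n)
    total <- 2^n
    w <- round(w)
    p_ge <- sum(counts[(w + 1):length(counts)]) / total
    p_le <- sum(counts[1:(w + 1)]) / total
    switch(alternative,
      greater = p_ge,
      less = p_le,
      two.sided = min(1, 2 * min(p_ge, p_le))
    )
  } else {
    mu <- n * (n + 1) / 4
    # tie correction: subtract sum(t^3 - t)/48 over tied groups of |d|
    ties <- table(a)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    sigma <- sqrt(sigma2)
    z_ge <- (w - mu - 0.5) / sigma
    z_le <- (w - mu + 0.5) / sigma
    switch(alternative,
      greater = stats::pnorm(z_ge, lower.tail = FALSE),
      less = stats::pnorm(z_le),
      two.sided = {
        z <- (w - mu - sign(w - mu) * 0.5) / sigma
        min(1, 2 * stats::pnorm(-abs(z)))
      }
    )
  }
}

# Null counts of the signed-rank statistic W+ for untied ranks 1..n:
# polynomial product prod_k (1 + x^k), coefficients by dynamic programming.
signrank_counts <- function(n) {
  maxw <- n * (n + 1) / 2
  counts <- numeric(maxw + 1)
  counts[1] <- 1
  for (k in seq_len(n)) {
    shifted <- c(numeric(k), counts[seq_len(maxw + 1 - k)])
    counts <- counts + shifted
  }
  counts
}

#' Correlation coefficient with significance test
#'
#' Pearson product-moment or Spearman rank correlation with its two-sided
#' p-value (t approximation), as used to relate per-organ percent changes of
#' the attenuation coefficient to percent changes of SUVmax. Thin wrapper
#' around [stats::cor.test()] with the module's input contract enforced.
#'
#' @param x,y numeric vectors, n >= 3, neither constant.
#' @param method `"pearson"` or `"spearman"`.
#' @return list: `coefficient`, `p`.
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  list(coefficient = unname(ct$estimate), p = ct$p.value)
}

#' Histogram and kernel-density summary
#'
#' Fixed-width histogram plus a Gaussian kernel density estimate with
#' Silverman's rule-of-thumb bandwidth, evaluated on a stated grid; used to
#' display the SUV and SUVR distributions of the two reconstructions.
#'
#' @param x numeric sample (n >= 2 for the density).
#' @param bins number of fixed-width histogram bins (default 20).
#' @param n_grid density evaluation grid size (default 512).
#' @return list: `histogram` (data.frame mid, count), `density` (data.frame
#'   x, y), `bandwidth`.
#' @export
distribution_curves <- function(x, bins = 20, n_grid = 512) {
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    breaks <- c(rng[1] - 0.5, rng[1] + 0.5)
  } else {
    breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  }
  cnt <- as.integer(table(cut(x, breaks, include.lowest = TRUE)))
  hist_df <- data.frame(mid = (breaks[-1] + breaks[-length(breaks)]) / 2, count = cnt)
  dens <- NULL
  bw <- NA_real_
  if (length(x) >= 2 && stats::sd(x) > 0) {
    de <- stats::density(x, bw = "nrd0", n = n_grid)
    dens <- data.frame(x = de$x, y = de$y)
    bw <- de$bw
  }
  list(histogram = hist_df, density = dens, bandwidth = bw)
}
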