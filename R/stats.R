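## Resampling significance for a single sequence's global slope, two-sample
## comparison of pooled slope samples, and threshold classification metrics.

resampling_result <- function(observed, null_slopes, n, seed) {
  asl <- sum(null_slopes <= observed$s, na.rm = TRUE) / n
  structure(list(observed = observed,
                 null_slopes = null_slopes,
                 asl = asl,
                 n_replicates = n,
                 n_nonfinite = sum(!is.finite(null_slopes)),
                 seed = seed),
            class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf("observed slope %.4f; ASL = %.4f (%d replicates, %d non-finite)\n",
              x$observed$s, x$asl, x$n_replicates, x$n_nonfinite))
  invisible(x)
}

#' Multinomial bootstrap achieved significance level of a global slope
#'
#' Draws `n` iid ("DNA-like") sequences of the same truncated length as the
#' input, with letter probabilities equal to the input's base proportions,
#' computes each one's global slope, and reports the achieved significance
#' level: the fraction of null slopes at or below the observed slope
#' (left-tail inclusive; non-finite null slopes stay in the denominator).
#'
#' @param seq Sequence string.
#' @param n Number of bootstrap replicates, default 10000.
#' @param seed Optional integer seed for reproducibility.
#' @inheritParams global_slope
#' @return A `resampling_result`: `observed`, `null_slopes`, `asl`,
#'   `n_replicates`, `n_nonfinite`, `seed`.
#' @export
bootstrap_asl <- function(seq, n = 10000L, seed = NULL,
                          mode = c("invariant", "single"), code = "ACGT",
                          reps = DEFAULT_REPRESENTATIVES, log_base = "e") {
  mode <- match.arg(mode)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  used <- attr(global_slope(seq, mode = mode, code = code, reps = reps,
                            log_base = log_base), "used_length")
  rowmaps <- resolve_rowmaps(mode, code, reps)
  # observed and null slopes go through the identical computation path
  observed <- slope_from_indices(seq_indices(seq, strict = FALSE)[seq_len(used)],
                                 rowmaps, log_base)
  attr(observed, "used_length") <- used
  probs <- composition_stats(seq)$proportions
  if (!is.null(seed)) set.seed(seed)
  null_slopes <- vapply(seq_len(n), function(i) {
    idx <- sample.int(4L, used, replace = TRUE, prob = probs)
    slope_from_indices(idx, rowmaps, log_base)$s
  }, numeric(1L))
  resampling_result(observed, null_slopes, n, seed)
}

#' Permutation test for a global slope
#'
#' Like [bootstrap_asl()] but each null sequence is a random permutation of
#' the observed (truncated) residues, so the base composition is preserved
#' exactly, not just in expectation. The empirical p-value is the fraction of
#' permuted slopes at or below the observed slope.
#'
#' @inheritParams bootstrap_asl
#' @param n Number of permutations, default 20000.
#' @return A `resampling_result`.
#' @export
permutation_test <- function(seq, n = 20000L, seed = NULL,
                             mode = c("invariant", "single"), code = "ACGT",
                             reps = DEFAULT_REPRESENTATIVES, log_base = "e") {
  mode <- match.arg(mode)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  used <- attr(global_slope(seq, mode = mode, code = code, reps = reps,
                            log_base = log_base), "used_length")
  idx0 <- seq_indices(seq, strict = FALSE)[seq_len(used)]
  rowmaps <- resolve_rowmaps(mode, code, reps)
  # observed goes through the identical path as the permuted replicates
  observed <- slope_from_indices(idx0, rowmaps, log_base)
  attr(observed, "used_length") <- used
  if (!is.null(seed)) set.seed(seed)
  null_slopes <- vapply(seq_len(n), function(i) {
    slope_from_indices(sample(idx0), rowmaps, log_base)$s
  }, numeric(1L))
  resampling_result(observed, null_slopes, n, seed)
}

#' Two-sample t-test on slope samples
#'
#' Classical pooled-variance Student t by default; Welch's unequal-variance
#' form behind `var_equal = FALSE`.
#'
#' @param x,y Numeric samples (finite values), each of size >= 2.
#' @param var_equal Pool the variances (default `TRUE`).
#' @param alternative Passed to [stats::t.test()].
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_t <- function(x, y, var_equal = TRUE, alternative = "two.sided") {
  if (length(x) < 2L || length(y) < 2L) {
    stop("each sample must contain at least 2 values", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("samples must be finite", call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = var_equal, alternative = alternative)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Confusion counts at a slope threshold
#'
#' Positive class = exon; predicted exon iff slope > threshold (ties fall on
#' the intron side).
#'
#' @param threshold Slope cut-off.
#' @param exon_slopes,intron_slopes Finite slope samples.
#' @return A `confusion_counts` list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_at <- function(threshold, exon_slopes, intron_slopes) {
  structure(list(
    tp = sum(exon_slopes > threshold),
    fp = sum(intron_slopes > threshold),
    fn = sum(exon_slopes <= threshold),
    tn = sum(intron_slopes <= threshold)
  ), class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' @param counts A `confusion_counts` or list with `tp`, `fp`, `fn`, `tn`.
#' @return List with `sensitivity`, `specificity`, `accuracy`, `mcc` and the
#'   input `counts`.
#' @export
metrics_from_confusion <- function(counts) {
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  fn <- as.numeric(counts$fn); tn <- as.numeric(counts$tn)
  if (min(tp + fn, tn + fp, tp + fp, tn + fn) <= 0) {
    stop("undefined metric: a confusion-table marginal is zero", call. = FALSE)
  }
  list(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / (tp + fp + fn + tn),
    mcc = (tp * tn - fp * fn) /
      sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)),
    counts = counts
  )
}

#' Youden-index optimal slope threshold
#'
#' Scans candidate thresholds at the midpoints between consecutive distinct
#' pooled slope values (plus sentinels outside the data range) and returns the
#' threshold maximizing J = sensitivity + specificity - 1, ties broken toward
#' the smallest threshold.
#'
#' @param exon_slopes,intron_slopes Finite slope samples, non-empty.
#' @return List with `threshold`, `J`, `sensitivity`, `specificity`,
#'   `accuracy`, `mcc`, `counts`.
#' @export
youden_threshold <- function(exon_slopes, intron_slopes) {
  if (!length(exon_slopes) || !length(intron_slopes)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(exon_slopes)) || !all(is.finite(intron_slopes))) {
    stop("samples must be finite", call. = FALSE)
  }
  v <- sort(unique(c(exon_slopes, intron_slopes)))
  grid <- c(v[1L] - 1,
            if (length(v) > 1L) (v[-length(v)] + v[-1L]) / 2,
            v[length(v)] + 1)
  J <- vapply(grid, function(th) {
    mean(exon_slopes > th) + mean(intron_slopes <= th) - 1
  }, numeric(1L))
  best <- which.max(J)  # grid ascending: first max = smallest threshold
  th <- grid[best]
  cc <- confusion_at(th, exon_slopes, intron_slopes)
  tp <- as.numeric(cc$tp); fp <- as.numeric(cc$fp)
  fn <- as.numeric(cc$fn); tn <- as.numeric(cc$tn)
  mcc <- if (min(tp + fn, tn + fp, tp + fp, tn + fn) > 0) {
    (tp * tn - fp * fn) / sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  } else NA_real_  # a degenerate threshold leaves a zero marginal
  list(threshold = th, J = J[best],
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       accuracy = (tp + tn) / (tp + fp + fn + tn), mcc = mcc, counts = cc)
}

#' One-dimensional Gaussian kernel density estimate
#'
#' Gaussian kernel with Silverman's rule-of-thumb bandwidth, evaluated on a
#' uniform grid of `n_points` points covering exactly the data range.
#'
#' @param values Numeric vector with >= 2 finite, not all identical, values.
#' @param n_points Grid size, default 100.
#' @return List with `grid`, `density`, `bandwidth`.
#' @export
kde_1d <- function(values, n_points = 100L) {
  x <- values[is.finite(values)]
  if (length(x) < 2L) stop("need at least 2 finite values", call. = FALSE)
  if (diff(range(x)) == 0) {
    stop("degenerate bandwidth: all values identical", call. = FALSE)
  }
  d <- stats::density(x, bw = "nrd0", kernel = "gaussian", n = n_points,
                      from = min(x), to = max(x))
  list(grid = d$x, density = d$y, bandwidth = d$bw)
}
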