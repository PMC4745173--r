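## Log-spectral slope: s = log(mean Z2^2) - log(mean Z1^2), where Z2 is the
## finest detail block of the scale-mixing transform and Z1 the next coarser
## one. Negative s: energy decays towards fine scales (regularity /
## persistence); s = 0: comparable energies, as for independent random
## nucleotides; positive s: energy explosion at fine scales (anti-persistent
## zig-zagging).

#' Detail-block layout for the slope
#'
#' Index ranges (1-based, inclusive) of the two detail blocks read by the
#' slope. For a 4-row transform of width N: `Z1 = Z[2, (N/4+1):(N/2)]`,
#' `Z2 = Z[3:4, (N/2+1):N]`. For the 16-row invariant transform:
#' `Z1 = Z[5:7, (N/4+1):(N/2)]`, `Z2 = Z[9:14, (N/2+1):N]` -- rows 8, 15 and
#' 16 are excluded because they only touch the zero padding rows.
#'
#' @param n_rows 4 or 16.
#' @param n_cols Transform width N, divisible by 4.
#' @return List with `z1_rows`, `z1_cols`, `z2_rows`, `z2_cols`.
#' @export
level_layout <- function(n_rows, n_cols) {
  if (n_cols %% 4 != 0) stop("n_cols must be divisible by 4", call. = FALSE)
  q <- n_cols / 4L
  if (n_rows == 4L) {
    list(z1_rows = 2L, z1_cols = (q + 1L):(2L * q),
         z2_rows = 3:4, z2_cols = (2L * q + 1L):n_cols)
  } else if (n_rows == 16L) {
    list(z1_rows = 5:7, z1_cols = (q + 1L):(2L * q),
         z2_rows = 9:14, z2_cols = (2L * q + 1L):n_cols)
  } else {
    stop("n_rows must be 4 or 16", call. = FALSE)
  }
}

log_base_value <- function(log_base) {
  if (identical(log_base, "e") || identical(log_base, exp(1))) return(exp(1))
  if (identical(log_base, "2") || identical(log_base, 2) || identical(log_base, 2L)) return(2)
  stop("log_base must be \"e\" or 2", call. = FALSE)
}

## Assemble a spectral_slope object from the two mean energies.
slope_from_energies <- function(e1, e2, log_base = "e") {
  base <- log_base_value(log_base)
  if (e1 > 0 && e2 > 0) {
    s <- (log(e2) - log(e1)) / log(base)
    flag <- "finite"
  } else if (e1 > 0 && e2 == 0) {
    s <- -Inf; flag <- "neg_inf"
  } else if (e1 == 0 && e2 > 0) {
    s <- Inf; flag <- "pos_inf"
  } else {
    s <- NA_real_; flag <- "missing"
  }
  structure(list(s = s, e1 = e1, e2 = e2, flag = flag,
                 log_base = if (base == 2) "2" else "e"),
            class = "spectral_slope")
}

missing_slope <- function(log_base = "e") {
  structure(list(s = NA_real_, e1 = NA_real_, e2 = NA_real_, flag = "missing",
                 log_base = if (log_base_value(log_base) == 2) "2" else "e"),
            class = "spectral_slope")
}

#' Log-spectral slope of a scale-mixing transform
#'
#' Mean squared entries are taken over the two detail blocks `Z1` (next
#' coarser) and `Z2` (finest); the slope is `log(mean Z2^2) - log(mean Z1^2)`
#' in the chosen base. A zero-energy finest block yields `-Inf`, a zero-energy
#' coarser block `+Inf`, and both zero a missing slope; none of these raise.
#'
#' @param Z Transform matrix from [scale_mixing_transform()].
#' @param layout Block layout; defaults to [level_layout()] of Z's shape.
#' @param log_base `"e"` (natural, default) or `2`.
#' @return A `spectral_slope` object: fields `s`, `e1`, `e2`, `flag`
#'   (`finite|pos_inf|neg_inf|missing`), `log_base`.
#' @export
spectral_slope <- function(Z, layout = NULL, log_base = "e") {
  if (is.null(layout)) layout <- level_layout(nrow(Z), ncol(Z))
  e1 <- mean(Z[layout$z1_rows, layout$z1_cols, drop = FALSE]^2)
  e2 <- mean(Z[layout$z2_rows, layout$z2_cols, drop = FALSE]^2)
  slope_from_energies(e1, e2, log_base)
}

#' @export
print.spectral_slope <- function(x, ...) {
  cat(sprintf("spectral slope (log base %s): %s  [e1 = %.6g, e2 = %.6g, %s]\n",
              x$log_base,
              formatC(x$s, digits = 6, format = "g"),
              x$e1, x$e2, x$flag))
  invisible(x)
}

## Row index of each DNA letter under each representative (list of length-4
## integer maps indexed by the global letter index A=1,C=2,G=3,T=4).
rep_rowmaps <- function(reps) {
  lapply(reps, function(r) match(DNA_LETTERS, check_assignment(r)))
}

## Core slope computation from a vector of letter indices (1..4, NA for
## unmappable residues). Uses Mallat filtering for the column transform; the
## explicit-product path is contract-equivalent (tested).
slope_from_indices <- function(idx, rowmaps, log_base = "e") {
  if (anyNA(idx)) return(missing_slope(log_base))
  N <- length(idx)
  nb <- length(rowmaps)
  nr <- if (nb == 3L) 16L else 4L
  Y <- matrix(0, nrow = nr, ncol = N)
  off <- 0L
  for (b in seq_len(nb)) {
    Y[cbind(off + rowmaps[[b]][idx], seq_len(N))] <- 1
    off <- off + 4L
  }
  Ystar <- t(apply(Y, 1L, cumsum))
  Z <- haar_dwt_rows(haar_matrix(nr, 2L) %*% Ystar, 2L)
  spectral_slope(Z, level_layout(nr, N), log_base)
}

resolve_rowmaps <- function(mode, code, reps) {
  mode <- match.arg(mode, c("invariant", "single"))
  if (mode == "invariant") {
    classes <- vapply(reps, classify_assignment, integer(1L))
    if (length(reps) != 3L || !setequal(classes, 1:3)) {
      stop("reps must contain one representative of each of the 3 equivalence classes",
           call. = FALSE)
    }
    rep_rowmaps(reps)
  } else {
    rep_rowmaps(code)
  }
}

seq_indices <- function(seq, strict = FALSE) {
  chars <- seq_to_chars(seq)
  idx <- match(chars, DNA_LETTERS)
  if (strict && anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("unmappable residue '%s' at position %d", chars[bad], bad),
         call. = FALSE)
  }
  idx
}

#' Global spectral slope of a sequence
#'
#' The sequence is truncated to its leading \eqn{2^{\lfloor\log_2 N\rfloor}}
#' residues (the transform needs a power-of-2 width), encoded, accumulated and
#' transformed, and the slope of the two finest detail levels is returned.
#'
#' @param seq Sequence string, length >= 8.
#' @param mode `"invariant"` (default, 16-row stacked encoding) or `"single"`.
#' @param code Assignment order for `mode = "single"`.
#' @param reps Representative triple for `mode = "invariant"`.
#' @param log_base `"e"` or `2`.
#' @param strict If `TRUE`, non-ACGT residues raise an error; otherwise they
#'   make the slope missing.
#' @param mallat_threshold Passed to [scale_mixing_transform()].
#' @return A `spectral_slope` with attribute `used_length`.
#' @export
global_slope <- function(seq, mode = c("invariant", "single"), code = "ACGT",
                         reps = DEFAULT_REPRESENTATIVES, log_base = "e",
                         strict = FALSE, mallat_threshold = 2^11) {
  mode <- match.arg(mode)
  idx <- seq_indices(seq, strict)
  N <- length(idx)
  if (N < 8L) stop("sequence too short: global slope needs length >= 8", call. = FALSE)
  used <- as.integer(2^floor(log2(N)))
  idx <- idx[seq_len(used)]
  out <- if (anyNA(idx)) {
    missing_slope(log_base)
  } else {
    nr <- if (mode == "invariant") 16L else 4L
    Y <- matrix(0, nrow = nr, ncol = used)
    rowmaps <- resolve_rowmaps(mode, code, reps)
    off <- 0L
    for (b in seq_along(rowmaps)) {
      Y[cbind(off + rowmaps[[b]][idx], seq_len(used))] <- 1
      off <- off + 4L
    }
    Ystar <- t(apply(Y, 1L, cumsum))
    Z <- scale_mixing_transform(Ystar, 2L, mallat_threshold)
    spectral_slope(Z, level_layout(nr, used), log_base)
  }
  attr(out, "used_length") <- used
  out
}

#' Per-class single-code slopes
#'
#' The three slopes \eqn{s_1, s_2, s_3} obtained by single-code encoding under
#' one representative of each equivalence class (well defined: every member of
#' a class yields the same slope), and their mean -- the simple averaged
#' alternative to the stacked invariant encoding.
#'
#' @inheritParams global_slope
#' @return List with `s1`, `s2`, `s3` (numeric, possibly non-finite), `mean`,
#'   and `slopes` (the three `spectral_slope` objects).
#' @export
per_class_slopes <- function(seq, log_base = "e", reps = DEFAULT_REPRESENTATIVES,
                             strict = FALSE) {
  classes <- vapply(reps, classify_assignment, integer(1L))
  ord <- order(classes)
  slopes <- lapply(reps[ord], function(r) {
    global_slope(seq, mode = "single", code = r, log_base = log_base, strict = strict)
  })
  s <- vapply(slopes, function(x) x$s, numeric(1L))
  list(s1 = s[[1L]], s2 = s[[2L]], s3 = s[[3L]], mean = mean(s), slopes = slopes)
}

#' Cumulative evolutionary slope (sliding-window slope series)
#'
#' A window of `window` nucleotides slides along the sequence in steps of
#' `step`; each window is encoded with its cumulative sums restarted at the
#' window start, transformed, and its slope recorded. Because Haar detail
#' blocks annihilate per-row constants, restarting the accumulation is
#' equivalent to slicing the whole-sequence cumulative matrix. Window and step
#' must be divisible by 4 (Haar alignment); a trailing partial window is
#' discarded. Windows containing non-ACGT residues yield missing slopes.
#'
#' @param seq Sequence string, length >= `window`.
#' @param window Window width in nucleotides, divisible by 4, >= 8; default 32.
#' @param step Shift in nucleotides, divisible by 4; default 8.
#' @inheritParams global_slope
#' @return A `slope_series` data frame with columns `window_start`,
#'   `window_end` (1-based inclusive), `slope`, `e1`, `e2`, `flag`, and
#'   attributes `window`, `step`, `log_base`.
#' @export
evolutionary_slope <- function(seq, window = 32L, step = 8L,
                               mode = c("invariant", "single"), code = "ACGT",
                               reps = DEFAULT_REPRESENTATIVES, log_base = "e",
                               strict = FALSE) {
  mode <- match.arg(mode)
  if (window %% 4 != 0 || window < 8) {
    stop("window must be divisible by 4 and >= 8", call. = FALSE)
  }
  if (step %% 4 != 0 || step < 4) stop("step must be divisible by 4", call. = FALSE)
  idx <- seq_indices(seq, strict)
  N <- length(idx)
  if (N < window) stop("sequence shorter than one window", call. = FALSE)
  starts <- seq.int(1L, N - window + 1L, by = step)
  rowmaps <- resolve_rowmaps(mode, code, reps)
  nr <- if (mode == "invariant") 16L else 4L
  Wr <- haar_matrix(nr, 2L)
  Wct <- t(haar_matrix(window, 2L))
  layout <- level_layout(nr, window)
  cols <- seq_len(window)
  res <- lapply(starts, function(st) {
    widx <- idx[st:(st + window - 1L)]
    if (anyNA(widx)) return(missing_slope(log_base))
    Y <- matrix(0, nrow = nr, ncol = window)
    off <- 0L
    for (b in seq_along(rowmaps)) {
      Y[cbind(off + rowmaps[[b]][widx], cols)] <- 1
      off <- off + 4L
    }
    Ystar <- t(apply(Y, 1L, cumsum))
    spectral_slope(Wr %*% Ystar %*% Wct, layout, log_base)
  })
  out <- data.frame(
    window_start = starts,
    window_end = starts + window - 1L,
    slope = vapply(res, function(x) x$s, numeric(1L)),
    e1 = vapply(res, function(x) x$e1, numeric(1L)),
    e2 = vapply(res, function(x) x$e2, numeric(1L)),
    flag = vapply(res, function(x) x$flag, character(1L)),
    stringsAsFactors = FALSE
  )
  attr(out, "window") <- as.integer(window)
  attr(out, "step") <- as.integer(step)
  attr(out, "log_base") <- if (log_base_value(log_base) == 2) "2" else "e"
  class(out) <- c("slope_series", "data.frame")
  out
}
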