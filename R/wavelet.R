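## Haar wavelet matrices and the 2-D scale-mixing transform.
##
## Conventions (load-bearing): rows of a transform matrix are ordered
## coarsest-first -- scaling rows, then detail rows from the coarsest level
## down to the finest. The finest detail row k has entries +sqrt(2)/2,
## -sqrt(2)/2 on columns 2k-1, 2k. With this ordering the depth-2 4x4 matrix
## is
##   [ 1/2  1/2  1/2  1/2 ]
##   [ 1/2  1/2 -1/2 -1/2 ]
##   [  c    -c    0    0 ]
##   [  0    0    c   -c  ]       c = sqrt(2)/2.

is_pow2 <- function(m) {
  is.numeric(m) && length(m) == 1L && m >= 1 && m == 2^round(log2(m))
}

#' Orthogonal Haar wavelet transform matrix
#'
#' Builds the m x m matrix of a depth-`depth` Haar analysis: the first
#' \eqn{m/2^{depth}} rows are scaling (smoothing) rows, followed by detail rows
#' from the coarsest retained level down to the finest. Each analysis step
#' replaces the current smooth block by pairwise sums and differences scaled by
#' \eqn{1/\sqrt 2}, so the matrix is orthogonal.
#'
#' @param m Matrix size, a power of 2.
#' @param depth Transform depth, `1 <= depth <= log2(m)`.
#' @return An m x m orthogonal numeric matrix.
#' @export
haar_matrix <- function(m, depth = 2L) {
  if (!is_pow2(m)) stop("m must be a power of 2", call. = FALSE)
  if (depth < 1L || depth > log2(m)) {
    stop(sprintf("depth must be between 1 and log2(m) = %d", as.integer(log2(m))),
         call. = FALSE)
  }
  smooth <- diag(m)
  details <- NULL
  for (k in seq_len(depth)) {
    n <- nrow(smooth)
    odd <- seq(1L, n, by = 2L)
    d <- (smooth[odd, , drop = FALSE] - smooth[odd + 1L, , drop = FALSE]) / sqrt(2)
    smooth <- (smooth[odd, , drop = FALSE] + smooth[odd + 1L, , drop = FALSE]) / sqrt(2)
    details <- rbind(d, details)  # coarser levels stack above finer ones
  }
  rbind(smooth, details)
}

#' Haar-transform the columns of a cumulative matrix
#'
#' Computes \eqn{D = W \cdot Y^*}: every column of `Ystar` is replaced by its
#' Haar coefficients, densifying the sparse accumulated unit vectors.
#'
#' @param Ystar Cumulative matrix (rows = wavelet dimension).
#' @param W Wavelet matrix from [haar_matrix()] with `nrow(W) == nrow(Ystar)`.
#' @return The numeric matrix `W %*% Ystar`.
#' @export
column_transform <- function(Ystar, W) {
  if (nrow(W) != nrow(Ystar)) {
    stop(sprintf("wavelet matrix size %d does not match row count %d",
                 nrow(W), nrow(Ystar)), call. = FALSE)
  }
  unname(W %*% Ystar)
}

## Depth-`depth` Haar analysis applied to each *row* of X by Mallat filtering;
## equals X %*% t(haar_matrix(ncol(X), depth)) with coarsest-first ordering.
haar_dwt_rows <- function(X, depth = 2L) {
  smooth <- X
  details <- NULL
  for (k in seq_len(depth)) {
    n <- ncol(smooth)
    odd <- seq(1L, n, by = 2L)
    d <- (smooth[, odd, drop = FALSE] - smooth[, odd + 1L, drop = FALSE]) / sqrt(2)
    smooth <- (smooth[, odd, drop = FALSE] + smooth[, odd + 1L, drop = FALSE]) / sqrt(2)
    details <- cbind(d, details)
  }
  cbind(smooth, details)
}

#' 2-D scale-mixing Haar transform of a cumulative matrix
#'
#' Computes \eqn{Z = W_r \cdot Y^* \cdot W_N'} where \eqn{W_r} is the depth-2
#' Haar matrix over the rows (4 or 16) and \eqn{W_N} the depth-`col_depth`
#' Haar matrix over the N columns. For long sequences
#' (`N > mallat_threshold`) the column transform is carried out by Mallat
#' pyramidal filtering instead of an explicit N x N matrix product; the two
#' paths agree to floating-point accuracy and conserve the Frobenius energy of
#' the input.
#'
#' @param Ystar Cumulative matrix with 4 or 16 rows; `ncol` divisible by
#'   `2^col_depth`.
#' @param col_depth Column transform depth, default 2 (the slope reads only the
#'   two finest column-detail blocks).
#' @param mallat_threshold Column count above which filtering replaces the
#'   matrix product; default `2^11`.
#' @return Numeric matrix Z of the same shape, with attributes `row_depth` and
#'   `col_depth`.
#' @export
scale_mixing_transform <- function(Ystar, col_depth = 2L, mallat_threshold = 2^11) {
  nr <- nrow(Ystar)
  N <- ncol(Ystar)
  if (!nr %in% c(4L, 16L)) {
    stop("Ystar must have 4 (single-code) or 16 (invariant) rows", call. = FALSE)
  }
  if (N %% 2^col_depth != 0) {
    stop(sprintf("column count %d is not divisible by 2^%d", N, col_depth),
         call. = FALSE)
  }
  D <- haar_matrix(nr, 2L) %*% Ystar
  Z <- if (N > mallat_threshold) {
    haar_dwt_rows(D, col_depth)
  } else {
    D %*% t(haar_matrix(N, col_depth))
  }
  Z <- unname(Z)
  attr(Z, "row_depth") <- 2L
  attr(Z, "col_depth") <- as.integer(col_depth)
  attr(Z, "mode") <- attr(Ystar, "mode")
  Z
}
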