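#' @keywords internal
DNA_LETTERS <- c("A", "C", "G", "T")

#' Default representative assignment orders, one per equivalence class
#'
#' The three orders head the three columns of the class table: `"ACGT"`
#' (amino/keto pairing AC|GT), `"AGCT"` (purine/pyrimidine AG|CT) and
#' `"ATCG"` (weak/strong hydrogen bonds AT|CG).
#' @export
DEFAULT_REPRESENTATIVES <- c("ACGT", "AGCT", "ATCG")

## Split a sequence string into an uppercase character vector.
seq_to_chars <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop("sequence must be a single character string", call. = FALSE)
  }
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  if (length(chars) < 1L) stop("sequence must contain at least one residue", call. = FALSE)
  chars
}

## Validate an assignment order ("ACGT"-style permutation); returns its letters.
check_assignment <- function(order) {
  chars <- strsplit(toupper(order[[1L]]), "", fixed = TRUE)[[1L]]
  if (length(chars) != 4L || anyDuplicated(chars) || !setequal(chars, DNA_LETTERS)) {
    stop(sprintf("invalid assignment '%s': must be a permutation of ACGT", order),
         call. = FALSE)
  }
  chars
}

#' Equivalence class of a nucleotide-to-unit-vector assignment
#'
#' An assignment order maps the letter at position \eqn{i} to the unit vector
#' \eqn{e_i}. Two assignments yield the same spectral slope if and only if one
#' is obtained from the other by permuting letters within its two letter-pairs
#' (positions 1--2 and 3--4) and/or swapping the pairs. The 24 permutations of
#' ACGT therefore collapse to \eqn{4!/(2!\,2!\,2!) = 3} classes, indexed by the
#' pair partition: 1 = \{AC|GT\} (amino/keto), 2 = \{AG|CT\}
#' (purine/pyrimidine), 3 = \{AT|CG\} (weak/strong hydrogen bonds).
#'
#' @param order A 4-letter permutation of `"ACGT"`, e.g. `"GATC"`.
#' @return Integer class id in `1:3`.
#' @examples
#' classify_assignment("ACGT")  # 1
#' classify_assignment("GATC")  # 2
#' @export
classify_assignment <- function(order) {
  chars <- check_assignment(order)
  pair <- paste(sort(chars[1:2]), collapse = "")
  class_map <- c(AC = 1L, GT = 1L, AG = 2L, CT = 2L, AT = 3L, CG = 3L)
  unname(class_map[[pair]])
}

#' Encode a sequence as a 4 x N unit-vector indicator matrix
#'
#' Under assignment `code`, the letter at position \eqn{i} of `code` is coded
#' as \eqn{e_i}; column \eqn{j} of the result is the unit vector of residue
#' \eqn{j}. Row names carry the letter each row indicates.
#'
#' @param seq Sequence string over ACGT (lowercase is accepted and uppercased).
#' @param code Assignment order, default `"ACGT"`.
#' @return A binary 4 x N matrix with attribute `mode = "single"`.
#' @export
encode_single <- function(seq, code = "ACGT") {
  chars <- seq_to_chars(seq)
  letters4 <- check_assignment(code)
  idx <- match(chars, letters4)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("unmappable residue '%s' at position %d", chars[bad], bad),
         call. = FALSE)
  }
  Y <- matrix(0L, nrow = 4L, ncol = length(chars),
              dimnames = list(letters4, NULL))
  Y[cbind(idx, seq_along(idx))] <- 1L
  attr(Y, "mode") <- "single"
  Y
}

#' Encode a sequence with the translation-invariant 16-row stacking
#'
#' One single-code encoding from each of the three equivalence classes is
#' stacked (rows 1--4, 5--8, 9--12); rows 13--16 are fixed at zero, padding the
#' row count to a power of two. Because the Haar basis is used downstream, the
#' zero padding never leaks into the detail blocks read by the slope, and the
#' resulting slope does not depend on which representative of each class is
#' chosen, nor on the block order.
#'
#' @param seq Sequence string over ACGT.
#' @param reps Three assignment orders, exactly one from each equivalence
#'   class, in any order. Default [DEFAULT_REPRESENTATIVES].
#' @return A binary 16 x N matrix with attribute `mode = "invariant"`.
#' @export
encode_invariant <- function(seq, reps = DEFAULT_REPRESENTATIVES) {
  if (length(reps) != 3L) {
    stop("reps must contain exactly three assignment orders", call. = FALSE)
  }
  classes <- vapply(reps, classify_assignment, integer(1L))
  if (!setequal(classes, 1:3)) {
    stop("reps must contain one representative of each of the 3 equivalence classes",
         call. = FALSE)
  }
  blocks <- lapply(reps, function(r) encode_single(seq, r))
  Y <- rbind(blocks[[1L]], blocks[[2L]], blocks[[3L]],
             matrix(0L, nrow = 4L, ncol = ncol(blocks[[1L]])))
  attr(Y, "mode") <- "invariant"
  Y
}

#' Row-wise cumulative sums of an indicator matrix
#'
#' Entry \eqn{(i, j)} of the result is the count of the row-\eqn{i} nucleotide
#' among the first \eqn{j} residues, so each row is a nondecreasing step
#' function and, in single-code mode, column \eqn{j} sums to \eqn{j}.
#'
#' @param Y An indicator matrix from [encode_single()] or [encode_invariant()].
#' @return An integer matrix of the same shape.
#' @export
cumulate <- function(Y) {
  if (!is.matrix(Y)) stop("Y must be a matrix", call. = FALSE)
  Ystar <- if (ncol(Y) == 1L) Y else t(apply(Y, 1L, cumsum))
  dimnames(Ystar) <- dimnames(Y)
  attr(Ystar, "mode") <- attr(Y, "mode")
  Ystar
}
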