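## Synthetic sequence and gene-fixture generators. Exons are modeled as iid
## multinomial strings; introns as persistent first-order Markov chains, the
## simplest mechanism that produces the more negative (more regular) slopes
## the intron sample is expected to show.

check_probs <- function(probs) {
  if (length(probs) != 4L || any(!is.finite(probs)) || any(probs < 0) ||
      abs(sum(probs) - 1) > 1e-9) {
    stop("probs must be 4 nonnegative values summing to 1", call. = FALSE)
  }
  p <- as.numeric(probs)
  names(p) <- DNA_LETTERS
  p
}

#' Random iid DNA sequence
#'
#' Independent multinomial draws over A, C, G, T.
#'
#' @param length Sequence length, >= 1.
#' @param probs Letter probabilities in A, C, G, T order; default uniform.
#' @param seed Optional integer seed.
#' @return Sequence string.
#' @export
random_dna <- function(length, probs = rep(0.25, 4), seed = NULL) {
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  probs <- check_probs(probs)
  if (!is.null(seed)) set.seed(seed)
  paste(sample(DNA_LETTERS, length, replace = TRUE, prob = probs), collapse = "")
}

#' Persistent first-order Markov DNA sequence
#'
#' Transition rule: with probability `persistence` the next letter repeats the
#' current one; otherwise it is drawn fresh from `stationary`. The transition
#' matrix is \eqn{\rho I + (1-\rho)\mathbf{1}p'}, whose stationary (and
#' marginal) distribution is `stationary`; the lag-1 letter agreement is
#' \eqn{\rho + (1-\rho)\sum_i p_i^2}. `persistence = 0` gives iid draws.
#'
#' @param length Sequence length, >= 1.
#' @param stationary Stationary letter probabilities (A, C, G, T order).
#' @param persistence Self-copy probability \eqn{\rho \in [0, 1)}.
#' @param seed Optional integer seed.
#' @return Sequence string.
#' @export
markov_dna <- function(length, stationary = rep(0.25, 4), persistence = 0.9,
                       seed = NULL) {
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  stationary <- check_probs(stationary)
  if (!is.finite(persistence) || persistence < 0 || persistence >= 1) {
    stop("persistence must be in [0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  fresh <- sample.int(4L, length, replace = TRUE, prob = stationary)
  stay <- c(FALSE, stats::runif(length - 1L) < persistence)
  # index of the most recent fresh draw at or before each position
  src <- cummax(ifelse(stay, 0L, seq_len(length)))
  paste(DNA_LETTERS[fresh[src]], collapse = "")
}

#' Synthetic gene: alternating iid exons and persistent-Markov introns
#'
#' Builds a gene of `n_exons` exon blocks separated by introns. Exon lengths
#' and intron lengths are drawn uniformly from their ranges; exons are iid
#' multinomial, introns persistent Markov. Defaults emulate a GC-poor
#' insect-like gene set: exon GC ~ 32 %, intron GC ~ 25 %, exons 50--400 nt,
#' introns 500--3000 nt.
#'
#' @param n_exons Number of exon blocks, >= 1.
#' @param exon_length_range,intron_length_range Inclusive length ranges.
#' @param exon_probs iid letter probabilities for exons (A, C, G, T).
#' @param intron_stationary Stationary letter probabilities for introns.
#' @param persistence Intron self-copy probability.
#' @param gene_id Identifier for the annotation.
#' @param seed Optional integer seed.
#' @return List with `sequence` and `annotation` (a [gene_annotation()] with
#'   strand `"+"` and the exon intervals in gene coordinates).
#' @export
synthetic_gene <- function(n_exons = 4L,
                           exon_length_range = c(50L, 400L),
                           intron_length_range = c(500L, 3000L),
                           exon_probs = c(A = 0.34, C = 0.16, G = 0.16, T = 0.34),
                           intron_stationary = c(A = 0.375, C = 0.125, G = 0.125, T = 0.375),
                           persistence = 0.9,
                           gene_id = "gene1", seed = NULL) {
  if (n_exons < 1L) stop("n_exons must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  exon_probs <- check_probs(exon_probs)
  intron_stationary <- check_probs(intron_stationary)
  exon_len <- sample.int(exon_length_range[2L] - exon_length_range[1L] + 1L,
                         n_exons, replace = TRUE) + exon_length_range[1L] - 1L
  n_introns <- n_exons - 1L
  intron_len <- if (n_introns > 0L) {
    sample.int(intron_length_range[2L] - intron_length_range[1L] + 1L,
               n_introns, replace = TRUE) + intron_length_range[1L] - 1L
  } else integer(0L)
  pieces <- character(2L * n_exons - 1L)
  starts <- integer(n_exons)
  ends <- integer(n_exons)
  pos <- 1L
  for (i in seq_len(n_exons)) {
    pieces[2L * i - 1L] <- random_dna(exon_len[i], exon_probs)
    starts[i] <- pos
    ends[i] <- pos + exon_len[i] - 1L
    pos <- pos + exon_len[i]
    if (i <= n_introns) {
      pieces[2L * i] <- markov_dna(intron_len[i], intron_stationary, persistence)
      pos <- pos + intron_len[i]
    }
  }
  list(sequence = paste(pieces, collapse = ""),
       annotation = gene_annotation(gene_id, "+",
                                    data.frame(start = starts, end = ends)))
}

#' Default synthetic gene set
#'
#' `n_genes` independent genes from [synthetic_gene()], each with a number of
#' exons drawn uniformly from `n_exon_range`. One seed drives the whole set.
#'
#' @param n_genes Number of genes, default 20.
#' @param n_exon_range Range of exon counts per gene, default 3--6.
#' @param seed Optional integer seed.
#' @param ... Further arguments to [synthetic_gene()].
#' @return Named list of genes (`sequence` + `annotation`).
#' @export
synthetic_gene_set <- function(n_genes = 20L, n_exon_range = c(3L, 6L),
                               seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n_ex <- sample.int(n_exon_range[2L] - n_exon_range[1L] + 1L, n_genes,
                     replace = TRUE) + n_exon_range[1L] - 1L
  ids <- sprintf("gene%03d", seq_len(n_genes))
  genes <- lapply(seq_len(n_genes), function(i) {
    synthetic_gene(n_exons = n_ex[i], gene_id = ids[i], ...)
  })
  names(genes) <- ids
  genes
}

#' Write a gene fixture to FASTA + BED6 + JSON metadata
#'
#' One FASTA record per gene; one BED6 line per exon (0-based half-open,
#' chrom = name = gene id, score 0); a JSON sidecar records the generation
#' parameters.
#'
#' @param genes Gene set from [synthetic_gene_set()].
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix, default `"fixture"`.
#' @param metadata Optional list stored in the JSON sidecar.
#' @return Invisibly, the three file paths.
#' @export
write_gene_fixture <- function(genes, dir, prefix = "fixture", metadata = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fasta <- file.path(dir, paste0(prefix, ".fa"))
  bed <- file.path(dir, paste0(prefix, ".bed"))
  meta <- file.path(dir, paste0(prefix, ".json"))
  seqs <- vapply(genes, function(g) g$sequence, character(1L))
  write_fasta(seqs, fasta)
  bed_lines <- unlist(lapply(genes, function(g) {
    ex <- g$annotation$exons
    sprintf("%s\t%d\t%d\t%s\t0\t%s", g$annotation$gene_id, ex$start - 1L,
            ex$end, g$annotation$gene_id, g$annotation$strand)
  }), use.names = FALSE)
  writeLines(bed_lines, bed)
  jsonlite::write_json(c(list(n_genes = length(genes)), metadata), meta,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fasta, bed = bed, metadata = meta))
}
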