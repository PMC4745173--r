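## Gene structure: exon intervals on the oriented gene sequence; everything
## else inside the gene is intron. Windows of the evolutionary slope are
## labeled exon / intron / combination and maximal runs of one label form
## sections, whose mean slopes are the observations pooled across genes.

#' Gene annotation object
#'
#' @param gene_id Gene identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data frame of 1-based inclusive
#'   `(start, end)` exon intervals on the forward-strand record coordinates;
#'   must be sorted and non-overlapping.
#' @return A `gene_annotation` object.
#' @export
gene_annotation <- function(gene_id, strand, exons) {
  if (!strand %in% c("+", "-")) {
    stop(sprintf("unknown strand symbol '%s'", strand), call. = FALSE)
  }
  exons <- as.data.frame(exons)
  if (ncol(exons) < 2L) stop("exons needs start and end columns", call. = FALSE)
  names(exons)[1:2] <- c("start", "end")
  exons <- exons[, c("start", "end")]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (nrow(exons) == 0L) stop("annotation must contain at least one exon", call. = FALSE)
  if (any(exons$start < 1L) || any(exons$end < exons$start)) {
    stop("exon intervals must satisfy 1 <= start <= end", call. = FALSE)
  }
  ord <- order(exons$start)
  exons <- exons[ord, , drop = FALSE]
  if (nrow(exons) > 1L && any(exons$start[-1L] <= exons$end[-nrow(exons)])) {
    bad <- which(exons$start[-1L] <= exons$end[-nrow(exons)])
    stop(sprintf("overlapping exon intervals at rows %s",
                 paste(bad + 1L, collapse = ", ")), call. = FALSE)
  }
  rownames(exons) <- NULL
  structure(list(gene_id = gene_id, strand = strand, exons = exons),
            class = "gene_annotation")
}

#' Strand-correct a sequence
#'
#' Forward-strand sequences are returned unchanged (uppercased); minus-strand
#' sequences are reverse complemented so every gene reads 5' to 3' left to
#' right.
#'
#' @param seq Sequence string.
#' @param strand `"+"` or `"-"`.
#' @return The oriented sequence string.
#' @export
strand_correct <- function(seq, strand) {
  if (!strand %in% c("+", "-")) {
    stop(sprintf("unknown strand symbol '%s'", strand), call. = FALSE)
  }
  seq <- toupper(seq)
  if (strand == "+") return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Orient a gene sequence and remap its annotation
#'
#' For minus-strand genes the sequence is reverse complemented and each exon
#' interval `(start, end)` is remapped to `(L - end + 1, L - start + 1)` where
#' `L` is the gene length, so the returned annotation lives on the oriented
#' gene's own coordinates with strand `"+"`.
#'
#' @param seq Gene sequence on forward-strand record coordinates.
#' @param annotation A [gene_annotation()].
#' @return List with oriented `seq` and remapped `annotation`.
#' @export
orient_gene <- function(seq, annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  L <- nchar(seq)
  if (any(annotation$exons$end > L)) {
    stop("exon interval exceeds sequence length", call. = FALSE)
  }
  if (annotation$strand == "+") {
    return(list(seq = toupper(seq), annotation = annotation))
  }
  ex <- annotation$exons
  flipped <- data.frame(start = L - ex$end + 1L, end = L - ex$start + 1L)
  list(seq = strand_correct(seq, "-"),
       annotation = gene_annotation(annotation$gene_id, "+", flipped))
}

#' Label a window as exon, intron or combination
#'
#' `"exon"` if every residue of the window falls in an exon interval,
#' `"intron"` if none does, `"combination"` otherwise. Combination windows are
#' kept apart so exon and intron slopes are never averaged together.
#'
#' @param start,end Window interval, 1-based inclusive.
#' @param annotation A [gene_annotation()] on the same coordinates.
#' @return `"exon"`, `"intron"` or `"combination"`.
#' @export
label_window <- function(start, end, annotation) {
  ex <- annotation$exons
  ov <- sum(pmax(0L, pmin(end, ex$end) - pmax(start, ex$start) + 1L))
  width <- end - start + 1L
  if (ov == width) "exon" else if (ov == 0L) "intron" else "combination"
}

#' Label every window of a slope series
#'
#' @param series A `slope_series` from [evolutionary_slope()].
#' @param annotation A [gene_annotation()] on the oriented gene coordinates.
#' @return Character vector of labels, one per window.
#' @export
label_series <- function(series, annotation) {
  mapply(label_window, series$window_start, series$window_end,
         MoreArgs = list(annotation = annotation), USE.NAMES = FALSE)
}

#' Collapse labeled windows into sections
#'
#' Maximal runs of identically labeled consecutive windows become sections.
#' A section's mean slope averages its finite window slopes; a section
#' containing any infinite window slope is flagged excluded (it is dropped
#' from pooled samples but still counted).
#'
#' @param series A `slope_series`.
#' @param labels One label per window, from [label_series()].
#' @return Data frame with columns `section_index`, `label`, `start`, `end`,
#'   `n_windows`, `mean_slope`, `excluded`.
#' @export
sectionize <- function(series, labels) {
  if (length(labels) != nrow(series)) {
    stop("need exactly one label per window", call. = FALSE)
  }
  runs <- rle(labels)
  stops <- cumsum(runs$lengths)
  starts <- stops - runs$lengths + 1L
  out <- lapply(seq_along(runs$values), function(i) {
    w <- starts[i]:stops[i]
    sl <- series$slope[w]
    finite <- sl[is.finite(sl)]
    data.frame(
      section_index = i,
      label = runs$values[i],
      start = series$window_start[starts[i]],
      end = series$window_end[stops[i]],
      n_windows = length(w),
      mean_slope = if (length(finite)) mean(finite) else NA_real_,
      excluded = any(is.infinite(sl)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Pool section mean slopes across genes
#'
#' Gathers non-excluded section means into exon, intron and combination
#' samples (combination sections are reported but never merged into the other
#' two), and counts genes affected by infinite slopes.
#'
#' @param gene_sections Named list of per-gene section data frames from
#'   [sectionize()].
#' @return List with numeric vectors `exon`, `intron`, `combination`;
#'   `n_genes`; `genes_with_infinite` (genes with >= 1 excluded section);
#'   `genes_infinite_intron_only` (of those, genes whose excluded sections are
#'   all intron); and `n_sections_excluded`.
#' @export
pool_sections <- function(gene_sections) {
  pick <- function(df, lab) {
    v <- df$mean_slope[df$label == lab & !df$excluded]
    v[!is.na(v)]
  }
  inf_any <- vapply(gene_sections, function(df) any(df$excluded), logical(1L))
  inf_intron_only <- vapply(gene_sections, function(df) {
    any(df$excluded) && all(df$label[df$excluded] == "intron")
  }, logical(1L))
  list(
    exon = unlist(lapply(gene_sections, pick, "exon"), use.names = FALSE),
    intron = unlist(lapply(gene_sections, pick, "intron"), use.names = FALSE),
    combination = unlist(lapply(gene_sections, pick, "combination"), use.names = FALSE),
    n_genes = length(gene_sections),
    genes_with_infinite = sum(inf_any),
    genes_infinite_intron_only = sum(inf_intron_only),
    n_sections_excluded = sum(vapply(gene_sections, function(df) sum(df$excluded), integer(1L)))
  )
}

#' Base composition of a sequence
#'
#' @param seq Sequence string.
#' @return List with `proportions` (named A/C/G/T fractions over mapped
#'   residues), `gc` (fraction), `length` (total residues) and `n_unmapped`.
#' @export
composition_stats <- function(seq) {
  chars <- seq_to_chars(seq)
  counts <- vapply(DNA_LETTERS, function(l) sum(chars == l), integer(1L))
  mapped <- sum(counts)
  if (mapped == 0L) stop("sequence contains no ACGT residues", call. = FALSE)
  props <- counts / mapped
  list(proportions = props,
       gc = unname(props[["C"]] + props[["G"]]),
       length = length(chars),
       n_unmapped = length(chars) - mapped)
}

#' Slope sections of one annotated gene
#'
#' Convenience pipeline: orient the gene, compute its evolutionary slope
#' series, label windows against the exon annotation, and sectionize.
#'
#' @inheritParams orient_gene
#' @inheritParams evolutionary_slope
#' @return Section data frame as from [sectionize()].
#' @export
gene_slope_sections <- function(seq, annotation, window = 32L, step = 8L,
                                log_base = "e", reps = DEFAULT_REPRESENTATIVES) {
  or <- orient_gene(seq, annotation)
  series <- evolutionary_slope(or$seq, window = window, step = step,
                               mode = "invariant", reps = reps,
                               log_base = log_base)
  sectionize(series, label_series(series, or$annotation))
}

#' Exon/intron regularity analysis over a gene set
#'
#' Runs [gene_slope_sections()] on every gene, pools section means, and
#' summarizes the exon-intron separation with a two-sample t-test and the
#' Youden-index threshold classification.
#'
#' @param genes Named list; each element has `sequence` and `annotation`.
#' @inheritParams gene_slope_sections
#' @return List with `sections` (per gene), `pooled` (see [pool_sections()]),
#'   `t_test` and `youden` (NULL when a sample is too small).
#' @export
regularity_analysis <- function(genes, window = 32L, step = 8L, log_base = "e") {
  sections <- lapply(genes, function(g) {
    gene_slope_sections(g$sequence, g$annotation, window = window, step = step,
                        log_base = log_base)
  })
  pooled <- pool_sections(sections)
  enough <- length(pooled$exon) >= 2L && length(pooled$intron) >= 2L
  list(
    sections = sections,
    pooled = pooled,
    t_test = if (enough) two_sample_t(pooled$exon, pooled$intron) else NULL,
    youden = if (enough) youden_threshold(pooled$exon, pooled$intron) else NULL
  )
}
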