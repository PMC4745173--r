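## File I/O: FASTA sequences, BED6/GFF3 gene annotations, TSV reports.
## Coordinates are 1-based inclusive everywhere inside the package; BED's
## 0-based half-open convention is converted at the file boundary (by
## rtracklayer, bit-exactly). Missing and infinite slopes are serialized as
## the literal tokens "NA", "+inf" and "-inf", never as empty cells.

#' Read a (multi-record) FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercased sequences, record ids (first
#'   whitespace-delimited word of each header) as names, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop(sprintf("no FASTA records in %s", path), call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1L), 1L)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width, default 70.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene annotations from BED6 or GFF3
#'
#' BED: each line is one exon; lines are grouped into genes by the `name`
#' column, and rtracklayer converts the 0-based half-open coordinates to the
#' internal 1-based inclusive convention. GFF3: `CDS` features define the
#' exons; features are grouped by their `Parent` attribute (falling back to
#' `ID`, then to the seqid). The seqid/chrom of a gene's features must match
#' the FASTA record that carries its sequence.
#'
#' @param path Annotation file path.
#' @param format `"bed"` or `"gff3"` (default: guessed from the extension).
#' @return Named list of [gene_annotation()] objects.
#' @export
read_annotation <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed")
  if (format == "gff3") {
    mc <- S4Vectors::mcols(gr)
    gr <- gr[!is.na(mc$type) & mc$type == "CDS"]
    if (length(gr) == 0L) stop("no CDS features in GFF3 file", call. = FALSE)
    mc <- S4Vectors::mcols(gr)
    ids <- rep(NA_character_, length(gr))
    if ("Parent" %in% names(mc)) {
      par <- mc$Parent
      has <- lengths(par) > 0L
      ids[has] <- vapply(as.list(par[has]), `[[`, character(1L), 1L)
    }
    if ("ID" %in% names(mc)) {
      ids[is.na(ids)] <- as.character(mc$ID[is.na(ids)])
    }
    ids[is.na(ids)] <- as.character(BiocGenerics::as.vector(
      GenomeInfoDb_seqnames(gr)))[is.na(ids)]
  } else {
    mc <- S4Vectors::mcols(gr)
    ids <- if ("name" %in% names(mc) && !all(is.na(mc$name))) {
      as.character(mc$name)
    } else {
      as.character(BiocGenerics::as.vector(GenomeInfoDb_seqnames(gr)))
    }
  }
  starts <- BiocGenerics::start(gr)
  ends <- BiocGenerics::end(gr)
  strands <- as.character(BiocGenerics::strand(gr))
  out <- lapply(split(seq_along(gr), ids), function(i) {
    st <- unique(strands[i])
    st <- st[st %in% c("+", "-")]
    if (length(st) == 0L) st <- "+"
    if (length(st) > 1L) {
      stop(sprintf("gene '%s' mixes strands", ids[i[1L]]), call. = FALSE)
    }
    gene_annotation(ids[i[1L]], st, data.frame(start = starts[i], end = ends[i]))
  })
  out[unique(ids)]
}

## seqnames() lives in GenomeInfoDb, pulled in by rtracklayer; accessed
## lazily so the package does not need a direct import.
GenomeInfoDb_seqnames <- function(gr) {
  getExportedValue("GenomeInfoDb", "seqnames")(gr)
}

format_slope <- function(s) {
  vapply(s, function(x) {
    if (is.na(x)) "NA"
    else if (is.infinite(x)) if (x > 0) "+inf" else "-inf"
    else sprintf("%.10g", x)
  }, character(1L))
}

#' Write a slope series to TSV
#'
#' Columns: `seq_id`, `window_start`, `window_end`, `slope`, `e1`, `e2`,
#' `flag`.
#'
#' @param series A `slope_series` from [evolutionary_slope()].
#' @param path Output path or `""` for stdout.
#' @param seq_id Identifier written in the first column.
#' @return Invisibly, `path`.
#' @export
write_slope_series <- function(series, path, seq_id = "seq") {
  df <- data.frame(seq_id = seq_id,
                   window_start = series$window_start,
                   window_end = series$window_end,
                   slope = format_slope(series$slope),
                   e1 = series$e1, e2 = series$e2, flag = series$flag)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write gene sections to TSV
#'
#' Columns: `gene_id`, `section_index`, `label`, `start`, `end`, `n_windows`,
#' `mean_slope`, `excluded`.
#'
#' @param gene_sections Named list of section data frames from [sectionize()].
#' @param path Output path or `""` for stdout.
#' @return Invisibly, `path`.
#' @export
write_sections <- function(gene_sections, path) {
  rows <- lapply(names(gene_sections), function(id) {
    df <- gene_sections[[id]]
    data.frame(gene_id = id, section_index = df$section_index, label = df$label,
               start = df$start, end = df$end, n_windows = df$n_windows,
               mean_slope = format_slope(df$mean_slope), excluded = df$excluded)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Bundles the tunable analysis settings so a run can be reproduced from a
#' plain-text file: encoding mode (and code for single mode), log base,
#' window and step, the Mallat switch-over threshold, the RNG seed, and the
#' strict-alphabet flag.
#'
#' @param mode `"invariant"` or `"single"`.
#' @param code Assignment order used in single mode.
#' @param log_base `"e"` or `"2"`.
#' @param window,step Evolutionary-slope window and step (nucleotides).
#' @param mallat_threshold Column count above which the column transform uses
#'   pyramidal filtering.
#' @param seed Integer seed or `NULL`.
#' @param strict_alphabet Raise on non-ACGT residues instead of yielding
#'   missing slopes.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = "invariant", code = "ACGT", log_base = "e",
                       window = 32L, step = 8L, mallat_threshold = 2^11,
                       seed = NULL, strict_alphabet = FALSE) {
  mode <- match.arg(mode, c("invariant", "single"))
  log_base_value(log_base)  # validates
  check_assignment(code)
  if (window %% 4 != 0 || window < 8 || step %% 4 != 0) {
    stop("window must be divisible by 4 and >= 8; step divisible by 4",
         call. = FALSE)
  }
  structure(list(mode = mode, code = code,
                 log_base = if (log_base_value(log_base) == 2) "2" else "e",
                 window = as.integer(window), step = as.integer(step),
                 mallat_threshold = as.integer(mallat_threshold),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 strict_alphabet = isTRUE(strict_alphabet)),
            class = "run_config")
}

#' Write / read a run configuration as JSON
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `write_run_config` invisibly returns `path`; `read_run_config`
#'   returns the validated `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x[!vapply(x, is.null, logical(1L))])
}
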