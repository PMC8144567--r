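# File formats used by the pipeline. All readers validate the declared
# dialect and fail with the offending line/column; all pairs satisfy
# read(write(x)) == x.

PLATE_COLS <- c("sample", "drug", "dose_uM", "ir_gy", "replicate", "viability_pct")
CALLS_COLS <- c("chrom", "pos", "ref", "alt", "caller", "t_depth", "t_alt",
                "n_alt", "pop_af", "vaf")

#' Write / read a tidy viability plate CSV
#'
#' Comma-separated, mandatory header, columns `sample, drug, dose_uM,
#' ir_gy, replicate, viability_pct`.
#'
#' @param plate Plate data.frame.
#' @param path File path.
#' @return `read_plate_csv` returns the plate data.frame.
#' @export
write_plate_csv <- function(plate, path) {
  stopifnot(all(PLATE_COLS %in% names(plate)))
  utils::write.csv(plate[PLATE_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(PLATE_COLS, names(df))
  if (length(missing)) {
    stop("plate CSV ", path, " lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Write / read a VCF-like somatic call TSV
#'
#' Tab-separated with header; positions are 1-based (`pos >= 1` is
#' enforced on read with the offending line reported). Core columns
#' `chrom, pos, ref, alt, caller, t_depth, t_alt, n_alt, pop_af, vaf`;
#' extra columns (`sample`, `gene`, `consequence`, `context`, ...) pass
#' through.
#'
#' @param calls Call data.frame.
#' @param path File path.
#' @return `read_calls_tsv` returns the call data.frame.
#' @export
write_calls_tsv <- function(calls, path) {
  stopifnot(all(CALLS_COLS %in% names(calls)))
  ordered <- calls[c(CALLS_COLS, setdiff(names(calls), CALLS_COLS))]
  utils::write.table(ordered, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
read_calls_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(CALLS_COLS, names(df))
  if (length(missing)) {
    stop("call TSV ", path, " lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(df$pos) | df$pos < 1)
  if (length(bad)) {
    stop("call TSV ", path, ": positions must be 1-based integers >= 1 (line ",
         bad[1] + 1L, ", column pos)", call. = FALSE)
  }
  df
}

#' Read / write gene sets in GMT format
#'
#' Tab-separated lines: set name, description, then gene names.
#'
#' @param path File path.
#' @param genesets Named list of character vectors.
#' @param descriptions Optional per-set description (defaults to the name).
#' @return `read_gmt` returns a named list of gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop("GMT ", path, " line ", i,
           ": expected at least name, description and one gene", call. = FALSE)
    }
    sets[[parts[1]]] <- parts[-(1:2)]
  }
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(genesets, path, descriptions = NULL) {
  stopifnot(is.list(genesets), !is.null(names(genesets)))
  if (is.null(descriptions)) descriptions <- names(genesets)
  lines <- mapply(function(nm, desc, genes) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(genesets), descriptions, genesets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read / write a BED interval mask
#'
#' Three tab-separated columns (`chrom`, `start`, `end`), no header,
#' 0-based half-open intervals.
#'
#' @param path File path.
#' @param bed data.frame `chrom`, `start`, `end`.
#' @return `read_bed_mask` returns the interval data.frame.
#' @export
read_bed_mask <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end"))
  bad <- which(df$end <= df$start | df$start < 0)
  if (length(bad)) {
    stop("BED ", path, " line ", bad[1],
         ": intervals must satisfy 0 <= start < end", call. = FALSE)
  }
  df
}

#' @rdname read_bed_mask
#' @export
write_bed_mask <- function(bed, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(bed)))
  utils::write.table(bed[c("chrom", "start", "end")], path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read an expression matrix TSV
#'
#' Tab-separated; first column `gene`, remaining columns one per sample.
#'
#' @param mat Numeric matrix with row and column names.
#' @param path File path.
#' @return `read_expression_tsv` returns the matrix.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") {
    stop("expression TSV ", path, " must start with a `gene` column", call. = FALSE)
  }
  mat <- as.matrix(df[-1])
  rownames(mat) <- df$gene
  mat
}

#' Write / read a signature reference matrix TSV
#'
#' Tab-separated; first column `context` (the 96 trinucleotide classes),
#' one column per signature.
#'
#' @param reference 96 x k matrix with dimnames.
#' @param path File path.
#' @return `read_signature_ref` returns the matrix.
#' @export
write_signature_ref <- function(reference, path) {
  df <- data.frame(context = rownames(reference), reference, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_signature_ref
#' @export
read_signature_ref <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "context") {
    stop("signature TSV ", path, " must start with a `context` column", call. = FALSE)
  }
  mat <- as.matrix(df[-1])
  rownames(mat) <- df$context
  mat
}

#' Write / read a JSON report
#'
#' @param report Named list (scalars unboxed).
#' @param path File path.
#' @return `read_json_report` returns the parsed list.
#' @export
write_json_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_json_report
#' @export
read_json_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
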