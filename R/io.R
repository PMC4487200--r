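.naStrings <- c("", "NA", "na", "Na", "NaN", "nan", "NAN")

#' Read an expression matrix from tab-delimited text
#'
#' Reads a genes-or-probes x samples matrix. Two dialects are auto-detected:
#' plain tab-delimited text (first column row identifier, header row of sample
#' identifiers) and the GCT dialect (version line `#1.2`, a dimensions line,
#' then `Name` and `Description` columns before the samples). Empty fields and
#' `NA`/`NaN` in any letter case are read as missing.
#'
#' @param path file path.
#' @return numeric matrix with row and column names; missing entries are `NA`.
#' @seealso [writeExpressionMatrix()]
#' @export
readExpressionMatrix <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#1.2")) {
    df <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                            na.strings = .naStrings)
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -(1:2), drop = FALSE])
  } else {
    df <- utils::read.delim(path, check.names = FALSE,
                            na.strings = .naStrings)
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
  }
  storage.mode(m) <- "double"
  rownames(m) <- ids
  .asExprMatrix(m)
}

#' Write an expression matrix as tab-delimited text
#'
#' @param m numeric matrix, genes x samples.
#' @param path output file path.
#' @param gct write the GCT dialect (`#1.2` header) instead of plain TSV.
#' @param idColumn header of the identifier column for the plain dialect.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(m, path, gct = FALSE, idColumn = "id") {
  m <- .asExprMatrix(m)
  vals <- matrix(vapply(m, function(x)
    if (is.na(x)) "" else format(x, digits = 15, trim = TRUE), character(1)),
    nrow(m), ncol(m))
  con <- file(path, "w")
  on.exit(close(con))
  if (gct) {
    writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
    header <- paste(c("Name", "Description", colnames(m)), collapse = "\t")
    body <- cbind(rownames(m), "na", vals)
  } else {
    header <- paste(c(idColumn, colnames(m)), collapse = "\t")
    body <- cbind(rownames(m), vals)
  }
  writeLines(header, con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene annotation table
#'
#' Two-column tab-delimited text: probe identifier, gene symbol. Lines
#' starting with `#` are ignored. Probes with an empty or `NA` symbol are kept
#' but flagged unmapped.
#'
#' @param path file path.
#' @param header whether the file carries a header row.
#' @return data.frame with columns `probe_id`, `gene_symbol` (`NA` =
#'   unmapped).
#' @export
readProbeAnnotation <- function(path, header = FALSE) {
  df <- utils::read.delim(path, header = header, comment.char = "#",
                          na.strings = .naStrings,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("annotation must have two columns")
  out <- data.frame(probe_id = df[[1L]], gene_symbol = df[[2L]],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$probe_id))
    stop("each probe may carry at most one gene symbol")
  out
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path file path.
#' @return named list of character vectors of gene symbols.
#' @seealso [writeGmt()]
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop("gene-set names must be unique")
  if (any(lengths(sets) == 0L)) stop("empty gene set in GMT file")
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output file path.
#' @param description description field written for every set.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read reference subset labels
#'
#' Two-column CSV `sample_id,label`.
#'
#' @param path file path.
#' @return named character vector, sample id -> subset label.
#' @export
readSubsetLabels <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  stats::setNames(df[[2L]], df[[1L]])
}

#' Read a long-format clinical table
#'
#' CSV with one row per patient-visit; required columns `patient_id`, `arm`,
#' `visit_day`, `mrss`; `disease_duration` and further covariates optional
#' (constant within patient).
#'
#' @param path file path.
#' @return data.frame.
#' @export
readClinicalTable <- function(path) {
  df <- utils::read.csv(path, na.strings = .naStrings)
  need <- c("patient_id", "arm", "visit_day", "mrss")
  if (!all(need %in% names(df)))
    stop("clinical table needs columns: ", paste(need, collapse = ", "))
  df
}
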