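# Expression-matrix input/output and scale conventions.
#
# Expression matrices are plain numeric matrices, features in rows and samples
# in columns, with unique rownames (feature ids) and colnames (sample ids).
# All values are kept on the linear scale, non-negative and finite.

#' Read an expression matrix from TSV or GCT
#'
#' TSV layout: row 1 is a header whose first field names the feature-id column
#' and whose remaining fields are sample ids; every following row is a feature
#' id plus one numeric value per sample. GCT is the 1.2 dialect: a `#1.2`
#' version line, a dimensions line, then a header with `Name`, `Description`
#' and the sample ids. Duplicate feature ids are collapsed by row-wise mean.
#'
#' @param path Path to the file.
#' @param format `"tsv"`, `"gct"`, or `"auto"` (decide from the extension and
#'   a leading `#1.2` line).
#' @return A numeric feature-by-sample matrix with unique dimnames.
#' @export
read_expression <- function(path, format = c("auto", "tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^#1\\.2", first) || grepl("\\.gct$", path, ignore.case = TRUE))
      "gct" else "tsv"
  }
  if (format == "gct") {
    hdr <- readLines(path, n = 2L)
    if (length(hdr) < 2L || !grepl("^#1\\.2", hdr[1L]))
      stop("malformed GCT header at line 1: expected '#1.2' in ", path)
    dims <- strsplit(hdr[2L], "\t")[[1L]]
    if (length(dims) < 2L || anyNA(suppressWarnings(as.integer(dims[1:2]))))
      stop("malformed GCT dimensions at line 2 in ", path)
    tab <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 3L || !identical(tolower(names(tab)[1:2]), c("name", "description")))
      stop("malformed GCT header at line 3: expected 'Name' and 'Description' columns")
    ids <- as.character(tab[[1L]])
    vals <- tab[, -(1:2), drop = FALSE]
  } else {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L)
      stop("malformed header at line 1: need a feature-id column plus >=1 sample")
    ids <- as.character(tab[[1L]])
    vals <- tab[, -1L, drop = FALSE]
  }
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric value at feature '%s', sample '%s'",
                     ids[bad[1L]], names(vals)[j]))
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at feature '%s', sample '%s'",
                 ids[idx[1L]], colnames(m)[idx[2L]]))
  }
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in header")
  if (anyDuplicated(ids)) {
    counts <- table(ids)[unique(ids)]
    m <- rowsum(m, group = ids, reorder = FALSE) / as.vector(counts)
    ids <- unique(ids)
  }
  rownames(m) <- ids
  if (!all(is.finite(m))) stop("non-finite expression values in ", path)
  m
}

#' Write an expression matrix to TSV or GCT
#'
#' @param m Numeric feature-by-sample matrix.
#' @param path Output path.
#' @param format `"tsv"` or `"gct"` (1.2 dialect).
#' @param id_col Header name of the feature-id column for TSV output.
#' @return The path, invisibly.
#' @export
write_expression <- function(m, path, format = c("tsv", "gct"),
                             id_col = "feature_id") {
  format <- match.arg(format)
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (format == "gct") {
    names(df)[1L] <- "Name"
    df <- cbind(df[1L], Description = rownames(m), df[-1L])
    con <- file(path, "w")
    writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  } else {
    names(df)[1L] <- id_col
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Enforce the linear expression scale
#'
#' Deconvolution operates on linear-scale expression. Matrices whose maximum
#' value is below 50 are taken to be log2 and are exponentiated; anything else
#' is passed through unchanged. The heuristic can be overridden.
#'
#' @param m Numeric expression matrix with finite values.
#' @param assume `"auto"` (threshold rule), `"linear"` (never transform), or
#'   `"log2"` (always transform).
#' @return The linear-scale matrix, with attribute `"delogged"` set to `TRUE`
#'   if a transformation was applied.
#' @export
ensure_linear_scale <- function(m, assume = c("auto", "linear", "log2")) {
  assume <- match.arg(assume)
  if (!all(is.finite(m))) stop("expression values must be finite")
  delog <- switch(assume,
    auto = max(m) < 50,
    linear = FALSE,
    log2 = TRUE)
  if (delog) {
    m <- 2^m
  } else if (any(m < 0)) {
    stop("negative values in a linear-scale expression matrix (corrupt input)")
  }
  attr(m, "delogged") <- delog
  m
}

#' Bundle an expression matrix with cell-type labels
#'
#' @param m Feature-by-sample expression matrix (linear scale).
#' @param labels Named character vector, `sample_id -> cell type`, or a
#'   2-column data frame (`sample_id`, `cell_type`).
#' @return A `td_reference` object: list with elements `matrix`, `labels`
#'   (named character, aligned to the matrix columns) and `cell_types`
#'   (ordered by first appearance).
#' @export
reference_set <- function(m, labels) {
  if (is.data.frame(labels)) {
    if (!all(c("sample_id", "cell_type") %in% names(labels)))
      stop("label table needs columns 'sample_id' and 'cell_type'")
    labels <- stats::setNames(as.character(labels$cell_type),
                              as.character(labels$sample_id))
  }
  miss <- setdiff(colnames(m), names(labels))
  if (length(miss))
    stop("unlabeled samples: ", paste(miss, collapse = ", "))
  labels <- labels[colnames(m)]
  types <- unique(unname(labels))
  if (length(types) < 2L) stop("a reference needs at least 2 cell types")
  structure(list(matrix = m, labels = labels, cell_types = types),
            class = "td_reference")
}

#' @export
print.td_reference <- function(x, ...) {
  cat(sprintf("Reference set: %d features x %d samples, %d cell types\n",
              nrow(x$matrix), ncol(x$matrix), length(x$cell_types)))
  print(table(factor(x$labels, levels = x$cell_types)))
  invisible(x)
}

#' Read sample-to-cell-type labels from TSV
#'
#' @param path TSV with columns `sample_id` and `cell_type`.
#' @return Named character vector `sample_id -> cell_type`.
#' @export
read_labels <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "cell_type") %in% names(tab)))
    stop("label file needs columns 'sample_id' and 'cell_type': ", path)
  stats::setNames(as.character(tab$cell_type), as.character(tab$sample_id))
}

#' Read a phenotype table from TSV
#'
#' Requires a `sample_id` column; optional `group`, `pair_id` and numeric
#' covariate columns. Every `pair_id` that is present must occur in exactly
#' two samples.
#'
#' @param path TSV path.
#' @return A data frame.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  if (!"sample_id" %in% names(tab))
    stop("phenotype table needs a 'sample_id' column: ", path)
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_id in phenotype table")
  if ("pair_id" %in% names(tab)) {
    counts <- table(tab$pair_id[!is.na(tab$pair_id)])
    bad <- names(counts)[counts != 2L]
    if (length(bad))
      stop("pair_id must occur in exactly 2 samples; offending: ",
           paste(bad, collapse = ", "))
  }
  tab
}
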