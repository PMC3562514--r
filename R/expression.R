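#' Expression matrix container
#'
#' A thin S3 wrapper around a numeric feature-by-sample matrix of
#' log2-scale expression indexes (the scale produced by RMA-style
#' pre-processing).  Rows are features (probesets, genes or miRNAs),
#' columns are samples.  The `role` records what the rows measure:
#' `"mrna"` for measured coding-gene expression, `"mirna"` for measured
#' miRNA expression, `"pseudo"` for in-silico predicted miRNA expression.
#'
#' @param values numeric matrix; all entries must be finite.
#' @param role one of `"mrna"`, `"mirna"`, `"pseudo"`.
#' @return An object of class `expr_matrix`: the matrix with a `role`
#'   attribute and unique, non-empty dimnames.
#' @export
expression_matrix <- function(values, role = c("mrna", "mirna", "pseudo")) {
  role <- match.arg(role)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (ncol(values) < 2L)
    stop("an expression matrix needs at least 2 samples (columns)")
  if (any(!is.finite(values)))
    stop("expression values must all be finite")
  rid <- rownames(values); cid <- colnames(values)
  if (is.null(rid) || is.null(cid))
    stop("`values` must carry row and column names")
  if (anyDuplicated(rid))
    stop("duplicate feature ids: ",
         paste(unique(rid[duplicated(rid)]), collapse = ", "))
  if (anyDuplicated(cid))
    stop("duplicate sample ids: ",
         paste(unique(cid[duplicated(cid)]), collapse = ", "))
  structure(values, role = role, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix role=%s> %d features x %d samples\n",
              attr(x, "role"), nrow(x), ncol(x)))
  print(head(unclass(x)[, seq_len(min(ncol(x), 6L)), drop = FALSE], 5L))
  invisible(x)
}

#' Role of an expression matrix
#' @param x an `expr_matrix`.
#' @return `"mrna"`, `"mirna"` or `"pseudo"`.
#' @export
expr_role <- function(x) attr(x, "role")

#' Read an expression matrix from delimited text
#'
#' Expects a header row of sample ids and a first column of feature ids.
#' The delimiter is sniffed from the extension (`.csv` vs tab) unless
#' given explicitly.
#'
#' @param path file path.
#' @param role matrix role, see [expression_matrix()].
#' @param sep field separator; default `","` for `.csv`, tab otherwise.
#' @return An `expr_matrix`.
#' @export
read_expression <- function(path, role = c("mrna", "mirna", "pseudo"),
                            sep = NULL) {
  role <- match.arg(role)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("expression file needs an id column and >=2 samples")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate feature ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric value %s at row %d (%s), column %s",
                 dQuote(body[bad[1L, 1L], bad[1L, 2L]]),
                 bad[1L, 1L], ids[bad[1L, 1L]], colnames(body)[bad[1L, 2L]]))
  dimnames(num) <- list(ids, colnames(body))
  expression_matrix(num, role)
}

#' Write an expression matrix to delimited text
#'
#' Inverse of [read_expression()]; values are written with full
#' precision (`format(..., digits = 17)`) so a round-trip is
#' bit-identical.
#'
#' @param x an `expr_matrix`.
#' @param path output path; `.csv` selects comma separation.
#' @param sep field separator override.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(feature_id = rownames(x),
                   format(unclass(x), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("feature_id", colnames(x))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quantile-normalize an expression matrix
#'
#' Cross-sample normalization: after normalization every column holds
#' the identical multiset of values (the mean of the per-rank values
#' across columns).  Backed by [limma::normalizeQuantiles()].
#'
#' @param x an `expr_matrix` with at least 2 columns.
#' @return A normalized `expr_matrix` with ids and role preserved.
#' @export
quantile_normalize <- function(x) {
  if (ncol(x) < 2L) stop("need >=2 columns to quantile-normalize")
  out <- limma::normalizeQuantiles(unclass(x), ties = FALSE)
  dimnames(out) <- dimnames(x)
  expression_matrix(out, expr_role(x))
}

#' Sample design table
#'
#' Assigns each sample to an experimental group.  A single grouping
#' vector is the usual two-group t-test design; a multi-column data
#' frame of factors is collapsed to one grouping by [interaction()] for
#' one-way ANOVA testing.
#'
#' @param sample_ids character vector of sample ids.
#' @param groups vector (or data frame of factor columns) of group
#'   labels, parallel to `sample_ids`.
#' @return A `design_table` data frame with columns `sample_id`, `group`.
#' @export
design_table <- function(sample_ids, groups) {
  if (is.data.frame(groups)) {
    if (nrow(groups) != length(sample_ids))
      stop("design rows must match sample ids")
    groups <- as.character(interaction(groups, drop = TRUE, sep = ":"))
  }
  groups <- as.character(groups)
  if (length(groups) != length(sample_ids))
    stop("`groups` must be parallel to `sample_ids`")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in design")
  tab <- table(groups)
  if (length(tab) < 2L) stop("design needs >=2 distinct groups")
  if (any(tab < 2L))
    stop("every group needs >=2 samples; offending: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  structure(data.frame(sample_id = as.character(sample_ids), group = groups,
                       stringsAsFactors = FALSE),
            class = c("design_table", "data.frame"))
}

#' Read a design table
#'
#' Two-column TSV (`sample_id`, `group`); extra columns are treated as
#' additional ANOVA factors and collapsed via [interaction()].
#'
#' @param path file path.
#' @return A `design_table`.
#' @export
read_design <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("design file needs sample_id plus >=1 group column")
  design_table(df[[1L]], df[, -1L, drop = FALSE])
}

# match design to matrix columns; errors if any column is unassigned
design_groups <- function(x, design) {
  idx <- match(colnames(x), design$sample_id)
  if (anyNA(idx))
    stop("samples missing from design: ",
         paste(colnames(x)[is.na(idx)], collapse = ", "))
  factor(design$group[idx])
}
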