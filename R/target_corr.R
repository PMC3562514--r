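#' miRNA-vs-mRNA correlation matrix
#'
#' Correlates every row of a (pseudo-)miRNA expression matrix against
#' every row of an mRNA expression matrix over the shared samples.
#' Positive entries indicate host-like co-expression; strong negative
#' entries indicate candidate repression targets.  Rows with zero
#' variance produce undefined correlations, recorded as `NA` and
#' counted in a message.
#'
#' @param mirna_mat miRNA or pseudo-expression `expr_matrix`.
#' @param mrna_mat mRNA `expr_matrix` with identical sample columns.
#' @param method `"pearson"`, `"spearman"` (average ranks on ties) or
#'   `"kendall"` (tau-b).
#' @return A `corr_matrix`: numeric matrix (miRNA rows x mRNA columns)
#'   with attribute `method`.
#' @export
correlate <- function(mirna_mat, mrna_mat,
                      method = c("pearson", "spearman", "kendall")) {
  method <- match.arg(method)
  if (!identical(colnames(mirna_mat), colnames(mrna_mat)))
    stop("matrices must share identical sample columns")
  cm <- suppressWarnings(
    cor(t(unclass(mirna_mat)), t(unclass(mrna_mat)), method = method))
  dimnames(cm) <- list(rownames(mirna_mat), rownames(mrna_mat))
  n_na <- sum(is.na(cm))
  if (n_na) message(n_na, " undefined correlation(s) from zero-variance rows")
  structure(cm, method = method, class = c("corr_matrix", "matrix", "array"))
}

#' Extract strongly anti-correlated miRNA-target pairs
#'
#' The anti-correlation filter: keeps every (miRNA, mRNA feature) pair
#' whose correlation is at or below a negative cutoff, sorted ascending
#' (strongest repression first).  The default cutoff of -0.8 trades
#' breadth for reliability; relax it (e.g. -0.6) for a broader but
#' noisier candidate list.  Undefined (`NA`) correlations never pass.
#'
#' @param corr a `corr_matrix`.
#' @param cutoff negative correlation threshold (default -0.8).
#' @return Data frame `mirna_id`, `target_id`, `correlation`, sorted
#'   ascending by correlation (possibly 0 rows).
#' @export
get_ht <- function(corr, cutoff = -0.8) {
  if (!is.numeric(cutoff) || cutoff >= 0)
    stop("`cutoff` must be a negative number")
  hit <- which(!is.na(corr) & corr <= cutoff, arr.ind = TRUE)
  out <- data.frame(mirna_id = rownames(corr)[hit[, 1L]],
                    target_id = colnames(corr)[hit[, 2L]],
                    correlation = corr[hit],
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$correlation), , drop = FALSE]
}

#' Direction of the predicted regulation
#'
#' Reads the regulatory direction from the two fold changes: an
#' up-regulated miRNA with a down-regulated gene means repression has
#' been gained; a down-regulated miRNA with an up-regulated gene means
#' existing repression has been lifted.  Concordant signs are kept but
#' labelled inconsistent.
#'
#' @param mirna_fc,gene_fc signed log2 fold changes.
#' @return `"repression_gained"`, `"repression_lifted"` or
#'   `"inconsistent"` (vectorized).
#' @export
direction_of_regulation <- function(mirna_fc, gene_fc) {
  ifelse(mirna_fc > 0 & gene_fc < 0, "repression_gained",
         ifelse(mirna_fc < 0 & gene_fc > 0, "repression_lifted",
                "inconsistent"))
}

#' Summarize predicted interactions into the three report lists
#'
#' Aggregates probe-level anti-correlation hits to the gene level and
#' produces: (1) influenced genes grouped by miRNA, (2) miRNAs grouped
#' by the genes they influence, and (3) the flat interaction list with
#' a support score — the number of (probeset, mature miRNA)
#' anti-correlated entries backing each (miRNA, gene) pair.  Probe ids
#' are translated to gene ids/symbols/names via the annotation table;
#' unannotated probes are kept under their raw id and flagged.
#'
#' @param interactions output of [get_ht()].
#' @param annotation data frame `probeset_id`, `entrez`, `symbol`,
#'   `name` (extra columns ignored); may be NULL for no translation.
#' @return A list of data frames `by_mirna`, `by_gene`, `interactions`.
#' @export
summarize_interactions <- function(interactions, annotation = NULL) {
  if (nrow(interactions) == 0L) {
    empty <- data.frame()
    return(list(by_mirna = empty, by_gene = empty, interactions = empty))
  }
  x <- interactions
  if (!is.null(annotation)) {
    idx <- match(x$target_id, annotation$probeset_id)
    x$entrez <- annotation$entrez[idx]
    x$symbol <- annotation$symbol[idx]
    x$gene_name <- annotation$name[idx]
    x$annotated <- !is.na(idx)
    x$symbol[is.na(x$symbol)] <- x$target_id[is.na(x$symbol)]
  } else {
    x$entrez <- NA_character_; x$gene_name <- NA_character_
    x$symbol <- x$target_id; x$annotated <- FALSE
  }
  key <- paste(x$mirna_id, x$symbol, sep = "\r")
  agg <- data.frame(
    mirna_id = tapply(x$mirna_id, key, `[`, 1L),
    symbol = tapply(x$symbol, key, `[`, 1L),
    entrez = tapply(x$entrez, key, `[`, 1L),
    gene_name = tapply(x$gene_name, key, `[`, 1L),
    correlation = tapply(x$correlation, key, min),
    support = as.integer(tapply(x$correlation, key, length)),
    annotated = tapply(x$annotated, key, `[`, 1L),
    stringsAsFactors = FALSE, row.names = NULL)
  agg <- agg[order(agg$correlation), , drop = FALSE]
  rownames(agg) <- NULL
  by_mirna <- agg[order(agg$mirna_id, agg$correlation), , drop = FALSE]
  rownames(by_mirna) <- NULL
  by_gene <- agg[order(agg$symbol, agg$correlation), , drop = FALSE]
  rownames(by_gene) <- NULL
  list(by_mirna = by_mirna, by_gene = by_gene, interactions = agg)
}
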