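#' Read a gene-set collection from GMT
#'
#' Standard GMT: one tab-separated line per term — term id, description,
#' then the member gene ids.  Members are de-duplicated within a term.
#'
#' @param path GMT file path.
#' @param label collection label (e.g. `"GO"`, `"KEGG"`, `"user"`).
#' @return A `gene_set_collection`: named list of character vectors with
#'   attributes `descriptions` and `label`.
#' @export
read_gmt <- function(path, label = "user") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  ids <- vapply(parts, `[`, character(1L), 1L)
  if (anyDuplicated(ids)) stop("duplicate term ids in ", path)
  sets <- lapply(parts, function(p) unique(p[-c(1L, 2L)]))
  names(sets) <- ids
  descs <- setNames(vapply(parts, `[`, character(1L), 2L), ids)
  structure(sets, descriptions = descs, label = label,
            class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#' @param x a `gene_set_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  descs <- attr(x, "descriptions")
  if (is.null(descs)) descs <- setNames(names(x), names(x))
  lines <- vapply(names(x), function(id)
    paste(c(id, descs[[id]], x[[id]]), collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation test
#'
#' For each term, tests whether the query gene list overlaps the term's
#' gene set more than expected under random draws from the universe:
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)` with universe size
#' `N`, term size `K` (after intersection with the universe), query
#' size `n` and overlap `k`.  Raw p-values are reported alongside a
#' Benjamini-Hochberg adjustment; rankings are unaffected by the
#' adjustment.
#'
#' @param query character vector of gene ids (must be within
#'   `universe`).
#' @param collection a `gene_set_collection`.
#' @param universe character vector of all testable gene ids (default
#'   in the pipeline: all annotated genes on the expression matrix).
#' @param adjust multiple-testing method for the `p_adj` column.
#' @return Data frame `term_id`, `description`, `k`, `K`, `n`, `N`,
#'   `p`, `p_adj`, sorted ascending by `p`.
#' @export
hypergeom_enrich <- function(query, collection, universe,
                             adjust = c("bh", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  query <- unique(query)
  if (!length(query)) stop("empty query")
  if (!all(query %in% universe))
    stop("query contains ids outside the universe: ",
         paste(head(setdiff(query, universe)), collapse = ", "))
  universe <- unique(universe)
  N <- length(universe); n <- length(query)
  res <- lapply(names(collection), function(id) {
    set <- intersect(collection[[id]], universe)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  descs <- attr(collection, "descriptions")
  out$description <- if (is.null(descs)) out$term_id else
    as.character(descs[out$term_id])
  out$p_adj <- adjust_pvalues(out$p, method = adjust)
  out <- out[order(out$p), c("term_id", "description", "k", "K", "n", "N",
                             "p", "p_adj")]
  rownames(out) <- NULL
  out
}

#' Adjust p-values for multiple testing
#'
#' Thin wrapper over [stats::p.adjust()] restricted to the methods the
#' reports use.
#'
#' @param pvals numeric vector in `[0, 1]`.
#' @param method `"bh"`, `"bonferroni"` or `"none"`.
#' @return Adjusted p-values, order-preserving.
#' @export
adjust_pvalues <- function(pvals, method = c("bh", "bonferroni", "none")) {
  method <- match.arg(method)
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  switch(method,
         bh = p.adjust(pvals, method = "BH"),
         bonferroni = p.adjust(pvals, method = "bonferroni"),
         none = pvals)
}

#' One-sided Fisher exact test on a 2x2 overlap table
#'
#' Tests whether the overlap `a` between two prediction sets is larger
#' than expected: the table is `[[a, b], [c, d]]` and the p-value is
#' the upper hypergeometric tail (alternative "greater").
#'
#' @param a,b,c,d nonnegative integer cell counts; `a` is the overlap.
#' @return One-sided p-value.
#' @export
fisher_overlap_test <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be nonnegative integers")
  if (sum(cells) == 0) stop("all-zero table")
  tab <- matrix(cells, nrow = 2L, byrow = TRUE)
  fisher.test(tab, alternative = "greater")$p.value
}
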