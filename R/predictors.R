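#' Scaling-function coefficients
#'
#' The three edge-attribute coefficients of the scaling predictor.
#' Intronic overlaps are promoted (the intron is spliced out and
#' available to the miRNA-maturation machinery) while exonic and UTR
#' overlaps, antisense edges and purely predicted annotations are
#' demoted.
#'
#' @param k_sense named numeric, default `c(sense = 1.2, antisense = 0.8)`.
#' @param k_overlap named numeric, default
#'   `c(intron = 2, exon = 0.8, utr3 = 0.8, utr5 = 0.8)`.
#' @param k_evidence named numeric, default
#'   `c(experimental = 1.2, predicted = 0.8)`.
#' @return A `scaling_coefficients` list.
#' @export
scaling_coefficients <- function(
    k_sense = c(sense = 1.2, antisense = 0.8),
    k_overlap = c(intron = 2, exon = 0.8, utr3 = 0.8, utr5 = 0.8),
    k_evidence = c(experimental = 1.2, predicted = 0.8)) {
  stopifnot(all(k_sense > 0), all(k_overlap > 0), all(k_evidence > 0))
  structure(list(k_sense = k_sense, k_overlap = k_overlap,
                 k_evidence = k_evidence),
            class = "scaling_coefficients")
}

#' Edge weights for the scaling predictor
#'
#' Per mapped host transcript i the weight is
#' `w_i = |FC_i| * (1 - pval_i) * k_sense * k_overlap * k_evidence`,
#' so strongly, confidently differential hosts on promoted edge classes
#' dominate the pseudo-expression average.
#'
#' @param hosts a `mapped_hosts` from [map_expression_rows()].
#' @param mapping the `mir_mapping` the hosts were derived from.
#' @param stats `diff_stats` covering every mapped host row (matched by
#'   feature id of the bound matrix).
#' @param mat the `expr_matrix` the hosts index into.
#' @param coeffs a [scaling_coefficients()].
#' @return Named list of numeric weight vectors, parallel to `hosts`.
#' @export
compute_weights <- function(hosts, mapping, stats, mat,
                            coeffs = scaling_coefficients()) {
  lapply(hosts, function(h) {
    if (nrow(h) == 0L) return(numeric(0L))
    ids <- rownames(mat)[h$row]
    idx <- match(ids, stats$feature_id)
    if (anyNA(idx))
      stop("no statistics for probeset(s): ",
           paste(ids[is.na(idx)], collapse = ", "))
    e <- as.data.frame(mapping)[h$edge, ]
    abs(stats$fc[idx]) * (1 - stats$pval[idx]) *
      coeffs$k_sense[e$strand] *
      coeffs$k_overlap[e$overlap] *
      coeffs$k_evidence[e$evidence]
  })
}

#' Scaling-function pseudo-expression predictor
#'
#' For each mature miRNA, the predicted expression in a sample is the
#' mean over its mapped host rows of host expression times edge weight.
#' The mean is deliberately unnormalized (not divided by the weight
#' sum): that is the predictor's stated form, at the cost of possibly
#' overestimating fold changes of highly expressed hosts.  Set
#' `normalize = TRUE` for a weighted mean normalized by the weight sum.
#'
#' @inheritParams compute_weights
#' @param normalize divide by the weight sum instead of the host count.
#' @return A `pseudo_expr` object: an `expr_matrix` with role
#'   `"pseudo"`, attribute `predictor = "scaling"`, and per-row host
#'   provenance in attribute `provenance`.  miRNAs with no mapped host
#'   are omitted; miRNAs whose weights are all zero yield an all-zero
#'   row (with warning).
#' @export
scaling_predict <- function(mat, stats, hosts, mapping,
                            coeffs = scaling_coefficients(),
                            normalize = FALSE) {
  if (expr_role(mat) != "mrna") stop("matrix role must be 'mrna'")
  w <- compute_weights(hosts, mapping, stats, mat, coeffs)
  keep <- vapply(hosts, nrow, integer(1L)) > 0L
  if (!any(keep)) stop("no miRNA has a mapped host in the matrix")
  hosts <- hosts[keep]; w <- w[keep]
  zero <- vapply(w, function(v) all(v == 0), logical(1L))
  if (any(zero))
    warning("all-zero weight vector for: ",
            paste(names(w)[zero], collapse = ", "))
  vals <- t(vapply(names(hosts), function(m) {
    e <- unclass(mat)[hosts[[m]]$row, , drop = FALSE]
    ww <- w[[m]]
    if (normalize && sum(ww) > 0) colSums(e * ww) / sum(ww)
    else colMeans(e * ww)
  }, numeric(ncol(mat))))
  colnames(vals) <- colnames(mat)
  out <- expression_matrix(vals, "pseudo")
  attr(out, "predictor") <- "scaling"
  attr(out, "provenance") <- lapply(hosts, function(h) rownames(mat)[h$row])
  class(out) <- c("pseudo_expr", class(out))
  out
}

#' Regression rows for the linear-model predictor
#'
#' The linear predictor cannot regress one miRNA on a variable number
#' of host transcripts directly, so it builds one row per
#' (miRNA, host transcript, sample): response = measured miRNA
#' expression, covariates per formula variant.  Variant `standard`
#' (the pipeline default) uses host expression `e`, `|FC|`, `(1 - pval)`
#' and the miRNA-identity factor; `full` adds the categorical edge
#' attributes; `minimal` keeps only `e` and the identity factor.
#'
#' @param mirna_mat measured miRNA `expr_matrix` (response), sharing
#'   sample ids with `mrna_mat`.
#' @param mrna_mat host mRNA `expr_matrix`.
#' @param stats `diff_stats` on `mrna_mat`.
#' @param hosts `mapped_hosts` binding mature miRNA ids of `mirna_mat`
#'   rows to `mrna_mat` rows.
#' @param mapping the `mir_mapping` behind `hosts`.
#' @param variant `"standard"`, `"full"` or `"minimal"`.
#' @return A data frame of regression rows: `mirid`, `transcript`,
#'   `sample`, `y`, `e`, `fc`, `pv` and (full) `overlap`, `strand`,
#'   `evidence`; attribute `variant`.
#' @export
build_design_rows <- function(mirna_mat, mrna_mat, stats, hosts, mapping,
                              variant = c("standard", "full", "minimal")) {
  variant <- match.arg(variant)
  if (!identical(colnames(mirna_mat), colnames(mrna_mat)))
    stop("paired matrices must share identical sample columns")
  common <- intersect(rownames(mirna_mat), names(hosts))
  if (!length(common)) stop("no miRNA row has mapped hosts")
  edf <- as.data.frame(mapping)
  out <- list()
  for (m in common) {
    h <- hosts[[m]]
    if (nrow(h) == 0L) next
    ids <- rownames(mrna_mat)[h$row]
    sidx <- match(ids, stats$feature_id)
    if (anyNA(sidx)) stop("missing statistics for host(s) of ", m)
    for (k in seq_len(nrow(h))) {
      out[[length(out) + 1L]] <- data.frame(
        mirid = m, transcript = ids[k], sample = colnames(mrna_mat),
        y = unclass(mirna_mat)[m, ],
        e = unclass(mrna_mat)[h$row[k], ],
        fc = abs(stats$fc[sidx[k]]),
        pv = 1 - stats$pval[sidx[k]],
        overlap = edf$overlap[h$edge[k]],
        strand = edf$strand[h$edge[k]],
        evidence = edf$evidence[h$edge[k]],
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  rows <- do.call(rbind, out)
  rownames(rows) <- NULL
  attr(rows, "variant") <- variant
  rows
}

# per-variant RHS of the per-miRNA regression (full factorial expansion
# of the continuous covariates; the miRNA-identity factor is realized
# as independent per-miRNA fits, which is the same model)
.variant_formula <- function(variant) {
  switch(variant,
         full = stats::as.formula("y ~ e * fc * pv * overlap * strand * evidence"),
         standard = stats::as.formula("y ~ e * fc * pv"),
         minimal = stats::as.formula("y ~ e"))
}

#' Fit the linear-model predictor
#'
#' Least-squares fit of the variant formula with per-miRNA
#' coefficients.  The miRNA-identity factor interacting with every term
#' is equivalent to independent per-miRNA regressions, which is how the
#' fit is computed.  Rows are split at random into a training set (2/3
#' by default) and a held-out test set; the reported `test_r` is the
#' Pearson correlation between predicted and observed miRNA expression
#' on the test rows (median-aggregated per miRNA and sample across
#' transcripts, as in prediction).
#'
#' @param rows output of [build_design_rows()].
#' @param train_frac training fraction of rows, default 2/3.
#' @param seed integer seed for the split.
#' @param prefilter keep only sense-strand intronic rows before
#'   fitting (the best-performing configuration); default TRUE.
#' @return A `linear_model_fit`: list of per-miRNA `lm` coefficient
#'   vectors, the variant, `mir_levels`, `test_r`, and split metadata.
#' @export
fit_linear_model <- function(rows, train_frac = 2 / 3, seed = 1L,
                             prefilter = TRUE) {
  variant <- attr(rows, "variant")
  if (is.null(variant)) stop("`rows` must come from build_design_rows()")
  if (prefilter && variant != "full") {
    keep <- rows$strand == "sense" & rows$overlap == "intron"
    if (any(keep)) rows <- rows[keep, , drop = FALSE]
    else message("pre-filter would drop all rows; skipped")
  }
  set.seed(seed)
  n <- nrow(rows)
  train <- sort(sample.int(n, size = max(2L, round(train_frac * n))))
  test <- setdiff(seq_len(n), train)
  tr <- rows[train, , drop = FALSE]
  form <- .variant_formula(variant)
  mir_levels <- sort(unique(tr$mirid))
  dropped <- setdiff(unique(rows$mirid), mir_levels)
  if (length(dropped))
    warning("miRNA(s) absent from the training split, excluded: ",
            paste(dropped, collapse = ", "))
  fits <- lapply(mir_levels, function(m) {
    d <- tr[tr$mirid == m, , drop = FALSE]
    if (nrow(d) < 2L) stop("miRNA ", m, " has <2 training rows")
    fit <- lm(form, data = d)
    cf <- coef(fit)
    sm <- suppressWarnings(summary(fit))$coefficients
    se <- setNames(rep(NA_real_, length(cf)), names(cf))
    se[rownames(sm)] <- sm[, "Std. Error"]
    if (anyNA(cf)) {
      message("aliased coefficient(s) dropped for ", m, ": ",
              paste(names(cf)[is.na(cf)], collapse = ", "))
      cf[is.na(cf)] <- 0
    }
    list(cf = cf, se = se)
  })
  names(fits) <- mir_levels
  obj <- structure(list(variant = variant, mir_levels = mir_levels,
                        coefficients = lapply(fits, `[[`, "cf"),
                        std_errors = lapply(fits, `[[`, "se"),
                        train_frac = train_frac,
                        seed = seed, prefilter = prefilter, test_r = NA_real_),
                   class = "linear_model_fit")
  if (length(test)) {
    te <- rows[test, , drop = FALSE]
    te <- te[te$mirid %in% mir_levels, , drop = FALSE]
    if (nrow(te)) {
      pred <- .lm_rows_predict(obj, te)
      key <- paste(te$mirid, te$sample)
      obs <- tapply(te$y, key, median)
      prd <- tapply(pred, key, median)
      obj$test_r <- cor(as.numeric(obs), as.numeric(prd))
    }
  }
  obj
}

# evaluate the per-miRNA fitted equations on prepared rows
.lm_rows_predict <- function(fit, rows) {
  form <- .variant_formula(fit$variant)
  pred <- numeric(nrow(rows))
  for (m in unique(rows$mirid)) {
    idx <- rows$mirid == m
    cf <- fit$coefficients[[m]]
    mm <- stats::model.matrix(stats::delete.response(stats::terms(form)),
                              data = rows[idx, , drop = FALSE])
    common <- intersect(colnames(mm), names(cf))
    pred[idx] <- as.numeric(mm[, common, drop = FALSE] %*% cf[common])
  }
  pred
}

#' @export
print.linear_model_fit <- function(x, ...) {
  cat(sprintf("<linear_model_fit %s> %d miRNAs, train %.2f, held-out r = %.4f\n",
              x$variant, length(x$mir_levels), x$train_frac, x$test_r))
  invisible(x)
}

#' Predict miRNA pseudo-expression with a fitted linear model
#'
#' Evaluates the per-miRNA fitted equations on every
#' (miRNA, transcript, sample) combination, then aggregates across a
#' miRNA's host transcripts by the median to give the final per-sample
#' prediction.
#'
#' @param fit a `linear_model_fit`.
#' @param mrna_mat host mRNA `expr_matrix`.
#' @param stats `diff_stats` on `mrna_mat`.
#' @param hosts `mapped_hosts` for `mrna_mat`.
#' @param mapping the mapping behind `hosts`.
#' @return A `pseudo_expr` (role `"pseudo"`, predictor `"linear"`).
#'   miRNAs not represented in the fit are omitted with a warning.
#' @export
lm_predict <- function(fit, mrna_mat, stats, hosts, mapping) {
  known <- intersect(names(hosts), fit$mir_levels)
  skipped <- setdiff(names(hosts)[vapply(hosts, nrow, integer(1L)) > 0L],
                     known)
  if (length(skipped))
    warning("miRNA(s) not in the fitted model, omitted: ",
            paste(skipped, collapse = ", "))
  if (!length(known)) stop("no mapped miRNA is present in the fit")
  fake_resp <- expression_matrix(
    matrix(0, length(known), ncol(mrna_mat),
           dimnames = list(known, colnames(mrna_mat))), "mirna")
  rows <- build_design_rows(fake_resp, mrna_mat, stats, hosts, mapping,
                            variant = fit$variant)
  if (fit$prefilter && fit$variant != "full") {
    keep <- rows$strand == "sense" & rows$overlap == "intron"
    if (any(keep)) rows <- rows[keep, , drop = FALSE]
  }
  rows$pred <- .lm_rows_predict(fit, rows)
  agg <- tapply(rows$pred, list(rows$mirid, rows$sample), median)
  agg <- agg[, colnames(mrna_mat), drop = FALSE]
  agg <- agg[rowSums(is.na(agg)) == 0L, , drop = FALSE]
  out <- expression_matrix(agg, "pseudo")
  attr(out, "predictor") <- "linear"
  attr(out, "provenance") <- lapply(
    split(rows$transcript, rows$mirid), unique)
  class(out) <- c("pseudo_expr", class(out))
  out
}

#' Significantly misregulated miRNAs from a pseudo-expression matrix
#'
#' Applies the same machinery used for genes — per-row test plus the
#' permutation-derived cutoff — to a pseudo-expression matrix, and
#' reads the direction of change from the sign of the pseudo fold
#' change.
#'
#' @param pseudo a `pseudo_expr` (or any `expr_matrix`).
#' @param design a [design_table()].
#' @param n_perm,seed,test passed to [permutation_cutoff()] /
#'   [row_stats()].
#' @return A `mirna_calls` data frame: `mirna_id`, `fc`, `pval`,
#'   `direction` (`up`/`down`); attributes `cutoff` and `predictor`.
#' @export
significant_mirnas <- function(pseudo, design, n_perm = 1L, seed,
                               test = c("welch", "student", "anova")) {
  test <- match.arg(test)
  if (nrow(pseudo) < 1L) stop("pseudo matrix has no rows")
  st <- suppressMessages(row_stats(pseudo, design, test = test))
  cut <- permutation_cutoff(pseudo, design, n_perm = n_perm, seed = seed,
                            test = test)
  keep <- st$pval < cut
  out <- data.frame(mirna_id = st$feature_id[keep], fc = st$fc[keep],
                    pval = st$pval[keep],
                    direction = ifelse(st$fc[keep] >= 0, "up", "down"),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, cutoff = as.numeric(cut),
            predictor = attr(pseudo, "predictor"),
            class = c("mirna_calls", "data.frame"))
}

#' Consensus of the two predictors
#'
#' The union of the significant-miRNA calls, each flagged with its
#' provenance (`scaling`, `linear`, or `both`).  An empty union is the
#' pipeline's termination condition: with no significant miRNA from
#' either predictor no downstream analysis is possible.
#'
#' @param calls_scaling,calls_linear `mirna_calls` data frames (either
#'   may be empty or NULL).
#' @return A `consensus_calls` data frame `mirna_id`, `direction`,
#'   `source`; attribute `terminate` is TRUE iff the union is empty.
#' @export
consensus <- function(calls_scaling = NULL, calls_linear = NULL) {
  a <- if (is.null(calls_scaling)) character(0) else calls_scaling$mirna_id
  b <- if (is.null(calls_linear)) character(0) else calls_linear$mirna_id
  ids <- union(a, b)
  src <- ifelse(ids %in% a & ids %in% b, "both",
                ifelse(ids %in% a, "scaling", "linear"))
  dir <- vapply(ids, function(i) {
    if (i %in% a) calls_scaling$direction[match(i, a)]
    else calls_linear$direction[match(i, b)]
  }, character(1L))
  out <- data.frame(mirna_id = ids, direction = unname(dir), source = src,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, terminate = length(ids) == 0L,
            class = c("consensus_calls", "data.frame"))
}
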