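#' Per-feature differential statistics
#'
#' Computes a signed log2 fold change and a p-value for every row of an
#' expression matrix under a sample design.  For two-group designs the
#' test is a Welch (default) or Student t-test; for two or more groups a
#' one-way ANOVA F-test is available.  The implementation is vectorized
#' over rows; it reproduces [stats::t.test()] / [stats::aov()] exactly
#' (checked in the test suite).
#'
#' Fold change convention: `fc = mean(group2) - mean(group1)` on the
#' log2 scale, groups ordered by factor level.  For ANOVA the fold
#' change of the extreme pair (max group mean minus min group mean,
#' nonnegative) is reported.  Rows with zero variance in every group
#' and equal means are degenerate: they get `pval = 1`, `fc = 0`, and
#' are counted in a message.
#'
#' @param x an `expr_matrix`.
#' @param design a [design_table()] covering all columns of `x`.
#' @param test `"welch"`, `"student"` or `"anova"`.
#' @return A `diff_stats` data frame with one row per feature:
#'   `feature_id`, `fc`, `pval`, `statistic`, `df`, and one
#'   `mean.<group>` column per group.
#' @export
row_stats <- function(x, design, test = c("welch", "student", "anova")) {
  test <- match.arg(test)
  g <- design_groups(x, design)
  lev <- levels(g)
  if (any(table(g) < 2L)) stop("every group needs >=2 samples")
  if (test %in% c("welch", "student") && length(lev) != 2L)
    stop("t-tests need exactly 2 groups; got ", length(lev))
  xm <- unclass(x)
  n  <- as.vector(table(g)[lev])
  means <- sapply(lev, function(l) rowMeans(xm[, g == l, drop = FALSE]))
  if (nrow(xm) == 1L) means <- matrix(means, nrow = 1L, dimnames = list(NULL, lev))
  vars <- sapply(seq_along(lev), function(i) {
    sub <- xm[, g == lev[i], drop = FALSE]
    rowSums((sub - means[, i])^2) / (n[i] - 1L)
  })
  if (nrow(xm) == 1L) vars <- matrix(vars, nrow = 1L)

  if (test == "anova") {
    N <- sum(n)
    k <- length(lev)
    grand <- rowSums(sweep(means, 2L, n, `*`)) / N
    ssb <- rowSums(sweep((means - grand)^2, 2L, n, `*`))
    ssw <- rowSums(sweep(vars, 2L, n - 1L, `*`))
    stat <- (ssb / (k - 1L)) / (ssw / (N - k))
    pval <- pf(stat, k - 1L, N - k, lower.tail = FALSE)
    dfree <- rep(N - k, nrow(xm))
    fc <- apply(means, 1L, max) - apply(means, 1L, min)
    degen <- ssw == 0 & ssb == 0
  } else {
    d <- means[, 2L] - means[, 1L]
    if (test == "welch") {
      se2 <- vars[, 1L] / n[1L] + vars[, 2L] / n[2L]
      dfree <- se2^2 / (vars[, 1L]^2 / (n[1L]^2 * (n[1L] - 1L)) +
                        vars[, 2L]^2 / (n[2L]^2 * (n[2L] - 1L)))
    } else {
      sp2 <- ((n[1L] - 1L) * vars[, 1L] + (n[2L] - 1L) * vars[, 2L]) /
        (sum(n) - 2L)
      se2 <- sp2 * (1 / n[1L] + 1 / n[2L])
      dfree <- rep(sum(n) - 2L, nrow(xm))
    }
    stat <- d / sqrt(se2)
    # zero within-group variance with distinct means: infinitely strong
    # evidence; give it the smallest possible p rather than NaN
    exact <- se2 == 0 & d != 0
    if (any(exact)) dfree[exact] <- sum(n) - 2L
    pval <- 2 * pt(-abs(stat), dfree)
    pval[exact] <- 0
    fc <- d
    degen <- vars[, 1L] == 0 & vars[, 2L] == 0 & d == 0
  }
  if (any(degen)) {
    pval[degen] <- 1; fc[degen] <- 0; stat[degen] <- 0
    message(sum(degen), " degenerate zero-variance row(s): pval set to 1")
  }
  out <- data.frame(feature_id = rownames(x), fc = fc, pval = pval,
                    statistic = stat, df = dfree,
                    stringsAsFactors = FALSE, row.names = NULL)
  gm <- as.data.frame(means)
  names(gm) <- paste0("mean.", lev)
  out <- cbind(out, gm)
  structure(out, test = test, class = c("diff_stats", "data.frame"))
}

#' Permutation-derived p-value cutoff
#'
#' Repeats the row test on `n_perm` label-shuffled copies of the design
#' (group sizes preserved) and returns the smallest per-row p-value seen
#' in any shuffled run.  That minimum is used as the significance
#' threshold for the real analysis: on null data it approximates the
#' smallest p-value one expects by chance alone.
#'
#' @inheritParams row_stats
#' @param n_perm number of label permutations (>= 1; default 1).
#' @param seed integer seed; mandatory so the cutoff is reproducible.
#' @return The cutoff (a single p-value) with attribute `n_perm`.
#' @export
permutation_cutoff <- function(x, design, n_perm = 1L, seed,
                               test = c("welch", "student", "anova")) {
  test <- match.arg(test)
  if (missing(seed)) stop("`seed` is mandatory")
  if (n_perm < 1L) stop("`n_perm` must be >= 1")
  g <- design_groups(x, design)
  set.seed(seed)
  mins <- vapply(seq_len(n_perm), function(i) {
    repeat {
      perm <- sample(as.character(g))
      if (length(unique(perm)) >= 2L && all(table(perm) >= 2L)) break
    }
    d <- design_table(colnames(x), perm)
    suppressMessages(min(row_stats(x, d, test = test)$pval))
  }, numeric(1L))
  structure(min(mins), n_perm = n_perm, seed = seed)
}

#' Filter features by significance
#'
#' Keeps the rows whose p-value falls strictly below the cutoff,
#' preserving the original row order, and subsets the statistics table
#' to match.
#'
#' @param x an `expr_matrix`.
#' @param stats the matching `diff_stats` from [row_stats()].
#' @param cutoff p-value threshold in (0, 1].
#' @return A list with elements `matrix` (filtered `expr_matrix`, or a
#'   0-row matrix if nothing survives) and `stats` (aligned subset).
#' @export
filter_significant <- function(x, stats, cutoff) {
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff > 1)
    stop("`cutoff` must be in (0, 1]")
  if (!identical(stats$feature_id, rownames(x)))
    stop("`stats` rows do not align with the matrix")
  keep <- stats$pval < cutoff
  if (!any(keep)) {
    warning("no features pass the significance cutoff")
    empty <- unclass(x)[0L, , drop = FALSE]
    return(list(
      matrix = structure(empty, role = expr_role(x),
                         class = c("expr_matrix", "matrix", "array")),
      stats = stats[0L, , drop = FALSE]))
  }
  sub <- unclass(x)[keep, , drop = FALSE]
  list(matrix = expression_matrix(sub, expr_role(x)),
       stats = stats[keep, , drop = FALSE])
}
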