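# minimal single-edge scenario builder: one miRNA, chosen hosts
mk_scenario <- function(expr_vals, strand = "sense", overlap = "intron",
                        evidence = "experimental", fc, pval) {
  n_host <- nrow(expr_vals)
  x <- mk_expr(expr_vals, rid = sprintf("p%d_at", seq_len(n_host)))
  edges <- data.frame(
    mirbase_id = "syn-mir-1", strand = strand, overlap = overlap,
    evidence = evidence, evidence_label = "x", gene_id = "G1",
    transcript_id = sprintf("T%d", seq_len(n_host)),
    probeset_id = rownames(x), chromosome = "1",
    start = 1L, end = 2L, mir = "syn-miR-1", mir_star = NA,
    stringsAsFactors = FALSE)
  map <- mir_mapping(edges)
  st <- data.frame(feature_id = rownames(x), fc = fc, pval = pval,
                   stringsAsFactors = FALSE)
  hosts <- suppressMessages(map_expression_rows(map, x))
  list(x = x, map = map, st = st, hosts = hosts)
}

test_that("edge weights multiply out the coefficient products", {
  s <- mk_scenario(matrix(1, 1, 2), fc = 1, pval = 0)
  w <- compute_weights(s$hosts, s$map, s$st, s$x)
  expect_equal(unname(w[["syn-miR-1"]]), 1 * 1 * 1.2 * 2 * 1.2)  # 2.88

  s2 <- mk_scenario(matrix(1, 1, 2), strand = "antisense",
                    overlap = "exon", evidence = "predicted",
                    fc = 2, pval = 0.5)
  w2 <- compute_weights(s2$hosts, s2$map, s2$st, s2$x)
  expect_equal(unname(w2[["syn-miR-1"]]), 2 * 0.5 * 0.8 * 0.8 * 0.8)  # .512

  s3 <- mk_scenario(matrix(1, 1, 2), fc = 5, pval = 1)
  expect_equal(unname(compute_weights(s3$hosts, s3$map, s3$st, s3$x)[[1]]), 0)
  # |FC| is used: a negative fold change weighs the same as a positive one
  s4 <- mk_scenario(matrix(1, 1, 2), fc = -1, pval = 0)
  expect_equal(compute_weights(s4$hosts, s4$map, s4$st, s4$x),
               compute_weights(s$hosts, s$map, s$st, s$x))
})

test_that("scaling predictor averages expression times weight", {
  # two hosts e=(4,6), weights (1, 0.5) -> mean(4, 3) = 3.5 in each sample
  s <- mk_scenario(rbind(c(4, 4), c(6, 6)), fc = c(1, 0.5), pval = c(0, 0))
  k1 <- scaling_coefficients(k_sense = c(sense = 1, antisense = 1),
                             k_overlap = c(intron = 1, exon = 1,
                                           utr3 = 1, utr5 = 1),
                             k_evidence = c(experimental = 1, predicted = 1))
  ps <- scaling_predict(s$x, s$st, s$hosts, s$map, coeffs = k1)
  expect_equal(unname(unclass(ps)["syn-miR-1", ]), c(3.5, 3.5))

  # single host with unit weight: identity limit
  s1 <- mk_scenario(matrix(c(4, 7), 1, 2), fc = 1, pval = 0)
  ps1 <- scaling_predict(s1$x, s1$st, s1$hosts, s1$map, coeffs = k1)
  expect_equal(unname(unclass(ps1)["syn-miR-1", ]),
               unname(unclass(s1$x)[1, ]))

  # linear in expression: scaling hosts by c scales the prediction by c
  s2 <- mk_scenario(rbind(c(4, 4), c(6, 6)) * 3, fc = c(1, 0.5),
                    pval = c(0, 0))
  ps2 <- scaling_predict(s2$x, s2$st, s2$hosts, s2$map, coeffs = k1)
  expect_equal(unclass(ps2), unclass(ps) * 3, ignore_attr = TRUE)

  # all-zero weights produce a zero row with a warning
  s0 <- mk_scenario(matrix(1, 1, 2), fc = 0, pval = 0)
  expect_warning(p0 <- scaling_predict(s0$x, s0$st, s0$hosts, s0$map),
                 "all-zero")
  expect_equal(unname(unclass(p0)[1, ]), c(0, 0))
})

test_that("weighting enriches strong miRNA-host correlations", {
  # each miRNA follows one informative host; a noise host dilutes the
  # unweighted average but has tiny weight (non-differential, p ~ 1)
  set.seed(8)
  n <- 20; S <- 30
  good <- matrix(rnorm(n * S, 8), n, S) +
    outer(rep(2, n), rep(c(0, 1), each = S / 2))
  noisy <- matrix(rnorm(n * S, 8, 3), n, S)
  expr_vals <- rbind(good, noisy)
  x <- mk_expr(expr_vals, rid = sprintf("p%d_at", seq_len(2 * n)))
  truth <- good + matrix(rnorm(n * S, 0, 0.1), n, S)
  edges <- do.call(rbind, lapply(seq_len(n), function(j) data.frame(
    mirbase_id = sprintf("syn-mir-%d", j), strand = "sense",
    overlap = "intron",
    evidence = c("experimental", "predicted"), evidence_label = "x",
    gene_id = "G", transcript_id = c("Ta", "Tb"),
    probeset_id = sprintf("p%d_at", c(j, n + j)), chromosome = "1",
    start = 1L, end = 2L, mir = sprintf("syn-miR-%d", j), mir_star = NA,
    stringsAsFactors = FALSE)))
  map <- mir_mapping(edges)
  d <- design_table(colnames(x), rep(c("A", "B"), each = S / 2))
  st <- suppressMessages(row_stats(x, d))
  hosts <- suppressMessages(map_expression_rows(map, x))
  ps_w <- scaling_predict(x, st, hosts, map)
  k1 <- scaling_coefficients(k_sense = c(sense = 1, antisense = 1),
                             k_overlap = c(intron = 1, exon = 1,
                                           utr3 = 1, utr5 = 1),
                             k_evidence = c(experimental = 1, predicted = 1))
  st1 <- st; st1$fc <- 1; st1$pval <- 0
  ps_u <- scaling_predict(x, st1, hosts, map, coeffs = k1)
  r_w <- sapply(seq_len(n), function(j)
    cor(unclass(ps_w)[sprintf("syn-miR-%d", j), ], truth[j, ]))
  r_u <- sapply(seq_len(n), function(j)
    cor(unclass(ps_u)[sprintf("syn-miR-%d", j), ], truth[j, ]))
  expect_gte(sum(r_w >= 0.6), sum(r_u >= 0.6))
  expect_gt(sum(r_w >= 0.6), n / 2)
})

test_that("design rows enumerate (miRNA, transcript, sample) triples", {
  ds <- make_paired_dataset(n_samples = 10, n_mirna = 5, n_genes = 60,
                            hosts_per_mirna = 3, seed = 2)
  st <- suppressMessages(row_stats(ds$mrna, ds$design))
  hosts <- suppressMessages(map_expression_rows(ds$mapping, ds$mrna))
  rows <- build_design_rows(ds$mirna, ds$mrna, st, hosts, ds$mapping)
  expect_identical(nrow(rows), 5L * 3L * 10L)
  one <- rows[rows$mirid == rownames(ds$mirna)[1], ]
  expect_identical(nrow(one), 30L)
  expect_identical(length(unique(one$transcript)), 3L)
})

test_that("the linear model interpolates a noiseless linear truth", {
  # all miRNAs carry the group effect: with zero noise a flat host would
  # leave the slope unidentifiable
  ds <- make_paired_dataset(n_samples = 12, n_mirna = 6, n_genes = 40,
                            noise_sd = 0, diff_fraction = 1, seed = 5)
  st <- suppressMessages(row_stats(ds$mrna, ds$design))
  hosts <- suppressMessages(map_expression_rows(ds$mapping, ds$mrna))
  rows <- build_design_rows(ds$mirna, ds$mrna, st, hosts, ds$mapping)
  fit <- suppressMessages(fit_linear_model(rows, seed = 3))
  expect_equal(fit$test_r, 1, tolerance = 1e-9)
  for (j in seq_len(6)) {
    m <- ds$truth$coefficients$mirna_id[j]
    cf <- fit$coefficients[[m]]
    expect_equal(unname(cf["(Intercept)"]), ds$truth$coefficients$a[j],
                 tolerance = 1e-6)
    expect_equal(unname(cf["e"]), ds$truth$coefficients$b[j],
                 tolerance = 1e-6)
  }
  # prediction equals truth on the same data
  pl <- suppressWarnings(lm_predict(fit, ds$mrna, st, hosts, ds$mapping))
  common <- intersect(rownames(pl), rownames(ds$mirna))
  expect_equal(unclass(pl)[common, ], unclass(ds$mirna)[common, ],
               tolerance = 1e-9, ignore_attr = TRUE)
  # determinism: same rows, same seed, bit-identical coefficients
  fit2 <- suppressMessages(fit_linear_model(rows, seed = 3))
  expect_identical(fit$coefficients, fit2$coefficients)
})

test_that("per-miRNA fits equal the global identity-factor regression", {
  set.seed(13)
  n_mir <- 3; n_host <- 4; S <- 15
  rows <- do.call(rbind, lapply(seq_len(n_mir), function(j) {
    do.call(rbind, lapply(seq_len(n_host), function(h) {
      e <- rnorm(S, 8)
      data.frame(mirid = sprintf("m%d", j), transcript = sprintf("t%d", h),
                 sample = sprintf("s%d", seq_len(S)),
                 y = rnorm(1, 2) + rnorm(1, 1) * e + rnorm(S, 0, 0.3),
                 e = e, fc = runif(1, 0.5, 2), pv = runif(1, 0.2, 1),
                 overlap = "intron", strand = "sense",
                 evidence = "experimental", stringsAsFactors = FALSE)
    }))
  }))
  attr(rows, "variant") <- "standard"
  fit <- suppressMessages(fit_linear_model(rows, train_frac = 1, seed = 1,
                                           prefilter = FALSE))
  glob <- lm(y ~ 0 + mirid / (e * fc * pv), data = rows)
  gcf <- coef(glob)
  for (m in fit$mir_levels) {
    cf <- fit$coefficients[[m]]
    gnames <- ifelse(names(cf) == "(Intercept)", paste0("mirid", m),
                     paste0("mirid", m, ":", names(cf)))
    expect_equal(unname(cf), unname(gcf[gnames]), tolerance = 1e-8)
  }
})

test_that("prediction aggregates transcripts by the median", {
  # hand-built minimal-variant fit: three transcripts predicting 2, 10, 4
  x <- mk_expr(matrix(0, 3, 2), rid = c("pA_at", "pB_at", "pC_at"))
  edges <- data.frame(
    mirbase_id = "syn-mir-1", strand = "sense", overlap = "intron",
    evidence = "experimental", evidence_label = "x", gene_id = "G",
    transcript_id = c("TA", "TB", "TC"), probeset_id = rownames(x),
    chromosome = "1", start = 1L, end = 2L, mir = "syn-miR-1",
    mir_star = NA, stringsAsFactors = FALSE)
  map <- mir_mapping(edges)
  st <- data.frame(feature_id = rownames(x), fc = 1, pval = 0,
                   stringsAsFactors = FALSE)
  hosts <- suppressMessages(map_expression_rows(map, x))
  fit <- structure(list(variant = "minimal", mir_levels = "syn-miR-1",
                        coefficients = list("syn-miR-1" = c("(Intercept)" = 0,
                                                            e = 1)),
                        std_errors = list(), train_frac = 1, seed = 1,
                        prefilter = FALSE, test_r = NA_real_),
                   class = "linear_model_fit")
  vals <- unclass(x); vals["pA_at", ] <- 2; vals["pB_at", ] <- 10
  vals["pC_at", ] <- 4
  x2 <- mk_expr(vals, rid = rownames(x))
  pl <- lm_predict(fit, x2, st, hosts, map)
  expect_equal(unname(unclass(pl)["syn-miR-1", ]), c(4, 4))
})

test_that("held-out correlation degrades monotonically with noise", {
  rs <- vapply(c(0, 0.1, 0.5, 1), function(sg) {
    ds <- make_paired_dataset(n_samples = 20, n_mirna = 8, n_genes = 60,
                              noise_sd = sg, seed = 17)
    st <- suppressMessages(row_stats(ds$mrna, ds$design))
    hosts <- suppressMessages(map_expression_rows(ds$mapping, ds$mrna))
    rows <- build_design_rows(ds$mirna, ds$mrna, st, hosts, ds$mapping)
    suppressMessages(fit_linear_model(rows, seed = 4))$test_r
  }, numeric(1))
  expect_true(all(diff(rs) <= 1e-9))
})

test_that("significant-miRNA calls find planted shifts with direction", {
  ds <- make_paired_dataset(n_samples = 20, n_mirna = 10, n_genes = 80,
                            effect = 2, noise_sd = 0.1,
                            diff_fraction = 0.4, seed = 9)
  st <- suppressMessages(row_stats(ds$mrna, ds$design))
  hosts <- suppressMessages(map_expression_rows(ds$mapping, ds$mrna))
  ps <- scaling_predict(ds$mrna, st, hosts, ds$mapping)
  calls <- significant_mirnas(ps, ds$design, seed = 31)
  planted <- ds$truth$coefficients$mirna_id[ds$truth$coefficients$differential]
  expect_true(all(planted %in% calls$mirna_id))
  expect_true(all(calls$direction[calls$mirna_id %in% planted] == "up"))
  calls2 <- significant_mirnas(ps, ds$design, seed = 31)
  expect_identical(calls, calls2)
})

test_that("null pseudo-expression yields about one call per run", {
  counts <- vapply(1:20, function(s) {
    x <- null_matrix(50, 5, seed = 100 + s)
    attr(x, "role") <- "pseudo"
    d <- two_group_design(5)
    nrow(significant_mirnas(x, d, seed = 200 + s))
  }, numeric(1))
  expect_lte(mean(counts), 3)
})

test_that("consensus is a flagged union with a termination signal", {
  a <- structure(data.frame(mirna_id = c("a", "b"), fc = 1, pval = 0.01,
                            direction = "up", stringsAsFactors = FALSE),
                 class = c("mirna_calls", "data.frame"))
  b <- structure(data.frame(mirna_id = c("b", "c"), fc = -1, pval = 0.01,
                            direction = "down", stringsAsFactors = FALSE),
                 class = c("mirna_calls", "data.frame"))
  u <- consensus(a, b)
  expect_setequal(u$mirna_id, c("a", "b", "c"))
  expect_identical(u$source[u$mirna_id == "b"], "both")
  expect_false(attr(u, "terminate"))

  one <- consensus(a, NULL)
  expect_setequal(one$mirna_id, c("a", "b"))
  expect_true(all(one$source == "scaling"))

  none <- consensus(a[0, ], b[0, ])
  expect_identical(nrow(none), 0L)
  expect_true(attr(none, "terminate"))
})
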