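# shared fixtures built in code

table1_path <- function() {
  system.file("extdata", "mapping_table1.csv", package = "mirhostpred")
}

# small labelled matrix helper
mk_expr <- function(values, role = "mrna",
                    rid = sprintf("g%d", seq_len(nrow(values))),
                    cid = sprintf("s%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(rid, cid)
  expression_matrix(values, role)
}

# two-group gaussian null matrix
null_matrix <- function(m, n_per_group = 5L, sd = 1, seed = 1L) {
  set.seed(seed)
  mk_expr(matrix(rnorm(m * 2L * n_per_group, sd = sd), nrow = m))
}

two_group_design <- function(n_per_group = 5L,
                             ids = sprintf("s%d", seq_len(2L * n_per_group))) {
  design_table(ids, rep(c("A", "B"), each = n_per_group))
}

# interval fixture for build_mapping: 2 genes with introns/exons/UTRs
toy_gene_models <- function() {
  rbind(
    data.frame(gene_id = "G1", transcript_id = "G1-T1", chromosome = "1",
               start = c(1000L, 1000L, 1090L, 1400L, 1470L),
               end = c(1500L, 1100L, 1100L, 1500L, 1500L),
               strand = "+",
               feature = c("transcript", "exon", "utr5", "exon", "utr3"),
               stringsAsFactors = FALSE),
    data.frame(gene_id = "G2", transcript_id = "G2-T1", chromosome = "2",
               start = c(5000L, 5000L, 5600L),
               end = c(6000L, 5200L, 6000L),
               strand = "-",
               feature = c("transcript", "exon", "exon"),
               stringsAsFactors = FALSE))
}

# brute-force per-pair correlation oracle
naive_cor <- function(a, b, method) {
  out <- matrix(NA_real_, nrow(a), nrow(b))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      out[i, j] <- cor(a[i, ], b[j, ], method = method)
  out
}

# exhaustive hypergeometric upper-tail oracle by subset enumeration
enum_hyper_tail <- function(N, K, n, k) {
  universe <- seq_len(N)
  inset <- seq_len(K)
  draws <- combn(N, n)
  hits <- apply(draws, 2L, function(d) sum(d %in% inset))
  mean(hits >= k)
}
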