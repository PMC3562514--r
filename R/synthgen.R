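#' Random RNA sequences
#' @param n number of sequences.
#' @param len length (recycled).
#' @return Character vector of uniform-random RNA sequences.
#' @keywords internal
random_rna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(len, function(L)
    paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = ""),
    character(1L))
}

#' Reverse complement of an RNA sequence
#' @param seq character vector of RNA sequences.
#' @return Reverse complements.
#' @export
revcomp_rna <- function(seq) {
  vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Generate a synthetic miRNA-host mapping table
#'
#' Emits a schema-valid edge table with attribute frequencies matching
#' the requested class proportions.  Defaults reflect the genomic
#' reality of intragenic miRNAs: overlaps are overwhelmingly intronic
#' (92%) and mostly on the coding strand (83%).
#'
#' @param n_mirna number of precursor miRNAs.
#' @param n_genes number of candidate host genes.
#' @param hosts_per_mirna host transcripts per miRNA (>= 1).
#' @param overlap_props named probabilities over
#'   `intron/exon/utr5/utr3`.
#' @param sense_prop probability of a sense-strand edge.
#' @param experimental_prop probability of experimental evidence.
#' @param seed integer seed.
#' @return A list: `mapping` (a `mir_mapping`), `truth` (data frame of
#'   each miRNA's host genes).
#' @export
make_mapping <- function(n_mirna, n_genes, hosts_per_mirna = 3L,
                         overlap_props = c(intron = 0.92, exon = 0.05,
                                           utr5 = 0.02, utr3 = 0.01),
                         sense_prop = 0.83, experimental_prop = 0.5,
                         seed = 1L) {
  if (hosts_per_mirna < 1L) stop("`hosts_per_mirna` must be >= 1")
  if (n_genes < hosts_per_mirna)
    stop("need at least `hosts_per_mirna` genes")
  set.seed(seed)
  mirnas <- sprintf("syn-mir-%03d", seq_len(n_mirna))
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  rows <- list()
  for (i in seq_len(n_mirna)) {
    hosts <- sample(genes, hosts_per_mirna)
    for (g in hosts) {
      gi <- match(g, genes)
      gstart <- 1e5 + gi * 5e4
      mstart <- gstart + sample(1000:40000, 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        mirbase_id = mirnas[i],
        strand = if (runif(1) < sense_prop) "sense" else "antisense",
        overlap = sample(names(overlap_props), 1L, prob = overlap_props),
        evidence = if (runif(1) < experimental_prop) "experimental"
                   else "predicted",
        evidence_label = "synthetic",
        gene_id = g, transcript_id = paste0(g, "-T1"),
        probeset_id = paste0(g, "_at"),
        chromosome = as.character(1L + (gi %% 22L)),
        start = as.integer(mstart), end = as.integer(mstart + 84L),
        mir = sub("mir", "miR", mirnas[i]),
        mir_star = NA_character_, stringsAsFactors = FALSE)
    }
  }
  edges <- do.call(rbind, rows)
  truth <- unique(edges[, c("mirbase_id", "mir", "gene_id", "probeset_id")])
  rownames(truth) <- NULL
  list(mapping = mir_mapping(edges), truth = truth)
}

#' Generate a paired miRNA-mRNA dataset with planted structure
#'
#' Emulates the statistical structure the pipeline exploits: host genes
#' carry a two-group differential signal, each miRNA is a linear
#' function of the mean of its hosts' realized expression
#' (`a_j + b_j * mean(hosts_j) + noise`), planted target genes are
#' anti-correlated with their miRNA at a controlled population
#' correlation, and decoy genes are independent noise.  All noise is
#' Gaussian on the log2 scale.
#'
#' With `noise_sd = 0` the construction degenerates exactly: miRNA rows
#' are exact linear functions of their hosts and planted target
#' correlations are exactly -1.
#'
#' @param n_samples total samples, split into two balanced groups
#'   (>= 6, even).
#' @param n_mirna number of miRNAs.
#' @param n_genes total mRNA features (hosts + targets + decoys).
#' @param effect log2 group shift applied to hosts of differential
#'   miRNAs (default 1, i.e. two-fold).
#' @param noise_sd Gaussian noise sd on the log2 scale (default 0.2).
#' @param target_strength target |population correlation| between a
#'   planted target and its miRNA (default 0.95).
#' @param hosts_per_mirna hosts per miRNA (default 1).
#' @param targets_per_mirna planted targets per miRNA (default 2).
#' @param diff_fraction fraction of miRNAs whose hosts carry the group
#'   effect (default 0.5).
#' @param seed integer seed.
#' @return A list: `mrna` and `mirna` (`expr_matrix`), `mapping`
#'   (`mir_mapping`, sense/intron/experimental host edges), `design`
#'   (a `design_table`), and `truth` (hosts, coefficients `a`/`b`,
#'   planted targets, differential flags and effect sizes).
#' @export
make_paired_dataset <- function(n_samples = 30L, n_mirna = 20L,
                                n_genes = 500L, effect = 1,
                                noise_sd = 0.2, target_strength = 0.95,
                                hosts_per_mirna = 1L,
                                targets_per_mirna = 2L,
                                diff_fraction = 0.5, seed = 1L) {
  if (n_samples < 6L || n_samples %% 2L != 0L)
    stop("`n_samples` must be an even number >= 6")
  n_host <- n_mirna * hosts_per_mirna
  n_targ <- n_mirna * targets_per_mirna
  if (n_genes < n_host + n_targ)
    stop("`n_genes` too small for the requested hosts and targets")
  set.seed(seed)
  samples <- sprintf("S%02d", seq_len(n_samples))
  group <- rep(c("A", "B"), each = n_samples / 2L)
  gB <- group == "B"
  genes <- sprintf("GENE%04d_at", seq_len(n_genes))
  mirnas <- sprintf("syn-miR-%03d", seq_len(n_mirna))

  host_ids <- genes[seq_len(n_host)]
  targ_ids <- genes[n_host + seq_len(n_targ)]
  decoy_ids <- genes[-seq_len(n_host + n_targ)]
  is_diff <- seq_len(n_mirna) %in%
    sample(n_mirna, round(diff_fraction * n_mirna))

  mrna <- matrix(0, n_genes, n_samples, dimnames = list(genes, samples))
  # hosts: baseline + group effect (if their miRNA is differential) + noise
  host_of <- rep(seq_len(n_mirna), each = hosts_per_mirna)
  for (h in seq_len(n_host)) {
    base <- runif(1, 6, 10)
    eff <- if (is_diff[host_of[h]]) effect else 0
    mrna[host_ids[h], ] <- base + eff * gB + rnorm(n_samples, 0, noise_sd)
  }
  # miRNAs: linear in the realized mean of their hosts
  a <- runif(n_mirna, 0, 2)
  b <- runif(n_mirna, 0.8, 1.2)
  mir <- matrix(0, n_mirna, n_samples, dimnames = list(mirnas, samples))
  for (j in seq_len(n_mirna)) {
    hrows <- host_ids[host_of == j]
    hmean <- colMeans(mrna[hrows, , drop = FALSE])
    mir[j, ] <- a[j] + b[j] * hmean + rnorm(n_samples, 0, noise_sd)
  }
  # planted targets: anti-correlated with their miRNA at target_strength
  targ_of <- rep(seq_len(n_mirna), each = targets_per_mirna)
  for (t in seq_len(n_targ)) {
    y <- mir[targ_of[t], ]
    sd_t <- if (noise_sd == 0) 0 else
      sd(y) * sqrt(1 / target_strength^2 - 1)
    mrna[targ_ids[t], ] <- runif(1, 6, 10) - (y - mean(y)) +
      rnorm(n_samples, 0, sd_t)
  }
  for (d in decoy_ids)
    mrna[d, ] <- runif(1, 6, 10) + rnorm(n_samples, 0, max(noise_sd, 0.1))

  edges <- data.frame(
    mirbase_id = sub("miR", "mir", mirnas[host_of]),
    strand = "sense", overlap = "intron", evidence = "experimental",
    evidence_label = "synthetic", gene_id = sub("_at$", "", host_ids),
    transcript_id = paste0(sub("_at$", "", host_ids), "-T1"),
    probeset_id = host_ids,
    chromosome = as.character(1L + (host_of %% 22L)),
    start = 1000L + 100L * seq_len(n_host),
    end = 1084L + 100L * seq_len(n_host),
    mir = mirnas[host_of], mir_star = NA_character_,
    stringsAsFactors = FALSE)

  truth <- list(
    hosts = data.frame(mirna_id = mirnas[host_of], host_id = host_ids,
                       stringsAsFactors = FALSE),
    coefficients = data.frame(mirna_id = mirnas, a = a, b = b,
                              differential = is_diff,
                              effect = ifelse(is_diff, effect, 0),
                              stringsAsFactors = FALSE),
    targets = data.frame(mirna_id = mirnas[targ_of], target_id = targ_ids,
                         stringsAsFactors = FALSE),
    decoys = decoy_ids)

  list(mrna = expression_matrix(mrna, "mrna"),
       mirna = expression_matrix(mir, "mirna"),
       mapping = mir_mapping(edges),
       design = design_table(samples, group),
       truth = truth)
}

#' Generate 3'UTR sequences with planted miRNA binding sites
#'
#' Produces uniform-random RNA sequences; a fraction of them carry the
#' exact reverse complement of an assigned mature miRNA at a recorded
#' position (a perfect binding site the energy scan should find).
#'
#' @param n_targets number of UTR sequences.
#' @param length_range min/max sequence length (>= 100 so the UTR
#'   length filter passes).
#' @param mirna_set named character vector of mature miRNA sequences.
#' @param planted_fraction fraction of sequences given a planted site.
#' @param seed integer seed.
#' @return A list: `utrs` (named sequences), `mirnas` (= `mirna_set`),
#'   `pairs` (data frame `mirna_id`, `target_id` pairing every UTR with
#'   its assigned miRNA), `truth` (planted flag and site position).
#' @export
make_sequences <- function(n_targets, length_range = c(150L, 300L),
                           mirna_set, planted_fraction = 0.5, seed = 1L) {
  if (min(length_range) < 100L)
    stop("`length_range` must be >= 100 nt to pass the UTR filter")
  set.seed(seed)
  lens <- sample(length_range[1L]:length_range[2L], n_targets,
                 replace = TRUE)
  utrs <- random_rna(n_targets, lens)
  names(utrs) <- sprintf("UTR%04d", seq_len(n_targets))
  assigned <- sample(names(mirna_set), n_targets, replace = TRUE)
  planted <- seq_len(n_targets) %in%
    sample(n_targets, round(planted_fraction * n_targets))
  pos <- rep(NA_integer_, n_targets)
  for (i in which(planted)) {
    site <- revcomp_rna(mirna_set[[assigned[i]]])
    w <- nchar(site)
    pos[i] <- sample(seq_len(lens[i] - w + 1L), 1L)
    substr(utrs[i], pos[i], pos[i] + w - 1L) <- site
  }
  list(utrs = utrs, mirnas = mirna_set,
       pairs = data.frame(mirna_id = assigned, target_id = names(utrs),
                          stringsAsFactors = FALSE),
       truth = data.frame(target_id = names(utrs), mirna_id = assigned,
                          planted = planted, site_pos = pos,
                          stringsAsFactors = FALSE))
}

#' Generate a synthetic gene-set collection with one planted term
#'
#' Random gene sets over a universe, plus one planted term built to
#' overlap a designated query (half the term drawn from the query).
#'
#' @param n_terms number of random terms.
#' @param term_size_range min/max term size.
#' @param universe character vector of gene ids.
#' @param query designated query gene list (subset of `universe`).
#' @param seed integer seed.
#' @return A list: `collection` (a `gene_set_collection`, the planted
#'   term id is `"PLANTED"`), `truth` (planted term id and its overlap
#'   with the query).
#' @export
make_genesets <- function(n_terms, term_size_range = c(10L, 50L),
                          universe, query, seed = 1L) {
  if (!length(universe)) stop("empty universe")
  if (max(term_size_range) > length(universe))
    stop("term size exceeds the universe")
  set.seed(seed)
  sets <- lapply(seq_len(n_terms), function(i)
    sample(universe, sample(term_size_range[1L]:term_size_range[2L], 1L)))
  names(sets) <- sprintf("TERM%03d", seq_len(n_terms))
  k <- max(2L, ceiling(length(query) / 2L))
  planted <- unique(c(sample(query, k),
                      sample(setdiff(universe, query),
                             max(term_size_range[1L] - k, 2L))))
  sets$PLANTED <- planted
  descs <- setNames(c(sprintf("random term %d", seq_len(n_terms)),
                      "planted enriched term"), names(sets))
  coll <- structure(sets, descriptions = descs, label = "synthetic",
                    class = "gene_set_collection")
  list(collection = coll,
       truth = list(term_id = "PLANTED",
                    overlap = length(intersect(planted, query))))
}
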