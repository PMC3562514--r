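#' Normalize an RNA sequence
#'
#' Upper-cases, converts DNA T to U and validates the `{A,C,G,U}`
#' alphabet.
#'
#' @param seq character vector of sequences.
#' @return Normalized sequences.
#' @export
rna_normalize <- function(seq) {
  out <- chartr("tT", "uU", seq)
  out <- toupper(out)
  bad <- grepl("[^ACGU]", out)
  if (any(bad))
    stop("non-RNA characters in sequence(s): ",
         paste(head(which(bad)), collapse = ", "))
  out
}

#' Read sequences from FASTA
#'
#' Ids are the first whitespace-delimited token of each header line.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences (raw, not normalized).
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA headers in ", path)
  ids <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 paste, character(1L), collapse = "")
  names(seqs) <- ids[as.integer(names(seqs))]
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids in ", path)
  seqs
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w"); on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Pick one 3'UTR isoform per gene
#'
#' For genes with several annotated 3'UTR isoforms the longest is kept
#' (sampling the largest span of potential binding sites); equal-length
#' ties resolve to the lexicographically smallest transcript id.  Genes
#' whose selected UTR is shorter than `min_len` (default 100 nt) are
#' discarded, with the count reported.
#'
#' @param seqs named character vector of UTR sequences (names =
#'   transcript ids).
#' @param gene_map data frame `transcript_id`, `gene_id`.
#' @param min_len minimum UTR length to keep.
#' @return Named character vector, one sequence per surviving gene
#'   (names = gene ids).
#' @export
select_longest_utr <- function(seqs, gene_map, min_len = 100L) {
  idx <- match(names(seqs), gene_map$transcript_id)
  if (anyNA(idx))
    stop("transcript(s) missing from gene_map: ",
         paste(head(names(seqs)[is.na(idx)]), collapse = ", "))
  gene <- gene_map$gene_id[idx]
  pick <- tapply(seq_along(seqs), gene, function(ii) {
    len <- nchar(seqs[ii])
    cand <- ii[len == max(len)]
    cand[order(names(seqs)[cand])][1L]
  })
  sel <- setNames(as.character(seqs[as.integer(pick)]), names(pick))
  short <- nchar(sel) < min_len
  if (any(short))
    message(sum(short), " gene(s) dropped: 3'UTR shorter than ", min_len,
            " nt")
  sel[!short]
}

.check_linker <- function(linker) {
  if (nchar(linker) < 1L || grepl("[ACGUacguTt]", linker))
    stop("linker must be non-empty and contain only unpairable symbols")
  linker
}

#' Duplex minimum free energy of a UTR window against a mature miRNA
#'
#' Computes the minimum free energy of the joined molecule
#' `[window + linker + miRNA]` where the artificial 8-base linker is
#' unpairable, so only window:miRNA hybridization contributes.  The
#' open structure has energy 0, hence results are always <= 0.
#'
#' The default `internal` backend is a nearest-neighbor hybridization
#' dynamic program (Watson-Crick + GU stacking, affine loop penalties,
#' duplex initiation and terminal AU penalties) compiled via Rcpp; it
#' forbids intra-strand pairs by construction.  Two adapters use the
#' external ViennaRNA binaries when installed: `"rnafold"` folds the
#' linker-joined molecule with `RNAfold` (the legacy protocol,
#' including intra-strand structure) and `"rnaduplex"` computes the
#' hybridization-only minimum with `RNAduplex` (like-for-like with the
#' internal model).
#'
#' @param window_seq character vector of window sequences (<= 25 nt
#'   each by convention).
#' @param mirna_seq single mature miRNA sequence.
#' @param backend `"internal"`, `"rnafold"` or `"rnaduplex"`.
#' @param linker unpairable linker placed between the strands; its
#'   symbols must not be standard bases.  The internal and rnaduplex
#'   backends are invariant to the linker's identity and length by
#'   construction.
#' @return Numeric vector of energies (kcal/mol, <= 0), one per window.
#' @export
duplex_energy <- function(window_seq, mirna_seq,
                          backend = c("internal", "rnafold", "rnaduplex"),
                          linker = "XXXXXXXX") {
  backend <- match.arg(backend)
  .check_linker(linker)
  window_seq <- rna_normalize(window_seq)
  mirna_seq <- rna_normalize(mirna_seq)
  switch(backend,
    internal = vapply(window_seq,
                      function(w) min(0, .duplex_mfe_cpp(w, mirna_seq)),
                      numeric(1L), USE.NAMES = FALSE),
    rnafold = .rnafold_energy(paste0(window_seq, linker, mirna_seq)),
    rnaduplex = .rnaduplex_energy(window_seq, mirna_seq))
}

# fold sequences with the external RNAfold binary (one batched call)
.rnafold_energy <- function(seqs) {
  if (Sys.which("RNAfold") == "")
    stop("RNAfold not found on PATH; use backend = \"internal\" or ",
         "install the ViennaRNA package")
  inp <- paste(seqs, collapse = "\n")
  out <- system2("RNAfold", args = c("--noPS"), input = inp, stdout = TRUE)
  en <- grep("\\(\\s*-?[0-9.]+\\s*\\)\\s*$", out, value = TRUE)
  if (length(en) != length(seqs)) stop("unexpected RNAfold output")
  as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", "\\1", en))
}

# hybridization-only MFE with the external RNAduplex binary; clamps to
# <= 0 (RNAduplex always reports the best duplex, even if unfavorable)
.rnaduplex_energy <- function(window_seq, mirna_seq) {
  if (Sys.which("RNAduplex") == "")
    stop("RNAduplex not found on PATH; use backend = \"internal\" or ",
         "install the ViennaRNA package")
  inp <- paste(rbind(window_seq, rep(mirna_seq, length(window_seq))),
               collapse = "\n")
  out <- system2("RNAduplex", input = inp, stdout = TRUE, stderr = FALSE)
  en <- grep("\\(\\s*-?[0-9.]+\\s*\\)\\s*$", out, value = TRUE)
  if (length(en) != length(window_seq)) stop("unexpected RNAduplex output")
  pmin(0, as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", "\\1", en)))
}

#' Sliding-window energy scan of a 3'UTR
#'
#' Scans the UTR with windows of `window` nt advancing by `step` nt
#' (incomplete trailing windows are dropped) and records the minimum
#' duplex energy against the miRNA and the window where it occurs (the
#' leftmost window on ties).  The minimum-energy window is the putative
#' binding site.
#'
#' @param mirna_seq mature miRNA sequence.
#' @param utr_seq 3'UTR sequence, at least `window` nt.
#' @param window window size in nt (default 25).
#' @param step step size in nt (default 5).
#' @inheritParams duplex_energy
#' @return A list of class `energy_walk_result`: `min_energy`,
#'   `window_start` (1-based), `n_windows`, `energies` (per window).
#' @export
energy_walk <- function(mirna_seq, utr_seq, window = 25L, step = 5L,
                        backend = c("internal", "rnafold", "rnaduplex"),
                        linker = "XXXXXXXX") {
  backend <- match.arg(backend)
  utr_seq <- rna_normalize(utr_seq)
  L <- nchar(utr_seq)
  if (L < window) stop("UTR shorter than the scan window")
  starts <- seq(1L, L - window + 1L, by = step)
  wins <- substring(utr_seq, starts, starts + window - 1L)
  en <- duplex_energy(wins, mirna_seq, backend = backend, linker = linker)
  i <- which.min(en)  # first occurrence wins ties
  structure(list(min_energy = en[i], window_start = starts[i],
                 n_windows = length(starts), energies = setNames(en, starts)),
            class = "energy_walk_result")
}

#' @export
print.energy_walk_result <- function(x, ...) {
  cat(sprintf("<energy_walk> min %.2f kcal/mol at position %d (%d windows)\n",
              x$min_energy, x$window_start, x$n_windows))
  invisible(x)
}

#' Run the energy walk over a set of miRNA-target pairs
#'
#' @param pairs data frame `mirna_id`, `target_id`.
#' @param mirnas named character vector of mature miRNA sequences.
#' @param utrs named character vector of 3'UTR sequences.
#' @inheritParams energy_walk
#' @return Data frame `mirna_id`, `target_id`, `min_energy`,
#'   `window_start`, `n_windows`.
#' @export
energy_walk_pairs <- function(pairs, mirnas, utrs, window = 25L, step = 5L,
                              backend = c("internal", "rnafold", "rnaduplex"),
                              linker = "XXXXXXXX") {
  backend <- match.arg(backend)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    mi <- pairs$mirna_id[i]; ta <- pairs$target_id[i]
    if (!mi %in% names(mirnas)) stop("unknown miRNA id: ", mi)
    if (!ta %in% names(utrs)) stop("unknown target id: ", ta)
    w <- energy_walk(mirnas[[mi]], utrs[[ta]], window = window, step = step,
                     backend = backend, linker = linker)
    data.frame(mirna_id = mi, target_id = ta, min_energy = w$min_energy,
               window_start = w$window_start, n_windows = w$n_windows,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Randomize pair labels (null model 1)
#'
#' Permutes the gene (target) assignment over the same multiset of
#' 3'UTR sequences, keeping the miRNA list fixed.  A derangement is not
#' enforced: occasional fixed points are part of the null.
#'
#' @param pairs data frame `mirna_id`, `target_id` (>= 2 rows).
#' @param seed integer seed.
#' @return The pairs with `target_id` permuted.
#' @export
randomize_labels <- function(pairs, seed) {
  if (nrow(pairs) < 2L) stop("need >= 2 pairs to permute")
  set.seed(seed)
  pairs$target_id <- sample(pairs$target_id)
  pairs
}

#' Substitute target sequences with random genes (null model 2)
#'
#' Replaces each pair's target with a uniformly drawn sequence from a
#' pool of other genes' 3'UTRs, without replacement while the pool
#' lasts; once exhausted, uniform-random synthetic sequences of matched
#' length are generated.
#'
#' @param pairs data frame `mirna_id`, `target_id`.
#' @param utrs named character vector: the original target sequences.
#' @param pool named character vector of alternative 3'UTRs (non-empty).
#' @param seed integer seed.
#' @return A list: `pairs` (target ids rewritten to the substitutes)
#'   and `utrs` (sequences for the substitute ids).
#' @export
randomize_sequences <- function(pairs, utrs, pool, seed) {
  if (!length(pool)) stop("pool of substitute sequences is empty")
  set.seed(seed)
  n <- nrow(pairs)
  take <- sample(names(pool), size = min(n, length(pool)))
  sub_ids <- character(n); sub_seq <- character(n)
  for (i in seq_len(n)) {
    if (i <= length(take)) {
      sub_ids[i] <- take[i]; sub_seq[i] <- pool[[take[i]]]
    } else {
      len <- nchar(utrs[[pairs$target_id[i]]])
      sub_ids[i] <- sprintf("synthetic_random_%d", i)
      sub_seq[i] <- paste(sample(c("A", "C", "G", "U"), len,
                                 replace = TRUE), collapse = "")
    }
  }
  pairs$target_id <- sub_ids
  list(pairs = pairs, utrs = setNames(sub_seq, sub_ids))
}

#' Welch two-sample t-test
#'
#' Compares two minimum-energy distributions under unequal variances:
#' `t = (mean(x) - mean(y)) / sqrt(s2x/nx + s2y/ny)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value
#' (computed by [stats::t.test()]).
#'
#' @param x,y numeric samples, each with >= 2 values.
#' @param labels length-2 character vector naming the groups.
#' @return An `energy_comparison` list: `labels`, `means`, `t`, `df`,
#'   `p`.
#' @export
welch_ttest <- function(x, y, labels = c("x", "y")) {
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs >= 2 values")
  if (var(x) == 0 && var(y) == 0) stop("zero variance in both samples")
  tt <- t.test(x, y, var.equal = FALSE)
  structure(list(labels = labels,
                 means = setNames(c(mean(x), mean(y)), labels),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value),
            class = "energy_comparison")
}

#' @export
print.energy_comparison <- function(x, ...) {
  cat(sprintf("<welch> %s (%.2f) vs %s (%.2f): t = %.3f, df = %.1f, p = %.3g\n",
              x$labels[1L], x$means[1L], x$labels[2L], x$means[2L],
              x$t, x$df, x$p))
  invisible(x)
}

#' Pairwise Welch comparison of energy distributions
#'
#' Mirrors the validation comparison grid: all pairwise Welch tests
#' between the matched (actual) minimum-energy distribution and the
#' randomized null distributions.
#'
#' @param groups named list of numeric vectors (>= 2 values each), e.g.
#'   `list(actual = ..., label_permuted = ..., sequence_randomized = ...)`.
#' @return Data frame `group1`, `group2`, `mean1`, `mean2`, `t`, `df`,
#'   `p` for every unordered pair.
#' @export
compare_energy_distributions <- function(groups) {
  nm <- names(groups)
  if (length(nm) < 2L) stop("need at least two groups")
  combos <- utils::combn(nm, 2L)
  res <- apply(combos, 2L, function(pr) {
    w <- welch_ttest(groups[[pr[1L]]], groups[[pr[2L]]], labels = pr)
    data.frame(group1 = pr[1L], group2 = pr[2L],
               mean1 = unname(w$means[1L]), mean2 = unname(w$means[2L]),
               t = w$t, df = w$df, p = w$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
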