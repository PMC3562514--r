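#' miRNA-to-host-gene mapping table
#'
#' The mapping connects precursor miRNAs to the protein-coding
#' transcripts they overlap genomically, with the attributes the
#' predictors consume: relative strand (sense/antisense), the class of
#' sequence overlapped (intron, exon, 3'UTR, 5'UTR) and the evidence
#' status of the annotation (experimental vs predicted).  Each edge also
#' carries the expression-array probeset id(s) of the host transcript
#' and the mature miRNA names (miR and miR*) derived from the precursor.
#'
#' @param edges data frame with columns `mirbase_id`, `strand`
#'   (`sense`/`antisense`), `overlap` (`intron`/`exon`/`utr3`/`utr5`),
#'   `evidence` (`experimental`/`predicted`), `evidence_label` (raw
#'   source string), `gene_id`, `transcript_id`, `probeset_id`
#'   (`;`-separated list allowed), `chromosome`, `start`, `end`, `mir`,
#'   `mir_star`.
#' @return A `mir_mapping` data frame (edge list).
#' @export
mir_mapping <- function(edges) {
  req <- c("mirbase_id", "strand", "overlap", "evidence", "evidence_label",
           "gene_id", "transcript_id", "probeset_id", "chromosome",
           "start", "end", "mir", "mir_star")
  miss <- setdiff(req, names(edges))
  if (length(miss)) stop("mapping is missing columns: ",
                         paste(miss, collapse = ", "))
  edges <- edges[, req]
  bad <- setdiff(unique(edges$overlap), c("intron", "exon", "utr3", "utr5"))
  if (length(bad)) stop("unknown overlap class: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(edges$strand), c("sense", "antisense"))
  if (length(bad)) stop("unknown strand value: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(edges$evidence), c("experimental", "predicted"))
  if (length(bad)) stop("unknown evidence class: ", paste(bad, collapse = ", "))
  edges$start <- as.integer(edges$start); edges$end <- as.integer(edges$end)
  if (any(edges$start > edges$end, na.rm = TRUE))
    stop("mapping has edges with start > end")
  no_mat <- (is.na(edges$mir) | edges$mir == "") &
    (is.na(edges$mir_star) | edges$mir_star == "")
  if (any(no_mat)) stop("every edge needs at least one mature miRNA id")
  rownames(edges) <- NULL
  structure(edges, class = c("mir_mapping", "data.frame"))
}

#' @export
print.mir_mapping <- function(x, ...) {
  cat(sprintf("<mir_mapping> %d edges, %d precursors, %d genes\n",
              nrow(x), length(unique(x$mirbase_id)),
              length(unique(x$gene_id))))
  print(head(as.data.frame(x), 5L))
  invisible(x)
}

# normalize the Overlap tokens found in mapping files
.norm_overlap <- function(ov) {
  ov <- tolower(trimws(ov))
  ov[ov %in% c("3'utr", "3utr", "utr3", "three_prime_utr")] <- "utr3"
  ov[ov %in% c("5'utr", "5utr", "utr5", "five_prime_utr")] <- "utr5"
  bad <- setdiff(unique(ov), c("intron", "exon", "utr3", "utr5"))
  if (length(bad)) stop("unknown overlap token: ", paste(bad, collapse = ", "))
  ov
}

# evidence binarization: free-text labels mentioning automatic/predicted
# annotation become "predicted", everything else "experimental"
.norm_evidence <- function(ev) {
  ifelse(grepl("automatic|predicted", ev, ignore.case = TRUE),
         "predicted", "experimental")
}

#' Read a mapping table from CSV
#'
#' Consumes the tabular mapping format: columns `mirbase_id`, `strand`
#' (`+`/`-` meaning sense/antisense, or the words themselves),
#' `overlap`, `evidence` (free-text source label), `gene_id`,
#' `transcript_id`, `probeset_id`, `chromosome`, `start`, `end`, `mir`,
#' `mir_star`.  Overlap tokens are case-normalized; evidence labels
#' containing "automatic" or "predicted" are classed predicted, all
#' others experimental, with the raw label kept in `evidence_label`.
#'
#' @param path CSV path.
#' @return A `mir_mapping`.
#' @export
read_mapping <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  strand <- trimws(df$strand)
  strand[strand == "+"] <- "sense"
  strand[strand == "-"] <- "antisense"
  raw_evidence <- if ("evidence_label" %in% names(df)) df$evidence_label
                  else df$evidence
  edges <- data.frame(
    mirbase_id = df$mirbase_id,
    strand = strand,
    overlap = .norm_overlap(df$overlap),
    evidence = .norm_evidence(raw_evidence),
    evidence_label = raw_evidence,
    gene_id = df$gene_id,
    transcript_id = df$transcript_id,
    probeset_id = df$probeset_id,
    chromosome = as.character(df$chromosome),
    start = as.integer(df$start),
    end = as.integer(df$end),
    mir = df$mir,
    mir_star = if ("mir_star" %in% names(df)) df$mir_star else NA_character_,
    stringsAsFactors = FALSE)
  mir_mapping(edges)
}

#' Write a mapping table to CSV
#' @param x a `mir_mapping`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mapping <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Build a mapping from genomic coordinates
#'
#' Coordinate-intersection mapping: every precursor miRNA locus that
#' genuinely overlaps a transcript yields one edge.  When a locus spans
#' feature boundaries the overlap class is resolved by the priority
#' utr3 > utr5 > exon > intron.  Strand relation is `sense` iff the two
#' strands are equal.  Coordinates are 1-based inclusive throughout.
#'
#' @param mirna_loci data frame: `id`, `chromosome`, `start`, `end`,
#'   `strand` (`+`/`-`).
#' @param gene_models data frame of features: `gene_id`,
#'   `transcript_id`, `chromosome`, `start`, `end`, `strand`, `feature`
#'   in `{transcript, exon, utr5, utr3}`.  A `transcript` row per
#'   transcript gives the full span; regions of the span not covered by
#'   exon/UTR features are introns.
#' @param probeset_map optional data frame `transcript_id`,
#'   `probeset_id`; defaults to using the transcript id as probeset id.
#' @param mature_map optional data frame `id`, `mir`, `mir_star` giving
#'   mature names per precursor; defaults to `mir = id`.
#' @return A `mir_mapping` with `evidence = "predicted"` (the edges are
#'   coordinate-derived, not curated).
#' @export
build_mapping <- function(mirna_loci, gene_models, probeset_map = NULL,
                          mature_map = NULL) {
  tx <- gene_models[gene_models$feature == "transcript", , drop = FALSE]
  if (nrow(tx) == 0L) stop("gene_models has no `transcript` spans")
  dropped <- 0L
  rows <- list()
  for (i in seq_len(nrow(mirna_loci))) {
    mi <- mirna_loci[i, ]
    if (!mi$chromosome %in% tx$chromosome) { dropped <- dropped + 1L; next }
    hit <- tx$chromosome == mi$chromosome &
      tx$start <= mi$end & tx$end >= mi$start
    for (j in which(hit)) {
      t <- tx[j, ]
      feats <- gene_models[gene_models$transcript_id == t$transcript_id &
                           gene_models$feature != "transcript", , drop = FALSE]
      cls <- "intron"
      for (want in c("utr3", "utr5", "exon")) {
        f <- feats[feats$feature == want, , drop = FALSE]
        if (nrow(f) && any(f$start <= mi$end & f$end >= mi$start)) {
          cls <- want; break
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        mirbase_id = mi$id,
        strand = if (mi$strand == t$strand) "sense" else "antisense",
        overlap = cls,
        evidence = "predicted",
        evidence_label = "coordinate_overlap",
        gene_id = t$gene_id, transcript_id = t$transcript_id,
        probeset_id = t$transcript_id,
        chromosome = mi$chromosome,
        start = as.integer(mi$start), end = as.integer(mi$end),
        mir = mi$id, mir_star = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (dropped) message(dropped, " miRNA locus/loci on chromosomes absent ",
                       "from the gene models (no edges emitted)")
  if (!length(rows)) stop("no overlaps found: empty mapping")
  edges <- do.call(rbind, rows)
  if (!is.null(probeset_map)) {
    idx <- match(edges$transcript_id, probeset_map$transcript_id)
    edges$probeset_id[!is.na(idx)] <-
      probeset_map$probeset_id[idx[!is.na(idx)]]
  }
  if (!is.null(mature_map)) {
    idx <- match(edges$mirbase_id, mature_map$id)
    edges$mir[!is.na(idx)] <- mature_map$mir[idx[!is.na(idx)]]
    if ("mir_star" %in% names(mature_map))
      edges$mir_star[!is.na(idx)] <- mature_map$mir_star[idx[!is.na(idx)]]
  }
  mir_mapping(edges)
}

#' Filter mapping edges by attribute
#'
#' Keeps edges satisfying every predicate given.  At least one predicate
#' is required.  The default predictor pre-filter is
#' `filter_edges(map, strand = "sense", overlap = "intron")`: antisense,
#' exonic and UTR overlaps correlate weakly with host expression and
#' mostly add noise.
#'
#' @param x a `mir_mapping`.
#' @param strand,overlap,evidence optional values to keep.
#' @return The filtered `mir_mapping` (possibly 0 edges, with warning).
#' @export
filter_edges <- function(x, strand = NULL, overlap = NULL, evidence = NULL) {
  if (is.null(strand) && is.null(overlap) && is.null(evidence))
    stop("give at least one of `strand`, `overlap`, `evidence`")
  keep <- rep(TRUE, nrow(x))
  if (!is.null(strand))   keep <- keep & x$strand %in% strand
  if (!is.null(overlap))  keep <- keep & x$overlap %in% overlap
  if (!is.null(evidence)) keep <- keep & x$evidence %in% evidence
  if (!any(keep)) warning("edge filter removed every edge")
  out <- as.data.frame(x)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("mir_mapping", "data.frame"))
}

#' Edge counts and percentages by class
#'
#' @param x a non-empty `mir_mapping`.
#' @return A list with data frames `overlap` and `strand`, each holding
#'   `class`, `count` and `pct` (percentage rounded to nearest integer).
#' @export
edge_statistics <- function(x) {
  if (nrow(x) == 0L) stop("empty mapping")
  one <- function(v) {
    tab <- sort(table(v), decreasing = TRUE)
    data.frame(class = names(tab), count = as.integer(tab),
               pct = as.integer(round(100 * as.integer(tab) / length(v))),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  list(overlap = one(x$overlap), strand = one(x$strand))
}

#' Map mature miRNAs to expression-matrix rows
#'
#' Realizes the mapping function: for every mature miRNA in the table,
#' finds the rows of an mRNA expression matrix whose feature id matches
#' one of the edge's probeset ids.  Probesets absent from the matrix
#' drop silently (counted in a message); miRNAs left with no host rows
#' get an empty entry.
#'
#' @param x a `mir_mapping`.
#' @param mat an `expr_matrix` with role `"mrna"`.
#' @return A named list (one element per mature miRNA id) of data frames
#'   `row` (matrix row index), `edge` (edge index in `x`), in edge
#'   order; class `mapped_hosts`.
#' @export
map_expression_rows <- function(x, mat) {
  if (expr_role(mat) != "mrna") stop("matrix role must be 'mrna'")
  edf <- as.data.frame(x)
  # expand to one record per (mature id, probeset id)
  recs <- list()
  for (i in seq_len(nrow(edf))) {
    mats <- unique(stats::na.omit(c(edf$mir[i], edf$mir_star[i])))
    mats <- mats[mats != ""]
    probes <- strsplit(edf$probeset_id[i], ";", fixed = TRUE)[[1L]]
    for (m in mats) for (p in probes)
      recs[[length(recs) + 1L]] <- c(m, p, i)
  }
  recs <- as.data.frame(do.call(rbind, recs), stringsAsFactors = FALSE)
  names(recs) <- c("mature", "probeset", "edge")
  recs$edge <- as.integer(recs$edge)
  recs$row <- match(recs$probeset, rownames(mat))
  n_missing <- sum(is.na(recs$row))
  if (n_missing) message(n_missing,
    " probeset reference(s) absent from the expression matrix")
  out <- lapply(split(recs, factor(recs$mature, unique(recs$mature))),
                function(d) {
    d <- d[!is.na(d$row), c("row", "edge"), drop = FALSE]
    rownames(d) <- NULL
    d
  })
  structure(out, class = "mapped_hosts")
}
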