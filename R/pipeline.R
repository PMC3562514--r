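#' Pipeline configuration
#'
#' Collects and validates every knob of the end-to-end run.  Inputs may
#' be file paths or in-memory objects (the corresponding reader is
#' applied to paths at run time).
#'
#' @param expr mRNA expression matrix (`expr_matrix` or TSV/CSV path).
#' @param design sample design (`design_table` or TSV path).
#' @param mapping miRNA-host mapping (`mir_mapping` or CSV path).
#' @param genesets named list of `gene_set_collection`s, a single
#'   collection, or GMT path(s); optional.
#' @param annotation probe annotation data frame (`probeset_id`,
#'   `entrez`, `symbol`, `name`) or CSV path; optional.
#' @param predictor `"scaling"`, `"linear"` or `"both"`.
#' @param lm_fit a pre-trained [fit_linear_model()] object (required
#'   for the linear predictor unless `mirna_train` is given).
#' @param mirna_train paired miRNA `expr_matrix` for training the
#'   linear predictor on the fly; optional.
#' @param coeffs [scaling_coefficients()] for the scaling predictor.
#' @param variant linear-model formula variant.
#' @param test row test (`"welch"`, `"student"`, `"anova"`).
#' @param corr_method correlation method for target extraction.
#' @param cutoff anti-correlation cutoff, must be negative
#'   (default -0.8).
#' @param n_perm permutations for the p-value cutoff.
#' @param seed integer seed (mandatory; every stochastic stage uses it).
#' @param out_dir report output directory, or NULL for no files.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(expr, design, mapping, genesets = NULL,
                            annotation = NULL,
                            predictor = c("scaling", "linear", "both"),
                            lm_fit = NULL, mirna_train = NULL,
                            coeffs = scaling_coefficients(),
                            variant = "standard",
                            test = "welch",
                            corr_method = "pearson",
                            cutoff = -0.8, n_perm = 1L, seed,
                            out_dir = NULL) {
  predictor <- match.arg(predictor)
  if (missing(seed)) stop("`seed` is mandatory")
  if (!is.numeric(cutoff) || cutoff >= 0)
    stop("`cutoff` must be a negative correlation value")
  for (p in c("expr", "design", "mapping", "annotation")) {
    v <- get(p)
    if (is.character(v) && !file.exists(v))
      stop("file not found for `", p, "`: ", v)
  }
  if (predictor %in% c("linear", "both") && is.null(lm_fit) &&
      is.null(mirna_train))
    stop("the linear predictor needs `lm_fit` or `mirna_train`")
  structure(list(expr = expr, design = design, mapping = mapping,
                 genesets = genesets, annotation = annotation,
                 predictor = predictor, lm_fit = lm_fit,
                 mirna_train = mirna_train, coeffs = coeffs,
                 variant = variant, test = test,
                 corr_method = corr_method, cutoff = cutoff,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Flat keys mirror the [pipeline_config()] arguments; values given in
#' `...` (e.g. from CLI flags) override file values.
#'
#' @param path `.yaml`/`.yml` or `.json` file of flat keys.
#' @param ... overrides passed on to [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is needed to read YAML configurations")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  over <- list(...)
  vals[names(over)] <- over
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' Executes the whole flow: differential statistics with the
#' permutation-derived cutoff, significance filtering, host mapping,
#' the selected pseudo-expression predictor(s), per-predictor
#' significant-miRNA calls, the consensus union, the anti-correlation
#' target filter, interaction summaries, gene-set over-representation,
#' and (optionally) CSV/HTML reports with a machine-readable manifest.
#'
#' If neither predictor yields a significant miRNA the run stops early
#' with `status = "empty_consensus"` — with nothing significant no
#' downstream analysis is meaningful.
#'
#' @param config a [pipeline_config()].
#' @return A `pipeline_result` list: `status` (`"ok"` or
#'   `"empty_consensus"`), `stats`, `cutoff`, `significant`, `pseudo`,
#'   `calls`, `consensus`, `correlation`, `interactions`, `summaries`,
#'   `enrichment`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  expr <- if (is.character(config$expr))
    read_expression(config$expr, "mrna") else config$expr
  design <- if (is.character(config$design))
    read_design(config$design) else config$design
  mapping <- if (is.character(config$mapping))
    read_mapping(config$mapping) else config$mapping
  annotation <- if (is.character(config$annotation))
    read.csv(config$annotation, stringsAsFactors = FALSE) else
      config$annotation
  genesets <- config$genesets
  if (is.character(genesets)) genesets <- lapply(genesets, read_gmt)
  if (inherits(genesets, "gene_set_collection"))
    genesets <- list(user = genesets)

  st <- suppressMessages(row_stats(expr, design, test = config$test))
  cut <- permutation_cutoff(expr, design, n_perm = config$n_perm,
                            seed = config$seed, test = config$test)
  sig <- filter_significant(expr, st, as.numeric(cut))
  manifest <- list(seed = config$seed, cutoff_pvalue = as.numeric(cut),
                   corr_cutoff = config$cutoff, n_perm = config$n_perm,
                   predictor = config$predictor,
                   n_features = nrow(expr), n_samples = ncol(expr),
                   n_significant = nrow(sig$matrix))
  if (nrow(sig$matrix) == 0L)
    return(.pipeline_done("empty_consensus", st, cut, sig, NULL, NULL,
                          NULL, NULL, NULL, NULL, manifest, config))

  hosts_all <- suppressMessages(map_expression_rows(mapping, expr))

  calls_s <- NULL; calls_l <- NULL; pseudo <- list()
  if (config$predictor %in% c("scaling", "both")) {
    ps <- suppressWarnings(
      scaling_predict(expr, st, hosts_all, mapping, coeffs = config$coeffs))
    pseudo$scaling <- ps
    calls_s <- significant_mirnas(ps, design, n_perm = config$n_perm,
                                  seed = config$seed, test = config$test)
  }
  if (config$predictor %in% c("linear", "both")) {
    fit <- config$lm_fit
    if (is.null(fit)) {
      rows <- build_design_rows(config$mirna_train, expr, st, hosts_all,
                                mapping, variant = config$variant)
      fit <- suppressMessages(fit_linear_model(rows, seed = config$seed))
    }
    pl <- suppressWarnings(lm_predict(fit, expr, st, hosts_all, mapping))
    pseudo$linear <- pl
    calls_l <- significant_mirnas(pl, design, n_perm = config$n_perm,
                                  seed = config$seed, test = config$test)
  }
  cons <- consensus(calls_s, calls_l)
  manifest$n_consensus <- nrow(cons)
  if (attr(cons, "terminate"))
    return(.pipeline_done("empty_consensus", st, cut, sig, pseudo,
                          list(scaling = calls_s, linear = calls_l),
                          cons, NULL, NULL, NULL, manifest, config))

  # correlate consensus pseudo rows against the significant genes
  psel <- pseudo[[if (!is.null(pseudo$scaling)) "scaling" else "linear"]]
  prows <- intersect(rownames(psel), cons$mirna_id)
  psub <- expression_matrix(unclass(psel)[prows, , drop = FALSE], "pseudo")
  cm <- suppressMessages(correlate(psub, sig$matrix,
                                   method = config$corr_method))
  inter <- get_ht(cm, cutoff = config$cutoff)
  manifest$n_interactions <- nrow(inter)
  summaries <- summarize_interactions(inter, annotation)

  enr <- NULL
  if (!is.null(genesets) && nrow(inter) > 0L) {
    to_sym <- function(ids) {
      if (is.null(annotation)) return(unique(ids))
      idx <- match(ids, annotation$probeset_id)
      out <- ifelse(is.na(idx), ids, annotation$symbol[idx])
      unique(out)
    }
    universe <- to_sym(rownames(expr))
    query <- to_sym(unique(inter$target_id))
    enr <- lapply(genesets, function(g)
      hypergeom_enrich(query, g, universe))
    manifest$n_collections <- length(enr)
  }
  res <- .pipeline_done("ok", st, cut, sig, pseudo,
                        list(scaling = calls_s, linear = calls_l),
                        cons, cm, list(interactions = inter,
                                       summaries = summaries),
                        enr, manifest, config)
  if (!is.null(config$out_dir)) render_reports(res, config$out_dir)
  res
}

.pipeline_done <- function(status, st, cut, sig, pseudo, calls, cons,
                           cm, targets, enr, manifest, config) {
  manifest$status <- status
  structure(list(status = status, stats = st, cutoff = as.numeric(cut),
                 significant = sig, pseudo = pseudo, calls = calls,
                 consensus = cons, correlation = cm,
                 interactions = if (is.null(targets)) NULL else
                   targets$interactions,
                 summaries = if (is.null(targets)) NULL else
                   targets$summaries,
                 enrichment = enr, manifest = manifest, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result status=%s> %d significant genes, %s consensus miRNAs, %s interactions\n",
              x$status, x$manifest$n_significant,
              x$manifest$n_consensus %||% 0,
              x$manifest$n_interactions %||% 0))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write CSV/HTML reports for a pipeline run
#'
#' Emits the three interaction lists, per-collection enrichment tables,
#' QC data (p-value histogram, volcano coordinates, sample PCA scores),
#' a JSON run manifest, and a static HTML index linking everything.
#'
#' @param res a `pipeline_result`.
#' @param out_dir output directory (created if needed).
#' @return Character vector of written files, invisibly.
#' @export
render_reports <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  files <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    files <<- c(files, name)
  }
  if (!is.null(res$summaries) && length(res$summaries$interactions)) {
    wr(res$summaries$interactions, "interactions.csv")
    wr(res$summaries$by_mirna, "genes_by_mirna.csv")
    wr(res$summaries$by_gene, "mirnas_by_gene.csv")
  } else {
    wr(data.frame(note = "zero interactions"), "interactions.csv")
  }
  if (!is.null(res$enrichment))
    for (nm in names(res$enrichment))
      wr(res$enrichment[[nm]], sprintf("enrichment_%s.csv", nm))
  # QC data
  st <- res$stats
  h <- graphics::hist(st$pval, breaks = seq(0, 1, by = 0.05), plot = FALSE)
  wr(data.frame(bin_start = h$breaks[-length(h$breaks)],
                bin_end = h$breaks[-1L], count = h$counts),
     "qc_pvalue_hist.csv")
  wr(data.frame(feature_id = st$feature_id, fc = st$fc,
                neg_log10_p = -log10(pmax(st$pval, 1e-300))),
     "qc_volcano.csv")
  x <- res$significant$matrix
  if (nrow(x) >= 2L) {
    pc <- prcomp(t(unclass(x)), center = TRUE, scale. = FALSE)
    k <- min(3L, ncol(pc$x))
    wr(data.frame(sample_id = colnames(x), pc$x[, seq_len(k), drop = FALSE]),
       "qc_pca.csv")
  }
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(res$manifest, mpath, auto_unbox = TRUE, digits = NA)
  files <- c(files, "manifest.json")
  html <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
            "<title>miRNA-mRNA interaction report</title></head><body>",
            sprintf("<h1>miRNA-mRNA interaction report (status: %s)</h1>",
                    res$status),
            sprintf("<p>%d significant genes; %s consensus miRNAs; %s interactions.</p>",
                    res$manifest$n_significant,
                    res$manifest$n_consensus %||% 0,
                    res$manifest$n_interactions %||% 0),
            "<ul>",
            sprintf("<li><a href='%s'>%s</a></li>", files, files),
            "</ul></body></html>")
  writeLines(html, file.path(out_dir, "index.html"))
  invisible(c(files, "index.html"))
}
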