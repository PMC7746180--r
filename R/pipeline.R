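#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one object, echoing
#' the defaults used throughout: expression filter >= 10, BH-adjusted
#' p < 0.05, |log2 FC| > 1, peak fold > 2, 3 kb promoter scan window, and
#' the -5 kb / +0.5 kb TSS promoter window for peak assignment.
#'
#' @param expression_threshold expression filter on per-condition replicate
#'   means.
#' @param q_threshold,logfc_threshold DE-calling cutoffs.
#' @param fold_threshold,peak_pseudocount peak-filter parameters.
#' @param promoter_window motif-scan promoter length (bases).
#' @param peak_upstream,peak_downstream promoter window around the TSS for
#'   peak assignment.
#' @param rule cluster-selection predicate (default
#'   [responsive_rule_default()]).
#' @param motifs list of [motif_consensus()] objects to scan (default: the
#'   SIE).
#' @param seed integer seed for any simulated stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(expression_threshold = 10, q_threshold = 0.05,
                            logfc_threshold = 1, fold_threshold = 2,
                            peak_pseudocount = 1, promoter_window = 3000,
                            peak_upstream = 5000, peak_downstream = 500,
                            rule = responsive_rule_default,
                            motifs = list(sie_motif()), seed = 1) {
  stopifnot(expression_threshold > 0, q_threshold >= 0, logfc_threshold >= 0,
            fold_threshold > 0, promoter_window > 0, peak_upstream > 0,
            peak_downstream > 0)
  structure(list(expression_threshold = expression_threshold,
                 q_threshold = q_threshold, logfc_threshold = logfc_threshold,
                 fold_threshold = fold_threshold,
                 peak_pseudocount = peak_pseudocount,
                 promoter_window = promoter_window,
                 peak_upstream = peak_upstream,
                 peak_downstream = peak_downstream,
                 rule = rule, motifs = motifs, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the analysis pipeline end to end
#'
#' Stages: expression filter -> size factors -> the four canonical NB exact
#' tests -> DE calling -> pattern assignment -> cluster enumeration ->
#' responsive-cluster selection, then optionally a promoter motif scan (if
#' promoter sequences are supplied), gene-set enrichment of the selected
#' genes (if a collection is supplied) and peak filtering/classification (if
#' peaks are supplied). Fails on the first stage error; per-stage summaries
#' go to `message()`.
#'
#' @param counts an [ox_counts()] object (e.g. from [simulate_counts()] or
#'   [read_count_table()]).
#' @param config a [pipeline_config()].
#' @param promoters named `DNAStringSet`/character vector of promoter
#'   sequences for the motif scan, or `NULL` to skip.
#' @param gene_sets named list of gene sets (e.g. [read_gmt()]) for
#'   enrichment of the selected genes, or `NULL` to skip.
#' @param peaks peak data.frame for fold filtering, or `NULL` to skip.
#' @param models a [gene_models()] object; when given with `peaks`, filtered
#'   peaks are assigned to promoters and classified.
#' @return list with elements `filtered`, `size_factors`, `de` (list of four
#'   called tables), `patterns`, `clusters`, `selected`, and (when inputs
#'   were given) `motif_hits`, `motif_summary`, `enrichment`,
#'   `peaks_kept`, `peak_classes`, `peak_genes`, plus `manifest` — a
#'   machine-readable run summary (config echo and per-stage row counts).
#' @export
run_all <- function(counts, config = pipeline_config(), promoters = NULL,
                    gene_sets = NULL, peaks = NULL, models = NULL) {
  stopifnot(inherits(counts, "ox_counts"), inherits(config, "pipeline_config"))
  res <- list()

  filtered <- filter_expressed(counts, config$expression_threshold)
  message("filter_expressed: ", nrow(filtered$counts), "/", nrow(counts$counts),
          " genes kept (threshold ", config$expression_threshold, ")")
  sf <- estimate_size_factors(filtered)
  res$filtered <- filtered
  res$size_factors <- sf

  de <- lapply(canonical_comparisons(), function(spec) {
    r <- nb_exact_test(filtered, spec, size_factors = sf)
    call_de(r, config$q_threshold, config$logfc_threshold)
  })
  names(de) <- vapply(canonical_comparisons(), `[[`, character(1), "name")
  for (t in de)
    message("DE ", attr(t, "comparison"), ": ", sum(t$significant),
            " significant (q<", config$q_threshold, ", |logfc|>",
            config$logfc_threshold, ")")
  res$de <- de

  patterns <- assign_patterns(de)
  clusters <- enumerate_clusters(patterns)
  selected <- select_responsive(clusters, config$rule)
  s <- attr(selected, "summary")
  message("patterns: ", sum(patterns$code != "0,0,0,0"), " DE genes in ",
          nrow(clusters), " clusters; ", s$n_selected,
          " responsive clusters (", s$n_up, " up / ", s$n_down, " down genes)")
  res$patterns <- patterns
  res$clusters <- clusters
  res$selected <- selected
  selected_genes <- unlist(selected$genes, use.names = FALSE)

  if (!is.null(promoters)) {
    hits <- lapply(config$motifs, function(mo) scan_promoters(promoters, mo))
    names(hits) <- vapply(config$motifs, `[[`, character(1), "name")
    res$motif_hits <- do.call(rbind, c(hits, make.row.names = FALSE))
    res$motif_summary <- lapply(hits, genes_with_motif,
                                gene_set = names(promoters))
    for (nm in names(res$motif_summary))
      message("motif ", nm, ": ", res$motif_summary[[nm]]$summary,
              " promoters with >=1 site")
  }

  if (!is.null(gene_sets)) {
    res$enrichment <- enrich(selected_genes, gene_sets,
                             universe = gene_ids(filtered))
    message("enrichment: ", nrow(res$enrichment), " sets tested, ",
            sum(res$enrichment$q < 0.05), " at q<0.05")
  }

  if (!is.null(peaks)) {
    kept <- filter_peaks_fold(peaks, config$fold_threshold,
                              config$peak_pseudocount)
    message("peak filter: ", nrow(kept), "/", nrow(peaks), " peaks >",
            config$fold_threshold, "-fold over control")
    res$peaks_kept <- kept
    if (!is.null(models)) {
      res$peak_classes <- classify_region(kept, models, config$peak_upstream,
                                          config$peak_downstream)
      res$peak_genes <- assign_to_promoters(kept, models,
                                            config$peak_upstream,
                                            config$peak_downstream)$genes
      message("peak classes: ",
              paste(names(table(res$peak_classes)),
                    table(res$peak_classes), sep = "=", collapse = ", "))
    }
  }

  res$manifest <- build_manifest(config, res, counts)
  res
}

# machine-readable run summary: config echo + per-stage row counts
build_manifest <- function(config, res, counts) {
  cfg <- config[setdiff(names(config), c("rule", "motifs"))]
  cfg$motifs <- lapply(config$motifs, function(m)
    list(name = m$name, pattern = m$pattern, max_mismatch = m$max_mismatch))
  stages <- list(
    input_genes = nrow(counts$counts),
    filtered_genes = nrow(res$filtered$counts),
    de_significant = lapply(res$de, function(t) sum(t$significant)),
    n_clusters = nrow(res$clusters),
    n_selected_clusters = nrow(res$selected),
    selected_genes = attr(res$selected, "summary")$n_genes,
    selected_up = attr(res$selected, "summary")$n_up,
    selected_down = attr(res$selected, "summary")$n_down)
  if (!is.null(res$motif_summary))
    stages$motif_genes <- lapply(res$motif_summary, `[[`, "summary")
  if (!is.null(res$peaks_kept)) stages$peaks_kept <- nrow(res$peaks_kept)
  if (!is.null(res$peak_classes))
    stages$peak_classes <- as.list(table(res$peak_classes))
  list(config = cfg, stages = stages)
}

#' Write a run manifest as JSON
#' @param manifest the `manifest` element of a [run_all()] result.
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
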