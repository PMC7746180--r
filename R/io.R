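# Adapters for the plain-text formats used by the pipeline. Output tables
# carry a leading '#' header line naming coordinate conventions and
# thresholds where relevant; readers skip '#' lines.

#' Write / read a count matrix with sample metadata
#'
#' Counts as TSV (`gene_id` + one column per sample); metadata as TSV with
#' columns `sample`, `genotype`, `treatment`, `replicate`.
#'
#' @param x an [ox_counts()] object.
#' @param counts_path,metadata_path file paths.
#' @return `write_count_table` returns the paths invisibly;
#'   `read_count_table` returns an `ox_counts` object.
#' @export
write_count_table <- function(x, counts_path, metadata_path) {
  stopifnot(inherits(x, "ox_counts"))
  df <- data.frame(gene_id = gene_ids(x), x$counts, check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$samples, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts_path, metadata_path))
}

#' @rdname write_count_table
#' @export
read_count_table <- function(counts_path, metadata_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id")
    stop("counts file ", counts_path, ": first column must be gene_id")
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  ox_counts(m, meta)
}

#' Read / write gene-set collections in GMT format
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#' Malformed lines (fewer than three fields) are an error naming the line.
#'
#' @param path GMT file path.
#' @return `read_gmt`: named list of character vectors, with a `description`
#'   attribute per set.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop("malformed GMT line(s) in ", path, ": ", paste(bad, collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  for (i in seq_along(sets))
    attr(sets[[i]], "description") <- parts[[i]][2]
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(!is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description") %||% nm
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a peak table
#'
#' BED3-plus-depths TSV: `contig`, `start`, `end` (0-based half-open),
#' `peak_id`, `sample_depth`, `control_depth`.
#'
#' @param peaks peak data.frame.
#' @param path file path.
#' @export
write_peak_table <- function(peaks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# peak table; coordinates 0-based half-open", con)
  utils::write.table(peaks, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("contig", "start", "end", "sample_depth", "control_depth")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("peak table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  df
}

#' Write a called DE table
#'
#' TSV with a comment header naming the comparison and the thresholds used.
#'
#' @param results a [call_de()] output.
#' @param path file path.
#' @param q_threshold,logfc_threshold the thresholds used (echoed in the
#'   header).
#' @export
write_de_table <- function(results, path, q_threshold = 0.05,
                           logfc_threshold = 1) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# comparison=%s position=%s; significant iff q<%g and |logfc|>%g",
    attr(results, "comparison") %||% "NA", attr(results, "position") %||% "NA",
    q_threshold, logfc_threshold), con)
  utils::write.table(results, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cluster table
#'
#' TSV with columns `code`, `n_genes`, `gene_ids` (semicolon-joined), plus
#' `direction` for selected-cluster tables.
#'
#' @param clusters an [enumerate_clusters()] or [select_responsive()] output.
#' @param path file path.
#' @export
write_cluster_table <- function(clusters, path) {
  df <- data.frame(code = clusters$code, n_genes = clusters$n_genes,
                   gene_ids = vapply(clusters$genes, paste, character(1),
                                     collapse = ";"),
                   stringsAsFactors = FALSE)
  if ("direction" %in% names(clusters)) df$direction <- clusters$direction
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
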