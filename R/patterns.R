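#' Parse a pattern code string
#'
#' Pattern codes are comma-joined signed integers over \{-1, 0, 1\}, e.g.
#' `"-1,0,0,1"`, in the fixed comparison order (see
#' [canonical_comparisons()]).
#'
#' @param code a code string.
#' @return integer vector of length 4.
#' @export
parse_pattern_code <- function(code) {
  v <- suppressWarnings(as.integer(strsplit(code, ",", fixed = TRUE)[[1]]))
  if (length(v) != 4 || anyNA(v) || !all(v %in% -1:1))
    stop("invalid pattern code \"", code,
         "\": expected four comma-joined values in {-1, 0, 1}")
  v
}

#' Format a pattern code
#' @param positions integer vector of length 4 over \{-1, 0, 1\}.
#' @return the code string, e.g. `"1,0,0,-1"`.
#' @export
format_pattern_code <- function(positions) {
  stopifnot(length(positions) == 4, all(positions %in% -1:1))
  paste(as.integer(positions), collapse = ",")
}

#' Discretise a comparison into -1 / 0 / 1
#'
#' A gene scores `sign(logfc)` in a comparison if it is significant there
#' (per [call_de()]) and 0 otherwise.
#'
#' @param significant logical vector.
#' @param logfc numeric vector of log2 fold changes.
#' @return integer vector over \{-1, 0, 1\}.
#' @export
discretise <- function(significant, logfc) {
  stopifnot(length(significant) == length(logfc))
  as.integer(ifelse(significant, sign(logfc), 0L))
}

#' Assign a four-position pattern code to every gene
#'
#' Takes the four called DE tables (one per comparison position), intersects
#' their gene universes (mismatches are reported with a warning), and
#' discretises each comparison into -1/0/1, yielding one pattern code per
#' gene.
#'
#' @param de_tables list of four [call_de()] outputs; their `position`
#'   attributes (or list order) must cover positions 1-4 exactly.
#' @return data.frame with columns `gene_id`, `pos1`..`pos4`, `code`.
#' @export
assign_patterns <- function(de_tables) {
  if (length(de_tables) != 4) stop("exactly four comparison tables are required")
  pos <- vapply(seq_along(de_tables), function(i)
    as.integer(attr(de_tables[[i]], "position") %||% i), integer(1))
  if (!setequal(pos, 1:4)) stop("comparison positions must cover 1-4 exactly")
  de_tables <- de_tables[order(pos)]
  for (t in de_tables)
    if (!all(c("gene_id", "significant", "logfc") %in% names(t)))
      stop("tables must be call_de() outputs (gene_id, logfc, significant)")
  common <- Reduce(intersect, lapply(de_tables, `[[`, "gene_id"))
  n_drop <- sum(vapply(de_tables, function(t)
    sum(!t$gene_id %in% common), integer(1)))
  if (n_drop > 0)
    warning(n_drop, " gene entries outside the shared universe were dropped")
  mat <- vapply(de_tables, function(t) {
    t <- t[match(common, t$gene_id), ]
    discretise(t$significant, t$logfc)
  }, integer(length(common)))
  out <- data.frame(gene_id = common, pos1 = mat[, 1], pos2 = mat[, 2],
                    pos3 = mat[, 3], pos4 = mat[, 4],
                    stringsAsFactors = FALSE)
  out$code <- paste(out$pos1, out$pos2, out$pos3, out$pos4, sep = ",")
  out
}

#' Enumerate pattern clusters
#'
#' Groups the DE gene set (genes with at least one nonzero position) by
#' pattern code. The all-zero code is never a cluster.
#'
#' @param patterns output of [assign_patterns()].
#' @return data.frame with columns `code`, `n_genes`, `genes` (list column),
#'   sorted by decreasing size then code.
#' @export
enumerate_clusters <- function(patterns) {
  stopifnot(all(c("gene_id", "code") %in% names(patterns)))
  de <- patterns[patterns$code != "0,0,0,0", ]
  if (nrow(de) == 0)
    return(data.frame(code = character(0), n_genes = integer(0),
                      genes = I(list())))
  by_code <- split(de$gene_id, de$code)
  out <- data.frame(code = names(by_code),
                    n_genes = lengths(by_code),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$genes <- I(unname(by_code))
  out[order(-out$n_genes, out$code), , drop = FALSE]
}

#' Default oxidation-responsive cluster rule
#'
#' Keeps a code iff the WT oxidation-v-basal response is significant
#' (position 1 nonzero), the C3S oxidation-v-basal response is absent
#' (position 3 zero), and the C3S cells are dis-regulated relative to WT in
#' at least one genotype comparison (position 2 or 4 nonzero).
#'
#' @param positions integer vector of length 4.
#' @return logical.
#' @export
responsive_rule_default <- function(positions) {
  positions[1] != 0 && positions[3] == 0 &&
    (positions[2] != 0 || positions[4] != 0)
}

#' Select oxidation-responsive clusters
#'
#' Applies a predicate over pattern codes to the cluster table and labels
#' each selected cluster with its response direction (the sign of
#' position 1: up- or down-regulated by oxidation in WT cells).
#'
#' @param clusters output of [enumerate_clusters()].
#' @param rule predicate `function(positions) -> logical`; default
#'   [responsive_rule_default()].
#' @return the selected rows of `clusters` with a `direction` column
#'   (`"up"`/`"down"`); a `summary` attribute carries `n_clusters`,
#'   `n_selected`, `n_genes`, `n_up`, `n_down`.
#' @export
select_responsive <- function(clusters, rule = responsive_rule_default) {
  stopifnot(is.function(rule))
  codes <- lapply(clusters$code, parse_pattern_code)
  keep <- vapply(codes, function(p) isTRUE(rule(p)), logical(1))
  sel <- clusters[keep, , drop = FALSE]
  sel$direction <- vapply(codes[keep], function(p)
    if (p[1] > 0) "up" else "down", character(1))
  attr(sel, "summary") <- list(
    n_clusters = nrow(clusters), n_selected = nrow(sel),
    n_genes = sum(sel$n_genes),
    n_up = sum(sel$n_genes[sel$direction == "up"]),
    n_down = sum(sel$n_genes[sel$direction == "down"]))
  sel
}
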