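#' Gene-by-sample count container
#'
#' A light container for a non-negative integer count matrix together with
#' the per-sample design labels of a two-genotype (WT / C3S) by two-treatment
#' (basal / oxidation) experiment with replicates.
#'
#' @param counts non-negative numeric matrix, genes in rows (rownames are the
#'   gene identifiers), samples in columns.
#' @param samples data.frame with one row per column of `counts` and columns
#'   `sample`, `genotype`, `treatment`, `replicate`.
#' @return An object of class `ox_counts`: a list with elements `counts`
#'   (integer matrix) and `samples` (data.frame).
#' @examples
#' m <- matrix(rpois(40, 20), nrow = 5,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
#' meta <- data.frame(sample = paste0("s", 1:8),
#'                    genotype = rep(c("WT", "C3S"), each = 4),
#'                    treatment = rep(c("basal", "oxidation"), each = 2, times = 2),
#'                    replicate = rep(1:2, times = 4))
#' x <- ox_counts(m, meta)
#' @export
ox_counts <- function(counts, samples) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix")
  if (is.null(rownames(counts))) stop("`counts` must have gene identifiers as rownames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene identifiers in `counts`")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  req <- c("sample", "genotype", "treatment", "replicate")
  if (!all(req %in% names(samples)))
    stop("`samples` must have columns: ", paste(req, collapse = ", "))
  if (nrow(samples) != ncol(counts))
    stop("`samples` rows (", nrow(samples), ") must match count columns (", ncol(counts), ")")
  samples <- as.data.frame(samples)[, req]
  samples$sample <- as.character(samples$sample)
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample
  if (!identical(colnames(counts), samples$sample))
    stop("column names of `counts` must equal samples$sample, in order")
  if (any(table(condition_key(samples$genotype, samples$treatment)) < 1))
    stop("every (genotype, treatment) cell needs at least one replicate")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, samples = samples), class = "ox_counts")
}

#' @export
print.ox_counts <- function(x, ...) {
  cat("ox_counts: ", nrow(x$counts), " genes x ", ncol(x$counts), " samples\n", sep = "")
  tab <- table(x$samples$genotype, x$samples$treatment)
  print(tab)
  invisible(x)
}

#' @export
dim.ox_counts <- function(x) dim(x$counts)

#' Gene identifiers of an ox_counts object
#' @param x an `ox_counts` object
#' @return character vector of gene identifiers
#' @export
gene_ids <- function(x) rownames(x$counts)

# column indices of one (genotype, treatment) group
group_columns <- function(x, group) {
  idx <- which(x$samples$genotype == group[[1]] & x$samples$treatment == group[[2]])
  if (length(idx) == 0)
    stop("no samples for group (", group[[1]], ", ", group[[2]], ")")
  idx
}
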