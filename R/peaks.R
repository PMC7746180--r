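#' Filter peaks by fold enrichment over control
#'
#' Keeps peaks whose sample read depth is strictly more than `fold_threshold`
#' times the control (IgG) depth, with a pseudocount added to both depths:
#' `fold = (sample_depth + pseudocount) / (control_depth + pseudocount)`.
#'
#' @param peaks data.frame with columns `contig`, `start`, `end` (0-based
#'   half-open), `sample_depth`, `control_depth` (and optionally `peak_id`).
#' @param fold_threshold strict fold cutoff (default 2: "more than 2-fold
#'   above control").
#' @param pseudocount added to both depths (default 1; guards zero-control
#'   peaks).
#' @return the kept rows with a `fold` column appended.
#' @export
filter_peaks_fold <- function(peaks, fold_threshold = 2, pseudocount = 1) {
  req <- c("contig", "start", "end", "sample_depth", "control_depth")
  stopifnot(all(req %in% names(peaks)))
  if (any(peaks$sample_depth < 0) || any(peaks$control_depth < 0))
    stop("read depths must be non-negative")
  if (any(peaks$end <= peaks$start)) stop("peak intervals must have end > start")
  peaks$fold <- (peaks$sample_depth + pseudocount) /
    (peaks$control_depth + pseudocount)
  out <- peaks[peaks$fold > fold_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene models for peak annotation
#'
#' @param genes data.frame with columns `gene_id`, `contig`, `start`, `end`
#'   (1-based inclusive gene span), `strand`. The TSS is the span start on
#'   the plus strand and the span end on the minus strand.
#' @param exons optional data.frame with columns `gene_id`, `contig`,
#'   `start`, `end` (1-based inclusive).
#' @return a `gene_models` list holding `GRanges` for gene spans, promoter
#'   anchors and exons.
#' @export
gene_models <- function(genes, exons = NULL) {
  req <- c("gene_id", "contig", "start", "end", "strand")
  stopifnot(all(req %in% names(genes)), all(genes$strand %in% c("+", "-")))
  span <- GenomicRanges::GRanges(genes$contig,
                                 IRanges::IRanges(genes$start, genes$end),
                                 strand = genes$strand, gene_id = genes$gene_id)
  exon_gr <- if (!is.null(exons) && nrow(exons))
    GenomicRanges::GRanges(exons$contig,
                           IRanges::IRanges(exons$start, exons$end),
                           gene_id = exons$gene_id)
  else GenomicRanges::GRanges()
  structure(list(span = span, exons = exon_gr), class = "gene_models")
}

# promoter windows [tss - upstream, tss + downstream) on the coding strand
promoter_windows <- function(models, upstream = 5000, downstream = 500) {
  tss <- GenomicRanges::resize(models$span, width = 1, fix = "start")
  suppressWarnings(GenomicRanges::trim(
    GenomicRanges::promoters(tss, upstream = upstream, downstream = downstream)))
}

peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(peaks$contig,
                         IRanges::IRanges(peaks$start + 1L, peaks$end))
}

#' Assign peaks to gene promoters
#'
#' A peak is assigned to every gene whose promoter window — `upstream` bases
#' before to `downstream` bases after the TSS, strand-aware — it overlaps by
#' at least one base. Defaults follow the -5 kb / +0.5 kb promoter
#' definition.
#'
#' @param peaks peak data.frame (0-based half-open `start`/`end`).
#' @param models a [gene_models()] object.
#' @param upstream,downstream promoter window extent around the TSS
#'   (defaults 5000 and 500).
#' @return list with `genes` (unique gene identifiers hit) and `assignments`
#'   (data.frame `peak` — row index into `peaks` — `peak_id` if present, and
#'   `gene_id`).
#' @export
assign_to_promoters <- function(peaks, models, upstream = 5000, downstream = 500) {
  stopifnot(inherits(models, "gene_models"))
  win <- promoter_windows(models, upstream, downstream)
  hits <- GenomicRanges::findOverlaps(peaks_to_granges(peaks), win,
                                      ignore.strand = TRUE)
  assignments <- data.frame(
    peak = S4Vectors::queryHits(hits),
    gene_id = S4Vectors::mcols(win)$gene_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  if ("peak_id" %in% names(peaks))
    assignments <- cbind(assignments[1],
                         peak_id = peaks$peak_id[assignments$peak],
                         assignments[2])
  list(genes = unique(assignments$gene_id), assignments = assignments)
}

#' Classify peaks into promoter / exon / intron / intergenic
#'
#' Precedence: a peak overlapping any promoter window is `promoter`;
#' otherwise overlapping any exon is `exon`; otherwise overlapping a gene
#' span is `intron`; otherwise `intergenic`.
#'
#' @inheritParams assign_to_promoters
#' @return character vector of class labels, one per peak row.
#' @export
classify_region <- function(peaks, models, upstream = 5000, downstream = 500) {
  stopifnot(inherits(models, "gene_models"))
  gr <- peaks_to_granges(peaks)
  in_prom <- GenomicRanges::countOverlaps(
    gr, promoter_windows(models, upstream, downstream), ignore.strand = TRUE) > 0
  in_exon <- GenomicRanges::countOverlaps(gr, models$exons,
                                          ignore.strand = TRUE) > 0
  in_span <- GenomicRanges::countOverlaps(gr, models$span,
                                          ignore.strand = TRUE) > 0
  ifelse(in_prom, "promoter",
         ifelse(in_exon, "exon", ifelse(in_span, "intron", "intergenic")))
}
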