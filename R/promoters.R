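#' Anchor positions from a GFF3 annotation
#'
#' Derives one promoter anchor per gene from a GFF3 file or an imported
#' `GRanges`. With `anchor = "ATG"` the anchor is the translation start: the
#' 5'-most CDS boundary of the gene (minimum CDS start on the plus strand,
#' maximum CDS end on the minus strand). With `anchor = "TSS"` it is the
#' 5'-most boundary of the gene/transcript features. Genes without a usable
#' feature are skipped with a warning.
#'
#' @param annotation path to a GFF3 file, or a `GRanges` as returned by
#'   `rtracklayer::import`.
#' @param anchor `"ATG"` (default) or `"TSS"`.
#' @return data.frame with columns `gene_id`, `contig`, `anchor` (1-based
#'   coordinate of the anchor base) and `strand`.
#' @export
anchors_from_gff <- function(annotation, anchor = c("ATG", "TSS")) {
  anchor <- match.arg(anchor)
  gr <- if (is.character(annotation)) rtracklayer::import(annotation) else annotation
  md <- S4Vectors::mcols(gr)
  gid <- if ("gene_id" %in% names(md)) as.character(md$gene_id)
  else if ("Parent" %in% names(md) && "ID" %in% names(md))
    ifelse(lengths(md$Parent) > 0, vapply(md$Parent, function(p)
      if (length(p)) as.character(p[1]) else NA_character_, character(1)),
      as.character(md$ID))
  else stop("annotation needs a gene_id, or ID/Parent, attribute")
  type <- as.character(md$type)
  want <- if (anchor == "ATG") type == "CDS"
  else type %in% c("gene", "mRNA", "transcript")
  if (!any(want)) stop("no ", if (anchor == "ATG") "CDS" else "gene/transcript",
                       " features in annotation")
  sel <- which(want & !is.na(gid))
  df <- data.frame(gene_id = gid[sel],
                   contig = as.character(GenomicRanges::seqnames(gr))[sel],
                   start = GenomicRanges::start(gr)[sel],
                   end = GenomicRanges::end(gr)[sel],
                   strand = as.character(GenomicRanges::strand(gr))[sel],
                   stringsAsFactors = FALSE)
  bad <- df$strand == "*"
  if (any(bad)) {
    warning(sum(bad), " feature(s) without strand skipped")
    df <- df[!bad, ]
  }
  out <- do.call(rbind, lapply(split(df, df$gene_id), function(g) {
    pos <- if (g$strand[1] == "+") min(g$start) else max(g$end)
    data.frame(gene_id = g$gene_id[1], contig = g$contig[1], anchor = pos,
               strand = g$strand[1], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Extract promoter windows upstream of gene anchors
#'
#' For a plus-strand gene with anchor at 1-based position `a`, the promoter
#' is the window `[a - window_length, a - 1]`; for a minus-strand gene it is
#' `[a + 1, a + window_length]`, reverse-complemented so the returned
#' sequence reads 5' to 3' toward the anchor. Windows are clipped at contig
#' boundaries and the actual length recorded. Genes on contigs absent from
#' the genome, or with an empty window after clipping, are skipped with a
#' warning.
#'
#' @param anchors data.frame as returned by [anchors_from_gff()] (columns
#'   `gene_id`, `contig`, `anchor`, `strand`).
#' @param genome named [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param window_length promoter window length in bases (default 3000).
#' @return list with `regions` (data.frame `gene_id`, `contig`, `start`,
#'   `end` — 1-based inclusive on the forward strand — `strand`, `length`)
#'   and `sequences` (a `DNAStringSet` named by gene).
#' @export
extract_promoters <- function(anchors, genome, window_length = 3000) {
  stopifnot(all(c("gene_id", "contig", "anchor", "strand") %in% names(anchors)),
            window_length >= 1)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  regions <- list(); seqs <- list()
  for (i in seq_len(nrow(anchors))) {
    g <- anchors[i, ]
    if (!g$contig %in% names(genome)) {
      warning("gene ", g$gene_id, ": contig ", g$contig, " absent from genome; skipped")
      next
    }
    clen <- Biostrings::width(genome[g$contig])
    if (g$strand == "+") {
      start <- max(1L, g$anchor - window_length); end <- g$anchor - 1L
    } else {
      start <- g$anchor + 1L; end <- min(clen, g$anchor + window_length)
    }
    if (end < start) {
      warning("gene ", g$gene_id, ": empty promoter window after clipping; skipped")
      next
    }
    sq <- Biostrings::subseq(genome[[g$contig]], start, end)
    if (g$strand == "-") sq <- Biostrings::reverseComplement(sq)
    regions[[length(regions) + 1L]] <- data.frame(
      gene_id = g$gene_id, contig = g$contig, start = start, end = end,
      strand = g$strand, length = end - start + 1L, stringsAsFactors = FALSE)
    seqs[[g$gene_id]] <- sq
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(gene_id = character(0), contig = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               length = integer(0))
  sequences <- Biostrings::DNAStringSet(vapply(seqs, as.character, character(1)))
  list(regions = regions, sequences = sequences)
}
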