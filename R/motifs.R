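#' IUPAC nucleotide classes
#'
#' Named list mapping each IUPAC letter to the set of unambiguous bases it
#' matches.
#' @export
IUPAC_CLASSES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                      R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                      B = "V", D = "H", H = "D", V = "B", N = "N")

#' Consensus motif definition
#'
#' @param name motif label (e.g. `"SIE"`).
#' @param pattern IUPAC consensus string.
#' @param max_mismatch mismatch budget for scanning (default 0).
#' @return a `motif_consensus` list.
#' @examples
#' sie_motif()  # the Stat3-inducible element, TTCCNGGAA, 2 mismatches
#' @export
motif_consensus <- function(name, pattern, max_mismatch = 0L) {
  pattern <- toupper(pattern)
  letters <- strsplit(pattern, "")[[1]]
  if (length(letters) == 0) stop("motif pattern must be non-empty")
  bad <- setdiff(letters, names(IUPAC_CLASSES))
  if (length(bad))
    stop("invalid IUPAC letter(s) in pattern: ", paste(unique(bad), collapse = ", "))
  stopifnot(max_mismatch >= 0)
  structure(list(name = name, pattern = pattern,
                 max_mismatch = as.integer(max_mismatch)),
            class = "motif_consensus")
}

#' Reverse complement of an IUPAC pattern
#' @param pattern IUPAC string.
#' @return the reverse-complemented IUPAC string.
#' @export
revcomp_iupac <- function(pattern) {
  letters <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(letters, names(IUPAC_COMPLEMENT))
  if (length(bad)) stop("invalid IUPAC letter(s): ", paste(bad, collapse = ", "))
  paste(rev(unname(IUPAC_COMPLEMENT[letters])), collapse = "")
}

#' Built-in consensus motifs
#'
#' `sie_motif()`: the Stat3-inducible element TTCCNGGAA, scanned with up to 2
#' mismatches. `are_motif()`: Nrf2 antioxidant response element TGACNNNGC, up
#' to 2 mismatches. `hre_motif()`: Hif-1 hypoxia response element core RCGTG,
#' exact. `tre_motif()`: AP-1 (cJun) TPA response element TGACTCA, exact.
#' HRE/TRE/ARE consensus strings and budgets are package defaults and fully
#' configurable through [motif_consensus()].
#'
#' @return a [motif_consensus()] object.
#' @export
sie_motif <- function() motif_consensus("SIE", "TTCCNGGAA", 2L)

#' @rdname sie_motif
#' @export
are_motif <- function() motif_consensus("ARE", "TGACNNNGC", 2L)

#' @rdname sie_motif
#' @export
hre_motif <- function() motif_consensus("HRE", "RCGTG", 0L)

#' @rdname sie_motif
#' @export
tre_motif <- function() motif_consensus("TRE", "TGACTCA", 0L)

# logical match table: rows A/C/G/T, one column per pattern position
pattern_match_table <- function(pattern) {
  letters <- strsplit(pattern, "")[[1]]
  vapply(letters, function(l) c("A", "C", "G", "T") %in% IUPAC_CLASSES[[l]],
         logical(4))
}

# mismatch counts of `pattern` at every window start of an integer-coded
# sequence (codes 1:4 = ACGT, NA = ambiguous base, always a mismatch)
mismatch_profile <- function(seqcode, pattern) {
  L <- nchar(pattern)
  W <- length(seqcode) - L + 1L
  if (W < 1) return(integer(0))
  tab <- pattern_match_table(pattern)
  mism <- integer(W)
  for (j in seq_len(L)) {
    ok <- tab[seqcode[j:(j + W - 1L)], j]
    ok[is.na(ok)] <- FALSE
    mism <- mism + !ok
  }
  mism
}

#' Scan a sequence for a consensus motif
#'
#' Reports every offset where the IUPAC-class-aware mismatch count is within
#' the motif's budget. With `strands = "both"` the reverse complement of the
#' pattern is also scanned (hits reported on strand `"-"` at their forward
#' offsets); for reverse-complement-palindromic patterns such as the SIE the
#' two strands coincide and hits are reported once, on `"+"`. Any base
#' outside A/C/G/T in the sequence (e.g. N) counts as a mismatch at that
#' position.
#'
#' @param sequence a character string, [Biostrings::DNAString] or length-1
#'   [Biostrings::DNAStringSet].
#' @param motif a [motif_consensus()].
#' @param strands `"both"` (default), `"plus"` or `"minus"`.
#' @return data.frame with columns `motif`, `offset` (0-based from the
#'   sequence 5' end), `strand`, `mismatches`, `site` (the matched
#'   sequence, forward orientation).
#' @export
scan_sequence <- function(sequence, motif, strands = c("both", "plus", "minus")) {
  strands <- match.arg(strands)
  stopifnot(inherits(motif, "motif_consensus"))
  if (inherits(sequence, "DNAStringSet")) sequence <- sequence[[1]]
  s <- toupper(as.character(sequence))
  chars <- strsplit(s, "")[[1]]
  seqcode <- match(chars, c("A", "C", "G", "T"))

  rc <- revcomp_iupac(motif$pattern)
  palindromic <- identical(rc, motif$pattern)
  hits <- list()
  if (strands %in% c("both", "plus")) {
    mm <- mismatch_profile(seqcode, motif$pattern)
    off <- which(mm <= motif$max_mismatch)
    if (length(off)) hits$plus <- data.frame(
      offset = off - 1L, strand = "+", mismatches = mm[off])
  }
  if ((strands == "minus") || (strands == "both" && !palindromic)) {
    mm <- mismatch_profile(seqcode, rc)
    off <- which(mm <= motif$max_mismatch)
    if (length(off)) hits$minus <- data.frame(
      offset = off - 1L, strand = "-", mismatches = mm[off])
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(offset = integer(0), strand = character(0),
               mismatches = integer(0))
  rownames(out) <- NULL
  L <- nchar(motif$pattern)
  out <- cbind(motif = rep(motif$name, nrow(out)), out)
  out$site <- if (nrow(out)) substring(s, out$offset + 1L, out$offset + L)
  else character(0)
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Scan a promoter collection for a consensus motif
#'
#' @param sequences named character vector or [Biostrings::DNAStringSet] of
#'   promoter sequences (names are gene identifiers).
#' @param motif a [motif_consensus()].
#' @param strands passed to [scan_sequence()].
#' @return data.frame of hits with a leading `gene_id` column.
#' @export
scan_promoters <- function(sequences, motif, strands = "both") {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  if (is.null(names(sequences))) stop("promoter sequences must be named by gene")
  res <- lapply(seq_along(sequences), function(i) {
    h <- scan_sequence(sequences[[i]], motif, strands)
    if (nrow(h)) cbind(gene_id = names(sequences)[i], h) else NULL
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(data.frame(gene_id = character(0), motif = character(0),
                      offset = integer(0), strand = character(0),
                      mismatches = integer(0), site = character(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Count genes carrying at least one motif hit
#'
#' @param hits output of [scan_promoters()].
#' @param gene_set character vector: the genes whose promoters were scanned.
#' @return list with `n_with`, `n_total`, `summary` (the `"k/n"` string) and
#'   `per_gene` (data.frame gene_id, n_hits, has_motif).
#' @export
genes_with_motif <- function(hits, gene_set) {
  gene_set <- unique(gene_set)
  counts <- table(factor(hits$gene_id[hits$gene_id %in% gene_set],
                         levels = gene_set))
  per_gene <- data.frame(gene_id = gene_set, n_hits = as.integer(counts),
                         has_motif = as.integer(counts) > 0,
                         row.names = NULL, stringsAsFactors = FALSE)
  n_with <- sum(per_gene$has_motif)
  list(n_with = n_with, n_total = length(gene_set),
       summary = sprintf("%d/%d", n_with, length(gene_set)),
       per_gene = per_gene)
}
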