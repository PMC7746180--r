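# small in-code fixtures shared across test files

# an ox_counts object with explicit per-condition values:
# `cell_means` is a gene x 4 matrix (WT.basal, WT.oxidation, C3S.basal,
# C3S.oxidation); each condition gets `reps` identical columns equal to the
# cell value (deterministic counts, no noise)
fixture_counts <- function(cell_means, reps = 2) {
  conds <- data.frame(genotype = rep(c("WT", "C3S"), each = 2),
                      treatment = rep(c("basal", "oxidation"), 2))
  m <- cell_means[, rep(seq_len(4), each = reps), drop = FALSE]
  samples <- data.frame(
    sample = paste0("s", seq_len(4 * reps)),
    genotype = rep(conds$genotype, each = reps),
    treatment = rep(conds$treatment, each = reps),
    replicate = rep(seq_len(reps), 4))
  colnames(m) <- samples$sample
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  ox_counts(m, samples)
}

# a called DE table with given flags, suitable for assign_patterns()
fixture_de_table <- function(gene_id, logfc, significant, position) {
  res <- data.frame(gene_id = gene_id, mean_a = 1, mean_b = 1,
                    logfc = logfc, p = ifelse(significant, 0.001, 0.5),
                    q = ifelse(significant, 0.01, 0.5),
                    significant = significant, stringsAsFactors = FALSE)
  attr(res, "position") <- position
  res
}

# three-gene annotation: two plus-strand and one minus-strand gene
fixture_models <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    contig = c("chr1", "chr1", "chr2"),
    start = c(100000, 300000, 50000),
    end = c(110000, 310000, 60000),
    strand = c("+", "+", "-"))
  exons <- data.frame(
    gene_id = c("gA", "gA", "gB", "gC"),
    contig = c("chr1", "chr1", "chr1", "chr2"),
    start = c(100000, 105000, 300000, 59000),
    end = c(100500, 105800, 300900, 60000))
  gene_models(genes, exons)
}

# character-level IUPAC mismatch count, independent of the scanner's
# integer-code path (used as brute-force oracle)
oracle_mismatches <- function(window_chars, pattern) {
  classes <- list(A = "A", C = "C", G = "G", T = "T",
                  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"))
  pat <- strsplit(pattern, "")[[1]]
  sum(vapply(seq_along(pat), function(j)
    !(window_chars[j] %in% classes[[pat[j]]]), logical(1)))
}

# brute-force both-strand scan of one sequence, collapsing palindromes
oracle_scan <- function(seq_string, pattern, budget) {
  chars <- strsplit(seq_string, "")[[1]]
  L <- nchar(pattern)
  rc <- redoxDE::revcomp_iupac(pattern)
  pats <- if (identical(rc, pattern)) c(`+` = pattern) else c(`+` = pattern, `-` = rc)
  out <- list()
  for (st in names(pats)) {
    for (off in 0:(length(chars) - L)) {
      mm <- oracle_mismatches(chars[(off + 1):(off + L)], pats[[st]])
      if (mm <= budget)
        out[[length(out) + 1]] <- data.frame(offset = off, strand = st,
                                             mismatches = mm)
    }
  }
  if (!length(out)) return(data.frame(offset = integer(0),
                                      strand = character(0),
                                      mismatches = integer(0)))
  do.call(rbind, out)
}

# random DNA string
random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# conditional-distribution oracle for the NB exact test: probabilities via
# dnbinom at an arbitrary common mean (which cancels), normalised directly
oracle_cond_nb_p <- function(sum_a, total, n_a, n_b, alpha, mu = 3.7) {
  pr <- dnbinom(0:total, size = n_a / alpha, mu = n_a * mu) *
    dnbinom(total:0, size = n_b / alpha, mu = n_b * mu)
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[sum_a + 1] * (1 + 1e-7)])
}
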