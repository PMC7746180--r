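#' Simulation design for synthetic count data
#'
#' Describes a 2 genotype x 2 treatment x k replicate negative-binomial count
#' simulation with pattern codes planted at a configurable log2 effect size.
#' The NB parameterisation is variance = mu + alpha * mu^2 (alpha =
#' `dispersion`); `dispersion = 0` gives Poisson counts.
#'
#' @param n_genes number of genes to simulate.
#' @param replicates_per_condition replicates per (genotype, treatment) cell
#'   (default 2, matching a two-replicate RNA-seq design).
#' @param baseline_mean NB mean of unaffected genes in the WT-basal anchor
#'   condition.
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2).
#' @param effect_logfc magnitude (>= 0) of the planted log2 fold change at
#'   every nonzero pattern position.
#' @param pattern_spec named numeric vector: names are pattern codes such as
#'   `"1,0,0,-1"`, values are fractions of genes planted with that code.
#'   Fractions must sum to <= 1; remaining genes are planted as `"0,0,0,0"`.
#' @param libsize_range length-2 numeric range from which per-sample library
#'   size factors are drawn uniformly (set to `c(1, 1)` for equal libraries).
#' @param seed integer seed controlling all randomness of the simulation.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n_genes, replicates_per_condition = 2,
                              baseline_mean = 100, dispersion = 0.05,
                              effect_logfc = 3, pattern_spec = NULL,
                              libsize_range = c(0.7, 1.3), seed = 1) {
  stopifnot(n_genes >= 1, replicates_per_condition >= 1, baseline_mean > 0,
            dispersion >= 0, effect_logfc >= 0, length(libsize_range) == 2,
            all(libsize_range > 0))
  pattern_spec <- pattern_spec %||% numeric(0)
  if (length(pattern_spec)) {
    if (is.null(names(pattern_spec))) stop("pattern_spec must be named by pattern code")
    lapply(names(pattern_spec), parse_pattern_code)
    if (sum(pattern_spec) > 1 + 1e-12) stop("pattern_spec fractions must sum to <= 1")
    if (any(pattern_spec < 0)) stop("pattern_spec fractions must be >= 0")
  }
  structure(list(n_genes = as.integer(n_genes),
                 replicates_per_condition = as.integer(replicates_per_condition),
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 effect_logfc = effect_logfc, pattern_spec = pattern_spec,
                 libsize_range = libsize_range, seed = as.integer(seed)),
            class = "simulation_design")
}

# Condition means implied by a pattern code, anchored at the WT-basal mean.
# Positions: 1 = WT ox vs WT basal, 2 = C3S basal vs WT basal,
#            3 = C3S ox vs C3S basal, 4 = C3S ox vs WT ox.
# The C3S-oxidation mean is derived from positions 1 and 4; position 3 must be
# consistent (checked in log space, tolerance 1e-9), otherwise the code is
# unrealisable and rejected.
condition_means_for_code <- function(code, baseline_mean, effect_logfc) {
  s <- parse_pattern_code(code)
  lfc <- s * effect_logfc
  mu <- c(WT.basal = 0, WT.oxidation = lfc[1], C3S.basal = lfc[2],
          C3S.oxidation = lfc[1] + lfc[4])
  implied_pos3 <- mu[["C3S.oxidation"]] - mu[["C3S.basal"]]
  if (abs(implied_pos3 - lfc[3]) * log(2) > 1e-9)
    stop("unrealisable pattern code \"", code,
         "\": positions 1,2,4 imply a position-3 log2 ratio of ",
         signif(implied_pos3, 4), " but the code asks for ", lfc[3])
  baseline_mean * 2^mu
}

#' Simulate a count matrix with planted expression patterns
#'
#' Draws NB counts for the 2 x 2 x k design of `design`, planting the pattern
#' codes of `design$pattern_spec` with |log2 fold change| = `effect_logfc` at
#' every nonzero position. Per-sample library size factors are drawn from
#' `libsize_range` and multiply the condition means, so size-factor
#' normalisation is exercised downstream.
#'
#' @param design a [simulation_design()].
#' @return list with elements `counts` (an [ox_counts()] object) and `truth`
#'   (list: `pattern` — named character vector gene -> planted code;
#'   `condition_means` — gene x condition matrix of NB means;
#'   `size_factors` — the sampled per-sample library factors).
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  n <- design$n_genes
  reps <- design$replicates_per_condition
  conds <- data.frame(genotype = rep(c("WT", "C3S"), each = 2),
                      treatment = rep(c("basal", "oxidation"), 2),
                      stringsAsFactors = FALSE)
  cond_keys <- condition_key(conds$genotype, conds$treatment)

  # realisability of every planted code is checked before any sampling
  spec <- design$pattern_spec
  mean_by_code <- lapply(names(spec), condition_means_for_code,
                         baseline_mean = design$baseline_mean,
                         effect_logfc = design$effect_logfc)
  names(mean_by_code) <- names(spec)
  null_means <- rep(design$baseline_mean, 4)
  names(null_means) <- c("WT.basal", "WT.oxidation", "C3S.basal", "C3S.oxidation")

  n_planted <- if (length(spec)) round(spec * n) else integer(0)
  if (sum(n_planted) > n) stop("pattern_spec fractions allocate more genes than n_genes")
  codes <- rep("0,0,0,0", n)
  at <- 1L
  for (i in seq_along(n_planted)) {
    k <- n_planted[i]
    if (k > 0) codes[at:(at + k - 1L)] <- names(spec)[i]
    at <- at + k
  }
  gids <- sprintf("gene%05d", seq_len(n))

  mu <- matrix(null_means[cond_keys], nrow = n, ncol = 4, byrow = TRUE,
               dimnames = list(gids, cond_keys))
  for (code in names(spec)) {
    sel <- codes == code
    if (any(sel)) mu[sel, ] <- matrix(mean_by_code[[code]][cond_keys],
                                      nrow = sum(sel), ncol = 4, byrow = TRUE)
  }

  samples <- data.frame(
    sample = paste(rep(cond_keys, each = reps), rep(seq_len(reps), 4), sep = "_"),
    genotype = rep(conds$genotype, each = reps),
    treatment = rep(conds$treatment, each = reps),
    replicate = rep(seq_len(reps), 4), stringsAsFactors = FALSE)
  samples$sample <- gsub(".", "_", samples$sample, fixed = TRUE)

  counts <- with_seed(design$seed, {
    sf <- stats::runif(nrow(samples), design$libsize_range[1], design$libsize_range[2])
    m <- matrix(0L, n, nrow(samples), dimnames = list(gids, samples$sample))
    for (j in seq_len(nrow(samples))) {
      mu_j <- mu[, condition_key(samples$genotype[j], samples$treatment[j])] * sf[j]
      m[, j] <- if (design$dispersion > 0)
        stats::rnbinom(n, size = 1 / design$dispersion, mu = mu_j)
      else stats::rpois(n, mu_j)
    }
    attr(m, "size_factors") <- sf
    m
  })
  sf <- attr(counts, "size_factors")
  attr(counts, "size_factors") <- NULL
  names(sf) <- samples$sample
  names(codes) <- gids

  list(counts = ox_counts(counts, samples),
       truth = list(pattern = codes, condition_means = mu, size_factors = sf))
}

#' Simulate promoter sequences with planted motif instances
#'
#' Background bases are i.i.d. with the requested GC fraction; planted
#' consensus instances are written verbatim at their offsets (ambiguity
#' letters in the consensus are realised by a random base of their class;
#' minus-strand instances are written as the reverse complement of the
#' realised instance, so a both-strand scan recovers them).
#'
#' @param gene_ids character vector of promoter names.
#' @param window_length promoter window length in bases (default 3000, i.e. a
#'   3 kb upstream window).
#' @param gc_fraction background GC content in `[0, 1]`.
#' @param planted data.frame with columns `gene_id`, `motif_name`,
#'   `consensus`, `offset` (0-based from the window 5' end), `strand`
#'   (`"+"`/`"-"`); may be `NULL`.
#' @param seed integer seed.
#' @return list with `sequences` (named [Biostrings::DNAStringSet]) and
#'   `truth` (the planted table with the realised instance appended).
#' @export
simulate_promoters <- function(gene_ids, window_length = 3000, gc_fraction = 0.5,
                               planted = NULL, seed = 1) {
  stopifnot(window_length >= 1, gc_fraction >= 0, gc_fraction <= 1,
            !anyDuplicated(gene_ids))
  if (!is.null(planted)) {
    req <- c("gene_id", "motif_name", "consensus", "offset", "strand")
    if (!all(req %in% names(planted))) stop("planted needs columns: ", paste(req, collapse = ", "))
    if (!all(planted$gene_id %in% gene_ids)) stop("planted gene_id not among gene_ids")
    if (!all(planted$strand %in% c("+", "-"))) stop("planted strand must be '+' or '-'")
    if (any(planted$offset < 0 | planted$offset + nchar(planted$consensus) > window_length))
      stop("planted motif does not fit inside the promoter window")
    # reject overlapping plantings on the same (gene, strand)
    by_gs <- split(planted, paste(planted$gene_id, planted$strand))
    for (g in by_gs) {
      if (nrow(g) < 2) next
      o <- order(g$offset)
      s <- g$offset[o]; e <- g$offset[o] + nchar(g$consensus)[o]
      if (any(s[-1] < e[-length(e)]))
        stop("offset collision between planted motifs in ", g$gene_id[1],
             " on strand ", g$strand[1])
    }
  }
  probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
             G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  out <- with_seed(seed, {
    seqs <- vapply(gene_ids, function(g)
      paste(sample(names(probs), window_length, replace = TRUE, prob = probs),
            collapse = ""), character(1))
    realised <- character(0)
    if (!is.null(planted) && nrow(planted)) {
      realised <- vapply(planted$consensus, realise_consensus, character(1))
      for (i in seq_len(nrow(planted))) {
        inst <- realised[i]
        if (planted$strand[i] == "-") inst <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(inst)))
        g <- planted$gene_id[i]
        substr(seqs[g], planted$offset[i] + 1L,
               planted$offset[i] + nchar(inst)) <- inst
      }
    }
    list(seqs = seqs, realised = realised)
  })
  truth <- if (is.null(planted)) NULL else cbind(planted, instance = out$realised)
  list(sequences = Biostrings::DNAStringSet(out$seqs), truth = truth)
}

# draw one concrete realisation of an IUPAC consensus
realise_consensus <- function(consensus) {
  letters <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(letters, names(IUPAC_CLASSES))
  if (length(bad)) stop("invalid IUPAC letter(s): ", paste(bad, collapse = ", "))
  paste(vapply(letters, function(l) {
    cls <- IUPAC_CLASSES[[l]]
    if (length(cls) == 1) cls else sample(cls, 1)
  }, character(1)), collapse = "")
}

#' Simulate a ChIP peak table with planted enrichment
#'
#' Peaks are placed uniformly on the given contigs. A planted-enriched peak
#' has expected sample/control read-depth ratio `enriched_fold`; others have
#' expected ratio 1. `depth_noise` is the standard deviation of log-normal
#' multiplicative noise applied independently to both depths (0 = exact).
#'
#' @param n_peaks number of peaks.
#' @param contig_lengths named integer vector of contig lengths.
#' @param enriched_fraction fraction of peaks planted as enriched.
#' @param enriched_fold expected sample/control depth ratio of enriched peaks
#'   (> 1; the downstream filter keeps peaks more than 2-fold above control).
#' @param depth_noise sd of log-normal depth noise.
#' @param base_depth expected control read depth.
#' @param peak_width width of each peak interval in bases.
#' @param seed integer seed.
#' @return list with `peaks` (data.frame: `contig`, `start`, `end` (0-based
#'   half-open), `peak_id`, `sample_depth`, `control_depth`) and `truth`
#'   (named logical vector peak_id -> planted enriched flag).
#' @export
simulate_peaks <- function(n_peaks, contig_lengths, enriched_fraction = 0.2,
                           enriched_fold = 4, depth_noise = 0, base_depth = 20,
                           peak_width = 200, seed = 1) {
  stopifnot(n_peaks >= 1, enriched_fold > 1, enriched_fraction >= 0,
            enriched_fraction <= 1, depth_noise >= 0, base_depth > 0,
            !is.null(names(contig_lengths)), all(contig_lengths >= peak_width))
  n_enr <- round(enriched_fraction * n_peaks)
  enriched <- c(rep(TRUE, n_enr), rep(FALSE, n_peaks - n_enr))
  ids <- sprintf("peak%05d", seq_len(n_peaks))
  names(enriched) <- ids
  peaks <- with_seed(seed, {
    contig <- sample(names(contig_lengths), n_peaks, replace = TRUE)
    start <- vapply(contig, function(cg)
      sample.int(contig_lengths[[cg]] - peak_width + 1L, 1L) - 1L, integer(1))
    noise <- function() if (depth_noise > 0)
      exp(stats::rnorm(n_peaks, 0, depth_noise)) else rep(1, n_peaks)
    control <- base_depth * noise()
    samp <- base_depth * ifelse(enriched, enriched_fold, 1) * noise()
    data.frame(contig = contig, start = start, end = start + peak_width,
               peak_id = ids, sample_depth = samp, control_depth = control,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  list(peaks = peaks, truth = enriched)
}
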