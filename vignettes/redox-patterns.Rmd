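---
title: "Methods: pattern analysis of redox-responsive differential expression"
author: "redoxDE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pattern analysis of redox-responsive differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxDE)
```

## The analysis

redoxDE implements the downstream computational analysis of a
two-genotype by two-treatment RNA-seq experiment: wild-type cells versus
cells carrying a redox-insensitive (cysteine-to-serine, "C3S") variant of a
transcription factor, each profiled under basal conditions and under acute
oxidative stress, with replicate libraries per cell. The question the
pipeline answers is which genes respond to oxidation *through* the
oxidisable factor: genes that move under oxidation in wild-type cells but
whose response is absent or distorted in the redox-insensitive mutant.

The pipeline has seven stages: expression filtering, library-size
normalisation, per-comparison negative-binomial testing, multiple-testing
correction and DE calling, discretisation of four comparisons into pattern
codes with cluster selection, promoter motif scanning, and gene-set /
ChIP-peak statistics. A synthetic-data generator with recorded planted truth
backs every stage with an oracle.

## Differential expression model

### Filtering and normalisation

A gene is *expressed* when the maximum over the four (genotype, treatment)
conditions of its replicate-mean raw count is at least 10 (configurable).
Library sizes are normalised by median-of-ratios factors: each sample's
factor is the median over reference genes of the ratio of its count to the
gene's geometric mean across samples, where reference genes are those with a
nonzero count in every sample. We take the median of linear-space ratios;
tools that median the log-ratios differ only in the even-count median
interpolation (relative differences around 1e-4 on typical matrices). Note
these factors are invariant to a global rescaling of the count matrix —
ratios to the per-gene geometric mean are scale-free.

### The conditional exact test

For one pairwise comparison with groups of $n_A$ and $n_B$ replicates,
normalised counts are rounded to the nearest integer (ties to even) and
summed within groups, $S_A$ and $S_B$. Modelling each replicate as
NB$(\mu, \alpha)$ with variance $\mu + \alpha\mu^2$, the group sums are
NB with sizes $r_A = n_A/\alpha$ and $r_B = n_B/\alpha$. Conditional on the
total $T = S_A + S_B$ and under the null of a common mean, the probability
of a split $x$ is

$$P(S_A = x \mid T) \;\propto\; \binom{x + r_A - 1}{x}\binom{T - x + r_B - 1}{T - x},$$

which does not depend on $\mu$. The two-sided p-value is the total
conditional probability of splits no more probable than the observed one
(ties counted with a relative tolerance of 1e-7). Weights are computed by a
log-ratio recursion, which stays accurate for any $r$ — including the
dispersion floor of 1e-8, where the test coincides with a conditional
binomial (Poisson-limit) test.

The observed fold change is reported as
$\log_2((\bar{x}_B + c)/(\bar{x}_A + c))$ with pseudocount $c = 0.5$ so that
zero-count genes stay finite; the orientation is always second-named group
over first-named group.

### Dispersion estimation

Per gene, the dispersion is estimated by method of moments pooled across the
two groups of the comparison: with within-group residual sum of squares $SS$
and $d = (n_A - 1) + (n_B - 1)$ degrees of freedom,
$\hat\alpha_g = (SS/d - \bar\mu)/\overline{\mu^2}$ (weighted by group
degrees of freedom). At two replicates per group this raw estimator has two
degrees of freedom and is far too noisy to calibrate an exact test: its
typical value falls well below the truth, many genes are effectively tested
as Poisson, and the null rejection rate at $p < 0.05$ runs near 0.16. We
therefore moderate each gene's estimate toward the across-gene mean
$\bar\alpha$ (which is unbiased) with a prior weight of 10 pseudo-degrees of
freedom:

$$\tilde\alpha_g = \frac{d\,\hat\alpha_g + 10\,\bar\alpha}{d + 10}.$$

The test suite verifies the resulting calibration on simulated null data
(rejection fraction at $p<0.05$ required to lie in $[0.03, 0.07]$ at 2000
genes, both for overdispersed and Poisson counts). `prior_weight = 0`
recovers the unshrunk per-gene estimator, and a known dispersion can be
passed directly. We deliberately stop short of full empirical-Bayes
machinery (trended priors, tagwise shrinkage à la edgeR/DESeq2): the
moderated moment estimator is transparent, has no fitted hyperparameters,
and suffices for calibration at this design size.

### DE calling

A gene is differentially expressed in a comparison when its BH-adjusted
p-value is below 0.05 **and** its |log2 fold change| exceeds 1, both strict
inequalities. The threshold on the adjusted (not raw) p-value is the
package's reading of "P < 0.05 with FDR correction"; both thresholds are
configurable.

## Pattern codes and cluster selection

The four canonical comparisons are ordered and signed once, and everything
downstream keys on that order:

| position | comparison | log2FC orientation |
|---|---|---|
| 1 | oxidation vs basal in WT | oxidation over basal |
| 2 | C3S vs WT at basal | C3S over WT |
| 3 | oxidation vs basal in C3S | oxidation over basal |
| 4 | C3S vs WT after oxidation | C3S over WT |

Each comparison contributes $-1$, $0$ or $+1$ (down, unchanged, up), giving
a four-position code such as `"1,0,0,-1"`; codes are serialised as
comma-joined signed integers. Genes with at least one nonzero position form
the DE set, which the distinct codes partition into clusters — the all-zero
code is never a cluster.

*Oxidation-responsive* clusters are selected by a predicate over codes. The
default keeps a code iff position 1 is nonzero (the gene responds to
oxidation in WT), position 3 is zero (the response is lost in the
redox-insensitive cells) and position 2 or 4 is nonzero (the mutant is
dis-regulated relative to WT somewhere). This admits 16 of the 80 possible
nonzero codes and reproduces the selected-cluster examples the analysis is
built around; because published cluster lists may be hand-curated, the rule
is an ordinary function argument and any explicit code list can be supplied
instead.

## The synthetic-data generator

`simulate_counts()` draws NB counts for the 2×2×k design with pattern codes
planted at a fixed |log2 FC| at every nonzero position. Condition means are
anchored at the WT-basal mean and derived through positions 1, 2 and 4;
position 3 is then implied, and a code whose position 3 contradicts the
implied value (in log space, tolerance 1e-9) is *unrealisable* and rejected
by name — e.g. `"1,0,0,0"` demands a C3S-oxidation mean that is
simultaneously changed and unchanged. (Real data can still exhibit such
codes through near-threshold effects; the generator, which plants exact
means, cannot.) Per-sample library factors are drawn uniformly from
[0.7, 1.3] so that normalisation is genuinely exercised.

Defaults mirror the study conditions the pipeline targets: 2 replicates per
condition, baseline NB mean 100, dispersion 0.05, planted |log2 FC| = 3.
Test and acceptance runs use 1000–2000 genes — large enough for stable rate
estimates, small enough to keep a full run in seconds.

The generator emulates the *statistical* structure (NB noise, planted
effects, library-size variation) but not gene-length effects, GC bias,
correlated genes, batch structure or outlier samples; passing tests
demonstrate correctness of the pipeline's logic under the stated model, not
robustness to every artefact of real libraries.

`simulate_promoters()` writes i.i.d. background bases at a chosen GC content
and plants consensus instances (IUPAC ambiguity letters realised randomly;
minus-strand instances reverse-complemented) at recorded offsets.
`simulate_peaks()` places fixed-width intervals uniformly on contigs with
expected sample/control depth ratio `enriched_fold` for planted peaks and 1
otherwise, under optional log-normal depth noise.

## Motif scanning

Consensus motifs are IUPAC strings scanned with a Hamming-style mismatch
budget; a window position matches when the sequence base belongs to the
IUPAC class of the consensus letter. Any base outside A/C/G/T in the
sequence (e.g. N) counts as a mismatch at that position. With both strands
requested, the reverse-complement pattern is scanned and reported at forward
offsets; for reverse-complement-palindromic patterns such as the SIE
(`TTCCNGGAA`) the two strands' hits coincide and are reported once. Built-in
motifs: SIE (`TTCCNGGAA`, budget 2), ARE (`TGACNNNGC`, budget 2), HRE
(`RCGTG`, exact), TRE (`TGACTCA`, exact); the HRE/TRE/ARE strings are
package defaults where the upstream literature is not explicit, and all are
configurable.

Promoter windows default to the 3 kb upstream of the translation start
(ATG), taken from the 5'-most CDS boundary of a GFF3 annotation; a TSS
anchor is available. Minus-strand windows are reverse-complemented so every
promoter reads 5'→3' toward its anchor. Internally coordinates are handled
1-based inclusive on the forward strand (GFF3 convention); peak tables use
BED-style 0-based half-open intervals, and table headers state the
convention. A mismatch budget of 2 on a 9-mer is permissive: on random 3 kb
sequence the expected number of ≤2-mismatch SIE windows is around a dozen,
so at that budget most promoters contain a site — exactly the behaviour the
published gene fractions show. Scans at budget 0 are the discriminating
variant and are what the planted-recovery checks use.

## Enrichment, overlap and peak statistics

Enrichment and overlap use the upper-tail hypergeometric probability
$P(X \ge k)$ for $X \sim \mathrm{Hypergeometric}(N, K, m)$, computed by the
numerically stable upper-tail routine and verified against exhaustive
summation for every configuration with $N \le 200$ (relative agreement
better than 1e-10 wherever the tail exceeds 1e-250, beneath which double
precision has no meaningful relative accuracy). BH correction across a
collection reuses the same step-up implementation as the DE stage. The
frequency-pruning step keeps terms annotating strictly between 0.1% and 1%
of the universe and then the top 5 by p-value; semantic-similarity
dispensability ranking would need an external ontology and is out of scope.
The enrichment universe defaults to the expressed-gene set and should be set
explicitly for real data.

ChIP peaks are kept when `(sample_depth + 1) / (control_depth + 1)` strictly
exceeds 2 (pseudocount and threshold configurable; the pseudocount guards
zero-control intervals). Kept peaks are assigned to every gene whose
promoter window — 5 kb upstream to 0.5 kb downstream of the TSS,
strand-aware — they overlap by at least one base, and classified with
precedence promoter > exon > intron > intergenic, where intron means inside
a gene span but outside exons. Merging of replicate depth tracks is upstream
of this module: inputs are interval-plus-depth tables.

## Numerical choices, degenerate inputs, limitations

- Exact-test weights: log-ratio recursion plus log-sum-exp normalisation;
  total $T = 0$ returns $p = 1$.
- Tie handling in two-sided exact p-values uses a relative tolerance of
  1e-7 so mirror-image splits of symmetric designs are always pooled.
- Rounding of normalised counts uses R's round-half-to-even.
- Empty results are legal everywhere: a filter that removes all genes warns;
  `q_threshold = 0` produces empty cluster tables and a clean run.
- The pipeline tests each comparison marginally; it does not fit a joint GLM
  with interaction terms, and a gene's four positions are therefore not
  statistically independent summaries.
- Cluster membership is hard (one code per gene); near-threshold genes can
  land in neighbouring codes, which is why planted-recovery guarantees are
  stated at a clear effect size (|log2 FC| = 3 at dispersion 0.05).

## A worked synthetic run

```{r example, eval = FALSE}
design <- simulation_design(
  n_genes = 1000, replicates_per_condition = 2, baseline_mean = 100,
  dispersion = 0.05, effect_logfc = 3,
  pattern_spec = c("1,0,0,-1" = 0.05, "-1,0,0,1" = 0.05), seed = 101)
sim <- simulate_counts(design)
res <- run_all(sim$counts)
res$selected[, c("code", "n_genes", "direction")]
```

The run log reports per-stage counts (genes filtered, significant genes per
comparison, clusters found and selected); `res$manifest` carries the same
numbers machine-readably together with an echo of every threshold used.
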