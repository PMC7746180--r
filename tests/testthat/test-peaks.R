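test_that("fold filter: pseudocount arithmetic and strict threshold", {
  peaks <- data.frame(contig = "chr1", start = c(0, 100, 200),
                      end = c(50, 150, 250),
                      sample_depth = c(10, 4, 100),
                      control_depth = c(2, 2, 10))
  # pseudocount 1: folds 11/3, 5/3, 101/11
  kept <- filter_peaks_fold(peaks, 2, 1)
  expect_equal(kept$start, c(0, 200))
  expect_equal(kept$fold[1], 11 / 3, tolerance = 1e-12)
  # pseudocount 0: sample 4 / control 2 = exactly 2 -> dropped (strict >)
  kept0 <- filter_peaks_fold(peaks, 2, 0)
  expect_false(100 %in% kept0$start)
  # zero-control peak with pseudocount 0 is +Inf fold and kept
  pz <- data.frame(contig = "c", start = 0, end = 10,
                   sample_depth = 5, control_depth = 0)
  expect_equal(nrow(filter_peaks_fold(pz, 2, 0)), 1)
  expect_error(filter_peaks_fold(transform(pz, control_depth = -1)),
               "non-negative")
  expect_error(filter_peaks_fold(transform(pz, end = 0)), "end > start")
})

test_that("raising the fold threshold never enlarges the kept set", {
  sim <- simulate_peaks(500, c(chr1 = 1e6), enriched_fraction = 0.4,
                        enriched_fold = 3, depth_noise = 0.5, seed = 23)
  prev <- sim$peaks$peak_id
  for (thr in c(1, 1.5, 2, 3, 5)) {
    kept <- filter_peaks_fold(sim$peaks, thr)$peak_id
    expect_true(all(kept %in% prev))
    prev <- kept
  }
})

test_that("planted enriched peaks are exactly the kept set at fold 4, no noise", {
  sim <- simulate_peaks(300, c(chr1 = 1e6, chr2 = 1e6),
                        enriched_fraction = 0.25, enriched_fold = 4,
                        depth_noise = 0, seed = 29)
  kept <- filter_peaks_fold(sim$peaks, 2, 1)
  expect_setequal(kept$peak_id, names(sim$truth)[sim$truth])
})

test_that("promoter assignment: window boundaries and multi-gene peaks", {
  models <- fixture_models()   # gA + at 100000, gB + at 300000, gC - at 60000
  peaks <- data.frame(
    contig = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    start = c(95500, 93999, 100400, 60100, 66000),
    end = c(95600, 94900, 100499, 60200, 66100),
    peak_id = paste0("p", 1:5),
    sample_depth = 10, control_depth = 1)
  res <- assign_to_promoters(peaks, models)
  # p1 inside [95000, 100499]; p2 ends at 94900 < 95000 -> not assigned
  expect_true("p1" %in% res$assignments$peak_id)
  expect_false("p2" %in% res$assignments$peak_id)
  # p3 overlaps the downstream end of gA's window (<= 100499)
  expect_true("p3" %in% res$assignments$peak_id)
  # minus-strand gC: TSS at 60000, window [59501, 65000]
  expect_true("p4" %in% res$assignments$peak_id)
  expect_false("p5" %in% res$assignments$peak_id)
  expect_setequal(res$genes, c("gA", "gC"))

  # quadratic all-pairs oracle on random peaks and models
  set.seed(31)
  rpeaks <- data.frame(contig = sample(c("chr1", "chr2"), 300, TRUE),
                       start = sample.int(4e5, 300), sample_depth = 1,
                       control_depth = 1)
  rpeaks$end <- rpeaks$start + 200
  rpeaks$peak_id <- paste0("r", seq_len(300))
  tss <- c(gA = 100000, gB = 300000, gC = 60000)
  win <- list(gA = c(95000, 100499), gB = c(295000, 300499),
              gC = c(59501, 65000))
  ctg <- c(gA = "chr1", gB = "chr1", gC = "chr2")
  got <- assign_to_promoters(rpeaks, models)$assignments
  for (i in seq_len(nrow(rpeaks))) for (g in names(win)) {
    # 1-based peak interval [start+1, end]; overlap iff intervals intersect
    olap <- rpeaks$contig[i] == ctg[[g]] &&
      rpeaks$start[i] + 1 <= win[[g]][2] && rpeaks$end[i] >= win[[g]][1]
    expect_equal(any(got$peak == i & got$gene_id == g), olap)
  }
})

test_that("promoter assignment is symmetric under strand mirroring", {
  # mirror the whole annotation and peak set around a fixed coordinate;
  # assignments must be identical
  L <- 400000
  genes <- data.frame(gene_id = c("g1", "g2"), contig = "chr1",
                      start = c(100000, 250000), end = c(110000, 260000),
                      strand = c("+", "-"))
  mirror_genes <- data.frame(gene_id = genes$gene_id, contig = "chr1",
                             start = L - genes$end + 1,
                             end = L - genes$start + 1,
                             strand = c("-", "+"))
  set.seed(37)
  peaks <- data.frame(contig = "chr1", start = sample.int(L - 300, 400),
                      sample_depth = 1, control_depth = 1)
  peaks$end <- peaks$start + 250
  peaks$peak_id <- paste0("p", seq_len(400))
  mirror_peaks <- peaks
  # 0-based half-open [s, e) mirrors to [L - e, L - s)
  mirror_peaks$start <- L - peaks$end
  mirror_peaks$end <- L - peaks$start
  a <- assign_to_promoters(peaks, gene_models(genes))$assignments
  b <- assign_to_promoters(mirror_peaks, gene_models(mirror_genes))$assignments
  key <- function(d) sort(paste(d$peak_id, d$gene_id))
  expect_equal(key(a), key(b))
})

test_that("region classification follows promoter > exon > intron > intergenic", {
  models <- fixture_models()
  peaks <- data.frame(
    contig = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(99000, 105100, 107000, 150000, 59100),
    end = c(100100, 105300, 107100, 150100, 59200),
    sample_depth = 1, control_depth = 1)
  cls <- classify_region(peaks, models)
  # peak 1 spans gA promoter window and first exon -> promoter wins
  # peak 2 inside gA exon2 but also within gA promoter? window is
  # [95000, 100499]; 105100 is outside -> exon
  # peak 3 inside gA span, no exon -> intron
  # peak 4 nowhere -> intergenic
  # peak 5 inside gC exon [59000,60000] but also gC promoter window
  # [59501, 65000]? 59100-59200 < 59501 -> exon
  expect_equal(cls, c("promoter", "exon", "intron", "intergenic", "exon"))

  # synthetic fixture truth: classes match construction exactly
  frac <- table(cls) / length(cls)
  expect_equal(unname(frac[["intergenic"]]), 0.2)
})
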