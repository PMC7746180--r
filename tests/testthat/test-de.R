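test_that("expression filter keeps genes by max per-condition replicate mean", {
  # replicate means (9, 9, 9, 10) across the four conditions -> kept at >= 10
  cm <- rbind(boundary = c(9, 9, 9, 10),
              allzero = c(0, 0, 0, 0),
              low = c(9.5, 9.5, 9.5, 9.5),
              high = c(200, 0, 0, 0))
  x <- fixture_counts(cm)
  kept <- filter_expressed(x, 10)
  expect_identical(gene_ids(kept), c("boundary", "high"))

  # idempotent
  expect_identical(filter_expressed(kept, 10)$counts, kept$counts)

  # brute-force per-gene recomputation on a random matrix
  set.seed(1)
  m <- matrix(rpois(500 * 8, 12), nrow = 500,
              dimnames = list(sprintf("g%03d", 1:500), NULL))
  x <- fixture_counts(matrix(0, 500, 4, dimnames = list(rownames(m), NULL)))
  x$counts[] <- m
  key <- paste(x$samples$genotype, x$samples$treatment)
  oracle <- vapply(seq_len(nrow(m)), function(i)
    max(tapply(as.numeric(m[i, ]), key, mean)) >= 10, logical(1))
  expect_identical(gene_ids(filter_expressed(x, 10)),
                   rownames(m)[oracle])
})

test_that("median-of-ratios size factors behave and match independent routes", {
  set.seed(2)
  m <- matrix(rnbinom(300 * 6, mu = 50, size = 10), nrow = 300,
              dimnames = list(paste0("g", 1:300), paste0("s", 1:6)))
  # identical columns -> all factors 1
  eq <- m[, c(1, 1, 1, 1)]
  colnames(eq) <- paste0("s", 1:4)
  expect_equal(unname(estimate_size_factors(eq)), rep(1, 4))

  # doubling one column doubles its factor relative to the others
  dbl <- m
  dbl[, 3] <- 2 * dbl[, 3]
  sf <- estimate_size_factors(dbl)
  sf0 <- estimate_size_factors(m)
  expect_equal(sf[3] / sf[1], 2 * sf0[3] / sf0[1], tolerance = 1e-12)

  # direct median-of-ratios oracle
  geo <- exp(rowMeans(log(m)))
  ok <- is.finite(log(geo)) & geo > 0
  oracle <- apply(m, 2, function(col) median((col / geo)[ok]))
  expect_equal(estimate_size_factors(m), oracle, tolerance = 1e-12)

  # cross-check against DESeq2's implementation (which takes the median in
  # log space: identical up to the even-count median interpolation)
  expect_equal(unname(estimate_size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-3)

  # invariance to gene order; ratios are unchanged by a global rescaling of
  # the counts, so the factors are too
  expect_equal(estimate_size_factors(m[sample(nrow(m)), ]),
               estimate_size_factors(m))
  expect_equal(estimate_size_factors(3 * m), estimate_size_factors(m),
               tolerance = 1e-12)

  expect_error(estimate_size_factors(matrix(c(0, 1, 1, 0), 2,
                                            dimnames = list(c("a", "b"), NULL))),
               "nonzero")
})

test_that("NB exact test: symmetry, enumeration oracle, Poisson limit", {
  # identical counts in both groups -> p = 1
  cm <- rbind(g1 = c(20, 20, 20, 20))
  x <- fixture_counts(cm)
  r <- nb_exact_test(x, canonical_comparisons()[[1]],
                     size_factors = rep(1, 8), dispersion = 0.1)
  expect_equal(r$p, 1)
  expect_equal(r$logfc, 0)

  # all totals <= 30, several dispersions, 2 v 2: match the dnbinom oracle
  worst <- 0
  for (total in c(1, 5, 10, 30)) for (alpha in c(0.01, 0.1, 1)) {
    for (sa in 0:total) {
      p_impl <- redoxDE:::cond_nb_pvalue(sa, total, 2, 2, alpha)
      p_orac <- oracle_cond_nb_p(sa, total, 2, 2, alpha)
      worst <- max(worst, abs(p_impl - p_orac))
    }
  }
  expect_lt(worst, 1e-10)

  # unequal group sizes too (2 v 3)
  for (sa in 0:12) {
    expect_equal(redoxDE:::cond_nb_pvalue(sa, 12, 2, 3, 0.2),
                 oracle_cond_nb_p(sa, 12, 2, 3, 0.2), tolerance = 1e-10)
  }

  # dispersion -> 0 with equal group sizes: conditional binomial by
  # exhaustive enumeration of all splits of the total
  binom_oracle <- function(sa, total, n_a, n_b) {
    pr <- dbinom(0:total, total, n_a / (n_a + n_b))
    sum(pr[pr <= pr[sa + 1] * (1 + 1e-7)])
  }
  for (total in c(7, 10, 21)) for (sa in 0:total) {
    expect_equal(redoxDE:::cond_nb_pvalue(sa, total, 2, 2, 1e-8),
                 binom_oracle(sa, total, 2, 2), tolerance = 1e-6)
  }
})

test_that("NB exact test p-values are near-uniform on simulated null data", {
  d <- simulation_design(2000, effect_logfc = 0, dispersion = 0.05, seed = 3)
  sim <- simulate_counts(d)
  x <- filter_expressed(sim$counts)
  sf <- estimate_size_factors(x)
  r <- nb_exact_test(x, canonical_comparisons()[[1]], size_factors = sf)
  frac <- mean(r$p < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("BH adjustment: hand case, properties, validation", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(4)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  # non-decreasing when sorted by p
  expect_true(all(diff(q[order(p)]) >= 0))
  # adjusted value follows its input position under permutation
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), q[perm])
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("DE calling applies both thresholds strictly", {
  res <- data.frame(gene_id = paste0("g", 1:4),
                    logfc = c(1.5, 0.8, 2, -2),
                    p = c(0.04, 0.001, 0.05, 0.002))
  out <- call_de(res, q_threshold = 0.05, logfc_threshold = 1)
  # BH here: q(g2) = q(g4) = 0.004; q(g1) = q(g3) = 0.05 exactly
  expect_equal(out$q, c(0.05, 0.004, 0.05, 0.004))
  expect_false(out$significant[out$gene_id == "g1"])   # q = 0.05, strict <
  expect_false(out$significant[out$gene_id == "g2"])   # |logfc| = 0.8 <= 1
  expect_false(out$significant[out$gene_id == "g3"])
  expect_true(out$significant[out$gene_id == "g4"])
  expect_equal(out$direction[out$gene_id == "g4"], -1)
  # a clearly passing gene: q = 0.04 and logfc 1.5 -> significant, up
  up <- call_de(data.frame(gene_id = "g", logfc = 1.5, p = 0.04))
  expect_true(up$significant)
  expect_equal(up$direction, 1)
  # logfc exactly 1 is not significant (strict >)
  res2 <- data.frame(gene_id = "g", logfc = 1, p = 1e-6)
  expect_false(call_de(res2)$significant)
})
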