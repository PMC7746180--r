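#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, m): the probability of observing at
#' least `k` members of a size-`K` annotation set in a size-`m` query drawn
#' without replacement from a universe of `N` genes. Computed via the
#' log-space-stable upper tail of the hypergeometric distribution.
#'
#' @param k observed overlap count.
#' @param m query size.
#' @param K annotation-set size within the universe.
#' @param N universe size.
#' @return the upper-tail probability.
#' @export
hypergeom_upper_tail <- function(k, m, K, N) {
  if (any(c(k, m, K, N) < 0) || k > min(m, K) || m > N || K > N)
    stop("inconsistent counts: need 0 <= k <= min(m, K) <= N")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, m, lower.tail = FALSE)
}

#' Hypergeometric enrichment of a query set against a collection
#'
#' One upper-tail hypergeometric test per collection set, BH-corrected across
#' the collection. Query members outside the universe are dropped (their
#' count is attached as the `n_dropped` attribute); collection sets that do
#' not intersect the universe are skipped.
#'
#' @param query character vector of gene identifiers.
#' @param collection named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe character vector of gene identifiers defining the test
#'   universe (typically all expressed genes).
#' @return data.frame with columns `set`, `k`, `m`, `K`, `N`, `p`, `q`,
#'   sorted by increasing `p`.
#' @export
enrich <- function(query, collection, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  if (is.null(names(collection)) || !length(collection))
    stop("collection must be a non-empty named list")
  query <- unique(query)
  n_dropped <- sum(!query %in% universe)
  query <- intersect(query, universe)
  N <- length(universe); m <- length(query)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(unique(collection[[nm]]), universe)
    K <- length(set)
    if (K == 0) return(NULL)
    k <- length(intersect(query, set))
    data.frame(set = nm, k = k, m = m, K = K, N = N,
               p = hypergeom_upper_tail(k, m, K, N), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(set = character(0), k = integer(0), m = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0))
  } else {
    out <- do.call(rbind, rows)
    out$q <- bh_adjust(out$p)
    out <- out[order(out$p, out$set), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Frequency pruning of enrichment results
#'
#' Keeps results whose annotation frequency `K/N` lies strictly between
#' `min_freq` and `max_freq`, then returns the `top_n` with the smallest p.
#' (Semantic-similarity dispensability pruning is out of scope; the top-n
#' step uses the p-value instead.)
#'
#' @param results output of [enrich()].
#' @param min_freq,max_freq open frequency interval (defaults 0.001 and
#'   0.01, i.e. terms annotating between 0.1 and 1 percent of the universe).
#' @param top_n maximum number of results returned (default 5).
#' @return the pruned data.frame, sorted by `p`.
#' @export
frequency_prune <- function(results, min_freq = 0.001, max_freq = 0.01,
                            top_n = 5) {
  freq <- results$K / results$N
  keep <- results[freq > min_freq & freq < max_freq, , drop = FALSE]
  keep <- keep[order(keep$p), , drop = FALSE]
  utils::head(keep, top_n)
}

#' Hypergeometric overlap test between two gene sets
#'
#' Upper-tail (over-representation) test of the overlap between `set_a` and
#' `set_b` within `universe`: `k = |a n b n U|`, `m = |a n U|`,
#' `K = |b n U|`, `N = |U|`.
#'
#' @param set_a,set_b character vectors of gene identifiers.
#' @param universe character vector defining the universe.
#' @return one-row data.frame with columns `k`, `m`, `K`, `N`, `p`.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  a <- intersect(unique(set_a), universe)
  b <- intersect(unique(set_b), universe)
  if (!length(a) || !length(b)) stop("both sets must intersect the universe")
  k <- length(intersect(a, b))
  data.frame(k = k, m = length(a), K = length(b), N = length(universe),
             p = hypergeom_upper_tail(k, length(a), length(b), length(universe)))
}
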