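#' Upper-tail hypergeometric overlap test
#'
#' Probability of observing at least `k` shared genes between a list of
#' size `K` and a list of size `n` drawn from a universe of size `N`:
#' `p = P(X >= k)` for X hypergeometric. Used to assess nonrandomness of
#' gene-list overlap across cohorts.
#'
#' @param N Universe size.
#' @param K First list size.
#' @param n Second list size.
#' @param k Observed overlap.
#' @return List with the counts and the upper-tail `p`.
#' @export
hypergeometric_overlap <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent counts: need 0 <= k <= min(K, n) <= N")
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(N = N, K = K, n = n, k = k, p = p)
}

#' Hypergeometric overlap of two gene lists
#'
#' Accepts either plain gene vectors or differential-expression tables
#' (data.frames with `gene` and `log2FC`); tables are first filtered to
#' `|log2FC| > lfc_threshold`. The overlap is then tested with
#' [hypergeometric_overlap()] against the given universe.
#'
#' @param list_a,list_b Gene id vectors or DE tables.
#' @param universe Gene id vector defining the background.
#' @param lfc_threshold Absolute log2-fold-change filter applied to DE
#'   tables (default 0.15).
#' @return As [hypergeometric_overlap()], plus the filtered lists.
#' @export
deg_overlap <- function(list_a, list_b, universe, lfc_threshold = 0.15) {
  if (length(universe) == 0L) stop("empty universe")
  as_list <- function(l) {
    if (is.data.frame(l)) l$gene[abs(l$log2FC) > lfc_threshold] else l
  }
  a <- intersect(as_list(list_a), universe)
  b <- intersect(as_list(list_b), universe)
  res <- hypergeometric_overlap(length(universe), length(a), length(b),
                                length(intersect(a, b)))
  res$list_a <- a
  res$list_b <- b
  res
}

#' Single-sample gene-set enrichment
#'
#' Per sample, genes are ranked by expression (descending, ties by gene
#' id); the enrichment score of a set is the integrated running sum whose
#' in-set increments are proportional to `rank_value^alpha` (rank value N
#' for the most highly expressed gene) normalized by the set's total
#' weight, and whose out-of-set decrements are `1/(N - set size)`. A set
#' equal to the whole universe scores 0 by convention (there are no
#' out-of-set positions to integrate against). Being rank-based, the score
#' is invariant to monotone transforms of a sample's expression values.
#'
#' @param x Expression matrix, genes x samples.
#' @param sets Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param alpha Rank-weight exponent (default 0.25).
#' @param meta Optional sample metadata with `sample_id` and `group`
#'   columns; when given, per-group mean scores are attached.
#' @return List of class `ssgsea_result`: `scores` (sets x samples matrix)
#'   and optionally `group_means` (sets x groups).
#' @export
ssgsea <- function(x, sets, alpha = 0.25, meta = NULL) {
  validate_expression(x)
  if (length(sets) == 0L) stop("no gene sets supplied")
  genes <- rownames(x)
  n <- length(genes)
  for (nm in names(sets)) {
    if (length(intersect(sets[[nm]], genes)) == 0L)
      stop("gene set has no members in the universe: ", nm)
  }
  scores <- matrix(0, length(sets), ncol(x),
                   dimnames = list(names(sets), colnames(x)))
  for (s in seq_len(ncol(x))) {
    ord <- order(-x[, s], genes)
    ranked <- genes[ord]
    rank_value <- n:1  # largest expression gets the largest rank value
    for (g in seq_along(sets)) {
      members <- intersect(sets[[g]], genes)
      in_set <- ranked %in% members
      m <- sum(in_set)
      if (m == n) { scores[g, s] <- 0; next }
      w <- numeric(n)
      rw <- rank_value^alpha
      w[in_set] <- rw[in_set] / sum(rw[in_set])
      w[!in_set] <- -1 / (n - m)
      scores[g, s] <- sum(cumsum(w))
    }
  }
  res <- list(scores = scores, alpha = alpha)
  if (!is.null(meta)) {
    grp <- meta$group[match(colnames(x), meta$sample_id)]
    res$group_means <- vapply(unique(grp), function(g)
      rowMeans(scores[, grp == g, drop = FALSE]), numeric(nrow(scores)))
    if (is.null(dim(res$group_means)))
      res$group_means <- matrix(res$group_means, nrow = nrow(scores),
                                dimnames = list(rownames(scores),
                                                unique(grp)))
  }
  class(res) <- "ssgsea_result"
  res
}
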