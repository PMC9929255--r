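# Independent brute-force oracles used by unit and acceptance tests.
# These deliberately use the most literal possible formulations so they
# stay independent of the package's implementations.

# Step-up BH by its definition: sort, multiply by m/i, cumulative min.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# AUC as the all-pairs concordance count.
oracle_auc <- function(scores, labels) {
  y <- as.logical(labels)
  pos <- scores[y]; neg <- scores[!y]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# TOM by the triple loop.
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- colSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- sum(a[i, ] * a[, j]) + a[i, j]
    tom[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# Plug-in MI from an explicitly built contingency table.
oracle_mi_table <- function(bx, by) {
  tab <- table(factor(bx), factor(by))
  n <- sum(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    pij <- tab[i, j] / n
    if (pij > 0)
      mi <- mi + pij * log(pij / (sum(tab[i, ]) / n * sum(tab[, j]) / n))
  }
  mi
}

# DPI by exhaustive scan over all node triples.
oracle_dpi <- function(edges, eps) {
  nodes <- unique(c(edges$a, edges$b))
  if (length(nodes) < 3) return(edges)
  w <- function(i, j) {
    hit <- (edges$a == i & edges$b == j) | (edges$a == j & edges$b == i)
    if (any(hit)) edges$w[which(hit)[1]] else 0
  }
  drop <- logical(nrow(edges))
  for (t in utils::combn(nodes, 3, simplify = FALSE)) {
    ws <- c(w(t[1], t[2]), w(t[1], t[3]), c(w(t[2], t[3])))
    if (any(ws == 0)) next
    for (e in seq_len(nrow(edges))) {
      pair <- c(edges$a[e], edges$b[e])
      if (all(pair %in% t)) {
        other <- setdiff(t, pair)
        if (edges$w[e] < (1 - eps) * min(w(pair[1], other), w(pair[2], other)))
          drop[e] <- TRUE
      }
    }
  }
  edges[!drop, , drop = FALSE]
}

# KS enrichment via an explicit walk down the list: the positive deviation
# is measured just after each tag is passed, the negative one just before.
oracle_ks <- function(tags, ranked_list) {
  t <- length(tags); n <- length(ranked_list)
  in_set <- ranked_list %in% tags
  seen <- 0; a <- -Inf; b <- -Inf
  for (i in seq_len(n)) {
    if (in_set[i]) {
      b <- max(b, i / n - seen / t)
      seen <- seen + 1
      a <- max(a, seen / t - i / n)
    }
  }
  if (a > b) a else -b
}

# Upper-tail hypergeometric p by full enumeration over all draws.
oracle_hyper <- function(N, K, n, k) {
  universe <- seq_len(N)
  marked <- seq_len(K)
  draws <- utils::combn(N, n, simplify = FALSE)
  mean(vapply(draws, function(d) sum(d %in% marked) >= k, logical(1)))
}

# Regulatory score by the literal per-edge loop.
oracle_rs <- function(edges, lfc, assignment) {
  out <- list()
  for (e in seq_len(nrow(edges))) {
    m <- assignment[[edges$target[e]]]
    key <- paste(edges$regulator[e], m)
    out[[key]] <- (if (is.null(out[[key]])) 0 else out[[key]]) +
      edges$weight[e] * abs(lfc[[edges$target[e]]])
  }
  out
}

# Greedy mRMR by literal exhaustive evaluation of the MID criterion,
# using its own contingency-table MI.
oracle_mrmr <- function(disc, y, genes, k) {
  sel <- character(0)
  avail <- genes
  for (step in seq_len(k)) {
    best <- -Inf; pick <- NULL
    for (g in sort(avail)) {
      rel <- oracle_mi_table(disc[g, ], y)
      red <- if (length(sel) == 0) 0 else
        mean(vapply(sel, function(s) oracle_mi_table(disc[g, ], disc[s, ]),
                    numeric(1)))
      sc <- rel - red
      if (sc > best + 1e-12) { best <- sc; pick <- g }
    }
    sel <- c(sel, pick)
    avail <- setdiff(avail, pick)
  }
  sel
}

# Exhaustive MIC over all grids with q*r <= cap: every way of cutting the
# v-ordered points into r contiguous rows, u-axis equipartitioned.
oracle_mic <- function(x, y, cap) {
  n <- length(x)
  ef <- function(v, b) as.integer(cut(rank(v, ties.method = "first"),
                                      breaks = seq(0.5, n + 0.5,
                                                   length.out = b + 1),
                                      include.lowest = TRUE))
  best <- 0
  for (orient in 1:2) {
    u <- if (orient == 1) x else y
    v <- if (orient == 1) y else x
    for (q in 2:floor(cap / 2)) {
      rmax <- floor(cap / q)
      if (rmax < 2) next
      cx <- ef(u, q)[order(v, seq_len(n))]
      for (r in 2:rmax) {
        cuts_all <- utils::combn(n - 1, r - 1, simplify = FALSE)
        for (cuts in cuts_all) {
          bounds <- c(0, cuts, n)
          rows <- rep(seq_len(r), diff(bounds))
          mi <- oracle_mi_table(rows, cx)
          best <- max(best, mi / log(min(q, r)))
        }
      }
    }
  }
  min(1, best)
}

# ssGSEA hand oracle for a single sample, alpha-weighted running sum.
oracle_ssgsea_sample <- function(expr, genes, set, alpha) {
  n <- length(genes)
  ord <- order(-expr, genes)
  ranked <- genes[ord]
  rank_value <- n:1
  in_set <- ranked %in% set
  m <- sum(in_set)
  if (m == n) return(0)
  w <- numeric(n)
  rw <- rank_value^alpha
  w[in_set] <- rw[in_set] / sum(rw[in_set])
  w[!in_set] <- -1 / (n - m)
  sum(cumsum(w))
}

# Map each truth module label to the detected label with maximal overlap.
match_modules <- function(assignment, truth) {
  shared <- intersect(names(assignment), names(truth))
  tab <- table(truth[shared], assignment[shared])
  apply(tab, 1, function(row) colnames(tab)[which.max(row)])
}

# Adjusted Rand index (Hubert & Arabie) between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Small fast cohort configuration used across tests.
small_config <- function(seed = 1L, ...) {
  synthetic_config(n_genes = 300L, module_sizes = c(40L, 35L, 30L, 25L, 20L),
                   seed = seed, ...)
}
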