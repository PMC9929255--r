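#' Minimum-redundancy maximum-relevance gene selection
#'
#' Greedy sequential selection using the difference (MID) criterion. The
#' first gene maximizes MI(gene, label); each subsequent gene maximizes
#' `MI(gene, label) - mean_s MI(gene, s)` over the already selected set s.
#' Mutual information uses the same rank-binned plug-in estimator as the
#' regulatory-network module, with the binary label treated as a 2-level
#' discrete variable. Ties are broken by gene id, so the ordering is
#' deterministic.
#'
#' @param x Expression matrix, genes x samples.
#' @param labels Binary vector (0/1 or two-level factor) over samples.
#' @param k Number of genes to select (default 100).
#' @return Ordered character vector of selected gene ids.
#' @export
mrmr_select <- function(x, labels, k = 100L) {
  validate_expression(x)
  y <- as.integer(factor(labels))
  if (length(unique(y)) != 2L) stop("labels must have exactly two classes")
  if (k > nrow(x)) stop("k exceeds the number of genes")
  n <- ncol(x)
  b <- mi_bins(n)
  disc <- t(apply(x, 1L, discretize_ef, b = b))
  genes <- rownames(x)
  mi_disc <- function(u, bu, v, bv) {
    counts <- matrix(tabulate(u + bu * (v - 1L), nbins = bu * bv), nrow = bu)
    max(0, mi_plugin(counts))
  }
  relevance <- vapply(seq_len(nrow(x)),
                      function(i) mi_disc(disc[i, ], b, y, 2L), numeric(1))
  selected <- integer(0)
  red_sum <- numeric(nrow(x))
  avail <- rep(TRUE, nrow(x))
  for (step in seq_len(k)) {
    score <- if (step == 1L) relevance else
      relevance - red_sum / length(selected)
    score[!avail] <- -Inf
    cand <- which(score == max(score))
    pick <- cand[order(genes[cand])][1L]
    selected <- c(selected, pick)
    avail[pick] <- FALSE
    if (step < k) {
      idx <- which(avail)
      red_sum[idx] <- red_sum[idx] + vapply(idx, function(i)
        mi_disc(disc[i, ], b, disc[pick, ], b), numeric(1))
    }
  }
  genes[selected]
}

#' Maximal information coefficient
#'
#' MINE-style approximation: one axis is equipartitioned into q
#' equal-frequency columns, the other axis's r row boundaries are optimized
#' by dynamic programming to maximize the mutual information of the grid;
#' the coefficient is the maximum over all grids with `q * r` at most
#' `floor(n^alpha)` cells (and both q, r at least 2) of
#' `MI / log(min(q, r))`. Both axis orientations are tried and the larger
#' value returned. Row cuts are placed in rank space, so the statistic is
#' invariant to monotone transforms of either variable.
#'
#' @param x,y Numeric vectors of equal length (n >= 10).
#' @param alpha Grid-size exponent (default 0.6).
#' @param max_cells_cap Optional hard cap on `q * r` overriding `n^alpha`
#'   (used for exhaustive-oracle testing on tiny grids).
#' @return MIC in \[0, 1\]; 0 for a constant input.
#' @export
mic <- function(x, y, alpha = 0.6, max_cells_cap = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 10L) stop("need n >= 10")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(0)
  cap <- if (is.null(max_cells_cap)) max(4L, floor(n^alpha))
         else as.integer(max_cells_cap)
  best <- 0
  for (orient in 1:2) {
    u <- if (orient == 1L) x else y
    v <- if (orient == 1L) y else x
    for (q in 2:max(2L, floor(cap / 2))) {
      rmax <- floor(cap / q)
      if (rmax < 2L) next
      val <- max_grid_mi(u, v, q, rmax)
      best <- max(best, val)
    }
  }
  min(1, best)
}

# Max over r in 2..rmax of MI(q x r grid)/log(min(q,r)), with the u-axis
# equipartitioned into q columns and the v-axis cuts optimized by DP.
max_grid_mi <- function(u, v, q, rmax) {
  n <- length(u)
  cx <- discretize_ef(u, q)
  ord <- order(v, seq_len(n))
  cx <- cx[ord]
  # cumulative column counts over v-ordered prefixes: (n+1) x q
  cum <- rbind(0, apply(vapply(seq_len(q), function(c) as.numeric(cx == c),
                               numeric(n)), 2L, cumsum))
  pc <- cum[n + 1L, ] / n
  hc <- -sum(ifelse(pc > 0, pc * log(pc), 0))
  # phi[i+1, j]: row contribution of the block covering v-order (i, j]
  plogp <- function(m) ifelse(m > 0, (m / n) * log(m / n), 0)
  phi <- matrix(-Inf, n + 1L, n)
  for (j in seq_len(n)) {
    i <- 0:(j - 1L)
    blocks <- matrix(rep(cum[j + 1L, ], each = length(i)),
                     nrow = length(i)) - cum[i + 1L, , drop = FALSE]
    m <- j - i
    phi[i + 1L, j] <- rowSums(plogp(blocks)) - plogp(m)
  }
  dp <- matrix(-Inf, n, rmax)
  dp[, 1L] <- phi[1L, ]
  for (l in 2:rmax) {
    for (j in l:n) {
      i <- (l - 1L):(j - 1L)
      dp[j, l] <- max(dp[i, l - 1L] + phi[i + 1L, j])
    }
  }
  vals <- vapply(2:rmax, function(r) (dp[n, r] + hc) / log(min(q, r)),
                 numeric(1))
  max(vals)
}

#' Rank genes by maximal information coefficient with the phenotype
#'
#' @param x Expression matrix, genes x samples.
#' @param labels Binary phenotype vector over samples.
#' @param k Number of top genes to return (default 100).
#' @param alpha Grid-size exponent passed to [mic()].
#' @return Ordered character vector: genes by decreasing MIC, ties broken
#'   by gene id.
#' @export
mic_top <- function(x, labels, k = 100L, alpha = 0.6) {
  validate_expression(x)
  y <- as.numeric(factor(labels))
  if (length(unique(y)) != 2L) stop("labels must have exactly two classes")
  scores <- vapply(seq_len(nrow(x)), function(i) mic(x[i, ], y, alpha),
                   numeric(1))
  ord <- order(-scores, rownames(x))
  rownames(x)[ord][seq_len(min(k, nrow(x)))]
}

#' Triple feature selection and intersection
#'
#' Runs the three selectors used for signature construction -- mRMR, MIC
#' ranking and differential-expression ranking (top k by adjusted p) -- and
#' intersects their top-k lists.
#'
#' @param x Expression matrix, genes x samples.
#' @param labels Binary phenotype over samples.
#' @param de Differential-expression table ([differential_expression()]).
#' @param k Per-method list length (default 100).
#' @return List of class `feature_selection_result` with `mrmr_top`,
#'   `mic_top`, `deg_top` (each ordered, length k) and `intersection`.
#' @export
select_features <- function(x, labels, de, k = 100L) {
  mrmr <- mrmr_select(x, labels, k)
  micl <- mic_top(x, labels, k)
  deg <- de$gene[order(de$rank)][seq_len(min(k, nrow(de)))]
  structure(list(mrmr_top = mrmr, mic_top = micl, deg_top = deg,
                 intersection = intersect_signature(
                   list(mrmr_top = mrmr, mic_top = micl, deg_top = deg))),
            class = "feature_selection_result")
}

#' Intersect the three feature-selection lists
#'
#' @param fs List with `mrmr_top`, `mic_top` and `deg_top` gene vectors.
#' @return Character vector: genes present in all three lists, sorted; a
#'   warning is emitted when the intersection is empty.
#' @export
intersect_signature <- function(fs) {
  common <- sort(Reduce(intersect, list(fs$mrmr_top, fs$mic_top, fs$deg_top)))
  if (length(common) == 0L) warning("empty feature intersection")
  common
}
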