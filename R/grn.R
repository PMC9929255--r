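#' Configuration for regulatory-network inference
#'
#' @param p_threshold Null-model tail probability defining the mutual-
#'   information significance threshold (default 1e-7).
#' @param dpi_tolerance Data-processing-inequality tolerance epsilon in
#'   \[0, 1) (default 0.1).
#' @param n_bootstraps Number of bootstrap resamples (default 100).
#' @param min_support Minimum bootstrap support for a consensus edge
#'   (default 0.5).
#' @param n_null_perms Number of permuted gene pairs used to build the MI
#'   null distribution (default 1e5; must be >= 1e4).
#' @param seed Integer seed controlling the null permutations and the
#'   bootstrap resamples.
#' @return A list of class `grn_config`.
#' @export
grn_config <- function(p_threshold = 1e-7, dpi_tolerance = 0.1,
                       n_bootstraps = 100L, min_support = 0.5,
                       n_null_perms = 1e5, seed = 1L) {
  if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold must be in (0,1)")
  if (dpi_tolerance < 0 || dpi_tolerance >= 1)
    stop("dpi_tolerance must be in [0,1)")
  structure(list(p_threshold = p_threshold, dpi_tolerance = dpi_tolerance,
                 n_bootstraps = as.integer(n_bootstraps),
                 min_support = min_support,
                 n_null_perms = as.integer(n_null_perms),
                 seed = as.integer(seed)),
            class = "grn_config")
}

# Equal-frequency discretization of a continuous vector into b bins.
# Ties are broken by position so the binning is deterministic.
discretize_ef <- function(v, b) {
  n <- length(v)
  as.integer(cut(rank(v, ties.method = "first"),
                 breaks = seq(0.5, n + 0.5, length.out = b + 1L),
                 include.lowest = TRUE))
}

# Number of equal-frequency bins used for n samples.
mi_bins <- function(n) max(2L, as.integer(floor(n^(1 / 3))))

#' Plug-in mutual information from a contingency table
#'
#' `MI = sum_ij p_ij ln(p_ij / (p_i p_j))` in nats, from joint counts.
#'
#' @param counts Non-negative integer matrix of joint counts.
#' @return Mutual information in nats (>= 0 up to floating error).
#' @export
mi_plugin <- function(counts) {
  n <- sum(counts)
  if (n == 0) stop("empty contingency table")
  p <- counts / n
  pr <- rowSums(p); pc <- colSums(p)
  pos <- p > 0
  sum(p[pos] * log(p[pos] / outer(pr, pc)[pos]))
}

#' Mutual information between two continuous variables
#'
#' Rank-transforms each variable, partitions both into
#' `max(2, floor(n^(1/3)))` equal-frequency bins, and returns the plug-in
#' mutual information of the resulting joint histogram, in nats. Symmetric
#' and non-negative; a constant variable gives MI = 0.
#'
#' @param x,y Numeric vectors of equal length (>= 20 recommended for
#'   estimation).
#' @param bins Optional bin-count override.
#' @return Mutual information in nats.
#' @export
mutual_information <- function(x, y, bins = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(0)
  b <- if (is.null(bins)) mi_bins(n) else as.integer(bins)
  bx <- discretize_ef(x, b)
  by <- discretize_ef(y, b)
  counts <- matrix(tabulate(bx + b * (by - 1L), nbins = b * b), nrow = b)
  max(0, mi_plugin(counts))
}

#' Mutual-information significance threshold from a permutation null
#'
#' Pools MI values from randomly selected gene pairs with one member's
#' sample order permuted, fits an exponential tail to the upper 5% of this
#' null (linear fit of log survival on MI), and extrapolates to the MI value
#' whose tail probability equals `config$p_threshold`. Extrapolation is
#' needed because thresholds like 1e-7 are far beyond what direct counting
#' can resolve at feasible permutation numbers.
#'
#' @param x Expression matrix, genes x samples.
#' @param config A [grn_config()].
#' @return The MI threshold (nats).
#' @export
mi_threshold <- function(x, config) {
  validate_expression(x)
  if (config$n_null_perms < 1e4) stop("n_null_perms must be >= 1e4")
  set.seed(config$seed)
  n <- ncol(x); g <- nrow(x)
  b <- mi_bins(n)
  disc <- t(apply(x, 1L, discretize_ef, b = b))
  nulls <- numeric(config$n_null_perms)
  i1 <- sample.int(g, config$n_null_perms, replace = TRUE)
  i2 <- sample.int(g, config$n_null_perms, replace = TRUE)
  for (i in seq_len(config$n_null_perms)) {
    bx <- disc[i1[i], ]
    by <- disc[i2[i], sample.int(n)]
    counts <- matrix(tabulate(bx + b * (by - 1L), nbins = b * b), nrow = b)
    nulls[i] <- mi_plugin(counts)
  }
  fit_exponential_tail(nulls, config$p_threshold)
}

# Fit log-survival ~ MI on the upper 5% of null MI values and return the
# MI at which the extrapolated tail probability equals p.
fit_exponential_tail <- function(nulls, p, tail_frac = 0.05) {
  if (all(nulls <= 0)) stop("degenerate null: all MI values are zero")
  s <- sort(nulls)
  m <- length(s)
  k <- max(10L, ceiling(tail_frac * m))
  tail_vals <- s[(m - k + 1L):m]
  surv <- (k:1) / m
  keep <- !duplicated(tail_vals)
  if (sum(keep) < 3L) stop("degenerate null: tail has too few distinct values")
  fit <- stats::lm(log(surv[keep]) ~ tail_vals[keep])
  a <- stats::coef(fit)[1L]; slope <- stats::coef(fit)[2L]
  if (slope >= 0) stop("degenerate null: non-decaying tail")
  as.numeric((log(p) - a) / slope)
}

#' Data-processing-inequality pruning
#'
#' For every triangle (i, j, k) in the undirected weighted graph, edge
#' (i, j) is marked for removal when `w_ij < (1 - eps) * min(w_ik, w_jk)`;
#' all removals are applied simultaneously after scanning every triangle.
#' With eps = 0 this removes the strictly weakest edge of each triangle,
#' the classic information-theoretic indirect-interaction filter.
#'
#' @param edges data.frame with columns `a`, `b`, `w` (undirected edges,
#'   non-negative weights).
#' @param eps Tolerance in \[0, 1).
#' @return The surviving subset of `edges`.
#' @export
dpi_prune <- function(edges, eps) {
  stopifnot(all(c("a", "b", "w") %in% colnames(edges)))
  if (nrow(edges) == 0L) return(edges)
  if (any(edges$w < 0)) stop("weights must be non-negative")
  nodes <- unique(c(edges$a, edges$b))
  ia <- match(edges$a, nodes); ib <- match(edges$b, nodes)
  nn <- length(nodes)
  w <- matrix(0, nn, nn)
  w[cbind(ia, ib)] <- edges$w
  w[cbind(ib, ia)] <- edges$w
  adj <- w > 0
  drop <- logical(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    i <- ia[e]; j <- ib[e]
    u <- which(adj[i, ] & adj[j, ])
    u <- setdiff(u, c(i, j))
    if (length(u) > 0 &&
        any(edges$w[e] < (1 - eps) * pmin(w[i, u], w[j, u])))
      drop[e] <- TRUE
  }
  edges[!drop, , drop = FALSE]
}

#' Construct a regulatory-network object
#'
#' @param edges data.frame with columns regulator, target, weight, support.
#' @param tf_list Character vector: the candidate-regulator universe.
#' @param scale_free_fit Optional scale-free fitting index of the network's
#'   regulator out-degree distribution.
#' @return A list of class `regulatory_network`.
#' @export
regulatory_network <- function(edges, tf_list, scale_free_fit = NA_real_) {
  stopifnot(all(c("regulator", "target", "weight", "support") %in%
                  colnames(edges)))
  if (nrow(edges) > 0) {
    if (!all(edges$regulator %in% tf_list))
      stop("all regulators must be in tf_list")
    if (any(edges$regulator == edges$target)) stop("self-edges not allowed")
    if (any(!is.finite(edges$weight)) || any(edges$weight < 0))
      stop("edge weights must be finite and non-negative")
  }
  structure(list(edges = edges, tf_list = tf_list,
                 scale_free_fit = scale_free_fit),
            class = "regulatory_network")
}

# MI of one discretized row against all rows of a discretized matrix.
mi_row_vs_all <- function(bt, disc, b) {
  n <- length(bt)
  code <- sweep(disc, 2L, (bt - 1L) * b, "+")
  counts <- t(apply(code, 1L, tabulate, nbins = b * b))
  p <- counts / n
  pc <- tabulate(bt, nbins = b) / n
  pr <- t(apply(disc, 1L, tabulate, nbins = b)) / n
  expc <- matrix(0, nrow(disc), b * b)
  for (jj in seq_len(b)) {
    expc[, (jj - 1L) * b + seq_len(b)] <- pr * pc[jj]
  }
  contrib <- ifelse(p > 0, p * log(p / expc), 0)
  pmax(0, rowSums(contrib))
}

#' Infer a TF-target regulatory network by bootstrapped mutual information
#'
#' ARACNe-style inference: a global MI significance threshold is calibrated
#' once on the input matrix via [mi_threshold()]; then for each bootstrap
#' resample of the samples, MI is computed for every TF-gene pair, pairs
#' below the threshold are discarded and the data-processing inequality
#' ([dpi_prune()]) removes indirect edges. Consensus edges are those present
#' in at least `min_support` of the bootstraps; their weight is the mean MI
#' over supporting bootstraps. TF-TF pairs are evaluated in both regulator
#' roles. The scale-free fitting index of the consensus out-degrees is
#' attached.
#'
#' @param x Expression matrix, genes x samples.
#' @param tf_list Candidate regulator gene ids (intersected with the
#'   matrix's genes).
#' @param config A [grn_config()].
#' @return A `regulatory_network`.
#' @export
infer_grn <- function(x, tf_list, config = grn_config()) {
  validate_expression(x)
  tfs <- intersect(tf_list, rownames(x))
  if (length(tfs) == 0L) stop("no candidate TFs present in the matrix")
  thr <- mi_threshold(x, config)
  set.seed(config$seed + 1L)
  n <- ncol(x); b <- mi_bins(n)
  genes <- rownames(x)
  counts_tab <- new.env(parent = emptyenv())
  B <- config$n_bootstraps
  for (boot in seq_len(B)) {
    idx <- sample.int(n, replace = TRUE)
    xb <- x[, idx, drop = FALSE]
    disc <- t(apply(xb, 1L, discretize_ef, b = b))
    # undirected candidate edges above threshold
    ea <- character(0); eb <- character(0); ew <- numeric(0)
    for (t in seq_along(tfs)) {
      ti <- match(tfs[t], genes)
      mi <- mi_row_vs_all(disc[ti, ], disc, b)
      mi[ti] <- 0
      # avoid double-counting TF-TF pairs: keep only later-indexed TFs
      earlier <- match(tfs[seq_len(t - 1L)], genes)
      mi[earlier] <- 0
      hit <- which(mi > thr)
      if (length(hit) > 0) {
        ea <- c(ea, rep(tfs[t], length(hit)))
        eb <- c(eb, genes[hit])
        ew <- c(ew, mi[hit])
      }
    }
    if (length(ea) == 0L) next
    kept <- dpi_prune(data.frame(a = ea, b = eb, w = ew,
                                 stringsAsFactors = FALSE),
                      config$dpi_tolerance)
    if (nrow(kept) == 0L) next
    key <- paste(kept$a, kept$b, sep = "\r")
    for (i in seq_along(key)) {
      prev <- counts_tab[[key[i]]]
      if (is.null(prev)) prev <- c(0, 0)
      counts_tab[[key[i]]] <- prev + c(1, kept$w[i])
    }
  }
  keys <- ls(counts_tab)
  if (length(keys) == 0L) {
    warning("empty consensus network")
    return(regulatory_network(
      data.frame(regulator = character(0), target = character(0),
                 weight = numeric(0), support = numeric(0)), tfs))
  }
  stats_m <- t(vapply(keys, function(k) counts_tab[[k]], numeric(2)))
  support <- stats_m[, 1] / B
  weight <- stats_m[, 2] / stats_m[, 1]
  keep <- support >= config$min_support
  parts <- do.call(rbind, strsplit(keys[keep], "\r", fixed = TRUE))
  if (is.null(parts)) {
    warning("empty consensus network")
    return(regulatory_network(
      data.frame(regulator = character(0), target = character(0),
                 weight = numeric(0), support = numeric(0)), tfs))
  }
  reg <- parts[, 1]; tgt <- parts[, 2]
  wgt <- weight[keep]; sup <- support[keep]
  # TF-TF pairs act in both regulator roles
  both <- tgt %in% tfs
  edges <- data.frame(
    regulator = c(reg, tgt[both]),
    target = c(tgt, reg[both]),
    weight = c(wgt, wgt[both]),
    support = c(sup, sup[both]),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  out_deg <- table(edges$regulator)
  sff <- tryCatch(scale_free_fit_index(as.numeric(out_deg)),
                  error = function(e) NA_real_)
  regulatory_network(edges, tfs, scale_free_fit = sff)
}
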