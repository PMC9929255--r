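#' Scale-free topology fitting index
#'
#' Bins node degrees into equal-width bins over their range, regresses
#' log10 bin frequency on log10 mean bin degree over occupied bins, and
#' returns the regression R-squared. Values near 1 indicate a power-law
#' (scale-free) degree distribution.
#'
#' @param degrees Non-negative node degrees (connectivities).
#' @param n_bins Number of equal-width bins (default 10).
#' @return R-squared of the log-log fit.
#' @export
scale_free_fit_index <- function(degrees, n_bins = 10L) {
  degrees <- degrees[is.finite(degrees) & degrees > 0]
  if (length(unique(degrees)) < 2L)
    stop("degenerate degree distribution: need >= 2 distinct positive degrees")
  breaks <- seq(min(degrees), max(degrees), length.out = n_bins + 1L)
  bin <- cut(degrees, breaks = breaks, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = n_bins)
  mean_deg <- vapply(seq_len(n_bins),
                     function(b) mean(degrees[as.integer(bin) == b]),
                     numeric(1))
  keep <- freq > 0 & mean_deg > 0
  if (sum(keep) < 2L) stop("degenerate degree distribution: too few occupied bins")
  fit <- stats::lm(log10(freq[keep]) ~ log10(mean_deg[keep]))
  summary(fit)$r.squared
}

#' Choose a soft-threshold power by scale-free fit
#'
#' Computes the unsigned weighted-network connectivity for each candidate
#' power and its scale-free fitting index; the chosen power is the smallest
#' one whose fit reaches `min(target_fit, max_fit - 0.05)`. Anchoring the
#' effective threshold to the fit curve's plateau guards against two
#' failure modes of a hard cut: a noisy curve that first crosses the target
#' at an extreme power, and a curve that never reaches it at all -- in both
#' cases chasing maximal fit erodes weakly loaded module genes while buying
#' marginal scale-freeness.
#'
#' @param x Expression matrix, genes x samples.
#' @param powers Candidate integer powers.
#' @param target_fit Scale-free fit threshold (default 0.85).
#' @return List of class `soft_threshold_report` with `report` (data.frame:
#'   power, fit_index, mean_connectivity, connectivities) and `chosen_power`.
#' @export
pick_soft_threshold <- function(x, powers = 1:20, target_fit = 0.85) {
  validate_expression(x)
  if (ncol(x) < 10L) stop("need >= 10 samples for soft-threshold selection")
  ac <- abs(stats::cor(t(x)))
  diag(ac) <- 0
  fit <- mean_k <- rep(NA_real_, length(powers))
  ks <- vector("list", length(powers))
  for (i in seq_along(powers)) {
    k <- colSums(ac^powers[i])
    ks[[i]] <- k
    mean_k[i] <- mean(k)
    fit[i] <- tryCatch(scale_free_fit_index(k), error = function(e) NA_real_)
  }
  eff <- min(target_fit, max(fit, na.rm = TRUE) - 0.05)
  ok <- which(!is.na(fit) & fit >= eff)
  chosen <- powers[ok[1L]]
  structure(list(report = data.frame(power = powers, fit_index = fit,
                                     mean_connectivity = mean_k),
                 connectivities = ks,
                 chosen_power = chosen,
                 target_fit = target_fit),
            class = "soft_threshold_report")
}

#' Unsigned weighted adjacency
#'
#' `a_ij = |cor(gene_i, gene_j)|^power`, zero diagonal.
#'
#' @param x Expression matrix, genes x samples.
#' @param power Soft-threshold power (>= 1).
#' @return Symmetric genes x genes matrix with entries in \[0, 1\].
#' @export
adjacency_matrix <- function(x, power) {
  validate_expression(x)
  if (power < 1) stop("power must be >= 1")
  v <- apply(x, 1L, stats::var)
  if (any(v == 0))
    stop("zero-variance gene: ", rownames(x)[which(v == 0)[1L]])
  a <- abs(stats::cor(t(x)))^power
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' i != j, with connectivity `k_i = sum_u a_iu`; the diagonal is 1. Shared
#' neighbours smooth the adjacency, making module structure crisper.
#'
#' @param a Symmetric adjacency matrix with zero diagonal, entries in
#'   \[0, 1\].
#' @return Symmetric matrix of topological overlaps.
#' @export
topological_overlap <- function(a) {
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  if (any(abs(diag(a)) > 1e-12)) stop("adjacency must have zero diagonal")
  k <- colSums(a)
  num <- tcrossprod(a) + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom
}

#' Module eigengene
#'
#' First principal component of the per-gene standardized member submatrix,
#' returned as a unit-norm vector over samples, with its sign oriented so
#' that it correlates non-negatively with the module's mean standardized
#' expression profile.
#'
#' @param x Expression matrix, genes x samples.
#' @param members Character vector of member gene ids.
#' @return Named numeric vector over samples.
#' @export
module_eigengene <- function(x, members) {
  if (length(members) == 0L) stop("empty member set")
  sub <- x[members, , drop = FALSE]
  z <- t(scale(t(sub)))
  if (anyNA(z)) stop("zero-variance gene among module members")
  sv <- svd(z, nu = 0, nv = 1)
  eg <- sv$v[, 1L]
  ref <- colMeans(z)
  if (sum(eg * ref) < 0) eg <- -eg
  stats::setNames(eg, colnames(x))
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering of the topological-overlap
#' dissimilarity (1 - TOM), with a static branch cut at 0.99 x the maximum
#' merge height. Clusters smaller than `min_size` become UNASSIGNED (the
#' catch-all module of non-co-expressed genes). Modules whose eigengenes
#' correlate above `merge_cor` are merged iteratively, largest pair first.
#' Final labels M1..Mk are assigned by decreasing module size.
#'
#' @param x Expression matrix, genes x samples.
#' @param power Soft-threshold power (see [pick_soft_threshold()]).
#' @param min_size Minimum module size (default 30).
#' @param merge_cor Eigengene correlation above which modules merge
#'   (default 0.75).
#' @param cut_frac Fraction of the maximum merge height at which the tree
#'   is cut (default 0.99).
#' @param kme_min Minimum absolute module membership (correlation between a
#'   gene's profile and its module eigengene); assigned genes below it are
#'   returned to UNASSIGNED, then the size filter is re-applied. This
#'   prunes background genes that attach to a module branch by chance
#'   (default 0.4).
#' @return A list of class `module_set`: `assignment` (named character
#'   vector gene -> module label or "UNASSIGNED"), `eigengenes` (modules x
#'   samples matrix, unit-norm rows), `power`.
#' @export
detect_modules <- function(x, power, min_size = 30L, merge_cor = 0.75,
                           cut_frac = 0.99, kme_min = 0.4) {
  validate_expression(x)
  genes <- rownames(x)
  if (nrow(x) < min_size) {
    warning("fewer than min_size genes: all genes UNASSIGNED")
    return(module_set(stats::setNames(rep("UNASSIGNED", nrow(x)), genes),
                      x, power))
  }
  a <- adjacency_matrix(x, power)
  tom <- topological_overlap(a)
  h <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(h, h = cut_frac * max(h$height))
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= min_size])
  cl[!(cl %in% keep)] <- 0L

  # iterative eigengene merging, largest combined pair first
  repeat {
    ids <- setdiff(sort(unique(cl)), 0L)
    if (length(ids) < 2L) break
    egs <- t(vapply(ids, function(i) module_eigengene(x, genes[cl == i]),
                    numeric(ncol(x))))
    cm <- stats::cor(t(egs))
    diag(cm) <- 0
    pairs <- which(cm > merge_cor, arr.ind = TRUE)
    pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
    if (nrow(pairs) == 0L) break
    comb <- vapply(seq_len(nrow(pairs)), function(r) {
      sum(cl == ids[pairs[r, 1]]) + sum(cl == ids[pairs[r, 2]])
    }, numeric(1))
    best <- pairs[order(-comb, -cm[pairs])[1L], ]
    cl[cl == ids[best[2]]] <- ids[best[1]]
  }

  # module-membership pruning: drop weakly attached genes
  ids <- setdiff(sort(unique(cl)), 0L)
  for (i in ids) {
    members <- genes[cl == i]
    eg <- module_eigengene(x, members)
    kme <- abs(as.numeric(stats::cor(t(x[members, , drop = FALSE]), eg)))
    cl[match(members[kme < kme_min], genes)] <- 0L
    if (sum(cl == i) < min_size) cl[cl == i] <- 0L
  }

  module_set(relabel_by_size(cl, genes), x, power)
}

# Label clusters M1..Mk by decreasing size; 0 becomes UNASSIGNED.
relabel_by_size <- function(cl, genes) {
  ids <- setdiff(sort(unique(cl)), 0L)
  sizes <- vapply(ids, function(i) sum(cl == i), numeric(1))
  ord <- ids[order(-sizes, ids)]
  lab <- rep("UNASSIGNED", length(cl))
  for (i in seq_along(ord)) lab[cl == ord[i]] <- paste0("M", i)
  stats::setNames(lab, genes)
}

#' Construct a module set
#'
#' Bundles a gene -> module assignment with per-module eigengenes computed
#' from the given expression matrix. UNASSIGNED genes get no eigengene.
#'
#' @param assignment Named character vector, gene id -> module label.
#' @param x Expression matrix used to compute eigengenes.
#' @param power Soft-threshold power recorded for provenance.
#' @return A list of class `module_set`.
#' @export
module_set <- function(assignment, x, power) {
  labels <- setdiff(unique(assignment), "UNASSIGNED")
  labels <- labels[order(as.integer(sub("^M", "", labels)))]
  eg <- if (length(labels) > 0) {
    t(vapply(labels,
             function(m) module_eigengene(x, names(assignment)[assignment == m]),
             numeric(ncol(x))))
  } else {
    matrix(numeric(0), nrow = 0, ncol = ncol(x),
           dimnames = list(NULL, colnames(x)))
  }
  rownames(eg) <- labels
  structure(list(assignment = assignment, eigengenes = eg,
                 power = power),
            class = "module_set")
}

#' Sizes of the modules in a module set
#'
#' @param modules A `module_set`.
#' @param include_unassigned Count the UNASSIGNED catch-all too?
#' @return Named integer vector of module sizes.
#' @export
module_sizes <- function(modules, include_unassigned = FALSE) {
  tab <- table(modules$assignment)
  if (!include_unassigned) tab <- tab[names(tab) != "UNASSIGNED"]
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[order(as.integer(sub("^M", "", sub("UNASSIGNED", "M999999", names(out)))))]
}

#' Module-trait correlation
#'
#' Pearson correlation between each module eigengene and each clinical
#' trait, with Student asymptotic p-values
#' (`t = r sqrt(n-2) / sqrt(1-r^2)` against t(n-2), two-sided) and BH
#' adjustment across modules separately within each trait.
#'
#' @param modules A `module_set` (eigengene columns named by sample id).
#' @param traits data.frame with `sample_id` plus numeric trait columns;
#'   only samples present in both are used.
#' @return data.frame with columns module, trait, r, p, p_adj.
#' @export
module_trait_correlation <- function(modules, traits) {
  stopifnot(inherits(modules, "module_set"))
  if (nrow(modules$eigengenes) == 0L) stop("module set has no modules")
  common <- intersect(colnames(modules$eigengenes), traits$sample_id)
  if (length(common) < 4L) stop("need >= 4 shared samples")
  eg <- modules$eigengenes[, common, drop = FALSE]
  trait_names <- setdiff(colnames(traits), "sample_id")
  tv <- traits[match(common, traits$sample_id), trait_names, drop = FALSE]
  n <- length(common)
  out <- list()
  for (tr in trait_names) {
    y <- tv[[tr]]
    if (stats::sd(y) == 0) stop("constant trait: ", tr)
    r <- as.numeric(stats::cor(t(eg), y))
    r <- pmin(pmax(r, -1), 1)
    tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    out[[tr]] <- data.frame(module = rownames(eg), trait = tr, r = r,
                            p = p, p_adj = bh_adjust(p),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
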