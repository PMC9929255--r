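#' Build an up/down signature from module-restricted differential expression
#'
#' Genes assigned to the kept modules with adjusted p below `alpha` are
#' split by fold-change sign into an up list (log2FC > 0) and a down list
#' (log2FC < 0), each ordered by decreasing absolute fold change.
#'
#' @param de Differential-expression table ([differential_expression()]).
#' @param modules A `module_set`.
#' @param keep Module labels whose genes may enter the signature.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return A list of class `signature` with ordered character vectors `up`
#'   and `down`.
#' @export
build_signature <- function(de, modules, keep, alpha = 0.05) {
  stopifnot(inherits(modules, "module_set"))
  if (length(keep) == 0L) stop("keep must name at least one module")
  mod <- modules$assignment[de$gene]
  sel <- !is.na(mod) & mod %in% keep & de$p_adj < alpha
  up <- de[sel & de$log2FC > 0, , drop = FALSE]
  dn <- de[sel & de$log2FC < 0, , drop = FALSE]
  if (nrow(up) + nrow(dn) == 0L) stop("no signature genes")
  structure(list(up = up$gene[order(-abs(up$log2FC), up$gene)],
                 down = dn$gene[order(-abs(dn$log2FC), dn$gene)]),
            class = "signature")
}

#' Kolmogorov-Smirnov enrichment statistic of a tag set in a ranked list
#'
#' The classic connectivity-map statistic: with t tags at ascending ranks
#' V(j) in a list of length N,
#' `a = max_j (j/t - V(j)/N)` and `b = max_j (V(j)/N - (j-1)/t)`;
#' the statistic is `a` if `a > b`, else `-b`. Positive values mean the
#' tags concentrate at the top of the list.
#'
#' @param tags Character vector of tag gene ids (all must be in the list).
#' @param ranked_list Ordered character vector of gene ids.
#' @return Enrichment statistic in \[-1, 1\].
#' @export
ks_enrichment <- function(tags, ranked_list) {
  if (length(tags) == 0L) stop("empty tag set")
  v <- match(tags, ranked_list)
  if (anyNA(v)) stop("tags must be members of the ranked list")
  v <- sort(v)
  t <- length(v); n <- length(ranked_list)
  j <- seq_len(t)
  a <- max(j / t - v / n)
  b <- max(v / n - (j - 1) / t)
  if (a > b) a else -b
}

#' Connectivity scores of perturbation profiles against a signature
#'
#' For each drug profile, genes are ranked by the profile's z-score in
#' descending order (ties broken by gene id); the KS enrichment of the
#' signature's up and down sets is computed on that ranking. The raw
#' connectivity `c = ES_up - ES_down` is set to 0 when both enrichments
#' share a sign; scores are then scaled within the database: positive c
#' divided by the maximum positive c, negative c by the absolute minimum
#' negative c, so the most extreme scores are +1 and -1. A score near -1
#' flags a profile that reverses the signature.
#'
#' @param signature A `signature` (lists `up`, `down`).
#' @param db Perturbation database data.frame: columns drug, cell_type,
#'   dose, duration, then one z-score column per gene.
#' @param cutoff Candidate cutoff passed to [candidate_filter()]
#'   (default -0.60).
#' @return data.frame with drug metadata, ES_up, ES_down, c, s and a
#'   candidate flag, sorted by s ascending.
#' @export
connectivity_scores <- function(signature, db, cutoff = -0.60) {
  stopifnot(inherits(signature, "signature"))
  if (nrow(db) == 0L) stop("empty perturbation database")
  meta_cols <- intersect(c("drug", "cell_type", "dose", "duration"),
                         colnames(db))
  genes <- setdiff(colnames(db), meta_cols)
  up <- intersect(signature$up, genes)
  dn <- intersect(signature$down, genes)
  n_missing <- (length(signature$up) - length(up)) +
    (length(signature$down) - length(dn))
  if (n_missing > 0)
    warning(n_missing, " signature genes absent from the profile universe")
  if (length(up) == 0L && length(dn) == 0L)
    stop("no signature genes in the profile universe")
  z <- as.matrix(db[, genes, drop = FALSE])
  es_up <- es_dn <- numeric(nrow(db))
  for (i in seq_len(nrow(db))) {
    ranking <- genes[order(-z[i, ], genes)]
    es_up[i] <- if (length(up) > 0) ks_enrichment(up, ranking) else 0
    es_dn[i] <- if (length(dn) > 0) ks_enrichment(dn, ranking) else 0
  }
  cc <- ifelse(sign(es_up) == sign(es_dn) & es_up != 0 & es_dn != 0,
               0, es_up - es_dn)
  s <- scale_connectivity(cc)
  res <- cbind(db[, meta_cols, drop = FALSE],
               data.frame(ES_up = es_up, ES_down = es_dn, c = cc, s = s))
  candidate_filter(res, cutoff)
}

#' Scale raw connectivity values to \[-1, 1\]
#'
#' Positive values are divided by the largest positive value, negative
#' values by the absolute most negative value, so the extremes of the
#' database map to +1 and -1 and zeros stay zero.
#'
#' @param cc Numeric vector of raw connectivity values.
#' @return Scaled scores in \[-1, 1\].
#' @export
scale_connectivity <- function(cc) {
  s <- numeric(length(cc))
  if (any(cc > 0)) s[cc > 0] <- cc[cc > 0] / max(cc[cc > 0])
  if (any(cc < 0)) s[cc < 0] <- cc[cc < 0] / abs(min(cc[cc < 0]))
  s
}

#' Flag candidate signature-reversing drugs
#'
#' Marks rows with scaled connectivity `s <= cutoff` as candidates and
#' sorts by s ascending (most strongly reversing first).
#'
#' @param results Connectivity result data.frame with an `s` column.
#' @param cutoff Score cutoff (default -0.60).
#' @return The data.frame with a logical `candidate` column, sorted by s.
#' @export
candidate_filter <- function(results, cutoff = -0.60) {
  results$candidate <- results$s <= cutoff
  results <- results[order(results$s, results$drug), , drop = FALSE]
  rownames(results) <- NULL
  results
}
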