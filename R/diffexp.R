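#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value. When both samples are constant with equal means the
#' result is t = 0, p = 1; constant samples with different means are a
#' degenerate input and raise an error.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs >= 2 values")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("non-finite values")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = na + nb - 2, p = 1))
    stop("degenerate variance: both samples constant with different means")
  }
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Mann-Whitney U test
#'
#' U statistic with midrank tie handling. The two-sided p-value is computed
#' by exhaustive enumeration over all label assignments when
#' `length(a) + length(b) <= 12`, and otherwise by the normal approximation
#' with tie-corrected variance and continuity correction.
#'
#' @param a,b Numeric vectors.
#' @return List with `U` (for sample `a`) and `p`.
#' @export
mann_whitney <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 1L || nb < 1L) stop("each sample needs >= 1 value")
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  n <- na + nb
  if (n <= 12L) {
    sel <- utils::combn(n, na)
    us <- colSums(matrix(r[sel], nrow = na)) - na * (na + 1) / 2
    mu <- na * nb / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-12)
  } else {
    mu <- na * nb / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v <- na * nb / 12 * ((n + 1) - tie_term)
    if (v <= 0) return(list(U = u, p = 1))
    z <- (abs(u - mu) - 0.5) / sqrt(v)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  }
  list(U = u, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate correction, capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-gene differential expression between two sample groups
#'
#' For every gene: log2 fold change as the mean difference (contrast group
#' minus reference) on the log2 scale, a Welch t-test p-value, BH-adjusted
#' p across all genes, and a deterministic rank (ascending adjusted p, ties
#' broken by raw p then gene id).
#'
#' @param x Expression matrix, genes x samples (log2 scale).
#' @param meta Sample metadata data.frame with `sample_id` plus `group` and
#'   `subgroup` columns.
#' @param contrast Character vector of length 2, `c(contrast, reference)`;
#'   labels are looked up in `group` first, then `subgroup`.
#' @return data.frame with columns gene, log2FC, p, p_adj, rank, ordered as
#'   the input genes; attribute `contrast` records the orientation.
#' @export
differential_expression <- function(x, meta, contrast = c("AMI", "control")) {
  validate_expression(x)
  stopifnot(length(contrast) == 2L)
  lab <- meta$group[match(colnames(x), meta$sample_id)]
  if (!all(contrast %in% lab)) {
    lab <- meta$subgroup[match(colnames(x), meta$sample_id)]
    if (!all(contrast %in% lab))
      stop("contrast labels not found in group or subgroup")
  }
  ia <- which(lab == contrast[1]); ib <- which(lab == contrast[2])
  if (length(ia) < 2L || length(ib) < 2L)
    stop("each contrast group needs >= 2 samples")
  xa <- x[, ia, drop = FALSE]; xb <- x[, ib, drop = FALSE]
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  lfc <- ma - mb
  t <- ifelse(se2 > 0, lfc / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               na + nb - 2)
  p <- 2 * stats::pt(-abs(t), df)
  p[se2 == 0 & lfc == 0] <- 1
  if (any(se2 == 0 & lfc != 0))
    stop("degenerate variance: constant gene with different group means")
  p_adj <- bh_adjust(p)
  ord <- order(p_adj, p, rownames(x))
  rk <- integer(nrow(x)); rk[ord] <- seq_len(nrow(x))
  res <- data.frame(gene = rownames(x), log2FC = lfc, p = p, p_adj = p_adj,
                    rank = rk, row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "contrast") <- paste(contrast, collapse = "-")
  res
}
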