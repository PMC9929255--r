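#' Restrict a regulatory network to targets in selected modules
#'
#' Keeps edges whose target gene is assigned to one of the kept
#' co-expression modules; the candidate-regulator universe is unchanged.
#' This mirrors building a trait-associated subnetwork in which only module
#' members may be regulated targets.
#'
#' @param network A `regulatory_network`.
#' @param modules A `module_set`.
#' @param keep Character vector of module labels to keep.
#' @return A `regulatory_network` with the filtered edge set.
#' @export
restrict_subnetwork <- function(network, modules, keep) {
  stopifnot(inherits(network, "regulatory_network"),
            inherits(modules, "module_set"))
  if (length(keep) == 0L) stop("keep must name at least one module")
  tgt_mod <- modules$assignment[network$edges$target]
  sel <- !is.na(tgt_mod) & tgt_mod %in% keep
  if (!any(sel)) warning("no edges target the kept modules")
  regulatory_network(network$edges[sel, , drop = FALSE], network$tf_list,
                     network$scale_free_fit)
}

#' Regulatory scores of candidate driver transcription factors
#'
#' For each (TF, module) pair, the regulatory score is the sum over the
#' TF's in-module targets of edge weight times the target's absolute log2
#' fold change: `RS = sum_t w(tf, t) * |log2FC(t)|`. High-RS TFs are
#' candidate drivers of the contrast that produced the fold changes.
#'
#' @param network A `regulatory_network` (typically module-restricted, see
#'   [restrict_subnetwork()]).
#' @param de Differential-expression table from
#'   [differential_expression()]; every network target must appear.
#' @param modules A `module_set` giving target module membership.
#' @return data.frame of class `regulator_score_table` with columns tf,
#'   module, RS, total_weight, n_targets, selected (all FALSE until
#'   [select_top_regulators()]).
#' @export
regulatory_scores <- function(network, de, modules) {
  stopifnot(inherits(network, "regulatory_network"),
            inherits(modules, "module_set"))
  edges <- network$edges
  miss <- setdiff(edges$target, de$gene)
  if (length(miss) > 0)
    stop("target missing from DE table: ", miss[1L])
  lfc <- abs(de$log2FC[match(edges$target, de$gene)])
  mod <- modules$assignment[edges$target]
  key <- paste(edges$regulator, mod, sep = "\r")
  rs <- tapply(edges$weight * lfc, key, sum)
  tw <- tapply(edges$weight, key, sum)
  nt <- tapply(edges$weight, key, length)
  parts <- do.call(rbind, strsplit(names(rs), "\r", fixed = TRUE))
  out <- data.frame(tf = parts[, 1], module = parts[, 2],
                    RS = as.numeric(rs), total_weight = as.numeric(tw),
                    n_targets = as.integer(nt), selected = FALSE,
                    stringsAsFactors = FALSE)
  out <- out[order(out$module, -out$RS, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("regulator_score_table", "data.frame")
  out
}

#' Select the top-fraction regulators per module
#'
#' Within each module, marks as selected the `max(1, ceiling(fraction *
#' module_size))` TFs with the highest regulatory score. Ties are broken by
#' larger total edge weight, then lexicographic TF id, so selection is
#' deterministic.
#'
#' @param scores A `regulator_score_table` from [regulatory_scores()].
#' @param modules The `module_set` supplying module sizes.
#' @param fraction Selection fraction of module size (default 0.01, i.e.
#'   the "top 1 percent relative to module size" rule).
#' @return The score table with the `selected` column filled in.
#' @export
select_top_regulators <- function(scores, modules, fraction = 0.01) {
  stopifnot(inherits(modules, "module_set"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  sizes <- table(modules$assignment)
  scores$selected <- FALSE
  for (m in unique(scores$module)) {
    rows <- which(scores$module == m)
    if (length(rows) == 0L) next
    msize <- sizes[[m]]
    if (is.null(msize) || is.na(msize)) {
      warning("module not found in module set: ", m)
      next
    }
    n_sel <- max(1L, ceiling(fraction * msize))
    ord <- rows[order(-scores$RS[rows], -scores$total_weight[rows],
                      scores$tf[rows])]
    scores$selected[ord[seq_len(min(n_sel, length(ord)))]] <- TRUE
  }
  scores
}
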