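#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes every stage end to end on one generated cohort and writes all
#' artifacts as plain-text tables under `outdir`: the simulated inputs,
#' differential expression (case vs control and Large vs Small), the
#' co-expression module assignment and eigengenes, module-trait
#' correlations on the AMI subcohort, the bootstrap consensus regulatory
#' network, regulatory-score driver ranking on the trait-associated
#' subnetwork, the up/down signature, connectivity scores against the
#' synthetic perturbation database, and the cross-validation report.
#' All randomness flows from `config$seed`, so two runs with the same
#' configuration produce byte-identical output files.
#'
#' @param config A [synthetic_config()]; its seed drives every stage.
#' @param outdir Output directory (created if absent).
#' @param n_bootstraps Bootstrap resamples for network inference; the
#'   default 20 keeps a 2,000-gene run on one core to a few minutes.
#' @param n_null_perms Null permutations for the MI threshold.
#' @param min_size Minimum co-expression module size (see
#'   [detect_modules()]); smaller cohorts warrant smaller values.
#' @param run_feature_selection Also run the triple feature selection and
#'   cross-validated classification (the most expensive stage)?
#' @return Invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(config = synthetic_config(), outdir,
                         n_bootstraps = 20L, n_null_perms = 2e4,
                         min_size = 30L, run_feature_selection = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(outdir, f)
  message("seed: ", config$seed)

  cohort <- generate_cohort(config)
  write_expression(cohort$expression, out("expression.tsv"))
  utils::write.table(cohort$meta, out("sample_meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$traits, out("traits.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$functional, out("functional.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  de_group <- differential_expression(cohort$expression, cohort$meta,
                                      c("AMI", "control"))
  utils::write.table(de_group, out("diffexp_AMI_vs_control.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  de_sub <- differential_expression(cohort$expression, cohort$meta,
                                    c("Large", "Small"))
  utils::write.table(de_sub, out("diffexp_Large_vs_Small.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # full-cohort co-expression network (all samples)
  sft_full <- pick_soft_threshold(cohort$expression, powers = 1:12)
  modules_full <- detect_modules(cohort$expression, sft_full$chosen_power,
                                 min_size = min_size)
  utils::write.table(
    data.frame(gene = names(modules_full$assignment),
               module = unname(modules_full$assignment)),
    out("modules_full.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  # AMI-only co-expression network against clinical traits
  ami <- cohort$meta$sample_id[cohort$meta$group == "AMI"]
  x_ami <- cohort$expression[, ami, drop = FALSE]
  sft <- pick_soft_threshold(x_ami, powers = 1:12)
  utils::write.table(sft$report, out("soft_threshold.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  modules <- detect_modules(x_ami, sft$chosen_power, min_size = min_size)
  utils::write.table(
    data.frame(gene = names(modules$assignment),
               module = unname(modules$assignment)),
    out("modules.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  mt <- module_trait_correlation(modules, cohort$traits)
  utils::write.table(mt, out("module_trait.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # trait-associated modules drive the driver ranking and the signature
  keep <- unique(mt$module[mt$p_adj < 0.05])
  if (length(keep) == 0L) keep <- unique(mt$module)

  gcfg <- grn_config(n_bootstraps = n_bootstraps,
                     n_null_perms = n_null_perms, seed = config$seed)
  tfs <- grep("^TF", rownames(cohort$expression), value = TRUE)
  network <- infer_grn(cohort$expression, tfs, gcfg)
  write_edge_list(network, out("grn_edges.tsv"))
  subnet <- restrict_subnetwork(network, modules, keep)
  scores <- select_top_regulators(
    regulatory_scores(subnet, de_sub, modules), modules)
  utils::write.table(scores, out("drivers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  signature <- build_signature(de_sub, modules, keep)
  sig_sets <- Filter(length, list(SIG_UP = signature$up,
                                  SIG_DOWN = signature$down))
  write_gmt(sig_sets, out("signature.gmt"))
  pdb <- generate_perturbation_db(config, signature,
                                  rownames(cohort$expression))
  conn <- connectivity_scores(signature, pdb$db)
  utils::write.table(conn, out("connectivity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  fs <- cv <- NULL
  if (run_feature_selection) {
    labels <- cohort$meta$group[match(colnames(cohort$expression),
                                      cohort$meta$sample_id)]
    fs <- select_features(cohort$expression, labels, de_group, k = 100L)
    utils::write.table(
      data.frame(rank = seq_len(100L), mrmr = fs$mrmr_top,
                 mic = fs$mic_top, deg = fs$deg_top),
      out("feature_lists.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(fs$intersection, out("feature_intersection.txt"))
    sig_x <- t(cohort$expression[fs$intersection, , drop = FALSE])
    cv <- stratified_cv_evaluate(sig_x, labels, base_seed = config$seed)
    utils::write.table(cv$folds, out("cv_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  invisible(list(cohort = cohort, de_group = de_group, de_sub = de_sub,
                 soft_threshold_full = sft_full, modules_full = modules_full,
                 soft_threshold = sft, modules = modules,
                 module_trait = mt, keep = keep, network = network,
                 drivers = scores, signature = signature,
                 perturbation = pdb, connectivity = conn,
                 features = fs, cv = cv))
}
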