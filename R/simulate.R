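#' Configuration for the synthetic discovery cohort
#'
#' Builds the parameter set of the linear-Gaussian factor model used to
#' generate discovery-cohort-like data with known ground truth. The default
#' cohort layout mirrors a serum-stimulation study: 47 AMI and 20 control
#' macrophage transcriptomes, with the AMI arm split into 23 Small and
#' 24 Large infarct-size subgroups.
#'
#' The generative model: each module m has a per-sample latent factor
#' f_m ~ N(0,1) + group_shift_m for AMI samples + subgroup_shift_m for Large
#' samples. A planted transcription factor for module m has expression
#' `tf_signal * f_m + N(0, noise_sd)`; each module gene i has expression
#' `lambda_i * f_m + N(0, noise_sd)` with loading lambda_i drawn uniformly
#' from `loading_range`; background genes are pure N(0,1). Clinical traits
#' are calibrated linear functions of their linked module factor (measured
#' on AMI samples only); functional readouts are linear functions of
#' designated module factors plus unit noise. All expression values are
#' finally mapped to a plausible log2 scale (`6 + 2 * value`).
#'
#' @param n_genes Total genes in the universe (transcription factors and
#'   module genes included).
#' @param n_ami,n_ctrl AMI and control sample counts.
#' @param n_small,n_large Split of the AMI arm into infarct-size subgroups;
#'   must sum to `n_ami`.
#' @param n_modules Number of planted co-expression modules.
#' @param module_sizes Integer vector of module gene counts (length
#'   `n_modules`, excluding the planted TF itself).
#' @param loading_range Range of gene loadings on the module factor.
#' @param group_shift Numeric, per module: shift of the module factor in AMI
#'   vs control samples, in factor-SD units.
#' @param subgroup_shift Numeric, per module: shift of the factor in Large vs
#'   Small AMI samples.
#' @param trait_couplings data.frame with columns `trait`, `module`, `r`:
#'   each clinical trait is coupled to one module factor at the target
#'   Pearson correlation `r` (|r| < 1).
#' @param n_tfs Number of planted transcription factors (one per module when
#'   equal to `n_modules`; assigned round-robin otherwise).
#' @param targets_per_tf Number of module genes recorded as regulon members
#'   of the module's TF in the ground truth.
#' @param tf_signal Coefficient of the module factor in the TF's expression.
#' @param n_drugs,n_reversers Perturbation-database size and number of
#'   planted signature-reversing drugs.
#' @param reverser_gain Magnitude of the z-score shift a reverser applies to
#'   signature genes (down-shifts up-genes, up-shifts down-genes).
#' @param noise_sd Residual SD of module-gene and TF expression.
#' @param prob_female Probability a sample is female; sex is independent of
#'   every signal unless `confound_sex` is set.
#' @param confound_sex If TRUE, sex is assigned by thresholding the first
#'   module factor, creating a deliberate confound for sensitivity checks.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000L,
                             n_ami = 47L, n_ctrl = 20L,
                             n_small = 23L, n_large = 24L,
                             n_modules = 5L,
                             module_sizes = c(100L, 90L, 80L, 70L, 60L),
                             loading_range = c(0.4, 0.9),
                             group_shift = c(1, 1, 1, 0, 0),
                             subgroup_shift = c(0, 0, 0, 1.5, -1.5),
                             trait_couplings = data.frame(
                               trait = c("infarct_size", "ejection_fraction",
                                         "edv"),
                               module = c(4L, 5L, 4L),
                               r = c(0.6, 0.6, 0.6)),
                             n_tfs = 5L,
                             targets_per_tf = 30L,
                             tf_signal = 1,
                             n_drugs = 100L,
                             n_reversers = 3L,
                             reverser_gain = 3,
                             noise_sd = 0.5,
                             prob_female = 0.5,
                             confound_sex = FALSE,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_ami = as.integer(n_ami),
              n_ctrl = as.integer(n_ctrl), n_small = as.integer(n_small),
              n_large = as.integer(n_large), n_modules = as.integer(n_modules),
              module_sizes = as.integer(module_sizes),
              loading_range = loading_range,
              group_shift = rep_len(group_shift, n_modules),
              subgroup_shift = rep_len(subgroup_shift, n_modules),
              trait_couplings = trait_couplings,
              n_tfs = as.integer(n_tfs),
              targets_per_tf = as.integer(targets_per_tf),
              tf_signal = tf_signal,
              n_drugs = as.integer(n_drugs),
              n_reversers = as.integer(n_reversers),
              reverser_gain = reverser_gain,
              noise_sd = noise_sd,
              prob_female = prob_female,
              confound_sex = isTRUE(confound_sex),
              seed = as.integer(seed))
  if (cfg$n_small + cfg$n_large != cfg$n_ami)
    stop("n_small + n_large must equal n_ami")
  if (length(cfg$module_sizes) != cfg$n_modules)
    stop("module_sizes must have length n_modules")
  if (sum(cfg$module_sizes) + cfg$n_tfs > cfg$n_genes)
    stop("module sizes plus TFs exceed n_genes")
  if (any(!is.finite(c(cfg$group_shift, cfg$subgroup_shift))))
    stop("shifts must be finite")
  if (any(abs(cfg$trait_couplings$r) >= 1))
    stop("trait correlation targets must satisfy |r| < 1")
  if (cfg$n_reversers > cfg$n_drugs)
    stop("n_reversers cannot exceed n_drugs")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic discovery cohort with known ground truth
#'
#' Draws one cohort from the factor model described in [synthetic_config()].
#' The returned ground truth (`truth`) records which gene belongs to which
#' planted module, which TF regulates which module, and which trait is
#' coupled to which module, so that every pipeline stage has a recovery
#' oracle.
#'
#' @param config A [synthetic_config()] object.
#' @return A list with elements `expression` (genes x samples log2 matrix),
#'   `meta` (sample metadata data.frame), `traits` (clinical trait table for
#'   AMI samples), `functional` (Macroscreen-like readout table for all
#'   samples), and `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n_s <- config$n_ami + config$n_ctrl
  sample_ids <- c(sprintf("CTRL_%02d", seq_len(config$n_ctrl)),
                  sprintf("AMI_%02d", seq_len(config$n_ami)))
  group <- rep(c("control", "AMI"), c(config$n_ctrl, config$n_ami))
  subgroup <- rep("none", n_s)
  subgroup[group == "AMI"] <- rep(c("Small", "Large"),
                                  c(config$n_small, config$n_large))
  is_ami <- group == "AMI"
  is_large <- subgroup == "Large"

  k <- config$n_modules
  factors <- matrix(stats::rnorm(k * n_s), nrow = k)
  factors <- factors + config$group_shift %o% as.numeric(is_ami) +
    config$subgroup_shift %o% as.numeric(is_large)
  rownames(factors) <- paste0("M", seq_len(k))

  tf_ids <- sprintf("TF%02d", seq_len(config$n_tfs))
  tf_module <- rep_len(seq_len(k), config$n_tfs)
  gene_ids <- c(tf_ids, sprintf("G%05d", seq_len(config$n_genes - config$n_tfs)))
  x <- matrix(stats::rnorm(config$n_genes * n_s), nrow = config$n_genes,
              dimnames = list(gene_ids, sample_ids))

  module_of_gene <- stats::setNames(rep("background", config$n_genes), gene_ids)
  loadings <- stats::setNames(rep(NA_real_, config$n_genes), gene_ids)
  regulator_of_module <- stats::setNames(vector("list", k), rownames(factors))
  targets_of_tf <- stats::setNames(vector("list", config$n_tfs), tf_ids)

  for (t in seq_len(config$n_tfs)) {
    m <- tf_module[t]
    x[tf_ids[t], ] <- config$tf_signal * factors[m, ] +
      stats::rnorm(n_s, sd = config$noise_sd)
    module_of_gene[tf_ids[t]] <- rownames(factors)[m]
    regulator_of_module[[m]] <- c(regulator_of_module[[m]], tf_ids[t])
  }

  offset <- config$n_tfs
  for (m in seq_len(k)) {
    idx <- offset + seq_len(config$module_sizes[m])
    lam <- stats::runif(config$module_sizes[m],
                        config$loading_range[1], config$loading_range[2])
    x[idx, ] <- lam %o% factors[m, ] +
      matrix(stats::rnorm(length(idx) * n_s, sd = config$noise_sd),
             nrow = length(idx))
    module_of_gene[idx] <- rownames(factors)[m]
    loadings[idx] <- lam
    tf_here <- tf_ids[tf_module == m]
    for (tf in tf_here) {
      tg <- gene_ids[idx][seq_len(min(config$targets_per_tf, length(idx)))]
      targets_of_tf[[tf]] <- tg
    }
    offset <- offset + config$module_sizes[m]
  }

  # clinical traits: AMI samples only, calibrated to the target correlation
  ami_ids <- sample_ids[is_ami]
  traits <- data.frame(sample_id = ami_ids, stringsAsFactors = FALSE)
  trait_units <- list(infarct_size = c(20, 10), ejection_fraction = c(50, 8),
                      edv = c(160, 30))
  for (i in seq_len(nrow(config$trait_couplings))) {
    tc <- config$trait_couplings[i, ]
    f <- factors[tc$module, is_ami]
    z <- (f - mean(f)) / stats::sd(f)
    raw <- tc$r * z + sqrt(1 - tc$r^2) * stats::rnorm(length(z))
    u <- trait_units[[tc$trait]]
    if (is.null(u)) u <- c(0, 1)
    traits[[tc$trait]] <- u[1] + u[2] * raw
  }

  # Macroscreen-like functional readouts, driven by the group-shifted factors
  readout_names <- c("phagocytosis", "lipid_uptake", "apoptosis",
                     "hypertrophy", "morphology", "actin_stress",
                     "granularity", "inflammasome", "cytokines")
  shifted <- which(config$group_shift != 0)
  if (length(shifted) == 0L) shifted <- 1L
  functional <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  for (j in seq_along(readout_names)) {
    m <- shifted[((j - 1L) %% length(shifted)) + 1L]
    functional[[readout_names[j]]] <- factors[m, ] + stats::rnorm(n_s)
  }

  sex <- if (config$confound_sex) {
    ifelse(factors[1, ] > stats::median(factors[1, ]), "F", "M")
  } else {
    sample(c("F", "M"), n_s, replace = TRUE,
           prob = c(config$prob_female, 1 - config$prob_female))
  }
  meta <- data.frame(sample_id = sample_ids, group = group,
                     subgroup = subgroup, sex = sex,
                     stringsAsFactors = FALSE)

  expr <- 6 + 2 * x

  truth <- list(
    module_of_gene = module_of_gene,
    loadings = loadings,
    regulator_of_module = regulator_of_module,
    targets_of_tf = targets_of_tf,
    trait_module_links = stats::setNames(
      paste0("M", config$trait_couplings$module), config$trait_couplings$trait),
    trait_target_r = stats::setNames(config$trait_couplings$r,
                                     config$trait_couplings$trait),
    factors = factors,
    reverser_drugs = character(0))

  list(expression = expr, meta = meta, traits = traits,
       functional = functional, truth = truth)
}

#' Generate a synthetic perturbation-profile database
#'
#' Emulates a cell-line perturbation compendium: each drug contributes a
#' per-gene differential z-score profile over the cohort's gene universe.
#' Planted "reverser" drugs shift signature up-genes down by
#' `reverser_gain` and signature down-genes up, on top of unit Gaussian
#' noise; decoy drugs are pure noise. Uses `config$seed + 1000` so that the
#' database stream is independent of the cohort stream.
#'
#' @param config A [synthetic_config()] object.
#' @param signature A signature (list with `up` and `down` gene id vectors),
#'   e.g. from [build_signature()].
#' @param gene_ids The gene universe over which profiles are generated.
#' @return A list with `db` (data.frame: drug, cell_type, dose, duration,
#'   then one z-score column per gene) and `reversers` (planted drug ids).
#' @export
generate_perturbation_db <- function(config, signature, gene_ids) {
  stopifnot(inherits(config, "synthetic_config"))
  if (length(signature$up) + length(signature$down) == 0L)
    stop("signature is empty")
  if (config$n_reversers > config$n_drugs)
    stop("n_reversers cannot exceed n_drugs")
  set.seed(config$seed + 1000L)
  drug_ids <- sprintf("DRUG_%03d", seq_len(config$n_drugs))
  reversers <- if (config$n_reversers > 0L)
    sort(sample(drug_ids, config$n_reversers)) else character(0)
  z <- matrix(stats::rnorm(config$n_drugs * length(gene_ids)),
              nrow = config$n_drugs,
              dimnames = list(drug_ids, gene_ids))
  up <- intersect(signature$up, gene_ids)
  dn <- intersect(signature$down, gene_ids)
  for (d in reversers) {
    z[d, up] <- z[d, up] - config$reverser_gain
    z[d, dn] <- z[d, dn] + config$reverser_gain
  }
  db <- data.frame(drug = drug_ids,
                   cell_type = "THP1",
                   dose = sample(c("0.1 uM", "1 uM", "10 uM"),
                                 config$n_drugs, replace = TRUE),
                   duration = sample(c("6 h", "24 h"),
                                     config$n_drugs, replace = TRUE),
                   stringsAsFactors = FALSE)
  db <- cbind(db, as.data.frame(z, check.names = FALSE))
  rownames(db) <- NULL
  list(db = db, reversers = reversers)
}
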