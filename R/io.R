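#' Read an expression matrix from a TSV file
#'
#' Reads a tab-separated table with a header row of identifiers and a first
#' column of identifiers, and returns a numeric matrix oriented genes x
#' samples. Values are expected on the log2 scale; missing, empty or
#' non-numeric cells are a hard error (no imputation is ever attempted).
#'
#' @param path Path to a TSV file.
#' @param orientation Either `"genes_by_samples"` (rows are genes, the
#'   default) or `"samples_by_genes"` (the file is transposed on read).
#' @return A numeric matrix, genes in rows and samples in columns, with
#'   rownames and colnames set to the identifiers found in the file.
#' @seealso [write_expression()]
#' @export
read_expression <- function(path,
                            orientation = c("genes_by_samples",
                                            "samples_by_genes")) {
  orientation <- match.arg(orientation)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           na.strings = NULL)
  if (ncol(tab) < 2L)
    stop("expression file must have an id column and at least one data column")
  row_ids <- tab[[1L]]
  body <- as.matrix(tab[, -1L, drop = FALSE])
  col_ids <- colnames(body)
  if (anyDuplicated(row_ids))
    stop("duplicate row ids: ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  if (anyDuplicated(col_ids))
    stop("duplicate column ids: ",
         paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "))
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric or missing value at row '%s', column '%s'",
                 row_ids[bad[1L, 1L]], col_ids[bad[1L, 2L]]))
  dimnames(num) <- list(row_ids, col_ids)
  if (orientation == "samples_by_genes") num <- t(num)
  validate_expression(num)
  num
}

#' Write an expression matrix to TSV
#'
#' @param x Numeric matrix, genes x samples, with dimnames.
#' @param path Output path.
#' @export
write_expression <- function(x, path) {
  validate_expression(x)
  df <- data.frame(gene = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Enforce the expression-matrix contract shared by every downstream stage.
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry gene and sample ids as dimnames")
  if (anyDuplicated(rownames(x))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids")
  if (anyNA(x)) stop("expression matrix contains missing values")
  invisible(TRUE)
}

#' Read gene sets in GMT format
#'
#' Each line holds a set name, a description and tab-separated member ids.
#' Members are deduplicated preserving first occurrence; duplicate set names
#' are an error.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    nm <- fields[[1L]]
    if (nm %in% names(sets)) stop("duplicate set name: ", nm)
    sets[[nm]] <- unique(fields[-(1:2)])
  }
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a regulatory network as a TSV edge list
#'
#' Columns are regulator, target, weight (mutual information, nats) and
#' support (bootstrap fraction). Weights are printed with full precision so
#' that a write/read round trip preserves them to well under 1e-9.
#'
#' @param network A `regulatory_network` object (see [infer_grn()]).
#' @param path Output path.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "regulatory_network"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV edge list back into a regulatory network
#'
#' @param path Path to a TSV written by [write_edge_list()].
#' @param tf_list Optional regulator universe; defaults to the regulators
#'   present in the file.
#' @return A `regulatory_network` object.
#' @export
read_edge_list <- function(path, tf_list = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("regulator", "target", "weight", "support")
  if (!all(need %in% colnames(df)))
    stop("edge list must have columns: ", paste(need, collapse = ", "))
  if (is.null(tf_list)) tf_list <- unique(df$regulator)
  regulatory_network(df[, need], tf_list = tf_list)
}

#' Read a sample metadata table
#'
#' TSV with columns `sample_id`, `group` (control/AMI), `subgroup`
#' (Small/Large/none) and `sex` (M/F/unknown).
#'
#' @param path Path to TSV file.
#' @return A data.frame.
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "subgroup", "sex")
  if (!all(need %in% colnames(meta)))
    stop("sample metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample ids in metadata")
  bad <- meta$subgroup != "none" & meta$group != "AMI"
  if (any(bad))
    stop("subgroup labels are only valid for AMI samples: ",
         paste(meta$sample_id[bad], collapse = ", "))
  meta
}

#' Read a clinical trait table
#'
#' CSV with a `sample_id` column and one numeric column per trait
#' (e.g. infarct size %, ejection fraction %, end-diastolic volume mL).
#'
#' @param path Path to CSV file.
#' @return A data.frame with `sample_id` plus numeric trait columns.
#' @export
read_trait_table <- function(path) {
  tr <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(tr))
    stop("trait table must have a sample_id column")
  num <- tr[setdiff(colnames(tr), "sample_id")]
  if (!all(vapply(num, is.numeric, logical(1))))
    stop("all trait columns must be numeric")
  if (any(!vapply(num, function(v) all(is.finite(v)), logical(1))))
    stop("trait table contains non-finite values")
  tr
}

#' Read a candidate transcription-factor list
#'
#' Plain text, one gene symbol per line; blank lines ignored.
#'
#' @param path Path to a text file.
#' @return Character vector of unique TF symbols.
#' @export
read_tf_list <- function(path) {
  tfs <- readLines(path, warn = FALSE)
  unique(trimws(tfs[nzchar(trimws(tfs))]))
}

#' Z-score functional readouts across samples
#'
#' Standardizes each functional readout (phagocytosis, lipid uptake,
#' apoptosis, hypertrophy, morphology, actin stress, granularity,
#' inflammasome, cytokines, ...) separately over samples, using the sample
#' standard deviation (n-1 denominator). A zero-variance readout is an error.
#'
#' @param profiles data.frame with a `sample_id` column and one numeric
#'   column per readout.
#' @return The same data.frame with each readout column standardized to
#'   mean 0 and unit sample variance.
#' @export
zscore_by_readout <- function(profiles) {
  if (!"sample_id" %in% colnames(profiles))
    stop("functional profiles must have a sample_id column")
  if (nrow(profiles) < 2L) stop("need at least 2 samples to z-score")
  readouts <- setdiff(colnames(profiles), "sample_id")
  for (r in readouts) {
    v <- profiles[[r]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) stop("zero variance in readout: ", r)
    profiles[[r]] <- (v - mean(v)) / s
  }
  profiles
}
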