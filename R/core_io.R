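#' Convert methylated/unmethylated intensities to a beta value
#'
#' The methylation fraction at a CpG is computed from the methylated (M) and
#' unmethylated (U) fluorescence intensities as
#' \deqn{\beta = \max(M,0) / (\max(M,0) + \max(U,0) + 100).}
#' Negative intensities (possible after background correction) are clamped to
#' zero; the +100 offset regularizes low-intensity probes, so the result lies
#' in \[0, 1).
#'
#' @param M Numeric vector of methylated signal intensities.
#' @param U Numeric vector of unmethylated signal intensities (recycled
#'   against `M`).
#' @return Numeric vector of beta values in \[0, 1).
#' @examples
#' compute_beta(100, 0)    # 0.5
#' compute_beta(-50, 300)  # 0: negative M clamps to zero
#' @export
compute_beta <- function(M, U) {
  if (!is.numeric(M) || !is.numeric(U)) {
    stop("compute_beta: M and U must be numeric")
  }
  if (any(!is.finite(M)) || any(!is.finite(U))) {
    stop("compute_beta: non-finite intensity")
  }
  Mp <- pmax(M, 0)
  Up <- pmax(U, 0)
  Mp / (Mp + Up + 100)
}

#' Construct a beta-value matrix container
#'
#' A `BetaMatrix` is a CpG-by-sample matrix of methylation fractions with
#' unique row (CpG) and column (sample) identifiers, all values finite and in
#' \[0, 1\].
#'
#' @param values Numeric matrix, rows = CpGs, columns = samples.
#' @param cpg_ids Character vector of unique CpG identifiers (defaults to
#'   rownames of `values`).
#' @param sample_ids Character vector of unique sample identifiers (defaults
#'   to colnames of `values`).
#' @return An object of class `BetaMatrix` (a numeric matrix with dimnames).
#' @export
beta_matrix <- function(values, cpg_ids = rownames(values),
                        sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cpg_ids) || is.null(sample_ids)) {
    stop("beta_matrix: cpg_ids and sample_ids are required")
  }
  cpg_ids <- as.character(cpg_ids)
  sample_ids <- as.character(sample_ids)
  if (length(cpg_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("beta_matrix: id lengths do not match matrix dimensions")
  }
  if (anyDuplicated(cpg_ids)) {
    stop("beta_matrix: duplicate CpG ids: ",
         paste(unique(cpg_ids[duplicated(cpg_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("beta_matrix: duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (any(!is.finite(values))) {
    stop("beta_matrix: missing or non-finite beta values are not allowed")
  }
  bad <- which(values < 0 | values > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    msg <- apply(utils::head(bad, 5), 1L, function(idx) {
      sprintf("[%s, %s] = %g", cpg_ids[idx[1L]], sample_ids[idx[2L]],
              values[idx[1L], idx[2L]])
    })
    stop("beta_matrix: values outside [0, 1]: ", paste(msg, collapse = "; "))
  }
  dimnames(values) <- list(cpg_ids, sample_ids)
  class(values) <- c("BetaMatrix", "matrix", "array")
  values
}

#' @export
print.BetaMatrix <- function(x, ...) {
  cat(sprintf("BetaMatrix: %d CpGs x %d samples\n", nrow(x), ncol(x)))
  cat(sprintf("  beta range: [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' Read a beta-value matrix from delimited text
#'
#' First column holds CpG identifiers, header row holds sample identifiers.
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter (default tab).
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("read_beta_matrix: file not found: ", path)
  dt <- data.table::fread(path, sep = delimiter, header = TRUE,
                          data.table = FALSE, colClasses = list(character = 1))
  if (ncol(dt) < 2) stop("read_beta_matrix: no sample columns in ", path)
  vals <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  beta_matrix(vals, cpg_ids = dt[[1]], sample_ids = colnames(dt)[-1])
}

#' Write a beta-value matrix to delimited text
#'
#' Values are printed with enough digits for a lossless read/write round trip.
#'
#' @param beta A [beta_matrix()].
#' @param path Output path.
#' @param delimiter Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path, delimiter = "\t") {
  dt <- data.table::data.table(cpg_id = rownames(beta))
  for (s in colnames(beta)) dt[[s]] <- unname(beta[, s])
  data.table::fwrite(dt, path, sep = delimiter)
  invisible(path)
}

.sheet_required_cols <- c("sample_id", "individual_id", "region", "lobe",
                          "diagnosis", "age", "sex")
.sheet_optional_cols <- c("bank", "cag_length", "vonsattel_grade",
                          "onset_age", "prop_neurons", "postmortem_interval")

#' Map a brain region label to its broad lobe category
#'
#' Regions are grouped into broader lobes: the parietal lobe comprises
#' parietal cortex and sensory cortex; the frontal lobe comprises frontal
#' regions and motor cortex; the occipital lobe comprises occipital cortex and
#' visual cortex. Any other region maps to `"other"`.
#'
#' @param region Character vector of region labels.
#' @return Character vector over `{frontal, parietal, occipital, other}`.
#' @export
region_to_lobe <- function(region) {
  r <- tolower(trimws(as.character(region)))
  out <- rep("other", length(r))
  out[grepl("parietal|sensory", r)] <- "parietal"
  out[grepl("frontal|motor", r)] <- "frontal"
  out[grepl("occipital|visual", r)] <- "occipital"
  out
}

#' Read and validate a sample sheet
#'
#' Required columns: sample_id, individual_id, region, lobe, diagnosis, age,
#' sex. Optional: bank, cag_length, vonsattel_grade, onset_age, prop_neurons,
#' postmortem_interval. Missing values in optional columns are preserved.
#' Soft invariants (HD rows with CAG < 36, prop_neurons outside \[0,1\])
#' raise warnings, not errors.
#'
#' @param path Path to a delimited file.
#' @param delimiter Field delimiter (default tab).
#' @return A `data.frame` with class `SampleSheet`.
#' @export
read_sample_sheet <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("read_sample_sheet: file not found: ", path)
  df <- data.table::fread(path, sep = delimiter, header = TRUE,
                          data.table = FALSE)
  sample_sheet(df)
}

#' Validate a data.frame as a sample sheet
#'
#' @param df A data.frame with the sample-sheet columns.
#' @return `df` with class `SampleSheet` prepended.
#' @export
sample_sheet <- function(df) {
  missing_cols <- setdiff(.sheet_required_cols, names(df))
  if (length(missing_cols) > 0) {
    stop("sample sheet: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  df$individual_id <- as.character(df$individual_id)
  if (anyDuplicated(df$sample_id)) {
    stop("sample sheet: duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  df$age <- as.numeric(df$age)
  if (any(!is.finite(df$age)) || any(df$age <= 0)) {
    stop("sample sheet: age must be present and > 0 for every sample")
  }
  if (!all(df$diagnosis %in% c("HD", "AD", "control"))) {
    stop("sample sheet: diagnosis must be one of HD, AD, control")
  }
  if (!all(df$sex %in% c("F", "M"))) {
    stop("sample sheet: sex must be F or M")
  }
  if ("cag_length" %in% names(df)) {
    bad <- which(df$diagnosis == "HD" & !is.na(df$cag_length) &
                   df$cag_length < 36)
    if (length(bad) > 0) {
      warning("sample sheet: HD sample(s) with cag_length < 36: ",
              paste(df$sample_id[bad], collapse = ", "))
    }
  }
  if ("prop_neurons" %in% names(df)) {
    pn <- df$prop_neurons
    if (any(!is.na(pn) & (pn < 0 | pn > 1))) {
      stop("sample sheet: prop_neurons outside [0, 1]")
    }
  }
  for (col in setdiff(.sheet_optional_cols, names(df))) df[[col]] <- NA
  class(df) <- c("SampleSheet", "data.frame")
  df
}

#' Align a beta matrix with a sample sheet
#'
#' Restricts and orders both objects to the intersection of sample ids (order
#' taken from the beta matrix) and reports dropped ids.
#'
#' @param beta A [beta_matrix()].
#' @param sheet A `SampleSheet`.
#' @return List with `beta`, `sheet` (aligned, same sample order),
#'   `dropped_beta`, `dropped_sheet`.
#' @export
align_samples <- function(beta, sheet) {
  common <- intersect(colnames(beta), sheet$sample_id)
  if (length(common) == 0) {
    stop("align_samples: no overlapping sample ids")
  }
  keep <- colnames(beta)[colnames(beta) %in% common]
  b2 <- beta[, keep, drop = FALSE]
  class(b2) <- class(beta)
  s2 <- sheet[match(keep, sheet$sample_id), , drop = FALSE]
  rownames(s2) <- NULL
  list(beta = b2,
       sheet = s2,
       dropped_beta = setdiff(colnames(beta), common),
       dropped_sheet = setdiff(sheet$sample_id, common))
}

#' Read a CpG annotation table
#'
#' Expected columns: cpg_id, gene_symbol (may be empty), chromosome, position.
#'
#' @param path Path to a delimited file.
#' @param delimiter Field delimiter (default tab).
#' @return A `data.frame` with one row per CpG.
#' @export
read_cpg_annotation <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("read_cpg_annotation: file not found: ", path)
  df <- data.table::fread(path, sep = delimiter, header = TRUE,
                          data.table = FALSE)
  need <- c("cpg_id", "gene_symbol", "chromosome", "position")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("annotation: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$cpg_id <- as.character(df$cpg_id)
  if (anyDuplicated(df$cpg_id)) stop("annotation: duplicate cpg_id")
  df$gene_symbol <- as.character(df$gene_symbol)
  df$gene_symbol[is.na(df$gene_symbol)] <- ""
  df
}

#' Write a generic TSV table
#' @param df A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
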