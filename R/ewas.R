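#' Filter CpGs by variance across lobes
#'
#' A CpG is retained when its sample variance reaches `threshold` in at
#' least one lobe. Default threshold 5e-4 in beta-value units squared.
#'
#' @param beta_list Named list of CpG-by-sample beta matrices, one per lobe,
#'   with identical row sets.
#' @param threshold Minimum variance (default `5e-4`).
#' @return List with `keep` (character vector of retained CpG ids),
#'   `n_kept`, `n_dropped`.
#' @export
variance_filter <- function(beta_list, threshold = 5e-4) {
  if (length(beta_list) < 1 || any(vapply(beta_list, nrow, 1L) == 0)) {
    stop("variance_filter: empty input")
  }
  ids <- rownames(beta_list[[1]])
  pass <- rep(FALSE, length(ids))
  for (b in beta_list) {
    b <- b[ids, , drop = FALSE]
    n <- ncol(b)
    v <- (rowSums(b^2) - n * rowMeans(b)^2) / (n - 1)
    pass <- pass | (v >= threshold)
  }
  list(keep = ids[pass], n_kept = sum(pass), n_dropped = sum(!pass))
}

#' Residualize methylation on age and sex
#'
#' Per CpG, retains the least-squares residuals of beta values regressed on
#' chronological age and a sex indicator. Residuals have zero mean and zero
#' sample covariance with both covariates. In a single-sex stratum the sex
#' term is dropped with a warning.
#'
#' @param beta CpG-by-sample matrix.
#' @param sheet `SampleSheet` aligned to `beta`'s columns.
#' @return Residualized matrix with the same dimnames.
#' @export
adjust_age_sex <- function(beta, sheet) {
  sheet <- sheet[match(colnames(beta), sheet$sample_id), , drop = FALSE]
  if (any(is.na(sheet$age))) stop("adjust_age_sex: missing age")
  X <- cbind(1, sheet$age)
  if (length(unique(sheet$sex)) > 1) {
    X <- cbind(X, as.integer(sheet$sex == "F"))
  } else {
    warning("adjust_age_sex: single-sex stratum; sex term dropped")
  }
  # residual maker applied to all CpGs at once: R = B - B X (X'X)^-1 X'
  bt <- t(as.matrix(beta))
  fit <- stats::lm.fit(X, bt)
  res <- t(fit$residuals)
  dimnames(res) <- dimnames(beta)
  res
}

#' Per-lobe EWAS of HD status
#'
#' Kruskal-Wallis test of HD versus control per CpG on (typically age/sex
#' residualized) methylation values, with the effect direction taken as the
#' sign of the HD-minus-control median difference (ties resolved to +1).
#' AD samples, if present, are excluded.
#'
#' @param resid CpG-by-sample matrix (residualized beta values).
#' @param diagnosis Diagnosis label per column (`HD` / `control` / `AD`).
#' @param min_group Minimum group size; CpGs are skipped (NA) when a group
#'   is smaller (default 3, applied once since group sizes are shared).
#' @return `data.frame` with cpg_id, statistic, p_value, direction.
#' @export
ewas_per_lobe <- function(resid, diagnosis, min_group = 3) {
  use <- diagnosis %in% c("HD", "control")
  resid <- resid[, use, drop = FALSE]
  diagnosis <- diagnosis[use]
  n_hd <- sum(diagnosis == "HD")
  n_ct <- sum(diagnosis == "control")
  if (n_hd == 0 || n_ct == 0) {
    stop("ewas_per_lobe: need both HD and control samples")
  }
  if (min(n_hd, n_ct) < min_group) {
    stop("ewas_per_lobe: group size below ", min_group)
  }
  is_hd <- diagnosis == "HD"
  out <- data.frame(cpg_id = rownames(resid), statistic = NA_real_,
                    p_value = NA_real_, direction = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(resid))) {
    x <- resid[i, ]
    kw <- kruskal_wallis(x, is_hd)
    d <- sign(stats::median(x[is_hd]) - stats::median(x[!is_hd]))
    out$statistic[i] <- kw$statistic
    out$p_value[i] <- kw$p_value
    out$direction[i] <- if (d == 0) 1L else as.integer(d)
  }
  out
}

#' Signed z-score from a two-sided p-value
#'
#' Inverse-normal transformation `z = direction * qnorm(1 - p/2)`,
#' underflow-safe for extremely small p.
#'
#' @param p Two-sided p-values in (0, 1].
#' @param direction Effect directions, +1 or -1.
#' @return Signed z-scores.
#' @export
p_to_signed_z <- function(p, direction) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p_to_signed_z: p must lie in (0, 1]")
  }
  if (!all(direction %in% c(-1, 1))) {
    stop("p_to_signed_z: direction must be +1 or -1")
  }
  direction * stats::qnorm(p / 2, lower.tail = FALSE)
}

#' Stouffer meta-analysis of signed z-scores
#'
#' Combines per-lobe signed z-scores as `Z = sum(z) / sqrt(N)`; under the
#' null Z is approximately standard normal, and the meta p-value is the
#' two-sided normal tail `2 * pnorm(-|Z|)`.
#'
#' @param z Numeric vector of finite signed z-scores (one per data set).
#' @return List with `z` (meta Z) and `p_value`.
#' @export
stouffer_meta <- function(z) {
  z <- z[is.finite(z)]
  if (length(z) == 0) stop("stouffer_meta: no finite z-scores")
  Z <- sum(z) / sqrt(length(z))
  list(z = Z, p_value = 2 * stats::pnorm(-abs(Z)))
}

#' Genomic inflation factor of a p-value set
#'
#' Median-based lambda: each p-value is back-transformed to a 1-df
#' chi-square statistic and the median is divided by the null median
#' `qchisq(0.5, 1) = 0.4549`. Lambda near 1 indicates well-calibrated
#' statistics; values substantially above 1 indicate inflation.
#'
#' @param p P-values in (0, 1].
#' @return Lambda (scalar).
#' @export
inflation_lambda <- function(p) {
  if (any(p <= 0 | p > 1, na.rm = TRUE)) {
    stop("inflation_lambda: p must lie in (0, 1]")
  }
  p <- p[!is.na(p)]
  if (length(p) < 100) {
    warning("inflation_lambda: fewer than 100 p-values; estimate is noisy")
  }
  chisq <- stats::qnorm(p / 2, lower.tail = FALSE)^2
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param m Number of tests (>= 1). The CpG-level default used throughout
#'   the package is 500000 regardless of the number actually tested, the
#'   conservative array-scale convention; pass the real count to override.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 500000) {
  if (m < 1) stop("bonferroni_threshold: m must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("bonferroni_threshold: alpha in (0,1)")
  alpha / m
}

#' Run the full per-lobe EWAS plus Stouffer meta-analysis
#'
#' Applies the variance filter across lobes, residualizes each lobe on age
#' and sex, runs the Kruskal-Wallis EWAS per lobe, converts each (p,
#' direction) to a signed z and combines across lobes with Stouffer's
#' method. Meta p-values are descriptive (repeated samples per individual
#' are not modeled).
#'
#' @param beta_list Named list of beta matrices, one per lobe.
#' @param sheet `SampleSheet` covering all samples.
#' @param variance_threshold Variance filter threshold (default 5e-4).
#' @return List with `per_lobe` (named list of per-lobe data.frames),
#'   `meta` (data.frame: cpg_id, per-lobe z columns, z_meta, p_meta,
#'   n_sets), `lambda` (named per-lobe + meta inflation factors),
#'   `n_kept`, `n_dropped`.
#' @export
run_ewas <- function(beta_list, sheet, variance_threshold = 5e-4) {
  vf <- variance_filter(beta_list, variance_threshold)
  if (vf$n_kept == 0) stop("run_ewas: variance filter removed every CpG")
  per_lobe <- list()
  zmat <- NULL
  for (lobe in names(beta_list)) {
    b <- beta_list[[lobe]][vf$keep, , drop = FALSE]
    al <- align_samples(beta_matrix(b), sheet)
    res <- adjust_age_sex(al$beta, al$sheet)
    ew <- ewas_per_lobe(res, al$sheet$diagnosis)
    per_lobe[[lobe]] <- ew
    z <- p_to_signed_z(ew$p_value, ew$direction)
    zmat <- cbind(zmat, z)
  }
  colnames(zmat) <- names(beta_list)
  z_meta <- rowSums(zmat) / sqrt(ncol(zmat))
  meta <- data.frame(cpg_id = vf$keep, stringsAsFactors = FALSE)
  for (lobe in names(beta_list)) meta[[paste0("z_", lobe)]] <- zmat[, lobe]
  meta$z_meta <- z_meta
  meta$p_meta <- 2 * stats::pnorm(-abs(z_meta))
  meta$n_sets <- ncol(zmat)
  lambda <- vapply(per_lobe, function(d) inflation_lambda(d$p_value), 1.0)
  lambda <- c(lambda, meta = inflation_lambda(meta$p_meta))
  list(per_lobe = per_lobe, meta = meta, lambda = lambda,
       n_kept = vf$n_kept, n_dropped = vf$n_dropped)
}

#' Export a Manhattan-plot-ready table
#'
#' Orders meta-analysis results by chromosome and position and attaches
#' -log10 p together with the Bonferroni threshold line value. CpGs absent
#' from the annotation are placed in an `"unknown"` bin at the end, with a
#' warning.
#'
#' @param meta Meta-analysis table from [run_ewas()] (`$meta`).
#' @param annotation CpG annotation from [read_cpg_annotation()].
#' @param threshold Horizontal significance line (default
#'   [bonferroni_threshold()] with its defaults).
#' @return `data.frame`: cpg_id, gene_symbol, chromosome, position,
#'   p_meta, neg_log10_p, threshold_line.
#' @export
manhattan_export <- function(meta, annotation,
                             threshold = bonferroni_threshold()) {
  idx <- match(meta$cpg_id, annotation$cpg_id)
  if (any(is.na(idx))) {
    warning("manhattan_export: ", sum(is.na(idx)),
            " CpG(s) missing from annotation; binned as 'unknown'")
  }
  out <- data.frame(cpg_id = meta$cpg_id,
                    gene_symbol = ifelse(is.na(idx), "",
                                         annotation$gene_symbol[idx]),
                    chromosome = ifelse(is.na(idx), "unknown",
                                        as.character(annotation$chromosome[idx])),
                    position = ifelse(is.na(idx), NA_integer_,
                                      annotation$position[idx]),
                    p_meta = meta$p_meta,
                    stringsAsFactors = FALSE)
  out$neg_log10_p <- -log10(out$p_meta)
  out$threshold_line <- -log10(threshold)
  chrom_key <- suppressWarnings(as.integer(sub("^chr", "", out$chromosome)))
  chrom_key[is.na(chrom_key)] <- match(out$chromosome[is.na(chrom_key)],
                                       c("X", "Y", "MT", "unknown")) + 100L
  out[order(chrom_key, out$position, out$cpg_id), , drop = FALSE]
}
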