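#' Kruskal-Wallis rank test
#'
#' Rank-based k-group comparison with the standard tie correction. Used for
#' group tests throughout because it is insensitive to the distribution of
#' methylation levels and to outliers. The H statistic is referred to a
#' chi-square distribution with k - 1 degrees of freedom.
#'
#' @param values Numeric vector.
#' @param groups Group labels (coerced to factor).
#' @return List with `statistic` (H, tie-corrected), `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  k <- nlevels(groups)
  if (k < 2) stop("kruskal_wallis: need at least 2 groups")
  if (any(tabulate(groups) == 0)) stop("kruskal_wallis: empty group")
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ng <- tabulate(groups)
  H <- 12 / (n * (n + 1)) * sum(ng * (rbar - (n + 1) / 2)^2)
  ties <- table(values)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tie_corr == 0) {  # all values identical
    return(list(statistic = 0, df = k - 1, p_value = 1))
  }
  H <- H / tie_corr
  list(statistic = unname(H), df = k - 1,
       p_value = stats::pchisq(H, df = k - 1, lower.tail = FALSE))
}

# Tukey biweight midcovariance weights for one vector, with the maxPOutliers
# cap: each tail's scaling is relaxed so that at most that fraction of
# observations per side is fully down-weighted.
.bicor_prep <- function(x, max_p_outliers = 0.05) {
  med <- stats::median(x)
  madx <- stats::mad(x, constant = 1)
  if (madx == 0) return(NULL)
  u <- (x - med) / (9 * madx)
  if (max_p_outliers < 0.5) {
    qlo <- stats::quantile(x, max_p_outliers, names = FALSE, type = 8)
    qhi <- stats::quantile(x, 1 - max_p_outliers, names = FALSE, type = 8)
    ulo <- (qlo - med) / (9 * madx)
    uhi <- (qhi - med) / (9 * madx)
    if (ulo < -1) u[u < 0] <- u[u < 0] / (-ulo)
    if (uhi > 1)  u[u > 0] <- u[u > 0] / uhi
  }
  w <- (1 - u^2)^2
  w[abs(u) >= 1] <- 0
  v <- (x - med) * w
  v / sqrt(sum(v^2))
}

#' Biweight midcorrelation
#'
#' Robust correlation based on Tukey biweights around the median, with the
#' `max_p_outliers` cap limiting the fraction of each tail that can be fully
#' down-weighted. Falls back to the Spearman rank correlation (with a
#' warning) when either vector has zero median absolute deviation.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param max_p_outliers Maximum fraction of observations per tail treated as
#'   outliers (default 0.05).
#' @return Correlation in \[-1, 1\].
#' @export
bicor <- function(x, y, max_p_outliers = 0.05) {
  if (length(x) != length(y)) stop("bicor: lengths differ")
  if (length(x) < 3) stop("bicor: need length >= 3")
  vx <- .bicor_prep(x, max_p_outliers)
  vy <- .bicor_prep(y, max_p_outliers)
  if (is.null(vx) || is.null(vy)) {
    warning("bicor: zero median absolute deviation; falling back to rank correlation")
    return(stats::cor(x, y, method = "spearman"))
  }
  r <- sum(vx * vy)
  max(-1, min(1, r))
}

#' All-pairs biweight midcorrelation of matrix rows
#'
#' Vectorized version of [bicor()] across the rows of a matrix (CpGs x
#' samples). Rows with zero median absolute deviation are computed by
#' Spearman correlation against all others, with a warning.
#'
#' @param x Numeric matrix; correlations are computed between rows.
#' @param max_p_outliers As in [bicor()].
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
bicor_matrix <- function(x, max_p_outliers = 0.05) {
  x <- as.matrix(x)
  n <- nrow(x)
  V <- matrix(0, n, ncol(x))
  bad <- logical(n)
  for (i in seq_len(n)) {
    v <- .bicor_prep(x[i, ], max_p_outliers)
    if (is.null(v)) bad[i] <- TRUE else V[i, ] <- v
  }
  R <- tcrossprod(V)
  if (any(bad)) {
    warning("bicor_matrix: ", sum(bad),
            " row(s) with zero MAD; using rank correlation for them")
    rk <- t(apply(x, 1, rank))
    rk <- rk - rowMeans(rk)
    nr <- sqrt(rowSums(rk^2))
    nr[nr == 0] <- 1
    Srk <- tcrossprod(rk / nr)
    R[bad, ] <- Srk[bad, ]
    R[, bad] <- Srk[, bad]
  }
  R[R > 1] <- 1
  R[R < -1] <- -1
  diag(R) <- 1
  dimnames(R) <- list(rownames(x), rownames(x))
  R
}

#' Correlation test (robust or Pearson)
#'
#' Computes the correlation and a p-value from the t approximation with
#' n - 2 degrees of freedom applied to r. The same approximation is used for
#' the biweight midcorrelation, standard practice for midcorrelation
#' inference.
#'
#' @param x,y Numeric vectors, length >= 4.
#' @param method `"bicor"` (default) or `"pearson"`.
#' @param max_p_outliers Passed to [bicor()].
#' @return List with `r`, `p_value`, `n`.
#' @export
cor_test <- function(x, y, method = c("bicor", "pearson"),
                     max_p_outliers = 0.05) {
  method <- match.arg(method)
  n <- length(x)
  if (n < 4) stop("cor_test: need n >= 4")
  r <- if (method == "bicor") bicor(x, y, max_p_outliers) else stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- .Machine$double.xmin  # underflow-safe floor
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- max(p, .Machine$double.xmin)
  }
  list(r = r, p_value = p, n = n)
}

#' Principal-component scores of a beta matrix
#'
#' Scores of the top-k right-singular directions of the row-centered
#' (per-CpG centered) matrix: one score vector per sample, mutually
#' orthogonal and ordered by explained variance. Scores are unit-norm
#' singular directions.
#'
#' @param beta CpG-by-sample matrix.
#' @param k Number of components.
#' @return List with `scores` (samples x k), `var_explained` (length-k
#'   fractions of total variance).
#' @export
principal_components <- function(beta, k) {
  if (k <= 0) stop("principal_components: k must be positive")
  x <- as.matrix(beta)
  if (k > min(dim(x))) stop("principal_components: k exceeds matrix rank bound")
  xc <- x - rowMeans(x)
  sv <- svd(xc, nu = 0, nv = k)
  scores <- sv$v[, seq_len(k), drop = FALSE]
  rownames(scores) <- colnames(x)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores,
       var_explained = (sv$d^2 / sum(sv$d^2))[seq_len(k)])
}

#' Multivariate linear models for DNAm age
#'
#' Ordinary least squares of DNAm age on HD status plus covariates, with the
#' categorical reference levels fixed (sex: Male; bank: NewZealand; region:
#' Frontal) so coefficient rows are comparable across runs. Three standard
#' model forms are supported: model 1 (diagnosis + age + sex + bank +
#' region), model 2 (model 1 + prop_neurons), model 3 (model 1 + PC1..PCk).
#' Repeated samples per individual are NOT modeled; a warning notes this
#' acknowledged simplification whenever individuals contribute multiple
#' samples.
#'
#' @param data Per-sample `data.frame` with columns `dnam_age`, `diagnosis`,
#'   `age`, `sex`, and the covariates required by `model`: `bank`, `region`,
#'   `prop_neurons`, `PC1`... as needed. `individual_id` is optional and used
#'   only for the repeated-measures warning.
#' @param model 1, 2 or 3.
#' @param n_pcs Number of PC columns used by model 3 (default 5).
#' @return List with `coefficients` (data.frame: term, estimate, se,
#'   p_value), `n`, `residual_sd`, and the underlying `fit`.
#' @export
fit_dnam_model <- function(data, model = 1, n_pcs = 5) {
  stopifnot(model %in% 1:3)
  data <- as.data.frame(data)
  need <- c("dnam_age", "diagnosis", "age", "sex")
  if (model %in% c(1, 3)) need <- c(need, "bank", "region")
  if (model == 2) need <- c(need, "bank", "region", "prop_neurons")
  if (model == 3) need <- c(need, paste0("PC", seq_len(n_pcs)))
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop("fit_dnam_model: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if ("individual_id" %in% names(data) &&
      anyDuplicated(data$individual_id) > 0) {
    warning("fit_dnam_model: multiple samples per individual are treated as ",
            "independent (no random effects); p-values are descriptive")
  }
  data$hd <- as.integer(data$diagnosis == "HD")
  data$sex <- factor(as.character(data$sex))
  if ("M" %in% levels(data$sex)) data$sex <- stats::relevel(data$sex, "M")
  if ("bank" %in% need) {
    lv <- unique(as.character(data$bank))
    ref <- if ("NewZealand" %in% lv) "NewZealand" else lv[1]
    data$bank <- stats::relevel(factor(data$bank), ref = ref)
  }
  if ("region" %in% need) {
    lv <- unique(as.character(data$region))
    ref <- lv[grepl("frontal", tolower(lv))][1]
    if (is.na(ref)) ref <- lv[1]
    data$region <- stats::relevel(factor(data$region), ref = ref)
  }
  rhs <- c("hd", "age")
  if (nlevels(data$sex) > 1) rhs <- c(rhs, "sex")
  if ("bank" %in% need && nlevels(data$bank) > 1) rhs <- c(rhs, "bank")
  if ("region" %in% need && nlevels(data$region) > 1) rhs <- c(rhs, "region")
  if (model == 2) rhs <- c(rhs, "prop_neurons")
  if (model == 3) rhs <- c(rhs, paste0("PC", seq_len(n_pcs)))
  fml <- stats::as.formula(paste("dnam_age ~", paste(rhs, collapse = " + ")))
  fit <- stats::lm(fml, data = data)
  if (any(is.na(stats::coef(fit)))) {
    stop("fit_dnam_model: rank-deficient design; aliased: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      p_value = sm[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  list(coefficients = coefs, n = nrow(data),
       residual_sd = summary(fit)$sigma, fit = fit)
}

#' Convert an HD coefficient to years of biological age
#'
#' In a model of DNAm age on HD status and chronological age, the increase
#' in biological age attributable to HD is the HD coefficient divided by the
#' chronological-age coefficient.
#'
#' @param hd_coef Coefficient of HD status (years of DNAm age).
#' @param age_coef Coefficient of chronological age (must be > 0).
#' @return Years of biological age.
#' @examples
#' coefficient_to_years(2.06, 0.646)  # ~3.2
#' @export
coefficient_to_years <- function(hd_coef, age_coef) {
  if (!is.finite(hd_coef) || !is.finite(age_coef)) {
    stop("coefficient_to_years: non-finite input")
  }
  if (age_coef <= 0) stop("coefficient_to_years: age_coef must be > 0")
  hd_coef / age_coef
}
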