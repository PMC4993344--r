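#' Age calibration transform of the epigenetic clock
#'
#' Monotone map used to linearize the fast methylation change of development:
#' logarithmic below the adult-age knot, linear above it,
#' \deqn{F(a) = \log(a+1) - \log(A+1) \; (a \le A), \quad
#'       F(a) = (a - A)/(A+1) \; (a > A)}
#' where `A` is `adult_age`. `F` is continuous and strictly increasing with
#' `F(A) = 0`.
#'
#' @param age Chronological age in years; must be > -1.
#' @param adult_age Knot of the transform in years (default 20).
#' @return Transformed age.
#' @seealso [inverse_transform_age()]
#' @export
transform_age <- function(age, adult_age = 20) {
  if (any(!is.finite(age)) || any(age <= -1)) {
    stop("transform_age: age must be finite and > -1")
  }
  ifelse(age <= adult_age,
         log(age + 1) - log(adult_age + 1),
         (age - adult_age) / (adult_age + 1))
}

#' Inverse of the clock age transform
#'
#' @param x Transformed age.
#' @param adult_age Knot of the transform in years (default 20).
#' @return Age in years such that `transform_age(age) == x`.
#' @export
inverse_transform_age <- function(x, adult_age = 20) {
  if (any(!is.finite(x))) stop("inverse_transform_age: non-finite input")
  ifelse(x <= 0,
         (adult_age + 1) * exp(x) - 1,
         x * (adult_age + 1) + adult_age)
}

#' Construct a linear epigenetic clock model
#'
#' A clock is a linear predictor on clock-CpG beta values whose output is
#' mapped to years through the inverse of [transform_age()]:
#' DNAm age = F^-1(intercept + sum_j w_j beta_j).
#'
#' @param cpg_ids Character vector of clock CpG identifiers (unique).
#' @param weights Numeric vector of per-CpG weights.
#' @param intercept Intercept of the linear predictor (transformed-age scale).
#' @param adult_age Transform knot in years.
#' @return An object of class `ClockModel`.
#' @export
clock_model <- function(cpg_ids, weights, intercept, adult_age = 20) {
  cpg_ids <- as.character(cpg_ids)
  if (length(cpg_ids) != length(weights)) {
    stop("clock_model: cpg_ids and weights lengths differ")
  }
  if (anyDuplicated(cpg_ids)) stop("clock_model: duplicate clock CpG ids")
  if (!is.finite(intercept) || any(!is.finite(weights))) {
    stop("clock_model: non-finite coefficients")
  }
  structure(list(cpg_ids = cpg_ids, weights = as.numeric(weights),
                 intercept = as.numeric(intercept),
                 adult_age = as.numeric(adult_age)),
            class = "ClockModel")
}

#' @export
print.ClockModel <- function(x, ...) {
  cat(sprintf("ClockModel: %d CpGs, intercept %.4g, adult_age %g\n",
              length(x$cpg_ids), x$intercept, x$adult_age))
  invisible(x)
}

#' Write a clock model to a TSV file
#'
#' Format: comment-prefixed key/value header lines (`#intercept`,
#' `#adult_age`) followed by a two-column table (cpg_id, weight).
#'
#' @param model A `ClockModel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clock_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#intercept\t%.17g", model$intercept),
               sprintf("#adult_age\t%.17g", model$adult_age),
               "cpg_id\tweight"), con)
  writeLines(sprintf("%s\t%.17g", model$cpg_ids, model$weights), con)
  invisible(path)
}

#' Read a clock model written by [write_clock_model()]
#' @param path Path to the clock file.
#' @return A `ClockModel`.
#' @export
read_clock_model <- function(path) {
  if (!file.exists(path)) stop("read_clock_model: file not found: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  kv <- do.call(rbind, strsplit(sub("^#", "", hdr), "\t", fixed = TRUE))
  vals <- stats::setNames(as.numeric(kv[, 2]), kv[, 1])
  if (!all(c("intercept", "adult_age") %in% names(vals))) {
    stop("read_clock_model: missing #intercept or #adult_age header")
  }
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")], sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  clock_model(tab$cpg_id, tab$weight, vals[["intercept"]], vals[["adult_age"]])
}

#' Estimate DNA methylation age
#'
#' Applies the clock's linear predictor to the clock-CpG rows of a beta
#' matrix and maps the result to years.
#'
#' @param beta A [beta_matrix()] containing every clock CpG.
#' @param model A `ClockModel`.
#' @return Named numeric vector of DNAm ages (years), one per sample.
#' @export
dnam_age <- function(beta, model) {
  missing_ids <- setdiff(model$cpg_ids, rownames(beta))
  if (length(missing_ids) > 0) {
    stop("dnam_age: clock CpGs missing from beta matrix: ",
         paste(utils::head(missing_ids, 5), collapse = ", "),
         if (length(missing_ids) > 5) sprintf(" (+%d more)", length(missing_ids) - 5))
  }
  lp <- drop(model$intercept +
               crossprod(beta[model$cpg_ids, , drop = FALSE], model$weights))
  if (any(!is.finite(lp))) stop("dnam_age: non-finite linear predictor")
  stats::setNames(inverse_transform_age(lp, model$adult_age), colnames(beta))
}

#' Fit the control-sample trend of DNAm age on chronological age
#'
#' Least-squares natural cubic spline with 2 effective degrees of freedom
#' (one interior knot at the median age), fitted through the non-HD samples.
#' The returned function extrapolates linearly outside the fitted age range
#' (with a warning when evaluated there).
#'
#' @param ages Chronological ages of the control (non-HD) samples.
#' @param dnam_ages Matching DNAm age estimates.
#' @return Function `trend(age)` returning predicted DNAm age.
#' @export
fit_control_trend <- function(ages, dnam_ages) {
  ok <- is.finite(ages) & is.finite(dnam_ages)
  ages <- ages[ok]; dnam_ages <- dnam_ages[ok]
  if (length(ages) < 10) {
    stop("fit_control_trend: need >= 10 control samples")
  }
  if (diff(range(ages)) < 20) {
    stop("fit_control_trend: control ages must span >= 20 years")
  }
  fit <- stats::lm(dnam_ages ~ splines::ns(ages, df = 2))
  lo <- min(ages); hi <- max(ages)
  eps <- max(1e-3, diff(range(ages)) * 1e-6)
  predict_at <- function(a) {
    unname(stats::predict(fit, newdata = list(ages = a)))
  }
  function(age) {
    age <- as.numeric(age)
    inside <- age >= lo & age <= hi
    out <- numeric(length(age))
    if (any(inside)) out[inside] <- predict_at(age[inside])
    if (any(!inside)) {
      warning("control trend evaluated outside fitted age range [",
              signif(lo, 4), ", ", signif(hi, 4), "]; extrapolating linearly")
      below <- !inside & age < lo
      above <- !inside & age > hi
      if (any(below)) {
        slope <- (predict_at(lo + eps) - predict_at(lo)) / eps
        out[below] <- predict_at(lo) + slope * (age[below] - lo)
      }
      if (any(above)) {
        slope <- (predict_at(hi) - predict_at(hi - eps)) / eps
        out[above] <- predict_at(hi) + slope * (age[above] - hi)
      }
    }
    out
  }
}

#' Epigenetic age acceleration relative to the control trend
#'
#' Vertical distance of each sample from the control-only spline regression
#' of DNAm age on chronological age: positive values mean the methylome looks
#' older than controls of the same age.
#'
#' @param dnam_ages DNAm age estimates (years).
#' @param ages Matching chronological ages.
#' @param trend Function from [fit_control_trend()].
#' @return Numeric vector of accelerations (years).
#' @export
age_acceleration <- function(dnam_ages, ages, trend) {
  dnam_ages - trend(ages)
}

#' Winsorize outlying DNAm age estimates within individuals
#'
#' Samples whose residual from the control trend exceeds `threshold` years in
#' absolute value are flagged and replaced by the individual's second most
#' extreme non-cerebellar DNAm age: the flagged value's side of the
#' individual's median determines the direction, and the replacement is the
#' most extreme remaining estimate on that side (estimates 50/52/90 with 90
#' flagged winsorize to 52). Cerebellar samples are never
#' flagged, never replaced, and never serve as donors (the cerebellum ages
#' more slowly than other brain regions). A flagged individual with fewer
#' than 2 non-cerebellar samples is left unchanged with a warning.
#'
#' @param dnam_ages Named or unnamed numeric vector of DNAm ages.
#' @param ages Matching chronological ages.
#' @param individual_ids Individual identifier per sample.
#' @param regions Region label per sample ("cerebellum" is treated specially,
#'   case-insensitively).
#' @param trend Control trend from [fit_control_trend()].
#' @param threshold Flagging threshold in years (default 15).
#' @return List with `dnam_age` (winsorized vector), `winsorized` (logical
#'   flags), `n_flagged`.
#' @export
winsorize_dnam_age <- function(dnam_ages, ages, individual_ids, regions,
                               trend, threshold = 15) {
  stopifnot(length(dnam_ages) == length(ages),
            length(dnam_ages) == length(individual_ids),
            length(dnam_ages) == length(regions))
  is_crbm <- grepl("cerebell", tolower(regions))
  resid <- dnam_ages - trend(ages)
  flagged <- abs(resid) > threshold & !is_crbm
  out <- dnam_ages
  for (i in which(flagged)) {
    ind <- individual_ids[i]
    donors <- which(individual_ids == ind & !is_crbm & seq_along(out) != i)
    if (length(donors) < 1) {
      warning("winsorize_dnam_age: individual ", ind,
              " flagged but has < 2 non-cerebellar samples; left unchanged")
      flagged[i] <- FALSE
      next
    }
    pool <- c(dnam_ages[donors], dnam_ages[i])
    med <- stats::median(pool)
    # replacement is the second most extreme estimate on the flagged value's
    # side of the individual's median: the largest donor when the outlier is
    # high, the smallest when it is low
    donor_vals <- dnam_ages[donors]
    out[i] <- if (dnam_ages[i] >= med) max(donor_vals) else min(donor_vals)
  }
  list(dnam_age = out, winsorized = flagged, n_flagged = sum(flagged))
}

#' Intrinsic epigenetic age acceleration
#'
#' Residual from regressing DNAm age on chronological age and the proportion
#' of neurons, removing cell-composition confounding. If `prop_neurons` is
#' constant the neuron term is dropped with a warning and an age-only
#' residual is returned.
#'
#' @param dnam_ages DNAm age estimates (years).
#' @param ages Matching chronological ages.
#' @param prop_neurons Neuron proportion per sample, in \[0, 1\].
#' @return Numeric vector of intrinsic accelerations (years).
#' @export
intrinsic_acceleration <- function(dnam_ages, ages, prop_neurons) {
  if (any(is.na(prop_neurons))) {
    stop("intrinsic_acceleration: prop_neurons must be present for all samples")
  }
  if (stats::sd(prop_neurons) == 0) {
    warning("intrinsic_acceleration: constant prop_neurons; using age-only residual")
    return(unname(stats::residuals(stats::lm(dnam_ages ~ ages))))
  }
  unname(stats::residuals(stats::lm(dnam_ages ~ ages + prop_neurons)))
}

#' Full clock stage on an aligned cohort
#'
#' Computes DNAm age, fits the control trend on non-HD non-cerebellar
#' samples, winsorizes outliers, refits the trend once, and derives both
#' acceleration measures.
#'
#' @param beta A [beta_matrix()] (all lobes/regions combined).
#' @param sheet Aligned `SampleSheet`.
#' @param model A `ClockModel`.
#' @param threshold Winsorization threshold in years.
#' @return `data.frame` with sample_id, dnam_age (winsorized), dnam_age_raw,
#'   winsorized flag, age_accel and (when prop_neurons is available)
#'   intrinsic_accel.
#' @export
clock_stage <- function(beta, sheet, model, threshold = 15) {
  dn <- dnam_age(beta, model)
  sheet <- sheet[match(colnames(beta), sheet$sample_id), , drop = FALSE]
  is_control <- sheet$diagnosis != "HD"
  is_crbm <- grepl("cerebell", tolower(sheet$region))
  trend0 <- fit_control_trend(sheet$age[is_control & !is_crbm],
                              dn[is_control & !is_crbm])
  w <- winsorize_dnam_age(dn, sheet$age, sheet$individual_id, sheet$region,
                          trend0, threshold = threshold)
  trend <- fit_control_trend(sheet$age[is_control & !is_crbm],
                             w$dnam_age[is_control & !is_crbm])
  accel <- age_acceleration(w$dnam_age, sheet$age, trend)
  res <- data.frame(sample_id = sheet$sample_id,
                    dnam_age = unname(w$dnam_age),
                    dnam_age_raw = unname(dn),
                    winsorized = w$winsorized,
                    age_accel = unname(accel),
                    stringsAsFactors = FALSE)
  if (!any(is.na(sheet$prop_neurons))) {
    res$intrinsic_accel <- intrinsic_acceleration(w$dnam_age, sheet$age,
                                                  sheet$prop_neurons)
  }
  res
}
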