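#' Network construction parameters
#'
#' @param soft_power Soft-thresholding exponent applied to positive
#'   correlations (default 6, the conventional signed-hybrid default).
#' @param max_p_outliers Biweight midcorrelation outlier cap (default 0.05).
#' @param consensus_quantile Quantile q used for the component-wise consensus
#'   across lobes (default 0 = component-wise minimum).
#' @param min_module_size Minimum branch size to become a module (default 20).
#' @param cut_height Static cut height as a fraction of the dendrogram's
#'   maximum merge height (default 0.995).
#' @return List of class `NetworkConfig`.
#' @export
network_config <- function(soft_power = 6, max_p_outliers = 0.05,
                           consensus_quantile = 0, min_module_size = 20,
                           cut_height = 0.995) {
  stopifnot(soft_power >= 1, consensus_quantile >= 0, consensus_quantile <= 1,
            min_module_size >= 1, cut_height > 0, cut_height <= 1)
  structure(list(soft_power = soft_power, max_p_outliers = max_p_outliers,
                 consensus_quantile = consensus_quantile,
                 min_module_size = min_module_size, cut_height = cut_height),
            class = "NetworkConfig")
}

#' Signed-hybrid network adjacency for one lobe
#'
#' Pairwise biweight midcorrelations between CpG profiles are mapped to a
#' "signed hybrid" similarity (the correlation when positive, zero
#' otherwise) and raised to the soft power, suppressing weak correlations
#' that may be noise. The diagonal is set to zero by convention for the
#' topological-overlap computation.
#'
#' @param resid CpG-by-sample matrix for one lobe (typically age/sex
#'   residualized).
#' @param config A [network_config()].
#' @return Symmetric adjacency matrix in \[0, 1\] with zero diagonal.
#' @export
signed_hybrid_adjacency <- function(resid, config = network_config()) {
  if (ncol(resid) < 3) stop("signed_hybrid_adjacency: need >= 3 samples")
  R <- bicor_matrix(resid, config$max_p_outliers)
  if (any(!is.finite(R))) {
    bad <- which(!is.finite(R), arr.ind = TRUE)[1, ]
    stop("signed_hybrid_adjacency: non-finite correlation for pair (",
         rownames(resid)[bad[1]], ", ", rownames(resid)[bad[2]], ")")
  }
  A <- pmax(R, 0)^config$soft_power
  diag(A) <- 0
  A
}

#' Topological overlap matrix
#'
#' For adjacency A with zero diagonal and row sums k, the topological
#' overlap between nodes i and j is
#' \deqn{TOM_{ij} = \frac{\sum_u A_{iu}A_{uj} + A_{ij}}
#'                       {\min(k_i, k_j) + 1 - A_{ij}},}
#' a normalized count of shared network neighbors; the diagonal is 1.
#'
#' @param A Symmetric non-negative adjacency with zero diagonal.
#' @return Symmetric TOM matrix in \[0, 1\] with unit diagonal.
#' @export
tom_matrix <- function(A) {
  if (any(A < 0)) stop("tom_matrix: negative adjacency entries")
  if (any(abs(diag(A)) > 1e-12)) stop("tom_matrix: diagonal must be zero")
  k <- rowSums(A)
  L <- A %*% A
  kmin <- outer(k, k, pmin)
  TOM <- (L + A) / (kmin + 1 - A)
  diag(TOM) <- 1
  dimnames(TOM) <- dimnames(A)
  TOM
}

#' Quantile-normalize the columns of a matrix
#'
#' Each column is replaced by the mean of the per-rank sorted values across
#' columns; ties within a column receive the average of the normalized
#' values they span. After normalization the sorted values of every column
#' are identical.
#'
#' @param x Numeric matrix (observations x data sets).
#' @return Matrix of the same shape.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  ranks <- apply(x, 2, rank, ties.method = "average")
  target <- rowMeans(apply(x, 2, sort, method = "quick"))
  out <- apply(ranks, 2, function(r) {
    # average the target values across each tie group (non-integer ranks)
    lo <- floor(r); hi <- ceiling(r)
    (target[lo] + target[hi]) / 2
  })
  dimnames(out) <- dimnames(x)
  out
}

#' Calibrate TOM matrices across lobes by quantile normalization
#'
#' The lower-triangle entries of each lobe's TOM are treated as one
#' "sample" and quantile-normalized across lobes so that all lobes share
#' the same TOM value distribution (the mean of the per-rank sorted
#' values). Symmetry is restored by mirroring and the diagonal is left
#' untouched.
#'
#' @param toms Named list of same-dimension TOM matrices.
#' @return Named list of calibrated TOM matrices.
#' @export
calibrate_toms <- function(toms) {
  dims <- vapply(toms, nrow, 1L)
  if (length(unique(dims)) != 1 ||
      length(unique(vapply(toms, ncol, 1L))) != 1) {
    stop("calibrate_toms: dimension mismatch across lobes")
  }
  n <- dims[1]
  low <- lower.tri(toms[[1]])
  mat <- vapply(toms, function(m) m[low], numeric(sum(low)))
  normed <- quantile_normalize(mat)
  out <- lapply(seq_along(toms), function(j) {
    m <- toms[[j]]
    m[low] <- normed[, j]
    m[upper.tri(m)] <- t(m)[upper.tri(m)]
    m
  })
  names(out) <- names(toms)
  out
}

#' Consensus dissimilarity across calibrated TOMs
#'
#' The consensus network is the component-wise q-quantile of the calibrated
#' TOMs (q = 0 gives the component-wise minimum, the conventional
#' conservative consensus); the dissimilarity is one minus the consensus.
#'
#' @param ctoms Named list (length >= 2) of calibrated TOM matrices.
#' @param q Consensus quantile in \[0, 1\].
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
consensus_dissimilarity <- function(ctoms, q = 0) {
  if (length(ctoms) < 2) stop("consensus_dissimilarity: need >= 2 matrices")
  if (q < 0 || q > 1) stop("consensus_dissimilarity: q must be in [0, 1]")
  cons <- elementwise_quantile(ctoms, q)
  d <- 1 - cons
  dimnames(d) <- dimnames(ctoms[[1]])
  d
}

# Element-wise type-7 quantile across a list of equal-shape arrays,
# vectorized via a pmin/pmax sorting network (fast for the few lobes of a
# consensus analysis, unlike per-element quantile() calls).
elementwise_quantile <- function(mats, q) {
  k <- length(mats)
  if (q == 0) return(Reduce(pmin, mats))
  if (q == 1) return(Reduce(pmax, mats))
  sorted <- mats
  for (pass in seq_len(k - 1)) {
    for (j in seq_len(k - pass)) {
      lo <- pmin(sorted[[j]], sorted[[j + 1]])
      hi <- pmax(sorted[[j]], sorted[[j + 1]])
      sorted[[j]] <- lo
      sorted[[j + 1]] <- hi
    }
  }
  h <- (k - 1) * q
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  sorted[[lo]] + (h - floor(h)) * (sorted[[hi]] - sorted[[lo]])
}

#' Identify consensus modules by static tree cut
#'
#' Average-linkage hierarchical clustering of the consensus dissimilarity;
#' branches below `cut_height * max(merge height)` with at least
#' `min_module_size` members become modules, labeled 1, 2, ... in order of
#' decreasing size (ties broken by first member). The label 0 ("grey") is
#' reserved for unassigned CpGs.
#'
#' @param cons_diss Consensus dissimilarity matrix with CpG dimnames.
#' @param config A [network_config()].
#' @return List with `labels` (named integer vector, 0 = unassigned),
#'   `colors` (named character alias, "grey" for 0), `dendrogram`
#'   (the `hclust` object), `cut_at` (absolute height used).
#' @export
cut_modules <- function(cons_diss, config = network_config()) {
  hc <- stats::hclust(stats::as.dist(cons_diss), method = "average")
  cut_at <- config$cut_height * max(hc$height)
  raw <- stats::cutree(hc, h = cut_at)
  sizes <- table(raw)
  big <- names(sizes)[sizes >= config$min_module_size]
  labels <- stats::setNames(integer(length(raw)), names(raw))
  if (length(big) == 0) {
    warning("cut_modules: no branch reaches min_module_size; all CpGs unassigned")
  } else {
    first_member <- vapply(big, function(g) which(raw == as.integer(g))[1], 1L)
    ord <- big[order(-sizes[big], first_member)]
    for (m in seq_along(ord)) labels[raw == as.integer(ord[m])] <- m
  }
  palette <- c("grey", "turquoise", "blue", "brown", "yellow", "green", "red",
               "black", "pink", "magenta", "purple", "greenyellow", "tan",
               "salmon", "cyan", "midnightblue", "lightcyan")
  colors <- palette[pmin(labels + 1L, length(palette))]
  extra <- labels + 1L > length(palette)
  colors[extra] <- paste0("module", labels[extra])
  list(labels = labels, colors = stats::setNames(colors, names(labels)),
       dendrogram = hc, cut_at = cut_at)
}

#' Module eigenvector (eigengene) in one lobe
#'
#' CpG profiles are standardized (mean 0, sd 1 across samples) and the
#' module summary profile is the top singular direction over samples: a
#' unit-norm vector with one value per sample, its sign chosen so the
#' average standardized profile correlates positively with it. Constant
#' CpGs are dropped with a warning.
#'
#' @param resid CpG-by-sample matrix for one lobe.
#' @param module_cpgs Character vector of CpG ids in the module (>= 2).
#' @return List with `eigenvector` (named per-sample), `var_explained`.
#' @export
module_eigenvector <- function(resid, module_cpgs) {
  x <- resid[intersect(module_cpgs, rownames(resid)), , drop = FALSE]
  if (nrow(x) < 2) stop("module_eigenvector: module must have >= 2 CpGs present")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warning("module_eigenvector: dropping ", sum(sds == 0), " constant CpG(s)")
    x <- x[sds > 0, , drop = FALSE]
    if (nrow(x) < 2) stop("module_eigenvector: too few non-constant CpGs")
    sds <- sds[sds > 0]
  }
  xs <- (x - rowMeans(x)) / apply(x, 1, stats::sd)
  sv <- svd(xs, nu = 0, nv = 1)
  E <- drop(sv$v)
  if (stats::cor(E, colMeans(xs)) < 0) E <- -E
  list(eigenvector = stats::setNames(E, colnames(x)),
       var_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Module membership of a CpG profile
#'
#' Correlation of the CpG's methylation profile with a module eigenvector,
#' the "fuzzy" membership in \[-1, 1\]; values near -1 are treated as low
#' membership (signed network convention). Constant profiles return NA with
#' a warning.
#'
#' @param x CpG profile across the lobe's samples.
#' @param eigenvector Module eigenvector from [module_eigenvector()].
#' @return Correlation in \[-1, 1\] or NA.
#' @export
module_membership <- function(x, eigenvector) {
  if (length(x) != length(eigenvector)) stop("module_membership: length mismatch")
  if (stats::sd(x) == 0) {
    warning("module_membership: constant profile; returning NA")
    return(NA_real_)
  }
  stats::cor(x, eigenvector)
}

#' Meta-analysis Z of per-lobe module memberships
#'
#' Each lobe's membership correlation is converted to a z-statistic by
#' Fisher's transform scaled by sqrt(n - 3) and the per-lobe z's are
#' combined with Stouffer's method. CpGs ranked by this meta Z within their
#' module are consensus hubs.
#'
#' @param mm Numeric vector of per-lobe module memberships (NA allowed).
#' @param n_samples Per-lobe sample counts (same length).
#' @return Meta Z (NA when every lobe is missing).
#' @export
consensus_hub_z <- function(mm, n_samples) {
  stopifnot(length(mm) == length(n_samples))
  ok <- !is.na(mm)
  if (!any(ok)) return(NA_real_)
  mmc <- pmax(pmin(mm[ok], 1 - 1e-15), -1 + 1e-15)
  z <- atanh(mmc) * sqrt(n_samples[ok] - 3)
  stouffer_meta(z)$z
}

#' Module-trait association with Stouffer meta-analysis across lobes
#'
#' Per lobe, the module eigenvector is tested against the trait with a
#' robust correlation test ([cor_test()] with biweight midcorrelation); the
#' signed z-scores are combined across lobes with Stouffer's method. Lobes
#' in which the trait is constant are skipped (reducing N_sets) with a
#' warning.
#'
#' @param eigenvectors Named list (per lobe) of matrices samples x modules
#'   (as produced by [consensus_network()]).
#' @param traits Named list (per lobe) of numeric trait vectors aligned to
#'   the lobe's samples.
#' @return `data.frame`: module, per-lobe r and p columns, z_meta, p_meta,
#'   n_sets.
#' @export
module_trait_meta <- function(eigenvectors, traits) {
  lobes <- names(eigenvectors)
  stopifnot(identical(sort(lobes), sort(names(traits))))
  modules <- colnames(eigenvectors[[1]])
  out <- data.frame(module = modules, stringsAsFactors = FALSE)
  zmat <- matrix(NA_real_, length(modules), length(lobes),
                 dimnames = list(modules, lobes))
  for (lobe in lobes) {
    tr <- traits[[lobe]]
    E <- eigenvectors[[lobe]]
    stopifnot(nrow(E) == length(tr))
    if (stats::sd(tr) == 0) {
      warning("module_trait_meta: constant trait in lobe ", lobe, "; skipped")
      out[[paste0("r_", lobe)]] <- NA_real_
      out[[paste0("p_", lobe)]] <- NA_real_
      next
    }
    rs <- numeric(length(modules)); ps <- numeric(length(modules))
    for (m in seq_along(modules)) {
      ct <- cor_test(E[, m], tr, method = "bicor")
      rs[m] <- ct$r; ps[m] <- ct$p_value
      zmat[m, lobe] <- sign(ct$r) * stats::qnorm(ct$p_value / 2,
                                                 lower.tail = FALSE)
    }
    out[[paste0("r_", lobe)]] <- rs
    out[[paste0("p_", lobe)]] <- ps
  }
  metas <- apply(zmat, 1, function(z) {
    z <- z[is.finite(z)]
    if (length(z) == 0) return(c(NA_real_, NA_real_, 0))
    sm <- stouffer_meta(z)
    c(sm$z, sm$p_value, length(z))
  })
  out$z_meta <- metas[1, ]
  out$p_meta <- metas[2, ]
  out$n_sets <- as.integer(metas[3, ])
  out
}

#' Consensus weighted co-methylation network across lobes
#'
#' Full consensus pipeline: per-lobe signed-hybrid adjacency from biweight
#' midcorrelations, topological overlap, quantile-normalization calibration
#' across lobes, component-wise consensus quantile, average-linkage
#' clustering with a static tree cut, per-lobe module eigenvectors,
#' per-lobe module memberships, and membership meta-analysis Z.
#'
#' @param resid_list Named list of CpG-by-sample matrices (same CpG rows),
#'   one per lobe, typically age/sex residualized.
#' @param config A [network_config()].
#' @return Object of class `ConsensusNetwork`: list with `adjacency`,
#'   `tom`, `ctom`, `cons_diss`, `modules` (from [cut_modules()]),
#'   `eigenvectors` (per-lobe samples x modules matrices),
#'   `var_explained`, `membership` (data.frame with per-lobe MM and meta
#'   Z per CpG x module), `config`.
#' @export
consensus_network <- function(resid_list, config = network_config()) {
  stopifnot(length(resid_list) >= 2)
  ids <- rownames(resid_list[[1]])
  stopifnot(all(vapply(resid_list, function(m) identical(rownames(m), ids),
                       TRUE)))
  adjacency <- lapply(resid_list, signed_hybrid_adjacency, config = config)
  toms <- lapply(adjacency, tom_matrix)
  ctoms <- calibrate_toms(toms)
  cons_diss <- consensus_dissimilarity(ctoms, config$consensus_quantile)
  modules <- cut_modules(cons_diss, config)
  mod_ids <- sort(unique(modules$labels[modules$labels > 0]))
  eigenvectors <- list(); var_explained <- list()
  for (lobe in names(resid_list)) {
    E <- matrix(NA_real_, ncol(resid_list[[lobe]]), length(mod_ids),
                dimnames = list(colnames(resid_list[[lobe]]),
                                paste0("M", mod_ids)))
    ve <- stats::setNames(numeric(length(mod_ids)), paste0("M", mod_ids))
    for (m in seq_along(mod_ids)) {
      me <- module_eigenvector(resid_list[[lobe]],
                               ids[modules$labels == mod_ids[m]])
      E[, m] <- me$eigenvector
      ve[m] <- me$var_explained
    }
    eigenvectors[[lobe]] <- E
    var_explained[[lobe]] <- ve
  }
  membership <- NULL
  if (length(mod_ids) > 0) {
    n_samples <- vapply(resid_list, ncol, 1L)
    membership <- expand.grid(cpg_id = ids, module = paste0("M", mod_ids),
                              stringsAsFactors = FALSE)
    mm_per_lobe <- lapply(names(resid_list), function(lobe) {
      x <- resid_list[[lobe]]
      xs <- x - rowMeans(x)
      nr <- sqrt(rowSums(xs^2)); nr[nr == 0] <- NA
      E <- eigenvectors[[lobe]]
      Ec <- sweep(E, 2, colMeans(E))
      En <- sweep(Ec, 2, sqrt(colSums(Ec^2)), "/")
      (xs / nr) %*% En  # CpG x module correlation matrix
    })
    names(mm_per_lobe) <- names(resid_list)
    for (lobe in names(resid_list)) {
      membership[[paste0("mm_", lobe)]] <- as.vector(mm_per_lobe[[lobe]])
    }
    mm_cols <- paste0("mm_", names(resid_list))
    membership$z_meta <- apply(as.matrix(membership[mm_cols]), 1,
                               consensus_hub_z, n_samples = n_samples)
  }
  structure(list(adjacency = adjacency, tom = toms, ctom = ctoms,
                 cons_diss = cons_diss, modules = modules,
                 eigenvectors = eigenvectors, var_explained = var_explained,
                 membership = membership, config = config),
            class = "ConsensusNetwork")
}

#' @export
print.ConsensusNetwork <- function(x, ...) {
  n_mod <- length(unique(x$modules$labels[x$modules$labels > 0]))
  cat(sprintf("ConsensusNetwork: %d CpGs, %d lobes, %d modules (+%d grey)\n",
              length(x$modules$labels), length(x$adjacency), n_mod,
              sum(x$modules$labels == 0)))
  invisible(x)
}
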