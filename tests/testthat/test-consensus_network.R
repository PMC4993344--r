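test_that("signed-hybrid adjacency zeroes negative correlations", {
  set.seed(31)
  base <- rnorm(20)
  m <- rbind(a = base, b = base + rnorm(20, 0, 0.05), c = -base)
  A <- signed_hybrid_adjacency(m, network_config(soft_power = 6))
  expect_equal(A, t(A))
  expect_equal(unname(diag(A)), rep(0, 3))
  expect_gt(A["a", "b"], 0.5)      # strong positive pair survives
  expect_equal(A["a", "c"], 0)     # negative correlation -> zero
  expect_true(all(A >= 0 & A <= 1))
  # power transform: bicor r maps to r^6
  R <- bicor_matrix(m)
  expect_equal(A["a", "b"], max(R["a", "b"], 0)^6, tolerance = 1e-12)
})

test_that("tom_matrix matches hand values and the brute-force oracle", {
  # no edge, no shared neighbors -> zero overlap
  A0 <- matrix(0, 3, 3)
  A0[1, 2] <- A0[2, 1] <- 0  # disconnected pair
  expect_equal(tom_matrix(A0)[1, 2], 0)
  # complete graph K4: off-diagonal TOM = (2+1)/(3+1-1) = 1
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  T4 <- tom_matrix(K4)
  expect_equal(unname(T4[lower.tri(T4)]), rep(1, 6))
  # random 8-node adjacency vs triple loop
  set.seed(32)
  A <- matrix(runif(64, 0, 0.8), 8, 8)
  A <- (A + t(A)) / 2; diag(A) <- 0
  TOM <- tom_matrix(A)
  k <- rowSums(A)
  for (i in 1:8) for (j in 1:8) {
    if (i == j) next
    num <- sum(A[i, ] * A[j, ]) + A[i, j]
    den <- min(k[i], k[j]) + 1 - A[i, j]
    expect_equal(TOM[i, j], num / den, tolerance = 1e-12)
  }
  expect_true(all(TOM >= 0 & TOM <= 1))
  expect_error(tom_matrix(matrix(-1, 2, 2)), "negative")
})

test_that("quantile_normalize equalizes distributions; limma oracle agrees", {
  set.seed(33)
  x <- matrix(rexp(300), 100, 3)
  qn <- quantile_normalize(x)
  expect_equal(sort(qn[, 1]), sort(qn[, 2]), tolerance = 1e-12)
  expect_equal(sort(qn[, 2]), sort(qn[, 3]), tolerance = 1e-12)
  expect_equal(sort(qn[, 1]), rowMeans(apply(x, 2, sort)), tolerance = 1e-12)
  ref <- limma::normalizeQuantiles(x, ties = TRUE)
  expect_equal(qn, ref, tolerance = 1e-10, ignore_attr = TRUE)
  # ties within a column share the averaged target value
  xt <- cbind(c(1, 1, 5, 9), c(2, 4, 6, 8))
  qt <- quantile_normalize(xt)
  expect_equal(qt[1, 1], qt[2, 1])
})

test_that("calibrate_toms equalizes TOM quantiles across lobes", {
  set.seed(34)
  n <- 30
  base <- matrix(runif(n * n, 0, 0.5), n, n)
  base <- (base + t(base)) / 2; diag(base) <- 1
  doubled <- pmin(2 * base, 1); diag(doubled) <- 1
  out <- calibrate_toms(list(a = base, b = doubled))
  la <- out$a[lower.tri(out$a)]
  lb <- out$b[lower.tri(out$b)]
  expect_equal(sort(la), sort(lb), tolerance = 1e-12)
  for (q in c(0.25, 0.5, 0.75)) {
    expect_equal(quantile(la, q), quantile(lb, q), tolerance = 1e-12)
  }
  expect_equal(out$a, t(out$a))          # symmetry restored
  expect_equal(unname(diag(out$a)), rep(1, n))  # diagonal untouched
  # identical inputs pass through unchanged
  same <- calibrate_toms(list(a = base, b = base))
  expect_equal(same$a, base, tolerance = 1e-12)
  expect_error(calibrate_toms(list(base, matrix(0, 2, 2))), "dimension")
})

test_that("consensus_dissimilarity implements the component-wise quantile", {
  m1 <- matrix(c(0, 0.2, 0.2, 0), 2, 2)
  m2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  m3 <- matrix(c(0, 0.9, 0.9, 0), 2, 2)
  expect_equal(consensus_dissimilarity(list(m1, m2, m3), q = 0)[1, 2], 0.8)
  mm <- list(matrix(c(0, 0.1, 0.1, 0), 2, 2),
             matrix(c(0, 0.2, 0.2, 0), 2, 2),
             matrix(c(0, 0.3, 0.3, 0), 2, 2))
  expect_equal(consensus_dissimilarity(mm, q = 0.5)[1, 2], 1 - 0.2)
  # identical lobes: ConsDiss = 1 - cTOM exactly, any q
  set.seed(35)
  x <- matrix(runif(25), 5, 5); x <- (x + t(x)) / 2; diag(x) <- 1
  for (q in c(0, 0.3, 1)) {
    expect_equal(consensus_dissimilarity(list(x, x, x), q), 1 - x,
                 tolerance = 1e-12)
  }
  expect_error(consensus_dissimilarity(list(m1), 0), ">= 2")
  expect_error(consensus_dissimilarity(list(m1, m2), 2), "\\[0, 1\\]")
})

test_that("elementwise_quantile matches the per-element quantile oracle", {
  set.seed(36)
  mats <- lapply(1:4, function(i) matrix(runif(40), 8, 5))
  for (q in c(0, 0.25, 1 / 3, 0.5, 0.8, 1)) {
    got <- epiclocknet:::elementwise_quantile(mats, q)
    want <- apply(simplify2array(mats), c(1, 2), quantile, probs = q,
                  names = FALSE, type = 7)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("cut_modules recovers planted blocks and orders labels by size", {
  net <- small_net()
  sim <- small_net_sim()
  truth <- sim$truth$module_label[names(net$modules$labels)]
  inmod <- truth > 0
  expect_equal(adjusted_rand_index(truth[inmod], net$modules$labels[inmod]), 1)
  # label 1 is the largest module
  sizes <- table(net$modules$labels[net$modules$labels > 0])
  expect_true(all(sizes == sort(sizes, decreasing = TRUE)))
  expect_identical(unname(net$modules$colors[net$modules$labels == 0][1]),
                   "grey")
  # min size above n -> everything grey, with a warning
  cd <- net$cons_diss
  expect_warning(
    all_grey <- cut_modules(cd, network_config(min_module_size = nrow(cd) + 1)),
    "min_module_size")
  expect_true(all(all_grey$labels == 0))
})

test_that("module eigenvector matches the eigendecomposition oracle", {
  set.seed(37)
  # identical profiles: eigenvector is that profile, variance explained 1
  prof <- rnorm(15)
  m <- rbind(a = prof, b = prof, c = prof)
  colnames(m) <- paste0("s", 1:15)
  me <- module_eigenvector(m, c("a", "b", "c"))
  expect_equal(abs(cor(me$eigenvector, prof)), 1, tolerance = 1e-10)
  expect_equal(me$var_explained, 1, tolerance = 1e-10)
  # oracle: top eigenvector of the standardized matrix's sample-side Gram
  x <- matrix(rnorm(5 * 12), 5, 12,
              dimnames = list(paste0("cg", 1:5), paste0("s", 1:12)))
  me2 <- module_eigenvector(x, rownames(x))
  xs <- t(scale(t(x)))
  eig <- eigen(crossprod(xs))
  expect_equal(abs(sum(me2$eigenvector * eig$vectors[, 1])), 1,
               tolerance = 1e-8)
  expect_equal(me2$var_explained, eig$values[1] / sum(eig$values),
               tolerance = 1e-8)
  # sign convention: positive correlation with the mean standardized profile
  expect_gt(cor(me2$eigenvector, colMeans(xs)), 0)
  # unit norm
  expect_equal(sum(me2$eigenvector^2), 1, tolerance = 1e-10)
})

test_that("constant CpGs are dropped from eigenvector computation", {
  set.seed(38)
  x <- matrix(rnorm(3 * 10), 3, 10,
              dimnames = list(c("cg1", "cg2", "const"), paste0("s", 1:10)))
  x["const", ] <- 0.5
  expect_warning(me <- module_eigenvector(x, rownames(x)), "constant")
  expect_length(me$eigenvector, 10)
})

test_that("module_membership is the profile-eigenvector correlation", {
  set.seed(39)
  E <- rnorm(20)
  expect_equal(module_membership(3 * E + 2, E), 1, tolerance = 1e-12)
  expect_equal(module_membership(-E, E), -1, tolerance = 1e-12)
  expect_warning(mm <- module_membership(rep(1, 20), E), "constant")
  expect_true(is.na(mm))
  # hub CpG: the planted latent has the top membership in its module
  net <- small_net()
  sim <- small_net_sim()
  memb <- net$membership
  m1 <- memb[memb$module == "M1", ]
  truth <- sim$truth$module_label[m1$cpg_id]
  expect_true(all(m1$cpg_id[order(-m1$z_meta)][1:10] %in%
                    names(truth)[truth == 1]))
})

test_that("consensus_hub_z combines Fisher-z memberships", {
  # atanh(0.999) * sqrt(37) * sqrt(3) ~ 40: very large positive
  expect_gt(consensus_hub_z(rep(0.999, 3), rep(40, 3)), 30)
  expect_equal(consensus_hub_z(rep(0, 3), rep(40, 3)), 0)
  expect_true(is.na(consensus_hub_z(c(NA, NA), c(40, 40))))
  # with equal sample sizes, ranking by meta Z equals ranking by mean Fisher z
  set.seed(40)
  mm <- matrix(runif(30, -0.9, 0.9), 10, 3)
  z <- apply(mm, 1, consensus_hub_z, n_samples = rep(50, 3))
  fisher_mean <- rowMeans(atanh(mm))
  expect_equal(order(z), order(fisher_mean))
})

test_that("module_trait_meta finds the planted HD module", {
  sim <- small_net_sim()
  resid_list <- residualized_lobes(sim)
  net <- small_net()
  traits <- hd_trait(sim, resid_list)
  mt <- module_trait_meta(net$eigenvectors, traits)
  # planted HD module (truth module 1) has the top |meta Z|
  truth <- sim$truth$module_label[names(net$modules$labels)]
  hd_found <- net$modules$labels[truth == 1][1]  # found label of truth module 1
  top <- mt$module[which.max(abs(mt$z_meta))]
  expect_identical(top, paste0("M", hd_found))
  expect_lt(mt$p_meta[mt$module == top], 0.05 / nrow(mt))
  # trait equal to an eigenvector: r = 1 in that lobe
  tr2 <- traits
  tr2$frontal <- net$eigenvectors$frontal[, 1]
  mt2 <- module_trait_meta(net$eigenvectors, tr2)
  expect_equal(mt2$r_frontal[mt2$module == "M1"], 1, tolerance = 1e-6)
  # constant trait: lobe skipped, n_sets reduced
  tr3 <- traits
  tr3$frontal <- rep(1, length(traits$frontal))
  expect_warning(mt3 <- module_trait_meta(net$eigenvectors, tr3), "constant")
  expect_true(all(mt3$n_sets == length(traits) - 1))
})

test_that("matrices stay symmetric in [0,1] at every network stage", {
  net <- small_net()
  for (lobe in names(net$adjacency)) {
    for (M in list(net$adjacency[[lobe]], net$tom[[lobe]], net$ctom[[lobe]])) {
      expect_equal(M, t(M), tolerance = 1e-10)
      expect_true(all(M >= -1e-12 & M <= 1 + 1e-12))
    }
  }
  expect_equal(net$cons_diss, t(net$cons_diss), tolerance = 1e-10)
  expect_true(all(net$cons_diss >= -1e-12 & net$cons_diss <= 1 + 1e-12))
})

test_that("the pipeline is equivariant to CpG permutation", {
  sim <- small_net_sim()
  resid_list <- residualized_lobes(sim)
  net <- small_net()
  set.seed(41)
  perm <- sample(nrow(resid_list[[1]]))
  permuted <- lapply(resid_list, function(m) m[perm, , drop = FALSE])
  net_p <- consensus_network(permuted)
  a <- net$modules$labels
  b <- net_p$modules$labels[names(a)]  # realign by CpG id
  expect_equal(adjusted_rand_index(a, b), 1)
})
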