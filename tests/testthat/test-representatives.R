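# compact fixtures: 3 lobes, 9 CpGs on 4 genes (sizes 3, 2, 1, and one
# unannotated CpG pair), with controllable adjacency/sd structure
make_rep_fixture <- function(seed = 51) {
  set.seed(seed)
  cpgs <- paste0("cg", 1:9)
  ann <- data.frame(
    cpg_id = cpgs,
    gene_symbol = c("GA", "GA", "GA", "GB", "GB", "GC", "", "", "GD"),
    chromosome = 1, position = seq_len(9) * 100)
  beta_list <- lapply(c(f = 1, p = 2, o = 3), function(i) {
    m <- matrix(runif(9 * 20, 0.3, 0.7), 9, 20,
                dimnames = list(cpgs, paste0("s", 1:20)))
    m
  })
  adjacency_list <- lapply(beta_list, function(b) {
    A <- signed_hybrid_adjacency(b, network_config(soft_power = 2))
    A
  })
  list(ann = ann, beta = beta_list, adj = adjacency_list, cpgs = cpgs)
}

test_that("gene_cpg_groups partitions genes by CpG count", {
  fx <- make_rep_fixture()
  g <- gene_cpg_groups(fx$ann, fx$cpgs)
  expect_equal(g$n_unannotated, 2)
  expect_equal(sort(names(g$groups)), c("GA", "GB", "GC", "GD"))
  expect_identical(unname(g$classes[c("GA", "GB", "GC", "GD")]),
                   c("kim3plus", "sd2", "single", "single"))
  expect_error(gene_cpg_groups(fx$ann, c("cg7", "cg8")), "no annotated")
})

test_that("consensus_kim matches hand and brute-force computation", {
  # all adjacencies 1 in every lobe: kIM = 2 for each of 3 CpGs
  ones <- matrix(1, 3, 3, dimnames = list(paste0("c", 1:3), paste0("c", 1:3)))
  diag(ones) <- 0
  k <- consensus_kim(list(a = ones, b = ones), paste0("c", 1:3), q = 0)
  expect_equal(unname(k), rep(2, 3))
  # doubling one lobe pre-calibration preserves the consensus ranking (the
  # quantile-normalization target shifts, so values move together but the
  # ordering and the selected hub are invariant)
  fx <- make_rep_fixture()
  set <- c("cg1", "cg2", "cg3", "cg9")
  adj2 <- fx$adj
  adj2$f <- pmin(adj2$f * 2, 1)  # monotone rescale preserves ranks
  k1 <- consensus_kim(fx$adj, set, q = 0)
  k2 <- consensus_kim(adj2, set, q = 0)
  expect_identical(order(k1), order(k2))
  expect_identical(names(which.max(k1)), names(which.max(k2)))
  # brute-force oracle on a seeded 4-CpG instance
  kim_brute <- sapply(fx$adj, function(A) {
    sapply(set, function(i) {
      s <- 0
      for (j in setdiff(set, i)) s <- s + A[i, j]
      s
    })
  })
  normed <- quantile_normalize(kim_brute)
  want <- apply(normed, 1, min)
  expect_equal(consensus_kim(fx$adj, set, q = 0), want, tolerance = 1e-12)
  expect_error(consensus_kim(fx$adj, c("cg1", "cg2"), 0), ">= 3")
})

test_that("consensus_sd calibrates and combines per-lobe sds", {
  fx <- make_rep_fixture()
  pair <- c("cg4", "cg5")
  # identical sds across lobes are returned unchanged
  b_same <- list(a = fx$beta$f, b = fx$beta$f)
  s <- consensus_sd(b_same, pair, q = 0)
  expect_equal(s, apply(fx$beta$f[pair, ], 1, sd), tolerance = 1e-12)
  # hand computation on the real fixture
  sds <- sapply(fx$beta, function(b) apply(b[pair, ], 1, sd))
  want <- apply(quantile_normalize(sds), 1, min)
  expect_equal(consensus_sd(fx$beta, pair, q = 0), want, tolerance = 1e-12)
  expect_error(consensus_sd(fx$beta, c("cg1", "cg2", "cg3")), "exactly 2")
})

test_that("select_representatives applies the three rules", {
  fx <- make_rep_fixture()
  g <- gene_cpg_groups(fx$ann, fx$cpgs)
  reps <- select_representatives(g, fx$adj, fx$beta, q = 0)
  expect_equal(nrow(reps), 4)                 # one per gene
  expect_false(anyDuplicated(reps$gene_symbol) > 0)
  expect_identical(reps$rule[reps$gene_symbol == "GC"], "single")
  expect_identical(reps$cpg_id[reps$gene_symbol == "GC"], "cg6")
  # the 2-CpG gene picks the higher consensus sd
  sc <- consensus_sd(fx$beta, c("cg4", "cg5"), q = 0)
  expect_identical(reps$cpg_id[reps$gene_symbol == "GB"],
                   names(sc)[which.max(sc)])
  # the 3-CpG gene picks the max consensus kIM
  kk <- consensus_kim(fx$adj, sort(c("cg1", "cg2", "cg3")), q = 0)
  expect_identical(reps$cpg_id[reps$gene_symbol == "GA"],
                   names(kk)[which.max(kk)])
})

test_that("gene_module_assignment inherits and conserves labels", {
  fx <- make_rep_fixture()
  g <- gene_cpg_groups(fx$ann, fx$cpgs)
  reps <- select_representatives(g, fx$adj, fx$beta, q = 0)
  labels <- setNames(c(1L, 1L, 1L, 2L, 2L, 0L, 0L, 0L, 2L), fx$cpgs)
  asn <- gene_module_assignment(reps, labels)
  expect_equal(nrow(asn), nrow(reps))  # conservation
  expect_equal(asn$module[asn$gene_symbol == "GA"], 1L)
  expect_equal(asn$module[asn$gene_symbol == "GC"], 0L)  # grey inherits
  expect_error(gene_module_assignment(reps, labels[1:3]), "without a module")
})

test_that("hypergeometric enrichment matches the exact tail-sum oracle", {
  # oracle: P(X >= 3) with universe 20, module draw 5, set 4
  oracle <- sum(sapply(3:4, function(k) {
    choose(4, k) * choose(16, 5 - k) / choose(20, 5)
  }))
  h <- hypergeometric_enrichment(paste0("g", 1:5),
                                 paste0("g", c(1, 2, 3, 19)),
                                 paste0("g", 1:20))
  expect_equal(h$overlap, 3)
  expect_equal(h$p_value, oracle, tolerance = 1e-12)
  expect_equal(round(h$p_value, 5), 0.03199)
  # module = set = universe forces overlap = |set| and p = 1
  u <- paste0("g", 1:6)
  hf <- hypergeometric_enrichment(u, u, u)
  expect_equal(hf$overlap, 6)
  expect_equal(hf$p_value, 1)
  # p monotone decreasing in overlap at fixed margins
  ps <- sapply(0:4, function(k) {
    stats::phyper(k - 1, 4, 16, 5, lower.tail = FALSE)
  })
  expect_true(all(diff(ps) < 0))
  # zero overlap with a small set: p near 1
  h0 <- hypergeometric_enrichment(paste0("g", 1:2), paste0("g", 19:20),
                                  paste0("g", 1:20))
  expect_gt(h0$p_value, 0.7)
  expect_error(hypergeometric_enrichment("a", "b", character(0)), "empty")
})

test_that("read_gmt parses sets and run_enrichment conserves genes", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tfirst set\tGA\tGB", "S2\tsecond\tGC\tGD\tGA"), path)
  sets <- read_gmt(path)
  expect_length(sets, 2)
  expect_identical(sets[[2]]$genes, c("GC", "GD", "GA"))

  fx <- make_rep_fixture()
  labels <- setNames(c(1L, 1L, 1L, 2L, 2L, 0L, 0L, 0L, 2L), fx$cpgs)
  enr <- run_enrichment(fx$ann, fx$cpgs, fx$adj, fx$beta, labels, sets, q = 0)
  expect_equal(nrow(enr$representatives), 4)
  expect_equal(nrow(enr$assignment), 4)
  expect_equal(sum(table(enr$assignment$module)), 4)  # conservation
  expect_true(all(enr$enrichment$p_value > 0 & enr$enrichment$p_value <= 1))
  expect_true(all(enr$enrichment$overlap <=
                    pmin(enr$enrichment$n_module, enr$enrichment$n_set)))
})

test_that("planted-module gene sets enrich in the recovered modules", {
  td <- withr::local_tempdir()
  cfg <- sim_config(seed = 52, n_cpgs = 500, n_clock_cpgs = 10,
                    module_sizes = c(60, 40), n_hd_modules = 1)
  write_fixture_set(cfg, td)
  sim <- simulate_cohort(cfg)
  resid_list <- residualized_lobes(sim)
  net <- consensus_network(resid_list)
  sets <- read_gmt(file.path(td, "gene_sets.gmt"))
  enr <- run_enrichment(sim$annotation, names(net$modules$labels),
                        net$adjacency, resid_list, net$modules$labels, sets)
  e <- enr$enrichment
  planted <- e[grepl("^SET_MOD", e$set_id), ]
  random <- e[grepl("^SET_RAND", e$set_id), ]
  expect_lt(min(planted$p_value), 1e-6)
  expect_gt(min(random$p_value), 1e-4)
})
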