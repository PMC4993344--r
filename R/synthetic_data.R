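#' Configuration of the synthetic multi-lobe cohort generator
#'
#' The generator emulates a 450k-style brain methylation cohort: three
#' lobes sampled from the same individuals, a linear epigenetic clock with
#' a planted HD age-acceleration, consensus co-methylation modules driven
#' by individual-level latents shared across lobes (a subset shifted by HD
#' status), age- and sex-associated CpGs, and a neuron/glia mixing
#' component. Beta values are Gaussian-noised pre-clipping; all downstream
#' statistics are rank-based or robust.
#'
#' @param n_hd,n_control Individuals per diagnosis group (default 20/20).
#' @param lobes Lobe names (default frontal/parietal/occipital).
#' @param samples_per_individual_per_lobe Replicate samples (default 1).
#' @param n_cpgs Total CpGs (default 2000).
#' @param n_clock_cpgs Clock CpGs (default 30).
#' @param module_sizes Sizes of the planted co-methylation modules
#'   (default 100, 80, 60, 50, 40).
#' @param n_hd_modules Leading modules whose latent shifts with HD status
#'   (default 2).
#' @param hd_effect_size Mean beta-unit shift of HD-module CpGs in HD
#'   samples (default 0.08).
#' @param age_effect_sd SD of per-year beta slopes at age-associated CpGs
#'   (default 0.001).
#' @param sex_effect_sd SD of female-vs-male beta shifts at sex-associated
#'   CpGs (default 0.02).
#' @param neuron_effect_sd SD of neuron-proportion loadings at
#'   cell-composition CpGs (default 0.08).
#' @param noise_sd Residual beta noise SD pre-clipping (default 0.02).
#' @param indiv_sd SD of the individual-level intercept shared across a
#'   person's samples at background CpGs (default 0.005).
#' @param hd_age_accel_years Planted epigenetic age acceleration of HD
#'   individuals (default 3.2 years); individual accelerations are drawn
#'   around the group mean with SD `accel_sd`.
#' @param accel_sd Between-individual SD of planted acceleration (1.5 y).
#' @param neuron_range Uniform range of the neuron proportion (0.2-0.6).
#' @param hd_neuron_loss Mean neuron-proportion deficit of HD individuals
#'   (default 0.08).
#' @param age_range_hd,age_range_control Uniform age ranges in years.
#' @param seed Integer RNG seed.
#' @return List of class `SimulationConfig`.
#' @export
sim_config <- function(n_hd = 20, n_control = 20,
                       lobes = c("frontal", "parietal", "occipital"),
                       samples_per_individual_per_lobe = 1,
                       n_cpgs = 2000, n_clock_cpgs = 30,
                       module_sizes = c(100, 80, 60, 50, 40),
                       n_hd_modules = 2, hd_effect_size = 0.08,
                       age_effect_sd = 0.001, sex_effect_sd = 0.02,
                       neuron_effect_sd = 0.08, noise_sd = 0.02,
                       indiv_sd = 0.005, hd_age_accel_years = 3.2,
                       accel_sd = 1.5, neuron_range = c(0.2, 0.6),
                       hd_neuron_loss = 0.08,
                       age_range_hd = c(30, 80),
                       age_range_control = c(20, 90), seed = 1L) {
  cfg <- list(n_hd = n_hd, n_control = n_control, lobes = lobes,
              samples_per_individual_per_lobe = samples_per_individual_per_lobe,
              n_cpgs = n_cpgs, n_clock_cpgs = n_clock_cpgs,
              module_sizes = module_sizes, n_hd_modules = n_hd_modules,
              hd_effect_size = hd_effect_size, age_effect_sd = age_effect_sd,
              sex_effect_sd = sex_effect_sd,
              neuron_effect_sd = neuron_effect_sd, noise_sd = noise_sd,
              indiv_sd = indiv_sd, hd_age_accel_years = hd_age_accel_years,
              accel_sd = accel_sd, neuron_range = neuron_range,
              hd_neuron_loss = hd_neuron_loss, age_range_hd = age_range_hd,
              age_range_control = age_range_control, seed = as.integer(seed))
  if (sum(cfg$module_sizes) > cfg$n_cpgs - cfg$n_clock_cpgs) {
    stop("sim_config: module_sizes sum exceeds n_cpgs - n_clock_cpgs")
  }
  if (cfg$n_hd_modules > length(cfg$module_sizes)) {
    stop("sim_config: n_hd_modules exceeds number of modules")
  }
  sds <- c(age_effect_sd, sex_effect_sd, noise_sd, indiv_sd, accel_sd)
  if (any(sds < 0)) stop("sim_config: negative sd")
  class(cfg) <- c("SimulationConfig", "list")
  cfg
}

# Center/scale of the transformed-age axis used by the synthetic clock; the
# linear predictor is t0 + s0 * u with u roughly in [-0.5, 0.5] over adult
# ages, keeping clock beta values well inside (0, 1).
.clock_t0 <- 1.5
.clock_s0 <- 4

#' Generate a synthetic linear epigenetic clock
#'
#' Weights have mixed signs and are constructed so that, on a cohort
#' generated by [simulate_cohort()] with zero noise, DNAm age equals
#' chronological age plus the planted acceleration exactly.
#'
#' @param n_clock_cpgs Number of clock CpGs (>= 2).
#' @param seed Integer seed.
#' @param adult_age Transform knot (default 20).
#' @return A [clock_model()] with the generating amplitudes/directions
#'   attached as attribute `"gen"`.
#' @export
make_synthetic_clock <- function(n_clock_cpgs, seed = 1L, adult_age = 20) {
  if (n_clock_cpgs < 2) stop("make_synthetic_clock: need >= 2 clock CpGs")
  set.seed(as.integer(seed))
  d <- sample(c(-1, 1), n_clock_cpgs, replace = TRUE)
  d[1] <- 1; d[2] <- -1  # guarantee mixed signs
  a <- stats::runif(n_clock_cpgs, 0.1, 0.3)
  # beta_j = 0.5 + d_j a_j u  =>  with w_j = d_j s0/(n a_j) the predictor
  # intercept + sum w_j beta_j equals t0 + s0 u exactly
  w <- d * .clock_s0 / (n_clock_cpgs * a)
  intercept <- .clock_t0 - 0.5 * sum(w)
  ids <- sprintf("cgclock%03d", seq_len(n_clock_cpgs))
  model <- clock_model(ids, w, intercept, adult_age)
  attr(model, "gen") <- list(direction = d, amplitude = a,
                             t0 = .clock_t0, s0 = .clock_s0)
  model
}

#' Simulate a multi-lobe methylation cohort with known ground truth
#'
#' See [sim_config()] for the generative model. Deterministic given the
#' config seed. Multiple samples from one individual share the
#' individual-level module latents, clock acceleration, and background
#' intercepts; each sample adds its own lobe/sample-level latent
#' innovation (half of the module latent variance) and measurement noise.
#'
#' @param config A [sim_config()].
#' @return List with `beta` (named list of [beta_matrix()] per lobe),
#'   `sheet` (a `SampleSheet`), `clock` (the generating `ClockModel`),
#'   `annotation` (pseudo-gene CpG annotation), `truth` (ground-truth
#'   list), `clip_rate`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n_ind <- config$n_hd + config$n_control
  ind_ids <- c(sprintf("HD%02d", seq_len(config$n_hd)),
               sprintf("CT%02d", seq_len(config$n_control)))
  is_hd_ind <- rep(c(TRUE, FALSE), c(config$n_hd, config$n_control))
  age <- numeric(n_ind)
  age[is_hd_ind] <- stats::runif(config$n_hd, config$age_range_hd[1],
                                 config$age_range_hd[2])
  age[!is_hd_ind] <- stats::runif(config$n_control,
                                  config$age_range_control[1],
                                  config$age_range_control[2])
  sex <- sample(c("F", "M"), n_ind, replace = TRUE)
  bank <- sample(c("NewZealand", "UCLA"), n_ind, replace = TRUE)
  accel <- stats::rnorm(n_ind, mean = config$hd_age_accel_years * is_hd_ind,
                        sd = config$accel_sd)
  prop_neurons <- stats::runif(n_ind, config$neuron_range[1],
                               config$neuron_range[2]) -
    config$hd_neuron_loss * is_hd_ind
  prop_neurons <- pmin(pmax(prop_neurons, 0.05), 0.95)
  cag <- ifelse(is_hd_ind, sample(40:50, n_ind, replace = TRUE), NA_integer_)
  grade <- ifelse(is_hd_ind, pmin(4L, pmax(1L, as.integer((cag - 38) / 3))),
                  NA_integer_)
  onset <- ifelse(is_hd_ind,
                  pmax(15, pmin(age - 2, 100 - 1.3 * cag + stats::rnorm(n_ind, 0, 5))),
                  NA_real_)

  # CpG layout: clock CpGs first, then module blocks, then background
  n_mod_cpgs <- sum(config$module_sizes)
  n_bg <- config$n_cpgs - config$n_clock_cpgs - n_mod_cpgs
  clock <- make_synthetic_clock(config$n_clock_cpgs, seed = config$seed + 1)
  set.seed(config$seed + 2)  # make_synthetic_clock reseeds; restart stream
  gen <- attr(clock, "gen")
  module_label <- c(rep(0L, config$n_clock_cpgs),
                    rep(seq_along(config$module_sizes), config$module_sizes),
                    rep(0L, n_bg))
  cpg_ids <- c(clock$cpg_ids,
               sprintf("cg%06d", seq_len(n_mod_cpgs + n_bg)))
  is_clock <- seq_len(config$n_cpgs) <= config$n_clock_cpgs
  is_bg <- module_label == 0L & !is_clock

  # per-module CpG loadings (positive: signed-hybrid-friendly co-methylation)
  load <- numeric(config$n_cpgs)
  load[module_label > 0] <- stats::runif(n_mod_cpgs, 0.04, 0.10)
  mu <- numeric(config$n_cpgs)
  mu[!is_clock] <- stats::runif(n_mod_cpgs + n_bg, 0.35, 0.65)
  mean_load <- vapply(seq_along(config$module_sizes),
                      function(m) mean(load[module_label == m]), 1.0)
  hd_latent_shift <- ifelse(seq_along(config$module_sizes) <= config$n_hd_modules,
                            config$hd_effect_size / mean_load, 0)

  # age / sex / neuron effects live on disjoint background CpG subsets
  n_eff <- min(200L, floor(n_bg / 3))
  bg_idx <- which(is_bg)
  age_cpgs <- bg_idx[seq_len(n_eff)]
  sex_cpgs <- bg_idx[n_eff + seq_len(n_eff)]
  neuron_cpgs <- bg_idx[2 * n_eff + seq_len(n_eff)]
  age_slope <- numeric(config$n_cpgs)
  age_slope[age_cpgs] <- stats::rnorm(n_eff, 0, config$age_effect_sd)
  sex_shift <- numeric(config$n_cpgs)
  sex_shift[sex_cpgs] <- stats::rnorm(n_eff, 0, config$sex_effect_sd)
  neuron_coef <- numeric(config$n_cpgs)
  neuron_coef[neuron_cpgs] <- stats::rnorm(n_eff, 0, config$neuron_effect_sd)

  # individual-level latents, shared by all of a person's samples
  n_modules <- length(config$module_sizes)
  z_ind <- matrix(stats::rnorm(n_ind * n_modules), n_ind, n_modules)
  bg_ind <- matrix(stats::rnorm(n_ind * config$n_cpgs, 0, config$indiv_sd),
                   n_ind, config$n_cpgs)
  bg_ind[, !is_bg] <- 0  # clock/module CpGs stay clean by construction

  spl <- config$samples_per_individual_per_lobe
  beta_list <- list()
  sheet_rows <- list()
  n_clipped <- 0; n_total <- 0
  true_eigen <- list()
  for (lobe in config$lobes) {
    for (rep_i in seq_len(spl)) {
      suffix <- if (spl > 1) sprintf("_%s_s%d", lobe, rep_i) else
        paste0("_", lobe)
      sample_ids <- paste0(ind_ids, suffix)
      # sample-level module latent: equal split of variance between the
      # individual component (consensus across lobes) and a lobe/sample
      # innovation; HD shift enters at sample level (diagnosis is
      # individual-level, so the shift is shared across lobes)
      z_sample <- sqrt(0.5) * z_ind +
        sqrt(0.5) * matrix(stats::rnorm(n_ind * n_modules), n_ind, n_modules)
      z_sample <- z_sample +
        outer(as.numeric(is_hd_ind), hd_latent_shift)
      u <- (transform_age(age + accel, clock$adult_age) - gen$t0) / gen$s0
      B <- matrix(0, config$n_cpgs, n_ind)
      B[is_clock, ] <- 0.5 + outer(gen$direction * gen$amplitude, u)
      mod_rows <- which(module_label > 0)
      B[mod_rows, ] <- mu[mod_rows] +
        load[mod_rows] * t(z_sample[, module_label[mod_rows], drop = FALSE])
      B[is_bg, ] <- mu[is_bg] + t(bg_ind[, is_bg, drop = FALSE])
      B <- B + outer(age_slope, age - 60) +
        outer(sex_shift, as.numeric(sex == "F")) +
        outer(neuron_coef, prop_neurons - mean(config$neuron_range))
      if (config$noise_sd > 0) {
        B <- B + matrix(stats::rnorm(length(B), 0, config$noise_sd),
                        nrow(B), ncol(B))
      }
      n_clipped <- n_clipped + sum(B < 0 | B > 1)
      n_total <- n_total + length(B)
      B <- pmin(pmax(B, 0), 1)
      dimnames(B) <- list(cpg_ids, sample_ids)
      key <- if (spl > 1) sprintf("%s_s%d", lobe, rep_i) else lobe
      beta_list[[key]] <- B
      true_eigen[[key]] <- z_sample
      sheet_rows[[key]] <- data.frame(
        sample_id = sample_ids, individual_id = ind_ids,
        region = paste0(lobe, "_cortex"), lobe = lobe,
        diagnosis = ifelse(is_hd_ind, "HD", "control"),
        age = age, sex = sex, bank = bank, cag_length = cag,
        vonsattel_grade = grade, onset_age = onset,
        prop_neurons = prop_neurons,
        postmortem_interval = stats::runif(n_ind, 4, 40),
        stringsAsFactors = FALSE)
    }
  }
  # merge replicate blocks per lobe
  lobe_beta <- list()
  for (lobe in config$lobes) {
    keys <- if (spl > 1) sprintf("%s_s%d", lobe, seq_len(spl)) else lobe
    lobe_beta[[lobe]] <- beta_matrix(do.call(cbind, beta_list[keys]))
  }
  sheet <- sample_sheet(do.call(rbind, c(sheet_rows, make.row.names = FALSE)))

  annotation <- .make_annotation(cpg_ids, seed = config$seed + 3)
  truth <- list(module_label = stats::setNames(module_label, cpg_ids),
                clock_cpgs = clock$cpg_ids,
                hd_modules = seq_len(config$n_hd_modules),
                accel = stats::setNames(accel, ind_ids),
                age_slope = stats::setNames(age_slope, cpg_ids),
                sex_shift = stats::setNames(sex_shift, cpg_ids),
                neuron_coef = stats::setNames(neuron_coef, cpg_ids),
                module_latents = true_eigen)
  list(beta = lobe_beta, sheet = sheet, clock = clock,
       annotation = annotation, truth = truth,
       clip_rate = n_clipped / n_total, config = config)
}

# Pseudo-gene annotation: gene CpG-count distribution 1 (50%), 2 (25%),
# 3-10 (25%); ~10% of CpGs left unannotated to exercise the discard rule.
.make_annotation <- function(cpg_ids, seed) {
  set.seed(as.integer(seed))
  n <- length(cpg_ids)
  n_unann <- floor(n * 0.1)
  unann <- sample(n, n_unann)
  remaining <- sample(setdiff(seq_len(n), unann))
  genes <- character(n)
  g <- 0L
  i <- 1L
  while (i <= length(remaining)) {
    g <- g + 1L
    u <- stats::runif(1)
    size <- if (u < 0.5) 1L else if (u < 0.75) 2L else sample(3:10, 1)
    size <- min(size, length(remaining) - i + 1L)
    genes[remaining[i:(i + size - 1L)]] <- sprintf("gene%04d", g)
    i <- i + size
  }
  data.frame(cpg_id = cpg_ids, gene_symbol = genes,
             chromosome = sample(1:22, n, replace = TRUE),
             position = sample.int(5e7, n), stringsAsFactors = FALSE)
}

#' Write a complete fixture set to disk
#'
#' Emits the TSV interfaces read by the package: one beta matrix per lobe,
#' the sample sheet, the clock file, the CpG annotation, ground-truth
#' tables, gene sets (GMT, built from the planted modules), a key/value
#' config echo, and a JSON manifest listing all paths and the seed.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest (named list), invisibly; also written as
#'   `manifest.json`.
#' @export
write_fixture_set <- function(config = sim_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("write_fixture_set: cannot create ", out_dir)
  sim <- simulate_cohort(config)
  paths <- list()
  for (lobe in names(sim$beta)) {
    p <- file.path(out_dir, sprintf("beta_%s.tsv", lobe))
    write_beta_matrix(sim$beta[[lobe]], p)
    paths[[paste0("beta_", lobe)]] <- p
  }
  paths$sample_sheet <- file.path(out_dir, "sample_sheet.tsv")
  write_tsv(as.data.frame(sim$sheet), paths$sample_sheet)
  paths$clock <- file.path(out_dir, "clock.tsv")
  write_clock_model(sim$clock, paths$clock)
  paths$annotation <- file.path(out_dir, "annotation.tsv")
  write_tsv(sim$annotation, paths$annotation)
  paths$truth_modules <- file.path(out_dir, "truth_modules.tsv")
  write_tsv(data.frame(cpg_id = names(sim$truth$module_label),
                       module = unname(sim$truth$module_label)),
            paths$truth_modules)
  paths$truth_accel <- file.path(out_dir, "truth_accel.tsv")
  write_tsv(data.frame(individual_id = names(sim$truth$accel),
                       accel = unname(sim$truth$accel)),
            paths$truth_accel)
  paths$gene_sets <- file.path(out_dir, "gene_sets.gmt")
  .write_truth_gene_sets(sim, paths$gene_sets)
  paths$config <- file.path(out_dir, "sim_config.txt")
  keys <- names(config)
  writeLines(sprintf("%s: %s", keys,
                     vapply(config[keys], function(v) paste(v, collapse = ","), "")),
             paths$config)
  manifest <- list(seed = config$seed, clip_rate = sim$clip_rate,
                   paths = lapply(paths, normalizePath))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# Gene sets with planted signal: for each true module, the genes whose CpGs
# are mostly in that module, diluted with random genes; plus pure-noise sets.
.write_truth_gene_sets <- function(sim, path) {
  ann <- sim$annotation
  ann <- ann[ann$gene_symbol != "", ]
  lab <- sim$truth$module_label[ann$cpg_id]
  gene_mod <- tapply(lab, ann$gene_symbol, function(l) {
    tb <- table(l[l > 0])
    if (length(tb) == 0) 0L else as.integer(names(tb)[which.max(tb)])
  })
  all_genes <- names(gene_mod)
  lines <- character(0)
  for (m in sort(unique(gene_mod[gene_mod > 0]))) {
    members <- all_genes[gene_mod == m]
    extra <- sample(all_genes[gene_mod != m],
                    size = max(3, round(length(members) / 2)))
    lines <- c(lines, paste(c(sprintf("SET_MOD%d", m),
                              sprintf("genes of planted module %d", m),
                              c(members, extra)), collapse = "\t"))
  }
  for (j in 1:2) {
    lines <- c(lines, paste(c(sprintf("SET_RAND%d", j), "random genes",
                              sample(all_genes, 25)), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
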