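#' Read a flat key/value run configuration file
#'
#' One `key: value` pair per line; `#` starts a comment; list values are
#' comma-separated. Recognized keys include `beta_<lobe>` (one per lobe),
#' `sample_sheet`, `clock`, `annotation`, `gene_sets`, `out_dir`, `stages`
#' (comma list from clock, association, ewas, network, enrichment),
#' `variance_threshold`, `soft_power`, `consensus_quantile`,
#' `min_module_size`, `cut_height`, `winsorize_threshold`, `seed`.
#'
#' @param path Path to the config file.
#' @return Named list of raw string values (lists split on commas).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("read_run_config: file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  if (any(lengths(kv) != 3)) {
    stop("read_run_config: malformed line(s): ",
         paste(lines[lengths(kv) != 3], collapse = "; "))
  }
  vals <- lapply(kv, function(m) {
    v <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
    if (length(v) == 1) v else v
  })
  stats::setNames(vals, vapply(kv, function(m) trimws(m[2]), ""))
}

.num_or <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else as.numeric(cfg[[key]])[1]
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the enabled stages in order (clock, association, ewas, network,
#' enrichment), writing each stage's TSV outputs plus a JSON run manifest
#' with input/output checksums, warnings, and timings under `out_dir`.
#' The enrichment stage requires the network stage.
#'
#' @param config Named list as returned by [read_run_config()], or a path
#'   to such a file.
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_run_config(config)
  }
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("run_pipeline: config must set out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (is.null(config$stages)) {
    c("clock", "association", "ewas", "network", "enrichment")
  } else as.character(config$stages)
  if ("enrichment" %in% stages && !"network" %in% stages) {
    stop("run_pipeline: the enrichment stage requires the network stage; ",
         "enable 'network' or drop 'enrichment'")
  }
  seed <- as.integer(.num_or(config, "seed", 1))
  warnings_log <- character(0)
  log_warn <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  manifest <- list(tool = "epiclocknet",
                   version = as.character(utils::packageVersion("epiclocknet")),
                   seed = seed, stages = list(), inputs = list(),
                   outputs = list(), warnings = character(0))

  beta_keys <- grep("^beta_", names(config), value = TRUE)
  if (length(beta_keys) == 0) stop("run_pipeline: no beta_<lobe> inputs")
  for (k in c(beta_keys, "sample_sheet", "clock", "annotation", "gene_sets")) {
    p <- config[[k]]
    if (!is.null(p)) {
      if (!file.exists(p)) stop("run_pipeline: missing input for ", k, ": ", p)
      manifest$inputs[[k]] <- list(path = p, md5 = unname(tools::md5sum(p)))
    }
  }
  beta_list <- lapply(config[beta_keys], read_beta_matrix)
  names(beta_list) <- sub("^beta_", "", beta_keys)
  sheet <- read_sample_sheet(config$sample_sheet)

  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_tsv(df, p)
    manifest$outputs[[name]] <<- list(path = p, md5 = unname(tools::md5sum(p)))
    p
  }
  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(withCallingHandlers(fn(), warning = log_warn),
                    error = function(e) {
                      stop("stage '", name, "' failed: ", conditionMessage(e),
                           call. = FALSE)
                    })
    manifest$stages[[name]] <<- list(status = "complete",
                                     seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  clock_res <- NULL; ewas_res <- NULL; net <- NULL; resid_list <- NULL
  if ("clock" %in% stages) {
    clock_res <- run_stage("clock", function() {
      model <- read_clock_model(config$clock)
      all_beta <- beta_matrix(do.call(cbind, lapply(beta_list, unclass)))
      al <- align_samples(all_beta, sheet)
      res <- clock_stage(al$beta, al$sheet, model,
                         threshold = .num_or(config, "winsorize_threshold", 15))
      emit(res, "acceleration.tsv")
      res
    })
  }
  if ("association" %in% stages) {
    run_stage("association", function() {
      if (is.null(clock_res)) stop("association requires the clock stage")
      d <- merge(clock_res, as.data.frame(sheet), by = "sample_id")
      out <- list()
      for (m in 1:2) {
        fit <- fit_dnam_model(d, model = m)
        cf <- fit$coefficients
        cf$model <- m
        out[[m]] <- cf
      }
      tab <- do.call(rbind, out)
      emit(tab, "dnam_age_models.tsv")
      tab
    })
  }
  if ("ewas" %in% stages) {
    ewas_res <- run_stage("ewas", function() {
      res <- run_ewas(beta_list, sheet,
                      variance_threshold = .num_or(config, "variance_threshold", 5e-4))
      emit(res$meta, "ewas_meta.tsv")
      for (lobe in names(res$per_lobe)) {
        emit(res$per_lobe[[lobe]], sprintf("ewas_%s.tsv", lobe))
      }
      if (!is.null(config$annotation)) {
        ann <- read_cpg_annotation(config$annotation)
        emit(manhattan_export(res$meta, ann), "manhattan.tsv")
      }
      emit(data.frame(set = names(res$lambda), lambda = unname(res$lambda)),
           "inflation.tsv")
      res
    })
  }
  if ("network" %in% stages) {
    net <- run_stage("network", function() {
      if (is.null(ewas_res)) {
        keep <- variance_filter(beta_list,
                                .num_or(config, "variance_threshold", 5e-4))$keep
      } else keep <- ewas_res$meta$cpg_id
      resid_list <<- lapply(beta_list, function(b) {
        al <- align_samples(beta_matrix(b[keep, , drop = FALSE]), sheet)
        adjust_age_sex(al$beta, al$sheet)
      })
      cfg <- network_config(
        soft_power = .num_or(config, "soft_power", 6),
        consensus_quantile = .num_or(config, "consensus_quantile", 0),
        min_module_size = .num_or(config, "min_module_size", 20),
        cut_height = .num_or(config, "cut_height", 0.995))
      net <- consensus_network(resid_list, cfg)
      emit(data.frame(cpg_id = names(net$modules$labels),
                      module = unname(net$modules$labels),
                      color = unname(net$modules$colors)),
           "modules.tsv")
      if (!is.null(net$membership)) emit(net$membership, "membership.tsv")
      traits <- lapply(resid_list, function(r) {
        s <- sheet[match(colnames(r), sheet$sample_id), ]
        as.numeric(s$diagnosis == "HD")
      })
      if (length(net$eigenvectors) > 0 && ncol(net$eigenvectors[[1]]) > 0) {
        mt <- module_trait_meta(net$eigenvectors, traits)
        emit(mt, "module_trait.tsv")
        for (lobe in names(net$eigenvectors)) {
          ev <- data.frame(sample_id = rownames(net$eigenvectors[[lobe]]),
                           net$eigenvectors[[lobe]], check.names = FALSE)
          emit(ev, sprintf("eigenvectors_%s.tsv", lobe))
        }
      }
      net
    })
  }
  if ("enrichment" %in% stages) {
    run_stage("enrichment", function() {
      if (is.null(net)) stop("enrichment requires the network stage")
      ann <- read_cpg_annotation(config$annotation)
      gene_sets <- read_gmt(config$gene_sets)
      enr <- run_enrichment(ann, names(net$modules$labels), net$adjacency,
                            resid_list, net$modules$labels, gene_sets,
                            q = .num_or(config, "consensus_quantile", 0))
      emit(enr$representatives, "representatives.tsv")
      emit(enr$assignment, "gene_modules.tsv")
      emit(enr$enrichment, "enrichment.tsv")
      enr
    })
  }
  manifest$warnings <- warnings_log
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Summarize a completed run directory as a markdown report
#'
#' Collates acceleration group means, EWAS counts, the module-trait table
#' and the top enrichment rows from the stage TSVs into a single markdown
#' document. Stages absent from the run directory are omitted; an
#' incomplete run produces a partial report with a warning.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @param sheet_path Optional path to the sample sheet (for group labels in
#'   the acceleration summary).
#' @return Path of the written `report.md`, invisibly.
#' @export
report_run <- function(run_dir, sheet_path = NULL) {
  if (!dir.exists(run_dir)) stop("report_run: no such directory: ", run_dir)
  lines <- c("# epiclocknet run report", "")
  f <- function(name) file.path(run_dir, name)
  if (file.exists(f("acceleration.tsv"))) {
    acc <- utils::read.delim(f("acceleration.tsv"))
    lines <- c(lines, "## Epigenetic age acceleration", "")
    if (!is.null(sheet_path) && file.exists(sheet_path)) {
      sheet <- read_sample_sheet(sheet_path)
      acc <- merge(acc, as.data.frame(sheet)[c("sample_id", "diagnosis")])
      for (g in unique(acc$diagnosis)) {
        m <- mean(acc$age_accel[acc$diagnosis == g])
        lines <- c(lines, sprintf("- mean age acceleration, %s: %.2f years",
                                  g, m))
      }
      if (all(c("HD", "control") %in% acc$diagnosis)) {
        d <- mean(acc$age_accel[acc$diagnosis == "HD"]) -
          mean(acc$age_accel[acc$diagnosis == "control"])
        lines <- c(lines, sprintf("- HD minus control: %.2f years", d))
      }
    }
    lines <- c(lines, sprintf("- winsorized samples: %d",
                              sum(acc$winsorized)), "")
  } else {
    warning("report_run: clock stage output missing; partial report")
  }
  if (file.exists(f("ewas_meta.tsv"))) {
    meta <- utils::read.delim(f("ewas_meta.tsv"))
    thr <- bonferroni_threshold(0.05, nrow(meta))
    lines <- c(lines, "## EWAS", "",
               sprintf("- CpGs tested: %d", nrow(meta)),
               sprintf("- meta p < %.3g (Bonferroni over tested CpGs): %d",
                       thr, sum(meta$p_meta < thr)), "")
    if (file.exists(f("inflation.tsv"))) {
      infl <- utils::read.delim(f("inflation.tsv"))
      lines <- c(lines, paste0("- lambda ", infl$set, ": ",
                               sprintf("%.2f", infl$lambda)), "")
    }
  }
  if (file.exists(f("module_trait.tsv"))) {
    mt <- utils::read.delim(f("module_trait.tsv"))
    mt <- mt[order(mt$p_meta), ]
    lines <- c(lines, "## Module-trait associations (HD status)", "",
               "| module | meta Z | meta p |", "|---|---|---|",
               sprintf("| %s | %.2f | %.3g |", mt$module, mt$z_meta,
                       mt$p_meta), "")
  }
  if (file.exists(f("enrichment.tsv"))) {
    enr <- utils::read.delim(f("enrichment.tsv"))
    top <- utils::head(enr[order(enr$p_value), ], 10)
    lines <- c(lines, "## Top gene-set enrichments", "",
               "| module | set | overlap | p |", "|---|---|---|---|",
               sprintf("| %s | %s | %d | %.3g |", top$module, top$set_id,
                       top$overlap, top$p_value), "")
  }
  out <- f("report.md")
  writeLines(lines, out)
  invisible(out)
}
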