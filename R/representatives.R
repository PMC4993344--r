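#' Group retained CpGs by gene
#'
#' CpGs without a gene annotation are discarded; the remaining genes are
#' partitioned into classes by CpG count (1, 2, >= 3), which determines the
#' representative-selection rule applied to each.
#'
#' @param annotation CpG annotation (`cpg_id`, `gene_symbol`, ...).
#' @param retained_cpgs Character vector of CpG ids that survived upstream
#'   filtering.
#' @return List with `groups` (named list gene -> CpG ids),
#'   `n_unannotated` (count of discarded CpGs), `classes` (named vector
#'   "single"/"sd2"/"kim3plus" per gene).
#' @export
gene_cpg_groups <- function(annotation, retained_cpgs) {
  ann <- annotation[match(retained_cpgs, annotation$cpg_id), , drop = FALSE]
  has_gene <- !is.na(ann$gene_symbol) & ann$gene_symbol != ""
  n_unannotated <- sum(!has_gene | is.na(ann$cpg_id))
  ann <- ann[has_gene & !is.na(ann$cpg_id), , drop = FALSE]
  if (nrow(ann) == 0) stop("gene_cpg_groups: no annotated CpGs")
  groups <- split(ann$cpg_id, ann$gene_symbol)
  sizes <- lengths(groups)
  classes <- ifelse(sizes == 1, "single", ifelse(sizes == 2, "sd2", "kim3plus"))
  list(groups = groups, n_unannotated = n_unannotated,
       classes = stats::setNames(classes, names(groups)))
}

#' Consensus intramodular connectivity for one gene's CpG set
#'
#' Treats the gene's CpGs as an artificial module: per lobe, each CpG's kIM
#' is the sum of its signed-hybrid adjacencies to the other CpGs of the
#' gene. The per-lobe kIM vectors are calibrated by quantile normalization
#' and combined component-wise at the consensus quantile q.
#'
#' @param adjacency_list Named list of per-lobe adjacency matrices covering
#'   the gene's CpGs.
#' @param cpgs Character vector of >= 3 CpG ids (one gene).
#' @param q Consensus quantile (default 0 = minimum).
#' @return Named numeric vector: consensus kIM per CpG.
#' @export
consensus_kim <- function(adjacency_list, cpgs, q = 0) {
  if (length(cpgs) < 3) stop("consensus_kim: need >= 3 CpGs (use consensus_sd)")
  kim <- vapply(adjacency_list, function(A) {
    a <- A[cpgs, cpgs, drop = FALSE]
    rowSums(a)  # diagonal is zero, so this is the sum over j != i
  }, numeric(length(cpgs)))
  if (length(adjacency_list) > 1) kim <- quantile_normalize(kim)
  cons <- apply(kim, 1, stats::quantile, probs = q, names = FALSE, type = 7)
  stats::setNames(cons, cpgs)
}

#' Consensus standard deviation for a 2-CpG gene
#'
#' Per lobe, the standard deviation of each CpG; the per-lobe sd vectors
#' are calibrated by quantile normalization and combined component-wise at
#' the consensus quantile q.
#'
#' @param beta_list Named list of per-lobe CpG-by-sample matrices.
#' @param cpgs Character vector of exactly 2 CpG ids.
#' @param q Consensus quantile (default 0).
#' @return Named numeric vector: consensus sd per CpG.
#' @export
consensus_sd <- function(beta_list, cpgs, q = 0) {
  if (length(cpgs) != 2) stop("consensus_sd: exactly 2 CpGs required")
  sds <- vapply(beta_list, function(b) {
    apply(b[cpgs, , drop = FALSE], 1, stats::sd)
  }, numeric(2))
  if (length(beta_list) > 1) sds <- quantile_normalize(sds)
  cons <- apply(sds, 1, stats::quantile, probs = q, names = FALSE, type = 7)
  stats::setNames(cons, cpgs)
}

#' Select one representative CpG per gene
#'
#' Genes with one CpG are represented by it; genes with two CpGs by the CpG
#' with the higher consensus standard deviation; genes with three or more
#' by the consensus hub CpG (highest consensus kIM). Ties break
#' lexicographically on CpG id for determinism.
#'
#' @param groups Output of [gene_cpg_groups()].
#' @param adjacency_list Per-lobe adjacency matrices (for kIM).
#' @param beta_list Per-lobe beta (or residual) matrices (for sd).
#' @param q Consensus quantile.
#' @return `data.frame`: gene_symbol, cpg_id, rule, score.
#' @export
select_representatives <- function(groups, adjacency_list, beta_list, q = 0) {
  genes <- names(groups$groups)
  out <- data.frame(gene_symbol = genes, cpg_id = NA_character_,
                    rule = unname(groups$classes[genes]), score = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    cpgs <- sort(groups$groups[[genes[i]]])
    if (length(cpgs) == 1) {
      out$cpg_id[i] <- cpgs
      out$score[i] <- NA_real_
    } else if (length(cpgs) == 2) {
      sc <- consensus_sd(beta_list, cpgs, q)
      best <- which(sc == max(sc))[1]  # cpgs sorted -> lexicographic tie-break
      out$cpg_id[i] <- cpgs[best]
      out$score[i] <- sc[best]
    } else {
      sc <- consensus_kim(adjacency_list, cpgs, q)
      best <- which(sc == max(sc))[1]
      out$cpg_id[i] <- cpgs[best]
      out$score[i] <- sc[best]
    }
  }
  out
}

#' Assign genes to modules through their representative CpG
#'
#' Each gene inherits the module label (including 0/grey) of its
#' representative CpG.
#'
#' @param representatives Output of [select_representatives()].
#' @param labels Named module label vector from [cut_modules()].
#' @return `data.frame`: gene_symbol, cpg_id, module.
#' @export
gene_module_assignment <- function(representatives, labels) {
  idx <- match(representatives$cpg_id, names(labels))
  if (any(is.na(idx))) {
    stop("gene_module_assignment: representative CpG(s) without a module label: ",
         paste(utils::head(representatives$cpg_id[is.na(idx)], 5), collapse = ", "))
  }
  data.frame(gene_symbol = representatives$gene_symbol,
             cpg_id = representatives$cpg_id,
             module = unname(labels[idx]),
             stringsAsFactors = FALSE)
}

#' Hypergeometric gene-set enrichment of one module
#'
#' Upper-tail hypergeometric probability of observing at least the realized
#' overlap between the module's genes and the gene set, within the stated
#' universe (gene-set membership is intersected with the universe first).
#'
#' @param module_genes Character vector of the module's genes.
#' @param set_genes Character vector of the gene set's members.
#' @param universe Character vector of the enrichment universe (default
#'   choice elsewhere in the package: all represented genes).
#' @return List with `overlap`, `n_module`, `n_set`, `n_universe`,
#'   `p_value`.
#' @export
hypergeometric_enrichment <- function(module_genes, set_genes, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("hypergeometric_enrichment: empty universe")
  module_genes <- unique(intersect(module_genes, universe))
  set_genes <- unique(intersect(set_genes, universe))
  overlap <- length(intersect(module_genes, set_genes))
  p <- stats::phyper(overlap - 1, length(set_genes),
                     length(universe) - length(set_genes),
                     length(module_genes), lower.tail = FALSE)
  list(overlap = overlap, n_module = length(module_genes),
       n_set = length(set_genes), n_universe = length(universe),
       p_value = min(1, p))
}

#' Read gene sets in GMT format
#'
#' Tab-separated lines: set id, description, then member gene symbols.
#'
#' @param path Path to a .gmt file.
#' @return List of lists with `set_id`, `description`, `genes`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("read_gmt: file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("read_gmt: malformed line: ", substr(l, 1, 40))
    list(set_id = parts[1], description = parts[2],
         genes = unique(parts[-(1:2)]))
  })
}

#' Full enrichment stage: representatives, assignment, gene-set tests
#'
#' Runs the consensus-representative procedure (one CpG per gene), assigns
#' genes to modules, and tests every module x gene-set pair
#' hypergeometrically against the universe of all represented genes.
#'
#' @param annotation CpG annotation.
#' @param retained_cpgs CpGs retained upstream (variance filter).
#' @param adjacency_list,beta_list Per-lobe adjacency and beta matrices.
#' @param labels Module labels from [cut_modules()].
#' @param gene_sets List from [read_gmt()] (or same structure).
#' @param q Consensus quantile.
#' @return List with `representatives`, `assignment`, `enrichment`
#'   (data.frame: module, set_id, description, overlap, n_module, n_set,
#'   n_universe, p_value, sorted by p within module).
#' @export
run_enrichment <- function(annotation, retained_cpgs, adjacency_list,
                           beta_list, labels, gene_sets, q = 0) {
  groups <- gene_cpg_groups(annotation, retained_cpgs)
  reps <- select_representatives(groups, adjacency_list, beta_list, q)
  assignment <- gene_module_assignment(reps, labels)
  universe <- assignment$gene_symbol
  mods <- sort(unique(assignment$module[assignment$module > 0]))
  rows <- list()
  for (m in mods) {
    mg <- assignment$gene_symbol[assignment$module == m]
    for (gs in gene_sets) {
      h <- hypergeometric_enrichment(mg, gs$genes, universe)
      rows[[length(rows) + 1]] <- data.frame(
        module = m, set_id = gs$set_id, description = gs$description,
        overlap = h$overlap, n_module = h$n_module, n_set = h$n_set,
        n_universe = h$n_universe, p_value = h$p_value,
        stringsAsFactors = FALSE)
    }
  }
  enrichment <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module = integer(), set_id = character(),
               description = character(), overlap = integer(),
               n_module = integer(), n_set = integer(),
               n_universe = integer(), p_value = numeric())
  enrichment <- enrichment[order(enrichment$module, enrichment$p_value), ,
                           drop = FALSE]
  rownames(enrichment) <- NULL
  list(representatives = reps, assignment = assignment,
       enrichment = enrichment)
}
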