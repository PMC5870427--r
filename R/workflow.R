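#' Assemble a run configuration
#'
#' Either a simulation run (`simulate = TRUE`: inputs come from
#' [generate_bundle()]) or a file-based run (per-system fold-change TSVs
#' plus optional annotations, gene sets, homology map and chemical
#' similarity table). Defaults mirror the standard analysis parameters:
#' k = 200 genes per direction, fold-change threshold 1.5, Dice cutoff
#' 0.4, alpha 0.05, L = 5..60, minimum category size 5.
#'
#' @param simulate run on a synthetic bundle instead of files.
#' @param synthetic a `synthetic_config` for simulation runs.
#' @param matrices named list of per-system fold-change TSV paths.
#' @param fc_scale `"log2"` or `"ratio"`, see [read_fold_change_matrix()].
#' @param annotations,gene_sets,homology,chemical optional input paths.
#' @param k,fc_threshold,cutoff,alpha,L_range,min_members,chem_cutoff
#'   analysis parameters.
#' @param out_dir output directory.
#' @param seed seed for any randomness (simulation, permutation baseline).
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = TRUE, synthetic = synthetic_config(),
                       matrices = NULL, fc_scale = "log2",
                       annotations = NULL, gene_sets = NULL,
                       homology = NULL, chemical = NULL,
                       k = 200L, fc_threshold = 1.5, cutoff = 0.4,
                       alpha = 0.05, L_range = 5:60, min_members = 5L,
                       chem_cutoff = 0.2, out_dir = "tgxprank_out",
                       seed = 1L) {
  if (!simulate) {
    if (is.null(matrices) || length(matrices) < 2L || is.null(names(matrices)))
      stop("file-based runs need a named list of >= 2 per-system matrix paths")
    for (p in c(unlist(matrices), annotations, gene_sets, homology, chemical))
      if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  stopifnot(k >= 1L, fc_threshold > 1, cutoff >= 0, cutoff <= 1,
            alpha > 0, alpha <= 1, min_members >= 2L)
  structure(list(simulate = simulate, synthetic = synthetic,
                 matrices = matrices, fc_scale = fc_scale,
                 annotations = annotations, gene_sets = gene_sets,
                 homology = homology, chemical = chemical,
                 k = as.integer(k), fc_threshold = fc_threshold,
                 cutoff = cutoff, alpha = alpha, L_range = L_range,
                 min_members = as.integer(min_members),
                 chem_cutoff = chem_cutoff, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys match the arguments of [run_config()]; a `synthetic`
#' block holds [synthetic_config()] arguments for simulation runs.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) {
    rho <- y$synthetic$rho
    if (!is.null(rho)) y$synthetic$rho <- do.call(rbind, lapply(rho, unlist))
    for (nm in c("categories", "planted_pathways"))
      if (!is.null(y$synthetic[[nm]]))
        y$synthetic[[nm]] <- do.call(rbind.data.frame, y$synthetic[[nm]])
    y$synthetic <- do.call(synthetic_config, y$synthetic)
  }
  do.call(run_config, y)
}

# internal: append a line to the run log
log_line <- function(state, fmt, ...) {
  state$log <- c(state$log, sprintf(fmt, ...))
  state
}

#' Run the full concordance analysis
#'
#' End-to-end orchestration: signatures, per-system similarity matrices
#' and mean similarity, PRank for every system pair, therapeutic-category
#' stability table, pathway over-representation with frequency rankings
#' and POP curves per system pair, gene-set-restricted PRank with the
#' top-15 pathway intersection, and (when a chemical table is given) the
#' chemical-vs-transcriptomic correlation. All outputs are written under
#' `config$out_dir` as TSV/JSON together with `manifest.json` (stage
#' completion) and `run_log.txt` (every parameter and automatic
#' decision). Reruns with the same config and seed are byte-identical.
#'
#' @param config a `run_config`.
#' @return Invisibly, a list with the in-memory results (`similarity`,
#'   `mean_similarity`, `prank`, `stability`, `enrichment`, `pop`,
#'   `pathway_prank`, `top_overlap`, `chem`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list(log = character(0))
  state <- log_line(state, "parameters: k=%d fc_threshold=%g cutoff=%g alpha=%g L=%d..%d min_members=%d seed=%d",
                    config$k, config$fc_threshold, config$cutoff,
                    config$alpha, min(config$L_range), max(config$L_range),
                    config$min_members, config$seed)
  manifest <- list()
  finish <- function() {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE)
    writeLines(state$log, file.path(config$out_dir, "run_log.txt"))
  }

  # ---- inputs ----
  if (config$simulate) {
    cfg <- config$synthetic
    cfg$seed <- config$seed
    bundle <- generate_bundle(cfg)
    systems <- bundle$matrices
    annotations <- bundle$annotations
    gene_sets <- bundle$gene_sets
    chem <- NULL
    state <- log_line(state, "inputs: synthetic bundle, %d systems x %d genes x %d compounds",
                      length(systems), cfg$n_genes, cfg$n_compounds)
  } else {
    homology <- if (!is.null(config$homology))
      read_homology_map(config$homology) else NULL
    systems <- lapply(names(config$matrices), function(sid)
      read_fold_change_matrix(config$matrices[[sid]], sid,
                              scale = config$fc_scale))
    names(systems) <- names(config$matrices)
    annotations <- if (!is.null(config$annotations))
      read_annotations(config$annotations) else NULL
    gene_sets <- if (!is.null(config$gene_sets))
      read_gene_sets(config$gene_sets, homology = homology) else NULL
    chem <- if (!is.null(config$chemical))
      read_chemical_similarity(config$chemical) else NULL
    state <- log_line(state, "inputs: %d systems read from files", length(systems))
  }
  manifest$inputs <- TRUE

  # ---- similarity ----
  sims <- lapply(names(systems), function(sid)
    pairwise_similarity(system_signatures(systems[[sid]], k = config$k), sid))
  names(sims) <- names(systems)
  for (sid in names(sims))
    write_similarity_matrix(sims[[sid]],
                            file.path(config$out_dir,
                                      paste0("similarity_", sid, ".tsv")))
  mean_sim <- vapply(sims, mean_similarity, numeric(1L))
  utils::write.table(
    data.frame(system_id = names(mean_sim), mean_dice = unname(mean_sim)),
    file.path(config$out_dir, "mean_similarity.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  state <- log_line(state, "similarity: mean Dice %s",
                    paste(sprintf("%s=%.4f", names(mean_sim), mean_sim),
                          collapse = ", "))
  manifest$similarity <- TRUE

  # ---- prank ----
  sys_ids <- names(sims)
  prank_rows <- list()
  for (i in seq_len(length(sys_ids) - 1L)) {
    for (j in seq(i + 1L, length(sys_ids))) {
      res <- prank_score(sims[[i]], sims[[j]], cutoff = config$cutoff)
      prank_rows[[length(prank_rows) + 1L]] <- as.data.frame(res)
    }
  }
  prank_tbl <- do.call(rbind, prank_rows)
  utils::write.table(prank_tbl, file.path(config$out_dir, "prank.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(prank_tbl, file.path(config$out_dir, "prank.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  manifest$prank <- TRUE

  # ---- stability ----
  stability <- NULL
  if (!is.null(annotations)) {
    stability <- suppressMessages(
      stability_table(sims, annotations, min_members = config$min_members))
    utils::write.table(stability, file.path(config$out_dir, "stability.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    state <- log_line(state, "stability: %d (system, category) rows",
                      nrow(stability))
    manifest$stability <- TRUE
  } else {
    state <- log_line(state, "stability: skipped (no annotations)")
    manifest$stability <- FALSE
  }

  # ---- pathway enrichment, POP, gene-set PRank ----
  enr <- pops <- pw_prank <- top_ov <- NULL
  if (!is.null(gene_sets) && length(gene_sets) > 0L) {
    enr <- lapply(systems, enrich_system, gene_sets = gene_sets,
                  k = config$k, alpha = config$alpha)
    for (sid in names(enr)) {
      utils::write.table(enr[[sid]]$table,
                         file.path(config$out_dir,
                                   paste0("enrichment_", sid, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(enr[[sid]]$ranking,
                         file.path(config$out_dir,
                                   paste0("pathway_ranking_", sid, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    pops <- list()
    for (i in seq_len(length(sys_ids) - 1L)) {
      for (j in seq(i + 1L, length(sys_ids))) {
        pc <- suppressMessages(pop(enr[[i]], enr[[j]],
                                   L_range = config$L_range))
        key <- paste(sys_ids[i], sys_ids[j], sep = "_vs_")
        pops[[key]] <- pc
        write_pop_curve(pc, file.path(config$out_dir,
                                      paste0("pop_", key, ".tsv")))
      }
    }
    jsonlite::write_json(lapply(pops, function(p) p$summary),
                         file.path(config$out_dir, "pop_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    pw_prank <- suppressMessages(
      prank_by_geneset(systems, gene_sets,
                       fc_threshold = config$fc_threshold,
                       cutoff = config$cutoff))
    utils::write.table(pw_prank,
                       file.path(config$out_dir, "pathway_prank.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    top_ov <- top_pathway_overlap(pw_prank, l = 15L)
    jsonlite::write_json(top_ov,
                         file.path(config$out_dir, "pathway_top15.json"),
                         auto_unbox = TRUE)
    state <- log_line(state, "pathways: %d sets; common top-15 across pairs: %d",
                      length(gene_sets), length(top_ov$common))
    manifest$pathways <- TRUE
  } else {
    state <- log_line(state, "pathways: skipped (no gene sets)")
    manifest$pathways <- FALSE
  }

  # ---- chemical space ----
  chem_res <- NULL
  if (!is.null(chem)) {
    chem_res <- lapply(sims, function(s)
      tryCatch(chem_tgx_correlation(s, chem, chem_cutoff = config$chem_cutoff),
               error = function(e) {message(conditionMessage(e)); NULL}))
    keep <- !vapply(chem_res, is.null, logical(1L))
    if (any(keep)) {
      df <- data.frame(system_id = names(chem_res)[keep],
                       pearson_r = vapply(chem_res[keep], `[[`, 1, "r"),
                       n_pairs = vapply(chem_res[keep], `[[`, 1L, "n_pairs"))
      utils::write.table(df, file.path(config$out_dir, "chem_correlation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest$chemical <- TRUE
  } else {
    manifest$chemical <- FALSE
  }

  finish()
  invisible(list(similarity = sims, mean_similarity = mean_sim,
                 prank = prank_tbl, stability = stability,
                 enrichment = enr, pop = pops, pathway_prank = pw_prank,
                 top_overlap = top_ov, chem = chem_res))
}
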