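#' Binarize a similarity matrix at a Dice cutoff
#'
#' Each unordered compound pair is called positive (1) when its Dice
#' coefficient is strictly greater than the cutoff, else negative (0);
#' the diagonal is excluded. The default 0.4 sits close to the 95%
#' quantile of pairwise Dice values in typical whole-transcriptome runs;
#' a quantile mode is available to set the cutoff from the data.
#'
#' @param matrix a `similarity_matrix`.
#' @param cutoff strict Dice cutoff (default 0.4).
#' @param quantile if non-NULL (e.g. 0.95), the cutoff is replaced by this
#'   quantile of the off-diagonal values.
#' @return Named integer vector of 0/1 labels keyed by unordered pair,
#'   with attribute `cutoff` recording the cutoff actually used.
#' @export
binarize <- function(matrix, cutoff = 0.4, quantile = NULL) {
  pairs <- sim_pairs(matrix)
  if (!is.null(quantile)) {
    stopifnot(quantile > 0, quantile < 1)
    cutoff <- stats::quantile(pairs$value, probs = quantile, names = FALSE)
  }
  labels <- stats::setNames(as.integer(pairs$value > cutoff), pairs$key)
  attr(labels, "cutoff") <- cutoff
  labels
}

#' ROC-AUC by the rank (Mann-Whitney) formulation
#'
#' The AUC equals the probability that a randomly chosen positive pair is
#' scored above a randomly chosen negative pair, with tied scores counting
#' 1/2. Computed via midranks: AUC = (R1 - n1(n1+1)/2) / (n1 n0), where R1
#' is the rank sum of the positives.
#'
#' @param labels named 0/1 vector.
#' @param scores named numeric vector over the same keys.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(labels, scores) {
  if (!is.null(names(labels)) && !is.null(names(scores))) {
    if (!setequal(names(labels), names(scores)))
      stop("labels and scores must be keyed by the same pairs")
    scores <- scores[names(labels)]
  } else if (length(labels) != length(scores)) {
    stop("labels and scores must have equal length")
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L) stop("no positive labels; AUC undefined")
  if (n0 == 0L) stop("no negative labels; AUC undefined")
  r <- rank(scores)  # midranks for ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Inter-system concordance (PRank score)
#'
#' Binarizes each system's pairwise compound similarities at the cutoff
#' and asks how well the other system's similarities rank those calls,
#' via ROC-AUC. Both label directions are computed and averaged into the
#' symmetric `prank_score`; the per-direction AUCs are retained. Compound
#' sets are intersected automatically (with a message) when the two
#' systems do not share all compounds.
#'
#' @param sim_a,sim_b `similarity_matrix` objects.
#' @param cutoff strict Dice cutoff for binarization (default 0.4).
#' @param quantile optional quantile-mode cutoff, see [binarize()].
#' @return A `prank_result`: list with `system_pair`, `cutoff` (per
#'   system), `auc_a_labels`, `auc_b_labels`, `prank_score`, `n_pairs`,
#'   `n_positive_a`, `n_positive_b`, `partial` (TRUE when one direction is
#'   single-class and only the other AUC enters the score).
#' @export
prank_score <- function(sim_a, sim_b, cutoff = 0.4, quantile = NULL) {
  stopifnot(inherits(sim_a, "similarity_matrix"),
            inherits(sim_b, "similarity_matrix"))
  common <- intersect(sim_a$compound_ids, sim_b$compound_ids)
  if (length(common) < 2L)
    stop("systems share fewer than 2 compounds")
  if (length(common) < length(sim_a$compound_ids) ||
      length(common) < length(sim_b$compound_ids))
    message(sprintf("prank_score: intersecting to %d common compounds (%s: %d, %s: %d)",
                    length(common), sim_a$system_id,
                    length(sim_a$compound_ids), sim_b$system_id,
                    length(sim_b$compound_ids)))
  sub <- function(s) similarity_matrix(
    s$values[common, common, drop = FALSE], s$system_id)
  sim_a <- sub(sim_a); sim_b <- sub(sim_b)
  labels_a <- binarize(sim_a, cutoff = cutoff, quantile = quantile)
  labels_b <- binarize(sim_b, cutoff = cutoff, quantile = quantile)
  scores_a <- stats::setNames(sim_pairs(sim_a)$value, sim_pairs(sim_a)$key)
  scores_b <- stats::setNames(sim_pairs(sim_b)$value, sim_pairs(sim_b)$key)
  auc_dir <- function(labels, scores) {
    if (length(unique(as.integer(labels))) < 2L) return(NA_real_)
    roc_auc(labels, scores)
  }
  auc_a <- auc_dir(labels_a, scores_b)
  auc_b <- auc_dir(labels_b, scores_a)
  aucs <- c(auc_a, auc_b)
  partial <- anyNA(aucs)
  score <- if (all(is.na(aucs))) NA_real_ else mean(aucs, na.rm = TRUE)
  structure(
    list(system_pair = c(sim_a$system_id, sim_b$system_id),
         cutoff = c(attr(labels_a, "cutoff"), attr(labels_b, "cutoff")),
         auc_a_labels = auc_a, auc_b_labels = auc_b,
         prank_score = score, n_pairs = length(labels_a),
         n_positive_a = sum(labels_a), n_positive_b = sum(labels_b),
         partial = partial),
    class = "prank_result"
  )
}

#' @export
print.prank_result <- function(x, ...) {
  cat(sprintf("<prank_result> %s vs %s: PRank = %s (AUC %s / %s over %d pairs%s)\n",
              x$system_pair[1L], x$system_pair[2L],
              format(round(x$prank_score, 3)),
              format(round(x$auc_a_labels, 3)),
              format(round(x$auc_b_labels, 3)), x$n_pairs,
              if (x$partial) ", partial" else ""))
  invisible(x)
}

#' @export
as.data.frame.prank_result <- function(x, ...) {
  data.frame(system_a = x$system_pair[1L], system_b = x$system_pair[2L],
             auc_a_labels = x$auc_a_labels, auc_b_labels = x$auc_b_labels,
             prank_score = x$prank_score, n_pairs = x$n_pairs,
             n_positive_a = x$n_positive_a, n_positive_b = x$n_positive_b,
             partial = x$partial, stringsAsFactors = FALSE)
}

#' Gene-set-restricted PRank across systems
#'
#' For each pathway: builds threshold-mode signatures restricted to the
#' pathway's genes in every system, computes pairwise Dice within each
#' system, and scores every system pair with [prank_score()]. Pathways
#' where a direction has single-class labels are reported with `partial`
#' or `NA` scores, never silently dropped.
#'
#' @param systems named list of `fc_matrix` (>= 2 systems).
#' @param gene_sets a `gene_set_collection`.
#' @param fc_threshold ratio-scale fold-change cutoff for the signatures
#'   (default 1.5).
#' @param cutoff Dice cutoff for binarization (default 0.4).
#' @return data.frame with one row per (pathway, system pair):
#'   pathway_id, system_a, system_b, per-direction AUCs, prank_score,
#'   n_pairs, partial.
#' @export
prank_by_geneset <- function(systems, gene_sets, fc_threshold = 1.5,
                             cutoff = 0.4) {
  stopifnot(length(systems) >= 2L, inherits(gene_sets, "gene_set_collection"))
  sys_ids <- names(systems)
  if (is.null(sys_ids)) stop("`systems` must be a named list")
  rows <- list()
  for (pw in names(gene_sets$sets)) {
    genes <- gene_sets$sets[[pw]]
    sims <- lapply(sys_ids, function(sid) {
      m <- systems[[sid]]
      sigs <- suppressWarnings(lapply(m$compound_ids, function(cpd)
        make_geneset_signature(m, cpd, genes, fc_threshold = fc_threshold)))
      pairwise_similarity(sigs, sid)
    })
    names(sims) <- sys_ids
    for (i in seq_len(length(sys_ids) - 1L)) {
      for (j in seq(i + 1L, length(sys_ids))) {
        res <- tryCatch(
          prank_score(sims[[i]], sims[[j]], cutoff = cutoff),
          error = function(e) NULL)
        row <- if (is.null(res)) {
          data.frame(system_a = sys_ids[i], system_b = sys_ids[j],
                     auc_a_labels = NA_real_, auc_b_labels = NA_real_,
                     prank_score = NA_real_, n_pairs = NA_integer_,
                     n_positive_a = NA_integer_, n_positive_b = NA_integer_,
                     partial = TRUE, stringsAsFactors = FALSE)
        } else as.data.frame(res)
        rows[[length(rows) + 1L]] <- cbind(pathway_id = pw, row)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Top-L pathways per system pair and their intersection
#'
#' Ranks pathways by PRank score within each system pair of a
#' [prank_by_geneset()] table (undefined scores last, ties broken by
#' pathway id) and intersects the per-pair top-L lists.
#'
#' @param tbl output of [prank_by_geneset()].
#' @param l list length per pair (default 15).
#' @return list with `top` (named list of character vectors per pair) and
#'   `common` (pathways present in every pair's top-L).
#' @export
top_pathway_overlap <- function(tbl, l = 15L) {
  pair_id <- paste(tbl$system_a, tbl$system_b, sep = "|")
  top <- lapply(split(tbl, pair_id), function(d) {
    d <- d[order(-d$prank_score, d$pathway_id, na.last = TRUE), ]
    utils::head(d$pathway_id[!is.na(d$prank_score)], l)
  })
  list(top = top, common = Reduce(intersect, top))
}

#' PRank over a grid of dose/time conditions
#'
#' Runs the top/bottom-k signature + Dice + PRank pipeline for every
#' condition and every system pair within that condition.
#'
#' @param grids named list (condition label -> named list of `fc_matrix`,
#'   one per system; each condition needs >= 2 systems).
#' @param cutoff Dice cutoff (default 0.4).
#' @param k signature size per direction (default 200).
#' @return Long data.frame: condition, dose, time, system pair columns,
#'   AUCs, prank_score, n_pairs, partial.
#' @export
condition_sweep <- function(grids, cutoff = 0.4, k = 200L) {
  stopifnot(is.list(grids), !is.null(names(grids)))
  rows <- list()
  for (cond in names(grids)) {
    systems <- grids[[cond]]
    if (length(systems) < 2L)
      stop("condition ", cond, " has fewer than 2 systems")
    sims <- lapply(names(systems), function(sid)
      pairwise_similarity(system_signatures(systems[[sid]], k = k), sid))
    names(sims) <- names(systems)
    cond_lab <- systems[[1L]]$condition
    for (i in seq_len(length(systems) - 1L)) {
      for (j in seq(i + 1L, length(systems))) {
        res <- prank_score(sims[[i]], sims[[j]], cutoff = cutoff)
        rows[[length(rows) + 1L]] <- cbind(
          condition = cond, dose = cond_lab[[1L]], time = cond_lab[[2L]],
          as.data.frame(res))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
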