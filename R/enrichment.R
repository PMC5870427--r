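#' One-sided over-representation test (Fisher / hypergeometric upper tail)
#'
#' Tests whether a compound signature is enriched for a pathway's genes
#' against a gene universe. With N = |universe|, K = |pathway ∩ universe|,
#' n = |signature| and k = |signature ∩ pathway|, the p-value is the
#' hypergeometric upper tail P(X >= k), the one-sided Fisher exact test
#' for over-representation.
#'
#' @param signature_genes character vector, must be a subset of `universe`.
#' @param pathway_genes character vector; intersected with the universe
#'   first.
#' @param universe character vector of measured genes.
#' @return list with `k`, `K`, `n`, `N`, `p_value`.
#' @export
fisher_enrich <- function(signature_genes, pathway_genes, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty gene universe")
  signature_genes <- unique(as.character(signature_genes))
  if (!all(signature_genes %in% universe))
    stop("signature contains genes outside the universe: ",
         setdiff(signature_genes, universe)[1L])
  path <- intersect(unique(as.character(pathway_genes)), universe)
  N <- length(universe)
  K <- length(path)
  n <- length(signature_genes)
  k <- length(intersect(signature_genes, path))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  list(k = k, K = K, n = n, N = N, p_value = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted values in input order: p(i) * m / rank(i) with the running
#' minimum enforced from the largest rank down, capped at 1.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return numeric vector of adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p_values) {
  p_values <- as.numeric(p_values)
  bad <- which(!is.finite(p_values) | p_values <= 0 | p_values > 1)
  if (length(bad))
    stop("p-value outside (0, 1] at position ", bad[1L])
  stats::p.adjust(p_values, method = "BH")
}

#' Per-compound pathway over-representation for one assay system
#'
#' For every compound: the 2k-gene combined signature (up and down pooled;
#' over-representation is direction-agnostic) is tested against each
#' pathway with [fisher_enrich()] over the universe of the matrix's
#' genes, and BH adjustment is applied across pathways within that
#' compound. Pathways are then ranked by perturbation frequency — the
#' number of compounds with adjusted p <= alpha — descending, ties broken
#' by ascending pathway id.
#'
#' @param matrix an `fc_matrix`.
#' @param gene_sets a `gene_set_collection`.
#' @param k signature size per direction (default 200).
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @return An `enrichment_result`: list with `system_id`, `table` (long
#'   data.frame: compound_id, pathway_id, k, K, n, N, p_value,
#'   adjusted_p, significant) and `ranking` (data.frame: rank,
#'   pathway_id, frequency).
#' @export
enrich_system <- function(matrix, gene_sets, k = 200L, alpha = 0.05) {
  stopifnot(inherits(matrix, "fc_matrix"),
            inherits(gene_sets, "gene_set_collection"))
  universe <- matrix$gene_ids
  pw_ids <- names(gene_sets$sets)
  if (!length(pw_ids)) stop("gene-set collection is empty")
  rows <- list()
  for (cpd in matrix$compound_ids) {
    sig <- make_signature(matrix, cpd, k = k)
    genes <- c(sig$up, sig$down)
    res <- lapply(pw_ids, function(pw)
      fisher_enrich(genes, gene_sets$sets[[pw]], universe))
    p <- vapply(res, `[[`, numeric(1L), "p_value")
    adj <- bh_adjust(p)
    rows[[cpd]] <- data.frame(
      compound_id = cpd, pathway_id = pw_ids,
      k = vapply(res, `[[`, numeric(1L), "k"),
      K = vapply(res, `[[`, numeric(1L), "K"),
      n = vapply(res, `[[`, numeric(1L), "n"),
      N = vapply(res, `[[`, numeric(1L), "N"),
      p_value = p, adjusted_p = adj, significant = adj <= alpha,
      stringsAsFactors = FALSE)
  }
  tbl <- do.call(rbind, rows)
  rownames(tbl) <- NULL
  freq <- tapply(tbl$significant, tbl$pathway_id, sum)
  freq <- freq[pw_ids]
  ord <- order(-freq, pw_ids)
  ranking <- data.frame(rank = seq_along(pw_ids),
                        pathway_id = pw_ids[ord],
                        frequency = as.integer(freq[ord]),
                        stringsAsFactors = FALSE)
  structure(list(system_id = matrix$system_id, alpha = alpha,
                 table = tbl, ranking = ranking),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> system %s: %d compounds x %d pathways, %d significant calls (BH p <= %g)\n",
              x$system_id, length(unique(x$table$compound_id)),
              nrow(x$ranking), sum(x$table$significant), x$alpha))
  invisible(x)
}

#' Percentage of overlapping pathways (POP) between two ranked lists
#'
#' POP(L) = |top-L(a) ∩ top-L(b)| / L for each L in `L_range`; the curve
#' is summarized by its mean over L. When a list is shorter than
#' max(L_range), the range is truncated to the shorter list with a
#' message.
#'
#' @param list_a,list_b ranked pathway lists: either `enrichment_result`
#'   objects, ranking data.frames, or character vectors (best first).
#' @param L_range integer vector of list depths (default 5:60).
#' @return A `pop_curve`: list with `pair`, `L`, `pop`, `summary`.
#' @export
pop <- function(list_a, list_b, L_range = 5:60) {
  as_ranked <- function(x) {
    if (inherits(x, "enrichment_result"))
      return(list(id = x$system_id, pw = x$ranking$pathway_id))
    if (is.data.frame(x)) return(list(id = NA_character_, pw = x$pathway_id))
    list(id = NA_character_, pw = as.character(x))
  }
  a <- as_ranked(list_a); b <- as_ranked(list_b)
  if (!length(a$pw) || !length(b$pw)) stop("empty ranked pathway list")
  shortest <- min(length(a$pw), length(b$pw))
  if (max(L_range) > shortest) {
    message(sprintf("pop: truncating L range to the shorter list (%d pathways)",
                    shortest))
    L_range <- L_range[L_range <= shortest]
    if (!length(L_range)) stop("no usable L: shortest list has ", shortest,
                               " pathways, below min(L_range)")
  }
  pops <- vapply(L_range, function(L)
    length(intersect(a$pw[seq_len(L)], b$pw[seq_len(L)])) / L, numeric(1L))
  structure(list(pair = c(a$id, b$id), L = as.integer(L_range), pop = pops,
                 summary = mean(pops)),
            class = "pop_curve")
}

#' @export
print.pop_curve <- function(x, ...) {
  cat(sprintf("<pop_curve> %s vs %s: mean POP %.3f over L = %d..%d\n",
              x$pair[1L], x$pair[2L], x$summary, min(x$L), max(x$L)))
  invisible(x)
}

#' Write a POP curve as TSV (L, pop)
#' @param x a `pop_curve`.
#' @param path output path.
#' @export
write_pop_curve <- function(x, path) {
  utils::write.table(data.frame(L = x$L, pop = x$pop), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
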