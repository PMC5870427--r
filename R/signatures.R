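#' Directional compound signature
#'
#' @param compound_id compound identifier.
#' @param up,down character vectors of gene ids, disjoint.
#' @param mode `"topk"` (fixed-size top/bottom-k lists) or `"threshold"`
#'   (fold-change-thresholded, data-dependent sizes).
#' @param k the k used for a topk signature (`NA` for threshold mode).
#' @return A `tgx_signature`.
#' @export
tgx_signature <- function(compound_id, up, down,
                          mode = c("topk", "threshold"), k = NA_integer_) {
  mode <- match.arg(mode)
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (length(intersect(up, down)))
    stop("up and down gene sets overlap: ", intersect(up, down)[1L])
  if (mode == "topk") {
    k <- as.integer(k)
    if (is.na(k) || length(up) != k || length(down) != k)
      stop("topk signature must have exactly k up and k down genes")
  }
  structure(list(compound_id = as.character(compound_id)[1L],
                 up = up, down = down, mode = mode, k = k),
            class = "tgx_signature")
}

#' @export
print.tgx_signature <- function(x, ...) {
  cat(sprintf("<tgx_signature> %s [%s]: %d up / %d down genes\n",
              x$compound_id, x$mode, length(x$up), length(x$down)))
  invisible(x)
}

#' Top/bottom-k directional signature of a compound
#'
#' The compound's signature is the k genes with the largest log2 fold
#' change (up) and the k with the smallest (down). Ties at either boundary
#' are broken by ascending lexicographic gene id, so the result is
#' deterministic and invariant to the row order of the matrix. Profiles so
#' degenerate that the two lists would overlap (massive ties around a
#' single value) are rejected.
#'
#' @param matrix an `fc_matrix`.
#' @param compound_id compound to extract.
#' @param k genes per direction (default 200, i.e. a 400-gene signature).
#' @return A `tgx_signature` of mode `"topk"`.
#' @export
make_signature <- function(matrix, compound_id, k = 200L) {
  stopifnot(inherits(matrix, "fc_matrix"))
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (!compound_id %in% matrix$compound_ids)
    stop("compound not in matrix: ", compound_id)
  n <- length(matrix$gene_ids)
  if (n < 2L * k)
    stop(sprintf("matrix has %d genes; top/bottom-%d signatures need at least %d",
                 n, k, 2L * k))
  v <- matrix$values[, compound_id]
  genes <- matrix$gene_ids
  up <- genes[order(-v, genes)][seq_len(k)]
  down <- genes[order(v, genes)][seq_len(k)]
  if (length(intersect(up, down)))
    stop("tied fold changes make the top and bottom lists overlap for ",
         compound_id, "; profile too degenerate for a top/bottom-k signature")
  tgx_signature(compound_id, up, down, mode = "topk", k = k)
}

#' Gene-set-restricted threshold signature
#'
#' Restricts the profile to genes in `gene_set` that are measured in the
#' matrix, then keeps genes whose fold change exceeds `fc_threshold` on
#' the ratio scale in either direction: up if log2FC > log2(threshold),
#' down if log2FC < -log2(threshold). Sizes are data-dependent and may be
#' zero.
#'
#' @param matrix an `fc_matrix`.
#' @param compound_id compound to extract.
#' @param gene_set character vector of gene ids (e.g. one pathway).
#' @param fc_threshold ratio-scale fold-change cutoff, strictly > 1
#'   (default 1.5; strict inequality, "more than 1.5-fold").
#' @return A `tgx_signature` of mode `"threshold"`.
#' @export
make_geneset_signature <- function(matrix, compound_id, gene_set,
                                   fc_threshold = 1.5) {
  stopifnot(inherits(matrix, "fc_matrix"))
  if (fc_threshold <= 1)
    stop("fc_threshold is on the ratio scale and must be > 1")
  if (!compound_id %in% matrix$compound_ids)
    stop("compound not in matrix: ", compound_id)
  genes <- intersect(matrix$gene_ids, unique(as.character(gene_set)))
  if (!length(genes))
    warning("gene set shares no genes with the matrix; signature for ",
            compound_id, " is empty")
  v <- matrix$values[genes, compound_id]
  thr <- log2(fc_threshold)
  tgx_signature(compound_id,
                up = genes[v > thr], down = genes[v < -thr],
                mode = "threshold")
}

#' Build topk signatures for every compound of a system
#'
#' @param matrix an `fc_matrix`.
#' @param k genes per direction.
#' @return Named list of `tgx_signature` (one per compound).
#' @export
system_signatures <- function(matrix, k = 200L) {
  stopifnot(inherits(matrix, "fc_matrix"))
  sigs <- lapply(matrix$compound_ids, function(cpd)
    make_signature(matrix, cpd, k = k))
  stats::setNames(sigs, matrix$compound_ids)
}

#' Serialize signatures as long TSV (compound_id, direction, gene_id)
#' @param signatures list of `tgx_signature`.
#' @param path output path.
#' @export
write_signatures <- function(signatures, path) {
  rows <- lapply(signatures, function(s) {
    rbind(
      if (length(s$up)) data.frame(compound_id = s$compound_id,
                                   direction = "up", gene_id = s$up),
      if (length(s$down)) data.frame(compound_id = s$compound_id,
                                     direction = "down", gene_id = s$down)
    )
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
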