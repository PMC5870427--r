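#' Direction-aware Dice similarity of two signatures
#'
#' Counts overlapping genes separately by regulation direction: with
#' N_up = |up_a ∩ up_b| and N_down = |down_a ∩ down_b|,
#' Dice = 2 (N_up + N_down) / (|up_a| + |down_a| + |up_b| + |down_b|).
#' For two top/bottom-k signatures this reduces to (N_up + N_down) / (2k),
#' i.e. (N_up + N_down) / 400 at the default k = 200. Genes up in one
#' compound and down in the other contribute nothing (no penalty term).
#'
#' @param sig_a,sig_b `tgx_signature` objects of the same mode (and, for
#'   topk, the same k).
#' @param denominator `"signature"` (default; the generalized form above)
#'   or `"fixed"` to force the denominator to `fixed_denom` genes for
#'   threshold-mode signatures.
#' @param fixed_denom denominator used when `denominator = "fixed"`
#'   (default 800, matching two 400-gene signatures).
#' @return Dice coefficient in [0, 1]; defined as 0 when both signatures
#'   are empty.
#' @export
dice <- function(sig_a, sig_b, denominator = c("signature", "fixed"),
                 fixed_denom = 800L) {
  stopifnot(inherits(sig_a, "tgx_signature"), inherits(sig_b, "tgx_signature"))
  denominator <- match.arg(denominator)
  if (sig_a$mode != sig_b$mode)
    stop("cannot mix signature modes: ", sig_a$mode, " vs ", sig_b$mode)
  if (sig_a$mode == "topk" && sig_a$k != sig_b$k)
    stop("topk signatures have different k: ", sig_a$k, " vs ", sig_b$k)
  n_up <- length(intersect(sig_a$up, sig_b$up))
  n_down <- length(intersect(sig_a$down, sig_b$down))
  denom <- if (sig_a$mode == "topk") 4L * sig_a$k
           else if (denominator == "fixed") fixed_denom
           else length(sig_a$up) + length(sig_a$down) +
                length(sig_b$up) + length(sig_b$down)
  if (denom == 0) return(0)
  2 * (n_up + n_down) / denom
}

#' Construct a similarity matrix object
#' @param values symmetric numeric matrix of Dice coefficients with
#'   compound ids as dimnames; diagonal is 1 by definition.
#' @param system_id assay-system label.
#' @return A `similarity_matrix`.
#' @export
similarity_matrix <- function(values, system_id) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(rownames(values)))
    stop("similarity matrix needs compound ids as dimnames")
  if (!isTRUE(all.equal(values, t(values), tolerance = 0)))
    stop("similarity matrix must be exactly symmetric")
  if (any(values < 0 | values > 1))
    stop("similarity values must lie in [0, 1]")
  diag(values) <- 1
  structure(list(values = values, system_id = as.character(system_id)[1L],
                 compound_ids = rownames(values)),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> system %s: %d compounds (%d pairs)\n",
              x$system_id, length(x$compound_ids),
              choose(length(x$compound_ids), 2L)))
  invisible(x)
}

#' Pairwise direction-aware Dice similarity within a system
#'
#' Computes [dice()] over all unordered compound pairs. Internally uses
#' 0/1 incidence matrices and cross products, which count the same set
#' intersections exactly (integer counts).
#'
#' @param signatures list of `tgx_signature` with unique compound ids,
#'   all of the same mode.
#' @param system_id assay-system label.
#' @param denominator,fixed_denom passed to [dice()] for threshold mode.
#' @return A `similarity_matrix` (diagonal 1).
#' @export
pairwise_similarity <- function(signatures, system_id,
                                denominator = c("signature", "fixed"),
                                fixed_denom = 800L) {
  denominator <- match.arg(denominator)
  if (length(signatures) < 2L)
    stop("need at least 2 signatures")
  ids <- vapply(signatures, function(s) s$compound_id, character(1L))
  if (anyDuplicated(ids))
    stop("duplicate compound id: ", ids[duplicated(ids)][1L])
  modes <- unique(vapply(signatures, function(s) s$mode, character(1L)))
  if (length(modes) != 1L)
    stop("all signatures must share one mode, found: ",
         paste(modes, collapse = ", "))
  if (modes == "topk") {
    ks <- unique(vapply(signatures, function(s) s$k, integer(1L)))
    if (length(ks) != 1L)
      stop("topk signatures have different k: ", paste(ks, collapse = ", "))
  }
  universe <- sort(unique(unlist(lapply(signatures, function(s)
    c(s$up, s$down)))))
  n <- length(signatures)
  if (length(universe) == 0L) {
    vals <- matrix(0, n, n, dimnames = list(ids, ids))
    return(similarity_matrix(vals, system_id))
  }
  U <- matrix(0L, length(universe), n, dimnames = list(universe, ids))
  D <- U
  for (j in seq_len(n)) {
    U[signatures[[j]]$up, j] <- 1L
    D[signatures[[j]]$down, j] <- 1L
  }
  n_up <- crossprod(U)
  n_down <- crossprod(D)
  if (modes == "topk") {
    vals <- (n_up + n_down) / (2L * signatures[[1L]]$k)
  } else if (denominator == "fixed") {
    vals <- 2 * (n_up + n_down) / fixed_denom
  } else {
    sizes <- colSums(U) + colSums(D)
    denom <- outer(sizes, sizes, `+`)
    vals <- 2 * (n_up + n_down) / denom
    vals[denom == 0] <- 0
  }
  dimnames(vals) <- list(ids, ids)
  similarity_matrix(vals, system_id)
}

# internal: strict upper-triangle pairs of a similarity matrix, as a
# data.frame with a canonical unordered-pair key
sim_pairs <- function(x) {
  stopifnot(inherits(x, "similarity_matrix"))
  ids <- x$compound_ids
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  data.frame(a = ids[idx[, 1L]], b = ids[idx[, 2L]],
             key = pair_key(ids[idx[, 1L]], ids[idx[, 2L]]),
             value = x$values[idx], stringsAsFactors = FALSE)
}

#' Mean off-diagonal similarity of a system
#'
#' Arithmetic mean of the Dice coefficient over the strict upper triangle
#' (all distinct compound pairs); the diagonal is excluded by definition.
#'
#' @param matrix a `similarity_matrix` with at least 2 compounds.
#' @return mean Dice coefficient.
#' @export
mean_similarity <- function(matrix) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  if (length(matrix$compound_ids) < 2L)
    stop("mean similarity needs at least one distinct compound pair")
  mean(matrix$values[upper.tri(matrix$values)])
}

#' Correlation of transcriptomic and chemical similarity
#'
#' Pearson correlation between precomputed chemical similarity (e.g.
#' FCFP-4 Dice) and transcriptomic Dice similarity, over unordered
#' compound pairs present in both inputs whose chemical similarity is
#' strictly greater than `chem_cutoff`.
#'
#' @param tgx a `similarity_matrix`.
#' @param chem a `chem_similarity` table.
#' @param chem_cutoff strict lower cutoff on chemical similarity
#'   (default 0.2).
#' @return list with `r` (Pearson correlation) and `n_pairs`.
#' @export
chem_tgx_correlation <- function(tgx, chem, chem_cutoff = 0.2) {
  stopifnot(inherits(tgx, "similarity_matrix"),
            inherits(chem, "chem_similarity"))
  pairs <- sim_pairs(tgx)
  keep <- pairs$key %in% names(chem)
  pairs <- pairs[keep, , drop = FALSE]
  cv <- unclass(chem)[pairs$key]
  surv <- cv > chem_cutoff
  if (sum(surv) < 3L)
    stop(sprintf("only %d pairs have chemical similarity > %g; need at least 3 for a correlation",
                 sum(surv), chem_cutoff))
  list(r = stats::cor(cv[surv], pairs$value[surv], method = "pearson"),
       n_pairs = sum(surv))
}

#' Write a similarity matrix (square TSV and/or long format)
#'
#' @param x a `similarity_matrix`.
#' @param path output path.
#' @param format `"square"` (ids as header row and first column) or
#'   `"long"` (compound_i, compound_j, similarity; strict upper triangle).
#' @export
write_similarity_matrix <- function(x, path, format = c("square", "long")) {
  stopifnot(inherits(x, "similarity_matrix"))
  format <- match.arg(format)
  if (format == "square") {
    df <- data.frame(compound_id = x$compound_ids, x$values,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    pairs <- sim_pairs(x)
    utils::write.table(pairs[, c("a", "b", "value")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       col.names = c("compound_i", "compound_j", "similarity"))
  }
  invisible(path)
}
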