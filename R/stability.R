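#' Stability ratio of one therapeutic category in one system
#'
#' The stability ratio contrasts within-category and across-category mean
#' pairwise Dice similarity: ratio = mean(Dice over within-category
#' pairs) / mean(Dice over across-category pairs). A ratio above 1 means
#' compounds sharing the category look more alike transcriptomically than
#' compounds from different categories, i.e. the assay discriminates the
#' category.
#'
#' Pair pools for a focal category (ATC level-2 code):
#' \itemize{
#'   \item within ("inter"): both compounds carry the code;
#'   \item across (`across = "focal"`, default): exactly one compound
#'     carries the code and the two compounds share no level-2 code at
#'     all. Pairs sharing some other code are excluded from both pools —
#'     overlapping memberships (e.g. antibacterials that are also
#'     ophthalmologicals) would otherwise blur the contrast;
#'   \item across (`across = "global"`): all pairs whose two compounds
#'     share no code, regardless of focal membership.
#' }
#'
#' @param matrix a `similarity_matrix`.
#' @param annotations a `compound_annotations` object.
#' @param category focal ATC level-2 code.
#' @param min_members minimum annotated category members present in the
#'   matrix (default 5).
#' @param across across-pair pool definition, `"focal"` or `"global"`.
#' @return A `stability_result`: list with `system_id`, `category`,
#'   `n_members`, `mean_inter`, `mean_across`, `ratio` (`NA` flagged via
#'   `undefined = TRUE` when mean_across is 0 or a pool is empty), and
#'   the `across` mode used.
#' @export
stability_ratio <- function(matrix, annotations, category,
                            min_members = 5L, across = c("focal", "global")) {
  stopifnot(inherits(matrix, "similarity_matrix"),
            inherits(annotations, "compound_annotations"))
  across <- match.arg(across)
  ids <- matrix$compound_ids
  codes <- lapply(ids, function(id) {
    if (id %in% names(annotations)) annotations[[id]] else character(0)
  })
  names(codes) <- ids
  members <- ids[vapply(codes, function(cd) category %in% cd, logical(1L))]
  if (length(members) < min_members)
    stop(sprintf("category %s has %d annotated members in the matrix; need at least %d",
                 category, length(members), min_members))
  pairs <- sim_pairs(matrix)
  in_a <- pairs$a %in% members
  in_b <- pairs$b %in% members
  shares_code <- mapply(function(a, b) length(intersect(codes[[a]], codes[[b]])) > 0L,
                        pairs$a, pairs$b)
  inter <- pairs$value[in_a & in_b]
  across_vals <- if (across == "focal") {
    pairs$value[xor(in_a, in_b) & !shares_code]
  } else {
    pairs$value[!shares_code]
  }
  mean_inter <- if (length(inter)) mean(inter) else NA_real_
  mean_across <- if (length(across_vals)) mean(across_vals) else NA_real_
  undefined <- is.na(mean_inter) || is.na(mean_across) || mean_across == 0
  structure(
    list(system_id = matrix$system_id, category = category,
         n_members = length(members), mean_inter = mean_inter,
         mean_across = mean_across,
         ratio = if (undefined) NA_real_ else mean_inter / mean_across,
         undefined = undefined, across = across),
    class = "stability_result"
  )
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result> %s / %s (n=%d): ratio = %s (inter %0.4f, across %0.4f)\n",
              x$system_id, x$category, x$n_members,
              format(round(x$ratio, 3)), x$mean_inter, x$mean_across))
  invisible(x)
}

#' Stability ratios for every qualifying category in every system
#'
#' One row per (system, category) for every category with at least
#' `min_members` annotated members present in that system's matrix;
#' categories below the threshold are omitted with a message.
#'
#' @param matrices list of `similarity_matrix`.
#' @param annotations a `compound_annotations` object.
#' @param min_members minimum category size (default 5).
#' @param across pool definition passed to [stability_ratio()].
#' @return data.frame: system_id, category, n_members, mean_inter,
#'   mean_across, ratio, undefined, across.
#' @export
stability_table <- function(matrices, annotations, min_members = 5L,
                            across = c("focal", "global")) {
  across <- match.arg(across)
  all_codes <- sort(unique(unlist(unclass(annotations))))
  rows <- list()
  for (m in matrices) {
    present <- intersect(m$compound_ids, names(annotations))
    for (cat in all_codes) {
      n_mem <- sum(vapply(present, function(id) cat %in% annotations[[id]],
                          logical(1L)))
      if (n_mem < min_members) {
        message(sprintf("stability_table: skipping %s in %s (%d < %d members)",
                        cat, m$system_id, n_mem, min_members))
        next
      }
      res <- stability_ratio(m, annotations, cat, min_members = min_members,
                             across = across)
      rows[[length(rows) + 1L]] <- data.frame(
        system_id = res$system_id, category = res$category,
        n_members = res$n_members, mean_inter = res$mean_inter,
        mean_across = res$mean_across, ratio = res$ratio,
        undefined = res$undefined, across = res$across,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(system_id = character(0), category = character(0),
                      n_members = integer(0), mean_inter = numeric(0),
                      mean_across = numeric(0), ratio = numeric(0),
                      undefined = logical(0), across = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
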