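#' Construct a fold-change matrix for one assay system
#'
#' The canonical container for one assay system (or one dose/time condition
#' of one system): a genes x compounds matrix of log2 fold changes of
#' treatment vs. matched control.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   compounds in columns (colnames = compound ids), log2 scale.
#' @param system_id single string identifying the assay system.
#' @param condition character vector of length 2, `c(dose, time)` labels.
#' @return An object of class `fc_matrix`: a list with elements `values`,
#'   `system_id`, `condition`, `gene_ids`, `compound_ids`.
#' @export
fold_change_matrix <- function(values, system_id,
                               condition = c(dose = "high", time = "last")) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  genes <- rownames(values)
  compounds <- colnames(values)
  if (is.null(genes) || is.null(compounds))
    stop("`values` must have gene ids as rownames and compound ids as colnames")
  dup_g <- genes[duplicated(genes)]
  if (length(dup_g))
    stop("duplicate gene id: ", dup_g[1L])
  dup_c <- compounds[duplicated(compounds)]
  if (length(dup_c))
    stop("duplicate compound id: ", dup_c[1L])
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("non-finite fold change at gene ", genes[bad[1L]],
         ", compound ", compounds[bad[2L]])
  }
  structure(
    list(values = values, system_id = as.character(system_id)[1L],
         condition = condition, gene_ids = genes, compound_ids = compounds),
    class = "fc_matrix"
  )
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> system %s: %d genes x %d compounds (log2 scale)\n",
              x$system_id, length(x$gene_ids), length(x$compound_ids)))
  cat("condition:", paste(x$condition, collapse = " / "), "\n")
  invisible(x)
}

#' Read a fold-change matrix from a tab-delimited file
#'
#' Expects a header row of compound ids and a first column of gene ids.
#' Input may be declared as already `"log2"` or as raw `"ratio"` fold
#' changes; ratios are log2-transformed on read (nonpositive ratios are
#' rejected) so the in-memory scale is always log2.
#'
#' @param path path to a TSV file.
#' @param system_id assay-system label attached to the result.
#' @param condition `c(dose, time)` labels attached to the result.
#' @param scale `"log2"` (default) or `"ratio"`.
#' @return An `fc_matrix`.
#' @export
read_fold_change_matrix <- function(path, system_id,
                                    condition = c(dose = "high", time = "last"),
                                    scale = c("log2", "ratio")) {
  scale <- match.arg(scale)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("fold-change file needs a gene-id column plus at least one compound")
  genes <- raw[[1L]]
  compounds <- colnames(raw)[-1L]
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(compounds),
                 dimnames = list(genes, compounds))
  for (j in seq_along(compounds)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d (gene %s), column %s",
                   col[bad[1L]], bad[1L], genes[bad[1L]], compounds[j]))
    vals[, j] <- num
  }
  if (scale == "ratio") {
    if (any(vals <= 0)) {
      bad <- which(vals <= 0, arr.ind = TRUE)[1L, ]
      stop(sprintf("nonpositive ratio %g at gene %s, compound %s cannot be log2-transformed",
                   vals[bad[1L], bad[2L]], genes[bad[1L]], compounds[bad[2L]]))
    }
    vals <- log2(vals)
  }
  fold_change_matrix(vals, system_id = system_id, condition = condition)
}

#' Write a fold-change matrix as TSV
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces every double exactly.
#'
#' @param x an `fc_matrix`.
#' @param path output path.
#' @export
write_fold_change_matrix <- function(x, path) {
  stopifnot(inherits(x, "fc_matrix"))
  body <- apply(x$values, 2L, function(col) sprintf("%.17g", col))
  if (is.null(dim(body))) body <- matrix(body, nrow = 1L)  # single-gene case
  lines <- c(paste(c("gene_id", x$compound_ids), collapse = "\t"),
             paste(x$gene_ids, apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a homology map (two-column TSV, no header)
#'
#' @param path path to a TSV with columns source gene id, target gene id.
#'   The mapping may be many-to-many.
#' @return A `homology_map`: a data.frame with columns `source`, `target`.
#' @export
read_homology_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("homology map needs two columns (source, target)")
  homology_map(df[[1L]], df[[2L]])
}

#' Construct a homology map from source/target id vectors
#' @param source,target character vectors of equal length.
#' @return A `homology_map` data.frame.
#' @export
homology_map <- function(source, target) {
  stopifnot(length(source) == length(target))
  df <- unique(data.frame(source = as.character(source),
                          target = as.character(target),
                          stringsAsFactors = FALSE))
  class(df) <- c("homology_map", "data.frame")
  df
}

#' Translate gene ids through a homology map
#'
#' A source id expands to all of its targets; an id already in the target
#' namespace is kept as is; ids in neither namespace are dropped. The rule
#' makes translation idempotent: translating an already-translated set
#' changes nothing.
#'
#' @param genes character vector of gene ids.
#' @param map a `homology_map`, or `NULL` for the identity.
#' @return character vector of unique translated ids.
#' @export
translate_genes <- function(genes, map) {
  if (is.null(map)) return(unique(genes))
  stopifnot(inherits(map, "homology_map"))
  mapped <- map$target[map$source %in% genes]
  kept <- genes[genes %in% map$target]
  unique(c(mapped, kept))
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (pathway id -> member gene
#'   ids); duplicates within a set are removed.
#' @param set_names optional named character vector of human-readable
#'   pathway names (defaults to the ids).
#' @param min_size retained for provenance; `gene_set_collection` does not
#'   re-filter, see [read_gene_sets()].
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, set_names = NULL, min_size = 200L) {
  stopifnot(is.list(sets))
  if (length(sets) && is.null(names(sets)))
    stop("`sets` must be a named list")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(set_names)) {
    set_names <- stats::setNames(names(sets), names(sets))
  }
  structure(list(sets = sets, set_names = set_names,
                 min_size = as.integer(min_size)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets (size filter: > %d genes)\n",
              length(x$sets), x$min_size))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read pathway gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member gene ids. Members are optionally translated through a
#' homology map (every target of each source retained, duplicates
#' removed), then sets whose size is not strictly greater than `min_size`
#' are dropped ("more than `min_size` genes").
#'
#' @param path path to a GMT file.
#' @param homology a `homology_map` or `NULL`.
#' @param min_size strict lower bound on retained set size (default 200).
#' @return A `gene_set_collection`.
#' @export
read_gene_sets <- function(path, homology = NULL, min_size = 200L) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); nm <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("malformed GMT line %d: expected at least 3 tab-separated fields, got %d",
                   i, length(fields)))
    id <- fields[1L]
    genes <- translate_genes(unique(fields[-(1:2)]), homology)
    sets[[id]] <- genes
    nm[id] <- fields[2L]
  }
  keep <- vapply(sets, length, 1L) > min_size
  gene_set_collection(sets[keep], nm[keep], min_size = min_size)
}

#' Write a gene-set collection as GMT
#' @param x a `gene_set_collection`.
#' @param path output path.
#' @export
write_gene_sets <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  lines <- vapply(names(x$sets), function(id) {
    paste(c(id, unname(x$set_names[id]), x$sets[[id]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read compound annotations (ATC level-2 therapeutic codes)
#'
#' Tab-delimited, no header: compound id, then a `;`-separated list of
#' level-2 ATC codes (letter + two digits, e.g. `C10`). An empty second
#' field gives an empty code set: such compounds take part in similarity
#' but not in category analysis.
#'
#' @param path path to the TSV.
#' @return A named list (compound id -> character vector of codes) of
#'   class `compound_annotations`.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  ids <- character(0); codes <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    id <- fields[1L]
    if (id %in% ids) stop("duplicate compound annotation: ", id)
    cd <- if (length(fields) < 2L || !nzchar(fields[2L])) character(0)
          else strsplit(fields[2L], ";", fixed = TRUE)[[1L]]
    cd <- trimws(cd)
    cd <- cd[nzchar(cd)]
    bad <- cd[!grepl("^[A-Z][0-9]{2}$", cd)]
    if (length(bad))
      stop(sprintf("malformed ATC level-2 code '%s' for compound %s (line %d)",
                   bad[1L], id, i))
    ids <- c(ids, id)
    codes[[id]] <- unique(cd)
  }
  structure(codes, class = "compound_annotations")
}

#' Construct compound annotations from a named list
#' @param codes named list, compound id -> character vector of ATC level-2
#'   codes.
#' @return A `compound_annotations` object.
#' @export
compound_annotations <- function(codes) {
  stopifnot(is.list(codes))
  if (length(codes) && is.null(names(codes)))
    stop("`codes` must be a named list")
  codes <- lapply(codes, function(x) unique(as.character(x)))
  structure(codes, class = "compound_annotations")
}

#' Write compound annotations as TSV
#' @param x a `compound_annotations` object.
#' @param path output path.
#' @export
write_annotations <- function(x, path) {
  lines <- vapply(names(x), function(id) {
    paste(id, paste(x[[id]], collapse = ";"), sep = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

# internal: canonical key for an unordered compound pair
pair_key <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
}

#' Read a precomputed chemical-similarity table
#'
#' Three-column TSV: compound_i, compound_j, similarity in [0, 1]
#' (e.g. Dice similarity of FCFP-4 fingerprints, computed upstream). A
#' header line is tolerated and skipped when its third field is not
#' numeric. Keys are unordered pairs, so the table is symmetric by
#' construction.
#'
#' @param path path to the TSV.
#' @return A `chem_similarity` object: named numeric vector keyed by
#'   unordered pair.
#' @export
read_chemical_similarity <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("chemical similarity table needs three columns")
  if (is.na(suppressWarnings(as.numeric(df[1L, 3L]))))
    df <- df[-1L, , drop = FALSE]
  sim <- as.numeric(df[[3L]])
  if (anyNA(sim)) stop("non-numeric similarity value at row ",
                       which(is.na(sim))[1L])
  if (any(sim < 0 | sim > 1))
    stop("chemical similarity outside [0, 1] at row ",
         which(sim < 0 | sim > 1)[1L])
  chemical_similarity(df[[1L]], df[[2L]], sim)
}

#' Construct a chemical-similarity table from pair vectors
#' @param a,b compound id vectors (unordered pairs).
#' @param similarity numeric vector in [0, 1].
#' @return A `chem_similarity` object.
#' @export
chemical_similarity <- function(a, b, similarity) {
  stopifnot(length(a) == length(b), length(a) == length(similarity),
            all(similarity >= 0 & similarity <= 1))
  structure(stats::setNames(as.numeric(similarity), pair_key(a, b)),
            class = "chem_similarity")
}
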