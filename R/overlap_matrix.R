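# Ternary pair-by-library overlap matrix, Ward clustering of both axes, and
# local hypergeometric gene-set enrichment.

#' Build the ternary overlap matrix
#'
#' Encodes pair-by-library status as 1 when the pair used overlapping TSSs,
#' 0.5 when there was expression without overlap (either both genes or a
#' single gene expressed), and 0 when neither gene was expressed. Only pairs
#' that overlap in at least one library are kept as rows.
#'
#' @param statuses Output of [call_overlaps()].
#' @return A numeric matrix (rows = pair ids, columns = library ids) with
#'   cells in `{0, 0.5, 1}`.
#' @export
build_overlap_matrix <- function(statuses) {
  cell <- c(overlap = 1, no_overlap = 0.5, single_expressed = 0.5,
            none_expressed = 0)
  vals <- cell[statuses$state]
  pair_ids <- sort(unique(statuses$pair_id))
  lib_ids <- sort(unique(statuses$library_id))
  m <- matrix(NA_real_, length(pair_ids), length(lib_ids),
              dimnames = list(pair_ids, lib_ids))
  m[cbind(match(statuses$pair_id, pair_ids),
          match(statuses$library_id, lib_ids))] <- vals
  if (anyNA(m)) stop("statuses do not cover every (pair, library) cell")
  m[apply(m == 1, 1, any), , drop = FALSE]
}

#' Ward clustering of the overlap matrix on both axes
#'
#' Hierarchical clustering with Ward's minimum-variance criterion on
#' Euclidean distances (`hclust` method `"ward.D2"`), applied to rows
#' (pairs) and columns (libraries) independently.
#'
#' @param m Overlap matrix from [build_overlap_matrix()].
#' @param k_rows,k_cols Optional number of flat clusters to cut each
#'   dendrogram into.
#' @return A list with `row_hclust`, `col_hclust`, leaf orders `row_order` /
#'   `col_order`, and (when requested) named label vectors `row_labels` /
#'   `col_labels`.
#' @export
cluster_bidirectional <- function(m, k_rows = NULL, k_cols = NULL) {
  stopifnot(is.matrix(m), nrow(m) >= 1, ncol(m) >= 1)
  one_axis <- function(x, k) {
    if (nrow(x) == 1) {
      hc <- NULL
      ord <- 1L
      labels <- stats::setNames(1L, rownames(x))
    } else {
      hc <- stats::hclust(stats::dist(x, method = "euclidean"), method = "ward.D2")
      ord <- hc$order
      labels <- if (is.null(k)) NULL else stats::cutree(hc, k = min(k, nrow(x)))
    }
    list(hclust = hc, order = ord, labels = labels)
  }
  rows <- one_axis(m, k_rows)
  cols <- one_axis(t(m), k_cols)
  list(row_hclust = rows$hclust, col_hclust = cols$hclust,
       row_order = rows$order, col_order = cols$order,
       row_labels = rows$labels, col_labels = cols$labels)
}

#' Local hypergeometric gene-set enrichment
#'
#' One-sided hypergeometric (Fisher) test of each reference set against a
#' query list within a finite universe. Sets sharing fewer than
#' `min_overlap` genes with the query are dropped before testing;
#' Benjamini-Hochberg FDR is computed over the reported sets. Results are
#' sorted in descending order of `minus_log10_p + minus_log10_fdr`.
#'
#' @param query_genes Character vector (subset of `universe`).
#' @param reference_sets Named list of character vectors.
#' @param universe Character vector of all eligible genes.
#' @param min_overlap Minimum query/set intersection size (default 4).
#' @return A data.frame `set_name`, `set_size`, `overlap_count`, `p_value`,
#'   `fdr`, `minus_log10_p`, `minus_log10_fdr`.
#' @export
enrich <- function(query_genes, reference_sets, universe, min_overlap = 4L) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  query_genes <- unique(intersect(query_genes, universe))
  rows <- lapply(names(reference_sets), function(nm) {
    set <- unique(intersect(reference_sets[[nm]], universe))
    k <- length(intersect(query_genes, set))
    if (k < min_overlap) return(NULL)
    # P(X >= k), X ~ Hypergeom(|set| white, |universe|-|set| black, |query| drawn)
    p <- stats::phyper(k - 1L, length(set), length(universe) - length(set),
                       length(query_genes), lower.tail = FALSE)
    data.frame(set_name = nm, set_size = length(set), overlap_count = k,
               p_value = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(set_name = character(), set_size = integer(),
                      overlap_count = integer(), p_value = numeric(),
                      fdr = numeric(), minus_log10_p = numeric(),
                      minus_log10_fdr = numeric()))
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$minus_log10_p <- -log10(out$p_value)
  out$minus_log10_fdr <- -log10(out$fdr)
  out <- out[order(out$minus_log10_p + out$minus_log10_fdr, decreasing = TRUE), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read an overlap matrix as TSV
#' @param m Matrix with row and column names.
#' @param path Output path.
#' @return `path` invisibly, or the matrix for the reader.
#' @export
write_overlap_matrix <- function(m, path) {
  df <- data.frame(pair_id = rownames(m), m, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_overlap_matrix
#' @export
read_overlap_matrix <- function(path) {
  df <- read_tsv_checked(path, required = "pair_id")
  m <- as.matrix(df[, setdiff(names(df), "pair_id"), drop = FALSE])
  rownames(m) <- df$pair_id
  storage.mode(m) <- "double"
  m
}
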