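# TSS admission rules: confidence flag, minimum expression in tags per
# million, and maximum distance from the annotated 5' end.

#' Convert raw tag counts to parts per million
#'
#' @param raw_count Nonnegative tag count(s).
#' @param library_total Total mapped tags in the library (> 0); recycled.
#' @return `raw_count / library_total * 1e6`.
#' @examples
#' compute_ppm(10, 2e6) # 5
#' @export
compute_ppm <- function(raw_count, library_total) {
  if (any(library_total <= 0)) stop("library_total must be > 0")
  if (any(raw_count < 0)) stop("raw_count must be >= 0")
  raw_count / library_total * 1e6
}

#' TSS filter configuration
#'
#' @param min_ppm Minimum expression in ppm; records strictly below are
#'   rejected (a record at exactly `min_ppm` is admitted).
#' @param max_distance_bp Maximum absolute distance between a TSS and the
#'   gene's annotated 5' end, measured symmetrically in both directions;
#'   a record at exactly `max_distance_bp` is admitted.
#' @param require_confident Reject records not flagged confident?
#' @return A list of class `"tss_filter_config"`.
#' @export
tss_filter_config <- function(min_ppm = 5, max_distance_bp = 5000L,
                              require_confident = TRUE) {
  stopifnot(min_ppm >= 0, max_distance_bp >= 0)
  structure(list(min_ppm = min_ppm, max_distance_bp = as.integer(max_distance_bp),
                 require_confident = isTRUE(require_confident)),
            class = "tss_filter_config")
}

#' Apply the TSS admission rules
#'
#' A record is admitted iff it is flagged confident (unless
#' `require_confident` is off), its expression is at least `min_ppm`, and its
#' position lies within `max_distance_bp` of the owning gene's annotated 5'
#' end (absolute distance, upstream or downstream). Duplicate rows for the
#' same (gene, library, strand, position) are merged beforehand by summing
#' raw counts and ppm.
#'
#' @param tss TSS record data.frame (see [read_tss_table()]).
#' @param genes Gene-model data.frame; every `gene_id` in `tss` must be
#'   present.
#' @param config A [tss_filter_config()].
#' @return The admitted records, with a `"rejection_report"` attribute
#'   counting rejections per rule (a record failing several rules is counted
#'   under each) and the admitted total.
#' @export
filter_tss <- function(tss, genes, config = tss_filter_config()) {
  stopifnot(inherits(config, "tss_filter_config"))
  unknown <- setdiff(unique(tss$gene_id), genes$gene_id)
  if (length(unknown)) stop("TSS records reference unknown genes: ",
                            paste(utils::head(unknown, 3), collapse = ", "))
  tss <- merge_duplicate_tss(tss)
  idx <- match(tss$gene_id, genes$gene_id)
  if (any(tss$strand != genes$strand[idx])) {
    stop("TSS strand disagrees with owning gene's strand")
  }
  dist <- abs(tss$position - genes$annotated_five_prime[idx])
  fail_conf <- config$require_confident & !tss$confident
  fail_ppm <- tss$expression_ppm < config$min_ppm
  fail_dist <- dist > config$max_distance_bp
  keep <- !(fail_conf | fail_ppm | fail_dist)
  out <- tss[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejection_report") <- data.frame(
    rule = c("not_confident", "below_min_ppm", "beyond_max_distance", "admitted"),
    n = c(sum(fail_conf), sum(fail_ppm), sum(fail_dist), sum(keep))
  )
  attr(out, "filter_config") <- config
  out
}

merge_duplicate_tss <- function(tss) {
  key <- paste(tss$gene_id, tss$library_id, tss$strand, tss$position, sep = "\r")
  if (!anyDuplicated(key)) return(tss)
  first <- !duplicated(key)
  out <- tss[first, , drop = FALSE]
  okey <- key[first]
  out$expression_ppm <- as.numeric(tapply(tss$expression_ppm, key, sum)[okey])
  if ("raw_count" %in% names(tss)) {
    out$raw_count <- as.numeric(tapply(tss$raw_count, key, sum)[okey])
  }
  # confidence of merged rows: confident iff every contributing row was
  out$confident <- as.logical(tapply(tss$confident, key, all)[okey])
  rownames(out) <- NULL
  out
}

#' Per-library TSS usage statistics
#'
#' Counts distinct admitted TSS positions per (gene, library) and summarises
#' each library: number of expressed genes, number of TSSs and mean TSSs per
#' gene.
#'
#' @param tss Admitted TSS records.
#' @return A list with `per_gene` (gene_id, library_id, n_tss) and
#'   `per_library` (library_id, n_genes, n_tss, mean_tss_per_gene; the mean
#'   is `NA` for a library with no expressed genes).
#' @export
tss_usage_stats <- function(tss) {
  if (nrow(tss) == 0) {
    return(list(
      per_gene = data.frame(gene_id = character(), library_id = character(),
                            n_tss = integer()),
      per_library = data.frame(library_id = character(), n_genes = integer(),
                               n_tss = integer(), mean_tss_per_gene = numeric())
    ))
  }
  dedup <- !duplicated(paste(tss$gene_id, tss$library_id, tss$position, sep = "\r"))
  t2 <- tss[dedup, , drop = FALSE]
  key <- paste(t2$gene_id, t2$library_id, sep = "\r")
  cnt <- table(key)
  parts <- do.call(rbind, strsplit(names(cnt), "\r", fixed = TRUE))
  per_gene <- data.frame(gene_id = parts[, 1], library_id = parts[, 2],
                         n_tss = as.integer(cnt), stringsAsFactors = FALSE)
  rownames(per_gene) <- NULL
  libs <- sort(unique(per_gene$library_id))
  n_genes <- vapply(libs, function(l) sum(per_gene$library_id == l), 1L)
  n_tss <- vapply(libs, function(l) sum(per_gene$n_tss[per_gene$library_id == l]), 1L)
  per_library <- data.frame(
    library_id = libs, n_genes = n_genes, n_tss = n_tss,
    mean_tss_per_gene = ifelse(n_genes > 0, n_tss / n_genes, NA_real_),
    stringsAsFactors = FALSE
  )
  rownames(per_library) <- NULL
  list(per_gene = per_gene, per_library = per_library)
}
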