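# Per-library overlap calling for head-to-head gene pairs. A gene's 5' end
# in a library is the most upstream admitted TSS; its 3' boundary always
# comes from the annotation. Two genes overlap in a library when their
# per-library extents share at least 1 bp at their 5' ends.

#' Effective 5' end of a gene in one library
#'
#' The most upstream admitted TSS: the minimum position for a `+` gene, the
#' maximum for a `-` gene; `NA` when the gene has no admitted TSS.
#'
#' @param positions Integer vector of admitted TSS positions (0-based) for
#'   one gene in one library; may be empty.
#' @param strand `"+"` or `"-"`.
#' @return A single genomic position, or `NA_integer_`.
#' @export
effective_five_prime <- function(positions, strand) {
  if (length(positions) == 0) return(NA_integer_)
  if (strand == "+") as.integer(min(positions)) else as.integer(max(positions))
}

#' Enumerate candidate head-to-head gene pairs
#'
#' Lists every (plus-strand gene, minus-strand gene) pair on the same
#' chromosome whose annotated 5' ends are within `max_gap_bp` of each other.
#' With the default gap of 10 kb — twice the 5 kb TSS admission radius — the
#' candidate set is a superset of every pair that can be called 5'-overlapping
#' under any admitted TSS choice.
#'
#' @param genes Gene-model data.frame.
#' @param max_gap_bp Maximum distance between annotated 5' ends.
#' @return A data.frame with `pair_id`, `gene_plus`, `gene_minus`, `chrom`.
#' @export
candidate_pairs <- function(genes, max_gap_bp = 10000L) {
  plus <- genes[genes$strand == "+", , drop = FALSE]
  minus <- genes[genes$strand == "-", , drop = FALSE]
  out <- list()
  for (chr in intersect(unique(plus$chrom), unique(minus$chrom))) {
    p <- plus[plus$chrom == chr, , drop = FALSE]
    m <- minus[minus$chrom == chr, , drop = FALSE]
    grid <- expand.grid(i = seq_len(nrow(p)), j = seq_len(nrow(m)))
    d <- abs(p$annotated_five_prime[grid$i] - m$annotated_five_prime[grid$j])
    grid <- grid[d <= max_gap_bp, , drop = FALSE]
    if (nrow(grid)) {
      out[[chr]] <- data.frame(
        gene_plus = p$gene_id[grid$i],
        gene_minus = m$gene_id[grid$j],
        chrom = chr, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(pair_id = character(), gene_plus = character(),
                      gene_minus = character(), chrom = character()))
  }
  pairs <- do.call(rbind, out)
  pairs <- pairs[order(pairs$gene_plus, pairs$gene_minus), , drop = FALSE]
  pairs <- data.frame(pair_id = paste(pairs$gene_plus, pairs$gene_minus, sep = ":"),
                      pairs, stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  pairs
}

#' Call per-library overlap status for candidate pairs
#'
#' For each pair and library, let `a` be the effective 5' end of the plus
#' gene and `b` that of the minus gene (both 0-based). The plus gene's
#' extent for the library is `[a, plus 3' boundary)` and the minus gene's is
#' `[minus 3' boundary, b]`. The pair overlaps iff both genes are expressed,
#' `b >= a`, and each gene's effective 5' end lies inside the other gene's
#' extent; the overlap region is then the inclusive span `[a, b]` with
#' length `b - a + 1`.
#'
#' @param pairs Candidate pairs from [candidate_pairs()].
#' @param genes Gene-model data.frame.
#' @param tss Admitted TSS records (after [filter_tss()]).
#' @param libraries Optional character vector of library ids to evaluate;
#'   defaults to the libraries present in `tss`. Libraries without admitted
#'   TSSs for a pair yield `none_expressed`.
#' @return A data.frame with one row per (pair, library): `pair_id`,
#'   `library_id`, `state` (`overlap`, `no_overlap`, `single_expressed`,
#'   `none_expressed`), effective 5' ends `five_prime_plus`/`five_prime_minus`,
#'   `overlap_start`/`overlap_end` (0-based inclusive bounds of the overlap
#'   region, `NA` unless overlapping), `overlap_len_bp`, per-gene TSS counts
#'   and classes (`absent`/`single`/`multiple`), and per-gene
#'   `frac_overlap_plus`/`frac_overlap_minus` — the fraction of the gene's
#'   admitted TSS expression (ppm) initiated inside the overlap region.
#' @export
call_overlaps <- function(pairs, genes, tss, libraries = NULL) {
  if (is.null(libraries)) libraries <- sort(unique(tss$library_id))
  gidx <- match(pairs$gene_plus, genes$gene_id)
  midx <- match(pairs$gene_minus, genes$gene_id)
  if (anyNA(gidx) || anyNA(midx)) stop("pair references unknown gene")
  if (any(genes$chrom[gidx] != genes$chrom[midx])) {
    stop("pair genes on different chromosomes")
  }
  if (any(genes$strand[gidx] != "+") || any(genes$strand[midx] != "-")) {
    stop("gene_plus must be on '+' and gene_minus on '-'")
  }

  # per-(gene, library) aggregates, computed once
  tkey <- paste(tss$gene_id, tss$library_id, sep = "\r")
  ord <- order(tkey, tss$position)
  tkey <- tkey[ord]
  tpos <- tss$position[ord]
  tppm <- tss$expression_ppm[ord]
  # merge duplicate positions within a key (records should already be merged
  # by filter_tss; this keeps the function safe on raw input)
  dup <- duplicated(paste(tkey, tpos, sep = "\r"))
  if (any(dup)) {
    agg <- rowsum(tppm, paste(tkey, tpos, sep = "\r"), reorder = FALSE)
    keep <- !dup
    tppm <- as.numeric(agg[, 1])
    tkey <- tkey[keep]; tpos <- tpos[keep]
  }
  first <- !duplicated(tkey)
  key_levels <- tkey[first]
  kidx <- match(tkey, key_levels)
  n_by_key <- tabulate(kidx, length(key_levels))
  min_by_key <- as.integer(tpos[first])                     # sorted by position
  last <- !duplicated(tkey, fromLast = TRUE)
  max_by_key <- as.integer(tpos[last])
  pos_by_key <- split(tpos, kidx)
  ppm_by_key <- split(tppm, kidx)

  grid <- expand.grid(pi = seq_len(nrow(pairs)), li = seq_along(libraries))
  n <- nrow(grid)
  kp <- match(paste(pairs$gene_plus[grid$pi], libraries[grid$li], sep = "\r"),
              key_levels)
  km <- match(paste(pairs$gene_minus[grid$pi], libraries[grid$li], sep = "\r"),
              key_levels)
  a <- ifelse(is.na(kp), NA_integer_, min_by_key[kp])   # + strand: most upstream
  b <- ifelse(is.na(km), NA_integer_, max_by_key[km])   # - strand: most upstream
  np <- ifelse(is.na(kp), 0L, n_by_key[kp])
  nm <- ifelse(is.na(km), 0L, n_by_key[km])
  plus_end3 <- genes$span_end[gidx[grid$pi]]    # half-open: last base span_end - 1
  minus_end3 <- genes$span_start[midx[grid$pi]] # minus gene's 3' boundary

  expressed_p <- !is.na(a); expressed_m <- !is.na(b)
  is_ov <- expressed_p & expressed_m & !is.na(a) & !is.na(b) &
    b >= a & a >= minus_end3 & b <= plus_end3 - 1L
  is_ov[is.na(is_ov)] <- FALSE
  state <- ifelse(is_ov, "overlap",
           ifelse(expressed_p & expressed_m, "no_overlap",
           ifelse(expressed_p | expressed_m, "single_expressed",
                  "none_expressed")))
  tss_class <- function(k) c("absent", "single", "multiple")[pmin(k, 2L) + 1L]
  frac_p <- ifelse(expressed_p, 0, NA_real_)
  frac_m <- ifelse(expressed_m, 0, NA_real_)
  ovr <- which(is_ov)
  for (r in ovr) {
    pp <- pos_by_key[[kp[r]]]; wp <- ppm_by_key[[kp[r]]]
    pm <- pos_by_key[[km[r]]]; wm <- ppm_by_key[[km[r]]]
    frac_p[r] <- sum(wp[pp >= a[r] & pp <= b[r]]) / sum(wp)
    frac_m[r] <- sum(wm[pm >= a[r] & pm <= b[r]]) / sum(wm)
  }
  res <- data.frame(
    pair_id = pairs$pair_id[grid$pi],
    library_id = libraries[grid$li],
    state = state,
    five_prime_plus = a, five_prime_minus = b,
    overlap_start = ifelse(is_ov, a, NA_integer_),
    overlap_end = ifelse(is_ov, b, NA_integer_),
    overlap_len_bp = ifelse(is_ov, b - a + 1L, 0L),
    n_tss_plus = np, n_tss_minus = nm,
    tss_class_plus = tss_class(np), tss_class_minus = tss_class(nm),
    frac_overlap_plus = frac_p, frac_overlap_minus = frac_m,
    stringsAsFactors = FALSE
  )
  res
}

#' Per-pair and per-library overlap summaries
#'
#' @param statuses Output of [call_overlaps()].
#' @return A list with `per_pair` (`n_libraries_both_expressed`,
#'   `n_libraries_overlap`, `always_overlap` — overlapping in every library
#'   where both genes are expressed, with at least one such library),
#'   `always_overlap_pairs` (character vector), and `per_library` overlap
#'   counts.
#' @export
pair_library_summary <- function(statuses) {
  pair_ids <- sort(unique(statuses$pair_id))
  both <- statuses$state %in% c("overlap", "no_overlap")
  ov <- statuses$state == "overlap"
  n_both <- vapply(pair_ids, function(p) sum(both & statuses$pair_id == p), 1L)
  n_ov <- vapply(pair_ids, function(p) sum(ov & statuses$pair_id == p), 1L)
  per_pair <- data.frame(
    pair_id = pair_ids,
    n_libraries_both_expressed = n_both,
    n_libraries_overlap = n_ov,
    always_overlap = n_both >= 1L & n_ov == n_both,
    stringsAsFactors = FALSE
  )
  rownames(per_pair) <- NULL
  libs <- sort(unique(statuses$library_id))
  per_library <- data.frame(
    library_id = libs,
    n_pairs_overlap = vapply(libs, function(l) sum(ov & statuses$library_id == l), 1L),
    n_pairs_both_expressed = vapply(libs, function(l) sum(both & statuses$library_id == l), 1L),
    stringsAsFactors = FALSE
  )
  rownames(per_library) <- NULL
  stopifnot(all(per_pair$n_libraries_overlap <= per_pair$n_libraries_both_expressed))
  list(per_pair = per_pair,
       always_overlap_pairs = per_pair$pair_id[per_pair$always_overlap],
       per_library = per_library)
}

#' Six-way organisation-by-TSS-count category
#'
#' Combines a gene's per-library organisation (overlapping partner,
#' expressed non-overlapping partner, or sole expressed gene of the pair)
#' with whether it used one or several admitted TSSs in that library.
#'
#' @param state Pair state for the library: `overlap`, `no_overlap` or
#'   `single_expressed` (`none_expressed` yields `NA` — no category).
#' @param n_tss Number of distinct admitted TSSs the classified gene used.
#' @return One of `overlap_single`, `overlap_multi`, `no_overlap_single`,
#'   `no_overlap_multi`, `single_expressed_single`, `single_expressed_multi`;
#'   vectorised.
#' @export
classify_state_six <- function(state, n_tss) {
  arm <- ifelse(state == "none_expressed", NA_character_, state)
  tss <- ifelse(n_tss >= 2, "multi", "single")
  ifelse(is.na(arm) | n_tss == 0, NA_character_, paste(arm, tss, sep = "_"))
}

#' Per-gene-per-library six-category observations
#'
#' Expands pair-library statuses into one row per expressed gene per library
#' carrying its six-way category, the unit of the category-stratified
#' expression comparison.
#'
#' @param statuses Output of [call_overlaps()].
#' @param pairs Candidate pair table (to resolve gene ids).
#' @return A data.frame `pair_id`, `library_id`, `gene_id`, `category`.
#' @export
six_category_observations <- function(statuses, pairs) {
  pidx <- match(statuses$pair_id, pairs$pair_id)
  rows <- list(
    data.frame(pair_id = statuses$pair_id, library_id = statuses$library_id,
               gene_id = pairs$gene_plus[pidx],
               category = classify_state_six(statuses$state, statuses$n_tss_plus),
               stringsAsFactors = FALSE),
    data.frame(pair_id = statuses$pair_id, library_id = statuses$library_id,
               gene_id = pairs$gene_minus[pidx],
               category = classify_state_six(statuses$state, statuses$n_tss_minus),
               stringsAsFactors = FALSE)
  )
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
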