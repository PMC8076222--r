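# Overlap-stratified expression statistics: contrast-pair selection, Pearson
# correlation classes, the paired overlap/no-overlap t-test, and TSS-count /
# six-category Mann-Whitney comparisons.
#
# Expression tables are long-format data.frames with columns gene_id,
# library_id, expression (ppm or FPKM; the unit is caller-declared). Tests
# operate on log2(x + 1) by default, since expression is heavy-tailed and
# the t-test assumes a roughly symmetric location-shift scale; raw-scale
# mode is available everywhere via log_transform = FALSE.

expr_lookup <- function(expression) {
  stats::setNames(expression$expression,
                  paste(expression$gene_id, expression$library_id, sep = "\r"))
}

expr_values <- function(lookup, gene, libs) {
  as.numeric(lookup[paste(gene, libs, sep = "\r")])
}

maybe_log <- function(x, log_transform) if (log_transform) log2(x + 1) else x

#' Select pairs with enough overlapping and non-overlapping libraries
#'
#' A pair qualifies when both genes are co-expressed with overlapping TSSs in
#' at least `min_each` libraries and co-expressed without overlap in at least
#' `min_each` other libraries.
#'
#' @param statuses Output of [call_overlaps()].
#' @param min_each Minimum library count per stratum (default 10).
#' @return A data.frame with `pair_id` and list-columns `libs_overlap`,
#'   `libs_no_overlap`.
#' @export
select_contrast_pairs <- function(statuses, min_each = 10L) {
  ov <- split(statuses$library_id[statuses$state == "overlap"],
              statuses$pair_id[statuses$state == "overlap"])
  no <- split(statuses$library_id[statuses$state == "no_overlap"],
              statuses$pair_id[statuses$state == "no_overlap"])
  ids <- sort(unique(statuses$pair_id))
  keep <- vapply(ids, function(p) {
    length(ov[[p]]) >= min_each && length(no[[p]]) >= min_each
  }, TRUE)
  ids <- ids[keep]
  data.frame(pair_id = ids,
             libs_overlap = I(unname(ov[ids])),
             libs_no_overlap = I(unname(no[ids])),
             stringsAsFactors = FALSE)
}

#' Pearson correlation verdict for one pair in one library stratum
#'
#' @param gene1,gene2 Gene ids.
#' @param expression Long-format expression table (or a prebuilt named
#'   lookup vector, used internally to avoid rebuilding it per pair).
#' @param libraries Libraries of the stratum (>= 3).
#' @param alpha Two-sided significance level for the class call.
#' @param log_transform Correlate on log2(x + 1)?
#' @return A one-row data.frame: `r`, `p`, `n`, `class` (`positive` /
#'   `negative` / `ns`). Zero variance in either gene gives class `ns` with
#'   `r = NA`.
#' @export
correlate_pair <- function(gene1, gene2, expression, libraries, alpha = 0.05,
                           log_transform = TRUE) {
  stopifnot(length(libraries) >= 3)
  lk <- if (is.data.frame(expression)) expr_lookup(expression) else expression
  x <- maybe_log(expr_values(lk, gene1, libraries), log_transform)
  y <- maybe_log(expr_values(lk, gene2, libraries), log_transform)
  if (anyNA(x) || anyNA(y)) stop("missing expression for stratum libraries")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(data.frame(r = NA_real_, p = NA_real_, n = length(x), class = "ns",
                      stringsAsFactors = FALSE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  cls <- if (ct$p.value <= alpha) {
    if (ct$estimate > 0) "positive" else "negative"
  } else "ns"
  data.frame(r = unname(ct$estimate), p = ct$p.value, n = length(x),
             class = cls, stringsAsFactors = FALSE)
}

#' Correlation verdicts for all contrast pairs in both strata
#'
#' @param contrasts Output of [select_contrast_pairs()].
#' @param pairs Candidate pair table (resolves gene ids).
#' @param expression Long-format expression table.
#' @inheritParams correlate_pair
#' @return A data.frame with one row per (pair, stratum).
#' @export
correlate_contrast_pairs <- function(contrasts, pairs, expression,
                                     alpha = 0.05, log_transform = TRUE) {
  pidx <- match(contrasts$pair_id, pairs$pair_id)
  lk <- expr_lookup(expression)
  rows <- list()
  for (i in seq_len(nrow(contrasts))) {
    for (stratum in c("overlap", "no_overlap")) {
      libs <- if (stratum == "overlap") contrasts$libs_overlap[[i]] else contrasts$libs_no_overlap[[i]]
      v <- correlate_pair(pairs$gene_plus[pidx[i]], pairs$gene_minus[pidx[i]],
                          lk, libs, alpha, log_transform)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(pair_id = contrasts$pair_id[i], stratum = stratum,
                   stringsAsFactors = FALSE), v)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired t-test of expression with vs without overlap
#'
#' For each gene of each contrast pair, computes its mean expression over the
#' pair's overlapping libraries and over its non-overlapping libraries, then
#' applies a classical paired t-test across genes.
#'
#' @param contrasts Output of [select_contrast_pairs()].
#' @param pairs Candidate pair table.
#' @param expression Long-format expression table.
#' @param log_transform Test on log2(x + 1)?
#' @param unit Unit of pairing: `"gene"` (default; each gene of each pair is
#'   one paired observation) or `"pair"` (the two genes' values are summed).
#' @return A list with `t`, `p`, `df`, `mean_overlap`, `mean_no_overlap`,
#'   and the per-unit `means` table.
#' @export
paired_overlap_test <- function(contrasts, pairs, expression,
                                log_transform = TRUE, unit = c("gene", "pair")) {
  unit <- match.arg(unit)
  lk <- expr_lookup(expression)
  pidx <- match(contrasts$pair_id, pairs$pair_id)
  rows <- list()
  for (i in seq_len(nrow(contrasts))) {
    for (g in c(pairs$gene_plus[pidx[i]], pairs$gene_minus[pidx[i]])) {
      mo <- mean(maybe_log(expr_values(lk, g, contrasts$libs_overlap[[i]]), log_transform))
      mn <- mean(maybe_log(expr_values(lk, g, contrasts$libs_no_overlap[[i]]), log_transform))
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = contrasts$pair_id[i], gene_id = g,
        mean_overlap = mo, mean_no_overlap = mn, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("fewer than 2 usable units for the paired t-test")
  means <- do.call(rbind, rows)
  means <- means[stats::complete.cases(means), , drop = FALSE]
  if (unit == "pair") {
    agg <- stats::aggregate(cbind(mean_overlap, mean_no_overlap) ~ pair_id,
                            means, sum)
    means_used <- agg
  } else {
    means_used <- means
  }
  if (nrow(means_used) < 2) stop("fewer than 2 usable units for the paired t-test")
  d <- means_used$mean_overlap - means_used$mean_no_overlap
  if (stats::sd(d) == 0) {
    # degenerate paired samples: no variance in the differences
    tt <- list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
               p.value = if (mean(d) == 0) 1 else 0,
               parameter = length(d) - 1)
  } else {
    tt <- stats::t.test(means_used$mean_overlap, means_used$mean_no_overlap,
                        paired = TRUE)
  }
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_overlap = mean(means_used$mean_overlap),
       mean_no_overlap = mean(means_used$mean_no_overlap),
       means = means)
}

#' Expression by number of utilised TSSs
#'
#' Groups per-gene per-library observations by how many admitted TSSs the
#' gene used in that library (counts above `cap` are pooled into the top
#' bin) and compares adjacent groups with two-sided Mann-Whitney U tests.
#'
#' @param usage_per_gene `per_gene` component of [tss_usage_stats()].
#' @param expression Long-format expression table.
#' @param cap Top TSS-count bin (default 5, i.e. "5+").
#' @param log_transform Compare log2(x + 1) values? (Rank tests are
#'   invariant to it; retained for the reported group means.)
#' @return A list with `observations` (gene, library, group, expression),
#'   `group_summary`, and `tests` (adjacent-group Mann-Whitney results).
#' @export
expression_by_tss_count <- function(usage_per_gene, expression, cap = 5L,
                                    log_transform = TRUE) {
  lk <- expr_lookup(expression)
  e <- expr_values(lk, usage_per_gene$gene_id, usage_per_gene$library_id)
  obs <- data.frame(gene_id = usage_per_gene$gene_id,
                    library_id = usage_per_gene$library_id,
                    group = pmin(usage_per_gene$n_tss, cap),
                    expression = maybe_log(e, log_transform),
                    stringsAsFactors = FALSE)
  obs <- obs[!is.na(obs$expression), , drop = FALSE]
  groups <- sort(unique(obs$group))
  group_summary <- data.frame(
    group = groups,
    n = vapply(groups, function(g) sum(obs$group == g), 1L),
    mean = vapply(groups, function(g) mean(obs$expression[obs$group == g]), 1),
    median = vapply(groups, function(g) stats::median(obs$expression[obs$group == g]), 1)
  )
  tests <- NULL
  if (length(groups) >= 2) {
    tests <- do.call(rbind, lapply(seq_len(length(groups) - 1L), function(i) {
      x <- obs$expression[obs$group == groups[i]]
      y <- obs$expression[obs$group == groups[i + 1L]]
      wt <- stats::wilcox.test(x, y, exact = FALSE)
      data.frame(group_low = groups[i], group_high = groups[i + 1L],
                 U = unname(wt$statistic), p = wt$p.value)
    }))
  }
  list(observations = obs, group_summary = group_summary, tests = tests)
}

#' Expression by six-way organisation/TSS-count category
#'
#' @param category_obs Output of [six_category_observations()].
#' @param expression Long-format expression table.
#' @param log_transform Compare log2(x + 1) values?
#' @return A list with `observations`, `category_summary`, and `tests` — the
#'   full pairwise two-sided Mann-Whitney matrix over categories with at
#'   least one observation.
#' @export
expression_by_category <- function(category_obs, expression, log_transform = TRUE) {
  lk <- expr_lookup(expression)
  e <- expr_values(lk, category_obs$gene_id, category_obs$library_id)
  obs <- cbind(category_obs, expression = maybe_log(e, log_transform))
  obs <- obs[!is.na(obs$expression), , drop = FALSE]
  cats <- c("overlap_single", "overlap_multi", "no_overlap_single",
            "no_overlap_multi", "single_expressed_single", "single_expressed_multi")
  present <- cats[cats %in% obs$category]
  category_summary <- data.frame(
    category = present,
    n = vapply(present, function(k) sum(obs$category == k), 1L),
    mean = vapply(present, function(k) mean(obs$expression[obs$category == k]), 1),
    median = vapply(present, function(k) stats::median(obs$expression[obs$category == k]), 1)
  )
  rownames(category_summary) <- NULL
  tests <- NULL
  if (length(present) >= 2) {
    cmb <- utils::combn(present, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      a <- cmb[1, j]; b <- cmb[2, j]
      wt <- stats::wilcox.test(obs$expression[obs$category == a],
                               obs$expression[obs$category == b], exact = FALSE)
      data.frame(category_a = a, category_b = b,
                 U = unname(wt$statistic), p = wt$p.value,
                 stringsAsFactors = FALSE)
    }))
  }
  list(observations = obs, category_summary = category_summary, tests = tests)
}
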