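# Promoter-switch detection between library conditions, differential
# expression thresholding, transcription-factor intersection, and
# TSS-specific motif-window association.

#' Detect pairs switching to overlap between conditions
#'
#' A pair switches when it is NOT overlapping (no_overlap, single_expressed
#' or none_expressed) in every control library and overlapping in every
#' treated library. For each gene of a switching pair, the condition-level
#' effective 5' end is the most upstream effective 5' end across the
#' condition's libraries; a gene is a switching gene when that position
#' differs between conditions, with the shift reported strand-aware
#' (positive = upstream: smaller coordinate on `+`, larger on `-`).
#' `new_tss_is_additional` records whether the control-condition TSS
#' position is still admitted in at least one treated library.
#'
#' @param statuses Output of [call_overlaps()] covering both conditions.
#' @param pairs Candidate pair table.
#' @param control_libs,treated_libs Disjoint, nonempty library-id sets.
#' @param tss Admitted TSS records (to evaluate `new_tss_is_additional`).
#' @return A data.frame with one row per switching gene of each switching
#'   pair: `pair_id`, `gene_id`, `strand`, `control_five_prime`,
#'   `treated_five_prime`, `upstream_shift_bp`, `new_tss_is_additional`.
#'   Pairs whose genes all kept their 5' ends are still reported with
#'   `gene_id = NA` (a switch driven purely by expression gain).
#' @export
detect_switches <- function(statuses, pairs, control_libs, treated_libs,
                            tss = NULL) {
  if (!length(control_libs) || !length(treated_libs)) {
    stop("both library sets must be nonempty")
  }
  if (length(intersect(control_libs, treated_libs))) {
    stop("control and treated library sets overlap")
  }
  st <- function(pid, libs) statuses$state[statuses$pair_id == pid &
                                             statuses$library_id %in% libs]
  candidates <- unique(statuses$pair_id)
  switching <- candidates[vapply(candidates, function(pid) {
    sc <- st(pid, control_libs); stt <- st(pid, treated_libs)
    length(sc) == length(control_libs) && length(stt) == length(treated_libs) &&
      all(sc != "overlap") && all(stt == "overlap")
  }, TRUE)]
  rows <- list()
  for (pid in switching) {
    pidx <- match(pid, pairs$pair_id)
    for (side in c("plus", "minus")) {
      g <- if (side == "plus") pairs$gene_plus[pidx] else pairs$gene_minus[pidx]
      strand <- if (side == "plus") "+" else "-"
      col <- paste0("five_prime_", side)
      eff <- function(libs) {
        v <- statuses[[col]][statuses$pair_id == pid &
                               statuses$library_id %in% libs]
        v <- v[!is.na(v)]
        if (!length(v)) NA_integer_ else effective_five_prime(v, strand)
      }
      ec <- eff(control_libs); et <- eff(treated_libs)
      if (is.na(et)) next
      moved <- is.na(ec) || ec != et
      if (!moved) next
      shift <- if (is.na(ec)) NA_integer_ else {
        if (strand == "+") ec - et else et - ec
      }
      additional <- NA
      if (!is.null(tss) && !is.na(ec)) {
        additional <- any(tss$gene_id == g & tss$library_id %in% treated_libs &
                            tss$position == ec)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = pid, gene_id = g, strand = strand,
        control_five_prime = ec, treated_five_prime = et,
        upstream_shift_bp = shift, new_tss_is_additional = additional,
        stringsAsFactors = FALSE)
    }
    if (!length(rows) || !any(vapply(rows, function(r) r$pair_id == pid, TRUE))) {
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = pid, gene_id = NA_character_, strand = NA_character_,
        control_five_prime = NA_integer_, treated_five_prime = NA_integer_,
        upstream_shift_bp = NA_integer_, new_tss_is_additional = NA,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(pair_id = character(), gene_id = character(),
                      strand = character(), control_five_prime = integer(),
                      treated_five_prime = integer(),
                      upstream_shift_bp = integer(),
                      new_tss_is_additional = logical()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply differential-expression thresholds
#'
#' Differentially expressed genes have `|log2fc|` strictly above `lfc_min`
#' and FDR strictly below `fdr_max` (both inequalities strict).
#'
#' @param de Data.frame with `gene_id`, `log2fc`, `fdr`.
#' @param lfc_min Log2 fold-change cutoff (default 1.5).
#' @param fdr_max FDR cutoff (default 0.05).
#' @return A list with character vectors `up` and `down`.
#' @export
apply_de_thresholds <- function(de, lfc_min = 1.5, fdr_max = 0.05) {
  stopifnot(all(c("gene_id", "log2fc", "fdr") %in% names(de)))
  if (any(de$fdr < 0 | de$fdr > 1, na.rm = TRUE)) stop("fdr outside [0, 1]")
  sig <- de$fdr < fdr_max
  list(up = de$gene_id[sig & de$log2fc > lfc_min],
       down = de$gene_id[sig & de$log2fc < -lfc_min])
}

#' Intersect differentially expressed genes with a TF list
#'
#' @param de_sets List with `up` and `down` gene-id vectors (from
#'   [apply_de_thresholds()]).
#' @param tf_ids Character vector of transcription-factor gene ids.
#' @return A list with `up` and `down` restricted to TFs.
#' @export
intersect_tf <- function(de_sets, tf_ids) {
  list(up = intersect(de_sets$up, tf_ids),
       down = intersect(de_sets$down, tf_ids))
}

#' Associate motif hits with a gene's TSSs
#'
#' A TF is associated with a TSS when any of its motif hits has its midpoint
#' within `window_bp` of the TSS (inclusive: a hit at exactly `window_bp` is
#' associated; symmetric upstream/downstream). A TF is TSS-specific when it
#' is associated with exactly one of the gene's TSSs. The anchor is the hit
#' midpoint by default; `anchor = "edge"` uses the nearest hit edge.
#'
#' @param tss_positions Named integer vector of the gene's TSS positions
#'   (names label the TSSs, e.g. `"control"` / `"treated"`).
#' @param hits Motif-hit data.frame (see [scan_pwm()]).
#' @param window_bp Association window (default 500).
#' @param anchor `"midpoint"` or `"edge"`.
#' @return A list with `associations` (data.frame `tss`, `tf_name`,
#'   `motif_id`, `min_distance`) and `tss_specific` (data.frame `tf_name`,
#'   `tss` for TFs seen at exactly one TSS).
#' @export
associate_tss_tfbs <- function(tss_positions, hits, window_bp = 500L,
                               anchor = c("midpoint", "edge")) {
  anchor <- match.arg(anchor)
  stopifnot(!is.null(names(tss_positions)))
  assoc <- list()
  for (ti in seq_along(tss_positions)) {
    tpos <- tss_positions[ti]
    d <- if (anchor == "midpoint") {
      mid <- (hits$start + hits$end - 1L) / 2
      abs(mid - tpos)
    } else {
      pmax(0, pmax(hits$start - tpos, tpos - (hits$end - 1L)))
    }
    sel <- which(d <= window_bp)
    if (!length(sel)) next
    df <- data.frame(tss = names(tss_positions)[ti],
                     tf_name = hits$tf_name[sel],
                     motif_id = hits$motif_id[sel],
                     distance = d[sel], stringsAsFactors = FALSE)
    key <- paste(df$tf_name, df$motif_id)
    keep <- !duplicated(key)
    df <- df[order(df$distance), , drop = FALSE]
    df <- df[!duplicated(paste(df$tf_name, df$motif_id)), , drop = FALSE]
    names(df)[names(df) == "distance"] <- "min_distance"
    assoc[[length(assoc) + 1L]] <- df
  }
  if (!length(assoc)) {
    return(list(associations = data.frame(tss = character(),
                                          tf_name = character(),
                                          motif_id = character(),
                                          min_distance = numeric()),
                tss_specific = data.frame(tf_name = character(),
                                          tss = character())))
  }
  associations <- do.call(rbind, assoc)
  rownames(associations) <- NULL
  n_tss_per_tf <- tapply(associations$tss, associations$tf_name,
                         function(x) length(unique(x)))
  specific_tfs <- names(n_tss_per_tf)[n_tss_per_tf == 1]
  tss_specific <- unique(associations[associations$tf_name %in% specific_tfs,
                                      c("tf_name", "tss")])
  rownames(tss_specific) <- NULL
  list(associations = associations, tss_specific = tss_specific)
}
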