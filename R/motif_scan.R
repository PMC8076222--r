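# Position-weight-matrix promoter scanning. PFM counts are converted to
# log2 odds against a background distribution, and windows on both strands
# are reported when their min-max relative score reaches the threshold
# (the conventional "relative score" of PWM scanning tools).

BASES <- c("A", "C", "G", "T")

#' Convert a position frequency matrix to a position weight matrix
#'
#' Column `j`, base `b`:
#' `log2(((count + pseudocount * bg_b) / (colsum + pseudocount)) / bg_b)`.
#' `score_min` / `score_max` are the sums of per-column minima / maxima, the
#' denominators of the min-max relative score.
#'
#' @param pfm A PFM as returned by [read_pfm()] (list with `motif_id`,
#'   `tf_name`, 4 x L `counts`), or a bare 4 x L count matrix.
#' @param pseudocount Total pseudocount distributed by background weight
#'   (default 0.8, a conventional choice).
#' @param background Base composition (A, C, G, T); uniform by default.
#' @return A list of class `"pwm"`: `motif_id`, `tf_name`, `mat` (4 x L
#'   log-odds), `score_min`, `score_max`, `length`.
#' @export
pfm_to_pwm <- function(pfm, pseudocount = 0.8,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (is.matrix(pfm)) pfm <- list(motif_id = "pfm", tf_name = "pfm", counts = pfm)
  counts <- pfm$counts
  if (is.null(dim(counts)) || nrow(counts) != 4 || ncol(counts) < 1) {
    stop("PFM must be a 4 x L matrix with L >= 1")
  }
  bg <- background / sum(background)
  probs <- sweep(counts + pseudocount * bg, 2,
                 colSums(counts) + pseudocount, "/")
  mat <- log2(probs / bg)
  rownames(mat) <- BASES
  structure(list(motif_id = pfm$motif_id, tf_name = pfm$tf_name, mat = mat,
                 score_min = sum(apply(mat, 2, min)),
                 score_max = sum(apply(mat, 2, max)),
                 length = ncol(mat)),
            class = "pwm")
}

seq_to_codes <- function(sequence) {
  chars <- strsplit(toupper(as.character(sequence)), "")[[1]]
  m <- match(chars, BASES) # N and other ambiguity codes -> NA
  m
}

revcomp_codes <- function(codes) rev(5L - codes)

#' Scan a sequence with a PWM
#'
#' Scores every window of the motif's length on the forward strand and (by
#' default) the reverse complement; windows containing non-ACGT characters
#' are skipped. A hit is reported when the min-max relative score
#' `(raw - score_min) / (score_max - score_min)` reaches `rel_min`.
#' Reverse-strand hits are reported on forward coordinates of the window.
#'
#' @param sequence A character string or `Biostrings::DNAString`.
#' @param pwm A `"pwm"` object from [pfm_to_pwm()].
#' @param rel_min Relative-score threshold in `[0, 1]` (default 0.95).
#' @param both_strands Also scan the reverse complement?
#' @param offset Genomic coordinate of the sequence's first base (0-based);
#'   hit starts are reported as `offset + window position`.
#' @param chrom Chromosome name attached to the hits.
#' @return A data.frame `motif_id`, `tf_name`, `chrom`, `start` (0-based),
#'   `end` (half-open), `strand`, `raw_score`, `rel_score`.
#' @export
scan_pwm <- function(sequence, pwm, rel_min = 0.95, both_strands = TRUE,
                     offset = 0L, chrom = ".") {
  stopifnot(inherits(pwm, "pwm"), rel_min >= 0, rel_min <= 1)
  codes <- seq_to_codes(sequence)
  L <- pwm$length
  n <- length(codes) - L + 1L
  empty <- data.frame(motif_id = character(), tf_name = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), raw_score = numeric(),
                      rel_score = numeric())
  if (n < 1) return(empty)
  strands <- if (both_strands) c("+", "-") else "+"
  denom <- pwm$score_max - pwm$score_min
  rows <- list()
  for (strand in strands) {
    sc <- if (strand == "+") codes else revcomp_codes(codes)
    # scores[i] = sum_j mat[sc[i + j - 1], j]
    scores <- numeric(n)
    valid <- rep(TRUE, n)
    for (j in seq_len(L)) {
      cj <- sc[j:(j + n - 1L)]
      valid <- valid & !is.na(cj)
      contrib <- pwm$mat[cbind(cj, j)]
      contrib[is.na(contrib)] <- 0
      scores <- scores + contrib
    }
    rel <- (scores - pwm$score_min) / denom
    hit <- valid & rel >= rel_min
    if (!any(hit)) next
    pos <- which(hit) # window start on the scanned orientation
    fwd_start <- if (strand == "+") pos - 1L else (length(codes) - (pos - 1L) - L)
    rows[[strand]] <- data.frame(
      motif_id = pwm$motif_id, tf_name = pwm$tf_name, chrom = chrom,
      start = offset + fwd_start, end = offset + fwd_start + L,
      strand = strand, raw_score = scores[hit], rel_score = rel[hit],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a set of promoter sequences with a set of PFMs
#'
#' @param sequences Named character vector or `DNAStringSet`; names are of
#'   the form `id|chrom|start0` (as written by the synthetic-data generator)
#'   or plain ids, in which case `offsets`/`chroms` supply coordinates.
#' @param pfms List of PFMs.
#' @param rel_min Relative-score threshold.
#' @param offsets,chroms Optional named vectors of genomic offsets and
#'   chromosome names per sequence.
#' @param pseudocount,background Passed to [pfm_to_pwm()].
#' @return A data.frame of hits with an extra `seq_id` column.
#' @export
scan_promoters <- function(sequences, pfms, rel_min = 0.95,
                           offsets = NULL, chroms = NULL,
                           pseudocount = 0.8,
                           background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  ids <- names(sequences)
  seqs <- as.character(sequences)
  if (is.null(ids)) stop("sequences must be named")
  pwms <- lapply(pfms, pfm_to_pwm, pseudocount = pseudocount, background = background)
  rows <- list()
  for (i in seq_along(seqs)) {
    parts <- strsplit(ids[i], "|", fixed = TRUE)[[1]]
    sid <- parts[1]
    chrom <- if (length(parts) >= 2) parts[2] else if (!is.null(chroms)) chroms[[sid]] else "."
    off <- if (length(parts) >= 3) as.integer(parts[3]) else if (!is.null(offsets)) as.integer(offsets[[sid]]) else 0L
    for (p in pwms) {
      h <- scan_pwm(seqs[i], p, rel_min = rel_min, offset = off, chrom = chrom)
      if (nrow(h)) rows[[length(rows) + 1L]] <- cbind(seq_id = sid, h)
    }
  }
  if (!length(rows)) {
    return(data.frame(seq_id = character(), motif_id = character(),
                      tf_name = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      raw_score = numeric(), rel_score = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write motif hits as BED6+2
#' @param hits Hit data.frame from [scan_pwm()]/[scan_promoters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_hits_bed <- function(hits, path) {
  df <- data.frame(hits$chrom, hits$start, hits$end, hits$motif_id,
                   round(1000 * hits$rel_score), hits$strand,
                   hits$rel_score, hits$raw_score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
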