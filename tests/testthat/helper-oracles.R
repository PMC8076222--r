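# Independent brute-force oracles used across the suite. These re-derive
# expected values from first principles (explicit base sets, exhaustive
# enumeration, direct formulas) and never call the implementation paths they
# check.

# Overlap verdict by materialising both per-library gene extents as explicit
# base sets: the pair overlaps iff each effective 5' end is a member of the
# partner's base set; the overlap length is the size of the intersection.
oracle_overlap <- function(a, b, plus_span_end, minus_span_start) {
  if (is.na(a) && is.na(b)) return(list(state = "none_expressed", len = 0L))
  if (is.na(a) || is.na(b)) return(list(state = "single_expressed", len = 0L))
  plus_set <- seq.int(a, plus_span_end - 1L)
  minus_set <- seq.int(minus_span_start, b)
  if ((a %in% minus_set) && (b %in% plus_set)) {
    list(state = "overlap", len = length(intersect(plus_set, minus_set)))
  } else {
    list(state = "no_overlap", len = 0L)
  }
}

# One random head-to-head configuration (genes <= 10 kb, <= 5 TSSs/gene),
# returned as the tables call_overlaps() consumes plus the raw TSS positions.
random_pair_config <- function() {
  m1 <- 20000L + sample.int(2000L, 1)
  m0 <- m1 - sample(500:9999, 1)
  p0 <- m1 + sample(-2000:2000, 1)
  p1 <- p0 + sample(500:9999, 1)
  genes <- data.frame(
    gene_id = c("GP", "GM"), chrom = "chrT", strand = c("+", "-"),
    span_start = c(p0, m0), span_end = c(p1, m1),
    annotated_five_prime = c(p0, m1 - 1L), biotype = "x",
    stringsAsFactors = FALSE)
  kp <- sample(0:5, 1)
  km <- sample(0:5, 1)
  tss_p <- if (kp) sample(seq.int(p0 - 3000L, p1 - 1L), kp) else integer()
  tss_m <- if (km) sample(seq.int(m0, m1 - 1L + 3000L), km) else integer()
  tss <- rbind(
    if (kp) data.frame(library_id = "L1", gene_id = "GP", chrom = "chrT",
                       strand = "+", position = tss_p, expression_ppm = 10,
                       confident = TRUE, stringsAsFactors = FALSE),
    if (km) data.frame(library_id = "L1", gene_id = "GM", chrom = "chrT",
                       strand = "-", position = tss_m, expression_ppm = 10,
                       confident = TRUE, stringsAsFactors = FALSE))
  pairs <- data.frame(pair_id = "GP:GM", gene_plus = "GP", gene_minus = "GM",
                      chrom = "chrT", stringsAsFactors = FALSE)
  list(genes = genes, tss = tss, pairs = pairs, tss_p = tss_p, tss_m = tss_m)
}

# Per-record re-evaluation of the three TSS admission predicates.
oracle_filter_keep <- function(tss, genes, min_ppm, max_dist, require_conf) {
  a5 <- genes$annotated_five_prime[match(tss$gene_id, genes$gene_id)]
  (tss$confident | !require_conf) &
    tss$expression_ppm >= min_ppm &
    abs(tss$position - a5) <= max_dist
}

# Direct minor-allele-fraction interval test.
oracle_snp_class <- function(ref, alt) {
  f <- pmin(ref, alt) / (ref + alt)
  out <- character(length(f))
  out[f < 0.02] <- "monoallelic"
  out[f >= 0.02 & f < 0.20] <- "skewed"
  out[f >= 0.20] <- "biallelic"
  out
}

# Mann-Whitney U by exhaustive pair counting.
oracle_mwu <- function(x, y) {
  u <- 0
  for (xi in x) u <- u + sum(xi > y) + 0.5 * sum(xi == y)
  u
}

# Pearson r from the definitional sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# Hypergeometric upper-tail P(X >= k) by direct summation of the pmf.
oracle_hyper_tail <- function(k, set_size, universe_size, query_size) {
  i <- k:min(set_size, query_size)
  sum(choose(set_size, i) * choose(universe_size - set_size, query_size - i)) /
    choose(universe_size, query_size)
}

# Window-by-window PWM scoring that recomputes every sum independently.
oracle_scan <- function(seq_chr, mat, rel_min, motif_id = "m") {
  bases <- c("A", "C", "G", "T")
  L <- ncol(mat)
  smin <- sum(apply(mat, 2, min)); smax <- sum(apply(mat, 2, max))
  revcomp <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                                      collapse = ""))
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq_chr else revcomp(seq_chr)
    for (i in seq_len(nchar(s) - L + 1L)) {
      w <- strsplit(substr(s, i, i + L - 1L), "")[[1]]
      if (any(!w %in% bases)) next
      sc <- 0
      for (j in seq_len(L)) sc <- sc + mat[w[j], j]
      rel <- (sc - smin) / (smax - smin)
      if (rel >= rel_min) {
        start <- if (strand == "+") i - 1L else nchar(s) - (i - 1L) - L
        out[[length(out) + 1L]] <- data.frame(start = start, strand = strand,
                                              raw_score = sc, rel_score = rel)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), strand = character(),
                      raw_score = numeric(), rel_score = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$strand), , drop = FALSE]
}

# Small well-formed TSS table builder for filter tests.
make_tss <- function(gene_id, position, ppm, confident = TRUE,
                     library_id = "L1", strand = "+") {
  data.frame(library_id = library_id, gene_id = gene_id, chrom = "chrT",
             strand = strand, position = as.integer(position),
             expression_ppm = ppm, confident = confident,
             stringsAsFactors = FALSE)
}

make_genes <- function(gene_id, strand = "+", span_start = 1000L,
                       span_end = 6000L) {
  g <- data.frame(gene_id = gene_id, chrom = "chrT", strand = strand,
                  span_start = as.integer(span_start),
                  span_end = as.integer(span_end), biotype = "x",
                  stringsAsFactors = FALSE)
  g$annotated_five_prime <- ifelse(g$strand == "+", g$span_start,
                                   g$span_end - 1L)
  g
}
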