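# Allele-specific expression classification from per-SNP heterozygous allele
# read counts. Classes are defined on the minor-allele read fraction
# f = min(ref, alt) / (ref + alt): monoallelic when f < 0.02 (at least 98% of
# reads from one allele, under 2% from the other), skewed when
# 0.02 <= f < 0.20, biallelic when f >= 0.20. The three intervals partition
# [0, 0.5].

#' Classify a heterozygous SNP by allele read counts
#'
#' @param ref_count,alt_count Nonnegative integer vectors (recycled);
#'   `ref_count + alt_count >= 1` for every element.
#' @return Character vector in `{monoallelic, skewed, biallelic}`.
#' @examples
#' classify_snp(100, 0) # monoallelic
#' classify_snp(98, 2)  # skewed: minor fraction exactly 0.02
#' classify_snp(80, 20) # biallelic: minor fraction exactly 0.20
#' @export
classify_snp <- function(ref_count, alt_count) {
  depth <- ref_count + alt_count
  if (any(depth < 1)) stop("SNP with zero depth; filter with usable_snps() first")
  if (any(ref_count < 0 | alt_count < 0)) stop("negative allele counts")
  f <- pmin(ref_count, alt_count) / depth
  ifelse(f < 0.02, "monoallelic", ifelse(f < 0.20, "skewed", "biallelic"))
}

#' Filter SNPs usable for ASE classification
#'
#' Retains a SNP iff its depth is at least `min_depth` and it lies outside
#' the overlap region of its gene's pair (signals from overlapping regions
#' can mimic biallelic expression because reads from the two genes are
#' superimposed). The overlap region of a pair is the union over libraries
#' of its called overlap spans.
#'
#' @param counts Allele-count data.frame (see [read_allele_counts()]).
#' @param overlap_mask Region mask of per-gene overlap spans with a
#'   `gene_id` column (see [overlap_region_mask()]); may be `NULL` to skip
#'   positional exclusion.
#' @param min_depth Minimum read depth (default 10; a SNP at exactly 10 is
#'   retained).
#' @return The retained rows, with a `"filter_report"` attribute.
#' @export
usable_snps <- function(counts, overlap_mask = NULL, min_depth = 10L) {
  depth <- counts$ref_count + counts$alt_count
  low <- depth < min_depth
  in_overlap <- rep(FALSE, nrow(counts))
  if (!is.null(overlap_mask) && nrow(overlap_mask) > 0) {
    q <- GenomicRanges::GRanges(counts$chrom,
                                IRanges::IRanges(start = counts$pos + 1L, width = 1L))
    m <- GenomicRanges::GRanges(overlap_mask$chrom,
                                IRanges::IRanges(start = overlap_mask$start + 1L,
                                                 end = overlap_mask$end))
    hits <- GenomicRanges::findOverlaps(q, m)
    same_gene <- counts$gene_id[S4Vectors::queryHits(hits)] ==
      overlap_mask$gene_id[S4Vectors::subjectHits(hits)]
    in_overlap[unique(S4Vectors::queryHits(hits)[same_gene])] <- TRUE
  }
  keep <- !(low | in_overlap)
  out <- counts[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_report") <- data.frame(
    rule = c("below_min_depth", "inside_overlap_region", "retained"),
    n = c(sum(low), sum(in_overlap), sum(keep)))
  out
}

#' Per-gene overlap-region mask from called statuses
#'
#' Union over libraries of each pair's called overlap spans, attributed to
#' both genes of the pair, as 0-based half-open intervals.
#'
#' @param statuses Output of [call_overlaps()].
#' @param pairs Candidate pair table.
#' @return A region-mask data.frame with an extra `gene_id` column.
#' @export
overlap_region_mask <- function(statuses, pairs) {
  ov <- statuses[statuses$state == "overlap", , drop = FALSE]
  if (nrow(ov) == 0) {
    return(cbind(region_mask(character(), integer(), integer(), label = "overlap"),
                 gene_id = character()))
  }
  pidx <- match(ov$pair_id, pairs$pair_id)
  both <- rbind(
    data.frame(chrom = pairs$chrom[pidx], start = ov$overlap_start,
               end = ov$overlap_end + 1L, gene_id = pairs$gene_plus[pidx]),
    data.frame(chrom = pairs$chrom[pidx], start = ov$overlap_start,
               end = ov$overlap_end + 1L, gene_id = pairs$gene_minus[pidx])
  )
  both <- unique(both)
  out <- region_mask(both$chrom, both$start, both$end, label = "overlap")
  out$gene_id <- both$gene_id
  rownames(out) <- NULL
  out
}

#' Per-library gene class from its SNP classes
#'
#' Unanimous SNP classes give that class; any disagreement between SNPs of
#' the same gene in the same library is inconclusive and yields
#' `noninformative`.
#'
#' @param snp_classes Character vector of per-SNP classes (>= 1).
#' @return A single class string.
#' @export
classify_gene_library <- function(snp_classes) {
  stopifnot(length(snp_classes) >= 1)
  u <- unique(snp_classes)
  if (length(u) == 1) u else "noninformative"
}

#' Overall gene class from per-library classes
#'
#' Ignoring noninformative libraries, a uniform class is returned as such and
#' discordant classes give `mixed`; all-noninformative gives
#' `noninformative`.
#'
#' @param library_classes Character vector of per-library classes (>= 1).
#' @return A single class string.
#' @export
aggregate_gene <- function(library_classes) {
  stopifnot(length(library_classes) >= 1)
  inf <- setdiff(unique(library_classes), "noninformative")
  if (length(inf) == 0) "noninformative" else if (length(inf) == 1) inf else "mixed"
}

#' Exclude genes unsuitable for ASE analysis
#'
#' A gene is analyzable iff its expression reaches `min_fpkm` in at least one
#' library and its genomic span does not intersect the nondiploid mask
#' (copy-number-altered regions violate the diploid assumption behind the
#' allele-fraction thresholds).
#'
#' @param genes Gene-model data.frame.
#' @param nondiploid_mask Region mask (may have zero rows).
#' @param expression Long-format expression table (FPKM).
#' @param min_fpkm Expression threshold (default 5; exactly 5 qualifies).
#' @return A list with `analyzable` (character vector of gene ids) and
#'   `report` (gene_id, status in `{analyzable, low_expression, nondiploid}`).
#' @export
exclude_genes <- function(genes, nondiploid_mask, expression, min_fpkm = 5) {
  max_expr <- tapply(expression$expression, expression$gene_id, max)
  expressed <- genes$gene_id %in% names(max_expr)[max_expr >= min_fpkm]
  nondiploid <- mask_overlaps(nondiploid_mask, genes$chrom,
                              genes$span_start, genes$span_end)
  status <- ifelse(nondiploid, "nondiploid",
                   ifelse(!expressed, "low_expression", "analyzable"))
  report <- data.frame(gene_id = genes$gene_id, status = status,
                       stringsAsFactors = FALSE)
  list(analyzable = genes$gene_id[status == "analyzable"], report = report)
}

#' Classify allele-specific expression for a gene set
#'
#' Full per-gene pipeline: SNP filtering ([usable_snps()]), per-SNP
#' classification, per-library consensus, and cross-library aggregation.
#'
#' @param counts Allele-count table.
#' @param overlap_mask Optional per-gene overlap-region mask.
#' @param min_depth Minimum SNP depth.
#' @param genes_analyzable Optional character vector restricting the genes
#'   classified (e.g. from [exclude_genes()]).
#' @return A list with `per_library` (gene_id, library_id, class,
#'   n_snps_used), and `overall` (gene_id, class, n_snps_used,
#'   n_libraries_informative).
#' @export
classify_ase <- function(counts, overlap_mask = NULL, min_depth = 10L,
                         genes_analyzable = NULL) {
  if (!is.null(genes_analyzable)) {
    counts <- counts[counts$gene_id %in% genes_analyzable, , drop = FALSE]
  }
  use <- usable_snps(counts, overlap_mask, min_depth)
  if (nrow(use) == 0) {
    return(list(per_library = data.frame(gene_id = character(),
                                         library_id = character(),
                                         class = character(),
                                         n_snps_used = integer()),
                overall = data.frame(gene_id = character(), class = character(),
                                     n_snps_used = integer(),
                                     n_libraries_informative = integer())))
  }
  use$snp_class <- classify_snp(use$ref_count, use$alt_count)
  key <- paste(use$gene_id, use$library_id, sep = "\r")
  per_lib_class <- tapply(use$snp_class, key, classify_gene_library)
  per_lib_n <- tapply(use$snp_class, key, length)
  parts <- do.call(rbind, strsplit(names(per_lib_class), "\r", fixed = TRUE))
  per_library <- data.frame(gene_id = parts[, 1], library_id = parts[, 2],
                            class = as.character(per_lib_class),
                            n_snps_used = as.integer(per_lib_n),
                            stringsAsFactors = FALSE)
  rownames(per_library) <- NULL
  overall_class <- tapply(per_library$class, per_library$gene_id, aggregate_gene)
  overall <- data.frame(
    gene_id = names(overall_class),
    class = as.character(overall_class),
    n_snps_used = as.integer(tapply(per_library$n_snps_used,
                                    per_library$gene_id, sum)),
    n_libraries_informative = as.integer(tapply(
      per_library$class, per_library$gene_id,
      function(x) sum(x != "noninformative"))),
    stringsAsFactors = FALSE
  )
  rownames(overall) <- NULL
  list(per_library = per_library, overall = overall)
}

#' Compare ASE class composition between gene sets
#'
#' Tabulates overall classes per set, computes each set's
#' monoallelic:biallelic ratio, and compares the monoallelic-vs-biallelic
#' composition of the two sets with Fisher's exact test.
#'
#' @param calls_a,calls_b `overall` tables from [classify_ase()] for the two
#'   sets (e.g. overlapping genes vs non-overlapping controls).
#' @param labels Length-2 character vector naming the sets.
#' @return A list with `counts` (class-by-set table), `ratio` (named
#'   mono/biallelic ratios; `NA` when a set has no biallelic genes, flagged
#'   via `ratio_defined`), `fisher_p` and `odds_ratio`.
#' @export
mae_summary <- function(calls_a, calls_b, labels = c("overlap", "control")) {
  classes <- c("monoallelic", "skewed", "biallelic", "mixed", "noninformative")
  cnt <- function(calls) {
    vapply(classes, function(k) sum(calls$class == k), 1L)
  }
  counts <- cbind(cnt(calls_a), cnt(calls_b))
  colnames(counts) <- labels
  ratio <- counts["monoallelic", ] / counts["biallelic", ]
  ratio_defined <- counts["biallelic", ] > 0
  ratio[!ratio_defined] <- NA_real_
  tab <- counts[c("monoallelic", "biallelic"), , drop = FALSE]
  ft <- if (all(colSums(tab) > 0)) stats::fisher.test(tab) else NULL
  list(counts = counts, ratio = ratio, ratio_defined = ratio_defined,
       fisher_p = if (is.null(ft)) NA_real_ else ft$p.value,
       odds_ratio = if (is.null(ft)) NA_real_ else unname(ft$estimate))
}
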