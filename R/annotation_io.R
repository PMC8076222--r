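# All coordinates inside the package are 0-based half-open. BED is native;
# GFF3 (1-based inclusive) is shifted at the boundary by rtracklayer and
# converted back here. No other module performs a coordinate shift.

#' Read gene models from BED or GFF3
#'
#' Parses an annotation file into a gene-model table with one row per gene.
#' Coordinates are normalised to the package-wide 0-based half-open
#' convention, and the annotated 5' end is derived strand-aware: it equals
#' `span_start` for `+` genes and `span_end - 1` for `-` genes.
#'
#' @param path Path to the annotation file (gzip-transparent).
#' @param format One of `"bed"` (BED6/BED12) or `"gff3"`.
#' @return A data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `span_start`, `span_end` (0-based half-open),
#'   `annotated_five_prime`, `biotype`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t500\tGENEA\t0\t+", bed)
#' read_gene_models(bed, format = "bed")
#' @export
read_gene_models <- function(path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = format),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e))
  )
  md <- S4Vectors::mcols(gr)
  if (format == "gff3") {
    keep <- if ("type" %in% names(md)) as.character(md$type) == "gene" else rep(TRUE, length(gr))
    gr <- gr[keep]
    md <- S4Vectors::mcols(gr)
    gene_id <- if ("ID" %in% names(md)) as.character(md$ID) else as.character(md$Name)
    biotype <- if ("biotype" %in% names(md)) as.character(md$biotype) else "protein_coding"
  } else {
    gene_id <- as.character(md$name)
    biotype <- "protein_coding"
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    stop("unstranded or unknown-strand gene records are not supported")
  }
  out <- data.frame(
    gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    span_start = BiocGenerics::start(gr) - 1L, # GRanges is 1-based inclusive
    span_end = BiocGenerics::end(gr),
    biotype = biotype,
    stringsAsFactors = FALSE
  )
  out$annotated_five_prime <- ifelse(out$strand == "+", out$span_start, out$span_end - 1L)
  validate_gene_models(out)
  out
}

#' Write gene models to BED6
#'
#' Inverse of [read_gene_models()] for the BED format; `write` then `read`
#' is the identity on the gene-model table (up to row order).
#'
#' @param genes Gene-model data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  validate_gene_models(genes)
  df <- data.frame(
    chrom = genes$chrom,
    start = format(genes$span_start, scientific = FALSE, trim = TRUE),
    end = format(genes$span_end, scientific = FALSE, trim = TRUE),
    name = genes$gene_id,
    score = 0L,
    strand = genes$strand
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_gene_models <- function(genes) {
  stopifnot(is.data.frame(genes))
  req <- c("gene_id", "chrom", "strand", "span_start", "span_end")
  missing <- setdiff(req, names(genes))
  if (length(missing)) stop("gene model table lacks columns: ", paste(missing, collapse = ", "))
  if (any(genes$span_start >= genes$span_end)) stop("gene model with span_start >= span_end")
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in gene model table")
  if ("annotated_five_prime" %in% names(genes)) {
    bad <- genes$annotated_five_prime < genes$span_start |
      genes$annotated_five_prime >= genes$span_end
    if (any(bad)) stop("annotated_five_prime outside gene span for: ",
                       paste(genes$gene_id[bad], collapse = ", "))
  }
  invisible(genes)
}

#' Read a per-library TSS table
#'
#' Reads a tab-separated TSS table with mandatory header columns
#' `library_id`, `gene_id`, `chrom`, `strand`, `position` and at least one of
#' `expression_ppm` / `raw_count`, plus an optional logical `confident`
#' column (assumed `TRUE` when absent). Positions are 0-based. When only raw
#' tag counts are present, ppm is computed per library from the library's
#' total raw count (or from `library_totals` when supplied, e.g. if the table
#' is a subset of a larger library).
#'
#' @param path Path to the TSV (gzip-transparent).
#' @param genes Optional gene-model data.frame; rows referencing unknown
#'   `gene_id`s are dropped with a warning and counted in the load report.
#' @param library_totals Optional named numeric vector of total raw tag
#'   counts per library, used for ppm conversion.
#' @return A data.frame of TSS records with attribute `"load_report"`
#'   (rows read, rows kept, unknown-gene rows skipped).
#' @export
read_tss_table <- function(path, genes = NULL, library_totals = NULL) {
  tab <- read_tsv_checked(path, required = c("library_id", "gene_id", "chrom",
                                             "strand", "position"))
  n_in <- nrow(tab)
  if (!"confident" %in% names(tab)) tab$confident <- TRUE
  tab$confident <- as.logical(tab$confident)
  if (!any(c("expression_ppm", "raw_count") %in% names(tab))) {
    stop("TSS table needs an 'expression_ppm' or 'raw_count' column: ", path)
  }
  if ("raw_count" %in% names(tab)) {
    if (any(tab$raw_count < 0, na.rm = TRUE)) stop("negative raw_count in ", path)
  }
  if (!"expression_ppm" %in% names(tab)) {
    totals <- if (is.null(library_totals)) {
      tapply(tab$raw_count, tab$library_id, sum)
    } else {
      library_totals[unique(tab$library_id)]
    }
    tab$expression_ppm <- compute_ppm(tab$raw_count,
                                      as.numeric(totals[tab$library_id]))
  }
  if (any(tab$expression_ppm < 0, na.rm = TRUE)) stop("negative expression_ppm in ", path)
  n_unknown <- 0L
  if (!is.null(genes)) {
    known <- tab$gene_id %in% genes$gene_id
    n_unknown <- sum(!known)
    if (n_unknown > 0) {
      warning(n_unknown, " TSS rows reference unknown gene_ids and were skipped")
      tab <- tab[known, , drop = FALSE]
    }
  }
  tab$position <- as.integer(tab$position)
  rownames(tab) <- NULL
  attr(tab, "load_report") <- list(rows_read = n_in, rows_kept = nrow(tab),
                                   unknown_gene_rows = n_unknown)
  tab
}

#' Write a TSS table
#' @param tss TSS record data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tss_table <- function(tss, path) {
  utils::write.table(tss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED interval file into a region mask
#'
#' @param path BED file path (0-based half-open intervals; gzip-transparent).
#' @param label Label attached to the mask (e.g. `"nondiploid"`).
#' @return A data.frame with columns `chrom`, `start`, `end`, `label`;
#'   possibly zero rows.
#' @export
read_region_mask <- function(path, label = "mask") {
  if (file.size(path) == 0 ||
      length(readLines(path, n = 1L, warn = FALSE)) == 0) {
    return(region_mask(character(), integer(), integer(), label = label))
  }
  gr <- rtracklayer::import(path, format = "bed")
  region_mask(as.character(GenomicRanges::seqnames(gr)),
              BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr), label = label)
}

#' Construct a region mask
#' @param chrom,start,end Parallel vectors of 0-based half-open intervals.
#' @param label Mask label.
#' @return A region-mask data.frame.
#' @export
region_mask <- function(chrom, start, end, label = "mask") {
  mask <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                     end = as.integer(end),
                     label = rep_len(label, length(chrom)),
                     stringsAsFactors = FALSE)
  if (any(mask$start >= mask$end)) stop("region mask interval with start >= end")
  mask
}

#' Point membership in a region mask
#'
#' Half-open semantics: a position `p` is inside `[start, end)` iff
#' `start <= p < end`.
#'
#' @param mask Region-mask data.frame.
#' @param chrom,pos Parallel vectors of query positions (0-based).
#' @return Logical vector.
#' @export
mask_contains <- function(mask, chrom, pos) {
  if (nrow(mask) == 0) return(rep(FALSE, length(pos)))
  lv <- unique(c(chrom, mask$chrom))
  q <- GenomicRanges::GRanges(factor(chrom, lv),
                              IRanges::IRanges(start = pos + 1L, width = 1L))
  m <- GenomicRanges::GRanges(factor(mask$chrom, lv),
                              IRanges::IRanges(start = mask$start + 1L, end = mask$end))
  IRanges::overlapsAny(q, m)
}

#' Interval overlap with a region mask
#'
#' @param mask Region-mask data.frame.
#' @param chrom,start,end Parallel vectors of 0-based half-open query
#'   intervals.
#' @return Logical vector: does each query interval intersect the mask?
#' @export
mask_overlaps <- function(mask, chrom, start, end) {
  if (nrow(mask) == 0) return(rep(FALSE, length(start)))
  lv <- unique(c(chrom, mask$chrom))
  q <- GenomicRanges::GRanges(factor(chrom, lv),
                              IRanges::IRanges(start = start + 1L, end = end))
  m <- GenomicRanges::GRanges(factor(mask$chrom, lv),
                              IRanges::IRanges(start = mask$start + 1L, end = mask$end))
  IRanges::overlapsAny(q, m)
}

#' Read JASPAR-format position frequency matrices
#'
#' Accepts both the 4-row raw JASPAR format and the bracketed
#' `A [ 1 2 3 ]` variant. Row order A, C, G, T is preserved.
#'
#' @param path PFM file path.
#' @return A named list of PFMs; each element is a list with `motif_id`,
#'   `tf_name` and a 4 x L `counts` matrix with rownames `A,C,G,T`.
#' @export
read_pfm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0) stop("no motif headers ('>') found in ", path)
  pfms <- list()
  for (i in seq_along(starts)) {
    from <- starts[i] + 1L
    to <- if (i < length(starts)) starts[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    if (length(block) != 4) stop("PFM block must have 4 rows (A,C,G,T) in ", path)
    header <- sub("^>\\s*", "", lines[starts[i]])
    parts <- strsplit(header, "[ \t]+")[[1]]
    motif_id <- parts[1]
    tf_name <- if (length(parts) > 1) parts[2] else parts[1]
    rows <- lapply(block, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("[\\[\\]]", " ", l, perl = TRUE)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    L <- unique(vapply(rows, length, 1L))
    if (length(L) != 1) stop("ragged PFM rows for motif ", motif_id)
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    if (any(counts < 0)) stop("negative counts in PFM ", motif_id)
    if (any(colSums(counts) <= 0)) stop("empty column in PFM ", motif_id)
    pfms[[motif_id]] <- list(motif_id = motif_id, tf_name = tf_name, counts = counts)
  }
  pfms
}

#' Write PFMs in JASPAR bracket format
#' @param pfms List of PFMs as returned by [read_pfm()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pfms) {
    writeLines(paste0(">", p$motif_id, " ", p$tf_name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(paste0(b, " [ ", paste(p$counts[b, ], collapse = " "), " ]"), con)
    }
  }
  invisible(path)
}

#' Read per-SNP allele read counts
#'
#' Tab-separated, VCF-derived table with mandatory columns `chrom`, `pos`
#' (0-based), `gene_id`, `library_id`, `ref_count`, `alt_count`. All listed
#' SNPs are heterozygous by construction of the upstream variant calling.
#'
#' @param path TSV path.
#' @return A data.frame of allele counts.
#' @export
read_allele_counts <- function(path) {
  tab <- read_tsv_checked(path, required = c("chrom", "pos", "gene_id",
                                             "library_id", "ref_count", "alt_count"))
  if (any(tab$ref_count < 0) || any(tab$alt_count < 0)) {
    stop("negative allele counts in ", path)
  }
  tab$pos <- as.integer(tab$pos)
  tab
}

#' Read a generic keyed tab-separated table
#'
#' Used for expression matrices (gene x library, long format), differential
#' expression tables and similar inputs.
#'
#' @param path TSV path (gzip-transparent).
#' @param required Character vector of mandatory column names.
#' @return A data.frame.
#' @export
read_table_keyed <- function(path, required = character()) {
  read_tsv_checked(path, required = required)
}

#' Read gene sets in GMT format
#' @param path GMT file: one set per line, `name<TAB>description<TAB>genes...`.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 50))
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1], "")
  out
}

read_tsv_checked <- function(path, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("table ", path, " lacks required columns: ", paste(missing, collapse = ", "))
  }
  tab
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
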