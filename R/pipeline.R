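# End-to-end orchestration: in-memory stage runner, file-based run-all with
# a JSON manifest, and recovery scoring against planted ground truth.

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Run directory.
#' @return A list with the same table components as [simulate_dataset()]
#'   (without `truth`).
#' @export
read_dataset <- function(dir) {
  genes <- read_gene_models(file.path(dir, "genes.bed"), format = "bed")
  list(
    genes = genes,
    tss = read_tss_table(file.path(dir, "tss.tsv"), genes = genes),
    expression = read_table_keyed(file.path(dir, "expression.tsv"),
                                  required = c("gene_id", "library_id", "expression")),
    allele_counts = read_allele_counts(file.path(dir, "allele_counts.tsv")),
    nondiploid_mask = read_region_mask(file.path(dir, "nondiploid.bed"),
                                       label = "nondiploid"),
    de_table = read_table_keyed(file.path(dir, "de_table.tsv"),
                                required = c("gene_id", "log2fc", "fdr")),
    tf_ids = readLines(file.path(dir, "tf_list.txt")),
    pfms = read_pfm(file.path(dir, "motifs.pfm")),
    promoters = {
      p <- file.path(dir, "promoters.fa")
      if (file.size(p) > 0) {
        ss <- Biostrings::readDNAStringSet(p)
        stats::setNames(as.character(ss), names(ss))
      } else character()
    },
    reference_sets = read_gmt(file.path(dir, "reference_sets.gmt")),
    libraries = read_table_keyed(file.path(dir, "libraries.tsv"),
                                 required = c("library_id", "group", "condition")))
}

#' Run every analysis stage on a dataset
#'
#' Executes the stages in dependency order: TSS filtering, candidate-pair
#' enumeration, per-library overlap calling, overlap-matrix construction and
#' Ward clustering, overlap-stratified expression statistics, ASE
#' classification, promoter-switch detection with motif-window TF
#' association, and group-wise gene-set enrichment.
#'
#' @param data Dataset list ([simulate_dataset()] output or [read_dataset()]).
#' @param filter_config A [tss_filter_config()].
#' @param min_each Contrast-pair stratum minimum (default 10).
#' @param k_library_clusters Flat clusters to cut the library dendrogram
#'   into; defaults to the number of `main`-condition library groups.
#' @param stages Character vector of stages to run; any of
#'   `c("filter", "overlap", "matrix", "expression", "ase", "switch",
#'   "enrich")`. Later stages silently skip when a dependency was skipped.
#' @return A list of stage outputs.
#' @export
run_pipeline <- function(data, filter_config = tss_filter_config(),
                         min_each = 10L, k_library_clusters = NULL,
                         stages = c("filter", "overlap", "matrix", "expression",
                                    "ase", "switch", "enrich")) {
  res <- list(skipped = setdiff(c("filter", "overlap", "matrix", "expression",
                                  "ase", "switch", "enrich"), stages))
  if (!"filter" %in% stages) return(res)
  res$tss_admitted <- filter_tss(data$tss, data$genes, filter_config)
  res$usage <- tss_usage_stats(res$tss_admitted)
  if (!"overlap" %in% stages) return(res)
  res$pairs <- candidate_pairs(data$genes)
  res$statuses <- call_overlaps(res$pairs, data$genes, res$tss_admitted,
                                libraries = sort(unique(data$tss$library_id)))
  res$summary <- pair_library_summary(res$statuses)
  if ("matrix" %in% stages) {
    res$matrix <- build_overlap_matrix(res$statuses)
    main_groups <- unique(data$libraries$group[data$libraries$condition == "main"])
    if (is.null(k_library_clusters)) k_library_clusters <- max(2L, length(main_groups))
    res$clustering <- cluster_bidirectional(res$matrix,
                                            k_rows = k_library_clusters,
                                            k_cols = k_library_clusters)
  }
  if ("expression" %in% stages) {
    res$contrasts <- select_contrast_pairs(res$statuses, min_each = min_each)
    if (nrow(res$contrasts) >= 2) {
      res$correlations <- correlate_contrast_pairs(res$contrasts, res$pairs,
                                                   data$expression)
      res$paired_test <- paired_overlap_test(res$contrasts, res$pairs,
                                             data$expression)
    }
    res$tss_count_expr <- expression_by_tss_count(res$usage$per_gene,
                                                  data$expression)
    contrast_status <- res$statuses[res$statuses$pair_id %in% res$contrasts$pair_id, ,
                                    drop = FALSE]
    res$category_expr <- expression_by_category(
      six_category_observations(contrast_status, res$pairs), data$expression)
  }
  if ("ase" %in% stages) {
    mask <- overlap_region_mask(res$statuses, res$pairs)
    excl <- exclude_genes(data$genes, data$nondiploid_mask, data$expression)
    res$ase_exclusions <- excl$report
    res$ase_overlap_mask <- mask
    res$ase <- classify_ase(data$allele_counts, overlap_mask = mask,
                            genes_analyzable = excl$analyzable)
    overlap_genes <- unique(c(res$pairs$gene_plus, res$pairs$gene_minus))
    calls <- res$ase$overall
    res$mae <- mae_summary(calls[calls$gene_id %in% overlap_genes, , drop = FALSE],
                           calls[!calls$gene_id %in% overlap_genes, , drop = FALSE])
  }
  if ("switch" %in% stages) {
    ctrl <- data$libraries$library_id[data$libraries$condition == "control"]
    trt <- data$libraries$library_id[data$libraries$condition == "treated"]
    if (length(ctrl) && length(trt)) {
      res$switches <- detect_switches(res$statuses, res$pairs, ctrl, trt,
                                      tss = res$tss_admitted)
      res$de_sets <- apply_de_thresholds(data$de_table)
      res$de_tfs <- intersect_tf(res$de_sets, data$tf_ids)
      if (nrow(res$switches) && length(data$promoters)) {
        res$motif_hits <- scan_promoters(data$promoters, data$pfms)
        res$tss_tfbs <- list()
        de_tf_all <- c(res$de_tfs$up, res$de_tfs$down)
        for (r in seq_len(nrow(res$switches))) {
          g <- res$switches$gene_id[r]
          if (is.na(g) || !any(res$motif_hits$seq_id == g)) next
          hits <- res$motif_hits[res$motif_hits$seq_id == g &
                                   res$motif_hits$tf_name %in% de_tf_all, ,
                                 drop = FALSE]
          res$tss_tfbs[[g]] <- associate_tss_tfbs(
            c(control = res$switches$control_five_prime[r],
              treated = res$switches$treated_five_prime[r]),
            hits)
        }
      }
    }
  }
  if ("enrich" %in% stages && !is.null(data$reference_sets)) {
    universe <- data$genes$gene_id
    freq <- overlap_frequency_by_group(res$statuses, data$libraries)
    res$enrichment <- lapply(stats::setNames(nm = colnames(freq)), function(g) {
      sel_pairs <- rownames(freq)[freq[, g] >= 0.5]
      pidx <- match(sel_pairs, res$pairs$pair_id)
      query <- unique(c(res$pairs$gene_plus[pidx], res$pairs$gene_minus[pidx]))
      enrich(query, data$reference_sets, universe)
    })
  }
  res
}

# per-pair overlap frequency within each main-condition library group
overlap_frequency_by_group <- function(statuses, libraries) {
  main <- libraries[libraries$condition == "main", , drop = FALSE]
  groups <- unique(main$group)
  pair_ids <- sort(unique(statuses$pair_id))
  freq <- matrix(0, length(pair_ids), length(groups),
                 dimnames = list(pair_ids, groups))
  for (g in groups) {
    libs <- main$library_id[main$group == g]
    sub <- statuses[statuses$library_id %in% libs, , drop = FALSE]
    ov <- tapply(sub$state == "overlap", sub$pair_id, mean)
    freq[names(ov), g] <- ov
  }
  freq
}

#' Score pipeline outputs against planted ground truth
#'
#' @param sim Output of [simulate_dataset()] (carries `truth`).
#' @param res Output of [run_pipeline()] on the same dataset.
#' @return A list of recovery metrics: `overlap_call` (per-cell confusion
#'   matrix and accuracy), `clustering_ari` (Ward clustering of
#'   main-condition libraries at k = number of groups, scored with the
#'   adjusted Rand index), `always_overlap` (planted constitutive pairs vs
#'   recovered always-overlap subset), `ase` (per-SNP and per-gene accuracy,
#'   and exactness of the `mixed` set), `switch` (precision/recall and shift
#'   agreement), `motif` (TSS-specific activator recall).
#' @export
truth_compare <- function(sim, res) {
  truth <- sim$truth
  out <- list()

  key <- function(d) paste(d$pair_id, d$library_id, sep = "\r")
  tstate <- stats::setNames(truth$states$state, key(truth$states))
  called <- res$statuses
  intended <- tstate[key(called)]
  if (anyNA(intended)) stop("status table does not match truth entities")
  out$overlap_call <- list(
    confusion = table(intended = intended, called = called$state),
    accuracy = mean(intended == called$state))

  main_libs <- truth$main_libs
  m <- res$matrix[, colnames(res$matrix) %in% main_libs, drop = FALSE]
  k <- length(unique(truth$library_groups$group[
    truth$library_groups$library_id %in% main_libs]))
  cl <- cluster_bidirectional(m, k_cols = k)
  grp <- truth$library_groups$group[match(colnames(m),
                                          truth$library_groups$library_id)]
  out$clustering_ari <- mclust::adjustedRandIndex(cl$col_labels, grp)

  planted_const <- truth$pair_info$pair_id[truth$pair_info$constitutive]
  out$always_overlap <- list(
    planted = planted_const,
    recovered = res$summary$always_overlap_pairs,
    exact = setequal(planted_const, res$summary$always_overlap_pairs))

  ## ASE recovery
  st <- truth$snp_truth
  usable <- st[st$usable, , drop = FALSE]
  ckey <- paste(sim$allele_counts$gene_id, sim$allele_counts$library_id,
                sim$allele_counts$pos, sep = "\r")
  ukey <- paste(usable$gene_id, usable$library_id, usable$pos, sep = "\r")
  idx <- match(ukey, ckey)
  snp_pred <- classify_snp(sim$allele_counts$ref_count[idx],
                           sim$allele_counts$alt_count[idx])
  gt <- truth$ase_gene_truth
  analyzable <- gt$gene_id[is.na(gt$excluded_reason)]
  keep <- usable$gene_id %in% analyzable
  snp_acc <- mean(snp_pred[keep] == usable$planted_class[keep])
  calls <- res$ase$overall
  gidx <- match(intersect(analyzable, calls$gene_id), calls$gene_id)
  gene_pred <- stats::setNames(calls$class[gidx], calls$gene_id[gidx])
  gene_true <- stats::setNames(gt$class, gt$gene_id)[names(gene_pred)]
  mixed_planted <- gt$gene_id[gt$class == "mixed" & is.na(gt$excluded_reason)]
  mixed_called <- names(gene_pred)[gene_pred == "mixed"]
  out$ase <- list(
    snp_accuracy = snp_acc,
    gene_accuracy = mean(gene_pred == gene_true),
    mixed_exact = setequal(mixed_planted, mixed_called),
    excluded_respected = !any(calls$gene_id %in%
                                gt$gene_id[!is.na(gt$excluded_reason)]))

  ## switch recovery
  planted_pairs <- unique(truth$switch_truth$pair_id)
  detected_pairs <- unique(res$switches$pair_id)
  tp <- length(intersect(planted_pairs, detected_pairs))
  skey <- function(d) paste(d$pair_id, d$gene_id, sep = "\r")
  det <- res$switches[!is.na(res$switches$gene_id), , drop = FALSE]
  midx <- match(skey(truth$switch_truth), skey(det))
  shift_ok <- !is.na(midx) &
    det$upstream_shift_bp[midx] == truth$switch_truth$upstream_shift_bp &
    det$upstream_shift_bp[midx] > 0
  out$switch <- list(
    precision = if (length(detected_pairs)) tp / length(detected_pairs) else NA_real_,
    recall = if (length(planted_pairs)) tp / length(planted_pairs) else NA_real_,
    shift_recovery = mean(shift_ok),
    additional_ok = all(det$new_tss_is_additional[midx[!is.na(midx)]] ==
                          truth$switch_truth$new_tss_is_additional[!is.na(midx)]))

  ## motif association recovery: the treated TSS gains a TSS-specific
  ## association with the planted upregulated TF
  mt <- truth$motif_truth
  if (nrow(mt)) {
    got <- vapply(seq_len(nrow(mt)), function(r) {
      a <- res$tss_tfbs[[mt$gene_id[r]]]
      !is.null(a) && any(a$tss_specific$tf_name == mt$tf_activator[r] &
                           a$tss_specific$tss == "treated")
    }, TRUE)
    out$motif <- list(activator_specific_recall = mean(got))
  }
  out
}

#' Simulate, run all stages on disk, and write a manifest
#'
#' File-based end-to-end run: generates a dataset (unless the directory
#' already holds one), re-reads it through the format readers, executes
#' [run_pipeline()], writes per-stage TSV outputs and a JSON manifest tying
#' every output to input digests, parameters, row counts and wall time.
#' Re-running on unchanged inputs reproduces identical outputs.
#'
#' @param config A [sim_config()] used when the directory has no dataset.
#' @param dir Run directory.
#' @param stages Stages to run (see [run_pipeline()]).
#' @param filter_config A [tss_filter_config()].
#' @return Invisibly, a list with `manifest`, `results` and (when simulated
#'   here) the `sim` object.
#' @export
run_all <- function(config = sim_config(), dir = tempfile("tssoverlap_run_"),
                    stages = c("filter", "overlap", "matrix", "expression",
                               "ase", "switch", "enrich"),
                    filter_config = tss_filter_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- NULL
  if (!file.exists(file.path(dir, "genes.bed"))) {
    sim <- simulate_dataset(config)
    write_dataset(sim, dir)
  }
  input_files <- list.files(dir, full.names = TRUE)
  input_files <- input_files[!dir.exists(input_files) &
                               basename(input_files) != "manifest.json"]
  digests <- tools::md5sum(input_files)
  t0 <- proc.time()[["elapsed"]]
  data <- read_dataset(dir)
  res <- run_pipeline(data, filter_config = filter_config, stages = stages)
  elapsed <- proc.time()[["elapsed"]] - t0

  out_dir <- file.path(dir, "output")
  dir.create(out_dir, showWarnings = FALSE)
  outputs <- character()
  emit <- function(obj, name) {
    p <- file.path(out_dir, name)
    write_tsv(obj, p)
    outputs[[name]] <<- p
  }
  if (!is.null(res$tss_admitted)) emit(res$tss_admitted, "tss_admitted.tsv")
  if (!is.null(res$tss_admitted)) emit(attr(res$tss_admitted, "rejection_report"),
                                       "tss_rejections.tsv")
  if (!is.null(res$statuses)) emit(res$statuses, "pair_library_status.tsv")
  if (!is.null(res$summary)) emit(res$summary$per_pair, "pair_summary.tsv")
  if (!is.null(res$matrix)) {
    p <- file.path(out_dir, "overlap_matrix.tsv")
    write_overlap_matrix(res$matrix, p)
    outputs[["overlap_matrix.tsv"]] <- p
  }
  if (!is.null(res$clustering) && !is.null(res$clustering$col_labels)) {
    emit(data.frame(library_id = names(res$clustering$col_labels),
                    cluster = as.integer(res$clustering$col_labels)),
         "library_clusters.tsv")
  }
  if (!is.null(res$correlations)) emit(res$correlations, "pair_correlations.tsv")
  if (!is.null(res$ase)) emit(res$ase$overall, "ase_calls.tsv")
  if (!is.null(res$switches)) emit(res$switches, "switch_events.tsv")
  if (!is.null(res$motif_hits)) {
    p <- file.path(out_dir, "motif_hits.bed")
    write_motif_hits_bed(res$motif_hits, p)
    outputs[["motif_hits.bed"]] <- p
  }
  if (!is.null(res$enrichment)) {
    for (g in names(res$enrichment)) {
      emit(res$enrichment[[g]], paste0("enrichment_", g, ".tsv"))
    }
  }

  manifest <- list(
    tool = "tssoverlap",
    version = as.character(utils::packageVersion("tssoverlap")),
    run_dir = dir,
    stages_run = stages,
    stages_skipped = res$skipped,
    parameters = list(filter = unclass(filter_config),
                      config = if (is.null(sim)) NULL else unclass(sim$config)),
    inputs = data.frame(file = basename(input_files), md5 = unname(digests)),
    row_counts = list(
      tss_in = nrow(data$tss),
      tss_admitted = if (is.null(res$tss_admitted)) 0L else nrow(res$tss_admitted),
      pairs = if (is.null(res$pairs)) 0L else nrow(res$pairs),
      statuses = if (is.null(res$statuses)) 0L else nrow(res$statuses),
      switches = if (is.null(res$switches)) 0L else nrow(res$switches)),
    wall_time_s = round(elapsed, 2),
    outputs = as.list(outputs))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, results = res, sim = sim))
}
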