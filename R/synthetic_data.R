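# Synthetic-data generator with planted ground truth. It emulates the
# structure the pipeline assumes: head-to-head gene pairs with alternative
# TSSs (one of which creates a >= 1 bp 5' overlap), library groups with
# group-specific overlap propensities, log-scale expression with an
# overlap-stratum uplift and controllable within-pair correlation, binomial
# allele counts under planted ASE classes, condition-specific promoter
# switches, and promoter sequences with planted motif instances.

#' Simulation configuration
#'
#' Defaults describe the generator's standard scenario: 200 head-to-head
#' pairs observed across three balanced library groups of 10 libraries each,
#' with within-group overlap propensity 0.9 and 0.4 elsewhere, plus a
#' transfection-like condition arm (2 control and 4 treated libraries) with
#' planted promoter switches.
#'
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @param n_pairs Number of regular head-to-head pairs.
#' @param n_constitutive How many of the first pairs overlap in every library
#'   where both genes are expressed.
#' @param n_singletons Non-overlapping control genes (on their own
#'   chromosome).
#' @param groups Named integer vector: library group sizes.
#' @param propensity_within,propensity_between Per-library probability that a
#'   pair uses overlapping TSSs in a library of its own group vs any other
#'   group.
#' @param expr_prob Per-library probability that a gene is expressed.
#' @param p_second_tss Probability that an expressed gene uses a second
#'   (non-effective-end) TSS in a library.
#' @param mu_log2,sigma_log2 Location/scale of log2 expression.
#' @param uplift_log2 Added log2 expression for genes of a pair in libraries
#'   where the pair overlaps.
#' @param rho Within-pair expression correlation, induced by a shared latent
#'   log-scale factor.
#' @param ase_minor Named minor-allele fractions planted per ASE class.
#' @param ase_class_probs Mixture over planted gene-level classes
#'   (`mixed` genes get discordant per-library classes).
#' @param ase_depth_base,ase_depth_lambda SNP depth is
#'   `ase_depth_base + Poisson(ase_depth_lambda)`; the default centres depth
#'   near 120x so the 2% minor-fraction boundary is resolvable.
#' @param ase_n_snps Informative SNPs per gene (outside overlap regions).
#' @param ase_n_pairs How many pairs contribute genes to the ASE overlap set
#'   (default: the smaller of 50 and `n_pairs`).
#' @param n_switch_pairs Pairs planted to switch from non-overlapping in all
#'   control libraries to overlapping in all treated libraries.
#' @param n_control_libs,n_treated_libs Sizes of the condition arms.
#' @param motif_length Length of generated PFMs.
#' @param noise_tss_prob Per-gene-library probability of a sub-threshold
#'   noise TSS row (plus lower-probability distant and non-confident rows).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_pairs = 200L,
                       n_constitutive = 5L,
                       n_singletons = 60L,
                       groups = c(adult = 10L, fetal = 10L, cancer = 10L),
                       propensity_within = 0.9,
                       propensity_between = 0.4,
                       expr_prob = 0.9,
                       p_second_tss = 0.5,
                       mu_log2 = 5,
                       sigma_log2 = 1,
                       uplift_log2 = 0.5,
                       rho = 0.5,
                       ase_minor = c(monoallelic = 0.005, skewed = 0.10,
                                     biallelic = 0.45),
                       ase_class_probs = c(monoallelic = 0.07, skewed = 0.10,
                                           biallelic = 0.73, mixed = 0.10),
                       ase_depth_base = 100L,
                       ase_depth_lambda = 20,
                       ase_n_snps = 3L,
                       ase_n_pairs = NULL,
                       n_switch_pairs = 8L,
                       n_control_libs = 2L,
                       n_treated_libs = 4L,
                       motif_length = 12L,
                       noise_tss_prob = 0.10) {
  if (is.null(ase_n_pairs)) ase_n_pairs <- min(50L, n_pairs)
  stopifnot(n_pairs >= 1, n_constitutive <= n_pairs,
            all(groups >= 1), length(groups) >= 1,
            propensity_within >= 0, propensity_within <= 1,
            propensity_between >= 0, propensity_between <= 1,
            expr_prob > 0, expr_prob <= 1,
            rho >= 0, rho <= 1,
            abs(sum(ase_class_probs) - 1) < 1e-8,
            ase_n_pairs <= n_pairs, motif_length >= 4)
  structure(as.list(environment()), class = "sim_config")
}

# fixed per-pair geometry, anchored at x (all offsets in bp):
#   plus gene  span [x - 100, x + 2900), annotated 5' = x - 100
#     TSSs: OV = x - 100 (overlap-creating), IN = x + 1200, IN2 = x + 1260
#   minus gene span [x - 2999, x + 1), annotated 5' = x
#     TSSs: M1 = x, M2 = x - 40, MOV = x + 1800 (upstream, overlap-creating)
# A pair overlaps iff the plus gene uses OV and/or the minus gene uses MOV.
.pair_geometry <- list(spacing = 200000L, plus_off = c(span0 = -100L, span1 = 2900L),
                       minus_off = c(span0 = -2999L, span1 = 1L),
                       OV = -100L, IN = 1200L, IN2 = 1260L,
                       M1 = 0L, M2 = -40L, MOV = 1800L)

#' Simulate binomial allele counts
#'
#' @param n Number of SNP observations.
#' @param minor_fraction True minor-allele fraction (scalar or length-n).
#' @param depth_base,depth_lambda Depth is `depth_base + Poisson(depth_lambda)`.
#' @return A data.frame `ref_count`, `alt_count`, `depth`,
#'   `true_minor_fraction`.
#' @export
simulate_allele_counts <- function(n, minor_fraction, depth_base = 100L,
                                   depth_lambda = 20) {
  depth <- depth_base + stats::rpois(n, depth_lambda)
  minor <- stats::rbinom(n, depth, rep_len(minor_fraction, n))
  minor_is_ref <- stats::runif(n) < 0.5
  data.frame(ref_count = ifelse(minor_is_ref, minor, depth - minor),
             alt_count = ifelse(minor_is_ref, depth - minor, minor),
             depth = depth,
             true_minor_fraction = rep_len(minor_fraction, n))
}

#' Generate a complete synthetic dataset with planted ground truth
#'
#' @param config A [sim_config()].
#' @return A list with the input tables every pipeline stage consumes
#'   (`genes`, `tss`, `expression`, `allele_counts`, `nondiploid_mask`,
#'   `de_table`, `tf_ids`, `pfms`, `promoters`, `reference_sets`,
#'   `libraries`) and a `truth` list recording every planted property.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  geo <- .pair_geometry
  n_switch <- config$n_switch_pairs
  n_all <- config$n_pairs + n_switch
  group_names <- names(config$groups)

  ## ---- libraries -------------------------------------------------------
  main_libs <- unlist(lapply(group_names, function(g) {
    sprintf("%s%02d", g, seq_len(config$groups[[g]]))
  }))
  main_groups <- rep(group_names, times = config$groups)
  ctrl_libs <- sprintf("ctrl%02d", seq_len(config$n_control_libs))
  trt_libs <- sprintf("trt%02d", seq_len(config$n_treated_libs))
  libraries <- data.frame(
    library_id = c(main_libs, ctrl_libs, trt_libs),
    group = c(main_groups, rep("control", length(ctrl_libs)),
              rep("treated", length(trt_libs))),
    condition = c(rep("main", length(main_libs)),
                  rep("control", length(ctrl_libs)),
                  rep("treated", length(trt_libs))),
    stringsAsFactors = FALSE)

  ## ---- gene models -----------------------------------------------------
  i <- seq_len(n_all)
  x <- geo$spacing * i
  pair_info <- data.frame(
    pair_id = sprintf("G%03dP:G%03dM", i, i),
    gene_plus = sprintf("G%03dP", i),
    gene_minus = sprintf("G%03dM", i),
    anchor = x,
    group = c(group_names[(seq_len(config$n_pairs) - 1L) %% length(group_names) + 1L],
              rep("switch", n_switch)),
    constitutive = i <= config$n_constitutive,
    is_switch = i > config$n_pairs,
    switch_type = NA_character_,
    stringsAsFactors = FALSE)
  if (n_switch > 0) {
    pair_info$switch_type[pair_info$is_switch] <-
      rep(c("plus", "minus", "both"), length.out = n_switch)
  }
  genes_pairs <- rbind(
    data.frame(gene_id = pair_info$gene_plus, chrom = "chr1", strand = "+",
               span_start = x + unname(geo$plus_off["span0"]),
               span_end = x + unname(geo$plus_off["span1"]), stringsAsFactors = FALSE),
    data.frame(gene_id = pair_info$gene_minus, chrom = "chr1", strand = "-",
               span_start = x + unname(geo$minus_off["span0"]),
               span_end = x + unname(geo$minus_off["span1"]), stringsAsFactors = FALSE))
  j <- seq_len(config$n_singletons)
  sx <- geo$spacing * j
  s_strand <- ifelse(j %% 2 == 1, "+", "-")
  genes_single <- data.frame(gene_id = sprintf("S%03d", j), chrom = "chr2",
                             strand = s_strand, span_start = sx,
                             span_end = sx + 3000L, stringsAsFactors = FALSE)
  genes <- rbind(genes_pairs, genes_single)
  genes$annotated_five_prime <- ifelse(genes$strand == "+", genes$span_start,
                                       genes$span_end - 1L)
  genes$biotype <- "protein_coding"
  rownames(genes) <- NULL

  ## ---- per-cell (pair x library) overlap intentions --------------------
  cells <- expand.grid(pi = i, li = seq_len(nrow(libraries)),
                       KEEP.OUT.ATTRS = FALSE)
  cells$library_id <- libraries$library_id[cells$li]
  cells$lib_group <- libraries$group[cells$li]
  cells$condition <- libraries$condition[cells$li]
  is_main <- cells$condition == "main"
  is_switch_pair <- pair_info$is_switch[cells$pi]

  # the group propensity is the per-cell probability that the pair uses
  # overlapping TSSs in that library; using overlapping TSSs entails that
  # both genes are expressed, so expression noise applies only to
  # non-overlap cells
  raw_expr_p <- ifelse(is_main, stats::runif(nrow(cells)) < config$expr_prob, TRUE)
  raw_expr_m <- ifelse(is_main, stats::runif(nrow(cells)) < config$expr_prob, TRUE)

  prop <- ifelse(pair_info$group[cells$pi] == cells$lib_group,
                 config$propensity_within, config$propensity_between)
  want <- stats::runif(nrow(cells)) < prop
  # constitutive pairs overlap whenever co-expressed
  const_cell <- pair_info$constitutive[cells$pi]
  want[const_cell] <- (raw_expr_p & raw_expr_m)[const_cell]
  # condition arm: regular pairs respond identically in control and treated
  # libraries (one draw per pair), so only planted pairs can switch
  w_pair <- stats::runif(n_all) < config$propensity_between
  in_arm <- !is_main
  want[in_arm] <- w_pair[cells$pi[in_arm]]
  want[in_arm & const_cell] <- TRUE
  want[in_arm & is_switch_pair] <- cells$condition[in_arm & is_switch_pair] == "treated"

  cells$expr_p <- want | raw_expr_p
  cells$expr_m <- want | raw_expr_m
  cells$overlap <- want
  cells$state <- ifelse(cells$overlap, "overlap",
                 ifelse(cells$expr_p & cells$expr_m, "no_overlap",
                 ifelse(cells$expr_p | cells$expr_m, "single_expressed",
                        "none_expressed")))

  ## ---- TSS usage per cell ----------------------------------------------
  r2p <- stats::runif(nrow(cells)) < config$p_second_tss
  r2m <- stats::runif(nrow(cells)) < config$p_second_tss
  # regular rule: overlap cells drive the plus gene to its upstream TSS
  use <- data.frame(
    OV = cells$overlap,
    IN = cells$expr_p & ((cells$overlap & r2p) | !cells$overlap),
    IN2 = cells$expr_p & !cells$overlap & r2p,
    M1 = cells$expr_m,
    M2 = cells$expr_m & r2m,
    MOV = rep(FALSE, nrow(cells)))
  # planted switches: treated libraries use the type-specific TSS sets
  sw_trt <- is_switch_pair & cells$condition == "treated"
  type <- pair_info$switch_type[cells$pi]
  sel <- sw_trt & type == "plus"
  use$OV[sel] <- TRUE; use$IN[sel] <- TRUE; use$IN2[sel] <- FALSE
  use$M1[sel] <- TRUE; use$M2[sel] <- FALSE; use$MOV[sel] <- FALSE
  sel <- sw_trt & type == "minus"
  use$OV[sel] <- FALSE; use$IN[sel] <- TRUE; use$IN2[sel] <- FALSE
  use$M1[sel] <- FALSE; use$M2[sel] <- FALSE; use$MOV[sel] <- TRUE
  sel <- sw_trt & type == "both"
  use$OV[sel] <- TRUE; use$IN[sel] <- FALSE; use$IN2[sel] <- FALSE
  use$M1[sel] <- TRUE; use$M2[sel] <- FALSE; use$MOV[sel] <- TRUE

  anchor <- pair_info$anchor[cells$pi]
  tss_kind <- list(
    OV = list(gene = "gene_plus", strand = "+", pos = anchor + geo$OV),
    IN = list(gene = "gene_plus", strand = "+", pos = anchor + geo$IN),
    IN2 = list(gene = "gene_plus", strand = "+", pos = anchor + geo$IN2),
    M1 = list(gene = "gene_minus", strand = "-", pos = anchor + geo$M1),
    M2 = list(gene = "gene_minus", strand = "-", pos = anchor + geo$M2),
    MOV = list(gene = "gene_minus", strand = "-", pos = anchor + geo$MOV))
  tss_rows <- list()
  for (k in names(tss_kind)) {
    selk <- use[[k]]
    if (!any(selk)) next
    nk <- sum(selk)
    tss_rows[[k]] <- data.frame(
      library_id = cells$library_id[selk],
      gene_id = pair_info[[tss_kind[[k]]$gene]][cells$pi[selk]],
      chrom = "chr1", strand = tss_kind[[k]]$strand,
      position = tss_kind[[k]]$pos[selk],
      expression_ppm = round(5 + stats::rlnorm(nk, 2, 0.8), 3),
      confident = TRUE, stringsAsFactors = FALSE)
  }

  # noise rows exercising the admission filter: sub-threshold ppm, distant
  # positions and non-confident records, all upstream enough to corrupt
  # effective 5' ends if admitted by mistake
  noise_rows <- list()
  add_noise <- function(sel, gene_col, strand, pos, ppm, confident) {
    if (!any(sel)) return(NULL)
    data.frame(library_id = cells$library_id[sel],
               gene_id = pair_info[[gene_col]][cells$pi[sel]],
               chrom = "chr1", strand = strand, position = pos[sel],
               expression_ppm = ppm, confident = confident,
               stringsAsFactors = FALSE)
  }
  low_p <- cells$expr_p & stats::runif(nrow(cells)) < config$noise_tss_prob
  noise_rows$low_p <- add_noise(low_p, "gene_plus", "+", anchor - 150L,
                                round(stats::runif(sum(low_p), 0.1, 4.99), 3), TRUE)
  low_m <- cells$expr_m & stats::runif(nrow(cells)) < config$noise_tss_prob
  noise_rows$low_m <- add_noise(low_m, "gene_minus", "-", anchor + 2050L,
                                round(stats::runif(sum(low_m), 0.1, 4.99), 3), TRUE)
  far_p <- cells$expr_p & stats::runif(nrow(cells)) < config$noise_tss_prob / 2
  noise_rows$far_p <- add_noise(far_p, "gene_plus", "+", anchor - 6101L,
                                round(5 + stats::rlnorm(sum(far_p), 2, 0.8), 3), TRUE)
  nc_m <- cells$expr_m & stats::runif(nrow(cells)) < config$noise_tss_prob / 2
  noise_rows$nc_m <- add_noise(nc_m, "gene_minus", "-", anchor + 900L,
                               round(5 + stats::rlnorm(sum(nc_m), 2, 0.8), 3), FALSE)

  ## singleton TSSs
  sgrid <- expand.grid(si = j, li = seq_len(nrow(libraries)),
                       KEEP.OUT.ATTRS = FALSE)
  s_expr <- stats::runif(nrow(sgrid)) < config$expr_prob
  s_second <- s_expr & stats::runif(nrow(sgrid)) < 0.3
  s_ann <- genes_single$span_start + ifelse(genes_single$strand == "+", 0L, 2999L)
  s_int <- s_ann + ifelse(genes_single$strand == "+", 300L, -300L)
  mk_srows <- function(sel, pos) {
    data.frame(library_id = libraries$library_id[sgrid$li[sel]],
               gene_id = genes_single$gene_id[sgrid$si[sel]],
               chrom = "chr2", strand = genes_single$strand[sgrid$si[sel]],
               position = pos[sgrid$si[sel]],
               expression_ppm = round(5 + stats::rlnorm(sum(sel), 2, 0.8), 3),
               confident = TRUE, stringsAsFactors = FALSE)
  }
  tss <- rbind(do.call(rbind, tss_rows), do.call(rbind, noise_rows),
               mk_srows(s_expr, s_ann), mk_srows(s_second, s_int))
  tss <- tss[order(tss$library_id, tss$gene_id, tss$position), , drop = FALSE]
  rownames(tss) <- NULL

  ## ---- expression ------------------------------------------------------
  z <- stats::rnorm(nrow(cells))
  eps_p <- stats::rnorm(nrow(cells))
  eps_m <- stats::rnorm(nrow(cells))
  mix <- function(eps) sqrt(config$rho) * z + sqrt(1 - config$rho) * eps
  lg_p <- config$mu_log2 + config$uplift_log2 * cells$overlap +
    config$sigma_log2 * mix(eps_p)
  lg_m <- config$mu_log2 + config$uplift_log2 * cells$overlap +
    config$sigma_log2 * mix(eps_m)
  expr_pairs <- rbind(
    data.frame(gene_id = pair_info$gene_plus[cells$pi],
               library_id = cells$library_id,
               expression = round(ifelse(cells$expr_p, 2^lg_p, 0), 3),
               stringsAsFactors = FALSE),
    data.frame(gene_id = pair_info$gene_minus[cells$pi],
               library_id = cells$library_id,
               expression = round(ifelse(cells$expr_m, 2^lg_m, 0), 3),
               stringsAsFactors = FALSE))
  # singletons: last two are low-expression (below the 5-FPKM bar), the two
  # before those sit in the nondiploid mask
  low_expr_genes <- utils::tail(genes_single$gene_id, 2)
  nondiploid_genes <- utils::head(utils::tail(genes_single$gene_id, 4), 2)
  s_lg <- config$mu_log2 + config$sigma_log2 * stats::rnorm(nrow(sgrid))
  s_val <- round(ifelse(s_expr, 2^s_lg, 0), 3)
  s_gene <- genes_single$gene_id[sgrid$si]
  s_val[s_gene %in% low_expr_genes] <- 2
  expression <- rbind(expr_pairs,
                      data.frame(gene_id = s_gene,
                                 library_id = libraries$library_id[sgrid$li],
                                 expression = s_val, stringsAsFactors = FALSE))
  rownames(expression) <- NULL

  nondiploid_mask <- region_mask(
    "chr2",
    genes_single$span_start[genes_single$gene_id %in% nondiploid_genes] - 10L,
    genes_single$span_end[genes_single$gene_id %in% nondiploid_genes] + 10L,
    label = "nondiploid")

  ## ---- allele counts with planted ASE classes --------------------------
  ase_pair_genes <- c(pair_info$gene_plus[seq_len(config$ase_n_pairs)],
                      pair_info$gene_minus[seq_len(config$ase_n_pairs)])
  ase_genes <- c(ase_pair_genes, genes_single$gene_id)
  ase_libs <- libraries$library_id[libraries$group == group_names[length(group_names)]]
  gene_class <- sample(names(config$ase_class_probs), length(ase_genes),
                       replace = TRUE, prob = config$ase_class_probs)
  names(gene_class) <- ase_genes

  snp_pos_of <- function(g) {
    gi <- match(g, genes$gene_id)
    a5 <- genes$annotated_five_prime[gi]
    if (startsWith(g, "S")) {
      genes$span_start[gi] + c(500L, 1000L, 1500L)[seq_len(config$ase_n_snps)]
    } else if (genes$strand[gi] == "+") {
      a5 + c(2100L, 2400L, 2700L)[seq_len(config$ase_n_snps)]
    } else {
      a5 - c(2100L, 2400L, 2700L)[seq_len(config$ase_n_snps)]
    }
  }
  half <- ceiling(length(ase_libs) / 2)
  snp_grid <- expand.grid(g = ase_genes, lib = ase_libs, s = seq_len(config$ase_n_snps),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lib_rank <- match(snp_grid$lib, ase_libs)
  cls <- gene_class[snp_grid$g]
  mixed <- cls == "mixed"
  cls[mixed] <- ifelse(lib_rank[mixed] <= half, "monoallelic", "biallelic")
  ac <- simulate_allele_counts(nrow(snp_grid), config$ase_minor[cls],
                               config$ase_depth_base, config$ase_depth_lambda)
  pos_lookup <- do.call(rbind, lapply(ase_genes, snp_pos_of))
  snp_main <- data.frame(
    chrom = ifelse(startsWith(snp_grid$g, "S"), "chr2", "chr1"),
    pos = pos_lookup[cbind(match(snp_grid$g, ase_genes), snp_grid$s)],
    gene_id = snp_grid$g, library_id = snp_grid$lib,
    ref_count = ac$ref_count, alt_count = ac$alt_count,
    stringsAsFactors = FALSE)
  truth_snp_main <- cbind(snp_main[c("chrom", "pos", "gene_id", "library_id")],
                          planted_class = cls, usable = TRUE,
                          stringsAsFactors = FALSE)

  # SNPs inside the pair overlap region: superimposed transcription mimics
  # biallelic signal; the classifier must exclude them positionally
  ov_grid <- expand.grid(g = ase_pair_genes, lib = ase_libs,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ov_anchor <- pair_info$anchor[match(sub("[PM]$", "", sub("^G", "", ov_grid$g)),
                                      sprintf("%03d", i))]
  ov_pos <- ov_anchor - ifelse(endsWith(ov_grid$g, "P"), 50L, 60L)
  ac_ov <- simulate_allele_counts(nrow(ov_grid), 0.45,
                                  config$ase_depth_base, config$ase_depth_lambda)
  snp_ov <- data.frame(chrom = "chr1", pos = ov_pos, gene_id = ov_grid$g,
                       library_id = ov_grid$lib, ref_count = ac_ov$ref_count,
                       alt_count = ac_ov$alt_count, stringsAsFactors = FALSE)
  truth_snp_ov <- cbind(snp_ov[c("chrom", "pos", "gene_id", "library_id")],
                        planted_class = "overlap_artifact", usable = FALSE,
                        stringsAsFactors = FALSE)

  # low-depth SNPs (below minDepth), one per gene in the first ASE library
  ld_pos <- vapply(ase_genes, function(g) {
    gi <- match(g, genes$gene_id)
    if (startsWith(g, "S")) genes$span_start[gi] + 1700L
    else if (genes$strand[gi] == "+") genes$annotated_five_prime[gi] + 2750L
    else genes$annotated_five_prime[gi] - 2750L
  }, 1L)
  ld_minor <- stats::rbinom(length(ase_genes), 5L,
                            config$ase_minor[ifelse(gene_class == "mixed",
                                                    "monoallelic", gene_class)])
  snp_ld <- data.frame(chrom = ifelse(startsWith(ase_genes, "S"), "chr2", "chr1"),
                       pos = ld_pos, gene_id = ase_genes,
                       library_id = ase_libs[1],
                       ref_count = 5L - ld_minor, alt_count = ld_minor,
                       stringsAsFactors = FALSE)
  truth_snp_ld <- cbind(snp_ld[c("chrom", "pos", "gene_id", "library_id")],
                        planted_class = "low_depth", usable = FALSE,
                        stringsAsFactors = FALSE)

  allele_counts <- rbind(snp_main, snp_ov, snp_ld)
  rownames(allele_counts) <- NULL
  snp_truth <- rbind(truth_snp_main, truth_snp_ov, truth_snp_ld)
  rownames(snp_truth) <- NULL

  ase_gene_truth <- data.frame(
    gene_id = ase_genes, class = unname(gene_class),
    excluded_reason = ifelse(ase_genes %in% nondiploid_genes, "nondiploid",
                      ifelse(ase_genes %in% low_expr_genes, "low_expression",
                             NA_character_)),
    in_overlap_set = ase_genes %in% ase_pair_genes,
    stringsAsFactors = FALSE)

  ## ---- switch scenario: DE table, TFs, PFMs, promoters ------------------
  tf_ids <- sprintf("TF%02d", 1:30)
  tf_activator <- "TF01"
  tf_repressor <- "TF02"
  sw <- pair_info[pair_info$is_switch, , drop = FALSE]
  switch_truth <- if (nrow(sw)) do.call(rbind, lapply(seq_len(nrow(sw)), function(r) {
    xs <- sw$anchor[r]
    rows <- list()
    if (sw$switch_type[r] %in% c("plus", "both")) {
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = sw$pair_id[r], gene_id = sw$gene_plus[r], strand = "+",
        control_five_prime = xs + geo$IN, treated_five_prime = xs + geo$OV,
        upstream_shift_bp = geo$IN - geo$OV,
        new_tss_is_additional = sw$switch_type[r] == "plus",
        stringsAsFactors = FALSE)
    }
    if (sw$switch_type[r] %in% c("minus", "both")) {
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = sw$pair_id[r], gene_id = sw$gene_minus[r], strand = "-",
        control_five_prime = xs + geo$M1, treated_five_prime = xs + geo$MOV,
        upstream_shift_bp = geo$MOV - geo$M1,
        new_tss_is_additional = sw$switch_type[r] == "both",
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })) else data.frame()

  de_decoys <- setdiff(c(pair_info$gene_plus[1:40], genes_single$gene_id),
                       if (nrow(sw)) switch_truth$gene_id else character())
  de_table <- rbind(
    if (nrow(sw)) data.frame(gene_id = switch_truth$gene_id,
                             log2fc = round(2 + stats::runif(nrow(switch_truth)), 3),
                             fdr = 1e-4, stringsAsFactors = FALSE),
    data.frame(gene_id = tf_activator, log2fc = 2.5, fdr = 1e-4),
    data.frame(gene_id = tf_repressor, log2fc = -2.5, fdr = 1e-4),
    data.frame(gene_id = sprintf("TF%02d", 3:10),
               log2fc = round(c(rep(2, 4), rep(-2, 4)) +
                                stats::runif(8, 0, 0.5) * c(1, 1, 1, 1, -1, -1, -1, -1), 3),
               fdr = 0.01),
    data.frame(gene_id = sprintf("TF%02d", 11:30),
               log2fc = round(stats::rnorm(20, 0, 0.3), 3),
               fdr = round(stats::runif(20, 0.2, 1), 3)),
    data.frame(gene_id = de_decoys,
               log2fc = round(stats::rnorm(length(de_decoys), 0, 0.3), 3),
               fdr = round(stats::runif(length(de_decoys), 0.2, 1), 3)))
  de_table <- de_table[!duplicated(de_table$gene_id), , drop = FALSE]
  rownames(de_table) <- NULL

  pfm_tfs <- sprintf("TF%02d", 1:5)
  pfms <- lapply(pfm_tfs, function(tf) {
    consensus <- sample(BASES, config$motif_length, replace = TRUE)
    counts <- matrix(5, 4, config$motif_length, dimnames = list(BASES, NULL))
    counts[cbind(match(consensus, BASES), seq_len(config$motif_length))] <- 85
    list(motif_id = paste0("MA_", tf), tf_name = tf, counts = counts)
  })
  names(pfms) <- vapply(pfms, `[[`, "", "motif_id")
  consensus_of <- function(p) paste(BASES[apply(p$counts, 2, which.max)], collapse = "")

  promoters <- character()
  motif_truth <- list()
  if (nrow(sw)) {
    for (r in seq_len(nrow(switch_truth))) {
      g <- switch_truth$gene_id[r]
      old_tss <- switch_truth$control_five_prime[r]
      new_tss <- switch_truth$treated_five_prime[r]
      lo <- min(old_tss, new_tss) - 600L
      hi <- max(old_tss, new_tss) + 600L
      s <- sample(BASES, hi - lo + 1L, replace = TRUE)
      plant <- function(s, mid_genomic, word) {
        start_local <- (mid_genomic - lo) - floor(nchar(word) / 2) + 1L
        s[start_local:(start_local + nchar(word) - 1L)] <- strsplit(word, "")[[1]]
        s
      }
      act_mid <- new_tss + if (new_tss < old_tss) 300L else -300L
      rep_mid <- old_tss + if (new_tss < old_tss) 300L else -300L
      s <- plant(s, act_mid, consensus_of(pfms[[paste0("MA_", tf_activator)]]))
      s <- plant(s, rep_mid, consensus_of(pfms[[paste0("MA_", tf_repressor)]]))
      promoters[paste0(g, "|chr1|", lo)] <- paste(s, collapse = "")
      motif_truth[[r]] <- data.frame(
        gene_id = g, tf_activator = tf_activator, tf_repressor = tf_repressor,
        control_tss = old_tss, treated_tss = new_tss,
        stringsAsFactors = FALSE)
    }
  }
  motif_truth <- if (length(motif_truth)) do.call(rbind, motif_truth) else data.frame()

  ## ---- enrichment reference sets ---------------------------------------
  universe <- genes$gene_id
  last_group <- group_names[length(group_names)]
  block_genes <- with(pair_info[pair_info$group == last_group, ],
                      c(gene_plus, gene_minus))
  reference_sets <- c(
    stats::setNames(list(sample(block_genes, min(40, length(block_genes)))),
                    paste0("SET_", toupper(last_group))),
    lapply(stats::setNames(1:5, sprintf("SET_RANDOM%d", 1:5)),
           function(k) sample(universe, min(40, length(universe)))))

  states <- data.frame(pair_id = pair_info$pair_id[cells$pi],
                       library_id = cells$library_id,
                       state = cells$state, stringsAsFactors = FALSE)

  list(
    config = config,
    genes = genes,
    tss = tss,
    expression = expression,
    allele_counts = allele_counts,
    nondiploid_mask = nondiploid_mask,
    de_table = de_table,
    tf_ids = tf_ids,
    pfms = pfms,
    promoters = promoters,
    reference_sets = reference_sets,
    libraries = libraries,
    truth = list(
      pair_info = pair_info,
      states = states,
      library_groups = libraries,
      snp_truth = snp_truth,
      ase_gene_truth = ase_gene_truth,
      switch_truth = switch_truth,
      motif_truth = motif_truth,
      tf_de_truth = list(up = c(switch_truth$gene_id, tf_activator,
                                sprintf("TF%02d", 3:6)),
                         down = c(tf_repressor, sprintf("TF%02d", 7:10))),
      enriched_set = paste0("SET_", toupper(last_group)),
      enriched_group = last_group,
      control_libs = ctrl_libs,
      treated_libs = trt_libs,
      main_libs = main_libs))
}

#' Write a simulated dataset to a run directory
#'
#' Emits every table in the format the corresponding reader consumes:
#' gene models as BED6, TSS/expression/allele-count/DE tables as TSV,
#' the nondiploid mask as BED, TF ids as plain text, PFMs in JASPAR bracket
#' format, promoters as FASTA and reference sets as GMT.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genes = file.path(dir, "genes.bed"),
    tss = file.path(dir, "tss.tsv"),
    expression = file.path(dir, "expression.tsv"),
    allele_counts = file.path(dir, "allele_counts.tsv"),
    nondiploid = file.path(dir, "nondiploid.bed"),
    de_table = file.path(dir, "de_table.tsv"),
    tf_list = file.path(dir, "tf_list.txt"),
    pfms = file.path(dir, "motifs.pfm"),
    promoters = file.path(dir, "promoters.fa"),
    gmt = file.path(dir, "reference_sets.gmt"),
    libraries = file.path(dir, "libraries.tsv"))
  write_gene_models(sim$genes, paths["genes"])
  write_tss_table(sim$tss, paths["tss"])
  write_tsv(sim$expression, paths["expression"])
  write_tsv(sim$allele_counts, paths["allele_counts"])
  utils::write.table(sim$nondiploid_mask[, c("chrom", "start", "end", "label")],
                     paths["nondiploid"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_tsv(sim$de_table, paths["de_table"])
  writeLines(sim$tf_ids, paths["tf_list"])
  write_pfm(sim$pfms, paths["pfms"])
  if (length(sim$promoters)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$promoters),
                                paths["promoters"])
  } else {
    file.create(paths["promoters"])
  }
  gmt_lines <- vapply(names(sim$reference_sets), function(nm) {
    paste(c(nm, "synthetic", sim$reference_sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(gmt_lines, paths["gmt"])
  write_tsv(sim$libraries, paths["libraries"])
  invisible(paths)
}
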