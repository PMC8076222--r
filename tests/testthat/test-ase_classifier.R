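test_that("SNP classes follow the minor-fraction boundaries literally", {
  expect_equal(classify_snp(100, 0), "monoallelic")
  expect_equal(classify_snp(99, 1), "monoallelic")  # f = 0.01
  expect_equal(classify_snp(98, 2), "skewed")       # f = 0.02, "at least 2%"
  expect_equal(classify_snp(2, 98), "skewed")       # symmetric in alleles
  expect_equal(classify_snp(81, 19), "skewed")      # f = 0.19
  expect_equal(classify_snp(80, 20), "biallelic")   # f = 0.20, "at least 20%"
  expect_equal(classify_snp(50, 50), "biallelic")
  expect_error(classify_snp(0, 0), "zero depth")
})

test_that("classification is exhaustive and unambiguous up to depth 60", {
  grid <- expand.grid(ref = 0:60, alt = 0:60)
  grid <- grid[grid$ref + grid$alt >= 1 & grid$ref + grid$alt <= 60, ]
  got <- classify_snp(grid$ref, grid$alt)
  expect_equal(got, oracle_snp_class(grid$ref, grid$alt))
  expect_true(all(got %in% c("monoallelic", "skewed", "biallelic")))
})

test_that("SNP filtering: depth boundary at 10 and overlap-region exclusion", {
  counts <- data.frame(
    chrom = "chr1", pos = c(100, 200, 300, 150),
    gene_id = c("GA", "GA", "GA", "GB"), library_id = "L1",
    ref_count = c(5, 6, 80, 40), alt_count = c(4, 4, 20, 40),
    stringsAsFactors = FALSE)
  mask <- region_mask("chr1", 250, 400, label = "overlap")
  mask$gene_id <- "GA"
  out <- usable_snps(counts, mask, min_depth = 10)
  # pos 100: depth 9 dropped; pos 200: depth 10 kept; pos 300: in GA's
  # overlap region dropped despite depth; GB's SNP at 150 unaffected by mask
  expect_setequal(out$pos, c(200, 150))
  rep <- attr(out, "filter_report")
  expect_equal(rep$n[rep$rule == "below_min_depth"], 1)
  expect_equal(rep$n[rep$rule == "inside_overlap_region"], 1)
})

test_that("SNP filtering equals brute-force predicate recheck on random fixtures", {
  withr::local_seed(88)
  n <- 300
  counts <- data.frame(
    chrom = "chr1", pos = sample(1:1000, n, TRUE),
    gene_id = sample(c("GA", "GB"), n, TRUE), library_id = "L1",
    ref_count = sample(0:30, n, TRUE), alt_count = sample(0:30, n, TRUE),
    stringsAsFactors = FALSE)
  mask <- region_mask("chr1", c(100, 500), c(200, 650), label = "overlap")
  mask$gene_id <- c("GA", "GB")
  out <- usable_snps(counts, mask, min_depth = 10)
  keep <- (counts$ref_count + counts$alt_count >= 10) &
    !((counts$gene_id == "GA" & counts$pos >= 100 & counts$pos < 200) |
        (counts$gene_id == "GB" & counts$pos >= 500 & counts$pos < 650))
  expect_equal(out$pos, counts$pos[keep])
  expect_equal(out$ref_count, counts$ref_count[keep])
})

test_that("per-library consensus and cross-library aggregation rules", {
  expect_equal(classify_gene_library(c("monoallelic", "monoallelic")), "monoallelic")
  expect_equal(classify_gene_library(c("monoallelic", "biallelic")), "noninformative")
  expect_equal(classify_gene_library("skewed"), "skewed")
  expect_equal(aggregate_gene(c("biallelic", "biallelic")), "biallelic")
  expect_equal(aggregate_gene(c("biallelic", "monoallelic")), "mixed")
  expect_equal(aggregate_gene(c("noninformative")), "noninformative")
  expect_equal(aggregate_gene(c("skewed", "noninformative", "skewed")), "skewed")
})

test_that("gene exclusion: FPKM floor at exactly 5 and nondiploid spans", {
  genes <- rbind(make_genes("GA", span_start = 1000, span_end = 2000),
                 make_genes("GB", span_start = 5000, span_end = 6000),
                 make_genes("GC", span_start = 9000, span_end = 9500))
  expr <- data.frame(gene_id = rep(c("GA", "GB", "GC"), each = 2),
                     library_id = rep(c("L1", "L2"), 3),
                     expression = c(4.9, 4.9, 5.0, 1.0, 100, 100))
  mask <- region_mask("chrT", 9400, 9600, label = "nondiploid")
  res <- exclude_genes(genes, mask, expr, min_fpkm = 5)
  expect_equal(sort(res$analyzable), "GB") # GA low, GC masked
  expect_equal(res$report$status[res$report$gene_id == "GA"], "low_expression")
  expect_equal(res$report$status[res$report$gene_id == "GC"], "nondiploid")
  # report partitions the gene list
  expect_setequal(res$report$gene_id, genes$gene_id)
})

test_that("planted-class recovery on binomial counts and mixed aggregation", {
  withr::local_seed(7)
  per_class <- 500
  fractions <- c(monoallelic = 0.005, skewed = 0.10, biallelic = 0.45)
  acc <- vapply(names(fractions), function(k) {
    ac <- simulate_allele_counts(per_class, fractions[[k]])
    mean(classify_snp(ac$ref_count, ac$alt_count) == k)
  }, 1)
  expect_gte(mean(acc), 0.95)
  # a gene with discordant per-library classes aggregates to mixed
  libs_cls <- vapply(1:6, function(l) {
    f <- if (l <= 3) 0.005 else 0.45
    ac <- simulate_allele_counts(3, f)
    classify_gene_library(classify_snp(ac$ref_count, ac$alt_count))
  }, "")
  expect_equal(aggregate_gene(libs_cls), "mixed")
})

test_that("classify_ase pipeline partitions and respects exclusions", {
  sim <- simulate_dataset(sim_config(seed = 9, n_pairs = 30, n_singletons = 20,
                                     ase_n_pairs = 10, n_switch_pairs = 0))
  adm <- filter_tss(sim$tss, sim$genes)
  pairs <- candidate_pairs(sim$genes)
  st <- call_overlaps(pairs, sim$genes, adm)
  mask <- overlap_region_mask(st, pairs)
  excl <- exclude_genes(sim$genes, sim$nondiploid_mask, sim$expression)
  calls <- classify_ase(sim$allele_counts, mask, genes_analyzable = excl$analyzable)
  gt <- sim$truth$ase_gene_truth
  expect_false(any(calls$overall$gene_id %in%
                     gt$gene_id[!is.na(gt$excluded_reason)]))
  expect_true(all(calls$overall$n_snps_used >= 1))
  pred <- calls$overall$class
  names(pred) <- calls$overall$gene_id
  truth <- stats::setNames(gt$class, gt$gene_id)[names(pred)]
  expect_gte(mean(pred == truth), 0.95)
})

test_that("MAE composition comparison reproduces planted ratios", {
  mk <- function(n_mono, n_bi) {
    data.frame(gene_id = sprintf("g%04d", seq_len(n_mono + n_bi)),
               class = c(rep("monoallelic", n_mono), rep("biallelic", n_bi)),
               stringsAsFactors = FALSE)
  }
  res <- mae_summary(mk(10, 111), mk(108, 1111))
  expect_equal(unname(res$ratio), c(10 / 111, 108 / 1111), tolerance = 1e-12)
  expect_gt(res$fisher_p, 0.05) # compositions close to 1:10 in both sets
  same <- mae_summary(mk(5, 50), mk(5, 50))
  expect_equal(same$fisher_p, 1)
  extreme <- mae_summary(mk(50, 0), mk(0, 50))
  expect_true(is.na(extreme$ratio[1]) || is.infinite(extreme$ratio[1]))
  expect_lt(extreme$fisher_p, 1e-10)
})
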