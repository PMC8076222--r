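make_expr <- function(gene_id, library_id, expression) {
  data.frame(gene_id = gene_id, library_id = library_id,
             expression = expression, stringsAsFactors = FALSE)
}

test_that("contrast selection enforces both stratum minima inclusively", {
  libs_ov <- paste0("O", 1:10)
  libs_no <- paste0("N", 1:10)
  st <- rbind(
    data.frame(pair_id = "P1", library_id = libs_ov, state = "overlap"),
    data.frame(pair_id = "P1", library_id = libs_no, state = "no_overlap"),
    data.frame(pair_id = "P2", library_id = libs_ov[1:9], state = "overlap"),
    data.frame(pair_id = "P2", library_id = paste0("N", 1:50), state = "no_overlap"))
  sel <- select_contrast_pairs(st, min_each = 10)
  expect_equal(sel$pair_id, "P1") # 10/10 in, 9/50 out
  expect_setequal(sel$libs_overlap[[1]], libs_ov)
  expect_setequal(sel$libs_no_overlap[[1]], libs_no)
})

test_that("contrast selection equals a brute-force recount on simulated data", {
  sim <- simulate_dataset(sim_config(seed = 13, n_pairs = 60, n_singletons = 4,
                                     n_switch_pairs = 0))
  adm <- filter_tss(sim$tss, sim$genes)
  pairs <- candidate_pairs(sim$genes)
  st <- call_overlaps(pairs, sim$genes, adm)
  sel <- select_contrast_pairs(st, min_each = 10)
  expected <- vapply(unique(st$pair_id), function(p) {
    sum(st$state == "overlap" & st$pair_id == p) >= 10 &&
      sum(st$state == "no_overlap" & st$pair_id == p) >= 10
  }, TRUE)
  expect_setequal(sel$pair_id, names(expected)[expected])
})

test_that("perfect linear relations give r = +/-1 with the right class", {
  libs <- paste0("L", 1:10)
  x <- 2^(1:10)
  e <- rbind(make_expr("A", libs, x), make_expr("B", libs, 2 * x))
  v <- correlate_pair("A", "B", e, libs, log_transform = FALSE)
  expect_equal(v$r, 1, tolerance = 1e-12)
  expect_equal(v$class, "positive")
  e2 <- rbind(make_expr("A", libs, x), make_expr("B", libs, max(x) - x + 1))
  v2 <- correlate_pair("A", "B", e2, libs, log_transform = FALSE)
  expect_equal(v2$r, -1, tolerance = 1e-12)
  expect_equal(v2$class, "negative")
  # zero variance -> ns with undefined r
  e3 <- rbind(make_expr("A", libs, 5), make_expr("B", libs, x))
  v3 <- correlate_pair("A", "B", e3, libs, log_transform = FALSE)
  expect_equal(v3$class, "ns")
  expect_true(is.na(v3$r))
})

test_that("Pearson r matches the definitional oracle for n <= 20", {
  withr::local_seed(5)
  for (n in c(3, 5, 12, 20)) {
    libs <- paste0("L", seq_len(n))
    x <- stats::rlnorm(n, 3, 1)
    y <- stats::rlnorm(n, 3, 1)
    e <- rbind(make_expr("A", libs, x), make_expr("B", libs, y))
    v <- correlate_pair("A", "B", e, libs, log_transform = FALSE)
    expect_equal(v$r, oracle_pearson(x, y), tolerance = 1e-10)
  }
})

test_that("planted correlation sign is recovered reliably", {
  withr::local_seed(2024)
  n <- 15
  hits <- 0
  reps <- 200
  for (k in seq_len(reps)) {
    z <- stats::rnorm(n)
    x <- sqrt(0.8) * z + sqrt(0.2) * stats::rnorm(n)
    y <- sqrt(0.8) * z + sqrt(0.2) * stats::rnorm(n)
    libs <- paste0("L", 1:n)
    e <- rbind(make_expr("A", libs, 2^x), make_expr("B", libs, 2^y))
    v <- correlate_pair("A", "B", e, libs, log_transform = TRUE)
    if (!is.na(v$r) && v$r > 0) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.95)
})

test_that("paired t-test degenerate and shift alternatives behave classically", {
  contrasts <- data.frame(pair_id = paste0("P", 1:10))
  contrasts$libs_overlap <- I(replicate(10, "LO", simplify = FALSE))
  contrasts$libs_no_overlap <- I(replicate(10, "LN", simplify = FALSE))
  pairs <- data.frame(pair_id = paste0("P", 1:10),
                      gene_plus = paste0("G", 1:10, "P"),
                      gene_minus = paste0("G", 1:10, "M"),
                      chrom = "chrT", stringsAsFactors = FALSE)
  genes <- c(pairs$gene_plus, pairs$gene_minus)
  vals <- seq(2, 40, by = 2)
  e_same <- rbind(make_expr(genes, "LO", vals), make_expr(genes, "LN", vals))
  r <- paired_overlap_test(contrasts, pairs, e_same, log_transform = FALSE)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  # constant uplift of +3 in the overlap stratum
  e_up <- rbind(make_expr(genes, "LO", vals + 3), make_expr(genes, "LN", vals))
  r2 <- paired_overlap_test(contrasts, pairs, e_up, log_transform = FALSE)
  expect_gt(r2$t, 0)
  expect_lt(r2$p, 1e-10)
  expect_error(paired_overlap_test(contrasts[0, ], pairs, e_same), "fewer than 2")
})

test_that("Mann-Whitney U equals exhaustive pair counting for n <= 20", {
  withr::local_seed(44)
  for (rep_i in 1:10) {
    nx <- sample(3:20, 1); ny <- sample(3:20, 1)
    x <- sample(1:15, nx, TRUE); y <- sample(1:15, ny, TRUE) # with ties
    ug <- data.frame(gene_id = c(paste0("a", 1:nx), paste0("b", 1:ny)),
                     library_id = "L1", n_tss = c(rep(1, nx), rep(2, ny)))
    e <- make_expr(ug$gene_id, "L1", c(x, y))
    res <- expression_by_tss_count(ug, e, log_transform = FALSE)
    expect_equal(unname(res$tests$U[1]), oracle_mwu(x, y))
  }
})

test_that("TSS-count grouping: identical groups give p near 1, shifted groups tiny p", {
  withr::local_seed(10)
  vals <- stats::rnorm(200, 10, 1)
  ug <- data.frame(gene_id = c(paste0("a", 1:200), paste0("b", 1:200)),
                   library_id = "L1", n_tss = rep(c(1, 2), each = 200))
  e_same <- make_expr(ug$gene_id, "L1", c(vals, vals))
  r <- expression_by_tss_count(ug, e_same, log_transform = FALSE)
  expect_gt(r$tests$p[1], 0.9)
  e_shift <- make_expr(ug$gene_id, "L1", c(vals, vals + 2)) # 2 sigma shift
  r2 <- expression_by_tss_count(ug, e_shift, log_transform = FALSE)
  expect_lt(r2$tests$p[1], 1e-6)
})

test_that("six-category observations partition and planted multi-TSS uplift is detected", {
  sim <- simulate_dataset(sim_config(seed = 55))
  adm <- filter_tss(sim$tss, sim$genes)
  pairs <- candidate_pairs(sim$genes)
  st <- call_overlaps(pairs, sim$genes, adm)
  obs <- six_category_observations(st, pairs)
  # partition: one observation per expressed gene per library
  n_expressed <- sum(st$n_tss_plus > 0) + sum(st$n_tss_minus > 0)
  expect_equal(nrow(obs), n_expressed)
  res <- expression_by_category(obs, sim$expression)
  expect_equal(sum(res$category_summary$n), nrow(res$observations))
  cs <- res$category_summary
  mean_of <- function(k) cs$mean[cs$category == k]
  # overlap uplift planted by the generator: overlap arms exceed no_overlap arms
  expect_gt(mean_of("overlap_single"), mean_of("no_overlap_single"))
  expect_gt(mean_of("overlap_multi"), mean_of("no_overlap_multi"))
})
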