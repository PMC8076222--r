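test_that("effective 5' end is strand-aware most upstream TSS", {
  expect_equal(effective_five_prime(c(100, 150), "+"), 100)
  expect_equal(effective_five_prime(c(100, 150), "-"), 150)
  expect_true(is.na(effective_five_prime(integer(), "+")))
})

test_that("candidate pairs require opposite strands within the gap", {
  genes <- rbind(make_genes("GP", "+", 10000, 15000),
                 make_genes("GM", "-", 5000, 11001), # 5' ends 1 kb apart
                 make_genes("GP2", "+", 11500, 16000))
  pairs <- candidate_pairs(genes, max_gap_bp = 11000)
  expect_setequal(pairs$gene_plus, c("GP", "GP2"))
  expect_true(all(pairs$gene_minus == "GM"))
  # same-strand genes never pair
  expect_equal(nrow(candidate_pairs(genes[genes$strand == "+", ])), 0)
})

test_that("candidate enumeration is complete for every called overlap", {
  withr::local_seed(303)
  for (rep_i in 1:20) {
    cfgs <- replicate(6, random_pair_config(), simplify = FALSE)
    # pool all genes on one chromosome, spaced out, then shift one pair's
    # genes together so geometry stays as drawn
    genes <- do.call(rbind, lapply(seq_along(cfgs), function(k) {
      g <- cfgs[[k]]$genes
      off <- k * 60000L
      g$gene_id <- paste0(g$gene_id, k)
      g$span_start <- g$span_start + off
      g$span_end <- g$span_end + off
      g$annotated_five_prime <- g$annotated_five_prime + off
      g
    }))
    cand <- candidate_pairs(genes, max_gap_bp = 10000L)
    # exhaustive all-vs-all: any opposite-strand pair whose spans could share
    # a base under some admitted TSS (within the 5 kb radius) must be listed
    plus <- genes[genes$strand == "+", ]
    minus <- genes[genes$strand == "-", ]
    for (i in seq_len(nrow(plus))) {
      for (j in seq_len(nrow(minus))) {
        reachable <- abs(plus$annotated_five_prime[i] -
                           minus$annotated_five_prime[j]) <= 10000
        if (reachable) {
          expect_true(any(cand$gene_plus == plus$gene_id[i] &
                            cand$gene_minus == minus$gene_id[j]))
        }
      }
    }
  }
})

test_that("minimal 1 bp overlap is called and a 1 bp miss is not", {
  genes <- rbind(make_genes("GP", "+", 100, 3000),
                 make_genes("GM", "-", 1, 101)) # minus 5' at 100
  pairs <- data.frame(pair_id = "GP:GM", gene_plus = "GP", gene_minus = "GM",
                      chrom = "chrT", stringsAsFactors = FALSE)
  tss <- rbind(make_tss("GP", 100, 10), make_tss("GM", 100, 10, strand = "-"))
  st <- call_overlaps(pairs, genes, tss)
  expect_equal(st$state, "overlap")
  expect_equal(st$overlap_len_bp, 1)

  tss2 <- rbind(make_tss("GP", 100, 10), make_tss("GM", 99, 10, strand = "-"))
  st2 <- call_overlaps(pairs, genes, tss2)
  expect_equal(st2$state, "no_overlap")
  expect_equal(st2$overlap_len_bp, 0)
})

test_that("verdict and length equal the base-set intersection oracle", {
  withr::local_seed(99)
  for (rep_i in 1:200) {
    cfg <- random_pair_config()
    st <- call_overlaps(cfg$pairs, cfg$genes,
                        if (is.null(cfg$tss)) make_tss("GP", 1, 1)[0, ] else cfg$tss,
                        libraries = "L1")
    a <- if (length(cfg$tss_p)) min(cfg$tss_p) else NA_integer_
    b <- if (length(cfg$tss_m)) max(cfg$tss_m) else NA_integer_
    orc <- oracle_overlap(a, b, cfg$genes$span_end[1], cfg$genes$span_start[2])
    expect_equal(st$state, orc$state)
    if (orc$state == "overlap") expect_equal(st$overlap_len_bp, orc$len)
  }
})

test_that("overlap is monotone under upstream movement within partner extent", {
  withr::local_seed(17)
  n_checked <- 0
  while (n_checked < 50) {
    cfg <- random_pair_config()
    if (!length(cfg$tss_p) || !length(cfg$tss_m)) next
    st <- call_overlaps(cfg$pairs, cfg$genes, cfg$tss, libraries = "L1")
    if (st$state != "overlap") next
    a <- min(cfg$tss_p)
    minus_start <- cfg$genes$span_start[cfg$genes$gene_id == "GM"]
    if (a <= minus_start) next
    new_a <- sample(seq.int(minus_start, a), 1)
    tss2 <- rbind(cfg$tss, make_tss("GP", new_a, 10))
    st2 <- call_overlaps(cfg$pairs, cfg$genes, tss2, libraries = "L1")
    expect_equal(st2$state, "overlap")
    expect_gte(st2$overlap_len_bp, st$overlap_len_bp)
    n_checked <- n_checked + 1
  }
})

test_that("overlap-expression fractions are in [0,1] and 1 for a sole overlapping TSS", {
  genes <- rbind(make_genes("GP", "+", 1000, 9000),
                 make_genes("GM", "-", 500, 2001))
  pairs <- data.frame(pair_id = "GP:GM", gene_plus = "GP", gene_minus = "GM",
                      chrom = "chrT", stringsAsFactors = FALSE)
  tss <- rbind(make_tss("GP", c(1500, 2500), c(10, 30)),
               make_tss("GM", 2000, 10, strand = "-"))
  st <- call_overlaps(pairs, genes, tss)
  expect_equal(st$state, "overlap")
  # overlap region [1500, 2000]: plus TSS at 1500 only -> 10 / 40
  expect_equal(st$frac_overlap_plus, 0.25)
  expect_equal(st$frac_overlap_minus, 1)
  expect_equal(st$tss_class_plus, "multiple")
  expect_equal(st$tss_class_minus, "single")
})

test_that("pair/library summary counts and the always-overlap subset", {
  sim <- simulate_dataset(sim_config(seed = 3, n_pairs = 40, n_constitutive = 4,
                                     n_singletons = 4, n_switch_pairs = 2))
  adm <- filter_tss(sim$tss, sim$genes)
  pairs <- candidate_pairs(sim$genes)
  st <- call_overlaps(pairs, sim$genes, adm,
                      libraries = sort(unique(sim$tss$library_id)))
  smry <- pair_library_summary(st)
  expect_true(all(smry$per_pair$n_libraries_overlap <=
                    smry$per_pair$n_libraries_both_expressed))
  planted <- sim$truth$pair_info$pair_id[sim$truth$pair_info$constitutive]
  expect_setequal(smry$always_overlap_pairs, planted)
  # cross-check one pair by direct counting
  p1 <- smry$per_pair$pair_id[10]
  expect_equal(smry$per_pair$n_libraries_overlap[10],
               sum(st$state == "overlap" & st$pair_id == p1))
})

test_that("six-way categories enumerate the full state x TSS-count table", {
  states <- rep(c("overlap", "no_overlap", "single_expressed"), each = 2)
  ntss <- rep(c(1, 3), 3)
  got <- classify_state_six(states, ntss)
  expect_setequal(got, c("overlap_single", "overlap_multi",
                         "no_overlap_single", "no_overlap_multi",
                         "single_expressed_single", "single_expressed_multi"))
  expect_true(is.na(classify_state_six("none_expressed", 0)))
  expect_true(is.na(classify_state_six("single_expressed", 0))) # unexpressed gene
})
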