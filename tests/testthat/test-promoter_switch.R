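switch_fixture <- function(seed = 101, n_switch = 6) {
  sim <- simulate_dataset(sim_config(seed = seed, n_pairs = 30, n_singletons = 4,
                                     ase_n_pairs = 5, n_switch_pairs = n_switch))
  adm <- filter_tss(sim$tss, sim$genes)
  pairs <- candidate_pairs(sim$genes)
  st <- call_overlaps(pairs, sim$genes, adm,
                      libraries = sort(unique(sim$tss$library_id)))
  list(sim = sim, adm = adm, pairs = pairs, st = st,
       ctrl = sim$truth$control_libs, trt = sim$truth$treated_libs)
}

test_that("planted switches are recovered exactly, with strand-correct shifts", {
  f <- switch_fixture()
  ev <- detect_switches(f$st, f$pairs, f$ctrl, f$trt, tss = f$adm)
  truth <- f$sim$truth$switch_truth
  expect_setequal(unique(ev$pair_id), unique(truth$pair_id))
  got <- ev[!is.na(ev$gene_id), ]
  key <- function(d) paste(d$pair_id, d$gene_id)
  m <- match(key(truth), key(got))
  expect_false(anyNA(m))
  expect_equal(got$upstream_shift_bp[m], truth$upstream_shift_bp)
  expect_true(all(got$upstream_shift_bp > 0)) # upstream on both strands
  expect_equal(got$new_tss_is_additional[m], truth$new_tss_is_additional)
  expect_equal(got$control_five_prime[m], truth$control_five_prime)
  expect_equal(got$treated_five_prime[m], truth$treated_five_prime)
})

test_that("the universal quantifier over treated libraries is enforced", {
  f <- switch_fixture()
  # corrupt one planted pair: make it non-overlapping in one treated library
  pid <- f$sim$truth$switch_truth$pair_id[1]
  st2 <- f$st
  row <- which(st2$pair_id == pid & st2$library_id == f$trt[1])
  st2$state[row] <- "no_overlap"
  ev <- detect_switches(st2, f$pairs, f$ctrl, f$trt)
  expect_false(pid %in% ev$pair_id)
  # and a pair overlapping in a control library is also disqualified
  pid2 <- f$sim$truth$switch_truth$pair_id[2]
  st3 <- f$st
  st3$state[st3$pair_id == pid2 & st3$library_id == f$ctrl[1]] <- "overlap"
  ev3 <- detect_switches(st3, f$pairs, f$ctrl, f$trt)
  expect_false(pid2 %in% ev3$pair_id)
})

test_that("event set is antitone in the treated library set", {
  f <- switch_fixture()
  ev_all <- unique(detect_switches(f$st, f$pairs, f$ctrl, f$trt)$pair_id)
  for (k in seq_along(f$trt)) {
    ev_sub <- unique(detect_switches(f$st, f$pairs, f$ctrl, f$trt[1:k])$pair_id)
    expect_true(all(ev_all %in% ev_sub))
  }
  expect_error(detect_switches(f$st, f$pairs, f$ctrl, c(f$ctrl[1], f$trt)),
               "overlap")
  expect_error(detect_switches(f$st, f$pairs, character(), f$trt), "nonempty")
})

test_that("DE thresholds are strict and equal a brute-force scan", {
  de <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                   log2fc = c(1.5, 1.6, -1.6, 2.0, -2.0),
                   fdr = c(0.01, 0.01, 0.01, 0.05, 0.049))
  sets <- apply_de_thresholds(de)
  expect_false("a" %in% sets$up)   # log2fc exactly 1.5 excluded (strict)
  expect_true("b" %in% sets$up)
  expect_true("c" %in% sets$down)
  expect_false("d" %in% sets$up)   # fdr exactly 0.05 excluded (strict)
  expect_true("e" %in% sets$down)

  withr::local_seed(61)
  de2 <- data.frame(gene_id = sprintf("g%03d", 1:200),
                    log2fc = stats::rnorm(200, 0, 2),
                    fdr = stats::runif(200))
  s2 <- apply_de_thresholds(de2)
  expect_setequal(s2$up, de2$gene_id[de2$log2fc > 1.5 & de2$fdr < 0.05])
  expect_setequal(s2$down, de2$gene_id[de2$log2fc < -1.5 & de2$fdr < 0.05])
})

test_that("TF intersection preserves direction labels", {
  sets <- list(up = c("a", "b", "tf1"), down = c("c", "tf2"))
  expect_equal(intersect_tf(sets, c("tf1", "tf2", "tf3")),
               list(up = "tf1", down = "tf2"))
  expect_equal(lengths(intersect_tf(sets, "zzz")), c(up = 0L, down = 0L))
  tfs <- c("a", "b", "tf1")
  expect_setequal(intersect_tf(sets, tfs)$up, intersect(sets$up, tfs))
})

test_that("TSS association window is inclusive at 500 bp and specificity needs one TSS", {
  hits <- data.frame(motif_id = c("M1", "M1", "M2"),
                     tf_name = c("TFA", "TFA", "TFB"),
                     chrom = "chr1",
                     # width-1 hits so midpoints are exactly the start
                     start = c(1500, 2400, 3500), end = c(1501, 2401, 3501),
                     strand = "+", raw_score = 1, rel_score = 1,
                     stringsAsFactors = FALSE)
  # TSS at 1000: hit 1 midpoint 1500 -> distance exactly 500 (associated);
  # hit 2 midpoint 2400 -> 1400/600 from both TSSs (never associated);
  # TSS at 3000: hit 3 midpoint 3500 -> distance exactly 500
  res <- associate_tss_tfbs(c(t1 = 1000, t2 = 3000), hits, window_bp = 500)
  a <- res$associations
  expect_true(any(a$tss == "t1" & a$tf_name == "TFA" & a$min_distance == 500))
  expect_false(any(a$tss == "t1" & a$tf_name == "TFB"))
  expect_true(any(a$tss == "t2" & a$tf_name == "TFB"))
  # TFA is specific to t1, TFB specific to t2
  expect_setequal(res$tss_specific$tf_name, c("TFA", "TFB"))
  # at 501 bp the hit is no longer associated
  res2 <- associate_tss_tfbs(c(t1 = 999), hits[1, ], window_bp = 500)
  expect_equal(nrow(res2$associations), 0)
  # a TF near both TSSs is associated with both and not TSS-specific
  both <- data.frame(motif_id = "M3", tf_name = "TFC", chrom = "chr1",
                     start = c(900, 3100), end = c(901, 3101), strand = "+",
                     raw_score = 1, rel_score = 1, stringsAsFactors = FALSE)
  res3 <- associate_tss_tfbs(c(t1 = 1000, t2 = 3000), both, window_bp = 500)
  expect_equal(nrow(res3$tss_specific), 0)
  expect_setequal(res3$associations$tss, c("t1", "t2"))
})

test_that("the planted activator becomes TSS-specific at the new TSS", {
  f <- switch_fixture(seed = 202)
  ev <- detect_switches(f$st, f$pairs, f$ctrl, f$trt, tss = f$adm)
  hits <- scan_promoters(f$sim$promoters, f$sim$pfms)
  de_tfs <- intersect_tf(apply_de_thresholds(f$sim$de_table), f$sim$tf_ids)
  mt <- f$sim$truth$motif_truth
  for (r in seq_len(nrow(mt))) {
    g <- mt$gene_id[r]
    erow <- ev[ev$gene_id == g, ][1, ]
    gh <- hits[hits$seq_id == g & hits$tf_name %in% c(de_tfs$up, de_tfs$down), ]
    assoc <- associate_tss_tfbs(c(control = erow$control_five_prime,
                                  treated = erow$treated_five_prime), gh)
    expect_true(any(assoc$tss_specific$tf_name == mt$tf_activator[r] &
                      assoc$tss_specific$tss == "treated"))
    expect_true(mt$tf_activator[r] %in% de_tfs$up)
  }
})
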