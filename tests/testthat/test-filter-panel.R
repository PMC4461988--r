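test_that("sequential Bonferroni matches hand-worked examples", {
  expect_equal(sequential_bonferroni(c(0.001, 0.02, 0.03), 0.05),
               c(TRUE, TRUE, TRUE))
  expect_equal(sequential_bonferroni(c(0.04, 0.04, 0.04), 0.05),
               rep(FALSE, 3))
  expect_equal(sequential_bonferroni(0.049, 0.05), TRUE)
  expect_equal(sequential_bonferroni(numeric(0)), logical(0))
  # stopping: once one fails, later (larger) p-values cannot be rejected
  expect_equal(sequential_bonferroni(c(0.03, 0.001, 0.4), 0.05),
               c(FALSE, TRUE, FALSE))
  expect_error(sequential_bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("locus filter retains everything when no test is significant", {
  # fixture drawn under the null; this seed yields raw HWE p-values all
  # comfortably above the threshold, so any exclusion is a defect
  gm <- gen_structured_genotypes(synthetic_spec(
    n_regions = 1, fields_per_region = 1, individuals_per_field = 40,
    n_loci = 6, target_fst = 0, target_fis = 0, missing_rate = 0,
    seed = 48))
  res <- filter_loci(gm, n_permutations = 99, em_starts = 2, seed = 1)
  expect_setequal(res$retained, gm$locus_ids)
  expect_true(all(res$report$excluded_reason == "none"))
})

test_that("one locus of each significant LD pair is removed, reproducibly", {
  set.seed(8)
  base <- cbind(sample(1:2, 50, TRUE), sample(1:2, 50, TRUE))
  indep <- cbind(sample(1:2, 50, TRUE), sample(1:2, 50, TRUE))
  a1 <- cbind(base[, 1], base[, 1], indep[, 1])
  a2 <- cbind(base[, 2], base[, 2], indep[, 2])
  gm <- genotype_matrix(a1, a2, locus_ids = c("L1", "L2", "L3"),
                        field = rep("f1", 50), region_of = c(f1 = "r1"))
  res <- filter_loci(gm, n_permutations = 199, em_starts = 2, seed = 7)
  dropped <- setdiff(gm$locus_ids, res$retained)
  expect_length(dropped, 1)
  expect_true(dropped %in% c("L1", "L2"))
  res2 <- filter_loci(gm, n_permutations = 199, em_starts = 2, seed = 7)
  expect_identical(res$retained, res2$retained)
})

test_that("chained LD (A-B, B-C) is broken with no more removals than a vertex cover", {
  set.seed(9)
  mid <- cbind(sample(1:2, 60, TRUE), sample(1:2, 60, TRUE))
  a1 <- cbind(mid[, 1], mid[, 1], mid[, 1])
  a2 <- cbind(mid[, 2], mid[, 2], mid[, 2])
  gm <- genotype_matrix(a1, a2, locus_ids = c("A", "B", "C"),
                        field = rep("f1", 60), region_of = c(f1 = "r1"))
  vc <- filter_loci(gm, n_permutations = 199, em_starts = 2, seed = 3,
                    removal = "vertex-cover")
  # all three loci are identical: every pair is significant, minimal
  # cover removes 2 of 3
  expect_length(vc$retained, 1)
  rnd <- filter_loci(gm, n_permutations = 199, em_starts = 2, seed = 3)
  expect_lte(length(setdiff(gm$locus_ids, rnd$retained)), 3)
  expect_gte(length(setdiff(gm$locus_ids, rnd$retained)),
             length(setdiff(gm$locus_ids, vc$retained)))
})

test_that("HWE-deviant loci are excluded with the hwe reason", {
  set.seed(10)
  good1 <- cbind(sample(1:2, 60, TRUE), sample(1:2, 60, TRUE))
  good2 <- cbind(sample(1:2, 60, TRUE), sample(1:2, 60, TRUE))
  bad <- cbind(rep(c(1L, 2L), each = 30), rep(c(1L, 2L), each = 30))
  gm <- genotype_matrix(cbind(good1[, 1], bad[, 1], good2[, 1]),
                        cbind(good1[, 2], bad[, 2], good2[, 2]),
                        locus_ids = c("ok1", "hom", "ok2"),
                        field = rep("f1", 60), region_of = c(f1 = "r1"))
  res <- filter_loci(gm, n_permutations = 99, em_starts = 2, seed = 2)
  expect_equal(res$report$excluded_reason[2], "hwe")
  expect_false("hom" %in% res$retained)
})

test_that("SNP panel selection applies every rule on a hand-checkable table", {
  cand <- snp_candidates(
    scaffold = c("s1", "s1", "s2", "s3", "s4", "s5", "s6", "s7", "s7", "s8"),
    position = c(100, 120, 500, 300, 400, 200, 250, 100, 5000, 700),
    alleles  = c("A/G", "C/T", "A/C", "A/G/T", "C/G", "A/T", "C/T", "A/G",
                 "G/T", "A/C"),
    maf      = c(0.25, 0.45, 0.12, 0.35, 0.28, 0.42, 0.33, 0.47, 0.22, 0.38),
    quality  = c(900, 800, 950, 999, 700, 600, 850, 500, 400, 300))
  sel <- suppressWarnings(
    select_snp_panel(cand, bin_quotas = c(2, 2, 2)))
  # s1 pair 20 bp apart: both out; s2 fails MAF floor; s3 tri-allelic;
  # survivors: s4(0.28,q700), s5(0.42,q600), s6(0.33,q850), s7@100(0.47,q500),
  # s7@5000(0.22,q400), s8(0.38,q300)
  # bin (0.2,0.3]: s4 then s7@5000 -> both; bin (0.3,0.4]: s6 then s8;
  # bin (0.4,0.5]: s5 and s7@100 -- but s7 already used: only s5
  expect_setequal(paste(sel$scaffold, sel$position),
                  c("s4 400", "s7 5000", "s6 250", "s8 700", "s5 200"))
  expect_false(anyDuplicated(sel$scaffold) > 0)
  expect_warning(select_snp_panel(cand, bin_quotas = c(2, 2, 2)),
                 "only")
})

test_that("close-pair spacing removes both SNPs of the pair", {
  cand <- snp_candidates(c("s1", "s1", "s1"), c(100, 130, 400),
                         c("A/G", "C/T", "A/C"), c(0.35, 0.35, 0.35),
                         c(10, 20, 30))
  sel <- suppressWarnings(select_snp_panel(cand, bin_quotas = c(0, 3, 0)))
  expect_equal(sel$position, 400)
})

test_that("transition:transversion ratio counts substitution classes", {
  cand <- snp_candidates(c("a", "b", "c"), 1:3, c("A/G", "C/T", "A/C"),
                         rep(0.3, 3), rep(10, 3))
  expect_equal(titv_ratio(cand)$ratio, 2)
  allti <- snp_candidates(c("a", "b"), 1:2, c("A/G", "A/G"), rep(0.3, 2),
                          rep(10, 2))
  res <- titv_ratio(allti)
  expect_true(is.na(res$ratio))
  expect_false(res$defined)
  bad <- snp_candidates("a", 1, list(c("A", "N")), 0.3, 10)
  expect_error(titv_ratio(bad), "nucleotide")
  # random pairs drift to the chance expectation of 1:2
  set.seed(2)
  pairs <- t(replicate(4000, sample(c("A", "C", "G", "T"), 2)))
  rnd <- snp_candidates(paste0("s", 1:4000), 1:4000,
                        lapply(seq_len(4000), function(i) pairs[i, ]),
                        rep(0.3, 4000), rep(10, 4000))
  expect_lt(abs(titv_ratio(rnd)$ratio - 0.5), 0.06)
})
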