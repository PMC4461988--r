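test_that("structured genotypes are bit-reproducible and honour dimensions", {
  spec <- synthetic_spec(seed = 17)
  gm1 <- gen_structured_genotypes(spec)
  gm2 <- gen_structured_genotypes(spec)
  expect_identical(gm1$a1, gm2$a1)
  expect_equal(dim(gm1), c(4 * 2 * 17, 81))
  expect_equal(length(unique(gm1$field)), 8)
  expect_equal(length(unique(gm1$region_of)), 4)
  expect_lt(abs(mean(is.na(gm1$a1)) - 0.025), 0.01)
})

test_that("generated matrices satisfy the container invariants across seeds", {
  for (s in seq(1, 100, by = 7)) {
    gm <- gen_structured_genotypes(synthetic_spec(
      individuals_per_field = 5, n_loci = 12, seed = s))
    expect_identical(dim(gm$a1), dim(gm$a2))
    expect_false(any(xor(is.na(gm$a1), is.na(gm$a2))))
    expect_true(all(unique(gm$field) %in% names(gm$region_of)))
    expect_true(all(gm$a1 <= gm$a2, na.rm = TRUE))
  }
})

test_that("null generator parameters produce null statistics", {
  ests <- t(vapply(1:20, function(s) {
    gm <- gen_structured_genotypes(synthetic_spec(
      target_fst = 0, target_fis = 0, missing_rate = 0, seed = 300 + s))
    fs <- global_fstats(gm, n_bootstrap = 0)
    c(fs$f_is, fs$f_st)
  }, numeric(2)))
  expect_lt(abs(mean(ests[, 1])), 0.01)
  expect_lt(abs(mean(ests[, 2])), 0.01)
})

test_that("complete inbreeding removes all heterozygotes", {
  gm <- gen_structured_genotypes(synthetic_spec(target_fis = 0.999999,
                                                missing_rate = 0,
                                                seed = 4))
  expect_equal(sum(gm$a1 != gm$a2), 0)
})

test_that("SNP candidate generator controls its composition", {
  expect_error(gen_snp_candidates(0), ">= 1")
  cand <- gen_snp_candidates(2000, seed = 13)
  tri <- mean(lengths(cand$alleles) == 3)
  expect_lt(abs(tri - 0.05), 0.02)
  expect_true(all(cand$position >= 1))
  expect_true(all(cand$maf <= 0.5))
  cand2 <- gen_snp_candidates(2000, seed = 13)
  expect_identical(cand$position, cand2$position)
})

test_that("panel selection on generated candidates respects all filters", {
  cand <- gen_snp_candidates(800, seed = 19)
  sel <- suppressWarnings(select_snp_panel(cand, bin_quotas = c(10, 15, 15)))
  expect_lte(nrow(sel), 40)
  # brute-force re-check of every rule on the selected set
  expect_true(all(sel$maf >= 0.2))
  expect_true(all(lengths(sel$alleles) == 2))
  expect_false(anyDuplicated(sel$scaffold) > 0)
  for (i in seq_len(nrow(sel))) {
    same <- cand$scaffold == sel$scaffold[i] &
      abs(cand$position - sel$position[i]) <= 50 &
      cand$position != sel$position[i]
    expect_false(any(same))
  }
  for (b in levels(sel$maf_bin)) {
    expect_lte(sum(sel$maf_bin == b), c(10, 15, 15)[match(b, levels(sel$maf_bin))])
  }
})

test_that("ploidy count generator recovers the true DMP in the pooled estimate", {
  pcs <- gen_ploidy_counts(8, true_dmp = 0.014, females_per_field = 185,
                           seed = 23)
  expect_equal(nrow(pcs), 8)
  expect_true(all(pcs$n_haploid + pcs$n_diploid_males + pcs$n_unknown ==
                    pcs$n_males_assayed))
  est <- aggregate_dmp(pcs)
  n <- 8 * 185
  se <- sqrt(0.014 * (1 - 0.014) / n)
  expect_lt(abs(est$dmp - 0.014), 3 * se)
  zero <- gen_ploidy_counts(5, true_dmp = 0, females_per_field = 100,
                            seed = 2)
  expect_true(all(zero$n_diploid_males == 0))
})

test_that("assay fraction thins the assayed haploid pool", {
  pcs <- gen_ploidy_counts(30, true_dmp = 0.01, females_per_field = 200,
                           assay_fraction = 2 / 3, seed = 31)
  # ~200 males per field at a balanced sex ratio, 2/3 assayed
  expect_lt(abs(mean(pcs$n_haploid + pcs$n_unknown) / 200 - 2 / 3), 0.05)
})
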