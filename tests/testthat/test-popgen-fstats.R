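test_that("heterozygosity matches hand-computed values on a toy locus", {
  gm <- toy_three_genotypes()
  h <- heterozygosity(gm)
  expect_equal(h$per_locus$ho, 1 / 3, tolerance = 1e-12)
  expect_equal(h$per_locus$he, 0.6, tolerance = 1e-12)  # (6/5)(1 - 0.5)
  mono <- genotype_matrix(cbind(rep(1L, 4)), cbind(rep(1L, 4)),
                          field = rep("f1", 4), region_of = c(f1 = "r1"))
  hm <- heterozygosity(mono)
  expect_equal(hm$per_locus$ho, 0)
  expect_equal(hm$per_locus$he, 0)
  expect_true(hm$per_locus$monomorphic)
})

test_that("populations fixed for alternate alleles give F_ST = 1", {
  gm <- toy_fixed_pops()
  fs <- global_fstats(gm, n_bootstrap = 0)
  expect_equal(fs$f_st, 1, tolerance = 1e-12)
})

test_that("universal heterozygotes give negative F_IS", {
  a1 <- matrix(1L, 10, 4)
  a2 <- matrix(2L, 10, 4)
  gm <- genotype_matrix(a1, a2, field = rep("f1", 10),
                        region_of = c(f1 = "r1"))
  fs <- global_fstats(gm, n_bootstrap = 0)
  expect_lt(fs$f_is, 0)
  expect_true(fs$single_group)
  expect_true(is.na(fs$f_st))
})

test_that("combined F-statistics satisfy (1-F_IT) = (1-F_IS)(1-F_ST)", {
  gm <- gen_structured_genotypes(synthetic_spec(seed = 21))
  fs <- global_fstats(gm, n_bootstrap = 50, seed = 2)
  expect_equal(1 - fs$f_it, (1 - fs$f_is) * (1 - fs$f_st),
               tolerance = 1e-12)
  expect_equal(dim(fs$ci), c(2L, 3L))
  # bootstrap is seeded
  fs2 <- global_fstats(gm, n_bootstrap = 50, seed = 2)
  expect_identical(fs$ci, fs2$ci)
})

test_that("per-field F_IS agrees with single-group estimation", {
  gm <- gen_structured_genotypes(synthetic_spec(seed = 22))
  pf <- fis_per_field(gm)
  expect_equal(nrow(pf), 8)
  f <- pf$field[1]
  sub <- subset_genotypes(gm, individuals = gm$field == f)
  expect_equal(pf$f_is[1],
               global_fstats(sub, grouping = rep("g", nrow(sub$a1)),
                             n_bootstrap = 0)$f_is)
})

test_that("pairwise F_ST detects disjoint fixation and honours the p-value convention", {
  gm <- toy_fixed_pops()
  pw <- pairwise_fst(gm, n_permutations = 99, seed = 3)
  expect_equal(pw$fst["f1", "f2"], 1, tolerance = 1e-12)
  expect_equal(pw$p_value["f1", "f2"], 1 / 100)
  expect_true(is.na(pw$fst["f1", "f1"]))
  one <- subset_genotypes(gm, individuals = gm$field == "f1")
  expect_error(pairwise_fst(one), "2 fields")
})

test_that("pairwise permutation test has power at study-scale differentiation", {
  hits <- vapply(1:10, function(s) {
    gm <- gen_structured_genotypes(synthetic_spec(
      n_regions = 1, fields_per_region = 2, individuals_per_field = 20,
      n_loci = 81, target_fst = 0.05, target_fis = 0, missing_rate = 0,
      seed = 100 + s))
    pw <- pairwise_fst(gm, n_permutations = 199, seed = s)
    pw$p_value[1, 2] < 0.05
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("AMOVA percentages sum to 100 and respect relabeling invariance", {
  gm <- gen_structured_genotypes(synthetic_spec(seed = 30))
  am <- amova(gm)
  expect_equal(sum(am$percent[1:3]), 100, tolerance = 0.1)
  expect_equal(am$df[1:3], c(3, 4, 2 * nrow(gm$a1) - 8))
  expect_equal(sum(am$df[1:3]), 2 * nrow(gm$a1) - 1)
  # shuffling individuals within fields changes nothing
  ord <- unlist(lapply(unique(gm$field), function(f) {
    idx <- which(gm$field == f)
    sample(idx)
  }))
  set.seed(1)
  gm2 <- subset_genotypes(gm, individuals = ord)
  expect_equal(amova(gm2)$variance, am$variance, tolerance = 1e-12)
})

test_that("AMOVA on identical genotypes leaves no between-group variance", {
  fields <- rep(c("f1", "f2", "f3", "f4"), each = 3)
  regions <- c(f1 = "r1", f2 = "r1", f3 = "r2", f4 = "r2")
  # monomorphic data: zero variance at every level (gene copies identical)
  mono <- genotype_matrix(matrix(1L, 12, 3), matrix(1L, 12, 3),
                          field = fields, region_of = regions)
  expect_equal(amova(mono)$variance, rep(0, 4), tolerance = 1e-12)
  # identical heterozygotes: variance exists within individuals (gene
  # copies differ) but none between fields or regions
  het <- genotype_matrix(matrix(1L, 12, 3), matrix(2L, 12, 3),
                         field = fields, region_of = regions)
  am <- amova(het)
  expect_equal(am$variance[1:2], c(0, 0), tolerance = 0.2)
  expect_gt(am$variance[3], 0)
})

test_that("AMOVA flags degenerate hierarchies by level", {
  gm <- gen_structured_genotypes(synthetic_spec(n_regions = 1, seed = 5))
  expect_error(amova(gm), "regions")
  gm2 <- gen_structured_genotypes(synthetic_spec(fields_per_region = 1,
                                                 seed = 5))
  expect_error(amova(gm2), "fields")
})

test_that("panmictic data place almost all AMOVA variance within fields", {
  pct <- vapply(1:10, function(s) {
    gm <- gen_structured_genotypes(synthetic_spec(target_fst = 0,
                                                  target_fis = 0,
                                                  seed = 200 + s))
    am <- amova(gm)
    am$percent[am$level == "within fields"]
  }, numeric(1))
  expect_gt(mean(pct), 95)
})
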