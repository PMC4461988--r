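test_that("sibmating rate from F_IS follows 4F/(3F+1) with a floor at 0", {
  expect_equal(sibmating_from_fis(0), 0)
  expect_equal(sibmating_from_fis(1), 1)
  expect_equal(sibmating_from_fis(0.021), 4 * 0.021 / (3 * 0.021 + 1),
               tolerance = 1e-12)
  expect_equal(sibmating_from_fis(0.021), 0.07902, tolerance = 1e-4)
  expect_equal(sibmating_from_fis(0.042), 0.14920, tolerance = 1e-4)
  expect_warning(a <- sibmating_from_fis(-0.05), "negative")
  expect_equal(a, 0)
  expect_error(sibmating_from_fis(-1 / 3), "exceed -1/3")
  expect_error(sibmating_from_fis(1.2), "not exceed 1")
})

test_that("F_IS <-> sibmating rate conversion roundtrips on [0,1]", {
  expect_equal(fis_from_sibmating(0), 0)
  expect_equal(fis_from_sibmating(1), 1)
  expect_equal(fis_from_sibmating(0.081), 0.081 / 3.757, tolerance = 1e-5)
  alphas <- seq(0, 1, by = 0.05)
  expect_equal(sibmating_from_fis(fis_from_sibmating(alphas)), alphas,
               tolerance = 1e-12)
  expect_error(fis_from_sibmating(-0.1), "\\[0, 1\\]")
  expect_error(fis_from_sibmating(1.1), "\\[0, 1\\]")
})

test_that("female class frequencies are viability-conditioned and sum to 1", {
  fc <- female_class_freqs(9, 9)
  expect_equal(fc$f_het_both, 0.8, tolerance = 1e-12)
  expect_equal(female_class_freqs(2, 2)$f_het_both, 1 / 3, tolerance = 1e-12)
  expect_gt(female_class_freqs(500, 500)$f_het_both, 0.99)
  for (k in c(2, 3, 9, 20)) {
    for (l in c(2, 5, 17)) {
      fc <- female_class_freqs(k, l)
      expect_equal(fc$f_het_both + fc$f_hom_locus1 + fc$f_hom_locus2, 1,
                   tolerance = 1e-12)
    }
  }
  expect_error(female_class_freqs(1, 9), ">= 2")
})

test_that("matched-mating frequency is 2/k under single-locus CSD", {
  expect_equal(matched_mating_freqs(csd_model_spec(1, k = 10))$theta, 0.2)
  expect_equal(matched_mating_freqs(csd_model_spec(1, k = 2))$theta, 1)
  mm <- matched_mating_freqs(csd_model_spec(2, k = 9, l = 9))
  expect_equal(mm$p_het, 0.8 * (2 / 9)^2, tolerance = 1e-12)
  expect_equal(mm$p_hom, 0.4 / 81, tolerance = 1e-12)
  expect_equal(mm$p_het, 0.039506, tolerance = 1e-4)
  expect_equal(mm$p_hom, 0.0049383, tolerance = 1e-4)
  expect_equal(mm$theta, mm$p_het + mm$p_hom, tolerance = 1e-12)
})

test_that("single-locus DMP prediction matches the closed form", {
  expect_equal(dmp_sl(0.081, 100), 0.02944, tolerance = 1e-10)
  expect_equal(round(dmp_sl(0.081, 100), 2), 0.03)
  expect_equal(dmp_sl(0, 2), 0.5)
  expect_equal(dmp_sl(1, 7), 0.25)
  expect_equal(dmp_sl(1, 100), 0.25)
})

test_that("two-locus DMP prediction matches the exact enumeration oracle", {
  expect_equal(dmp_2l(0.081, 9, 9), 0.019446, tolerance = 1e-4)
  expect_equal(dmp_2l(0.081, 20, 20), 0.008807, tolerance = 1e-4)
  expect_lt(dmp_2l(0, 100, 100), 1e-3)
  for (k in 2:30) {
    for (a in c(0, 0.081, 0.5, 1)) {
      spec <- csd_model_spec(2, k = k, l = k, alpha = a)
      expect_equal(dmp_2l(a, k, k), brute_force_dmp(spec),
                   tolerance = 1e-12)
      spec1 <- csd_model_spec(1, k = k, alpha = a)
      expect_equal(dmp_sl(a, k), brute_force_dmp(spec1), tolerance = 1e-12)
    }
  }
})

test_that("a second sex locus never increases the diploid male load", {
  for (k in c(2, 5, 12, 30)) {
    for (l in c(2, 8, 30)) {
      for (a in c(0, 0.3, 1)) {
        expect_lte(dmp_2l(a, k, l), dmp_sl(a, min(k, l)) + 1e-12)
      }
    }
  }
})

test_that("DMP is non-increasing in allele number and affine in alpha", {
  ks <- 2:40
  for (a in c(0, 0.081, 0.7)) {
    v1 <- vapply(ks, function(k) dmp_sl(a, k), numeric(1))
    v2 <- vapply(ks, function(k) dmp_2l(a, k, k), numeric(1))
    expect_true(all(diff(v1) <= 1e-12))
    expect_true(all(diff(v2) <= 1e-12))
  }
  # affine: value at midpoint equals average of endpoints
  for (k in c(5, 20)) {
    expect_equal(dmp_2l(0.25, k, k),
                 (dmp_2l(0, k, k) + dmp_2l(0.5, k, k)) / 2,
                 tolerance = 1e-12)
  }
})

test_that("survival adjustment renormalizes among surviving diploids", {
  m <- dmp_sl(0.1, 10)
  s <- 0.6
  expect_equal(dmp_sl(0.1, 10, dm_survival = s),
               s * m / (s * m + 1 - m), tolerance = 1e-12)
  expect_equal(dmp_sl(0.1, 10, dm_survival = 1), m)
  expect_equal(dmp_sl(0.1, 10, dm_survival = 0), 0)
})

test_that("prediction bands equal a dense grid min/max over alpha", {
  for (spec in list(csd_model_spec(1, k = 100),
                    csd_model_spec(2, k = 20, l = 20))) {
    b <- dmp_band(0, 0.151, spec)
    g <- grid_dmp_range(spec, 0, 0.151)
    expect_equal(b$band_low, g[1], tolerance = 1e-12)
    expect_equal(b$band_high, g[2], tolerance = 1e-12)
    expect_lte(b$band_low, b$band_high)
  }
  sl <- dmp_band(0, 0.151, csd_model_spec(1, k = 100))
  expect_equal(sl$band_low, 0.01, tolerance = 1e-12)
  expect_equal(sl$band_high, 0.25 * 0.151 + (1 - 0.151) / 100,
               tolerance = 1e-12)  # 0.04624
  deg <- dmp_band(0.1, 0.1, csd_model_spec(1, k = 10))
  expect_equal(deg$band_low, deg$band_high)
  expect_equal(deg$band_low, dmp_sl(0.1, 10))
  expect_error(dmp_band(0.5, 0.1, csd_model_spec(1, k = 10)))
})

test_that("allele numbers consistent with the observed DMP form 9..20", {
  ks <- consistent_allele_range(0.014, 0, 0.151)
  expect_equal(ks, 9:20)
  expect_length(consistent_allele_range(1.0, 0, 0.151, k_values = 3:100), 0)
  # inclusive containment at a band endpoint
  b <- dmp_band(0, 0.151, csd_model_spec(2, k = 9, l = 9))
  expect_true(9L %in% consistent_allele_range(b$band_low, 0, 0.151))
  expect_error(consistent_allele_range(0.014, 0, 0.1, k_values = integer(0)))
})

test_that("minimum allele number search honours the sibmating floor", {
  expect_identical(min_alleles_required(0.014, 0.081, model = 1),
                   NA_integer_)
  expect_identical(min_alleles_required(0.014, 0, model = 1), 72L)
  expect_identical(min_alleles_required(0.5, 0, model = 1), 2L)
  expect_lt(min_alleles_required(0.014, 0.081, model = 2), 72L)
})

test_that("model spec validates its domain", {
  expect_error(csd_model_spec(3), "1 or 2")
  expect_error(csd_model_spec(1, k = 1), ">= 2")
  expect_error(csd_model_spec(2, k = 5, l = 1), "`l`")
  expect_error(csd_model_spec(1, k = 5, alpha = 1.2), "proportion")
  expect_error(csd_model_spec(1, k = 5, dm_survival = -0.1), "proportion")
})
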