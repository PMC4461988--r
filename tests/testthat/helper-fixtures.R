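# Small deterministic fixtures shared across test files.

# A 3-individual, 1-locus matrix: genotypes AA, AB, BB (codes 1/2).
toy_three_genotypes <- function() {
  genotype_matrix(a1 = cbind(c(1L, 1L, 2L)), a2 = cbind(c(1L, 2L, 2L)),
                  individual_ids = c("i1", "i2", "i3"),
                  locus_ids = "L1", field = rep("f1", 3),
                  region_of = c(f1 = "r1"))
}

# Two populations fixed for alternate alleles at every locus.
toy_fixed_pops <- function(n_per_pop = 10, n_loci = 5) {
  n <- 2 * n_per_pop
  a <- matrix(rep(c(1L, 2L), each = n_per_pop), n, n_loci)
  genotype_matrix(a, a, field = rep(c("f1", "f2"), each = n_per_pop),
                  region_of = c(f1 = "r1", f2 = "r1"))
}

# Exact DMP by brute-force expectation over the mating table; used as an
# independent check of the closed forms (not via expected_dmp()).
brute_force_dmp <- function(spec) {
  tab <- enumerate_mating_table(spec)
  sum(tab$probability * tab$dm_fraction)
}

# Dense alpha grid evaluation used to verify band endpoints.
grid_dmp_range <- function(spec, alpha_low, alpha_high, n_grid = 101) {
  alphas <- seq(alpha_low, alpha_high, length.out = n_grid)
  vals <- vapply(alphas, function(a) {
    if (spec$n_sex_loci == 1L) dmp_sl(a, spec$k, spec$dm_survival)
    else dmp_2l(a, spec$k, spec$l, spec$dm_survival)
  }, numeric(1))
  range(vals)
}
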