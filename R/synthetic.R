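#' Specification for the structured-genotype generator
#'
#' The defaults emulate the shape of the motivating field study: 8
#' subpopulations (fields) nested in 4 regions, roughly 17 diploid
#' females per field genotyped at 81 biallelic SNP loci with minor allele
#' frequency at least 0.2, weak differentiation (target
#' \eqn{F_{ST} = 0.05}), weak inbreeding (target \eqn{F_{IS} = 0.02})
#' and 2.5\% missing calls.
#'
#' @param n_regions Number of regions.
#' @param fields_per_region Fields per region.
#' @param individuals_per_field Diploid individuals per field.
#' @param n_loci Number of biallelic loci.
#' @param target_fst Balding-Nichols differentiation parameter.
#' @param target_fis Within-field inbreeding coefficient.
#' @param maf_floor Lower bound of the ancestral minor allele frequency.
#' @param missing_rate Fraction of calls set to missing.
#' @param seed Integer seed (required at generation time).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_regions = 4, fields_per_region = 2,
                           individuals_per_field = 17, n_loci = 81,
                           target_fst = 0.05, target_fis = 0.02,
                           maf_floor = 0.2, missing_rate = 0.025,
                           seed = 1) {
  props <- c(target_fst, target_fis, maf_floor, missing_rate)
  if (any(props < 0) || any(props >= 1)) {
    stop("proportions must lie in [0, 1)", call. = FALSE)
  }
  counts <- c(n_regions, fields_per_region, individuals_per_field, n_loci)
  if (any(counts < 1)) stop("counts must be positive", call. = FALSE)
  structure(list(n_regions = n_regions, fields_per_region = fields_per_region,
                 individuals_per_field = individuals_per_field,
                 n_loci = n_loci, target_fst = target_fst,
                 target_fis = target_fis, maf_floor = maf_floor,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a hierarchically structured genotype matrix
#'
#' Draws ancestral allele frequencies uniformly on
#' `[maf_floor, 0.5]`, perturbs them per field with the Balding-Nichols
#' Beta model at differentiation `target_fst` (field frequency
#' `~ Beta(p(1-F)/F, (1-p)(1-F)/F)`), and samples genotypes with a
#' within-field homozygote excess `target_fis`
#' (P(hom ref) = `p^2 + F_IS p(1-p)`, etc.). Calls are then masked at
#' `missing_rate`.
#'
#' @param spec A [synthetic_spec()].
#' @return A [genotype_matrix()] with fields `field1..` and regions
#'   `region1..`.
#' @export
gen_structured_genotypes <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  nf <- spec$n_regions * spec$fields_per_region
  npf <- spec$individuals_per_field
  n <- nf * npf
  L <- spec$n_loci
  p_anc <- stats::runif(L, spec$maf_floor, 0.5)
  fst <- spec$target_fst
  fis <- spec$target_fis
  a1 <- a2 <- matrix(NA_integer_, n, L)
  field <- rep(paste0("field", seq_len(nf)), each = npf)
  region_of <- stats::setNames(
    paste0("region", rep(seq_len(spec$n_regions),
                         each = spec$fields_per_region)),
    paste0("field", seq_len(nf)))
  for (f in seq_len(nf)) {
    p_f <- if (fst > 0) {
      stats::rbeta(L, p_anc * (1 - fst) / fst, (1 - p_anc) * (1 - fst) / fst)
    } else p_anc
    rows <- which(field == paste0("field", f))
    # genotype probabilities with inbreeding coefficient fis
    p_hom1 <- p_f^2 + fis * p_f * (1 - p_f)
    p_het <- 2 * p_f * (1 - p_f) * (1 - fis)
    u <- matrix(stats::runif(npf * L), npf, L)
    g1 <- u < rep(p_hom1, each = npf)                       # 1/1
    g2 <- !g1 & u < rep(p_hom1 + p_het, each = npf)          # 1/2
    a1[rows, ] <- ifelse(g1 | g2, 1L, 2L)
    a2[rows, ] <- ifelse(g1, 1L, 2L)
  }
  if (spec$missing_rate > 0) {
    miss <- matrix(stats::runif(n * L) < spec$missing_rate, n, L)
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
  }
  genotype_matrix(a1, a2,
                  individual_ids = paste0("ind", seq_len(n)),
                  locus_ids = paste0("snp", seq_len(L)),
                  field = field, region_of = region_of)
}

#' Generate genotypes from an explicit sibmating pedigree
#'
#' Runs the individual-based haplodiploid simulator
#' ([simulate_generations()]) at sibmating rate `alpha` and returns the
#' final generation's females as a [genotype_matrix()] (a single field in
#' a single region). The realized inbreeding coefficient converges toward
#' the sibmating equilibrium \eqn{\alpha/(4-3\alpha)}, providing pedigree
#' ground truth for [sibmating_from_fis()].
#'
#' @param alpha Sibmating rate in \[0, 1\].
#' @param generations Number of generations (>= 5).
#' @param spec A [synthetic_spec()]; `individuals_per_field` scales the
#'   population (`n_females = individuals_per_field * fields_per_region *
#'   n_regions`), `n_loci` the number of neutral loci, `seed` the RNG.
#' @param n_females Breeding females per generation; overrides the
#'   spec-derived default.
#' @param csd A [csd_model_spec()] for the sex loci; its `alpha` is
#'   replaced by the `alpha` argument.
#' @return A list: `genotypes` (a `genotype_matrix`), `series` (the
#'   per-generation data.frame), `extinct`.
#' @export
gen_sibmating_genotypes <- function(alpha, generations = 10,
                                    spec = synthetic_spec(),
                                    n_females = spec$individuals_per_field *
                                      spec$fields_per_region * spec$n_regions,
                                    csd = csd_model_spec(2, k = 20, l = 20)) {
  stopifnot(generations >= 5)
  csd <- csd_model_spec(csd$n_sex_loci, k = csd$k,
                        l = if (is.na(csd$l)) csd$k else csd$l,
                        alpha = alpha, dm_survival = csd$dm_survival)
  sim <- simulate_generations(csd, n_females = max(n_females, 10),
                              n_generations = generations,
                              n_neutral_loci = spec$n_loci,
                              seed = spec$seed)
  a1 <- sim$final_females$a1
  a2 <- sim$final_females$a2
  gm <- if (!sim$extinct && nrow(a1) > 0) {
    genotype_matrix(a1, a2,
                    individual_ids = paste0("fem", seq_len(nrow(a1))),
                    locus_ids = paste0("neu", seq_len(ncol(a1))),
                    field = rep("field1", nrow(a1)),
                    region_of = c(field1 = "region1"))
  } else NULL
  list(genotypes = gm, series = sim$series, extinct = sim$extinct)
}

#' Generate a synthetic SNP candidate table
#'
#' Places candidate SNPs on scaffolds with length-weighted placement,
#' minor allele frequencies uniform on (0, 0.5], caller-like quality
#' scores, about 5\% tri-allelic rows and a controlled fraction of
#' close (< `spacing` bp) neighbour pairs, so the panel-selection rules
#' all have work to do.
#'
#' @param n Number of candidate SNPs (>= 1).
#' @param seed Integer seed.
#' @param n_scaffolds Number of scaffolds to distribute SNPs over.
#' @param tri_fraction Fraction of rows given a third allele.
#' @param close_fraction Fraction of rows duplicated as a near neighbour
#'   within `spacing` bp.
#' @param spacing Neighbour distance used by `close_fraction`.
#' @return A [snp_candidates()] table.
#' @export
gen_snp_candidates <- function(n, seed = 1, n_scaffolds = max(2, n %/% 5),
                               tri_fraction = 0.05, close_fraction = 0.05,
                               spacing = 50) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  set.seed(seed)
  sc_len <- sort(round(stats::runif(n_scaffolds, 17000, 58000)),
                 decreasing = TRUE)
  sc_id <- paste0("scaffold", seq_len(n_scaffolds))
  pick <- sample.int(n_scaffolds, n, replace = TRUE, prob = sc_len)
  pos <- vapply(pick, function(s) sample.int(sc_len[s], 1L), integer(1))
  nts <- c("A", "C", "G", "T")
  alleles <- lapply(seq_len(n), function(i) sample(nts, 2))
  tri <- stats::runif(n) < tri_fraction
  alleles[tri] <- lapply(alleles[tri], function(a)
    c(a, sample(setdiff(nts, a), 1)))
  maf <- stats::runif(n, 0.01, 0.5)
  qual <- round(stats::runif(n, 30, 999))
  depth <- pmax(3L, stats::rpois(n, 45))
  out <- snp_candidates(sc_id[pick], pos, alleles, maf, qual, depth)
  # plant close neighbours for a controlled fraction of rows
  n_close <- round(close_fraction * n)
  if (n_close > 0) {
    src <- sample.int(n, n_close)
    nb <- out[src, , drop = FALSE]
    nb$position <- pmax(1L, nb$position +
                          sample(c(-spacing:-1, 1:spacing), n_close,
                                 replace = TRUE))
    out <- rbind(out, nb)
    class(out) <- c("snp_candidates", "data.frame")
  }
  rownames(out) <- NULL
  out
}

#' Generate per-field ploidy counts
#'
#' Emulates a field collection with a known true diploid male
#' proportion. Per field, the diploid-male count is binomial given the
#' female count (`Binom(n_females, true_dmp / (1 - true_dmp))`, so that
#' `diploid males / (diploid males + females)` is centred on
#' `true_dmp`); all diploid males are assumed confirmed. The haploid
#' male pool (roughly one per female, a balanced primary sex ratio) is
#' subsampled at `assay_fraction` for the ploidy assay, and a small
#' share of assays fail to an unknown ploidy class.
#'
#' @param n_fields Number of fields.
#' @param true_dmp True diploid male proportion among diploids.
#' @param females_per_field Females per field (scalar or per-field
#'   vector).
#' @param assay_fraction Fraction of haploid males assayed (default 2/3).
#' @param unknown_rate Fraction of assays yielding unknown ploidy.
#' @param seed Integer seed.
#' @return A stacked [ploidy_counts()] data.frame, one row per field.
#' @export
gen_ploidy_counts <- function(n_fields, true_dmp, females_per_field,
                              assay_fraction = 2 / 3, unknown_rate = 0.01,
                              seed = 1) {
  if (any(c(true_dmp, assay_fraction, unknown_rate) < 0) ||
      any(c(true_dmp, assay_fraction, unknown_rate) > 1) || true_dmp >= 1) {
    stop("proportions must be in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  n_fem <- rep_len(females_per_field, n_fields)
  rows <- lapply(seq_len(n_fields), function(f) {
    n_dm <- stats::rbinom(1, n_fem[f], true_dmp / (1 - true_dmp))
    n_males_total <- stats::rbinom(1, 2 * n_fem[f], 0.5)
    n_assayed_h <- stats::rbinom(1, n_males_total, assay_fraction)
    n_unknown <- stats::rbinom(1, n_assayed_h + n_dm, unknown_rate)
    n_unknown <- min(n_unknown, n_assayed_h)   # failures come from haploids
    ploidy_counts(paste0("field", f),
                  n_haploid = n_assayed_h - n_unknown,
                  n_diploid_males = n_dm,
                  n_unknown = n_unknown,
                  n_females = n_fem[f])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ploidy_counts", "data.frame")
  out
}
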