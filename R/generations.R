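#' Multi-generation individual-based haplodiploid CSD simulation
#'
#' Simulates discrete, non-overlapping generations of a haplodiploid
#' population with complementary sex determination and partial sibmating.
#' Each female mates once: with probability `spec$alpha` with a brother
#' drawn uniformly from her sibship's sons (falling back to a random male
#' when she has no brothers), otherwise with a random male of her
#' generation. Unfertilized eggs develop as haploid sons; fertilized eggs
#' homozygous at every sex locus are diploid males and are removed from
#' the breeding pool (they are reproductive dead ends); the remaining
#' diploids are daughters. Unlinked neutral biallelic loci are transmitted
#' by Mendelian haplodiploid inheritance and used to track the inbreeding
#' coefficient.
#'
#' The per-generation \eqn{F_{IS}} at the neutral loci converges in
#' expectation to the sibmating equilibrium
#' \eqn{\alpha/(4 - 3\alpha)} (see [fis_from_sibmating()]).
#'
#' @param spec A [csd_model_spec()].
#' @param n_females Breeding females per generation (>= 10).
#' @param n_generations Number of generations to simulate.
#' @param n_neutral_loci Number of unlinked neutral biallelic loci.
#' @param seed Integer seed (required).
#' @param n_eggs Eggs laid per female.
#' @param fertilization_prob Probability an egg is fertilized.
#' @return A list of class `generation_series`: `series`, a data.frame
#'   with one row per simulated generation (`generation`, `fis`,
#'   `n_sex_alleles_1`, `n_sex_alleles_2`, `dmp`, `n_females`,
#'   `sib_fallbacks`), `extinct` flag, and `final_females`, a list with
#'   the last generation's neutral genotypes (`a1`, `a2` matrices of 1/2
#'   allele codes).
#' @export
simulate_generations <- function(spec, n_females = 500, n_generations = 10,
                                 n_neutral_loci = 50, seed,
                                 n_eggs = 10, fertilization_prob = 0.5) {
  stopifnot(inherits(spec, "csd_model_spec"), n_females >= 10,
            n_generations >= 1, n_neutral_loci >= 1)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  set.seed(seed)
  n_loci <- spec$n_sex_loci
  nall <- c(spec$k, if (n_loci == 2L) spec$l)
  L <- n_neutral_loci

  # Founders: unrelated females (heterozygous at each sex locus) and males.
  fem_sex <- lapply(seq_len(n_loci), function(i) {
    a1 <- sample.int(nall[i], n_females, replace = TRUE)
    shift <- sample.int(nall[i] - 1L, n_females, replace = TRUE)
    cbind(a1, 1L + (a1 - 1L + shift) %% nall[i])
  })
  fem_a1 <- matrix(sample.int(2L, n_females * L, replace = TRUE),
                   n_females, L)
  fem_a2 <- matrix(sample.int(2L, n_females * L, replace = TRUE),
                   n_females, L)
  fem_sib <- seq_len(n_females)      # founders all from distinct sibships
  n_males <- n_females
  male_sex <- lapply(seq_len(n_loci), function(i)
    sample.int(nall[i], n_males, replace = TRUE))
  male_hap <- matrix(sample.int(2L, n_males * L, replace = TRUE), n_males, L)
  male_sib <- rep(0L, n_males)       # founder males: no sibship

  rows <- vector("list", n_generations)
  extinct <- FALSE

  for (gen in seq_len(n_generations)) {
    nf <- nrow(fem_a1)
    # --- choose a mate for each female
    want_sib <- stats::runif(nf) < spec$alpha
    father <- integer(nf)
    sib_fallback <- 0L
    by_sib <- split(seq_along(male_sib), male_sib)
    for (i in seq_len(nf)) {
      if (want_sib[i]) {
        bros <- by_sib[[as.character(fem_sib[i])]]
        if (length(bros) > 0L) {
          father[i] <- bros[sample.int(length(bros), 1L)]
          next
        }
        sib_fallback <- sib_fallback + 1L
      }
      father[i] <- sample.int(length(male_sib), 1L)
    }

    # --- lay eggs (vectorized at the egg level)
    mother <- rep(seq_len(nf), each = n_eggs)
    ne <- length(mother)
    fert <- stats::runif(ne) < fertilization_prob
    # maternal gametes: sex loci
    gam_sex <- lapply(seq_len(n_loci), function(i) {
      pick <- sample.int(2L, ne, replace = TRUE)
      fem_sex[[i]][cbind(mother, pick)]
    })
    # maternal gametes: neutral loci (unlinked, independent choices)
    pick_n <- matrix(stats::runif(ne * L) < 0.5, ne, L)
    gam_neu <- ifelse(pick_n, fem_a1[mother, , drop = FALSE],
                      fem_a2[mother, , drop = FALSE])
    pat <- father[mother]

    # sons: unfertilized eggs carry the maternal gamete only
    son_idx <- which(!fert)
    new_male_sex <- lapply(gam_sex, function(g) g[son_idx])
    new_male_hap <- gam_neu[son_idx, , drop = FALSE]
    new_male_sib <- mother[son_idx]

    # diploids: maternal gamete + paternal haplotype
    dip_idx <- which(fert)
    hom_all <- rep(TRUE, length(dip_idx))
    for (i in seq_len(n_loci)) {
      hom_all <- hom_all &
        gam_sex[[i]][dip_idx] == male_sex[[i]][pat[dip_idx]]
    }
    n_dm <- sum(hom_all)
    dau_idx <- dip_idx[!hom_all]
    dmp <- if (length(dip_idx) > 0L) n_dm / length(dip_idx) else NA_real_

    new_fem_sex <- lapply(seq_len(n_loci), function(i)
      cbind(gam_sex[[i]][dau_idx], male_sex[[i]][pat[dau_idx]]))
    new_fem_a1 <- gam_neu[dau_idx, , drop = FALSE]
    new_fem_a2 <- male_hap[pat[dau_idx], , drop = FALSE]
    new_fem_sib <- mother[dau_idx]

    # --- sample the next breeding generation
    if (length(dau_idx) == 0L || length(son_idx) == 0L) {
      extinct <- TRUE
      rows[[gen]] <- data.frame(
        generation = gen, fis = NA_real_,
        n_sex_alleles_1 = NA_integer_, n_sex_alleles_2 = NA_integer_,
        dmp = dmp, n_females = 0L, sib_fallbacks = sib_fallback)
      rows <- rows[seq_len(gen)]
      break
    }
    keep <- if (length(dau_idx) > n_females) {
      sample.int(length(dau_idx), n_females)
    } else seq_along(dau_idx)
    fem_sex <- lapply(new_fem_sex, function(m) m[keep, , drop = FALSE])
    fem_a1 <- new_fem_a1[keep, , drop = FALSE]
    fem_a2 <- new_fem_a2[keep, , drop = FALSE]
    fem_sib <- new_fem_sib[keep]
    male_sex <- new_male_sex
    male_hap <- new_male_hap
    male_sib <- new_male_sib

    rows[[gen]] <- data.frame(
      generation = gen,
      fis = fis_neutral(fem_a1, fem_a2),
      n_sex_alleles_1 = length(unique(c(fem_sex[[1]], male_sex[[1]]))),
      n_sex_alleles_2 = if (n_loci == 2L) {
        length(unique(c(fem_sex[[2]], male_sex[[2]])))
      } else NA_integer_,
      dmp = dmp,
      n_females = nrow(fem_a1),
      sib_fallbacks = sib_fallback)
  }

  structure(
    list(series = do.call(rbind, rows), extinct = extinct,
         final_females = list(a1 = fem_a1, a2 = fem_a2),
         seed = as.integer(seed)),
    class = "generation_series")
}

# Multilocus F_IS = 1 - sum(Ho)/sum(He) over polymorphic biallelic loci,
# with He the unbiased gene diversity 2n/(2n-1) * 2p(1-p).
fis_neutral <- function(a1, a2) {
  n <- nrow(a1)
  if (n < 2) return(NA_real_)
  ho <- colMeans(a1 != a2)
  p <- (colSums(a1 == 1L) + colSums(a2 == 1L)) / (2 * n)
  he <- 2 * n / (2 * n - 1) * 2 * p * (1 - p)
  poly <- he > 0
  if (!any(poly)) return(NA_real_)
  1 - sum(ho[poly]) / sum(he[poly])
}
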