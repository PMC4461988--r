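#' Exact mating table for a CSD model
#'
#' Enumerates the joint distribution of female genotype class and male
#' match pattern under a mixture of sibmating (probability `spec$alpha`,
#' with the conditional match probabilities 1/2 for single-locus and
#' single-locus-homozygous females and 1/4 for double-heterozygous
#' females) and random mating (equal allele frequencies). Each row carries
#' the probability of that mating type and the fraction of its diploid
#' offspring that develop as males. The table is the brute-force oracle
#' for [dmp_sl()] and [dmp_2l()]: its expected DMP,
#' `sum(probability * dm_fraction) / sum(probability * <any diploids>)`,
#' reduces to the closed forms.
#'
#' @param spec A [csd_model_spec()].
#' @return A data.frame of class `mating_table` with columns
#'   `female_class`, `match_pattern`, `component` (`"sib"`/`"random"`),
#'   `probability`, `dm_fraction`, plus attribute `expected_dmp`.
#' @examples
#' tab <- enumerate_mating_table(csd_model_spec(1, k = 10, alpha = 0))
#' sum(tab$probability[tab$dm_fraction > 0]) # theta = 0.2
#' @export
enumerate_mating_table <- function(spec) {
  stopifnot(inherits(spec, "csd_model_spec"))
  a <- spec$alpha
  rows <- list()
  add <- function(female_class, match_pattern, component, probability,
                  dm_fraction) {
    rows[[length(rows) + 1L]] <<- data.frame(
      female_class = female_class, match_pattern = match_pattern,
      component = component, probability = probability,
      dm_fraction = dm_fraction, stringsAsFactors = FALSE)
  }
  if (spec$n_sex_loci == 1L) {
    theta <- 2 / spec$k
    add("het", "matched",   "sib",    a * 0.5,            0.5)
    add("het", "unmatched", "sib",    a * 0.5,            0)
    add("het", "matched",   "random", (1 - a) * theta,     0.5)
    add("het", "unmatched", "random", (1 - a) * (1 - theta), 0)
  } else {
    k <- spec$k
    l <- spec$l
    fc <- female_class_freqs(k, l)
    # Sibmating component: the stated conditional match probabilities.
    add("het-both", "matched-both", "sib", a * fc$f_het_both * 0.25, 0.25)
    add("het-both", "not-matched-both", "sib",
        a * fc$f_het_both * 0.75, 0)
    add("hom1", "matched", "sib", a * fc$f_hom_locus1 * 0.5, 0.5)
    add("hom1", "unmatched", "sib", a * fc$f_hom_locus1 * 0.5, 0)
    add("hom2", "matched", "sib", a * fc$f_hom_locus2 * 0.5, 0.5)
    add("hom2", "unmatched", "sib", a * fc$f_hom_locus2 * 0.5, 0)
    # Random-mating component: per-locus match probabilities 2/alleles at
    # a heterozygous locus, 1/alleles at a homozygous locus.
    m1h <- 2 / k; m2h <- 2 / l   # matched at a het locus
    m1o <- 1 / k; m2o <- 1 / l   # matched at a hom locus
    r <- 1 - a
    # double-het female: diploid males only when matched at both loci
    add("het-both", "matched-both", "random",
        r * fc$f_het_both * m1h * m2h, 0.25)
    add("het-both", "matched-one", "random",
        r * fc$f_het_both * (m1h * (1 - m2h) + (1 - m1h) * m2h), 0)
    add("het-both", "matched-none", "random",
        r * fc$f_het_both * (1 - m1h) * (1 - m2h), 0)
    # female homozygous at locus 1 (het at locus 2)
    add("hom1", "matched-both", "random",
        r * fc$f_hom_locus1 * m1o * m2h, 0.5)
    add("hom1", "not-matched-both", "random",
        r * fc$f_hom_locus1 * (1 - m1o * m2h), 0)
    add("hom2", "matched-both", "random",
        r * fc$f_hom_locus2 * m1h * m2o, 0.5)
    add("hom2", "not-matched-both", "random",
        r * fc$f_hom_locus2 * (1 - m1h * m2o), 0)
  }
  tab <- do.call(rbind, rows)
  expected <- sum(tab$probability * tab$dm_fraction)
  stopifnot(abs(sum(tab$probability) - 1) < 1e-12)
  attr(tab, "expected_dmp") <- dm_survival_adjust(expected, spec$dm_survival)
  class(tab) <- c("mating_table", "data.frame")
  tab
}

#' Expected diploid male proportion of a mating table
#'
#' @param table A table from [enumerate_mating_table()].
#' @return The expected fraction of diploid offspring that are male.
#' @export
expected_dmp <- function(table) {
  stopifnot(inherits(table, "mating_table"))
  attr(table, "expected_dmp")
}

# ---- explicit genotypes -----------------------------------------------

#' Construct a sex-locus genotype
#'
#' A female carries an unordered allele pair at each sex locus; a male
#' (haploid) carries a single allele per locus. Alleles are integer labels
#' in `1..k` (locus 1) and `1..l` (locus 2). A diploid homozygous at every
#' sex locus develops as a male and is rejected as a female genotype.
#'
#' @param female_alleles For a female: a list with one length-2 integer
#'   vector per locus; `NULL` for a male.
#' @param male_alleles For a male: an integer vector with one allele per
#'   locus; `NULL` for a female.
#' @return An object of class `sex_genotype`.
#' @export
sex_genotype <- function(female_alleles = NULL, male_alleles = NULL) {
  if (is.null(female_alleles) == is.null(male_alleles)) {
    stop("supply exactly one of `female_alleles`, `male_alleles`",
         call. = FALSE)
  }
  if (!is.null(female_alleles)) {
    if (!is.list(female_alleles) ||
        !all(vapply(female_alleles, length, 1L) == 2L)) {
      stop("`female_alleles` must be a list of per-locus allele pairs",
           call. = FALSE)
    }
    if (all(vapply(female_alleles, function(p) p[1] == p[2], logical(1)))) {
      stop("a diploid homozygous at every sex locus is male, not female",
           call. = FALSE)
    }
    structure(list(sex = "female", alleles = lapply(female_alleles, sort)),
              class = "sex_genotype")
  } else {
    structure(list(sex = "male", alleles = as.list(male_alleles)),
              class = "sex_genotype")
  }
}

#' Offspring class distribution of a single mating
#'
#' Unfertilized eggs (probability `1 - fertilization_prob`) develop as
#' haploid males. Fertilized eggs are diploid and develop as males exactly
#' when homozygous at every sex locus, else as females. The probability of
#' sex-locus homozygosity is computed by exact enumeration of maternal
#' gametes against the father's haplotype.
#'
#' @param mother,father [sex_genotype()] objects (female, male).
#' @param fertilization_prob Probability an egg is fertilized, in \[0, 1\].
#' @return Named numeric vector with components `haploid_male`,
#'   `diploid_female`, `diploid_male`, summing to 1.
#' @examples
#' m <- sex_genotype(female_alleles = list(c(1, 2)))
#' f <- sex_genotype(male_alleles = 1)
#' offspring_distribution(m, f, 1) # 50% diploid males
#' @export
offspring_distribution <- function(mother, father, fertilization_prob = 0.5) {
  stopifnot(inherits(mother, "sex_genotype"), mother$sex == "female",
            inherits(father, "sex_genotype"), father$sex == "male")
  if (length(mother$alleles) != length(father$alleles)) {
    stop("parents must have the same number of sex loci", call. = FALSE)
  }
  if (fertilization_prob < 0 || fertilization_prob > 1) {
    stop("`fertilization_prob` must be in [0, 1]", call. = FALSE)
  }
  # P(offspring hom at a locus) = P(maternal gamete equals paternal allele)
  p_hom_all <- prod(vapply(seq_along(mother$alleles), function(i) {
    mean(mother$alleles[[i]] == father$alleles[[i]])
  }, numeric(1)))
  f <- fertilization_prob
  c(haploid_male = 1 - f,
    diploid_female = f * (1 - p_hom_all),
    diploid_male = f * p_hom_all)
}

# ---- Monte-Carlo mating simulation ------------------------------------

# Sample n female genotypes from the viable-female class distribution with
# uniform allele labels. Returns per-locus allele matrices (two columns per
# locus); a homozygous pair encodes a hom-at-that-locus female (2l only).
sample_female_genotypes <- function(n, spec, class_override = NULL) {
  k <- spec$k
  if (spec$n_sex_loci == 1L) {
    a1 <- sample.int(k, n, replace = TRUE)
    shift <- sample.int(k - 1L, n, replace = TRUE)
    a2 <- 1L + (a1 - 1L + shift) %% k   # distinct from a1, uniform
    return(list(loc1 = cbind(a1, a2)))
  }
  l <- spec$l
  fc <- female_class_freqs(k, l)
  cls <- if (is.null(class_override)) {
    sample(c("het-both", "hom1", "hom2"), n, replace = TRUE,
           prob = c(fc$f_het_both, fc$f_hom_locus1, fc$f_hom_locus2))
  } else rep(class_override, n)
  het_pair <- function(n, nall) {
    a1 <- sample.int(nall, n, replace = TRUE)
    shift <- sample.int(nall - 1L, n, replace = TRUE)
    cbind(a1, 1L + (a1 - 1L + shift) %% nall)
  }
  hom_pair <- function(n, nall) {
    a <- sample.int(nall, n, replace = TRUE)
    cbind(a, a)
  }
  loc1 <- het_pair(n, k)
  loc2 <- het_pair(n, l)
  hom1 <- cls == "hom1"
  hom2 <- cls == "hom2"
  if (any(hom1)) loc1[hom1, ] <- hom_pair(sum(hom1), k)
  if (any(hom2)) loc2[hom2, ] <- hom_pair(sum(hom2), l)
  list(loc1 = loc1, loc2 = loc2, class = cls)
}

# Probability that a fertilized egg of (female pair, male allele) is
# homozygous at that locus, vectorized.
p_hom_locus <- function(pair, male) {
  (pair[, 1] == male) / 2 + (pair[, 2] == male) / 2
}

#' Monte-Carlo simulation of CSD matings
#'
#' Simulates `n` matings and reports the realized matched-mating
#' frequency, the expected diploid male proportion among diploid
#' offspring, and the matched frequency among sibmatings.
#'
#' Two sampling schemes are available. `"paper-conditional"` samples the
#' female class and the match event at the model's stated probabilities
#' (1/2 for sibmatings with single-locus or homozygous females, 1/4 for
#' double-heterozygous females; per-locus `2/alleles` and `1/alleles`
#' under random mating) — a Monte-Carlo rendering of
#' [enumerate_mating_table()]. `"pedigree"` builds each sibmating
#' explicitly from a two-generation family (grandmother x grandfather, a
#' viable daughter mated to one of her brothers) and measures the realized
#' match rate, which need not equal the stated conditionals for females
#' whose homozygosity arose from a heterozygous mother.
#'
#' @param spec A [csd_model_spec()]; `spec$alpha` is the sibmating rate.
#' @param n Number of matings to simulate.
#' @param mode `"paper-conditional"` or `"pedigree"`.
#' @param fertilization_prob Probability an egg is fertilized (affects
#'   only the haploid-male share, not DMP among diploids).
#' @param seed Integer seed (required).
#' @param founder_female_class Pedigree mode only: fix the grandmother's
#'   class (`"het-both"`, `"hom1"`, `"hom2"`); `NULL` samples it. Under
#'   single-locus CSD all females are heterozygous.
#' @param founder_male_matched Pedigree mode only: if `FALSE`, condition
#'   the grandfather on being unmatched at every locus; `NULL` leaves him
#'   random.
#' @param detail Pedigree mode only: if `TRUE`, attach a per-mating
#'   data.frame (`detail`) with the founder female's class, the mated
#'   female's own class, `is_sib`, `matched` and the expected diploid
#'   male fraction of each mating.
#' @return A list of class `mating_sim_result`: `n_matings`,
#'   `matched_freq`, `dmp`, `sib_matched_freq`, `seed` (and `detail` when
#'   requested).
#' @export
simulate_matings <- function(spec, n,
                             mode = c("paper-conditional", "pedigree"),
                             fertilization_prob = 0.5, seed,
                             founder_female_class = NULL,
                             founder_male_matched = NULL,
                             detail = FALSE) {
  stopifnot(inherits(spec, "csd_model_spec"), n >= 1)
  mode <- match.arg(mode)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  set.seed(seed)
  a <- spec$alpha
  is_sib <- stats::runif(n) < a

  if (mode == "paper-conditional") {
    tab <- enumerate_mating_table(spec)
    idx <- sample.int(nrow(tab), n, replace = TRUE, prob = tab$probability)
    dm_frac <- tab$dm_fraction[idx]
    matched <- dm_frac > 0
    is_sib <- tab$component[idx] == "sib"
    res <- list(
      n_matings = as.integer(n),
      matched_freq = mean(matched),
      dmp = mean(dm_frac),
      sib_matched_freq = if (any(is_sib)) mean(matched[is_sib]) else NA_real_,
      seed = as.integer(seed))
    class(res) <- "mating_sim_result"
    return(res)
  }

  # pedigree mode: explicit families for sibmatings, random draws otherwise
  n_loci <- spec$n_sex_loci
  nall <- c(spec$k, if (n_loci == 2L) spec$l)
  gm <- sample_female_genotypes(n, spec, class_override = founder_female_class)
  # grandfather haplotype, optionally conditioned on being unmatched
  gf <- lapply(seq_len(n_loci), function(i) {
    pair <- gm[[i]]
    m <- sample.int(nall[i], n, replace = TRUE)
    if (isFALSE(founder_male_matched)) {
      if (nall[i] < 3) {
        stop("an unmatched founder male requires >= 3 alleles per locus",
             call. = FALSE)
      }
      bad <- which(m == pair[, 1] | m == pair[, 2])
      while (length(bad) > 0L) {
        m[bad] <- sample.int(nall[i], length(bad), replace = TRUE)
        bad <- bad[m[bad] == pair[bad, 1] | m[bad] == pair[bad, 2]]
      }
    }
    m
  })

  # Daughter: one maternal allele per locus + the paternal allele, redrawn
  # until viable (not hom at every locus); equivalent to picking a viable
  # daughter uniformly from a large sibship.
  draw_daughter <- function() {
    mat <- lapply(seq_len(n_loci), function(i) {
      pick <- sample.int(2L, n, replace = TRUE)
      gm[[i]][cbind(seq_len(n), pick)]
    })
    mat
  }
  mat <- draw_daughter()
  repeat {
    hom_all <- Reduce(`&`, lapply(seq_len(n_loci),
                                  function(i) mat[[i]] == gf[[i]]))
    if (!any(hom_all)) break
    redo <- which(hom_all)
    for (i in seq_len(n_loci)) {
      pick <- sample.int(2L, length(redo), replace = TRUE)
      mat[[i]][redo] <- gm[[i]][cbind(redo, pick)]
    }
  }
  daughter <- lapply(seq_len(n_loci), function(i) cbind(mat[[i]], gf[[i]]))
  # Brother: a maternal haplotype (haploid, from an unfertilized egg).
  brother <- lapply(seq_len(n_loci), function(i) {
    pick <- sample.int(2L, n, replace = TRUE)
    gm[[i]][cbind(seq_len(n), pick)]
  })
  # Random male for non-sib matings.
  randmale <- lapply(seq_len(n_loci), function(i)
    sample.int(nall[i], n, replace = TRUE))
  male <- lapply(seq_len(n_loci), function(i)
    ifelse(is_sib, brother[[i]], randmale[[i]]))

  p_hom <- Reduce(`*`, lapply(seq_len(n_loci), function(i)
    p_hom_locus(daughter[[i]], male[[i]])))
  matched <- p_hom > 0
  res <- list(
    n_matings = as.integer(n),
    matched_freq = mean(matched),
    dmp = mean(p_hom),
    sib_matched_freq = if (any(is_sib)) mean(matched[is_sib]) else NA_real_,
    seed = as.integer(seed))
  if (detail) {
    hom_at <- vapply(seq_len(n_loci), function(i)
      daughter[[i]][, 1] == daughter[[i]][, 2], logical(n))
    dim(hom_at) <- c(n, n_loci)
    female_class <- if (n_loci == 1L) rep("het", n) else
      ifelse(hom_at[, 1], "hom1", ifelse(hom_at[, 2], "hom2", "het-both"))
    res$detail <- data.frame(
      founder_class = if (n_loci == 1L) rep("het", n) else gm$class,
      female_class = female_class,
      is_sib = is_sib, matched = matched, dm_fraction = p_hom)
  }
  class(res) <- "mating_sim_result"
  res
}

#' @export
print.mating_sim_result <- function(x, ...) {
  cat(sprintf(
    "%d simulated matings (seed %d): matched %.4f, DMP %.4f, sib-matched %s\n",
    x$n_matings, x$seed, x$matched_freq, x$dmp,
    ifelse(is.na(x$sib_matched_freq), "NA",
           sprintf("%.4f", x$sib_matched_freq))))
  invisible(x)
}
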