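#' Model specification for complementary sex determination (CSD)
#'
#' Bundles the parameters of the CSD genetic-load model: the number of
#' independent sex loci (one or two), the number of equally frequent sex
#' alleles segregating at each locus, the sibmating rate \eqn{\alpha}, and
#' the developmental survival of diploid males relative to females.
#'
#' Under CSD, fertilized (diploid) eggs that are homozygous at every sex
#' locus develop as males; heterozygosity at one or more loci gives a
#' female. Diploid males are a genetic load because they are produced at
#' the expense of daughters and typically have near-zero fitness.
#'
#' @param n_sex_loci Number of independent sex loci, 1 or 2.
#' @param k Number of sex alleles at the first locus (>= 2).
#' @param l Number of sex alleles at the second locus (>= 2); ignored when
#'   `n_sex_loci = 1`.
#' @param alpha Sibmating rate in \[0, 1\]: the proportion of matings that
#'   are between full siblings.
#' @param dm_survival Developmental survival of diploid males relative to
#'   females, in \[0, 1\]. The default 1 treats diploid males as fully
#'   viable.
#'
#' @return An object of class `csd_model_spec`.
#' @examples
#' csd_model_spec(2, k = 9, l = 9, alpha = 0.081)
#' @export
csd_model_spec <- function(n_sex_loci = 1, k = 10, l = k, alpha = 0,
                           dm_survival = 1) {
  if (!n_sex_loci %in% c(1L, 2L)) {
    stop("`n_sex_loci` must be 1 or 2", call. = FALSE)
  }
  n_sex_loci <- as.integer(n_sex_loci)
  if (length(k) != 1L || !is.finite(k) || k < 2 || k != round(k)) {
    stop("`k` must be a single integer >= 2", call. = FALSE)
  }
  if (n_sex_loci == 2L &&
      (length(l) != 1L || !is.finite(l) || l < 2 || l != round(l))) {
    stop("`l` must be a single integer >= 2 when `n_sex_loci` is 2",
         call. = FALSE)
  }
  if (length(alpha) != 1L || !is.finite(alpha) || alpha < 0 || alpha > 1) {
    stop("`alpha` must be a proportion in [0, 1]", call. = FALSE)
  }
  if (length(dm_survival) != 1L || !is.finite(dm_survival) ||
      dm_survival < 0 || dm_survival > 1) {
    stop("`dm_survival` must be a proportion in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_sex_loci = n_sex_loci, k = as.integer(k),
         l = if (n_sex_loci == 2L) as.integer(l) else NA_integer_,
         alpha = alpha, dm_survival = dm_survival),
    class = "csd_model_spec"
  )
}

#' @export
print.csd_model_spec <- function(x, ...) {
  loci <- if (x$n_sex_loci == 1L) {
    sprintf("single-locus CSD, k = %d", x$k)
  } else {
    sprintf("two-locus CSD, k = %d, l = %d", x$k, x$l)
  }
  cat(sprintf("CSD model: %s, alpha = %g, diploid male survival = %g\n",
              loci, x$alpha, x$dm_survival))
  invisible(x)
}

#' Sibmating rate from the inbreeding coefficient
#'
#' Converts a within-population inbreeding coefficient \eqn{F_{IS}} into
#' the equilibrium proportion of sibmatings
#' \deqn{\alpha = 4 F_{IS} / (3 F_{IS} + 1).}
#' Negative \eqn{F_{IS}} (heterozygote excess) has no sibmating
#' interpretation and is floored at \eqn{\alpha = 0} with a warning.
#'
#' @param fis Inbreeding coefficient, in (-1/3, 1\].
#' @return Sibmating rate(s) in \[0, 1\].
#' @examples
#' sibmating_from_fis(0.021) # ~0.079
#' @seealso [fis_from_sibmating()] for the inverse.
#' @export
sibmating_from_fis <- function(fis) {
  if (!is.numeric(fis) || any(!is.finite(fis))) {
    stop("`fis` must be finite numeric", call. = FALSE)
  }
  if (any(fis <= -1 / 3)) {
    stop("`fis` must exceed -1/3 (denominator 3*fis + 1 must be positive)",
         call. = FALSE)
  }
  if (any(fis > 1)) stop("`fis` must not exceed 1", call. = FALSE)
  alpha <- 4 * fis / (3 * fis + 1)
  if (any(alpha < 0)) {
    warning("negative F_IS mapped to sibmating rate 0", call. = FALSE)
    alpha <- pmax(alpha, 0)
  }
  pmin(alpha, 1)
}

#' Inbreeding coefficient implied by a sibmating rate
#'
#' Algebraic inverse of [sibmating_from_fis()]:
#' \eqn{F_{IS} = \alpha / (4 - 3\alpha)}. This is the equilibrium
#' inbreeding coefficient of a population in which a proportion
#' \eqn{\alpha} of matings are between full siblings.
#'
#' @param alpha Sibmating rate(s) in \[0, 1\].
#' @return Inbreeding coefficient(s).
#' @export
fis_from_sibmating <- function(alpha) {
  if (!is.numeric(alpha) || any(!is.finite(alpha)) ||
      any(alpha < 0) || any(alpha > 1)) {
    stop("`alpha` must be in [0, 1]", call. = FALSE)
  }
  alpha / (4 - 3 * alpha)
}

#' Female genotype-class frequencies under two-locus CSD
#'
#' With `k` equally frequent sex alleles at the first locus and `l` at the
#' second, random union of gametes produces diploids heterozygous at both
#' loci, homozygous at exactly one, or homozygous at both; the last class
#' develops as males. The returned frequencies are conditioned on female
#' viability (division by \eqn{1 - 1/(kl)}), so they sum to 1 among
#' females.
#'
#' @param k,l Number of sex alleles at each locus (>= 2).
#' @return A list with components `f_het_both`, `f_hom_locus1`,
#'   `f_hom_locus2`.
#' @examples
#' female_class_freqs(9, 9)$f_het_both # 0.8
#' @export
female_class_freqs <- function(k, l) {
  if (any(c(k, l) < 2) || any(c(k, l) != round(c(k, l)))) {
    stop("`k` and `l` must be integers >= 2", call. = FALSE)
  }
  viable <- 1 - 1 / (k * l)
  list(
    f_het_both  = (1 - 1 / k) * (1 - 1 / l) / viable,
    f_hom_locus1 = (1 / k) * (1 - 1 / l) / viable,
    f_hom_locus2 = (1 - 1 / k) * (1 / l) / viable
  )
}

#' Matched-mating frequencies under random mating
#'
#' A mating is "matched" when the male's sex allele(s) also occur in the
#' female's genotype, so that some diploid offspring are homozygous at
#' every sex locus and develop as males. Under random mating with equally
#' frequent alleles, a male matches a heterozygous locus with probability
#' `2/alleles` and a homozygous locus with probability `1/alleles`.
#'
#' For single-locus CSD the overall matched frequency is \eqn{\theta =
#' 2/k}. For two-locus CSD, `p_het` is the frequency of matings matched at
#' both loci with a double-heterozygous female and `p_hom` the frequency
#' of matched matings with a female homozygous at one locus;
#' `theta = p_het + p_hom`.
#'
#' @param spec A [csd_model_spec()].
#' @return A list with components `theta`, `p_het`, `p_hom`.
#' @examples
#' matched_mating_freqs(csd_model_spec(1, k = 10))$theta # 0.2
#' @export
matched_mating_freqs <- function(spec) {
  stopifnot(inherits(spec, "csd_model_spec"))
  if (spec$n_sex_loci == 1L) {
    theta <- 2 / spec$k
    return(list(theta = theta, p_het = theta, p_hom = 0))
  }
  k <- spec$k
  l <- spec$l
  fc <- female_class_freqs(k, l)
  p_het <- fc$f_het_both * (2 / k) * (2 / l)
  p_hom <- fc$f_hom_locus1 * (1 / k) * (2 / l) +
    fc$f_hom_locus2 * (2 / k) * (1 / l)
  list(theta = p_het + p_hom, p_het = p_het, p_hom = p_hom)
}

# Renormalize a conceived diploid-male fraction m for relative survival s:
# among surviving diploids the male share is s*m / (s*m + (1 - m)).
dm_survival_adjust <- function(m, s) {
  if (s == 1) return(m)
  s * m / (s * m + (1 - m))
}

#' Predicted diploid male proportion under single-locus CSD
#'
#' The proportion of diploids that are male (DMP) when a fraction
#' \eqn{\alpha} of matings are sibmatings and `k` equally frequent sex
#' alleles segregate at a single sex locus:
#' \deqn{DMP = 0.25\,\alpha + (1 - \alpha)/k.}
#' Half of sibmatings are matched, and matched matings yield 50\% diploid
#' males; random matings are matched with probability \eqn{2/k}.
#'
#' @param alpha Sibmating rate in \[0, 1\].
#' @param k Number of sex alleles (>= 2).
#' @param dm_survival Relative developmental survival of diploid males;
#'   values below 1 renormalize the male share among surviving diploids.
#' @return Predicted DMP.
#' @examples
#' dmp_sl(0.081, 100) # ~0.029, prints as 0.03
#' @export
dmp_sl <- function(alpha, k, dm_survival = 1) {
  if (any(alpha < 0) || any(alpha > 1)) {
    stop("`alpha` must be in [0, 1]", call. = FALSE)
  }
  if (any(k < 2)) stop("`k` must be >= 2", call. = FALSE)
  base <- 0.25 * alpha + (1 - alpha) / k
  dm_survival_adjust(base, dm_survival)
}

#' Predicted diploid male proportion under two-locus CSD
#'
#' With two independent sex loci, diploid males require homozygosity at
#' both loci. Writing \eqn{f_{HET}} for the frequency of females
#' heterozygous at both loci and \eqn{p_{HET}}, \eqn{p_{HOM}} for the
#' random-mating matched-mating frequencies (see
#' [matched_mating_freqs()]),
#' \deqn{DMP = 0.0625\,\alpha f_{HET} + 0.25\,\alpha (1 - f_{HET})
#'   + 0.25 (1 - \alpha) p_{HET} + 0.5 (1 - \alpha) p_{HOM}.}
#' Sibmatings with double-heterozygous females are matched at both loci a
#' quarter of the time and then yield 25\% diploid males; sibmatings with
#' single-locus-homozygous females behave like single-locus CSD.
#'
#' @inheritParams dmp_sl
#' @param l Number of sex alleles at the second locus (>= 2).
#' @return Predicted DMP.
#' @examples
#' dmp_2l(0.081, 9, 9) # ~0.0194
#' @export
dmp_2l <- function(alpha, k, l = k, dm_survival = 1) {
  if (any(alpha < 0) || any(alpha > 1)) {
    stop("`alpha` must be in [0, 1]", call. = FALSE)
  }
  if (any(c(k, l) < 2)) stop("`k` and `l` must be >= 2", call. = FALSE)
  fc <- female_class_freqs(k, l)
  mm <- matched_mating_freqs(csd_model_spec(2, k = k, l = l))
  base <- 0.0625 * alpha * fc$f_het_both +
    0.25 * alpha * (1 - fc$f_het_both) +
    0.25 * (1 - alpha) * mm$p_het +
    0.5 * (1 - alpha) * mm$p_hom
  dm_survival_adjust(base, dm_survival)
}

# Dispatch on the spec's locus count.
dmp_predict <- function(alpha, spec) {
  if (spec$n_sex_loci == 1L) {
    dmp_sl(alpha, spec$k, spec$dm_survival)
  } else {
    dmp_2l(alpha, spec$k, spec$l, spec$dm_survival)
  }
}

#' Prediction band for the diploid male proportion over a sibmating range
#'
#' Evaluates the DMP prediction at the endpoints of a sibmating-rate
#' interval (for example the 95\% confidence bounds on \eqn{\alpha}
#' estimated from field \eqn{F_{IS}}). With full diploid-male survival the
#' prediction is affine in \eqn{\alpha}, so the interval endpoints bound
#' the prediction over the whole range.
#'
#' @param alpha_low,alpha_high Sibmating interval endpoints,
#'   `0 <= alpha_low <= alpha_high <= 1`.
#' @param spec A [csd_model_spec()]; its own `alpha` gives the point
#'   prediction.
#' @return A list of class `dmp_prediction` with elements `spec`, `dmp`
#'   (prediction at `spec$alpha`), `band_low`, `band_high`.
#' @export
dmp_band <- function(alpha_low, alpha_high, spec) {
  stopifnot(inherits(spec, "csd_model_spec"))
  if (alpha_low < 0 || alpha_high > 1 || alpha_low > alpha_high) {
    stop("need 0 <= alpha_low <= alpha_high <= 1", call. = FALSE)
  }
  ends <- sort(c(dmp_predict(alpha_low, spec), dmp_predict(alpha_high, spec)))
  structure(
    list(spec = spec, dmp = dmp_predict(spec$alpha, spec),
         band_low = ends[1], band_high = ends[2]),
    class = "dmp_prediction"
  )
}

#' Sex-allele numbers consistent with an observed diploid male proportion
#'
#' For each candidate allele number `k` (with `l = k` under two-locus
#' CSD), computes the DMP prediction band over a sibmating interval and
#' returns the `k` whose band contains the observed DMP (inclusive
#' containment at the band endpoints).
#'
#' @param dmp_obs Observed diploid male proportion.
#' @param alpha_low,alpha_high Sibmating interval endpoints.
#' @param k_values Candidate allele numbers, each >= 2. Default `3:100`.
#' @param spec_template A [csd_model_spec()] supplying the model (number
#'   of sex loci, survival); its `k`/`l` are overridden per candidate.
#' @return Integer vector of consistent allele numbers (possibly empty).
#' @examples
#' consistent_allele_range(0.014, 0, 0.151,
#'                         spec_template = csd_model_spec(2, k = 3, l = 3))
#' @export
consistent_allele_range <- function(dmp_obs, alpha_low, alpha_high,
                                    k_values = 3:100,
                                    spec_template = csd_model_spec(2, k = 3,
                                                                   l = 3)) {
  if (length(k_values) == 0L) stop("`k_values` must be nonempty",
                                   call. = FALSE)
  if (any(k_values < 2)) stop("all `k_values` must be >= 2", call. = FALSE)
  keep <- vapply(k_values, function(k) {
    spec <- csd_model_spec(spec_template$n_sex_loci, k = k, l = k,
                           alpha = spec_template$alpha,
                           dm_survival = spec_template$dm_survival)
    b <- dmp_band(alpha_low, alpha_high, spec)
    dmp_obs >= b$band_low && dmp_obs <= b$band_high
  }, logical(1))
  as.integer(k_values[keep])
}

#' Minimum sex-allele number reaching an observed diploid male proportion
#'
#' Smallest `k` (with `l = k` for the two-locus model) whose predicted DMP
#' at sibmating rate `alpha` does not exceed `dmp_obs`, or `NA` if no
#' `k <= k_max` suffices. Under single-locus CSD the sibmating term
#' `0.25 * alpha` is a floor that no allele diversity can undercut.
#'
#' @param dmp_obs Observed diploid male proportion.
#' @param alpha Sibmating rate.
#' @param model 1 (single-locus) or 2 (two-locus CSD).
#' @param k_max Largest allele number to consider.
#' @return Integer, or `NA_integer_` when unattainable.
#' @examples
#' min_alleles_required(0.014, alpha = 0, model = 1) # 72
#' @export
min_alleles_required <- function(dmp_obs, alpha, model = 1, k_max = 1000L) {
  if (k_max < 2) stop("`k_max` must be >= 2", call. = FALSE)
  spec1 <- csd_model_spec(model, k = 2, l = 2, alpha = alpha)
  # DMP is non-increasing in k, so scan upward and stop at the first hit.
  for (k in 2:k_max) {
    spec <- csd_model_spec(model, k = k, l = k, alpha = alpha)
    if (dmp_predict(alpha, spec) <= dmp_obs) return(as.integer(k))
  }
  NA_integer_
}
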