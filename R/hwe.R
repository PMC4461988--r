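# Log-probability (up to an additive constant in the allele counts) of a
# genotype count table under the exact Hardy-Weinberg null conditional on
# allele counts: log P = const + h*log(2) - sum(log(n_ij!)), where h is
# the number of heterozygous individuals.
hwe_log_weight <- function(tab_het, tab_counts) {
  tab_het * log(2) - sum(lgamma(tab_counts + 1))
}

# Full enumeration of biallelic genotype tables with fixed allele counts.
# Returns the exact conditional p-value: the summed probability of all
# tables no more probable than the observed one.
hwe_exact_biallelic <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  m_a <- 2 * n_aa + n_ab
  obs <- hwe_log_weight(n_ab, c(n_aa, n_ab, n_bb))
  # enumerate over the count of A-homozygotes
  naa_min <- max(0, m_a - n)
  naa_max <- floor(m_a / 2)
  lw <- vapply(naa_min:naa_max, function(aa) {
    ab <- m_a - 2 * aa
    bb <- n - aa - ab
    if (bb < 0) return(-Inf)
    hwe_log_weight(ab, c(aa, ab, bb))
  }, numeric(1))
  w <- exp(lw - max(lw))
  p <- sum(w[lw <= obs + 1e-9]) / sum(w)
  min(p, 1)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Tests a single locus for deviation from Hardy-Weinberg genotype
#' proportions, conditioning on the observed allele counts. The p-value
#' is the total conditional probability of all genotype tables no more
#' probable than the observed table.
#'
#' For biallelic loci the null distribution is enumerated exactly
#' (`method = "exact"`). For loci with more alleles, or on request, a
#' Markov chain over genotype tables is run (`method = "mcmc"`): the
#' state is the pairing of the `2n` observed gene copies into genotypes,
#' each step proposes swapping one allele between two randomly chosen
#' individuals (a move whose stationary distribution is uniform over
#' pairings, hence the exact conditional null over tables), and the
#' p-value is the post-dememorization fraction of states no more
#' probable than the observed table.
#'
#' @param calls A two-column matrix (or data.frame) of allele codes, one
#'   row per individual; rows with `NA` are dropped.
#' @param method `"auto"` (exact when biallelic, else MCMC), `"exact"`,
#'   or `"mcmc"`.
#' @param chain_steps,dememorization Markov-chain lengths (defaults:
#'   1e6 steps after 1e5 dememorization steps).
#' @param seed Integer seed for the chain.
#' @return A list of class `hwe_test`: `p_value`, `method`, `n`,
#'   `n_alleles`, `monomorphic`.
#' @examples
#' hwe_test(cbind(c(1, 2), c(1, 2)))$p_value # 1/3
#' @export
hwe_test <- function(calls, method = c("auto", "exact", "mcmc"),
                     chain_steps = 1e6, dememorization = 1e5, seed = 1) {
  method <- match.arg(method)
  calls <- as.matrix(calls)
  stopifnot(ncol(calls) == 2)
  calls <- calls[stats::complete.cases(calls), , drop = FALSE]
  n <- nrow(calls)
  codes <- sort(unique(as.vector(calls)))
  if (length(codes) < 2) {
    return(structure(list(p_value = NA_real_, method = "none", n = n,
                          n_alleles = length(codes), monomorphic = TRUE),
                     class = "hwe_test"))
  }
  if (method == "auto") {
    method <- if (length(codes) == 2) "exact" else "mcmc"
  }
  if (method == "exact") {
    if (length(codes) != 2) {
      stop("exact enumeration implemented for biallelic loci; use mcmc",
           call. = FALSE)
    }
    a <- codes[1]
    n_aa <- sum(calls[, 1] == a & calls[, 2] == a)
    n_ab <- sum(calls[, 1] != calls[, 2])
    n_bb <- n - n_aa - n_ab
    p <- hwe_exact_biallelic(n_aa, n_ab, n_bb)
  } else {
    p <- hwe_mcmc(calls, codes, chain_steps, dememorization, seed)
  }
  structure(list(p_value = p, method = method, n = n,
                 n_alleles = length(codes), monomorphic = FALSE),
            class = "hwe_test")
}

# Transposition Markov chain over allele pairings; see hwe_test().
hwe_mcmc <- function(calls, codes, chain_steps, dememorization, seed) {
  set.seed(seed)
  n <- nrow(calls)
  k <- length(codes)
  idx <- matrix(match(calls, codes), ncol = 2)
  # genotype count table (upper triangle, i <= j)
  tab <- matrix(0L, k, k)
  for (i in seq_len(n)) {
    a <- sort(idx[i, ])
    tab[a[1], a[2]] <- tab[a[1], a[2]] + 1L
  }
  het <- sum(idx[, 1] != idx[, 2])
  logw <- function(tab, het) het * log(2) - sum(lgamma(tab + 1))
  cur <- logw(tab, het)
  obs <- cur
  pairs <- t(apply(idx, 1, sort))
  total <- dememorization + chain_steps
  # pre-draw the random choices to keep the loop light
  pick1 <- sample.int(n, total, replace = TRUE)
  pick2 <- sample.int(n, total, replace = TRUE)
  side1 <- sample.int(2L, total, replace = TRUE)
  side2 <- sample.int(2L, total, replace = TRUE)
  hits <- 0L
  kept <- 0L
  for (s in seq_len(total)) {
    i <- pick1[s]; j <- pick2[s]
    if (i != j) {
      ai <- pairs[i, side1[s]]
      aj <- pairs[j, side2[s]]
      if (ai != aj) {
        # remove old genotypes, insert swapped ones
        gi <- pairs[i, ]; gj <- pairs[j, ]
        tab[gi[1], gi[2]] <- tab[gi[1], gi[2]] - 1L
        tab[gj[1], gj[2]] <- tab[gj[1], gj[2]] - 1L
        het <- het - (gi[1] != gi[2]) - (gj[1] != gj[2])
        ni <- sort(c(pairs[i, 3 - side1[s]], aj))
        nj <- sort(c(pairs[j, 3 - side2[s]], ai))
        tab[ni[1], ni[2]] <- tab[ni[1], ni[2]] + 1L
        tab[nj[1], nj[2]] <- tab[nj[1], nj[2]] + 1L
        het <- het + (ni[1] != ni[2]) + (nj[1] != nj[2])
        pairs[i, ] <- ni
        pairs[j, ] <- nj
        cur <- logw(tab, het)
      }
    }
    if (s > dememorization) {
      kept <- kept + 1L
      if (cur <= obs + 1e-9) hits <- hits + 1L
    }
  }
  hits / kept
}
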