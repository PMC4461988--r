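# Two-locus unphased genotypes are aggregated into distinct genotype
# patterns with multiplicities before any likelihood work: for biallelic
# loci there are at most 9 patterns, so EM and the LRT cost does not grow
# with sample size.
ld_aggregate <- function(geno, ka, kb) {
  key <- ((geno[, 1] - 1) * ka + (geno[, 2] - 1)) * kb * kb +
    (geno[, 3] - 1) * kb + geno[, 4]
  tab <- table(key)
  keys <- as.numeric(names(tab))
  b2 <- (keys - 1) %% kb + 1
  rest <- (keys - 1 - (b2 - 1)) / kb
  b1 <- rest %% kb + 1
  rest <- (rest - (b1 - 1)) / kb
  a2 <- rest %% ka + 1
  a1 <- (rest - (a2 - 1)) / ka + 1
  list(pat = cbind(a1, a2, b1, b2), w = as.numeric(tab))
}

# Log-likelihood of aggregated genotype patterns given haplotype
# frequencies h (alleles_A x alleles_B). Each pattern's probability sums
# its (at most two) phase resolutions with HWE multiplicities.
ld_loglik <- function(agg, h) {
  pat <- agg$pat
  dhet <- pat[, 1] != pat[, 2] & pat[, 3] != pat[, 4]
  p <- h[cbind(pat[, 1], pat[, 3])] * h[cbind(pat[, 2], pat[, 4])]
  p2 <- h[cbind(pat[, 1], pat[, 4])] * h[cbind(pat[, 2], pat[, 3])]
  single_het <- !dhet & (pat[, 1] != pat[, 2] | pat[, 3] != pat[, 4])
  prob <- ifelse(dhet, 2 * p + 2 * p2, ifelse(single_het, 2 * p, p))
  sum(agg$w * log(pmax(prob, 1e-300)))
}

# EM for two-locus haplotype frequencies; only double heterozygotes are
# phase-ambiguous.
ld_em <- function(agg, ka, kb, h0, max_iter = 200, tol = 1e-10) {
  pat <- agg$pat
  w <- agg$w
  dhet <- pat[, 1] != pat[, 2] & pat[, 3] != pat[, 4]
  h <- h0
  ll_old <- -Inf
  ll <- -Inf
  converged <- FALSE
  i11 <- cbind(pat[, 1], pat[, 3]); i22 <- cbind(pat[, 2], pat[, 4])
  i12 <- cbind(pat[, 1], pat[, 4]); i21 <- cbind(pat[, 2], pat[, 3])
  for (it in seq_len(max_iter)) {
    wa <- h[i11] * h[i22]
    wb <- h[i12] * h[i21]
    tot <- wa + wb
    fix <- dhet & tot <= 0
    wa[fix] <- wb[fix] <- 0.5
    tot[fix] <- 1
    r <- ifelse(dhet, wa / tot, 1)
    cnt <- matrix(0, ka, kb)
    add <- function(idx, val) {
      for (q in seq_along(val)) {
        cnt[idx[q, 1], idx[q, 2]] <<- cnt[idx[q, 1], idx[q, 2]] + val[q]
      }
    }
    add(i11, w * r)
    add(i22, w * r)
    add(i12, w * (1 - r))
    add(i21, w * (1 - r))
    h <- cnt / sum(cnt)
    ll <- ld_loglik(agg, h)
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  list(h = h, loglik = ll, converged = converged)
}

ld_lrt_stat <- function(agg, ka, kb, em_starts) {
  n2 <- 2 * sum(agg$w)
  pa <- (colSums(agg$w * (outer(agg$pat[, 1], seq_len(ka), "==") +
                            outer(agg$pat[, 2], seq_len(ka), "==")))) / n2
  pb <- (colSums(agg$w * (outer(agg$pat[, 3], seq_len(kb), "==") +
                            outer(agg$pat[, 4], seq_len(kb), "==")))) / n2
  h_indep <- outer(pa, pb)
  ll0 <- ld_loglik(agg, h_indep)
  best <- list(loglik = -Inf, converged = FALSE)
  starts <- c(list(h_indep), lapply(seq_len(max(em_starts - 1, 0)),
                                    function(s) {
    h <- matrix(stats::rexp(ka * kb), ka, kb)
    h / sum(h)
  }))
  for (h0 in starts) {
    fit <- ld_em(agg, ka, kb, h0)
    if (fit$loglik > best$loglik) best <- fit
  }
  list(lrt = max(2 * (best$loglik - ll0), 0), converged = best$converged)
}

#' Likelihood-ratio test of linkage disequilibrium for unphased genotypes
#'
#' Estimates two-locus haplotype frequencies by
#' expectation-maximization (phase is unknown; only double heterozygotes
#' are ambiguous) and compares the maximized likelihood with the
#' likelihood under linkage equilibrium (haplotype frequencies equal to
#' the product of single-locus allele frequencies). Significance is
#' assessed by permuting one locus's genotypes across individuals, which
#' preserves both single-locus genotype distributions while breaking any
#' association; the p-value is `(exceedances + 1) / (n_permutations + 1)`.
#'
#' @param calls_a,calls_b Two-column matrices of allele codes for the two
#'   loci (one row per individual); individuals missing at either locus
#'   are dropped.
#' @param n_permutations Number of permutations.
#' @param em_starts Number of EM initializations (the linkage-equilibrium
#'   start plus `em_starts - 1` random starts); the best likelihood wins.
#' @param seed Integer seed.
#' @return A list of class `ld_test`: `lrt`, `p_value`, `n`,
#'   `em_converged`.
#' @export
ld_test <- function(calls_a, calls_b, n_permutations = 1000, em_starts = 5,
                    seed = 1) {
  calls_a <- as.matrix(calls_a)
  calls_b <- as.matrix(calls_b)
  ok <- stats::complete.cases(calls_a) & stats::complete.cases(calls_b)
  calls_a <- calls_a[ok, , drop = FALSE]
  calls_b <- calls_b[ok, , drop = FALSE]
  codes_a <- sort(unique(as.vector(calls_a)))
  codes_b <- sort(unique(as.vector(calls_b)))
  if (length(codes_a) < 2 || length(codes_b) < 2) {
    stop("both loci must be polymorphic", call. = FALSE)
  }
  ka <- length(codes_a)
  kb <- length(codes_b)
  # order alleles within each locus so pattern keys are canonical
  ga <- t(apply(matrix(match(calls_a, codes_a), ncol = 2), 1, sort))
  gb <- t(apply(matrix(match(calls_b, codes_b), ncol = 2), 1, sort))
  geno <- cbind(ga, gb)
  set.seed(seed)
  obs <- ld_lrt_stat(ld_aggregate(geno, ka, kb), ka, kb, em_starts)
  exceed <- 0L
  if (n_permutations > 0) {
    n <- nrow(geno)
    for (p in seq_len(n_permutations)) {
      perm <- geno
      perm[, 3:4] <- perm[sample.int(n), 3:4, drop = FALSE]
      st <- ld_lrt_stat(ld_aggregate(perm, ka, kb), ka, kb, em_starts)
      if (st$lrt >= obs$lrt - 1e-9) exceed <- exceed + 1L
    }
  }
  structure(
    list(lrt = obs$lrt,
         p_value = if (n_permutations > 0) {
           (exceed + 1) / (n_permutations + 1)
         } else NA_real_,
         n = nrow(geno), em_converged = obs$converged),
    class = "ld_test")
}
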