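# Weir-Cockerham (1984) variance components per locus, summed over
# alleles. `pop` assigns individuals to groups; populations with fewer
# than 2 genotyped individuals at a locus are dropped for that locus.
# Returns per-locus vectors a (among populations), b (among individuals
# within populations), c (within individuals).
wc_components <- function(a1, a2, pop) {
  pop <- as.factor(pop)
  pops <- levels(pop)
  r_max <- length(pops)
  L <- ncol(a1)
  codes <- sort(unique(c(a1[!is.na(a1)], a2[!is.na(a2)])))
  ni <- matrix(0, r_max, L)
  p_arr <- h_arr <- array(0, c(length(codes), r_max, L))
  for (ip in seq_len(r_max)) {
    rows <- which(pop == pops[ip])
    s1 <- a1[rows, , drop = FALSE]
    s2 <- a2[rows, , drop = FALSE]
    ni[ip, ] <- colSums(!is.na(s1))
    het <- !is.na(s1) & s1 != s2
    for (ci in seq_along(codes)) {
      code <- codes[ci]
      cnt <- colSums(s1 == code, na.rm = TRUE) +
        colSums(s2 == code, na.rm = TRUE)
      ok <- ni[ip, ] > 0
      p_arr[ci, ip, ok] <- cnt[ok] / (2 * ni[ip, ok])
      h_arr[ci, ip, ok] <- colSums(het & (s1 == code | s2 == code))[ok] /
        ni[ip, ok]
    }
  }
  use <- ni >= 2
  r <- colSums(use)
  ni_u <- ni * use
  n_tot <- colSums(ni_u)
  nbar <- n_tot / pmax(r, 1)
  nc <- ifelse(r > 1, (n_tot - colSums(ni_u^2) / n_tot) / (r - 1), NA_real_)
  A <- B <- C <- numeric(L)
  for (ci in seq_along(codes)) {
    p <- p_arr[ci, , , drop = FALSE]
    dim(p) <- c(r_max, L)
    h <- h_arr[ci, , , drop = FALSE]
    dim(h) <- c(r_max, L)
    pbar <- colSums(ni_u * p) / n_tot
    hbar <- colSums(ni_u * h) / n_tot
    s2 <- ifelse(r > 1,
                 colSums(ni_u * sweep(p, 2, pbar)^2) / ((r - 1) * nbar),
                 0)
    inner <- pbar * (1 - pbar) - ifelse(r > 1, (r - 1) / r, 0) * s2
    a <- ifelse(r > 1,
                (nbar / nc) * (s2 - (inner - hbar / 4) / (nbar - 1)),
                0)
    b <- (nbar / (nbar - 1)) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
    c_ <- hbar / 2
    A <- A + ifelse(is.finite(a), a, 0)
    B <- B + ifelse(is.finite(b), b, 0)
    C <- C + c_
  }
  list(a = A, b = B, c = C, r = r)
}

fstat_ratios <- function(comp, loci = seq_along(comp$a)) {
  A <- sum(comp$a[loci])
  B <- sum(comp$b[loci])
  C <- sum(comp$c[loci])
  c(f_is = 1 - C / (B + C),
    f_st = A / (A + B + C),
    f_it = 1 - C / (A + B + C))
}

#' Global Weir-Cockerham F-statistics with bootstrap confidence intervals
#'
#' Multilocus \eqn{F_{IS}}, \eqn{F_{ST}} and \eqn{F_{IT}} from
#' Weir-Cockerham variance components summed over alleles and loci, with
#' percentile bootstrap confidence intervals obtained by resampling loci.
#' The combined estimates satisfy
#' \eqn{(1 - F_{IT}) = (1 - F_{IS})(1 - F_{ST})} by construction.
#'
#' @param gm A [genotype_matrix()].
#' @param grouping Field labels per individual; defaults to `gm$field`.
#'   Pass a single-level grouping (or a one-field matrix) to estimate
#'   \eqn{F_{IS}} only.
#' @param n_bootstrap Bootstrap replicates over loci (0 disables CIs).
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level.
#' @return A list of class `fstat_result`: `f_is`, `f_st`, `f_it`, their
#'   `ci` (matrix), per-locus `components`, and `n_bootstrap`. In
#'   single-group mode `f_st`/`f_it` are `NA`.
#' @export
global_fstats <- function(gm, grouping = gm$field, n_bootstrap = 1000,
                          seed = 1, conf = 0.95) {
  stopifnot(inherits(gm, "genotype_matrix"))
  single <- length(unique(grouping)) < 2
  comp <- wc_components(gm$a1, gm$a2, grouping)
  est <- fstat_ratios(comp)
  if (single) est[c("f_st", "f_it")] <- NA_real_
  ci <- NULL
  if (n_bootstrap > 0) {
    set.seed(seed)
    L <- length(comp$a)
    boot <- t(vapply(seq_len(n_bootstrap), function(b) {
      fstat_ratios(comp, sample.int(L, L, replace = TRUE))
    }, numeric(3)))
    alpha <- (1 - conf) / 2
    ci <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE)
  }
  structure(
    list(f_is = unname(est["f_is"]), f_st = unname(est["f_st"]),
         f_it = unname(est["f_it"]), ci = ci,
         components = data.frame(locus = gm$locus_ids, a = comp$a,
                                 b = comp$b, c = comp$c),
         n_bootstrap = n_bootstrap, single_group = single),
    class = "fstat_result")
}

#' @export
print.fstat_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham F-statistics (%d loci):\n",
              nrow(x$components)))
  cat(sprintf("  F_IS = %.4f  F_ST = %.4f  F_IT = %.4f\n",
              x$f_is, x$f_st, x$f_it))
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% CI (bootstrap over loci, %d reps): F_IS [%.4f, %.4f]",
                x$n_bootstrap, x$ci[1, "f_is"], x$ci[2, "f_is"]))
    if (!x$single_group) {
      cat(sprintf(", F_ST [%.4f, %.4f]", x$ci[1, "f_st"], x$ci[2, "f_st"]))
    }
    cat("\n")
  }
  invisible(x)
}

#' Per-field inbreeding coefficients
#'
#' Weir-Cockerham within-population \eqn{F_{IS}} computed separately for
#' each field.
#'
#' @param gm A [genotype_matrix()].
#' @return A data.frame with columns `field`, `n`, `f_is`.
#' @export
fis_per_field <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  fields <- sort(unique(gm$field))
  data.frame(
    field = fields,
    n = vapply(fields, function(f) sum(gm$field == f), integer(1)),
    f_is = vapply(fields, function(f) {
      sub <- subset_genotypes(gm, individuals = gm$field == f)
      global_fstats(sub, grouping = rep("one", nrow(sub$a1)),
                    n_bootstrap = 0)$f_is
    }, numeric(1)),
    row.names = NULL)
}

#' Pairwise F_ST between fields with permutation tests
#'
#' Weir-Cockerham \eqn{\theta} for every pair of fields. Significance is
#' assessed by permuting individuals between the two fields; the p-value
#' is `(exceedances + 1) / (n_permutations + 1)` for the one-sided test
#' of differentiation.
#'
#' @param gm A [genotype_matrix()].
#' @param n_permutations Permutations per pair (0 disables testing).
#' @param seed Integer seed.
#' @return A list of class `pairwise_fst`: `fst` (symmetric matrix),
#'   `p_value` (matrix, `NA` on the diagonal), `n_permutations`.
#' @export
pairwise_fst <- function(gm, n_permutations = 999, seed = 1) {
  stopifnot(inherits(gm, "genotype_matrix"))
  fields <- sort(unique(gm$field))
  nf <- length(fields)
  if (nf < 2) stop("need at least 2 fields", call. = FALSE)
  fst <- matrix(NA_real_, nf, nf, dimnames = list(fields, fields))
  pv <- fst
  set.seed(seed)
  for (i in seq_len(nf - 1)) {
    for (j in (i + 1):nf) {
      rows <- which(gm$field %in% fields[c(i, j)])
      a1 <- gm$a1[rows, , drop = FALSE]
      a2 <- gm$a2[rows, , drop = FALSE]
      lab <- gm$field[rows]
      obs <- fstat_ratios(wc_components(a1, a2, lab))["f_st"]
      fst[i, j] <- fst[j, i] <- obs
      if (n_permutations > 0) {
        exceed <- 0L
        for (p in seq_len(n_permutations)) {
          perm <- sample(lab)
          th <- fstat_ratios(wc_components(a1, a2, perm))["f_st"]
          if (!is.na(th) && th >= obs) exceed <- exceed + 1L
        }
        pv[i, j] <- pv[j, i] <- (exceed + 1) / (n_permutations + 1)
      }
    }
  }
  structure(list(fst = fst, p_value = pv,
                 n_permutations = n_permutations),
            class = "pairwise_fst")
}

#' @export
print.pairwise_fst <- function(x, ...) {
  m <- x$fst
  m[upper.tri(m)] <- x$p_value[upper.tri(m)]
  cat("Pairwise F_ST (below diagonal) and permutation p-values (above):\n")
  print(round(m, 4))
  invisible(x)
}
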