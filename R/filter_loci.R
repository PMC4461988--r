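#' Sequential Bonferroni (Holm) correction
#'
#' Sorts the p-values ascending and compares the i-th smallest against
#' `alpha / (m - i + 1)`, stopping at the first failure; all later tests
#' are retained as non-significant. Rejection flags are returned in the
#' original input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param alpha Familywise significance level.
#' @return Logical vector of rejections, aligned with `p_values`.
#' @examples
#' sequential_bonferroni(c(0.001, 0.02, 0.03), 0.05) # all TRUE
#' @export
sequential_bonferroni <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L) return(logical(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  m <- length(p_values)
  ord <- order(p_values)
  reject <- logical(m)
  for (i in seq_len(m)) {
    p <- p_values[ord[i]]
    if (is.na(p) || p > alpha / (m - i + 1)) break
    reject[ord[i]] <- TRUE
  }
  reject
}

# Brute-force minimum vertex cover on a small edge list (used as the
# minimal-removal mode and as a test oracle). Vertices are locus indices.
min_vertex_cover <- function(edges, vertices) {
  if (nrow(edges) == 0L) return(integer(0))
  best <- vertices
  for (size in 0:length(vertices)) {
    combs <- utils::combn(vertices, size, simplify = FALSE)
    for (cc in combs) {
      covered <- edges[, 1] %in% cc | edges[, 2] %in% cc
      if (all(covered)) return(cc)
    }
  }
  best
}

#' Filter loci by Hardy-Weinberg and linkage-disequilibrium tests
#'
#' Reproduces the marker-curation procedure for a de novo SNP panel:
#' loci deviating from Hardy-Weinberg equilibrium are removed first (raw
#' per-locus threshold by default; optionally after sequential
#' Bonferroni), then all pairs among the remaining loci are tested for
#' linkage disequilibrium, the pair p-values are corrected by sequential
#' Bonferroni (by default), and one randomly chosen locus of each
#' significant pair is excluded iteratively until no significant pair
#' remains. A `"vertex-cover"` removal mode instead excludes a provably
#' minimal set of loci covering all significant pairs.
#'
#' @param gm A [genotype_matrix()].
#' @param hwe_alpha Per-locus HWE significance level.
#' @param ld_alpha LD significance level (applied after correction when
#'   `ld_correction = "bonferroni"`).
#' @param hwe_correction,ld_correction `"none"` or `"bonferroni"`
#'   (sequential). Defaults: raw HWE, corrected LD.
#' @param n_permutations Permutations for each LD test.
#' @param em_starts EM starts per LD test.
#' @param chain_steps,dememorization Passed to [hwe_test()] for loci with
#'   more than two alleles.
#' @param removal `"random"` (one random locus per significant pair,
#'   iterated) or `"vertex-cover"` (minimal removal).
#' @param seed Integer seed governing the HWE chains, LD permutations and
#'   random removals.
#' @return A list of class `locus_filter`: `retained` (locus ids),
#'   `report` (data.frame `locus`, `ho`, `he`, `hwe_p`, `monomorphic`,
#'   `excluded_reason`), `ld_pairs` (tested pairs with `lrt`, `p_value`,
#'   `significant`).
#' @export
filter_loci <- function(gm, hwe_alpha = 0.05, ld_alpha = 0.05,
                        hwe_correction = c("none", "bonferroni"),
                        ld_correction = c("bonferroni", "none"),
                        n_permutations = 1000, em_starts = 5,
                        chain_steps = 1e6, dememorization = 1e5,
                        removal = c("random", "vertex-cover"), seed = 1) {
  stopifnot(inherits(gm, "genotype_matrix"))
  hwe_correction <- match.arg(hwe_correction)
  ld_correction <- match.arg(ld_correction)
  removal <- match.arg(removal)
  L <- ncol(gm$a1)
  het <- heterozygosity(gm)
  report <- data.frame(locus = gm$locus_ids,
                       ho = het$per_locus$ho[match(gm$locus_ids,
                                                   het$per_locus$locus)],
                       he = het$per_locus$he[match(gm$locus_ids,
                                                   het$per_locus$locus)],
                       hwe_p = NA_real_, monomorphic = FALSE,
                       excluded_reason = "none",
                       stringsAsFactors = FALSE)

  for (j in seq_len(L)) {
    calls <- cbind(gm$a1[, j], gm$a2[, j])
    ht <- hwe_test(calls, chain_steps = chain_steps,
                   dememorization = dememorization, seed = seed + j)
    report$hwe_p[j] <- ht$p_value
    report$monomorphic[j] <- ht$monomorphic
  }
  testable <- !report$monomorphic
  hwe_sig <- logical(L)
  if (hwe_correction == "bonferroni") {
    hwe_sig[testable] <- sequential_bonferroni(report$hwe_p[testable],
                                               hwe_alpha)
  } else {
    hwe_sig[testable] <- report$hwe_p[testable] < hwe_alpha
  }
  report$excluded_reason[hwe_sig] <- "hwe"
  keep <- which(!hwe_sig & testable)

  ld_pairs <- NULL
  if (length(keep) >= 2) {
    pr <- utils::combn(keep, 2)
    lrt <- pv <- numeric(ncol(pr))
    for (q in seq_len(ncol(pr))) {
      i <- pr[1, q]; j <- pr[2, q]
      lt <- ld_test(cbind(gm$a1[, i], gm$a2[, i]),
                    cbind(gm$a1[, j], gm$a2[, j]),
                    n_permutations = n_permutations,
                    em_starts = em_starts, seed = seed + 1000L + q)
      lrt[q] <- lt$lrt
      pv[q] <- lt$p_value
    }
    sig <- if (ld_correction == "bonferroni") {
      sequential_bonferroni(pv, ld_alpha)
    } else pv < ld_alpha
    ld_pairs <- data.frame(locus_a = gm$locus_ids[pr[1, ]],
                           locus_b = gm$locus_ids[pr[2, ]],
                           lrt = lrt, p_value = pv, significant = sig,
                           stringsAsFactors = FALSE)
    set.seed(seed + 99L)
    if (removal == "vertex-cover") {
      edges <- cbind(pr[1, sig], pr[2, sig])
      drop <- min_vertex_cover(edges, sort(unique(as.vector(edges))))
      report$excluded_reason[drop] <- "ld"
      keep <- setdiff(keep, drop)
    } else {
      # iteratively break significant pairs, one random locus at a time
      edges <- cbind(pr[1, sig], pr[2, sig])
      while (nrow(edges) > 0L) {
        e <- edges[1, ]
        drop <- e[sample.int(2L, 1L)]
        report$excluded_reason[drop] <- "ld"
        keep <- setdiff(keep, drop)
        live <- edges[, 1] != drop & edges[, 2] != drop
        edges <- edges[live, , drop = FALSE]
      }
    }
  }
  structure(list(retained = gm$locus_ids[sort(keep)], report = report,
                 ld_pairs = ld_pairs),
            class = "locus_filter")
}
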