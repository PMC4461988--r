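#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Locus-by-locus AMOVA partitioning genetic variance among regions,
#' among fields within regions, and within fields. The analysis operates
#' at the gene-copy level (each diploid individual contributes two
#' copies), with the distance between two copies at a locus equal to 0
#' when they carry the same allele and 1 otherwise; sums of squares and
#' variance components are computed per locus and summed.
#'
#' Degrees of freedom follow the gene-copy convention: with `G` regions,
#' `F` fields and `N = 2 * n_individuals` copies, the levels have
#' `G - 1`, `F - G` and `N - F` degrees of freedom (total `N - 1`).
#' Missing calls reduce the sums of squares but not the reported degrees
#' of freedom, which describe the sampling design.
#'
#' @param gm A [genotype_matrix()]; the hierarchy comes from `gm$field`
#'   and `gm$region_of`.
#' @return A data.frame of class `amova_result` with rows
#'   `between regions`, `between fields within regions`, `within fields`
#'   and `total`, and columns `df`, `ss`, `variance`, `percent`.
#' @export
amova <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  field <- gm$field
  region <- unname(gm$region_of[field])
  fields <- sort(unique(field))
  regions <- sort(unique(region))
  G <- length(regions)
  F_ <- length(fields)
  if (G < 2) stop("degenerate hierarchy: need >= 2 regions", call. = FALSE)
  if (!any(table(gm$region_of[fields]) >= 2)) {
    stop("degenerate hierarchy: no region holds >= 2 fields", call. = FALSE)
  }

  # SSD of a multiset of allele copies with 0/1 distance:
  # (1/n) * sum_{i<j} d_ij = (n - sum(counts^2)/n) / 2
  ssd <- function(counts) {
    n <- sum(counts)
    if (n == 0) return(0)
    (n - sum(counts^2) / n) / 2
  }

  L <- ncol(gm$a1)
  ss_tot <- ss_wf <- ss_wr <- 0
  for (j in seq_len(L)) {
    all_cnt <- allele_counts(gm, j)
    ss_tot <- ss_tot + ssd(all_cnt)
    for (f in fields) {
      ss_wf <- ss_wf + ssd(allele_counts(gm, j, which(field == f)))
    }
    for (rg in regions) {
      ss_wr <- ss_wr + ssd(allele_counts(gm, j, which(region == rg)))
    }
  }
  ss_b <- ss_wr - ss_wf          # among fields within regions
  ss_a <- ss_tot - ss_wr          # among regions

  # design sizes in gene copies
  n_f <- 2 * vapply(fields, function(f) sum(field == f), integer(1))
  n_g <- 2 * vapply(regions, function(rg) sum(region == rg), integer(1))
  N <- sum(n_f)
  df_a <- G - 1
  df_b <- F_ - G
  df_w <- N - F_
  sum_nf2_by_g <- sum(vapply(regions, function(rg) {
    ff <- fields[gm$region_of[fields] == rg]
    sum(n_f[match(ff, fields)]^2) / n_g[match(rg, regions)]
  }, numeric(1)))
  n1 <- (N - sum_nf2_by_g) / df_b
  n2 <- (sum_nf2_by_g - sum(n_f^2) / N) / df_a
  n3 <- (N - sum(n_g^2) / N) / df_a

  ms_w <- ss_wf / df_w
  ms_b <- ss_b / df_b
  ms_a <- ss_a / df_a
  sig_c <- ms_w
  sig_b <- (ms_b - sig_c) / n1
  sig_a <- (ms_a - sig_c - n2 * sig_b) / n3
  total <- sig_a + sig_b + sig_c

  out <- data.frame(
    level = c("between regions", "between fields within regions",
              "within fields", "total"),
    df = c(df_a, df_b, df_w, N - 1),
    ss = c(ss_a, ss_b, ss_wf, ss_tot),
    variance = c(sig_a, sig_b, sig_c, total),
    percent = if (total == 0) rep(NA_real_, 4) else
      100 * c(sig_a, sig_b, sig_c, total) / total)
  class(out) <- c("amova_result", "data.frame")
  out
}
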