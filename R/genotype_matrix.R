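#' Diploid genotype matrix with a region > field hierarchy
#'
#' The substrate for all population-genetic statistics in the package:
#' unordered diploid allele calls for individuals at codominant loci,
#' with each individual assigned to a field (subpopulation) and each
#' field to a region. Allele calls are small positive integers; missing
#' calls are `NA` in both allele slots.
#'
#' @param a1,a2 Integer matrices (individuals x loci) holding the two
#'   allele codes of each call; `NA` in both marks a missing call.
#' @param individual_ids,locus_ids Row and column labels.
#' @param field Character/factor of length `nrow(a1)`: field of each
#'   individual.
#' @param region_of Named character vector mapping each field label to
#'   its region.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(a1, a2,
                            individual_ids = rownames(a1),
                            locus_ids = colnames(a1),
                            field, region_of) {
  a1 <- as.matrix(a1)
  a2 <- as.matrix(a2)
  if (!identical(dim(a1), dim(a2))) {
    stop("`a1` and `a2` must have identical dimensions", call. = FALSE)
  }
  if (any(xor(is.na(a1), is.na(a2)))) {
    stop("half-missing calls are not allowed: a call is either a full ",
         "allele pair or missing", call. = FALSE)
  }
  n <- nrow(a1)
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(n))
  if (is.null(locus_ids)) locus_ids <- paste0("locus", seq_len(ncol(a1)))
  if (anyDuplicated(individual_ids)) {
    stop("duplicated individual ids", call. = FALSE)
  }
  field <- as.character(field)
  if (length(field) != n) {
    stop("`field` must have one entry per individual", call. = FALSE)
  }
  if (missing(region_of)) {
    region_of <- stats::setNames(rep("region1", length(unique(field))),
                                 unique(field))
  }
  if (!all(unique(field) %in% names(region_of))) {
    stop("every field needs a region in `region_of`", call. = FALSE)
  }
  # normalize call order so (2,1) and (1,2) compare equal
  swap <- !is.na(a1) & a1 > a2
  tmp <- a1[swap]
  a1[swap] <- a2[swap]
  a2[swap] <- tmp
  dimnames(a1) <- dimnames(a2) <- list(individual_ids, locus_ids)
  structure(
    list(a1 = a1, a2 = a2,
         individual_ids = individual_ids, locus_ids = locus_ids,
         field = field,
         region_of = region_of[sort(unique(field))]),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d individuals x %d loci, %d fields in %d regions, %.1f%% missing\n",
    nrow(x$a1), ncol(x$a1), length(unique(x$field)),
    length(unique(x$region_of)), 100 * mean(is.na(x$a1))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$a1)

#' Subset a genotype matrix by individuals and/or loci
#'
#' @param x A [genotype_matrix()].
#' @param individuals,loci Index vectors (integer, logical or by label);
#'   missing means keep all.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(x, individuals = NULL, loci = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  ii <- if (is.null(individuals)) seq_len(nrow(x$a1)) else individuals
  if (is.character(ii)) ii <- match(ii, x$individual_ids)
  ll <- if (is.null(loci)) seq_len(ncol(x$a1)) else loci
  if (is.character(ll)) ll <- match(ll, x$locus_ids)
  genotype_matrix(x$a1[ii, ll, drop = FALSE], x$a2[ii, ll, drop = FALSE],
                  individual_ids = x$individual_ids[ii],
                  locus_ids = x$locus_ids[ll],
                  field = x$field[ii], region_of = x$region_of)
}

# Allele frequency table for one locus within a subset of individuals:
# named vector of counts over observed allele codes.
allele_counts <- function(gm, locus, rows = seq_len(nrow(gm$a1))) {
  alle <- c(gm$a1[rows, locus], gm$a2[rows, locus])
  table(alle[!is.na(alle)])
}

#' Observed and expected heterozygosity per locus
#'
#' Observed heterozygosity `ho` is the fraction of heterozygous calls
#' among non-missing calls. Expected heterozygosity `he` is the unbiased
#' gene diversity \eqn{\frac{n}{n-1}(1 - \sum \hat p_a^2)} with `n` the
#' number of non-missing gene copies. Loci with fewer than 2 genotyped
#' individuals in the group are dropped with a warning.
#'
#' @param gm A [genotype_matrix()].
#' @param group A field label to restrict to, or `"all"` (default) for
#'   the full sample.
#' @return A list with `per_locus` (data.frame `locus`, `n`, `ho`, `he`,
#'   `monomorphic`) and `mean` (data.frame with mean and standard error
#'   of `ho` and `he` over loci).
#' @export
heterozygosity <- function(gm, group = "all") {
  stopifnot(inherits(gm, "genotype_matrix"))
  rows <- if (identical(group, "all")) {
    seq_len(nrow(gm$a1))
  } else which(gm$field == group)
  if (length(rows) == 0L) stop("no individuals in group ", group,
                               call. = FALSE)
  a1 <- gm$a1[rows, , drop = FALSE]
  a2 <- gm$a2[rows, , drop = FALSE]
  n_obs <- colSums(!is.na(a1))
  ho <- colSums(a1 != a2, na.rm = TRUE) / n_obs
  he <- vapply(seq_len(ncol(a1)), function(j) {
    cnt <- allele_counts(gm, j, rows)
    n <- sum(cnt)
    if (n < 2) return(NA_real_)
    p <- cnt / n
    n / (n - 1) * (1 - sum(p^2))
  }, numeric(1))
  bad <- n_obs < 2
  if (any(bad)) {
    warning(sum(bad), " locus/loci with < 2 genotyped individuals excluded",
            call. = FALSE)
  }
  per_locus <- data.frame(
    locus = gm$locus_ids, n = n_obs, ho = ho, he = he,
    monomorphic = !is.na(he) & he == 0)[!bad, , drop = FALSE]
  se <- function(v) stats::sd(v) / sqrt(length(v))
  list(per_locus = per_locus,
       mean = data.frame(
         statistic = c("ho", "he"),
         mean = c(mean(per_locus$ho), mean(per_locus$he)),
         se = c(se(per_locus$ho), se(per_locus$he))))
}
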