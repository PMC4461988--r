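#' Per-field ploidy counts
#'
#' Counts of assayed males by ploidy class and of females, the raw
#' material for estimating the diploid male proportion (DMP). The three
#' male classes must sum to the number of males assayed.
#'
#' @param field_id Field label.
#' @param n_haploid,n_diploid_males,n_unknown Assayed males by ploidy.
#' @param n_females Females collected in the field.
#' @param n_males_assayed Total assayed males; defaults to the class sum.
#' @return A one-row data.frame of class `ploidy_counts`.
#' @export
ploidy_counts <- function(field_id, n_haploid, n_diploid_males,
                          n_unknown = 0L, n_females,
                          n_males_assayed = n_haploid + n_diploid_males +
                            n_unknown) {
  counts <- c(n_haploid, n_diploid_males, n_unknown, n_females,
              n_males_assayed)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (n_haploid + n_diploid_males + n_unknown != n_males_assayed) {
    stop("ploidy classes must sum to `n_males_assayed`", call. = FALSE)
  }
  out <- data.frame(field_id = as.character(field_id),
                    n_males_assayed = as.integer(n_males_assayed),
                    n_haploid = as.integer(n_haploid),
                    n_diploid_males = as.integer(n_diploid_males),
                    n_unknown = as.integer(n_unknown),
                    n_females = as.integer(n_females),
                    stringsAsFactors = FALSE)
  class(out) <- c("ploidy_counts", "data.frame")
  out
}

clopper_pearson <- function(x, n, level) {
  alpha <- 1 - level
  lo <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lo, upper = hi)
}

#' Diploid male proportion with Clopper-Pearson interval
#'
#' DMP is the proportion of diploids that are male:
#' `diploid males / (diploid males + females)`. Haploid males and males
#' of unknown ploidy do not enter the estimate. The exact
#' (Clopper-Pearson) binomial interval is reported.
#'
#' @param counts A [ploidy_counts()] row (or any data.frame with
#'   `n_diploid_males` and `n_females`).
#' @param ci_level Confidence level (default 0.95).
#' @return A list of class `dmp_estimate`: `dmp`, `ci_low`, `ci_high`,
#'   `n_diploid_males`, `n_diploids`, `defined`.
#' @examples
#' dmp_estimate(ploidy_counts("f1", 95, 2, 3, n_females = 98))$dmp # 0.02
#' @export
dmp_estimate <- function(counts, ci_level = 0.95) {
  x <- sum(counts$n_diploid_males)
  n <- x + sum(counts$n_females)
  if (n == 0) {
    warning("no diploids: DMP undefined", call. = FALSE)
    return(structure(list(dmp = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, n_diploid_males = x,
                          n_diploids = 0L, defined = FALSE),
                     class = "dmp_estimate"))
  }
  ci <- clopper_pearson(x, n, ci_level)
  structure(list(dmp = x / n, ci_low = unname(ci["lower"]),
                 ci_high = unname(ci["upper"]),
                 n_diploid_males = as.integer(x), n_diploids = as.integer(n),
                 defined = TRUE),
            class = "dmp_estimate")
}

#' Pooled diploid male proportion across fields
#'
#' Pools diploid-male and female counts over all fields and applies the
#' same exact binomial interval as [dmp_estimate()].
#'
#' @param counts_list A data.frame of stacked [ploidy_counts()] rows, or
#'   a list of them.
#' @param ci_level Confidence level.
#' @return A `dmp_estimate` for the pooled counts.
#' @export
aggregate_dmp <- function(counts_list, ci_level = 0.95) {
  if (is.data.frame(counts_list)) counts_list <- list(counts_list)
  if (length(counts_list) == 0L) stop("empty counts list", call. = FALSE)
  pooled <- do.call(rbind, counts_list)
  dmp_estimate(pooled, ci_level = ci_level)
}

# Weighted mean and its standard error with normalized weights and the
# unbiased weighted sample variance.
weighted_mean_se <- function(x, w) {
  w <- w / sum(w)
  m <- sum(w * x)
  denom <- 1 - sum(w^2)
  if (length(x) < 2 || denom <= 0) {
    return(c(mean = m, se = NA_real_))
  }
  v <- sum(w * (x - m)^2) / denom
  c(mean = m, se = sqrt(v * sum(w^2)))
}

#' Field-level collection summaries
#'
#' Per-plant infestation and parasitoid counts are summarized per field:
#' mean infestation per plant (+/- se), the parasitism rate
#' `cocoons / (cocoons + hosts)` averaged over plants with weights equal
#' to the plant's infestation level, the male sex ratio averaged with
#' weights equal to the plant's adult parasitoid count, and the field's
#' DMP from its ploidy counts.
#'
#' @param plants A data.frame with columns `field_id`, `hosts` (moth
#'   larvae per plant), `cocoons` (parasitoid cocoons per plant).
#' @param sexes A data.frame with columns `field_id`, `plant`, `males`,
#'   `females` (emerged adults per plant).
#' @param ploidy A stacked [ploidy_counts()] data.frame, or `NULL`.
#' @param ci_level Confidence level for the DMP interval.
#' @return A data.frame of class `field_summary`, one row per field.
#' @export
field_summaries <- function(plants, sexes, ploidy = NULL, ci_level = 0.95) {
  stopifnot(all(c("field_id", "hosts", "cocoons") %in% names(plants)))
  stopifnot(all(c("field_id", "males", "females") %in% names(sexes)))
  fields <- unique(plants$field_id)
  rows <- lapply(fields, function(f) {
    pl <- plants[plants$field_id == f, , drop = FALSE]
    if (nrow(pl) == 0L) {
      warning("field ", f, " has no plants; skipped", call. = FALSE)
      return(NULL)
    }
    infest <- pl$hosts + pl$cocoons
    inf_ms <- c(mean = mean(infest),
                se = if (nrow(pl) > 1) {
                  stats::sd(infest) / sqrt(nrow(pl))
                } else NA_real_)
    par_rate <- ifelse(infest > 0, pl$cocoons / infest, NA_real_)
    ok <- !is.na(par_rate)
    par_ms <- weighted_mean_se(par_rate[ok], infest[ok])
    sx <- sexes[sexes$field_id == f, , drop = FALSE]
    adults <- sx$males + sx$females
    ok <- adults > 0
    sr_ms <- weighted_mean_se(sx$males[ok] / adults[ok], adults[ok])
    dmp <- c(NA_real_, NA_real_, NA_real_)
    if (!is.null(ploidy)) {
      pc <- ploidy[ploidy$field_id == f, , drop = FALSE]
      if (nrow(pc) > 0) {
        d <- dmp_estimate(pc, ci_level = ci_level)
        dmp <- c(d$dmp, d$ci_low, d$ci_high)
      }
    }
    data.frame(field_id = f, n_plants = nrow(pl),
               infestation = inf_ms["mean"], infestation_se = inf_ms["se"],
               parasitism = par_ms["mean"], parasitism_se = par_ms["se"],
               sex_ratio = sr_ms["mean"], sex_ratio_se = sr_ms["se"],
               dmp = dmp[1], dmp_ci_low = dmp[2], dmp_ci_high = dmp[3],
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("field_summary", "data.frame")
  out
}
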