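#' Write the analysis report tables
#'
#' Writes plain CSV tables mirroring the shapes of a field-study report:
#' per-field heterozygosity and inbreeding, the pairwise matrix with
#' \eqn{F_{ST}} below and permutation p-values above the diagonal, the
#' AMOVA table, the locus filter report, and the model predictions.
#' Only components present in `results` are written.
#'
#' @param results A named list; recognized names are `het_fis`
#'   (data.frame), `pairwise` (a [pairwise_fst()] result), `amova` (an
#'   [amova()] result), `filter` (a [filter_loci()] result),
#'   `predictions` (data.frame), `fstats` (a [global_fstats()] result).
#' @param dir Output directory (created if needed).
#' @return The paths written, invisibly.
#' @export
write_reports <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  w <- function(obj, name) {
    p <- file.path(dir, name)
    utils::write.csv(obj, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(results$het_fis)) w(results$het_fis, "per_field.csv")
  if (!is.null(results$pairwise)) {
    m <- results$pairwise$fst
    m[upper.tri(m)] <- results$pairwise$p_value[upper.tri(m)]
    w(cbind(field = rownames(m), as.data.frame(m)), "pairwise_fst.csv")
  }
  if (!is.null(results$amova)) w(as.data.frame(results$amova), "amova.csv")
  if (!is.null(results$filter)) w(results$filter$report, "locus_filter.csv")
  if (!is.null(results$predictions)) w(results$predictions,
                                       "dmp_predictions.csv")
  if (!is.null(results$fstats)) {
    fs <- results$fstats
    w(data.frame(statistic = c("f_is", "f_st", "f_it"),
                 estimate = c(fs$f_is, fs$f_st, fs$f_it),
                 ci_low = if (is.null(fs$ci)) NA else fs$ci[1, ],
                 ci_high = if (is.null(fs$ci)) NA else fs$ci[2, ]),
      "fstats.csv")
  }
  invisible(paths)
}

#' DMP prediction table over a range of sex-allele numbers
#'
#' For each candidate allele number, the prediction band over a
#' sibmating interval and whether it contains an observed DMP — the
#' numbers behind a prediction-band figure.
#'
#' @param alpha_low,alpha_high Sibmating interval.
#' @param k_values Candidate allele numbers.
#' @param model 1 or 2 sex loci (`l = k` under the two-locus model).
#' @param dmp_obs Optional observed DMP for the `consistent` column.
#' @param dm_survival Relative diploid-male survival.
#' @return A data.frame `k`, `dmp_low`, `dmp_high`, `consistent`.
#' @export
predict_dmp_table <- function(alpha_low, alpha_high, k_values = 3:100,
                              model = 2, dmp_obs = NA, dm_survival = 1) {
  rows <- lapply(k_values, function(k) {
    spec <- csd_model_spec(model, k = k, l = k, alpha = alpha_low,
                           dm_survival = dm_survival)
    b <- dmp_band(alpha_low, alpha_high, spec)
    data.frame(k = k, dmp_low = b$band_low, dmp_high = b$band_high,
               consistent = if (is.na(dmp_obs)) NA else
                 dmp_obs >= b$band_low && dmp_obs <= b$band_high)
  })
  do.call(rbind, rows)
}

#' Run the full population-level CSD analysis
#'
#' Orchestrates the analysis stages in their natural order: locus
#' filtering (HWE, then LD), global and per-field F-statistics, pairwise
#' \eqn{F_{ST}}, AMOVA, sibmating estimation from \eqn{F_{IS}} and its
#' bootstrap interval, and DMP prediction bands over a grid of
#' sex-allele numbers for both CSD models. Every stochastic stage is
#' seeded from `seed`; rerunning with the same inputs reproduces the
#' outputs exactly.
#'
#' @param gm A [genotype_matrix()] of diploid females.
#' @param dmp_obs Observed diploid male proportion (optional; enables
#'   the consistency column of the prediction tables).
#' @param k_values Sex-allele grid for the predictions.
#' @param filter Logical: run the HWE/LD locus filter first.
#' @param n_permutations,n_bootstrap,em_starts Test effort parameters.
#' @param hwe_chain_steps,hwe_dememorization HWE chain lengths for loci
#'   with more than two alleles.
#' @param seed Integer seed (required).
#' @param out Optional output directory for [write_reports()].
#' @return A list with the stage results: `filter`, `genotypes` (the
#'   retained matrix), `fstats`, `het_fis`, `pairwise`, `amova`,
#'   `alpha` (point and interval), `predictions_sl`, `predictions_2l`.
#' @export
run_csd_pipeline <- function(gm, dmp_obs = NA, k_values = 3:100,
                             filter = TRUE, n_permutations = 999,
                             n_bootstrap = 1000, em_starts = 5,
                             hwe_chain_steps = 1e6,
                             hwe_dememorization = 1e5,
                             seed, out = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  flt <- NULL
  if (filter) {
    flt <- filter_loci(gm, n_permutations = n_permutations,
                       em_starts = em_starts,
                       chain_steps = hwe_chain_steps,
                       dememorization = hwe_dememorization, seed = seed)
    gm <- subset_genotypes(gm, loci = flt$retained)
  }
  fs <- global_fstats(gm, n_bootstrap = n_bootstrap, seed = seed + 1L)
  hetf <- merge(
    fis_per_field(gm),
    do.call(rbind, lapply(sort(unique(gm$field)), function(f) {
      h <- heterozygosity(gm, f)$mean
      data.frame(field = f,
                 ho = h$mean[h$statistic == "ho"],
                 ho_se = h$se[h$statistic == "ho"],
                 he = h$mean[h$statistic == "he"],
                 he_se = h$se[h$statistic == "he"])
    })), by = "field")
  pw <- pairwise_fst(gm, n_permutations = n_permutations, seed = seed + 2L)
  am <- amova(gm)
  fis_pt <- fs$f_is
  fis_ci <- if (!is.null(fs$ci)) fs$ci[, "f_is"] else c(fis_pt, fis_pt)
  alpha <- list(
    point = sibmating_from_fis(max(fis_pt, 0)),
    low = sibmating_from_fis(max(fis_ci[1], 0)),
    high = sibmating_from_fis(max(fis_ci[2], 0)))
  pred_sl <- predict_dmp_table(alpha$low, alpha$high, k_values, model = 1,
                               dmp_obs = dmp_obs)
  pred_2l <- predict_dmp_table(alpha$low, alpha$high, k_values, model = 2,
                               dmp_obs = dmp_obs)
  res <- list(filter = flt, genotypes = gm, fstats = fs, het_fis = hetf,
              pairwise = pw, amova = am, alpha = alpha,
              predictions_sl = pred_sl, predictions_2l = pred_2l,
              seed = as.integer(seed))
  if (!is.null(out)) {
    write_reports(list(het_fis = hetf, pairwise = pw, amova = am,
                       filter = flt, fstats = fs,
                       predictions = cbind(model = "2l", pred_2l)), out)
  }
  res
}
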