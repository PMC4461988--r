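#' Construct a SNP candidate table
#'
#' Validates a table of putative SNPs as produced by reference-based
#' variant calling: scaffold, 1-based position, allele list, minor
#' allele frequency, a caller quality score and read depth.
#'
#' @param scaffold Character scaffold ids.
#' @param position 1-based positions (positive integers).
#' @param alleles List of character vectors (nucleotides), or a
#'   character vector like `"A/G"`.
#' @param maf Minor allele frequencies, each <= 0.5.
#' @param quality Caller quality scores.
#' @param depth Read depths.
#' @return A data.frame of class `snp_candidates`.
#' @export
snp_candidates <- function(scaffold, position, alleles, maf, quality,
                           depth = NA_integer_) {
  if (is.character(alleles)) alleles <- strsplit(alleles, "/", fixed = TRUE)
  stopifnot(is.list(alleles))
  if (any(position < 1 | position != round(position))) {
    stop("positions must be positive integers", call. = FALSE)
  }
  if (any(maf > 0.5 | maf <= 0)) {
    stop("`maf` must be in (0, 0.5]", call. = FALSE)
  }
  if (any(lengths(alleles) < 2)) {
    stop("each SNP needs at least 2 alleles", call. = FALSE)
  }
  out <- data.frame(scaffold = as.character(scaffold),
                    position = as.integer(position),
                    maf = maf, quality = quality, depth = depth,
                    stringsAsFactors = FALSE)
  out$alleles <- alleles
  class(out) <- c("snp_candidates", "data.frame")
  out
}

#' Select a genotyping panel from SNP candidates
#'
#' Applies the panel-design rules used for a de novo KASP-style assay
#' set: drop candidates with minor allele frequency below `maf_floor` or
#' with more than two alleles, drop any candidate that has another
#' candidate within `spacing` bp up- or downstream on the same scaffold
#' (both members of a close pair are removed), bin the survivors by MAF,
#' rank by quality within bins, and fill each bin's quota taking at most
#' one SNP per scaffold.
#'
#' @param candidates A [snp_candidates()] table.
#' @param maf_floor Minimum minor allele frequency (default 0.2).
#' @param spacing Exclusion distance in bp (default 50); absolute
#'   distance `<= spacing` on the same scaffold disqualifies both SNPs.
#' @param bin_edges MAF bin edges; bin i is `(bin_edges[i],
#'   bin_edges[i+1]]`.
#' @param bin_quotas SNPs to select per bin (defaults 20/40/40).
#' @return A `snp_candidates` table of the selected rows with an added
#'   `maf_bin` column, ordered by bin then descending quality. A warning
#'   is raised for any bin whose quota cannot be filled.
#' @export
select_snp_panel <- function(candidates, maf_floor = 0.2, spacing = 50,
                             bin_edges = c(0.2, 0.3, 0.4, 0.5),
                             bin_quotas = c(20, 40, 40)) {
  stopifnot(inherits(candidates, "snp_candidates"))
  if (length(bin_quotas) != length(bin_edges) - 1) {
    stop("`bin_quotas` must align with the bins of `bin_edges`",
         call. = FALSE)
  }
  x <- candidates
  keep <- x$maf >= maf_floor & lengths(x$alleles) == 2
  # spacing filter: both members of any close same-scaffold pair go
  crowded <- rep(FALSE, nrow(x))
  for (sc in unique(x$scaffold)) {
    idx <- which(x$scaffold == sc)
    if (length(idx) < 2) next
    pos <- sort(x$position[idx])
    near <- diff(pos) <= spacing
    bad_pos <- unique(c(pos[c(near, FALSE)], pos[c(FALSE, near)]))
    crowded[idx[x$position[idx] %in% bad_pos]] <- TRUE
  }
  keep <- keep & !crowded
  x <- x[keep, , drop = FALSE]
  x$maf_bin <- cut(x$maf, breaks = bin_edges, include.lowest = FALSE)
  x <- x[!is.na(x$maf_bin), , drop = FALSE]

  picked <- list()
  used_scaffolds <- character(0)
  for (b in seq_along(bin_quotas)) {
    lev <- levels(x$maf_bin)[b]
    rows <- x[x$maf_bin == lev, , drop = FALSE]
    rows <- rows[order(-rows$quality), , drop = FALSE]
    sel <- integer(0)
    for (i in seq_len(nrow(rows))) {
      if (length(sel) >= bin_quotas[b]) break
      if (rows$scaffold[i] %in% used_scaffolds) next
      sel <- c(sel, i)
      used_scaffolds <- c(used_scaffolds, rows$scaffold[i])
    }
    if (length(sel) < bin_quotas[b]) {
      warning(sprintf("bin %s: only %d of %d SNPs available", lev,
                      length(sel), bin_quotas[b]), call. = FALSE)
    }
    picked[[b]] <- rows[sel, , drop = FALSE]
  }
  out <- do.call(rbind, picked)
  class(out) <- c("snp_candidates", "data.frame")
  rownames(out) <- NULL
  out
}

#' Transition:transversion ratio of a SNP candidate table
#'
#' Counts transitions (A<->G, C<->T) and transversions among biallelic
#' nucleotide substitutions. Chance alone would give a ratio of 0.5
#' (2 transition pairs out of the 6 unordered nucleotide pairs), so
#' ratios near published genome-wide values (roughly 2-3) support the
#' validity of a SNP-calling procedure.
#'
#' @param candidates A [snp_candidates()] table; rows with more than two
#'   alleles are ignored.
#' @return A list with `ratio` (`NA` and `defined = FALSE` when no
#'   transversions are present), `transitions`, `transversions`.
#' @export
titv_ratio <- function(candidates) {
  stopifnot(inherits(candidates, "snp_candidates"))
  bial <- candidates$alleles[lengths(candidates$alleles) == 2]
  pairs <- vapply(bial, function(a) paste(sort(toupper(a)), collapse = ""),
                  character(1))
  if (!all(unlist(bial) %in% c("A", "C", "G", "T", "a", "c", "g", "t"))) {
    stop("non-nucleotide alleles in candidate table", call. = FALSE)
  }
  ti <- sum(pairs %in% c("AG", "CT"))
  tv <- length(pairs) - ti
  list(ratio = if (tv == 0) NA_real_ else ti / tv,
       defined = tv > 0, transitions = ti, transversions = tv)
}
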