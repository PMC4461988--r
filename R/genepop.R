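#' Read a Genepop genotype file
#'
#' Parses the classic Genepop text format: a title line, one locus name
#' per line (or a single comma-separated line), and `POP`-delimited
#' population blocks of `id , 0101 0202 ...` rows with 2- or 3-digit
#' allele codes (`00`/`000` = missing). Population blocks become field
#' labels.
#'
#' @param path Path to a Genepop file.
#' @param field_names Optional labels for the POP blocks (defaults
#'   `pop1`, `pop2`, ...).
#' @param region_of Optional named vector mapping field labels to
#'   regions; default places all fields in one region.
#' @return A [genotype_matrix()].
#' @export
read_genepop <- function(path, field_names = NULL, region_of = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("not a Genepop file: too short", call. = FALSE)
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no POP line found", call. = FALSE)
  header <- lines[2:(first_pop - 1)]
  loci <- trimws(unlist(strsplit(header, ",", fixed = TRUE)))
  loci <- loci[nzchar(loci)]
  n_loci <- length(loci)

  ids <- character(0)
  field <- character(0)
  a1 <- a2 <- NULL
  pop_idx <- 0L
  code_width <- NA_integer_
  for (ln in seq(first_pop, length(lines))) {
    line <- trimws(lines[ln])
    if (toupper(line) == "POP") {
      pop_idx <- pop_idx + 1L
      next
    }
    parts <- strsplit(line, ",", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      stop("line ", ln, ": expected `id , genotypes`", call. = FALSE)
    }
    id <- trimws(parts[1])
    codes <- strsplit(trimws(parts[2]), "\\s+")[[1]]
    if (length(codes) != n_loci) {
      stop("line ", ln, ": ", length(codes), " genotypes for ", n_loci,
           " declared loci", call. = FALSE)
    }
    w <- unique(nchar(codes)) / 2
    if (length(w) != 1 || !w %in% c(2, 3)) {
      stop("line ", ln, ": allele codes must all be 2 or 3 digits",
           call. = FALSE)
    }
    if (is.na(code_width)) code_width <- w
    if (w != code_width) {
      stop("line ", ln, ": mixed allele code widths", call. = FALSE)
    }
    x1 <- as.integer(substr(codes, 1, w))
    x2 <- as.integer(substr(codes, w + 1, 2 * w))
    x1[x1 == 0L] <- NA_integer_
    x2[x2 == 0L] <- NA_integer_
    miss <- is.na(x1) | is.na(x2)
    x1[miss] <- x2[miss] <- NA_integer_
    ids <- c(ids, id)
    field <- c(field, paste0("pop", pop_idx))
    a1 <- rbind(a1, x1)
    a2 <- rbind(a2, x2)
  }
  if (!is.null(field_names)) {
    field <- field_names[as.integer(sub("^pop", "", field))]
  }
  if (is.null(region_of)) {
    region_of <- stats::setNames(rep("region1", length(unique(field))),
                                 unique(field))
  }
  if (anyDuplicated(ids)) {
    ids <- make.unique(ids, sep = "_")
  }
  genotype_matrix(a1, a2, individual_ids = ids, locus_ids = loci,
                  field = field, region_of = region_of)
}

#' Write a genotype matrix to a Genepop file
#'
#' Fields become `POP` blocks (in sorted label order); allele codes are
#' zero-padded to `digits` digits with `00`/`000` for missing.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @param title Title line.
#' @param digits Allele code width, 2 or 3.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(gm, path, title = "csdload export", digits = 2) {
  stopifnot(inherits(gm, "genotype_matrix"), digits %in% c(2, 3))
  if (max(c(gm$a1, gm$a2), na.rm = TRUE) >= 10^digits) {
    stop("allele codes too large for ", digits, "-digit Genepop",
         call. = FALSE)
  }
  fmt <- function(x) {
    out <- formatC(x, width = digits, flag = "0")
    out[is.na(x)] <- strrep("0", digits)
    out
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(gm$locus_ids, con)
  for (f in sort(unique(gm$field))) {
    writeLines("POP", con)
    for (i in which(gm$field == f)) {
      geno <- paste0(fmt(gm$a1[i, ]), fmt(gm$a2[i, ]))
      writeLines(paste(gm$individual_ids[i], ",",
                       paste(geno, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read genotypes from the package's CSV dialect
#'
#' Header `id,region,field,<locus>...`; calls are `A1/A2` allele codes
#' with `./.` for missing.
#'
#' @param path Path to a CSV file.
#' @return A [genotype_matrix()].
#' @export
read_genotype_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  need <- c("id", "region", "field")
  if (!identical(names(df)[1:3], need)) {
    stop("CSV must start with columns id,region,field", call. = FALSE)
  }
  if (anyDuplicated(df$id)) stop("duplicated individual ids", call. = FALSE)
  loci <- names(df)[-(1:3)]
  parse_col <- function(v) {
    parts <- strsplit(v, "/", fixed = TRUE)
    bad <- lengths(parts) != 2
    if (any(bad)) stop("malformed call(s): ", v[bad][1], call. = FALSE)
    m <- matrix(unlist(parts), ncol = 2, byrow = TRUE)
    m[m == "."] <- NA
    matrix(as.integer(m), ncol = 2)
  }
  mats <- lapply(loci, function(lc) parse_col(df[[lc]]))
  a1 <- do.call(cbind, lapply(mats, function(m) m[, 1]))
  a2 <- do.call(cbind, lapply(mats, function(m) m[, 2]))
  region_of <- tapply(df$region, df$field, function(r) {
    u <- unique(r)
    if (length(u) != 1) stop("field mapped to multiple regions",
                             call. = FALSE)
    u
  })
  genotype_matrix(a1, a2, individual_ids = df$id, locus_ids = loci,
                  field = df$field,
                  region_of = stats::setNames(as.character(region_of),
                                              names(region_of)))
}

#' Write genotypes to the package's CSV dialect
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_csv <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  call_str <- matrix(paste0(ifelse(is.na(gm$a1), ".", gm$a1), "/",
                            ifelse(is.na(gm$a2), ".", gm$a2)),
                     nrow = nrow(gm$a1),
                     dimnames = list(NULL, gm$locus_ids))
  df <- data.frame(id = gm$individual_ids,
                   region = unname(gm$region_of[gm$field]),
                   field = gm$field, check.names = FALSE)
  df <- cbind(df, as.data.frame(call_str, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
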