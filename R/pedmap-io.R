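#' Write genotypes as PLINK text PED/MAP files
#'
#' The PED file carries the six standard leading columns (family id,
#' individual id, paternal id 0, maternal id 0, sex, phenotype -9) followed
#' by two allele columns per SNP, coded `A` for the reference allele and `B`
#' for the alternate; missing calls are written as `0 0`. The MAP file lists
#' chromosome 1, the SNP id, genetic distance 0 and the SNP index as the
#' base-pair position.
#'
#' @param G A [genotype_matrix()].
#' @param prefix Output path prefix; `<prefix>.ped` and `<prefix>.map` are
#'   written.
#' @param sex Integer vector (1 = male, 2 = female) recycled over
#'   individuals; defaults to 1.
#' @return The two file paths, invisibly.
#' @seealso [read_ped_map()]
#' @export
write_ped_map <- function(G, prefix, sex = 1L) {
  stopifnot(inherits(G, "genotype_matrix"))
  n <- nrow(G$doses)
  m <- ncol(G$doses)
  sex <- rep_len(as.integer(sex), max(n, 1L))
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  a1 <- matrix("0", n, m)
  a2 <- matrix("0", n, m)
  d <- G$doses
  a1[!is.na(d) & d >= 1L] <- "A"
  a1[!is.na(d) & d == 0L] <- "B"
  a2[!is.na(d) & d == 2L] <- "A"
  a2[!is.na(d) & d <= 1L] <- "B"
  geno <- matrix("", n, 2L * m)
  if (m > 0) {
    geno[, seq(1L, 2L * m, by = 2L)] <- a1
    geno[, seq(2L, 2L * m, by = 2L)] <- a2
  }
  lead <- cbind(rownames(d), rownames(d), "0", "0", as.character(sex[seq_len(n)]), "-9")
  lines <- apply(cbind(lead, geno), 1L, paste, collapse = " ")
  ok <- try(writeLines(lines, ped_path), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write PED file '", ped_path, "': ", attr(ok, "condition")$message)
  map <- sprintf("1 %s 0 %d", colnames(d), seq_len(m))
  ok <- try(writeLines(map, map_path), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write MAP file '", map_path, "': ", attr(ok, "condition")$message)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read PLINK text PED/MAP files into a genotype matrix
#'
#' Doses count copies of the reference allele at each SNP, taken as allele
#' `A` when present and otherwise the alphabetically first allele observed;
#' `0` denotes a missing allele and any half-missing genotype is treated as
#' missing. Allele frequencies are not stored in the text format, so the
#' returned object carries none; estimate them with [allele_frequencies()].
#'
#' @param prefix Path prefix of the `<prefix>.ped` / `<prefix>.map` pair.
#' @return A [genotype_matrix()].
#' @export
read_ped_map <- function(prefix) {
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  for (p in c(ped_path, map_path))
    if (!file.exists(p)) stop("file not found: '", p, "'")
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 4L)
    stop("malformed MAP file '", map_path, "': expected 4 columns")
  snp_ids <- as.character(map[[2L]])
  m <- length(snp_ids)
  lines <- readLines(ped_path)
  n <- length(lines)
  doses <- matrix(NA_integer_, n, m)
  ids <- character(n)
  # per-SNP allele registry, learned while streaming the lines; doses are
  # stored relative to the first allele seen and re-oriented afterwards
  ax <- rep(NA_character_, m)
  ay <- rep(NA_character_, m)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(f) != 6L + 2L * m)
      stop(sprintf("malformed PED file '%s' at line %d: %d fields, expected %d",
                   ped_path, i, length(f), 6L + 2L * m))
    ids[i] <- f[2L]
    if (m == 0) next
    al1 <- f[seq(7L, by = 2L, length.out = m)]
    al2 <- f[seq(8L, by = 2L, length.out = m)]
    miss <- al1 == "0" | al2 == "0"
    for (al in list(al1, al2)) {
      new1 <- !miss & is.na(ax)
      ax[new1] <- al[new1]
      new2 <- !miss & !is.na(ax) & al != ax & is.na(ay)
      ay[new2] <- al[new2]
    }
    bad <- !miss & (al1 != ax & (is.na(ay) | al1 != ay) |
                      al2 != ax & (is.na(ay) | al2 != ay))
    if (any(bad))
      stop(sprintf("malformed PED file '%s' at line %d: more than two alleles at SNP '%s'",
                   ped_path, i, snp_ids[which(bad)[1L]]))
    dose <- (al1 == ax) + (al2 == ax)
    dose[miss] <- NA_integer_
    doses[i, ] <- dose
  }
  # orient each SNP to its reference allele: "A" when the SNP uses this
  # package's A/B coding (or "A" appears at all), else the alphabetically
  # first allele observed
  both <- ifelse(is.na(ay), ax, pmin(ax, ay))
  ref <- ifelse(!is.na(ax) &
                  (ax == "A" | (!is.na(ay) & ay == "A") |
                     (ax %in% c("A", "B") & (is.na(ay) | ay %in% c("A", "B")))),
                "A", both)
  flip <- which(!is.na(ax) & ax != ref)
  if (length(flip)) doses[, flip] <- 2L - doses[, flip]
  genotype_matrix(doses, sample_ids = ids, snp_ids = snp_ids)
}

.cohort_cols <- c("id", "sbp", "bmi", "smoking", "alcohol", "gender", "age",
                  "treated", "affected", "is_cr", "liability", "liability_g")

#' Write a cohort table as CSV
#'
#' Columns follow the documented cohort layout (`id, sbp, bmi, smoking,
#' alcohol, gender, age, treated, affected, is_cr, liability, liability_g`);
#' an empty cohort produces a header-only file.
#'
#' @param cohort Cohort data frame as produced by [simulate_cohort()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  miss <- setdiff(.cohort_cols, names(cohort))
  if (length(miss))
    stop("cohort table lacks column(s): ", paste(miss, collapse = ", "))
  ok <- try(utils::write.csv(cohort[, .cohort_cols, drop = FALSE], path,
                             row.names = FALSE, quote = FALSE), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write cohort CSV '", path, "': ", attr(ok, "condition")$message)
  invisible(path)
}

#' Read a cohort table from CSV
#' @param path File written by [write_cohort_csv()].
#' @return Cohort data frame with typed columns.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character"))
  miss <- setdiff(.cohort_cols, names(out))
  if (length(miss))
    stop("cohort CSV '", path, "' lacks column(s): ", paste(miss, collapse = ", "))
  for (cc in c("treated", "affected", "is_cr")) out[[cc]] <- as.logical(out[[cc]])
  for (cc in c("smoking", "alcohol", "gender")) out[[cc]] <- as.integer(out[[cc]])
  out
}
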