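#' Edit 305-day lactation records
#'
#' Applies the herd-level edits for 305-day lactation yields: records are
#' removed when lactation length < 105 days, milk yield < 100 kg, fat or
#' protein yield < 3 kg, or the deviation from median kidding date exceeds
#' +/- 90 days. Boundary values are kept (the removal rules are strict
#' inequalities). The rules are conjunctive, so the kept set does not depend
#' on the order in which they are applied; the `reason` reported for a
#' dropped record is the first rule violated in the order above.
#'
#' @param records data.frame of lactation records with columns
#'   `animal`, `milk_yield`, `fat_yield`, `protein_yield`,
#'   `lactation_length`, `dmkd` (and any others, carried through).
#' @return List with `kept` (data.frame) and `dropped` (data.frame with an
#'   added `reason` column).
#' @export
filter_lactations <- function(records) {
  stopifnot(is.data.frame(records))
  rules <- list(
    lactation_length = records$lactation_length < 105,
    milk_yield = records$milk_yield < 100,
    fat_yield = records$fat_yield < 3,
    protein_yield = records$protein_yield < 3,
    dmkd = abs(records$dmkd) > 90
  )
  reason <- rep(NA_character_, nrow(records))
  for (nm in rev(names(rules))) reason[which(rules[[nm]])] <- nm
  drop <- !is.na(reason)
  dropped <- records[drop, , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- reason[drop]
  else dropped$reason <- character(0)
  list(kept = records[!drop, , drop = FALSE], dropped = dropped)
}

#' Somatic cell score
#'
#' The average somatic cell score of a lactation: the mean of log2 somatic
#' cell counts over the herd tests.
#'
#' @param scc numeric vector of somatic cell counts (cells/mL), all > 0.
#' @return Mean log2 count (a single number).
#' @examples
#' somatic_cell_score(c(1024, 4096))  # 11
#' @export
somatic_cell_score <- function(scc) {
  if (any(!is.finite(scc) | scc <= 0))
    stop("somatic cell counts must be positive")
  mean(log2(scc))
}

#' Parity contemporary-group class
#'
#' Lactation numbers are grouped into classes 1, 2, 3, 4 and ">=5".
#' @param parity integer vector >= 1.
#' @return Factor with levels `1`, `2`, `3`, `4`, `5+`.
#' @export
parity_class <- function(parity) {
  stopifnot(all(parity >= 1))
  factor(ifelse(parity >= 5, "5+", as.character(parity)),
         levels = c("1", "2", "3", "4", "5+"))
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of observed genotype counts against
#' Hardy-Weinberg expectations at the observed allele frequency, without
#' continuity correction. Monomorphic markers fit exactly (p = 1).
#'
#' @param n_AA,n_AB,n_BB genotype counts.
#' @return The p-value.
#' @examples
#' hwe_test(25, 50, 25)  # exact fit: p = 1
#' @export
hwe_test <- function(n_AA, n_AB, n_BB) {
  n <- n_AA + n_AB + n_BB
  if (n <= 0) stop("no genotype observations")
  p <- (2 * n_AA + n_AB) / (2 * n)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  o <- c(n_AA, n_AB, n_BB)
  nz <- e > 0
  chisq <- sum((o[nz] - e[nz])^2 / e[nz])
  stats::pchisq(chisq, df = 1, lower.tail = FALSE)
}

#' Construct a genotype set
#'
#' @param dosages numeric matrix (animals x markers) of counted-allele
#'   dosages in `{0, 1, 2}` with `NA` for missing calls; animal identifiers
#'   as rownames, marker identifiers as colnames.
#' @param map optional data.frame of marker metadata with columns `marker`,
#'   `chrom`, `pos`; defaults to a synthetic single-chromosome map.
#' @return Object of class `genotype_set`.
#' @export
genotype_set <- function(dosages, map = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("id", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("snp", seq_len(ncol(dosages)))
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  if (is.null(map))
    map <- data.frame(marker = colnames(dosages), chrom = 1L,
                      pos = seq_len(ncol(dosages)), stringsAsFactors = FALSE)
  stopifnot(identical(map$marker, colnames(dosages)))
  structure(list(dosages = dosages, map = map), class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat("genotype_set:", nrow(x$dosages), "animals x",
      ncol(x$dosages), "markers;",
      format(100 * mean(is.na(x$dosages)), digits = 3), "% missing\n")
  invisible(x)
}

#' Allele frequencies of the counted allele
#' @param gs a [genotype_set()].
#' @return Per-marker frequency over non-missing calls.
#' @export
allele_freqs <- function(gs) {
  colMeans(gs$dosages, na.rm = TRUE) / 2
}

#' Call rates
#' @param gs a [genotype_set()].
#' @return List with `animal` and `marker` call-rate vectors.
#' @export
call_rates <- function(gs) {
  list(animal = rowMeans(!is.na(gs$dosages)),
       marker = colMeans(!is.na(gs$dosages)))
}

#' SNP and animal quality control
#'
#' Animal-level filtering precedes marker-level filtering: animals with a
#' call rate below `animal_call_min` are removed first, then markers failing
#' the call-rate, minor-allele-frequency, or Hardy-Weinberg thresholds
#' (computed over the surviving animals) are removed.
#'
#' @param gs a [genotype_set()].
#' @param animal_call_min minimum per-animal call rate (default 0.95).
#' @param snp_call_min minimum per-marker call rate (default 0.90).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_alpha Hardy-Weinberg rejection threshold (default 1e-6).
#' @return Filtered `genotype_set` with an attribute `qc_log`: a data.frame
#'   of removed animals/markers and the first rule each violated.
#' @export
snp_qc <- function(gs, animal_call_min = 0.95, snp_call_min = 0.90,
                   maf_min = 0.01, hwe_alpha = 1e-6) {
  stopifnot(inherits(gs, "genotype_set"))
  stopifnot(animal_call_min > 0, animal_call_min < 1,
            snp_call_min > 0, snp_call_min < 1)
  log_ <- data.frame(unit = character(0), id = character(0),
                     reason = character(0), stringsAsFactors = FALSE)
  cr_a <- rowMeans(!is.na(gs$dosages))
  bad_a <- cr_a < animal_call_min
  if (any(bad_a))
    log_ <- rbind(log_, data.frame(unit = "animal",
                                   id = rownames(gs$dosages)[bad_a],
                                   reason = "call_rate"))
  M <- gs$dosages[!bad_a, , drop = FALSE]

  cr_m <- colMeans(!is.na(M))
  p <- colMeans(M, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  hwe_p <- vapply(seq_len(ncol(M)), function(k) {
    x <- M[, k]
    hwe_test(sum(x == 2, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
             sum(x == 0, na.rm = TRUE))
  }, numeric(1))
  reason <- rep(NA_character_, ncol(M))
  reason[hwe_p < hwe_alpha] <- "hwe"
  reason[is.na(maf) | maf < maf_min] <- "maf"
  reason[cr_m < snp_call_min] <- "call_rate"
  bad_m <- !is.na(reason)
  if (all(bad_m)) stop("all markers removed by quality control")
  if (any(bad_m))
    log_ <- rbind(log_, data.frame(unit = "marker",
                                   id = colnames(M)[bad_m],
                                   reason = reason[bad_m]))
  out <- genotype_set(M[, !bad_m, drop = FALSE],
                      gs$map[!bad_m, , drop = FALSE])
  attr(out, "qc_log") <- log_
  out
}

#' Write the QC report
#' @param gs a `genotype_set` returned by [snp_qc()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(gs, path) {
  log_ <- attr(gs, "qc_log")
  if (is.null(log_)) stop("no qc_log attribute; run snp_qc() first")
  utils::write.table(log_, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Centered marker covariates
#'
#' Mean-imputes missing dosages per marker and centers every column to mean
#' zero over the supplied animals, yielding the marker covariate matrix of
#' the genotyped animals.
#'
#' @param gs a [genotype_set()] (post-QC).
#' @return Numeric matrix of centered covariates with zero column means.
#' @export
marker_covariates <- function(gs) {
  M <- gs$dosages
  mu <- colMeans(M, na.rm = TRUE)
  for (k in which(colSums(is.na(M)) > 0)) M[is.na(M[, k]), k] <- mu[k]
  sweep(M, 2, colMeans(M), "-")
}

## ---- file formats ----------------------------------------------------------

#' Read / write a pedigree CSV
#'
#' Columns: `animal,sire,dam,birth_order,breed`. Empty sire/dam fields denote
#' unrecorded parents; breed labels are meaningful for founders only.
#'
#' @param path file path.
#' @return [read_pedigree_csv()]: a [goat_pedigree()].
#' @export
read_pedigree_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(animal = "character",
                                       sire = "character",
                                       dam = "character"))
  goat_pedigree(df$animal, df$sire, df$dam, df$birth_order, df$breed)
}

#' @rdname read_pedigree_csv
#' @param ped a [goat_pedigree()].
#' @export
write_pedigree_csv <- function(ped, path) {
  df <- as.data.frame(ped)
  df$sire[is.na(df$sire)] <- ""
  df$dam[is.na(df$dam)] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a phenotype CSV
#'
#' Columns: `animal,parity,lactation_length,dim,dmkd,milk_yield,fat_yield,`
#' `protein_yield,scs`.
#' @param path file path.
#' @return [read_phenotypes_csv()]: a data.frame of lactation records.
#' @export
read_phenotypes_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(animal = "character"))
}

#' @rdname read_phenotypes_csv
#' @param records data.frame of lactation records.
#' @export
write_phenotypes_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write genotypes as a PLINK text fileset
#'
#' The `.ped` file carries family/animal/sire/dam/sex/phenotype columns
#' followed by two allele calls per marker, with alleles coded `A` (the
#' counted allele) and `B` and missing calls as `0 0`; the `.map` file
#' carries chromosome, marker id, genetic distance and position.
#'
#' @param prefix path prefix; `<prefix>.ped` and `<prefix>.map` are used.
#' @return [read_plink()]: a [genotype_set()].
#' @export
read_plink <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), stringsAsFactors = FALSE,
                           col.names = c("chrom", "marker", "cm", "pos"))
  ped <- utils::read.table(paste0(prefix, ".ped"), stringsAsFactors = FALSE,
                           colClasses = "character")
  p <- nrow(map)
  stopifnot(ncol(ped) == 6 + 2 * p)
  al1 <- as.matrix(ped[, 6 + 2 * seq_len(p) - 1, drop = FALSE])
  al2 <- as.matrix(ped[, 6 + 2 * seq_len(p), drop = FALSE])
  dos <- (al1 == "A") + (al2 == "A")
  dos[al1 == "0" | al2 == "0"] <- NA
  rownames(dos) <- ped[[2]]
  colnames(dos) <- map$marker
  genotype_set(dos, data.frame(marker = map$marker, chrom = map$chrom,
                               pos = map$pos, stringsAsFactors = FALSE))
}

#' @rdname read_plink
#' @param gs a [genotype_set()].
#' @export
write_plink <- function(gs, prefix) {
  map <- data.frame(chrom = gs$map$chrom, marker = gs$map$marker, cm = 0,
                    pos = gs$map$pos)
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  D <- gs$dosages
  n <- nrow(D); p <- ncol(D)
  alleles <- matrix("0", n, 2 * p)
  a1 <- ifelse(is.na(D), "0", ifelse(D >= 1, "A", "B"))
  a2 <- ifelse(is.na(D), "0", ifelse(D == 2, "A", "B"))
  alleles[, 2 * seq_len(p) - 1] <- a1
  alleles[, 2 * seq_len(p)] <- a2
  out <- cbind("FAM1", rownames(D), "0", "0", "0", "-9", alleles)
  utils::write.table(out, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read / write genotypes as an additive-dosage CSV
#'
#' First column `animal`, then one column per marker holding dosages 0/1/2
#' (empty = missing).
#' @param path file path.
#' @return [read_dosage_csv()]: a [genotype_set()].
#' @export
read_dosage_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = c(animal = "character"))
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "numeric"
  rownames(M) <- df$animal
  genotype_set(M)
}

#' @rdname read_dosage_csv
#' @param gs a [genotype_set()].
#' @export
write_dosage_csv <- function(gs, path) {
  df <- data.frame(animal = rownames(gs$dosages), gs$dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
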