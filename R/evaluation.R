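#' Age-based training/validation split
#'
#' Splits the phenotyped herd into a training set of the oldest
#' `fraction_training` of animals (smallest birth order; ties broken by
#' identifier) and a validation set of the youngest remainder, whose
#' phenotypes are withheld from model fitting.
#'
#' @param herd data.frame with columns `animal` and `birth_order`.
#' @param fraction_training proportion in (0, 1); default 0.7.
#' @return List with `training_ids` and `validation_ids` (disjoint,
#'   covering the herd). Training size is `floor(fraction_training * n)`.
#' @examples
#' h <- data.frame(animal = as.character(1:10), birth_order = 1:10)
#' lengths(age_split(h))  # 7 training, 3 validation
#' @export
age_split <- function(herd, fraction_training = 0.7) {
  stopifnot(fraction_training > 0, fraction_training < 1)
  n <- nrow(herd)
  if (n < 2) stop("need at least two animals to split")
  ord <- order(herd$birth_order, herd$animal)
  n_train <- floor(fraction_training * n)
  list(training_ids = herd$animal[ord[seq_len(n_train)]],
       validation_ids = herd$animal[ord[(n_train + 1):n]])
}

#' Classify validation animals by available pedigree information
#'
#' Assigns each validation animal every label whose condition holds (the
#' categories overlap by construction):
#' A — both sire and dam recorded; B — sire recorded with at least
#' `min_progeny` progeny in the herd; C — dam recorded with at least one
#' lactation record; D — neither parent recorded.
#'
#' @param validation_ids identifiers of validation animals.
#' @param ped a [goat_pedigree()].
#' @param phenotyped_ids identifiers of animals with lactation records.
#' @param min_progeny sire-progeny threshold for scenario B (default 5).
#' @return data.frame with columns `animal`, logical `A`, `B`, `C`, `D`,
#'   and an attribute `counts` with the per-label totals.
#' @export
classify_scenarios <- function(validation_ids, ped, phenotyped_ids,
                               min_progeny = 5) {
  i <- match(validation_ids, ped$animal)
  if (anyNA(i)) stop("validation animals absent from pedigree")
  sire <- ped$sire[i]; dam <- ped$dam[i]
  progeny <- table(c(ped$sire, ped$dam))
  n_prog <- function(id) ifelse(is.na(id), 0L,
                                as.integer(progeny[id]))
  np <- vapply(sire, n_prog, integer(1))
  out <- data.frame(
    animal = validation_ids,
    A = !is.na(sire) & !is.na(dam),
    B = !is.na(sire) & np >= min_progeny,
    C = !is.na(dam) & dam %in% phenotyped_ids,
    D = is.na(sire) & is.na(dam),
    stringsAsFactors = FALSE)
  attr(out, "counts") <- colSums(out[, c("A", "B", "C", "D")])
  out
}

#' Mask the parents of selected animals
#'
#' Sets the sire and dam of each target animal to missing and rebuilds
#' (re-sorts) the pedigree, leaving all other records untouched. Used to
#' rerun the evaluation as if the target animals had no recorded pedigree.
#'
#' @param ped a [goat_pedigree()].
#' @param target_ids identifiers whose parents are masked.
#' @return A new [goat_pedigree()].
#' @export
mask_parents <- function(ped, target_ids) {
  stopifnot(inherits(ped, "goat_pedigree"))
  hit <- ped$animal %in% target_ids
  sire <- ped$sire; dam <- ped$dam
  sire[hit] <- NA_character_; dam[hit] <- NA_character_
  goat_pedigree(ped$animal, sire, dam, ped$birth_order, ped$breed)
}

#' Standardize breeding values to a genetic base
#'
#' Expresses breeding values as deviations from the mean of a base group,
#' so EBVs and GBVs from independent evaluations are on a consistent base.
#' Idempotent: standardizing twice with the same base changes nothing.
#'
#' @param values named numeric vector of breeding values.
#' @param base_ids identifiers of the base group (non-empty, present in
#'   `values`).
#' @return `values` minus the mean over `base_ids`.
#' @export
standardize_to_base <- function(values, base_ids) {
  base_ids <- intersect(base_ids, names(values))
  if (length(base_ids) == 0) stop("empty base group")
  values - mean(values[base_ids])
}

#' Genomic inflation slope
#'
#' Ordinary least-squares slope of standardized GBVs on standardized EBVs,
#' together with their Pearson correlation. A slope of one indicates that
#' the genomic predictions are on the same scale as the pedigree
#' predictions (no inflation or deflation).
#'
#' @param gbv_std,ebv_std standardized breeding values (length >= 3).
#' @return List with `slope`, `correlation`, `se` (standard error of the
#'   slope).
#' @export
inflation_slope <- function(gbv_std, ebv_std) {
  stopifnot(length(gbv_std) == length(ebv_std))
  n <- length(ebv_std)
  if (n < 3) stop("need at least 3 animals")
  sxx <- sum((ebv_std - mean(ebv_std))^2)
  if (sxx == 0) stop("EBVs have zero variance")
  slope <- sum((ebv_std - mean(ebv_std)) *
                 (gbv_std - mean(gbv_std))) / sxx
  res <- gbv_std - mean(gbv_std) - slope * (ebv_std - mean(ebv_std))
  list(slope = slope,
       correlation = stats::cor(gbv_std, ebv_std),
       se = sqrt(sum(res^2) / (n - 2) / sxx))
}

#' Combine breed and J coefficients
#'
#' The breed effect reported from the single-step model is the sum of the
#' breed coefficient and the breed-specific J coefficient per group (the
#' Saanen breed coefficient is constrained to zero), because the two sets
#' are confounded individually but their sum is well estimated. When
#' posterior draws are supplied, the standard error of each sum is the
#' posterior standard deviation of the per-draw sum.
#'
#' @param d_hat named breed coefficients (`anto`, `unknown`; Saanen
#'   implicitly 0).
#' @param q_hat named J coefficients for all three groups.
#' @param d_draws,q_draws optional posterior draw matrices (columns named
#'   as the coefficients).
#' @return data.frame with columns `breed`, `combined`, and `se` (NA
#'   without draws).
#' @examples
#' combine_breed_and_J(c(anto = 94.04, unknown = -164.89),
#'                     c(saanen = -112.54, anto = -458.60,
#'                       unknown = 100.85))
#' @export
combine_breed_and_J <- function(d_hat, q_hat, d_draws = NULL,
                                q_draws = NULL) {
  groups <- breed_groups()
  if (!all(names(q_hat) %in% groups) || !all(names(d_hat) %in% groups))
    stop("mismatched breed groups between d and q coefficients")
  d_full <- stats::setNames(numeric(3), groups)
  d_full[names(d_hat)] <- d_hat
  q_full <- stats::setNames(numeric(3), groups)
  q_full[names(q_hat)] <- q_hat
  se <- rep(NA_real_, 3)
  if (!is.null(d_draws) && !is.null(q_draws)) {
    for (g in seq_along(groups)) {
      dg <- if (groups[g] %in% colnames(d_draws))
        d_draws[, groups[g]] else 0
      qg <- if (groups[g] %in% colnames(q_draws))
        q_draws[, groups[g]] else 0
      se[g] <- stats::sd(dg + qg)
    }
  }
  data.frame(breed = groups, combined = unname(d_full + q_full), se = se,
             stringsAsFactors = FALSE)
}

#' Percent gain in prediction accuracy
#'
#' Relative gain of genomic over pedigree accuracy,
#' `100 * (r_gbv - r_ebv) / r_ebv`, rounded to the nearest integer for
#' reporting (computed from unrounded accuracies).
#'
#' @param r_ebv,r_gbv mean prediction accuracies; `r_ebv` must be > 0 for
#'   the gain to be defined.
#' @param round round to integer percent (default `TRUE`).
#' @return Percent gain, or `NA` (undefined) when `r_ebv` is 0.
#' @examples
#' percent_gain(0.22, 0.38)  # +73
#' @export
percent_gain <- function(r_ebv, r_gbv, round = TRUE) {
  if (any(r_ebv < 0, na.rm = TRUE))
    stop("accuracies must be non-negative")
  g <- ifelse(is.na(r_ebv) | is.na(r_gbv) | r_ebv == 0, NA_real_,
              100 * (r_gbv - r_ebv) / r_ebv)
  if (round) g <- round(g)
  g
}

#' Scatterplot of standardized GBVs against EBVs
#'
#' @param gbv_std,ebv_std standardized breeding values.
#' @param main plot title.
#' @return The [inflation_slope()] result, invisibly.
#' @export
plot_inflation <- function(gbv_std, ebv_std, main = "GBV vs EBV") {
  sl <- inflation_slope(gbv_std, ebv_std)
  graphics::plot(ebv_std, gbv_std, pch = 20,
                 xlab = "standardized EBV", ylab = "standardized GBV",
                 main = main)
  graphics::abline(stats::lm(gbv_std ~ ebv_std), col = "red")
  graphics::abline(0, 1, lty = 2, col = "grey50")
  graphics::legend("topleft", bty = "n", legend = sprintf(
    "slope = %.2f, r = %.2f", sl$slope, sl$correlation))
  invisible(sl)
}
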