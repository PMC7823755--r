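#' Prior variance components for the evaluated traits
#'
#' Across-breed variance components used as known ("parametric") values in
#' both evaluation models, estimated beforehand on a much larger population
#' of the same breeds: the residual polygenic variance, the variance captured
#' by the markers, and the residual variance, per trait, together with the
#' mixture-prior null probability `pi`.
#'
#' @return data.frame with one row per trait (`milk_yield`, `fat_yield`,
#'   `protein_yield`, `scs`) and columns `polygenic`, `snp`, `residual`,
#'   `pi`.
#' @export
trait_variances <- function() {
  data.frame(
    trait = c("milk_yield", "fat_yield", "protein_yield", "scs"),
    polygenic = c(9098.6, 8.66, 5.69, 0.51),
    snp = c(1011.0, 1.33, 0.88, 0.08),
    residual = c(30345.0, 35.20, 23.10, 2.50),
    pi = 0.98,
    stringsAsFactors = FALSE
  )
}

#' Model parameters for one trait
#'
#' Assembles the per-trait parameter set used by both models: total genetic
#' variance (polygenic + marker-captured), residual variance, the polygenic
#' fraction `w` of the genetic variance, and the mixture null probability
#' `pi`. By default `w` is derived from the variance components themselves
#' (`polygenic / (polygenic + snp)`), keeping the marker-captured fraction
#' consistent with the component table.
#'
#' @param trait one of `"milk_yield"`, `"fat_yield"`, `"protein_yield"`,
#'   `"scs"`.
#' @param w optional override of the polygenic fraction.
#' @return List with `sigma_g2`, `sigma_e2`, `w`, `pi`, `h2`.
#' @export
trait_params <- function(trait = c("milk_yield", "fat_yield",
                                   "protein_yield", "scs"), w = NULL) {
  trait <- match.arg(trait)
  tv <- trait_variances()
  row <- tv[tv$trait == trait, ]
  sigma_g2 <- row$polygenic + row$snp
  if (is.null(w)) w <- row$polygenic / sigma_g2
  list(trait = trait, sigma_g2 = sigma_g2, sigma_e2 = row$residual,
       w = w, pi = row$pi, h2 = sigma_g2 / (sigma_g2 + row$residual))
}
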