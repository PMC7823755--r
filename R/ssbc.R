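#' Impute marker covariates for non-genotyped animals
#'
#' Marker covariates of non-genotyped animals are their conditional
#' expectations given genotyped relatives, `Mn = Ang Agg^-1 Mg`, computed by
#' solving linear systems in `Agg` (the explicit inverse is never formed).
#'
#' @param Mg centered marker covariates of the genotyped animals.
#' @param Ang,Agg relationship-matrix blocks from
#'   [partition_relationship()].
#' @return Matrix of imputed covariates, one row per non-genotyped animal.
#' @export
impute_covariates <- function(Mg, Ang, Agg) {
  stopifnot(ncol(Ang) == nrow(Agg), nrow(Mg) == nrow(Agg))
  sol <- tryCatch(solve(Agg, Mg), error = function(e)
    stop("Agg is singular: ", conditionMessage(e)))
  out <- Ang %*% sol
  rownames(out) <- rownames(Ang)
  out
}

#' Breed-fraction J covariates
#'
#' Builds the J covariates that absorb the mean difference in breeding value
#' between genotyped-founder and non-genotyped-founder animals of each breed
#' group. For genotyped animals `Jg` is the full breed-fraction matrix
#' (including the Saanen column, unlike the breed design `D`); for
#' non-genotyped animals `Jn = Ang Agg^-1 Jg`, the same projection used for
#' the marker covariates.
#'
#' @param composition breed fractions from [breed_composition()].
#' @param genotyped_ids identifiers of genotyped animals.
#' @param Ang,Agg relationship blocks from [partition_relationship()]
#'   (orderings must match `genotyped_ids` / the non-genotyped rows).
#' @return List with matrices `Jg` and `Jn`.
#' @export
build_J <- function(composition, genotyped_ids, Ang, Agg) {
  Jg <- composition[genotyped_ids, , drop = FALSE]
  Jn <- if (nrow(Ang) > 0) impute_covariates(Jg, Ang, Agg)
        else matrix(0, 0, 3, dimnames = list(NULL, colnames(Jg)))
  list(Jg = Jg, Jn = Jn)
}

#' Per-locus prior variance scale
#'
#' Allocates the total marker-captured genetic variance across loci: the
#' common marker-effect variance is chosen so that the expected total,
#' `(1 - pi) * sum_k 2 p_k (1 - p_k) * E[sigma_ak2]`, equals
#' `sigma_snp_total`.
#'
#' @param sigma_snp_total genetic variance to be captured by the markers.
#' @param freqs counted-allele frequencies of the fitted markers.
#' @param pi prior null probability of the mixture (< 1).
#' @return The expected per-locus effect variance `E[sigma_ak2]`.
#' @export
marker_prior_scale <- function(sigma_snp_total, freqs, pi) {
  if (pi >= 1) stop("pi must be < 1 for markers to carry variance")
  denom <- sum(2 * freqs * (1 - freqs))
  if (denom <= 0) stop("all markers are monomorphic")
  sigma_snp_total / ((1 - pi) * denom)
}

#' Assemble the single-step BayesC model
#'
#' Builds every ingredient of the single-step Bayesian regression: the
#' fixed-effect design shared with the animal model, centered marker
#' covariates of genotyped animals and their pedigree imputation for
#' non-genotyped animals, the J covariates, the sparse inverse relationship
#' matrix for the polygenic effect, and the imputation-residual precision
#' (the non-genotyped block of the inverse relationship matrix).
#'
#' @param records edited lactation records (training phenotypes only).
#' @param ped a [goat_pedigree()].
#' @param gs a post-QC [genotype_set()]; animals not in the pedigree are
#'   ignored.
#' @param composition breed fractions; defaults to
#'   [breed_composition()] of `ped`.
#' @param trait phenotype column to model.
#' @param params variance/prior parameters from [trait_params()], or a list
#'   with `sigma_g2`, `sigma_e2`, `w`, `pi`.
#' @return Object of class `ssbc_model`.
#' @export
ssbc_model <- function(records, ped, gs,
                       composition = breed_composition(ped),
                       trait = "milk_yield",
                       params = trait_params(trait)) {
  stopifnot(inherits(ped, "goat_pedigree"), inherits(gs, "genotype_set"))
  base <- pblup_design(records, ped, composition, trait)
  genotyped <- intersect(ped$animal, rownames(gs$dosages))
  if (length(genotyped) == 0) stop("no genotyped animals in the pedigree")

  A <- relationship_matrix(ped)
  part <- partition_relationship(A, genotyped)
  Mg <- marker_covariates(gs)[part$genotyped, , drop = FALSE]
  Mn <- if (length(part$nongenotyped) > 0)
    impute_covariates(Mg, part$Ang, part$Agg)
  else matrix(0, 0, ncol(Mg))
  J <- build_J(composition, part$genotyped, part$Ang, part$Agg)

  n_anim <- nrow(ped)
  M_all <- matrix(0, n_anim, ncol(Mg),
                  dimnames = list(ped$animal, colnames(Mg)))
  M_all[part$genotyped, ] <- Mg
  if (nrow(Mn) > 0) M_all[part$nongenotyped, ] <- Mn
  J_all <- matrix(0, n_anim, 3, dimnames = list(ped$animal, breed_groups()))
  J_all[part$genotyped, ] <- as.matrix(J$Jg)
  if (nrow(J$Jn) > 0) J_all[part$nongenotyped, ] <- as.matrix(J$Jn)

  Ainv <- relationship_inverse(ped)
  ng <- part$nongenotyped
  Knn <- Ainv[ng, ng, drop = FALSE]  # precision of the imputation residual

  freqs <- allele_freqs(gs)
  # pi = 1 empties the mixture: markers stay out of the model entirely
  sigma_a2 <- if (params$pi >= 1) 0 else
    marker_prior_scale((1 - params$w) * params$sigma_g2, freqs, params$pi)
  structure(list(
    y = base$y, X = base$X, zid = base$zid, animal = ped$animal,
    record_animal = base$record_animal,
    D_full = base$D_full, M_all = M_all, J_all = J_all,
    genotyped = part$genotyped, nongenotyped = ng,
    Ainv = Ainv, Knn = Knn, freqs = freqs,
    sigma_g2 = params$sigma_g2, sigma_e2 = params$sigma_e2,
    sigma_a2 = sigma_a2, w = params$w, pi = params$pi,
    trait = trait, centers = base$centers), class = "ssbc_model")
}

#' Run the single-step BayesC Gibbs sampler
#'
#' Single-site Gibbs updates cycling over the flat-prior effects (fixed
#' effects, breed fractions, J covariates), each marker's
#' inclusion-indicator/effect pair from the BayesC full conditional with
#' fixed `pi`, the residual polygenic effects through the sparse inverse
#' relationship matrix, the imputation residuals of non-genotyped animals,
#' and (optionally) the variances from scaled-inverse-chi-square full
#' conditionals. By default the variance components are held fixed at their
#' parametric values.
#'
#' @param model an [ssbc_model()].
#' @param n_iter total chain length (default 50000).
#' @param burn_in discarded initial iterations (default 1000).
#' @param thin keep every `thin`-th post-burn-in draw (default 10).
#' @param seed master seed; all draws flow from R's RNG.
#' @param update_variances if `TRUE`, sample the residual and total genetic
#'   variances; if `FALSE` (default) hold them at their parametric values.
#' @param update_marker_variance if `TRUE` (default), sample the common
#'   marker-effect variance from its scaled-inverse-chi-square full
#'   conditional, letting the mixture adapt to large-effect loci; if
#'   `FALSE` hold it at the allocation of [marker_prior_scale()].
#' @param nu degrees of freedom of the scaled-inverse-chi-square priors
#'   (default 4); prior scales are set from the model's parametric values.
#' @return Object of class `ssbc_mcmc` holding the retained draws of every
#'   unknown, per-marker inclusion frequencies, and chain metadata.
#' @export
ssbc_gibbs <- function(model, n_iter = 50000, burn_in = 1000, thin = 10,
                       seed = 1, update_variances = FALSE,
                       update_marker_variance = TRUE, nu = 4) {
  stopifnot(inherits(model, "ssbc_model"), burn_in < n_iter, thin >= 1)
  set.seed(seed)
  nf_x <- ncol(model$X)
  Frec <- cbind(model$X,
                model$D_full[model$zid, , drop = FALSE],
                model$J_all[model$zid, , drop = FALSE])
  Mrec <- model$M_all[model$zid, , drop = FALSE]
  ng_idx <- match(model$nongenotyped, model$animal)
  if (length(ng_idx) == 0) ng_idx <- integer(0)

  Ag <- as(as(model$Ainv, "generalMatrix"), "CsparseMatrix")
  Kg <- as(as(model$Knn, "generalMatrix"), "CsparseMatrix")

  p <- ncol(Mrec)
  # prior scales: S^2 = E[sigma^2] (nu - 2) / nu so the prior mean matches
  Sa2 <- model$sigma_a2 * (nu - 2) / nu
  Se2 <- model$sigma_e2 * (nu - 2) / nu
  Sg2 <- model$sigma_g2 * (nu - 2) / nu

  # flat-prior effects are drawn as one multivariate-normal block; aliased
  # columns (exact collinearity, e.g. every phenotyped animal genotyped
  # makes the Saanen J covariate equal to the intercept) are pinned to
  # zero, as lm() does for aliased terms
  qrF <- qr(Frec)
  keep <- sort(qrF$pivot[seq_len(qrF$rank)])
  Fk <- Frec[, keep, drop = FALSE]
  Lchol <- t(chol(crossprod(Fk)))

  res <- .gibbs_cpp(
    as.numeric(model$y), Fk, Mrec,
    as.integer(model$zid), length(model$animal), as.integer(ng_idx),
    Ag@p, Ag@i, Ag@x, Kg@p, Kg@i, Kg@x,
    model$pi, model$sigma_e2, model$sigma_g2, model$sigma_a2, model$w,
    update_variances, update_variances, update_marker_variance,
    nu, Se2, nu, Sg2, nu, Sa2,
    as.integer(n_iter), as.integer(burn_in), as.integer(thin),
    Lchol, TRUE)

  beta_full <- matrix(0, nrow(res$beta), ncol(Frec))
  beta_full[, keep] <- res$beta
  nb <- ncol(model$D_full)
  structure(list(
    b = beta_full[, seq_len(nf_x), drop = FALSE],
    d = structure(beta_full[, nf_x + seq_len(nb), drop = FALSE],
                  dimnames = list(NULL, colnames(model$D_full))),
    q = structure(beta_full[, nf_x + nb + seq_len(3), drop = FALSE],
                  dimnames = list(NULL, breed_groups())),
    alpha = res$alpha, u = res$u, eps = res$eps,
    sigma_e2 = res$sigma_e2, sigma_g2 = res$sigma_g2,
    sigma_a2 = res$sigma_a2, inclusion = res$inclusion,
    n_kept = res$n_kept,
    meta = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                seed = seed, update_variances = update_variances,
                update_marker_variance = update_marker_variance, nu = nu,
                fixed_names = colnames(model$X))),
    class = "ssbc_mcmc")
}

#' @export
print.ssbc_mcmc <- function(x, ...) {
  cat("ssbc_mcmc:", x$n_kept, "retained draws (chain", x$meta$n_iter,
      "/ burn-in", x$meta$burn_in, "/ thin", x$meta$thin, ")\n")
  invisible(x)
}

#' Genomic breeding values from an MCMC run
#'
#' Per retained draw, the across-breed genomic breeding value of every
#' pedigree animal is
#' `GBV = D d + J q + M alpha + eps + u`: the breed-expected mean plus all
#' genetic components of the model (marker, imputation-residual, and
#' residual polygenic). With `include_polygenic = FALSE` the polygenic term
#' is left out and the GBV spans only the marker-captured fraction of the
#' genetic variance. The point estimate is the posterior mean. The
#' prediction error variance is the posterior variance of the draws of the
#' animal's genetic deviation (`M alpha + eps + u`), excluding the
#' fixed breed-mean part `D d + J q` — exactly parallel to the animal-model
#' PEV, which likewise excludes the variance of the fixed-effect solutions —
#' and is converted to reliability and accuracy against the total genetic
#' variance. When `base_ids` is supplied the point estimates are expressed
#' as deviations from the mean GBV of that base group (a constant shift;
#' prediction error variances are unaffected).
#'
#' @param run an [ssbc_gibbs()] result.
#' @param model the [ssbc_model()] that produced it.
#' @param include_polygenic add the polygenic draw `u` to each GBV draw
#'   (default `TRUE`; set `FALSE` for the marker-and-breed-only
#'   definition).
#' @param base_ids optional identifiers defining the genetic base.
#' @return Object of class `ssbc_fit`: data.frame `animals` with `animal`,
#'   `gbv`, `pev`, `reliability`, `accuracy`; plus posterior summaries of
#'   breed (`d`), J (`q`), and variance draws.
#' @export
ssbc_gbv <- function(run, model, include_polygenic = TRUE,
                     base_ids = NULL) {
  stopifnot(inherits(run, "ssbc_mcmc"), inherits(model, "ssbc_model"))
  # random genetic components (drive the PEV)
  G <- model$M_all %*% t(run$alpha)
  if (length(model$nongenotyped) > 0 && ncol(run$eps) > 0) {
    ng_rows <- match(model$nongenotyped, model$animal)
    G[ng_rows, ] <- G[ng_rows, ] + t(run$eps)
  }
  if (include_polygenic) G <- G + t(run$u)
  pev <- apply(G, 1, stats::var)
  # full GBV adds the breed-mean part
  G <- G + model$D_full %*% t(run$d) + model$J_all %*% t(run$q)
  rownames(G) <- model$animal
  gbv <- rowMeans(G)
  if (!is.null(base_ids)) gbv <- standardize_to_base(gbv, base_ids)
  ra <- reliability_accuracy(pmin(pev, model$sigma_g2), model$sigma_g2)
  d_hat <- colMeans(run$d); q_hat <- colMeans(run$q)
  structure(list(
    animals = data.frame(animal = model$animal, gbv = gbv, pev = pev,
                         reliability = ra$reliability,
                         accuracy = ra$accuracy, stringsAsFactors = FALSE),
    breed = d_hat, breed_se = apply(run$d, 2, stats::sd),
    J = q_hat, J_se = apply(run$q, 2, stats::sd),
    sigma_g2 = model$sigma_g2, trait = model$trait),
    class = "ssbc_fit")
}

#' Posterior summary TSV
#'
#' Writes the per-animal GBV summary plus per-marker posterior inclusion
#' frequencies.
#' @param fit an [ssbc_gbv()] result.
#' @param run the [ssbc_gibbs()] run.
#' @param model the [ssbc_model()].
#' @param path output path; the marker table goes to
#'   `<path>.markers.tsv`.
#' @return `path`, invisibly.
#' @export
write_ssbc_tsv <- function(fit, run, model, path) {
  utils::write.table(fit$animals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mk <- data.frame(marker = colnames(model$M_all),
                   inclusion = run$inclusion,
                   alpha_mean = colMeans(run$alpha))
  utils::write.table(mk, paste0(path, ".markers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
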