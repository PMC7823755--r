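#' Build the single-trait animal-model design
#'
#' Assembles the design of the multibreed animal model
#' `y = Xb + ZDd + Za + e`: fixed effects are the parity contemporary group
#' (reference class dropped) and the covariates deviation-from-median-kidding
#' date, days in milk, and general heterosis; `D` regresses on the ANTO and
#' unknown breed fractions with the Saanen coefficient constrained to zero;
#' `Z` maps each record to its animal in the pedigree. Covariates are
#' centered for conditioning; the stored centers let the intercept be
#' reported on the original scale.
#'
#' @param records data.frame of edited lactation records (one per animal)
#'   with columns `animal`, `parity`, `dim`, `dmkd` and the trait column.
#' @param ped a [goat_pedigree()] containing every phenotyped animal.
#' @param composition breed-fraction matrix from [breed_composition()].
#' @param trait name of the phenotype column to model.
#' @return Object of class `pblup_model`: the response `y`, fixed design
#'   `X`, record-level breed design `Drec`, full breed design `D_full`
#'   (all pedigree animals), animal index `zid`, and metadata.
#' @export
pblup_design <- function(records, ped, composition = breed_composition(ped),
                         trait = "milk_yield") {
  stopifnot(inherits(ped, "goat_pedigree"))
  if (anyDuplicated(records$animal))
    stop("at most one lactation record per animal is allowed")
  zid <- match(records$animal, ped$animal)
  if (anyNA(zid))
    stop("phenotyped animals absent from pedigree: ",
         paste(records$animal[is.na(zid)], collapse = ", "))
  y <- records[[trait]]
  if (is.null(y)) stop("trait column not found: ", trait)

  pc <- parity_class(records$parity)
  pc <- droplevels(pc)
  Xp <- if (nlevels(pc) > 1)
    stats::model.matrix(~pc)[, -1, drop = FALSE] else NULL
  if (!is.null(Xp))
    colnames(Xp) <- paste0("parity", levels(pc)[-1])
  het <- heterosis(composition, records$animal)
  cov <- cbind(dmkd = records$dmkd, dim = records$dim, heterosis = het)
  centers <- colMeans(cov)
  cov <- sweep(cov, 2, centers, "-")
  X <- cbind(intercept = 1, Xp, cov)

  D_full <- composition[ped$animal, c("anto", "unknown"), drop = FALSE]
  Drec <- D_full[zid, , drop = FALSE]
  structure(list(y = y, X = X, Drec = Drec, D_full = D_full, zid = zid,
                 animal = ped$animal, record_animal = records$animal,
                 centers = centers, trait = trait),
            class = "pblup_model")
}

#' Solve the mixed model equations
#'
#' Henderson's mixed model equations for the animal model, with the ratio
#' `lambda = sigma_e2 / sigma_g2` applied to the animal block through the
#' sparse inverse relationship matrix. Prediction error variances of the
#' animal effects come from the corresponding diagonal block of the inverse
#' coefficient matrix (dense inverse; exact).
#'
#' @param model a [pblup_design()].
#' @param Ainv inverse numerator relationship matrix from
#'   [relationship_inverse()], ordered as the pedigree.
#' @param sigma_g2 additive genetic variance (> 0).
#' @param sigma_e2 residual variance (> 0).
#' @return Object of class `pblup_fit`: data.frame `animals` with columns
#'   `animal`, `a_hat`, `pev`, `reliability`, `accuracy`, plus elements
#'   `fixed` (named vector, intercept on the original covariate scale),
#'   `breed` (ANTO and unknown coefficients), `breed_se`, and the variance
#'   components.
#' @export
pblup_solve <- function(model, Ainv, sigma_g2, sigma_e2) {
  stopifnot(inherits(model, "pblup_model"))
  stopifnot(sigma_g2 > 0, sigma_e2 > 0)
  Fall <- cbind(model$X, breed_anto = model$Drec[, "anto"],
                breed_unknown = model$Drec[, "unknown"])
  # all-zero columns (e.g. no unknown ancestry, purebred herd heterosis)
  # carry no information: their coefficients are fixed at zero
  nonzero <- colSums(Fall != 0) > 0
  F <- Fall[, nonzero, drop = FALSE]
  qrF <- qr(F)
  if (qrF$rank < ncol(F)) {
    bad <- colnames(F)[qrF$pivot[(qrF$rank + 1):ncol(F)]]
    stop("confounded fixed-effect columns: ", paste(bad, collapse = ", "))
  }
  n_anim <- length(model$animal)
  nf <- ncol(F)
  lambda <- sigma_e2 / sigma_g2
  Zt <- Matrix::sparseMatrix(i = model$zid, j = seq_along(model$y),
                             x = 1, dims = c(n_anim, length(model$y)))
  ZtZ <- Matrix::Diagonal(n_anim, x = tabulate(model$zid, n_anim))
  ZtF <- as.matrix(Zt %*% F)
  C <- rbind(cbind(crossprod(F), t(ZtF)),
             cbind(ZtF, as.matrix(ZtZ + lambda * Ainv)))
  rhs <- c(crossprod(F, model$y), as.vector(Zt %*% model$y))
  Cinv <- tryCatch(chol2inv(chol(C)), error = function(e)
    stop("singular mixed-model coefficient matrix: ", conditionMessage(e)))
  sol <- Cinv %*% rhs
  beta <- stats::setNames(numeric(ncol(Fall)), colnames(Fall))
  beta[colnames(F)] <- sol[seq_len(nf)]
  beta_se <- stats::setNames(rep(NA_real_, ncol(Fall)), colnames(Fall))
  beta_se[colnames(F)] <- sqrt(sigma_e2 * diag(Cinv)[seq_len(nf)])
  a_hat <- sol[nf + seq_len(n_anim)]
  pev <- sigma_e2 * diag(Cinv)[nf + seq_len(n_anim)]
  ra <- reliability_accuracy(pev, sigma_g2)

  # intercept back-transformed to the uncentered covariate scale
  fixed <- beta[seq_len(ncol(model$X))]
  fixed["intercept"] <- fixed["intercept"] -
    sum(model$centers * fixed[names(model$centers)])
  breed <- beta[c("breed_anto", "breed_unknown")]
  names(breed) <- c("anto", "unknown")
  breed_se <- beta_se[c("breed_anto", "breed_unknown")]
  names(breed_se) <- names(breed)

  structure(list(
    animals = data.frame(animal = model$animal, a_hat = a_hat, pev = pev,
                         reliability = ra$reliability,
                         accuracy = ra$accuracy, stringsAsFactors = FALSE),
    fixed = fixed, breed = breed, breed_se = breed_se,
    sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, trait = model$trait),
    class = "pblup_fit")
}

#' Across-breed estimated breeding values
#'
#' `EBV_i = D_i d_hat + a_hat_i` for every pedigree animal, phenotyped or
#' not: the breed-expected mean plus the animal's additive deviation.
#'
#' @param fit a [pblup_solve()] result.
#' @param D_full breed design over all animals (columns `anto`, `unknown`);
#'   taken from the model by default.
#' @param model the [pblup_design()] used for the fit (supplies `D_full`).
#' @return Named vector of EBVs over all pedigree animals.
#' @export
pblup_ebv <- function(fit, model = NULL, D_full = model$D_full) {
  stopifnot(inherits(fit, "pblup_fit"))
  if (is.null(D_full)) stop("supply `model` or `D_full`")
  ebv <- as.vector(D_full %*% fit$breed) + fit$animals$a_hat
  names(ebv) <- fit$animals$animal
  ebv
}

#' Reliability and accuracy from prediction error variance
#'
#' `reliability = 1 - PEV / sigma_g2`; `accuracy = sqrt(reliability)`.
#' PEVs outside `[0, sigma_g2]` are clipped with a warning (they can arise
#' only from numerical error).
#'
#' @param pev vector of prediction error variances.
#' @param sigma_g2 total genetic variance (> 0).
#' @return List with `reliability` and `accuracy` vectors.
#' @export
reliability_accuracy <- function(pev, sigma_g2) {
  if (sigma_g2 <= 0) stop("sigma_g2 must be positive")
  if (any(pev < -1e-8 * sigma_g2 | pev > sigma_g2 * (1 + 1e-8)))
    warning("PEV outside [0, sigma_g2]; clipping")
  rel <- pmin(pmax(1 - pev / sigma_g2, 0), 1)
  list(reliability = rel, accuracy = sqrt(rel))
}

#' Write per-animal solutions as TSV
#'
#' @param fit a `pblup_fit` or `ssbc_fit`.
#' @param model the corresponding design/model object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_solutions_tsv <- function(fit, model, path) {
  df <- fit$animals
  if (inherits(fit, "pblup_fit")) {
    df$ebv <- pblup_ebv(fit, model)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
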