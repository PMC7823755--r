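# shared fixtures and independent oracles

# trio: sire, dam, offspring
trio_ped <- function() {
  goat_pedigree(c("s", "d", "o"), c(NA, NA, "s"), c(NA, NA, "d"),
                breed = c("saanen", "anto", NA))
}

# small config for fast herd simulation
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_founder_sires = 5, n_founder_dams = 12,
         n_per_generation = c(20, 20), n_markers = 80, n_qtl = 6),
    list(...))
  do.call(sim_config, args)
}

# Monte-Carlo gene-dropping estimate of the additive relationship matrix:
# founders carry unique allele labels; alleles drop through the pedigree;
# relationships are twice the proportion of alleles identical by descent.
gene_drop_A <- function(ped, ndrop = 1e5) {
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$animal
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  a1 <- matrix(0L, n, ndrop); a2 <- matrix(0L, n, ndrop)
  next_allele <- 0L
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      a1[i, ] <- next_allele + 1L; next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(ndrop) < 0.5
      a1[i, ] <- ifelse(pick, a1[si[i], ], a2[si[i], ])
    }
    if (is.na(di[i])) {
      a2[i, ] <- next_allele + 1L; next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(ndrop) < 0.5
      a2[i, ] <- ifelse(pick, a1[di[i], ], a2[di[i], ])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        A[i, i] <- 1 + mean(a1[i, ] == a2[i, ])
      } else {
        f <- mean((a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
                    (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])) / 4
        A[i, j] <- A[j, i] <- 2 * f
      }
    }
  }
  A
}

# exact mixed-model (GLS) oracle for the animal model via the full variance
# matrix; returns fixed solutions and BLUPs
gls_oracle <- function(y, F, Z, A, sigma_g2, sigma_e2) {
  V <- sigma_g2 * Z %*% A %*% t(Z) + sigma_e2 * diag(length(y))
  Vi <- solve(V)
  beta <- solve(t(F) %*% Vi %*% F, t(F) %*% Vi %*% y)
  a <- sigma_g2 * A %*% t(Z) %*% Vi %*% (y - F %*% beta)
  list(beta = as.vector(beta), a = as.vector(a))
}

# incidence matrix of records on animals
incidence_Z <- function(zid, n_anim) {
  Z <- matrix(0, length(zid), n_anim)
  Z[cbind(seq_along(zid), zid)] <- 1
  Z
}

# batch-means Monte-Carlo standard errors of posterior means (per column)
mc_se <- function(draws, n_batches = 20) {
  n <- nrow(draws)
  bs <- floor(n / n_batches)
  bm <- sapply(seq_len(n_batches), function(b)
    colMeans(draws[(b - 1) * bs + seq_len(bs), , drop = FALSE]))
  if (is.null(dim(bm))) bm <- matrix(bm, nrow = 1)
  apply(bm, 1, stats::sd) / sqrt(n_batches)
}
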