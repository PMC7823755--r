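test_that("covariate imputation follows the relationship projection", {
  # non-genotyped offspring of two genotyped, unrelated parents:
  # Ang Agg^-1 = (0.5, 0.5), so the imputed row is the parent mean
  ped <- trio_ped()
  A <- relationship_matrix(ped)
  part <- partition_relationship(A, c("s", "d"))
  Mg <- rbind(c(1, -1, 0.5), c(0, 1, -0.5))
  Mn <- impute_covariates(Mg, part$Ang, part$Agg)
  expect_equal(unname(Mn["o", ]), colMeans(Mg))
  # animal unrelated to every genotyped animal gets a zero row
  ped2 <- goat_pedigree(c("g1", "g2", "x"), NA, NA)
  part2 <- partition_relationship(relationship_matrix(ped2), c("g1", "g2"))
  expect_equal(unname(impute_covariates(Mg[, 1:2], part2$Ang,
                                        part2$Agg)["x", ]), c(0, 0))
  # dense-inverse oracle on a simulated pedigree
  set.seed(71)
  sim <- simulate_pedigree(tiny_config())
  A <- relationship_matrix(sim$ped)
  g <- sample(sim$ped$animal, 15)
  part <- partition_relationship(A, g)
  Mg <- matrix(rnorm(15 * 7), 15, 7)
  Mn <- impute_covariates(Mg, part$Ang, part$Agg)
  expect_lt(max(abs(Mn - part$Ang %*% solve(part$Agg) %*% Mg)), 1e-9)
  # projecting the genotyped block through itself reproduces it exactly
  expect_equal(unname(impute_covariates(Mg, part$Agg, part$Agg)),
               unname(Mg), tolerance = 1e-9)
})

test_that("J covariates use the same projection as the markers", {
  ped <- goat_pedigree(c("s", "d", "o"), c(NA, NA, "s"), c(NA, NA, "d"),
                       breed = c("saanen", "anto", NA))
  comp <- breed_composition(ped)
  A <- relationship_matrix(ped)
  part <- partition_relationship(A, c("s", "d"))
  J <- build_J(comp, part$genotyped, part$Ang, part$Agg)
  expect_equal(unname(J$Jg["s", ]), c(1, 0, 0))  # genotyped purebred Saanen
  expect_equal(unname(J$Jn["o", ]), c(0.5, 0.5, 0))  # parent-mean row
  # all animals genotyped: no imputed block
  partg <- partition_relationship(A, ped$animal)
  Jg <- build_J(comp, partg$genotyped, partg$Ang, partg$Agg)
  expect_equal(nrow(Jg$Jn), 0L)
})

test_that("the marker-variance allocation reproduces the target", {
  # single marker at p = 0.5, pi = 0
  expect_equal(marker_prior_scale(10, 0.5, 0), 10 / 0.5)
  # doubling the marker count halves the per-locus scale
  f <- rep(0.3, 8)
  expect_equal(marker_prior_scale(5, c(f, f), 0.9),
               marker_prior_scale(5, f, 0.9) / 2)
  # plug-back identity for a random frequency vector
  set.seed(12)
  fr <- runif(50, 0.05, 0.95)
  s <- marker_prior_scale(123.4, fr, 0.98)
  expect_equal((1 - 0.98) * sum(2 * fr * (1 - fr)) * s, 123.4,
               tolerance = 1e-10)
  expect_error(marker_prior_scale(1, c(0, 1), 0.5), "monomorphic")
  expect_error(marker_prior_scale(1, 0.5, 1), "pi")
})

test_that("the model assembly centers markers and stacks blocks", {
  set.seed(42)
  h <- simulate_herd(tiny_config(), seed = 11)
  kept <- filter_lactations(h$records)$kept
  sm <- ssbc_model(kept, h$ped, h$gs)
  # genotyped rows are the centered observed covariates
  expect_lt(max(abs(colMeans(sm$M_all[sm$genotyped, ]))), 1e-10)
  # imputed rows of a childless animal with two genotyped parents equal
  # the parent mean (conditional expectation given the genotyped set)
  ped <- h$ped
  parents <- c(ped$sire, ped$dam)
  cand <- sm$nongenotyped[vapply(sm$nongenotyped, function(a) {
    r <- ped[ped$animal == a, ]
    !is.na(r$sire) && !is.na(r$dam) &&
      r$sire %in% sm$genotyped && r$dam %in% sm$genotyped &&
      !(a %in% parents)
  }, logical(1))]
  for (a in cand) {
    r <- ped[ped$animal == a, ]
    expect_equal(sm$M_all[a, ],
                 (sm$M_all[r$sire, ] + sm$M_all[r$dam, ]) / 2,
                 tolerance = 1e-9)
    expect_equal(sm$J_all[a, ],
                 (sm$J_all[r$sire, ] + sm$J_all[r$dam, ]) / 2,
                 tolerance = 1e-9)
  }
  expect_error(ssbc_model(kept, h$ped,
                          genotype_set(matrix(0, 1, 2,
                            dimnames = list("zz", c("a", "b"))))),
               "no genotyped")
})

test_that("Gibbs draws match the exact joint solution of the linear model", {
  # pi = 0 and fixed variances make the model jointly Gaussian, so the
  # posterior mean equals the solution of one big mixed-model system;
  # non-genotyped animals exercise the imputation-residual machinery
  set.seed(19)
  h <- simulate_herd(tiny_config(n_markers = 25), seed = 21)
  kept <- filter_lactations(h$records)$kept
  pars <- trait_params("milk_yield")
  pars$pi <- 0
  sm <- ssbc_model(kept, h$ped, h$gs, params = pars)
  run <- ssbc_gibbs(sm, n_iter = 42000, burn_in = 2000, thin = 4,
                    seed = 5, update_marker_variance = FALSE)
  n_anim <- length(sm$animal)
  Frec <- cbind(sm$X, sm$D_full[sm$zid, ], sm$J_all[sm$zid, ])
  keep <- qr(Frec)$pivot[seq_len(qr(Frec)$rank)]
  Frec <- Frec[, sort(keep)]
  Mrec <- sm$M_all[sm$zid, ]
  Z <- incidence_Z(sm$zid, n_anim)
  Zn <- Z[, match(sm$nongenotyped, sm$animal), drop = FALSE]
  W <- cbind(Frec, Mrec, Z, Zn)
  K <- crossprod(W)
  nf <- ncol(Frec); p <- ncol(Mrec)
  lam_a <- pars$sigma_e2 / sm$sigma_a2
  iu <- nf + p + seq_len(n_anim)
  ie <- nf + p + n_anim + seq_along(sm$nongenotyped)
  diag(K)[nf + seq_len(p)] <- diag(K)[nf + seq_len(p)] + lam_a
  K[iu, iu] <- K[iu, iu] + pars$sigma_e2 *
    as.matrix(sm$Ainv) / (sm$w * pars$sigma_g2)
  K[ie, ie] <- K[ie, ie] + pars$sigma_e2 *
    as.matrix(sm$Knn) / ((1 - sm$w) * pars$sigma_g2)
  sol <- solve(K, crossprod(W, sm$y))
  # compare posterior means to the exact solution, scaled by MC error
  est <- c(colMeans(run$alpha), colMeans(run$u), colMeans(run$eps))
  se <- c(mc_se(run$alpha), mc_se(run$u), mc_se(run$eps))
  truth <- c(sol[nf + seq_len(p)], sol[iu], sol[ie])
  z <- abs(est - truth) / pmax(se, 1e-8)
  expect_lt(mean(z > 3), 0.05)
  expect_gt(cor(est, truth), 0.999)
})

test_that("ssBC with markers and imputation switched off matches PBLUP", {
  # pi = 1 empties the mixture and w = 1 removes the imputation residual:
  # what remains is exactly the animal model with J columns appended
  set.seed(77)
  h <- simulate_herd(tiny_config(), seed = 31)
  kept <- filter_lactations(h$records)$kept
  pars <- trait_params("milk_yield")
  pars$pi <- 1; pars$w <- 1
  sm <- ssbc_model(kept, h$ped, h$gs, params = pars)
  run <- ssbc_gibbs(sm, n_iter = 22000, burn_in = 2000, thin = 4, seed = 6)
  expect_true(all(run$alpha == 0))
  # exact MME solution of the same augmented fixed design
  Frec <- cbind(sm$X, sm$D_full[sm$zid, ], sm$J_all[sm$zid, ])
  keep <- sort(qr(Frec)$pivot[seq_len(qr(Frec)$rank)])
  Frec <- Frec[, keep]
  n_anim <- length(sm$animal)
  Z <- incidence_Z(sm$zid, n_anim)
  W <- cbind(Frec, Z)
  K <- crossprod(W)
  iu <- ncol(Frec) + seq_len(n_anim)
  K[iu, iu] <- K[iu, iu] + pars$sigma_e2 * as.matrix(sm$Ainv) /
    pars$sigma_g2
  sol <- solve(K, crossprod(W, sm$y))
  z <- abs(colMeans(run$u) - sol[iu]) / pmax(mc_se(run$u), 1e-8)
  expect_lt(mean(z > 3), 0.05)
  expect_gt(cor(colMeans(run$u), sol[iu]), 0.999)
})

test_that("null data leave the mixture at its prior inclusion rate", {
  # small records, wide residual: the likelihood is flat, so marker
  # inclusion stays near 1 - pi and effects center on zero
  set.seed(55)
  h <- simulate_herd(tiny_config(n_markers = 120), seed = 41)
  kept <- filter_lactations(h$records)$kept
  pars <- trait_params("milk_yield")
  kept$milk_yield <- rnorm(nrow(kept), 0, sqrt(pars$sigma_e2))
  sm <- ssbc_model(kept, h$ped, h$gs, params = pars)
  run <- ssbc_gibbs(sm, n_iter = 6000, burn_in = 1000, thin = 5, seed = 8,
                    update_marker_variance = FALSE)
  expect_lt(max(abs(colMeans(run$alpha))), 3)
  pool <- mean(run$inclusion)
  se <- sd(run$inclusion) / sqrt(ncol(run$alpha))
  expect_lt(abs(pool - 0.02), 3 * se + 0.01)
})

test_that("chain bookkeeping is exact and bit-reproducible", {
  set.seed(9)
  h <- simulate_herd(tiny_config(), seed = 2)
  kept <- filter_lactations(h$records)$kept
  sm <- ssbc_model(kept, h$ped, h$gs)
  r1 <- ssbc_gibbs(sm, n_iter = 600, burn_in = 100, thin = 5, seed = 4)
  expect_equal(r1$n_kept, (600 - 100) / 5)
  expect_equal(nrow(r1$alpha), 100)
  r2 <- ssbc_gibbs(sm, n_iter = 600, burn_in = 100, thin = 5, seed = 4)
  expect_identical(r1$alpha, r2$alpha)
  expect_identical(r1$u, r2$u)
  r3 <- ssbc_gibbs(sm, n_iter = 600, burn_in = 100, thin = 5, seed = 5)
  expect_false(identical(r1$alpha, r3$alpha))
  expect_error(ssbc_gibbs(sm, n_iter = 100, burn_in = 200), "burn_in")
})

test_that("GBV assembly matches a by-hand reconstruction of the draws", {
  set.seed(13)
  h <- simulate_herd(tiny_config(), seed = 3)
  kept <- filter_lactations(h$records)$kept
  sm <- ssbc_model(kept, h$ped, h$gs)
  run <- ssbc_gibbs(sm, n_iter = 1000, burn_in = 200, thin = 4, seed = 2)
  fit <- ssbc_gbv(run, sm)
  # streaming-mean oracle over the stored draws
  G <- sm$D_full %*% t(run$d) + sm$J_all %*% t(run$q) +
    sm$M_all %*% t(run$alpha) + t(run$u)
  G[match(sm$nongenotyped, sm$animal), ] <-
    G[match(sm$nongenotyped, sm$animal), ] + t(run$eps)
  expect_equal(fit$animals$gbv, unname(rowMeans(G)), tolerance = 1e-12)
  # genotyped animals take no imputation-residual contribution
  fit0 <- ssbc_gbv(run, sm, include_polygenic = FALSE)
  Gg <- sm$D_full %*% t(run$d) + sm$J_all %*% t(run$q) +
    sm$M_all %*% t(run$alpha)
  ig <- match(sm$genotyped, sm$animal)
  expect_equal(fit0$animals$gbv[ig], unname(rowMeans(Gg)[ig]),
               tolerance = 1e-12)
  # base standardization shifts point estimates, not PEVs
  fitb <- ssbc_gbv(run, sm, base_ids = sm$genotyped)
  expect_equal(fitb$animals$pev, fit$animals$pev)
  expect_lt(abs(mean(fitb$animals$gbv[ig])), 1e-10)
  expect_true(all(fit$animals$reliability >= 0 &
                    fit$animals$reliability <= 1))
})

test_that("record order does not change the chain", {
  set.seed(23)
  h <- simulate_herd(tiny_config(), seed = 14)
  kept <- filter_lactations(h$records)$kept
  sm1 <- ssbc_model(kept, h$ped, h$gs)
  perm <- sample(nrow(kept))
  sm2 <- ssbc_model(kept[perm, ], h$ped, h$gs)
  r1 <- ssbc_gibbs(sm1, n_iter = 500, burn_in = 100, thin = 2, seed = 9)
  r2 <- ssbc_gibbs(sm2, n_iter = 500, burn_in = 100, thin = 2, seed = 9)
  # update schedule is over animals in pedigree order, so permuting the
  # record rows leaves every draw identical
  expect_equal(r1$u, r2$u, tolerance = 1e-12)
  expect_equal(r1$alpha, r2$alpha, tolerance = 1e-12)
})

test_that("genomic gain vanishes when markers carry no genetic variance", {
  # generator puts the whole genetic variance in the polygenic term
  # (w = 1); the two models then draw on the same information and their
  # mean validation accuracies differ only by noise
  set.seed(24)
  diffs <- numeric(4)
  for (s in 1:4) {
    cfg <- tiny_config(n_per_generation = c(80, 80), n_markers = 150,
                       w = 1)
    h <- simulate_herd(cfg, seed = 30 + s)
    gs <- snp_qc(h$gs)
    kept <- filter_lactations(h$records)$kept
    herd <- data.frame(
      animal = kept$animal,
      birth_order = h$ped$birth_order[match(kept$animal, h$ped$animal)])
    split <- age_split(herd)
    train <- kept[kept$animal %in% split$training_ids, ]
    pars <- trait_params("milk_yield")
    dm <- pblup_design(train, h$ped)
    pf <- suppressWarnings(pblup_solve(dm, relationship_inverse(h$ped),
                                       pars$sigma_g2, pars$sigma_e2))
    sm <- ssbc_model(train, h$ped, gs, params = pars)
    run <- ssbc_gibbs(sm, n_iter = 3000, burn_in = 600, thin = 3,
                      seed = 40 + s)
    sf <- ssbc_gbv(run, sm, base_ids = split$training_ids)
    val <- split$validation_ids
    am <- function(fit) mean(fit$animals$accuracy[
      match(val, fit$animals$animal)])
    diffs[s] <- am(sf) - am(pf)
  }
  # no significant positive genomic gain (one-sided paired check)
  tt <- t.test(diffs, alternative = "greater")
  expect_gt(tt$p.value, 0.01)
})
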