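test_that("pedigree generator produces the configured herd structure", {
  set.seed(1)
  sim <- simulate_pedigree(tiny_config())
  expect_s3_class(sim$ped, "goat_pedigree")
  does <- names(sim$generation)[sim$generation > 0]
  expect_length(does, 40)
  # every doe is sired by a founder sire in the complete pedigree
  tp <- sim$true_ped
  expect_true(all(grepl("^S", tp$sire[tp$animal %in% does])))
  # founder sires have several progeny each (half-sib family structure)
  prog <- table(tp$sire)
  expect_gt(mean(prog), 4)
  # no missing parents when both masking fractions are zero
  set.seed(2)
  sim0 <- simulate_pedigree(tiny_config(missing_sire_frac = 0,
                                        missing_dam_frac = 0))
  off <- sim0$ped[sim0$ped$animal %in% does, ]
  expect_false(anyNA(off$sire))
  expect_false(anyNA(off$dam))
  scen <- classify_scenarios(does, sim0$ped, character(0))
  expect_equal(sum(scen$D), 0)
})

test_that("gene dropping respects Mendelian inheritance and Fst", {
  set.seed(3)
  cfg <- tiny_config(n_markers = 400, missing_call_rate = 0)
  sim <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(sim, cfg)
  dos <- geno$gs_full$dosages
  tp <- sim$true_ped
  # offspring of a 0 x 2 mating is always heterozygous
  for (i in which(!is.na(tp$sire) & !is.na(tp$dam))) {
    s <- dos[tp$sire[i], ]; d <- dos[tp$dam[i], ]; o <- dos[tp$animal[i], ]
    fixed <- (s == 0 & d == 2) | (s == 2 & d == 0)
    expect_true(all(o[fixed] == 1))
    # offspring dosage never exceeds what the parents can transmit
    expect_true(all(o <= ceiling(s / 2) + ceiling(d / 2)))
    expect_true(all(o >= floor(s / 2) + floor(d / 2)))
  }
})

test_that("founder genotypes are Hardy-Weinberg when Fst is zero", {
  set.seed(4)
  cfg <- sim_config(n_founder_sires = 60, n_founder_dams = 240,
                    n_per_generation = c(10), n_markers = 500, fst = 0)
  sim <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(sim, cfg)
  founders <- sim$true_ped$animal[sim$generation == 0]
  dos <- geno$gs_full$dosages[founders, ]
  pass <- vapply(seq_len(ncol(dos)), function(k) {
    x <- dos[, k]
    hwe_test(sum(x == 2), sum(x == 1), sum(x == 0)) >= 0.001
  }, logical(1))
  expect_gte(mean(pass), 0.99)
})

test_that("the Hudson Fst estimator recovers the configured Fst", {
  set.seed(6)
  cfg <- sim_config(n_founder_sires = 150, n_founder_dams = 350,
                    n_per_generation = c(5), n_markers = 2000, fst = 0.1,
                    founder_breed_probs = c(saanen = 0.5, anto = 0.5,
                                            unknown = 0))
  sim <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(sim, cfg)
  tp <- sim$true_ped
  founders <- tp$animal[sim$generation == 0]
  sa <- founders[tp$breed[match(founders, tp$animal)] == "saanen"]
  an <- founders[tp$breed[match(founders, tp$animal)] == "anto"]
  p1 <- colMeans(geno$gs_full$dosages[sa, ]) / 2
  p2 <- colMeans(geno$gs_full$dosages[an, ]) / 2
  n1 <- length(sa); n2 <- length(an)
  # Hudson estimator: ratio of averages
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  fst_hat <- mean(num) / mean(den)
  expect_lt(abs(fst_hat - 0.1), 0.03)
})

test_that("trait architecture decomposes as configured", {
  set.seed(7)
  # residual-only degenerate architecture
  tv <- trait_variances()
  tv$polygenic <- 1e-4; tv$snp <- 1e-4
  cfg <- tiny_config(n_per_generation = c(150, 150), traits = tv,
    breed_effects = list(
    milk_yield = c(anto = 0, unknown = 0), fat_yield = c(anto = 0, unknown = 0),
    protein_yield = c(anto = 0, unknown = 0), scs = c(anto = 0, unknown = 0)),
    heterosis_effects = list(milk_yield = 0, fat_yield = 0,
                             protein_yield = 0, scs = 0))
  h <- simulate_herd(cfg, seed = 8)
  res <- resid(lm(milk_yield ~ parity_class(parity) + dmkd + dim,
                  data = h$records))
  expect_lt(abs(var(res) / tv$residual[1] - 1), 0.35)
})

test_that("realized heritability matches the parametric value at n = 2000", {
  set.seed(9)
  cfg <- sim_config(n_founder_sires = 46, n_founder_dams = 600,
                    n_per_generation = c(670, 670, 660), n_markers = 300,
                    n_qtl = 12)
  h <- simulate_herd(cfg, seed = 10)
  tr <- h$truth$milk_yield
  does <- h$records$animal
  g <- tr$bv[does]
  # realized h2 by the generator's own decomposition: genetic deviations
  # against genetic-plus-residual variance, with the residual taken from
  # the phenotype after removing all modelled fixed and genetic parts
  i <- match(does, h$ped$animal)
  comp <- breed_composition(h$true_ped)
  fixed_part <- cfg$trait_means[["milk_yield"]] +
    cfg$parity_effects$milk_yield[h$records$parity] +
    cfg$beta_dmkd[["milk_yield"]] * h$records$dmkd +
    cfg$beta_dim[["milk_yield"]] * (h$records$dim - 245) +
    cfg$heterosis_effects$milk_yield * heterosis(comp, does) +
    as.vector(comp[does, c("anto", "unknown")] %*% tr$breed_effects)
  e <- h$records$milk_yield - fixed_part - g
  h2 <- var(g) / (var(g) + var(e))
  h2_param <- tr$sigma_g2 / (tr$sigma_g2 + tr$sigma_e2)
  expect_lt(abs(h2 - h2_param), 0.04)
  # phenotype-breeding value correlation approaches h
  expect_lt(abs(cor(g + e, g) - sqrt(h2_param)), 0.05)
})

test_that("somatic cell scores come from per-test counts", {
  set.seed(11)
  h <- simulate_herd(tiny_config(), seed = 12)
  expect_equal(dim(h$scc_tests), c(nrow(h$records), 8))
  expect_true(all(h$scc_tests > 0))
  expect_equal(h$records$scs,
               unname(apply(h$scc_tests, 1, somatic_cell_score)))
})

test_that("simulation is bit-reproducible under a fixed seed", {
  h1 <- simulate_herd(tiny_config(), seed = 42)
  h2 <- simulate_herd(tiny_config(), seed = 42)
  expect_identical(h1$records, h2$records)
  expect_identical(h1$gs$dosages, h2$gs$dosages)
  expect_identical(as.data.frame(h1$ped), as.data.frame(h2$ped))
  h3 <- simulate_herd(tiny_config(), seed = 43)
  expect_false(identical(h1$records$milk_yield, h3$records$milk_yield))
})

test_that("herd writers round-trip through the package readers", {
  h <- simulate_herd(tiny_config(), seed = 13)
  tmp <- withr::local_tempdir()
  write_herd(h, tmp)
  ped <- read_pedigree_csv(file.path(tmp, "pedigree.csv"))
  expect_equal(as.data.frame(ped), as.data.frame(h$ped))
  rec <- read_phenotypes_csv(file.path(tmp, "phenotypes.csv"))
  expect_equal(rec$animal, h$records$animal)
  gs <- read_plink(file.path(tmp, "genotypes"))
  expect_equal(gs$dosages, h$gs$dosages)
  truth <- jsonlite::read_json(file.path(tmp, "truth.json"))
  expect_equal(truth$milk_yield$sigma_g2, h$truth$milk_yield$sigma_g2)
})
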