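#' Simulation configuration
#'
#' Defaults emulate the statistical structure of the herd the evaluation
#' models assume: roughly 839 phenotyped does descending from 46 founder
#' sires, a mixed breed composition dominated by crossbreds of Saanen and
#' the ANTO aggregate, about 46% of the does genotyped (biased toward
#' recent generations), a sparse trait architecture with one large-effect
#' QTL on the milk traits plus a polygenic background, and per-test somatic
#' cell counts from which the somatic cell score is computed. Trait variance
#' components default to [trait_variances()].
#'
#' @param n_founder_sires,n_founder_dams founder counts (46 sires and a
#'   wide pool of 589 dams, most contributing one or two offspring).
#' @param n_per_generation does born per generation (default
#'   `c(280, 280, 279)`, one lactation record each).
#' @param dam_herd_frac probability that a mating uses a phenotyped doe of
#'   the previous generation as dam rather than a founder-pool dam
#'   (default 0.03; dams with their own lactation records are rare in the
#'   herd, as in the scenario-C counts).
#' @param sire_use_shape optional gamma shape for skewed sire-usage
#'   weights (small values concentrate matings on few sires); the default
#'   `NULL` uses all founder sires uniformly, giving half-sib families of
#'   around `sum(n_per_generation) / n_founder_sires` does.
#' @param founder_breed_probs probabilities that a founder is Saanen, ANTO
#'   or of unknown breed.
#' @param n_markers markers on the panel (default 2000).
#' @param n_qtl markers carrying true effects (default 40, matching the
#'   mixture sparsity `(1 - pi) * n_markers` at the default panel size).
#' @param fst differentiation between breed-group founder allele
#'   frequencies (Balding-Nichols; default 0.1).
#' @param genotyped_fraction fraction of phenotyped does genotyped (0.46).
#' @param missing_sire_frac,missing_dam_frac probabilities that a doe's
#'   sire or dam is absent from the recorded pedigree (0.03 / 0.33;
#'   missing dams are common, mirroring the share of validation animals
#'   with only the sire recorded).
#' @param missing_call_rate genotype missing-call rate (0.005).
#' @param n_scc_tests herd tests per lactation for somatic cell counts (8).
#' @param scc_test_sd within-lactation SD of log2 somatic cell count (0.8).
#' @param traits data.frame of variance components as
#'   [trait_variances()].
#' @param w polygenic fraction of the genetic variance used when
#'   generating trait values (`NULL`: per-trait from the components).
#' @param breed_effects,heterosis_effects named lists of true breed-group
#'   means (deviations from Saanen) and heterosis effects per trait.
#' @param qtl_large_share optional fraction of the marker-linked genetic
#'   variance carried by a single large QTL, the remainder split evenly
#'   over the other loci. The default (`NULL`) draws all QTL effects
#'   i.i.d. normal — the architecture the mixture prior assumes — in which
#'   case the largest draw still acts as a moderately large QTL.
#'   Concentrated values (e.g. 0.6) emulate a major known QTL but are
#'   deliberately mismatched to the common-variance prior.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_founder_sires = 46, n_founder_dams = 589,
                       n_per_generation = c(280, 280, 279),
                       dam_herd_frac = 0.03, sire_use_shape = NULL,
                       founder_breed_probs = c(saanen = 0.55, anto = 0.35,
                                               unknown = 0.10),
                       n_markers = 2000, n_qtl = 40, fst = 0.1,
                       genotyped_fraction = 0.46,
                       missing_sire_frac = 0.03,
                       missing_dam_frac = 0.33,
                       missing_call_rate = 0.005,
                       n_scc_tests = 8, scc_test_sd = 0.8,
                       traits = trait_variances(), w = NULL,
                       breed_effects = NULL, heterosis_effects = NULL,
                       qtl_large_share = NULL) {
  if (is.null(breed_effects))
    breed_effects <- list(
      milk_yield = c(anto = -200, unknown = -80),
      fat_yield = c(anto = -4, unknown = -1.5),
      protein_yield = c(anto = -5, unknown = -1.5),
      scs = c(anto = 0.3, unknown = 0.15))
  if (is.null(heterosis_effects))
    heterosis_effects <- list(milk_yield = 40, fat_yield = 1.2,
                              protein_yield = 1.0, scs = -0.1)
  structure(list(
    n_founder_sires = n_founder_sires, n_founder_dams = n_founder_dams,
    n_per_generation = n_per_generation, dam_herd_frac = dam_herd_frac,
    sire_use_shape = sire_use_shape,
    founder_breed_probs = founder_breed_probs,
    n_markers = n_markers, n_qtl = n_qtl, fst = fst,
    genotyped_fraction = genotyped_fraction,
    missing_sire_frac = missing_sire_frac,
    missing_dam_frac = missing_dam_frac,
    missing_call_rate = missing_call_rate,
    n_scc_tests = n_scc_tests, scc_test_sd = scc_test_sd,
    traits = traits, w = w,
    breed_effects = breed_effects, heterosis_effects = heterosis_effects,
    qtl_large_share = qtl_large_share,
    trait_means = c(milk_yield = 1002, fat_yield = 31.8,
                    protein_yield = 31.8, scs = 9.5),
    parity_effects = list(
      milk_yield = c(0, 120, 160, 150, 110),
      fat_yield = c(0, 3.5, 4.5, 4.2, 3.2),
      protein_yield = c(0, 3.5, 4.5, 4.2, 3.2),
      scs = c(0, 0.2, 0.4, 0.6, 0.8)),
    beta_dmkd = c(milk_yield = -0.8, fat_yield = -0.02,
                  protein_yield = -0.02, scs = 0.002),
    beta_dim = c(milk_yield = 2.0, fat_yield = 0.06,
                 protein_yield = 0.06, scs = -0.004)),
    class = "sim_config")
}

#' Simulate a multibreed pedigree
#'
#' Founders are assigned pure breed labels. Every doe is sired by one of a
#' small set of founder sires (large paternal half-sib families); dams come
#' almost entirely from a wide founder-dam pool without records of their
#' own, with a small fraction of matings using a phenotyped doe of the
#' previous generation. Configurable fractions of recorded sires and dams
#' are then dropped to create animals with incomplete pedigree (and hence
#' partially unknown breed); missing dams are common.
#'
#' @param config a [sim_config()].
#' @return List with `ped` (the recorded [goat_pedigree()]), `true_ped`
#'   (complete parentage, used for gene dropping), and `generation` (named
#'   integer vector; founders are generation 0).
#' @export
simulate_pedigree <- function(config) {
  sires <- sprintf("S%03d", seq_len(config$n_founder_sires))
  dams0 <- sprintf("D%03d", seq_len(config$n_founder_dams))
  founders <- c(sires, dams0)
  probs <- config$founder_breed_probs
  breed <- sample(names(probs), length(founders), replace = TRUE,
                  prob = probs)
  animal <- founders
  sire <- rep(NA_character_, length(founders))
  dam <- rep(NA_character_, length(founders))
  gen <- rep(0L, length(founders))
  herd_dams <- character(0)
  sire_w <- if (is.null(config$sire_use_shape)) NULL else
    stats::rgamma(length(sires), shape = config$sire_use_shape)
  idno <- 0L
  for (g in seq_along(config$n_per_generation)) {
    ng <- config$n_per_generation[g]
    off <- sprintf("G%dA%04d", g, idno + seq_len(ng))
    idno <- idno + ng
    animal <- c(animal, off)
    sire <- c(sire, sample(sires, ng, replace = TRUE, prob = sire_w))
    use_herd <- length(herd_dams) > 0 &
      stats::runif(ng) < config$dam_herd_frac
    dams_g <- sample(dams0, ng, replace = TRUE)
    if (any(use_herd))
      dams_g[use_herd] <- sample(herd_dams, sum(use_herd), replace = TRUE)
    dam <- c(dam, dams_g)
    breed <- c(breed, rep("unknown", ng))
    gen <- c(gen, rep(g, ng))
    herd_dams <- off
  }
  true_ped <- goat_pedigree(animal, sire, dam, seq_along(animal), breed)
  # mask a fraction of recorded parents (founders keep their records)
  is_off <- gen > 0
  drop_s <- is_off & stats::runif(length(animal)) < config$missing_sire_frac
  drop_d <- is_off & stats::runif(length(animal)) < config$missing_dam_frac
  sire[drop_s] <- NA_character_
  dam[drop_d] <- NA_character_
  ped <- goat_pedigree(animal, sire, dam, seq_along(animal), breed)
  names(gen) <- animal
  list(ped = ped, true_ped = true_ped, generation = gen)
}

#' Simulate genotypes by gene dropping
#'
#' Founder allele frequencies per breed group follow the Balding-Nichols
#' construction at the configured Fst around common ancestral frequencies;
#' founder genotypes are Hardy-Weinberg within breed, and descendants
#' receive alleles by Mendelian gene dropping through the complete
#' pedigree. Genotyping status is assigned to the configured fraction of
#' phenotyped does with sampling weights increasing by generation.
#'
#' @param sim result of [simulate_pedigree()].
#' @param config a [sim_config()].
#' @return List with `gs_full` (a [genotype_set()] over all animals,
#'   no missingness; ground truth), `gs` (observed panel: genotyped does
#'   only, with missing calls), and `genotyped_ids`.
#' @export
simulate_genotypes <- function(sim, config) {
  tp <- sim$true_ped
  n <- nrow(tp); p <- config$n_markers
  anc <- stats::runif(p, 0.1, 0.9)
  fst <- config$fst
  breed_p <- list()
  for (b in c("saanen", "anto")) {
    breed_p[[b]] <- if (fst > 0)
      stats::rbeta(p, anc * (1 - fst) / fst, (1 - anc) * (1 - fst) / fst)
    else anc
  }
  breed_p$unknown <- anc
  dos <- matrix(0L, n, p, dimnames = list(tp$animal, sprintf("snp%04d", 1:p)))
  pi_ <- .parent_idx(tp)
  for (i in seq_len(n)) {
    s <- pi_$s[i]; d <- pi_$d[i]
    if (is.na(s) && is.na(d)) {
      pf <- breed_p[[tp$breed[i]]]
      dos[i, ] <- stats::rbinom(p, 2, pf)
    } else {
      from_s <- if (is.na(s)) stats::rbinom(p, 1, anc)
        else stats::rbinom(p, 1, dos[s, ] / 2)
      from_d <- if (is.na(d)) stats::rbinom(p, 1, anc)
        else stats::rbinom(p, 1, dos[d, ] / 2)
      dos[i, ] <- from_s + from_d
    }
  }
  gs_full <- genotype_set(dos)

  gen <- sim$generation[tp$animal]
  does <- tp$animal[gen > 0]
  wts <- (gen[does] + 0.5)^2  # recent generations more likely genotyped
  n_g <- round(config$genotyped_fraction * length(does))
  genotyped <- sample(does, n_g, prob = wts)
  obs <- dos[genotyped, , drop = FALSE]
  miss <- matrix(stats::runif(length(obs)) < config$missing_call_rate,
                 nrow(obs), ncol(obs))
  obs[miss] <- NA
  list(gs_full = gs_full, gs = genotype_set(obs), genotyped_ids = genotyped)
}

#' Simulate lactation phenotypes with ground truth
#'
#' Each trait value is the sum of a parity effect, the DMKD and DIM
#' covariate effects, the breed-group mean (through the true breed
#' composition), a heterosis effect, QTL effects summed over a sparse set of
#' panel markers (the first QTL large), a polygenic term drawn from
#' `N(0, A w sigma_g2)` through the pedigree Cholesky, and a residual. QTL
#' effects are scaled so the marker-linked variance realized among animals
#' equals `(1 - w) sigma_g2`. The somatic cell score is delivered through
#' per-test somatic cell counts drawn lognormal around the animal-level
#' mean, so [somatic_cell_score()] applies.
#'
#' @param sim result of [simulate_pedigree()].
#' @param geno result of [simulate_genotypes()].
#' @param config a [sim_config()].
#' @return List with `records` (lactation records of all does),
#'   `scc_tests` (matrix of per-test counts), and `truth` (true breeding
#'   values per trait, QTL effects and positions, variance components,
#'   breed/heterosis effects).
#' @export
simulate_phenotypes <- function(sim, geno, config) {
  tp <- sim$true_ped
  gen <- sim$generation[tp$animal]
  does <- tp$animal[gen > 0]
  n_rec <- length(does)
  comp <- breed_composition(tp)
  het <- heterosis(comp)
  A <- relationship_matrix(tp)
  L <- chol(A + diag(1e-8, nrow(A)))

  parity <- sample(1:5, n_rec, replace = TRUE,
                   prob = c(0.15, 0.40, 0.25, 0.15, 0.05))
  dmkd <- stats::runif(n_rec, -90, 90)
  dim_ <- pmin(round(stats::runif(n_rec, 185, 305)), 305)

  records <- data.frame(animal = does, parity = parity,
                        lactation_length = dim_, dim = dim_, dmkd = dmkd,
                        stringsAsFactors = FALSE)
  truth <- list(config = config)
  Mc <- scale(geno$gs_full$dosages, center = TRUE, scale = FALSE)
  # QTL among common markers, so their effects are observable in principle
  common <- which(pmin(1 - colMeans(Mc == min(Mc)), 1) > 0 &
                  apply(Mc, 2, stats::var) > 0.2)
  if (length(common) < config$n_qtl) common <- seq_len(ncol(Mc))
  qtl_idx <- sort(sample(common, config$n_qtl))
  scc_tests <- NULL
  for (tr in config$traits$trait) {
    row <- config$traits[config$traits$trait == tr, ]
    sigma_g2 <- row$polygenic + row$snp
    w <- if (is.null(config$w)) row$polygenic / sigma_g2 else config$w
    # QTL effects: i.i.d. normal at sparse loci (matching the mixture
    # prior) or, optionally, one locus carrying a fixed variance share;
    # rescaled so the realized marker-linked variance is exact
    target <- (1 - w) * sigma_g2
    if (is.null(config$qtl_large_share)) {
      raw <- stats::rnorm(config$n_qtl)
    } else {
      shares <- c(config$qtl_large_share,
                  rep((1 - config$qtl_large_share) / (config$n_qtl - 1),
                      config$n_qtl - 1))
      vloc <- apply(Mc[, qtl_idx, drop = FALSE], 2, stats::var)
      raw <- sample(c(-1, 1), config$n_qtl, replace = TRUE) *
        sqrt(shares * target / vloc)
    }
    qg <- as.vector(Mc[, qtl_idx, drop = FALSE] %*% raw)
    sc <- if (stats::var(qg) > 0) sqrt(target / stats::var(qg)) else 0
    qtl_eff <- raw * sc
    qg <- qg * sc
    u <- as.vector(crossprod(L, stats::rnorm(nrow(A)))) * sqrt(w * sigma_g2)
    names(u) <- tp$animal
    bv <- u + qg
    names(bv) <- tp$animal
    bd <- config$breed_effects[[tr]]
    breed_mean <- as.vector(comp[, c("anto", "unknown")] %*% bd)
    names(breed_mean) <- tp$animal

    i <- match(does, tp$animal)
    yval <- config$trait_means[[tr]] +
      config$parity_effects[[tr]][parity] +
      config$beta_dmkd[[tr]] * dmkd + config$beta_dim[[tr]] * (dim_ - 245) +
      config$heterosis_effects[[tr]] * het[i] +
      breed_mean[i] + bv[i] +
      stats::rnorm(n_rec, 0, sqrt(row$residual))
    if (tr == "scs") {
      # deliver SCS through per-test lognormal somatic cell counts
      tests <- matrix(stats::rnorm(n_rec * config$n_scc_tests,
                                   mean = rep(yval, config$n_scc_tests),
                                   sd = config$scc_test_sd),
                      n_rec, config$n_scc_tests)
      scc_tests <- 2^tests
      rownames(scc_tests) <- does
      yval <- apply(scc_tests, 1, somatic_cell_score)
    }
    records[[tr]] <- yval
    truth[[tr]] <- list(bv = bv, bv_across = bv + breed_mean,
                        polygenic = u, qtl_idx = qtl_idx,
                        qtl_eff = qtl_eff, sigma_g2 = sigma_g2,
                        sigma_e2 = row$residual, w = w,
                        breed_effects = bd,
                        heterosis_effect = config$heterosis_effects[[tr]])
  }
  list(records = records, scc_tests = scc_tests, truth = truth)
}

#' Simulate a complete herd
#'
#' Convenience wrapper: pedigree, genotypes and phenotypes under one seed.
#' Generators are bit-reproducible for a fixed seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return List with `ped` (recorded pedigree), `true_ped`, `records`,
#'   `gs` (observed genotypes), `gs_full`, `genotyped_ids`, `truth`,
#'   `generation`, `scc_tests`.
#' @export
simulate_herd <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  sim <- simulate_pedigree(config)
  geno <- simulate_genotypes(sim, config)
  phe <- simulate_phenotypes(sim, geno, config)
  c(sim, geno, phe)
}

#' Write a simulated herd to disk
#'
#' Emits the same pedigree CSV, phenotype CSV and PLINK fileset that the
#' readers consume, plus a ground-truth sidecar JSON (true breeding values
#' and variance components).
#'
#' @param herd a [simulate_herd()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_herd <- function(herd, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree_csv(herd$ped, file.path(dir, "pedigree.csv"))
  write_phenotypes_csv(herd$records, file.path(dir, "phenotypes.csv"))
  write_plink(herd$gs, file.path(dir, "genotypes"))
  tr <- herd$truth
  sidecar <- lapply(tr[setdiff(names(tr), "config")], function(t)
    list(bv = as.list(t$bv), sigma_g2 = t$sigma_g2,
         sigma_e2 = t$sigma_e2, w = t$w))
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
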