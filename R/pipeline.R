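#' Run the full two-model validation protocol
#'
#' Composes the whole evaluation for one trait: phenotype edits, age-based
#' 70/30 split, pedigree BLUP and single-step BayesC fits on the training
#' phenotypes, scenario classification of the validation animals by
#' available pedigree information, a pedigree-masked rerun of both models
#' (scenario D), base standardization, the genomic inflation slope, and the
#' combined breed-effect report.
#'
#' @param ped a [goat_pedigree()].
#' @param records lactation records (edits are applied internally).
#' @param gs a post-QC [genotype_set()].
#' @param trait trait column to evaluate.
#' @param params variance/prior parameters ([trait_params()] defaults).
#' @param fraction_training age-split fraction (default 0.7).
#' @param n_iter,burn_in,thin Gibbs chain controls.
#' @param seed master seed for the samplers.
#' @param min_progeny sire-progeny threshold for scenario B.
#' @param gbv_base base group for GBV summaries: `"training"` (default)
#'   standardizes each draw to the training-animal mean.
#' @return Object of class `comparison_report`.
#' @export
run_validation <- function(ped, records, gs, trait = "milk_yield",
                           params = trait_params(trait),
                           fraction_training = 0.7,
                           n_iter = 50000, burn_in = 1000, thin = 10,
                           seed = 1, min_progeny = 5,
                           gbv_base = c("training", "none")) {
  gbv_base <- match.arg(gbv_base)
  kept <- filter_lactations(records)$kept
  herd <- data.frame(animal = kept$animal,
                     birth_order = ped$birth_order[match(kept$animal,
                                                         ped$animal)])
  split <- age_split(herd, fraction_training)
  train <- kept[kept$animal %in% split$training_ids, , drop = FALSE]

  comp <- breed_composition(ped)
  Ainv <- relationship_inverse(ped)
  fit_models <- function(p, Ai) {
    dm <- pblup_design(train, p, breed_composition(p), trait)
    pf <- pblup_solve(dm, Ai, params$sigma_g2, params$sigma_e2)
    sm <- ssbc_model(train, p, gs, breed_composition(p), trait, params)
    run <- ssbc_gibbs(sm, n_iter, burn_in, thin, seed = seed)
    base_ids <- if (gbv_base == "training") split$training_ids else NULL
    sf <- ssbc_gbv(run, sm, base_ids = base_ids)
    list(dm = dm, pf = pf, sm = sm, run = run, sf = sf)
  }
  main <- fit_models(ped, Ainv)

  scen <- classify_scenarios(split$validation_ids, ped, kept$animal,
                             min_progeny)
  mask_ids <- scen$animal[scen$A]
  ped_masked <- mask_parents(ped, mask_ids)
  masked <- fit_models(ped_masked, relationship_inverse(ped_masked))

  acc_of <- function(fit, ids) {
    if (length(ids) == 0) return(NA_real_)
    a <- fit$animals
    mean(a$accuracy[match(ids, a$animal)])
  }
  val <- split$validation_ids
  summary_row <- function(label, ids, pf, sf) {
    data.frame(scenario = label, n = length(ids),
               r_ebv = acc_of(pf, ids), r_gbv = acc_of(sf, ids),
               stringsAsFactors = FALSE)
  }
  acc <- rbind(
    summary_row("all", val, main$pf, main$sf),
    summary_row("A", scen$animal[scen$A], main$pf, main$sf),
    summary_row("B", scen$animal[scen$B], main$pf, main$sf),
    summary_row("C", scen$animal[scen$C], main$pf, main$sf),
    summary_row("D", unique(c(scen$animal[scen$D], mask_ids)),
                masked$pf, masked$sf))
  acc$gain_pct <- percent_gain(acc$r_ebv, acc$r_gbv)

  ebv <- standardize_to_base(pblup_ebv(main$pf, main$dm),
                             split$training_ids)
  gbv <- standardize_to_base(
    stats::setNames(main$sf$animals$gbv, main$sf$animals$animal),
    split$training_ids)
  slope_ids <- scen$animal[scen$A]
  infl <- inflation_slope(gbv[slope_ids], ebv[slope_ids])

  breed <- combine_breed_and_J(main$sf$breed, main$sf$J,
                               main$run$d, main$run$q)
  structure(list(
    trait = trait, accuracy = acc, inflation = infl,
    breed_effects = breed,
    pblup_breed = data.frame(breed = names(main$pf$breed),
                             coef = unname(main$pf$breed),
                             se = unname(main$pf$breed_se)),
    geweke = geweke_report(main$run),
    split = split, scenarios = scen,
    ebv = ebv, gbv = gbv,
    params = params,
    meta = list(seed = seed, n_iter = n_iter, burn_in = burn_in,
                thin = thin, base = "training set",
                n_herd = nrow(herd), masked_n = length(mask_ids))),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Validation report --", x$trait, "\n")
  cat(sprintf("  herd n = %d (training %d / validation %d); base: %s\n",
              x$meta$n_herd, length(x$split$training_ids),
              length(x$split$validation_ids), x$meta$base))
  print(x$accuracy, row.names = FALSE, digits = 3)
  cat(sprintf("  inflation slope %.3f (r = %.3f)\n",
              x$inflation$slope, x$inflation$correlation))
  invisible(x)
}

#' Write a comparison report
#'
#' Emits a machine-readable JSON and a human TSV of the accuracy table,
#' plus a manifest (seed, chain controls, package version) alongside.
#'
#' @param report a [run_validation()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, paste0("report_", report$trait))
  utils::write.table(report$accuracy, paste0(base, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    trait = report$trait,
    accuracy = report$accuracy,
    inflation = report$inflation[c("slope", "correlation")],
    breed_effects = report$breed_effects,
    geweke = as.list(report$geweke),
    meta = report$meta), paste0(base, ".json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  manifest <- list(package = "capragen",
                   version = as.character(utils::packageVersion("capragen")),
                   seed = report$meta$seed,
                   chain = report$meta[c("n_iter", "burn_in", "thin")],
                   params = report$params,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a run configuration
#'
#' Reads a YAML configuration for [run_validation()], merged over the
#' defaults: input file paths (`pedigree`, `phenotypes`, `genotypes`), the
#' `trait`, chain controls (`n_iter`, `burn_in`, `thin`), `fraction_training`,
#' `min_progeny`, `seed`, and optional variance-component overrides
#' (`sigma_g2`, `sigma_e2`, `w`, `pi`).
#'
#' @param path YAML file path.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(trait = "milk_yield", fraction_training = 0.7,
                   n_iter = 50000, burn_in = 1000, thin = 10,
                   min_progeny = 5, seed = 1)
  utils::modifyList(defaults, cfg)
}

#' Run the pipeline from a configuration
#'
#' Loads the pedigree, phenotype and genotype files named in the
#' configuration, applies SNP quality control, runs [run_validation()], and
#' writes the report to `config$output`.
#'
#' @param config list from [read_run_config()].
#' @return The [run_validation()] report, invisibly.
#' @export
run_pipeline <- function(config) {
  ped <- read_pedigree_csv(config$pedigree)
  records <- read_phenotypes_csv(config$phenotypes)
  gs <- if (grepl("\\.csv$", config$genotypes))
    read_dosage_csv(config$genotypes) else read_plink(config$genotypes)
  gs <- snp_qc(gs)
  params <- trait_params(config$trait)
  for (nm in c("sigma_g2", "sigma_e2", "w", "pi"))
    if (!is.null(config[[nm]])) params[[nm]] <- config[[nm]]
  rep <- run_validation(ped, records, gs, trait = config$trait,
                        params = params,
                        fraction_training = config$fraction_training,
                        n_iter = config$n_iter, burn_in = config$burn_in,
                        thin = config$thin, seed = config$seed,
                        min_progeny = config$min_progeny)
  if (!is.null(config$output)) write_report(rep, config$output)
  invisible(rep)
}
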