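#' Simulation configuration
#'
#' Builds the configuration object consumed by the synthetic-data generator
#' ([simulate_orthogroups()], [simulate_counts()], [simulate_dnds()],
#' [simulate_hitcounts()] and the [simulate_interferome()] wrapper). Defaults
#' emulate the design of a ten-species type I IFN stimulation experiment in
#' fibroblast-like cultures: nine mammals plus the chicken as the avian
#' outgroup, a planted all-species core ISG set, additional mammal-only and
#' lineage-restricted responders, species-unique responders, weakly
#' down-regulated IRGs, paralog expansions enriched among widely shared ISGs,
#' and dN/dS values stochastically higher for ISGs.
#'
#' @param species character vector of species identifiers. The outgroup (see
#'   `outgroup`) is excluded from "mammal" sets.
#' @param outgroup the species treated as the non-mammalian outgroup.
#' @param n_replicates replicates per condition (mock and IFN) per species;
#'   at least 2.
#' @param n_orthogroups number of orthologous gene clusters to simulate.
#' @param core_fraction proportion of orthogroups planted as all-species ISGs.
#' @param lineage_blocks list of planted lineage-restricted ISG blocks, each
#'   `list(species = <character>, n = <int>)`. Blocks with a single species
#'   plant species-unique responders. The default plants a mammal-wide block
#'   of 28 plus ruminant and bat blocks.
#' @param species_specific_n number of species-unique ISGs planted per
#'   species (added on top of `lineage_blocks`).
#' @param irg_fraction proportion of orthogroups planted as IRGs; each IRG
#'   responds in a random subset of species (never all of them).
#' @param isg_effect_mean mean planted log2 fold change for ISGs (default
#'   1.64, the overall average up-regulation reported for multispecies
#'   interferomes).
#' @param irg_effect_mean mean planted log2FC for IRGs (default -0.56).
#' @param isg_effect_sd,irg_effect_sd standard deviation of the per-gene
#'   (orthogroup-level) planted effect.
#' @param species_effect_sd standard deviation of the per-species jitter
#'   around an orthogroup's planted effect.
#' @param effect_floor minimum absolute planted log2FC for a responding
#'   (gene, species) pair; a planted responder must actually respond.
#' @param dispersion negative-binomial dispersion (squared biological
#'   coefficient of variation); 0.01 corresponds to BCV 0.1, typical of
#'   replicate cultures of genetically identical cells.
#' @param library_size_mean expected mapped reads per sample; per-sample
#'   size factors are drawn log-normally with ~20% spread.
#' @param expansion_prob_isg probability that a gene family carries more than
#'   one copy in a given species when the family responds in every species;
#'   families responding in fewer species interpolate linearly towards
#'   `expansion_prob_background`.
#' @param expansion_prob_background expansion probability for non-responding
#'   families.
#' @param absence_prob probability that a non-responding family is missing
#'   (unannotated) in a given species; responders are always present.
#' @param antiviral_panel_size number of planted ISGs designated "antiviral";
#'   30 are drawn from broadly shared responders and the remainder from
#'   lineage/species-restricted ones.
#' @param antiviral_boost additional log2FC given to panel genes in species
#'   where they respond.
#' @param basal_shift named numeric vector of basal-expression multipliers
#'   applied to responding genes of given species (default: 4x in both bats,
#'   emulating a constitutively elevated antiviral state).
#' @param dnds_shift additive shift of the ISG dN/dS distribution.
#' @param seed integer global seed; all stages derive sub-seeds from it.
#'
#' @return an object of class `sim_config` (a named list).
#' @examples
#' cfg <- simulation_config(n_orthogroups = 200, seed = 1)
#' cfg$core_n
#' @export
simulation_config <- function(species = c("human", "rat", "cow", "sheep",
                                          "pig", "horse", "dog", "microbat",
                                          "fruitbat", "chicken"),
                              outgroup = "chicken",
                              n_replicates = 3,
                              n_orthogroups = 2000,
                              core_fraction = 62 / 2000,
                              lineage_blocks = NULL,
                              species_specific_n = 40,
                              irg_fraction = 0.1,
                              isg_effect_mean = 1.64,
                              irg_effect_mean = -0.56,
                              isg_effect_sd = 0.5,
                              irg_effect_sd = 0.15,
                              species_effect_sd = 0.15,
                              effect_floor = 0.25,
                              dispersion = 0.01,
                              library_size_mean = 5e6,
                              expansion_prob_isg = 0.10,
                              expansion_prob_background = 0.05,
                              absence_prob = 0.02,
                              antiviral_panel_size = 40,
                              antiviral_boost = 0.75,
                              basal_shift = c(microbat = 4, fruitbat = 4),
                              dnds_shift = 0.1,
                              seed = 1L) {
  if (length(species) < 2 || anyDuplicated(species)) {
    abort("`species` must be >= 2 unique identifiers",
          class = "crossferome_config_error")
  }
  if (!outgroup %in% species) {
    abort("`outgroup` must be one of `species`",
          class = "crossferome_config_error")
  }
  if (!is.numeric(n_replicates) || n_replicates < 2) {
    abort("`n_replicates` must be >= 2", class = "crossferome_config_error")
  }
  check_proportion(core_fraction, "core_fraction")
  check_proportion(irg_fraction, "irg_fraction")
  check_proportion(expansion_prob_isg, "expansion_prob_isg")
  check_proportion(expansion_prob_background, "expansion_prob_background")
  check_proportion(absence_prob, "absence_prob")
  check_positive(dispersion, "dispersion")
  check_positive(library_size_mean, "library_size_mean")
  if (dnds_shift < 0) {
    abort("`dnds_shift` must be >= 0", class = "crossferome_config_error")
  }

  mammals <- setdiff(species, outgroup)
  if (is.null(lineage_blocks)) {
    lineage_blocks <- list(
      list(species = mammals, n = 28L)
    )
    laurasiatheria <- intersect(c("cow", "sheep", "pig", "horse", "dog",
                                  "microbat", "fruitbat"), species)
    euarchontoglires <- intersect(c("human", "rat"), species)
    ruminants <- intersect(c("cow", "sheep"), species)
    bats <- intersect(c("microbat", "fruitbat"), species)
    for (blk in list(list(species = laurasiatheria, n = 20L),
                     list(species = euarchontoglires, n = 15L),
                     list(species = ruminants, n = 25L),
                     list(species = bats, n = 25L))) {
      if (length(blk$species) > 1) lineage_blocks <- c(lineage_blocks, list(blk))
    }
  }
  for (b in lineage_blocks) {
    if (!all(b$species %in% species) || length(b$species) >= length(species)) {
      abort("each lineage block must name a strict subset of `species`",
            class = "crossferome_config_error")
    }
    if (!is.numeric(b$n) || b$n < 0) {
      abort("lineage block sizes must be non-negative",
            class = "crossferome_config_error")
    }
  }

  core_n <- round(core_fraction * n_orthogroups)
  irg_n <- round(irg_fraction * n_orthogroups)
  planted <- core_n + irg_n + sum(vapply(lineage_blocks, function(b) b$n, 0)) +
    species_specific_n * length(species)
  if (planted > n_orthogroups) {
    abort("planted groups exceed `n_orthogroups`; increase it or shrink blocks",
          class = "crossferome_config_error")
  }

  structure(
    list(
      species = species, outgroup = outgroup, mammals = mammals,
      n_replicates = as.integer(n_replicates),
      n_orthogroups = as.integer(n_orthogroups),
      core_fraction = core_fraction, core_n = as.integer(core_n),
      lineage_blocks = lineage_blocks,
      species_specific_n = as.integer(species_specific_n),
      irg_fraction = irg_fraction, irg_n = as.integer(irg_n),
      isg_effect_mean = isg_effect_mean, irg_effect_mean = irg_effect_mean,
      isg_effect_sd = isg_effect_sd, irg_effect_sd = irg_effect_sd,
      species_effect_sd = species_effect_sd, effect_floor = effect_floor,
      dispersion = dispersion, library_size_mean = library_size_mean,
      expansion_prob_isg = expansion_prob_isg,
      expansion_prob_background = expansion_prob_background,
      absence_prob = absence_prob,
      antiviral_panel_size = as.integer(antiviral_panel_size),
      antiviral_boost = antiviral_boost,
      basal_shift = basal_shift,
      dnds_shift = dnds_shift,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  species       :", paste(x$species, collapse = ", "), "\n")
  cat("  orthogroups   :", x$n_orthogroups,
      sprintf("(core %d, IRG %d)", x$core_n, x$irg_n), "\n")
  cat("  replicates    :", x$n_replicates, "per condition\n")
  cat("  effects (log2):", sprintf("ISG %.2f, IRG %.2f", x$isg_effect_mean,
                                   x$irg_effect_mean), "\n")
  cat("  dispersion    :", x$dispersion, "\n")
  cat("  seed          :", x$seed, "\n")
  invisible(x)
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file's top-level keys mirror the arguments of [simulation_config()];
#' unknown keys raise a configuration error.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `sim_config` object.
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path),
          class = "crossferome_config_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- names(formals(simulation_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) {
    abort(paste0("unknown config field(s): ", paste(bad, collapse = ", ")),
          class = "crossferome_config_error")
  }
  if (!is.null(raw$basal_shift)) raw$basal_shift <- unlist(raw$basal_shift)
  if (!is.null(raw$lineage_blocks)) {
    raw$lineage_blocks <- lapply(raw$lineage_blocks, function(b) {
      list(species = unlist(b$species), n = as.integer(b$n))
    })
  }
  do.call(simulation_config, raw)
}
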