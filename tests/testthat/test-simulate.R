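# Synthetic-data generator: structure, determinism, calibration, recovery.

test_that("configuration validation rejects bad inputs", {
  expect_error(simulation_config(core_fraction = 1.2),
               class = "crossferome_config_error")
  expect_error(simulation_config(n_replicates = 1),
               class = "crossferome_config_error")
  expect_error(simulation_config(dispersion = 0),
               class = "crossferome_config_error")
  expect_error(simulation_config(dnds_shift = -1),
               class = "crossferome_config_error")
  expect_error(simulation_config(species = c("a", "b"), outgroup = "c"),
               class = "crossferome_config_error")
  # planted groups cannot exceed the number of orthogroups
  expect_error(simulation_config(n_orthogroups = 100),
               class = "crossferome_config_error")
})

test_that("planted truth has the configured structure", {
  cfg <- small_config(seed = 3)
  truth <- simulate_orthogroups(cfg)
  og <- truth$orthogroups

  expect_equal(sum(og$label == "core"), 10)
  expect_equal(sum(og$label == "irg"), cfg$irg_n)
  # planted core genes respond as ISGs in every species
  core_eff <- dplyr::filter(truth$effects, .data$label == "core")
  expect_true(all(core_eff$responds))
  expect_true(all(core_eff$planted_log2fc > 0))
  expect_true(all(core_eff$present))
  # IRGs respond downwards, never in all species
  irg_eff <- dplyr::filter(truth$effects, .data$label == "irg", .data$responds)
  expect_true(all(irg_eff$planted_log2fc < 0))
  irg_counts <- dplyr::count(irg_eff, .data$orthogroup_id)
  expect_true(all(irg_counts$n < length(cfg$species)))
  # every simulated gene id appears exactly once
  expect_equal(anyDuplicated(truth$genes$gene_id), 0L)
  # antiviral panel recorded and unique
  expect_equal(length(truth$antiviral_panel), cfg$antiviral_panel_size)
  expect_equal(anyDuplicated(truth$antiviral_panel), 0L)
})

test_that("generator is byte-identical under a fixed seed", {
  cfg <- small_config(seed = 11)
  s1 <- simulate_interferome(cfg, n_genomes = 4)
  s2 <- simulate_interferome(cfg, n_genomes = 4)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$dnds, s2$dnds)
  expect_identical(s1$hitcounts, s2$hitcounts)
  s3 <- simulate_interferome(small_config(seed = 12), n_genomes = 4)
  expect_false(identical(s1$counts, s3$counts))
})

test_that("count tables conserve the gene universe", {
  truth <- simulate_orthogroups(small_config(seed = 5))
  counts <- simulate_counts(truth)
  simulated <- unlist(lapply(counts, function(d) d$counts$gene_id))
  expect_setequal(simulated, truth$genes$gene_id)
  expect_equal(length(simulated), nrow(truth$genes))
})

test_that("equal expansion probabilities give equal ratios up to noise", {
  cfg <- simulation_config(
    species = c("a", "b", "c"), outgroup = "c", n_orthogroups = 1000,
    core_fraction = 0.4, lineage_blocks = list(), species_specific_n = 0,
    irg_fraction = 0, expansion_prob_isg = 0.1,
    expansion_prob_background = 0.1, absence_prob = 0,
    antiviral_panel_size = 0, basal_shift = numeric(), seed = 21
  )
  truth <- simulate_orthogroups(cfg)
  eff <- truth$effects
  # brute-force count of expanded families, responders vs background
  rate <- function(rows) sum(rows$n_copies > 1) / nrow(rows)
  r_isg <- rate(dplyr::filter(eff, .data$responds))
  r_bg <- rate(dplyr::filter(eff, !.data$responds))
  expect_lt(abs(r_isg - r_bg), 0.03)

  # and a genuinely enriched configuration separates them
  cfg2 <- simulation_config(
    species = c("a", "b", "c"), outgroup = "c", n_orthogroups = 1000,
    core_fraction = 0.4, lineage_blocks = list(), species_specific_n = 0,
    irg_fraction = 0, expansion_prob_isg = 0.3,
    expansion_prob_background = 0.05, absence_prob = 0,
    antiviral_panel_size = 0, basal_shift = numeric(), seed = 21
  )
  eff2 <- simulate_orthogroups(cfg2)$effects
  expect_gt(rate(dplyr::filter(eff2, .data$responds)),
            rate(dplyr::filter(eff2, !.data$responds)) + 0.1)
})

test_that("null counts give log2FC estimates centred at zero", {
  cfg <- null_config(seed = 31)
  sim <- simulate_interferome(cfg)
  d <- sim$counts[["a"]]
  de <- run_de(d$counts, d$samples, d$gene_lengths)
  expect_gt(nrow(de), 1900)
  expect_lt(abs(mean(de$log2FC)), 0.05)
})

test_that("strong planted effects are recovered in the estimates", {
  cfg <- null_config(seed = 41, n_orthogroups = 500, n_replicates = 4,
                     core_fraction = 0.2, isg_effect_mean = 5,
                     isg_effect_sd = 0.01, species_effect_sd = 0,
                     antiviral_panel_size = 0)
  sim <- simulate_interferome(cfg)
  d <- sim$counts[["a"]]
  de <- run_de(d$counts, d$samples, d$gene_lengths)
  planted <- sim$truth$genes$gene_id[
    sim$truth$genes$orthogroup_id %in%
      sim$truth$orthogroups$orthogroup_id[sim$truth$orthogroups$label == "core"] &
      sim$truth$genes$species == "a"]
  est <- de$log2FC[de$gene_id %in% planted]
  expect_lt(abs(mean(est) - 5), 0.5)
  expect_gt(mean(abs(est - 5) < 0.5), 0.9)
})

test_that("doubling the mean library size doubles total counts", {
  truth <- simulate_orthogroups(small_config(seed = 51))
  c1 <- simulate_counts(truth, small_config(seed = 51))
  c2 <- simulate_counts(truth, small_config(seed = 51, library_size_mean = 1e7))
  t1 <- sum(sapply(c1, function(d) sum(d$counts[-1])))
  t2 <- sum(sapply(c2, function(d) sum(d$counts[-1])))
  expect_lt(abs(t2 / t1 - 2), 0.05)
})

test_that("dN/dS support and shift behave as designed", {
  cfg <- small_config(seed = 61)
  dnds <- simulate_dnds(simulate_orthogroups(cfg))
  expect_true(all(dnds$ds > 0))
  expect_true(all(dnds$dn >= 0))
  # with the default shift, a decent sample separates ISGs from the rest
  w <- wilcox.test(dnds$dnds[dnds$isg], dnds$dnds[!dnds$isg])
  expect_lt(w$p.value, 0.001)
})

test_that("shifted dN/dS distributions are detected in most replicates", {
  cfg0 <- simulation_config(
    species = c("a", "b"), outgroup = "b", n_orthogroups = 700,
    core_fraction = 0.5, lineage_blocks = list(), species_specific_n = 0,
    irg_fraction = 0, dnds_shift = 0.1, antiviral_panel_size = 0,
    basal_shift = numeric(), seed = 1
  )
  hits <- vapply(1:20, function(s) {
    cfg <- simulation_config(
      species = c("a", "b"), outgroup = "b", n_orthogroups = 700,
      core_fraction = 0.5, lineage_blocks = list(), species_specific_n = 0,
      irg_fraction = 0, dnds_shift = 0.1, antiviral_panel_size = 0,
      basal_shift = numeric(), seed = s
    )
    dnds <- simulate_dnds(simulate_orthogroups(cfg))
    x <- dnds$dnds[dnds$isg][1:500]
    y <- dnds$dnds[!dnds$isg][1:500]
    wilcox.test(x, y)$p.value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("hit-count screens plant deletions and stay deterministic", {
  truth <- simulate_orthogroups(small_config(seed = 71))
  og <- truth$orthogroups$orthogroup_id
  h0 <- simulate_hitcounts(truth, n_genomes = 6)
  expect_true(all(h0 >= 1))
  spec <- setNames(list(c("genome03")), og[1])
  h1 <- simulate_hitcounts(truth, n_genomes = 6, deletion_spec = spec)
  expect_equal(h1[og[1], "genome03"], 0)
  expect_identical(simulate_hitcounts(truth, n_genomes = 6,
                                      deletion_spec = spec), h1)
  expect_error(simulate_hitcounts(truth, n_genomes = 1),
               class = "crossferome_config_error")
  expect_error(simulate_hitcounts(truth, n_genomes = 6,
                                  deletion_spec = list(nope = 1)),
               class = "crossferome_data_error")
})

test_that("written simulations round-trip through the TSV dialect", {
  dir <- withr::local_tempdir()
  sim <- simulate_interferome(small_config(seed = 81), n_genomes = 4)
  write_simulation(sim, dir)
  expect_true(file.exists(file.path(dir, "counts_human.tsv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  counts_back <- read_tsv_table(file.path(dir, "counts_human.tsv"))
  expect_equal(counts_back, sim$counts$human$counts)
  map_back <- load_orthogroups(file.path(dir, "orthogroups.tsv"))
  expect_equal(nrow(map_back), nrow(sim$truth$genes))
})
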