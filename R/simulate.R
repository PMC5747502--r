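#' Simulate orthology structure and planted IFN responses
#'
#' Generates the ground truth for a multi-species interferome simulation:
#' orthologous gene clusters with per-species copy numbers, planted
#' response labels (all-species core ISGs, lineage-restricted and
#' species-unique ISGs, IRGs, nulls), per-species planted log2 fold changes
#' and a designated antiviral gene panel.
#'
#' Planted effects are drawn once per orthogroup from a truncated normal
#' (mean `isg_effect_mean` / `irg_effect_mean`), then jittered per species;
#' a conserved responder has a conserved induction strength. Expansion
#' probability interpolates from `expansion_prob_background` for
#' non-responders to `expansion_prob_isg` for all-species responders, so
#' widely shared ISGs are more likely to carry paralogs.
#'
#' @param config a [simulation_config()] object.
#' @return an object of class `sim_truth`: a list with tibbles
#'   `orthogroups` (id, label, antiviral flag, number of responding species),
#'   `effects` (orthogroup x species: presence, copies, planted log2FC),
#'   `genes` (one row per simulated gene: id, orthogroup, species, copy
#'   index, length in bp, relative basal expression), the `antiviral_panel`
#'   of orthogroup ids, and the `config`.
#' @examples
#' truth <- simulate_orthogroups(simulation_config(n_orthogroups = 100, seed = 1))
#' dplyr::count(truth$orthogroups, label)
#' @export
simulate_orthogroups <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(sub_seed(config$seed, "orthogroups"), {
    n <- config$n_orthogroups
    sp <- config$species
    n_sp <- length(sp)
    ids <- sprintf("og%05d", seq_len(n))

    # --- labels ----------------------------------------------------------
    label <- rep("null", n)
    block_species <- vector("list", n)
    i <- 0L
    take <- function(k) {
      out <- seq.int(i + 1L, length.out = k)
      i <<- i + k
      out
    }
    core_idx <- take(config$core_n)
    label[core_idx] <- "core"
    block_species[core_idx] <- list(sp)
    for (b in config$lineage_blocks) {
      idx <- take(b$n)
      label[idx] <- if (length(b$species) == 1) "species_specific" else "lineage"
      block_species[idx] <- list(b$species)
    }
    for (s in sp) {
      idx <- take(config$species_specific_n)
      label[idx] <- "species_specific"
      block_species[idx] <- list(s)
    }
    irg_idx <- take(config$irg_n)
    label[irg_idx] <- "irg"
    for (j in irg_idx) {
      repeat {
        resp <- sp[rbinom(n_sp, 1, 0.4) == 1]
        if (length(resp) >= 1 && length(resp) < n_sp) break
      }
      block_species[[j]] <- resp
    }

    orthogroups <- tibble(
      orthogroup_id = ids, label = label,
      n_responding = vapply(block_species, length, 0L) * (label != "null")
    )

    # --- per-(group, species) responses and effects ----------------------
    rtruncnorm <- function(k, mean, sd, lower) {
      out <- rnorm(k, mean, sd)
      while (any(bad <- out < lower)) out[bad] <- rnorm(sum(bad), mean, sd)
      out
    }
    base_eff <- numeric(n)
    isg_like <- label %in% c("core", "lineage", "species_specific")
    base_eff[isg_like] <- rtruncnorm(sum(isg_like), config$isg_effect_mean,
                                     config$isg_effect_sd, config$effect_floor)
    base_eff[label == "irg"] <- -rtruncnorm(sum(label == "irg"),
                                            abs(config$irg_effect_mean),
                                            config$irg_effect_sd,
                                            config$effect_floor)

    resp_mat <- matrix(FALSE, n, n_sp, dimnames = list(ids, sp))
    for (j in which(label != "null")) {
      resp_mat[j, match(block_species[[j]], sp)] <- TRUE
    }
    effects <- tidyr::expand_grid(orthogroup_id = ids, species = sp) |>
      mutate(
        label = rep(label, each = n_sp),
        responds = as.vector(t(resp_mat)),
        base = rep(base_eff, each = n_sp)
      )

    jitter <- rnorm(nrow(effects), 0, config$species_effect_sd)
    eff <- effects$base + jitter
    eff <- ifelse(effects$base > 0, pmax(eff, config$effect_floor),
                  pmin(eff, -config$effect_floor))
    effects$planted_log2fc <- ifelse(effects$responds, eff, 0)

    # --- antiviral panel -------------------------------------------------
    broad <- which(isg_like & orthogroups$n_responding >= n_sp - 1)
    narrow <- which(isg_like & orthogroups$n_responding < n_sp - 1)
    k_broad <- min(30L, config$antiviral_panel_size, length(broad))
    k_narrow <- min(config$antiviral_panel_size - k_broad, length(narrow))
    panel <- c(sample(broad, k_broad), sample(narrow, k_narrow))
    orthogroups$antiviral <- seq_len(n) %in% panel
    boost_rows <- effects$orthogroup_id %in% ids[panel] & effects$responds &
      effects$planted_log2fc > 0
    effects$planted_log2fc[boost_rows] <-
      effects$planted_log2fc[boost_rows] + config$antiviral_boost
    # `isg_effect_mean` is the overall average up-regulation across the whole
    # interferome, panel included; re-centre so the planted overall mean hits
    # it after the panel boost
    up_rows <- effects$responds & effects$planted_log2fc > 0
    if (any(up_rows)) {
      delta <- mean(effects$planted_log2fc[up_rows]) - config$isg_effect_mean
      effects$planted_log2fc[up_rows] <-
        pmax(effects$planted_log2fc[up_rows] - delta, config$effect_floor)
    }

    # --- presence and copy number ----------------------------------------
    p_interp <- config$expansion_prob_background +
      (config$expansion_prob_isg - config$expansion_prob_background) *
        ifelse(effects$label == "irg", 0, rep(orthogroups$n_responding, each = n_sp) / n_sp)
    effects$present <- effects$responds |
      rbinom(nrow(effects), 1, 1 - config$absence_prob) == 1
    effects$n_copies <- ifelse(effects$present,
                               1L + rbinom(nrow(effects), 1, p_interp), 0L)

    # --- genes -----------------------------------------------------------
    group_expr <- rlnorm(n, meanlog = 0, sdlog = 1)
    genes <- effects |>
      filter(.data$present) |>
      select("orthogroup_id", "species", "n_copies") |>
      mutate(copy_index = map(.data$n_copies, seq_len)) |>
      unnest("copy_index") |>
      mutate(
        gene_id = str_c(.data$orthogroup_id, "_", .data$species, "_g",
                        .data$copy_index),
        length_bp = round(runif(n(), 500, 5000)),
        rel_expr = group_expr[match(.data$orthogroup_id, ids)] *
          rlnorm(n(), 0, 0.25)
      ) |>
      select("gene_id", "orthogroup_id", "species", "copy_index",
             "length_bp", "rel_expr")

    # basal shift (e.g. constitutively active antiviral state in bats)
    if (length(config$basal_shift)) {
      resp_key <- str_c(effects$orthogroup_id, effects$species)[effects$responds &
                                                                  effects$planted_log2fc > 0]
      for (s in names(config$basal_shift)) {
        hit <- genes$species == s &
          str_c(genes$orthogroup_id, genes$species) %in% resp_key
        genes$rel_expr[hit] <- genes$rel_expr[hit] * config$basal_shift[[s]]
      }
    }

    structure(
      list(
        orthogroups = orthogroups,
        effects = effects |>
          select("orthogroup_id", "species", "label", "responds", "present",
                 "n_copies", "planted_log2fc"),
        genes = genes,
        antiviral_panel = ids[panel],
        config = config
      ),
      class = "sim_truth"
    )
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>", nrow(x$orthogroups), "orthogroups,",
      nrow(x$genes), "genes across", length(x$config$species), "species\n")
  print(count(x$orthogroups, .data$label))
  invisible(x)
}

#' Simulate negative-binomial count tables
#'
#' Draws per-species RNA-seq-like count matrices and sample sheets from a
#' [simulate_orthogroups()] truth. Expected counts are proportional to a
#' gene's relative basal expression times its length; IFN samples of planted
#' responders have their mean scaled by `2^planted_log2fc`; mock means depend
#' only on basal expression. Counts are NB(mean, dispersion) with per-sample
#' library-size factors drawn log-normally (~20% spread).
#'
#' @param truth a `sim_truth` object.
#' @param config a [simulation_config()]; defaults to the one inside `truth`.
#' @return a named list (class `sim_counts`), one element per species, each
#'   a list with `counts` (tibble: `gene_id` + one column per sample),
#'   `samples` (sample sheet: sample, condition `mock`/`ifn`, replicate) and
#'   `gene_lengths` (gene_id, length_bp).
#' @export
simulate_counts <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  with_seed(sub_seed(config$seed, "counts"), {
    n_rep <- config$n_replicates
    phi <- config$dispersion
    out <- list()
    for (s in config$species) {
      g <- filter(truth$genes, .data$species == s)
      eff <- filter(truth$effects, .data$species == s)
      fc <- 2^eff$planted_log2fc[match(g$orthogroup_id, eff$orthogroup_id)]
      rel <- g$rel_expr * g$length_bp
      rel <- rel / sum(rel)

      samples <- tibble(
        sample = str_c(s, "_", rep(c("mock", "ifn"), each = n_rep), "_",
                       rep(seq_len(n_rep), 2)),
        condition = rep(c("mock", "ifn"), each = n_rep),
        replicate = rep(seq_len(n_rep), 2)
      )
      size_factors <- rlnorm(nrow(samples), meanlog = -0.02, sdlog = 0.2)
      mat <- matrix(0L, nrow(g), nrow(samples),
                    dimnames = list(g$gene_id, samples$sample))
      for (j in seq_len(nrow(samples))) {
        mu <- rel * config$library_size_mean * size_factors[j]
        if (samples$condition[j] == "ifn") mu <- mu * fc
        mat[, j] <- rnbinom(nrow(g), mu = mu, size = 1 / phi)
      }
      out[[s]] <- list(
        counts = bind_cols(tibble(gene_id = g$gene_id),
                           as_tibble(mat)),
        samples = samples,
        gene_lengths = tibble(gene_id = g$gene_id, length_bp = g$length_bp)
      )
    }
    structure(out, class = "sim_counts")
  })
}

#' Simulate per-gene dN/dS values
#'
#' Draws pairwise dN and dS values (against a reference genome) for every
#' simulated gene. dS is gamma-distributed and strictly positive; the dN/dS
#' ratio is gamma-distributed with an additive shift of `dnds_shift` for
#' genes whose orthogroup responds as an ISG in that species, emulating the
#' elevated evolutionary rates of antiviral effectors under positive
#' selection.
#'
#' @inheritParams simulate_counts
#' @return tibble: gene_id, orthogroup_id, species, `isg` (truth label),
#'   dn, ds, dnds.
#' @export
simulate_dnds <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  if (config$dnds_shift < 0) {
    abort("`dnds_shift` must be >= 0", class = "crossferome_config_error")
  }
  with_seed(sub_seed(config$seed, "dnds"), {
    g <- truth$genes
    eff <- truth$effects
    key <- match(str_c(g$orthogroup_id, g$species),
                 str_c(eff$orthogroup_id, eff$species))
    isg <- eff$responds[key] & eff$planted_log2fc[key] > 0
    ds <- rgamma(nrow(g), shape = 5, rate = 25)
    omega <- rgamma(nrow(g), shape = 2, rate = 10) + config$dnds_shift * isg
    tibble(
      gene_id = g$gene_id, orthogroup_id = g$orthogroup_id,
      species = g$species, isg = isg,
      dn = omega * ds, ds = ds, dnds = omega
    )
  })
}

#' Simulate a homology hit-count matrix
#'
#' Emulates an in silico genome screen: for each gene family (orthogroup)
#' and each screened genome, the number of above-threshold similarity
#' matches. Baseline rates guarantee at least one hit per cell; cells listed
#' in `deletion_spec` are planted as deletions (zero hits).
#'
#' @param truth a `sim_truth` object.
#' @param n_genomes number of genomes screened (>= 2).
#' @param deletion_spec named list: orthogroup id -> genome names (or
#'   indices) in which the family is deleted.
#' @param config a [simulation_config()]; defaults to the one inside `truth`.
#' @return integer matrix (orthogroups x genomes) with dimnames.
#' @export
simulate_hitcounts <- function(truth, n_genomes = 20,
                               deletion_spec = list(),
                               config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  if (n_genomes < 2) {
    abort("`n_genomes` must be >= 2", class = "crossferome_config_error")
  }
  ids <- truth$orthogroups$orthogroup_id
  genomes <- sprintf("genome%02d", seq_len(n_genomes))
  unknown <- setdiff(names(deletion_spec), ids)
  if (length(unknown)) {
    abort(paste0("deletion_spec refers to unknown gene(s): ",
                 paste(unknown, collapse = ", ")),
          class = "crossferome_data_error")
  }
  with_seed(sub_seed(config$seed, "hitcounts"), {
    base <- rgamma(length(ids), shape = 3, rate = 1)     # per-family rate
    genome_f <- rlnorm(n_genomes, 0, 0.2)                # assembly quality
    mat <- 1L + matrix(rpois(length(ids) * n_genomes,
                             outer(base, genome_f)),
                       length(ids), n_genomes,
                       dimnames = list(ids, genomes))
    for (id in names(deletion_spec)) {
      cols <- deletion_spec[[id]]
      if (is.numeric(cols)) cols <- genomes[cols]
      bad <- setdiff(cols, genomes)
      if (length(bad)) {
        abort(paste0("deletion_spec refers to unknown genome(s): ",
                     paste(bad, collapse = ", ")),
              class = "crossferome_data_error")
      }
      mat[id, cols] <- 0L
    }
    mat
  })
}

#' Run the whole generator
#'
#' Convenience wrapper: [simulate_orthogroups()], [simulate_counts()],
#' [simulate_dnds()] and [simulate_hitcounts()] under one config.
#'
#' @param config a [simulation_config()].
#' @param n_genomes genomes for the hit-count screen.
#' @return list with `truth`, `counts`, `dnds`, `hitcounts`.
#' @export
simulate_interferome <- function(config = simulation_config(), n_genomes = 20) {
  truth <- simulate_orthogroups(config)
  list(
    truth = truth,
    counts = simulate_counts(truth, config),
    dnds = simulate_dnds(truth, config),
    hitcounts = simulate_hitcounts(truth, n_genomes, config = config)
  )
}

#' Write a simulated dataset to disk
#'
#' Writes the generator's outputs in the package's TSV dialect: one count
#' table and sample sheet per species, an orthogroup map, the dN/dS table,
#' the hit-count matrix, the antiviral panel, and a JSON truth manifest.
#'
#' @param sim result of [simulate_interferome()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- sim$truth
  for (s in names(sim$counts)) {
    write_tsv_table(sim$counts[[s]]$counts,
                    file.path(dir, str_c("counts_", s, ".tsv")))
    write_tsv_table(sim$counts[[s]]$samples,
                    file.path(dir, str_c("samples_", s, ".tsv")))
  }
  write_tsv_table(
    truth$genes |>
      select("orthogroup_id", "species", "gene_id", "length_bp"),
    file.path(dir, "orthogroups.tsv")
  )
  write_tsv_table(sim$dnds, file.path(dir, "dnds.tsv"))
  write_tsv_table(
    as_tibble(sim$hitcounts, rownames = "orthogroup_id"),
    file.path(dir, "hitcounts.tsv")
  )
  write_tsv_table(tibble(orthogroup_id = truth$antiviral_panel),
                  file.path(dir, "antiviral_panel.tsv"))
  jsonlite::write_json(
    list(
      config = unclass(truth$config),
      orthogroups = truth$orthogroups,
      effects = truth$effects
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
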