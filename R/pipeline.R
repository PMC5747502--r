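# End-to-end orchestration: simulate -> DE -> merge -> cores/bins -> stats,
# with a reproducibility manifest and a human-readable report.

pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full comparative-interferome pipeline on simulated data
#'
#' Generates a dataset under `config`, runs per-species differential
#' expression, merges results onto orthogroups, extracts bins and core
#' sets, computes the comparative statistics, and writes every stage
#' output plus a manifest (config snapshot, seeds, file checksums, stage
#' timings) into `out_dir`. The manifest is written last, so its presence
#' marks a complete run. Identical config and seed reproduce identical
#' outputs.
#'
#' @param config a [simulation_config()] object or a path to a YAML/JSON
#'   config file.
#' @param out_dir output directory.
#' @param de_method DE test, see [test_de()].
#' @param B antiviral resamples (default 100).
#' @param k antiviral resample size (default 40).
#' @param n_background expansion background resamples (default 500).
#' @param trend_B trend permutations (default 10000).
#' @param n_genomes genomes in the simulated hit-count screen.
#' @return (invisibly) a list with all in-memory stage results: `truth`,
#'   `de`, `table`, `bins`, `cores`, `stats`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir,
                         de_method = c("moderated", "welch"),
                         B = 100, k = 40, n_background = 500,
                         trend_B = 10000, n_genomes = 20) {
  de_method <- match.arg(de_method)
  if (is.character(config)) config <- read_simulation_config(config)
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- Sys.time()
    out <- force(expr)
    timings[[stage]] <<- round(as.numeric(difftime(Sys.time(), t0, "secs")), 3)
    pipeline_log(stage, "done in ", timings[[stage]], "s")
    out
  }

  sim <- clock("simulate", simulate_interferome(config, n_genomes = n_genomes))
  write_simulation(sim, file.path(out_dir, "inputs"))

  de <- clock("de", {
    lapply(sim$counts, function(d) {
      run_de(d$counts, d$samples, d$gene_lengths, method = de_method)
    })
  })
  for (s in names(de)) {
    write_tsv_table(de[[s]], file.path(out_dir, str_c("de_", s, ".tsv")))
  }

  table <- clock("merge", {
    map <- sim$truth$genes |>
      select("orthogroup_id", "species", "gene_id", "length_bp")
    merge_de(load_orthogroups(map), de)
  })
  write_tsv_table(big_table_wide(table), file.path(out_dir, "big_table.tsv"))

  bins <- clock("bins", bin_by_species_count(table))
  write_tsv_table(
    bins |> mutate(species = map_chr(.data$species, paste, collapse = ";")),
    file.path(out_dir, "bins.tsv")
  )

  cores <- clock("core", core_sets(table, config$mammals, config$species))
  jsonlite::write_json(
    list(core_vert = cores$core_vert,
         core_mamm_extra = cores$core_mamm_extra,
         species_unique = cores$species_unique,
         species_unique_high_conf = cores$species_unique_high_conf),
    file.path(out_dir, "core_sets.json"), auto_unbox = TRUE, digits = NA
  )

  # a statistic whose preconditions a (small) dataset cannot meet is
  # reported as "not run" with its message, not a pipeline failure
  try_stat <- function(expr) {
    tryCatch(expr, crossferome_data_error = function(e) conditionMessage(e))
  }
  stats <- clock("stats", {
    res <- list(seed = config$seed)
    res$similarity_up <- similarity_matrix(table, "up")
    res$similarity_down <- similarity_matrix(table, "down")
    res$pca <- try_stat(pca_core(table, config$mammals))
    res$antiviral <- try_stat(
      antiviral_enrichment(table, sim$truth$antiviral_panel, B = B,
                           k = min(k, length(sim$truth$antiviral_panel)),
                           seed = config$seed))
    res$expansion <- try_stat(expansion_test(table, n = n_background,
                                             seed = config$seed))
    res$trend <- try_stat(bin_expansion_trend(bins,
                                              summarise_copy_class(table),
                                              B = trend_B,
                                              seed = config$seed))
    res$dnds <- try_stat(dnds_contrast(filter(sim$dnds, .data$isg),
                                       filter(sim$dnds, !.data$isg)))
    bats <- intersect(c("microbat", "fruitbat"), config$species)
    res$basal <- if (length(bats) >= 1 && length(config$species) > length(bats)) {
      try_stat(basal_fpkm_contrast(table, list(
        chiroptera = bats, other = setdiff(config$species, bats))))
    }
    res$anova <- try_stat(induction_by_copyclass(table, cores$core_vert))
    res$hitnorm <- normalize_hitcounts(sim$hitcounts)
    res
  })
  write_tsv_table(tidy(stats$similarity_up),
                  file.path(out_dir, "similarity_up.tsv"))
  write_tsv_table(tidy(stats$similarity_down),
                  file.path(out_dir, "similarity_down.tsv"))
  ran <- function(x) !is.character(x) && !is.null(x)
  stats_json <- list(
    seed = config$seed,
    antiviral = if (ran(stats$antiviral)) tidy(stats$antiviral)
                else stats$antiviral,
    expansion = if (ran(stats$expansion))
      as_tibble(stats$expansion) |> select(-"background")
      else stats$expansion,
    trend = if (ran(stats$trend)) glance(stats$trend) else stats$trend,
    dnds = if (ran(stats$dnds)) as_tibble(stats$dnds) else stats$dnds,
    basal = stats$basal,
    anova = if (ran(stats$anova)) as_tibble(stats$anova) else stats$anova
  )
  jsonlite::write_json(stats_json, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- setdiff(outputs, file.path(out_dir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("crossferome")),
    config = unclass(config),
    seed = config$seed,
    de_method = de_method,
    timings = timings,
    checksums = as.list(tools::md5sum(sort(outputs)) |>
                          setNames(sort(sub(paste0("^", out_dir, "/?"), "",
                                            outputs))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log("manifest", "pipeline complete: ", out_dir)

  invisible(list(truth = sim$truth, sim = sim, de = de, table = table,
                 bins = bins, cores = cores, stats = stats,
                 manifest = manifest))
}

#' Human-readable pipeline report
#'
#' Summarises a pipeline run: core-set sizes, per-species ISG/IRG counts,
#' bin occupancy, and every statistical test with its p-value and seed.
#' Sections whose outputs are missing are marked "not run" rather than
#' failing.
#'
#' @param run either the list returned by [run_pipeline()] or the path of
#'   its output directory.
#' @return character vector of report lines (class `crossferome_report`),
#'   printed with one line per row.
#' @export
make_report <- function(run) {
  if (is.character(run)) {
    return(make_report_from_dir(run))
  }
  lines <- c("== comparative interferome report ==", "")
  cores <- run$cores
  if (!is.null(cores)) {
    lines <- c(lines,
               sprintf("core (all species)       : %d", length(cores$core_vert)),
               sprintf("additional mammal core   : %d",
                       length(cores$core_mamm_extra)))
  } else {
    lines <- c(lines, "core sets: not run")
  }
  if (!is.null(run$table)) {
    counts <- as_tibble(run$table) |>
      group_by(.data$species) |>
      summarise(ISG = sum(.data$call == "ISG"),
                IRG = sum(.data$call == "IRG"), .groups = "drop")
    lines <- c(lines, "", "per-species calls:",
               sprintf("  %-10s ISG %4d  IRG %4d",
                       counts$species, counts$ISG, counts$IRG))
  }
  if (!is.null(run$bins) && nrow(run$bins) > 0) {
    occ <- run$bins |> count(.data$direction, .data$bin)
    lines <- c(lines, "", "bin occupancy (direction bin n):",
               sprintf("  %-5s %2d %5d", occ$direction, occ$bin, occ$n))
  } else {
    lines <- c(lines, "", "bins: empty")
  }
  st <- run$stats
  if (is.null(st)) {
    lines <- c(lines, "", "statistics: not run")
  } else {
    lines <- c(lines, "", sprintf("statistics (seed %s):", st$seed))
    section <- function(title, x, fmt) {
      if (is.character(x)) {
        sprintf("  %-24s: not run (%s)", title, x)
      } else if (is.null(x)) {
        sprintf("  %-24s: not run", title)
      } else {
        fmt(x)
      }
    }
    if (!is.null(st$antiviral)) {
      lines <- c(lines, section("antiviral enrichment", st$antiviral,
        function(x) sprintf(
          "  antiviral enrichment    : %d/%d species with p < 0.05 (min p %.4g)",
          sum(x$p < 0.05), nrow(x), min(x$p))))
    }
    if (!is.null(st$expansion)) {
      lines <- c(lines, section("expansion enrichment", st$expansion,
        function(x) sprintf(
          "  expansion enrichment    : %d/%d species with p < 0.05",
          sum(x$p < 0.05, na.rm = TRUE), nrow(x))))
    }
    if (!is.null(st$trend)) {
      lines <- c(lines, section("bin-expansion trend", st$trend,
        function(x) sprintf("  bin-expansion trend     : slope %.4f, p %.4g",
                            x$slope, x$p)))
    }
    if (is.data.frame(st$dnds)) {
      lines <- c(lines, sprintf(
        "  dN/dS ISG vs non-ISG    : Wilcoxon p %.3g, Kruskal-Wallis p %.3g",
        st$dnds$wilcoxon_p, st$dnds$kruskal_p))
    }
    if (is.data.frame(st$basal) && "p" %in% names(st$basal)) {
      lines <- c(lines, sprintf(
        "  basal FPKM contrast     : Kruskal-Wallis p %.3g", st$basal$p))
    }
    if (is.data.frame(st$anova) && "F_copy_class" %in% names(st$anova)) {
      lines <- c(lines, sprintf(
        "  induction ~ copy class  : F %.3f, p %.3g", st$anova$F_copy_class,
        st$anova$p_copy_class))
    } else if (!is.null(st$anova)) {
      lines <- c(lines, paste0("  induction ~ copy class  : not run (",
                               st$anova, ")"))
    }
  }
  structure(lines, class = "crossferome_report")
}

make_report_from_dir <- function(dir) {
  grab <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) p else NULL
  }
  run <- list()
  if (!is.null(grab("core_sets.json"))) {
    cs <- jsonlite::read_json(grab("core_sets.json"), simplifyVector = TRUE)
    run$cores <- list(core_vert = cs$core_vert,
                      core_mamm_extra = cs$core_mamm_extra)
  }
  if (!is.null(grab("big_table.tsv"))) {
    wide <- read_tsv_table(grab("big_table.tsv"))
    call_cols <- grep("_call$", names(wide), value = TRUE)
    run$table <- wide |>
      select("orthogroup_id", all_of(call_cols)) |>
      pivot_longer(-"orthogroup_id", names_to = "species",
                   values_to = "call") |>
      mutate(species = sub("_call$", "", .data$species))
  }
  if (!is.null(grab("bins.tsv"))) {
    run$bins <- read_tsv_table(grab("bins.tsv"))
  }
  if (!is.null(grab("stats.json"))) {
    sj <- jsonlite::read_json(grab("stats.json"), simplifyVector = TRUE)
    df_or_msg <- function(x) {
      if (is.null(x) || is.character(x) || !length(x)) x else as_tibble(x)
    }
    run$stats <- list(
      seed = sj$seed,
      antiviral = df_or_msg(sj$antiviral),
      expansion = df_or_msg(sj$expansion),
      trend = df_or_msg(sj$trend),
      dnds = df_or_msg(sj$dnds),
      basal = if (length(sj$basal)) df_or_msg(sj$basal),
      anova = df_or_msg(sj$anova)
    )
  }
  make_report(run)
}

#' @export
print.crossferome_report <- function(x, ...) {
  cat(paste(x, collapse = "\n"), "\n")
  invisible(x)
}
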