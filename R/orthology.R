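# Merging per-species DE results onto orthologous clusters.

#' Load and validate an orthogroup map
#'
#' The map has one row per (orthogroup, species, gene) membership, columns
#' `orthogroup_id`, `species`, `gene_id` (extra columns such as
#' `length_bp` are carried through). Duplicate (species, gene_id) pairs and
#' fully duplicated rows are rejected with the offending row numbers.
#'
#' @param map a data frame or a path to a TSV file.
#' @return a validated tibble of class `orthogroup_map`.
#' @export
load_orthogroups <- function(map) {
  if (is.character(map) && length(map) == 1) map <- read_tsv_table(map)
  required <- c("orthogroup_id", "species", "gene_id")
  missing_cols <- setdiff(required, names(map))
  if (length(missing_cols)) {
    abort(paste0("orthogroup map lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "crossferome_parse_error")
  }
  bad <- which(!complete.cases(map[required]) |
                 map$orthogroup_id == "" | map$gene_id == "")
  if (length(bad)) {
    abort(paste0("malformed orthogroup map row(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "crossferome_parse_error")
  }
  dup <- which(duplicated(map[c("species", "gene_id")]))
  if (length(dup)) {
    abort(paste0("duplicate (species, gene_id) in orthogroup map, row(s): ",
                 paste(head(dup, 5), collapse = ", ")),
          class = "crossferome_parse_error")
  }
  out <- as_tibble(map)
  class(out) <- c("orthogroup_map", class(out))
  out
}

#' Copy-number classes per orthogroup and species
#'
#' Counts members of each orthogroup in each species and classifies the
#' copy number as `absent` (0), `single` (1) or `multiple` (>1).
#'
#' @param groups an [load_orthogroups()] map.
#' @param species species to classify over; defaults to those observed in
#'   the map. Species absent from a group get class `absent`.
#' @return tibble: orthogroup_id, species, n_copies, copy_class.
#' @export
classify_copy_number <- function(groups, species = NULL) {
  species <- species %||% sort(unique(groups$species))
  groups |>
    filter(.data$species %in% !!species) |>
    count(.data$orthogroup_id, .data$species, name = "n_copies") |>
    tidyr::complete(orthogroup_id = unique(groups$orthogroup_id),
                    species = !!species,
                    fill = list(n_copies = 0L)) |>
    mutate(copy_class = case_when(
      .data$n_copies == 0 ~ "absent",
      .data$n_copies == 1 ~ "single",
      TRUE ~ "multiple"
    )) |>
    arrange(.data$orthogroup_id, .data$species)
}

#' One-to-one orthogroups over a species set
#'
#' An orthogroup is one-to-one over a species set iff it has exactly one
#' member in every species of that set (an absent species breaks the flag).
#'
#' @param groups an orthogroup map (or the output of
#'   [classify_copy_number()]).
#' @param species_set the species that must each carry exactly one copy.
#' @return tibble: orthogroup_id, one_to_one.
#' @export
one_to_one_groups <- function(groups, species_set) {
  classes <- if ("copy_class" %in% names(groups)) groups else
    classify_copy_number(groups, species = species_set)
  classes |>
    filter(.data$species %in% species_set) |>
    group_by(.data$orthogroup_id) |>
    summarise(one_to_one = all(.data$n_copies == 1) &
                n() == length(species_set),
              .groups = "drop")
}

#' Merge per-species DE results onto orthogroups
#'
#' Produces the merged interferome table: one row per (orthogroup, species)
#' with paralog-aggregated log2FC, FDR, basal FPKM and the response call.
#' Aggregation rules: single-copy values are copied through. For expanded
#' families, if at least one paralog is an ISG (FDR < threshold, log2FC > 0)
#' the species value is the mean log2FC over the up-regulated paralogs and
#' the call is `ISG` (the minimum FDR among them is stored; calls are always
#' recomputed per paralog, never from aggregated FDRs); symmetrically for
#' IRGs. Discordant families (ISG and IRG paralogs) are flagged `conflict`
#' and excluded from bins. Otherwise the call is `none` with the mean log2FC
#' over all paralogs. FPKM is summed over paralogs (locus-level abundance).
#' Genes present in the map but missing from a species' DE table (e.g.
#' removed by the low-count filter) count as measured-but-not-responding;
#' a species with no member at all is `absent`.
#'
#' @param groups an [load_orthogroups()] map.
#' @param de_tables named list (species -> [run_de()] tibble). Every species
#'   in the map must have a table.
#' @param fdr_threshold FDR below which a paralog is called (default 0.05,
#'   strict `<`).
#' @return tibble of class `interferome_tbl`: orthogroup_id, species,
#'   n_copies, copy_class, log2FC, FDR, basal_fpkm, call.
#' @export
merge_de <- function(groups, de_tables, fdr_threshold = 0.05) {
  species <- sort(unique(groups$species))
  missing_sp <- setdiff(species, names(de_tables))
  if (length(missing_sp)) {
    abort(paste0("no DE table for species: ",
                 paste(missing_sp, collapse = ", ")),
          class = "crossferome_data_error")
  }
  de_all <- imap(de_tables[species], function(d, s) {
    tibble(species = s, gene_id = d$gene_id, log2FC = d$log2FC,
           FDR = d$FDR, basal_fpkm = d$basal_fpkm)
  }) |> list_rbind()

  gene_level <- groups |>
    as_tibble() |>
    select("orthogroup_id", "species", "gene_id") |>
    left_join(de_all, by = c("species", "gene_id")) |>
    mutate(call = call_response(.data$log2FC, .data$FDR,
                                fdr_threshold = fdr_threshold))

  merged <- gene_level |>
    group_by(.data$orthogroup_id, .data$species) |>
    summarise(
      n_copies = n(),
      n_isg = sum(.data$call == "ISG"),
      n_irg = sum(.data$call == "IRG"),
      l2fc_isg = mean(.data$log2FC[.data$call == "ISG"]),
      l2fc_irg = mean(.data$log2FC[.data$call == "IRG"]),
      l2fc_all = mean(.data$log2FC, na.rm = TRUE),
      fdr_isg = suppressWarnings(min(.data$FDR[.data$call == "ISG"])),
      fdr_irg = suppressWarnings(min(.data$FDR[.data$call == "IRG"])),
      fdr_min = suppressWarnings(min(.data$FDR, na.rm = TRUE)),
      basal_fpkm = if (all(is.na(.data$basal_fpkm))) NA_real_ else
        sum(.data$basal_fpkm, na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(
      call = case_when(
        .data$n_isg > 0 & .data$n_irg > 0 ~ "conflict",
        .data$n_isg > 0 ~ "ISG",
        .data$n_irg > 0 ~ "IRG",
        TRUE ~ "none"
      ),
      log2FC = case_when(
        call == "ISG" ~ .data$l2fc_isg,
        call == "IRG" ~ .data$l2fc_irg,
        TRUE ~ ifelse(is.nan(.data$l2fc_all), NA_real_, .data$l2fc_all)
      ),
      FDR = case_when(
        call == "ISG" ~ .data$fdr_isg,
        call == "IRG" ~ .data$fdr_irg,
        TRUE ~ ifelse(is.finite(.data$fdr_min), .data$fdr_min, NA_real_)
      )
    ) |>
    select("orthogroup_id", "species", "n_copies", "log2FC", "FDR",
           "basal_fpkm", "call") |>
    tidyr::complete(
      orthogroup_id = unique(groups$orthogroup_id), species = !!species,
      fill = list(n_copies = 0L, call = "absent")
    ) |>
    mutate(copy_class = case_when(
      .data$n_copies == 0 ~ "absent",
      .data$n_copies == 1 ~ "single",
      TRUE ~ "multiple"
    )) |>
    select("orthogroup_id", "species", "n_copies", "copy_class",
           "log2FC", "FDR", "basal_fpkm", "call") |>
    arrange(.data$orthogroup_id, .data$species)

  attr(merged, "species") <- species
  attr(merged, "fdr_threshold") <- fdr_threshold
  class(merged) <- c("interferome_tbl", class(merged))
  merged
}

#' Pivot a merged interferome table to the wide "big table" layout
#'
#' One row per orthogroup, per-species column quadruples
#' (`<sp>_log2FC`, `<sp>_FDR`, `<sp>_FPKM`, `<sp>_call`).
#'
#' @param table an [merge_de()] result.
#' @return a wide tibble, one row per orthogroup.
#' @export
big_table_wide <- function(table) {
  table |>
    as_tibble() |>
    select("orthogroup_id", "species", "log2FC", "FDR",
           FPKM = "basal_fpkm", "call") |>
    pivot_wider(names_from = "species",
                values_from = c("log2FC", "FDR", "FPKM", "call"),
                names_glue = "{species}_{.value}") |>
    arrange(.data$orthogroup_id)
}
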