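# Response calling, species-count bins, core sets and table queries.

#' Call the IFN response of a gene
#'
#' An ISG is a gene up-regulated with FDR below the threshold (strictly;
#' `FDR = 0.05` is not significant), regardless of effect size; an IRG is
#' the down-regulated counterpart. Missing values yield `none`.
#'
#' @param log2fc log2 fold change(s), IFN vs mock.
#' @param fdr BH-adjusted p-value(s) in [0, 1].
#' @param fdr_threshold significance threshold (default 0.05).
#' @return character vector: `"ISG"`, `"IRG"` or `"none"`.
#' @examples
#' call_response(c(1.2, 1.2, -0.3), c(0.049, 0.05, 0.01))
#' @export
call_response <- function(log2fc, fdr, fdr_threshold = 0.05) {
  if (any(fdr < 0 | fdr > 1, na.rm = TRUE)) {
    abort("FDR values must lie in [0, 1]", class = "crossferome_data_error")
  }
  case_when(
    is.na(log2fc) | is.na(fdr) ~ "none",
    fdr < fdr_threshold & log2fc > 0 ~ "ISG",
    fdr < fdr_threshold & log2fc < 0 ~ "IRG",
    TRUE ~ "none"
  )
}

#' Bin orthogroups by the number of responding species
#'
#' For each direction, an orthogroup's bin is the number of species in which
#' it carries that call (bin `n_species` = the all-species core). A group
#' that is up-regulated in some species and down-regulated in others appears
#' in both an up and a down bin, flagged `discordant`. Groups with no call
#' in a direction are omitted from that direction.
#'
#' @param table an [merge_de()] interferome table.
#' @return tibble: orthogroup_id, direction (`up`/`down`), bin,
#'   species (list-column of contributing species), discordant.
#' @export
bin_by_species_count <- function(table) {
  calls <- table |>
    as_tibble() |>
    filter(.data$call %in% c("ISG", "IRG")) |>
    mutate(direction = ifelse(.data$call == "ISG", "up", "down"))
  bins <- calls |>
    group_by(.data$orthogroup_id, .data$direction) |>
    summarise(bin = n(), species = list(sort(.data$species)),
              .groups = "drop")
  bins |>
    group_by(.data$orthogroup_id) |>
    mutate(discordant = n() > 1) |>
    ungroup() |>
    arrange(.data$direction, desc(.data$bin), .data$orthogroup_id)
}

#' Extract core and species-unique ISG sets
#'
#' `core_vert` holds orthogroups called ISG in every species of
#' `all_species`; `core_mamm_extra` those called ISG in every mammal but not
#' in all species. Core membership requires presence (an annotated
#' ortholog): an orthogroup absent from one species cannot be core,
#' whatever its calls elsewhere. Species-unique sets are the up-bin-1
#' orthogroups per species; the high-confidence subset additionally requires
#' log2FC >= `unique_log2fc_cutoff` in that species.
#'
#' @param table an [merge_de()] interferome table.
#' @param mammal_species,all_species species sets; `mammal_species` must be
#'   a subset of `all_species`, which must all appear in the table.
#' @param unique_log2fc_cutoff log2FC cutoff for the high-confidence
#'   species-unique subset (default 2).
#' @return object of class `core_sets`: list with `core_vert`,
#'   `core_mamm_extra` (character vectors of orthogroup ids),
#'   `species_unique` and `species_unique_high_conf` (tibbles:
#'   orthogroup_id, species, log2FC).
#' @export
core_sets <- function(table, mammal_species, all_species,
                      unique_log2fc_cutoff = 2) {
  present <- unique(table$species)
  unknown <- setdiff(c(mammal_species, all_species), present)
  if (length(unknown)) {
    abort(paste0("species not in table: ", paste(unknown, collapse = ", ")),
          class = "crossferome_data_error")
  }
  if (!all(mammal_species %in% all_species)) {
    abort("`mammal_species` must be a subset of `all_species`",
          class = "crossferome_data_error")
  }
  tbl <- as_tibble(table)
  isg_in_all <- function(set) {
    tbl |>
      filter(.data$species %in% set) |>
      group_by(.data$orthogroup_id) |>
      summarise(core = all(.data$call == "ISG") & n() == length(set),
                .groups = "drop") |>
      filter(.data$core) |>
      pull("orthogroup_id")
  }
  core_vert <- isg_in_all(all_species)
  core_mamm <- isg_in_all(mammal_species)
  core_mamm_extra <- setdiff(core_mamm, core_vert)

  up1 <- bin_by_species_count(tbl) |>
    filter(.data$direction == "up", .data$bin == 1) |>
    mutate(species = map_chr(.data$species, 1)) |>
    select("orthogroup_id", "species")
  uniq <- up1 |>
    left_join(tbl |> select("orthogroup_id", "species", "log2FC"),
              by = c("orthogroup_id", "species"))

  structure(
    list(
      core_vert = core_vert,
      core_mamm_extra = core_mamm_extra,
      species_unique = uniq,
      species_unique_high_conf =
        filter(uniq, .data$log2FC >= unique_log2fc_cutoff),
      all_species = all_species, mammal_species = mammal_species
    ),
    class = "core_sets"
  )
}

#' @export
print.core_sets <- function(x, ...) {
  cat("<core_sets>\n")
  cat("  all-species core       :", length(x$core_vert), "orthogroups\n")
  cat("  additional mammal core :", length(x$core_mamm_extra), "orthogroups\n")
  cat("  species-unique (>=2 log2FC high-conf):",
      nrow(x$species_unique), sprintf("(%d)", nrow(x$species_unique_high_conf)),
      "\n")
  invisible(x)
}

#' Query a merged interferome table
#'
#' Webserver-style filtering: rows (orthogroups) satisfying the conjunction
#' of the supplied criteria, returned in stable orthogroup-id order.
#'
#' @param table an [merge_de()] interferome table.
#' @param orthogroups restrict to these orthogroup ids.
#' @param species restrict the per-species criteria below to these species
#'   (default: all species in the table).
#' @param call require this call (`"ISG"`/`"IRG"`/`"none"`) in every
#'   selected species.
#' @param min_log2fc,max_fdr per-species expression criteria, applied in
#'   every selected species.
#' @param min_species_up,min_species_down require at least this many species
#'   (among `species`) with an ISG / IRG call.
#' @return the filtered table (long layout, all species retained for the
#'   matching orthogroups).
#' @export
query_interferome <- function(table, orthogroups = NULL, species = NULL,
                              call = NULL, min_log2fc = NULL, max_fdr = NULL,
                              min_species_up = NULL,
                              min_species_down = NULL) {
  tbl <- as_tibble(table)
  if (!is.null(species)) {
    unknown <- setdiff(species, unique(tbl$species))
    if (length(unknown)) {
      abort(paste0("unknown species: ", paste(unknown, collapse = ", ")),
            class = "crossferome_data_error")
    }
  }
  if (!is.null(call) && !call %in% c("ISG", "IRG", "none", "absent")) {
    abort("unknown call value", class = "crossferome_data_error")
  }
  sel <- unique(tbl$orthogroup_id)
  if (!is.null(orthogroups)) sel <- intersect(sel, orthogroups)
  sub <- filter(tbl, .data$species %in% (!!species %||% unique(tbl$species)))

  keep_all <- function(cond_tbl) {
    cond_tbl |>
      group_by(.data$orthogroup_id) |>
      summarise(ok = all(.data$ok), .groups = "drop") |>
      filter(.data$ok) |>
      pull("orthogroup_id")
  }
  if (!is.null(call)) {
    sel <- intersect(sel, keep_all(mutate(sub, ok = .data$call == !!call)))
  }
  if (!is.null(min_log2fc)) {
    sel <- intersect(sel, keep_all(
      mutate(sub, ok = !is.na(.data$log2FC) & .data$log2FC >= min_log2fc)))
  }
  if (!is.null(max_fdr)) {
    sel <- intersect(sel, keep_all(
      mutate(sub, ok = !is.na(.data$FDR) & .data$FDR <= max_fdr)))
  }
  count_dir <- function(what) {
    sub |>
      group_by(.data$orthogroup_id) |>
      summarise(k = sum(.data$call == what), .groups = "drop")
  }
  if (!is.null(min_species_up)) {
    sel <- intersect(sel, count_dir("ISG") |>
                       filter(.data$k >= min_species_up) |>
                       pull("orthogroup_id"))
  }
  if (!is.null(min_species_down)) {
    sel <- intersect(sel, count_dir("IRG") |>
                       filter(.data$k >= min_species_down) |>
                       pull("orthogroup_id"))
  }
  out <- tbl |>
    filter(.data$orthogroup_id %in% sel) |>
    arrange(.data$orthogroup_id, .data$species)
  attr(out, "species") <- attr(table, "species")
  out
}

#' The packaged core-ISG catalogue
#'
#' Reads the catalogue of 90 core interferon-stimulated genes identified
#' across ten vertebrate species (nine mammals and the chicken): 62 genes
#' up-regulated in all ten species and 28 additional genes flagged
#' `mammal_only` (up-regulated in the nine mammals but not the chicken).
#' Family entries (HLA, APOL) are single rows with their members listed in
#' the `members` column.
#'
#' @param path path to the TSV; defaults to the copy shipped with the
#'   package.
#' @return tibble: gene, alias, functional_category, mammal_only, members.
#' @export
read_core_table <- function(path = system.file("extdata", "core_isgs.tsv",
                                               package = "crossferome")) {
  tbl <- read_tsv_table(path)
  required <- c("gene", "functional_category", "mammal_only")
  if (!all(required %in% names(tbl))) {
    abort("core table lacks required columns",
          class = "crossferome_parse_error")
  }
  if (anyDuplicated(tbl$gene)) {
    abort("duplicate gene entries in core table",
          class = "crossferome_parse_error")
  }
  mutate(tbl, mammal_only = as.logical(.data$mammal_only))
}

#' Summary counts of the core-ISG catalogue
#'
#' @param core_table a [read_core_table()] tibble.
#' @return tibble with one row: n_total, n_core_vert, n_core_mamm_extra and
#'   per-category core counts for the antigen-presentation and antiviral
#'   categories.
#' @export
core_table_counts <- function(core_table = read_core_table()) {
  tibble(
    n_total = nrow(core_table),
    n_core_vert = sum(!core_table$mammal_only),
    n_core_mamm_extra = sum(core_table$mammal_only),
    n_core_vert_antigen_presentation = sum(
      !core_table$mammal_only &
        core_table$functional_category == "antigen_presentation"),
    n_core_vert_antiviral = sum(
      !core_table$mammal_only & core_table$functional_category == "antiviral")
  )
}
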