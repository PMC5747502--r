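# Resampling statistics: antiviral-panel enrichment, gene-expansion ratios
# with resampled backgrounds, and the bin-vs-expansion trend.

#' Empirical p-value with the add-one rule
#'
#' `p = (r + 1) / (B + 1)` where `r` counts null values at least as extreme
#' as the observed statistic; the add-one rule keeps p off zero, so the
#' smallest attainable value is `1 / (B + 1)`.
#'
#' @param observed observed statistic.
#' @param null numeric vector of `B` null statistics.
#' @param alternative `"greater"` (null >= observed is extreme), `"less"`,
#'   or `"two_sided"` (compared on absolute values).
#' @return single numeric p-value.
#' @export
empirical_pvalue <- function(observed,
                             null,
                             alternative = c("greater", "less", "two_sided")) {
  alternative <- match.arg(alternative)
  if (length(null) < 1) {
    abort("need at least one null value (B >= 1)",
          class = "crossferome_data_error")
  }
  r <- switch(alternative,
    greater = sum(null >= observed),
    less = sum(null <= observed),
    two_sided = sum(abs(null) >= abs(observed))
  )
  (r + 1) / (length(null) + 1)
}

new_resampling_result <- function(species, observed, null, p, seed,
                                  n_panel = NA_integer_, flag = NA_character_) {
  tibble(species = species, observed = observed, B = length(null),
         null = list(null), p = p, seed = seed, n_panel = n_panel,
         flag = flag)
}

#' Antiviral-panel enrichment by ISG resampling
#'
#' For each species, compares the mean log2FC of the antiviral-panel genes
#' that are ISGs in that species against `B` resamples of `k` ISGs drawn
#' without replacement from the species' whole ISG repertoire. The
#' empirical p-value uses the add-one rule, so with `B = 100` the smallest
#' attainable p is 1/101 (< 0.01).
#'
#' @param table an [merge_de()] interferome table.
#' @param panel character vector of panel orthogroup ids (names unique).
#' @param B number of resamples (default 100).
#' @param k resample size (default 40, the panel size).
#' @param seed integer seed recorded in the result.
#' @param species species to test (default: all in the table).
#' @param min_panel_isgs species with fewer panel ISGs than this are flagged
#'   (statistic still reported).
#' @return tibble of class `resampling_result`, one row per species:
#'   species, observed, B, null (list-column), p, seed, n_panel, flag.
#' @export
antiviral_enrichment <- function(table, panel, B = 100, k = 40, seed = 1L,
                                 species = NULL, min_panel_isgs = 5) {
  if (B < 1) {
    abort("`B` must be >= 1", class = "crossferome_config_error")
  }
  if (anyDuplicated(panel)) {
    abort("panel gene names must be unique", class = "crossferome_data_error")
  }
  tbl <- as_tibble(table)
  species <- species %||% (attr(table, "species") %||% sort(unique(tbl$species)))
  with_seed(sub_seed(seed, "resample"), {
    out <- lapply(species, function(s) {
      isgs <- filter(tbl, .data$species == s, .data$call == "ISG")
      if (nrow(isgs) < k) {
        abort(sprintf("species '%s' has %d ISGs, fewer than k = %d",
                      s, nrow(isgs), k),
              class = "crossferome_data_error")
      }
      in_panel <- isgs$orthogroup_id %in% panel
      observed <- mean(isgs$log2FC[in_panel])
      null <- vapply(seq_len(B), function(b) {
        mean(isgs$log2FC[sample.int(nrow(isgs), k)])
      }, 0)
      new_resampling_result(
        s, observed, null,
        empirical_pvalue(observed, null, "greater"), seed,
        n_panel = sum(in_panel),
        flag = if (sum(in_panel) < min_panel_isgs) "few_panel_isgs"
               else NA_character_
      )
    })
    res <- list_rbind(out)
    class(res) <- c("resampling_result", class(res))
    res
  })
}

#' @exportS3Method
tidy.resampling_result <- function(x, ...) {
  as_tibble(x) |> select(-"null")
}

#' @exportS3Method
glance.resampling_result <- function(x, ...) {
  tibble(n_species = nrow(x), B = x$B[1],
         n_significant = sum(x$p < 0.05), min_p = min(x$p))
}

#' @exportS3Method
autoplot.resampling_result <- function(object, ...) {
  nulls <- as_tibble(object) |>
    select("species", "null") |>
    unnest("null")
  ggplot2::ggplot(nulls, ggplot2::aes(.data$species, .data$null)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_point(data = as_tibble(object),
                        ggplot2::aes(.data$species, .data$observed),
                        colour = "firebrick", shape = 8, size = 3) +
    ggplot2::labs(x = NULL, y = "mean log2FC",
                  subtitle = "panel mean (star) vs resampled ISG means") +
    ggplot2::theme_minimal()
}

#' Gene-expansion ratio of a gene set
#'
#' The ratio between the number of genes carried as multiple copies
#' (paralogs) and those carried as a single copy, a proxy for gene
#' expansion. Undefined (NA, flagged) when there are no single-copy genes.
#'
#' @param copy_class character vector of copy classes (`"single"` /
#'   `"multiple"`; other values are ignored with a warning).
#' @param label optional set label carried into the result.
#' @return tibble: label, n_multiple, n_single, ratio, flag.
#' @export
expansion_ratio <- function(copy_class, label = NA_character_) {
  known <- copy_class %in% c("single", "multiple")
  if (!all(known)) {
    warn("ignoring copy classes other than single/multiple")
    copy_class <- copy_class[known]
  }
  n_multiple <- sum(copy_class == "multiple")
  n_single <- sum(copy_class == "single")
  tibble(label = label, n_multiple = n_multiple, n_single = n_single,
         ratio = if (n_single == 0) NA_real_ else n_multiple / n_single,
         flag = if (n_single == 0) "undefined_ratio" else NA_character_)
}

#' Resampled background expansion ratios
#'
#' Draws `n` random same-size subsets from a pool of copy classes (the
#' non-ISG background) and returns each subset's expansion ratio.
#'
#' @param pool_classes copy classes of the background pool.
#' @param size subset size (the size of the ISG set being compared).
#' @param n number of resamples (default 500).
#' @param seed integer seed.
#' @return numeric vector of `n` background ratios (NA where a draw has no
#'   single-copy genes).
#' @export
expansion_background <- function(pool_classes, size, n = 500, seed = 1L) {
  if (size < 1 || size > length(pool_classes)) {
    abort("`size` must be between 1 and the pool size",
          class = "crossferome_data_error")
  }
  with_seed(sub_seed(seed, "background"), {
    vapply(seq_len(n), function(i) {
      cls <- pool_classes[sample.int(length(pool_classes), size)]
      n_s <- sum(cls == "single")
      if (n_s == 0) NA_real_ else sum(cls == "multiple") / n_s
    }, 0)
  })
}

#' Per-species expansion enrichment of ISGs
#'
#' For each species, compares the expansion ratio of its ISGs with `n`
#' same-size draws from its non-ISG genes, with an add-one empirical
#' p-value (one-sided: background at least as expanded as the ISGs).
#'
#' @param table an [merge_de()] interferome table.
#' @param n background resamples (default 500).
#' @param seed integer seed.
#' @param species species to test (default: all in the table).
#' @return tibble of class `expansion_summary`: species, n_multiple,
#'   n_single, ratio, background (list-column), p, seed, flag.
#' @export
expansion_test <- function(table, n = 500, seed = 1L, species = NULL) {
  tbl <- filter(as_tibble(table), .data$copy_class != "absent")
  species <- species %||% (attr(table, "species") %||% sort(unique(tbl$species)))
  out <- lapply(species, function(s) {
    sub <- filter(tbl, .data$species == s)
    isg <- filter(sub, .data$call == "ISG")
    bg <- filter(sub, .data$call != "ISG")
    obs <- expansion_ratio(isg$copy_class, label = s)
    null <- expansion_background(bg$copy_class, size = nrow(isg), n = n,
                                 seed = sub_seed(seed, "resample") + match(s, species))
    p <- if (is.na(obs$ratio)) NA_real_ else
      empirical_pvalue(obs$ratio, null[!is.na(null)], "greater")
    tibble(species = s, n_multiple = obs$n_multiple, n_single = obs$n_single,
           ratio = obs$ratio, background = list(null), p = p,
           seed = seed, flag = obs$flag)
  })
  res <- list_rbind(out)
  class(res) <- c("expansion_summary", class(res))
  res
}

#' @exportS3Method
autoplot.expansion_summary <- function(object, ...) {
  bg <- as_tibble(object) |>
    select("species", "background") |>
    unnest("background")
  ggplot2::ggplot(bg, ggplot2::aes(.data$species, .data$background)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_point(data = as_tibble(object),
                        ggplot2::aes(.data$species, .data$ratio),
                        colour = "firebrick", shape = 4, size = 3) +
    ggplot2::labs(x = NULL, y = "multiple/single ratio") +
    ggplot2::theme_minimal()
}

#' Trend between species-count bin and gene expansion
#'
#' Computes the expansion ratio of each up-regulation bin (the genes
#' up-regulated in exactly `bin` species), regresses ratio on bin index,
#' and tests the slope by permuting the bin labels of the underlying
#' orthogroups. A positive slope means widely shared ISGs are more likely
#' to carry paralogs.
#'
#' @param bins a [bin_by_species_count()] tibble (one direction is
#'   selected via `direction`).
#' @param copy_classes tibble orthogroup_id, copy_class giving each
#'   orthogroup's copy class in the relevant species (use
#'   `summarise_copy_class()` or any per-genome class); orthogroups absent
#'   from this table are dropped.
#' @param direction `"up"` or `"down"`.
#' @param B number of label permutations (default 10000).
#' @param seed integer seed.
#' @return list of class `expansion_trend`: per-bin ratios, slope, p, B,
#'   seed.
#' @export
bin_expansion_trend <- function(bins, copy_classes, direction = "up",
                                B = 10000, seed = 1L) {
  dat <- bins |>
    filter(.data$direction == !!direction) |>
    inner_join(copy_classes, by = "orthogroup_id") |>
    filter(.data$copy_class %in% c("single", "multiple"))
  if (length(unique(dat$bin)) < 3) {
    abort("need >= 3 non-empty bins for a trend",
          class = "crossferome_data_error")
  }
  mult <- dat$copy_class == "multiple"
  ub <- sort(unique(dat$bin))
  idx <- match(dat$bin, ub)
  n_per <- tabulate(idx, length(ub))
  xc <- ub - mean(ub)
  sxx <- sum(xc^2)
  ratios_of <- function(m) {
    s <- vapply(seq_along(ub), function(i) sum(m[idx == i]), 0)
    s / pmax(n_per - s, 1)
  }
  slope_of <- function(r) sum(xc * r) / sxx
  obs_ratio <- ratios_of(mult)
  obs_tbl <- tibble(bin = ub, ratio = obs_ratio, n = n_per)
  if (max(obs_ratio) - min(obs_ratio) < .Machine$double.eps^0.5) {
    return(structure(list(per_bin = obs_tbl, slope = 0, p = 1, B = B,
                          seed = seed), class = "expansion_trend"))
  }
  obs_slope <- slope_of(obs_ratio)
  with_seed(sub_seed(seed, "trend"), {
    null <- vapply(seq_len(B), function(b) {
      slope_of(ratios_of(mult[sample.int(length(mult))]))
    }, 0)
    structure(
      list(per_bin = obs_tbl, slope = obs_slope,
           p = empirical_pvalue(obs_slope, null, "two_sided"),
           null = null, B = B, seed = seed),
      class = "expansion_trend"
    )
  })
}

#' @exportS3Method
glance.expansion_trend <- function(x, ...) {
  tibble(slope = x$slope, p = x$p, B = x$B, n_bins = nrow(x$per_bin))
}

#' @exportS3Method
autoplot.expansion_trend <- function(object, ...) {
  ggplot2::ggplot(object$per_bin, ggplot2::aes(.data$bin, .data$ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "number of responding species",
                  y = "multiple/single ratio") +
    ggplot2::theme_minimal()
}
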