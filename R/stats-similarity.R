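# Pairwise interferome similarity and PCA of shared one-to-one orthologs.

#' Pairwise interferome similarity between species
#'
#' For each species pair, the overlap of their called gene sets in one
#' direction. `method = "jaccard"` (default) uses
#' `|S_i intersect S_j| / |S_i union S_j|`, already normalised to [0, 1];
#' `method = "pearson"` correlates log2FC over orthogroups called in both
#' species, rescaled from [-1, 1] to [0, 1]. The diagonal is 1; a species
#' with no calls gets `NA` rows/columns.
#'
#' @param table an [merge_de()] interferome table.
#' @param direction `"up"` (ISGs) or `"down"` (IRGs).
#' @param method `"jaccard"` or `"pearson"`.
#' @return object of class `similarity_matrix`: a symmetric species x
#'   species matrix.
#' @export
similarity_matrix <- function(table, direction = c("up", "down"),
                              method = c("jaccard", "pearson")) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  want <- if (direction == "up") "ISG" else "IRG"
  tbl <- as_tibble(table)
  species <- attr(table, "species") %||% sort(unique(tbl$species))
  sets <- lapply(setNames(species, species), function(s) {
    tbl$orthogroup_id[tbl$species == s & tbl$call == want]
  })
  n <- length(species)
  m <- matrix(NA_real_, n, n, dimnames = list(species, species))
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      si <- sets[[i]]; sj <- sets[[j]]
      if (length(si) == 0 || length(sj) == 0) next
      v <- if (method == "jaccard") {
        length(intersect(si, sj)) / length(union(si, sj))
      } else {
        shared <- intersect(si, sj)
        if (length(shared) < 3) {
          NA_real_
        } else {
          xi <- tbl$log2FC[tbl$species == species[i] &
                             tbl$orthogroup_id %in% shared]
          xj <- tbl$log2FC[tbl$species == species[j] &
                             tbl$orthogroup_id %in% shared]
          (stats::cor(xi, xj) + 1) / 2
        }
      }
      m[i, j] <- m[j, i] <- v
    }
    if (length(sets[[i]]) > 0) m[i, i] <- 1
  }
  structure(m, class = c("similarity_matrix", "matrix"),
            direction = direction, method = method)
}

#' @exportS3Method
tidy.similarity_matrix <- function(x, ...) {
  as_tibble(unclass(x), rownames = "species_a") |>
    pivot_longer(-"species_a", names_to = "species_b",
                 values_to = "similarity")
}

#' @exportS3Method
autoplot.similarity_matrix <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$species_a, .data$species_b,
                                 fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white",
                                 high = if (attr(object, "direction") == "up")
                                   "firebrick" else "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = paste0("similarity (",
                                attr(object, "direction"), ")")) +
    ggplot2::theme_minimal()
}

#' PCA of shared one-to-one ortholog responses
#'
#' Restricts the table to orthogroups that are one-to-one over
#' `species_set` and called ISG in every one of those species, then runs a
#' centred (unscaled) PCA of the species x orthogroup log2FC matrix.
#' Components are ordered by decreasing variance explained.
#'
#' @param table an [merge_de()] interferome table.
#' @param species_set species defining the shared core (e.g. the mammals).
#' @return object of class `interferome_pca`: list with `scores` (tibble:
#'   species, PC1..), `var_explained`, `orthogroups` used, and the `prcomp`
#'   fit.
#' @export
pca_core <- function(table, species_set) {
  tbl <- filter(as_tibble(table), .data$species %in% species_set)
  usable <- tbl |>
    group_by(.data$orthogroup_id) |>
    summarise(ok = all(.data$call == "ISG" & .data$n_copies == 1) &
                n() == length(species_set), .groups = "drop") |>
    filter(.data$ok) |>
    pull("orthogroup_id")
  if (length(usable) < 2) {
    abort("fewer than 2 one-to-one orthogroups up-regulated in all species",
          class = "crossferome_data_error")
  }
  wide <- tbl |>
    filter(.data$orthogroup_id %in% usable) |>
    select("orthogroup_id", "species", "log2FC") |>
    pivot_wider(names_from = "orthogroup_id", values_from = "log2FC")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$species
  fit <- prcomp(m, center = TRUE, scale. = FALSE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  structure(
    list(
      scores = bind_cols(tibble(species = rownames(m)),
                         as_tibble(fit$x)),
      var_explained = ve,
      orthogroups = usable,
      fit = fit
    ),
    class = "interferome_pca"
  )
}

#' @exportS3Method
tidy.interferome_pca <- function(x, ...) x$scores

#' @exportS3Method
glance.interferome_pca <- function(x, ...) {
  tibble(n_orthogroups = length(x$orthogroups),
         n_components = length(x$var_explained),
         pc1_var = x$var_explained[1],
         pc2_var = if (length(x$var_explained) > 1) x$var_explained[2] else NA_real_)
}

#' @exportS3Method
autoplot.interferome_pca <- function(object, ...) {
  lab <- function(i) sprintf("PC%d (%.0f%%)", i, 100 * object$var_explained[i])
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$PC1, .data$PC2, colour = .data$species)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
}
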