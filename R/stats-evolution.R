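# dN/dS contrasts, basal-expression contrasts, induction-by-copy-class
# ANOVA, and hit-count normalisation.

#' Orthogroup-level copy class across species
#'
#' Collapses per-(orthogroup, species) copy classes to one class per
#' orthogroup: `multiple` if the family is expanded in at least one species
#' where it is present, else `single`. Used as the expansion proxy for the
#' bin-vs-expansion trend.
#'
#' @param table an [merge_de()] interferome table (or any tibble with
#'   orthogroup_id, copy_class).
#' @return tibble: orthogroup_id, copy_class.
#' @export
summarise_copy_class <- function(table) {
  as_tibble(table) |>
    filter(.data$copy_class != "absent") |>
    group_by(.data$orthogroup_id) |>
    summarise(copy_class = if (any(.data$copy_class == "multiple"))
      "multiple" else "single", .groups = "drop")
}

#' Contrast dN/dS distributions of ISGs and non-ISGs
#'
#' Computes per-gene dN/dS (genes with dS = 0 are excluded and counted in
#' the result) and compares the ISG and non-ISG distributions with the
#' two-sided Wilcoxon rank-sum test (with continuity correction) and the
#' Kruskal-Wallis rank-sum test.
#'
#' @param isg_dnds,non_isg_dnds tibbles with columns `dn` and `ds` (a
#'   precomputed `dnds` column is used if present and dn/ds are absent).
#' @return tibble of class `dnds_contrast`: medians, both test statistics
#'   and p-values, group sizes, and the number of dS = 0 exclusions.
#' @export
dnds_contrast <- function(isg_dnds, non_isg_dnds) {
  get_ratio <- function(d) {
    if (all(c("dn", "ds") %in% names(d))) {
      excl <- sum(d$ds == 0)
      list(ratio = d$dn[d$ds > 0] / d$ds[d$ds > 0], excluded = excl)
    } else if ("dnds" %in% names(d)) {
      list(ratio = d$dnds, excluded = 0L)
    } else {
      abort("need columns dn/ds (or dnds)", class = "crossferome_data_error")
    }
  }
  a <- get_ratio(isg_dnds)
  b <- get_ratio(non_isg_dnds)
  if (length(a$ratio) == 0 || length(b$ratio) == 0) {
    abort("both groups must be non-empty", class = "crossferome_data_error")
  }
  x <- a$ratio; y <- b$ratio
  if (length(unique(c(x, y))) == 1) {
    warn("all dN/dS values tied; p = 1")
    res <- tibble(median_isg = median(x), median_non_isg = median(y),
                  wilcoxon_W = NA_real_, wilcoxon_p = 1,
                  kruskal_chisq = NA_real_, kruskal_p = 1,
                  n_isg = length(x), n_non_isg = length(y),
                  n_excluded_ds0 = a$excluded + b$excluded)
  } else {
    w <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                      correct = TRUE))
    kw <- kruskal.test(list(x, y))
    res <- tibble(median_isg = median(x), median_non_isg = median(y),
                  wilcoxon_W = unname(w$statistic), wilcoxon_p = w$p.value,
                  kruskal_chisq = unname(kw$statistic), kruskal_p = kw$p.value,
                  n_isg = length(x), n_non_isg = length(y),
                  n_excluded_ds0 = a$excluded + b$excluded)
  }
  class(res) <- c("dnds_contrast", class(res))
  res
}

#' Contrast basal expression between species groups
#'
#' Kruskal-Wallis test of basal (mock) FPKM across two or more species
#' groups, over a gene subset (the whole interferome, or e.g. an antiviral
#' panel). Each (orthogroup, species) basal FPKM contributes one
#' observation to its species' group.
#'
#' @param table an [merge_de()] interferome table.
#' @param groups named list of species character vectors (>= 2 groups).
#' @param gene_subset optional orthogroup ids to restrict to.
#' @param responding_only if TRUE (default) only rows called ISG enter,
#'   i.e. the comparison is over each species' interferome.
#' @return tibble: kruskal_chisq, df, p, per-group n.
#' @export
basal_fpkm_contrast <- function(table, groups, gene_subset = NULL,
                                responding_only = TRUE) {
  if (!is.list(groups) || length(groups) < 2) {
    abort("`groups` must be a list of >= 2 species groups",
          class = "crossferome_data_error")
  }
  tbl <- as_tibble(table)
  if (!is.null(gene_subset)) {
    tbl <- filter(tbl, .data$orthogroup_id %in% gene_subset)
  }
  if (responding_only) tbl <- filter(tbl, .data$call == "ISG")
  tbl <- filter(tbl, !is.na(.data$basal_fpkm))
  if (nrow(tbl) == 0) {
    abort("empty gene subset", class = "crossferome_data_error")
  }
  grp_names <- names(groups) %||% paste0("group", seq_along(groups))
  values <- lapply(groups, function(sp) tbl$basal_fpkm[tbl$species %in% sp])
  if (any(vapply(values, length, 0L) == 0)) {
    abort("every group needs at least one observation",
          class = "crossferome_data_error")
  }
  kw <- kruskal.test(values)
  tibble(kruskal_chisq = unname(kw$statistic),
         df = unname(kw$parameter), p = kw$p.value,
         n = paste(grp_names, vapply(values, length, 0L),
                   sep = "=", collapse = ", "))
}

#' Two-way ANOVA of induction by species and copy class
#'
#' Fits the additive model `log2FC ~ species + copy_class` on
#' per-(orthogroup, species) log2FC of a core gene set, and reports the
#' copy-class F test: are single-copy orthologs induced to a different
#' level than expanded families?
#'
#' @param table an [merge_de()] interferome table.
#' @param core_ids orthogroup ids of the core set to analyse.
#' @param responding_only if TRUE (default) only ISG-called rows enter.
#' @return tibble of class `copyclass_anova`: F and p for the copy-class
#'   factor, degrees of freedom, n, plus the underlying `aov` fit as an
#'   attribute.
#' @export
induction_by_copyclass <- function(table, core_ids, responding_only = TRUE) {
  dat <- as_tibble(table) |>
    filter(.data$orthogroup_id %in% core_ids,
           .data$copy_class %in% c("single", "multiple"),
           !is.na(.data$log2FC))
  if (responding_only) dat <- filter(dat, .data$call == "ISG")
  if (length(unique(dat$copy_class)) < 2 || length(unique(dat$species)) < 2) {
    abort("both factors need >= 2 levels",
          class = "crossferome_data_error")
  }
  fit <- aov(log2FC ~ species + copy_class, data = dat)
  tab <- summary(fit)[[1]]
  i <- trimws(rownames(tab)) == "copy_class"
  f_val <- tab[i, "F value"]
  p_val <- tab[i, "Pr(>F)"]
  if (var(dat$log2FC) == 0) {
    # constant response: no effect of anything (avoid 0/0 round-off)
    f_val <- 0
    p_val <- 1
  }
  res <- tibble(
    F_copy_class = f_val, p_copy_class = p_val,
    df_copy_class = tab[i, "Df"],
    df_residual = tab[trimws(rownames(tab)) == "Residuals", "Df"],
    n = nrow(dat),
    mean_single = mean(dat$log2FC[dat$copy_class == "single"]),
    mean_multiple = mean(dat$log2FC[dat$copy_class == "multiple"])
  )
  attr(res, "fit") <- fit
  class(res) <- c("copyclass_anova", class(res))
  res
}

#' Median-normalise a homology hit-count matrix
#'
#' Divides each gene's hit counts by its median across genomes (to correct
#' for exon-number differences between genes). Zero cells are flagged as
#' candidate deletions; rows with median zero cannot be normalised and are
#' flagged.
#'
#' @param mat non-negative integer matrix, genes x genomes.
#' @return list of class `hitcount_norm`: `normalised` matrix (NA rows
#'   where the median is 0), `deletions` tibble (gene, genome of each zero
#'   cell), `unnormalisable` gene names.
#' @export
normalize_hitcounts <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) == 0 || ncol(mat) == 0) {
    abort("`mat` must be a non-empty matrix", class = "crossferome_data_error")
  }
  if (any(mat < 0) || any(mat != round(mat))) {
    abort("hit counts must be non-negative integers",
          class = "crossferome_data_error")
  }
  med <- apply(mat, 1, median)
  norm <- mat / med
  norm[med == 0, ] <- NA_real_
  zero_idx <- which(mat == 0, arr.ind = TRUE)
  deletions <- tibble(
    gene = rownames(mat)[zero_idx[, 1]] %||% as.character(zero_idx[, 1]),
    genome = colnames(mat)[zero_idx[, 2]] %||% as.character(zero_idx[, 2])
  )
  structure(
    list(normalised = norm, deletions = deletions,
         unnormalisable = rownames(mat)[med == 0] %||% which(med == 0)),
    class = "hitcount_norm"
  )
}

#' @exportS3Method
tidy.hitcount_norm <- function(x, ...) {
  as_tibble(x$normalised, rownames = "gene") |>
    pivot_longer(-"gene", names_to = "genome", values_to = "relative_hits")
}
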