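# Per-species filtering, normalisation and differential-expression testing:
# a documented, simplified stand-in for a full NB-GLM analysis, operating on
# log2(normalised count + pseudo) values.

counts_matrix <- function(counts) {
  if (!is.data.frame(counts) || !"gene_id" %in% names(counts)) {
    abort("`counts` must be a data frame with a `gene_id` column",
          class = "crossferome_data_error")
  }
  if (anyDuplicated(counts$gene_id)) {
    abort("duplicate gene ids in count table", class = "crossferome_data_error")
  }
  mat <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  if (ncol(mat) < 1 || nrow(mat) < 1) {
    abort("count table is empty", class = "crossferome_data_error")
  }
  if (anyDuplicated(colnames(mat))) {
    abort("duplicate sample ids in count table",
          class = "crossferome_data_error")
  }
  rownames(mat) <- counts$gene_id
  storage.mode(mat) <- "double"
  mat
}

#' Remove genes with insufficient read support
#'
#' Removes a gene when it has fewer than one mapped read in at least half of
#' all samples (both conditions pooled); equivalently, a gene is retained iff
#' it has at least one read in more than half of the samples. A tie (zeros in
#' exactly half the samples) counts toward removal.
#'
#' @param counts tibble with a `gene_id` column and one column per sample.
#' @return the filtered count tibble.
#' @examples
#' x <- tibble::tibble(gene_id = c("a", "b"), s1 = c(0, 3), s2 = c(0, 0))
#' filter_low_counts(x)  # gene "a" removed, "b" removed too (tie)
#' @export
filter_low_counts <- function(counts) {
  mat <- counts_matrix(counts)
  n_low <- rowSums(mat < 1)
  counts[n_low < ncol(mat) / 2, , drop = FALSE]
}

#' Per-sample library-size factors
#'
#' `method = "total"` implements the documented definition: each sample's
#' factor is its total count divided by the geometric mean of all totals.
#' `method = "median_ratio"` computes median-of-ratios factors against the
#' per-gene geometric-mean reference (rescaled to geometric mean one), which
#' is robust to composition differences between conditions and is the
#' default used inside [test_de()].
#'
#' @param counts count tibble (`gene_id` + samples).
#' @param method `"total"` or `"median_ratio"`.
#' @return tibble: sample, size_factor.
#' @export
normalize_libsizes <- function(counts, method = c("total", "median_ratio")) {
  method <- match.arg(method)
  mat <- counts_matrix(counts)
  totals <- colSums(mat)
  if (any(totals <= 0)) {
    abort("sample(s) with zero total counts", class = "crossferome_data_error")
  }
  f <- if (method == "total") {
    totals / exp(mean(log(totals)))
  } else {
    ref <- exp(rowMeans(log(mat + 0.5)))
    f0 <- apply((mat + 0.5) / ref, 2, median)
    f0 / exp(mean(log(f0)))
  }
  tibble(sample = colnames(mat), size_factor = unname(f))
}

#' Test for differential expression between IFN and mock samples
#'
#' The log2 fold change is `log2((mean normalised IFN count + c) /
#' (mean normalised mock count + c))` with pseudo-count `c`. P-values come
#' from a two-sided test of the condition effect on `log2(normalised count +
#' c)`: either limma's moderated t statistic (default; variance is pooled
#' across genes, which is essential at 2-4 replicates) or a gene-wise
#' Welch t test.
#'
#' @param counts count tibble (`gene_id` + samples), normally already passed
#'   through [filter_low_counts()].
#' @param samples sample sheet with columns `sample` and `condition`
#'   (`"mock"`/`"ifn"`).
#' @param method `"moderated"` (limma) or `"welch"`.
#' @param pseudo_count pseudo-count `c` (default 0.5).
#' @param norm_method passed to [normalize_libsizes()].
#' @return tibble: gene_id, log2FC, pvalue, mean_mock, mean_ifn (normalised
#'   condition means).
#' @export
test_de <- function(counts, samples, method = c("moderated", "welch"),
                    pseudo_count = 0.5,
                    norm_method = c("median_ratio", "total")) {
  method <- match.arg(method)
  norm_method <- match.arg(norm_method)
  mat <- counts_matrix(counts)
  if (!all(c("sample", "condition") %in% names(samples))) {
    abort("`samples` needs columns `sample` and `condition`",
          class = "crossferome_data_error")
  }
  cond <- samples$condition[match(colnames(mat), samples$sample)]
  if (anyNA(cond)) {
    abort("every count column must appear in the sample sheet",
          class = "crossferome_data_error")
  }
  if (!all(c("ifn", "mock") %in% cond) || min(table(cond)) < 2) {
    abort("need >= 2 samples in each of conditions 'ifn' and 'mock'",
          class = "crossferome_data_error")
  }

  sf <- normalize_libsizes(counts, method = norm_method)
  norm <- sweep(mat, 2, sf$size_factor[match(colnames(mat), sf$sample)], "/")
  y <- log2(norm + pseudo_count)
  is_ifn <- cond == "ifn"

  mean_mock <- rowMeans(norm[, !is_ifn, drop = FALSE])
  mean_ifn <- rowMeans(norm[, is_ifn, drop = FALSE])
  log2fc <- log2((mean_ifn + pseudo_count) / (mean_mock + pseudo_count))

  p <- if (method == "moderated") {
    design <- cbind(intercept = 1, ifn = as.numeric(is_ifn))
    fit <- limma::eBayes(limma::lmFit(y, design), trend = FALSE)
    fit$p.value[, "ifn"]
  } else {
    welch_p(y[, is_ifn, drop = FALSE], y[, !is_ifn, drop = FALSE])
  }

  tibble(gene_id = rownames(mat), log2FC = unname(log2fc),
         pvalue = unname(p), mean_mock = unname(mean_mock),
         mean_ifn = unname(mean_ifn))
}

# vectorised two-sided Welch t test over the rows of two matrices
welch_p <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tt), df)
  # constant rows: no evidence either way
  p[se2 == 0] <- 1
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (`adjusted_(i) = min_{j >= rank(i)}
#' min(1, p_(j) m / j)`), order-preserving. Inputs outside [0, 1] raise an
#' error rather than being clamped.
#'
#' @param p numeric vector of p-values.
#' @return vector of adjusted values (FDR), same order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort("p-values must be numeric in [0, 1]", class = "crossferome_data_error")
  }
  p.adjust(p, method = "BH")
}

#' Basal expression as FPKM
#'
#' Fragments per kilobase of transcript per million mapped reads,
#' `count / ((length/1e3) * (sample_total/1e6))`, averaged over the selected
#' samples (by default the mock samples only, i.e. expression in the absence
#' of IFN).
#'
#' @param counts count tibble (`gene_id` + samples).
#' @param gene_lengths tibble: gene_id, length_bp.
#' @param samples sample sheet; required when `subset = "mock"`.
#' @param subset `"mock"`, `"ifn"` or `"all"`.
#' @return tibble: gene_id, fpkm.
#' @export
compute_fpkm <- function(counts, gene_lengths, samples = NULL,
                         subset = c("mock", "ifn", "all")) {
  subset <- match.arg(subset)
  mat <- counts_matrix(counts)
  len <- gene_lengths$length_bp[match(rownames(mat), gene_lengths$gene_id)]
  if (anyNA(len) || any(len <= 0)) {
    abort("every gene needs a positive length", class = "crossferome_data_error")
  }
  if (subset != "all") {
    if (is.null(samples)) {
      abort("`samples` is required to select a condition subset",
            class = "crossferome_data_error")
    }
    keep <- samples$sample[samples$condition == subset]
    mat <- mat[, colnames(mat) %in% keep, drop = FALSE]
    if (ncol(mat) == 0) {
      abort(paste0("no samples in condition '", subset, "'"),
            class = "crossferome_data_error")
    }
  }
  totals <- colSums(mat)
  if (any(totals <= 0)) {
    abort("sample(s) with zero total counts", class = "crossferome_data_error")
  }
  fpkm <- sweep(mat, 2, totals / 1e6, "/") / (len / 1e3)
  tibble(gene_id = rownames(mat), fpkm = unname(rowMeans(fpkm)))
}

#' Full per-species differential-expression table
#'
#' Chains [filter_low_counts()], [test_de()], [bh_adjust()] and
#' [compute_fpkm()] into the per-species record used downstream: log2FC,
#' raw p, BH FDR and basal (mock) FPKM per retained gene.
#'
#' @inheritParams test_de
#' @param gene_lengths tibble: gene_id, length_bp.
#' @return tibble: gene_id, log2FC, pvalue, FDR, basal_fpkm, mean_mock,
#'   mean_ifn.
#' @export
run_de <- function(counts, samples, gene_lengths,
                   method = c("moderated", "welch"), pseudo_count = 0.5) {
  method <- match.arg(method)
  kept <- filter_low_counts(counts)
  if (nrow(kept) == 0) {
    abort("no genes survive the low-count filter",
          class = "crossferome_data_error")
  }
  de <- test_de(kept, samples, method = method, pseudo_count = pseudo_count)
  de$FDR <- bh_adjust(de$pvalue)
  fpkm <- compute_fpkm(kept, gene_lengths, samples, subset = "mock")
  de |>
    left_join(fpkm, by = "gene_id") |>
    rename(basal_fpkm = "fpkm") |>
    select("gene_id", "log2FC", "pvalue", "FDR", "basal_fpkm",
           "mean_mock", "mean_ifn")
}
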