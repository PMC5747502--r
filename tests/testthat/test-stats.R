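# Comparative statistics: similarity, PCA, resampling, trend, dN/dS,
# basal contrast, ANOVA, hit-count normalisation.

test_that("similarity matrix reproduces hand-computed Jaccard overlaps", {
  calls <- rbind(
    a = c("ISG", "ISG", "none"),
    b = c("ISG", "ISG", "none"),
    c = c("none", "ISG", "ISG")
  )
  # sp1 = {a,b}, sp2 = {a,b,c}, sp3 = {c}
  m <- similarity_matrix(make_table(calls), "up")
  expect_equal(m["sp1", "sp2"], 2 / 3)
  expect_equal(m["sp1", "sp3"], 0)          # disjoint
  expect_equal(m["sp1", "sp1"], 1)          # identical sets
  expect_equal(unclass(m), t(unclass(m)), ignore_attr = TRUE)  # symmetric

  # the worked overlap {a,b} vs {b,c} -> 1/3
  calls2 <- rbind(a = c("ISG", "none"), b = c("ISG", "ISG"),
                  c = c("none", "ISG"))
  m2 <- similarity_matrix(make_table(calls2), "up")
  expect_equal(m2["sp1", "sp2"], 1 / 3)
})

test_that("similarity is invariant to species order and flags empty sets", {
  set.seed(23)
  calls <- matrix(sample(c("ISG", "none"), 40 * 4, replace = TRUE), 40, 4)
  colnames(calls) <- c("w", "x", "y", "z")
  tab <- make_table(calls)
  m <- similarity_matrix(tab, "up")
  perm <- c("z", "x", "w", "y")
  tab2 <- make_table(calls[, perm])
  m2 <- similarity_matrix(tab2, "up")
  expect_equal(unclass(m)[perm, perm], unclass(m2), ignore_attr = TRUE)
  # a species with zero IRG calls yields missing entries
  m_down <- similarity_matrix(tab, "down")
  expect_true(all(is.na(unclass(m_down))))
})

test_that("PCA of shared one-to-one responses behaves geometrically", {
  set.seed(29)
  n <- 12
  base <- rnorm(n, 2, 0.5)
  l2fc <- cbind(sp1 = base, sp2 = base, sp3 = rnorm(n, 2, 0.5),
                sp4 = 2 * base - 1)
  calls <- matrix("ISG", n, 4, dimnames = list(sprintf("og%02d", 1:n),
                                               colnames(l2fc)))
  tab <- make_table(calls, log2fc = l2fc)
  pca <- pca_core(tab, colnames(l2fc))
  # identical log2FC vectors give identical coordinates
  expect_equal(as.numeric(pca$scores[pca$scores$species == "sp1", -1]),
               as.numeric(pca$scores[pca$scores$species == "sp2", -1]))
  # variance explained sums to one
  expect_equal(sum(pca$var_explained), 1)
  # rank-2 input (sp4 is affine in sp1): components >= 3 carry ~no variance
  expect_lt(sum(pca$var_explained[3:length(pca$var_explained)]), 1e-10)
  # too few usable orthogroups errors
  calls_bad <- calls
  calls_bad[, "sp1"] <- "none"
  expect_error(pca_core(make_table(calls_bad, log2fc = l2fc),
                        colnames(l2fc)),
               class = "crossferome_data_error")
})

test_that("empirical p-values follow the add-one rule exactly", {
  set.seed(31)
  for (i in 1:100) {
    B <- sample(5:200, 1)
    null <- rnorm(B)
    obs <- rnorm(1)
    r <- sum(null >= obs)
    expect_equal(empirical_pvalue(obs, null, "greater"), (r + 1) / (B + 1))
    r2 <- sum(abs(null) >= abs(obs))
    expect_equal(empirical_pvalue(obs, null, "two_sided"),
                 (r2 + 1) / (B + 1))
  }
  expect_error(empirical_pvalue(1, numeric()),
               class = "crossferome_data_error")
})

test_that("a panel stronger than every resample attains p = 1/101", {
  set.seed(37)
  n <- 200
  calls <- matrix("ISG", n, 1, dimnames = list(sprintf("og%03d", 1:n), "sp1"))
  l2fc <- matrix(rnorm(n, 2, 0.3), n, 1, dimnames = dimnames(calls))
  panel <- rownames(calls)[1:40]
  l2fc[panel, 1] <- l2fc[panel, 1] + 5    # overwhelming enrichment
  tab <- make_table(calls, log2fc = l2fc)
  res <- antiviral_enrichment(tab, panel, B = 100, k = 40, seed = 4)
  expect_equal(res$p, 1 / 101)
  expect_lt(res$p, 0.01)
  expect_equal(res$B, 100)
  expect_equal(length(res$null[[1]]), 100)
  expect_error(antiviral_enrichment(tab, panel, B = 0),
               class = "crossferome_config_error")
  expect_error(antiviral_enrichment(tab, panel, k = 300),
               class = "crossferome_data_error")
  # few panel members among the ISGs is flagged
  res2 <- antiviral_enrichment(tab, panel[1:2], B = 20, k = 40, seed = 4)
  expect_equal(res2$flag, "few_panel_isgs")
})

test_that("expansion ratios are simple count ratios with flags", {
  expect_equal(expansion_ratio(rep(c("multiple", "single"), c(4, 8)))$ratio,
               0.5)
  expect_equal(expansion_ratio(rep("single", 10))$ratio, 0)
  und <- expansion_ratio(rep("multiple", 3))
  expect_true(is.na(und$ratio))
  expect_equal(und$flag, "undefined_ratio")
  expect_warning(expansion_ratio(c("single", "absent")), "ignoring")
})

test_that("planted expansion enrichment is detected per species", {
  set.seed(41)
  n <- 600
  calls <- matrix(rep(c("ISG", "none"), c(150, 450)), n, 2)
  rownames(calls) <- sprintf("og%03d", 1:n)
  copies <- matrix(1L, n, 2)
  # ISGs expanded at 30%, background at 5%
  copies[1:150, ] <- 1L + rbinom(300, 1, 0.3)
  copies[151:n, ] <- 1L + rbinom(900, 1, 0.05)
  tab <- make_table(calls, copies = copies)
  res <- expansion_test(tab, n = 200, seed = 5)
  expect_true(all(res$p < 0.05))
  expect_true(all(lengths(res$background) == 200))
})

test_that("bin-expansion trends are detected and degenerate cases handled", {
  set.seed(43)
  bins_per <- rep(1:5, each = 80)
  p_exp <- 0.05 + 0.08 * (bins_per - 1)
  og <- sprintf("og%03d", seq_along(bins_per))
  bins <- tibble::tibble(orthogroup_id = og, direction = "up",
                         bin = bins_per)
  classes <- tibble::tibble(
    orthogroup_id = og,
    copy_class = ifelse(rbinom(length(og), 1, p_exp) == 1, "multiple",
                        "single")
  )
  tr <- bin_expansion_trend(bins, classes, B = 999, seed = 6)
  expect_gt(tr$slope, 0)
  expect_lt(tr$p, 0.05)
  expect_gte(tr$p, 1 / (999 + 1))

  # constant ratios: slope 0, p 1
  classes0 <- dplyr::mutate(classes, copy_class = "single")
  tr0 <- bin_expansion_trend(bins, classes0, B = 99, seed = 6)
  expect_equal(tr0$slope, 0)
  expect_equal(tr0$p, 1)
  expect_error(
    bin_expansion_trend(dplyr::filter(bins, bin < 3), classes, B = 99),
    class = "crossferome_data_error"
  )
})

test_that("dN/dS contrasts run both rank tests with sensible edge cases", {
  set.seed(47)
  omega <- rgamma(500, 2, 10)
  ds <- rgamma(500, 5, 25)
  x <- tibble::tibble(dn = omega * ds, ds = ds)
  same <- dnds_contrast(x, x)
  expect_gt(same$wilcoxon_p, 0.99)
  # a 0.1 ratio shift at n = 500 is essentially always detected
  y <- tibble::tibble(dn = (omega + 0.1) * ds, ds = ds)
  shift <- dnds_contrast(y, x)
  expect_lt(shift$wilcoxon_p, 1e-6)
  expect_lt(shift$kruskal_p, 1e-6)
  # dN = 0 gives ratio 0 and stays in the sample
  z <- tibble::tibble(dn = c(0, 1), ds = c(1, 2))
  res <- dnds_contrast(z, x)
  expect_equal(res$n_isg, 2)
  # dS = 0 rows are excluded and counted
  z0 <- tibble::tibble(dn = c(1, 1), ds = c(0, 1))
  expect_equal(dnds_contrast(z0, x)$n_excluded_ds0, 1)
  # complete ties: p = 1 with a warning
  tied <- tibble::tibble(dn = rep(1, 5), ds = rep(2, 5))
  expect_warning(res_t <- dnds_contrast(tied, tied), "tied")
  expect_equal(res_t$wilcoxon_p, 1)
})

test_that("basal FPKM contrasts separate planted shifts", {
  set.seed(53)
  n <- 150
  calls <- matrix("ISG", n, 4,
                  dimnames = list(sprintf("og%03d", 1:n),
                                  c("bat1", "bat2", "sp3", "sp4")))
  fpkm <- matrix(rlnorm(n * 4, 1, 0.8), n, 4, dimnames = dimnames(calls))
  fpkm[, c("bat1", "bat2")] <- fpkm[, c("bat1", "bat2")] * 4
  tab <- make_table(calls, fpkm = fpkm)
  res <- basal_fpkm_contrast(tab, list(bats = c("bat1", "bat2"),
                                       rest = c("sp3", "sp4")))
  expect_lt(res$p, 0.05)
  expect_error(basal_fpkm_contrast(tab, list(only = "bat1")),
               class = "crossferome_data_error")
  expect_error(basal_fpkm_contrast(tab, list(a = "bat1", b = "sp3"),
                                   gene_subset = "nope"),
               class = "crossferome_data_error")
  # identical distributions: calibrated rejection over replicates
  hits <- vapply(1:100, function(i) {
    f <- matrix(rlnorm(n * 4, 1, 0.8), n, 4, dimnames = dimnames(calls))
    t2 <- make_table(calls, fpkm = f)
    basal_fpkm_contrast(t2, list(a = c("bat1", "bat2"),
                                 b = c("sp3", "sp4")))$p < 0.05
  }, TRUE)
  expect_lt(mean(hits), 0.12)
})

test_that("induction-by-copy-class ANOVA detects a planted boost", {
  set.seed(59)
  n <- 90
  sp <- paste0("sp", 1:9)
  calls <- matrix("ISG", n, 9, dimnames = list(sprintf("og%02d", 1:n), sp))
  copies <- matrix(1L + rbinom(n * 9, 1, 0.3), n, 9)
  l2fc <- matrix(rnorm(n * 9, 1.6, 0.4), n, 9) +
    0.5 * (copies == 1)                      # one-to-one boost
  tab <- make_table(calls, log2fc = l2fc, copies = copies)
  res <- induction_by_copyclass(tab, rownames(calls))
  expect_lt(res$p_copy_class, 0.05)
  expect_gt(res$mean_single, res$mean_multiple)

  # no planted effect: roughly nominal rejection
  hits <- vapply(1:100, function(i) {
    cp <- matrix(1L + rbinom(n * 9, 1, 0.3), n, 9)
    lf <- matrix(rnorm(n * 9, 1.6, 0.4), n, 9)
    t0 <- make_table(calls, log2fc = lf, copies = cp)
    induction_by_copyclass(t0, rownames(calls))$p_copy_class < 0.05
  }, TRUE)
  expect_lt(mean(hits), 0.12)

  # constant response in a balanced design: F = 0
  const <- make_table(calls, log2fc = matrix(1, n, 9), copies = copies)
  expect_equal(induction_by_copyclass(const, rownames(calls))$F_copy_class, 0)
  # single-level factor errors
  single_cp <- make_table(calls, log2fc = l2fc,
                          copies = matrix(1L, n, 9))
  expect_error(induction_by_copyclass(single_cp, rownames(calls)),
               class = "crossferome_data_error")
})

test_that("hit-count normalisation divides by row medians and flags zeros", {
  mat <- rbind(g1 = c(2L, 4L, 8L), g2 = c(3L, 3L, 3L),
               g3 = c(0L, 5L, 10L), g4 = c(0L, 0L, 1L))
  colnames(mat) <- paste0("gn", 1:3)
  res <- normalize_hitcounts(mat)
  expect_equal(unname(res$normalised["g1", ]), c(0.5, 1, 2))
  expect_equal(unname(res$normalised["g2", ]), c(1, 1, 1))
  # planted deletion cell flagged
  expect_true(any(res$deletions$gene == "g3" & res$deletions$genome == "gn1"))
  # median-zero row unnormalisable
  expect_equal(res$unnormalisable, "g4")
  expect_true(all(is.na(res$normalised["g4", ])))
  expect_error(normalize_hitcounts(matrix(numeric(), 0, 0)),
               class = "crossferome_data_error")
  expect_error(normalize_hitcounts(rbind(c(-1L, 2L))),
               class = "crossferome_data_error")
})

test_that("tidiers and autoplot methods return well-formed objects", {
  calls <- rbind(a = c("ISG", "ISG"), b = c("ISG", "none"),
                 c = c("ISG", "ISG"))
  tab <- make_table(calls)
  m <- similarity_matrix(tab, "up")
  td <- tidy(m)
  expect_true(all(c("species_a", "species_b", "similarity") %in% names(td)))
  expect_s3_class(autoplot(m), "ggplot")

  set.seed(61)
  n <- 80
  calls2 <- matrix("ISG", n, 2, dimnames = list(sprintf("og%02d", 1:n),
                                                c("s1", "s2")))
  tab2 <- make_table(calls2,
                     log2fc = matrix(rnorm(n * 2, 2, 0.5), n, 2))
  av <- antiviral_enrichment(tab2, rownames(calls2)[1:10], B = 30, k = 10,
                             seed = 2)
  expect_s3_class(tidy(av), "tbl_df")
  expect_false("null" %in% names(tidy(av)))
  expect_equal(glance(av)$n_species, 2)
  expect_s3_class(autoplot(av), "ggplot")
})
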