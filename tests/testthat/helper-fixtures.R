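# Shared fixtures, all built in code.

`%||%` <- rlang::`%||%`

# a small but fully structured simulation config (4 species)
small_config <- function(seed = 1L, ...) {
  simulation_config(
    species = c("human", "cow", "sheep", "chicken"),
    outgroup = "chicken",
    n_orthogroups = 300,
    core_fraction = 10 / 300,
    lineage_blocks = list(
      list(species = c("human", "cow", "sheep"), n = 8L),
      list(species = c("cow", "sheep"), n = 8L)
    ),
    species_specific_n = 5,
    antiviral_panel_size = 10,
    seed = seed,
    ...
  )
}

# a config in which nothing responds (global null)
null_config <- function(seed = 1L, n_orthogroups = 2000,
                        species = c("a", "b"), ...) {
  args <- list(
    species = species, outgroup = species[length(species)],
    n_orthogroups = n_orthogroups, core_fraction = 0,
    lineage_blocks = list(), species_specific_n = 0, irg_fraction = 0,
    antiviral_panel_size = 0, basal_shift = numeric(), seed = seed
  )
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

# deterministic count table: one gene per row of `mat`
make_counts <- function(mat, gene_ids = sprintf("g%02d", seq_len(nrow(mat))),
                        sample_ids = sprintf("s%d", seq_len(ncol(mat)))) {
  colnames(mat) <- sample_ids
  dplyr::bind_cols(tibble::tibble(gene_id = gene_ids),
                   tibble::as_tibble(mat))
}

make_samples <- function(conditions,
                         sample_ids = sprintf("s%d", seq_along(conditions))) {
  tibble::tibble(sample = sample_ids, condition = conditions,
                 replicate = stats::ave(seq_along(conditions), conditions,
                                        FUN = seq_along))
}

# hand-built merged interferome table from a call matrix
# calls: orthogroup x species character matrix ("ISG"/"IRG"/"none"/"absent")
make_table <- function(calls, log2fc = NULL, fdr = NULL, fpkm = NULL,
                       copies = NULL) {
  og <- rownames(calls) %||% sprintf("og%03d", seq_len(nrow(calls)))
  sp <- colnames(calls) %||% sprintf("sp%d", seq_len(ncol(calls)))
  default_l2fc <- ifelse(calls == "ISG", 2, ifelse(calls == "IRG", -1, 0))
  default_fdr <- ifelse(calls %in% c("ISG", "IRG"), 0.01, 0.5)
  n_cop <- copies %||% matrix(1L, nrow(calls), ncol(calls))
  n_cop[calls == "absent"] <- 0L
  tbl <- tidyr::expand_grid(orthogroup_id = og, species = sp) |>
    dplyr::mutate(
      call = as.vector(t(calls)),
      log2FC = as.vector(t(log2fc %||% default_l2fc)),
      FDR = as.vector(t(fdr %||% default_fdr)),
      basal_fpkm = as.vector(t(fpkm %||% matrix(5, nrow(calls), ncol(calls)))),
      n_copies = as.vector(t(n_cop)),
      copy_class = dplyr::case_when(n_copies == 0 ~ "absent",
                                    n_copies == 1 ~ "single",
                                    TRUE ~ "multiple")
    )
  tbl$log2FC[tbl$call == "absent"] <- NA_real_
  tbl$FDR[tbl$call == "absent"] <- NA_real_
  attr(tbl, "species") <- sp
  class(tbl) <- c("interferome_tbl", class(tbl))
  tbl
}

# independent brute-force BH step-up (oracle)
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    vals <- vapply(seq(rank_i, m), function(j) min(1, p[ord[j]] * m / j), 0)
    adj[i] <- min(vals)
  }
  adj
}

run_small_pipeline <- function(seed = 1L, dir = withr::local_tempdir()) {
  suppressMessages(
    run_pipeline(small_config(seed = seed), dir, B = 20, k = 10,
                 n_background = 50, trend_B = 200, n_genomes = 5)
  )
}
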