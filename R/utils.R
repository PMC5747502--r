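# Internal helpers: seeds, TSV i/o, input checks.

# Derive a stage-specific seed from the global one so that stages are
# decoupled: changing, say, the dN/dS stage never perturbs the count draws.
# Kept strictly below 2^31 - 1 (R integers are 32-bit).
sub_seed <- function(seed, stage) {
  offsets <- c(
    orthogroups = 11L, counts = 23L, dnds = 37L, hitcounts = 53L,
    resample = 71L, background = 89L, trend = 101L
  )
  k <- offsets[[stage]]
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Read and write tab-separated tables
#'
#' Thin wrappers around [utils::read.delim()] / [utils::write.table()] using
#' the package's TSV dialect: tab-separated, UTF-8, header row, `NA` for
#' missing values, no quoting or row names.
#'
#' @param path file path.
#' @param x data frame to write.
#' @return `read_tsv_table()` returns a tibble.
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "crossferome_io_error")
  }
  as_tibble(read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                       stringsAsFactors = FALSE))
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(paste0("`", name, "` must be a single proportion in [0, 1]"),
          class = "crossferome_config_error")
  }
  invisible(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    abort(paste0("`", name, "` must be a single positive number"),
          class = "crossferome_config_error")
  }
  invisible(x)
}
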