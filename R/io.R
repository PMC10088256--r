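#' Read a count table
#'
#' Reads a subjects x taxa count table from a TSV file (first column sample
#' identifiers, remaining columns integer taxon counts) or, when the file
#' ends in `.biom`, via the biomformat package (which stores taxa x samples;
#' the matrix is transposed on read).
#'
#' @param path file path.
#' @return integer matrix with sample row names and taxon column names.
#' @export
read_counts <- function(path) {
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM files requires the 'biomformat' package",
           call. = FALSE)
    }
    b <- biomformat::read_biom(path)
    m <- t(as.matrix(biomformat::biom_data(b)))
    storage.mode(m) <- "double"
    return(m)
  }
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count table needs sample IDs plus taxa", call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate sample identifiers", call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count cells", call. = FALSE)
  rownames(m) <- ids
  m
}

#' Read a sample metadata table
#'
#' TSV with the first column holding sample identifiers matching the count
#' table rows.
#'
#' @param path file path.
#' @return data frame with sample-ID row names.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate sample identifiers", call. = FALSE)
  df <- df[, -1L, drop = FALSE]
  rownames(df) <- ids
  df
}

#' Write analysis results
#'
#' Writes the node table as TSV (`nodes.tsv`) and the run summary --
#' global p-value, harmonic-mean statistic, null-mixture estimates, and all
#' settings -- as JSON (`summary.json`), so a run can be reconstructed from
#' its outputs.
#'
#' @param fit a [treemed()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_results <- function(fit, dir) {
  stopifnot(inherits(fit, "treemed"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nodes_path <- file.path(dir, "nodes.tsv")
  json_path <- file.path(dir, "summary.json")
  write.table(fit$node_table, nodes_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  summary <- list(
    global_p = fit$global_p, p_ring = fit$p_ring, combiner = fit$combiner,
    J = fit$J, n_degenerate = fit$n_degenerate,
    null_mix = fit$null_mix[c("pi00", "pi10", "pi01", "pi0_alpha",
                              "pi0_beta", "pi0", "approach")],
    settings = fit$settings)
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(nodes = nodes_path, summary = json_path))
}
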