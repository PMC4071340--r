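#' Read an interaction dataset from TSV files
#'
#' Load the motif-search input tables from tab-delimited files with
#' headers: `tf_binding` (columns `tf`, `target`), `physical`
#' (`gene_a`, `gene_b`, `throughput` with values `low`/`high`),
#' `genetic` (`gene_a`, `gene_b`, `category`), an optional
#' `global_regulators` file (one gene id per line, no header), and an
#' optional `overrides` file (`gene_a`, `gene_b`, `relation`).
#'
#' @param tf_binding,physical,genetic Paths to the three TSV tables
#'   (any may be `NULL` for an empty table).
#' @param global_regulators Optional path to the exclusion list.
#' @param overrides Optional path to the manual sign-relation table.
#' @return An [interaction_dataset()].
#' @export
read_interaction_dataset <- function(tf_binding = NULL, physical = NULL,
                                     genetic = NULL,
                                     global_regulators = NULL,
                                     overrides = NULL) {
  read_tsv_quiet <- function(path) {
    if (is.null(path)) return(NULL)
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
  gl <- if (is.null(global_regulators)) character() else {
    if (!file.exists(global_regulators)) {
      stop("file not found: ", global_regulators, call. = FALSE)
    }
    readr::read_lines(global_regulators, progress = FALSE)
  }
  interaction_dataset(
    tf_binding = read_tsv_quiet(tf_binding),
    physical = read_tsv_quiet(physical),
    genetic = read_tsv_quiet(genetic),
    global_regulators = gl[nzchar(gl)],
    overrides = read_tsv_quiet(overrides)
  )
}

#' Write an interaction dataset as TSV files
#'
#' Writes the same dialect [read_interaction_dataset()] reads:
#' `tf_binding.tsv`, `physical.tsv`, `genetic.tsv`,
#' `global_regulators.txt` under `dir`.
#'
#' @param ds An [interaction_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_interaction_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "interaction_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    tf_binding = file.path(dir, "tf_binding.tsv"),
    physical = file.path(dir, "physical.tsv"),
    genetic = file.path(dir, "genetic.tsv"),
    global_regulators = file.path(dir, "global_regulators.txt")
  )
  readr::write_tsv(ds$tf_binding, paths[["tf_binding"]], progress = FALSE)
  readr::write_tsv(ds$physical, paths[["physical"]], progress = FALSE)
  readr::write_tsv(ds$genetic, paths[["genetic"]], progress = FALSE)
  readr::write_lines(ds$global_regulators, paths[["global_regulators"]])
  invisible(paths)
}

#' Write sweep records to CSV
#'
#' Flat one-row-per-network table with header; list columns are not
#' present so the file round-trips losslessly.
#'
#' @param records A `"dosage_sweep"` tibble.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_sweep_csv <- function(records, path) {
  readr::write_csv(tibble::as_tibble(unclass(records)), path,
                   progress = FALSE)
  invisible(path)
}

#' Read sweep records from CSV
#'
#' @param path CSV written by [write_sweep_csv()].
#' @param cfg Optional [sweep_config()] to re-attach.
#' @return A `"dosage_sweep"` tibble.
#' @export
read_sweep_csv <- function(path, cfg = NULL) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  structure(out, class = c("dosage_sweep", class(out)), config = cfg)
}
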