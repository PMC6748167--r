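# Readers and writers for the external formats: TSV/CSV probe-by-sample
# matrices (probe IDs in the first column, sample IDs in the header),
# sample sheets, plain-text blacklists, manifest CSVs, YAML study
# configurations and JSON summaries. Tab-separated is the canonical
# output; comma vs tab is sniffed on input.

sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a probe-by-sample matrix from TSV/CSV
#'
#' @param path File with probe IDs in the first column and sample IDs in
#'   the header; `NA` encodes missing values. Tab or comma separated
#'   (sniffed).
#' @return Numeric matrix with probe rownames and sample colnames.
#' @export
read_beta_matrix <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop_structural("duplicate probe IDs in ", path, ": ",
                    paste(utils::head(unique(ids[duplicated(ids)]), 5),
                          collapse = ", "))
  body <- df[, -1, drop = FALSE]
  num <- suppressWarnings(
    vapply(body, as.numeric, numeric(nrow(body))))
  num <- matrix(num, nrow = nrow(body))
  bad <- which(is.na(num) & !(body == "NA" | body == "" | is.na(body)),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_input("non-numeric value in ", path, " at probe ",
               ids[bad[1, 1]], ", sample ", colnames(body)[bad[1, 2]])
  dimnames(num) <- list(ids, colnames(body))
  num
}

#' Write a probe-by-sample matrix as TSV
#'
#' @param mat Matrix with probe rownames and sample colnames.
#' @param path Output path.
#' @export
write_beta_matrix <- function(mat, path) {
  df <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' @param path TSV/CSV with required columns `sample_id`, `group`, `age`,
#'   `glial_proportion`; optional columns (e.g. `sex`, `batch`) are kept
#'   as covariates.
#' @return Validated data.frame; `group` as a factor with the first
#'   observed level as reference.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sample_id", "group", "age", "glial_proportion")
  missing_col <- setdiff(required, names(df))
  if (length(missing_col))
    stop_structural("sample sheet lacks required column(s): ",
                    paste(missing_col, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop_structural("duplicate sample IDs in sample sheet")
  for (col in c("age", "glial_proportion")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v) & !is.na(df[[col]])))
      stop_input("non-numeric '", col, "' in sample sheet")
    df[[col]] <- v
  }
  df$group <- factor(df$group, levels = unique(df$group))
  if (nlevels(df$group) < 2 || any(table(df$group) < 2))
    stop_structural("group must have >= 2 levels with >= 2 samples each")
  df
}

#' Read a probe blacklist (one probe ID per line)
#' @param path Plain-text file; blank lines and `#` comments ignored.
#' @return Character vector of probe IDs.
#' @export
read_blacklist <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a probe annotation manifest
#' @param path CSV/TSV with columns `probe_id`, `chr`, `pos`, `gene`.
#' @return Data.frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("probe_id", "chr", "pos", "gene")
  if (!all(need %in% names(df)))
    stop_structural("manifest needs columns: ", paste(need, collapse = ", "))
  df
}

#' Read a YAML study configuration
#'
#' The configuration must contain exactly one of `inputs:` (paths to
#' `bs`, `oxbs`, `coverage` or `coverage_bs`/`coverage_ox`,
#' `sample_sheet`, optional `detection_p`, `blacklist`, `manifest`) or
#' `simulation:` (arguments for [sim_config()]). Optional blocks:
#' `thresholds:` (`detection_p`, `sample_fail_fraction`, `low_beta`,
#' `sep_mode`, `sep_threshold`, `paired_threshold`), `model:`
#' (`covariates`, `quad_points`, `squeeze_epsilon`, `include_batch_re`),
#' plus top-level `seed` and `output_dir`.
#'
#' @param path YAML file.
#' @return List of class `"study_config"`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  has_inputs <- !is.null(cfg$inputs)
  has_sim <- !is.null(cfg$simulation)
  if (has_inputs == has_sim)
    stop_structural("config must contain exactly one of 'inputs' or ",
                    "'simulation'")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  class(cfg) <- "study_config"
  cfg
}

#' Write study outputs to a directory
#'
#' Writes `results.tsv` (per-probe result table), `comparison.json`,
#' `filter_report.json` and `run_log.txt` (seed, stage counts, package
#' version). Re-running with identical inputs reproduces identical
#' bytes.
#'
#' @param study A `"dualmark_study"` object from [run_study()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(results = file.path(outdir, "results.tsv"),
             comparison = file.path(outdir, "comparison.json"),
             filter_report = file.path(outdir, "filter_report.json"),
             log = file.path(outdir, "run_log.txt"))
  utils::write.table(study$results, paths["results"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(study$comparison), paths["comparison"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass(study$filter_report), paths["filter_report"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(study$log, paths["log"])
  invisible(paths)
}
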