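# Probe/sample filtering stages. Each filter returns the filtered data
# plus a `delta` list that run_study() accumulates into a FilterReport,
# so the probe-count waterfall is fully accounted for.

#' Filter failed samples and probes by detection p-value
#'
#' First excludes samples whose fraction of failed probes (detection
#' p-value above `p_threshold`) exceeds `sample_fail_fraction`; then
#' removes every probe with a detection failure in ANY remaining sample.
#'
#' @param betas Named list of probe-by-sample matrices to filter in
#'   lockstep (e.g. `list(bs = ..., ox = ..., coverage = ...)`), or a
#'   single matrix.
#' @param detection_p Probe-by-sample matrix of detection p-values,
#'   aligned with the beta matrices.
#' @param p_threshold Detection p-value above which a measurement is a
#'   failure (default 0.05).
#' @param sample_fail_fraction Maximum tolerated fraction of failed
#'   probes per sample (default 0.10).
#' @return List with `data` (filtered matrices, same shape as input),
#'   `delta` (`n_removed_detection`, `samples_excluded`).
#' @export
filter_detection <- function(betas, detection_p, p_threshold = 0.05,
                             sample_fail_fraction = 0.10) {
  single <- is.matrix(betas)
  mats <- if (single) list(betas) else betas
  for (m in mats) check_aligned(m, detection_p, "betas", "detection p")

  fail <- detection_p > p_threshold
  fail[is.na(fail)] <- TRUE
  bad_samples <- colnames(fail)[colMeans(fail) > sample_fail_fraction]
  keep_s <- setdiff(colnames(fail), bad_samples)
  fail <- fail[, keep_s, drop = FALSE]
  keep_p <- rownames(fail)[rowSums(fail) == 0]
  out <- lapply(mats, function(m) m[keep_p, keep_s, drop = FALSE])
  list(data = if (single) out[[1]] else out,
       delta = list(n_removed_detection = nrow(detection_p) - length(keep_p),
                    samples_excluded = bad_samples))
}

#' Remove blacklisted probes
#'
#' Drops probes named in a blacklist (e.g. published cross-reactive or
#' SNP-containing probe lists). Blacklist entries absent from the data are
#' ignored, with their count logged.
#'
#' @param betas Named list of aligned probe-by-sample matrices, or a
#'   single matrix.
#' @param blacklist Character vector of probe IDs.
#' @return List with `data` and `delta` (`n_removed_blacklist`,
#'   `n_blacklist_absent`).
#' @export
filter_blacklist <- function(betas, blacklist) {
  single <- is.matrix(betas)
  mats <- if (single) list(betas) else betas
  probes <- rownames(mats[[1]])
  hit <- intersect(probes, blacklist)
  keep <- setdiff(probes, hit)
  if (length(keep) == 0) warning("blacklist removed every probe")
  out <- lapply(mats, function(m) m[keep, , drop = FALSE])
  list(data = if (single) out[[1]] else out,
       delta = list(n_removed_blacklist = length(hit),
                    n_blacklist_absent = length(setdiff(blacklist, probes))))
}

#' Remove probes with low mean 5-mC or 5-hmC
#'
#' Drops a probe when its across-sample mean estimated 5-mC OR mean
#' estimated 5-hmC beta value is below `mean_threshold` (strict `<`;
#' missing values are excluded from the means). Run AFTER MLE estimation:
#' the rule operates on estimated 5-hmC, not raw channel values, and it
#' is what removes the zero-inflated part of the 5-hmC distribution
#' before beta-regression modeling.
#'
#' @param mc,hmc Aligned probe-by-sample matrices of estimated beta
#'   values.
#' @param extra Optional named list of further aligned matrices to subset
#'   in lockstep (e.g. the boundary-flag matrix).
#' @param mean_threshold Default 0.1.
#' @return List with `mc`, `hmc`, `extra`, `delta`
#'   (`n_removed_lowbeta`).
#' @export
filter_low_beta <- function(mc, hmc, extra = list(), mean_threshold = 0.1) {
  check_aligned(mc, hmc, "5-mC", "5-hmC")
  keep <- rowMeans(mc, na.rm = TRUE) >= mean_threshold &
    rowMeans(hmc, na.rm = TRUE) >= mean_threshold
  keep[is.na(keep)] <- FALSE
  list(mc = mc[keep, , drop = FALSE],
       hmc = hmc[keep, , drop = FALSE],
       extra = lapply(extra, function(m) m[keep, , drop = FALSE]),
       delta = list(n_removed_lowbeta = sum(!keep)))
}

#' Remove probes with any missing estimated value
#'
#' @param mc,hmc Aligned probe-by-sample matrices.
#' @param extra Optional named list of further aligned matrices.
#' @return List with `mc`, `hmc`, `extra`, `delta`
#'   (`n_removed_missing`).
#' @export
filter_missing <- function(mc, hmc, extra = list()) {
  check_aligned(mc, hmc, "5-mC", "5-hmC")
  keep <- rowSums(is.na(mc)) == 0 & rowSums(is.na(hmc)) == 0
  if (!any(keep)) warning("every probe has missing values")
  list(mc = mc[keep, , drop = FALSE],
       hmc = hmc[keep, , drop = FALSE],
       extra = lapply(extra, function(m) m[keep, , drop = FALSE]),
       delta = list(n_removed_missing = sum(!keep)))
}

# Assemble a FilterReport from accumulated deltas.
make_filter_report <- function(n_input, deltas) {
  rep <- list(n_input_probes = n_input,
              n_removed_detection = 0L, n_removed_blacklist = 0L,
              n_removed_lowbeta = 0L, n_removed_missing = 0L,
              samples_excluded = character(0))
  for (d in deltas) {
    for (nm in intersect(names(d), names(rep))) {
      if (nm == "samples_excluded")
        rep[[nm]] <- c(rep[[nm]], d[[nm]])
      else rep[[nm]] <- rep[[nm]] + d[[nm]]
    }
  }
  rep$n_final <- n_input - rep$n_removed_detection -
    rep$n_removed_blacklist - rep$n_removed_lowbeta - rep$n_removed_missing
  class(rep) <- "filter_report"
  rep
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Probe filtering waterfall\n",
      " input probes:      ", x$n_input_probes, "\n",
      " detection p:      -", x$n_removed_detection, "\n",
      " blacklist:        -", x$n_removed_blacklist, "\n",
      " low mean beta:    -", x$n_removed_lowbeta, "\n",
      " missing values:   -", x$n_removed_missing, "\n",
      " final probes:      ", x$n_final, "\n", sep = "")
  if (length(x$samples_excluded))
    cat(" samples excluded:  ",
        paste(x$samples_excluded, collapse = ", "), "\n", sep = "")
  invisible(x)
}
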