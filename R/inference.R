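# Multiple-testing correction and probe classification. Flags follow the
# field's shorthand: DMP = differentially methylated probe (5-mC model),
# DHMP = differentially hydroxymethylated probe (5-hmC model), DIP =
# differential interaction probe (significant condition-by-modification
# interaction in the paired model).

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Computes `q_(i) = min_{j >= i} min(1, p_(j) * m / j)` over the ordered
#' p-values. Missing entries are excluded from `m` and returned as `NA`,
#' so probes whose model failed to converge do not penalize valid tests.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Vector of q-values in the original order.
#' @examples
#' bh_adjust(c(0.005, 0.1, 0.9))
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop_input("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(pvals))
  obs <- which(!is.na(pvals))
  m <- length(obs)
  if (m == 0) return(q)
  p <- pvals[obs]
  o <- order(p, decreasing = TRUE)   # step-up: cumulative min from the top
  adj <- pmin(1, cummin(m / seq(m, 1) * p[o]))
  q[obs[o]] <- adj
  q
}

#' Flag significant probes on one result channel
#'
#' @param results Result data.frame containing `<channel>_coef`,
#'   `<channel>_p` and `<channel>_q` columns, where channel is one of
#'   `"mc"`, `"hmc"`, `"int"`.
#' @param channel `"mc"`, `"hmc"` or `"interaction"`.
#' @param mode `"fdr"` (threshold on q) or `"raw_p"` (threshold on p).
#' @param threshold Significance cutoff (strict `<`).
#' @return `results` with added logical flag column (`dmp`, `dhmp` or
#'   `dip`) and a direction column (`"negative"`, `"positive"`, `"none"`,
#'   from the coefficient sign; `NA` where the probe is not flagged).
#' @export
call_significant <- function(results, channel = c("mc", "hmc", "interaction"),
                             mode = c("fdr", "raw_p"), threshold) {
  channel <- match.arg(channel)
  mode <- match.arg(mode)
  key <- c(mc = "mc", hmc = "hmc", interaction = "int")[[channel]]
  flag_col <- c(mc = "dmp", hmc = "dhmp", interaction = "dip")[[channel]]
  stat <- results[[paste0(key, if (mode == "fdr") "_q" else "_p")]]
  if (is.null(stat))
    stop_input("channel '", channel, "' not present in results")
  coefs <- results[[paste0(key, "_coef")]]
  flag <- !is.na(stat) & stat < threshold
  dir <- rep(NA_character_, nrow(results))
  dir[flag] <- ifelse(coefs[flag] > 0, "positive",
                      ifelse(coefs[flag] < 0, "negative", "none"))
  results[[flag_col]] <- flag
  results[[paste0("direction_", flag_col)]] <- dir
  results
}

#' Compare the paired interaction analysis with the separate per-mark
#' analysis
#'
#' Set accounting over flagged probe IDs: how many probes each analysis
#' flags, how many probes the two separate models flag jointly, and how
#' much of the separate analysis the paired interaction model recovers.
#'
#' @param results Result data.frame after [call_significant()] has set
#'   `dmp`, `dhmp` and `dip`.
#' @return List of class `"comparison_summary"`: `n_dmp`, `n_dhmp`,
#'   `n_dip`, `n_overlap_sep` (probes flagged by BOTH separate models),
#'   `n_dip_covering_overlap` (of those, how many are also DIPs),
#'   `n_single_mark` (flagged by exactly one separate model),
#'   `n_single_mark_covered`, `n_dip_only` (DIPs missed entirely by the
#'   separate analysis), `n_sep_only` (separate hits that are not DIPs).
#' @export
compare_paired_vs_separate <- function(results) {
  for (col in c("dmp", "dhmp", "dip"))
    if (is.null(results[[col]]))
      stop_input("results lack the '", col, "' flag; run call_significant()")
  ids <- results$probe_id
  dmp <- ids[results$dmp]
  dhmp <- ids[results$dhmp]
  dip <- ids[results$dip]
  sep <- union(dmp, dhmp)
  overlap <- intersect(dmp, dhmp)
  single <- setdiff(sep, overlap)
  structure(list(
    n_dmp = length(dmp),
    n_dhmp = length(dhmp),
    n_dip = length(dip),
    n_overlap_sep = length(overlap),
    n_dip_covering_overlap = length(intersect(dip, overlap)),
    n_single_mark = length(single),
    n_single_mark_covered = length(intersect(dip, single)),
    n_dip_only = length(setdiff(dip, sep)),
    n_sep_only = length(setdiff(sep, dip))), class = "comparison_summary")
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat("Paired vs separate analysis\n",
      " DMP (5-mC):            ", x$n_dmp, "\n",
      " DHMP (5-hmC):          ", x$n_dhmp, "\n",
      " overlap of separate:   ", x$n_overlap_sep,
      " (", x$n_dip_covering_overlap, " also DIPs)\n",
      " single-mark hits:      ", x$n_single_mark,
      " (", x$n_single_mark_covered, " also DIPs)\n",
      " DIP (interaction):     ", x$n_dip, "\n",
      " DIP only:              ", x$n_dip_only, "\n",
      " separate only:         ", x$n_sep_only, "\n", sep = "")
  invisible(x)
}

#' Tally coefficient signs among flagged probes
#'
#' @param results Result data.frame after [call_significant()].
#' @param channel `"mc"`, `"hmc"` or `"interaction"`.
#' @return List with `negative`, `positive`, `zero` counts, `total`, and
#'   the corresponding percentages. Probes with an exactly zero
#'   coefficient are counted as neither sign and reported separately.
#' @export
summarize_directions <- function(results,
                                 channel = c("mc", "hmc", "interaction")) {
  channel <- match.arg(channel)
  key <- c(mc = "mc", hmc = "hmc", interaction = "int")[[channel]]
  flag_col <- c(mc = "dmp", hmc = "dhmp", interaction = "dip")[[channel]]
  if (is.null(results[[flag_col]]))
    stop_input("results lack the '", flag_col, "' flag")
  coefs <- results[[paste0(key, "_coef")]][results[[flag_col]]]
  neg <- sum(coefs < 0, na.rm = TRUE)
  pos <- sum(coefs > 0, na.rm = TRUE)
  zer <- sum(coefs == 0, na.rm = TRUE)
  tot <- length(coefs)
  pct <- function(k) if (tot > 0) 100 * k / tot else NA_real_
  list(negative = neg, positive = pos, zero = zer, total = tot,
       pct_negative = pct(neg), pct_positive = pct(pos))
}
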