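# End-to-end driver. Stage order matters and is fixed: detection-p
# filtering, blacklist removal, MLE estimation of (5-mC, 5-hmC), the
# low-mean-beta filter (which must see ESTIMATED 5-hmC, not raw channel
# values), the missingness filter, then per-probe modeling, BH
# correction per channel, classification, comparison and annotation.

default_thresholds <- function() {
  list(detection_p = 0.05, sample_fail_fraction = 0.10, low_beta = 0.1,
       sep_mode = "raw_p", sep_threshold = 0.001,
       paired_mode = "fdr", paired_threshold = 0.05)
}

default_model <- function() {
  list(covariates = c("glial_proportion", "age"), quad_points = 9L,
       squeeze_epsilon = 1e-6, include_batch_re = FALSE,
       interaction_test = "wald")
}

#' Run the full paired 5-mC/5-hmC study
#'
#' Executes the whole analysis from BS/oxBS beta matrices (or a
#' simulation spec) to a per-probe result table: filtering, constrained
#' MLE estimation of (5-mC, 5-hmC), the two separate per-mark beta
#' regressions, the paired mixed-effects model with its
#' condition-by-modification interaction test, Benjamini-Hochberg
#' correction per channel, DMP/DHMP/DIP classification, the
#' paired-vs-separate comparison, and (optionally) annotation. Fully
#' deterministic given the configuration and seed.
#'
#' Default significance calling follows the reference analysis: the
#' separate models use a lenient raw p < 0.001 (the cutoff under which
#' the two analyses are compared), the paired interaction uses
#' FDR < 0.05; both are configurable (e.g. `sep_mode = "fdr"`,
#' `sep_threshold = 0.10` for strict separate calling).
#'
#' @param config A `"study_config"` from [read_study_config()], or an
#'   equivalent list with `inputs` (paths or in-memory objects: `bs`,
#'   `oxbs`, `coverage_bs`, `coverage_ox`, `sample_sheet`, optional
#'   `detection_p`, `blacklist`, `manifest`) or `simulation` (arguments
#'   to [sim_config()]), plus optional `thresholds`, `model`, `seed`,
#'   `output_dir`.
#' @return Object of class `"dualmark_study"`: `results` (per-probe
#'   table), `comparison`, `filter_report`, `directions` (sign tallies
#'   per channel), `annotation` (if a manifest was given), `rejects`
#'   (probes whose models failed), `log` (character vector), `seed`.
#' @export
run_study <- function(config) {
  thr <- utils::modifyList(default_thresholds(),
                           config$thresholds %||% list())
  mdl <- utils::modifyList(default_model(), config$model %||% list())
  seed <- as.integer(config$seed %||% 1L)
  log <- c(paste0("dualmark ",
                  as.character(utils::packageVersion("dualmark"))),
           paste0("seed: ", seed))
  set.seed(seed)

  # ---- load or simulate inputs -------------------------------------
  blacklist <- character(0)
  detection_p <- NULL
  manifest <- NULL
  if (!is.null(config$simulation)) {
    sim_args <- config$simulation
    sim_args$seed <- sim_args$seed %||% seed
    cfg <- do.call(sim_config, sim_args)
    ds <- generate_dataset(cfg)
    bs <- ds$bs; ox <- ds$ox
    cov_bs <- ds$coverage_bs; cov_ox <- ds$coverage_ox
    sheet <- ds$sheet
    sheet$group <- factor(sheet$group)
    log <- c(log, paste0("simulated ", cfg$n_probes, " probes x ",
                         nrow(sheet), " samples"))
  } else {
    ins <- config$inputs
    get_mat <- function(x) if (is.character(x)) read_beta_matrix(x) else x
    bs <- get_mat(ins$bs)
    ox <- get_mat(ins$oxbs %||% ins$ox)
    cov_bs <- get_mat(ins$coverage_bs %||% ins$coverage)
    cov_ox <- get_mat(ins$coverage_ox %||% ins$coverage_bs %||% ins$coverage)
    sheet <- if (is.character(ins$sample_sheet))
      read_sample_sheet(ins$sample_sheet) else ins$sample_sheet
    sheet$group <- factor(sheet$group)
    if (!is.null(ins$detection_p)) detection_p <- get_mat(ins$detection_p)
    if (!is.null(ins$blacklist))
      blacklist <- if (is.character(ins$blacklist) &&
                         length(ins$blacklist) == 1L &&
                         file.exists(ins$blacklist))
        read_blacklist(ins$blacklist) else ins$blacklist
    if (!is.null(ins$manifest))
      manifest <- if (is.character(ins$manifest))
        read_manifest(ins$manifest) else ins$manifest
  }
  n_input <- nrow(bs)
  deltas <- list()

  # ---- stage 1: detection-p filter ---------------------------------
  mats <- list(bs = bs, ox = ox, cov_bs = cov_bs, cov_ox = cov_ox)
  if (!is.null(detection_p)) {
    fd <- filter_detection(mats, detection_p, thr$detection_p,
                           thr$sample_fail_fraction)
    mats <- fd$data
    deltas <- c(deltas, list(fd$delta))
    if (length(fd$delta$samples_excluded)) {
      sheet <- sheet[!sheet$sample_id %in% fd$delta$samples_excluded, ,
                     drop = FALSE]
      sheet$group <- droplevels(sheet$group)
    }
    log <- c(log, paste0("detection filter removed ",
                         fd$delta$n_removed_detection, " probes, ",
                         length(fd$delta$samples_excluded), " samples"))
  }

  # ---- stage 2: blacklist ------------------------------------------
  fb <- filter_blacklist(mats, blacklist)
  mats <- fb$data
  deltas <- c(deltas, list(fb$delta))
  log <- c(log, paste0("blacklist removed ", fb$delta$n_removed_blacklist,
                       " probes"))

  # ---- stage 3: MLE estimation -------------------------------------
  est <- estimate_matrix(mats$bs, mats$ox, mats$cov_bs, mats$cov_ox)
  log <- c(log, paste0("MLE boundary (5-hmC clipped to 0) in ",
                       sum(est$boundary, na.rm = TRUE), " entries"))

  # ---- stage 4: low mean beta (on estimated values) ----------------
  fl <- filter_low_beta(est$beta_mc, est$beta_hmc,
                        extra = list(boundary = est$boundary),
                        mean_threshold = thr$low_beta)
  deltas <- c(deltas, list(fl$delta))
  log <- c(log, paste0("low-beta filter removed ",
                       fl$delta$n_removed_lowbeta, " probes"))

  # ---- stage 5: missingness ----------------------------------------
  fm <- filter_missing(fl$mc, fl$hmc, extra = fl$extra)
  deltas <- c(deltas, list(fm$delta))
  log <- c(log, paste0("missingness filter removed ",
                       fm$delta$n_removed_missing, " probes"))

  filter_report <- make_filter_report(n_input, deltas)
  calls <- list(beta_mc = fm$mc, beta_hmc = fm$hmc)
  probes <- rownames(fm$mc)
  log <- c(log, paste0("modeling ", length(probes), " probes on ",
                       nrow(sheet), " samples"))

  # ---- per-probe models --------------------------------------------
  group_term <- paste0("group", levels(sheet$group)[2])
  rows <- vector("list", length(probes))
  rejects <- character(0)
  for (i in seq_along(probes)) {
    pr <- probes[i]
    row <- list(probe_id = pr,
                mc_coef = NA_real_, mc_p = NA_real_,
                hmc_coef = NA_real_, hmc_p = NA_real_,
                int_coef = NA_real_, int_p = NA_real_,
                converged = FALSE)
    res <- tryCatch({
      long <- to_long(calls, sheet, pr, epsilon = mdl$squeeze_epsilon)
      f_mc <- main_effect_model(long, "5mC", mdl$covariates)
      f_hmc <- main_effect_model(long, "5hmC", mdl$covariates)
      f_pair <- fit_paired(long, covariates = mdl$covariates,
                           include_batch_re = mdl$include_batch_re,
                           nodes = mdl$quad_points,
                           lrt = identical(mdl$interaction_test, "lrt"))
      w_mc <- wald_test(f_mc, group_term)
      w_hmc <- wald_test(f_hmc, group_term)
      w_int <- interaction_test(f_pair, type = mdl$interaction_test)
      list(mc_coef = w_mc$coef, mc_p = w_mc$p,
           hmc_coef = w_hmc$coef, hmc_p = w_hmc$p,
           int_coef = w_int$coef, int_p = w_int$p,
           converged = f_mc$converged && f_hmc$converged &&
             f_pair$converged)
    }, error = function(e) NULL)
    if (is.null(res) || !res$converged) rejects <- c(rejects, pr)
    if (!is.null(res)) row[names(res)] <- res
    rows[[i]] <- row
  }
  results <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (is.null(results))
    results <- data.frame(probe_id = character(0), mc_coef = numeric(0),
                          mc_p = numeric(0), hmc_coef = numeric(0),
                          hmc_p = numeric(0), int_coef = numeric(0),
                          int_p = numeric(0), converged = logical(0))
  # non-converged probes get missing p (excluded from BH's m)
  for (ch in c("mc", "hmc", "int"))
    results[[paste0(ch, "_p")]][!results$converged] <- NA_real_
  log <- c(log, paste0(length(rejects), " probes failed model fitting"))

  # ---- inference ----------------------------------------------------
  for (ch in c("mc", "hmc", "int"))
    results[[paste0(ch, "_q")]] <-
      bh_adjust(results[[paste0(ch, "_p")]])
  results <- results[, c("probe_id", "mc_coef", "mc_p", "mc_q",
                         "hmc_coef", "hmc_p", "hmc_q",
                         "int_coef", "int_p", "int_q", "converged")]
  results <- call_significant(results, "mc", thr$sep_mode,
                              thr$sep_threshold)
  results <- call_significant(results, "hmc", thr$sep_mode,
                              thr$sep_threshold)
  results <- call_significant(results, "interaction", thr$paired_mode,
                              thr$paired_threshold)
  comparison <- compare_paired_vs_separate(results)
  directions <- list(mc = summarize_directions(results, "mc"),
                     hmc = summarize_directions(results, "hmc"),
                     interaction = summarize_directions(results,
                                                        "interaction"))
  annotation <- NULL
  if (!is.null(manifest)) {
    ann <- annotate(results, manifest)
    results <- ann$results
    annotation <- ann$unique_genes
  }
  log <- c(log, paste0("DMP: ", comparison$n_dmp, "  DHMP: ",
                       comparison$n_dhmp, "  DIP: ", comparison$n_dip))

  study <- structure(list(results = results, comparison = comparison,
                          filter_report = filter_report,
                          directions = directions,
                          annotation = annotation,
                          rejects = rejects, log = log, seed = seed),
                     class = "dualmark_study")
  if (!is.null(config$output_dir)) write_results(study, config$output_dir)
  study
}

#' @export
print.dualmark_study <- function(x, ...) {
  print(x$filter_report)
  print(x$comparison)
  if (length(x$rejects))
    cat(length(x$rejects), "probes failed model fitting\n")
  invisible(x)
}

#' Annotate results with a probe manifest
#'
#' Left-joins chromosome, position and gene onto the result table and
#' tallies unique gene IDs among flagged probes (multi-gene fields are
#' split on `";"`).
#'
#' @param results Result data.frame with `probe_id` (and optionally the
#'   `dmp`/`dhmp`/`dip` flags).
#' @param manifest Data.frame with columns `probe_id`, `chr`, `pos`,
#'   `gene` (unique probe IDs).
#' @return List with `results` (annotated; unmatched probes get `NA`)
#'   and `unique_genes` (named counts per available flag).
#' @export
annotate <- function(results, manifest) {
  if (anyDuplicated(manifest$probe_id))
    stop_structural("duplicate probe IDs in manifest")
  if (nrow(manifest) == 0) warning("empty manifest; all annotation NA")
  idx <- match(results$probe_id, manifest$probe_id)
  results$chr <- manifest$chr[idx]
  results$pos <- manifest$pos[idx]
  results$gene <- manifest$gene[idx]
  tally <- function(flag) {
    if (is.null(results[[flag]])) return(NULL)
    genes <- results$gene[results[[flag]] %in% TRUE]
    genes <- genes[!is.na(genes) & nzchar(genes)]
    length(unique(unlist(strsplit(genes, ";", fixed = TRUE))))
  }
  ug <- Filter(Negate(is.null),
               list(dmp = tally("dmp"), dhmp = tally("dhmp"),
                    dip = tally("dip")))
  list(results = results, unique_genes = ug)
}
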