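# A small deterministic toy study used in examples and tests. Every
# filter stage is triggered by exactly one constructed probe, so the
# filtering waterfall is known by construction: 20 input probes, one
# removed per stage (detection, blacklist, low mean beta, missingness),
# 16 modeled. All annotation in the fixture is synthetic.

#' Build the bundled toy study fixture
#'
#' 20 probes by 10 samples (5 control, 5 case), built from the synthetic
#' generator with a fixed internal seed and then edited so that exactly
#' one probe triggers each filter stage:
#' `probe_00001` fails detection in one sample, `probe_00002` is
#' blacklisted, `probe_00003` has zero estimated 5-hmC (low-mean-beta
#' removal), `probe_00004` has a missing BS value. `probe_00005` carries
#' a planted scenario-A effect and `probe_00006` a constant-total
#' scenario-B shift; the remaining probes are null.
#'
#' @param dir If non-`NULL`, the fixture is also written there in the
#'   standard file formats (`bs.tsv`, `oxbs.tsv`, `coverage_bs.tsv`,
#'   `coverage_ox.tsv`, `detection_p.tsv`, `sample_sheet.tsv`,
#'   `blacklist.txt`, `manifest_synthetic.csv`, `truth.tsv`,
#'   `config.yaml`).
#' @return List with `bs`, `ox`, `coverage_bs`, `coverage_ox`,
#'   `detection_p`, `sheet`, `blacklist`, `manifest`, `truth`, and
#'   `expected_report` (the FilterReport the fixture must reproduce).
#' @export
make_fixture <- function(dir = NULL) {
  cfg <- sim_config(
    n_probes = 20, n_control = 5, n_case = 5,
    hmc_mean_range = c(0.20, 0.30),  # solid margin over the 0.1 rule
    zero_inflation = 0, sigma_b = 0.3,
    effects = list(
      list(probes = 5L, scenario = "A", effect_mc = -1.2, effect_hmc = 0.4),
      list(probes = 6L, scenario = "B", effect_mc = -0.8)),
    seed = 20201L)
  ds <- generate_dataset(cfg)

  # probe_00003: oxBS identical to BS -> estimated 5-hmC is exactly 0
  ds$ox[3, ] <- ds$bs[3, ]
  ds$coverage_ox[3, ] <- ds$coverage_bs[3, ]
  # probe_00004: one missing BS measurement
  ds$bs[4, 2] <- NA
  # detection p-values: one failure at probe_00001 / first sample
  detection_p <- matrix(0.01, nrow(ds$bs), ncol(ds$bs),
                        dimnames = dimnames(ds$bs))
  detection_p[1, 1] <- 0.06
  blacklist <- c("probe_00002", "probe_absent")
  manifest <- data.frame(
    probe_id = rownames(ds$bs),
    chr = paste0("chr", rep(1:4, each = 5)),
    pos = 1000L * seq_len(20),
    gene = paste0("GENE", rep(1:10, each = 2),
                  ifelse(seq_len(20) %% 4 == 0, ";GENEX", "")),
    stringsAsFactors = FALSE)

  fx <- list(bs = ds$bs, ox = ds$ox, coverage_bs = ds$coverage_bs,
             coverage_ox = ds$coverage_ox, detection_p = detection_p,
             sheet = ds$sheet, blacklist = blacklist,
             manifest = manifest, truth = ds$truth,
             expected_report = list(
               n_input_probes = 20L, n_removed_detection = 1L,
               n_removed_blacklist = 1L, n_removed_lowbeta = 1L,
               n_removed_missing = 1L, n_final = 16L))

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_beta_matrix(fx$bs, file.path(dir, "bs.tsv"))
    write_beta_matrix(fx$ox, file.path(dir, "oxbs.tsv"))
    write_beta_matrix(fx$coverage_bs, file.path(dir, "coverage_bs.tsv"))
    write_beta_matrix(fx$coverage_ox, file.path(dir, "coverage_ox.tsv"))
    write_beta_matrix(fx$detection_p, file.path(dir, "detection_p.tsv"))
    utils::write.table(fx$sheet, file.path(dir, "sample_sheet.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(fx$blacklist, file.path(dir, "blacklist.txt"))
    utils::write.table(fx$manifest,
                       file.path(dir, "manifest_synthetic.csv"),
                       sep = ",", quote = FALSE, row.names = FALSE)
    utils::write.table(fx$truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(list(
      inputs = list(bs = "bs.tsv", oxbs = "oxbs.tsv",
                    coverage_bs = "coverage_bs.tsv",
                    coverage_ox = "coverage_ox.tsv",
                    detection_p = "detection_p.tsv",
                    sample_sheet = "sample_sheet.tsv",
                    blacklist = "blacklist.txt",
                    manifest = "manifest_synthetic.csv"),
      seed = 1L), file.path(dir, "config.yaml"))
  }
  fx
}
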