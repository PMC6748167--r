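#' Constrained maximum-likelihood estimate of 5-mC and 5-hmC from paired
#' BS/oxBS signals
#'
#' Bisulfite (BS) conversion leaves both 5-mC and 5-hmC unconverted, so the
#' BS channel measures the total modified proportion `beta_mc + beta_hmc`;
#' oxidative bisulfite (oxBS) converts 5-hmC, so the oxBS channel measures
#' `beta_mc` alone. Given modified-signal counts and totals for both
#' channels, this function maximizes the joint binomial log-likelihood
#'
#' \deqn{\log B(m_{bs}; n_{bs}, \beta_{mC}+\beta_{hmC}) +
#'       \log B(m_{ox}; n_{ox}, \beta_{mC})}
#'
#' over the simplex \eqn{\beta_{mC} \ge 0, \beta_{hmC} \ge 0,
#' \beta_{mC}+\beta_{hmC} \le 1}.
#'
#' When the channel proportions are concordant
#' (`m_bs/n_bs >= m_ox/n_ox`) the unconstrained optimum
#' `(m_ox/n_ox, m_bs/n_bs - m_ox/n_ox)` is feasible and is returned
#' exactly. Otherwise the optimum lies on the `beta_hmc = 0` boundary,
#' where the problem collapses to a single-proportion binomial MLE with
#' both channels pooled: `beta_mc = (m_bs + m_ox)/(n_bs + n_ox)`, and
#' `boundary` is set. Note the boundary convention for `beta_mc` (a pooled
#' proportion, not the oxBS proportion) is a choice of this package;
#' alternative conventions exist.
#'
#' @param m_bs,n_bs Modified-signal count and total signal, BS channel.
#' @param m_ox,n_ox Modified-signal count and total signal, oxBS channel.
#'   All four arguments are vectorized and recycled to a common length.
#' @param id Optional identifier(s) used in error messages (e.g.
#'   `"probe cg000001 / sample S3"`).
#' @return A data.frame with columns `beta_mc`, `beta_hmc`, `beta_c`
#'   (`= 1 - beta_mc - beta_hmc`) and logical `boundary`. Rows with any
#'   `NA` input, or a zero total in either channel, are `NA` throughout.
#' @seealso [estimate_naive()] for the subtraction estimator,
#'   [estimate_matrix()] for whole-matrix application.
#' @examples
#' estimate_paired_mle(80, 100, 50, 100)   # feasible: (0.5, 0.3)
#' estimate_paired_mle(40, 100, 60, 100)   # discordant: pooled boundary
#' @export
estimate_paired_mle <- function(m_bs, n_bs, m_ox, n_ox, id = NULL) {
  k <- max(length(m_bs), length(n_bs), length(m_ox), length(n_ox))
  m_bs <- rep_len(as.numeric(m_bs), k); n_bs <- rep_len(as.numeric(n_bs), k)
  m_ox <- rep_len(as.numeric(m_ox), k); n_ox <- rep_len(as.numeric(n_ox), k)

  miss <- is.na(m_bs) | is.na(n_bs) | is.na(m_ox) | is.na(n_ox)
  # degenerate zero totals yield a missing call, mirroring failed probes
  miss <- miss | (!is.na(n_bs) & n_bs == 0) | (!is.na(n_ox) & n_ox == 0)

  ok <- !miss
  bad <- ok & (m_bs > n_bs | m_ox > n_ox | m_bs < 0 | m_ox < 0 |
                 n_bs < 0 | n_ox < 0)
  if (any(bad)) {
    lab <- if (is.null(id)) paste0("entry ", which(bad)[1]) else
      rep_len(as.character(id), k)[which(bad)[1]]
    stop_input("invalid signal counts (need 0 <= m <= n, n > 0) at ", lab)
  }

  beta_mc <- beta_hmc <- rep(NA_real_, k)
  boundary <- rep(NA, k)

  p_bs <- m_bs / n_bs
  p_ox <- m_ox / n_ox
  feas <- ok & p_bs >= p_ox
  beta_mc[feas] <- p_ox[feas]
  beta_hmc[feas] <- p_bs[feas] - p_ox[feas]
  boundary[feas] <- FALSE

  infeas <- ok & !feas
  beta_mc[infeas] <- (m_bs[infeas] + m_ox[infeas]) /
    (n_bs[infeas] + n_ox[infeas])
  beta_hmc[infeas] <- 0
  boundary[infeas] <- TRUE

  data.frame(beta_mc = beta_mc, beta_hmc = beta_hmc,
             beta_c = 1 - beta_mc - beta_hmc, boundary = boundary)
}

#' Naive subtraction estimate of 5-mC and 5-hmC from BS/oxBS beta values
#'
#' The simple alternative to [estimate_paired_mle()]: take the oxBS beta
#' value as 5-mC and the BS minus oxBS difference as 5-hmC, clipping
#' negative differences to zero.
#'
#' @param beta_bs,beta_ox BS- and oxBS-channel beta values in `[0, 1]`;
#'   vectorized.
#' @param id Optional identifier(s) for error messages.
#' @return A data.frame as in [estimate_paired_mle()]; `boundary` flags
#'   entries where the negative difference was clipped.
#' @examples
#' estimate_naive(0.8, 0.5)
#' estimate_naive(0.4, 0.6)  # clipped, boundary = TRUE
#' @export
estimate_naive <- function(beta_bs, beta_ox, id = NULL) {
  k <- max(length(beta_bs), length(beta_ox))
  beta_bs <- rep_len(as.numeric(beta_bs), k)
  beta_ox <- rep_len(as.numeric(beta_ox), k)
  ok <- !(is.na(beta_bs) | is.na(beta_ox))
  bad <- ok & (beta_bs < 0 | beta_bs > 1 | beta_ox < 0 | beta_ox > 1)
  if (any(bad)) {
    lab <- if (is.null(id)) paste0("entry ", which(bad)[1]) else
      rep_len(as.character(id), k)[which(bad)[1]]
    stop_input("beta values must lie in [0, 1] at ", lab)
  }
  beta_mc <- ifelse(ok, beta_ox, NA_real_)
  beta_hmc <- ifelse(ok, pmax(0, beta_bs - beta_ox), NA_real_)
  boundary <- ifelse(ok, beta_bs < beta_ox, NA)
  data.frame(beta_mc = beta_mc, beta_hmc = beta_hmc,
             beta_c = 1 - beta_mc - beta_hmc, boundary = boundary)
}

#' Estimate 5-mC and 5-hmC matrices from BS/oxBS beta-value matrices
#'
#' Applies [estimate_paired_mle()] elementwise to probe-by-sample matrices
#' of BS and oxBS beta values. Array intensities are not integer counts, so
#' beta values are converted to pseudo-counts `m = round(beta * n)` using
#' the per-entry totals in `coverage_bs`/`coverage_ox` before the binomial
#' MLE is applied.
#'
#' @param bs,ox Numeric probe-by-sample matrices of BS and oxBS beta
#'   values, with probe IDs as rownames and sample IDs as colnames.
#' @param coverage_bs,coverage_ox Matching matrices of positive totals
#'   (coverage / total signal) per channel. `coverage_ox` defaults to
#'   `coverage_bs`.
#' @return A list with probe-by-sample matrices `beta_mc`, `beta_hmc` and
#'   logical `boundary`. Missing inputs (or zero coverage) propagate to
#'   missing outputs.
#' @examples
#' bs <- matrix(0.8, 2, 2, dimnames = list(c("p1", "p2"), c("s1", "s2")))
#' ox <- matrix(0.5, 2, 2, dimnames = dimnames(bs))
#' n  <- matrix(100, 2, 2, dimnames = dimnames(bs))
#' estimate_matrix(bs, ox, n)$beta_hmc
#' @export
estimate_matrix <- function(bs, ox, coverage_bs, coverage_ox = coverage_bs) {
  check_aligned(bs, ox, "BS betas", "oxBS betas")
  check_aligned(bs, coverage_bs, "BS betas", "BS coverage")
  check_aligned(bs, coverage_ox, "BS betas", "oxBS coverage")
  if (any(coverage_bs <= 0 & !is.na(bs), na.rm = TRUE) ||
      any(coverage_ox <= 0 & !is.na(ox), na.rm = TRUE)) {
    # zero totals are treated as missing by estimate_paired_mle; negative
    # coverage is a genuine input error
    if (any(coverage_bs < 0, na.rm = TRUE) || any(coverage_ox < 0, na.rm = TRUE))
      stop_input("negative coverage values")
  }
  ids <- paste0("probe ", rownames(bs)[row(bs)], " / sample ",
                colnames(bs)[col(bs)])
  est <- estimate_paired_mle(round(as.vector(bs) * as.vector(coverage_bs)),
                             as.vector(coverage_bs),
                             round(as.vector(ox) * as.vector(coverage_ox)),
                             as.vector(coverage_ox),
                             id = ids)
  shape <- function(v) matrix(v, nrow = nrow(bs), dimnames = dimnames(bs))
  list(beta_mc = shape(est$beta_mc), beta_hmc = shape(est$beta_hmc),
       boundary = shape(est$boundary))
}
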