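# The paired repeated-measures model: per probe, the 5-mC and 5-hmC beta
# values of each sample are treated as two measures of one
# "DNA modification" outcome. A beta regression with logit mean link gets
# a random intercept per sample (capturing the within-sample correlation
# of the two marks) and a condition-by-modification interaction whose sign
# and significance describe shifts in the 5-mC/5-hmC balance.

#' Reshape one probe's paired beta values to long (repeated-measures) form
#'
#' @param calls List with probe-by-sample matrices `beta_mc` and
#'   `beta_hmc` (as produced by [estimate_matrix()]).
#' @param sheet Sample sheet data.frame with at least `sample_id` and
#'   `group`; extra columns (age, glial_proportion, sex, batch) are carried
#'   along as covariates.
#' @param probe Probe ID (must be a rowname of both matrices).
#' @param epsilon Boundary squeeze applied to the beta values, see
#'   [squeeze()].
#' @return Data.frame with one row per sample per modification:
#'   `sample_id`, `mod_cat` (factor, levels `"5mC"` then `"5hmC"`, so 5-mC
#'   is the reference), `y`, plus all sample-sheet columns. Rows whose
#'   beta value is missing are dropped.
#' @export
to_long <- function(calls, sheet, probe, epsilon = 1e-6) {
  mc <- calls$beta_mc
  hmc <- calls$beta_hmc
  if (!probe %in% rownames(mc) || !probe %in% rownames(hmc))
    stop_input("probe '", probe, "' not found in the beta matrices")
  samples <- as.character(sheet$sample_id)
  if (!all(samples %in% colnames(mc)))
    stop_structural("sample sheet IDs missing from matrices: ",
                    paste(setdiff(samples, colnames(mc)), collapse = ", "))
  y_mc <- as.numeric(mc[probe, samples])
  y_hmc <- as.numeric(hmc[probe, samples])
  if (all(is.na(y_mc)) || all(is.na(y_hmc)))
    stop_structural("probe '", probe,
                    "' has no observed values for one modification")
  long <- rbind(
    data.frame(sample_id = samples, mod_cat = "5mC", y = y_mc,
               sheet[, setdiff(names(sheet), "sample_id"), drop = FALSE],
               row.names = NULL),
    data.frame(sample_id = samples, mod_cat = "5hmC", y = y_hmc,
               sheet[, setdiff(names(sheet), "sample_id"), drop = FALSE],
               row.names = NULL))
  long$mod_cat <- factor(long$mod_cat, levels = c("5mC", "5hmC"))
  long <- long[!is.na(long$y), , drop = FALSE]
  long$y <- squeeze(long$y, epsilon)
  long
}

# build the fixed-effects design for the long data
paired_design <- function(obs, covariates, interaction = TRUE) {
  obs$group <- if (is.factor(obs$group)) droplevels(obs$group)
    else factor(obs$group)
  if (nlevels(obs$group) < 2)
    stop_structural("need at least two groups, got: ",
                    paste(levels(obs$group), collapse = ", "))
  covariates <- intersect(covariates, names(obs))
  rhs <- if (interaction) "group * mod_cat" else "group + mod_cat"
  fml <- stats::as.formula(paste("~", paste(c(rhs, covariates),
                                            collapse = " + ")))
  stats::model.matrix(fml, data = obs)
}

#' Fit the paired mixed-effects beta regression for one probe
#'
#' Fits, by marginal maximum likelihood, the model
#' \deqn{y_{is} \sim Beta(\mu_{is}\phi, (1-\mu_{is})\phi), \quad
#'   logit(\mu_{is}) = X_{is}\beta + u_s, \quad u_s \sim N(0, \sigma_b^2)}
#' where `s` indexes samples and `i` the modification category (5-mC or
#' 5-hmC), so the random intercept `u_s` absorbs the within-sample
#' correlation of the two marks. Fixed effects use treatment coding with
#' the first group level and 5-mC as references; the full factorial
#' `group * mod_cat` (both main effects plus the interaction) is fitted,
#' and under this coding a positive interaction coefficient means a shift
#' toward 5-hmC in the non-reference group (swapping reference levels
#' flips the sign). The random intercept is integrated out by adaptive
#' Gauss-Hermite quadrature (mode and curvature located per sample by a
#' damped Newton search).
#'
#' @param obs Long-format data from [to_long()].
#' @param covariates Character vector of covariate columns to adjust for
#'   (defaults to glial proportion and age, when present).
#' @param include_batch_re If `TRUE` and `obs$batch` exists, adds an
#'   independent normal random intercept per batch, integrated by nested
#'   (outer non-adaptive, inner adaptive) quadrature. Off by default.
#' @param nodes Number of quadrature nodes (default 9).
#' @param sigma_b `NULL` to estimate the random-intercept SD (on the log
#'   scale, floored at 1e-6); a fixed numeric value (e.g. `0`) to hold it
#'   there, in which case `0` reduces the model to an independent beta
#'   regression.
#' @param lrt If `TRUE`, additionally fits the reduced model without the
#'   interaction and stores a 1-df likelihood-ratio test (`lrt_stat`,
#'   `lrt_p`) for use by [interaction_test()].
#' @param maxit,reltol Optimizer controls (BFGS).
#' @return Object of class `"paired_fit"`: `coef`, `se`, `sigma_b`,
#'   `sigma_batch` (NA unless batch RE used), `log_precision`, `loglik`,
#'   `converged`, `reason`, `quad_points`, `n_samples`,
#'   `interaction_term` (the column name of the group-by-modification
#'   coefficient).
#' @seealso [interaction_test()], [main_effect_model()]
#' @export
fit_paired <- function(obs, covariates = c("glial_proportion", "age"),
                       include_batch_re = FALSE, nodes = 9L,
                       sigma_b = NULL, lrt = FALSE, maxit = 500L,
                       reltol = 1e-9) {
  if (!all(c("sample_id", "mod_cat", "y", "group") %in% names(obs)))
    stop_structural("long data must have sample_id, mod_cat, y, group")
  obs$mod_cat <- factor(obs$mod_cat, levels = c("5mC", "5hmC"))
  if (any(is.na(obs$mod_cat)) || nlevels(droplevels(obs$mod_cat)) < 2)
    stop_structural("both modification categories must be present")
  gtab <- table(unique(obs[, c("sample_id", "group")])$group)
  gtab <- gtab[gtab > 0]
  if (length(gtab) < 2 || any(gtab < 2))
    stop_structural("need >= 2 samples in each of >= 2 groups")
  if (any(gtab < 4))
    warning("fewer than 4 samples in a group; estimates may be unstable")

  X <- paired_design(obs, covariates, interaction = TRUE)
  if (qr(X)$rank < ncol(X)) stop_structural("singular design matrix")
  y <- obs$y
  sid <- factor(obs$sample_id)
  id0 <- as.integer(sid) - 1L
  nsam <- nlevels(sid)
  gh <- gh_rule(nodes)
  int_term <- grep(":", colnames(X), value = TRUE)[1]

  fixed_sigma <- !is.null(sigma_b)
  if (fixed_sigma && (!is.numeric(sigma_b) || sigma_b < 0))
    stop_input("fixed sigma_b must be a non-negative number")
  sigma_floor <- 1e-6

  use_batch <- include_batch_re && "batch" %in% names(obs) &&
    nlevels(droplevels(factor(obs$batch))) > 1
  bid <- if (use_batch) droplevels(factor(obs$batch)) else NULL

  # run the marginal-ML optimization for one fixed-effects design
  optimize_design <- function(X) {
  p <- ncol(X)
  umode <- numeric(nsam)   # warm-started integrand modes, reused across evals

  nll <- function(par) {
    coefs <- par[seq_len(p)]
    log_phi <- par[p + 1L]
    if (fixed_sigma) {
      if (sigma_b == 0 && !use_batch)
        return(paired_nll_cpp(c(coefs, log_phi, 0), y, X, id0, nsam,
                              gh$nodes, gh$weights, TRUE, numeric(0),
                              numeric(0)))
      lsig <- log(max(sigma_b, sigma_floor))
      extra <- 0L
    } else {
      lsig <- log(sigma_floor + exp(par[p + 2L]))
      extra <- 1L
    }
    parc <- c(coefs, log_phi, lsig)
    if (!use_batch)
      return(paired_nll_cpp(parc, y, X, id0, nsam, gh$nodes, gh$weights,
                            fixed_sigma && sigma_b == 0, numeric(0),
                            umode))
    # nested quadrature: outer (batch) nodes are non-adaptive at scale
    # sigma_batch; inner per-sample integral is adaptive as above
    sig_bt <- sigma_floor + exp(par[p + 1L + extra + 1L])
    tot <- 0
    for (b in levels(bid)) {
      sel <- bid == b
      sidb <- factor(obs$sample_id[sel])
      idb <- as.integer(sidb) - 1L
      lb <- vapply(seq_along(gh$nodes), function(k) {
        v <- sqrt(2) * sig_bt * gh$nodes[k]
        cond <- -paired_nll_cpp(parc, y[sel], X[sel, , drop = FALSE],
                                idb, nlevels(sidb), gh$nodes, gh$weights,
                                fixed_sigma && sigma_b == 0,
                                rep(v, sum(sel)), numeric(0))
        log(gh$weights[k]) - 0.5 * log(pi) + cond
      }, numeric(1))
      m <- max(lb)
      if (!is.finite(m)) return(1e10)
      tot <- tot - (m + log(sum(exp(lb - m))))
    }
    tot
  }

  # analytic-free gradient: central differences taken inside compiled
  # code, with the chain rule for the floored sigma transform
  gr <- if (!use_batch) function(par) {
    coefs <- par[seq_len(p)]
    log_phi <- par[p + 1L]
    if (fixed_sigma) {
      zero <- sigma_b == 0
      lsig <- log(max(sigma_b, sigma_floor))
      g <- paired_nll_grad_cpp(c(coefs, log_phi, lsig), y, X, id0, nsam,
                               gh$nodes, gh$weights, zero, numeric(0),
                               1e-5, umode)
      g[seq_len(p + 1L)]
    } else {
      es <- exp(par[p + 2L])
      lsig <- log(sigma_floor + es)
      g <- paired_nll_grad_cpp(c(coefs, log_phi, lsig), y, X, id0, nsam,
                               gh$nodes, gh$weights, FALSE, numeric(0),
                               1e-5, umode)
      g[p + 2L] <- g[p + 2L] * es / (sigma_floor + es)
      g
    }
  } else NULL

  start_fit <- try(fit_betareg(X, y), silent = TRUE)
  start <- if (!inherits(start_fit, "try-error") && start_fit$converged)
    c(start_fit$coef, start_fit$log_precision)
  else c(betareg_start(X, y))
  if (!fixed_sigma) start <- c(start, log(0.25))
  if (use_batch) start <- c(start, log(0.1))

  opt <- stats::optim(start, nll, gr, method = "BFGS", hessian = TRUE,
                      control = list(maxit = maxit, reltol = reltol))
  vc <- try(solve(opt$hessian), silent = TRUE)
  ok <- opt$convergence == 0L && !inherits(vc, "try-error") &&
    all(is.finite(diag(vc)[seq_len(p)])) && all(diag(vc)[seq_len(p)] > 0)
  se <- if (ok) sqrt(diag(vc)[seq_len(p)]) else rep(NA_real_, p)
  list(opt = opt, ok = ok, se = se, p = p)
  }  # end optimize_design

  main <- optimize_design(X)
  opt <- main$opt
  ok <- main$ok
  p <- main$p
  se <- main$se
  sb <- if (fixed_sigma) sigma_b else sigma_floor + exp(opt$par[p + 2L])
  sbt <- if (use_batch) sigma_floor + exp(opt$par[length(opt$par)])
    else NA_real_

  lrt_stat <- lrt_p <- NA_real_
  if (lrt) {
    X0 <- paired_design(obs, covariates, interaction = FALSE)
    red <- optimize_design(X0)
    if (red$ok && ok) {
      lrt_stat <- max(0, 2 * (red$opt$value - opt$value))
      lrt_p <- stats::pchisq(lrt_stat, df = 1, lower.tail = FALSE)
    }
  }

  structure(list(
    coef = stats::setNames(opt$par[seq_len(p)], colnames(X)),
    se = stats::setNames(se, colnames(X)),
    sigma_b = sb,
    sigma_batch = sbt,
    log_precision = unname(opt$par[p + 1L]),
    loglik = -opt$value,
    converged = ok,
    reason = if (ok) "converged" else
      if (opt$convergence != 0L) paste0("optim code ", opt$convergence)
      else "singular information matrix",
    quad_points = as.integer(nodes),
    n_samples = nsam,
    n_obs = length(y),
    lrt_stat = lrt_stat,
    lrt_p = lrt_p,
    interaction_term = int_term), class = "paired_fit")
}

#' @export
coef.paired_fit <- function(object, ...) object$coef

#' @export
logLik.paired_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coef) + 2L,
            nobs = object$n_obs, class = "logLik")
}

#' @export
print.paired_fit <- function(x, ...) {
  cat("Paired mixed-effects beta regression:", x$n_samples, "samples,",
      x$n_obs, "observations", if (!x$converged) "[NOT CONVERGED]", "\n")
  print(round(cbind(coef = x$coef, se = x$se), 4))
  cat("sigma_b =", signif(x$sigma_b, 4),
      " phi =", round(exp(x$log_precision), 2),
      " logLik =", round(x$loglik, 2), "\n")
  invisible(x)
}

#' Test the condition-by-modification interaction
#'
#' Tests the interaction coefficient of a [fit_paired()] model. Under
#' treatment coding (reference group, 5-mC reference level), a positive
#' coefficient indicates a shift toward a greater proportion of 5-hmC in
#' the non-reference group; a negative coefficient a shift toward 5-mC.
#' The default is the Wald z-test; a 1-df likelihood-ratio test is
#' available when the model was fitted with `lrt = TRUE`.
#'
#' @param fit A `"paired_fit"` object.
#' @param type `"wald"` (default) or `"lrt"` (requires
#'   `fit_paired(..., lrt = TRUE)`).
#' @return List with `coef`, `se`, `z`, `p`, and `direction` (one of
#'   `"toward-5hmC"`, `"toward-5mC"`, `"none"`).
#' @export
interaction_test <- function(fit, type = c("wald", "lrt")) {
  type <- match.arg(type)
  if (is.na(fit$interaction_term))
    stop_input("fit has no interaction term")
  wt <- wald_test(fit, fit$interaction_term)
  if (type == "lrt") {
    if (is.null(fit$lrt_p) || is.na(fit$lrt_p))
      stop_input("no likelihood-ratio test stored; refit with lrt = TRUE")
    wt$z <- sqrt(fit$lrt_stat) * sign(wt$coef)
    wt$p <- fit$lrt_p
  }
  wt$direction <- if (!is.finite(wt$coef) || wt$coef == 0) "none"
    else if (wt$coef > 0) "toward-5hmC" else "toward-5mC"
  wt
}

#' Fit the separate main-effect model on one modification category
#'
#' Restricts the long data to a single modification (5-mC or 5-hmC) and
#' fits the fixed-effects beta regression `y ~ group + covariates` via
#' [fit_betareg()] — the per-mark model of the traditional analysis.
#'
#' @param obs Long data from [to_long()].
#' @param mod_subset `"5mC"` or `"5hmC"`.
#' @param covariates As in [fit_paired()].
#' @return A `"betareg_fit"` object.
#' @export
main_effect_model <- function(obs, mod_subset = c("5mC", "5hmC"),
                              covariates = c("glial_proportion", "age")) {
  mod_subset <- match.arg(mod_subset)
  sub <- obs[obs$mod_cat == mod_subset, , drop = FALSE]
  if (nrow(sub) == 0) stop_structural("no rows for ", mod_subset)
  sub$group <- droplevels(factor(sub$group))
  if (nlevels(sub$group) < 2)
    stop_structural("subset contains a single group")
  covariates <- intersect(covariates, names(sub))
  fml <- stats::as.formula(paste("~", paste(c("group", covariates),
                                            collapse = " + ")))
  fit_betareg(stats::model.matrix(fml, data = sub), sub$y)
}
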