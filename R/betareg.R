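# Beta regression with a logit mean link and a single (intercept-only,
# log-link) precision parameter phi. The response y_i ~ Beta(mu_i*phi,
# (1-mu_i)*phi) with mu_i = plogis(X_i %*% coef). This is the per-mark
# model used for the "traditional" separate analyses of 5-mC and 5-hmC.

# negative log-likelihood and analytic gradient in par = c(coef, log_phi)
betareg_nll <- function(par, X, y) {
  p <- ncol(X)
  eta <- drop(X %*% par[seq_len(p)])
  mu <- stats::plogis(eta)
  phi <- exp(par[p + 1L])
  -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

betareg_grad <- function(par, X, y) {
  p <- ncol(X)
  eta <- drop(X %*% par[seq_len(p)])
  mu <- stats::plogis(eta)
  phi <- exp(par[p + 1L])
  ystar <- log(y) - log1p(-y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  d_eta <- phi * (ystar - mustar) * mu * (1 - mu)
  g_coef <- -drop(crossprod(X, d_eta))
  d_phi <- sum(digamma(phi) - mu * digamma(mu * phi) -
                 (1 - mu) * digamma((1 - mu) * phi) +
                 mu * log(y) + (1 - mu) * log1p(-y))
  c(g_coef, -phi * d_phi)
}

# starting values: least squares on the logit scale, method-of-moments phi
betareg_start <- function(X, y) {
  z <- stats::qlogis(squeeze(y, 1e-4))
  fit <- stats::lm.fit(X, z)
  mu0 <- stats::plogis(drop(X %*% fit$coefficients))
  dof <- max(length(y) - ncol(X), 1L)
  s2 <- sum(fit$residuals^2) / dof
  vy <- s2 * (mu0 * (1 - mu0))^2          # delta-method response variance
  phi0 <- mean(mu0 * (1 - mu0) / pmax(vy, 1e-8) - 1)
  phi0 <- min(max(phi0, 1.1), 1e4)
  c(fit$coefficients, log(phi0))
}

#' Fit a beta regression with logit mean link and constant precision
#'
#' Maximizes the beta log-likelihood by quasi-Newton (BFGS) with analytic
#' gradients, started from a logit-scale least-squares fit with a
#' method-of-moments precision. Standard errors come from the inverse
#' observed information (numerical Hessian at the optimum).
#'
#' @param X Design matrix (full column rank, no missing entries, named
#'   columns). Typically built with [stats::model.matrix()].
#' @param y Response proportions strictly inside `(0, 1)`; apply
#'   [squeeze()] first if boundary values may occur.
#' @param maxit Maximum BFGS iterations.
#' @param reltol Relative convergence tolerance.
#' @return An object of class `"betareg_fit"`: list with `coef` (named,
#'   logit-mean scale), `se`, `log_precision`, `vcov`, `loglik`,
#'   `converged`, `reason`, `n_obs`.
#' @examples
#' set.seed(1)
#' x <- rnorm(100)
#' mu <- plogis(-1 + x)
#' y <- rbeta(100, mu * 30, (1 - mu) * 30)
#' f <- fit_betareg(cbind(`(Intercept)` = 1, x = x), y)
#' coef(f)
#' @export
fit_betareg <- function(X, y, maxit = 200L, reltol = 1e-8) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)) - 1L)
  if (nrow(X) != length(y))
    stop_structural("design matrix rows (", nrow(X),
                    ") do not match response length (", length(y), ")")
  if (anyNA(X) || anyNA(y)) stop_structural("missing values in X or y")
  if (any(y <= 0 | y >= 1))
    stop_input("response values must lie strictly in (0, 1); use squeeze()")
  if (qr(X)$rank < ncol(X))
    stop_structural("design matrix is rank deficient")

  p <- ncol(X)
  start <- betareg_start(X, y)
  opt <- stats::optim(start, betareg_nll, betareg_grad, X = X, y = y,
                      method = "BFGS", hessian = TRUE,
                      control = list(maxit = maxit, reltol = reltol))
  vc <- try(solve(opt$hessian), silent = TRUE)
  ok <- opt$convergence == 0L && !inherits(vc, "try-error") &&
    all(is.finite(diag(vc))) && all(diag(vc) > 0)
  se <- if (ok) sqrt(diag(vc)[seq_len(p)]) else rep(NA_real_, p)
  structure(list(
    coef = stats::setNames(opt$par[seq_len(p)], colnames(X)),
    se = stats::setNames(se, colnames(X)),
    log_precision = unname(opt$par[p + 1L]),
    vcov = if (ok) vc[seq_len(p), seq_len(p), drop = FALSE] else NULL,
    loglik = -opt$value,
    converged = ok,
    reason = if (ok) "converged" else
      if (opt$convergence != 0L) paste0("optim code ", opt$convergence)
      else "singular information matrix",
    n_obs = length(y)), class = "betareg_fit")
}

#' @export
coef.betareg_fit <- function(object, ...) object$coef

#' @export
logLik.betareg_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coef) + 1L,
            nobs = object$n_obs, class = "logLik")
}

#' @export
print.betareg_fit <- function(x, ...) {
  cat("Beta regression (logit link), n =", x$n_obs,
      if (!x$converged) "[NOT CONVERGED]", "\n")
  print(round(cbind(coef = x$coef, se = x$se), 4))
  cat("phi =", round(exp(x$log_precision), 2),
      " logLik =", round(x$loglik, 2), "\n")
  invisible(x)
}

#' Wald test for a single model term
#'
#' Two-sided Wald z-test of one coefficient against zero: `z = coef/se`,
#' `p = 2 * pnorm(-|z|)`. Works on [fit_betareg()] and [fit_paired()]
#' objects.
#'
#' @param fit A `"betareg_fit"` or `"paired_fit"` object.
#' @param term Name of the coefficient to test.
#' @return List with `coef`, `se`, `z`, `p`. A non-converged fit yields
#'   `NA` for `z` and `p`.
#' @export
wald_test <- function(fit, term) {
  if (!term %in% names(fit$coef))
    stop_input("unknown term '", term, "'; available: ",
               paste(names(fit$coef), collapse = ", "))
  est <- unname(fit$coef[term])
  se <- unname(fit$se[term])
  if (!isTRUE(fit$converged) || !is.finite(se) || se <= 0)
    return(list(coef = est, se = se, z = NA_real_, p = NA_real_))
  z <- est / se
  list(coef = est, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}
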