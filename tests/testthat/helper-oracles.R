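# Independent oracles used across tests.

# Grid-search argmax of the joint binomial log-likelihood over the
# simplex, at step `step` in beta_mc. For fixed beta_mc the BS-channel
# likelihood is unimodal in the total p_t = beta_mc + beta_hmc with
# unconstrained argmax m_bs/n_bs, so the constrained optimum in p_t is
# the clamp max(beta_mc, m_bs/n_bs) — profiling it out leaves an exact
# 1-D grid search.
grid_mle <- function(m_bs, n_bs, m_ox, n_ox, step = 1e-3) {
  bm <- seq(0, 1, by = step)
  pt <- pmax(bm, m_bs / n_bs)
  ll <- stats::dbinom(m_bs, n_bs, pt, log = TRUE) +
    stats::dbinom(m_ox, n_ox, bm, log = TRUE)
  i <- which.max(ll)
  c(beta_mc = bm[i], beta_hmc = pt[i] - bm[i])
}

# literal 2-D grid over (beta_mc, beta_hmc) on the simplex
grid_mle_2d <- function(m_bs, n_bs, m_ox, n_ox, step = 1e-3) {
  bm <- seq(0, 1, by = step)
  best <- c(-Inf, NA, NA)
  for (b in bm) {
    bh <- seq(0, 1 - b, by = step)
    ll <- stats::dbinom(m_bs, n_bs, b + bh, log = TRUE) +
      stats::dbinom(m_ox, n_ox, b, log = TRUE)
    i <- which.max(ll)
    if (ll[i] > best[1]) best <- c(ll[i], b, bh[i])
  }
  c(beta_mc = best[2], beta_hmc = best[3])
}

# direct step-up BH formula (independent of bh_adjust's implementation)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- seq(i, m)
    q[o[i]] <- min(1, min(p[o[j]] * m / j))
  }
  q
}

# simulate one probe's long data directly on the model scale (no
# BS/oxBS channel noise): group effects on each mark's logit mean, a
# shared per-sample intercept, beta noise at precision phi
sim_long <- function(n_control = 13, n_case = 22, base_mc = 0.45,
                     base_hmc = 0.18, eff_mc = 0, eff_hmc = 0,
                     sigma_b = 0.5, phi = 30) {
  n <- n_control + n_case
  g <- rep(c("control", "case"), c(n_control, n_case))
  u <- stats::rnorm(n, 0, sigma_b)
  glial <- stats::runif(n, 0.3, 0.7)
  age <- stats::runif(n, 60, 95)
  case <- as.numeric(g == "case")
  mu_mc <- stats::plogis(stats::qlogis(base_mc) + eff_mc * case + u)
  mu_hmc <- stats::plogis(stats::qlogis(base_hmc) + eff_hmc * case + u)
  data.frame(
    sample_id = rep(sprintf("S%03d", seq_len(n)), 2),
    mod_cat = factor(rep(c("5mC", "5hmC"), each = n),
                     levels = c("5mC", "5hmC")),
    y = squeeze(c(stats::rbeta(n, mu_mc * phi, (1 - mu_mc) * phi),
                  stats::rbeta(n, mu_hmc * phi, (1 - mu_hmc) * phi))),
    group = factor(rep(g, 2), levels = c("control", "case")),
    glial_proportion = rep(glial, 2),
    age = rep(age, 2))
}
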