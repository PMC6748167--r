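# Constrained binomial MLE of (5-mC, 5-hmC) from paired BS/oxBS signals.

test_that("worked examples match the grid-search oracle and closed forms", {
  # concordant channels: plug-in proportions (grid-verified)
  e <- estimate_paired_mle(80, 100, 50, 100)
  expect_equal(e$beta_mc, 0.5)
  expect_equal(e$beta_hmc, 0.3)
  expect_false(e$boundary)
  g <- grid_mle(80, 100, 50, 100)
  expect_equal(unname(g["beta_mc"]), 0.5, tolerance = 2e-3)
  expect_equal(unname(g["beta_hmc"]), 0.3, tolerance = 2e-3)

  # equal proportions: zero 5-hmC without boundary clipping
  e <- estimate_paired_mle(50, 100, 50, 100)
  expect_equal(e$beta_mc, 0.5)
  expect_equal(e$beta_hmc, 0)
  expect_false(e$boundary)

  # discordant channels: pooled boundary estimate (grid-verified)
  e <- estimate_paired_mle(40, 100, 60, 100)
  expect_equal(e$beta_mc, 0.5)   # (40+60)/200
  expect_equal(e$beta_hmc, 0)
  expect_true(e$boundary)
  g <- grid_mle(40, 100, 60, 100)
  expect_equal(unname(g["beta_mc"]), 0.5, tolerance = 2e-3)
  expect_equal(unname(g["beta_hmc"]), 0, tolerance = 2e-3)
})

test_that("MLE matches the grid-search argmax on random signal pairs", {
  set.seed(101)
  n_pairs <- 200
  n_bs <- sample(10:200, n_pairs, replace = TRUE)
  n_ox <- sample(10:200, n_pairs, replace = TRUE)
  m_bs <- rbinom(n_pairs, n_bs, runif(n_pairs))
  m_ox <- rbinom(n_pairs, n_ox, runif(n_pairs))
  est <- estimate_paired_mle(m_bs, n_bs, m_ox, n_ox)
  for (i in seq_len(n_pairs)) {
    g <- grid_mle(m_bs[i], n_bs[i], m_ox[i], n_ox[i])
    expect_lt(abs(est$beta_mc[i] - g["beta_mc"]), 2e-3)
    expect_lt(abs(est$beta_hmc[i] - g["beta_hmc"]), 2e-3)
  }
  # literal 2-D simplex grid agrees with the profiled 1-D grid
  for (i in 1:5) {
    # the profiled grid's total is off-grid, so the two argmaxes can
    # differ by up to one step in the 5-hmC coordinate
    g1 <- grid_mle(m_bs[i], n_bs[i], m_ox[i], n_ox[i], step = 5e-3)
    g2 <- grid_mle_2d(m_bs[i], n_bs[i], m_ox[i], n_ox[i], step = 5e-3)
    expect_lt(max(abs(g1 - g2)), 5e-3 + 1e-12)
  }
})

test_that("simplex is conserved and components stay in [0,1]", {
  set.seed(102)
  n_bs <- sample(10:200, 300, replace = TRUE)
  n_ox <- sample(10:200, 300, replace = TRUE)
  est <- estimate_paired_mle(rbinom(300, n_bs, runif(300)), n_bs,
                             rbinom(300, n_ox, runif(300)), n_ox)
  expect_true(all(abs(est$beta_mc + est$beta_hmc + est$beta_c - 1) < 1e-9))
  expect_true(all(est$beta_mc >= 0 & est$beta_mc <= 1))
  expect_true(all(est$beta_hmc >= 0 & est$beta_hmc <= 1))
  expect_true(all(est$beta_c >= -1e-12 & est$beta_c <= 1))
})

test_that("feasible case equals plug-in proportions exactly", {
  set.seed(103)
  for (i in 1:100) {
    n1 <- sample(10:200, 1); n2 <- sample(10:200, 1)
    m2 <- rbinom(1, n2, 0.4)
    m1 <- rbinom(1, n1, min(1, m2 / n2 + 0.2))
    if (m1 / n1 >= m2 / n2) {
      e <- estimate_paired_mle(m1, n1, m2, n2)
      expect_identical(e$beta_mc, m2 / n2)
      expect_identical(e$beta_hmc, m1 / n1 - m2 / n2)
    }
  }
})

test_that("naive and MLE agree for equal totals and feasible difference", {
  set.seed(104)
  n <- 100
  m_ox <- rbinom(50, n, 0.3)
  m_bs <- pmin(n, m_ox + rbinom(50, n - max(m_ox), 0.2))
  mle <- estimate_paired_mle(m_bs, n, m_ox, n)
  nai <- estimate_naive(m_bs / n, m_ox / n)
  expect_equal(mle$beta_mc, nai$beta_mc)
  expect_equal(mle$beta_hmc, nai$beta_hmc)
})

test_that("5-hmC estimate is non-decreasing in the BS signal", {
  est <- estimate_paired_mle(0:100, 100, 40, 80)
  expect_true(all(diff(est$beta_hmc) >= 0))
})

test_that("naive estimator clips negative differences and flags them", {
  e <- estimate_naive(0.8, 0.5)
  expect_equal(c(e$beta_mc, e$beta_hmc), c(0.5, 0.3))
  e <- estimate_naive(0.4, 0.6)
  expect_equal(c(e$beta_mc, e$beta_hmc), c(0.6, 0))
  expect_true(e$boundary)
  e <- estimate_naive(0, 0)
  expect_equal(c(e$beta_mc, e$beta_hmc), c(0, 0))
  expect_error(estimate_naive(1.2, 0.5), "\\[0, 1\\]")
})

test_that("invalid counts raise input errors naming the entry", {
  expect_error(estimate_paired_mle(110, 100, 50, 100), "invalid signal")
  expect_error(estimate_paired_mle(-1, 100, 50, 100), "invalid signal")
  expect_error(estimate_paired_mle(110, 100, 50, 100, id = "cg0001/S2"),
               "cg0001/S2")
})

test_that("zero totals and missing inputs yield missing calls", {
  e <- estimate_paired_mle(c(0, NA, 10), c(0, 100, 100), c(0, 5, 5),
                           c(10, 100, 100))
  expect_true(is.na(e$beta_mc[1]) && is.na(e$beta_mc[2]))
  expect_false(is.na(e$beta_mc[3]))
})

test_that("matrix estimation is elementwise and propagates missingness", {
  dn <- list(c("p1", "p2"), c("s1", "s2"))
  bs <- matrix(0.8, 2, 2, dimnames = dn)
  ox <- matrix(0.5, 2, 2, dimnames = dn)
  nn <- matrix(100, 2, 2, dimnames = dn)
  est <- estimate_matrix(bs, ox, nn)
  expect_equal(unname(est$beta_mc), matrix(0.5, 2, 2))
  expect_equal(unname(est$beta_hmc), matrix(0.3, 2, 2))

  bs[1, 2] <- NA
  est <- estimate_matrix(bs, ox, nn)
  expect_true(is.na(est$beta_mc[1, 2]) && is.na(est$beta_hmc[1, 2]))
  expect_equal(sum(is.na(est$beta_mc)), 1L)

  one <- estimate_matrix(matrix(0.5, 1, 1, dimnames = list("p", "s")),
                         matrix(0.5, 1, 1, dimnames = list("p", "s")),
                         matrix(50, 1, 1, dimnames = list("p", "s")))
  expect_equal(unname(one$beta_mc[1, 1]), 0.5)
  expect_equal(unname(one$beta_hmc[1, 1]), 0)
})

test_that("misaligned matrices raise structural errors naming offenders", {
  bs <- matrix(0.5, 2, 2, dimnames = list(c("p1", "p2"), c("s1", "s2")))
  ox <- matrix(0.5, 2, 2, dimnames = list(c("p1", "p3"), c("s1", "s2")))
  nn <- matrix(100, 2, 2, dimnames = dimnames(bs))
  expect_error(estimate_matrix(bs, ox, nn), "p3")
})
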