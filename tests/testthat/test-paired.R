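# Paired repeated-measures mixed-effects beta regression.

make_calls <- function(n_probes = 3, seed = 7, sigma_b = 0.5) {
  cfg <- sim_config(n_probes = n_probes, zero_inflation = 0,
                    sigma_b = sigma_b, seed = seed)
  ds <- generate_dataset(cfg)
  est <- estimate_matrix(ds$bs, ds$ox, ds$coverage_bs, ds$coverage_ox)
  list(est = est, sheet = ds$sheet)
}

test_that("to_long produces two rows per sample with matching values", {
  mc <- matrix(c(0.5, 0.6, 0.7), 1, 3,
               dimnames = list("p1", c("a", "b", "c")))
  hmc <- matrix(c(0.1, 0.2, 0.3), 1, 3, dimnames = dimnames(mc))
  sheet <- data.frame(sample_id = c("a", "b", "c"),
                      group = c("x", "x", "y"), age = c(70, 75, 80),
                      glial_proportion = c(0.4, 0.5, 0.6))
  long <- to_long(list(beta_mc = mc, beta_hmc = hmc), sheet, "p1")
  expect_equal(nrow(long), 6L)
  counts <- table(long$sample_id)
  expect_true(all(counts == 2L) && length(counts) == 3L)
  expect_equal(long$y[long$sample_id == "b" & long$mod_cat == "5mC"], 0.6)
  expect_equal(long$y[long$sample_id == "c" & long$mod_cat == "5hmC"], 0.3)
  expect_equal(levels(long$mod_cat), c("5mC", "5hmC"))
  expect_error(to_long(list(beta_mc = mc, beta_hmc = hmc), sheet, "nope"),
               "not found")
  # a modification with no observed values is structural, not silent
  hmc[] <- NA
  expect_error(to_long(list(beta_mc = mc, beta_hmc = hmc), sheet, "p1"),
               "no observed values")
})

test_that("group-symmetric data yield zero group and interaction effects", {
  # both groups carry the same multiset of (5mC, 5hmC) pairs, so the
  # likelihood is symmetric under group relabeling
  sheet <- data.frame(sample_id = sprintf("s%d", 1:8),
                      group = rep(c("ctl", "case"), each = 4))
  vals_mc <- rep(c(0.5, 0.5, 0.7, 0.7), 2)
  vals_hmc <- rep(c(0.1, 0.1, 0.3, 0.3), 2)
  long <- data.frame(sample_id = rep(sheet$sample_id, 2),
                     mod_cat = factor(rep(c("5mC", "5hmC"), each = 8),
                                      levels = c("5mC", "5hmC")),
                     y = c(vals_mc, vals_hmc),
                     group = factor(rep(sheet$group, 2),
                                    levels = c("ctl", "case")))
  f <- fit_paired(long, covariates = character(0))
  expect_lt(abs(f$coef[["groupcase"]]), 1e-4)
  expect_lt(abs(f$coef[[f$interaction_term]]), 1e-4)
})

test_that("with sigma_b fixed at zero the fit reduces to beta regression", {
  cl <- make_calls(seed = 7, sigma_b = 0)
  long <- to_long(cl$est, cl$sheet, "probe_00001")
  X <- stats::model.matrix(~ group * mod_cat + glial_proportion + age,
                           long)
  fb <- fit_betareg(X, long$y)
  fp <- fit_paired(long, sigma_b = 0)
  expect_lt(abs(fb$loglik - fp$loglik), 1e-8)
  expect_lt(max(abs(fb$coef - fp$coef)), 1e-3)
  # on model-scale independent data, the estimated sigma_b collapses
  # and the fixed effects coincide with the plain beta regression
  set.seed(71)
  long2 <- sim_long(sigma_b = 0)
  X2 <- stats::model.matrix(~ group * mod_cat + glial_proportion + age,
                            long2)
  fb2 <- fit_betareg(X2, long2$y)
  fe <- fit_paired(long2)
  expect_lt(fe$sigma_b, 0.1)
  expect_lt(max(abs(fe$coef - fb2$coef)), 1e-3)
})

test_that("the planted interaction is recovered within 3 SE", {
  set.seed(301)
  long <- sim_long(n_control = 18, n_case = 18, eff_mc = -0.8,
                   eff_hmc = 0, sigma_b = 0.5, phi = 30)
  f <- fit_paired(long, covariates = character(0))
  w <- interaction_test(f)
  # true interaction = eff_hmc - eff_mc = +0.8
  expect_lt(abs(w$coef - 0.8) / w$se, 3)
  expect_equal(w$direction, "toward-5hmC")
})

test_that("quadrature node count barely moves the estimates", {
  cl <- make_calls(seed = 11)
  long <- to_long(cl$est, cl$sheet, "probe_00002")
  f5 <- fit_paired(long, nodes = 5)
  f15 <- fit_paired(long, nodes = 15)
  expect_lt(abs(f5$coef[[f5$interaction_term]] -
                  f15$coef[[f15$interaction_term]]), 1e-3)
  expect_lt(abs(f5$loglik - f15$loglik), 1e-3)
})

test_that("fits agree with an independent Laplace-approximation fitter", {
  skip_if_not_installed("glmmTMB")
  cl <- make_calls(seed = 42)
  long <- to_long(cl$est, cl$sheet, "probe_00001")
  f <- fit_paired(long)
  long$sid <- factor(long$sample_id)
  g <- glmmTMB::glmmTMB(
    y ~ group * mod_cat + glial_proportion + age + (1 | sid),
    family = glmmTMB::beta_family(), data = long)
  co <- summary(g)$coefficients$cond
  expect_lt(max(abs(f$coef - co[names(f$coef), "Estimate"])), 0.05)
  expect_lt(max(abs(f$se - co[names(f$coef), "Std. Error"]) /
                  co[names(f$coef), "Std. Error"]), 0.05)
})

test_that("interaction_test reports direction by coefficient sign", {
  fake <- structure(list(coef = c(`groupcase:mod_cat5hmC` = -0.5),
                         se = c(`groupcase:mod_cat5hmC` = 0.1),
                         converged = TRUE,
                         interaction_term = "groupcase:mod_cat5hmC"),
                    class = "paired_fit")
  expect_equal(interaction_test(fake)$direction, "toward-5mC")
  fake$coef[1] <- 0.5
  expect_equal(interaction_test(fake)$direction, "toward-5hmC")
  fake$coef[1] <- 0
  w <- interaction_test(fake)
  expect_equal(w$direction, "none")
  expect_equal(w$p, 1)
  fake$converged <- FALSE
  expect_true(is.na(interaction_test(fake)$p))
})

test_that("main_effect_model equals the separate per-mark fit exactly", {
  cl <- make_calls(seed = 9)
  long <- to_long(cl$est, cl$sheet, "probe_00003")
  for (mod in c("5mC", "5hmC")) {
    sub <- long[long$mod_cat == mod, ]
    X <- stats::model.matrix(~ group + glial_proportion + age, sub)
    direct <- fit_betareg(X, sub$y)
    viafun <- main_effect_model(long, mod)
    expect_equal(viafun$coef, direct$coef, tolerance = 1e-10)
    expect_equal(viafun$loglik, direct$loglik, tolerance = 1e-10)
  }
  one_group <- long[long$group == "case", ]
  expect_error(main_effect_model(one_group, "5mC"), "single group")
})

test_that("degenerate paired designs raise structural errors", {
  long <- sim_long(n_control = 4, n_case = 4)
  long2 <- long[long$mod_cat == "5mC", ]
  expect_error(fit_paired(long2), "both modification categories")
  long3 <- long
  long3$group <- factor("case", levels = c("control", "case"))
  expect_error(fit_paired(long3), ">= 2")
})

test_that("the optional batch random effect fits and stays near zero
          when batches are uninformative", {
  set.seed(303)
  long <- sim_long(n_control = 8, n_case = 8)
  long$batch <- rep(rep(c("b1", "b2"), each = 8), 2)
  f <- fit_paired(long, covariates = character(0), include_batch_re = TRUE)
  expect_true(is.finite(f$loglik))
  expect_true(f$sigma_batch < 0.5)   # no batch signal was planted
  f0 <- fit_paired(long, covariates = character(0))
  expect_lt(abs(f$coef[[f$interaction_term]] -
                  f0$coef[[f0$interaction_term]]), 0.05)
})
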