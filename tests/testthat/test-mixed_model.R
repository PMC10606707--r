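## small helper: phenotypes + relationship structures from a tiny simulation
tiny_model_fixture <- function(seed = 1L, ...) {
  cfg <- tiny_sim_config(seed = seed, ...)
  sim <- simulate_dataset(cfg)
  hinv <- suppressWarnings(
    h_inverse(sim$pedigree, sim$genotypes, sim$genotypes$samples))
  list(phen = sim$phenotypes, hinv = hinv,
       het = heterozygosity_percent(sim$genotypes), sim = sim)
}

test_that("fixed-effects-only system reproduces ordinary least squares", {
  fx <- tiny_model_fixture(seed = 701)
  spec <- model_spec("tnb", hys = FALSE, additive = FALSE, pe = FALSE)
  sys <- build_mme(fx$phen, spec, vc = c(a = 1, p = 1, h = 1, e = 2.5))
  fit <- solve_mme(sys, targets = seq_along(sys$labels))
  ols <- lm(tnb ~ factor(parity), data = fx$phen)
  expect_equal(unname(fit$solution[seq_along(sys$labels)]),
               unname(coef(ols)), tolerance = 1e-10)
})

test_that("intercept-only model returns the mean with variance s2e/n", {
  fx <- tiny_model_fixture(seed = 702)
  phen <- fx$phen
  phen$parity <- 1L      # single fixed column: the intercept
  spec <- model_spec("tnb", hys = FALSE, additive = FALSE, pe = FALSE)
  s2e <- 3.2
  sys <- build_mme(phen, spec, vc = c(a = 1, p = 1, h = 1, e = s2e))
  fit <- solve_mme(sys, targets = 1L)
  expect_equal(unname(fit$solution[1L]), mean(phen$tnb))
  expect_equal(unname(fit$se[1L]), sqrt(s2e / nrow(phen)))
})

test_that("MME solutions equal dense GLS on random small instances", {
  set.seed(703)
  for (i in 1:12) {
    fx <- tiny_model_fixture(seed = 7030 + i)
    vc <- c(a = runif(1, 0.1, 0.5), p = runif(1, 0.1, 0.6),
            h = runif(1, 0.05, 0.4), e = runif(1, 1, 4))
    spec <- model_spec(sample(c("tnb", "nba"), 1), covariate = i %% 2 == 0)
    sys <- build_mme(fx$phen, spec, fx$hinv, vc,
                     het = if (spec$covariate) fx$het)
    fit <- solve_mme(sys, targets = seq_along(sys$labels))
    oracle <- gls_oracle(sys, fx$hinv)
    expect_equal(unname(fit$solution[sys$blocks$fixed]), unname(oracle$beta),
                 tolerance = 1e-8)
    expect_equal(unname(fit$se), unname(oracle$se), tolerance = 1e-8)
  }
})

test_that("solutions are invariant to record order", {
  fx <- tiny_model_fixture(seed = 704)
  vc <- c(a = 0.2, p = 0.3, h = 0.15, e = 2.9)
  spec <- model_spec("tnb")
  sys1 <- build_mme(fx$phen, spec, fx$hinv, vc)
  perm <- sample(nrow(fx$phen))
  phen2 <- fx$phen[perm, ]
  class(phen2) <- class(fx$phen)
  sys2 <- build_mme(phen2, spec, fx$hinv, vc)
  f1 <- solve_mme(sys1)
  f2 <- solve_mme(sys2)
  expect_equal(f1$solution[sys1$blocks$fixed], f2$solution[sys2$blocks$fixed],
               tolerance = 1e-9)
  expect_equal(unname(f1$solution[sys1$blocks$u]),
               unname(f2$solution[sys2$blocks$u]), tolerance = 1e-9)
})

test_that("collinear fixed columns are constrained, estimable parts unchanged", {
  fx <- tiny_model_fixture(seed = 705)
  sows <- unique(fx$phen$sow)
  carrier_all <- stats::setNames(rep(1, length(sows)), sows) # = intercept
  vc <- c(a = 0.2, p = 0.3, h = 0.15, e = 2.9)
  base_spec <- model_spec("tnb")
  dup_spec <- model_spec("tnb", carrier = TRUE)
  base <- solve_mme(build_mme(fx$phen, base_spec, fx$hinv, vc))
  sys_dup <- build_mme(fx$phen, dup_spec, fx$hinv, vc, carrier = carrier_all)
  expect_true(length(sys_dup$aliased) == 1L)
  dup <- solve_mme(sys_dup)
  ## fitted values are an estimable function: identical under the constraint
  yhat_base <- as.numeric(sys_dup$M[, -sys_dup$aliased] %*%
                            dup$solution[-sys_dup$aliased])
  sys_b <- build_mme(fx$phen, base_spec, fx$hinv, vc)
  yhat0 <- as.numeric(sys_b$M %*% base$solution)
  expect_equal(yhat_base, yhat0, tolerance = 1e-8)
})

test_that("one-sided tail probabilities match the published worked examples", {
  ## printed estimate/SE pairs for the heterozygosity covariate
  expect_equal(round(one_sided_p(0.055, 0.026, "greater"), 3), 0.017)
  expect_equal(round(one_sided_p(0.057, 0.028, "greater"), 3), 0.021)
  expect_equal(one_sided_p(0.077, 0.051, "greater"), 0.065, tolerance = 0.01)
  expect_equal(round(one_sided_p(0.067, 0.050, "greater"), 3), 0.090)
})

test_that("one-sided p is 0.5 at zero, complementary, monotone, validated", {
  expect_equal(one_sided_p(0, 1.3, "greater"), 0.5)
  expect_equal(one_sided_p(0, 0.2, "less"), 0.5)
  x <- 0.4; s <- 0.25
  expect_equal(one_sided_p(x, s, "greater") + one_sided_p(x, s, "less"), 1)
  ps <- one_sided_p(seq(-1, 1, by = 0.1), 0.5, "greater")
  expect_true(all(diff(ps) < 0))
  expect_error(one_sided_p(1, 0, "greater"), "positive")
  ## finite df reference: heavier tails than normal
  expect_gt(one_sided_p(2, 1, "greater", df = 5),
            one_sided_p(2, 1, "greater"))
})

test_that("AI-REML finds only residual variance when the others are zero", {
  set.seed(706)
  cfg <- tiny_sim_config(seed = 706,
                         varcomp_true = c(a = 0, p = 0, h = 0, e = 2.5),
                         het_slope_true = 0)
  sim <- simulate_dataset(cfg)
  hinv <- suppressWarnings(
    h_inverse(sim$pedigree, sim$genotypes, sim$genotypes$samples))
  vc <- ai_reml(sim$phenotypes, model_spec("tnb"), hinv)
  ## rounding to integers adds 1/12 to the effective residual variance
  expect_equal(unname(vc$sigma2["e"]), 2.5 + 1 / 12, tolerance = 0.25)
  expect_lt(unname(vc$sigma2["a"]), 0.05)
  expect_lt(unname(vc$sigma2["p"]), 0.05)
  expect_lt(unname(vc$sigma2["h"]), 0.05)
})

test_that("AI-REML matches the closed-form REML of balanced one-way data", {
  set.seed(707)
  ng <- 30; nrep <- 6
  grp <- rep(sprintf("g%02d", seq_len(ng)), each = nrep)
  y <- pmax(round(8 + rnorm(ng, 0, sqrt(0.6))[as.integer(factor(grp))] +
                    rnorm(ng * nrep, 0, sqrt(2))), 0)
  phen <- phenotype_table(paste0("s", seq_along(y)), 1, grp, y, y)
  vc <- ai_reml(phen, model_spec("tnb", hys = TRUE, additive = FALSE,
                                 pe = FALSE), tol = 1e-10)
  ms <- anova(lm(y ~ factor(grp)))[["Mean Sq"]]
  expect_equal(unname(vc$sigma2["e"]), ms[2], tolerance = 1e-6)
  expect_equal(unname(vc$sigma2["h"]), (ms[1] - ms[2]) / nrep,
               tolerance = 1e-6)
})

test_that("AI-REML agrees with lme4 on an unbalanced two-component model", {
  set.seed(708)
  n <- 400
  grp <- sample(sprintf("g%02d", 1:18), n, replace = TRUE)
  sow <- sample(sprintf("w%02d", 1:60), n, replace = TRUE)
  y <- pmax(round(8 + rnorm(18, 0, 0.6)[as.integer(factor(grp))] +
                    rnorm(60, 0, 0.7)[as.integer(factor(sow))] +
                    rnorm(n, 0, 1.6)), 0)
  phen <- phenotype_table(sow, sample(1:5, n, TRUE), grp, y, y)
  vc <- ai_reml(phen, model_spec("tnb", additive = FALSE), tol = 1e-9)
  fit <- lme4::lmer(y ~ factor(phen$parity) + (1 | grp) + (1 | sow),
                    REML = TRUE)
  vl <- as.data.frame(lme4::VarCorr(fit))
  lme4_named <- stats::setNames(vl$vcov, vl$grp)
  expect_equal(unname(vc$sigma2["h"]), unname(lme4_named["grp"]),
               tolerance = 1e-4)
  expect_equal(unname(vc$sigma2["p"]), unname(lme4_named["sow"]),
               tolerance = 1e-4)
  expect_equal(unname(vc$sigma2["e"]), unname(lme4_named["Residual"]),
               tolerance = 1e-4)
})

test_that("AI-REML estimates scale by c^2 when the trait is scaled by c", {
  fx <- tiny_model_fixture(seed = 709)
  spec <- model_spec("tnb")
  vc1 <- ai_reml(fx$phen, spec, fx$hinv)
  phen2 <- fx$phen
  phen2$tnb <- phen2$tnb * 3
  vc2 <- ai_reml(phen2, spec, fx$hinv)
  free <- !vc1$convergence$boundary & !vc2$convergence$boundary
  expect_equal(vc2$sigma2[free], 9 * vc1$sigma2[free], tolerance = 1e-4)
})

test_that("AI-REML is invariant to record order", {
  fx <- tiny_model_fixture(seed = 710)
  spec <- model_spec("tnb")
  vc1 <- ai_reml(fx$phen, spec, fx$hinv)
  perm <- sample(nrow(fx$phen))
  phen2 <- fx$phen[perm, ]
  class(phen2) <- class(fx$phen)
  vc2 <- ai_reml(phen2, spec, fx$hinv)
  expect_equal(vc1$sigma2, vc2$sigma2, tolerance = 1e-6)
})

test_that("the carrier term is refused during variance estimation", {
  fx <- tiny_model_fixture(seed = 711)
  expect_error(ai_reml(fx$phen, model_spec("tnb", carrier = TRUE), fx$hinv),
               "carrier")
})

test_that("fit_het_covariate reports slope, SE and upper-tail p", {
  fx <- tiny_model_fixture(seed = 712)
  vc <- variance_components(a = 0.145, p = 0.366, h = 0.17, e = 2.901)
  est <- fit_het_covariate(fx$phen, model_spec("tnb"), fx$hinv, vc, fx$het)
  expect_true(is.finite(est$estimate) && est$se > 0)
  expect_equal(est$p, one_sided_p(est$estimate, est$se, "greater"))
  ## constant covariate is rejected
  const <- stats::setNames(rep(30, length(fx$het)), names(fx$het))
  expect_error(fit_het_covariate(fx$phen, model_spec("tnb"), fx$hinv, vc,
                                 const), "constant")
})
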