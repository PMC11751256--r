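test_that("Grubbs screening masks planted outliers and nothing else", {
  set.seed(61)
  x <- rnorm(30)
  x[7] <- 10  # 10-SD outlier
  keep <- remove_outliers(x)
  expect_false(keep[7])
  expect_equal(attr(keep, "n_removed"), 1L)

  # clean normal sample: removal is rare (alpha-level); fixed seed
  clean <- rnorm(50)
  k2 <- remove_outliers(clean)
  expect_lte(attr(k2, "n_removed"), 2L)

  # constant vector: zero variance guarded, no removals
  k3 <- remove_outliers(rep(1, 20))
  expect_true(all(k3))

  expect_warning(k4 <- remove_outliers(c(1, 2)), "fewer than 3")
  expect_equal(length(k4), 2L)

  # deterministic and terminating: same mask twice
  expect_identical(remove_outliers(x), remove_outliers(x))
})

test_that("the kurtosis test separates flat from normal tails", {
  set.seed(62)
  flat <- runif(200)           # excess kurtosis -1.2
  kt <- kurtosis_test(flat, alternative = "less")
  expect_lt(kt$excess, -0.8)
  expect_lt(kt$p, 0.01)
  norm <- rnorm(200)
  kt2 <- kurtosis_test(norm, alternative = "less")
  expect_gt(kt2$p, 0.05)
})

test_that("replicate noise drives the measurement-error verdict", {
  # no replicate noise: error MS ~ 0, signal overwhelmingly resolvable
  d0 <- make_cohort(trait_spec("a2", fa_sd = 0.01, me_sd = 0), n = 40,
                    seed = 63)
  me0 <- suppressWarnings(assess_measurement_error(d0$measurements))
  expect_lt(me0$var_error, 1e-20)
  expect_true(me0$resolvable)

  # duplicated replicates: error MS exactly zero
  m <- d0$measurements
  m$value[m$replicate == 2] <- m$value[m$replicate == 1]
  me_dup <- suppressWarnings(assess_measurement_error(m))
  expect_equal(me_dup$var_error, 0)

  # noise-dominated cohorts fail the gate most of the time
  verdicts <- vapply(1:20, function(k) {
    d <- make_cohort(archetype_card()$ME_dominated, n = 60,
                     seed = 700 + k)
    isFALSE(assess_measurement_error(d$measurements)$resolvable)
  }, logical(1))
  expect_gte(mean(verdicts), 0.85)

  # tiny cohorts get no verdict
  d_small <- make_cohort(trait_spec("a2"), n = 3, seed = 64)
  expect_warning(me_s <- assess_measurement_error(d_small$measurements),
                 "fewer than 5")
  expect_true(is.na(me_s$resolvable))
  expect_true(me_s$pct_me >= 0 && me_s$pct_me <= 100)
})

test_that("the prestep retains real predictors and drops null ones", {
  ind <- simulate_individuals(n_per_cell = 9, seed = 65)   # 324
  hw <- simulate_headwidth(ind, beta_wing = 0.05, beta_size = 0.1,
                           beta_sex = 0, sd_month = 0, sd_ind = 0.01,
                           sd_resid = 0.02, seed = 66)
  d <- carabid_dataset(ind, hw)
  pre <- prestep_screen(d)
  expect_true(all(c("wing_score", "size_z") %in% pre$retained))
  expect_true("sex" %in% pre$dropped)
})

test_that("the head-width LMM reduces to OLS when random variances vanish", {
  ind <- simulate_individuals(n_per_cell = 6, seed = 67)
  hw <- simulate_headwidth(ind, beta_wing = 0.04, beta_size = 0.08,
                           sd_month = 0, sd_ind = 0, sd_resid = 0.03,
                           seed = 68)
  d <- carabid_dataset(ind, hw)
  lmm <- suppressMessages(fit_headwidth_lmm(d))
  tab <- merge(hw, ind, by = "individual_id")
  tab$size_z <- as.numeric(scale(tab$body_size))
  ols <- lm(value ~ treatment + size_z + wing_score, data = tab)
  expect_equal(unname(lme4::fixef(lmm$fit)), unname(coef(ols)),
               tolerance = 1e-6)
  expect_true(lmm$r2_marginal >= 0 && lmm$r2_conditional <= 1)
  expect_true(lmm$r2_marginal <= lmm$r2_conditional + 1e-12)
})

test_that("a known body-size slope is recovered at study scale", {
  ind <- simulate_individuals(n_per_cell = 9, seed = 69)
  hw <- simulate_headwidth(ind, beta_size = 0.3, sd_month = 0.02,
                           sd_ind = 0.03, sd_resid = 0.03, seed = 70)
  d <- carabid_dataset(ind, hw)
  lmm <- fit_headwidth_lmm(d)
  est <- lme4::fixef(lmm$fit)[["size_z"]]
  expect_lt(abs(est - 0.3), 0.05)
  wald <- lmm$wald
  expect_lt(wald$`Pr(>Chisq)`[wald$term == "size_z"], 1e-6)
})

test_that("the Bayesian head-width model matches the likelihood and is seeded", {
  ind <- simulate_individuals(n_per_cell = 5, seed = 71)
  hw <- simulate_headwidth(ind, beta_wing = 0.05, beta_size = 0.1,
                           sd_month = 0, sd_ind = 0, sd_resid = 0.05,
                           seed = 72)
  d <- carabid_dataset(ind, hw)
  b <- fit_headwidth_bglm(d, chains = 2, iter = 2000, seed = 73,
                          rhat_threshold = 1.1)
  # maximum-likelihood oracle on the same design
  tab <- merge(hw, ind, by = "individual_id")
  tab$size_z <- as.numeric(scale(tab$body_size))
  tab$treatment <- factor(tab$treatment,
                          levels = c("clearing", "control", "ecotone"))
  ml <- lm(value ~ wing_score * treatment + size_z, data = tab)
  cf <- b$posterior$coefficients
  post_sd <- cf$sd
  expect_lt(max(abs(cf$mean - unname(coef(ml))) / post_sd), 0.3)
  # conditional-effects grid covers wing scores x treatments
  expect_equal(nrow(b$conditional_effects), 9L)
  expect_true(all(b$conditional_effects$l95 <= b$conditional_effects$u95))

  b2 <- fit_headwidth_bglm(d, chains = 2, iter = 2000, seed = 73,
                           rhat_threshold = 1.1)
  expect_identical(b$posterior$coefficients, b2$posterior$coefficients)
})

test_that("treatment-variability screen responds to group differences", {
  set.seed(74)
  vals <- c(rnorm(40, 1), rnorm(40, 2), rnorm(40, 1))
  trt <- rep(c("clearing", "control", "ecotone"), each = 40)
  sc <- screen_treatment_variability(vals, trt)
  expect_true(sc$varies)
  sc0 <- screen_treatment_variability(rnorm(120), trt)
  expect_gt(sc0$p, 0.001)
})
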