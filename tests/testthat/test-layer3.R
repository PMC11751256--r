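test_that("signed relative asymmetry follows its definition", {
  expect_equal(signed_relative_asymmetry(2.0, 2.0), 0)
  expect_equal(signed_relative_asymmetry(1.1, 0.9), 0.2)
  expect_equal(signed_relative_asymmetry(0.9, 1.1), -0.2)
  # antisymmetric under side swap, invariant under unit change
  set.seed(81)
  R <- runif(50, 1, 2); L <- runif(50, 1, 2)
  expect_equal(signed_relative_asymmetry(R, L),
               -signed_relative_asymmetry(L, R))
  expect_equal(signed_relative_asymmetry(R, L),
               signed_relative_asymmetry(10 * R, 10 * L),
               tolerance = 1e-12)
  expect_true(is.na(signed_relative_asymmetry(0, 0)))
})

test_that("the corrected FA index centres its cohort exactly", {
  cf <- corrected_fa(rep(0.3, 10))
  expect_equal(cf$fa, rep(0, 10))
  expect_equal(cf$da_term, 0.3)

  cf2 <- corrected_fa(c(0.1, -0.1, 0.1, -0.1, 0.1, -0.1))
  expect_equal(cf2$da_term, 0, tolerance = 1e-15)

  set.seed(82)
  for (i in 1:20) {
    s <- rnorm(sample(5:60, 1), mean = runif(1, -0.1, 0.1), sd = 0.05)
    cf3 <- corrected_fa(s)
    expect_lt(abs(sum(cf3$fa)), 1e-12)
  }
  expect_true(corrected_fa(c(0.1, 0.2), min_n = 5)$low_n)
})

test_that("the DA test reads the uncorrected asymmetries", {
  # all-zero cohort is not flagged
  da0 <- test_directional_asymmetry(rep(0, 20))
  expect_false(da0$flag)
  # strong shift (effect size 1, n = 50) is flagged
  set.seed(83)
  s <- rnorm(50, mean = 0.02, sd = 0.02)
  expect_true(test_directional_asymmetry(s)$flag)
  # the corrected index is mean-zero by construction: its t statistic is
  # identically 0, so a DA test applied to it would be vacuous
  cf <- corrected_fa(s)
  t_corr <- t.test(cf$fa, mu = 0)$statistic
  expect_lt(abs(t_corr), 1e-8)
})

test_that("antisymmetry is flagged by platykurtosis only", {
  d <- make_cohort(archetype_card()$antisymmetry, n = 60, seed = 84)
  av <- asymmetry_table(d, d$individuals$species[1], "a2")
  anti <- test_antisymmetry(av$s)
  expect_lt(anti$excess, -1)
  expect_true(anti$flag)

  set.seed(85)
  g <- test_antisymmetry(rnorm(60, 0, 0.01))
  expect_false(isTRUE(g$flag) && g$p < 0.001)  # no strong false signal
  expect_true(is.na(test_antisymmetry(rep(0.01, 30))$flag))
  expect_warning(small <- test_antisymmetry(rnorm(5)), "n < 10")
  expect_true(is.na(small$flag))
})

test_that("size-dependent asymmetry is detected and annotated", {
  d <- make_cohort(archetype_card()$size_dependent, n = 60, seed = 86)
  av <- asymmetry_table(d, d$individuals$species[1], "a2")
  sz <- test_size_dependence(av$abs_diff, av$body_size)
  expect_true(sz$flag)

  z0 <- test_size_dependence(rep(0, 30), runif(30, 3, 4))
  expect_equal(z0$F, 0)
  expect_false(z0$flag)
  expect_warning(test_size_dependence(runif(30), rep(3.5, 30)),
                 "constant body size")
})

test_that("verdict precedence follows ME > antisymmetry > DA > size", {
  ok <- list(flag = FALSE); bad <- list(flag = TRUE)
  me_ok <- list(resolvable = TRUE, low_n = FALSE)
  me_bad <- list(resolvable = FALSE, low_n = FALSE)
  expect_equal(classify_trait(me_ok, ok, ok, ok, n = 30), "true_FA")
  expect_equal(classify_trait(me_ok, bad, ok, bad, n = 30), "DA")
  expect_equal(classify_trait(me_ok, bad, bad, bad, n = 30),
               "antisymmetry")
  expect_equal(classify_trait(me_bad, bad, bad, bad, n = 30),
               "ME_dominated")
  expect_equal(classify_trait(me_ok, ok, ok, bad, n = 30),
               "size_dependent")
  expect_equal(classify_trait(me_ok, ok, ok, ok, n = 3), "low_n")
})

test_that("assess_trait assembles a complete one-row assessment", {
  d <- make_cohort(archetype_card()$true_FA, n = 60, seed = 87)
  ta <- assess_trait(d, d$individuals$species[1], "a2")
  expect_equal(nrow(ta), 1L)
  expect_true(ta$verdict %in% c("true_FA", "DA", "antisymmetry",
                                "ME_dominated", "size_dependent"))
  expect_true(all(c(ta$da_p, ta$anti_p, ta$size_p, ta$me_p) >= 0))
  expect_true(all(c(ta$da_p, ta$anti_p, ta$size_p, ta$me_p) <= 1))
  ta_small <- assess_trait(d, "nobody", "a2")
  expect_equal(ta_small$verdict, "low_n")
})

test_that("the FA modelling table keeps replicate structure and transforms", {
  d <- make_cohort(trait_spec("a2", fa_sd = 0.01, me_sd = 0.003), n = 40,
                   seed = 88)
  sp <- d$individuals$species[1]
  ft <- fa_index_table(d, sp, "a2", magnitude = "abs")
  expect_equal(sort(unique(ft$replicate)), c(1L, 2L))
  expect_equal(ft$fa_mag, abs(ft$fa))
  ft2 <- fa_index_table(d, sp, "a2", magnitude = "square")
  expect_equal(ft2$fa_mag, ft2$fa^2)
  # per-individual corrected values still centre the cohort
  per_ind <- ft$fa_individual[!duplicated(ft$individual_id)]
  expect_lt(abs(sum(per_ind)), 1e-12)
  expect_null(fa_index_table(d, "nobody", "a2"))
})

test_that("treatment models find injected FA inflation and not phantoms", {
  ind <- simulate_individuals(n_per_cell = 4, seed = 89)  # 144
  mult <- ifelse(ind$treatment == "clearing", 2.0, 1.0)
  m <- simulate_bilateral(ind, trait_spec("a2", fa_sd = 0.01,
                                          me_sd = 0.002),
                          seed = 90, fa_sd_multiplier = mult)
  d <- carabid_dataset(ind, m)
  ft <- fa_index_table(d, ind$species[1], "a2")
  fit <- fit_treatment_lmm(ft)
  expect_lt(fit$wald$`Pr(>Chisq)`[fit$wald$term == "treatment"], 0.01)
  expect_equal(nrow(fit$contrasts), 3L)
  best <- fit$lsmeans$emmean[fit$lsmeans$treatment == "clearing"]
  expect_gt(best, max(fit$lsmeans$emmean[
    fit$lsmeans$treatment != "clearing"]))

  # literally identical groups: every contrast is zero, adjusted p ~ 1
  ft0 <- ft[ft$treatment == "control", ]
  clones <- lapply(c("clearing", "control", "ecotone"), function(tr) {
    g <- ft0
    g$treatment <- tr
    g$individual_id <- paste0(g$individual_id, "_", tr)
    g
  })
  ftc <- do.call(rbind, clones)
  fit0 <- suppressMessages(fit_treatment_lmm(ftc))
  expect_true(all(abs(fit0$contrasts$estimate) < 1e-10))
  expect_true(all(fit0$contrasts$p.value > 0.999))
})

test_that("staged interaction models run and Levene reads variances", {
  ind <- simulate_individuals(n_per_cell = 4, seed = 92)
  mult <- ifelse(ind$sex == "M", 1.8, 1.0)
  m <- simulate_bilateral(ind, trait_spec("a2", fa_sd = 0.01,
                                          me_sd = 0.002),
                          seed = 93, fa_sd_multiplier = mult)
  ft <- fa_index_table(carabid_dataset(ind, m), ind$species[1], "a2")
  im <- fit_interaction_models(ft)
  expect_false(is.null(im$stage1))
  expect_false(is.null(im$stage2))
  s3terms <- im$stage3$term
  expect_true("sex" %in% s3terms || "sex:treatment" %in% s3terms)
  sexp <- im$stage3$`Pr(>Chisq)`[im$stage3$term == "sex"]
  expect_lt(sexp, 0.05)
  expect_true(im$levene$p >= 0 && im$levene$p <= 1)
})

test_that("Kendall concordance matches closed forms and guards", {
  ranks <- 1:12
  M <- cbind(t1 = ranks, t2 = ranks, t3 = ranks)
  kc <- kendall_concordance(M)
  expect_equal(kc$W, 1, tolerance = 1e-12)
  expect_lt(kc$p, 0.001)

  set.seed(94)
  Mr <- cbind(t1 = sample(30), t2 = sample(30), t3 = sample(30))
  kr <- kendall_concordance(Mr, n_tests = 4)
  expect_lt(kr$W, 0.4)
  expect_equal(kr$p_bonf, min(1, kr$p * 4))
  expect_gte(kr$p_bonf, kr$p)

  expect_message(k2 <- kendall_concordance(M[, 1:2]), "fewer than 3")
  expect_null(k2)
})

test_that("the environmental Bayesian model recovers an injected litter effect", {
  sim <- simulate_community(community_spec(), seed = 95)
  env <- sim$environment
  ind <- simulate_individuals(n_per_cell = 10, seed = 96)  # 360
  key <- paste0(ind$site_id, "_M", ind$month)
  lit_z <- as.numeric(scale(env$litter))[match(key, env$sample_id)]
  mult <- pmax(0.2, 1 + 1.5 * lit_z)
  m <- simulate_bilateral(ind, trait_spec("a2", fa_sd = 0.012,
                                          me_sd = 0.002),
                          seed = 97, fa_sd_multiplier = mult)
  ft <- fa_index_table(carabid_dataset(ind, m), ind$species[1], "a2")
  # a reduced predictor set: the full seven are strongly collinear by
  # design (all track the canopy gradient), which shares the credit and
  # is exercised by the pipeline tests instead
  fit <- suppressWarnings(
    fit_env_bglm(ft, env, env_vars = c("litter", "collembola",
                                       "air_temp", "soil_moisture"),
                 chains = 2, iter = 2000, seed = 98))
  cf <- fit$posterior$coefficients
  lit <- cf[cf$term == "litter", ]
  expect_gt(lit$mean, 0)
  expect_gte(lit$p_positive, 0.95)
  expect_true(fit$posterior$loo$pct_k_ok >= 0 &&
                fit$posterior$loo$pct_k_ok <= 100)
})
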