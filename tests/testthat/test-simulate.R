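test_that("the individual generator fills the design deterministically", {
  ind <- simulate_individuals(n_per_cell = 1, seed = 4)
  expect_equal(nrow(ind), 3 * 6 * 2)
  expect_setequal(unique(ind$treatment),
                  c("clearing", "control", "ecotone"))
  ind2 <- simulate_individuals(n_per_cell = 1, seed = 4)
  expect_identical(ind, ind2)

  flat <- simulate_individuals(n_per_cell = 2, body_size_cv = 0, seed = 4)
  expect_equal(var(flat$body_size), 0)
  expect_true(all(flat$body_size == 3.5))

  expect_equal(nrow(simulate_individuals(n_per_cell = 0, seed = 1)), 0L)
})

test_that("zero measurement noise makes replicates identical", {
  spec <- trait_spec("a2", fa_sd = 0.01, me_sd = 0)
  d <- make_cohort(spec, n = 36, seed = 2)
  m <- d$measurements
  w <- reshape(m, idvar = c("individual_id", "side"),
               timevar = "replicate", direction = "wide")
  expect_equal(w$value.1, w$value.2, tolerance = 1e-15)
})

test_that("a pure directional shift reproduces exactly with no noise", {
  spec <- trait_spec("a2", fa_sd = 0, da_shift = 0.1, antisym_amp = 0,
                     me_sd = 0)
  ind <- simulate_individuals(n_per_cell = 28, seed = 5)  # ~1000
  m <- simulate_bilateral(ind, spec, seed = 6)
  av <- asymmetry_table(carabid_dataset(ind, m), ind$species[1], "a2")
  expect_equal(mean(av$R - av$L), 0.1, tolerance = 1e-12)
})

test_that("the antisymmetry mixture is platykurtic at the closed-form value", {
  # kurtosis of a +/-a two-point mixture is 1 (excess -2); with light
  # noise the sample excess should sit far below 0
  spec <- trait_spec("a2", fa_sd = 0, da_shift = 0, antisym_amp = 0.2,
                     me_sd = 1e-4)
  ind <- simulate_individuals(n_per_cell = 28, seed = 7)
  m <- simulate_bilateral(ind, spec, seed = 8)
  av <- asymmetry_table(carabid_dataset(ind, m), ind$species[1], "a2")
  diff <- av$R - av$L
  expect_lt(e1071::kurtosis(diff, type = 1), -1.8)
  expect_gt(min(abs(diff)), 0.19)  # bimodal at +/- 0.2
})

test_that("sample moments of R - L match the generative model", {
  spec <- trait_spec("a2", fa_sd = 0.01, da_shift = 0.005,
                     antisym_amp = 0.008, me_sd = 0.004)
  ind <- simulate_individuals(n_per_cell = 56, seed = 9)  # ~2000
  m <- simulate_bilateral(ind, spec, seed = 10)
  av <- asymmetry_table(carabid_dataset(ind, m), ind$species[1], "a2")
  diff <- av$R - av$L
  n <- length(diff)
  # mean within 3 SE of the directional shift
  sd_expect <- sqrt(spec$fa_sd^2 + spec$antisym_amp^2 + spec$me_sd^2)
  expect_lt(abs(mean(diff) - 0.005), 3 * sd_expect / sqrt(n))
  # variance of the replicate-averaged difference:
  # fa^2 + a^2 + me^2 (each side averages two replicates)
  expect_equal(var(diff), sd_expect^2, tolerance = 0.12)
  # replicate differences within (individual, side) have variance 2 me^2
  w <- reshape(m, idvar = c("individual_id", "side"),
               timevar = "replicate", direction = "wide")
  expect_equal(var(w$value.1 - w$value.2), 2 * spec$me_sd^2,
               tolerance = 0.12)
})

test_that("negative lengths are resampled away", {
  spec <- trait_spec("a2", base_size = 0.01, fa_sd = 0.0, me_sd = 0.02)
  ind <- simulate_individuals(n_per_cell = 1, seed = 11)
  m <- simulate_bilateral(ind, spec, seed = 12)
  expect_true(all(m$value > 0))
  expect_gt(attr(m, "n_resampled"), 0)
})

test_that("community generator honours the association contract", {
  # association 0: per-species expected abundance equal across samples
  sim0 <- simulate_community(community_spec(association = 0,
                                            abundance_scale = 30),
                             seed = 13)
  cv <- apply(sim0$community, 2, function(x) var(x) / mean(x))
  # Poisson with constant mean: variance/mean ratio near 1
  expect_lt(median(cv), 1.6)

  # strong association to herbs: abundance tracks the herb gradient
  sim1 <- simulate_community(
    community_spec(association = 2, gradient_vars = "herbs",
                   abundance_scale = 10), seed = 14)
  z <- sim1$environment$herbs
  cors <- apply(sim1$community, 2, function(x)
    suppressWarnings(cor(x, z, method = "spearman")))
  expect_gt(max(abs(cors), na.rm = TRUE), 0.5)

  # single species, single sample
  tiny <- simulate_community(
    community_spec(n_species = 1, n_sites_per_treatment = 1,
                   n_months = 1), seed = 15)
  expect_equal(dim(tiny$community), c(3, 1))  # one site per treatment

  # every community species has an identity-trait row
  expect_setequal(colnames(sim1$community), sim1$species_traits$species)
})

test_that("the archetype suite is pure by construction and reproducible", {
  card <- archetype_card()
  expect_identical(card$DA$da_shift, 2 * card$DA$fa_sd)
  expect_equal(card$true_FA$da_shift, 0)
  expect_equal(card$true_FA$antisym_amp, 0)
  expect_gt(card$ME_dominated$me_sd, 3 * card$ME_dominated$fa_sd)

  s1 <- make_archetype_suite(seed = 1)
  s2 <- make_archetype_suite(seed = 1)
  expect_identical(s1, s2)
  expect_setequal(names(s1), c("true_FA", "DA", "antisymmetry",
                               "ME_dominated", "size_dependent"))
  expect_identical(s1$DA$truth, "DA")
})

test_that("seed fan-out is deterministic and in integer range", {
  expect_identical(fan_seed(1, 5), fan_seed(1, 5))
  expect_false(fan_seed(1, 5) == fan_seed(1, 6))
  s <- vapply(1:50, function(k) fan_seed(123456, k), integer(1))
  expect_true(all(s > 0 & s < 2^31))
})
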