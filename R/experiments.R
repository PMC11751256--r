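# Seeded simulation experiments that quantify the pipeline's operating
# characteristics: gating verdict recovery on the archetype suite,
# type-I calibration of the component tests, and parameter recovery of
# the mixed and Bayesian models. Used by the test suite and by
# scripts/acceptance.R.

# Replicate seeds are drawn from a master Mersenne-Twister stream rather
# than derived arithmetically: consecutive LCG-style seeds can leave
# faint correlations between replicate streams.
.child_seeds <- function(seed, n) {
  .with_seed(seed, sample.int(2147483645L, n))
}

#' Gating verdict recovery on the archetype suite
#'
#' Replicates the shipped archetype suite (`n_reps` independent seeded
#' datasets per suitability class), runs [assess_trait()] on each cohort
#' and scores the verdict against the generative truth.
#'
#' @param seed integer seed.
#' @param n_reps replicates per class.
#' @param n_individuals cohort size.
#' @param alpha gating significance level.
#' @return list with `overall` accuracy (fraction), `per_class` named
#'   vector, and the replicate-level `table`.
#' @export
gating_recovery <- function(seed = 1, n_reps = 200, n_individuals = 60,
                            alpha = 0.05) {
  child <- .child_seeds(seed, n_reps)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    suite <- make_archetype_suite(seed = child[r],
                                  n_individuals = n_individuals)
    rows[[r]] <- do.call(rbind, lapply(suite, function(a) {
      d <- carabid_dataset(a$individuals, a$measurements)
      ta <- assess_trait(d, a$individuals$species[1], "a2", alpha = alpha)
      data.frame(truth = a$truth, verdict = ta$verdict, rep = r,
                 stringsAsFactors = FALSE)
    }))
  }
  tab <- do.call(rbind, rows)
  tab$correct <- tab$truth == tab$verdict
  per_class <- tapply(tab$correct, tab$truth, mean)
  list(overall = mean(tab$correct),
       per_class = per_class[names(archetype_card())], table = tab)
}

#' Empirical type-I error of the screening and permutation tests
#'
#' Simulates data under the corresponding null hypothesis through the
#' package's own generators and records the rejection rate of each test
#' at level `alpha`:
#' \describe{
#'   \item{da}{one-sample t on signed asymmetries with no directional
#'     shift}
#'   \item{antisymmetry}{platykurtosis test on Gaussian asymmetries}
#'   \item{size}{regression of |R - L| on body size with zero slope}
#'   \item{levene}{variance homogeneity across sex x treatment groups of
#'     identically distributed FA values}
#'   \item{permutation}{cyclic-shift restricted pseudo-F of an
#'     environmental variable unrelated to the community}
#' }
#'
#' @param test which null to calibrate.
#' @param seed integer seed.
#' @param n_reps null replicates.
#' @param n cohort size (individuals) for the asymmetry tests.
#' @param alpha nominal level.
#' @param n_perm permutations for the restricted test.
#' @return list with `rate` (empirical type-I error), `n_reps`, and the
#'   vector of p-values.
#' @export
calibrate_type1 <- function(test = c("da", "antisymmetry", "size",
                                     "levene", "permutation"),
                            seed = 1, n_reps = 500, n = 50, alpha = 0.05,
                            n_perm = 199) {
  test <- match.arg(test)
  null_spec <- trait_spec("a2", fa_sd = 0.01, da_shift = 0,
                          antisym_amp = 0, me_sd = 0.002,
                          size_dep_slope = 0)
  child <- .child_seeds(seed, n_reps)
  pvals <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    s_r <- child[r]
    if (test %in% c("da", "antisymmetry", "size")) {
      ind <- simulate_individuals(n_per_cell = ceiling(n / 36),
                                  seed = s_r)
      ind <- ind[seq_len(n), ]
      m <- simulate_bilateral(ind, null_spec, seed = fan_seed(s_r, 2))
      av <- asymmetry_table(carabid_dataset(ind, m), ind$species[1], "a2")
      pvals[r] <- switch(test,
        da = test_directional_asymmetry(av$s, alpha)$p,
        antisymmetry = test_antisymmetry(av$s, alpha)$p,
        size = test_size_dependence(av$abs_diff, av$body_size, alpha)$p)
    } else if (test == "levene") {
      ind <- simulate_individuals(n_per_cell = 2, seed = s_r)  # 72
      m <- simulate_bilateral(ind, null_spec, seed = fan_seed(s_r, 2))
      ft <- fa_index_table(carabid_dataset(ind, m), ind$species[1], "a2")
      per_ind <- ft[!duplicated(ft$individual_id), ]
      grp <- interaction(per_ind$sex, per_ind$treatment, drop = TRUE)
      lev <- car::leveneTest(abs(per_ind$fa_individual), grp,
                             center = stats::median)
      pvals[r] <- lev$`Pr(>F)`[1]
    } else {
      sim <- simulate_community(
        community_spec(n_species = 8, n_sites_per_treatment = 1,
                       association = 0, abundance_scale = 5),
        seed = s_r)
      Ytr <- transform_abundances(sim$community)
      X <- sim$environment[, "herbs", drop = FALSE]
      blocks <- sub("_M[0-9]+$", "", rownames(sim$community))
      ord <- fit_pcca(Ytr, X)
      pvals[r] <- restricted_permutation_test(
        ord, blocks, n_perm = n_perm, seed = fan_seed(s_r, 3))$p
    }
  }
  list(rate = mean(pvals < alpha), n_reps = n_reps, pvals = pvals)
}

#' Fixed-effect recovery of the head-width mixed model
#'
#' Repeatedly simulates the study design with a known body-size slope,
#' fits the head-width LMM and records how often the estimate falls
#' within `band` of the truth.
#'
#' @param seed integer seed.
#' @param n_reps replicates.
#' @param beta_size true slope per body-size SD.
#' @param n_individuals individuals per replicate.
#' @param band half-width of the recovery band.
#' @return list with `rate`, `estimates`, `n_individuals`.
#' @export
lmm_recovery <- function(seed = 1, n_reps = 200, beta_size = 0.3,
                         n_individuals = 300, band = 0.05) {
  child <- .child_seeds(seed, n_reps)
  est <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    s_r <- child[r]
    ind <- simulate_individuals(n_per_cell = ceiling(n_individuals / 36),
                                seed = s_r)
    ind <- ind[seq_len(n_individuals), ]
    hw <- simulate_headwidth(ind, beta_size = beta_size, sd_month = 0.02,
                             sd_ind = 0.03, sd_resid = 0.03,
                             seed = fan_seed(s_r, 2))
    d <- carabid_dataset(ind, hw)
    fit <- suppressMessages(suppressWarnings(fit_headwidth_lmm(d)))
    est[r] <- lme4::fixef(fit$fit)[["size_z"]]
  }
  list(rate = mean(abs(est - beta_size) <= band), estimates = est,
       n_individuals = n_individuals)
}

#' Credible-interval coverage for null coefficients
#'
#' Simulates Gaussian regressions whose non-intercept coefficients are
#' all zero, fits the Bayesian model and records how often each 95%
#' credible interval covers zero.
#'
#' @param seed integer seed.
#' @param n_reps replicates.
#' @param n observations per replicate.
#' @param n_null null coefficients per replicate.
#' @param chains,iter MCMC settings per fit.
#' @return list with `coverage` (fraction over `n_reps * n_null`
#'   intervals) and `n_checks`.
#' @export
bayes_null_coverage <- function(seed = 1, n_reps = 60, n = 150,
                                n_null = 3, chains = 2, iter = 1500) {
  child <- .child_seeds(seed, n_reps)
  hits <- logical(0)
  for (r in seq_len(n_reps)) {
    s_r <- child[r]
    X <- .with_seed(s_r, {
      M <- cbind(1, matrix(rnorm(n * n_null), n, n_null))
      colnames(M) <- c("(Intercept)", paste0("x", seq_len(n_null)))
      M
    })
    y <- .with_seed(fan_seed(s_r, 2), 0.5 + rnorm(n, 0, 0.5))
    post <- fit_bglm(y, X, chains = chains, iter = iter,
                     seed = fan_seed(s_r, 3))
    cf <- post$coefficients[-1, ]   # null coefficients only
    hits <- c(hits, cf$l95 <= 0 & cf$u95 >= 0)
  }
  list(coverage = mean(hits), n_checks = length(hits))
}
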