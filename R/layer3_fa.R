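# Layer 3: fluctuating asymmetry. The index is the signed relative side
# difference centred on its cohort mean (a directional-asymmetry
# correction); a gating procedure screens each species x trait cohort for
# measurement-error dominance, antisymmetry, directional asymmetry and
# size-dependent asymmetry before any FA inference.

#' Signed relative asymmetry
#'
#' `s = (R - L) / (0.5 * (L + R))`: the side difference scaled by trait
#' size, hence dimensionless, antisymmetric under side swap and invariant
#' under a uniform rescaling of all lengths (mm vs cm). Undefined
#' (missing) when `L + R` is not positive.
#'
#' @param R,L right and left replicate-averaged lengths (mm).
#' @return numeric vector of s.
#' @export
signed_relative_asymmetry <- function(R, L) {
  s <- (R - L) / (0.5 * (L + R))
  s[!is.finite(s) | (L + R) <= 0] <- NA_real_
  s
}

#' Build the per-individual asymmetry table for one species x trait
#'
#' Averages the two replicates per side, then computes the signed
#' relative asymmetry and |R - L|, joined with the individual
#' descriptors. Per-replicate values of s (used as the modelling response
#' so that individual can serve as the replicate grouping factor) are
#' attached as `s_rep1`/`s_rep2`.
#'
#' @param dataset a `carabid_dataset`.
#' @param species,trait cohort selectors.
#' @return data frame, one row per individual with both sides present.
#' @export
asymmetry_table <- function(dataset, species, trait) {
  ind <- dataset$individuals[dataset$individuals$species == species, ]
  m <- dataset$measurements
  m <- m[m$individual_id %in% ind$individual_id & m$trait == trait, ]
  if (nrow(m) == 0)
    return(data.frame())
  wide <- stats::reshape(
    stats::aggregate(value ~ individual_id + side, data = m, FUN = mean),
    idvar = "individual_id", timevar = "side", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  if (!all(c("L", "R") %in% names(wide))) return(data.frame())
  wide <- wide[complete.cases(wide[, c("L", "R")]), ]
  byrep <- stats::reshape(m[, c("individual_id", "replicate", "side",
                                "value")],
                          idvar = c("individual_id", "replicate"),
                          timevar = "side", direction = "wide")
  names(byrep) <- sub("^value\\.", "", names(byrep))
  srep <- do.call(rbind, lapply(split(byrep, byrep$individual_id),
    function(b) {
      b <- b[order(b$replicate), ]
      data.frame(individual_id = b$individual_id[1],
                 s_rep1 = if (nrow(b) >= 1 && !is.na(b$L[1]) &&
                                !is.na(b$R[1]))
                   signed_relative_asymmetry(b$R[1], b$L[1]) else NA_real_,
                 s_rep2 = if (nrow(b) >= 2 && !is.na(b$L[2]) &&
                                !is.na(b$R[2]))
                   signed_relative_asymmetry(b$R[2], b$L[2]) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  out <- merge(wide, srep, by = "individual_id")
  out$s <- signed_relative_asymmetry(out$R, out$L)
  out$abs_diff <- abs(out$R - out$L)
  out <- merge(out, ind, by = "individual_id")
  out$species_trait <- paste(species, trait, sep = ":")
  out$trait <- trait
  out
}

#' Directional-asymmetry corrected FA index
#'
#' For a cohort of N individuals of one species x trait,
#' `FA_corrected_i = s_i - sum(s) / N`: the signed relative asymmetry
#' minus the cohort mean, which removes any directional component. The
#' corrected values sum to zero by construction. Magnitude transforms
#' (`|.|` or squared) of the corrected index are what stress models use.
#'
#' @param s signed relative asymmetries of the cohort.
#' @param min_n minimum cohort size.
#' @return list with `fa` (corrected values), `da_term` (the subtracted
#'   cohort mean), `n`, `low_n`.
#' @export
corrected_fa <- function(s, min_n = 5) {
  s <- s[is.finite(s)]
  n <- length(s)
  if (n < min_n)
    return(list(fa = NULL, da_term = NA_real_, n = n, low_n = TRUE))
  da <- mean(s)
  list(fa = s - da, da_term = da, n = n, low_n = FALSE)
}

#' One-sample t-test for directional asymmetry
#'
#' Two-sided test of mean(s) = 0 on the uncorrected signed relative
#' asymmetries (the corrected index has mean zero by construction, so
#' testing it would be vacuous). A significant mean flags the trait as
#' biased by directional asymmetry and excludes it from FA inference.
#'
#' @param s uncorrected signed relative asymmetries.
#' @param alpha flag level.
#' @return list with `t`, `p`, `mean_s`, `flag`.
#' @export
test_directional_asymmetry <- function(s, alpha = 0.05) {
  s <- s[is.finite(s)]
  if (sd(s) == 0) {
    p <- if (mean(s) != 0) 0 else 1
    message("zero-variance cohort in DA test")
    return(list(t = if (mean(s) != 0) Inf else 0, p = p,
                mean_s = mean(s), flag = p < alpha))
  }
  tt <- t.test(s, mu = 0)
  list(t = unname(tt$statistic), p = tt$p.value, mean_s = mean(s),
       flag = tt$p.value < alpha)
}

#' Platykurtosis test for antisymmetry
#'
#' Antisymmetry (either side consistently larger, at random) produces a
#' bimodal, platykurtic distribution of the signed asymmetry. The flag
#' fires when the Anscombe-Glynn kurtosis test is significantly below
#' normal (one-sided).
#'
#' @param s signed relative asymmetries, `n >= 10`.
#' @param alpha flag level.
#' @return list with `excess` kurtosis, `z`, `p`, `flag` (`NA` verdict
#'   for degenerate or too-small cohorts).
#' @export
test_antisymmetry <- function(s, alpha = 0.05) {
  s <- s[is.finite(s)]
  if (length(s) < 10) {
    warning("n < 10: no antisymmetry verdict")
    return(list(excess = NA_real_, z = NA_real_, p = NA_real_, flag = NA))
  }
  if (sd(s) == 0) {
    return(list(excess = NA_real_, z = NA_real_, p = NA_real_, flag = NA))
  }
  kt <- kurtosis_test(s, alternative = "less")
  list(excess = kt$excess, z = kt$z, p = kt$p, flag = kt$p < alpha)
}

#' Regression test of size-dependent asymmetry
#'
#' One-way regression ANOVA of `|R - L|` on body size (right-elytron
#' length). A significant slope does not exclude the trait; it requires
#' body size as a covariate in the downstream FA models.
#'
#' @param abs_diff absolute side differences (mm).
#' @param body_size body sizes (mm).
#' @param alpha flag level.
#' @return list with `F`, `p`, `slope`, `flag`.
#' @export
test_size_dependence <- function(abs_diff, body_size, alpha = 0.05) {
  ok <- is.finite(abs_diff) & is.finite(body_size)
  abs_diff <- abs_diff[ok]; body_size <- body_size[ok]
  if (sd(body_size) == 0) {
    warning("constant body size: size-dependence untestable")
    return(list(F = NA_real_, p = NA_real_, slope = NA_real_, flag = NA))
  }
  if (sd(abs_diff) == 0) {
    return(list(F = 0, p = 1, slope = 0, flag = FALSE))
  }
  fit <- stats::lm(abs_diff ~ body_size)
  a <- anova(fit)
  list(F = a$`F value`[1], p = a$`Pr(>F)`[1],
       slope = unname(coef(fit)[2]), flag = a$`Pr(>F)`[1] < alpha)
}

#' Combine component tests into a trait suitability verdict
#'
#' Precedence: `ME_dominated` > `antisymmetry` > `DA` > `size_dependent`
#' > `true_FA`. Measurement-error dominance, antisymmetry and directional
#' asymmetry each exclude the trait; a size-dependent trait proceeds to
#' modelling with body size as covariate, as does a clean `true_FA`
#' trait. Cohorts below the minimum size get verdict `low_n`.
#'
#' @param me an `me_assessment` (or `NULL` to skip the ME gate).
#' @param da,anti,size component test results.
#' @param n cohort size.
#' @param min_n minimum cohort size.
#' @return verdict string.
#' @export
classify_trait <- function(me, da, anti, size, n, min_n = 5) {
  if (n < min_n || (!is.null(me) && isTRUE(me$low_n))) return("low_n")
  if (!is.null(me) && identical(me$resolvable, FALSE)) return("ME_dominated")
  if (isTRUE(anti$flag)) return("antisymmetry")
  if (isTRUE(da$flag)) return("DA")
  if (isTRUE(size$flag)) return("size_dependent")
  "true_FA"
}

#' Full suitability assessment of one species x trait cohort
#'
#' Runs the measurement-error ANOVA, the directional-asymmetry t-test,
#' the antisymmetry (platykurtosis) test and the size-dependence
#' regression on the cohort and combines them with [classify_trait()].
#'
#' @param dataset a `carabid_dataset`.
#' @param species,trait cohort selectors.
#' @param alpha significance level shared by the component tests.
#' @param min_n minimum cohort size for a verdict.
#' @param outlier_screen apply the iterative Grubbs screen to the signed
#'   asymmetries before testing.
#' @return a `trait_assessment` (single-row data frame): verdict plus all
#'   component statistics.
#' @export
assess_trait <- function(dataset, species, trait, alpha = 0.05, min_n = 5,
                         outlier_screen = FALSE) {
  av <- asymmetry_table(dataset, species, trait)
  n <- nrow(av)
  if (n < min_n) {
    return(data.frame(species = species, trait = trait, n = n,
                      verdict = "low_n", da_t = NA, da_p = NA,
                      kurtosis_excess = NA, anti_p = NA, size_F = NA,
                      size_p = NA, me_F = NA, me_p = NA, pct_me = NA,
                      n_outliers_removed = 0L, stringsAsFactors = FALSE))
  }
  if (outlier_screen) {
    keep <- remove_outliers(av$s, alpha = alpha)
    n_out <- attr(keep, "n_removed")
    av <- av[keep, ]
  } else n_out <- 0L
  mrows <- dataset$measurements
  mrows <- mrows[mrows$individual_id %in% av$individual_id &
                   mrows$trait == trait, ]
  me <- suppressWarnings(assess_measurement_error(mrows, alpha = alpha))
  da <- test_directional_asymmetry(av$s, alpha = alpha)
  anti <- suppressWarnings(test_antisymmetry(av$s, alpha = alpha))
  size <- suppressWarnings(
    test_size_dependence(av$abs_diff, av$body_size, alpha = alpha))
  verdict <- classify_trait(me, da, anti, size, n = nrow(av),
                            min_n = min_n)
  data.frame(species = species, trait = trait, n = nrow(av),
             verdict = verdict, da_t = da$t, da_p = da$p,
             kurtosis_excess = anti$excess, anti_p = anti$p,
             size_F = size$F, size_p = size$p,
             me_F = me$F_signal, me_p = me$p_signal, pct_me = me$pct_me,
             n_outliers_removed = n_out, stringsAsFactors = FALSE)
}

#' FA index table for modelling
#'
#' Per-replicate rows of the corrected index (the DA term is the cohort
#' mean of the replicate-averaged asymmetries), so that individual is an
#' estimable random-effect grouping for the two measurement replicates,
#' together with the chosen magnitude transform and the individual
#' descriptors.
#'
#' @param dataset a `carabid_dataset`.
#' @param species,trait cohort selectors.
#' @param magnitude `"abs"`, `"square"` or `"signed"` transform for the
#'   modelled response `fa_mag`.
#' @param min_n minimum cohort size.
#' @return data frame with columns `fa` (signed corrected index per
#'   replicate), `fa_mag`, `replicate`, descriptors; `NULL` if the cohort
#'   is too small.
#' @export
fa_index_table <- function(dataset, species, trait,
                           magnitude = c("abs", "square", "signed"),
                           min_n = 5) {
  magnitude <- match.arg(magnitude)
  av <- asymmetry_table(dataset, species, trait)
  cf <- corrected_fa(av$s, min_n = min_n)
  if (cf$low_n) return(NULL)
  long <- rbind(
    data.frame(av, replicate = 1L, s_rep = av$s_rep1,
               stringsAsFactors = FALSE),
    data.frame(av, replicate = 2L, s_rep = av$s_rep2,
               stringsAsFactors = FALSE))
  long <- long[is.finite(long$s_rep), ]
  long$fa <- long$s_rep - cf$da_term
  long$fa_mag <- switch(magnitude, abs = abs(long$fa),
                        square = long$fa^2, signed = long$fa)
  long$fa_individual <- long$s - cf$da_term
  long$size_z <- as.numeric(scale(long$body_size))
  attr(long, "da_term") <- cf$da_term
  long
}

.fa_lmm <- function(formula_fixed, fa_tab) {
  form <- as.formula(paste("fa_mag ~", formula_fixed,
                           "+ (1 | month) + (1 | individual_id)"))
  suppressMessages(lme4::lmer(form, data = fa_tab, REML = TRUE))
}

#' Mixed model of FA on treatment with Tukey contrasts
#'
#' FA magnitude on treatment (plus body size when the trait is
#' size-dependent), with random intercepts for collection month and for
#' individual (grouping the two measurement replicates). Treatment is
#' tested with a type-II Wald chi-squared ANOVA; pairwise treatment
#' differences are least-squares means with Tukey adjustment.
#'
#' @param fa_tab table from [fa_index_table()].
#' @param include_size include standardised body size as covariate.
#' @return list with `fit`, `wald`, `lsmeans`, `contrasts`
#'   (Tukey-adjusted), pseudo-R2 components.
#' @export
fit_treatment_lmm <- function(fa_tab, include_size = FALSE) {
  fa_tab$treatment <- factor(fa_tab$treatment)
  small <- names(which(table(fa_tab$treatment[!duplicated(
    fa_tab$individual_id)]) < 2))
  if (length(small) > 0)
    warning("treatment level(s) with n < 2 individuals: ",
            paste(small, collapse = ", "),
            "; contrasts involving them are unreliable")
  fe <- if (include_size) "treatment + size_z" else "treatment"
  fit <- .fa_lmm(fe, fa_tab)
  wald <- car::Anova(fit, type = 2)
  em <- emmeans::emmeans(fit, "treatment")
  ct <- summary(emmeans::contrast(em, method = "pairwise",
                                  adjust = "tukey"))
  r2 <- pseudo_r2(fit)
  list(fit = fit,
       wald = data.frame(term = rownames(wald), wald, row.names = NULL,
                         check.names = FALSE),
       lsmeans = summary(em), contrasts = ct,
       r2_marginal = r2$marginal, r2_conditional = r2$conditional)
}

#' Staged wing x sex x treatment models of FA with Levene check
#'
#' Fits the study's model sequence on the FA magnitude: (i) wing-morph
#' score crossed with sex, (ii) treatment crossed with wing-morph score,
#' (iii) the final model combining both interactions plus sex x
#' treatment. Each stage is a mixed model (month and individual random
#' intercepts) reported as a Wald chi-squared table. Homogeneity of FA
#' variance across sex x treatment groups is checked with Levene's test
#' (median-centred).
#'
#' @param fa_tab table from [fa_index_table()].
#' @return list of per-stage Wald tables (`stage1`, `stage2`, `stage3`),
#'   the fitted stage-3 model, and `levene` (`F`, `p`).
#' @export
fit_interaction_models <- function(fa_tab) {
  fa_tab$sex <- factor(fa_tab$sex)
  fa_tab$treatment <- factor(fa_tab$treatment)
  cell <- table(fa_tab$sex, fa_tab$treatment)
  if (any(cell == 0))
    warning("empty sex x treatment cell(s); the sex:treatment ",
            "interaction is estimated on the remaining cells")
  stages <- list(
    stage1 = "wing_score * sex",
    stage2 = "treatment * wing_score",
    stage3 = "wing_score:sex + treatment:wing_score + sex * treatment + wing_score")
  fits <- lapply(stages, function(fe)
    tryCatch(.fa_lmm(fe, fa_tab), error = function(e) NULL))
  tabs <- lapply(fits, function(f) {
    if (is.null(f)) return(NULL)
    w <- car::Anova(f, type = 2)
    data.frame(term = rownames(w), w, row.names = NULL,
               check.names = FALSE)
  })
  # Levene on per-individual values: the two replicate rows of an
  # individual are not independent units
  per_ind <- fa_tab[!duplicated(fa_tab$individual_id), ]
  v <- abs(per_ind$fa_individual)
  grp <- interaction(per_ind$sex, per_ind$treatment, drop = TRUE)
  lev <- car::leveneTest(v, grp, center = stats::median)
  list(stage1 = tabs$stage1, stage2 = tabs$stage2, stage3 = tabs$stage3,
       fit_final = fits$stage3,
       levene = list(F = lev$`F value`[1], p = lev$`Pr(>F)`[1]))
}

#' Kendall concordance of FA trends across traits
#'
#' When a species shows true FA in three or more traits, agreement of the
#' per-individual FA magnitude rankings across traits is tested with
#' Kendall's coefficient of concordance W (via [vegan::kendall.global()],
#' complete cases only), with Bonferroni correction over the number of
#' species tested.
#'
#' @param fa_by_trait individuals x traits matrix of FA magnitudes.
#' @param n_tests number of species tested (Bonferroni denominator).
#' @return list with `W`, `chi2`, `F`, `p` (F-test), `p_bonf`, `n`,
#'   `n_traits`; `NULL` (with a message) when fewer than 3 traits.
#' @export
kendall_concordance <- function(fa_by_trait, n_tests = 1) {
  M <- as.matrix(fa_by_trait)
  M <- M[complete.cases(M), , drop = FALSE]
  if (ncol(M) < 3) {
    message("fewer than 3 true-FA traits: concordance skipped")
    return(NULL)
  }
  kg <- vegan::kendall.global(M)
  ca <- kg$Concordance_analysis
  W <- ca["W", 1]
  list(W = W, chi2 = ca["Chi2", 1], F = ca["F", 1],
       p = ca["Prob.F", 1], p_bonf = min(1, ca["Prob.F", 1] * n_tests),
       n = nrow(M), n_traits = ncol(M))
}

#' Bayesian model of FA against environmental factors
#'
#' Joins the FA table to the sample environment via site x month, fits a
#' Bayesian Gaussian regression of the FA magnitude on the standardised
#' environmental predictors (Formica and Collembola activity, litter,
#' canopy openness, herb cover, air temperature, soil moisture by
#' default) with random intercepts for month, individual (replicate
#' grouping) and sex. 4 chains x 4000 iterations; convergence accepted at
#' R-hat < 1.2; PSIS-LOO and the % of observations with reliable
#' Pareto k are reported. An effect is called significant when its 95%
#' credible interval excludes zero.
#'
#' @param fa_tab table from [fa_index_table()].
#' @param env environment table (one row per sample).
#' @param env_vars predictors to include.
#' @param chains,iter,seed MCMC settings.
#' @param rhat_threshold convergence threshold (study level: 1.2).
#' @return list with the `posterior_summary` and the joined model frame.
#' @export
fit_env_bglm <- function(fa_tab, env,
                         env_vars = c("formica", "collembola", "litter",
                                      "canopy_openness", "herbs",
                                      "air_temp", "soil_moisture"),
                         chains = 4, iter = 4000, seed = 1,
                         rhat_threshold = 1.2) {
  fa_tab$sample_id <- paste0(fa_tab$site_id, "_M", fa_tab$month)
  dat <- merge(fa_tab, env[, c("sample_id", env_vars)], by = "sample_id")
  if (nrow(dat) == 0) stop("no FA rows could be joined to environment ",
                           "samples (site x month keys)")
  X <- cbind(`(Intercept)` = 1,
             sapply(env_vars, function(v) as.numeric(scale(dat[[v]]))))
  post <- fit_bglm(dat$fa_mag, X,
                   groups = list(month = dat$month,
                                 individual = dat$individual_id,
                                 sex = dat$sex),
                   chains = chains, iter = iter, seed = seed,
                   rhat_threshold = rhat_threshold)
  list(posterior = post, data = dat)
}
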