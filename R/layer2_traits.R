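# Layer 2: trait screening and head-width models.

#' Sides x individuals measurement-error ANOVA
#'
#' Two-way mixed ANOVA on the replicated measurements of one species x
#' trait (sides fixed, individuals random, side x individual interaction
#' random). The asymmetry signal is deemed resolvable when the
#' side x individual mean square significantly exceeds the replicate
#' error mean square (F-test): only then is between-side variation
#' interpretable above measurement noise.
#'
#' @param measurements measurement-format data frame (one species x
#'   trait, both sides, 2 replicates).
#' @param alpha significance level of the signal F-test.
#' @return an `me_assessment`: variance components (among-individual,
#'   side x individual, replicate error), `F_signal`, `p_signal`,
#'   `pct_me` (error variance as % of the between-sides variance pool),
#'   `resolvable`, `n`.
#' @export
assess_measurement_error <- function(measurements, alpha = 0.05) {
  m <- measurements
  stopifnot(all(c("individual_id", "side", "replicate", "value") %in%
                  names(m)))
  m <- m[m$side %in% c("L", "R"), ]
  ids <- unique(m$individual_id)
  n <- length(ids)
  low_n <- n < 5
  if (low_n)
    warning("fewer than 5 individuals: measurement-error assessment ",
            "emitted without verdict")
  m$individual_id <- factor(m$individual_id)
  m$side <- factor(m$side)
  a <- anova(stats::lm(value ~ side * individual_id, data = m))
  ms <- a$`Mean Sq`; names(ms) <- rownames(a)
  ms_side <- ms[["side"]]
  ms_ind <- ms[["individual_id"]]
  ms_si <- ms[["side:individual_id"]]
  ms_err <- ms[["Residuals"]]
  df_si <- a["side:individual_id", "Df"]
  df_err <- a["Residuals", "Df"]
  # variance components (2 replicates, 2 sides)
  var_err <- ms_err
  var_si <- max(0, (ms_si - ms_err) / 2)
  var_ind <- max(0, (ms_ind - ms_si) / 4)
  F_signal <- ms_si / ms_err
  p_signal <- pf(F_signal, df_si, df_err, lower.tail = FALSE)
  denom <- var_err + var_si
  structure(list(var_individual = var_ind, var_side_ind = var_si,
                 var_error = var_err,
                 pct_me = if (denom > 0) 100 * var_err / denom else NA_real_,
                 F_signal = F_signal, p_signal = p_signal,
                 resolvable = if (low_n) NA else p_signal < alpha,
                 ms = ms, n = n, low_n = low_n),
            class = "me_assessment")
}

#' Screen treatment variability of a trait
#'
#' One-way ANOVA of trait values across treatments; the screening
#' criterion retains traits whose values differ among treatments.
#'
#' @param values numeric trait values.
#' @param treatment treatment factor.
#' @param alpha significance level.
#' @return list with `F`, `p`, `varies`.
#' @export
screen_treatment_variability <- function(values, treatment, alpha = 0.05) {
  a <- anova(stats::lm(values ~ factor(treatment)))
  list(F = a$`F value`[1], p = a$`Pr(>F)`[1],
       varies = a$`Pr(>F)`[1] < alpha)
}

.headwidth_table <- function(dataset) {
  m <- dataset$measurements
  hw <- m[m$trait == "head_width", ]
  if (nrow(hw) == 0) stop("no head_width measurements in dataset")
  tab <- merge(hw, dataset$individuals, by = "individual_id")
  tab$size_z <- as.numeric(scale(tab$body_size))
  tab
}

#' Prestep predictor screen for the head-width model
#'
#' Fits the full fixed-effects model of head width on wing-morph score
#' (numeric 1-3), sex and standardised body size, and drops candidates
#' whose Wald p-value exceeds `alpha`. In the study this step removed
#' sex.
#'
#' @param dataset a `carabid_dataset` with head-width measurements.
#' @param alpha retention level.
#' @return list with `retained`, `dropped`, and the Wald `table`.
#' @export
prestep_screen <- function(dataset, alpha = 0.05) {
  tab <- .headwidth_table(dataset)
  fit <- stats::lm(value ~ wing_score + sex + size_z, data = tab)
  wt <- car::Anova(fit, type = 2)
  cand <- c("wing_score", "sex", "size_z")
  p <- wt[cand, "Pr(>F)"]
  names(p) <- cand
  retained <- cand[p <= alpha]
  list(retained = retained, dropped = setdiff(cand, retained),
       table = data.frame(term = cand, p = p, row.names = NULL))
}

#' Linear mixed model for head width
#'
#' Head width (replicate-level) on treatment, standardised body size and
#' wing-morph score (numeric covariate), with random intercepts for
#' collection month and for individual (the grouping of the two
#' measurement replicates). REML fit via [lme4::lmer()]; fixed effects
#' are tested with a type-II Wald chi-squared ANOVA. A singular
#' random-effect term is dropped with a flag and the model refitted.
#'
#' @param dataset a `carabid_dataset`.
#' @param predictors fixed-effect terms (defaults to the study's final
#'   set; pass the prestep's `retained` plus `treatment` to reproduce the
#'   screened model).
#' @return an `lmm_result`: `fit`, `fixed` (estimates and SEs), `wald`
#'   (chi-squared table), random-effect variances, Nakagawa
#'   marginal/conditional pseudo-R2, `singular_dropped`.
#' @export
fit_headwidth_lmm <- function(dataset,
                              predictors = c("treatment", "size_z",
                                             "wing_score")) {
  tab <- .headwidth_table(dataset)
  fe <- paste(predictors, collapse = " + ")
  form <- as.formula(paste("value ~", fe,
                           "+ (1 | month) + (1 | individual_id)"))
  fit <- lme4::lmer(form, data = tab, REML = TRUE)
  dropped <- character(0)
  if (lme4::isSingular(fit, tol = 1e-5)) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    zero_grp <- vc$grp[vc$vcov < 1e-10 & vc$grp != "Residual"]
    if (length(zero_grp) > 0) {
      keep_re <- setdiff(c("month", "individual_id"), zero_grp)
      dropped <- intersect(c("month", "individual_id"), zero_grp)
      form2 <- if (length(keep_re) > 0)
        as.formula(paste("value ~", fe,
                         paste0("+ (1 | ", keep_re, ")", collapse = "")))
      else NULL
      if (!is.null(form2)) fit <- lme4::lmer(form2, data = tab, REML = TRUE)
    }
  }
  wald <- car::Anova(fit, type = 2)
  sfit <- summary(fit)
  r2 <- pseudo_r2(fit)
  structure(list(fit = fit, fixed = coef(sfit),
                 wald = data.frame(term = rownames(wald), wald,
                                   row.names = NULL, check.names = FALSE),
                 ranef_var = as.data.frame(lme4::VarCorr(fit)),
                 r2_marginal = r2$marginal, r2_conditional = r2$conditional,
                 singular_dropped = dropped, data = tab),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat("linear mixed model (REML), n =", nrow(x$data), "\n")
  print(signif(x$fixed, 4))
  cat("Wald chi-squared (type II):\n")
  print(x$wald, row.names = FALSE)
  cat(sprintf("pseudo-R2: marginal %.3f, conditional %.3f\n",
              x$r2_marginal, x$r2_conditional))
  invisible(x)
}

#' Bayesian head-width model with wing x treatment structure
#'
#' Extends the head-width LMM with the wing-morph x treatment interaction
#' and fits it as a Bayesian Gaussian regression (JAGS; Gaussian priors,
#' 4 chains x 3000 iterations by default). Reports per-coefficient 95%
#' credible intervals, the posterior sign probability of each interaction
#' (its "reliability"), R-hat convergence and PSIS-LOO, plus a
#' conditional-effects grid of predicted head width over wing score x
#' treatment.
#'
#' @param dataset a `carabid_dataset`.
#' @param chains,iter MCMC settings.
#' @param seed integer seed.
#' @param rhat_threshold convergence flag threshold (R-hat ~ 1 expected).
#' @return list with the `posterior_summary`, `conditional_effects` grid
#'   and the design column names.
#' @export
fit_headwidth_bglm <- function(dataset, chains = 4, iter = 3000, seed = 1,
                               rhat_threshold = 1.01) {
  tab <- .headwidth_table(dataset)
  tab$treatment <- factor(tab$treatment,
                          levels = .carafa_levels$treatment)
  X <- model.matrix(~ wing_score * treatment + size_z, data = tab)
  post <- fit_bglm(tab$value, X,
                   groups = list(month = tab$month,
                                 individual = tab$individual_id),
                   chains = chains, iter = iter, seed = seed,
                   rhat_threshold = rhat_threshold)
  grid <- expand.grid(wing_score = 1:3,
                      treatment = levels(tab$treatment),
                      KEEP.OUT.ATTRS = FALSE)
  grid$size_z <- 0
  Xg <- model.matrix(~ wing_score * treatment + size_z, data = grid)
  pred <- Xg %*% t(post$draws)
  grid$mean <- rowMeans(pred)
  grid$l95 <- apply(pred, 1, quantile, 0.025)
  grid$u95 <- apply(pred, 1, quantile, 0.975)
  list(posterior = post, conditional_effects = grid,
       design = colnames(X))
}
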