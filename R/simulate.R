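# Seed handling: every generator is a pure function of (spec, seed).
# A single run seed fans out to per-stage child seeds through a fixed
# LCG-style map so stages are independently reproducible.

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a run seed
#'
#' Deterministic fan-out so each pipeline stage can be replayed in
#' isolation. Always returns an integer in `[1, 2^31 - 2]`.
#'
#' @param seed integer run seed.
#' @param stage integer stage index (or small offset).
#' @return integer child seed.
#' @export
fan_seed <- function(seed, stage) {
  as.integer((abs(as.numeric(seed)) * 69069 + as.numeric(stage) * 1013 + 1) %%
               2147483629)
}

#' Specification of one bilateral trait's generative components
#'
#' Encodes the separable components of the side difference R - L used by
#' the generator: directional asymmetry (`da_shift`, an additive mean
#' shift), fluctuating asymmetry (`fa_sd`, SD of the individual-level
#' signed component), antisymmetry (`antisym_amp`, half-separation of a
#' symmetric two-point mixture), replicate measurement noise (`me_sd`) and
#' a size-dependence slope applied multiplicatively to the side difference
#' as `(1 + size_dep_slope * z(body_size))`.
#'
#' @param trait trait code.
#' @param base_size mean trait length, mm.
#' @param allometric_slope log-log slope of trait size on body size.
#' @param fa_sd SD (mm) of the signed FA component, >= 0.
#' @param da_shift additive mean R - L shift, mm.
#' @param antisym_amp half-separation (mm) of the +/- antisymmetry
#'   mixture, >= 0.
#' @param me_sd replicate-level measurement noise SD, mm, >= 0.
#' @param size_dep_slope dimensionless coefficient linking |R - L| to
#'   standardised body size.
#' @return a `trait_spec` list.
#' @export
trait_spec <- function(trait, base_size = 0.5, allometric_slope = 0,
                       fa_sd = 0.01, da_shift = 0, antisym_amp = 0,
                       me_sd = 0.002, size_dep_slope = 0) {
  stopifnot(fa_sd >= 0, antisym_amp >= 0, me_sd >= 0, base_size > 0)
  structure(list(trait = trait, base_size = base_size,
                 allometric_slope = allometric_slope, fa_sd = fa_sd,
                 da_shift = da_shift, antisym_amp = antisym_amp,
                 me_sd = me_sd, size_dep_slope = size_dep_slope),
            class = "trait_spec")
}

#' Simulate individual beetle records
#'
#' Fills a treatment x month x sex factorial with `n_per_cell` individuals
#' each. Three treatments with paired transects (two sites per treatment)
#' and six monthly collection periods mirror the study design; body size
#' (right-elytron length, mm) is drawn log-normal with the given median and
#' coefficient of variation, and wing morphs are sampled with the given
#' probabilities.
#'
#' @param n_per_cell individuals per treatment x month x sex cell.
#' @param species species code assigned to all records.
#' @param treatments,months,sexes design levels.
#' @param wing_probs probabilities for morphs A, B, M.
#' @param body_size_median,body_size_cv log-normal body-size parameters
#'   (mm; CV 0 gives constant size).
#' @param trap_type trap type label.
#' @param seed integer seed.
#' @return data frame of individual records.
#' @export
simulate_individuals <- function(n_per_cell, species = "CARSP1",
                                 treatments = .carafa_levels$treatment,
                                 months = 1:6, sexes = c("F", "M"),
                                 wing_probs = c(A = 0.2, B = 0.3, M = 0.5),
                                 body_size_median = 3.5, body_size_cv = 0.08,
                                 trap_type = "pitfall", seed = 1) {
  stopifnot(n_per_cell >= 0, body_size_cv >= 0)
  cells <- expand.grid(treatment = treatments, month = months, sex = sexes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(cells) * n_per_cell
  if (n == 0) {
    out <- data.frame(individual_id = character(0), species = character(0),
                      sex = character(0), wing_morph = character(0),
                      treatment = character(0), site_id = character(0),
                      month = integer(0), trap_type = character(0),
                      body_size = numeric(0), wing_score = integer(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  idx <- rep(seq_len(nrow(cells)), each = n_per_cell)
  .with_seed(seed, {
    morph <- sample(names(wing_probs), n, replace = TRUE, prob = wing_probs)
    sdlog <- sqrt(log(1 + body_size_cv^2))
    bs <- rlnorm(n, meanlog = log(body_size_median), sdlog = sdlog)
    # paired transects: two sites per treatment, alternated within cell
    site_no <- (seq_len(n) %% 2L) + 1L
    trt <- cells$treatment[idx]
    site <- paste0(substr(trt, 1, 2), site_no)
    data.frame(individual_id = sprintf("%s_i%04d", species, seq_len(n)),
               species = species, sex = cells$sex[idx], wing_morph = morph,
               treatment = trt, site_id = site, month = cells$month[idx],
               trap_type = trap_type, body_size = bs,
               wing_score = wing_morph_score(morph),
               stringsAsFactors = FALSE)
  })
}

#' Simulate replicated bilateral measurements
#'
#' For each individual and trait the signed side difference is
#' `d = (da_shift + FA + A) * (1 + size_dep_slope * z)` with
#' `FA ~ N(0, fa_sd^2)`, `A = +/- antisym_amp` (fair mixture) and `z` the
#' standardised body size; side means are `base +/- d/2` where `base`
#' follows the allometric power law. Each of the two replicates per side
#' adds independent `N(0, me_sd^2)` noise. Non-positive generated lengths
#' are resampled (truncation); the number of resamples is recorded in
#' attribute `"n_resampled"`.
#'
#' Analytic moments of the replicate-averaged difference R - L:
#' mean `da_shift`, variance `fa_sd^2 + antisym_amp^2 + me_sd^2` (each side
#' averages 2 replicates), when `size_dep_slope = 0`. The within-(individual,
#' side) replicate difference has variance `2 * me_sd^2`.
#'
#' @param individuals data frame from [simulate_individuals()].
#' @param specs a `trait_spec` or list of them.
#' @param seed integer seed.
#' @param fa_sd_multiplier optional per-individual multiplier on `fa_sd`
#'   (length `nrow(individuals)`), used to inject treatment-, sex- or
#'   environment-linked differences in developmental instability.
#' @param unpaired traits measured on the right side only.
#' @return data frame of (individual_id, trait, side, replicate, value).
#' @export
simulate_bilateral <- function(individuals, specs, seed = 1,
                               fa_sd_multiplier = NULL,
                               unpaired = c("head_width", "elytron_r")) {
  if (inherits(specs, "trait_spec")) specs <- list(specs)
  n <- nrow(individuals)
  if (is.null(fa_sd_multiplier)) fa_sd_multiplier <- rep(1, n)
  stopifnot(length(fa_sd_multiplier) == n)
  bs <- individuals$body_size
  z <- if (stats::sd(bs) > 0) (bs - mean(bs)) / stats::sd(bs) else rep(0, n)
  n_resampled <- 0L
  out <- .with_seed(seed, {
    pieces <- lapply(specs, function(sp) {
      base <- sp$base_size *
        (bs / stats::median(bs))^sp$allometric_slope
      fa <- rnorm(n, 0, sp$fa_sd) * fa_sd_multiplier
      a <- if (sp$antisym_amp > 0)
        sp$antisym_amp * sample(c(-1, 1), n, replace = TRUE) else rep(0, n)
      d <- (sp$da_shift + fa + a) * (1 + sp$size_dep_slope * z)
      sides <- if (sp$trait %in% unpaired) "R" else c("L", "R")
      rows <- expand.grid(i = seq_len(n), side = sides, replicate = 1:2,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      mu <- ifelse(rows$side == "R", base[rows$i] + d[rows$i] / 2,
                   base[rows$i] - d[rows$i] / 2)
      val <- mu + rnorm(nrow(rows), 0, sp$me_sd)
      bad <- which(val <= 0)
      while (length(bad) > 0) {
        n_resampled <<- n_resampled + length(bad)
        val[bad] <- mu[bad] + rnorm(length(bad), 0, sp$me_sd)
        bad <- bad[val[bad] <= 0]
      }
      data.frame(individual_id = individuals$individual_id[rows$i],
                 trait = sp$trait, side = rows$side,
                 replicate = rows$replicate, value = val,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, pieces)
  })
  out <- out[order(out$individual_id, out$trait, out$side, out$replicate), ]
  rownames(out) <- NULL
  attr(out, "n_resampled") <- n_resampled
  out
}

#' Specification of a synthetic community
#'
#' Species respond to standardised environmental gradients through
#' Gaussian niches; expected abundance is
#' `scale * exp(association * sum_k -(z_k - mu_k)^2 / (2 w_k^2))`,
#' renormalised so that `association = 0` yields identical expectations in
#' every sample (the null used for permutation-test calibration). Counts
#' are Poisson.
#'
#' @param n_species number of species.
#' @param n_sites_per_treatment sites (transects) per treatment.
#' @param n_months monthly collection periods.
#' @param association strength of the env-species coupling (0 = null).
#' @param abundance_scale expected count per sample per species at the
#'   niche optimum.
#' @param niche_width common niche width on the standardised env scale.
#' @param gradient_vars environment variables the niches respond to.
#' @param seed_labels seed for the valence/diet label assignment rule.
#' @return a `community_spec` list.
#' @export
community_spec <- function(n_species = 26, n_sites_per_treatment = 2,
                           n_months = 6, association = 1,
                           abundance_scale = 4, niche_width = 1.2,
                           gradient_vars = c("herbs", "litter"),
                           seed_labels = 1) {
  stopifnot(niche_width > 0, abundance_scale > 0, association >= 0)
  structure(list(n_species = n_species,
                 n_sites_per_treatment = n_sites_per_treatment,
                 n_months = n_months, association = association,
                 abundance_scale = abundance_scale,
                 niche_width = niche_width, gradient_vars = gradient_vars,
                 seed_labels = seed_labels),
            class = "community_spec")
}

# Treatment-level means for the environmental variables; noise SDs chosen
# to keep treatments separable but overlapping, as in open/ecotone/closed
# forest stands.
.env_profile <- list(
  herbs           = list(clearing = 65, ecotone = 40, control = 12, sd = 8),
  canopy_openness = list(clearing = 75, ecotone = 45, control = 15, sd = 7),
  litter          = list(clearing = 0.4, ecotone = 0.8, control = 1.3,
                         sd = 0.12),
  soil_moisture   = list(clearing = 35, ecotone = 50, control = 60, sd = 8),
  collembola      = list(clearing = 30, ecotone = 45, control = 55, sd = 10),
  formica         = list(clearing = 10, ecotone = 25, control = 45, sd = 8)
)
# Seasonal air-temperature curve (deg C) over the six 25-day periods
# mid-April..mid-October.
.season_temp <- c(11, 15, 19, 21, 17, 11)

#' Simulate a community matrix with matching environment and trait tables
#'
#' @param spec a [community_spec()].
#' @param seed integer seed.
#' @return list with `community` (samples x species count matrix),
#'   `environment` (one row per sample) and `species_traits`.
#' @export
simulate_community <- function(spec = community_spec(), seed = 1) {
  stopifnot(inherits(spec, "community_spec"))
  trts <- .carafa_levels$treatment
  sites <- unlist(lapply(trts, function(t)
    paste0(substr(t, 1, 2), seq_len(spec$n_sites_per_treatment))))
  site_trt <- rep(trts, each = spec$n_sites_per_treatment)
  grid <- expand.grid(site = seq_along(sites), month = seq_len(spec$n_months),
                      KEEP.OUT.ATTRS = FALSE)
  sample_id <- paste0(sites[grid$site], "_M", grid$month)
  ns <- nrow(grid)

  .with_seed(seed, {
    env <- data.frame(sample_id = sample_id,
                      treatment = site_trt[grid$site],
                      month = grid$month, stringsAsFactors = FALSE)
    for (v in names(.env_profile)) {
      pr <- .env_profile[[v]]
      mu <- unlist(pr[env$treatment])
      x <- rnorm(ns, mu, pr$sd)
      if (v %in% c("herbs", "canopy_openness")) x <- pmin(100, pmax(0, x))
      else x <- pmax(0, x)
      env[[v]] <- x
    }
    env$air_temp <- .season_temp[env$month] + rnorm(ns, 0, 1)

    # Gaussian niches on standardised gradients
    K <- spec$n_species
    zenv <- sapply(spec$gradient_vars, function(v) as.numeric(scale(env[[v]])))
    mu_k <- sapply(spec$gradient_vars, function(v)
      runif(K, min = -1.5, max = 1.5))
    if (K == 1) mu_k <- matrix(mu_k, nrow = 1)
    loglam <- matrix(log(spec$abundance_scale), ns, K)
    if (spec$association > 0) {
      for (k in seq_len(K)) {
        resp <- rowSums(-(sweep(zenv, 2, mu_k[k, ]))^2 /
                          (2 * spec$niche_width^2))
        resp <- resp - mean(resp)   # keep overall abundance comparable
        loglam[, k] <- loglam[, k] + spec$association * resp
      }
    }
    com <- matrix(rpois(ns * K, exp(loglam)), ns, K)
    spnames <- sprintf("sp%02d", seq_len(K))
    dimnames(com) <- list(sample_id, spnames)

    # identity traits: valence follows the litter-axis niche position when
    # litter is a gradient (closed-stand species = relic specialists)
    set.seed(fan_seed(seed, spec$seed_labels))
    lit_ax <- match("litter", spec$gradient_vars)
    valence <- if (!is.na(lit_ax)) {
      ifelse(mu_k[, lit_ax] > 0.5, "specialist", "generalist")
    } else sample(c("specialist", "generalist"), K, replace = TRUE)
    diet <- sample(c("predator", "seed", "gastropod", "collembola"),
                   K, replace = TRUE, prob = c(0.45, 0.25, 0.15, 0.15))
    st <- data.frame(species = spnames, ecological_valence = valence,
                     dietary_preference = diet, stringsAsFactors = FALSE)
    list(community = com, environment = env, species_traits = st)
  })
}

#' The shipped archetype parameter card
#'
#' One pure-component generative spec per suitability class. Values (mm)
#' are on the scale of a small antennal segment (base 0.5 mm):
#' the signal class has fluctuating asymmetry well above replicate noise;
#' the directional class shifts the mean by two FA standard deviations;
#' the antisymmetric class separates a two-point mixture by four times the
#' residual jitter; the error-dominated class drowns a weak FA signal in
#' replicate noise; the size-dependent class doubles the side difference
#' per body-size standard deviation.
#'
#' @return named list of [trait_spec()] objects, one per archetype.
#' @export
archetype_card <- function() {
  list(
    true_FA = trait_spec("a2", fa_sd = 0.010, da_shift = 0, antisym_amp = 0,
                         me_sd = 0.002, size_dep_slope = 0),
    DA = trait_spec("a2", fa_sd = 0.010, da_shift = 0.020, antisym_amp = 0,
                    me_sd = 0.002, size_dep_slope = 0),
    antisymmetry = trait_spec("a2", fa_sd = 0.003, da_shift = 0,
                              antisym_amp = 0.015, me_sd = 0.002,
                              size_dep_slope = 0),
    ME_dominated = trait_spec("a2", fa_sd = 0.0015, da_shift = 0,
                              antisym_amp = 0, me_sd = 0.010,
                              size_dep_slope = 0),
    size_dependent = trait_spec("a2", fa_sd = 0.010, da_shift = 0,
                                antisym_amp = 0, me_sd = 0.002,
                                size_dep_slope = 1.0)
  )
}

#' Generate the labelled archetype suite
#'
#' One dataset per suitability archetype, each pure in a single asymmetry
#' component, with its truth label attached. Used by the gating
#' recovery experiments.
#'
#' @param seed integer seed.
#' @param n_individuals cohort size per archetype.
#' @param card parameter card, default [archetype_card()].
#' @return named list; each element has `truth`, `spec`, `individuals`,
#'   `measurements`.
#' @export
make_archetype_suite <- function(seed = 1, n_individuals = 60,
                                 card = archetype_card()) {
  out <- lapply(seq_along(card), function(k) {
    sp <- card[[k]]
    ind <- simulate_individuals(
      n_per_cell = ceiling(n_individuals / 36), species = names(card)[k],
      seed = fan_seed(seed, 100 + k))
    ind <- ind[seq_len(min(n_individuals, nrow(ind))), , drop = FALSE]
    meas <- simulate_bilateral(ind, sp, seed = fan_seed(seed, 200 + k))
    list(truth = names(card)[k], spec = sp, individuals = ind,
         measurements = meas)
  })
  names(out) <- names(card)
  out
}

#' Simulate replicated head-width measurements with known fixed effects
#'
#' Generates the layer-2 response: two replicate measurements of head
#' width per individual, with linear effects of wing-morph score,
#' treatment and standardised body size, plus month and individual random
#' intercepts and replicate-level residual noise.
#'
#' @param individuals data frame from [simulate_individuals()].
#' @param intercept mean head width, mm.
#' @param beta_wing effect per wing-morph score unit.
#' @param beta_treatment named numeric offsets (clearing/control/ecotone).
#' @param beta_size effect per body-size SD.
#' @param beta_sex additive offset for males.
#' @param sd_month,sd_ind,sd_resid random-effect and residual SDs.
#' @param seed integer seed.
#' @return measurement-format data frame (trait `head_width`, side R).
#' @export
simulate_headwidth <- function(individuals, intercept = 1.0,
                               beta_wing = 0, beta_treatment = c(clearing = 0,
                                 control = 0, ecotone = 0), beta_size = 0,
                               beta_sex = 0, sd_month = 0.02, sd_ind = 0.02,
                               sd_resid = 0.02, seed = 1) {
  n <- nrow(individuals)
  z <- as.numeric(scale(individuals$body_size))
  if (anyNA(z)) z <- rep(0, n)
  .with_seed(seed, {
    months <- sort(unique(individuals$month))
    u_month <- setNames(rnorm(length(months), 0, sd_month),
                        as.character(months))
    u_ind <- rnorm(n, 0, sd_ind)
    mu <- intercept + beta_wing * individuals$wing_score +
      beta_treatment[individuals$treatment] + beta_size * z +
      beta_sex * (individuals$sex == "M") +
      u_month[as.character(individuals$month)] + u_ind
    rows <- expand.grid(i = seq_len(n), replicate = 1:2,
                        KEEP.OUT.ATTRS = FALSE)
    val <- mu[rows$i] + rnorm(nrow(rows), 0, sd_resid)
    val[val <= 0] <- 1e-4
    data.frame(individual_id = individuals$individual_id[rows$i],
               trait = "head_width", side = "R", replicate = rows$replicate,
               value = val, stringsAsFactors = FALSE)
  })
}

#' Simulate a complete study-scale dataset
#'
#' Convenience wrapper producing all five tables at the study's scale:
#' a 26-species community over 6 sites x 6 months with environmental
#' gradients, plus focal-species individuals carrying bilateral trait
#' measurements and head width, for end-to-end pipeline runs.
#'
#' @param seed integer seed.
#' @param n_focal_species species with individual-level measurements.
#' @param n_per_cell individuals per design cell per focal species.
#' @param association env-species association strength for the community.
#' @param traits trait codes to simulate bilaterally.
#' @return a `carabid_dataset`.
#' @export
simulate_study <- function(seed = 1, n_focal_species = 4, n_per_cell = 1,
                           association = 1,
                           traits = c("a2", "a3", "f_femur", "pm2")) {
  com <- simulate_community(community_spec(association = association),
                            seed = fan_seed(seed, 1))
  focal <- utils::head(colnames(com$community), n_focal_species)
  ind_list <- lapply(seq_along(focal), function(k) {
    simulate_individuals(n_per_cell, species = focal[k],
                         body_size_median = 2.5 + 0.8 * k,
                         seed = fan_seed(seed, 10 + k))
  })
  individuals <- do.call(rbind, ind_list)
  meas_list <- lapply(seq_along(focal), function(k) {
    ind <- ind_list[[k]]
    specs <- lapply(traits, function(tr)
      trait_spec(tr, base_size = 0.4 + 0.1 * match(tr, traits),
                 fa_sd = 0.008, me_sd = 0.002))
    bm <- simulate_bilateral(ind, specs, seed = fan_seed(seed, 20 + k))
    hw <- simulate_headwidth(ind, intercept = 0.8 + 0.2 * k,
                             beta_wing = 0.03, beta_size = 0.05,
                             seed = fan_seed(seed, 30 + k))
    el <- .with_seed(fan_seed(seed, 40 + k), {
      data.frame(individual_id = rep(ind$individual_id, each = 2),
                 trait = "elytron_r", side = "R",
                 replicate = rep(1:2, nrow(ind)),
                 value = rep(ind$body_size, each = 2) +
                   rnorm(2 * nrow(ind), 0, 0.002),
                 stringsAsFactors = FALSE)
    })
    rbind(bm, hw, el)
  })
  measurements <- do.call(rbind, meas_list)
  rownames(measurements) <- NULL
  carabid_dataset(individuals = individuals, measurements = measurements,
                  community = com$community, environment = com$environment,
                  species_traits = com$species_traits)
}
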