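# End-to-end orchestration of the three layers from one configuration.

#' Build and validate a run configuration
#'
#' @param seed integer seed (required: every stage that draws random
#'   numbers fans its own child seed out of it).
#' @param input_dir directory with the five standard CSV tables, or
#'   `NULL` to simulate a study-scale dataset.
#' @param out_dir output directory for result files, or `NULL` to skip
#'   writing.
#' @param alpha significance level used across the pipeline.
#' @param n_perm permutations for layer-1 tests.
#' @param layers named logical toggles `assemblage`, `traits`, `fa`.
#' @param run_bayes fit the Bayesian stages (the slow part).
#' @param covariables layer-1 covariables (month enters as categorical
#'   dummies, air temperature as continuous).
#' @param candidates layer-1 forward-selection candidates.
#' @param env_vars environmental predictors for the layer-3 Bayesian
#'   model when layer 1 is disabled or selects nothing.
#' @param magnitude FA magnitude transform.
#' @param min_n minimum FA cohort size.
#' @param outlier_screen Grubbs-screen asymmetries before gating.
#' @param mcmc list with `chains`, `iter_traits`, `iter_env`.
#' @param delim delimiter of the input tables.
#' @return a `run_config` list.
#' @export
run_config <- function(seed, input_dir = NULL, out_dir = NULL,
                       alpha = 0.05, n_perm = 999,
                       layers = c(assemblage = TRUE, traits = TRUE,
                                  fa = TRUE),
                       run_bayes = TRUE,
                       covariables = c("month", "air_temp"),
                       candidates = c("treatment", "herbs", "litter"),
                       env_vars = c("formica", "collembola", "litter",
                                    "canopy_openness", "herbs", "air_temp",
                                    "soil_moisture"),
                       magnitude = "abs", min_n = 5,
                       outlier_screen = TRUE,
                       mcmc = list(chains = 4, iter_traits = 3000,
                                   iter_env = 4000),
                       delim = ",") {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("config error: seed is required")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("config error: alpha must be in (0, 1)")
  if (n_perm < 1) stop("config error: n_perm must be positive")
  if (!magnitude %in% c("abs", "square", "signed"))
    stop("config error: magnitude must be abs, square or signed")
  cfg <- list(seed = as.integer(seed), input_dir = input_dir,
              out_dir = out_dir, alpha = alpha, n_perm = n_perm,
              layers = layers, run_bayes = run_bayes,
              covariables = covariables, candidates = candidates,
              env_vars = env_vars, magnitude = magnitude, min_n = min_n,
              outlier_screen = outlier_screen, mcmc = mcmc, delim = delim)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; unknown keys
#' are rejected.
#'
#' @param path YAML file.
#' @param ... overrides applied on top of the file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(y), known)
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  over <- list(...)
  y[names(over)] <- over
  if (!is.null(y$layers)) y$layers <- unlist(y$layers)
  do.call(run_config, y)
}

.stage <- function(report, name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(list(ok = TRUE, value = expr, error = NULL),
                  error = function(e)
                    list(ok = FALSE, value = NULL,
                         error = conditionMessage(e)))
  report$stages[[name]] <- list(
    status = if (res$ok) "ok" else "failed", error = res$error,
    elapsed_s = round(as.numeric(difftime(Sys.time(), t0,
                                          units = "secs")), 2))
  list(report = report, value = res$value, ok = res$ok)
}

#' Run the three-layer pipeline
#'
#' Loads (or simulates) the dataset, validates it, then executes layer 1
#' (ordination + forward selection + trait projections), layer 2
#' (measurement-error screen, prestep, head-width LMM and Bayesian
#' model) and layer 3 (trait gating, FA models, concordance,
#' environmental Bayesian model). The environmental variables that layer
#' 1 selects are handed to layer 3 unless layer 1 is disabled, in which
#' case the configured list is used. A failed stage is recorded in the
#' report and later independent stages still run.
#'
#' @param config a [run_config()].
#' @return a `run_report`: per-stage status and key statistics, the
#'   result objects, warnings, and the echoed config.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  report <- list(stages = list(), config = unclass(config),
                 started = format(Sys.time()),
                 r_version = R.version.string)
  results <- list()

  st <- .stage(report, "load", {
    if (is.null(config$input_dir)) {
      simulate_study(seed = fan_seed(config$seed, 1))
    } else {
      load_dataset(
        individuals = file.path(config$input_dir, "individuals.csv"),
        measurements = file.path(config$input_dir, "measurements.csv"),
        community = file.path(config$input_dir, "community.csv"),
        environment = file.path(config$input_dir, "environment.csv"),
        species_traits = file.path(config$input_dir, "species_traits.csv"),
        delim = config$delim)
    }
  })
  report <- st$report
  if (!st$ok) {
    report$finished <- format(Sys.time())
    return(structure(list(report = report, results = results),
                     class = "run_report"))
  }
  d <- st$value
  vr <- validate_dataset(d)
  report$validation <- list(pass = vr$pass,
                            n_findings = length(vr$entries))
  results$validation <- vr

  env_for_fa <- config$env_vars

  if (isTRUE(config$layers[["assemblage"]])) {
    st <- .stage(report, "assemblage", {
      env <- d$environment
      env <- env[match(rownames(d$community), env$sample_id), ]
      Ytr <- transform_abundances(d$community)
      X <- env[, intersect(config$candidates, names(env)), drop = FALSE]
      Zdf <- data.frame(row.names = seq_len(nrow(env)))
      if ("month" %in% config$covariables)
        Zdf$month <- factor(env$month)
      if ("air_temp" %in% config$covariables)
        Zdf$air_temp <- env$air_temp
      ord <- fit_pcca(Ytr, X, Zdf)
      blocks <- sub("_M[0-9]+$", "", env$sample_id)
      overall <- restricted_permutation_test(
        ord, blocks, n_perm = config$n_perm,
        seed = fan_seed(config$seed, 2))
      fs <- forward_select(Ytr, X, Zdf, blocks,
                           n_perm = config$n_perm,
                           seed = fan_seed(config$seed, 3),
                           alpha = config$alpha)
      st_tab <- d$species_traits
      cwm_val <- compute_cwm(d$community,
                             setNames(st_tab$ecological_valence,
                                      st_tab$species))
      cwm_diet <- compute_cwm(d$community,
                              setNames(st_tab$dietary_preference,
                                       st_tab$species))
      raoq <- compute_raoq(d$community, species_trait_distance(st_tab))
      proj <- project_supplementary(
        ord, cbind(cwm_val, cwm_diet, raoq = raoq))
      list(ordination = ord, overall_test = overall,
           forward_selection = fs,
           cwm = list(valence = cwm_val, diet = cwm_diet), raoq = raoq,
           projection = proj)
    })
    report <- st$report
    if (st$ok) {
      results$assemblage <- st$value
      fs <- st$value$forward_selection
      sel_env <- fs$variable[fs$selected]
      sel_env <- intersect(sel_env, config$env_vars)
      if (length(sel_env) > 0) env_for_fa <- sel_env
      report$stages$assemblage$key_stats <- list(
        explained_after_partial =
          st$value$ordination$explained_after_partial,
        pseudo_F = st$value$overall_test$pseudo_F,
        p = st$value$overall_test$p,
        selected = fs$variable[fs$selected])
    }
  }

  if (isTRUE(config$layers[["traits"]])) {
    st <- .stage(report, "traits", {
      species_n <- table(d$individuals$species)
      focal <- names(species_n)[species_n >= config$min_n]
      bilateral <- setdiff(unique(d$measurements$trait),
                           c("head_width", "elytron_r"))
      me_tab <- do.call(rbind, lapply(focal, function(sp) {
        ids <- d$individuals$individual_id[d$individuals$species == sp]
        do.call(rbind, lapply(bilateral, function(tr) {
          m <- d$measurements[d$measurements$individual_id %in% ids &
                                d$measurements$trait == tr, ]
          if (length(unique(m$individual_id)) < config$min_n) return(NULL)
          me <- suppressWarnings(assess_measurement_error(
            m, alpha = config$alpha))
          data.frame(species = sp, trait = tr, n = me$n,
                     F_signal = me$F_signal, p_signal = me$p_signal,
                     pct_me = me$pct_me, resolvable = me$resolvable,
                     stringsAsFactors = FALSE)
        }))
      }))
      pre <- prestep_screen(d, alpha = config$alpha)
      lmm <- fit_headwidth_lmm(d)
      bglm <- if (isTRUE(config$run_bayes))
        fit_headwidth_bglm(d, chains = config$mcmc$chains,
                           iter = config$mcmc$iter_traits,
                           seed = fan_seed(config$seed, 4))
      else NULL
      list(me_screen = me_tab, prestep = pre, lmm = lmm, bglm = bglm)
    })
    report <- st$report
    if (st$ok) {
      results$traits <- st$value
      report$stages$traits$key_stats <- list(
        prestep_retained = st$value$prestep$retained,
        r2_marginal = st$value$lmm$r2_marginal)
    }
  }

  if (isTRUE(config$layers[["fa"]])) {
    st <- .stage(report, "fa", {
      species_n <- table(d$individuals$species)
      focal <- names(species_n)[species_n >= config$min_n]
      bilateral <- setdiff(unique(d$measurements$trait),
                           c("head_width", "elytron_r"))
      gating <- do.call(rbind, unlist(lapply(focal, function(sp)
        lapply(bilateral, function(tr)
          assess_trait(d, sp, tr, alpha = config$alpha,
                       min_n = config$min_n,
                       outlier_screen = config$outlier_screen))),
        recursive = FALSE))
      usable <- gating[gating$verdict %in% c("true_FA", "size_dependent"), ]
      models <- list(); conc <- list(); env_fit <- NULL
      for (k in seq_len(nrow(usable))) {
        sp <- usable$species[k]; tr <- usable$trait[k]
        fa_tab <- fa_index_table(d, sp, tr, magnitude = config$magnitude,
                                 min_n = config$min_n)
        if (is.null(fa_tab)) next
        key <- paste(sp, tr, sep = ":")
        models[[key]] <- list(
          treatment = tryCatch(
            suppressWarnings(fit_treatment_lmm(
              fa_tab, include_size = usable$verdict[k] == "size_dependent")),
            error = function(e) list(error = conditionMessage(e))),
          interactions = tryCatch(
            suppressWarnings(fit_interaction_models(fa_tab)),
            error = function(e) list(error = conditionMessage(e))))
        if (is.null(env_fit) && isTRUE(config$run_bayes) &&
              !is.null(d$environment)) {
          env_fit <- tryCatch(
            fit_env_bglm(fa_tab, d$environment, env_vars = env_for_fa,
                         chains = config$mcmc$chains,
                         iter = config$mcmc$iter_env,
                         seed = fan_seed(config$seed, 5)),
            error = function(e) list(error = conditionMessage(e)))
          if (!is.null(env_fit)) attr(env_fit, "cohort") <- key
        }
      }
      for (sp in unique(usable$species)) {
        trs <- usable$trait[usable$species == sp]
        if (length(trs) < 3) next
        mats <- lapply(trs, function(tr) {
          ft <- fa_index_table(d, sp, tr, magnitude = config$magnitude,
                               min_n = config$min_n)
          stats::aggregate(fa_mag ~ individual_id, data = ft, FUN = mean)
        })
        ids <- Reduce(intersect, lapply(mats, `[[`, "individual_id"))
        if (length(ids) < 5) next
        M <- sapply(seq_along(mats), function(j)
          mats[[j]]$fa_mag[match(ids, mats[[j]]$individual_id)])
        colnames(M) <- trs
        conc[[sp]] <- kendall_concordance(
          M, n_tests = length(unique(usable$species)))
      }
      list(gating = gating, models = models, concordance = conc,
           env_bglm = env_fit, env_vars_used = env_for_fa)
    })
    report <- st$report
    if (st$ok) {
      results$fa <- st$value
      report$stages$fa$key_stats <- list(
        verdicts = table(st$value$gating$verdict),
        env_vars_used = st$value$env_vars_used)
    }
  }

  report$finished <- format(Sys.time())
  out <- structure(list(report = report, results = results),
                   class = "run_report")
  if (!is.null(config$out_dir)) write_run_results(out, config$out_dir)
  out
}

#' Write the pipeline's result tables and run summary
#'
#' @param run a `run_report` from [run_pipeline()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_run_results <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  r <- run$results
  if (!is.null(r$assemblage)) {
    write_results(r$assemblage$forward_selection,
                  file.path(dir, "forward_selection.csv"))
    sc <- r$assemblage$ordination$site_scores
    write_results(data.frame(sample_id = rownames(sc), sc),
                  file.path(dir, "site_scores.csv"))
    write_results(data.frame(variable =
                               rownames(r$assemblage$projection$arrows),
                             r$assemblage$projection$arrows,
                             r2 = r$assemblage$projection$r2),
                  file.path(dir, "trait_projection.csv"))
  }
  if (!is.null(r$traits)) {
    if (!is.null(r$traits$me_screen))
      write_results(r$traits$me_screen, file.path(dir, "me_screen.csv"))
    write_results(r$traits$lmm$wald, file.path(dir, "headwidth_wald.csv"))
    if (!is.null(r$traits$bglm))
      write_results(r$traits$bglm$posterior$coefficients,
                    file.path(dir, "headwidth_posterior.csv"))
  }
  if (!is.null(r$fa)) {
    write_results(r$fa$gating, file.path(dir, "trait_assessment.csv"))
    if (!is.null(r$fa$env_bglm) && is.null(r$fa$env_bglm$error) &&
          !is.null(r$fa$env_bglm$posterior))
      write_results(r$fa$env_bglm$posterior$coefficients,
                    file.path(dir, "fa_env_posterior.csv"))
  }
  summ <- run$report
  summ$stages <- lapply(summ$stages, function(s) {
    s$key_stats <- lapply(s$key_stats, function(v)
      if (is.table(v)) as.list(v) else v)
    s
  })
  write_results(summ, file.path(dir, "run_summary.json"))
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("carafa pipeline run (seed ", x$report$config$seed, ")\n", sep = "")
  for (nm in names(x$report$stages)) {
    s <- x$report$stages[[nm]]
    cat(sprintf("  %-12s %-7s %6.1fs", nm, s$status, s$elapsed_s))
    if (!is.null(s$error)) cat("  ", s$error)
    cat("\n")
  }
  invisible(x)
}
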