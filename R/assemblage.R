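# Layer 1: assemblage composition. Constrained ordination is delegated to
# vegan::cca; this module adds the study's conventions around it
# (abundance transform with rare-species downweighting, cyclic-shift
# restricted permutation tests, FDR-adjusted forward selection, passive
# trait projections).

.as_model_cols <- function(df) {
  # one column per factor level (no reference suppression): each level of
  # a categorical variable is its own forward-selection candidate
  cols <- list()
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.character(v)) v <- factor(v)
    if (is.factor(v)) {
      for (lv in levels(v)) cols[[paste0(nm, "_", lv)]] <- as.numeric(v == lv)
    } else {
      cols[[nm]] <- as.numeric(v)
    }
  }
  if (length(cols) == 0) return(NULL)
  m <- do.call(cbind, cols)
  rownames(m) <- rownames(df)
  m
}

#' Transform a community abundance matrix
#'
#' Applies the study's preprocessing: `ln(y + 1)` transform and
#' downweighting of rare species. A species occurring in `f` samples is
#' downweighted by `f / (f_max / 5)` when `f < f_max / 5`, where `f_max`
#' is the highest occurrence frequency in the matrix; commoner species
#' keep weight 1.
#'
#' @param Y non-negative samples x species matrix.
#' @param log apply `ln(y + 1)`.
#' @param downweight apply the rare-species rule.
#' @return transformed matrix with attribute `"species_weights"`.
#' @export
transform_abundances <- function(Y, log = TRUE, downweight = TRUE) {
  Y <- as.matrix(Y)
  if (any(Y < 0)) stop("abundances must be non-negative")
  if (all(Y == 0)) stop("all-zero community matrix")
  out <- if (log) base::log(Y + 1) else Y
  w <- rep(1, ncol(Y))
  if (downweight) {
    f <- colSums(Y > 0)
    f_max <- max(f)
    thr <- f_max / 5
    low <- f < thr & f > 0
    w[low] <- f[low] / thr
    out <- sweep(out, 2, w, `*`)
  }
  names(w) <- colnames(Y)
  attr(out, "species_weights") <- w
  out
}

#' Partial canonical correspondence analysis
#'
#' Fits (p)CCA of a transformed abundance matrix on constraint variables
#' after removing covariable effects by weighted projection. Thin wrapper
#' over [vegan::cca()] returning the quantities the pipeline reports.
#'
#' @param Y transformed samples x species matrix (see
#'   [transform_abundances()]).
#' @param X constraints: data frame (factors get one dummy per level) or
#'   numeric matrix.
#' @param Z covariables in the same form, or `NULL` for plain CCA.
#' @return an `ordination_result`: list with the vegan fit, canonical
#'   `eigenvalues`, `total_inertia`, `conditional_inertia`,
#'   `constrained_inertia`, `explained_of_total` and
#'   `explained_after_partial` (both as fractions), site/species/biplot
#'   scores.
#' @export
fit_pcca <- function(Y, X, Z = NULL) {
  Y <- as.matrix(Y)
  Xm <- if (is.data.frame(X)) .as_model_cols(X) else as.matrix(X)
  Zm <- if (is.null(Z)) NULL
        else if (is.data.frame(Z)) .as_model_cols(Z) else as.matrix(Z)
  stopifnot(nrow(Xm) == nrow(Y), is.null(Zm) || nrow(Zm) == nrow(Y))
  fit <- if (is.null(Zm)) vegan::cca(Y, Xm) else vegan::cca(Y, Xm, Zm)
  ev <- fit$CCA$eig
  tot <- fit$tot.chi
  cond <- if (is.null(fit$pCCA)) 0 else fit$pCCA$tot.chi
  constr <- fit$CCA$tot.chi
  res <- list(
    fit = fit,
    eigenvalues = ev,
    total_inertia = tot,
    conditional_inertia = cond,
    constrained_inertia = constr,
    explained_of_total = constr / tot,
    explained_after_partial = constr / (tot - cond),
    site_scores = suppressWarnings(
      vegan::scores(fit, display = "wa", choices = seq_along(ev))),
    lc_scores = suppressWarnings(
      vegan::scores(fit, display = "lc", choices = seq_along(ev))),
    species_scores = suppressWarnings(
      vegan::scores(fit, display = "sp", choices = seq_along(ev))),
    biplot_scores = fit$CCA$biplot,
    row_weights = fit$rowsum
  )
  class(res) <- "ordination_result"
  res
}

#' @export
print.ordination_result <- function(x, ...) {
  cat("pCCA: ", length(x$eigenvalues), " canonical axes\n", sep = "")
  cat("  total inertia      ", signif(x$total_inertia, 4), "\n")
  cat("  covariables remove ", signif(x$conditional_inertia, 4), "\n")
  cat("  constrained        ", signif(x$constrained_inertia, 4),
      " (", signif(100 * x$explained_after_partial, 3),
      "% of partialled inertia)\n", sep = "")
  invisible(x)
}

.cyclic_how <- function(blocks, n_perm) {
  permute::how(within = permute::Within(type = "series", mirror = FALSE),
               plots = permute::Plots(strata = as.factor(blocks),
                                      type = "none"),
               nperm = n_perm)
}

#' Restricted Monte-Carlo permutation test for a constrained ordination
#'
#' Significance of the canonical axes assessed by permutations restricted
#' to independent random cyclic shifts of each block's time series (sites
#' are blocks; samples within a block must be in temporal order). The
#' zero-shift arrangement is a member of the permutation set, so
#' `p >= 1 / (n_perm + 1)`. When the full cyclic group is small enough it
#' is enumerated completely and the test is exact.
#'
#' @param ord an `ordination_result` from [fit_pcca()].
#' @param blocks block (site) factor aligned to the ordination rows.
#' @param n_perm requested number of permutations.
#' @param seed integer seed.
#' @return list with `pseudo_F`, `p`, `n_perm` (permutations actually
#'   used).
#' @export
restricted_permutation_test <- function(ord, blocks, n_perm = 199,
                                        seed = 1) {
  stopifnot(inherits(ord, "ordination_result"))
  blocks <- as.factor(blocks)
  if (any(table(blocks) == 1))
    message("restricted_permutation_test: block(s) of length 1 are ",
            "invariant under cyclic shifts")
  ctrl <- .cyclic_how(blocks, n_perm)
  a <- .with_seed(seed,
                  suppressMessages(anova(ord$fit, permutations = ctrl)))
  list(pseudo_F = a$F[1], p = a[["Pr(>F)"]][1],
       n_perm = attr(a, "control")$nperm %||% n_perm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Forward selection of constraining variables
#'
#' Greedy inclusion by largest conditional (partial) contribution to
#' explained variation, each candidate tested at entry with the
#' cyclic-shift restricted permutation test; raw p-values are
#' Benjamini-Hochberg adjusted across the candidate list. Categorical
#' candidates contribute one dummy per level, each selected on its own.
#' All candidates are reported in entry order with their conditional
#' effects, whether or not selected.
#'
#' @param Y transformed abundance matrix.
#' @param candidates data frame of candidate variables.
#' @param Z covariables (data frame or matrix), or `NULL`.
#' @param blocks block factor for the restricted permutations.
#' @param n_perm permutations per test (study used 999).
#' @param seed integer seed.
#' @param alpha selection level applied to adjusted p-values.
#' @return data frame: `variable`, `explained_pct` (conditional
#'   contribution as % of the inertia left after partialling the
#'   covariables), `pseudo_F`, `p`, `p_adj`, `selected`, `entry_order`.
#' @export
forward_select <- function(Y, candidates, Z = NULL, blocks, n_perm = 999,
                           seed = 1, alpha = 0.05) {
  Y <- as.matrix(Y)
  Cm <- .as_model_cols(as.data.frame(candidates))
  Zm <- if (is.null(Z)) NULL
        else if (is.data.frame(Z)) .as_model_cols(Z) else as.matrix(Z)
  base_cond <- if (is.null(Zm)) 0 else {
    f0 <- vegan::cca(Y, Zm)
    f0$CCA$tot.chi
  }
  tot <- vegan::cca(Y)$tot.chi
  denom <- tot - base_cond

  remaining <- colnames(Cm)
  selected_cols <- NULL
  rows <- list()
  step <- 0L
  while (length(remaining) > 0) {
    step <- step + 1L
    contrib <- vapply(remaining, function(v) {
      Zfull <- cbind(Zm, selected_cols)
      f <- tryCatch(suppressWarnings({
        if (is.null(Zfull)) vegan::cca(Y, Cm[, v, drop = FALSE])
        else vegan::cca(Y, Cm[, v, drop = FALSE], Zfull)
      }), error = function(e) NULL)
      if (is.null(f) || is.null(f$CCA)) 0 else f$CCA$tot.chi
    }, numeric(1))
    best <- remaining[which.max(contrib)]
    Zfull <- cbind(Zm, selected_cols)
    ordb <- fit_pcca(Y, Cm[, best, drop = FALSE], Zfull)
    pt <- if (ordb$constrained_inertia > 1e-12) {
      restricted_permutation_test(ordb, blocks, n_perm,
                                  seed = fan_seed(seed, step))
    } else list(pseudo_F = 0, p = 1)
    rows[[step]] <- data.frame(
      variable = best,
      explained_pct = 100 * max(contrib[best], 0) / denom,
      pseudo_F = pt$pseudo_F, p = pt$p, stringsAsFactors = FALSE)
    selected_cols <- cbind(selected_cols, Cm[, best, drop = FALSE])
    remaining <- setdiff(remaining, best)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$selected <- out$p_adj <= alpha
  out$entry_order <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Community-weighted mean of a species trait
#'
#' `CWM_s = sum_i p_si x_i` with `p_si` the relative abundance of species
#' i in sample s. Categorical traits are one-hot encoded, yielding one
#' CWM column (a proportion) per level. Samples with zero total abundance
#' give `NA`.
#'
#' @param Y samples x species abundance matrix.
#' @param trait_values numeric vector or factor, named by species or in
#'   column order of `Y`.
#' @return numeric vector (numeric trait) or matrix (categorical).
#' @export
compute_cwm <- function(Y, trait_values) {
  Y <- as.matrix(Y)
  if (!is.null(names(trait_values)) && !is.null(colnames(Y))) {
    trait_values <- trait_values[colnames(Y)]
  }
  stopifnot(length(trait_values) == ncol(Y))
  tot <- rowSums(Y)
  P <- sweep(Y, 1, ifelse(tot > 0, tot, NA), `/`)
  if (is.character(trait_values)) trait_values <- factor(trait_values)
  if (is.factor(trait_values)) {
    X <- sapply(levels(trait_values), function(lv)
      as.numeric(trait_values == lv))
    out <- P %*% X
    colnames(out) <- levels(trait_values)
    return(out)
  }
  as.numeric(P %*% as.numeric(trait_values))
}

#' Rao's quadratic entropy per sample
#'
#' `Q_s = sum_ij d_ij p_si p_sj`: the expected functional distance between
#' two randomly drawn individuals of a sample. With `d_ij = 1` for all
#' distinct pairs this reduces to the Simpson-type identity
#' `1 - sum_i p_i^2`.
#'
#' @param Y samples x species abundance matrix.
#' @param D symmetric species x species distance matrix, zero diagonal.
#' @return numeric vector of Q per sample (`NA` for empty samples).
#' @export
compute_raoq <- function(Y, D) {
  Y <- as.matrix(Y)
  D <- as.matrix(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-10)))
    stop("species distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be zero")
  if (any(D < 0)) stop("distances must be non-negative")
  if (!is.null(colnames(Y)) && !is.null(rownames(D)))
    D <- D[colnames(Y), colnames(Y)]
  stopifnot(ncol(Y) == ncol(D))
  tot <- rowSums(Y)
  P <- sweep(Y, 1, ifelse(tot > 0, tot, NA), `/`)
  rowSums((P %*% D) * P)
}

#' Simple-matching distance between species identity traits
#'
#' Fraction of categorical identity traits (ecological valence, dietary
#' preference) on which two species differ; the distance fed to
#' [compute_raoq()].
#'
#' @param species_traits data frame with `species` plus categorical
#'   columns.
#' @return species x species distance matrix.
#' @export
species_trait_distance <- function(species_traits) {
  st <- species_traits
  cols <- setdiff(names(st), "species")
  n <- nrow(st)
  D <- matrix(0, n, n, dimnames = list(st$species, st$species))
  for (cc in cols) {
    v <- st[[cc]]
    D <- D + outer(v, v, `!=`)
  }
  D / length(cols)
}

#' Passively project per-sample values into an ordination
#'
#' Weighted least-squares regression of each centred value vector on the
#' site scores of the chosen axes (weights = CCA row masses); the fitted
#' coefficients are the arrow coordinates. The projection has no effect
#' on the eigen-structure.
#'
#' @param ord an `ordination_result`.
#' @param values data frame / matrix of per-sample vectors (e.g. CWMs,
#'   RaoQ), rows aligned to ordination samples.
#' @param axes which axes to project on.
#' @return list with `arrows` (variables x axes) and `r2` per variable.
#' @export
project_supplementary <- function(ord, values, axes = c(1, 2)) {
  stopifnot(inherits(ord, "ordination_result"))
  V <- as.matrix(values)
  axes <- axes[axes <= ncol(ord$site_scores)]
  S <- ord$site_scores[, axes, drop = FALSE]
  w <- ord$row_weights
  arrows <- matrix(0, ncol(V), length(axes),
                   dimnames = list(colnames(V), colnames(S)))
  r2 <- setNames(numeric(ncol(V)), colnames(V))
  for (j in seq_len(ncol(V))) {
    v <- V[, j]
    ok <- is.finite(v)
    if (stats::sd(v[ok]) == 0 || sum(ok) < length(axes) + 1) {
      warning("constant or degenerate supplementary variable: ",
              colnames(V)[j], " (zero-length arrow)")
      next
    }
    fit <- stats::lm(v ~ S, weights = w, subset = ok)
    arrows[j, ] <- coef(fit)[-1]
    mu <- stats::weighted.mean(v[ok], w[ok])
    ss_tot <- sum(w[ok] * (v[ok] - mu)^2)
    ss_res <- sum(w[ok] * resid(fit)^2)
    r2[j] <- 1 - ss_res / ss_tot
  }
  list(arrows = arrows, r2 = r2)
}
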