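# Small statistical primitives not provided by the installed stack:
# iterative Grubbs outlier screening and the Anscombe-Glynn kurtosis test.

#' Grubbs critical value
#'
#' Two-sided critical value of the Grubbs extreme-outlier statistic
#' `G = max|x - mean| / sd` at level `alpha` for sample size `n`.
#'
#' @param n sample size (>= 3).
#' @param alpha significance level.
#' @return critical value of G.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  stopifnot(n >= 3)
  t2 <- qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)^2
  ((n - 1) / sqrt(n)) * sqrt(t2 / (n - 2 + t2))
}

#' Iterative Grubbs outlier screen
#'
#' Repeatedly tests the single most extreme value with Grubbs' test and
#' removes it while significant at `alpha`. The order of removal is
#' deterministic (always the current most extreme value) and the loop
#' terminates at `n = 3` at the latest. The input is never mutated; an
#' inclusion mask is returned.
#'
#' @param values numeric vector, `n >= 3` for any removal to happen.
#' @param alpha significance level per step.
#' @param max_prop maximal fraction of points that may be removed.
#' @return logical inclusion mask (TRUE = keep), with attribute
#'   `"n_removed"`.
#' @export
remove_outliers <- function(values, alpha = 0.05, max_prop = 0.2) {
  n0 <- length(values)
  keep <- rep(TRUE, n0)
  keep[!is.finite(values)] <- FALSE
  if (sum(keep) < 3) {
    warning("fewer than 3 finite values: no outlier screening")
    attr(keep, "n_removed") <- 0L
    return(keep)
  }
  removed <- 0L
  repeat {
    idx <- which(keep)
    x <- values[idx]
    n <- length(x)
    if (n < 3 || removed >= floor(max_prop * n0)) break
    s <- sd(x)
    if (s == 0) break   # zero variance: nothing is extreme
    g <- abs(x - mean(x)) / s
    j <- which.max(g)
    if (g[j] > grubbs_critical(n, alpha)) {
      keep[idx[j]] <- FALSE
      removed <- removed + 1L
    } else break
  }
  attr(keep, "n_removed") <- removed
  keep
}

#' Anscombe-Glynn test of kurtosis
#'
#' Normal-approximation test of the sample kurtosis `b2 = m4 / m2^2`
#' against its value 3 under normality. `alternative = "less"` is the
#' platykurtosis (antisymmetry) direction.
#'
#' @param x numeric vector, `n >= 10`.
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return list with `b2` (raw kurtosis), `excess` (`b2 - 3`), `z`, `p`.
#' @export
kurtosis_test <- function(x, alternative = c("two.sided", "less",
                                             "greater")) {
  alternative <- match.arg(alternative)
  x <- x[is.finite(x)]
  n <- length(x)
  stopifnot(n >= 10)
  b2 <- e1071::kurtosis(x, type = 1) + 3
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  m3 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / m3 * (2 / m3 + sqrt(1 + 4 / m3^2))
  d <- (b2 - eb2) / sqrt(vb2)
  t1 <- (1 - 2 / (9 * a))
  denom <- 1 + d * sqrt(2 / (a - 4))
  if (denom <= 0) {
    # beyond the domain of the Wilson-Hilferty transform: kurtosis is so
    # far below its null expectation that the approximation wraps around;
    # the evidence for platykurtosis is overwhelming
    z <- -Inf
  } else {
    base <- (1 - 2 / a) / denom
    t2 <- sign(base) * abs(base)^(1 / 3)   # signed cube root
    z <- (t1 - t2) / sqrt(2 / (9 * a))
  }
  p <- switch(alternative,
              two.sided = 2 * pnorm(-abs(z)),
              less = pnorm(z),
              greater = pnorm(z, lower.tail = FALSE))
  list(b2 = b2, excess = b2 - 3, z = z, p = p)
}

#' Nakagawa pseudo-R2 for a Gaussian mixed model
#'
#' Marginal R2 (fixed effects only) and conditional R2 (fixed + random)
#' for an [lme4::lmer] fit with a Gaussian response.
#'
#' @param fit an `lmerMod`.
#' @return list with `marginal` and `conditional`.
#' @export
pseudo_r2 <- function(fit) {
  vf <- var(as.numeric(model.matrix(fit) %*% lme4::fixef(fit)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vr <- sum(vc$vcov[is.na(vc$var2) & vc$grp != "Residual"])
  ve <- vc$vcov[vc$grp == "Residual"]
  list(marginal = vf / (vf + vr + ve),
       conditional = (vf + vr) / (vf + vr + ve))
}
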