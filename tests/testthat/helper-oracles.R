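# Independent oracles and small fixture builders used across the suite.

# Brute-force (p)CCA eigenvalues as a direct weighted eigenproblem:
# chi-square standardised matrix projected (in the row-mass metric) onto
# the covariable-residualised constraint space; eigenvalues are squared
# singular values. Independent of vegan.
brute_cca_eig <- function(Y, X, Z = NULL) {
  Y <- as.matrix(Y); tot <- sum(Y)
  P <- Y / tot; r <- rowSums(P); cc <- colSums(P)
  Qbar <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
  proj <- function(M) {
    q <- qr(M)
    qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  }
  if (!is.null(Z)) {
    Zw <- sqrt(r) * cbind(1, as.matrix(Z))
    Qz <- proj(Zw)
    Qbar <- Qbar - Qz %*% crossprod(Qz, Qbar)
    Xw <- sqrt(r) * as.matrix(X)
    Xw <- Xw - Qz %*% crossprod(Qz, Xw)
  } else {
    Xw <- sqrt(r) * as.matrix(X)
    ones <- sqrt(r)
    Xw <- Xw - outer(ones, crossprod(ones, Xw)[1, ] / sum(r))
  }
  Qx <- proj(Xw)
  d <- svd(Qx %*% crossprod(Qx, Qbar))$d
  ev <- d^2
  ev[ev > 1e-12]
}

# A tiny hand-written dataset: one individual, one paired trait
# (2 sides x 2 replicates = 4 measurement rows).
make_tiny_dataset <- function() {
  ind <- data.frame(individual_id = "i1", species = "spA", sex = "F",
                    wing_morph = "M", treatment = "control",
                    site_id = "co1", month = 2L, trap_type = "pitfall",
                    body_size = 3.5, stringsAsFactors = FALSE)
  meas <- data.frame(individual_id = "i1", trait = "a2",
                     side = rep(c("L", "R"), each = 2),
                     replicate = rep(1:2, 2),
                     value = c(0.50, 0.51, 0.52, 0.53),
                     stringsAsFactors = FALSE)
  carabid_dataset(individuals = ind, measurements = meas)
}

# Cohort builder: individuals plus bilateral measurements for one trait
# spec, returned as a carabid_dataset.
make_cohort <- function(spec, n = 60, seed = 1) {
  ind <- simulate_individuals(n_per_cell = ceiling(n / 36), seed = seed)
  ind <- ind[seq_len(n), ]
  meas <- simulate_bilateral(ind, spec, seed = seed + 1)
  carabid_dataset(individuals = ind, measurements = meas)
}

# Null community for permutation calibration: species independent of the
# environment (association 0), with site blocks of consecutive months.
make_null_community <- function(seed, n_sites = 3, n_months = 6,
                                n_species = 8) {
  sp <- community_spec(n_species = n_species,
                       n_sites_per_treatment = 1, n_months = n_months,
                       association = 0)
  sim <- simulate_community(sp, seed = seed)
  keep <- seq_len(n_sites * n_months)
  list(Y = sim$community[keep, , drop = FALSE],
       env = sim$environment[keep, , drop = FALSE],
       blocks = sub("_M[0-9]+$", "", rownames(sim$community)[keep]))
}
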