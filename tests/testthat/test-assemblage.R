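test_that("abundance transform applies log and the rare-species rule", {
  Y <- matrix(c(0, 3, 5,
                2, 0, 1,
                4, 1, 0,
                6, 2, 3), 4, 3, byrow = TRUE)
  tr <- transform_abundances(Y, log = TRUE, downweight = FALSE)
  expect_equal(tr[1, 1], 0)           # ln(0 + 1) = 0
  expect_equal(tr[4, 1], log(7))

  # equal frequencies: downweighting is the identity
  Yeq <- matrix(1:12, 4, 3)
  treq <- transform_abundances(Yeq)
  expect_equal(unname(attr(treq, "species_weights")), rep(1, 3))

  # species in 1 of 10 samples vs f_max = 10: weight = 1 / (10/5) = 0.5
  Yr <- cbind(common = rep(1, 10), rare = c(1, rep(0, 9)))
  trr <- transform_abundances(Yr)
  w <- attr(trr, "species_weights")
  expect_equal(unname(w["rare"]), 0.5)
  expect_equal(unname(w["common"]), 1)
  expect_equal(unname(trr[1, "rare"]), 0.5 * log(2))

  expect_error(transform_abundances(matrix(0, 2, 2)), "all-zero")
  expect_error(transform_abundances(matrix(c(-1, 1, 1, 1), 2)),
               "non-negative")
})

test_that("pCCA eigenvalues match the brute-force weighted eigenproblem", {
  set.seed(21)
  for (i in 1:6) {
    n <- sample(4:6, 1); p <- sample(3:6, 1)
    Y <- matrix(rpois(n * p, 4) + 1, n, p)
    X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("x1", "x2")))
    Z <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "z"))
    ord <- fit_pcca(Y, X)
    expect_equal(unname(ord$eigenvalues),
                 brute_cca_eig(Y, X)[seq_along(ord$eigenvalues)],
                 tolerance = 1e-8)
    ordp <- fit_pcca(Y, X, Z)
    expect_equal(unname(ordp$eigenvalues),
                 brute_cca_eig(Y, X, Z)[seq_along(ordp$eigenvalues)],
                 tolerance = 1e-8)
    # eigenvalues non-increasing, in [0, 1)
    expect_true(all(diff(ordp$eigenvalues) <= 1e-12))
    expect_true(all(ordp$eigenvalues >= 0 & ordp$eigenvalues < 1))
  }
})

test_that("an empty covariable set reduces pCCA to plain CCA", {
  set.seed(22)
  Y <- matrix(rpois(30, 5) + 1, 6, 5)
  X <- data.frame(herbs = rnorm(6))
  a <- fit_pcca(Y, X)
  b <- fit_pcca(Y, X, Z = NULL)
  expect_identical(a$eigenvalues, b$eigenvalues)
  expect_equal(a$conditional_inertia, 0)
  expect_equal(a$explained_of_total, a$explained_after_partial)
})

test_that("partial and joint constrained inertias decompose additively", {
  # inertia(Y ~ X + Z jointly) = inertia(Y ~ Z) + inertia(Y ~ X | Z),
  # and the partial term can never exceed the joint term
  set.seed(23)
  for (i in 1:5) {
    Y <- matrix(rpois(60, 5) + 1, 10, 6)
    X <- matrix(rnorm(20), 10, 2)
    Z <- matrix(rnorm(10), 10, 1)
    joint <- fit_pcca(Y, cbind(X, Z))
    zonly <- fit_pcca(Y, Z)
    part <- fit_pcca(Y, X, Z)
    expect_equal(part$constrained_inertia + zonly$constrained_inertia,
                 joint$constrained_inertia, tolerance = 1e-10)
    expect_lte(part$constrained_inertia,
               joint$constrained_inertia + 1e-12)
  }
})

test_that("cyclic-shift permutations reach exactly T orderings per block", {
  blocks <- rep("b1", 5)
  ctrl <- carafa:::.cyclic_how(blocks, 199)
  perms <- permute::shuffleSet(5, control = ctrl)
  perms <- rbind(1:5, as.matrix(perms))  # observed ordering is a member
  expect_lte(nrow(unique(perms)), 5)    # the cyclic group has order T
  # every row is a cyclic shift
  is_shift <- apply(unique(perms), 1, function(p)
    any(vapply(0:4, function(k) all(p == ((0:4 + k) %% 5) + 1),
               logical(1))))
  expect_true(all(is_shift))
})

test_that("the restricted permutation test flags real structure only", {
  nc <- make_null_community(seed = 31)
  Ytr <- transform_abundances(nc$Y)
  Xnull <- data.frame(noise = rnorm(nrow(Ytr)))
  ord0 <- fit_pcca(Ytr, Xnull)
  r0 <- restricted_permutation_test(ord0, nc$blocks, n_perm = 199,
                                    seed = 32)
  expect_gte(r0$p, 1 / (r0$n_perm + 1))
  expect_lte(r0$p, 1)

  sim <- simulate_community(community_spec(association = 2,
                                           gradient_vars = "herbs"),
                            seed = 33)
  Y1 <- transform_abundances(sim$community)
  X1 <- sim$environment[, "herbs", drop = FALSE]
  blocks <- sub("_M[0-9]+$", "", rownames(sim$community))
  ord1 <- fit_pcca(Y1, X1)
  r1 <- restricted_permutation_test(ord1, blocks, n_perm = 199, seed = 34)
  expect_lt(r1$p, 0.05)
  expect_gt(r1$pseudo_F, 1)
})

test_that("forward selection reports conditional effects sensibly", {
  set.seed(41)
  sim <- simulate_community(community_spec(association = 1.5,
                                           gradient_vars = "herbs"),
                            seed = 42)
  Ytr <- transform_abundances(sim$community)
  blocks <- sub("_M[0-9]+$", "", rownames(sim$community))

  # single candidate: conditional effect equals its marginal effect
  X1 <- sim$environment[, "herbs", drop = FALSE]
  fs1 <- forward_select(Ytr, X1, Z = NULL, blocks, n_perm = 99, seed = 43)
  marg <- fit_pcca(Ytr, X1)
  expect_equal(fs1$explained_pct[1],
               100 * marg$constrained_inertia / marg$total_inertia,
               tolerance = 1e-8)

  # a duplicated candidate contributes nothing once its twin is in
  X2 <- data.frame(herbs = sim$environment$herbs,
                   herbs_copy = sim$environment$herbs)
  fs2 <- forward_select(Ytr, X2, Z = NULL, blocks, n_perm = 99, seed = 44)
  expect_equal(fs2$explained_pct[2], 0, tolerance = 1e-8)
  expect_false(fs2$selected[2])

  # adjusted p never below raw p; entry order recorded
  expect_true(all(fs2$p_adj >= fs2$p - 1e-12))
  expect_equal(fs2$entry_order, seq_len(nrow(fs2)))
})

test_that("the driving gradient is selected first in repeated simulations", {
  hits <- vapply(1:5, function(k) {
    sim <- simulate_community(community_spec(association = 1.5,
                                             gradient_vars = "herbs"),
                              seed = 400 + k)
    Ytr <- transform_abundances(sim$community)
    blocks <- sub("_M[0-9]+$", "", rownames(sim$community))
    X <- sim$environment[, c("herbs", "soil_moisture"), drop = FALSE]
    fs <- forward_select(Ytr, X, Z = NULL, blocks, n_perm = 49,
                         seed = 500 + k)
    fs$variable[1] == "herbs"
  }, logical(1))
  expect_true(all(hits))
})

test_that("community-weighted means follow the definition", {
  Y <- matrix(c(1, 3,
                5, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("spA", "spB")))
  x <- c(spA = 0, spB = 1)
  cwm <- compute_cwm(Y, x)
  expect_equal(cwm, c(0.75, 0))          # p = (0.25, 0.75) -> 0.75
  # single species present: CWM equals that species' value
  expect_equal(compute_cwm(Y, x)[2], 0)
  # constant trait: constant CWM
  expect_equal(compute_cwm(Y, c(spA = 2, spB = 2)), c(2, 2))
  # categorical: proportions per level
  cwm_cat <- compute_cwm(Y, factor(c("pred", "seed"),
                                   levels = c("pred", "seed")))
  expect_equal(unname(cwm_cat[1, ]), c(0.25, 0.75))
  # empty sample is missing
  Y0 <- rbind(Y, s3 = c(0, 0))
  expect_true(is.na(compute_cwm(Y0, x)[3]))
})

test_that("Rao quadratic entropy matches its closed forms", {
  # single species: Q = 0
  expect_equal(compute_raoq(matrix(5, 1, 1), matrix(0, 1, 1)), 0)
  # two equally abundant species at unit distance: Q = 0.5
  Y <- matrix(c(2, 2), 1, 2)
  D <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(unname(compute_raoq(Y, D)), 0.5)
  # n equally abundant species, d = 1: Q = 1 - 1/n
  for (n in c(3, 7)) {
    Yn <- matrix(1, 1, n)
    Dn <- 1 - diag(n)
    expect_equal(unname(compute_raoq(Yn, Dn)), 1 - 1 / n,
                 tolerance = 1e-12)
  }
  expect_error(compute_raoq(Y, matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("passive projection recovers axis-aligned vectors", {
  set.seed(51)
  Y <- matrix(rpois(80, 5) + 1, 10, 8)
  X <- matrix(rnorm(30), 10, 3)
  ord <- fit_pcca(Y, X)
  v1 <- ord$site_scores[, 1]
  pr <- project_supplementary(ord, cbind(ax1 = v1, neg2 = -ord$site_scores[, 2]))
  # arrow along axis 1: slope 1 on axis 1, 0 on axis 2
  expect_equal(unname(pr$arrows["ax1", ]), c(1, 0), tolerance = 1e-8)
  expect_equal(unname(pr$arrows["neg2", ]), c(0, -1), tolerance = 1e-8)
  expect_equal(unname(pr$r2["ax1"]), 1, tolerance = 1e-8)
  # constant vector: zero-length arrow with warning
  expect_warning(pr0 <- project_supplementary(ord, cbind(k = rep(2, 10))),
                 "constant")
  expect_equal(unname(pr0$arrows["k", ]), c(0, 0))
})
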