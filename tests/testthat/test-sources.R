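test_that("pearson matrix matches the hand formula and flags duplicates", {
  x <- cbind(a = c(1, 2, 4, 7, 11), b = c(2, 1, 5, 8, 9))
  res <- pearson_matrix(cbind(x, a2 = x[, "a"]))
  expect_equal(res$r["a", "a2"], 1)

  # direct covariance / sd-product evaluation
  r_hand <- sum((x[, 1] - mean(x[, 1])) * (x[, 2] - mean(x[, 2]))) /
    (4 * sd(x[, 1]) * sd(x[, 2]))
  expect_equal(res$r["a", "b"], r_hand, tolerance = 1e-12)
  expect_true(all(abs(res$r) <= 1))
  expect_equal(res$r, t(res$r))

  expect_warning(pearson_matrix(cbind(x, const = 1)), "constant")
})

test_that("independent columns decorrelate as n grows", {
  set.seed(3)
  x <- matrix(rnorm(5000 * 4), ncol = 4)
  r <- pearson_matrix(x)$r
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)
})

test_that("KMO matches the closed form for an equicorrelated matrix", {
  r <- matrix(0.5, 3, 3)
  diag(r) <- 1
  # partial correlation of an exchangeable trivariate is rho/(1+rho) = 1/3;
  # KMO = 6*0.25 / (6*0.25 + 6*(1/9)) = 9/13
  expect_equal(kmo(r), 9 / 13, tolerance = 1e-12)
  expect_error(kmo(matrix(1, 3, 3)), "singular")
})

test_that("Bartlett statistic is zero at the identity and grows with
           correlation", {
  id <- diag(8)
  b0 <- bartlett_sphericity(id, 72)
  expect_equal(b0$statistic, 0)
  expect_equal(b0$p_value, 1)
  expect_equal(b0$df, 28)

  r <- matrix(0.6, 8, 8)
  diag(r) <- 1
  b1 <- bartlett_sphericity(r, 72)
  expect_gt(b1$statistic, b0$statistic)
  expect_lt(b1$p_value, 0.001)
  expect_error(bartlett_sphericity(id, 8), "n >")
})

test_that("PCA retains rank-matching components and conserves variance", {
  d <- generate_soil_data(seed = 1)
  p <- pair_layers(d$samples)
  for (l in soil_layers()) {
    pc <- pca_varimax(p[[l]])
    expect_equal(pc$n_retained, 2)
    expect_equal(sum(pc$eigenvalues), 8, tolerance = 1e-9)  # trace identity
    expect_false(is.unsorted(rev(pc$eigenvalues)))
    expect_gt(pc$kmo, 0.5)                    # adequacy gate
    expect_lt(pc$bartlett$p_value, 0.001)
    # rotation is orthogonal: communalities are preserved
    expect_equal(rowSums(pc$loadings^2), rowSums(pc$unrotated^2),
                 tolerance = 1e-9)
  }
})

test_that("varimax leaves an already simple structure essentially fixed", {
  set.seed(4)
  f1 <- rnorm(300)
  f2 <- rnorm(300)
  x <- cbind(f1, f1, f1 + 0.01 * rnorm(300), f2, f2,
             f2 + 0.01 * rnorm(300)) + 0.05 * matrix(rnorm(1800), 300)
  pc <- pca_varimax(x)
  expect_equal(pc$n_retained, 2)
  # every variable loads on exactly one rotated component
  primary <- apply(abs(pc$loadings), 1, max)
  cross <- apply(abs(pc$loadings), 1, min)
  expect_true(all(primary > 0.9))
  expect_true(all(cross < 0.1))
})

test_that("uncertainty matrix follows the detection-limit convention", {
  mdl <- detection_limits()
  x <- matrix(c(0.0005, 0.46), 2, 1, dimnames = list(NULL, "Cd"))
  u <- build_uncertainty(x, mdl, delta = 0.1)
  expect_equal(unname(u[1, 1]), 5 / 6 * 0.001, tolerance = 1e-12) # below MDL
  expect_equal(unname(u[2, 1]), sqrt((0.1 * 0.46)^2 + (0.001 / 3)^2),
               tolerance = 1e-12)
  expect_equal(unname(u[2, 1]), 0.046, tolerance = 1e-4)

  # MDL -> 0 shrinks u towards delta * c for quantified values
  u_small <- sqrt((0.1 * 0.46)^2 + (1e-9 / 3)^2)
  expect_gt(u[2, 1], u_small)
  expect_equal(u_small, 0.1 * 0.46, tolerance = 1e-9)
  expect_error(build_uncertainty(x, mdl, delta = 0), "delta")
  expect_true(all(build_uncertainty(matrix(0, 3, 8,
    dimnames = list(NULL, soil_metals())), mdl) > 0))
})

test_that("PMF reaches an exact factorization on separable rank-2 data", {
  # anchored scores (a pure sample per source) make the truth the unique
  # nonnegative factorization
  set.seed(7)
  G0 <- rbind(c(1, 0), c(0, 1),
              cbind(runif(10, 0.2, 2), runif(10, 0.2, 2)))
  F0 <- default_source_profiles()
  X <- G0 %*% F0
  fit <- suppressWarnings(   # plateau warning expected on exact data
    pmf_fit(X, matrix(1, nrow(X), ncol(X)), k = 2, n_restarts = 5,
            seed = 1))
  expect_lt(fit$Q, 1e-6 * sum(X^2))
  est <- contribution_percent(fit)
  # mass-weighted truth: mean score times profile, per factor
  tru <- contribution_percent(diag(colMeans(G0)) %*% F0)
  # within one point; the residual reflects the conditioning of this
  # small fit (near-parallel profile rows), not an identifiability gap
  expect_lt(max(abs(align_factors(est, tru) - tru)), 1)
})

test_that("PMF objective matches an independent box-constrained optimizer", {
  set.seed(12)
  X <- matrix(runif(24, 0.5, 4), 6, 4)
  U <- matrix(1, 6, 4)
  fit <- pmf_fit(X, U, k = 2, n_restarts = 10, seed = 2, polish = FALSE)

  # oracle: generic quasi-Newton minimization over vectorized (G, F)
  qfun <- function(par) {
    G <- matrix(par[1:12], 6, 2)
    F <- matrix(par[13:20], 2, 4)
    sum((X - G %*% F)^2)
  }
  best <- Inf
  for (s in 1:10) {
    set.seed(100 + s)
    o <- optim(runif(20, 0.1, 2), qfun, method = "L-BFGS-B",
               lower = 0, control = list(maxit = 2000, factr = 1e4))
    best <- min(best, o$value)
  }
  expect_lt(fit$Q, best * 1.01 + 1e-10)
  expect_lt(abs(fit$Q - best), 0.01 * max(best, 1e-8) + 1e-8)
})

test_that("the PMF objective is nonincreasing within a run", {
  d <- generate_soil_data(synthetic_config(n_sites = 20), seed = 3)
  p <- pair_layers(d$samples)
  fit <- pmf_fit(p$surface, build_uncertainty(p$surface), n_restarts = 3,
                 seed = 1)
  expect_true(all(diff(fit$q_trace) <= 1e-8 * fit$q_trace[-1] + 1e-12))
  expect_gte(fit$Q, 0)
  # Q is the weighted residual norm of the returned factors
  W <- 1 / build_uncertainty(p$surface)^2
  expect_equal(fit$Q, sum(W * fit$E^2), tolerance = 1e-8)
})

test_that("PMF contract errors fire", {
  X <- matrix(runif(24, 1, 2), 6, 4)
  U <- matrix(1, 6, 4)
  expect_error(pmf_fit(X, U, k = 4), "k must be")
  Xn <- X
  Xn[1, 1] <- -1
  expect_error(pmf_fit(Xn, U), "nonnegative")
  expect_error(pmf_fit(X, U * 0), "positive")
})

test_that("contribution percentages renormalize published profiles", {
  f <- reference_profiles("surface")
  pct <- contribution_percent(t(f))
  expect_equal(unname(colSums(pct)), rep(100, 8), tolerance = 1e-12)
  expect_equal(pct["factor1", "Cu"], 65.4, tolerance = 0.05)
  expect_equal(contribution_percent(rbind(c(2, 1), c(2, 1)))[1, ],
               c(50, 50))
  expect_error(contribution_percent(rbind(c(1, 0), c(1, 0))), "all-zero")
})

test_that("factor labelling is permutation invariant and anchored on
           background tracers", {
  d <- generate_soil_data(seed = 1)
  p <- pair_layers(d$samples)
  fit <- pmf_fit(p$surface, build_uncertainty(p$surface), n_restarts = 5,
                 seed = 1)
  lab <- assign_factor_labels(fit)
  # generator truth: natural factor carries all Pb
  expect_gt(lab$contributions["natural", "Pb"], 90)

  swapped <- fit$F[2:1, ]
  lab2 <- assign_factor_labels(swapped)
  expect_equal(lab$contributions, lab2$contributions, tolerance = 1e-9)

  expect_error(assign_factor_labels(fit$F[1, , drop = FALSE]), "k = 2")
})

test_that("layer comparison reports anthropogenic shifts", {
  s <- matrix(c(60, 40, 30, 70), 2, 2,
              dimnames = list(c("natural", "anthropogenic"), c("Cu", "As")))
  expect_equal(unname(compare_layers(s, s)), c(0, 0))
  d2 <- s
  d2["anthropogenic", "As"] <- 80
  d2["natural", "As"] <- 20
  expect_equal(compare_layers(s, d2)[["As"]], 10)
  expect_equal(compare_layers(d2, s), -compare_layers(s, d2))
  colnames(d2) <- c("Cu", "Pb")
  expect_error(compare_layers(s, d2), "mismatched")
})
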