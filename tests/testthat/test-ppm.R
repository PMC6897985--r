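test_that("eigen analysis matches closed-form solutions", {
  # single stage
  ea1 <- eigen_analysis(ppm(matrix(1)))
  expect_equal(ea1$lambda, 1)
  expect_equal(unname(ea1$w), 1)
  expect_equal(unname(ea1$v), 1)

  # 2-stage with closed-form quadratic root
  p <- ppm(rbind(c(0.5, 2.0), c(0.3, 0.0)))
  ea <- eigen_analysis(p)
  lam <- quad_lambda(0.5, 2.0, 0.3)
  expect_equal(ea$lambda, lam, tolerance = 1e-12)
  # w from the eigenvector equation: w2/w1 = a21 / lambda
  w1 <- 1 / (1 + 0.3 / lam)
  expect_equal(unname(ea$w), c(w1, 1 - w1), tolerance = 1e-12)
  # normalisations
  expect_equal(sum(ea$w), 1, tolerance = 1e-9)
  expect_equal(sum(ea$v * ea$w), 1, tolerance = 1e-9)
  expect_true(all(ea$w > 0) && all(ea$v > 0))
  # cross-check lambda by long-run projection ratio
  tr <- project(p, c(1, 1), 1000)
  expect_equal(tr$densities[1001] / tr$densities[1000], lam,
               tolerance = 1e-9)

  # equal column sums: ones-vector is a left eigenvector, lambda = 0.8
  p2 <- ppm(rbind(c(0.2, 0.2), c(0.6, 0.6)))
  ea2 <- eigen_analysis(p2)
  expect_equal(ea2$lambda, 0.8, tolerance = 1e-12)
  expect_equal(unname(ea2$v[1]), unname(ea2$v[2]), tolerance = 1e-12)
  expect_equal(stable_growth_rate(p2), 0.8, tolerance = 1e-12)
})

test_that("eigen analysis rejects degenerate input", {
  # reducible matrix: reproductive value has a zero entry
  expect_error(eigen_analysis(ppm(rbind(c(0.5, 0), c(0.3, 0.2)))),
               "reducible|imprimitive|positive")
  expect_error(ppm(rbind(c(-0.1, 1), c(0.2, 0))), "non-negative")
  expect_error(ppm(matrix(c(1, 2, 3, 4, 5, 6), 2, 3)), "square")
  # a periodic (imprimitive) life cycle still has a real Perron root, but
  # its damping ratio is 1: no convergence to the stable structure
  ea <- eigen_analysis(ppm(rbind(c(0, 2), c(0.3, 0))))
  expect_equal(ea$damping_ratio, 1, tolerance = 1e-9)
})

test_that("projection follows the matrix recurrence", {
  p <- ppm(rbind(c(0.5, 2.0), c(0.3, 0.0)))
  tr <- project(p, c(1, 0), 1)
  expect_equal(unname(tr$stage_vectors[, 2]), c(0.5, 0.3))

  tr5 <- project(ppm(matrix(1)), 3, 5)
  expect_equal(tr5$densities, rep(3, 6))

  expect_error(project(p, c(1, 0, 0), 2), "stages|length")
  expect_error(project(p, c(-1, 1), 2), "non-negative")
  expect_error(project(p, c(0, 0), 2), "all zero")
})

test_that("stable-start projections are exactly log-linear with slope log lambda", {
  for (seed in c(2, 5, 9)) {
    p <- rand_ppm(4, seed)
    ea <- eigen_analysis(p)
    tr <- project(p, ea$w * 10, 30)
    expect_equal(tr$densities, 10 * ea$lambda^(0:30), tolerance = 1e-9)
    logN <- log(tr$densities)
    resid <- logN - (logN[1] + (0:30) * log(ea$lambda))
    expect_lt(max(abs(resid)), 1e-9)
  }
})

test_that("inertia bounds bracket 1 and collapse iff reproductive value is constant", {
  # collapse case: equal column sums
  b0 <- inertia_bounds(ppm(rbind(c(0.2, 0.2), c(0.6, 0.6))))
  expect_equal(b0$rho_upper, 1, tolerance = 1e-12)
  expect_equal(b0$rho_lower, 1, tolerance = 1e-12)
  b1 <- inertia_bounds(ppm(matrix(1)))
  expect_equal(c(b1$rho_lower, b1$rho_upper), c(1, 1))

  for (seed in 1:20) {
    k <- 2 + seed %% 7
    p <- rand_ppm(k, 100 + seed)
    b <- inertia_bounds(p)
    expect_lte(b$rho_lower, 1 + 1e-12)
    expect_gte(b$rho_upper, 1 - 1e-12)
    expect_true(b$rho_lower > 0 && is.finite(b$rho_upper))
  }
})

test_that("inertia bounds and growth rate transform correctly under rescaling", {
  p <- rand_ppm(5, 42)
  b <- inertia_bounds(p)
  for (cc in c(0.1, 3.7)) {
    ps <- ppm(p$A * cc)
    bs <- inertia_bounds(ps)
    expect_equal(bs$rho_upper, b$rho_upper, tolerance = 1e-9)
    expect_equal(bs$rho_lower, b$rho_lower, tolerance = 1e-9)
    expect_equal(stable_growth_rate(ps), cc * stable_growth_rate(p),
                 tolerance = 1e-9)
  }
})

test_that("brute-force projection attains the inertia bounds on basis vectors", {
  p <- ppm(rbind(c(0.5, 2.0), c(0.3, 0.0)))
  b <- inertia_bounds(p)
  ea <- eigen_analysis(p)
  # stable start has no transient
  expect_equal(inertia_bruteforce(p, ea$w, T = 500), 1.0, tolerance = 1e-9)
  # basis vector of the stage with max (min) reproductive value attains the bound
  up <- inertia_bruteforce(p, as.numeric(seq_along(ea$v) == which.max(ea$v)),
                           T = 2000)
  lo <- inertia_bruteforce(p, as.numeric(seq_along(ea$v) == which.min(ea$v)),
                           T = 2000)
  expect_equal(up, b$rho_upper, tolerance = 1e-6)
  expect_equal(lo, b$rho_lower, tolerance = 1e-6)

  # non-convergence is reported for an imprimitive-style short horizon
  expect_error(inertia_bruteforce(p, c(1, 0), T = 4), "converged")
})

test_that("arbitrary-start log offsets converge into the inertia interval", {
  for (seed in c(3, 8, 13)) {
    p <- rand_ppm(4, seed)
    ea <- eigen_analysis(p)
    b <- inertia_bounds(p)
    set.seed(seed)
    n0 <- runif(4)
    tr <- project(p, n0, 400)
    offset <- log(tr$densities[401]) -
      (log(sum(n0)) + 400 * log(ea$lambda))
    expect_gte(offset, log(b$rho_lower) - 1e-6)
    expect_lte(offset, log(b$rho_upper) + 1e-6)
  }
})

test_that("transient envelope has the stated geometry", {
  # single stage: all lines identical
  e1 <- transient_envelope(ppm(matrix(1)), T = 3)
  expect_equal(e1$upper, rep(1, 4))
  expect_equal(e1$lower, rep(1, 4))

  # collapse case: zero-width envelope around 0.8^t
  e2 <- transient_envelope(ppm(rbind(c(0.2, 0.2), c(0.6, 0.6))), T = 5)
  expect_equal(e2$central, 0.8^(0:5))
  expect_equal(e2$upper, e2$lower, tolerance = 1e-12)

  # width ratio is constant in t and equals rho_upper / rho_lower
  p <- rand_ppm(5, 21)
  b <- inertia_bounds(p)
  e <- transient_envelope(p, T = 10, N0 = 2)
  expect_equal(unique(round(e$upper / e$lower, 9)),
               round(b$rho_upper / b$rho_lower, 9))
  expect_equal(e$central[1], 2)
})

test_that("recruitment per stage follows the stated definition", {
  U <- matrix(0, 2, 2)
  p1 <- ppm(rbind(c(0, 4), c(0, 0)), matU = U, matF = rbind(c(0, 4), c(0, 0)))
  expect_equal(recruitment_per_stage(p1), 2)
  p2 <- ppm(rbind(c(1, 2), c(0, 0)), matU = U, matF = rbind(c(1, 2), c(0, 0)))
  expect_equal(recruitment_per_stage(p2), 1.5)
  expect_equal(recruitment_per_stage(p2, reproductive_only = TRUE), 1.5)
  p3 <- ppm(rbind(c(0, 3), c(0, 0)), matU = U, matF = rbind(c(0, 3), c(0, 0)))
  expect_equal(recruitment_per_stage(p3, reproductive_only = TRUE), 3)
  # all-zero recruitment gives 0 (log undefined downstream)
  p0 <- ppm(rbind(c(0.1, 0), c(0.2, 0.3)), matU = rbind(c(0.1, 0), c(0.2, 0.3)),
            matF = matrix(0, 2, 2))
  expect_equal(recruitment_per_stage(p0), 0)
  # absent split is an error
  expect_error(recruitment_per_stage(ppm(rbind(c(0.5, 2), c(0.3, 0)))),
               "matF")
})
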