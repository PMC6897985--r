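test_that("Brownian covariance from a tree has shared-path-length entries", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- vcv_from_tree(tr, scale_depth = FALSE)
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "A"], 2)
  expect_equal(C["A", "C"], 0)

  # two tips: no shared path
  C2 <- vcv_from_tree(ape::read.tree(text = "(A:1,B:1);"), scale_depth = FALSE)
  expect_equal(unname(C2), diag(2))

  # star tree: identity
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  expect_equal(unname(vcv_from_tree(star, scale_depth = FALSE)), diag(4))

  # depth scaling
  expect_equal(max(diag(vcv_from_tree(tr))), 1)

  # species subsetting drops absentees with a warning, errors on empty
  expect_warning(Cs <- vcv_from_tree(tr, c("A", "Z")), "dropped")
  expect_equal(rownames(Cs), "A")
  expect_error(vcv_from_tree(tr, c("X", "Y")), "none")
})

test_that("fixed-variance posterior mean of beta matches generalised least squares", {
  cats2 <- rep(c("restricted_native", "invasive_naturalised"), each = 15)
  lv <- c("restricted_native", "invasive_naturalised")
  X <- stats::model.matrix(~ 0 + factor(cats2, levels = lv))
  for (fx in 1:5) {
    tr <- generate_tree(30, seed = 600 + fx)
    C <- vcv_from_tree(tr)
    sim <- simulate_phylo_response(C, X, c(1, 1.5), 0.3, 0.2,
                                   seed = 700 + fx)
    tab <- make_metrics_table(rownames(C), cats2, sim$y)
    spec <- model_spec(n_iter = 6000, burnin = 1000, thin = 1,
                       seed = 800 + fx)
    fit <- fit_phylo_mixed_model(tab, C, spec,
                                 fix_sigma = c(phylo = 0.3, resid = 0.2))
    V <- 0.3 * C[tab$species, tab$species] + 0.2 * diag(30)
    Vi <- solve(V)
    bg <- as.numeric(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% sim$y))
    names(bg) <- lv
    for (jname in lv) {
      d <- fit$draws[, jname]
      mcse <- sd(d) / sqrt(demamp:::effective_size(d))
      expect_lt(abs(mean(d) - bg[jname]), 3 * mcse + 1e-12)
    }
  }
})

test_that("sampler reduces to the ordinary linear model when the phylogenetic variance is zero", {
  set.seed(31)
  n <- 60
  cats <- rep(c("restricted_native", "invasive_naturalised"), each = n / 2)
  y <- rnorm(n, ifelse(cats == "invasive_naturalised", 1.4, 1.0), 0.4)
  tab <- make_metrics_table(sprintf("s%02d", 1:n), cats, y)
  spec <- model_spec(n_iter = 8000, burnin = 1000, thin = 1, seed = 5)
  fit <- fit_phylo_mixed_model(tab, NULL, spec,
                               fix_sigma = c(phylo = 0, resid = 0.16))
  ols <- tapply(y, cats, mean)
  for (nm in names(ols)) {
    d <- fit$draws[, nm]
    mcse <- sd(d) / sqrt(demamp:::effective_size(d))
    expect_lt(abs(mean(d) - ols[[nm]]), 3 * mcse + 1e-10)
  }
  expect_true(all(fit$draws[, "sigma2_phylo"] == 0))
})

test_that("identical seed and spec reproduce identical draws", {
  tr <- generate_tree(25, seed = 9)
  C <- vcv_from_tree(tr)
  cats <- rep(c("restricted_native", "invasive_native"), length.out = 25)
  X <- stats::model.matrix(~ 0 + factor(cats))
  sim <- simulate_phylo_response(C, X, c(1, 1.3), 0.2, 0.1, seed = 2)
  tab <- make_metrics_table(rownames(C), cats, sim$y)
  spec <- model_spec(n_iter = 800, burnin = 100, thin = 2, seed = 123)
  f1 <- fit_phylo_mixed_model(tab, C, spec)
  f2 <- fit_phylo_mixed_model(tab, C, spec)
  expect_identical(f1$draws, f2$draws)
})

test_that("category contrasts flag separation and respect the reference", {
  # generator with the reference shifted far up and tiny noise: all credible
  set.seed(17)
  n <- 40
  cats <- rep(c("restricted_native", "introduced_native",
                "invasive_naturalised", "invasive_native"), each = 10)
  mu <- ifelse(cats == "invasive_naturalised", 5, 0)
  tab <- make_metrics_table(sprintf("s%02d", 1:n), cats,
                            rnorm(n, mu, 0.01))
  spec <- model_spec(n_iter = 2000, burnin = 500, thin = 1, seed = 3)
  fit <- fit_phylo_mixed_model(tab, NULL, spec)
  cc <- category_contrasts(fit, "invasive_naturalised")
  expect_equal(nrow(cc), 3)
  expect_true(all(cc$credible))
  expect_true(all(cc$difference > 4))
  expect_error(category_contrasts(fit, "introduced_naturalised"), "absent")
})

test_that("phylogenetic signal concentrates near one when residual noise vanishes", {
  tr <- generate_tree(60, seed = 41)
  C <- vcv_from_tree(tr)
  cats <- rep("restricted_native", 60)
  X <- matrix(1, 60, 1)
  sim <- simulate_phylo_response(C, X, 1, sigma2_phylo = 1,
                                 sigma2_resid = 1e-6, seed = 6)
  tab <- make_metrics_table(rownames(C), cats, sim$y)
  spec <- model_spec(n_iter = 4000, burnin = 1000, thin = 1, seed = 8)
  fit <- fit_phylo_mixed_model(tab, C, spec, fixed = ~ 1)
  sig <- phylo_signal(fit)
  expect_gt(sig$h_median, 0.8)
  expect_true(sig$credible_signal)
  # threshold is honoured
  expect_false(phylo_signal(fit, threshold = 0.999)$credible_signal)
})

test_that("the inertia-recruitment regression recovers a noiseless slope", {
  set.seed(53)
  n <- 40
  x <- rnorm(n)
  tab <- data.frame(species = sprintf("s%02d", 1:n),
                    category = "restricted_native",
                    log_rho_upper = 0.3 + 0.7 * x,
                    log_mean_recruitment = x, stringsAsFactors = FALSE)
  spec <- model_spec(n_iter = 4000, burnin = 1000, thin = 1, seed = 4)
  reg <- metric_regression(tab, NULL, spec)
  expect_equal(reg$slope_mean, 0.7, tolerance = 0.02)
  expect_true(reg$credibly_positive)
  expect_error(metric_regression(tab[1:2, ], NULL, spec), "three")
})

test_that("rerooted ML ancestral states equal brute-force GLS", {
  skip_if_not_installed("phytools")
  # two tips, equal branches: midpoint exactly
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(unname(ancestral_states_bm(tr2, c(A = 0, B = 2))), 1)
  # unequal branches: inverse-distance weighting
  tr3 <- ape::read.tree(text = "(A:1,B:3);")
  expect_equal(unname(ancestral_states_bm(tr3, c(A = 0, B = 2))), 0.5)
  # constancy
  tr6 <- generate_tree(6, seed = 15)
  const <- setNames(rep(3.3, 6), tr6$tip.label)
  expect_equal(unname(ancestral_states_bm(tr6, const)), rep(3.3, 5))

  for (fx in 1:6) {
    tree <- generate_tree(6, seed = 900 + fx)
    set.seed(fx)
    x <- setNames(rnorm(6), tree$tip.label)
    est <- ancestral_states_bm(tree, x)
    for (node in as.integer(names(est))) {
      ref <- brute_node_estimate(tree, x, node)
      expect_equal(unname(est[as.character(node)]), ref, tolerance = 1e-8)
    }
    # cross-check against the independent rerooting-ML implementation
    fa <- phytools::fastAnc(tree, x)
    expect_lt(max(abs(est - as.numeric(fa[names(est)]))), 1e-6)
  }

  # zero-length branches are rejected with the offending node named
  trz <- ape::read.tree(text = "(A:0,B:1);")
  expect_error(ancestral_states_bm(trz, c(A = 0, B = 2)), "branch")
})
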