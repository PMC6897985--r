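#' Brownian-motion covariance matrix from a phylogeny
#'
#' Shared-path-length (Brownian motion) covariance among species:
#' `C[i, j]` is the branch length shared by the root-to-tip paths of tips
#' `i` and `j`, and `C[i, i]` is the root-to-tip depth. By default the
#' matrix is rescaled to unit maximum depth so that the phylogenetic
#' variance component is comparable across trees.
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @param species optional character vector of species to retain; species
#'   absent from the tree are dropped with a warning.
#' @param scale_depth rescale so that the maximum root-to-tip depth is 1.
#' @return A symmetric positive semi-definite matrix with species dimnames.
#' @export
vcv_from_tree <- function(tree, species = NULL, scale_depth = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(species)) {
    present <- species %in% tree$tip.label
    if (!any(present)) {
      stop("none of the requested species are tips of the tree")
    }
    if (!all(present)) {
      warning(sprintf("%d species absent from the tree were dropped: %s",
                      sum(!present),
                      paste(utils::head(species[!present], 5), collapse = ", ")))
    }
    species <- species[present]
    tree <- ape::keep.tip(tree, species)
  }
  C <- ape::vcv(tree)
  if (!is.null(species)) C <- C[species, species, drop = FALSE]
  if (scale_depth) C <- C / max(diag(C))
  C
}

#' Specification of the phylogenetic mixed model and its MCMC settings
#'
#' The model for a species-level log metric `y` is
#' `y = X beta + u + e`, with `u ~ N(0, sigma2_phylo * C)` a phylogenetic
#' species effect and `e ~ N(0, sigma2_resid * I)`. Both variances carry
#' proper weakly-informative inverse-gamma priors (shape = scale = 0.001 by
#' default), fixed effects a diffuse normal prior, and the phylogenetic
#' variance is sampled with a parameter-expanded (redundant multiplier)
#' update to improve mixing when the variance is near zero.
#'
#' @param response which log metric the model explains.
#' @param n_iter total MCMC iterations.
#' @param burnin iterations discarded as burn-in.
#' @param thin thinning interval for stored draws.
#' @param prior_shape,prior_scale inverse-gamma prior parameters for both
#'   variance components.
#' @param beta_prior_var prior variance of fixed effects.
#' @param px_prior_var prior variance of the parameter-expansion multiplier.
#' @param seed RNG seed used by the sampler.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(response = c("log_rho_upper", "log_lambda",
                                    "log_rho_lower"),
                       n_iter = 110000L, burnin = 10000L, thin = 100L,
                       prior_shape = 0.001, prior_scale = 0.001,
                       beta_prior_var = 1e8, px_prior_var = 1e3,
                       seed = 1L) {
  response <- match.arg(response)
  if (n_iter <= burnin) stop("'n_iter' must exceed 'burnin'")
  if (thin < 1) stop("'thin' must be at least 1")
  structure(
    list(response = response, n_iter = as.integer(n_iter),
         burnin = as.integer(burnin), thin = as.integer(thin),
         prior_shape = prior_shape, prior_scale = prior_scale,
         beta_prior_var = beta_prior_var, px_prior_var = px_prior_var,
         seed = as.integer(seed)),
    class = "model_spec"
  )
}

rinvgamma1 <- function(shape, scale) 1 / stats::rgamma(1, shape, rate = scale)

# Gibbs sampler for the species-level model (one observation per species).
# The model is rotated into the eigenbasis of C, where the phylogenetic
# effect has a diagonal covariance, so every update is O(n).
gibbs_species_level <- function(y, X, C, spec, fix_sigma = NULL) {
  n <- length(y)
  p <- ncol(X)
  eC <- eigen(C, symmetric = TRUE)
  if (min(eC$values) < -1e-9 * max(eC$values)) {
    stop("'C' is not positive semi-definite")
  }
  d <- pmax(eC$values, 1e-10 * max(eC$values))
  E <- eC$vectors
  ys <- as.numeric(crossprod(E, y))
  Xs <- crossprod(E, X)
  XtX <- crossprod(Xs)
  a <- spec$prior_shape
  b <- spec$prior_scale
  Vb <- spec$beta_prior_var
  Va <- spec$px_prior_var

  fixed_var <- !is.null(fix_sigma)
  if (fixed_var) {
    stopifnot(all(c("phylo", "resid") %in% names(fix_sigma)))
  }
  phylo_on <- !(fixed_var && fix_sigma[["phylo"]] <= 0)
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  s2e <- if (fixed_var) fix_sigma[["resid"]] else vy / 2
  s2eta <- if (fixed_var && phylo_on) fix_sigma[["phylo"]] else vy / 2
  alpha <- 1
  eta <- numeric(n)

  n_store <- (spec$n_iter - spec$burnin) %/% spec$thin
  draws <- matrix(NA_real_, n_store, p + 2)
  si <- 0
  for (it in seq_len(spec$n_iter)) {
    r_u <- ys - alpha * eta
    Prec <- XtX / s2e
    diag(Prec) <- diag(Prec) + 1 / Vb
    ch <- chol(Prec)
    mu <- backsolve(ch, forwardsolve(t(ch), crossprod(Xs, r_u) / s2e))
    beta <- as.numeric(mu + backsolve(ch, stats::rnorm(p)))
    z <- ys - as.numeric(Xs %*% beta)
    if (phylo_on) {
      pr <- alpha^2 / s2e + 1 / (s2eta * d)
      eta <- (alpha / s2e) * z / pr + stats::rnorm(n) / sqrt(pr)
      if (!fixed_var) {
        pa <- sum(eta^2) / s2e + 1 / Va
        alpha <- stats::rnorm(1, (sum(eta * z) / s2e) / pa, 1 / sqrt(pa))
        s2eta <- rinvgamma1(a + n / 2, b + sum(eta^2 / d) / 2)
      }
    }
    resid <- z - alpha * eta
    if (!fixed_var) s2e <- rinvgamma1(a + n / 2, b + sum(resid^2) / 2)
    if (it > spec$burnin && (it - spec$burnin) %% spec$thin == 0) {
      si <- si + 1
      draws[si, ] <- c(beta, if (phylo_on) alpha^2 * s2eta else 0, s2e)
    }
  }
  draws
}

# Gibbs sampler for the population-level (nested) model: observations are
# populations, with a phylogenetic species effect (covariance sigma2_phylo*C)
# and an additional exchangeable species effect. O(n^3) per iteration.
gibbs_nested <- function(y, X, sp_index, C, spec) {
  N <- length(y)
  p <- ncol(X)
  n <- nrow(C)
  m <- tabulate(sp_index, nbins = n)
  Cinv <- chol2inv(chol(C + diag(1e-10 * max(diag(C)), n)))
  XtX <- crossprod(X)
  a <- spec$prior_shape
  b <- spec$prior_scale
  Vb <- spec$beta_prior_var
  Va <- spec$px_prior_var
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  s2e <- vy / 3
  s2eta <- vy / 3
  s2s <- vy / 3
  alpha <- 1
  eta <- numeric(n)
  wsp <- numeric(n)

  n_store <- (spec$n_iter - spec$burnin) %/% spec$thin
  draws <- matrix(NA_real_, n_store, p + 3)
  si <- 0
  for (it in seq_len(spec$n_iter)) {
    ranef_obs <- (alpha * eta + wsp)[sp_index]
    Prec <- XtX / s2e
    diag(Prec) <- diag(Prec) + 1 / Vb
    ch <- chol(Prec)
    mu <- backsolve(ch, forwardsolve(t(ch), crossprod(X, y - ranef_obs) / s2e))
    beta <- as.numeric(mu + backsolve(ch, stats::rnorm(p)))
    z <- y - as.numeric(X %*% beta)
    # phylogenetic effect (parameter-expanded)
    z_eta <- z - wsp[sp_index]
    Q <- Cinv / s2eta
    diag(Q) <- diag(Q) + alpha^2 * m / s2e
    chq <- chol(Q)
    rhs <- alpha * rowsum_vec(z_eta, sp_index, n) / s2e
    eta <- as.numeric(backsolve(chq, forwardsolve(t(chq), rhs) +
                                  stats::rnorm(n)))
    pa <- sum(m * eta^2) / s2e + 1 / Va
    alpha <- stats::rnorm(1, (sum(eta * rowsum_vec(z_eta, sp_index, n)) / s2e) / pa,
                          1 / sqrt(pa))
    s2eta <- rinvgamma1(a + n / 2, b + as.numeric(t(eta) %*% Cinv %*% eta) / 2)
    # exchangeable species effect
    z_w <- z - alpha * eta[sp_index]
    prw <- m / s2e + 1 / s2s
    wsp <- (rowsum_vec(z_w, sp_index, n) / s2e) / prw +
      stats::rnorm(n) / sqrt(prw)
    s2s <- rinvgamma1(a + n / 2, b + sum(wsp^2) / 2)
    resid <- z - (alpha * eta + wsp)[sp_index]
    s2e <- rinvgamma1(a + N / 2, b + sum(resid^2) / 2)
    if (it > spec$burnin && (it - spec$burnin) %% spec$thin == 0) {
      si <- si + 1
      draws[si, ] <- c(beta, alpha^2 * s2eta, s2s, s2e)
    }
  }
  draws
}

rowsum_vec <- function(x, index, n) {
  out <- numeric(n)
  agg <- rowsum(x, index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Fit the Bayesian phylogenetic mixed model by Gibbs sampling
#'
#' Samples the posterior of `y = X beta + u + e` with
#' `u ~ N(0, sigma2_phylo * C)` and `e ~ N(0, sigma2_resid * I)` under the
#' priors of [model_spec()]. At species level (default) the model is
#' rotated into the eigenbasis of `C`, making every Gibbs update
#' conditionally independent; with `nested = TRUE` the response is at
#' population level and an additional exchangeable species effect is
#' included. A non-phylogenetic fit is obtained by passing `C = NULL`
#' (identity covariance). With `fix_sigma` both variances are held fixed,
#' in which case the posterior mean of `beta` coincides with the
#' generalised-least-squares estimator up to Monte-Carlo error.
#'
#' @param table data frame of species metrics (see
#'   [species_category_means()]); must contain `species`, the response
#'   column named by `spec$response`, and any variables used in `fixed`.
#' @param C phylogenetic covariance from [vcv_from_tree()], or `NULL` for
#'   an identity (non-phylogenetic) covariance. Species absent from `C`
#'   are dropped with a warning.
#' @param spec a [model_spec()].
#' @param fixed one-sided formula for the fixed effects, evaluated in
#'   `table` (default `~ 0 + category`, giving one mean per category).
#' @param fix_sigma optional named vector `c(phylo = , resid = )` fixing
#'   the variance components (disables their updates and the parameter
#'   expansion).
#' @param nested population-level model with species as an additional
#'   exchangeable random effect (`table` then has one row per population).
#' @return An object of class `phylo_fit`: stored draws, coefficient
#'   names, the spec, and convergence diagnostics (effective sample size
#'   and Geweke z per stored parameter).
#' @export
fit_phylo_mixed_model <- function(table, C, spec = model_spec(),
                                  fixed = ~ 0 + category,
                                  fix_sigma = NULL, nested = FALSE) {
  stopifnot(is.data.frame(table), inherits(spec, "model_spec"))
  if (!spec$response %in% names(table)) {
    stop(sprintf("response '%s' is not a column of 'table'", spec$response))
  }
  tab <- table[!is.na(table[[spec$response]]), , drop = FALSE]
  species <- unique(tab$species)
  if (is.null(C)) {
    C <- diag(length(species))
    dimnames(C) <- list(species, species)
  }
  keep <- tab$species %in% rownames(C)
  if (!all(keep)) {
    warning(sprintf("%d rows dropped: species absent from the covariance matrix",
                    sum(!keep)))
    tab <- tab[keep, , drop = FALSE]
  }
  if (nrow(tab) < 2) stop("fewer than two usable rows")
  if ("category" %in% all.vars(fixed)) {
    tab$category <- factor(tab$category,
                           levels = intersect(invasiveness_categories(),
                                              unique(tab$category)))
    if (nlevels(tab$category) < 2 && length(all.vars(fixed)) == 1) {
      stop("at least two categories must be present")
    }
  }
  X <- stats::model.matrix(fixed, data = tab)
  colnames(X) <- sub("^category", "", colnames(X))
  y <- tab[[spec$response]]

  set.seed(spec$seed)
  if (nested) {
    sp_levels <- sort(unique(tab$species))
    Csub <- C[sp_levels, sp_levels, drop = FALSE]
    sp_index <- match(tab$species, sp_levels)
    draws <- gibbs_nested(y, X, sp_index, Csub, spec)
    colnames(draws) <- c(colnames(X), "sigma2_phylo", "sigma2_species",
                         "sigma2_resid")
  } else {
    if (anyDuplicated(tab$species)) {
      stop("species-level model needs one row per species; use nested = TRUE")
    }
    Csub <- C[tab$species, tab$species, drop = FALSE]
    draws <- gibbs_species_level(y, X, Csub, spec, fix_sigma = fix_sigma)
    colnames(draws) <- c(colnames(X), "sigma2_phylo", "sigma2_resid")
  }
  diagnostics <- data.frame(
    parameter = colnames(draws),
    ess = apply(draws, 2, effective_size),
    geweke_z = apply(draws, 2, geweke_z),
    row.names = NULL
  )
  structure(
    list(draws = draws, beta_names = colnames(X), spec = spec,
         n = nrow(tab), nested = nested, fixed = fixed,
         fix_sigma = fix_sigma, diagnostics = diagnostics),
    class = "phylo_fit"
  )
}

#' @export
print.phylo_fit <- function(x, ...) {
  cat(sprintf("phylogenetic mixed model fit: %d rows, %d stored draws\n",
              x$n, nrow(x$draws)))
  qs <- t(apply(x$draws, 2, stats::quantile, c(0.025, 0.5, 0.975)))
  print(round(cbind(mean = colMeans(x$draws), qs), 4))
  invisible(x)
}

# effective sample size via initial-positive-sequence autocorrelation sum
effective_size <- function(x) {
  n <- length(x)
  if (n < 3 || stats::var(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1, 10 * floor(sqrt(n))),
                    plot = FALSE)$acf[-1]
  s <- 0
  for (r in rho) {
    if (r < 0) break
    s <- s + r
  }
  n / (1 + 2 * s)
}

# Geweke-style z comparing the first 10% and last 50% of the chain
geweke_z <- function(x) {
  n <- length(x)
  if (n < 20 || stats::var(x) == 0) return(0)
  a <- x[seq_len(max(2, floor(0.1 * n)))]
  b <- x[seq.int(floor(0.5 * n) + 1, n)]
  (mean(a) - mean(b)) /
    sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
}

#' Highest posterior density interval
#'
#' Shortest empirical interval containing a given posterior mass.
#'
#' @param x numeric vector of posterior draws.
#' @param prob interval mass (default 0.95).
#' @return Length-2 numeric vector (lower, upper).
#' @export
hpd_interval <- function(x, prob = 0.95) {
  xs <- sort(x)
  n <- length(xs)
  m <- max(1, ceiling(prob * n))
  if (m >= n) return(c(xs[1], xs[n]))
  i <- which.min(xs[seq.int(m, n)] - xs[seq_len(n - m + 1)])
  c(xs[i], xs[i + m - 1])
}

#' Posterior contrasts of category means against a reference category
#'
#' For each non-reference category, the posterior distribution of the
#' difference (reference minus category) is summarised by its mean and
#' central 95% interval; a contrast is flagged credible when the interval
#' excludes zero.
#'
#' @param fit a `phylo_fit` from a categorical model.
#' @param reference reference category (default the invasive species
#'   measured in the naturalised range).
#' @return Data frame with one row per non-reference category:
#'   `difference`, `lower`, `upper`, `credible`.
#' @export
category_contrasts <- function(fit, reference = "invasive_naturalised") {
  stopifnot(inherits(fit, "phylo_fit"))
  cats <- intersect(fit$beta_names, invasiveness_categories())
  if (!reference %in% cats) {
    stop(sprintf("reference category '%s' is absent from the fit", reference))
  }
  others <- setdiff(cats, reference)
  rows <- lapply(others, function(cc) {
    dd <- fit$draws[, reference] - fit$draws[, cc]
    if (length(dd) == 1) {
      lo <- hi <- dd
    } else {
      q <- stats::quantile(dd, c(0.025, 0.975), names = FALSE)
      lo <- q[1]
      hi <- q[2]
    }
    data.frame(category = cc, difference = mean(dd), lower = lo, upper = hi,
               credible = (lo > 0 | hi < 0), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "reference") <- reference
  out
}

#' Phylogenetic signal report
#'
#' Summarises the posterior of the phylogenetic variance and of the
#' variance ratio `h = sigma2_phylo / (sigma2_phylo + sigma2_resid)`.
#' Because a variance posterior is always positive, "credibly above zero"
#' is operationalised as the lower bound of the 95% HPD interval of `h`
#' exceeding a configurable threshold.
#'
#' @param fit a `phylo_fit`.
#' @param threshold lower HPD bound of `h` that counts as credible signal
#'   (default 0.05).
#' @return A list of class `phylo_signal` with posterior summaries of
#'   `sigma2_phylo` and `h`, the HPD bounds, the threshold, and the flag
#'   `credible_signal`.
#' @export
phylo_signal <- function(fit, threshold = 0.05) {
  stopifnot(inherits(fit, "phylo_fit"))
  s2p <- fit$draws[, "sigma2_phylo"]
  s2e <- fit$draws[, "sigma2_resid"]
  h <- s2p / (s2p + s2e)
  hpd_p <- hpd_interval(s2p)
  hpd_h <- hpd_interval(h)
  structure(
    list(sigma2_phylo_mean = mean(s2p), sigma2_phylo_hpd = hpd_p,
         h_mean = mean(h), h_median = stats::median(h), h_hpd = hpd_h,
         threshold = threshold,
         credible_signal = hpd_h[1] > threshold),
    class = "phylo_signal"
  )
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat(sprintf("phylogenetic variance: %.4f (95%% HPD %.4f-%.4f)\n",
              x$sigma2_phylo_mean, x$sigma2_phylo_hpd[1], x$sigma2_phylo_hpd[2]))
  cat(sprintf("h = s2_phylo/(s2_phylo+s2_resid): %.3f (95%% HPD %.3f-%.3f)\n",
              x$h_mean, x$h_hpd[1], x$h_hpd[2]))
  cat(sprintf("credible signal (HPD lower bound > %.2f): %s\n",
              x$threshold, x$credible_signal))
  invisible(x)
}

#' Inertia-recruitment regression
#'
#' Regresses the species-level log upper inertia bound on log mean
#' recruitment per stage, using the same phylogenetic mixed-model
#' machinery (identity covariance when `C` is `NULL`), optionally with
#' category as a covariate. Reports the posterior of the slope and whether
#' it is credibly positive.
#'
#' @param table species metrics table with `log_rho_upper` and
#'   `log_mean_recruitment`.
#' @param C phylogenetic covariance or `NULL`.
#' @param spec a [model_spec()] (its `response` is forced to
#'   `log_rho_upper`).
#' @param include_category add the category factor to the fixed effects.
#' @return A list of class `metric_regression`: slope posterior mean,
#'   95% interval, posterior probability of positivity, the credibility
#'   flag, and the underlying `phylo_fit`.
#' @export
metric_regression <- function(table, C = NULL, spec = model_spec(),
                              include_category = FALSE) {
  ok <- !is.na(table$log_rho_upper) & !is.na(table$log_mean_recruitment)
  tab <- table[ok, , drop = FALSE]
  if (nrow(tab) < 3) {
    stop("need at least three species with non-missing recruitment")
  }
  spec$response <- "log_rho_upper"
  fixed <- if (include_category) {
    ~ log_mean_recruitment + category
  } else {
    ~ log_mean_recruitment
  }
  fit <- fit_phylo_mixed_model(tab, C, spec, fixed = fixed)
  slope <- fit$draws[, "log_mean_recruitment"]
  q <- stats::quantile(slope, c(0.025, 0.975), names = FALSE)
  structure(
    list(slope_mean = mean(slope), lower = q[1], upper = q[2],
         prob_positive = mean(slope > 0),
         credibly_positive = q[1] > 0,
         n = fit$n, fit = fit),
    class = "metric_regression"
  )
}

#' @export
print.metric_regression <- function(x, ...) {
  cat(sprintf(paste0("inertia-recruitment slope: %.4f (95%% CI %.4f to %.4f),",
                     " P(slope > 0) = %.3f\n"),
              x$slope_mean, x$lower, x$upper, x$prob_positive))
  invisible(x)
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' For each internal node, the Brownian-motion maximum-likelihood estimate
#' of the nodal state: the generalised-least-squares root-state estimate of
#' the tree rerooted at that node,
#' `xhat = (1' Cr^-1 x) / (1' Cr^-1 1)` under the rerooted covariance `Cr`.
#' Computed in linear time by two-pass Gaussian message passing along the
#' tree (equivalent to rerooting at every node), so no covariance matrix is
#' ever inverted.
#'
#' @param tree a rooted `phylo` with strictly positive branch lengths.
#' @param x named numeric vector of tip values covering every tip.
#' @return Named numeric vector of estimates for internal nodes (names are
#'   the ape node numbers `Ntip+1 ... Ntip+Nnode`).
#' @export
ancestral_states_bm <- function(tree, x) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("'tree' must be rooted")
  n <- length(tree$tip.label)
  if (is.null(names(x)) || !all(tree$tip.label %in% names(x))) {
    stop("'x' must be a named vector covering every tip")
  }
  if (is.null(tree$edge.length)) stop("'tree' must have branch lengths")
  if (any(tree$edge.length <= 0)) {
    bad <- tree$edge[tree$edge.length <= 0, 2]
    stop(sprintf("non-positive branch length above node(s) %s",
                 paste(bad, collapse = ", ")))
  }
  x <- x[tree$tip.label]
  N <- n + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  elen <- po$edge.length
  parent_of <- integer(N)
  edge_len_to_parent <- numeric(N)
  parent_of[edge[, 2]] <- edge[, 1]
  edge_len_to_parent[edge[, 2]] <- elen

  up_m <- numeric(N)   # message node -> parent: mean
  up_v <- numeric(N)   # message node -> parent: variance (incl. own edge)
  sub_prec <- numeric(N)
  sub_mean <- numeric(N)
  up_m[seq_len(n)] <- x
  up_v[seq_len(n)] <- edge_len_to_parent[seq_len(n)]
  children <- split(edge[, 2], edge[, 1])

  # visit each parent only once all its child edges have been seen:
  # order internal nodes by the last postorder position of their child edges
  v_order <- rev(unique(rev(edge[, 1])))
  for (v in v_order) {
    kids <- children[[as.character(v)]]
    prec <- sum(1 / up_v[kids])
    m <- sum(up_m[kids] / up_v[kids]) / prec
    sub_prec[v] <- prec
    sub_mean[v] <- m
    up_m[v] <- m
    up_v[v] <- 1 / prec + edge_len_to_parent[v]
  }

  root <- n + 1L
  down_m <- rep(NA_real_, N)
  down_v <- rep(NA_real_, N)
  # preorder: reverse postorder edge order visits parents before children
  for (ei in rev(seq_len(nrow(edge)))) {
    v <- edge[ei, 1]
    c_node <- edge[ei, 2]
    sibs <- setdiff(children[[as.character(v)]], c_node)
    prec <- sum(1 / up_v[sibs])
    msum <- sum(up_m[sibs] / up_v[sibs])
    if (v != root) {
      prec <- prec + 1 / down_v[v]
      msum <- msum + down_m[v] / down_v[v]
    }
    down_m[c_node] <- msum / prec
    down_v[c_node] <- 1 / prec + elen[ei]
  }

  internal <- seq.int(root, N)
  est <- vapply(internal, function(v) {
    prec <- sub_prec[v]
    msum <- sub_mean[v] * sub_prec[v]
    if (v != root) {
      prec <- prec + 1 / down_v[v]
      msum <- msum + down_m[v] / down_v[v]
    }
    msum / prec
  }, numeric(1))
  names(est) <- as.character(internal)
  est
}
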