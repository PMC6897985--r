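#' Configuration for the synthetic dataset generator
#'
#' Describes a synthetic comparative study: how many species, their
#' life-cycle sizes, spatial and temporal replication, the category mix,
#' the true category effects on log upper inertia, the phylogenetic and
#' residual variances, and the rates at which pathological records
#' (reducible matrices, greenhouse settings, treatments, pooled or mean
#' matrices, post-reproductive censuses, seed-problem structures) are
#' injected to exercise the QC engine.
#'
#' Defaults emulate the statistical structure the comparative analysis
#' assumes: species-level log inertia values around 1.2 (invasive
#' categories +0.5), phylogenetic variance 0.2 and species residual
#' variance 0.1 on a depth-1 tree, small life cycles (2-5 stages), 1-3
#' populations per species and 1-4 annual matrices per population.
#'
#' @param seed master integer seed; all sub-generators derive their seeds
#'   from it.
#' @param n_species number of species.
#' @param stages_range inclusive range of stage counts (within 2..8).
#' @param populations_per_species inclusive range of spatial replicates.
#' @param years_per_population inclusive range of annual matrices.
#' @param category_probabilities probabilities of the five categories (in
#'   the order of [invasiveness_categories()]).
#' @param true_category_effects named or ordered 5-vector of category means
#'   of log upper inertia.
#' @param sigma2_phylo phylogenetic variance of the species effect.
#' @param sigma2_resid species-level residual variance.
#' @param population_sd standard deviation of population-level noise around
#'   the species value.
#' @param fecundity_meanlog,fecundity_sdlog log-normal parameters of base
#'   per-capita fecundities.
#' @param survival_concentration Dirichlet-type concentration used to
#'   allocate survival across destination stages.
#' @param pathology_rates named list of injection rates (per matrix record):
#'   `reducible`, `greenhouse`, `pooled`, `mean_matrix`, `treatment`,
#'   `post_census`, `seed_problem`. All default to 0.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_species = 50L,
                             stages_range = c(2L, 5L),
                             populations_per_species = c(1L, 3L),
                             years_per_population = c(1L, 4L),
                             category_probabilities =
                               c(0.55, 0.2, 0.02, 0.1, 0.13),
                             true_category_effects =
                               c(restricted_native = 1.2,
                                 introduced_native = 1.2,
                                 introduced_naturalised = 1.2,
                                 invasive_native = 1.7,
                                 invasive_naturalised = 1.7),
                             sigma2_phylo = 0.2,
                             sigma2_resid = 0.1,
                             population_sd = 0.1,
                             fecundity_meanlog = 1.0,
                             fecundity_sdlog = 0.7,
                             survival_concentration = 1.5,
                             pathology_rates = list()) {
  stopifnot(length(category_probabilities) == 5,
            abs(sum(category_probabilities) - 1) < 1e-9,
            length(true_category_effects) == 5,
            sigma2_phylo >= 0, sigma2_resid >= 0, population_sd >= 0,
            stages_range[1] >= 2, stages_range[2] <= 8,
            stages_range[1] <= stages_range[2],
            populations_per_species[1] >= 1,
            populations_per_species[1] <= populations_per_species[2],
            years_per_population[1] >= 1,
            years_per_population[1] <= years_per_population[2])
  if (is.null(names(true_category_effects))) {
    names(true_category_effects) <- invasiveness_categories()
  }
  defaults <- list(reducible = 0, greenhouse = 0, pooled = 0,
                   mean_matrix = 0, treatment = 0, post_census = 0,
                   seed_problem = 0)
  defaults[names(pathology_rates)] <- pathology_rates
  structure(
    list(seed = as.integer(seed), n_species = as.integer(n_species),
         stages_range = as.integer(stages_range),
         populations_per_species = as.integer(populations_per_species),
         years_per_population = as.integer(years_per_population),
         category_probabilities = category_probabilities,
         true_category_effects = true_category_effects,
         sigma2_phylo = sigma2_phylo, sigma2_resid = sigma2_resid,
         population_sd = population_sd,
         fecundity_meanlog = fecundity_meanlog,
         fecundity_sdlog = fecundity_sdlog,
         survival_concentration = survival_concentration,
         pathology_rates = defaults),
    class = "synthetic_config"
  )
}

# deterministic seed-splitting: sub-stream s of master seed
sub_seed <- function(seed, stream) {
  (as.numeric(seed) * 2654435 + as.numeric(stream) * 97 + 13) %% 2147483647
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Generate a random primitive projection matrix
#'
#' Draws a stage-structured life cycle: per-stage survival is allocated
#' across destination stages by a concentration-parameterised simplex draw
#' (weighted towards stasis and progression) and scaled by a survival
#' probability below 1, and per-capita recruitment into the first stage is
#' drawn log-normally from the reproductive (later) stages. Candidates are
#' rejection-sampled until irreducible and primitive. Identical
#' `(k, params, seed)` give an identical matrix.
#'
#' @param k number of stages (2..8).
#' @param params a [synthetic_config()] supplying fecundity and survival
#'   parameters (defaults used when omitted).
#' @param seed integer seed.
#' @param homogeneous_survival draw one common survival probability for all
#'   stages (gives near-equal column sums, hence near-constant reproductive
#'   value and inertia bounds close to 1 at low recruitment).
#' @return A [ppm] with `matU`/`matF` split, pre-reproductive census.
#' @export
generate_ppm <- function(k, params = synthetic_config(), seed = 1L,
                         homogeneous_survival = FALSE) {
  if (k < 2 || k > 8) stop("'k' must be between 2 and 8")
  set.seed(seed)
  conc <- params$survival_concentration
  for (attempt in seq_len(100)) {
    surv <- if (homogeneous_survival) {
      rep(stats::runif(1, 0.2, 0.95), k)
    } else {
      stats::runif(k, 0.2, 0.95)
    }
    matU <- matrix(0, k, k)
    for (j in seq_len(k)) {
      alpha <- rep(0.3, k)
      alpha[j] <- conc                      # stasis
      if (j < k) alpha[j + 1] <- conc * 1.5 # progression
      matU[, j] <- surv[j] * rdirichlet1(alpha)
    }
    matF <- matrix(0, k, k)
    repro <- seq.int(max(2, ceiling(k / 2) + 1), k)
    matF[1, repro] <- stats::rlnorm(length(repro), params$fecundity_meanlog,
                                    params$fecundity_sdlog)
    A <- matU + matF
    pm <- ppm(A, matU = matU, matF = matF, census = "pre_reproductive")
    if (is_irreducible(pm) && is_primitive(pm)) return(pm)
  }
  stop("rejection budget exhausted while generating a primitive matrix")
}

#' Generate a Yule (pure-birth) phylogeny
#'
#' Grows a pure-birth tree to the requested number of tips, retaining all
#' extant lineages to the stopping time, so the tree is ultrametric. Tips
#' are labelled `sp001, sp002, ...`.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed.
#' @param birth birth rate of the Yule process.
#' @return A `phylo` object.
#' @export
generate_tree <- function(n_tips, seed = 1L, birth = 1) {
  if (n_tips < 2) stop("'n_tips' must be at least 2")
  set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = birth, death = 0)
  tr$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  tr
}

#' Draw a response from the phylogenetic mixed model's generative form
#'
#' `y = X beta + u + e` with `u ~ N(0, sigma2_phylo * C)` and
#' `e ~ N(0, sigma2_resid * I)`. Returns the response together with the
#' hidden `u` and `e` for recovery tests.
#'
#' @param C phylogenetic covariance matrix.
#' @param X fixed-effect design matrix (rows matching `C`).
#' @param beta fixed-effect coefficients.
#' @param sigma2_phylo,sigma2_resid variance components (>= 0).
#' @param seed integer seed.
#' @return A list with `y`, `u`, `e`.
#' @export
simulate_phylo_response <- function(C, X, beta, sigma2_phylo, sigma2_resid,
                                    seed = 1L) {
  n <- nrow(C)
  stopifnot(nrow(X) == n, ncol(X) == length(beta))
  set.seed(seed)
  u <- if (sigma2_phylo > 0) {
    L <- chol(C + diag(1e-12 * max(diag(C)), n))
    sqrt(sigma2_phylo) * as.numeric(crossprod(L, stats::rnorm(n)))
  } else {
    numeric(n)
  }
  e <- if (sigma2_resid > 0) stats::rnorm(n, 0, sqrt(sigma2_resid)) else
    numeric(n)
  list(y = as.numeric(X %*% beta) + u + e, u = u, e = e)
}

#' Simulate a species metrics table with known truth
#'
#' Assigns categories by the configured probabilities and draws the
#' response (log upper inertia) from the generative form of the
#' phylogenetic mixed model on the supplied tree. Returns both the
#' observable table and the hidden truth.
#'
#' @param tree a `phylo` with at least `cfg$n_species` tips.
#' @param cfg a [synthetic_config()].
#' @param response name of the simulated response column.
#' @return A list with `table` (species metrics data frame) and `truth`
#'   (`beta`, `u`, `e`, `C`).
#' @export
simulate_species_metrics <- function(tree, cfg = synthetic_config(),
                                     response = "log_rho_upper") {
  n <- cfg$n_species
  if (length(tree$tip.label) < n) stop("tree has fewer tips than species")
  species <- tree$tip.label[seq_len(n)]
  C <- vcv_from_tree(tree, species)
  set.seed(sub_seed(cfg$seed, 1))
  cats <- sample(invasiveness_categories(), n, replace = TRUE,
                 prob = cfg$category_probabilities)
  X <- stats::model.matrix(~ 0 + factor(cats, invasiveness_categories()))
  colnames(X) <- invasiveness_categories()
  beta <- cfg$true_category_effects[invasiveness_categories()]
  sim <- simulate_phylo_response(C, X, beta, cfg$sigma2_phylo,
                                 cfg$sigma2_resid,
                                 seed = sub_seed(cfg$seed, 2))
  status <- sub("_(native|naturalised)$", "", cats)
  range_ctx <- sub("^.*_", "", cats)
  tab <- data.frame(
    species = species, category = cats, range_context = range_ctx,
    global_status = status, log_lambda = NA_real_,
    log_rho_upper = NA_real_, log_rho_lower = NA_real_,
    log_mean_recruitment = NA_real_, n_populations = 1L,
    stringsAsFactors = FALSE
  )
  tab[[response]] <- sim$y
  list(table = tab, truth = list(beta = beta, u = sim$u, e = sim$e, C = C))
}

# Scale the recruitment component of a base life cycle so that the
# resulting matrix attains a target log upper inertia bound.
match_inertia_target <- function(base, target_log_rho, theta_range = c(-8, 9)) {
  f <- function(ltheta) {
    matF <- base$matF * exp(ltheta)
    pm <- ppm(base$matU + matF, stages = base$stages, matU = base$matU,
              matF = matF, census = base$census)
    log(inertia_bounds(pm)$rho_upper) - target_log_rho
  }
  tryCatch({
    lo <- f(theta_range[1])
    hi <- f(theta_range[2])
    if (is.na(lo) || is.na(hi) || lo * hi > 0) return(NULL)
    root <- stats::uniroot(f, theta_range, tol = 1e-10)$root
    matF <- base$matF * exp(root)
    ppm(base$matU + matF, stages = base$stages, matU = base$matU, matF = matF,
        census = base$census)
  }, error = function(e) NULL)
}

# Build yearly matrices around a population mean matrix. Each year rescales
# every column of matU and matF by a positive factor; the factors average
# exactly to 1 across years, so the temporal mean is exactly the mean
# matrix, the zero pattern (hence irreducibility and primitivity) is
# preserved, and survival column sums stay below 1 by construction.
yearly_matrices_around <- function(mean_pm, n_years, rel_sd = 0.15) {
  if (n_years == 1) return(list(mean_pm))
  k <- nrow(mean_pm$A)
  centered_factors <- function(bound) {
    # bound: largest admissible |deviation| per column
    z <- matrix(stats::rnorm(k * n_years), k, n_years)
    z <- z - rowMeans(z)
    zmax <- apply(abs(z), 1, max)
    zsd <- apply(z, 1, stats::sd)
    scale <- pmin(rel_sd / pmax(zsd, 1e-12), bound / pmax(zmax, 1e-12))
    1 + z * scale
  }
  csum <- colSums(mean_pm$matU)
  boundU <- pmin(0.9, ifelse(csum > 0, 0.95 / pmax(csum, 1e-12) - 1, 0.9))
  cU <- centered_factors(pmax(boundU, 0))
  cF <- centered_factors(rep(0.9, k))
  lapply(seq_len(n_years), function(t) {
    matU <- sweep(mean_pm$matU, 2, cU[, t], `*`)
    matF <- sweep(mean_pm$matF, 2, cF[, t], `*`)
    ppm(matU + matF, stages = mean_pm$stages, matU = matU, matF = matF,
        census = mean_pm$census)
  })
}

sample_range <- function(r) {
  if (r[1] >= r[2]) r[1] else sample(seq.int(r[1], r[2]), 1)
}

#' Generate a full synthetic study dataset
#'
#' Emits per-matrix records for a whole comparative study: a Yule
#' phylogeny over the species, categories assigned by the configured
#' probabilities, species-level log upper inertia values drawn from the
#' phylogenetic mixed model's generative form, and for every population a
#' mean life cycle whose upper inertia bound matches its target (via
#' root-finding on a recruitment scale factor) with yearly matrices
#' averaging exactly to that mean. Pathologies are injected at the
#' configured rates, with ground-truth bookkeeping of which records should
#' survive filtering.
#'
#' @param cfg a [synthetic_config()].
#' @return A list of class `synthetic_dataset` with `records` (list of
#'   matrix records), `tree`, and `truth` (category effects, species table
#'   with targets and random effects, per-record `should_keep` flags and
#'   reasons).
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  tree <- generate_tree(cfg$n_species, seed = sub_seed(cfg$seed, 101))
  sim <- simulate_species_metrics(tree, cfg)
  tab <- sim$table
  rates <- cfg$pathology_rates

  records <- list()
  truth_rows <- list()
  set.seed(sub_seed(cfg$seed, 3))
  mid <- 0
  for (i in seq_len(nrow(tab))) {
    sp <- tab$species[i]
    n_pops <- sample_range(cfg$populations_per_species)
    k <- sample_range(cfg$stages_range)
    for (p in seq_len(n_pops)) {
      target <- tab$log_rho_upper[i] +
        stats::rnorm(1, 0, cfg$population_sd)
      target <- max(target, 0.05)   # inertia upper bound cannot fall below 1
      mean_pm <- NULL
      for (try in seq_len(50)) {
        base <- generate_ppm(k, cfg,
                             seed = sub_seed(cfg$seed,
                                             1000 + i * 37 + p * 7 + try),
                             homogeneous_survival = try > 10)
        mean_pm <- match_inertia_target(base, target)
        if (!is.null(mean_pm)) break
      }
      if (is.null(mean_pm)) {
        stop(sprintf("could not match inertia target %.3f for %s", target, sp))
      }
      n_years <- sample_range(cfg$years_per_population)
      yearly <- yearly_matrices_around(mean_pm, n_years)
      pop_id <- sprintf("%s_pop%d", sp, p)
      for (yy in seq_len(n_years)) {
        mid <- mid + 1
        pm <- yearly[[yy]]
        pathologies <- character(0)
        setting <- "field"
        pooled <- FALSE
        mtype <- "individual"
        treatment <- "none"
        seed_stage <- NA
        if (stats::runif(1) < rates$reducible) {
          # cut all inflow to stage 1: stage 1 becomes unreachable
          matU <- pm$matU
          matF <- pm$matF
          matU[1, ] <- 0
          matF[1, ] <- 0
          matU[1, 1] <- 0.1
          pm <- ppm(matU + matF, stages = pm$stages, matU = matU,
                    matF = matF, census = pm$census)
          pathologies <- c(pathologies, "reducible")
        }
        if (stats::runif(1) < rates$greenhouse) {
          setting <- "greenhouse"
          pathologies <- c(pathologies, "greenhouse")
        }
        if (stats::runif(1) < rates$pooled) {
          pooled <- TRUE
          pathologies <- c(pathologies, "pooled")
        }
        if (stats::runif(1) < rates$mean_matrix) {
          mtype <- "mean"
          pathologies <- c(pathologies, "mean_matrix")
        }
        if (stats::runif(1) < rates$treatment) {
          treatment <- sample(c("burning", "herbicide", "harvesting",
                                "grazing", "nutrient"), 1)
          pathologies <- c(pathologies, "treatment")
        }
        if (stats::runif(1) < rates$seed_problem) {
          pm <- inject_seed_problem(pm)
          seed_stage <- 1L
          pathologies <- c(pathologies, "seed_problem")
        }
        if (stats::runif(1) < rates$post_census) {
          pm <- ppm(pm$A, stages = pm$stages, matU = pm$matU, matF = pm$matF,
                    census = "post_reproductive")
          pathologies <- c(pathologies, "post_census")
        }
        matrix_id <- sprintf("m%05d", mid)
        records[[mid]] <- list(
          matrix_id = matrix_id, species = sp, population_id = pop_id,
          year = 2000 + yy,
          range_context = tab$range_context[i],
          global_status = tab$global_status[i],
          timestep_years = 1, pooled = pooled, setting = setting,
          matrix_type = mtype,
          individuals_available = (mtype == "mean"),
          treatment = treatment, seed_stage = seed_stage, pm = pm
        )
        should_keep <- !any(pathologies %in%
                              c("reducible", "greenhouse", "pooled",
                                "mean_matrix", "treatment"))
        truth_rows[[mid]] <- data.frame(
          matrix_id = matrix_id, species = sp, population_id = pop_id,
          should_keep = should_keep,
          pathologies = paste(pathologies, collapse = ";"),
          target_log_rho_upper = target,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  structure(
    list(records = records, tree = tree,
         truth = list(beta = sim$truth$beta, u = sim$truth$u,
                      e = sim$truth$e,
                      species = tab,
                      records = do.call(rbind, c(truth_rows,
                                                 list(make.row.names = FALSE))))),
    class = "synthetic_dataset"
  )
}

# Turn a pre-reproductive life cycle into one exhibiting the seed problem:
# prepend recruitment into a seed stage... here, restructure in place by
# routing all recruitment through stage 1 treated as a pure seed stage whose
# survivors germinate into stage 2 the following year.
inject_seed_problem <- function(pm) {
  k <- nrow(pm$A)
  matU <- pm$matU
  matF <- pm$matF
  g <- sum(matU[, 1])
  matU[, 1] <- 0
  matU[2, 1] <- max(g, 0.1)      # delayed germination into stage 2
  # recruitment lands in the seed stage only
  total <- colSums(matF)
  matF[] <- 0
  matF[1, ] <- total
  ppm(matU + matF, stages = pm$stages, matU = matU, matF = matF,
      census = pm$census)
}
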