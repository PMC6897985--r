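#' Is a projection matrix irreducible?
#'
#' A projection matrix is irreducible when every stage is reachable from
#' every other through the life cycle, i.e. the directed graph with an edge
#' j -> i whenever `A[i, j] > 0` is strongly connected. Reducible matrices
#' have stages that cannot contribute to (or be reached from) parts of the
#' life cycle, and their asymptotic dynamics can depend on the initial
#' condition.
#'
#' @inheritParams eigen_analysis
#' @return `TRUE` or `FALSE`.
#' @export
is_irreducible <- function(pm) {
  pm <- as_ppm(pm)
  A <- pm$A
  if (nrow(A) == 1) return(A[1, 1] > 0)
  g <- igraph::graph_from_adjacency_matrix(t(A) > 0, mode = "directed")
  igraph::components(g, mode = "strong")$no == 1
}

# boolean matrix power by repeated squaring
bool_power <- function(B, p) {
  R <- diag(nrow(B)) > 0
  P <- B
  while (p > 0) {
    if (p %% 2 == 1) R <- (R %*% P) > 0
    P <- (P %*% P) > 0
    p <- p %/% 2
  }
  R
}

#' Is a projection matrix primitive?
#'
#' Primitivity (irreducibility plus aperiodicity) guarantees that projections
#' converge to the stable stage structure from any initial condition. Checked
#' via the Wielandt bound: an irreducible non-negative k x k matrix is
#' primitive iff `A^(k^2 - 2k + 2)` is elementwise positive.
#'
#' @inheritParams eigen_analysis
#' @return `TRUE` or `FALSE`. Errors on reducible input.
#' @export
is_primitive <- function(pm) {
  pm <- as_ppm(pm)
  if (!is_irreducible(pm)) {
    stop("primitivity is only defined here for irreducible matrices")
  }
  k <- nrow(pm$A)
  if (k == 1) return(pm$A[1, 1] > 0)
  B <- pm$A > 0
  all(bool_power(B, k^2 - 2 * k + 2))
}

#' Is a projection matrix ergodic?
#'
#' Ergodicity — convergence to the same stable structure from any non-negative
#' initial condition — is diagnosed by strict positivity of the dominant left
#' eigenvector (reproductive value) of the matrix.
#'
#' @inheritParams eigen_analysis
#' @return `TRUE` or `FALSE`. Errors if the dominant eigenvalue is complex.
#' @export
is_ergodic <- function(pm) {
  pm <- as_ppm(pm)
  A <- pm$A
  e <- eigen(t(A))
  i <- which.max(Re(e$values))
  lam <- e$values[i]
  if (abs(Im(lam)) > 1e-8 * max(1, abs(Re(lam)))) {
    stop("dominant eigenvalue is not real; ergodicity undefined")
  }
  v <- e$vectors[, i]
  if (max(abs(Im(v))) > 1e-8 * max(abs(v))) {
    stop("dominant left eigenvector is not real; ergodicity undefined")
  }
  v <- Re(v)
  if (sum(v) < 0) v <- -v
  all(v > 1e-12 * max(abs(v)))
}

#' Detect the seed problem
#'
#' The seed problem is a parameterisation artefact in which the seed or
#' propagule stage is erroneously forced to wait a full projection interval
#' before germinating. Operational rule: a designated seed stage that (a)
#' receives recruitment, while (b) no recruitment enters any other stage
#' directly, and (c) has outgoing germination transitions in the survival
#' component, is flagged. Detection requires stage metadata naming the seed
#' stage; without it the matrix is passed through with a warning.
#'
#' @inheritParams eigen_analysis
#' @param seed_stage index or label of the seed/propagule stage, or `NULL`
#'   / `NA` when no stage is designated.
#' @return `TRUE`, `FALSE`, or `NA` (no stage metadata; warning issued).
#' @export
detect_seed_problem <- function(pm, seed_stage) {
  pm <- as_ppm(pm)
  if (missing(seed_stage) || is.null(seed_stage) ||
      (length(seed_stage) == 1 && is.na(seed_stage))) {
    warning("no seed-stage metadata; seed-problem status unknown")
    return(NA)
  }
  if (is.character(seed_stage)) seed_stage <- match(seed_stage, pm$stages)
  s <- as.integer(seed_stage)
  if (is.na(s) || s < 1 || s > nrow(pm$A)) {
    stop("'seed_stage' does not name a stage of the matrix")
  }
  if (is.null(pm$matU) || is.null(pm$matF)) {
    warning("matrix has no survival/recruitment split; seed-problem status unknown")
    return(NA)
  }
  recruits_to_seed <- any(pm$matF[s, ] > 0)
  direct_recruitment <- any(pm$matF[-s, , drop = FALSE] > 0)
  germination_out <- any(pm$matU[-s, s] > 0)
  recruits_to_seed && !direct_recruitment && germination_out
}

#' Correct the seed problem
#'
#' Removes the compulsory one-year seed delay by composing the seed column's
#' transition rates into recruitment: newly produced seeds germinate (or
#' enter the seed bank) in their year of production. For seed stage `s` the
#' corrected recruitment is `F'[i, j] = matU[i, s] * matF[s, j]` — germinants
#' flow directly into the stages the seed column feeds, and only genuine
#' seed-bank survival (`matU[s, s]`) retains seeds in the seed stage. The
#' survival component is unchanged, so column survival bounds are preserved.
#'
#' @inheritParams detect_seed_problem
#' @return A corrected [ppm]; the input unchanged when no seed problem is
#'   detected.
#' @export
correct_seed_problem <- function(pm, seed_stage) {
  pm <- as_ppm(pm)
  flag <- detect_seed_problem(pm, seed_stage)
  if (!isTRUE(flag)) return(pm)
  if (is.character(seed_stage)) seed_stage <- match(seed_stage, pm$stages)
  s <- as.integer(seed_stage)
  newF <- outer(pm$matU[, s], pm$matF[s, ])
  dimnames(newF) <- dimnames(pm$A)
  if (any(newF < 0)) stop("seed-problem correction produced negative recruitment")
  ppm(pm$matU + newF, stages = pm$stages, matU = pm$matU, matF = newF,
      census = pm$census, timestep_years = pm$timestep_years)
}

#' Convert a post-reproductive census matrix to pre-reproductive form
#'
#' On a post-reproductive census, recruitment entries compound parental
#' survival with fecundity; on a pre-reproductive census they compound
#' fecundity with first-year recruit survival. Post-reproductive recruitment
#' tends to be high, which inflates measures of demographic amplification,
#' so all matrices are standardised to the pre-reproductive convention. The
#' rule re-expresses the recruitment component: per-stage fecundity is
#' recovered as `phi_j = sum_i matF[i, j] / sigma_j` with `sigma_j` the
#' column survival sum of `matU`, and pre-reproductive recruitment is
#' `F_pre[i, j] = phi_j * g_i` with `g_i` the first-year recruit survival
#' into stage `i` (defaulting to the recruit-stage column of `matU`).
#' The survival component is left unchanged; for consistent life cycles
#' (common per-capita fecundity across stages, `g = matU[, recruit_stage]`)
#' the conversion preserves `lambda` exactly.
#'
#' @inheritParams eigen_analysis
#' @param g numeric vector of first-year recruit survival into each stage;
#'   when `NULL`, taken as the column of `matU` for `recruit_stage`.
#' @param recruit_stage stage whose `matU` column describes first-year
#'   recruit fates (default 1).
#' @return A [ppm] with `census = "pre_reproductive"`. Matrices already on a
#'   pre-reproductive census are returned unchanged; matrices lacking the
#'   `matU`/`matF` split are returned unconverted with a warning and an
#'   attribute `conversion_skipped = TRUE`.
#' @export
convert_post_to_pre <- function(pm, g = NULL, recruit_stage = 1) {
  pm <- as_ppm(pm)
  if (pm$census != "post_reproductive") return(pm)
  if (is.null(pm$matU) || is.null(pm$matF)) {
    warning("no survival/recruitment split; matrix passed through unconverted")
    attr(pm, "conversion_skipped") <- TRUE
    return(pm)
  }
  sigma <- colSums(pm$matU)
  fcol <- colSums(pm$matF)
  bad <- sigma == 0 & fcol > 0
  if (any(bad)) {
    stop(sprintf(paste("post-reproductive recruitment through non-surviving",
                       "stage(s) %s is inconsistent"),
                 paste(pm$stages[bad], collapse = ", ")))
  }
  phi <- ifelse(fcol > 0, fcol / sigma, 0)
  if (is.null(g)) g <- pm$matU[, recruit_stage]
  g <- as.numeric(g)
  if (length(g) != nrow(pm$A) || any(g < 0)) {
    stop("'g' must be a non-negative vector with one entry per stage")
  }
  newF <- outer(g, phi)
  dimnames(newF) <- dimnames(pm$A)
  ppm(pm$matU + newF, stages = pm$stages, matU = pm$matU, matF = newF,
      census = "pre_reproductive", timestep_years = pm$timestep_years)
}

#' Filter configuration for study inclusion rules
#'
#' The inclusion/exclusion rules applied to candidate matrix records. All
#' rules default to on: matrices must describe annual or multi-annual
#' (integer-year) timesteps; matrices pooled across sites, from laboratory
#' or greenhouse populations, mean matrices whose individual constituents
#' are available, reducible matrices, and experimentally manipulated
#' populations (burning, herbicide, harvesting, grazing, nutrient
#' supplement) are excluded.
#'
#' @param require_annual_timestep exclude records whose timestep is not a
#'   positive integer number of years.
#' @param exclude_pooled exclude matrices pooled across multiple sites.
#' @param exclude_lab_greenhouse exclude laboratory/greenhouse populations.
#' @param exclude_mean_when_individuals_available exclude mean matrices when
#'   their constituent individual matrices are available.
#' @param exclude_reducible exclude reducible matrices.
#' @param exclude_manipulated exclude experimentally manipulated populations.
#' @param manipulation_keywords treatment keywords that mark manipulation.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(require_annual_timestep = TRUE,
                          exclude_pooled = TRUE,
                          exclude_lab_greenhouse = TRUE,
                          exclude_mean_when_individuals_available = TRUE,
                          exclude_reducible = TRUE,
                          exclude_manipulated = TRUE,
                          manipulation_keywords = c("burning", "herbicide",
                                                    "harvesting", "grazing",
                                                    "nutrient")) {
  structure(
    list(require_annual_timestep = require_annual_timestep,
         exclude_pooled = exclude_pooled,
         exclude_lab_greenhouse = exclude_lab_greenhouse,
         exclude_mean_when_individuals_available =
           exclude_mean_when_individuals_available,
         exclude_reducible = exclude_reducible,
         exclude_manipulated = exclude_manipulated,
         manipulation_keywords = manipulation_keywords),
    class = "filter_config"
  )
}

#' Read / write a filter configuration
#'
#' Plain-text (YAML) serialisation mirroring the [filter_config()] fields.
#'
#' @param path file path.
#' @return `read_filter_config` returns a `filter_config`;
#'   `write_filter_config` returns `path` invisibly.
#' @export
read_filter_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(filter_config, vals[intersect(names(vals),
                                        names(formals(filter_config)))])
}

#' @rdname read_filter_config
#' @param cfg a `filter_config`.
#' @export
write_filter_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# metadata accessor: NULL or NA counts as missing
meta_field <- function(rec, field) {
  x <- rec[[field]]
  if (is.null(x) || (length(x) == 1 && is.na(x))) NULL else x
}

#' Apply inclusion/exclusion rules to matrix records
#'
#' Each record is a list carrying a [ppm] in `$pm` plus the metadata fields
#' the rules inspect (`matrix_id`, `timestep_years`, `pooled`, `setting`,
#' `matrix_type`, `individuals_available`, `treatment`). Every enabled rule
#' is applied to every record and each exclusion is attributed to named
#' rules. A record missing a metadata field needed by an enabled rule is
#' excluded conservatively with reason `missing_metadata:<field>`.
#'
#' @param records list of matrix records.
#' @param cfg a [filter_config()].
#' @return A list with `kept` (the surviving records) and `report`, a
#'   data frame with one row per record: structural diagnostics
#'   (`irreducible`, `ergodic`, `primitive`), `excluded`, and
#'   semicolon-joined `exclusion_reasons`.
#' @export
filter_records <- function(records, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  n <- length(records)
  rows <- vector("list", n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    rec <- records[[i]]
    pm <- rec$pm
    reasons <- character(0)
    irr <- is_irreducible(pm)
    erg <- tryCatch(is_ergodic(pm), error = function(e) NA)
    prim <- if (irr) is_primitive(pm) else FALSE

    if (cfg$require_annual_timestep) {
      ts <- meta_field(rec, "timestep_years")
      if (is.null(ts)) {
        reasons <- c(reasons, "missing_metadata:timestep_years")
      } else if (ts <= 0 || abs(ts - round(ts)) > 1e-9) {
        reasons <- c(reasons, "require_annual_timestep")
      }
    }
    if (cfg$exclude_pooled) {
      pooled <- meta_field(rec, "pooled")
      if (is.null(pooled)) {
        reasons <- c(reasons, "missing_metadata:pooled")
      } else if (isTRUE(pooled)) {
        reasons <- c(reasons, "exclude_pooled")
      }
    }
    if (cfg$exclude_lab_greenhouse) {
      setting <- meta_field(rec, "setting")
      if (is.null(setting)) {
        reasons <- c(reasons, "missing_metadata:setting")
      } else if (tolower(setting) %in% c("laboratory", "lab", "greenhouse")) {
        reasons <- c(reasons, "exclude_lab_greenhouse")
      }
    }
    if (cfg$exclude_mean_when_individuals_available) {
      mtype <- meta_field(rec, "matrix_type")
      if (is.null(mtype)) {
        reasons <- c(reasons, "missing_metadata:matrix_type")
      } else if (tolower(mtype) == "mean" &&
                 isTRUE(meta_field(rec, "individuals_available"))) {
        reasons <- c(reasons, "exclude_mean_when_individuals_available")
      }
    }
    if (cfg$exclude_reducible && !irr) {
      reasons <- c(reasons, "exclude_reducible")
    }
    if (cfg$exclude_manipulated) {
      treatment <- meta_field(rec, "treatment")
      if (is.null(treatment)) {
        reasons <- c(reasons, "missing_metadata:treatment")
      } else if (any(vapply(cfg$manipulation_keywords,
                            function(kw) grepl(kw, tolower(treatment),
                                               fixed = TRUE),
                            logical(1)))) {
        reasons <- c(reasons, "exclude_manipulated")
      }
    }

    keep[i] <- length(reasons) == 0
    rows[[i]] <- data.frame(
      matrix_id = if (!is.null(rec$matrix_id)) rec$matrix_id else
        sprintf("record_%d", i),
      irreducible = irr, ergodic = erg, primitive = prim,
      seed_problem_detected = NA, census_converted = NA,
      excluded = !keep[i],
      exclusion_reasons = paste(reasons, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  list(kept = records[keep], report = do.call(rbind, c(rows,
       list(make.row.names = FALSE))))
}
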