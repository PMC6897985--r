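#' Temporal mean of yearly projection matrices
#'
#' Elementwise arithmetic mean of the yearly matrices of one population
#' (and of the `matU`/`matF` components when all matrices carry them).
#' The census flag is propagated when uniform across years.
#'
#' @param matrices a list of [ppm] objects with identical stage labels.
#' @return A single [ppm].
#' @export
temporal_mean_matrix <- function(matrices) {
  if (length(matrices) == 0) stop("need at least one matrix")
  matrices <- lapply(matrices, as_ppm)
  stages <- matrices[[1]]$stages
  for (m in matrices) {
    if (!identical(m$stages, stages)) {
      stop("all matrices must share stage count and stage labels")
    }
  }
  mean_of <- function(get) {
    parts <- lapply(matrices, get)
    if (any(vapply(parts, is.null, logical(1)))) return(NULL)
    Reduce(`+`, parts) / length(parts)
  }
  A <- mean_of(function(m) m$A)
  census <- unique(vapply(matrices, function(m) m$census, character(1)))
  ppm(A, stages = stages,
      matU = mean_of(function(m) m$matU),
      matF = mean_of(function(m) m$matF),
      census = if (length(census) == 1) census else "unknown",
      timestep_years = matrices[[1]]$timestep_years)
}

#' Demographic metrics for one population
#'
#' Computes the population-level metrics on the temporal mean matrix (not
#' the mean of yearly metrics): natural logs of the stable growth rate, of
#' the upper and lower inertia bounds, and of mean recruitment per stage.
#' Populations whose temporal mean matrix fails structural QC (reducible or
#' imprimitive) are reported as skipped.
#'
#' @param pop a population record: a list with `species`, `population_id`,
#'   `range_context`, `global_status` and `matrices` (list of [ppm]).
#' @return A one-row data frame with the log metrics, or `NULL` (with
#'   attribute-free message via `warning`) when QC fails.
#' @export
population_metrics <- function(pop) {
  stopifnot(is.list(pop), length(pop$matrices) >= 1)
  mm <- temporal_mean_matrix(pop$matrices)
  if (!is_irreducible(mm) || !is_primitive(mm)) {
    warning(sprintf("population %s of %s skipped: temporal mean matrix %s",
                    pop$population_id, pop$species,
                    if (!is_irreducible(mm)) "is reducible" else "is imprimitive"))
    return(NULL)
  }
  ea <- eigen_analysis(mm)
  b <- inertia_bounds(mm)
  rec <- if (is.null(mm$matF)) NA_real_ else recruitment_per_stage(mm)
  log_rec <- if (is.na(rec) || rec <= 0) NA_real_ else log(rec)
  data.frame(
    species = pop$species,
    population_id = pop$population_id,
    range_context = pop$range_context,
    global_status = pop$global_status,
    category = assign_category(pop$global_status, pop$range_context),
    n_years = length(pop$matrices),
    log_lambda = log(ea$lambda),
    log_rho_upper = log(b$rho_upper),
    log_rho_lower = log(b$rho_lower),
    log_mean_recruitment = log_rec,
    stringsAsFactors = FALSE
  )
}

#' Group matrix records into population records
#'
#' Collects per-matrix records (as produced by [generate_dataset()] or
#' [read_matrix_table()]) into one record per species x population, carrying
#' the yearly matrices in chronological order.
#'
#' @param records list of matrix records (each with `species`,
#'   `population_id`, `range_context`, `global_status`, `year`, `pm`).
#' @return A list of population records suitable for [population_metrics()].
#' @export
group_populations <- function(records) {
  if (length(records) == 0) return(list())
  key <- vapply(records, function(r) paste(r$species, r$population_id,
                                           sep = "\r"), character(1))
  lapply(split(records, key), function(rs) {
    years <- vapply(rs, function(r) as.numeric(r$year %||% NA_real_),
                    numeric(1))
    rs <- rs[order(years)]
    list(species = rs[[1]]$species,
         population_id = rs[[1]]$population_id,
         range_context = rs[[1]]$range_context,
         global_status = rs[[1]]$global_status,
         matrices = lapply(rs, function(r) r$pm))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign the five-level invasiveness category
#'
#' Combines a species' global invasiveness status (`restricted`,
#' `introduced`, `invasive`) with the range context of the study
#' (`native`, `naturalised`). A restricted species studied in a naturalised
#' range is a definitional contradiction and is rejected.
#'
#' @param global_status character vector of global statuses.
#' @param range_context character vector of range contexts (recycled).
#' @return Character vector of category labels, e.g.
#'   `"invasive_naturalised"`.
#' @export
assign_category <- function(global_status, range_context) {
  global_status <- as.character(global_status)
  range_context <- as.character(range_context)
  if (!all(global_status %in% c("restricted", "introduced", "invasive"))) {
    stop("'global_status' must be restricted, introduced or invasive")
  }
  if (!all(range_context %in% c("native", "naturalised"))) {
    stop("'range_context' must be native or naturalised")
  }
  n <- max(length(global_status), length(range_context))
  global_status <- rep_len(global_status, n)
  range_context <- rep_len(range_context, n)
  bad <- global_status == "restricted" & range_context == "naturalised"
  if (any(bad)) {
    stop(paste("a species restricted to its native range cannot be studied",
               "in a naturalised range"))
  }
  paste(global_status, range_context, sep = "_")
}

#' All five invasiveness categories
#' @return Character vector of the five valid category labels.
#' @export
invasiveness_categories <- function() {
  c("restricted_native", "introduced_native", "introduced_naturalised",
    "invasive_native", "invasive_naturalised")
}

#' Species-by-category means of log demographic metrics
#'
#' Averages each log metric across the populations of a species within a
#' range category. A species studied in both its native and naturalised
#' range contributes one row per range category. Missing recruitment values
#' are dropped from the recruitment mean (and stay missing when no
#' population has recruitment).
#'
#' @param pop_metrics data frame of per-population metrics, as rows from
#'   [population_metrics()].
#' @return A data frame with one row per species x category: the mean log
#'   metrics and `n_populations`.
#' @export
species_category_means <- function(pop_metrics) {
  stopifnot(is.data.frame(pop_metrics), nrow(pop_metrics) >= 1)
  key <- paste(pop_metrics$species, pop_metrics$category, sep = "\r")
  rows <- lapply(split(pop_metrics, key), function(d) {
    mean_na <- function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0) NA_real_ else mean(x)
    }
    data.frame(
      species = d$species[1],
      category = d$category[1],
      range_context = d$range_context[1],
      global_status = d$global_status[1],
      log_lambda = mean(d$log_lambda),
      log_rho_upper = mean(d$log_rho_upper),
      log_rho_lower = mean(d$log_rho_lower),
      log_mean_recruitment = mean_na(d$log_mean_recruitment),
      n_populations = nrow(d),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$species, out$category), , drop = FALSE]
}
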