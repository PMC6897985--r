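#' Write matrix records to a delimited text table
#'
#' Long plain-text format, one CSV with two row types per matrix record:
#' a `meta` row per metadata field (`field`, `text`) and an `entry` row per
#' matrix entry (`field` = component `U`/`F`/`A`, `i`, `j`, `value`).
#' Matrices with a survival/recruitment split store `U` and `F` entries;
#' matrices without a split store `A` entries. Zero entries are omitted.
#' Floating-point values are written with 12 significant digits.
#'
#' @param records list of matrix records (see [filter_records()] for the
#'   expected fields).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_table <- function(records, path) {
  meta_fields <- c("species", "population_id", "year", "range_context",
                   "global_status", "census", "timestep_years", "pooled",
                   "setting", "matrix_type", "individuals_available",
                   "treatment", "seed_stage")
  rows <- list()
  for (rec in records) {
    id <- rec$matrix_id
    pm <- rec$pm
    add <- function(field, i = NA, j = NA, value = NA, text = NA) {
      rows[[length(rows) + 1]] <<- data.frame(
        matrix_id = id, row_type = if (is.na(i)) "meta" else "entry",
        field = field, i = i, j = j,
        value = if (is.na(value)) NA_character_ else
          sprintf("%.12g", value),
        text = as.character(text), stringsAsFactors = FALSE)
    }
    add("stages", text = paste(pm$stages, collapse = ";"))
    add("census", text = pm$census)
    for (f in meta_fields) {
      if (f == "census") next
      val <- rec[[f]]
      if (!is.null(val)) add(f, text = val)
    }
    emit <- function(M, name) {
      nz <- which(M != 0, arr.ind = TRUE)
      for (r in seq_len(nrow(nz))) {
        add(name, i = nz[r, 1], j = nz[r, 2], value = M[nz[r, 1], nz[r, 2]])
      }
    }
    if (!is.null(pm$matU) && !is.null(pm$matF)) {
      emit(pm$matU, "U")
      emit(pm$matF, "F")
    } else {
      emit(pm$A, "A")
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read matrix records from a delimited text table
#'
#' Inverse of [write_matrix_table()]: reconstructs the list of matrix
#' records, with typed metadata and [ppm] objects. Malformed records are
#' reported by matrix id.
#'
#' @param path input file path.
#' @return A list of matrix records (empty, with a warning, for an empty
#'   file).
#' @export
read_matrix_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(matrix_id = "character",
                                        row_type = "character",
                                        field = "character",
                                        i = "integer", j = "integer",
                                        value = "character",
                                        text = "character"))
  if (nrow(tab) == 0) {
    warning("empty matrix table; returning no records")
    return(list())
  }
  logical_fields <- c("pooled", "individuals_available")
  numeric_fields <- c("year", "timestep_years")
  ids <- unique(tab$matrix_id)
  lapply(ids, function(id) {
    rows <- tab[tab$matrix_id == id, , drop = FALSE]
    meta <- rows[rows$row_type == "meta", , drop = FALSE]
    entries <- rows[rows$row_type == "entry", , drop = FALSE]
    get_meta <- function(field) {
      v <- meta$text[meta$field == field]
      if (length(v) == 0) NULL else v[1]
    }
    stages <- get_meta("stages")
    if (is.null(stages)) {
      stop(sprintf("record %s is malformed: no 'stages' metadata row", id))
    }
    stages <- strsplit(stages, ";", fixed = TRUE)[[1]]
    k <- length(stages)
    if (nrow(entries) > 0 &&
        (any(is.na(entries$i)) || any(is.na(entries$j)) ||
         any(entries$i < 1) || any(entries$j < 1) ||
         any(entries$i > k) || any(entries$j > k))) {
      stop(sprintf("record %s is malformed: entry indices outside 1..%d (rows %s)",
                   id, k,
                   paste(utils::head(rownames(entries)[
                     is.na(entries$i) | is.na(entries$j) |
                       entries$i < 1 | entries$j < 1 |
                       entries$i > k | entries$j > k], 3), collapse = ", ")))
    }
    build <- function(name) {
      e <- entries[entries$field == name, , drop = FALSE]
      if (nrow(e) == 0) return(NULL)
      M <- matrix(0, k, k)
      M[cbind(e$i, e$j)] <- as.numeric(e$value)
      M
    }
    matU <- build("U")
    matF <- build("F")
    A <- build("A")
    if (is.null(A)) {
      if (is.null(matU) && is.null(matF)) {
        stop(sprintf("record %s is malformed: no matrix entries", id))
      }
      if (is.null(matU)) matU <- matrix(0, k, k)
      if (is.null(matF)) matF <- matrix(0, k, k)
      A <- matU + matF
    }
    census <- get_meta("census") %||% "unknown"
    ts <- get_meta("timestep_years")
    rec <- list(
      matrix_id = id,
      species = get_meta("species"),
      population_id = get_meta("population_id"),
      year = as.numeric(get_meta("year") %||% NA),
      range_context = get_meta("range_context"),
      global_status = get_meta("global_status"),
      timestep_years = as.numeric(ts %||% NA),
      pooled = as.logical(get_meta("pooled") %||% NA),
      setting = get_meta("setting"),
      matrix_type = get_meta("matrix_type"),
      individuals_available = as.logical(get_meta("individuals_available") %||% NA),
      treatment = get_meta("treatment"),
      seed_stage = {
        ss <- get_meta("seed_stage")
        if (is.null(ss) || ss %in% c("NA", "")) NA else as.integer(ss)
      },
      pm = ppm(A, stages = stages, matU = matU, matF = matF,
               census = census,
               timestep_years = as.numeric(ts %||% 1))
    )
    rec
  })
}

#' Read and write phylogenies in Newick format
#'
#' Thin wrappers over the standard Newick reader/writer that additionally
#' reject duplicated tip labels. Round trips preserve topology and branch
#' lengths.
#'
#' @param path file path.
#' @return `read_newick` returns a `phylo`; `write_newick` returns `path`
#'   invisibly.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop(sprintf("tree file '%s' does not exist", path))
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop(sprintf("could not parse Newick file '%s'", path))
  if (anyDuplicated(tree$tip.label)) {
    stop(sprintf("duplicated tip label(s): %s",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                       collapse = ", ")))
  }
  tree
}

#' @rdname read_newick
#' @param tree a `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

write_table_12g <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.12g", x))
  df[num] <- lapply(df[num], function(x) ifelse(x == "NA", "", x))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full comparative pipeline
#'
#' Chains the stages: filter records, apply seed-problem correction and
#' census conversion, compute per-population metrics on temporal mean
#' matrices, aggregate to species-by-category means, fit the phylogenetic
#' mixed model for each log metric, derive contrasts against the reference
#' category and the phylogenetic-signal report, fit the
#' inertia-recruitment regression, and export transient envelope
#' coordinates. All tabular outputs are written as delimited text with 12
#' significant digits, together with a machine-readable run manifest.
#'
#' @param records list of matrix records, or a path to a matrix table.
#' @param tree a `phylo` object or path to a Newick file.
#' @param outdir output directory (created if needed); `NULL` writes
#'   nothing.
#' @param spec a [model_spec()] used (with the response switched) for all
#'   three metric models.
#' @param cfg_filter a [filter_config()].
#' @param reference reference category for contrasts.
#' @param seed seed recorded in the manifest and used for the model fits.
#' @param envelope_T horizon for exported envelope coordinates.
#' @return A list of class `demamp_run` with the QC report, population
#'   metrics, species table, fits, contrasts, signal reports, regression
#'   and manifest.
#' @export
run_pipeline <- function(records, tree, outdir = NULL,
                         spec = model_spec(n_iter = 11000L, burnin = 1000L,
                                           thin = 10L),
                         cfg_filter = filter_config(),
                         reference = "invasive_naturalised",
                         seed = 1L, envelope_T = 20L) {
  if (is.character(records)) records <- read_matrix_table(records)
  if (is.character(tree)) tree <- read_newick(tree)
  if (length(records) == 0) stop("no input records")

  fl <- filter_records(records, cfg_filter)
  report <- fl$report
  kept <- fl$kept

  # corrections on surviving records
  kept <- lapply(kept, function(rec) {
    det <- if (is.null(rec$seed_stage) ||
               (length(rec$seed_stage) == 1 && is.na(rec$seed_stage))) {
      FALSE
    } else {
      isTRUE(detect_seed_problem(rec$pm, rec$seed_stage))
    }
    if (det) rec$pm <- correct_seed_problem(rec$pm, rec$seed_stage)
    rec$seed_problem_corrected <- det
    conv <- rec$pm$census == "post_reproductive"
    if (conv) rec$pm <- convert_post_to_pre(rec$pm)
    rec$census_converted <- conv
    rec
  })
  idx <- match(vapply(kept, `[[`, "", "matrix_id"), report$matrix_id)
  report$seed_problem_detected <- FALSE
  report$census_converted <- FALSE
  report$seed_problem_detected[idx] <-
    vapply(kept, `[[`, logical(1), "seed_problem_corrected")
  report$census_converted[idx] <-
    vapply(kept, `[[`, logical(1), "census_converted")

  pops <- group_populations(kept)
  pop_metrics <- do.call(rbind, c(
    Filter(Negate(is.null), lapply(pops, population_metrics)),
    list(make.row.names = FALSE)))
  if (is.null(pop_metrics) || nrow(pop_metrics) == 0) {
    stop("no population passed structural QC")
  }
  species_tab <- species_category_means(pop_metrics)

  C <- vcv_from_tree(tree, unique(species_tab$species))
  responses <- c("log_rho_upper", "log_lambda", "log_rho_lower")
  fits <- list()
  contrasts <- list()
  signals <- list()
  for (i in seq_along(responses)) {
    sp <- spec
    sp$response <- responses[i]
    sp$seed <- as.integer(seed) + i
    fits[[responses[i]]] <- fit_phylo_mixed_model(species_tab, C, sp)
    contrasts[[responses[i]]] <-
      tryCatch(category_contrasts(fits[[responses[i]]], reference),
               error = function(e) NULL)
    signals[[responses[i]]] <- phylo_signal(fits[[responses[i]]])
  }
  sp <- spec
  sp$seed <- as.integer(seed) + 10L
  regression <- tryCatch(metric_regression(species_tab, C, sp),
                         error = function(e) NULL)

  envelopes <- do.call(rbind, c(lapply(seq_along(pops), function(i) {
    pop <- pops[[i]]
    mm <- temporal_mean_matrix(pop$matrices)
    if (!is_irreducible(mm) || !is_primitive(mm)) return(NULL)
    env <- transient_envelope(mm, envelope_T)
    data.frame(species = pop$species, population_id = pop$population_id,
               t = env$times, central = env$central, upper = env$upper,
               lower = env$lower, stringsAsFactors = FALSE)
  }), list(make.row.names = FALSE)))

  manifest <- list(
    package = "demamp",
    version = as.character(utils::packageVersion("demamp")),
    r_version = R.version.string,
    seed = as.integer(seed),
    n_records_in = length(records),
    n_records_kept = length(kept),
    n_populations = nrow(pop_metrics),
    n_species_rows = nrow(species_tab),
    reference = reference,
    model = list(n_iter = spec$n_iter, burnin = spec$burnin,
                 thin = spec$thin),
    filter = unclass(cfg_filter),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  manifest$config_hash <- {
    tmp <- tempfile()
    on.exit(unlink(tmp), add = TRUE)
    writeLines(yaml::as.yaml(manifest[setdiff(names(manifest),
                                              "timestamp")]), tmp)
    unname(tools::md5sum(tmp))
  }

  result <- structure(
    list(qc_report = report, population_metrics = pop_metrics,
         species_table = species_tab, fits = fits, contrasts = contrasts,
         signals = signals, regression = regression, envelopes = envelopes,
         manifest = manifest),
    class = "demamp_run"
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_table_12g(report, file.path(outdir, "qc_report.csv"))
    write_table_12g(pop_metrics, file.path(outdir, "population_metrics.csv"))
    write_table_12g(species_tab, file.path(outdir, "species_metrics.csv"))
    for (resp in names(fits)) {
      qs <- t(apply(fits[[resp]]$draws, 2, stats::quantile,
                    c(0.025, 0.5, 0.975)))
      summ <- data.frame(parameter = colnames(fits[[resp]]$draws),
                         mean = colMeans(fits[[resp]]$draws),
                         lower = qs[, 1], median = qs[, 2], upper = qs[, 3],
                         row.names = NULL)
      write_table_12g(summ,
                      file.path(outdir, sprintf("posterior_%s.csv", resp)))
      if (!is.null(contrasts[[resp]])) {
        write_table_12g(contrasts[[resp]],
                        file.path(outdir, sprintf("contrasts_%s.csv", resp)))
      }
      sg <- signals[[resp]]
      write_table_12g(
        data.frame(response = resp, sigma2_phylo_mean = sg$sigma2_phylo_mean,
                   h_mean = sg$h_mean, h_hpd_lower = sg$h_hpd[1],
                   h_hpd_upper = sg$h_hpd[2],
                   credible_signal = sg$credible_signal),
        file.path(outdir, sprintf("signal_%s.csv", resp)))
    }
    if (!is.null(regression)) {
      write_table_12g(
        data.frame(slope_mean = regression$slope_mean,
                   lower = regression$lower, upper = regression$upper,
                   prob_positive = regression$prob_positive,
                   n = regression$n),
        file.path(outdir, "inertia_recruitment_regression.csv"))
    }
    if (!is.null(envelopes)) {
      write_table_12g(envelopes, file.path(outdir, "envelopes.csv"))
    }
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA),
               file.path(outdir, "manifest.json"))
  }
  result
}

#' @export
print.demamp_run <- function(x, ...) {
  cat(sprintf("comparative demography run: %d records kept, %d populations, %d species rows\n",
              x$manifest$n_records_kept, x$manifest$n_populations,
              x$manifest$n_species_rows))
  for (resp in names(x$contrasts)) {
    cc <- x$contrasts[[resp]]
    if (is.null(cc)) next
    cat(sprintf("%s contrasts vs %s: %d credible of %d\n", resp,
                attr(cc, "reference"), sum(cc$credible), nrow(cc)))
  }
  invisible(x)
}
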