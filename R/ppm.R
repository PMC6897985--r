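#' Construct a population projection matrix object
#'
#' A `ppm` bundles a stage-structured annual projection matrix `A` with an
#' optional split into a survival/growth component `matU` and a recruitment
#' component `matF` (so that `A = matU + matF`), together with stage labels
#' and census metadata. Entry `A[i, j]` is the annual per-capita contribution
#' of stage `j` individuals to stage `i`.
#'
#' @param A non-negative square numeric matrix of per-capita transition rates.
#' @param stages optional character vector of stage labels (defaults to
#'   `"stage_1" ... "stage_k"`).
#' @param matU optional survival/growth component, same shape as `A`. Column
#'   sums of `matU` may not exceed 1 (survival cannot exceed certainty).
#' @param matF optional recruitment component, same shape as `A`. When both
#'   components are given they must sum to `A` (elementwise, tolerance 1e-9).
#' @param census census type: `"pre_reproductive"`, `"post_reproductive"`, or
#'   `"unknown"`.
#' @param timestep_years length of the projection interval in years.
#'
#' @return An object of class `ppm`.
#' @examples
#' p <- ppm(rbind(c(0.5, 2.0), c(0.3, 0.0)))
#' stable_growth_rate(p)
#' @export
ppm <- function(A, stages = NULL, matU = NULL, matF = NULL,
                census = c("unknown", "pre_reproductive", "post_reproductive"),
                timestep_years = 1) {
  census <- match.arg(census)
  A <- as.matrix(A)
  if (!is.numeric(A) || nrow(A) != ncol(A)) {
    stop("'A' must be a square numeric matrix")
  }
  k <- nrow(A)
  if (any(!is.finite(A))) stop("all entries of 'A' must be finite")
  if (any(A < 0)) stop("all entries of 'A' must be non-negative")
  if (is.null(stages)) stages <- sprintf("stage_%d", seq_len(k))
  if (length(stages) != k) stop("'stages' must have one label per stage")
  if (!is.numeric(timestep_years) || length(timestep_years) != 1 ||
      timestep_years <= 0) {
    stop("'timestep_years' must be a single positive number")
  }
  if (!is.null(matU)) {
    matU <- as.matrix(matU)
    if (!identical(dim(matU), dim(A))) stop("'matU' must have the shape of 'A'")
    if (any(matU < 0)) stop("'matU' must be non-negative")
    cs <- colSums(matU)
    if (any(cs > 1 + 1e-9)) {
      stop("column sums of 'matU' exceed 1: survival cannot exceed certainty")
    }
  }
  if (!is.null(matF)) {
    matF <- as.matrix(matF)
    if (!identical(dim(matF), dim(A))) stop("'matF' must have the shape of 'A'")
    if (any(matF < 0)) stop("'matF' must be non-negative")
  }
  if (!is.null(matU) && !is.null(matF)) {
    if (max(abs(A - (matU + matF))) > 1e-9) {
      stop("'A' must equal 'matU' + 'matF' (elementwise, tolerance 1e-9)")
    }
  }
  dimnames(A) <- list(stages, stages)
  structure(
    list(A = A, stages = stages, matU = matU, matF = matF,
         census = census, timestep_years = timestep_years),
    class = "ppm"
  )
}

#' @export
print.ppm <- function(x, ...) {
  k <- nrow(x$A)
  cat(sprintf("Population projection matrix: %d stages, census = %s\n",
              k, x$census))
  print(round(x$A, 4))
  if (!is.null(x$matU) && !is.null(x$matF)) {
    cat("(split into survival matU and recruitment matF)\n")
  }
  invisible(x)
}

as_ppm <- function(x) {
  if (inherits(x, "ppm")) x else ppm(x)
}

#' Dominant eigen-analysis of a projection matrix
#'
#' Extracts the dominant eigen-pair of a projection matrix by full
#' eigendecomposition: the stable growth rate `lambda` (dominant eigenvalue),
#' the stable stage structure `w` (dominant right eigenvector, normalised to
#' sum to 1), the reproductive value vector `v` (dominant left eigenvector,
#' scaled so that `sum(v * w) = 1`), and the damping ratio
#' `lambda / |lambda_2|`. The matrix should be irreducible and primitive
#' (see [is_primitive()]) so that Perron-Frobenius theory guarantees a simple
#' real dominant root and strictly positive `w` and `v`.
#'
#' @param pm a [ppm] object (or a plain matrix, which is wrapped).
#' @return A list of class `ppm_eigen` with elements `lambda`, `w`, `v` and
#'   `damping_ratio`.
#' @examples
#' eigen_analysis(ppm(rbind(c(0.5, 2), c(0.3, 0))))
#' @export
eigen_analysis <- function(pm) {
  pm <- as_ppm(pm)
  A <- pm$A
  k <- nrow(A)
  tol <- 1e-9 * max(1, max(abs(A)))

  dominant <- function(M, what) {
    e <- eigen(M)
    i <- which.max(Re(e$values))
    lam <- e$values[i]
    if (abs(Im(lam)) > 1e-8 * max(1, abs(Re(lam)))) {
      stop(sprintf("dominant eigenvalue of %s is not real (possible imprimitivity)",
                   what))
    }
    vec <- e$vectors[, i]
    if (max(abs(Im(vec))) > 1e-8 * max(abs(vec))) {
      stop(sprintf("dominant eigenvector of %s is not real", what))
    }
    vec <- Re(vec)
    if (sum(vec) < 0) vec <- -vec
    list(lambda = Re(lam), vec = vec, values = e$values)
  }

  r <- dominant(A, "the projection matrix")
  l <- dominant(t(A), "the transposed projection matrix")
  if (r$lambda <= 0) {
    stop("dominant eigenvalue is not positive; matrix is degenerate")
  }
  w <- r$vec
  v <- l$vec
  if (any(w <= tol * max(w)) || any(v <= tol * max(v))) {
    stop(paste("dominant eigenvectors have non-positive entries;",
               "matrix is reducible or imprimitive"))
  }
  w <- w / sum(w)
  v <- v / sum(v * w)
  mods <- sort(Mod(r$values), decreasing = TRUE)
  damping <- if (k > 1 && mods[2] > 0) r$lambda / mods[2] else Inf
  names(w) <- names(v) <- pm$stages
  structure(
    list(lambda = r$lambda, w = w, v = v, damping_ratio = damping),
    class = "ppm_eigen"
  )
}

#' @export
print.ppm_eigen <- function(x, ...) {
  cat(sprintf("lambda = %.6f  (damping ratio %.4f)\n",
              x$lambda, x$damping_ratio))
  cat("w (stable structure):", paste(sprintf("%.4f", x$w), collapse = " "), "\n")
  cat("v (reproductive value):", paste(sprintf("%.4f", x$v), collapse = " "), "\n")
  invisible(x)
}

#' Stable population growth rate
#'
#' The dominant eigenvalue `lambda` of the projection matrix: the asymptotic
#' geometric rate of increase. For a population started at the stable stage
#' structure, `log(N_t) = log(N_0) + t * log(lambda)` exactly.
#'
#' @inheritParams eigen_analysis
#' @return A positive number.
#' @export
stable_growth_rate <- function(pm) {
  eigen_analysis(pm)$lambda
}

#' Bounds on demographic inertia
#'
#' Demographic inertia is the asymptotic ratio of the density of a population
#' disturbed at time zero to the density of a population initiated at the
#' stable stage structure. It depends on the initial structure, but over all
#' non-negative initial structures it is bounded by quantities of the matrix
#' alone: the upper bound (amplification) is `v_max * ||w||_1 / (v'w)` and
#' the lower bound (attenuation) is `v_min * ||w||_1 / (v'w)`, where `v_max`
#' and `v_min` are the largest and smallest entries of the reproductive value
#' vector. Both bounds are invariant to positive rescaling of `v`, `w`, or
#' the matrix itself.
#'
#' @inheritParams eigen_analysis
#' @return A list of class `inertia_bounds` with elements `rho_upper`
#'   (>= 1) and `rho_lower` (in (0, 1]).
#' @examples
#' inertia_bounds(ppm(rbind(c(0.5, 2), c(0.3, 0))))
#' @export
inertia_bounds <- function(pm) {
  ea <- eigen_analysis(pm)
  vw <- sum(ea$v * ea$w)
  w1 <- sum(ea$w)
  structure(
    list(rho_upper = max(ea$v) * w1 / vw,
         rho_lower = min(ea$v) * w1 / vw),
    class = "inertia_bounds"
  )
}

#' @export
print.inertia_bounds <- function(x, ...) {
  cat(sprintf("demographic inertia bounds: [%.6f, %.6f]\n",
              x$rho_lower, x$rho_upper))
  invisible(x)
}

#' Project population dynamics forward in time
#'
#' Iterates `n[t + 1] = A n[t]` from an initial stage vector and records the
#' total density (one-norm) at each step.
#'
#' @inheritParams eigen_analysis
#' @param n0 non-negative initial stage vector (not all zero).
#' @param T number of projection steps (>= 0).
#' @return A list of class `ppm_trajectory` with `times` (0..T), `densities`
#'   (total size per time), `stage_vectors` (k x (T+1) matrix) and `N0`.
#' @export
project <- function(pm, n0, T) {
  pm <- as_ppm(pm)
  A <- pm$A
  k <- nrow(A)
  n0 <- as.numeric(n0)
  if (length(n0) != k) {
    stop(sprintf("'n0' has length %d but the matrix has %d stages",
                 length(n0), k))
  }
  if (any(n0 < 0)) stop("'n0' must be non-negative")
  if (all(n0 == 0)) stop("'n0' must not be all zero")
  if (T < 0 || T != round(T)) stop("'T' must be a non-negative integer")
  out <- matrix(0, k, T + 1)
  out[, 1] <- n0
  n <- n0
  t <- 0
  while (t < T) {
    n <- as.numeric(A %*% n)
    t <- t + 1
    out[, t + 1] <- n
  }
  rownames(out) <- pm$stages
  structure(
    list(times = 0:T, densities = colSums(out), stage_vectors = out,
         N0 = sum(n0)),
    class = "ppm_trajectory"
  )
}

#' Brute-force demographic inertia by long projection
#'
#' Computes the asymptotic ratio `||A^t n0_hat||_1 / lambda^t` at `t = T`,
#' where `n0_hat` is the initial vector scaled to unit total density. This is
#' the realised demographic inertia for that initial structure, and serves as
#' an independent oracle for [inertia_bounds()]: over the standard basis
#' vectors its maximum and minimum attain the upper and lower bounds.
#' Convergence is monitored by comparing the ratio at `t = T/2` and `t = T`.
#'
#' @inheritParams project
#' @param T projection horizon (default 2000).
#' @param tol relative convergence tolerance between checkpoints.
#' @return A positive number: the realised inertia for `n0`.
#' @export
inertia_bruteforce <- function(pm, n0, T = 2000, tol = 1e-8) {
  pm <- as_ppm(pm)
  A <- pm$A
  lam <- eigen_analysis(pm)$lambda
  n0 <- as.numeric(n0)
  if (length(n0) != nrow(A)) stop("'n0' has the wrong length")
  if (any(n0 < 0) || all(n0 == 0)) {
    stop("'n0' must be non-negative and not all zero")
  }
  m <- n0 / sum(n0)
  half <- floor(T / 2)
  ratio_half <- NA_real_
  for (t in seq_len(T)) {
    m <- as.numeric(A %*% m) / lam   # renormalise by lambda each step
    if (t == half) ratio_half <- sum(m)
  }
  ratio <- sum(m)
  if (!is.finite(ratio) || ratio <= 0) {
    stop("projection did not remain positive and finite; check the matrix")
  }
  if (is.finite(ratio_half) &&
      abs(ratio - ratio_half) > tol * max(abs(ratio), 1e-300)) {
    stop(sprintf(paste("inertia projection had not converged at T = %d",
                       "(relative change %.3g); increase T or check",
                       "primitivity of the matrix"),
                 T, abs(ratio - ratio_half) / ratio))
  }
  ratio
}

#' Transient envelope of population trajectories
#'
#' The envelope of amplified and attenuated trajectories around the stable
#' projection: the central line is `N0 * lambda^t`, the upper boundary
#' `N0 * lambda^t * rho_upper` and the lower boundary
#' `N0 * lambda^t * rho_lower`, with the asymptotic inertia multipliers
#' applied from `t = 0` onward. The ratio of upper to lower boundary is
#' constant in time and equals `rho_upper / rho_lower`.
#'
#' @inheritParams eigen_analysis
#' @param T number of projection steps.
#' @param N0 initial total density (> 0).
#' @return A list of class `transient_envelope` with `times`, `central`,
#'   `upper`, `lower`, `lambda` and the inertia bounds.
#' @export
transient_envelope <- function(pm, T, N0 = 1) {
  if (N0 <= 0) stop("'N0' must be positive")
  if (T < 0 || T != round(T)) stop("'T' must be a non-negative integer")
  ea <- eigen_analysis(pm)
  b <- inertia_bounds(pm)
  times <- 0:T
  central <- N0 * ea$lambda^times
  structure(
    list(times = times, central = central,
         upper = central * b$rho_upper, lower = central * b$rho_lower,
         lambda = ea$lambda, rho_upper = b$rho_upper, rho_lower = b$rho_lower,
         N0 = N0),
    class = "transient_envelope"
  )
}

#' Mean recruitment per life stage
#'
#' The mean over all stages of the per-capita recruitment column sums of the
#' recruitment component `matF`. The natural log of this quantity is the
#' recruitment axis of the inertia-recruitment relationship. The alternative
#' definition averaging over reproductive stages only (columns of `matF`
#' with any recruitment) is available via `reproductive_only = TRUE`.
#'
#' @inheritParams eigen_analysis
#' @param reproductive_only average only over stages with non-zero
#'   recruitment columns.
#' @return A non-negative number; zero when there is no recruitment (its log
#'   is then undefined and should be recorded as missing downstream).
#' @export
recruitment_per_stage <- function(pm, reproductive_only = FALSE) {
  pm <- as_ppm(pm)
  if (is.null(pm$matF)) {
    stop(paste("recruitment component 'matF' is absent; supply the",
               "survival/recruitment split of the matrix"))
  }
  cs <- colSums(pm$matF)
  if (reproductive_only) {
    repro <- cs > 0
    if (!any(repro)) return(0)
    mean(cs[repro])
  } else {
    mean(cs)
  }
}
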