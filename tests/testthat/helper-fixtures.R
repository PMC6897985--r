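# shared fixtures and independent oracles used across the suite

# positive root of lambda^2 - a11*lambda - a12*a21 = 0: the dominant
# eigenvalue of [[a11, a12], [a21, 0]] in closed form
quad_lambda <- function(a11, a12, a21) {
  (a11 + sqrt(a11^2 + 4 * a12 * a21)) / 2
}

# a random primitive life-cycle matrix (k stages), via the package generator
rand_ppm <- function(k, seed) generate_ppm(k, seed = seed)

# consistent post-/pre-reproductive pair: common per-capita fecundity phi
# across all stages. A_post = U + phi * e1 * sigma', which factors as
# (I + phi e1 1') U; the converted matrix is U (I + phi e1 1'), so both share
# their non-zero spectrum exactly.
consistent_post_ppm <- function(k, phi, seed) {
  base <- generate_ppm(k, seed = seed)
  U <- base$matU
  Fpost <- matrix(0, k, k)
  Fpost[1, ] <- phi * colSums(U)
  ppm(U + Fpost, matU = U, matF = Fpost, census = "post_reproductive")
}

# brute-force rerooted GLS estimate of the state at an internal node: build
# the Brownian covariance of the tree rerooted at that node directly from
# patristic distances, Cr[i, j] = (d(v, i) + d(v, j) - d(i, j)) / 2, and
# evaluate (1' Cr^-1 x) / (1' Cr^-1 1). Exact: no edge-splitting surgery.
brute_node_estimate <- function(tree, x, node) {
  n <- length(tree$tip.label)
  d <- ape::dist.nodes(tree)
  tips <- seq_len(n)
  Cr <- (outer(d[node, tips], rep(1, n)) + outer(rep(1, n), d[node, tips]) -
           d[tips, tips]) / 2
  Ci <- solve(Cr)
  one <- rep(1, n)
  as.numeric((one %*% Ci %*% x[tree$tip.label]) / (one %*% Ci %*% one))
}

# boolean-power irreducibility oracle: (I + A)^(k-1) elementwise positive
brute_irreducible <- function(A) {
  k <- nrow(A)
  M <- diag(k) + A
  P <- diag(k)
  for (i in seq_len(k - 1)) P <- P %*% M
  all(P > 0)
}

# species metrics table for model tests
make_metrics_table <- function(species, cats, y) {
  data.frame(species = species, category = cats, log_rho_upper = y,
             stringsAsFactors = FALSE)
}
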