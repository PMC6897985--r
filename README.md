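# demamp

Comparative demography of stage-structured plant populations, built around
a simple question from invasion biology: can we predict which plants will
become invasive outside their native range from demography measured *in*
the native range? Stable population growth rates describe undisturbed
populations, but invasion is an affair of disturbance — so `demamp`
centres on **demographic inertia**: the permanent multiplicative offset a
population's trajectory acquires when it starts away from its stable
stage structure.

The package is for population ecologists and invasion biologists working
with stage-structured projection matrices (for example records compiled
in the COMPADRE-style databases) who want a tested, reproducible pipeline
from raw matrices to phylogenetically controlled category comparisons.

## The quantities at the core

For a non-negative, irreducible, primitive projection matrix *A* with
dominant eigenvalue λ, stable stage structure **w** (dominant right
eigenvector) and reproductive values **v** (dominant left eigenvector),
a population initiated at **w** satisfies

    log N_t = log N_0 + t log λ,

while any other start acquires an asymptotic offset log ρ∞ bounded by

    ρ̄∞ = v_max ‖w‖₁ / (vᵀw)   (amplification: upper bound, ≥ 1)
    ρ̲∞ = v_min ‖w‖₁ / (vᵀw)   (attenuation: lower bound, ≤ 1)

Both bounds are invariant to rescaling of **v**, **w**, and *A*. The
pipeline computes log λ, log ρ̄∞, log ρ̲∞ and log mean recruitment per
life stage on each population's temporal mean matrix, averages them to
species-by-category means (five categories: restricted / introduced /
invasive, studied in the native or naturalised range), and compares the
categories with a Bayesian phylogenetic mixed model

    y = Xβ + u + e,   u ~ N(0, σ²ₚ C),   e ~ N(0, σ²ₑ I)

fitted by Gibbs sampling with inverse-gamma priors and parameter
expansion, where *C* is the Brownian-motion covariance from the
phylogeny. Contrasts against the invasive-in-naturalised-range reference
are called credible when their 95% interval excludes zero; phylogenetic
signal is summarised through h = σ²ₚ/(σ²ₚ+σ²ₑ).

## Worked example

Single-matrix metrics (a 2-stage rosette/flowering life cycle):

```r
library(demamp)
p <- ppm(rbind(c(0.5, 2.0), c(0.3, 0.0)),
         stages = c("rosette", "flowering"),
         matU = rbind(c(0.5, 0), c(0.3, 0)),
         matF = rbind(c(0, 2), c(0, 0)))
eigen_analysis(p)
#> lambda = 1.063941  (damping ratio 1.8866)
#> w (stable structure): 0.7800 0.2200
#> v (reproductive value): 0.8379 1.5750
inertia_bounds(p)
#> demographic inertia bounds: [0.837862, 1.575016]
```

This population grows 6.4% per year at stable structure; a disturbance
concentrating individuals in the flowering stage leaves it permanently
57.5% larger than the stable-start projection, one concentrated in
rosettes permanently 16.2% smaller.

A full synthetic study — generate records with a known invasiveness
effect (0.5 log-units on ρ̄∞), then run the whole pipeline:

```r
cfg <- synthetic_config(seed = 1, n_species = 100)
ds  <- generate_dataset(cfg)
res <- run_pipeline(ds$records, ds$tree, seed = 1)
res
#> comparative demography run: 496 records kept, 203 populations, 100 species rows
#> log_rho_upper contrasts vs invasive_naturalised: 3 credible of 4
#> log_lambda contrasts vs invasive_naturalised: 0 credible of 4
#> log_rho_lower contrasts vs invasive_naturalised: 0 credible of 4
res$contrasts$log_rho_upper
#>                 category difference  lower upper credible
#> 1      restricted_native     0.4317  0.215 0.669     TRUE
#> 2      introduced_native     0.4333  0.184 0.694     TRUE
#> 3 introduced_naturalised     0.8602  0.014 1.699     TRUE
#> 4        invasive_native     0.0902 -0.163 0.342    FALSE
res$signals$log_rho_upper
#> phylogenetic variance: 0.3667 (95% HPD 0.1101-0.6212)
#> h = s2_phylo/(s2_phylo+s2_resid): 0.806 (95% HPD 0.584-0.950)
#> credible signal (HPD lower bound > 0.05): TRUE
```

The amplification bound separates the invasive-in-naturalised-range
reference from the non-invasive categories (differences ≈ 0.43–0.86,
intervals excluding zero) but not from invasives measured in the native
range — the injected pattern — while λ shows no credible contrasts, and
the amplification metric carries credible phylogenetic signal. Passing
`outdir =` writes the QC report, metric tables, posterior summaries,
contrasts, signal reports, envelope coordinates and a run manifest as
delimited text. A thin command-line wrapper over the same functions is in
`scripts/demamp_cli.R`.

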