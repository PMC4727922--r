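# cernacap

Information capacity of miRNA-mediated ceRNA regulatory channels.

## The problem

MicroRNAs repress their target RNAs by binding and degrading them. When two
RNA species (*competing endogenous RNAs*, ceRNAs) share a miRNA regulator,
activating one of them titrates miRNA molecules away from the other and
derepresses it — an effective positive coupling known as the ceRNA effect.
This opens an indirect, post-transcriptional route for controlling a gene:
instead of dosing the target's own transcription factor (TF), a cell can
dose the competitor's TF and let titration do the rest.

`cernacap` implements a stochastic kinetic model of the minimal titration
circuit — two ceRNAs (`m1`, `m2`), one shared miRNA (`mu`), two
miRNA-ceRNA complexes (`c1`, `c2`), each transcription unit driven by its
own TF through a cooperative (Hill) promoter — and asks, in
information-theoretic terms, *how well* each route can set the target
level:

- **miRNA channel**: TF₁ → ceRNA₁ → (titration) → ceRNA₂, input `f1`,
  output `m2`;
- **TF channel**: TF₂ → ceRNA₂ directly, input `f2`, output `m2`.

It is intended for systems/quantitative biologists studying
post-transcriptional regulation, noise in gene expression, and the design
limits of small-RNA circuits.

## The model

Promoter occupancies equilibrate fast and are frozen at the Hill value
n̄(f) = fʰ/(fʰ + k_out/k_in). The network evolves by mass-action kinetics
with 14 elementary reactions: transcription (rates `b1·n1`, `b2·n2`,
`beta·nmu`), spontaneous decay (`d1`, `d2`, `delta`), complex association
`ki+` / dissociation `ki-`, and complex decay that is either
*stoichiometric* (`sigma_i`, miRNA lost) or *catalytic* (`kappa_i`, miRNA
recycled). At steady state the target obeys

    m2 = (b2 n2 / d2) · mu0 / (mu0 + mu),    mu0 = (d2/k2+)(1 + k2-/(sigma2+kappa2)),

so `mu0` is a soft threshold separating the free, susceptible and
repressed regimes of the target. Fluctuations come from three estimators:
an exact Gillespie simulator (Rcpp), the linear noise approximation
(Jacobian `A`, diffusion matrix `Gamma`, stationary covariance `C` with
`A C + C Aᵀ + Gamma = 0`), or the deterministic solver (means only).

Regulatory power is quantified two ways. The **amplitude of variation**
(AOV) is the output range `m2(f_max) − m2(f_min)`. The **channel
capacity** uses the small-noise Gaussian channel: the optimal input
density is p_opt(f) ∝ [ (dm̄₂/df)² / (2πe σ²ₘ₂(f)) ]^½, its normalisation
`Z` counts distinguishable output levels, and the capacity is
`I = log2(Z)` bits (clamped at 0). A Poissonian channel
(variance = mean) has the closed-form ceiling
`I = log2[ 2/√(2πe) (√m_max − √m_min) ]`.

## Worked example

Compare the two channels for the matched-output protocol (preset `fig9`:
both channels span the same target range, ~11 to ~220 molecules):

```r
library(cernacap)
cc <- compare_channels(cerna_preset("fig9", "mirna"),
                       cerna_preset("fig9", "tf"))
print(cc)
#> Channel comparison (lna estimator)
#>   I_TF    = 2.47 bits (AOV 208.5 molecules)
#>   I_miRNA = 1.9 bits (AOV 209.1 molecules)
#>   dI = I_TF - I_miRNA = 0.566 bits
```

Both channels produce the same derepression amplitude (AOV ≈ 209
molecules), yet the direct channel resolves about 2⁰·⁵⁷ ≈ 1.5 times more
distinguishable target levels: titration noise costs the indirect channel
about half a bit here. Rescaling to a large pool of weakly interacting
miRNAs (`rescale_omega(params, omega)` with small `omega`) closes the gap:

```r
sw <- omega_sweep(sweep_config("omega", grid_n = 4, n_points = 30))
as.data.frame(sw)[, c("omega", "I_tf", "I_mirna", "dI", "fano_m2")]
#>   omega     I_tf  I_mirna         dI  fano_m2
#> 1  0.01 2.471751 2.429574 0.04217744 1.006667
#> 2  0.10 2.471751 2.235859 0.23589212 1.064588
#> 3  1.00 2.471751 1.904847 0.56690474 1.491937
#> 4 10.00 2.471751 1.695170 0.77658128 2.454038
```

As `omega` shrinks the target's Fano factor approaches the Poisson level
and the miRNA channel transmits as much as the direct one.

A stochastic trajectory and its stationary statistics:

```r
pre <- cerna_preset("fig2")
rs  <- reaction_system(pre$params, c(tf_occupancy(12, pre$params), 0.71, 0.9))
st  <- stationary_stats(simulate_ssa(rs, t_end = 500, seed = 1), burn_in = 100)
st
#>   species      mean       var      fano
#> 1      m1 402.99388 647.62870 1.6070435
#> 2      m2 426.42570 318.08033 0.7459220
#> 3      mu  67.63365  72.87226 1.0774557
#> 4      c1 109.77861  92.26000 0.8404187
#> 5      c2  28.66220  28.87204 1.0073213
```

A thin command-line front end ships in `inst/cli/cernacap`
(`simulate`, `capacity`, `compare`, `sweep`, `reproduce`).

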