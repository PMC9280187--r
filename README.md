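# coreshell

Simulation and calibration of drug release from **core–shell
microparticles** — a drug-loaded core wrapped in a thin polymeric shell,
such as a layer-by-layer (LbL) polyelectrolyte coating homogenized into a
single equivalent layer.  The intended users are drug-delivery modellers
who want a mechanistic, parameter-interpretable alternative to empirical
release laws (Peppas, Weibull, ...) for designing coated particles and for
extracting transport/kinetic parameters from in vitro release curves.

## The model

Four fields on the core Ω₀ and shell Ω₁: undissolved drug `b0`, dissolved
drug `c0`/`c1`, and permanently bound drug `b1`:

    ∂b0/∂t = − β b0^α (S − c0)                  in Ω0   (dissolution)
    ∂c0/∂t = ∇·(D0 ∇c0) + β b0^α (S − c0)       in Ω0   (diffusion)
    ∂c1/∂t = ∇·(D1 ∇c1) − k c1                  in Ω1   (diffusion + binding)
    ∂b1/∂t = + k c1                             in Ω1

with concentration/flux continuity at the interface, a perfect sink
(`c1 = 0`) at the outer surface, and initial data `b0 = B0`, `b1 = B1`,
`c0 = c1 = 0`.  Dissolution follows a Noyes–Whitney-type law with surface
exponent α; binding is irreversible and first order, producing the fraction
of the dose that is never released.  Outputs are the total mass `Mtot(t)`,
the cumulative release `%Mrel(t) = 100 (Mtot(0) − Mtot(t))/Mtot(0)` and the
release time `t_r` (earliest time past which the curve varies by less than
0.1 percentage points).

Two solvers share the model: a radial finite-volume method-of-lines solver
for the (2D disk / 3D sphere) symmetric case, and a 2D P1 finite-element
solver on triangulated disk/ellipse cross-sections for shape-sensitivity
studies.  On circular particles the two agree to ~0.1 percentage points,
and each is audited for global mass conservation at every output time.

## Worked example

The reference case: a 1.39 µm calcium-carbonate core loaded with
2.5·10⁻⁴ µg of metronidazole, coated to a total diameter of 1.52 µm, with
the best-fit transport/kinetic parameters.

```r
library(coreshell)

geom <- particle_geometry()        # d0 = 1.39 um, d1 = 1.52 um, 2D disk
p    <- reference_parameters()     # D0, D1, alpha, beta, S, k, M0
sim  <- simulate_particle(geom, p) # 400 h horizon, stiff adaptive solver
release_summary(sim)
#> $released_pct_final
#> [1] 85.15929
#> $release_time_h
#> [1] 378.9396
#> $bound_fraction_pct
#> [1] 14.36738
#> $mass_balance_residual
#> [1] 2.067952e-15
```

About 85% of the dose is released; the remaining ~14% is permanently bound
in the shell (the shell's binding modulus √(k/D1)·L ≈ 0.58 captures ~15% of
the transiting drug).  Release is dissolution-limited: the curve rises
near-linearly early on (~16% in the first 12 h), then flattens past ~140 h.

Varying the binding rate k one order of magnitude either way changes the
retained fraction but not the timing:

```r
sweep_parameter("k", c(0.1, 1, 10), p, geom)
#>   parameter ratio t_r_h released_pct_final
#> 1         k   0.1 381.4              97.92
#> 2         k   1.0 378.9              85.16
#> 3         k  10.0 352.0              31.56
```

Flattening the particle into area-preserving ellipses (2D FEM) thins the
shell at the flat ends and releases more drug at an unchanged release time:

```r
eccentricity_sweep(c(0, 0.3, 0.6), p)
#>   lambda released_pct_final t_r_h
#> 1    0.0              85.24   379
#> 2    0.3              85.26   379
#> 3    0.6              85.57   379
```

Calibration against an observed release curve (CSV columns `time_h`,
`release_pct`, optional `sd_pct`):

```r
obs <- read_release_csv("release.csv")
fit <- fit_release(obs, p, fit_spec(free = c("beta", "S", "k", "D1")))
fit$parameters
```

Note the identifiability caveats in the methods vignette
(`vignettes/coreshell-methods.Rmd`): a cumulative release curve pins the
product β·S and the ratio-like binding modulus much more tightly than the
individual factors.

## Command line

A thin CLI is installed as `exec/coreshell`:

```sh
coreshell simulate --config config.json --out results/
coreshell sweep --param k --ratios 0.1,1,10 --out results/
coreshell release-time --data results/release_curve.csv
coreshell fit --data observed.csv --free beta,S,k,D1 --out results/
```

Configs are JSON or YAML with `geometry`, `parameters` and `solver` blocks
(all optional; omitted keys default to the reference case — see
`?load_config` for the schema).  All runs are deterministic given
`--seed`.

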