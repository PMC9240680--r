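# dentdist

Sharks shed teeth continuously, and tooth size tracks body size, so the
size-frequency distribution of teeth accumulated at a locality — its
**dental distribution** — records the size structure of the population
that used the site. For fossil sand tigers this is usually the only record
there is. `dentdist` is an R package for palaeoecologists and shark
ecologists who want to ask what life-history processes could have produced
an observed dental distribution: in particular, whether a locality was a
**nursery** (juvenile site) or an **adult habitat**, and how strict the
juvenile and adult dispersal strategies were.

## The model and statistic at its core

A deterministic two-site, size-structured metapopulation of female sand
tigers. Individuals are born at the nursery, grow along the West
ontogenetic trajectory with a Q10 temperature dependence,

dm/dt = a(T) m^(3/4) (1 − (m/M)^(1/4)),    a(T) = a_ref · q10^((T − T_ref)/10),

die at a constant per-capita rate μ, and disperse twice in life: juveniles
leave the nursery at a logistic, mass-triggered rate centred on the
maturation mass m_j with width **ξ_j** (the juvenile dispersal window,
grams), and adults return annually in a wrapped-Gaussian pulse with
timing spread **ξ_a** (the adult dispersal window, days), staying about
150 days. Teeth are shed at a constant per-capita rate and accumulate per
site as crown-height histograms through a calibrated tooth–length–mass
allometry.

An observed distribution is compared against the simulated juvenile- and
adult-site distributions through seven shape parameters w₁..w₇ (mean,
variance, quartiles, mode count, Δmode):

ε = Σₖ |wₖ_sim − wₖ_obs| / wₖ_obs,

computed across a grid of (ξ_j, ξ_a) candidates. The hypothesis (juvenile
vs adult site) with the lower minimum ε wins, near-ties are flagged
ambiguous, and the winning argmin estimates the dispersal windows. See
`vignettes/dental-distributions.Rmd` for assumptions, defaults and
numerical choices.

## Worked example

Read a (synthetic) Arctic-style tooth collection, summarise its shape, and
check sample-size adequacy:

```r
library(dentdist)
tms <- read_tooth_csv(system.file("extdata", "banks_island_synthetic.csv",
                                  package = "dentdist"))
#> Tooth measurements from 'banks_island_synthetic'
#>   397 rows read, 397 kept (0 invalid heights, 0 non-anterior)
compute_shape_vector(as_dental_distribution(tms))
#>       mean   variance        p25        p50        p75    n_modes delta_mode
#>   13.76549   11.43434   11.60000   13.80000   16.20000    1.00000    0.00000
```

The distribution is unimodal with a 13.8 mm mean crown height — small
teeth, consistent with a juvenile-dominated site — and a bootstrap
(`bootstrap_shape_uncertainty`) pins the mean and median to within about
0.2 mm at this n, adequate for shape fitting.

Simulate the default two-site system and fit a synthetic observed sample
with known truth:

```r
sim <- run_simulation(default_config())
compute_shape_vector(site_distribution(sim, "juvenile"))
#>       mean   variance        p25        p50        p75    n_modes delta_mode
#>  14.943136  16.987719  11.357822  14.611007  18.122659   2.000000   2.891355
compute_shape_vector(site_distribution(sim, "adult"))
#>       mean   variance        p25        p50        p75    n_modes delta_mode
#>  21.169067   2.963321  19.739506  20.820684  22.234382   1.000000   0.000000

grid <- default_dispersal_grid(5)
sims <- simulate_grid(default_config(), grid)   # ~70 s, reusable
obs <- generate_synthetic_observed(default_config(), grid$xi_j_values[4],
                                   grid$xi_a_values[4], "adult",
                                   n_teeth = 5000, seed = 1, sims = sims)
classify_site(compute_error_surface(obs, sims = sims))
#> Site identity: adult (eps_j_min = 0.839, eps_a_min = 0.109)
#>   best-fit xi_j = 1.442e+04 g, xi_a = 10 days
```

The nursery carries a mixture of resident juveniles and visiting adults
(two modes; mean 14.9 mm) while the adult site is unimodal around large
teeth (21.2 mm). The fit recovers the true site identity and the juvenile
window exactly (truth: ξ_j = 14417 g), and places the adult window one
grid cell from its true value (10 vs 31.6 days) — ξ_a is the
weakly-identified direction of the surface, matching the flat 10% error
bands seen along that axis.

A thin command-line wrapper over the same functions ships at
`inst/cli/dentdist.R` (subcommands `simulate`, `fit`, `shapes`, `synth`,
`bootstrap`).

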