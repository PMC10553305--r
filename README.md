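# mpencounter

Encounter rates between zooplankton and microplastic particles in a
shallow tropical estuary, under calm and wind-driven turbulent
conditions.

Suspended microplastics behave like passive "alleged prey": before a
zooplankter can ingest a particle or become entangled in it, the two
must first meet. `mpencounter` estimates how often that happens for
three common estuarine taxa with very different kinematics — the copepod
*Acartia tonsa*, the chaetognath *Parasagitta friderici*, and the
luciferid shrimp *Belzebub faxoni* — from surface microplastic
concentrations measured at a set of sampling stations. It is aimed at
plankton ecologists and ecotoxicologists who want reproducible,
station-data-driven encounter-rate profiles rather than one-off
spreadsheet calculations.

## The models

Calm water uses the Gerritsen–Strickler ballistic encounter model. For a
searcher with encounter (perception) radius *R* (m) swimming at speed
*y* (m s⁻¹) among particles at density *N* (m⁻³) moving at speed *x*:

    C_GS = (pi R^2 N / 6) * [ (x + y)^3 - |x - y|^3 ] / (x y)

For stationary particles (*x* = 0, the microplastic case) this reduces
exactly to the swept-cylinder rate `C = pi R^2 N y`. Wind-driven
turbulence is introduced through the Rothschild–Osborn substitution:
each speed *v* is replaced by `sqrt(v^2 + w^2)`, where *w* is the
small-scale turbulent velocity. The RO/GS ratio (the "turbulence
multiplier") is independent of *R* and *N* and always ≥ 1.

The turbulent velocity itself comes from a wind-forced vertical
submodel, `w(z) = w0 * exp(-z / 0.25 m)` with `w0 ≈ 0.036 U` for wind
speed *U*, together with turbulent kinetic energy `k = w^2` and
dissipation rate `eps = w^3 / 0.27 m`. Station-to-station variability in
microplastic concentration is propagated by a classical bootstrap (1000
resamples of the station set, rate evaluated at each resample mean), and
a brute-force Monte-Carlo simulation of a searcher in a periodic box of
Poisson-distributed particles validates the closed forms independently.

## Worked example

```r
library(mpencounter)

# one taxon/season/model profile
prof <- encounter_profile("june", "chaetognath", "GS")
prof$mean[1]   # surface mean rate, particles per individual per hour

# the full 3 taxa x 2 seasons x 2 models study
study <- run_full_study(study_config(seed = 42))
study
```

```
<encounter_study> 12 profiles, 1000 bootstrap reps, seed 42
   season       taxon surface_gs surface_ro multiplier
1    june     copepod        1.6        1.8        1.2
2    june chaetognath     2510.0     3510.0        1.4
3    june   luciferid     1000.0     2680.0        2.7
4 october     copepod        0.2        0.3        1.3
5 october chaetognath      361.0      596.0        1.6
6 october   luciferid      145.0      501.0        3.5
```

`surface_gs` and `surface_ro` are surface encounter rates in particles
per individual per hour under calm (GS) and turbulent (RO) conditions;
`multiplier` is their ratio. Chaetognaths meet thousands of particles
per hour in June because of their large perception radius and fast
swimming; copepods meet one or two. June rates exceed October rates for
every taxon because the June surveys found roughly seven times more
microplastics (mean 13.5 vs 2 particles/L), despite October's stronger
wind. The slowest swimmer (the luciferid) gains the most from
turbulence. Surface rates here are computed from the packaged synthetic
station sets, whose means match the published survey summaries to within
a few percent, so the table reproduces the published values at that
accuracy.

`write_profiles(study, "out/")` exports each depth profile as a CSV
(`z_m, mean_rate_per_h, sd_rate_per_h`) plus a JSON run manifest
recording seeds and parameters. The Monte-Carlo check is one call:
`oracle_check()` prints empirical vs analytic rates with z-scores.

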