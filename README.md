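# darkfieldr

Grating-based X-ray dark-field (XDF) imaging measures ultra-small-angle
scattering from structure far below the pixel size — alveolar walls in lung
tissue, cell walls in foams, shells in microsphere packings. `darkfieldr`
implements the analysis chain that links *spectral* (two-energy-bin) XDF
signals to structural size measures of porous two-phase media, and exercises
it end-to-end on synthetic volumes. It is aimed at people developing or
evaluating dark-field imaging methods who need a reproducible, fully
synthetic testbed: phantom generators, microstructure statistics, and the
polychromatic dark-field forward model in one place.

## The model

A Talbot–Lau interferometer probes the sample at the autocorrelation length

```
xi_corr(E) = (d_S,G2 / p_G2) * hc / E
```

(`d_S,G2` sample–analyzer distance, `p_G2` analyzer grating period). The
dark-field signal `D` relates to the projected real-space correlation
function `G` of the sample's electron density and its thickness `t`:

```
-ln D(xi_corr) = sigma * t * [1 - G(xi_corr)],    sigma = sigma0 * lambda^2
```

`G(xi)` is computed from a 3D volume by the correlation theorem
(`gamma = F^-1[ F(delta_rho) F*(delta_rho) ]` on the mean-subtracted field),
projected along the beam axis and radially averaged in the sensitivity
plane. For a polychromatic beam in a counting bin `[E1, E2)` the effective
autocorrelation length is the fluence-and-visibility weighted mean

```
<xi>_w = Int Phi_eff(E) V(E) xi(E) dE / Int Phi_eff(E) V(E) dE .
```

The structural size measure is the mean chord length (MCL): cavity
intercepts along isotropic uniform random test lines, boundary-touching
chords excluded — the stereology standard for alveolar airspace size (for a
convex cavity MCL = 4V/S; a sphere of diameter d gives 2d/3). The package's
study endpoint is the correlation between the low/high-bin quotient
`-ln D_low / -ln D_high` and the MCL across a family of foams.

## Worked example

Recompute the published setup numbers (geometry `d_S,G2 = 0.571` m,
`p_G2 = 10` um; weighted energies 43.0 and 80.9 keV):

```r
library(darkfieldr)
geom <- interferometer_geometry(d_s_g2 = 0.571, p_g2 = 10)
round(correlation_length(c(43.0, 80.9), geom), 2)
#> [1] 1.65 0.88

reproduce_worked_examples()
#> # A tibble: 12 × 7
#>   quantity         material bin   computed printed compared match
#>   <chr>            <chr>    <chr>    <dbl>   <dbl> <lgl>    <lgl>
#> 1 xi_corr_um       <NA>     low       1.65    1.65 TRUE     TRUE
#> 2 xi_corr_um       <NA>     high      0.88    0.88 TRUE     TRUE
#> 3 neg_log_D_per_A2 CR-L     low      12.7    12.7  TRUE     TRUE
#> 4 neg_log_D_per_A2 CR-L     high     16      16    TRUE     TRUE
#> 5 neg_log_D_per_A2 EPDM     low      12.5    12.6  FALSE    TRUE
#> # i 7 more rows
```

The two energy bins sample autocorrelation lengths of 1.65 um (low) and
0.88 um (high); `neg_log_D_per_A2` is the wavelength-normalized scattering
signal `-ln D / lambda_w^2` in 1/Å² per material and bin. (The two EPDM
rows are reported but not compared: they are not reproducible from the
rounded per-bin inputs.)

Analyse a synthetic closed-cell foam:

```r
ph <- make_voronoi_foam(shape = c(64, 64, 64), voxel_size = 2,
                        n_seeds = 40, wall_um = 4, seed = 1)
profile <- ph$volume |> mean_subtract() |> autocorrelation_3d() |> projected_profile()
print(profile, n = 4)
#> # A tibble: 90 × 4
#>   xi_um     G one_minus_G n_samples
#>   <dbl> <dbl>       <dbl>     <int>
#> 1     0 1           0             1
#> 2     2 0.867       0.133         8
#> 3     4 0.713       0.287        12
#> 4     6 0.567       0.433        16
#> # i 86 more rows

mean_chord_length(ph$phase, n_lines = 2000, seed = 1)
#> <chord_distribution> MCL = 22.49 um (SE 0.32), 1297 chords from 2000 lines (1194 excluded at boundary)
```

`G` starts at 1 and decays over the cell scale; `1 - G` is the quantity the
dark-field signal probes. The MCL of 22.5 um says the average cavity
intercept is about half the mean cell size of this foam.

The whole study — five foams spanning MCL ~20–150 um, two-bin forward
signals, ratio-versus-MCL correlation — is one call:

```r
study <- run_study(study_config(seed = 1))
glance(study)      # Spearman rho of ratio vs MCL, monotonicity flag
tidy(study)        # per-material, per-bin results
autoplot(study)    # the ratio-vs-MCL scatter
```

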