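# phenopanel

Cell-line panel selection for high-content phenotypic screening.

Image-based screens profile thousands of compounds by reducing each treated
cell to a vector of morphology, intensity and texture features (a
Cell-Painting-style panel). Which cell line — or small panel of lines — you
screen in determines what you can see. `phenopanel` scores that choice from
per-cell feature tables:

- **Phenotypic profiles.** Each treatment in each cell line becomes a
  vector of *signed Kolmogorov–Smirnov* statistics, one per feature,
  comparing treated cells with same-plate DMSO controls: the magnitude is
  the two-sample KS distance \(D = \sup_x |F_{trt} - F_{ctrl}|\), the sign
  the direction of the dominant ECDF branch. DMSO wells get leave-one-well-out
  self-profiles, so the vehicle control forms its own nondegenerate point
  cloud.
- **Phenoactivity** of an MOA (mechanism-of-action class) in a line:
  the one-sided KS statistic
  \(\max(0, \sup_x [F_{DMSO}(x) - F_{MOA}(x)])\) between the distances of
  DMSO and MOA profiles to the DMSO cloud centroid — 0 when the MOA sits
  inside the vehicle cloud, 1 when fully separated. A companion IQR rule
  counts compounds "outside the cloud" (distance > median + 1 IQR of the
  DMSO distances).
- **Phenosimilarity** of an MOA:
  \(1 - \max(0, \sup_x [F_{nbr}(x) - F_{within}(x)])\), comparing
  within-MOA pairwise distances with each member's k-nearest-neighbor
  distances over the whole compound library — 1 when members are mutually
  nearest neighbors, falling toward 0 when they scatter past their local
  neighborhood scale.
- **Panel optimization.** A set of lines scores each MOA by its best
  member (max aggregation); sets are ranked by the mean over MOAs, with
  robustness estimated by re-scoring 50 random subsamples of 2/3 of the
  compound library.
- **Synthetic screens.** A generator plants per-(MOA, line) effect
  magnitudes and per-MOA compound heterogeneity in Gaussian single-cell
  data, so the whole pipeline is testable with known ground truth.

See `vignettes/phenopanel-methods.Rmd` for the model, the conventions
(tie-breaks, leave-one-out distances, quantile type) and their rationale.

## Worked example

```r
library(phenopanel)

# a small three-line screen: MOAs differ in effect magnitude per line
set.seed(42)
a <- matrix(runif(6 * 3, 0.3, 2), 6, 3)
cfg <- synthetic_screen_config(
  n_cell_lines = 3, n_features = 20, n_moas = 6, compounds_per_moa = 6,
  dmso_wells_per_plate = 8, cells_per_well = 50,
  effect_magnitude = a, heterogeneity = 0.4, seed = 7)
screen <- generate_screen(cfg)

profiles <- build_profiles(screen$cells)
pa <- score_all_phenoactivity(profiles, screen$annotation, min_moa_size = 5)
head(pa, 3)
#> # A tibble: 3 × 6
#>   cell_line moa    n_compounds score n_outside threshold
#>   <chr>     <chr>        <int> <dbl>     <int>     <dbl>
#> 1 line_01   moa_01           6 1             6     0.711
#> 2 line_01   moa_02           6 1             6     0.711
#> 3 line_01   moa_03           6 0.542         3     0.711
```

`score` is the phenoactivity of the MOA in that line; `n_outside` counts
its compounds beyond the DMSO cloud's median + IQR `threshold`. Ranking
panels of up to two lines, with compound-subsampling robustness:

```r
rk <- rank_sets(profiles, screen$annotation, "phenoactivity",
                max_set_size = 2, min_moa_size = 5,
                n_draws = 50, fraction = 2/3, seed = 17)
rk[1:4, c("lines", "n_moas", "summary", "subsample_mean", "subsample_sd")]
#> # A tibble: 4 × 5
#>   lines           n_moas summary subsample_mean subsample_sd
#>   <chr>            <int>   <dbl>          <dbl>        <dbl>
#> 1 line_01;line_02      6   1              1           0
#> 2 line_02;line_03      6   0.958          0.953       0.0657
#> 3 line_01;line_03      6   0.951          0.953       0.0558
#> 4 line_02              6   0.917          0.9         0.140

best1 <- rk$summary[rk$n_lines == 1][1]
best2 <- rk$summary[rk$n_lines == 2][1]
improvement(best1, best2)
#> [1] 9.090909
```

The best pair covers every MOA that either member detects, here a 9.1%
gain in mean phenoactivity over the best single line.

## The analysis workflow

Numbered drivers under `analysis/` run a full desk-scale study over the
package (6 lines × 20 MOAs × 5 compounds × 200 cells/well × 77 features),
writing tables to `results/` and intermediates to `scratch/`:

1. `01_simulate.R` — generate the screen with planted per-line effects.
2. `02_profile.R` — signed-KS profiles for all lines.
3. `03_score.R` — phenoactivity and phenosimilarity score tables.
4. `04_optimize_panel.R` — single-line and pair rankings with subsampling.
5. `05_parameter_recovery.R` — score response to planted effect and
   heterogeneity grids.

Run them in order from the repository root with `Rscript analysis/<file>`.

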