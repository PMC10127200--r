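---
title: "Scoring cell lines for phenotypic screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring cell lines for phenotypic screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenopanel)
```

## The problem

High-content phenotypic screens image cells under thousands of compound
treatments and reduce each cell to a vector of morphology, intensity and
texture features (a Cell-Painting-style panel, 77 features by default here).
Before running such a screen one must choose the cell line — and lines
differ enormously in how visibly they respond to perturbation. `phenopanel`
quantifies that choice with two scores per (cell line, mechanism-of-action)
pair, computed from single-cell feature tables, and then ranks cell-line
panels by how well their best member covers each MOA.

- **Phenoactivity**: how far an MOA's compounds move cells away from the
  DMSO vehicle control, in profile space.
- **Phenosimilarity**: how tightly an MOA's compounds cluster, relative to
  the local density of the whole compound library around them.

## Signed-KS phenotypic profiles

For one treatment in one cell line, each feature's treated cell population
is compared with the DMSO cell population pooled from the same plate(s)
(configurable to global pooling; the per-plate default limits plate-level
drift without an explicit normalization step). The comparison is the
two-sample Kolmogorov–Smirnov statistic with a sign:

$$ s = \begin{cases} +D^{+}, & D^{+} > D^{-} \\ -D^{-}, & D^{-} > D^{+},
\end{cases} \qquad
D^{+} = \sup_x\,[F_{\mathrm{ctrl}}(x) - F_{\mathrm{trt}}(x)],\;
D^{-} = \sup_x\,[F_{\mathrm{trt}}(x) - F_{\mathrm{ctrl}}(x)] $$

so $|s|$ is the classical KS distance and the sign says whether treated
cells are stochastically larger (+) or smaller (−) in that feature. A
treatment's profile is this statistic across all features — a point in
$[-1,1]^{77}$. KS is rank-based per feature, so no feature standardization
is needed or applied.

Two conventions are worth stating precisely:

- **Branch ties.** When $D^{+} = D^{-}$ exactly (possible because ECDF
  differences are rationals; e.g. two samples interleaved as ABBA), the sign
  is taken from the first nonzero ECDF difference along the sorted pooled
  points. Swapping the samples negates every difference, so the statistic is
  exactly antisymmetric, which a "ties go positive" rule is not.
- **Pooling.** Replicate wells of a compound are pooled into one profile
  (one point per compound in profile space); a per-well mode exists behind
  `per_well = TRUE`.

### The DMSO self-profiles

The DMSO condition must itself form a nondegenerate point cloud: its spread
calibrates everything downstream. Profiling DMSO against itself would give
exact zeros, so each control well is profiled leave-one-well-out against the
other control cells on its plate. Plates need at least two DMSO wells;
single-well plates are skipped with a warning.

## Phenoactivity

For each cell line, all profiles are reduced to distances from the centroid
(coordinate-wise mean; median available) of the DMSO self-profile cloud.
The phenoactivity of an MOA is the one-sided KS statistic between the two
distance distributions:

$$ \mathrm{PA} = \max\!\big(0,\ \sup_x\,[F_{\mathrm{DMSO}}(x) -
F_{\mathrm{MOA}}(x)]\big) $$

which is 0 when the MOA's distances are stochastically no larger than the
DMSO cloud's own spread and 1 when every MOA compound sits beyond every
DMSO replicate. The exact functional used by the original study is not
published in its main text; this one-sided-KS form was chosen because it is
bounded in $[0,1]$, reads directly off the distance-distribution plots the
approach is built on, and stays in the same KS toolkit as the profiles
themselves. It is a package-level design decision, flagged here.

**Leave-one-out DMSO distances.** A DMSO profile helps define the centroid
it is measured against, so its pooled-centroid distance is biased low by a
factor of roughly $\sqrt{(n+1)/(n-1)}$ with $n$ wells. In 77 dimensions the
distance distributions are concentrated enough that this bias alone pushes
the null score above 0.5 with 8 wells. Each DMSO distance is therefore
computed to the centroid of the *other* DMSO profiles, putting the
reference distribution on the same footing as the (independent) compound
distances. The residual difference is slightly conservative. The
uncorrected behaviour is available as `dmso_reference = "pooled"`.

**Outside-the-cloud rule.** A compound is called outside the DMSO cloud
when its centroid distance exceeds the median DMSO distance by more than
one IQR. Quartiles use linear interpolation (`stats::quantile` type 7) and
the comparison is strict; both choices move the threshold, so they are
fixed and documented.

## Phenosimilarity

For an MOA with $n \ge 2$ compounds, two distance multisets are compared:
the $\binom{n}{2}$ within-MOA pairwise distances, and each member's
distances to its $k$ nearest neighbors among *all* compound profiles (self
excluded, DMSO excluded — proximity to DMSO is phenoactivity's job). By
default $k = n - 1$, making the multisets size-comparable. The score is

$$ \mathrm{PS} = 1 - \max\!\big(0,\ \sup_x\,[F_{\mathrm{nbr}}(x) -
F_{\mathrm{within}}(x)]\big): $$

1 when the MOA's members are mutually nearest neighbors (the distributions
coincide), falling toward 0 as within-MOA distances exceed each member's
local neighborhood scale. Neighbor ties are broken by compound identifier,
so results are deterministic. As with phenoactivity, the exact published
functional is unavailable; this form operationalizes the stated idea
("nearest neighbors of a compound will be another compound in the same MOA
and the two distributions will closely overlap") and is flagged as a design
decision.

Because the neighbor multiset collects *order statistics* of the library's
distance distribution, an undistinguished MOA in a homogeneous cloud scores
well below 1 — its members' nearest neighbors are systematically closer
than a random pair. This matches the low library-wide averages the approach
reports on real screens.

## Panel optimization

A set of cell lines detects an MOA as well as its best member does: the
set's per-MOA score is the max over lines, its summary the mean over MOAs
scored in every member line (median available). Subsets up to
`max_set_size` are enumerated exhaustively (at most 63 sets for six lines);
ordering is total (summary desc, then fewer lines, then names).
`improvement()` reports the percent gain of a set over a baseline summary.

Max-aggregation makes the summary monotone: adding a line never lowers it,
provided the line shares the scored MOA panel (the eligibility rule
restricts sets to MOAs scored in all members, so a line missing MOAs can
shrink the panel — not possible in the complete screens generated here).

Robustness to library composition is estimated by compound subsampling:
each of `n_draws = 50` draws retains $\lfloor 2N/3 \rfloor$ compounds
without replacement, re-scores, and re-summarizes. MOAs falling below the
size filter within a draw drop out of that draw. Per-draw seeds are
`seed + draw`, so one global seed reproduces the whole distribution, and
`fraction = 1` reproduces the full-library values exactly.

MOAs with fewer than 5 compounds are excluded from reported summaries (the
computation itself accepts any size ≥ 1 for phenoactivity, ≥ 2 for
phenosimilarity).

## The synthetic screen generator

Real screens of this kind are large external datasets; the generator
produces screens with known ground truth so every pipeline stage is
testable from code alone. Cells are Gaussian per feature (a heavy-tailed
Student-t option stress-tests KS robustness): DMSO cells draw from a
per-line baseline $\mathcal N(\mu_{l}, \sigma_{l})$, and cells treated with
compound $c$ in line $l$ are shifted by

$$ v_{c,l} = a_{m(c),\,l}\, u_{m(c),\,l} + \tau_{m(c)}\, \varepsilon_{c} $$

where $u$ is a per-(MOA, line) unit direction, $a \ge 0$ the planted effect
magnitude (the phenoactivity control), $\varepsilon_c \sim \mathcal N(0,
I/D)$ a per-compound latent drawn once and shared across lines (the
compound's biological identity), and $\tau \ge 0$ the per-MOA heterogeneity
(the phenosimilarity control). Because $\|u\| = 1$ and
$E\|\varepsilon_c\|^2 = 1$, both $a$ and $\tau$ are mean displacement
magnitudes in units of the cell-level noise SD, comparable across feature
dimensionalities. Defaults are desk-scale (6 lines × 20 MOAs × 5 compounds
× 200 cells/well × 77 features) and the whole screen is a deterministic
function of the config, including its seed.

What the generator does *not* emulate: plate/batch artifacts (a config hook
is reserved), feature correlations within a cell, segmentation errors,
dose–response structure, and the low-dimensional manifold geometry of real
morphological profiles. Passing tests therefore validate the scoring
machinery and its monotone response to planted structure — not performance
on real Cell Painting data.

### Conditions for the validation sweeps

The dynamic range of both scores depends on the signed-KS noise floor: with
$n$ treated cells against an $m$-cell control pool, null per-feature values
have RMS $\approx 0.87\sqrt{(n+m)/nm}$, and profile-space displacements
scale as $\approx 0.4a$ for small effects. The sweep conditions were chosen
once from this argument so the prescribed grids sit inside the sensitive
range:

- **Effect sweep** ($a \in \{0, 1, 2, 4\}$, $\tau = 0$, 20 replicate
  screens): 1 line, 20 features, 6 MOAs × 4 compounds, 8 DMSO wells, 20
  cells/well. At 20 cells/well the noise floor keeps $a = 2$ off the
  ceiling, so the grid means are strictly increasing (Spearman 1.0).
- **Heterogeneity sweep** ($\tau \in \{0, 0.5, 2\}$, $a = 1$, 20 replicate
  screens): 1 line, 20 features, 16 MOAs × 4 compounds, 100 cells/well.
  Phenosimilarity degrades with $\tau$ only when members can scatter past
  their local neighbor spacing, which requires a reasonably dense library
  with moderate common effects — the regime of real reference screens. With
  few, strongly separated MOAs the members remain mutual nearest neighbors
  at any $\tau$ and the score cannot fall; that regime is deliberately
  avoided.
- **Best-line recovery**: 3 lines, one planted with $a = 3$ on every MOA
  against $a = 1$ elsewhere (margin 2), $\tau = 0.25$, 30 cells/well, 20
  replicate screens; the planted line must rank first in at least 18.

## Numerical choices and degenerate inputs

- ECDF suprema are evaluated at the sorted pooled sample points, where the
  sup of a difference of right-continuous step functions is attained.
- Quantiles: linear interpolation (type 7) everywhere.
- Ties: neighbor search by (distance, compound id); set ranking by
  (summary desc, set size, line names); signed-KS branch ties by first
  nonzero ECDF difference.
- Missing feature values drop the cell, never imputed; the drop count is
  logged. KS needs no imputation and rows are exchangeable, so the retained
  set is order-independent.
- Empty samples, MOAs without profiled compounds, plates without controls,
  and sub-minimum configs raise errors naming the offending input; MOAs
  with one compound (phenosimilarity) and single-DMSO-well plates are
  skipped with warnings.

## Known limitations

- Both score functionals are this package's operationalization of verbally
  described quantities; reproduction of published per-MOA tables on the
  original deposited screen is contingent on those definitions matching the
  original supplementary material, which is not redistributed here.
- Phenosimilarity depends on library density through the neighbor order
  statistics; absolute values are not comparable across libraries of very
  different size.
- Max-aggregation monotonicity holds on a common MOA panel; with ragged
  panels the eligibility intersection can shrink a set's summary.
- Subsampling resamples compounds, not MOAs; very small MOAs vanish from
  many draws and contribute unstable summaries.
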