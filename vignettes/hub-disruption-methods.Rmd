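---
title: "Hub disruption in voxel-wise functional networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hub disruption in voxel-wise functional networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubdisrupt)
```

## The scientific question

Focal brain injury does not only damage tissue locally: it perturbs the
correlational structure of spontaneous activity across the whole brain.
Voxel-wise functional networks — binary graphs whose nodes are gray-matter
voxels and whose edges are the strongest BOLD correlations — summarise that
structure, and nodal graph metrics (degree, betweenness centrality,
clustering, efficiency, participation) quantify each voxel's role in it.
This package implements two complementary analyses on such networks:

* a **global** analysis via the hub-disruption index, asking whether a
  subject's whole topology is reorganised relative to a normative control
  reference, and
* a **local** analysis via voxel-wise degree maps, asking *where* the
  network differs between groups and whether regional degree relates to a
  behavioural score (here a 0–66 upper-extremity motor scale and its
  recovery ratio).

## The hub-disruption index

For a nodal metric vector $m_s$ of subject $s$ and the control-group mean
profile $m_{\mathrm{ref}}$, the index $k_D$ is the OLS slope of

$$ m_s(v) - m_{\mathrm{ref}}(v) \;=\; \alpha + k_D\, m_{\mathrm{ref}}(v) + \varepsilon_v $$

across voxels $v$. A subject whose hubs (high-metric voxels) have lost
standing while low-metric voxels gained shows $k_D < 0$; a subject matching
the reference has $k_D = 0$. Three modelling choices deserve comment:

* **The intercept is estimated, not fixed at zero.** The construction is an
  affine trend; omitting the intercept forces any mean shift of the profile
  into the slope and biases $k_D$ toward $-1$. `kd_fit()` therefore always
  fits $\alpha$.
* **Controls are referenced leave-one-out** (`kd_profiles(hc_reference =
  "loo")`). A control included in its own reference is pulled toward
  $k_D = 0$ by construction, which deflates the control spread and biases
  the group contrast. The full-mean mode is available for comparison.
* **Attenuation.** Metric profiles estimated from finite, filtered time
  series are noisy; noise shrinks the individual profile toward its mean,
  which pushes *everyone's* $k_D$ below zero (visible in the README worked
  example). Because the shrinkage applies to both groups, group contrasts
  and the correlation between planted and recovered slopes survive; the
  absolute level of $k_D$ should not be over-interpreted.

The repeated-measures group test is implemented as the between-subject
ANCOVA on density-averaged $k_D$ with age and gender covariates — exactly
the between-subject effect of the classical split-plot decomposition, which
needs no sphericity correction because the within-subject (density) factor
is not an endpoint. Its F statistic has $(1, N-4)$ degrees of freedom.

## Networks at fixed link density

Correlation matrices are Fisher z-transformed ($|r|$ capped at
$1-10^{-7}$ so duplicated series stay finite; zero-variance voxels are
flagged and their edges sunk to $-\infty$) and thresholded by *link
density*: the strongest $L = \mathrm{round}(d\,V(V-1)/2)$ edges by signed z
are kept, for $d$ = 1–10%. Fixing density rather than a correlation cutoff
equates network cost across subjects, so topology — not overall correlation
strength — drives group differences. Determinism choices: half-up rounding
of $L$ and lexicographic $(i,j)$ tie-breaking, so the edge set is
reproducible across platforms; ranking uses signed z (at ≤10% density this
selects positive correlations; an absolute-value mode exists behind a
flag).

Degree maps exclude links between voxels at Euclidean centre-to-centre
distance ≤ 2 grid units (12 mm on a 6 mm grid): short links are the most
inflated by residual motion and point-spread. "Within two adjacent voxels"
admits other readings (city-block, 26-neighbourhood shell); Euclidean is
the most literal and is the default, with a Chebyshev option. ROI-seeded
maps count surviving links from each voxel into the ROI (the link-count
reading of a seed map, consistent with degree maps; the seed-mean
correlation map is a different quantity and is out of scope).

## Graph metrics

Degree, clustering coefficient ($2t_i/k_i(k_i-1)$, zero below degree 2),
unnormalised Brandes betweenness, nodal efficiency (mean inverse BFS
distance; the integration-flavoured form, not local efficiency), and
participation coefficient $1-\sum_m (k_{im}/k_i)^2$. The participation
coefficient needs a module partition that connectivity data alone do not
dictate; the default is a seeded greedy modularity maximisation per subject
network (`detect_modules()`), with the alternative of passing one fixed
partition (e.g. from the control mean network) to remove subject-level
partition noise. Betweenness is left unnormalised because the $k_D$
regression is scale-equivariant — normalisation would only rescale slopes.

## Preprocessing and scrubbing

The cleaning chain is fixed and logged: discard 4 volumes → grand-mean
scaling to 10,000 (the conventional choice; invisible to correlations) →
high-pass 0.008 Hz → nuisance regression (6 motion parameters, CSF, WM,
global signal; OLS per voxel, pseudo-inverse under collininearity) → censor
detection → linear interpolation of censored volumes → band-pass
0.008–0.1 Hz → deletion of censored volumes.

* **Censoring**: FD $> 0.5$ mm, or z-normalised DVARS or volume-SD
  $> 2.3$; every flagged volume is expanded to $\{i-2,\dots,i+2\}$ clipped
  to the run. FD and DVARS are set to 0 at the first volume (backward
  differences are undefined there), and z-normalisation excludes that
  placeholder. The z-scores are computed on the data entering the censoring
  step (post nuisance regression); published descriptions of this scrubbing
  scheme leave the alternative (computing them earlier) open, so the choice
  is logged.
* **Filter-vs-scrub order**: filtering a scrubbed series breaks uniform
  sampling. The package interpolates censored volumes, applies the
  zero-phase band-pass on the uniform grid, then deletes the censored
  columns — preserving the filter's frequency interpretation while keeping
  censored volumes out of the connectivity estimate.
* **Filter realisation**: the band-pass is applied in the frequency domain
  as the squared magnitude response of a 4th-order Butterworth — exactly
  the transfer function of a forward–backward (zero-phase) pass, which
  doubles the effective order. A recursive (IIR) realisation is nearly
  unstable at the 0.008 Hz edge at TR = 2.5 s (poles essentially on the
  unit circle) and its transients corrupt correlation structure; the
  spectral application is exact and stable. The series is extended by even
  periodic reflection `[x, rev(x)]` so the circular transform sees no
  discontinuity.
* **QC**: fewer than 120 retained volumes (5 min at TR = 2.5 s) fails the
  subject.

## Permutation inference with TFCE

Voxel-wise group comparisons use a Freedman–Lane permutation GLM: maps are
residualised on the nuisance covariates, residual rows permuted, the
reduced-model fit added back, and the contrast t map recomputed; TFCE
($\mathrm{TFCE}(v)=\sum_h e(h,v)^{E} h^{H}\,dh$ with $E=0.5$, $H=2$,
$dh = \max|t|/100$, 26-connectivity) is applied to both contrast
directions, and the maximum enhanced statistic per permutation forms the
family-wise null. P-values use the add-one convention
$(1+\#\{\max \ge \mathrm{obs}\})/(n_{\mathrm{perm}}+1)$, which keeps them
valid (never exactly zero). When the requested permutation count reaches
the number of distinct row permutations the scheme enumerates all of them
instead. Cluster tables report connected components of
$p_{\mathrm{FWE}} < \alpha$ with peak statistic, peak grid coordinate and
size in voxels and mm³.

Behavioural associations use a covariate-adjusted Spearman correlation:
rank-transform both variables, residualise the ranks on an intercept plus
covariates, and correlate the residuals, with the t approximation on
$n-2-k$ degrees of freedom. With no covariates this is exactly the
classical Spearman coefficient (averaged tie ranks).

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` produces the study conditions the pipeline is validated
under: 32 controls and 28 patients, 230 volumes at TR = 2.5 s, 6 mm grid,
networks generated at 10% density. Its structure:

* **Reference network**: a preferential-attachment-style graph with an
  exact edge count. Hubs are required — the disruption index is a slope
  over the metric range and degenerates on flat-degree graphs. Nodes are
  laid out with degree decreasing from the grid centre, emulating the
  spatial clustering of real voxel-level hubs, and the planted ROI is the
  central 24-voxel hub block (≈5,200 mm³, within the range of reported
  cluster sizes on a 6 mm grid).
* **Covariance**: $\Sigma = \ell I + w(A+I)$ with edge weight $w = 0.3$;
  linked voxels correlate at $w/(\ell+w)$, unlinked voxels at exactly 0.
  One diagonal load $\ell$ (the smallest spectrally safe value across the
  whole cohort, with a 10% margin) is shared by every subject: a
  per-subject load would tie correlation strength to disruption level and
  confound the planted effect. The spectral bound
  $\ell > w\,|\lambda_{\min}(A+I)|$ caps attainable edge correlations near
  0.12 for hub-bearing graphs — an honest, structural limit on how sharply
  a 230-volume scan can recover the generating network.
* **Disruption**: each patient's network is rewired toward the degree
  sequence implied by a per-patient slope $\kappa \sim N(-0.3, 0.3)$
  (truncated to $\pm0.9$), preserving edge count. Published stroke-cohort
  analyses of this kind report test statistics but not effect sizes, so the
  $\kappa$ distribution is a conventional choice: disruption centred at a
  moderate negative slope with wide individual variability.
* **Motion and artefacts**: baseline jitter keeps FD well below 0.5 mm;
  spike volumes carry both a motion step (FD ≥ 0.8 mm) and a large
  image-intensity artefact. The artefact matters: it is what the DVARS/SD
  criteria exist to detect, and without it z-threshold censoring would
  systematically truncate the largest genuine signal excursions instead.
* **Behaviour**: baseline score = $66\,\mathrm{logit}^{-1}(\beta_b z +
  \varepsilon)$ with $\beta_b = -1.5$ per SD of planted ROI degree (more
  severe impairment with higher ROI degree), respecting the 0–66 scale
  bounds; the recovery ratio couples positively ($\beta_r = +0.25$ per
  SD). Ground-truth ROI degree is defined under the same 2-unit link
  exclusion the analysis applies.
* **Seeds**: one master seed fans out to every stream through
  `fan_seed(master, counter) = (master·10007 + counter) mod (2³¹−1)`, so
  cohorts regenerate bit-identically.

What it does **not** emulate: hemodynamic response shapes (volumes are
temporally white by default; an AR(1) flag exists), lesion geometry,
physiological noise, registration error, or spatially varying smoothness.
Passing tests therefore demonstrate that the *pipeline machinery* is
correct and calibrated and that planted effects of realistic size are
recoverable — not that effect sizes in real cohorts will match.

## Problem sizes and numerical choices in the validation suite

The test-suite calibration studies use 125-voxel (5×5×5) grids with 20
subjects and 500 permutations × 200 replicates for the family-wise error
rate, 1,000 replicates for the ANCOVA type-I rate, and 20 seeded runs of
the default cohort for the end-to-end association sign checks; slope
recovery uses 200 synthetic subjects across $\kappa \in \{-0.5, -0.3, 0,
+0.2\}$. These sizes give binomial standard errors comfortably inside the
asserted calibration bands while keeping the default run reproducible on a
single CPU. Tolerances: graph metrics match oracles to $10^{-9}$; the
$k_D$ closed form holds to $10^{-12}$; TFCE equals the exhaustive
per-threshold oracle exactly on the shared threshold grid $h = i\,dh$
(the grid is defined multiplicatively for floating-point agreement).
Degenerate inputs are handled explicitly: constant DVARS/SD series return
zero z-scores with a warning, a constant reference profile is an error for
`kd_fit()`, zero-variance voxels can never be selected as edges, and a
zero-measure contrast yields a zero t map.

## Known limitations

* The absolute $k_D$ level is attenuation-biased at realistic scan lengths
  (see above); only contrasts and correlations are interpretable.
* The Bonferroni-corrected significance level for cluster–behaviour
  associations is implemented as the adjusted *threshold* $\alpha/m$
  (printed 0.006 at $\alpha = 0.05$, $m = 8$); the alternative reading as
  an adjusted p-value is not used.
* The per-map TFCE step $dh = \max|t|/100$ follows the cited tool's
  default; it makes enhanced values weakly dependent on the map maximum.
* Weighted or negative-edge networks, parcel-level $k_D$, and
  cluster-extent (non-TFCE) inference are out of scope.
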