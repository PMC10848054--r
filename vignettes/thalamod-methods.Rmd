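---
title: "Modular thalamocortical network analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular thalamocortical network analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalamod)
```

## What the package computes

`thalamod` studies how the modular organization of resting-state cortical
functional networks breaks down in temporal lobe epilepsy (TLE), and what
role the thalamus plays in that organization, separately for patients with
normal cognition (TLE-CN) and with cognitive impairment (TLE-CI, Montreal
Cognitive Assessment score below 26). The analysis chain is:

1. **Temporal preprocessing** of parcel time series: initial-volume
   dropping, linear detrending, band-pass filtering (0.01–0.08 Hz), and
   nuisance regression (Friston-24 motion expansion plus white-matter and
   CSF signals), with subject exclusion when head motion exceeds 3 mm /
   3 degrees or mean framewise displacement exceeds 0.2 mm.
2. **Cortical connectome**: Pearson correlation over 200 cortical parcels
   labelled with the seven-network partition (VIS, SMN, DAN, VAN, LIM,
   FPN, DMN), proportionally thresholded into binary graphs at sparsities
   0.1–1.0 (step 0.1), each metric summarized by its trapezoidal area
   under the curve (AUC) across the sweep.
3. **Modular metrics**: modularity Q on the fixed seven-network partition,
   per-module modular segregation index (MSI), and intra-/intermodular
   edge counts.
4. **Thalamic parcellation**: winner-take-all labelling of thalamic voxels
   (inside a probabilistic mask thresholded at 10%) by the cortical
   network whose seed shows the strongest group-average functional
   connectivity.
5. **Thalamocortical hub metrics**: a 207-node network (200 parcels + 7
   thalamic subdivisions) thresholded block-wise ("two-step"), with the
   participation coefficient (PC) and within-module degree z-score (WMD)
   of each thalamic node.
6. **Statistics**: normality-gated group comparisons (pooled t / one-way
   ANOVA versus Mann-Whitney / Kruskal-Wallis), chi-square for categorical
   demographics, Bonferroni correction per metric family, and
   metric-versus-MoCA correlations within patient groups.

No raw imaging data accompany the original study, so the package ships a
**synthetic cohort generator** that plants known modular structure; every
downstream stage is validated against that ground truth.

## The generative model

Per subject, seven latent network signals $L_1,\dots,L_7$ (temporally
white, unit variance) are drawn with a latent correlation matrix chosen so
that observable parcel correlations hit their targets. A parcel $i$ of
module $m$ is

$$x_i = \sqrt{a_i}\,L_m + \sqrt{1-a_i}\,\varepsilon_i,$$

so two parcels of module $m$ correlate at $\sqrt{a_i a_j}$, and the
module-level target `within_coupling` equals $a$ exactly when parcels are
homogeneous. Setting the latent correlation between modules $m,n$ to
$b_{mn}/\sqrt{a_m a_n}$ makes the parcel-level between-module correlation
equal `between_coupling` $b_{mn}$. This closed form is the point of the
construction: the tests can verify the pipeline against analytic truth.

Two features are deliberately more structured than the simplest block
model, because without them the planted clinical effects cannot exist:

* **Parcel heterogeneity** (`parcel_coupling_spread`, default 0.3): each
  parcel's coupling is scaled by a fixed multiplier drawn uniformly on
  $1 \pm 0.3$. With homogeneous parcels, every within-module correlation
  is identical, so binarized modules saturate (every node the same
  within-degree) from sparsity ~0.3 onward and within-module degree
  z-scores degenerate to zero. Real parcels load heterogeneously on their
  networks.
* **Shared subdivision noise** (`thal_label_noise_share`, default 0.5): a
  thalamic voxel of subdivision $n$ is
  $\sqrt{c}\,M_n + \sqrt{1-c}\,(\sqrt{h}\,\eta_n + \sqrt{1-h}\,e)$, where
  $M_n$ is a unit-variance blend of the own-network latent with the other
  six (`thal_diffuse` sets the blend) and $\eta_n$ is shared by all voxels
  of the label. Because correlation is scale-invariant, with purely
  independent voxel noise ($h = 0$) the subdivision mean washes the noise
  out and the coupling $c$ cancels from every subdivision-level
  correlation — no thalamic coupling effect could then be planted at all.
  $h$ is the fraction of "local" thalamic signal that does not follow the
  cortex.

MoCA scores are linear in the subject-level thalamo-SMN coupling
(per-group intercepts; common slope 14 points per unit coupling; noise SD
1.2), rounded, clamped to $[0, 30]$ and to the group's cognitive category.
Subject-level coupling varies with SD 0.10 around the group value, which
is what makes the cognition-to-hub-metric correlation estimable.

### Planted group conditions (the defaults)

The default `cohort_spec()` encodes the study conditions: group sizes
37/35/18 (HC / TLE-CN / TLE-CI), 230 volumes at TR 2 s, and coupling
tables planting the reported effect *directions* (magnitudes are not
recoverable from published figures, so they are chosen for detectability
at cohort scale):

* Patients: VAN and DMN within-coupling 0.25 (HC 0.45) **and** raised
  between-coupling on pairs involving VAN/DMN (0.20; DAN–DMN 0.22; HC
  0.15). Both routes — weakened segregation and strengthened integration —
  are needed: weakened within-coupling alone leaves thresholded edge sets
  nearly unchanged as long as it still outranks every between-module
  correlation.
* Thalamus: baseline voxel-to-network coupling 0.25. TLE-CN SMN 0.45;
  TLE-CI SMN 0.75 with diffuse blend 0.20; patients' DMN 0.20. The low
  control baseline reflects that thalamic subdivisions couple to their
  networks more weakly than cortical parcels do to each other; with a high
  baseline the control tha_SMN node would already top its module's
  strength distribution, leaving no headroom for the planted impairment
  effect.

## Numerical and algorithmic choices

* **Thresholding.** Edge budget $K = \lfloor s\,N(N-1)/2 + 0.5\rfloor$
  (halves away from zero), strongest positive correlations first, exact
  ties broken by ascending node-index pair. Negative correlations are
  never edges; if fewer than $K$ positive entries exist the achieved
  sparsity is recorded. Graphs are binary: the analysis counts
  connections, which presupposes binarization.
* **Two-step thresholding.** The cortical–cortical (200×200),
  thalamo-thalamic (7×7) and thalamo-cortical (7×200) blocks are
  thresholded independently at the same sparsity and reassembled. This
  guarantees the bipartite block keeps $\lfloor 1400s + 0.5\rfloor$ edges
  even when every thalamocortical correlation is weaker than every
  cortical one — the regime in which single-step thresholding would
  discard the thalamus entirely (both behaviours are asserted in the
  tests on an adversarial matrix).
* **Modularity Q** uses Newman's degree-corrected form on the *a-priori*
  seven-network partition, not a detected one, because all module-resolved
  results refer to those fixed labels; a Louvain-based detected-partition
  modularity (`modularity_q_detected`, via igraph) is available as a
  sensitivity check.
* **MSI** is computed once per subject on the unthresholded positive
  weights, $(\bar W - \bar B)/\bar W$ with negative entries zeroed, then
  replicated across the sparsity axis so it carries an AUC on the common
  scale. On binary graphs MSI would be a deterministic function of the
  edge counts already reported.
* **PC and WMD** follow the standard hub-classification definitions on
  the binary graph; WMD uses the population SD over the node's module and
  returns 0 for degenerate (constant-degree) modules. Disconnected nodes
  get PC 0 and are flagged.
* **Winner-take-all** breaks exact ties by the fixed network order (first
  label wins, with a warning) and labels non-positive winners anyway but
  flags them. The mask uses a strict `> 0.10` probability cutoff.
* **Group averaging** of seed-to-voxel maps is Fisher-z based
  (variance-stabilized); correlations at $\pm 1$ are clipped to
  $\pm(1-10^{-7})$ with a warning. Parcellation averages over *all*
  participants, patients and controls combined.
* **Band-pass filter**: 4th-order Butterworth applied forward-backward
  (zero phase) via `signal::filtfilt`; an ideal FFT mask filter is
  available for cross-checks. The passband gain contract (within 10% in
  band, at least threefold attenuation one octave outside) is asserted on
  probe sinusoids.
* **Statistics**: pooled-variance t (the printed reference statistics
  reproduce under pooled, not Welch, variance), chi-square without
  continuity correction (likewise), tie-corrected Mann-Whitney z with
  exact enumeration for small tie-free samples, Kolmogorov-Smirnov
  normality gating with the sample's own mean and SD, Bonferroni
  correction as $\min(1, m\,p)$ with families defined per metric type.
  Correlations are Pearson when both variables pass the normality gate,
  Spearman otherwise.

## Validation experiments and their scale

The packaged simulation studies (also run by `scripts/acceptance.R`) use
problem sizes at which a desk machine completes in minutes while the
planted effects remain detectable:

* label recovery: 20 subjects, 300 volumes, coupling 0.5, 10 seeds —
  winner-take-all recovers ≥ 95% of planted voxel labels;
* direction-of-effect: 25 subjects per group, 300 volumes, 20 seeds per
  contrast — lower Q AUC and VAN/DMN MSI in patients, higher tha_SMN PC
  and WMD AUC in TLE-CI, and a positive tha_SMN-PC-versus-MoCA correlation
  in TLE-CI, each counted as detected when the direction is right at
  p < 0.05.

```{r example, eval = FALSE}
cfg <- pipeline_config(
  cohort = cohort_spec(n_per_group = c(HC = 10, `TLE-CN` = 10, `TLE-CI` = 10),
                       n_timepoints = 200),
  out_dir = tempfile("thalamod_demo_"), seed = 1)
res <- run_pipeline(cfg)
res$comparisons
```

## What the synthetic cohorts do and do not show

The generator emulates block-structured correlations, voxel-to-network
coupling, motion-like nuisance series, and phenotype tables with the
reference cohort's marginal distributions. It does **not** emulate
spatial autocorrelation, scanner drifts and physiological noise spectra,
hemodynamic lag, lesion anatomy, or the real (unpublished) connectivity
magnitudes. Passing the planted-truth tests therefore demonstrates that
the *pipeline* measures what it claims to measure — not that the original
biological effect sizes are reproduced. Published summary statistics
(demographics table) are the one point of direct quantitative contact:
they are rebuilt from printed means, SDs and counts and match to printed
rounding.

## Known limitations

* The seven-network parcel assignment uses fixed per-network sizes; no
  subject-level parcellation variability is modelled.
* MoCA's dependence on a single coupling parameter is a deliberately
  minimal cognition model.
* The Mann-Whitney exact mode enumerates only small samples (n ≤ 10);
  larger samples use the tie-corrected normal approximation, as standard.
* Whether the original analysis binarized graphs, its negative-edge
  policy, and its exact MSI evaluation mode are not recoverable from the
  published description; the choices above are documented and the
  alternatives (weighted mode, per-level MSI) would change absolute values
  but not the planted-direction logic.
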