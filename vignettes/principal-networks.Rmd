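---
title: "Hubs, principal networks and clinical associations in synthetic MS connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hubs, principal networks and clinical associations in synthetic MS connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnms)
```

## The model and its assumptions

A structural connectome here is a symmetric, nonnegative, zero-diagonal
115×115 matrix `W` over a fixed cortical/subcortical parcellation; an entry
is the summed streamline weight connecting two regions. All analyses in the
package operate on this object and make three standing assumptions:

* edge weights are meaningful on a ratio scale (so group means and strength
  sums are interpretable);
* group-level network organisation is captured by the entrywise mean matrix
  of a group;
* the spectral components of that mean matrix are identifiable, i.e. the
  leading eigenvalues are well separated.

**Hubs.** The nodal strength is the row sum `s_i = Σ_j w_ij`. On a group-mean
matrix, a region is a hub when `s_i ≥ mean(s) + 1·SD(s)`. The threshold is
inclusive and the SD uses the sample (n − 1) formula over the 115 node
strengths; with 115 nodes the (n vs n − 1) choice moves the threshold by
under 1% and never changes a hub set in the package's test conditions.
Degenerate strength vectors (SD = 0) are flagged rather than silently
returning all nodes.

**Principal networks.** A PN is an eigencomponent of the group-mean matrix:
`W̄ = Σ_k λ_k v_k v_kᵀ` with eigenvalues sorted in descending signed order.
The loadings are the entries of the unit-norm eigenvector; membership is
`|v_k,i| ≥ τ` with `τ = 0.1` by default, inclusive. Decomposition operates
on the raw weighted matrix — no degree normalisation and no Laplacian; the
"normalised" in *normalised eigenvectors* is read as unit norm, which makes
membership invariant under uniform rescaling of the weights. Reproducibility
details: each eigenvector's sign is fixed so its largest-magnitude entry is
positive (ties broken by first index); components with negative eigenvalues
are computed but flagged and never reported as PN1/PN2; nearly degenerate
eigenvalues (gap below `1e-10·‖W‖`) flag the component as unstable, and
membership comparison refuses flagged ranks. A member's loading sign is
reported separately and does not affect membership; mixed-sign PNs are
flagged, not suppressed. Only group-mean matrices are decomposed — there is
no subject-level PN decomposition, no rotation, and no inferential test on
loadings.

**Subnetwork strengths.** PN1 and PN2 as identified in the healthy-control
group serve as fixed bases for every subject in every group: the subject's
own matrix is restricted to the reference member set (original edge weights,
not the rank-one partial matrix) and nodal strengths are computed inside the
induced subnetwork. A node's subnetwork strength equals its full strength
minus its weight to non-members — an identity the tests assert exactly.

**Association models.** A shared OLS core (QR factorisation through
`stats::lm`, two-sided t tests, t-based 95% CIs, listwise deletion,
hard errors on rank deficiency) backs two model families:

* hub comparisons: per-subject strength of one hub on group indicator +
  age, sex, lesion load, disease duration, TIV, pooling HC with one MS
  group. Lesion load and duration are undefined in HC and set to 0 there;
  the group indicator absorbs the offset. A significant reduction is a
  negative group coefficient with p < 0.05 (no multiplicity correction, by
  design).
* clinical models: EDSS or SDMT on one subnetwork strength + age, sex,
  disease duration, lesion load and deep-grey-matter volume, in MS subjects
  only. TIV is deliberately not in this covariate set (DGM volume takes its
  place because the predictors are subcortical); both covariate sets are
  explicit function arguments of the workflow, not hidden defaults. EDSS is
  treated as continuous despite its ordinal 0–10, 0.5-step scale. The
  exploratory association matrix uses Pearson correlation with
  pairwise-complete observations, while the regressions use listwise
  deletion.

## What the synthetic generator emulates

The generator produces cohorts whose *group-level statistics* match the
study conditions the analysis is designed for: 51/58/28/36 subjects
(HC/RRMS/PPMS/SPMS); 18 hub regions whose per-group mean strengths and SDs
follow the calibration table in `hub_strength_reference()` (units of 1e5);
demographics from `demographics_reference()`; a PN structure in which PN1
is a 10-region fronto-parietal/thalamic core with predominantly
inter-hemispheric member-member weight and PN2 its intra-hemispheric
counterpart containing the right thalamus and right putamen; progressive
loss of the right putamen (all MS) and right thalamus (SPMS) from those
networks; and clinical scores coupled to the right-thalamus/right-putamen
subnetwork strengths with covariate confounding.

### Template architecture

Each group's deterministic template is assembled from interpretable parts:

* **Frontal cliques.** Within each hemisphere the precentral, superior
  frontal and middle frontal gyri form a dense rank-one clique whose row
  sums equal the node's core budget (`block_share` of its target strength
  minus its homotopic edge). Cliques are solved exactly by a scalar root
  find on the clique total.
* **Homotopic edges.** Every left/right pair carries one homotopic edge, a
  configured share of the pair's mean strength; shares are larger for the
  core regions than for the background pairs.
* **Coupled nodes.** The postcentral gyri and thalami attach to the cliques
  following the clique strength profile. The left thalamus splits evenly
  between hemispheres, the right thalamus is ipsilaterally dominant
  (`thal_lat`), and the postcentral gyri are transcallosally dominant
  (`postc_lat` < 0.5). Under homotopic coupling the two cliques hybridise
  into a symmetric leading mode — PN1 — and an antisymmetric second mode —
  PN2. The lateralisation surpluses are what give the right thalamus and
  the postcentral pair their PN2 loadings, while the left thalamus, coupled
  symmetrically, loads on PN1 only. This was a genuinely open design area:
  a planted rank-two spectral core was tried first and abandoned, because
  the homotopic weight needed for PN1's inter-hemispheric dominance
  necessarily drains an antisymmetric mode planted in the same nodes; the
  clique-plus-coupling architecture escapes that trade-off because the
  postcentral cross-coupling feeds both surfaces at once.
* **Right-putamen satellite.** A thalamo-striatal edge plus weak edges to
  the right frontal clique couple the right putamen into the antisymmetric
  mode (whose right-thalamic pole is large) far more than into the
  symmetric one, so it is a PN2 member below the PN1 threshold.
* **Fans.** Every hub routes most of its remaining strength through a
  deterministic fan over ~20 non-hub regions (overlapping round-robin
  partner sets, total capped at `fan_cap`). A fan is a star whose top
  eigenvalue is only `total/√n_partners`, so hubs keep their strength
  without creating spectral competitors between PN2 and the diffuse
  background. This matters because any nonnegative wiring of the non-core
  mass has a top eigenvalue of at least its mean row sum — the diffuse
  spectrum has a hard floor, and the architecture keeps PN2 well above it.
* **Background.** A rank-one-seeded diffuse graph over all remaining pairs
  is rescaled by symmetric iterative proportional fitting (convergence
  `1e-10`, 500 sweeps max) so every node's strength hits its target
  exactly; the core block is masked out so the planted spectrum stays
  clean.
* **Dropout.** The right putamen (all MS groups) and right thalamus (SPMS)
  have their core edges attenuated by `dropout_factor` — graded
  0.3/0.2/0.1 across RRMS/PPMS/SPMS — *before* the fans, which then refill
  the strength deficit diffusely. Membership loss therefore has to emerge
  from the eigendecomposition; nothing deletes the node.

Non-hub regions share a single strength target (0.5e5, SD 0.1e5). The value
is a declared design choice: it must sit far enough below the smallest hub
strength that the mean + 1 SD criterion returns exactly the 18 calibrated
hubs in every group (a closed-form desk check rules out values above
roughly 0.8e5), and low enough that the diffuse background's Perron mode
stays clearly below PN2.

### Subject-level model

A subject's matrix is the group template, warped and noised:

* **Severity.** For MS subjects the template interpolates between the HC
  and group templates with a severity multiplier `m` of mean 1, composed of
  an unmediated share and shares proportional to the subject's lesion load
  and disease duration (`severity_w0/wll/wdd`, per group). The mediated
  shares make the group deficit partially explainable by the covariates —
  the confounding structure that covariate adjustment then removes. The
  unmediated share is larger in the progressive groups (0.95) than in RRMS
  (0.62), reflecting lesion-driven versus diffuse neurodegenerative damage.
* **Covariate scaling.** Weights scale as `(TIV/E[TIV|sex])^0.6`, placing a
  realistic slice of each region's across-subject variance under the TIV
  covariate. An age slope is available (`age_slope`) but defaults to 0: the
  group strength targets already embed the groups' age differences, and a
  common within-group age slope would transfer part of the group contrast
  to the age covariate.
* **Noise.** Mean-one log-normal factors per edge (`sigma_edge` 0.10), per
  node, and per subject (`sigma_global` 0.02). The per-node scale is solved
  per group so the across-subject SD of each region's strength matches its
  calibration target after accounting for the severity, covariate and edge
  components; where a printed SD target lies below that attainable floor
  (a few calibration SDs are implausibly small — 0.02e5 on means above
  2e5), the solver floors the residual scale and the realised SD sits
  somewhat above target rather than below the noise floor.
* **Clinical scores.** EDSS (MS only) is a group base (2 / 6 / 6.5) plus
  negative couplings to the subject's right-thalamus (PN1) and
  right-putamen (PN2) subnetwork strengths — centred on the group
  template's own values so the group medians stay put — plus a small age
  term and Gaussian noise, rounded to the 0.5 grid and clipped to [0, 10].
  SDMT is analogous with positive couplings, an integer floor at 0, and is
  generated for every subject. DGM volume carries a weak coupling to
  thalamic strength (too strong a coupling would make the DGM covariate
  collinear with the predictor of interest and mask the planted effect).
* **Seeding.** One root seed; each group derives an independent stream of
  per-subject seeds, so regenerating with a different size for one group
  leaves every other group's subjects bit-identical.

### Calibration protocol and what passing tests show

All architecture shares and the confounding parameters were fixed once,
during the generator's design, by feasibility analysis and small pilot
simulations against the generator's contract: exact hub sets, PN
memberships and losses, edge-composition orderings, strength calibration,
the adjusted group-comparison counts, and planted-effect recovery. The test
suite then verifies that the frozen configuration meets the contract across
seeds (median over 25 seeds for stochastic quantities; the acceptance
script uses the same problem sizes — 25 cohorts of 173 subjects, and 100
cohorts for the recovery rate — chosen so a full run completes in a few
minutes on one CPU).

Passing tests therefore demonstrate that the *pipeline* measures what it
claims on data with this statistical structure, and that the effects it is
meant to detect are detectable at the study's sample sizes. They do not
validate tractography, parcellation, or any claim about real MS brains:
real connectomes have heavier-tailed edge distributions, distance-dependent
connectivity, subject-level topology differences and registration artefacts
that the generator deliberately omits.

## Numerical choices and degenerate inputs

* Asymmetry up to a relative `1e-8` is repaired as `(W + Wᵀ)/2`; larger
  asymmetry is a hard error. Nonzero diagonals are zeroed with a warning.
* Matrices are dense labelled TSVs; labels are the join key and the
  node-table file order is canonical, so outputs are platform-stable.
* Hub detection on fewer than 2 nodes errors; SD = 0 flags degeneracy.
* `pn_decompose` requires symmetric input and `τ ∈ (0, 1)`; an extreme
  threshold that empties the PNs is reported (`empty_pns`) rather than an
  error, and the pipeline skips membership comparison in that case.
* OLS refuses rank-deficient designs and models with no residual degrees of
  freedom; clinical models refuse fewer than 15 complete cases; association
  cells with fewer than 3 complete pairs are `NA`.

## Known limitations

* Only strength-based metrics are implemented — no betweenness, rich-club,
  efficiency or clustering, and no subject-level decomposition.
* EDSS enters OLS as a continuous outcome; an ordinal model would be more
  faithful to the scale but is out of scope.
* No multiple-comparison correction anywhere, by design; counts of
  significant hubs must be read accordingly.
* The generator's printed-SD floor (above) means a few regions are
  simulated with slightly more between-subject spread than their
  calibration targets.
* Cross-study comparability of eigenvalues is limited because the matrix is
  not normalised before decomposition; memberships, which are scale-free,
  are unaffected.
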