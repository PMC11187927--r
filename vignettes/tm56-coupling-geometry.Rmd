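---
title: "TM5/TM6 geometry and G-protein coupling selectivity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TM5/TM6 geometry and G-protein coupling selectivity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcoupler)
```

## The model

Activated class A GPCRs select their primary transducer — Gs or Gi/o —
largely through the shape of the cytosolic cavity formed when TM6 swings
outward. This package operationalizes that observation as a
three-feature classifier. Per receptor structure we measure:

* `tm5_len`, `tm6_len`: residue counts from the cytosolic tip of the helix
  to the conserved anchor (5.50 / 6.50), on the generic-residue-number
  (GRN, Ballesteros–Weinstein) scale: `length = |tip position − 50|`. A
  TM5 tip at 5.75 gives 25; a TM6 tip at 6.29 gives 21. Counting GRN
  positions rather than modeled residues makes the length insensitive to
  unmodeled gaps. TM6 length is extracted but excluded from
  classification: its distributions in the two classes are
  indistinguishable.
* `tm5_tilt`: angle between the receptor's cytosolic TM5 orientation and
  the reference receptor's TM5 axis.
* `tm6_outward`: angle between the cytosolic TM6 orientation and the
  intracellular membrane normal (0, 0, −1) — the activation-amplitude
  hallmark.

Angles are unsigned, in degrees; no in-plane direction is encoded because
the decision rule uses magnitudes only.

### Helix orientation from carbonyl averaging

The orientation of a helix end is the normalized mean of per-residue unit
C→O backbone carbonyl vectors over a window of 11 residues counted from
the cytosolic tip (residues missing C or O are skipped and the window
extends one residue deeper; at least 4 usable residues are required). In
an ideal α helix (3.6 residues per turn) carbonyls are near-parallel to
the axis, and over ≈3 full turns their perpendicular components cancel,
so the window average estimates the local axis to a few tenths of a
degree.

A design point worth recording: we do *not* project the carbonyl mean
onto the principal Cα axis of the window. Projection onto a line followed
by renormalization simply returns that line, and on an 11-residue window
the Cα principal axis is itself biased by several degrees when the window
is not a whole number of turns — the carbonyl average is the better
estimator, so cancellation-by-averaging is the implementation. The
orientation vector is sign-disambiguated to point toward the cytosolic
tip.

The TM5 *reference* orientation is computed from the reference receptor
with a 22-residue window (twice the standard window) for extra stability;
the TM6 reference is the Z axis by definition. Consequently the reference
receptor's own `tm5_tilt`, computed with the standard 11-residue window,
is a small nonzero value rather than exactly zero — we accept this for
consistency with how every other receptor is measured.

### The membrane frame

All angles are defined in a common frame in which the membrane normal is
Z (+Z extracellular). The frame comes from a user-supplied pre-oriented
reference structure; every other structure is rigidly superposed onto it
(Kabsch, via SVD with a determinant guard so a reflection is never
returned and an error on collinear correspondence sets). The default
superposition atom set is Cα of GRN-matched residues in TM1–TM4 and TM7 —
the helices that stay congruent across activated class A receptors — so
the frame is not biased by TM5/TM6, whose geometry is being measured. The
same receptor-defined frame is used for Gα-side displacement
measurements.

### The cytosolic tip

The tip is the modeled segment residue furthest along the intracellular
arm on the GRN scale (largest position for TM5, smallest for TM6), with
two degeneracy guards: the tip's GRN must lie on the intracellular side
of the anchor, and its Cα must not sit above the anchor's in Z (an
inverted or mis-framed helix is refused). We deliberately do not take the
raw minimum-Z residue: on a strongly tilted ideal helix the 2.3 Å helical
spiral can outweigh the ~1.5 Å per-residue rise along Z and misidentify
the tip by one residue, which would break exact length recovery. Where a
deposited model carries an unwound C-terminal extension the distinction
between "last modeled" and "last helical" residue is real; segment
boundaries are therefore taken from the dataset manifest, not from
secondary-structure assignment.

## The classifier stack

Features are standardized (centering/scaling; population SD by default,
with a `ddof` switch since the convention behind the reference scales is
not documented) and projected onto two principal components fitted by
SVD. The PCA sign is pinned so that the TM5-length loading of PC1 and the
TM6-outward loading of PC2 are positive, matching the reference
eigenvectors [0.649, 0.569, 0.506] and [−0.081, −0.609, 0.789].

`reference_projection_model()` carries the constants fitted on the
98-receptor homology-model training set (24 Gs : 74 Gi/o). Expanding
standardize-then-project into raw coordinates gives the closed-form rule

```{r}
cf <- raw_coefficients(reference_projection_model())
round(unlist(cf), 3)
```

with Gs predicted when X strictly exceeds 0.7 (a score exactly at the
boundary falls to the majority Gi/o class). At the class-mean geometries:

```{r}
m <- reference_projection_model()
raw_projection(rbind(c(23.1, 12.3, 23.8), c(18.9, 5.90, 19.7)), m)
```

The trained counterpart is a deliberately constrained random forest: 15
depth-1 stumps, each fit on a with-replacement bag of `ceiling(0.7 n)`
rows ("bagging" is read as sampling with replacement), each restricted to
one randomly drawn feature, with class weights Gs:74 / Gi/o:24 applied to
both the Gini impurity and the leaf votes. The weights are
inverse-frequency balancing for the 24:74 training composition
(24·74 = 74·24), which is the only reading under which they balance the
classes; the class encoding follows from that. The forest's Gs score is
the unweighted fraction of stumps voting Gs; a tied vote falls to Gi/o.
Seed 2784 is the default; fits are bit-reproducible per seed within this
package, but reproducing any externally trained forest tree-for-tree is
out of scope because RNG streams differ across implementations.

Cross-validation is stratified k-fold (default 10) with fold class ratios
within one member, standardization refit on each training fold, and k
reduced with a warning when the rarer class has fewer than k members.
Metrics use Gs as the positive class; AUC is the Mann–Whitney rank
statistic on the Gs score with midrank ties. Group contrasts use the
two-sided Mann–Whitney U test (exact for small untied samples, normal
approximation with tie correction otherwise, via `wilcox.test`).

## Interface analysis

"Contact area" is half the buried solvent-accessible surface area,
`0.5·(SASA(A) + SASA(B) − SASA(A∪B))`, with a 1.4 Å probe and Bondi-type
radii — the standard interface convention, recorded in output metadata and
configurable (including full-ΔSASA via `half = FALSE`) since the
convention behind published interface figures is often unstated. SASA is
Shrake–Rupley with a deterministic golden-spiral lattice of 960 points
per atom, so areas are reproducible without a seed; the implementation is
validated against the analytic sphere (exact to machine precision at the
lattice) and the two-sphere spherical-cap closed form (< 2%).

Extended TMs follow the GRN thresholds: TM5 residues at 5.69 and beyond
for Gs-coupled receptors (TM5 longer than 18), TM6 residues at 6.29 and
beyond for Gi/o-coupled receptors (TM6 longer than 20.5), both inclusive.
The contact-area-per-extended-residue relation is ordinary least squares
with the slope's standard error and R².

## The synthetic-data generator

The generator is first-class, tested code, and defines the study
conditions for everything stochastic:

* **Ideal helices** are grown by internal-coordinate chain extension
  (N–CA 1.458, CA–C 1.525, C–N 1.329, C=O 1.231 Å; standard angles;
  φ/ψ = −57/−47°), giving chemically realistic carbonyl orientations that
  a Cα-trace fixture could not provide. The helix is oriented by the
  exact screw axis of its residue-to-residue rigid motion — the Cα
  principal axis of a short helix is biased by the spiral — so the
  realized tilt equals the requested tilt. Helix topology follows GRN
  parity: odd helices run extracellular→cytosolic from N to C terminus,
  even helices the reverse.
* **Receptor stubs** combine a TM5 and TM6 fixture with a fixed scaffold
  of short vertical TM1–TM4/TM7 helices (identical across stubs) so that
  manifest-driven superposition works exactly as on real receptors.
* **Feature tables** are Gaussian draws at the class group models
  (Gs: TM5 length 23.1 ± 4.6, tilt 12.3 ± 7.1°, outward 23.8 ± 8.4°;
  Gi/o: 18.9 ± 3.1, 5.90 ± 2.9°, 19.7 ± 7.6°), with lengths rounded to
  whole residues (floor 4) and angles floored at 0. TM6 length uses the
  class medians 20.5/22 with an SD of 3 residues — a value we chose as
  typical of the observed spread, since only medians are documented.
  Feature covariance is diagonal by default; a hook injects the TM5
  length–tilt correlation (~0.5–0.6) seen in Gs-coupled receptors for
  correlation studies. The default 24:74 composition mirrors the
  homology-model training set.
* **Toy complexes** pair a helix with a flat pseudo-atom slab standing in
  for the flattened Gα surface — sufficient for SASA behavior, with no
  pretension to a real Gα fold.

What passing tests on these fixtures do and do not show: they validate
the estimators (axis recovery to ≤1°, exact GRN lengths, SASA against
closed forms, classifier behavior at the documented group statistics) but
not robustness to real-structure pathologies — side chains, helix kinks
beyond a single tilt, unwound extensions, or coordinate error. Validation
against deposited receptor–Gα complexes requires supplying those
structures and their GRN tables via the manifest.

## Problem sizes and numerical choices

The test and acceptance runs use: 100 random helix specs for parameter
recovery; 100 seeds × 10-fold CV at n = 98 for the classifier property
(the stump forest beats the 74/98 majority baseline in ≥95% of seeds —
mean CV accuracy is ≈0.83, consistent with three overlapping Gaussian
features and a depth-1 ensemble); 500 replicates for the Mann–Whitney
null-uniformity check; 960 sphere points per atom for SASA (doubling
changes totals by < 1%). Simulated receptor sets use 12–24 structures.
These sizes were chosen so every property is measured with comfortable
statistical margin while a full run stays in the tens of seconds.

Other numerical choices: alternate locations resolve to the highest
occupancy conformer (ties: first encountered); waters are excluded;
PDB coordinates round-trip at the format's 10⁻³ Å column precision;
degenerate superposition sets (collinear) are refused rather than
returning an arbitrary rotation; a constant feature column is a hard
error in standardization; and X = 0.7 exactly is classified Gi/o.

## Known limitations

* GRN maps are consumed, never inferred: no alignment-based numbering.
* No secondary-structure assignment, kink detection, or trajectory
  analysis; one tilt angle summarizes the cytosolic TM5 orientation.
* The closed-form rule and the reference constants are specific to
  activated class A receptors measured in the documented frame; applying
  them to inactive states or other classes is extrapolation.
* Backbone-only fixtures bury roughly half the area per residue of a
  side-chain-bearing helix, so synthetic contact-area slopes are on a
  smaller scale than published per-residue values from full structures.
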