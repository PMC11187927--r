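# gcoupler

Predicts the primary G-protein coupling class — Gs versus Gi/o — of
activated class A G-protein-coupled receptors (GPCRs) from the cytosolic
geometry of transmembrane helices 5 and 6.

## The science

When a class A GPCR activates, TM6 swings outward to open the cytosolic
cavity that receives the G protein's α5 helix. Across receptor–G-protein
complex structures, three geometric descriptors of that cytosolic face
separate Gs- from Gi/o-coupled receptors:

* **TM5 length** — residue count from the cytosolic tip to the conserved
  position 5.50 (Ballesteros–Weinstein numbering). Gs-coupled receptors
  carry a longer TM5 (23.1 ± 4.6 residues vs 18.9 ± 3.1).
* **TM5 tilt** — angle between the cytosolic TM5 orientation and a
  reference receptor's TM5 axis (12.3 ± 7.1° vs 5.9 ± 2.9°).
* **TM6 outward movement** — angle between the cytosolic TM6 orientation
  and the membrane normal (23.8 ± 8.4° vs 19.7 ± 7.6°).

Helix orientations are estimated from the average backbone carbonyl (C=O)
vector over an 11-residue window at the cytosolic tip: in an α helix the
carbonyls run nearly parallel to the axis and their perpendicular
components cancel over the window's ≈3 turns. All structures are placed in
a common membrane frame by Kabsch superposition onto a pre-oriented
reference (membrane normal = Z, +Z extracellular), fitted over Cα atoms of
TM1–TM4 and TM7 so the frame is not biased by the helices being measured.

After feature-wise standardization (means 20.276, 8.474, 18.749; scales
4.164, 5.264, 9.156, fitted on a 98-receptor homology-model training set of
24 Gs- and 74 Gi/o-coupled class A receptors) and projection onto the first
principal component, the decision boundary collapses to a closed form on
the raw geometries:

```
X = 0.156·tm5_len + 0.108·tm5_tilt + 0.055·tm6_outward − 5.110
```

with **X > 0.7 → Gs**, otherwise Gi/o. The package also implements the
trained counterpart of this rule — a bagged forest of 15 class-weighted
depth-1 decision stumps (max one random feature per stump, bag fraction
0.7, class weights Gs:74 / Gi/o:24) with stratified 10-fold
cross-validation and accuracy/F1/AUC/MCC metrics — plus buried-interface
analysis (Shrake–Rupley SASA) of the "extended" TM residues (TM5 beyond
5.69 in Gs receptors, TM6 beyond 6.29 in Gi/o receptors) against the
Gα subunit, and a deterministic ideal-helix generator that makes the whole
pipeline testable without downloading structures.

## Worked example

Simulate a small labeled dataset of receptor stubs on disk, re-extract
their geometry from the PDB files, and classify:

```r
library(gcoupler)

run_simulate("demo", n_gs = 4, n_gio = 4, seed = 42)
res  <- run_extract("demo/manifest.csv")
pred <- run_classify(res$features)
print(pred, digits = 3, row.names = FALSE)
```

```
 structure_id      X      Y predicted label
   sim_gs_001  1.708 -1.528        GS    GS
   sim_gs_002  0.603 -0.118       GIO    GS
   sim_gs_003  2.527 -1.433        GS    GS
   sim_gs_004  1.847  0.391        GS    GS
  sim_gio_001 -0.503  0.819       GIO   GIO
  sim_gio_002 -2.492  0.716       GIO   GIO
  sim_gio_003 -1.508  0.897       GIO   GIO
  sim_gio_004  0.907  0.324        GS   GIO
```

`X` is the PC1 score of each receptor's (tm5_len, tm5_tilt, tm6_outward);
rows with X > 0.7 are called Gs-coupled. Borderline geometries land on the
wrong side (here `sim_gs_002`, a Gs receptor drawn with a short TM5, and
`sim_gio_004`, a Gi/o receptor drawn with a long one) — that is the
overlap of the two group distributions, not an extraction error:
the recovered lengths are exact and the recovered angles are within ~0.2°
of the constructed ground truth.

Cross-validate the stump forest on a training-composition sample:

```r
tab <- sample_feature_table(n_per_group = c(24, 74), seed = 42)
cv  <- run_crossval(tab, k = 10, seed = 42)
print(cv$pooled)
```

```
accuracy 0.8469  F1 0.6939  AUC 0.8702  MCC 0.5921
     predicted
true  GS GIO
  GS  17   8
  GIO  7  66
```

A command-line wrapper with the same verbs (`simulate`, `extract`,
`classify`, `fit`, `crossval`, `measure`) is installed at
`inst/scripts/gcoupler`.

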