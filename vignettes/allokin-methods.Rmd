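---
title: "Binding-mode annotation and pose evaluation for allosteric kinase ligands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding-mode annotation and pose evaluation for allosteric kinase ligands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allokin)
```

## Motivation

Most kinase inhibitors in structural databases occupy the orthosteric
(ATP) site, so docking models trained on such data oversample ATP-site
poses and struggle with allosteric ligands. Working with allosteric
kinase complexes therefore needs three ingredients that this package
provides as reusable, testable components:

1. a *geometric binding-mode annotator* that assigns each kinase-ligand
   complex to one of the six Modi-Dunbrack modes (Type I, I1/2 front,
   I1/2 back, II, III, IV) from region-resolved contacts;
2. *binding-mode-resolved evaluation* of docked or cofolded poses
   (symmetry-corrected RMSD, centroid distance, strict sub-2-Angstrom
   success rates with Wilson intervals, pocket assignment via a KLIFS
   fingerprint PCA embedding);
3. *dataset curation operators* (artifact filtering, time splits,
   deduplication, stratified selection, diversity analysis, MD frame
   filtering) plus the deterministic mathematics of a tempered diffusion
   perturbation schedule and its beta-distributed time sampler.

## The binding-mode heuristics

A `KinaseRegionMap` names the residue sets that the heuristics consult.
The default map uses Aurora A numbering: hinge 211-213; back pocket
166-193, 196-204, 205-207 and 273-275 (43 residues: the alpha-C helix,
parts of beta4-beta5, the X-DFG/DFG-Asp backbone and the DFG-Phe side
chain); Type-II-only pocket 184, 188, 247 and 254, exposed only in
DFG-out conformations.

Two positions are defined relative to the alpha-C helix and are not
printed as residue lists in the annotation literature; the defaults
anchor them at the Aurora A alpha-C glutamate (Glu181): the Glu(+4)
position is residue 185 and the alpha-C N-terminal region is 176-180.
Both are plain inputs — per-kinase maps are supplied as CSV/JSON tables
via `read_region_maps()`, and the 84 KLIFS fingerprint residues of the
default map are a documented generic catalytic-cleft span standing in
for a database-derived list.

`compute_contacts()` reduces a complex to per-region minimum heavy-atom
distances and contact counts; a residue counts as a contact when its
minimum heavy-atom distance to the ligand is strictly below the contact
cutoff (default 4.5 Angstrom, a standard protein-ligand contact
threshold; the annotation literature never defines "contact", so the
cutoff is exposed as configuration). Hydrogens are excluded on both
sides, since crystal structures typically lack them.

`classify_binding_mode()` applies the rules in a fixed precedence:

* **Type IV** — hinge and alpha-C-Glu(+4) minimum distances both
  strictly greater than 6.5 Angstrom (remote allosteric);
* **Type II** — at least 3 back-pocket contacts and at least one
  Type-II-only pocket contact (DFG-out);
* **Type III** — hinge minimum distance greater than 6 Angstrom and at
  least 3 back-pocket contacts (alpha-C-out);
* **Type I1/2 front / back** — at least 3 back-pocket contacts, split by
  the presence of an alpha-C N-terminal contact;
* **Type I** — everything else.

The published rules do not resolve overlaps (a DFG-out ligand with a
hinge distance above 6 Angstrom satisfies both the II and III wordings).
The precedence above is a design choice: the Type-II-pocket contact is
the more specific structural evidence, so II precedes III, and III
precedes I1/2 because its hinge condition is strictly more restrictive.
All "within" comparisons are strict inequalities, matching the strict
">6.5" style of the thresholds applied in complement. Regions with no
resolved residue get an infinite distance sentinel and a warning — a
fully disordered hinge can therefore only yield Type IV when the
Glu(+4) distance also exceeds the threshold.

```{r classify-example}
sc <- make_kinase_scaffold()
lig <- place_ligand_for_mode(sc, sc$map, "III")
classify_binding_mode(compute_contacts(sc$receptor, lig, sc$map))
```

## Structure input and curation rules

`read_structure()` parses PDB/mmCIF through bio3d, resolves alternate
locations to the highest-occupancy conformer (ties broken by altloc
identifier order), always drops waters, and emits every remaining
non-polymer component occurrence as a ligand candidate — two copies in
one asymmetric unit stay two candidates, and `deduplicate()` operates
later at the dataset level. Modified amino acids recognised from a
fixed component table (MSE, SEP, TPO, PTR, ...) stay in the receptor
flagged noncanonical; `flag_noncanonical_proximity()` reports whether
any ligand heavy atom lies strictly within 5 Angstrom of one.
`filter_ligands()` removes components on an exclusion list (a packaged
default covers common ions, buffers and cryoprotectants; any list can
be substituted) and anything below 6 heavy atoms — the curation
literature mentions manual screening without a printed size rule, so
the cutoff is explicit configuration here.

## Hydrogen correction at pH 7.4

`correct_hydrogens()` applies a fixed physiological-pH rule table to
five functional groups, then writes explicit hydrogens: carboxylic
acids and tetrazoles deprotonate (pKa near 5, well below 7.4),
aliphatic amines protonate (pKa near 10) unless amide-, aniline- or
guanidine-like, nitro groups are normalised to the charge-separated
N(+)/O(-) form, and imidazoles stay neutral with a single ring NH (the
lower-index nitrogen keeps the proton when both carry one). The
original pipeline names the groups without printing the corrections;
the table follows standard pKa reasoning, is implemented as molecular
graph pattern matching on the package's own ligand type, and is
idempotent by construction. Full pKa prediction and tautomer
enumeration are out of scope.

## Ligand diversity

`morgan_fingerprint()` produces circular-substructure fingerprints of
radius 3 folded to 2048 bits (ECFP6-class environments computed by
OpenBabel through ChemmineOB; deterministic and atom-order invariant).
`butina_cluster()` implements sphere-exclusion clustering: pairs at
Tanimoto similarity of at least 0.8 are neighbours, and the unassigned
item with the most unassigned neighbours repeatedly becomes a centroid,
absorbing them. The original algorithm leaves tie-breaks open; here
equal neighbour counts resolve to the lowest input index, making the
partition fully deterministic, which the tests exploit by comparing
against an independently written quadratic reference. `shannon_index()`
summarises cluster sizes in bits; 346 mutually dissimilar ligands give
the maximal log2(346) = 8.43 bits.

## Pose evaluation

`symmetry_corrected_rmsd()` minimises the in-place heavy-atom RMSD over
all element- and bond-order-preserving graph automorphisms of the
ligand (igraph VF2), so chemically equivalent relabelings — a flipped
ring, swapped para substituents — cannot inflate the error. There is no
re-superposition, and hydrogens are excluded, per standard practice.
Automorphism enumeration is capped (default 1e5) with an identity-map
fallback and warning; ligands that symmetric are rare.
`centroid_distance()` compares unweighted heavy-atom means ("center of
the ligand" is otherwise underspecified).

`evaluate_pose_set()` follows the ten-sample protocol: the top-ranked
pose provides Top-1 metrics, the minimum over all poses the "Any"
metrics. `success_summary()` counts strict sub-threshold values
(default 2 Angstrom) and attaches a Wilson score interval;
`compare_success()` tests two success rates with a two-sided pooled
two-proportion z-test at alpha 0.05 (the interval literature cited for
the protocol never names the comparison test; Fisher's exact test is
available as an alternative).

For cofolding-style outputs whose residue numbering differs from the
reference, `align_and_superimpose()` first maps residues by global
Needleman-Wunsch alignment (match +1, mismatch -1, linear gap -2 —
affine gaps add nothing at Cα-mapping fidelity) and then performs an
all-Cα Kabsch superposition constrained to a proper rotation
(determinant +1), returning the transform to apply to the predicted
ligand before metric computation.

## Pocket fingerprinting and assignment

`fingerprint_pose()` measures the minimum heavy-atom distance from the
ligand to each of the 84 KLIFS residues, giving an 84-vector in
Angstrom; unresolved residues are masked and later imputed with the
training mean (the source procedure does not address missing KLIFS
residues). `fit_embedding()` runs PCA on mean-centred, *unscaled*
vectors — all features share units, so variance scaling would only
amplify noise — and places one centroid per pocket class in the
projected space. The ATP-competitive modes (I, I1/2F, I1/2B, II) pool
into a single "orthosteric" class alongside Type III and Type IV,
matching the three-colour reading of the published embedding; when a
per-class training subsample is requested (e.g. 100/100/100), sampling
is seeded. Two components are kept by default. `assign_pocket()`
projects a query and returns the Euclidean-nearest centroid, with exact
ties — a probability-zero event kept deterministic — broken by the
fixed order orthosteric < III < IV.

## Dataset operators

`time_split()` partitions on the deposition date with a strict
pre-cutoff training side (default cutoff 2019-01-01, the convention
that keeps post-cutoff complexes out of upstream docking training
sets). `deduplicate()` keeps the first occurrence per (UniProt ID,
ligand name); sort by date first if the earliest structure should
survive. `stratified_select()` draws seeded uniform samples without
replacement within each binding mode — requesting 34 Type III from 49
leaves 15 for validation, matching the protocol's arithmetic.
`bin_affinity()` bins -log(BA) with weak strictly below 4 and
medium/strong at or above 6. `md_frame_filter()` keeps trajectory
frames whose symmetry-corrected ligand RMSD to the crystal pose is
strictly below 2 Angstrom — excluding dissociated complexes and
binding-mode changes — and draws a seeded sample of two by default, so
originals plus selections triple a training set.

## Tempered schedule mathematics

The perturbation schedule of a temperature-sampling diffusion docking
sampler is exposed as standalone numerics. `sigma_interp()` is the
log-linear (geometric) interpolation between noise-scale bounds.
`lambda_scale()` computes the temperature factor
`(eps + sigma) / (eps + sigma * T)`, and `perturbation_magnitude()` the
tempered update `dsigma2 * (lambda + T0 * psi^2)^exponent +
t * (1 + psi) * z`. The printed source formulas lack explicit
operators; this grouping is the package's documented reading, chosen so
that `T = 1` makes lambda identically 1 and reduces the update exactly
to the untempered `dsigma2 + t*z` — consistent with the observation
that disabling temperature sampling changes little — and it is isolated
behind these two functions so an alternative reading is a one-function
change. The per-component exponents are stored under a single
`exponent` field to avoid any collision with the Beta shape parameters
of the time sampler, which have distinct names.

`beta_pdf()` and `sample_time()` implement the Beta(1.25, 2.25) time
sampler that biases training times toward the early stages of reverse
diffusion; sampling is inverse-CDF on a seeded uniform stream for
cross-platform reproducibility. The density integrates to one within
1e-6 and the analytic mode sits at (alpha-1)/(alpha+beta-2) = 1/6.

## Synthetic fixtures: what they emulate and what they do not

`make_kinase_scaffold()` builds a toy receptor — one CA atom plus a CB
pseudoatom per residue — whose regions occupy geometrically separated
sites: hinge at the origin, the back-pocket grid at x 7-14, the
Type-II-only site adjacent to the cleft at (10-11, 6-7), the alpha-C
N-terminal cluster near the cleft entrance, the Glu(+4) anchor below
the back pocket, and a remote site 7.0 Angstrom from the nearest hinge
atom on the far side of the N-lobe. `place_ligand_for_mode()` positions
a rigid six-atom heteroatom chain so the rule inequalities for the
requested mode hold with at least 0.5 Angstrom margin; a seeded jitter
of at most 0.1 Angstrom per coordinate varies instances without
crossing a boundary, and the remote placement deliberately sits just
beyond the 6.5 Angstrom threshold so a 2 Angstrom hinge-ward shift
flips its label. `make_pose_set()` adds per-atom Gaussian noise and
optional whole-ligand translations (wrong-pocket emulation);
`make_fingerprint_cloud()` draws three Gaussian classes in the
84-dimensional fingerprint space with a tunable centre separation
(per-coordinate noise 1 Angstrom, distances clipped at 0.1).

These fixtures exercise every classifier branch, every metric path and
the full annotate-fingerprint-embed-assign loop with known ground
truth. They are *not* physically realistic kinase folds: passing tests
demonstrate the correctness of the geometry, statistics and
bookkeeping, not docking accuracy on real structures. Conclusions about
real-data success rates additionally require real complexes and real
pose generators, which are outside this package's scope (as are score
and confidence models, MD execution, lDDT computation and database
clients — region maps and pose sets are consumed as inputs).

## Problem sizes and numerical choices

The shipped test-and-acceptance workload uses problem sizes a laptop
handles in seconds: 60-complex classifier closure (10 seeds x 6 modes),
150 training fingerprints for the embedding, 40 synthetic pose sets of
10 poses, 100 random molecules of 5-10 heavy atoms for the brute-force
RMSD cross-check, 50-fingerprint Butina suites over 20 seeds, and 1e5
draws for the time-sampler calibration. Tolerances follow the quantity:
exact identities (partition equality, permutation minima) are checked
to 1e-9 or tighter, quadrature to 1e-6, sampled moments to 0.005. The
Wilson interval uses the normal quantile at the requested confidence;
degenerate inputs (k = 0, k = n) stay inside [0, 1] by construction.
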