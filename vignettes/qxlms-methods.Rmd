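---
title: "Quantifying conformational dynamics with qXL-MS: methods and design"
author: "qxlms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying conformational dynamics with qXL-MS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qxlms)
```

## The problem

Chemical cross-linking followed by quantitative mass spectrometry (qXL-MS)
reads out protein conformational dynamics in solution. A reagent such as
DSBU bridges pairs of reactive residues — lysine side chains, and to a
lesser degree serine, threonine and tyrosine — that come within its span,
about 30 Å between Cα atoms. The signal intensity of each residue-resolved
cross-link (or of a monolink, where only one end of the reagent reacted and
the other was quenched) reports how often that geometry was sampled during
the labelling reaction. Comparing intensities between two conditions — for
example a myosin motor domain with and without a bound small-molecule
inhibitor — therefore reports where the molecule's conformational ensemble
tightened or loosened, even for states too transient to resolve
structurally.

The interpretation hinges on the reach criterion. A cross-link whose
Cα–Cα distance in a reference atomic model is within the reagent's reach is
compatible with the modelled state; an increase in its signal means that
state is sampled more (reduced dynamics). A cross-link whose model distance
exceeds the reach is *exploratory*: it can only form during excursions away
from the modelled state, so its signal tracks those excursions. The same
fold change thus carries opposite meanings depending on where the link
falls on the structure, which is why the pipeline couples differential
statistics to structure mapping.

## Pipeline

`qxlms` implements the full chain as composable steps:

1. **Input** (`read_quant_table()`, `read_fasta()`): a long-format table,
   one row per peptide species per (condition, replicate), validated
   against the construct sequences. Site validation is total — every row is
   either accepted or reported with a reason; nothing is silently dropped.
   Missing intensities stay `NA` and are never imputed as zero, which would
   bias fold changes of low-abundance species.
2. **Normalization** (`compute_norm_factors()`): label-free MS1 runs vary
   in loading and spray efficiency. Each replicate is scaled by its total
   signal over peptides bearing *no* cross-linker modification, which
   tracks loading independently of cross-linking yield. Factors are
   anchored on the geometric mean of the replicate totals: the anchor is
   symmetric, scale-stable, and cancels exactly in any between-condition
   fold change, so its choice is a presentation convention, not a
   modelling assumption. A replicate with zero unreacted signal is an
   error — normalization is undefined there.
3. **Site-ambiguity resolution** (`resolve_ambiguous()`): when a peptide
   carries several reactive residues and neither chromatography nor MS2
   evidence localizes the reagent, the site is assigned to the most
   reactive residue: lysine beats S/T/Y; among lysines, the one supported
   by the most other links and monolinks in the dataset wins; remaining
   ties go to the lowest residue index. The rule is deterministic, so
   reprocessing a dataset reproduces assignments exactly.
4. **Aggregation** (`aggregate_links()`): signal is summed over all
   peptide species (charge states, lengths, modification variants) sharing
   the same residue pair, after normalization. Summation is the only
   combination rule that conserves total signal; the package's tests
   verify conservation per sample. A cell is missing only if missing in
   every member. The result is a links × samples intensity matrix with
   link and sample metadata — deliberately shaped like the expression-set
   containers of differential-expression packages.
5. **Differential test** (`differential_test()`): a pooled-variance
   (homoscedastic) two-sample t statistic per link on the normalized
   intensities, with a one-tailed p-value. By default the tail follows
   each link's observed direction, which is how a single procedure yields
   both increasing and decreasing calls. Significance requires p < 0.05
   *and* fold change strictly above 2 (or below 0.5). The twofold *census*
   (`count_changed_links()`) is inclusive (≥ 2), distinct from the strict
   significance threshold. No multiple-testing correction is applied by
   default, to keep parity with raw-p workflows; a Benjamini–Hochberg
   option exists (`adjust = "BH"`).
6. **Structure mapping** (`read_structure()`,
   `annotate_link_distances()`): links live in construct coordinates
   (1-based in the supplied FASTA, initiator methionine included); models
   may use mature-protein numbering and arbitrary chain ids. The bridge is
   one chain id and one integer offset per protein per model
   (`set_model_mapping()`) — never a hard-coded constant, because
   construct-versus-mature offsets differ between preparations. Distances
   are straight-line Cα–Cα; the reach test is inclusive at 30.0 Å (the
   literature writes both "< 30 Å" and "within 30 Å", so the boundary is
   declared inclusive and configurable). For a link with ambiguous
   candidate residues the *minimum* distance over candidates decides
   reach: reachability requires only one candidate in range.
7. **Dynamics classification** (`classify_dynamics()`): each significant
   link is placed in exactly one category from the cross of its direction
   with its reach pattern across models. Models carry declared *roles*:
   "primary" for the reference conformations of the compared states, and
   "alternate" for a distinct conformation (such as a bent-lever,
   folded-back head geometry) that a link might selectively report.
   Increase within reach in the primaries → `stabilized_state`; increase
   beyond primary reach but within reach of an alternate model →
   `alternate_state_sampling`; increase beyond reach everywhere →
   `increased_dynamics`. Decrease beyond reach → `lost_exploratory`
   (excursions suppressed); decrease within reach → `redistribution`.
   Non-significant links are `no_change`; links whose residues fall in
   regions unmodelled in every supplied structure are `unannotated`.
   Classification is total and order-invariant.

Geometry utilities (`superpose()`, `per_residue_deviation()`,
`segment_rotation_angle()`, `atom_pair_distance()`, `polar_contacts()`)
support the structural side: least-squares rigid superposition (Kabsch,
via singular value decomposition, with an explicit collinearity check),
per-residue Cα deviation profiles after aligning on a chosen selection,
and the rotation of a segment between two models reported as the
axis-angle magnitude of its residual Kabsch rotation after aligning on a
fixed selection. The axis-angle magnitude was chosen over a projection
onto a named plane because it is a reproducible scalar that requires no
definition of a reference plane; the rotation axis is reported alongside
for directional interpretation. Alignment and segment selections are
user inputs (`"A:780-840"` syntax), not constants: a rotation angle is
only defined relative to a stated alignment frame, and different frame
choices legitimately give different values. Interface polar contacts are
enumerated as nitrogen/oxygen pairs within a heavy-atom cutoff
(default 3.5 Å, no angular term — a deliberate geometric proxy, recorded
as such, since hydrogen positions are usually absent from the models
this targets).

## Statistical behaviour worth knowing

**One-tailed size.** A one-tailed test has its nominal 5% size against a
*fixed* alternative. With the default data-driven tail (`tail = "auto"`),
a null link can cross p < 0.05 in either direction, so the expected null
rate is 2α = 10%. The package exposes fixed tails
(`tail = "increase"`/`"decrease"`) for calibration work; the acceptance
suite verifies that the fixed-tail null rate sits inside the 99% binomial
band around 0.05 on 10,000 simulated null links. In practice the
fold-change gate (> 2 or < 0.5) is the dominant filter at realistic
coefficients of variation.

**Normalization noise is shared.** The normalization factor of a
replicate is estimated from its unreacted-peptide total, so its
estimation error is shared by every link in that replicate. Across a
large link set this induces correlated errors: dataset-wide false-positive
fractions become overdispersed relative to the binomial expectation even
when each individual test is calibrated. With a realistic unreacted
background (hundreds of peptides) the shared component is small compared
with per-link noise, but the effect is why the type-I calibration
property is evaluated on directly simulated intensities rather than
through the normalization layer.

**Degenerate cases are flagged, not hidden.** Zero pooled variance with
unequal means yields p = 0 with `degenerate_variance = TRUE` (this is the
normal situation for noise-free synthetic data); a zero control mean
yields an infinite fold change with `zero_control_mean = TRUE`.

**Head-count comparison.** The negative-stain folded-head assay is a
separate, simpler statistic: per-image percentages of folded (IHM-like)
particles, compared between conditions with a two-tailed unpaired
Student's t-test. Images with fewer than 250 particles are excluded
before testing — a plain count threshold so that each retained image
estimates its fraction with adequate precision. Percentages are used
untransformed; with per-image fractions in the 20–80% range the arcsine
transform changes nothing material.

## The synthetic-data generators

`simulate_quant_dataset()` emulates the design of a three-replicate,
two-condition label-free experiment: MS1 intensities drawn log-normally
(positive, multiplicative-error dominated — the standard model for MS1
signal) around condition means scaled by planted fold changes and
per-replicate loading factors; an unreacted carrier-peptide background so
the normalization denominator exists; each link observed as two charge
states so aggregation is always exercised; and an optional fraction of
peptides carrying an ambiguous S/T decoy site near the true lysine.
Identical seeds reproduce tables bit-for-bit. Default noise is a 10%
coefficient of variation, typical of well-behaved MS1 quantification over
manually curated peaks.

What the generator does *not* emulate: retention-time drift, interference
and co-elution, peak-integration failures, missing-not-at-random dropout,
charge-state-dependent response, or search-engine misassignment. Passing
tests on synthetic data therefore demonstrate the correctness of the
computations — normalization algebra, aggregation bookkeeping, test
calibration, classification logic — not robustness to every pathology of
real chromatography.

`generate_toy_hinge()` builds two models of a single-chain "motor +
lever" toy with a planted lever rotation about a hinge axis, plus ground
truth (the angle and a table of Cα pair distances spanning the 30 Å
boundary, recomputed from the emitted coordinates so stored truth matches
the files exactly, noise included). Each arm is L-shaped — two
perpendicular helical legs — because a single straight α-helix leaves
twist about its own axis constrained only by the 2.3 Å helical radius,
making sub-degree rotation recovery under coordinate noise impossible for
any estimator; the L-shape conditions all three rotational degrees of
freedom. The default arm length (60 residues, ≈ 9 nm span) is comparable
to a myosin lever. A separate calibration chain holds two Cα atoms at
exactly 30.0 Å, probing the inclusive reach boundary.

`simulate_dynamics_benchmark()` wires both together: seven links planted
at controlled distances in two primary models and one alternate model,
with fold changes of 4, 1/4 or 1, covering every dynamics category
including `unannotated` (residues absent from all models). At zero noise
the full pipeline must recover every planted category — the acceptance
suite asserts the confusion matrix is exactly diagonal.

## Numerical choices and edge behaviour

- Superposition requires ≥ 3 non-collinear shared Cα pairs; collinearity
  is detected by the rank of the centred coordinate cloud, and the proper
  rotation branch of the SVD solution is enforced (determinant +1).
- The rotation angle is `acos((tr(R) − 1)/2)` with the argument clamped
  to [−1, 1]; at angles near 0 the axis is undefined and reported as
  `NA`, and near 180° it is recovered from the +1 eigenvector.
- Alternate locations in coordinate files are resolved to the
  highest-occupancy conformer before any measurement.
- The unordered residue-pair key is canonicalized by lexicographic
  (protein, index) order, so link identity is independent of the order
  sites appear in the search output.
- Problem sizes used by the test and acceptance suites — 10,000 null
  links for calibration, 1,000 planted effects for power, the
  {1, 5, 9, 12, 30}° rotation grid — run in seconds on one core.

## Known limitations

- Straight-line Cα–Cα distance, not solvent-accessible surface distance:
  a link can be "within reach" through the protein interior. For the
  30 Å DSBU criterion on compact domains this is standard practice, but
  exploratory calls near the boundary deserve inspection.
- The classifier conditions only on the reach pattern, not on distance
  magnitudes; a 31 Å and a 70 Å exploratory link are treated alike.
- The homoscedastic t-test on untransformed intensities follows the
  label-free qXL-MS convention it implements; a `log_scale` option exists
  for variance-stabilized testing but is off by default for parity.
- With three replicates per arm, power is adequate only for large fold
  changes (the planted 2.5-fold effect at 10% CV is recovered > 90% of
  the time); subtler changes need more replicates, not a different test.
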