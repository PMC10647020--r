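---
title: "Conformer ensembles for rigid screening: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformer ensembles for rigid screening: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confscreen)
```

## The problem

A rigid screening method never sees a molecule's full conformational
continuum — only the finite ensemble stored in the library. Two questions
follow. First, does the ensemble contain a conformer close to the
*bioactive* geometry (the one the crystal structure shows bound to the
receptor)? Second, when it does, does a downstream screen (pharmacophore
matching, docking pose evaluation) actually benefit, given that larger
ensembles also admit more false positives? `confscreen` provides the
measurement machinery for both questions and a synthetic generator that
makes every stage testable end to end.

## Symmetry-corrected RMSD

All geometric comparisons use one statistic: the minimum RMSD over every
valid atom matching,

$$\mathrm{rmsd}_{sym}(a,b) \;=\; \min_{\sigma \in \mathrm{Aut}(G)}
  \mathrm{RMSD}\big(a,\, \sigma(b)\big),$$

where $\mathrm{Aut}(G)$ is the automorphism group of the molecular graph:
permutations preserving element, formal charge and bond order. Without the
minimization, a benzene ring rotated in labeling but not in space would
score a spurious ~1.4 Å. Automorphisms are found by VF2 backtracking on a
colored graph (igraph); aromatic bonds form their own bond-order class
after ring perception, so Kekulé forms do not artificially split the group.
The group is capped at 10,000 mappings (flagged when truncated) — far above
anything drug-like.

Inside the minimization, `align = TRUE` (the default almost everywhere)
superposes the two point sets by the Kabsch algorithm: the proper rotation
from the SVD of the cross-covariance matrix, with a sign flip of the
smallest singular vector when the unconstrained optimum would be a
reflection. A single point superposes by translation with RMSD 0 — defined,
not an error. The one deliberate exception to aligning is docking-pose
evaluation (below).

Two conventions the field rarely states explicitly, fixed here as defaults
with flags to change them: RMSD is computed on **heavy atoms only**
(hydrogens excluded, as in common `obrms` usage), and the automorphism
group is that of the heavy-atom graph in that case.

## Selection policies

Given a full ensemble (capped at 250 conformers in the intended workflow),
three subsetting rules are compared:

* `unbiased` — a uniform random sample without replacement, seeded. We read
  "unbiased sampling" as random-N rather than first-N; for an exchangeable
  generator the two are distributionally identical, and random-N keeps the
  policy honest when generation order is not exchangeable.
* `lowest_energy` — the N lowest energies, ascending, ties broken by
  generation index so the result is deterministic.
* `energy_rmsd_filtered` — sort ascending by energy, then greedily keep a
  conformer only if its aligned symmetry-corrected RMSD to *every* kept
  conformer exceeds a threshold (0.5–2.0 Å are the useful magnitudes). The
  first kept conformer is always the global energy minimum; the output can
  be much smaller than N when the threshold is aggressive — that shrinkage
  is real behavior, not an error, and is reported as such.

Conformers without an energy are refused by the energy-based policies with
the offending index named: guessing an energy ranking would silently change
the science.

## Pharmacophore screening

Feature perception is a deliberately small, editable rule table
(`feature_rules()`): donors are neutral N/O with at least one hydrogen
(explicit or implied by default valences); acceptors are neutral N/O with a
lone pair, excluding amide and aniline-type nitrogens; aromatic features
sit at perceived ring centroids; ionic features at centroids of charged
groups; hydrophobic features at centroids of ≥ 3 connected non-aromatic
carbons with no attached heteroatom. These are *a* reasonable set of
heuristics, not a canonical one; absolute screening figures depend on them,
which is one reason the package's claims are about trends, not absolute F1
values.

Interactions pair complementary classes within per-class distance cutoffs
(donor–acceptor 4.0 Å; ionic, aromatic, hydrophobic 5.0 Å; all
configurable). The distinct interacting ligand features form a pool, and
*every* subset of size ≥ 3 becomes a query — the "omniscient oracle"
protocol: screening all queries and reporting the best F1 separates the
effect of ensemble construction from the separate problem of query
elucidation.

Matching is rigid, with one tolerance radius per feature (1.0 Å default)
and no directional constraints. The definition of a match is: an injective
type-respecting correspondence plus a proper rigid transform placing every
matched conformer feature within its query feature's tolerance. We decide
feasibility in two stages: correspondences are pruned by the sound bound
$|d_{query}(i,j) - d_{conf}(a,b)| \le r_i + r_j$, and surviving
correspondences are decided by Kabsch superposition followed by per-feature
residual tests. Least-squares superposition is not guaranteed to find a
feasible placement whenever one exists (it optimizes the sum of squares,
not the maximum residual), so the superposition check *is* the match
definition here; the brute-force oracle in the test suite applies the same
definition through an independent code path (exhaustive correspondences,
Horn quaternion superposition) and agrees on ≥ 99% of random instances.

Since rigid matching produces flags, not rankings, screens are scored by
confusion counts: the F1 score (harmonic mean of precision and recall) per
query, with the best F1 across queries as the headline number. Degenerate
conventions are explicit: an undefined precision or recall is treated as 0,
and best-F1 ties go to the query with fewer features, then lexicographic
id.

## Docking statistics

Docking success is the fraction of systems whose *top-ranked* pose lies
within a cutoff (2.0 Å by convention) of the reference pose. The RMSD here
is symmetry-corrected but **not** aligned: pose and reference share the
receptor coordinate frame, and superposing would forgive placement errors.
A flag restores alignment for the rare workflows that want it.
Uncertainties are percentile bootstrap intervals (1000 resamples, 95%
level, seeded); percentile rather than BCa because the estimand is a simple
proportion and the percentile interval's calibration is verified directly
in the test suite. Cross-docking sets are downsampled to at most 100 pairs
per target before computing rates, so heavily crystallized targets do not
dominate.

## The synthetic generator

The generator stands in for crystal-structure and screening datasets while
preserving the statistical structure the analysis depends on:

* **Torsion chains.** Linear heavy-atom chains (1.54 Å bonds, 109.5°
  angles) whose conformations are discrete dihedral states per rotatable
  bond, default $\{-60°, 60°, -180°\}$; the reference ("bioactive")
  geometry sits at the last state on every bond. Chains are decorated with
  periodic O/N substitutions so automorphism groups stay small and feature
  detection has polar atoms to find; a pure-carbon mode exists for
  symmetry stress tests. Flexibility spans the 1–16 rotatable-bond range of
  typical ligand sets; the tests mostly use 2–4 torsions.
* **Ensembles.** Each conformer is a near-reference draw with probability
  $w$ (the mixing weight) and otherwise samples every torsion from the
  non-reference states, plus isotropic Cartesian jitter. Retrieval of the
  reference in an $n$-conformer ensemble is therefore exactly
  $1-(1-w)^n$ at zero noise — a closed form the tests check against.
  Energies are sums of per-torsion potentials whose minimum lies at a
  *non-reference* state, with the reference state's energy at the mean of
  the others, plus Gaussian noise (σ = 0.2 in kcal/mol-like units). This
  makes energy rank statistically independent of distance-to-reference
  (verified: mean |Pearson r| ≈ 0.03 over 250-conformer ensembles), which
  is the regime where an isolated-molecule energy is uninformative about
  the bound geometry and geometric diversity has to do the work.
* **Planted libraries.** A 3–6-feature query geometry is sampled with
  pairwise distances in roughly 4–14 Å; actives carry a conformer whose
  feature atoms sit at the planted points, decoys (and the non-planted
  conformers of actives) place their feature atoms on a line with ≥ 19 Å
  spacings. Every decoy pairwise distance then exceeds every planted one
  by more than twice the tolerance-plus-margin, so by the triangle
  inequality no rigid placement can match under *any* correspondence —
  separation is provable, not just empirically observed. Receptor features
  of the complementary class sit 3 Å from each planted point, inside all
  interaction cutoffs.

What the generator does **not** emulate: real force-field energy surfaces,
ring conformations and nitrogen inversions, correlated torsions, realistic
decoy property matching, and feature-detection edge cases of real
chemotypes. Passing tests on synthetic data therefore demonstrate that the
machinery implements its definitions correctly and that the *directional*
claims (diversity filtering beats pure energy ranking when energies are
uninformative; recall is monotone in ensemble size; retrieval is monotone
in threshold) hold under controlled conditions — they do not certify
absolute retrieval or F1 levels on real datasets.

## Numerical and design choices

* Energy ties and best-F1 ties break deterministically (generation index /
  simpler query), so every pipeline output is byte-reproducible for a
  given config; all randomness flows from explicit seeds and never touches
  the caller's RNG state.
* The greedy filter's RMSD is the aligned, symmetry-corrected value — the
  same statistic used for evaluation — with a flag for unaligned filtering.
* Kabsch degeneracies (collinear and planar point sets, reflections) are
  resolved by the determinant-sign correction; single points superpose
  trivially.
* SDF I/O goes through ChemmineR; energies live in a configurable data
  field (`energy` by default), formal charges in atom-block charge codes.
  Records ChemmineR cannot parse are skipped, warned about and counted,
  except zero-bond records which a minimal fixed-format fallback handles.
* Problem sizes in the shipped tests — 250-conformer ensembles, 200
  synthetic molecules for the policy comparison, 500 replicates for the
  closed form, 1000 bootstrap datasets — were chosen as the smallest sizes
  at which the statistical assertions have comfortable power.
* Statistical assertions on binomial rates use exact tails where the
  normal ±3 SE band would be narrower than the estimator's discreteness
  (rates within ~1/n of 0 or 1).

## Known limitations

* Feature heuristics and interaction cutoffs are plausible defaults, not a
  reimplementation of any specific screening server; absolute F1 values on
  real libraries will differ with the rule table.
* The matcher's linear scan over conformers is exact but makes no attempt
  at sublinear indexing; it is sized for method evaluation, not production
  screening of millions of compounds.
* Conformer *generation*, force-field minimization and docking itself are
  out of scope by design: ensembles, energies and poses are inputs,
  produced by whatever external tools the user prefers.
* Receptor feature perception from PDB files is residue-level and ignores
  protonation states and metals.
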