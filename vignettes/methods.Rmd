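---
title: "Methods: packing cliques, depth and conservation for missense effect prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: packing cliques, depth and conservation for missense effect prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cliquepred)
```

## The model

A missense mutation can break a protein in two distinct ways: by disrupting
the packing of its structural neighbourhood, or by replacing a functionally
conserved residue without structural consequence. `cliquepred` scores both
channels and combines them linearly:

$$PS = w_S \cdot S + w_H \cdot H + w_F \cdot F, \qquad
  \text{neutral iff } PS > t.$$

The shipped defaults $(w_S, w_H, w_F, t) = (1.5, 1.75, 0.5, 1.6)$ are the
constants a grid-search training run produces on saturation-mutagenesis-style
labeled data; the trainer itself (`grid_search_weights()`) is part of the
package, so the constants can be re-derived for any labeled set.

### Residue depth

Depth is the distance (Å) from an atom to the nearest *bulk* water after
explicitly solvating the structure (`solvate()`, `compute_depth()`): a cubic
water lattice is laid over the molecule in a randomly rotated and translated
pose, waters clashing with protein heavy atoms are removed, and non-bulk
waters — those left with fewer than `min_water_neighbors` water neighbours
within `bulk_neighbor_radius`, e.g. trapped in grooves or small cavities —
are removed iteratively until stable. Atom depth is averaged over `n_cycles`
independently posed lattices; residue depth is the mean over the residue's
heavy atoms. Depth drives two discretisations:

* the five potential strata 2.80–5.25, 4.25–6.25, 5.25–7.25, 6.25–8.25 and
  7.25–∞ Å, deliberately overlapping;
* the three burial zones — exposed (< 5 Å), intermediate (5–8 Å, both ends
  inclusive, so the three zones partition the depth axis), buried (> 8 Å) —
  used for substitution-matrix routing and stratified evaluation.

Defaults (`depth_params()`): `water_spacing` 2.8 Å (bulk-water-like
density), `clash_distance` 2.6 Å (just under a water-heavy-atom contact
distance), `bulk_neighbor_radius` 4.2 Å (first hydration shell),
`min_water_neighbors` 2, `n_cycles` 5, `seed` 17. Published descriptions of
depth say little more than "default parameters", so all of these are
configurable; the values above follow the classical lattice-solvation
construction. The lattice is anchored to an absolute origin (not the
bounding box), which makes depth *exactly* monotone under embedding: adding
a shell of atoms around a structure can only remove candidate waters, never
move them.

### The clique statistical potential

Two residues are *linked* at cut-off $d_{cut}$ when at least four, or more
than half (strictly more than $n/2$, i.e. $\lfloor n/2\rfloor + 1$),
whichever is smaller, of the side-chain heavy atoms of one lie within
$d_{cut}$ of *any* heavy atom of the other. Glycine contributes its Cα in
lieu of a side chain. The published wording of the rule is one-directional;
we declare a pair linked when **either** direction satisfies the count,
which is the weakest reading that still guarantees an undirected graph.
An $(N, d_{cut})$ clique is any complete subgraph on exactly $N$ residues —
all of them, not only maximal ones (delegated to `igraph::cliques()`, with
an exhaustive-enumeration oracle in the tests).

Composition counts are collected from every model of every corpus structure
(multi-model inputs stand in for conformational spread, each model weight
one). Each clique's depth mean $\mu$ assigns it to **every** stratum whose
half-open interval $[d_i, d_f)$ contains $\mu$ — the printed strata overlap
by construction, so exclusive binning would contradict them; the overlap is
undone at scoring time by the Gaussian re-weighting. The pseudo-energy is

$$E^c = -kT\,\log\frac{P^c_{obs} + \alpha P^c_{exp}}
                      {P^c_{exp} + \alpha P^c_{exp}}$$

with natural log, $\alpha = 0$ and the prefactor taken literally as the
constant $1$, so **positive energies mark enriched (favourably packed)
compositions**. The reference state $P^c_{exp}$ is not pinned down by the
formulation, so we use the standard quasi-chemical choice: per stratum,
stratum total × multinomial coefficient × product of corpus amino-acid
frequencies. It is implemented as a separate function (`expected_count()`)
and is swappable.

Numerical choices:

* With $\alpha = 0$, unobserved compositions diverge to $-\infty$; their
  energy is floored at (minimum observed energy − 1), which keeps scores
  finite while preserving the ordering, and such lookups are flagged.
* The clique score re-weights stratum energies by the Gaussian mass of the
  clique's depth distribution:
  $S^c_{\mu,\sigma} = \sum_d \frac{1}{d_f - d_i} E^c_d
  \int_{d_i}^{d_f} N(x\,|\,\mu,\sigma)\,dx$, computed as normal-CDF
  differences. $\sigma = 0$ is a point mass at $\mu$ with the same
  half-open containment convention as counting, so the $\sigma \to 0$ limit
  reduces exactly to $E/(d_f - d_i)$ when $\mu$ is interior to one stratum.
* The unbounded last stratum integrates to infinity via the survival
  function; its $1/(d_f - d_i)$ normaliser is undefined, so it uses an
  effective width of 2.0 Å, matching the bounded strata (2.45/2/2/2 Å).

A residue scores the arithmetic mean over all cliques containing it; a
protein the mean over its residue scores.

Clique parameters default to $N = 3$, $d_{cut} = 8.0$ Å — the centre of the
conventional sweep ranges ($N$ 2–4, $d_{cut}$ 7.0–10.5 Å). No single
production pair is canonical, so both are mandatory, explicit configuration
everywhere and the sweep is scriptable.

### Mutation scoring

A mutation is scored *in place*: the cliques containing the mutated position
keep their geometry, member atoms, depths and $(\mu, \sigma)$; only the
amino-acid type at the position changes inside each clique composition, the
mutant inheriting every structural property of the wild-type residue. This
avoids mutant model building at the cost of ignoring side-chain volume
change.

The $S$ entering the combined score is the **mutant's absolute** residue
clique score. The alternative reading — the wild-type-minus-mutant
difference — is equally compatible with the published wording; since the
trained threshold is only meaningful under the convention it was trained
with, both are implemented (`s_mode = "mutant"` or `"delta"`) and the
absolute convention is the default.

Degenerate inputs degrade per row, never fatally: a position in no clique
gets $S = 0$ with a `no_clique` flag (entropy and substitution still drive
the call); a missing alignment gives $H = 0$ (`no_msa`), which is
conservative toward destabilizing; a missing matrix set gives $F = 0$
(`no_matrix`); a wild-type mismatch errors that row only.

### Conservation

$H = -\sum_i P_i \log_2 P_i$ in bits over the 20 amino-acid fractions of the
alignment column mapped to the position. Gaps and X are excluded and the
remainder renormalised (the sum runs over amino acids only); a
gap-as-21st-symbol policy is available. No sequence weighting or
pseudo-counts — the entropy is the raw column composition, and the query row
is included in the counts. Structure position $i$ maps to the $i$-th non-gap
column of the query row; the gap-stripped query must match the chain
sequence at ≥ 95% identity unless an explicit mapping is supplied.

### Substitution matrices

A matrix set is one 20×20 wt→mut likelihood table per burial zone, routed
through the same 5/8 Å boundaries as everywhere else. Real depth-dependent
substitution matrices are derived from large structural-alignment corpora
and are not redistributable here; the package ships a **synthetic** set
(`synthetic_matrix_set()`, identity-dominant with physicochemical grouping
and zone-dependent penalties, labeled `synthetic-v1`) and reads user-supplied
matrices in a documented TSV schema. Scores from the synthetic set exercise
the machinery; they do not approximate any published matrix's values.

### Evaluation, training and meta-prediction

The positive class ("class 1") is *neutral* throughout; both class views are
reported. MCC follows the standard four-count formula with zero-denominator
cases flagged undefined rather than coerced. The trainer scans the full
13 × 13 × 13 × 21 grid (weights 0–3 step 0.25, threshold 0–2 step 0.1),
maximises MCC and breaks ties toward the lexicographically smallest
$(w_S, w_H, w_F, t)$ — near-ties are common on real data, so the full score
surface is exportable for inspection. Spearman's $\rho$ uses the
$1 - 6\sum d^2 / (n(n^2-1))$ form on tie-free data; graded phenotype scores
are heavily tied, and the plain formula presumes distinct ranks, so tied
inputs are evaluated as the Pearson correlation of midranks (identical where
ties are absent). $n$ is the number of observations. Experimental
mutational-sensitivity grades map to labels as MS = 2 → neutral, MS > 2 →
destabilizing.

The meta-predictor picks, per category (wild-type amino acid, or
wild-type→mutant pair × burial zone), the method with the best category
accuracy, ties resolved toward the method with the better overall MCC, and
assembles the routed predictions. Selection and evaluation happen **on the
same set**: this in-sample construction bounds what routing could achieve;
it is not an unbiased performance estimate, and the package deliberately
provides no train/test split for it.

## Synthetic data: what it does and does not show

The generators (`make_structure()`, `make_corpus()`, `make_msa()`,
`make_labeled_mutations()`) are pure functions of their seed and restore the
caller's RNG state. Structures are ideal-geometry backbones (helix, extended
strand, or a compact globule with ~85 Å³ per residue and 3.4 Å minimum Cα
separation) carrying side-chain pseudo-atom clusters with the canonical
heavy-atom count per amino acid — enough to exercise the contact rule,
clique enumeration and solvation geometry. A globule of ~100 residues, like
a real single domain, develops a buried (> 8 Å) core; the test suite uses
that size where burial matters. Alignments plant per-column conservation;
labeled mutation sets plant a linear rule with feature ranges matching what
the pipeline produces (S roughly ±2, H over its full 0–log₂20 range, F ±3)
and a small exclusion margin (0.05, below the threshold grid step) so that
the planted rule is the unique best grid point at a few thousand mutations —
with a wide margin, whole families of near-parallel grid separators tie and
the lexicographic tie-break would report a different (equally perfect)
optimum.

What passing tests show: the geometry, counting, scoring, training and
evaluation machinery is correct to its definitions, including against
independent brute-force oracles. What they cannot show: predictive accuracy
on real proteins — that depends on a large curated structure corpus, real
depth-dependent substitution matrices and deep alignments, none of which are
bundled. Published-scale accuracy figures are reproduced here only at the
level of the metric engine applied to published confusion counts.

## Problem sizes

The default test and acceptance runs use corpora of 2–5 structures of 18–30
residues, single target structures of 15–100 residues, alignments of 50–200
sequences, 10,000 sampled cliques for enrichment recovery and 2,000
mutations for weight recovery — sizes chosen so the full suite completes in
well under a minute while leaving every statistical check comfortably
powered (the recovery tests pass with 4σ Monte-Carlo headroom).

## Known limitations

* In-place mutant scoring ignores side-chain repacking and volume change.
* The solvation defaults are a reconstruction of the classical depth
  construction, not a fit to any particular server's output.
* The floor for unobserved compositions is a ranking device, not an energy;
  small corpora floor many compositions (flagged per score).
* Entropy is position-specific, identical for all mutants at a site; it
  carries no direction-of-change information.
* The meta-predictor is in-sample by design and must not be read as an
  expected-accuracy estimate.
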