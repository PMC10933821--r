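---
title: "REG analysis of IQA energy partitions: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{REG analysis of IQA energy partitions: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regiqa)
```

## The model

IQA assigns the total electronic energy of an *N*-atom system to
non-overlapping, space-filling atomic basins: one intra-atomic term per
atom and one interatomic term per atom pair,

$$E_\mathrm{tot} = \sum_A E_\mathrm{intra}^A + \sum_{A<B} V_\mathrm{inter}^{AB}.$$

This package stores each unordered pair **once**, so no factor of 1/2
appears anywhere in the code; the familiar 1/2 in the ordered-pair form of
the identity only compensates double counting. This is worth stating
prominently because mixing the two conventions is the classic way to break
the additivity identity.

The interatomic term decomposes as
$V_\mathrm{inter}^{AB} = V_\mathrm{cl}^{AB} + V_\mathrm{xc}^{AB}
(+ V_\mathrm{D3}^{AB})$: a classical electrostatic part, an
exchange–correlation part, and optionally a pairwise empirical dispersion
correction. Because D3-type corrections are pairwise additive, the
dispersion term flows through validation, aggregation and regression as
just another pair term. When raw components are available
($T$, $V_{ee}$, $V_{en}$ intra-atomically; $V_{nn}$, $V_{en}$, $V_{ne}$,
$V_\mathrm{coul}$, $V_x$, $V_c$ between pairs) the corresponding identities
are cross-checked by `validate_profile()`. The directional raw pair types
deserve a note: $V_{en}^{AB}$ (electrons of *A* with nucleus of *B*) and
$V_{ne}^{AB}$ are each other's mirror, so when the canonicalisation of an
unordered pair swaps its participants, `Ven` is renamed `Vne` and vice
versa rather than silently changing meaning.

The classical term splits further into a monopolar charge-transfer piece
and a polarisation remainder,

$$V_\mathrm{ct}^{AB} = \frac{q_A\,q_B}{r_{AB}}, \qquad
  V_\mathrm{pl}^{AB} = V_\mathrm{cl}^{AB} - V_\mathrm{ct}^{AB},$$

in atomic units (charges in e, distances in bohr). The split needs
per-geometry charges; these are taken from the profile's atoms table and
never computed internally — any charge definition the user trusts
(typically basin populations per geometry) can be supplied. Because
$V_\mathrm{pl}$ is defined as a remainder the split closes by
construction; in floating point the re-addition
$V_\mathrm{ct} + V_\mathrm{pl}$ can differ from $V_\mathrm{cl}$ by at most
one ulp, which is what the test suite asserts.

Fragment (IQF) energies are plain sums of the member pair terms with one
atom in each of two disjoint groups. Within-group pairs and intra-atomic
terms are deliberately excluded from a between-group energy; the
linearity of sums is what makes fragment-level REG values equal the sum of
their member atomistic REG values.

## The REG statistic

Over the $M$ geometries of a segment, the REG value of term $i$ is the
ordinary least-squares slope of the mean-centred term series on the
mean-centred total-energy series,

$$m_{\mathrm{REG},i} =
  \frac{\langle E_i^\mathrm{transl}, E_\mathrm{tot}^\mathrm{transl}\rangle}
       {\langle E_\mathrm{tot}^\mathrm{transl},
                E_\mathrm{tot}^\mathrm{transl}\rangle}.$$

Two modelling decisions follow directly from this definition and are baked
into `reg_values()`:

* **The control coordinate never enters the numerics.** $s$ orders the
  points and defines segment membership; the regression is of $E_i$ on
  $E_\mathrm{tot}$. Uneven spacing of the scan is therefore irrelevant.
* **Mean-centring makes REG values translation-invariant.** Adding any
  constant to any term (or to the total) changes nothing — the synthetic
  generator draws random per-term offsets precisely to keep this property
  under test.

Linearity of least squares gives two exact identities the suite verifies
at every opportunity: the REG values of a complete additive partition sum
to 1, and the REG value of a sum of terms is the sum of their REG values
(aggregation linearity). Both hold to rounding error only, independent of
noise.

A REG value is only meaningful when the term–total relationship is close
to linear. The admissibility flag applies a threshold to $R^2$ (the square
of the Pearson correlation of the two raw series), default 0.8, following
the field's convention. A practical observation from working with
published rankings: printed top-10 tables can include entries with
$|R|\approx0.82$–$0.89$, i.e. $R^2$ below 0.8. The engine keeps the strict
$R^2$ semantics and instead lets the caller lower the threshold or pass
`keep_inadmissible = TRUE` when reproducing such tables. Terms with zero
variance get REG 0 and an undefined (NA) correlation, flagged
inadmissible rather than erroring, since frozen terms are legitimate in
partial scans.

Ranking is most-positive-first. Ties are broken by term type, then by
canonical participant order, so reports are deterministic. The reference
for REG Ratios is the most positive *atomistic* REG value; ratios are
`reference / reg_i`, and entries with $|m_{\mathrm{REG},i}| < 10^{-6}$
(dimensionless) are flagged unstable because a ratio against a
noise-level slope is unbounded. `cross_system_compare()` lines up ratios
of shared keys across systems in a user-given order (for substituted
series, typically most electron-withdrawing to most electron-donating)
and labels each term's trend as increasing, decreasing or mixed.

### Sign convention

Profiles are expected to be ordered so that the **final** point is the
conformer whose formation is under study (e.g. transition state first,
closed conformer last). Positive REG then means "helps formation". The
package documents and follows this convention but does not try to infer
or enforce it from the data — reversing a profile flips every sign
coherently, and only the user knows which end is which.

## Units, rounding, tolerances

* Energies are hartree internally; reports convert with
  1 hartree = 2625.4996 kJ/mol. Experimental comparisons are in kJ/mol;
  the free-energy relation $\Delta G = -RT\ln K$ uses
  $R = 8.31446\ \mathrm{J\,mol^{-1}K^{-1}}$.
* Identity checks default to a tolerance of $10^{-8}$ hartree: basin
  integration error in real data sits well above machine precision, and
  no tighter figure is standard. The tolerance is an argument everywhere.
* Reports round REG to 1 decimal, Pearson R to 2, and REG Ratios to the
  nearest integer — half away from zero, matching how printed tables are
  rounded — while full precision is retained in every returned object and
  available via `full_precision = TRUE`.
* Profile CSVs serialise numbers with 17 significant digits, so a
  write/read round trip is bit-identical.
* `M < 3` is accepted at read time but rejected by the regression: storage
  and statistical preconditions are separate concerns. A zero-variance
  total over the segment is a hard error, since every slope would be
  undefined.

## The interchange schema

Wavefunction-analysis programs emit partitioned energies in heterogeneous
formats, so the package defines a minimal CSV interchange: one row per
(point, term) with columns `point_index, s, term_type, atom_a, atom_b,
energy_hartree`, a companion atoms table `point_index, atom, q, x, y, z`,
and fragment schemes as YAML. Converting a particular program's output
into this schema is a thin external step and out of scope here, as is any
parsing of wavefunctions or basin integration. Atom labels are
element-plus-index (`n1`, `c4`), case-insensitive on input and lowercase
canonically; unordered pairs are stored sorted by (element, index), which
is deterministic even though published tables often print the
chemically-salient atom first. Profiles lacking `V_D3` rows are treated as
dispersion-free (zero for every pair) with a one-time note, since both the
dispersion-corrected and uncorrected compositions are legitimate inputs.

## The synthetic generator

`synthetic_profile()` emulates exactly the statistical structure the
analysis relies on, with every default chosen to mirror a desk-scale
conformational segment:

* a **monotone barrier-shaped total** (quadratic in $s$, transition state
  at the first point, minimum at the last), default amplitude 0.02 hartree
  (≈ 50 kJ/mol, a typical conformational barrier) over `m_points = 15`
  geometries — the order of magnitude of a relaxed dihedral scan;
* a complete term set (`E_intra` per atom; `V_cl`, `V_xc`, `V_D3` per
  pair) with ground-truth slopes that sum to exactly 1; each term is
  `slope · E_shape(s) + offset + noise`;
* noise applied in term space and then **mean-projected per point** so the
  terms still sum exactly to the stored total. Without this projection the
  partition-sum identity would only hold approximately and the validator
  would flag every generated profile;
* offsets drawn per term (and centred so they cancel in the sum) to
  exercise translation invariance;
* optional per-point charges and jittered chain coordinates so the
  charge-transfer split has inputs;
* full determinism from a single integer seed (Mersenne–Twister with
  inversion normals, stated so the stream is reproducible across
  platforms).

`synthetic_balance()` arranges a 12-atom system with the qualitative
structure of a closing molecular balance: a dominant positive
electrostatic pair term on the amide-bond analogue (slope 4.0), a dominant
negative intra-atomic term on its nitrogen (−2.5), and a counterbalancing
positive/negative carbonyl-like pair (±0.7) — magnitudes chosen to match
the relative standing such terms have in published atomistic rankings —
plus a fragment scheme with singleton and multi-atom groups.

What the generator does **not** emulate: wavefunction physics. Terms are
independent affine functions of the total plus projected noise; real IQA
terms are strongly inter-correlated, their linearity with the total
varies, and integration error is not i.i.d. Gaussian. Passing tests
therefore demonstrate the estimator's algebraic correctness and the
pipeline's plumbing, not chemical accuracy on real systems. Conclusions
about any real balance must come from real partitioned energies.

## Problem sizes used in the test suite

The suite runs on profiles of 3–12 atoms and 4–15 points: large enough
that every code path (complete partitions, fragment pairs, charge splits)
is exercised with hundreds of terms, small enough that the whole suite
and the acceptance script complete in a couple of minutes on one core.
Property checks loop over 20–100 seeds at three noise levels
($\sigma \in \{0, 10^{-5}, 10^{-3}\}$ hartree, from exact to roughly the
size of basin-integration error).

## Known limitations

* No automatic segmentation of a profile at energy extrema; segments are
  user-specified point ranges. Analyses of multi-barrier landscapes must
  split profiles explicitly.
* The charge-transfer split is only as meaningful as the supplied charges;
  no charge model is provided.
* Fragment schemes must be disjoint. Reproducing published nested-group
  analyses (where one group is a superset of another) requires one scheme
  per comparison, not one scheme containing both.
* The most-positive REG reference for ratios is taken after tie-breaking;
  when the maximum is not unique the first-ranked entry under the
  deterministic tie-break is used.
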