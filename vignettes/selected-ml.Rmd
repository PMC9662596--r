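---
title: "Selected machine learning of frontier orbital energies: methods and design"
author: "selml authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selected machine learning of frontier orbital energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

HOMO–LUMO gaps are intensive electronic properties: molecules with nearly
identical composition and geometry (cyclohexanol, cyclohex-2-enol, phenol)
can have gaps several eV apart, while dissimilar molecules can agree
closely. Kernel models built on geometric similarity therefore learn gaps
slowly — the property is not smooth over chemical compound space as seen by
a conventional representation. The empirical gap distribution of small
organic molecules is trimodal, and the three modes line up with simple
structural features: fully saturated molecules sit under the highest-gap
peak, molecules with a single unsaturated bond under the middle one, and
aromatic or polyunsaturated carbonyl compounds under the lowest one.

`selml` exploits this: it partitions a dataset into those three chemically
defined classes *before* training and fits one independent kernel ridge
regression (KRR) model per class ("selected" machine learning, SML). The
package provides the whole pipeline — file readers, rule-based
classification, spectral representations, KRR with width selection,
learning-curve protocols, delta-learning between two levels of theory, and
a synthetic data generator so that everything can be exercised offline.

## Classification rules

Structural tags come from declarative SMARTS patterns evaluated with
OpenBabel (via ChemmineR/ChemmineOB), using OpenBabel's default
aromaticity perception after sanitisation; the model used is recorded in
the tag table's metadata because perception models differ between
toolkits. The unsaturation count `n_u` counts every double, triple or
aromatic bond between heavy atoms once — benzene contributes six, and a
C=O double bond counts.

The class assignment is a fixed decision sequence, total and
deterministic:

1. `n_u == 0` → **class I** (saturated);
2. amide, carboxylic acid/ester, or α-amino acid → **class II**;
3. aromatic → **class III**;
4. carbonyl with `n_u > 1` → **class III**;
5. otherwise → **class II**.

Branch 2 fires before the aromaticity test, so aromatic amides land in
class II. The prose this rule set is reconstructed from does not spell out
that corner case; we fix the amide-first order because amides and
carboxylates form well-localised sub-distributions under the middle peak,
and a fixed order is required for the classes to be disjoint and
exhaustive. The SMARTS patterns are the minimal literal encodings of the
named groups (`[CX3]=[OX1]`, `[NX3][CX3]=[OX1]`, `[OX2][CX3]=[OX1]`, and
an α-amino-acid pattern); they are exposed through `classifierPatterns()`
and can be replaced wholesale.

Two structure-blind baselines support the analysis rather than the
classification itself: `frequencyAnalysis()` decomposes the gap
distribution into per-tag kernel density estimates scaled so each curve
integrates to its tag's dataset fraction, and `gmmBaseline()` fits a 1-D
Gaussian mixture to the gap values (mclust's EM, components relabelled by
ascending mean).

## Representation

`slatmVector()` implements a spectral representation with one-, two- and
three-body channels over a dataset-wide basis: per element, the atom count
times nuclear charge; per element pair, interatomic distances smeared with
a normalised Gaussian onto a radial grid and weighted by the
London-dispersion-style factor `0.5 Z_i Z_j / r^6 · dr`; per (pair,
centre) triple, the angle at the centre atom smeared onto an angular grid
and weighted by `Z_i Z_j Z_k / 3 · dθ`. Defaults: radial grid 0.2–8.0 Å at
0.05 Å with width 0.05 Å, 40 angular bins with width 0.05 rad, three-body
cutoff 4.8 Å. These are conventional values for this family of spectra and
fully exposed in `repConfig()`; the three-body weight is a documented
simple-Gaussian variant of the angular term. Because the spectrum is built
from internal distances and angles only, it is invariant under rigid
motion and atom reindexing by construction — the test suite asserts this
to 1e-8 over random transforms. `coulombEigs()` provides the heuristic
Coulomb-matrix eigenspectrum as a fallback.

Representations are computed from the geometries as provided; no geometry
is regenerated from SMILES.

## Regression

KRR with the Laplacian kernel `k(x, x') = exp(−‖x − x'‖₁/σ)`. Coefficients
solve `(K + λI)α = y` by Cholesky factorisation; on numerical failure the
jitter escalates tenfold (at most three times, with a warning) before an
SVD least-squares fallback, so duplicated molecules degrade gracefully.
λ defaults to 1e-12: the labels are computed quantities, noiseless to
machine precision, so the ridge term only stabilises the factorisation.

σ is selected per training set by 5-fold cross-validated grid search
(seeded shuffle; ties go to the smallest width). The default grid is
powers of four from 2⁴ to 2²⁶. The wide upper end is deliberate: L1
distances between spectral vectors are of order 10³–10⁴, and a Laplacian
KRR model can only represent a near-constant target — such as a
delta-learning correction between two well-correlated levels of theory —
when σ is far above the pairwise-distance diameter (the prediction error
of a constant c scales like c·Δd/σ). Cross validation discards the
extremes whenever the target actually varies, so widening the grid costs
only CV time.

## The comparison protocol

`makeSplits()` draws, per repetition: one fixed test set per class;
a generic training pool sampled uniformly from all remaining molecules;
and a selected pool per class sampled within the class. All test
molecules — of every class — are excluded from every training draw, the
strictest reading of "no overlap"; draws are nested by size so the points
of one learning curve are comparable. `runSmlComparison()` then evaluates
the generic machine and the class machine on *identical* test molecules,
repetition by repetition (10 by default, seeds derived from the base
seed), and `fitLogLog()` summarises each averaged curve as
`log10(MAE) = offset + slope·log10(N)`. The expected signature of
successful selection is a large offset drop at nearly unchanged slope.

Delta learning (`deltaTrain()`/`deltaPredict()`) trains on the difference
between a target and a baseline level and adds the predicted correction
back onto the baseline.

## The synthetic fixture

The generator emulates exactly the statistical structure the method
assumes, so every claim can be tested offline:

* **Class structure.** SMILES are drawn from curated per-branch template
  families with combinatorial decoration (saturated chains/rings/alcohols/
  amines; single alkenes/alkynes/lone carbonyls; amides, esters, amino
  acids, dienes; aromatics, diketones, enones), covering every branch of
  the decision sequence, and each molecule's intended class provably
  equals its rule-based class.
* **Geometries.** Toy scaffold templates: atoms placed sequentially at
  bond-scale steps (1.35–1.6 Å) with a 0.9 Å minimum-separation rejection
  rule, seeded by a stable hash of the SMILES, plus per-molecule Gaussian
  jitter (sd 0.02 Å). These are deliberately synthetic — consistent,
  distinct, never chemically relaxed.
* **Labels.** `gap = classMean + smoothWeight · f(rep) + N(0, noiseSd)`
  with `f` a fixed functional of the representation: the projection onto a
  seeded random unit direction, mapped through its within-class Gaussian
  scores and scaled by the class spread. The map is monotone in a single
  structural coordinate, hence learnable by a kernel model, and it makes
  each class-conditional gap distribution exactly Gaussian. A direct
  saturating squash of the raw projection was rejected: toy representation
  space is clustered by template subfamily, and a saturating map piles a
  subfamily onto the saturation boundary, producing a spurious secondary
  mode inside a class — the generator must produce unimodal
  class-conditional distributions, because that is the empirical structure
  the classification exploits. HOMO is anchored at −(gap/2 + 4) eV and
  LUMO at HOMO + gap, so the gap identity holds by construction. Defaults:
  class means (9.5, 7.0, 5.0) eV, spreads (0.5, 0.6, 0.7) eV — a separated
  trimodal mixture; smoothWeight 0.8 and noiseSd 0.02 eV keep labels
  dominated by learnable structure.
* **Two levels.** `baseline = 0.95·target − 0.5 + N(0, 0.05)` eV. At the
  default between-class spread (pooled gap sd ≈ 1.9 eV) the implied
  correlation is r = (1 + (0.05/(0.95·1.9))²)^(−1/2) ≈ 0.9996 > 0.99, the
  regime in which delta learning pays off.

What passing on this fixture does **not** show: real quantum-chemistry
labels have heavier tails, class-dependent noise, and representation
mismatch (conformers, long-range effects) that the generator omits; and
toy geometries make the within-class maps smoother than relaxed organic
geometries would be. Results on the fixture validate the machinery and
the qualitative structure of the claims, not full-scale error magnitudes —
reproducing published benchmark MAEs requires the public QM7b/QM9
downloads, for which the readers and protocol configuration are provided
but no download client is.

## Numerical choices

* KDE curves are evaluated on a common 512-point grid spanning the pooled
  gap range extended by **four** bandwidths per side. With three
  bandwidths, a boundary-heavy sample can lose up to 2·Φ(−3) ≈ 0.27% of
  its kernel mass, breaking the integral-equals-weight identity at the
  1e-3 quadrature tolerance; four bandwidths bound the deficit at ~6e-5.
* Radial Gaussians are truncated at ±8σ for speed; the truncation error is
  below 1e-14 of a channel's weight.
* Tie-breaks: σ selection prefers the smallest width; mixture components
  are relabelled by ascending mean, which makes labels permutation-stable.
* Degenerate inputs: duplicated training molecules trigger jitter
  escalation then an SVD fallback; coincident atoms are a hard error in
  the Coulomb matrix (division by zero) and in the two-body spectrum.
* Problem sizes: the shipped study fixture uses 3 × 500 molecules,
  training sizes 16–256, test sets of 200 per class and 10 repetitions —
  large enough for stable curve fits, small enough to run on one CPU in a
  few minutes. The size schedule, like every other knob, is configuration,
  and the same protocol runs unchanged on QM7b/QM9-scale inputs.

## Known limitations

* The classifier depends on OpenBabel's aromaticity model; molecules near
  the aromaticity boundary (e.g. some fused heterocycles) may be tagged
  differently by other toolkits. The pattern set is exposed precisely so
  users can pin their own.
* The three-body angular term uses a plain Gaussian without the
  cosine-product modulation used by some published spectra; at fixed
  configuration this changes vector values, not invariances, and the
  kernel widths are re-selected by CV in any case.
* A single fixed class partition is assumed; datasets whose gap
  distribution is not governed by saturation/aromaticity/carbonyl
  chemistry need a different rule set (the machinery accepts any
  tag-to-class mapping).
* `gmmBaseline()` relies on mclust's deterministic initialisation; its
  `seed` argument exists for interface stability only.
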