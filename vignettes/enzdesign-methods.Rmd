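---
title: "Methods: conservation, co-evolution, structure and quantification in enzdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation, co-evolution, structure and quantification in enzdesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzdesign)
```

# Scope and model

enzdesign implements the computational half of an iterative enzyme-redesign
loop: given a family alignment, a structural model with bound cofactor and
substrate, and LC-MS chromatograms, it proposes, annotates, clusters and
shortlists single-residue substitutions, and quantifies the product spectrum
of tested variants. Everything upstream (database searches, homology
modelling, ligand docking) and downstream (cloning, expression, atomistic
scoring) is deliberately out of scope; the design stage exposes an external
score hook so docking- or physics-based energies can replace the default
evidence score when available.

# Sequence conservation

Rows are redundancy-weighted: the weight of a sequence is the reciprocal of
the number of rows within 80% identity of it (identity counted over the
row's own non-gap columns), the standard co-evolution convention. The
effective count `neff` is the weight sum.

The PSSM uses single-parameter background mixing,
`p_i(a) = (n_i(a) + alpha * q(a)) / (n_i + alpha)` with `alpha = 1` and a
uniform background `q = 1/20` by default, scored in bits. PSI-BLAST-style
data-dependent pseudocounts were rejected on purpose: they need external
frequency tables, and only the sign and ranking of scores are consumed
downstream. The background is user-overridable; position numbers are
1-based alignment columns so they match the field's residue numbering
(e.g. 352). Columns that are entirely gaps score 0 with a warning.

Counts of "substitutions with positive PSSM values" reported for real
families depend on the search database snapshot and the PSI-BLAST scheme,
so they are not treated as reproducible quantities here; the contract is
the arithmetic, which is tested against a hand-computed oracle to 1e-12.

# Co-evolution

The Potts model is fitted by symmetric pseudolikelihood: minimize

```
sum_s w_s sum_i -log P(x_i^s | x_-i^s; h, J)
  + lambda_h ||h||^2 + lambda_J ||J||^2
```

with `lambda_h = 0.01` and `lambda_J = 0.2 (L-1)` — the published
direct-coupling convention; an overall `1/neff` rescaling of this objective
would not move the optimum, so it is omitted. The objective is convex;
L-BFGS from zero initialization with a projected-gradient tolerance of
1e-3 gives a reproducible optimum, and non-convergence within `max_iter`
returns the fit with a warning carrying the final gradient norm.

The gap is an ordinary 21st state by default. `alphabet = "observed"`
restricts the fit to states actually present in the alignment — the fast
projection intended for reduced-alphabet synthetic data (q = 8 recovery
tests run in seconds instead of minutes). Dense coupling storage limits
practical use to L of a few hundred.

Scores are Frobenius norms of the 20 x 20 non-gap coupling block after the
zero-sum gauge (double-centering), followed by average product correction.
APC is exactly `S_ij - S̄_i S̄_j / S̄` (row means exclude the diagonal); at
L = 2 it is identically zero, an algebraic property the tests assert.
Substitution proposals scan both members of each top pair, maximizing
`J_ij(a, x_j) + h_i(a)` over the 20 residues; only positive gains are
reported. The number of pairs scanned defaults to `1.5 L`, a free parameter
because no published score cutoff exists for the corresponding experiment.

# Structural environment

Solvent accessibility is Shrake–Rupley with a Fibonacci point lattice,
960 points and a 1.4 Å probe by default; 960 points reproduce the analytic
isolated-sphere area within 1% and refinement to 3840 points moves results
by under 0.5%. Van der Waals radii are a fixed element table (C 1.70,
N 1.55, O 1.52, S 1.80, Fe 2.00 Å). Ligand atoms are excluded as occluders
by default so pocket residues are classified by protein-only accessibility;
this is configurable.

RSA divides residue SASA by the Tien et al. theoretical maxima. Burial
bands are literature-standard — surface at RSA >= 0.25, buried at <= 0.05,
semi-exposed between — chosen because the redesign experiments this
supports define the labels only by example. Pocket membership is any heavy
atom within 6.0 Å of any ligand atom, a typical first-shell definition for
P450 pockets. SASA scales quadratically under coordinate scaling while the
reference maxima are fixed, so RSA is meaningful only at physical scale —
a documented non-invariance.

# Variant design

Nomenclature follows the field: `L48F-S49A-…`, with alias prefixes
(`V1-K352I`) composing left-to-right on a named base variant. A token at an
already-substituted position replaces it and the net from-residue is taken
from the original base, so composing `K352I` on a base carrying `T352K`
stores a net `T352I`; both the display name and the canonical net form are
kept, because published figure captions use the former and sequence-level
bookkeeping needs the latter.

Variant distance converts PAM30 similarities to a squared-distance-like
form per mutated position, `(s(x,x) + s(y,y) - 2 s(x,y)) / 2`, summed over
the union of mutated positions. This guarantees zero self-distance and
symmetry; the triangle inequality is *not* guaranteed and is not asserted.
The PAM30 values are NCBI's, taken at run time from Biostrings rather than
re-transcribed.

Clustering is agglomerative with average linkage, cut at k = 8 by default
(the group count used in the motivating experiment; the criterion itself
was unpublished, so the linkage is this package's choice). Merge ties break
on the smallest (cluster-id, cluster-id) pair with a cluster identified by
its smallest member index, making the partition deterministic and
order-invariant. Per cluster the lowest-scored variant is the
representative, ties by canonical name. The default score is
`-(PSSM bits) - (coupling gain)`; an external per-variant score file
replaces it when configured.

# Quantification

Monoisotopic masses use the standard table (C = 12 exactly,
H = 1.00782503, O = 15.99491462, …) and positive adducts subtract the
electron mass (0.00054858 Da) — without that correction the reference EIC
value 443.3884 for protonated C30H50O2 is missed at the fourth decimal.
One printed reference value, 441.3709 for the carbonyl product C30H48O2,
does not match the computed 441.3728 (a ~1.9 mDa gap, while the other two
values match exactly); it is documented but not used as a check.

EICs sum peak intensities within a ppm window (default 20 ppm — no
tolerance was published); areas are trapezoidal with edge interpolation, so
integrals are additive over adjacent windows. Baseline correction defaults
to none because the synthetic data are baseline-free; a constant-baseline
option subtracts the window-edge mean (vendor peak-picking algorithms are
proprietary and are not emulated). Standard curves are ordinary least
squares of area on concentration; curve sharing between structurally
similar compounds (the hydroxy product quantified on the carbonyl
standard's curve) is explicit configuration, not a heuristic. Yields are
floored at zero and percentages normalized to total yield.

# Synthetic data: what it does and does not establish

The alignment generator Gibbs-samples a known Potts model (single chain,
1000 burn-in sweeps, thinning 10) with diagonal planted couplings
`J(a,b) = beta * 1[a==b]` at `beta = 1` by default — a strong, unambiguous
covariation signal — plus optional conserved columns with field strength 2.
Defaults (L = 30, N = 2000, q = 8, 10 planted pairs) are the recovery-test
conditions. Sequences are i.i.d. given the model: there is no phylogenetic
correlation, no alignment error, and no gap structure unless planted. A
green recovery test therefore establishes that inference recovers planted
couplings from clean data at realistic depth; it does not establish
performance on real families with shared ancestry, where APC mitigates but
does not remove confounding.

The toy structure is an ideal helix trace (rise 1.5 Å, twist 100°/residue)
of poly-alanine CA/CB pseudo-atoms with a single iron ligand at a stated
offset — enough geometry to exercise exposure gradients and pocket cutoffs,
not a physical model; absolute RSA values on it are meaningful only
relative to each other. Chromatograms are Gaussian peaks with optional
clipped Gaussian noise and no baseline drift or isotope patterns.

# Numerical choices

* Optimizer: `optim(method = "L-BFGS-B")`, `factr = 0`, convergence on the
  projected gradient infinity norm; reported in the model object.
* Sphere points: Fibonacci lattice (deterministic, no RNG in SASA).
* Tie-breaks are defined everywhere results are ordered: PSSM substitutions
  by (score desc, position, residue); coupled pairs by (score desc, i, j);
  proposals by (gain desc, position, partner); cluster merges and
  representatives as above.
* Degenerate inputs fail loudly: empty alignments, all-gap columns
  (warning + zero scores), zero total yield, non-positive curve slopes,
  windows outside the time range.

# Limitations

* No phylogenetic correction beyond sequence weighting and APC.
* Dense coupling storage; not intended for L >> 500 or metagenome-scale N.
* The PDB reader covers ATOM/HETATM essentials (first model, altloc A,
  no insertion-code handling) — sufficient for model coordinates, not for
  arbitrary crystallographic files.
* Quantification assumes baseline-resolved peaks and linear response;
  no deconvolution or isotope-pattern modelling.
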