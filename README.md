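# enzdesign

Data-driven redesign of enzymes — worked out for the kind of problem where a
multifunctional plant cytochrome P450 (e.g. a cucurbitadienol oxidase) is to
be converted into an efficient single-step hydroxylase. The package turns
family sequence data, a structural model and LC-MS read-outs into a ranked,
clustered shortlist of candidate substitutions:

1. **Conservation** — a position-specific scoring matrix (PSSM) from a
   redundancy-weighted multiple sequence alignment. For column *i* and
   residue *a*,
   `score(i,a) = log2 p_i(a) / q(a)` with
   `p_i(a) = (n_i(a) + α q(a)) / (n_i + α)`; substitutions with positive
   score at non-native residues are conservation-supported candidates.
2. **Co-evolution** — a Potts model (pairwise Markov random field over
   alignment columns) fitted by L2-regularized pseudolikelihood, scored by
   Frobenius norms of the zero-sum-gauge coupling blocks with average
   product correction (APC): `S^APC_ij = S_ij − S̄_i S̄_j / S̄`. Top coupled
   pairs propose residues maximizing `J_ij(a, x_j) + h_i(a)`.
3. **Structure** — Shrake–Rupley solvent-accessible surface area on a PDB
   model, relative accessibility against the Tien et al. maxima, and
   classification into surface (RSA ≥ 0.25) / semi-exposed / buried
   (RSA ≤ 0.05), plus active-pocket membership within 6 Å of a bound ligand
   (heme, docked substrate).
4. **Variant design** — candidate enumeration from both evidence streams,
   PAM30-derived distances
   `d(x,y) = Σ (s(x,x) + s(y,y) − 2 s(x,y)) / 2`, deterministic
   average-linkage clustering (default k = 8), lowest-scored representative
   per cluster, and hyphenated variant nomenclature
   (`L48F-S49A-…`, alias composition `V1-K352I` with replacement semantics).
5. **Quantification** — theoretical adduct m/z from monoisotopic masses
   (electron-mass corrected), extracted-ion chromatograms at ppm tolerance,
   trapezoidal peak areas, linear standard curves (with explicit
   curve-sharing between structurally similar products), and product
   percentages normalized to total yield.

A synthetic-data module (Potts-sampled alignments with planted couplings,
toy helix structures with a placed ligand, Gaussian-peak chromatograms)
makes every stage testable offline.

## Worked example

```r
library(enzdesign)

# synthetic family + structure stand in for an MSA and a docked model
m <- sample_potts_msa(L = 20, N = 300, q = 6, n_pairs = 3,
                      conserved = c(2L, 5L), seed = 1)
write_alignment(m$alignment, "msa.fasta")
write_pdb(make_toy_structure(20, ligand_resno = 10, ligand_offset = 5),
          "model.pdb")

rep <- run_design(list(alignment = "msa.fasta", structure = "model.pdb",
                       target = m$alignment$rows[1],
                       potts_alphabet = "observed", cluster_k = 4,
                       tol = 1e-2, n_points = 240, out_dir = "out"))
rep
#> DesignReport: 100 candidates -> 4 clusters; neff 300.0; Potts converged

head(read.delim("out/candidates.tsv")[, c("name", "provenance",
     "burial_class", "score", "cluster")])
#>   name       provenance burial_class      score cluster
#> 1  G1A             pssm      surface -1.8709791       1
#> 2  G1C             pssm      surface -1.8175893       1
#> 3  G1D coevolution,pssm      surface -2.8016080       1
#> 4  G1E coevolution,pssm      surface -1.7515335       1
#> 5  G1F             pssm      surface -1.8709791       1
#> 6  D2A             pssm      surface -0.4138387       1
```

Each row is a single-substitution candidate on the target: `G1D` means
glycine 1 to aspartate, supported here by both conservation and
co-evolution, on the protein surface, with score
`−(PSSM bits) − (coupling gain)` (lower is better). `cluster` is the PAM30
average-linkage group; the lowest-scored member of each cluster is flagged
`representative` — the set one would take to the bench.

The quantification side reproduces instrument-style arithmetic, e.g. the
protonated ion of a hydroxylated triterpene C30H50O2:

```r
adduct_mz("C30H50O2", "[M+H]+")
#> 443.3884
```

## Command line

```sh
Rscript -e 'enzdesign::main()' design run --config design.json
Rscript -e 'enzdesign::main()' quant run  --config quant.json
Rscript -e 'enzdesign::main()' synth msa --seed 1 --out msa.fasta
```

Exit codes: 0 success, 2 validation error, 3 stage failure. See the methods
vignette (`vignettes/enzdesign-methods.Rmd`) for the model details, defaults
and limitations.
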