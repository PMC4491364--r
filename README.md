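# esfold

Early-stage (ES) protein folding intermediates modelled with a seven-letter
structural alphabet, plus a statistical-dictionary predictor that maps amino
acid sequence to that alphabet.

## The model

The ES model assumes that, before a protein reaches its native fold, its
backbone passes through an intermediate whose conformation is restricted to a
limited region of Ramachandran (φ, ψ) space: an elliptical path. Every
residue's observed dihedral pair is projected onto the nearest point of that
path (nearest in the torus metric, so angle wrap-around at ±180° is handled),
giving a path parameter `t ∈ [0, 1)`. The distribution of projected residues
along the path shows seven local maxima; each maximum defines one letter of a
structural alphabet `A`–`G`, and each residue is assigned the letter of its
nearest maximum. Code `C` corresponds to helical conformations, `E` and `F`
to extended ones, and `A`, `B`, `D`, `G` make up a coil-like group. Residues
with missing backbone atoms (including the undefined first φ and last ψ of a
chain) are encoded as `X`.

Sequence-to-code prediction uses a family of subdictionaries `D_i` for odd
window lengths `i = 1, 3, …, l_max` (default 13). Each subdictionary maps a
length-`i` amino-acid window, padded with `X` at chain termini, to seven
counters recording which code the *middle* residue of that window adopted in
the training set. Prediction of a position tries the longest window first:
exact lookup, then an approximate lookup allowing exactly one mismatching
position (counters summed over all Hamming-distance-1 hits), then falls back
to the next shorter window, and ultimately to the training set's global
majority code. A tetrapeptide contingency-table baseline
(`build_contingency()` / `predict_contingency()`) is included for comparison.

Evaluation follows Q3-style conventions generalized to seven classes:
per-chain accuracy `100·m/n` with observed-`X` positions excluded, per-class
accuracies with a 0%-if-absent convention, totals as the unweighted mean over
chains, three-class groupings of both the ES codes and DSSP classes
(helix / extended / coil), and a row-percentage confusion table. Residues in
contact with ligands, other proteins, or nucleic acids (2.9 Å heavy-atom
cutoff) can be flagged and excluded.

The ellipse coefficients and the seven maxima positions are configurable
(`es_path()`, `code_assignment()`, config files via `read_es_config()`); the
shipped defaults are placeholder values chosen for a well-conditioned path,
not a literature calibration. `estimate_maxima()` can recover maxima
empirically from projected data by circular kernel density estimation.

## Worked example

Simulate a reproducible corpus with a known sequence→code rule (window width
5) and 5% code noise, build a dictionary, and predict:

```r
library(esfold)

corpus <- gen_corpus(n_chains = 30, chain_length = 120, mapping_width = 5,
                     noise_rate = 0.05, seed = 11, keep_truth = TRUE)
dict <- build_dictionary(corpus, l_max = 13)
dict
#> <es_dictionary> l_max = 13, 30 chains, 3600 residues, majority code E
#>   D_1: 20 keys
#>   D_3: 2931 keys
#>   D_5: 3600 keys
#>   D_7: 3600 keys
#>   D_9: 3600 keys
#>   D_11: 3600 keys
#>   D_13: 3600 keys

pred <- predict_chain(corpus$sequence[1], dict)
pred
#> # A tibble: 120 × 6
#>    position residue code  window_length match_kind support
#>       <int> <chr>   <chr>         <int> <chr>      <list>
#>  1        1 H       E                13 exact      <int [7]>
#>  2        2 C       C                13 exact      <int [7]>
#>  3        3 N       E                13 exact      <int [7]>
#>  # … with 117 more rows

glance(pred)
#> # A tibble: 1 × 5
#>       n n_exact n_one_mismatch n_fallback mean_window
#>   <int>   <int>          <int>      <int>       <dbl>
#> 1   120     120              0          0          13
```

Because every 13-mer in this corpus is unique, predicting the training chains
reproduces the (noisy) training codes exactly. Scoring against the noise-free
ground truth instead shows the 5% corruption:

```r
preds <- vapply(corpus$sequence,
                function(s) prediction_string(predict_chain(s, dict)),
                character(1))
truth <- corpus
truth$codes <- truth$codes_true
evaluate_predictions(truth, preds)
#> <es_evaluation> 30 chains, 3600 positions, exclusion: none
#> total accuracy (chain mean): 94.92%
#> per-class accuracy (chain mean, 0% if absent):
#>  class accuracy n_obs n_chains_absent
#>      A    93.54   509               0
#>      B    92.91   521               0
#>      C    96.30   513               0
#>      D    95.05   511               0
#>      E    95.02   521               0
#>      F    97.31   503               0
#>      G    94.24   522               0
```

The geometric side — generate backbone dihedrals for a code string, project
them back onto the path, and re-encode:

```r
cfg <- default_es_config()
dih <- gen_dihedral_chain("XCCCCEEEEABDGX", cfg$path, cfg$assignment,
                          sigma = 4, seed = 3)
encode_chain(dih, cfg$path, cfg$assignment)
#> [1] "XCCCCEEEEABDGX"

project_to_path(dih, cfg$path)
#> # A tibble: 14 × 4
#>        t phi_e psi_e distance
#>    <dbl> <dbl> <dbl>    <dbl>
#>  1 NA     NA    NA   NA
#>  2  0.317 -84.8  63.9  1.77
#>  3  0.311 -81.3  64.9  1.27
#>  # … with 11 more rows
```

Real structures enter through `read_pdb_backbone()` (PDB files, highest-
occupancy altloc kept, waters dropped), `compute_dihedrals()`, and
`flag_interacting()`; DSSP class strings are read with
`read_dssp_classes()` and grouped with `group_dssp()` for three-class
comparison against `group_es()` of the predicted codes.

## Command-line interface

`inst/scripts/esfold` (installed under `system.file("scripts", "esfold",
package = "esfold")`) wraps the same operations:

```sh
esfold simulate --out corpus.txt --n-chains 30 --length 120 --width 5 --seed 11
esfold build    --corpus corpus.txt --out dict.txt --l-max 13
esfold predict  --dict dict.txt --input corpus.txt --out pred.txt --report report.tsv
esfold evaluate --observed corpus.txt --predicted pred.txt --outdir reports/
esfold encode   --pdb structure.pdb --out encoded.txt
```

Corpora are plain-text, FASTA-like records (`>id|sequence`, `>id|codes`,
optional `>id|flags`); dictionaries serialize to a deterministic text format,
byte-identical for the same corpus regardless of record order.

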