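---
title: "Methods: the ES structural alphabet and dictionary predictor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ES structural alphabet and dictionary predictor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model and its assumptions

The early-stage (ES) intermediate model assumes a folding intermediate whose
backbone conformations lie near a one-dimensional path in Ramachandran
space: an ellipse in the (φ, ψ) plane. Three assumptions carry the whole
construction:

1. **Projection is meaningful.** Every observed dihedral pair can be
   projected to its nearest point on the path, where "nearest" uses the
   torus metric — each of φ and ψ wraps at ±180°, so distances are computed
   on the flat torus, not in the plane. The projection discards the
   off-path component and keeps only the path parameter `t ∈ [0, 1)`.
2. **Seven natural classes.** The distribution of projected residues along
   the path is multimodal with seven maxima. Each maximum is one letter
   `A`–`G`; a residue takes the letter of the maximum nearest to its `t`
   (cyclically). `C` sits in the helical region; `E` and `F` in the
   extended region; `A`, `B`, `D`, `G` form a coil-like group.
3. **Local sequence determines local code.** The code of a residue is
   statistically predictable from a short window of amino acids around it,
   which the dictionary family below exploits.

Missing data is explicit: a residue without a defined (φ, ψ) — chain
termini, incomplete backbones — is encoded `X`, excluded from accuracy
denominators, but retained as context for its neighbours.

## Parameters and the placeholder path

The ellipse (`es_path()`: centre, semi-axes, rotation, parameter origin) and
the seven maxima positions (`code_assignment()`) are *configuration*, not
constants. The values shipped in `inst/extdata/default_path.cfg` are
placeholders chosen so the path is well conditioned (it crosses the helical
and extended regions and the seven maxima are distinct and ordered); they are
not calibrated against any experimental dataset, and the config file says so.
Users with a calibrated path should write their own config
(`write_es_config()`) or pass `es_path()` / `code_assignment()` objects
directly. `estimate_maxima()` recovers maxima positions from projected data
by circular kernel density estimation: the sample is replicated at `t − 1`
and `t + 1` so density leakage across the 0/1 seam cancels, local maxima are
taken on a fixed grid, and a minimum peak-to-trough contrast (default 1.5)
guards against reading seven "maxima" off an essentially flat density.
Maxima may also be residue-specific (`by_residue`), with a global fallback.

## What the synthetic generator emulates — and what it does not

`gen_corpus()` draws i.i.d. amino-acid sequences (optionally biased via
`alphabet_bias`) and assigns each position the code of a *deterministic hash*
of its width-`w` window (`X`-padded at the termini), then flips a fraction
`noise_rate` of codes to a uniformly random *different* code. This emulates
exactly one property of real data: codes are a (noisy) local function of
sequence with a known context width. It deliberately does not emulate
sequence composition, code autocorrelation along the chain (real secondary
structure comes in runs), or any geometry. Its purpose is to provide ground
truth with controllable difficulty: memorization corpora (unique long
windows), coverage-complete corpora (small alphabets), and noise ladders.
`gen_dihedral_chain()` covers the geometric side separately: it places
residues at their code's maximum on the path plus Gaussian angular noise, so
projection and encoding can be tested against a known generating string.

Two experimental-design choices deserve justification because they are easy
to get silently wrong:

- **Generalization experiments use a reduced residue alphabet and a
  dictionary depth matched to the generative context width.** With the full
  20-letter alphabet there are 20⁵ ≈ 3.2 million width-5 contexts, so no
  desk-scale training corpus can cover the contexts appearing in held-out
  chains, and held-out prediction is dominated by fallback behaviour. A
  4-letter alphabet has 4⁵ = 1024 contexts, saturated by a 50 000-residue
  corpus. Depth matters for a subtler reason: with a small alphabet and a
  deep dictionary (`l_max = 13`), a held-out 9- or 11-mer almost always has
  some Hamming-distance-1 neighbour in the training set, and when the
  mismatching position falls inside the width-5 generative context the
  retrieved code is essentially random. The one-mismatch stage then fires
  *before* the informative exact 5-mer lookup is ever reached, capping
  held-out accuracy far below what the data supports. Setting
  `l_max = 5` — the generative width — makes every covered position resolve
  as an exact hit whose counter argmax is the generating rule. On real
  data, where the "true context width" is unknown and codes are not a hash,
  longer windows carry real signal and the full depth is appropriate; the
  cap is a property of hash-generated ground truth, not of the method.
- **Noise experiments score against the noise-free truth**
  (`keep_truth = TRUE`). Scoring a memorizing predictor against the
  corrupted training codes would report 100% at any noise rate.

## Numerical choices

- **Projection.** `project_to_path()` scans a dense grid of path points
  (3600 by default) and refines the best candidate with a fixed-iteration
  golden-section search. `stats::optimize()` is not used because its
  internal tolerance floor (√machine-epsilon on the argument) leaves
  ~10⁻⁶-scale jitter in `t`, which breaks projection idempotence —
  re-projecting a point already on the path should return the same `t` to
  well below 10⁻⁶. Sixty golden-section iterations cost little and converge
  to machine precision.
- **Tie-breaking is alphabetical everywhere.** Counter argmax
  (`best_class()`), nearest-maximum assignment, and the contingency baseline
  all resolve ties toward the alphabetically earliest code, so results are
  reproducible across platforms and hash orderings.
- **One-mismatch aggregation sums counters over all Hamming-1 hits** rather
  than, say, taking the best single hit. Summation uses all available
  evidence and keeps the operation order-independent.
- **Deterministic serialization.** Dictionary keys are radix-sorted and the
  file format carries a content digest rather than a timestamp, so the same
  corpus yields byte-identical dictionary files in any record order — a
  property the test suite checks and downstream caching can rely on.
- **Aggregation over chains is unweighted.** Total accuracy is the
  arithmetic mean of per-chain accuracies, not a residue-weighted pool, so
  short chains count as much as long ones; per-class totals follow the same
  convention, with classes absent from a chain contributing 0% (reports
  retain an "absent" marker because that convention understates per-class
  accuracy when a class is rare).

## Limitations

- The default path and maxima are placeholders; absolute encodings of real
  structures are only as meaningful as the configured path.
- The predictor is a frequency dictionary: it has no notion of long-range
  interactions, and with small training sets its one-mismatch stage can be
  noise-dominated (see the depth discussion above).
- Interaction flags serialize one letter per residue with priority
  ligand > protein > nucleic; a residue in contact with several categories
  is lossy in the text format (the in-memory table keeps all three).
- DSSP input is consumed as pre-computed class strings; the package does not
  compute DSSP assignments from coordinates.
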