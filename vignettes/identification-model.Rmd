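---
title: "Profile-HMM identification of proteins from probabilistic sequencer readouts"
author: "proseqid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-HMM identification of proteins from probabilistic sequencer readouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proseqid)
```

## The problem

Early single-molecule protein sequencers are unlikely to read all twenty
amino acids reliably. Whether the physics is nanopore translocation,
fluorescent labelling with Edman cycles, or Raman scattering, the realistic
output of the decoding stage is not a sequence but a *probabilistic
readout*: for each position of the molecule, a posterior probability
distribution over the 20 amino acids. The practical question is then not
*de novo* sequencing but **identification** — given one noisy readout (or a
few fragments), which protein in a known database did it come from?

`proseqid` implements both halves of this problem:

1. a configurable **device simulator** that turns a protein (or fragment)
   into a 20 × L posterior matrix under a chosen signal quality, detectable
   amino-acid subset, and insertion/deletion error process, and
2. an **identification engine** that converts a readout into a profile
   hidden Markov model (HMM) and scores every database sequence with
   Forward (or Viterbi) log-odds dynamic programming, inferring the
   originating protein as the top-scoring hit.

## The device model

The simulator has deliberately few degrees of freedom:

* **`pMax`** — the posterior assigned to the correct amino acid at each
  position, constant along the molecule. The remaining `1 - pMax` is spread
  equally over the 19 incorrect residues. `pMax = 1` is a perfect reader;
  `pMax = 0.05 = 1/20` is the fully unresolved limit where the column is
  exactly flat.
* **detection set** — the subset of amino acids the device can discriminate
  at all (e.g. `"LSEAG"` for a five-dye labelling chemistry). A residue
  outside the set yields the flat 1/20 column: observing it carries no
  information.
* **fragments** — `sampleFragments()` draws fixed-length windows uniformly
  over the valid start range, independently and with replacement; proteins
  shorter than the window contribute their full sequence.
* **indel errors** — *exact-count* rates, not per-position coin flips: a
  readout of pre-error length L loses `round(d·L)` columns at distinct
  uniform positions and then gains `round(i·L)` spurious columns at uniform
  gap positions (with replacement). Deletions are applied first so an
  inserted column can never be deleted again. Each inserted column is the
  device posterior of an amino acid drawn uniformly from the twenty — a
  spurious but *plausible-looking* decoded position, which is the worst
  case for the search. Rounding is half away from zero.

All error positions are uniform and `pMax` is constant: real devices will
have position-dependent signal quality (translocation speed depends on the
local physics), which this model intentionally does not attempt.

## The identification model

A readout of L′ columns becomes a profile HMM with one match state per
column; the posteriors are used verbatim as match emissions. Insert states
emit the database background frequencies; the null model emits residues
i.i.d. from the same background, so insert emissions cancel in the log-odds
score. Transitions are position-independent:

| transition | probability |
|---|---|
| match → match | 0.8 |
| match → insert | 0.1 |
| match → delete | 0.1 |
| insert → match / insert → insert | 0.9 / 0.1 |
| delete → match / delete → delete | 0.9 / 0.1 |

The 0.8/0.1/0.1 triplet keeps the model strongly diagonal while tolerating
indels; the 0.9/0.1 continuation values are conventional profile-search
defaults. All seven are configurable through `ProfileParams()` — if the
error rates of a real device were known, the match transitions should be
re-derived from them.

**Alignment mode.** The default is *glocal over the query, local over the
target*: the readout is one complete sequenced molecule, so every one of
its columns must be matched or deleted (entry is Begin → M1 with
probability 1, exit from the final match or delete state), while the
fragment may sit anywhere inside a longer target protein — flanking target
residues are absorbed at background frequency and zero log-odds cost, so
scores are comparable across targets of different lengths. A
`"local-query/local-target"` mode (uniform entry/exit over match-state
pairs, as conventional local search engines use) is available in
`buildProfile()`; its role is discussed below.

Scores are reported in bits:
`log2 P(target | profile) / P(target | null)`. The Forward score sums over
all alignments and is the ranking score; Viterbi (best single alignment) is
available and is never larger. The dynamic programming runs in odds space
with power-of-two rescaling per target column; zero-probability emissions
(`pMax = 1`) propagate as exact zeros rather than being smoothed, because
smoothing would silently change the perfect-device semantics. Cells more
than ~290 orders of magnitude below the working scale are flushed to zero
(far below any contribution that could affect a sum or a max, and it keeps
the recursion out of subnormal arithmetic). Restart paths more than ~2^1000
below the running scale are likewise dropped. `bruteForceScore()`
enumerates every legal state path on tiny instances (≤ 5 match states,
target ≤ 6) and is the independent oracle the test suite holds the DP to,
at an absolute tolerance of 10⁻⁹ bits.

**Identification.** `scoreDatabase()` scores every record,
`inferProtein()` takes the arg-max with a deterministic tie-break
(lexicographically smallest accession) and flags ties; a tie resolved away
from the truth counts as incorrect, so reported accuracies are
conservative. For multiple fragments of the same molecule,
`combineFragments()` sums each target's bit scores across fragments before
the arg-max — no per-fragment normalisation, matching how summed search
scores behave.

## The synthetic database generator

`generateDatabase()` draws i.i.d. sequences from a background frequency
vector; the bundled `humanLikeBackground()` preset is a fixed 20-vector
with the abundance ordering characteristic of the human proteome (L, S, E,
A, G most frequent; W, M, C, H, Y least). Lengths can be fixed, uniform in
a range, or log-normal with median 411 residues — the median of a typical
curated human proteome — with log-sd 0.75. Accessions are `SYN000001…` and
generation is byte-reproducible for a fixed seed.

What the generator deliberately does **not** model is homology: real
proteomes contain families, repeats and shared domains, which are the main
source of confusions for fingerprint-style identification at the
20 000-protein scale. Identification on an i.i.d. database of a few
hundred sequences is therefore *easier* than on a real proteome, and test
accuracies here are upper bounds on real-data behaviour. Two consequences
show up in the benchmark suite and are worth stating plainly:

* very short fragments (5 residues) identify most proteins in a
  300-sequence i.i.d. database because a given 5-mer is usually unique
  there (expected number of other carriers ≈ 0.05), whereas in a
  20 000-protein proteome hundreds of proteins share it and accuracy falls
  to chance;
* the fine ordering between two weak detection sets (`CYK` vs `WMCHY`)
  does not resolve on a small easy database where both saturate near
  accuracy 1; only the robust contrast (`LSEAG` far ahead of both) is
  reproducible at this scale.

## Curation semantics

`curateDb()` removes records whose length is strictly above the requested
percentile of the length distribution (linear-interpolation percentile,
`quantile(..., type = 7)`, the common statistical default) — the usual
pruning of extreme outliers such as titin (34 350 residues) before large
benchmarks. Curation is *declarative*: the percentile is recorded on the
object and re-curation at the same percentile is a no-op. This matters
because re-applying an interpolated percentile to an already-truncated
distribution would keep shaving the longest records on every call, which
is never the intent of "curate at the 99th percentile".

Nonstandard residues follow a fixed mapping policy: U (selenocysteine) → C
and O (pyrrolysine) → K, their canonical structural analogues; records
containing any other non-canonical letter (B, Z, J, X, …) are dropped and
counted, since an ambiguity code cannot be scored against a 20-letter
emission model.

## Benchmarking and problem sizes

`runCondition()` evaluates one experimental condition over a whole
database (per-protein RNG substreams are derived from the condition seed
and the accession, so results are independent of iteration order and
parallelisation), and `runSweep()` runs a Cartesian grid with per-condition
TSV persistence and resume-on-rerun. Accuracy is the fraction of proteins
whose top hit equals the source; confidence intervals are percentile
bootstrap over proteins (1000 resamples by default).

The bundled benchmark suite uses synthetic databases of 200–500 sequences
with lengths 80–400 (uniform), chosen so the full suite — several hundred
thousand profile-vs-target Forward alignments — completes in minutes on a
single core while still separating the regimes of interest: the sharp
chance-to-perfect transition in `pMax` around 0.05–0.2, the fragment-length
ladder at `pMax` 0.8, the detection-set contrast, and the indel breakdown.

## Error robustness and the choice of alignment mode

The two alignment modes answer different questions under heavy indel
noise. The glocal query *knows* the readout is complete, and threading all
columns through a target recovers the 40 % of genuine signal left even at
60 %/60 % insertion/deletion rates — identification barely degrades on a
small i.i.d. database (accuracy ≈ 0.96 at n = 200). A local-query search,
like conventional search engines perform, may score only the
best-supported island of the alignment; under the same 60 %/60 % noise it
collapses (accuracy ≈ 0.2–0.3), while remaining perfect through 30 %/30 %.
The error-robustness benchmark therefore reports the local-query mode as
the faithful analogue of engine-based searching — whose characteristic
breakdown between 30 % and 60 % it reproduces — alongside the more
forgiving glocal default. For a real instrument the glocal mode is the
right choice whenever whole-molecule readouts can be guaranteed; the
comparison quantifies how much that guarantee buys.

## Interoperability

`writeHmmer3Profile()` exports any readout profile in the `HMMER3/f` ASCII
dialect (emissions as negative natural logs, `*` for probability zero, the
glocal entry/exit encoded in the node-0 and final-node transition lines),
so an external `hmmsearch --max` can consume the same query. The export
exists for cross-validation — the package's own engine does the ranking —
and the statistics lines carry nominal calibration values only (E-values
from the export are not meaningful; bit-score ranking is).

## Worked example

```{r example}
db <- generateDatabase(n = 50, lengths = c(80, 200), seed = 7)
truth <- accessions(db)[10]
device <- DeviceConfig(pMax = 0.8, detectionSet = "LSEAG")
ro <- simulateReadout(as.character(sequences(db))[10], device,
                      errors = ErrorModel(0.1, 0.1), seed = 7,
                      sourceAccession = truth)
hmm <- buildProfile(ro, ProfileParams(background = background(db)))
res <- inferProtein(scoreDatabase(hmm, db), truth = truth)
head(res$rankedHits, 3)
res$correct
```

## Known limitations

* No homology structure in the synthetic generator (see above); results on
  i.i.d. databases overstate real-proteome accuracy, increasingly so the
  weaker the fingerprint.
* Constant `pMax` and uniform error placement; no position-dependent
  signal model.
* No open-set rejection: every readout is assigned its best hit, with no
  E-value or bit-score threshold for contaminant peptides.
* Score ranking uses full-sequence Forward bits; no multi-hit (repeat
  domain) architecture.
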