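---
title: "Tiled exact-match profiling of short-read libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiled exact-match profiling of short-read libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readtiler)
```

## The reverse-mapping model

Conventional short-read analysis maps every read of a library to a
reference genome and asks, for a region of interest, how many alignments
fall on it. readtiler inverts that: the *library* is indexed once with a
suffix array over the concatenation of its reads, and a query sequence is
then mapped *against the library*. A query of length $n$ is decomposed
into all $n - k + 1$ substrings of length $k$ (tiles, step 1), each tile
is counted in the index by binary search over the sorted suffixes, and the
count of the tile starting at position $i$ is recorded as $N_i$. Two views
summarise the result:

* **starts**: the vector $N_i$, $i = 1, \dots, n-k+1$;
* **coverage**: $C_j = \sum_{i \,:\, i \le j \le i+k-1} N_i$, the sum of the
  counts of every tile overlapping position $j$.

Each tile contributes its count to exactly $k$ positions, so
$\sum_j C_j = k \sum_i N_i$ always; with $k = 1$ the two views coincide.
These invariants are exercised continuously in the test suite.

Counts are *occurrence* counts: a tile occurring twice in one read counts
twice, and duplicate reads each contribute (multiplicity encodes
abundance). This matches "how many times does the tile occur in the
dataset"; a per-read containment count would differ only for tiles
repeated within a read and is not implemented.

### The tile size

$k$ is deliberately a required parameter with no default: it is the user's
central control. Small tiles match short fragments of the query by chance
(high sensitivity, low specificity); large tiles demand long exact matches
(the reverse). Two consequences are sharp enough to test: at a fixed start
position the hit count is non-increasing in $k$ (a $(k{+}1)$-tile contains
the $k$-tile), and once $k$ exceeds the longest read in the library every
count is zero. For sRNA-seq libraries, whose inserts are bounded by the
~22 nt mature miRNA length, the all-zero transition happens at $k = 23$.

### Alphabet, case, strand

Reads and queries live over \{A,C,G,T,N\}. Input is uppercased and U is
transliterated to T, so RNA-alphabet miRBase precursors query DNA reads
directly. `N` is a literal fifth symbol — the method is exact-match, and
wildcard semantics would change the contract; `drop_n` (indexing) and
`skip_n` (querying, which marks N-tiles "not evaluated" with `NA`) are
provided instead. Queries run against reads as stored; `revcomp = TRUE`
additionally counts each tile's reverse complement into a separate vector,
never silently summed, since sRNA-seq libraries are conventionally
sense-stranded and the choice should stay visible.

### The index

Reads are joined with a separator sentinel (`#`) plus a distinct terminal
sentinel (`!`), both outside the read alphabet, so no pattern over the
alphabet can match across a read boundary. The suffix array is built by
prefix doubling ($O(n \log n)$) in compiled code; counting a pattern is two
binary searches ($O(m \log n)$ for a pattern of length $m$). Persistence
(`.rtidx`) is a little-endian binary layout — magic bytes, format version,
library id, alphabet, text, suffix order — and loading validates magic,
version, lengths and that the suffix order is a permutation, erroring on
any mismatch rather than risking silent misreads.

Coordinates are 1-based inclusive throughout the R API, the R/Bioconductor
interval convention; 0-based half-open coordinates appear only where a
format demands them (bedGraph), and the profile TSV carries both
conventions in labelled `pos0`/`pos1` columns so downstream consumers can
pick either without arithmetic.

## The miRNA layer

A pre-miRNA hairpin is processed to an ~22 nt duplex; the *mature* strand
is biologically active, the *star* strand typically degraded. In an
sRNA-seq library a genuine miRNA therefore shows a two-block profile:
nearly all tile hits start inside the mature interval, a smaller block
inside the star interval, and almost nothing elsewhere. `arm_sums()` pools
the starts vector by arm — a tile belongs to an arm iff its *start
position* lies inside the arm's interval, because $N_i$ is indexed by tile
starts; whole-tile containment would silently shrink every arm by $k-1$.
One edge effect follows and is documented rather than corrected: positions
within $k-1$ of the precursor 3' end have no tile start, so a 3' arm
contributes $k-1$ fewer terms than its nominal length.

With $N_m$ (mature sum), $N_s$ (star sum) and total $\sum_i N_i$ over all
tile starts, the mis-annotation screen flags a precursor when

$$ N_m + N_s < 0.95 \times \sum_i N_i $$

with strict inequality, evaluated at tile size 20 by default. A flagged,
spread-out, tRNA/snoRNA-like profile is evidence the annotation may
describe some other non-coding RNA; downstream confirmation (genomic
context, fold structure, snoRNA prediction) is out of scope and the tool
emits only the flag and the profile. A zero-total precursor is reported
*indeterminate* (`NA`), never flagged: absence of expression is not
evidence of mis-annotation. The threshold comparison is exact at
representable shares — the decision boundary recovered by bisection over
integer arm counts sits at exactly 95%, with 95.00% itself unflagged.

`mirna_summary()` applies this per precursor against one library (rows
sorted by total hits, ties broken by id; precursors shorter than $k$ are
reported `evaluated = FALSE` rather than erroring), and
`libraries_expressing()` inverts the question, listing libraries whose
mature-arm sum reaches `min_hits`. "Expressed" has no canonical hit count,
so `min_hits` is an explicit parameter defaulting to 1.

## What the synthetic generator emulates

`planted_spec()`/`generate_library()` produce libraries with *analytically
known* profiles. For each planted interval, the library receives `copies`
exact copies of every `read_length`-mer lying fully inside the interval
("clipped so reads fit": an interval exactly one read long yields exactly
one distinct read). On a reference whose $k$-mers are all distinct
(`random_reference(unique_k = ...)` rejects and resamples until so), a
planted read of length $L$ at start $s$ contains the $k$-tile at $i$ iff
$s \le i \le s + L - k$, giving the closed form in `planted_truth()`.
Background reads are drawn from an independent random sequence and
resampled until they share no `guard_k`-mer (default 12) with the
reference, so exact-recovery guarantees hold for
$\text{guard\_k} \le k \le L$. The defaults mirror sRNA-seq: read lengths
18–28 nt, precursor-scale references, mature/star arms of 22 nt.

`mirna_fixture()` packages the two study patterns: *canonical* (reads only
from the arms; mature planted at 50 copies, star at 10, the usual
asymmetry) and *uniform* (reads tiled evenly across the whole hairpin at 2
copies — arm fraction ≈ 0.65 at $k = 20$, well below threshold). The
canonical fixture is never flagged, the uniform one always.

Deliberate simplifications: reads are error-free (the method is
exact-match, so sequencing errors only dilute counts; an optional
per-base substitution rate exists for robustness demonstrations but is
excluded from exact-recovery checks), abundances are uniform per planted
position rather than Dirichlet-distributed, and there is no adapter
contamination. Passing tests therefore demonstrate correctness of the
counting, tiling and flagging machinery — not robustness to real-library
noise, which exact matching handles only by losing the erroneous reads.

## Numerical and design choices

* **Problem sizes.** Validation uses libraries of tens of reads and
  references of ≤ 300 nt: the oracle-equivalence suite checks 1,000
  random (library, pattern) instances against a naive per-read scan, the
  conservation suite 200 random profiles, planted recovery 50 random
  specs at every admissible tile size. These sizes make every check exact
  and exhaustive at small scale; the index itself is the same code path at
  any scale.
* **Determinism.** Every stochastic component is seed-parameterised
  (`withr::with_seed`, so the session RNG is untouched); identical
  configurations produce byte-identical outputs.
* **Ties.** Summary rows sort by total descending then id ascending;
  library listings by mature hits descending then library id — stable,
  documented tie-breaks.
* **Degenerate inputs.** Empty libraries and empty patterns are errors
  (the simulator may *represent* an empty library, but it cannot be
  indexed); a precursor shorter than the tile size yields a
  "not-evaluated" row; a zero-total assessment is indeterminate.
* **Catalog vocabulary.** Experiment type is a closed set (Genomic DNA,
  ChIP-Seq, RNA-Seq, sRNA-Seq) enforced at load; tissue is free text with
  exact case-insensitive matching by default and opt-in substring
  matching, since tissue names are an open vocabulary.

## Limitations

Exact matching only: no mismatches, gaps or quality-aware alignment —
sensitivity is tuned solely through the tile size. Occurrence counts are
not normalised for library depth; cross-library comparisons should divide
by library size. The mis-annotation flag is a screen, not a verdict: the
confirmatory analyses that would settle a flagged case are intentionally
outside this package. Indexes hold the full concatenated text plus one
integer per character in memory, which is generous for the queries this
tool targets (genes, precursors, small libraries) but not engineered for
multi-gigabase corpora.

## A worked example

```{r example}
fx <- mirna_fixture("canonical", seed = 42)
idx <- build_index(fx$library)
prof <- tile_query(idx, fx$record$precursor, k = 20,
                   query_id = fx$record$mirna_id)
assess_annotation(prof, fx$record)

uni <- mirna_fixture("uniform", seed = 42)
assess_annotation(tile_query(build_index(uni$library),
                             uni$record$precursor, 20),
                  uni$record)
```
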