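---
title: "Tracing the taxonomic origins of small RNA sequencing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing the taxonomic origins of small RNA sequencing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladetrace)
```

## The method

MicroRNA families arise continuously over evolutionary time and are almost
never secondarily lost, so every major animal and plant clade owns a set of
mature miRNAs found nowhere else. A sequencing read that carries one of
these clade-specific sequences is direct evidence that material from that
clade is present in the library — a presence/absence signal that, unlike
barcoding loci, is not eroded by back-mutations or sequencing errors in
other genes. cladetrace implements this idea as a complete small-RNA-seq
toolchain: pre-processing, RNA-type annotation, clade (or species) tracing,
QC flagging, and post-sequencing removal of index-misassignment
contamination.

### Pre-processing

Raw reads pass through a fixed sequence of rules:

1. **UMI trimming** (`umi_prefix_len`, default 0). Protocols that prepend
   unique molecular identifiers have them stripped first, before any other
   step, since the UMI bases are not part of the biological insert.
2. **Truncation** to 50 nt. Mature miRNAs are ~22 nt; anything beyond 50 nt
   is adapter or filler.
3. **Quality filter**: a read is discarded when *more than* 50% of its
   bases have PHRED < 20 (exactly half still passes; the wording is
   strict).
4. **Adapter trimming**, protocol-specific:
   * *TruSeq/QiaSeq*: the read is searched for the first 8-mer of the 3'
     adapter; the **last** occurrence and everything after it are removed.
     If the 8-mer is absent, the longest read suffix equal to an adapter
     prefix (7 down to 1 nt) is removed, and the read counts as
     "adapter unrecognized".
   * *NEXTflex*: 4 randomized bases flank the insert on both sides — the 4
     leading bases are cut, the adapter trimmed as above, and 4 trailing
     bases removed when the adapter was found.
   * *CATS*: 3 template-switch bases are cut and the left-most poly-A
     8-mer marks the tail; shorter trailing poly-A runs (7 down to a single
     A) are trimmed when no 8-mer occurs.
5. **Insert filters**, applied to the final insert in this order: any
   non-ACGT symbol (`ambiguous_nt`); tandem repeats of a 1–3-nt motif
   (`low_complexity`); length < 18 nt (`too_short`).

Reads surviving all filters are *QC-passed*, in two flavours:
`qc_passed_adapter_found` and `qc_passed_adapter_unrecognized`. The
category counts always partition the input exactly — this conservation
identity is asserted in the test suite.

Two details were genuinely open and are this package's own decisions. The
low-complexity rule is concretized as "tandem repetition of a motif of
length 1–3, repeated at least twice, truncated final unit allowed"; the
repeat-at-least-twice clause keeps zero-length adapter-dimer inserts in the
`too_short` category where they are diagnostically useful. And reads
shorter than 18 nt are discarded as `too_short` whether or not an adapter
was found, since a sub-18-nt insert is unusable either way.

### RNA-type annotation

Each QC-passed insert is matched as an ungapped substring (no indels — the
simplest consistent reading of the mismatch rules, and the one an
independent oracle can verify) against ordered reference collections:
miRNA precursors, then tRNA, then rRNA, first demanding 0 mismatches in
all three collections, then repeating the cascade allowing 1 substitution.
The first collection to hit wins; pass 1 completes before pass 2 starts,
so an exact rRNA hit beats a 1-mismatch precursor hit. Reads that survive
both passes are compared against sequencing-artifact sequences, matching
when read and artifact share at least one 18-nt stretch of identity;
everything else is `unknown`. Ties inside a collection resolve to the
lexicographically smallest reference ID, keeping classification a pure
function of insert and database.

Sample complexity is tracked as the cumulative number of distinct miRNA
precursors versus sequencing depth, where depth counts processed *raw*
reads. Checkpoints default to every 10,000 reads — a plotting granularity,
not a semantic choice.

### Clade and species tracing

The marker catalog maps curated clade-specific family numbers to clades.
Mature sequences are admitted when their miRBase-style ID parses to a
listed family (`hsa-miR-580-5p` → family 580; `let-7` lives in its own
namespace, distinct from miR-7). In **clade mode** every 20-nt window of
every admitted sequence is indexed; in **species mode** only the first
20 nt, so species assignment is strictly prefix-to-prefix. A read is
clade-specific when its *first 20 nt* exactly match an indexed 20-mer;
matching is strand-specific and allows no mismatches. The all-windows
reading for clade mode is deliberate: the published rule says only that
the first 20 nt must "have an exact match to a reference sequence", and
indexing all windows is the permissive reading; the prefix-only behaviour
remains available via species mode.

A 20-mer observed under two clades would break the marker logic, so such
k-mers are excluded at catalog build time and surfaced in an ambiguity
report, rather than multi-counted. Composition percentages use
clade-specific reads as the denominator, and foreign clades are reported
from a single read upward (`min_reads = 1`) — single-digit marker counts
are already meaningful.

The specificity of exact 20-mer matching is quantified by a binomial
model: a uniform-random read hits a `W`-key index with probability
`1 - (1 - 4^-20)^W`, so ten million random reads against a ~30,000-window
index yield an expected `r round(expected_spurious_matches(30000, 1e7), 3)`
spurious matches — below one, which the package confirms with a seeded
Monte-Carlo simulation (20-mers drawn as exact 40-bit integers under a
2-bit encoding, equivalent to random strings but fast enough for 10^7
draws).

### Cleaning index mis-assignment

Pooled libraries are demultiplexed by a sample index read in a dedicated
reaction. Two failure modes contaminate samples after the bench work is
done: *misreads* (sequencing errors in the index read) and *mis-pairings*
(a correctly read index attached to the wrong insert). Because short
inserts let the main read run through the 3' adapter into the index, the
index is read twice — and the second, inline copy exposes mis-pairings.

`demultiplex()` offers three regimes of increasing stringency: `mismatch1`
(assign within Hamming distance 1, the common demultiplexer default),
`strict` (perfect match only — removes misreads), and `strict_consistent`
(additionally reject reads whose readable inline index differs from the
sequencer index — removes mis-pairings). Retained sets are provably nested.
The inline comparison is exact, with `N` counting as a mismatch, and the
*entire* adapter must be present before any bases are trusted as inline
index, so insert bases are never misread as index. Reads whose inline
index is unreadable are retained by default (`assigned_unverifiable`):
they are mostly genuine long-insert reads, and rejecting them would trade
real signal for stringency; `drop_unverifiable = TRUE` enables the
aggressive variant.

## The synthetic-data generator

Every test and acceptance quantity in this package runs on synthetic data
with recorded ground truth; nothing is downloaded. The generator emulates:

* a **reference bundle** — clade catalog, mature markers realizing it,
  precursors embedding each mature in random flanks, tRNA/rRNA decoys, and
  artifact sequences containing the standard TruSeq adapter. Defaults (14
  clades × 24 families × 4 species ≈ 29,600 nt of markers) match the scale
  of the real curated catalog. Mature sequences are resampled until no
  20-mer is shared between any two, so catalog construction has zero
  ambiguity exclusions and error-free reads trace exactly — tests against
  this bundle measure the pipeline's bookkeeping, not marker curation.
* **reads** — insert + protocol decorations + index + filler, truncated to
  the 75-nt read length whose arithmetic (22 + 33 + 6 ≤ 75) keeps inline
  indices readable; substitution-only errors (matching the ungapped
  matching model); per-base Gaussian PHRED qualities drawn from a
  256-string pool per spec (statistically equivalent for histograms,
  much cheaper at 10^6 reads).
* **mixtures** — `spike_mix()` draws `round(fraction × total_n)`
  contaminant reads without replacement; note that 0.0001% of 10^6 reads
  is a single read, so sensitivity experiments must size `total_n` to the
  fraction grid.
* **multiplexed runs** — per-base index misreads and cross-sample
  mis-pairings applied at controlled rates, with the inline index left
  true under mis-pairing, exactly the physics the consistency filter
  exploits.

What the generator does *not* emulate: realistic Illumina error profiles
(errors are uniform substitutions), PCR duplicates, expression-abundance
skew between miRNAs, or incomplete/unbalanced marker annotation between
clades. Passing tests therefore demonstrate the correctness of the
algorithms under their stated models, not the field error rates of real
libraries; in real data, cross-clade abundance comparisons are known to be
skewed by unequal marker-set sizes, and this package (by design) does not
correct for that.

## Worked example

```{r example}
bundle <- generate_reference_bundle(seed = 7)
catalog <- build_clade_catalog(
  tibble::tibble(family_key = paste0("miR-", bundle$catalog$family_number),
                 clade = bundle$catalog$clade),
  bundle$mature
)
catalog

host <- generate_sample(synth_spec(50000, seed = 1), bundle, "rodent")
fly <- generate_sample(synth_spec(1000, seed = 2), bundle, "hexapoda")
mix <- spike_mix(host, fly, fraction = 0.001, total_n = 50000, seed = 3)

cfg <- sample_config("serum", adapter = TRUSEQ_ADAPTER,
                     expected_clade = "rodent")
pre <- preprocess_reads(mix$reads, cfg)
table(pre$status)

qc <- startsWith(pre$status, "qc_passed")
profile <- build_clade_profile(pre$insert[qc], catalog)
profile
detect_contamination(profile, "rodent")
```

## Numerical choices and problem sizes

* All thresholds surface in function arguments with the published values
  as defaults: 50-nt cap, Q20/50% quality rule, 18-nt minimum insert,
  8-mer adapter search key, 20-mer markers, 18-mer artifact stretches,
  10 RPM / 2-fold DE rules, and the three QC flag thresholds (25% of
  sequences in 20–25 nt, 10% miRNA content, 10% of known precursors), all
  with strict inequalities as printed.
* The insert-length histogram covers *all* adapter-trimmed reads, not only
  QC-passed ones, so zero-length bars (adapter dimers) and bars at the
  read cap (unrecognized adapters) remain visible; its total is input
  minus quality-discarded reads.
* Acceptance-scale runs use a million-read host sample for the spike-in
  threshold and 50,000 reads per clade across all 14 clades for assignment
  accuracy; the specificity fixture is sized to ≈30,000 indexed 20-mer
  windows (14 × 179 × 4 markers). These sizes keep every quantity
  computable on a laptop while preserving the quantities' meaning.
* R's vectorized string machinery processes whole files at once rather
  than streaming record-by-record; at the million-read scale used here
  this is the idiomatic and efficient choice.

## Limitations

Clade mode indexes all reference windows, so a read matching an internal
window of a marker counts as clade-specific; the prefix-only rule is
available via species mode when stricter anchoring is wanted. The cleaning
filter can only reject mis-pairings whose inline index is readable — reads
with long inserts are unverifiable by construction, which is why complete
cleaning of every sample cannot be guaranteed. Cross-clade composition
percentages are not corrected for marker-set size or expression differences
between clades.
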