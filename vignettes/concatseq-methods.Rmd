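---
title: "Concatemer amplicon sequencing: models and methods in concatseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concatemer amplicon sequencing: models and methods in concatseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concatseq)
```

## The library model

Single-molecule long-read platforms read one molecule per sequencing
unit, so loading them with ~200 bp amplicons wastes most of each
polymerase read.  Concatemer library preparation works around this:
every amplicon (the *target*, flanked by constant *spacers* introduced
in a first PCR round — together the *fragment*) receives one copy of a
shared 30 bp *adapter* on each end, and Gibson assembly then joins
these adapter-flanked *monomers* into long chains (*n-mers*) in random
order and random orientation, adjacent monomers merging their abutting
adapter copies into one.

Three identities follow from this geometry and drive everything in the
package:

* a monomer of fragment length $f$ and adapter length $y$ has length
  $x = f + 2y$ (`with_adapters()`);
* an n-mer has expected length $nx - (n-1)y$
  (`expected_nmer_length()`), equivalently $nf + (n+1)y$: $n$
  fragments and $n+1$ adapters;
* each unit beyond the first adds $x - y$ bases.

The default architecture (`architecture()`) is a 120 bp target, 67 bp
of spacer and a 30 bp adapter, i.e. $f = 187$, $x = 247$.  The spacer
total is a design constraint of the assay; its 33/34 split across the
two sides is a package default, configurable, because only the total
is constrained by the design.

The bundled adapter (`default_adapter()`) is 30 bp with GC fraction
exactly 0.40 and no homopolymer of length 5 — the design constraints
for an efficient Gibson overlap.  Adapter sequences are
laboratory-specific; the bundled one was
chosen (by constrained random search) to additionally lie at edit
distance 18 from its own reverse complement, so that forward and
reverse-complement occurrences are never confusable at the scanning
thresholds below.  The adapter is a required, configurable input
everywhere; nothing in the code depends on the bundled sequence.

`scaleup_factor()` implements the run-planning identity: if size
selection keeps a fraction $q$ of the library, $1/q$ times more input
mass is needed for the retained sub-population to match the original
amount.

## The simulator

`simulate_library()` emits consensus-level reads directly (it does not
model raw polymerase passes or consensus calling) together with a
*truth sidecar*: a table of adapter / fragment / remnant intervals
that tiles every error-free read exactly, plus per-unit amplicon,
orientation, applied variants, and artifact flags.  Every downstream
stage is validated against this sidecar.

A read is assembled as `adapter + unit + adapter + ... + adapter`.
Defaults, and why:

| parameter | default | rationale |
|---|---|---|
| `nmer` | truncated geometric, mean 5, max 50 | empirical unit-count distributions in this assay class are heavy-tailed with a mode at small n, chains up to ~50 units, and ~5 fragments per read on average; no generative law is published, so this is an explicit modelling choice |
| `orientation_prob` | 0.5 | units ligate in either orientation with no bias |
| `error_rates` | sub 0.006, ins 0.002, del 0.002 per base | ~1% total, matching circular-consensus accuracy at a handful of passes |
| `hairpin_remnant_prob` | 0.4 per read end | A-tailed ligation of the sequencing hairpin leaves a single A or T base outside the terminal adapter in a sizeable minority of reads |
| `end_truncation_prob` | 0.3 per end, uniform 1..29 retained bases | terminal adapters are frequently eroded, which is what produces the oversized terminal-fragment population |
| `hybrid_prob` | 0.005 per junction | adapter-free fusions (attributed to exonuclease chew-back joining regions of homology) occur at the few-per-thousand-fragments scale |

Hybrid junctions are simulated as a direct fusion at a random 5–20 bp
exact-homology overlap: the first bases of the right-hand unit are
treated as shared with the left-hand unit's tail, and the junction
adapter is omitted.  Units sharing a junction adapter may disagree in
orientation; the junction adapter copy takes the orientation of the
unit to its right (the trailing adapter that of the last unit).  This
convention is arbitrary — the two pools of complementary adapters make
either orientation observable at a junction — and nothing downstream
depends on it beyond seeing both orientations.

Randomness uses the single R stream, seeded once per library.  Draw
order per read: unit count; per unit in order (amplicon, orientation,
one Bernoulli per panel variant); per junction (hybrid flag, overlap
length); leading/trailing truncation; leading/trailing remnant;
sequencing errors.  Identical seeds give byte-identical FASTQ and
sidecar files.

What the generator does **not** emulate: quality-value realism
(constant Q30 placeholders; nothing consumes qualities), context-
dependent error profiles, chimeric reads from the instrument itself,
unequal per-amplicon PCR efficiency (available only through explicit
pool `weights`), and consensus-depth-dependent accuracy.  Passing
tests therefore demonstrate correctness of the algorithms under the
structural model, not performance on any particular instrument run.

## Deconcatenation

`scan_adapters()` slides a 30 bp window along each read and compares
it to the adapter and its reverse complement by unit-cost Levenshtein
distance (C++ kernel, capped DP with early abandon).  A window within
`max_edits = 4` qualifies; the relaxed rescan uses 6.  These are the
assay's standard tolerances for calling an adapter and for rescuing a
heavily eroded one.

Two refinements make the greedy scan exact on clean data:

* **Run-minimum placement.** A window shifted $s$ bases off a true
  adapter still matches within $2s$ edits, so the *first* qualifying
  position typically precedes the adapter by up to 2 bases at $k = 4$.
  Accepting it would shave bases off one neighbouring fragment and pad
  the other.  Instead, on entering a contiguous run of qualifying
  positions the hit is placed at the run's leftmost minimum-distance
  position (explored at most one window ahead).  On error-free reads
  the true position has distance 0 and is always chosen, which is what
  makes exact truth recovery possible; the test-suite oracle
  implements the same declared semantics independently (on
  `utils::adist`).
* **Scaled terminal windows.** When fewer than 30 bases remain, the
  remaining window (if at least 10 bases) is compared against the
  adapter *prefix* of matching length at the proportionally scaled
  threshold `ceiling(4 * len / 30)`, keeping per-base stringency
  constant.  An unscaled threshold of 4 on a 10-base window would
  accept a few percent of random sequence.  Below 10 bases a distance
  threshold is meaningless and the bases stay with the terminal
  fragment.

Hits are fixed-width windows even when the optimal alignment implies a
26–34 bp occupancy under indels; this keeps the partition property
exact (fragments + adapters tile each read), and the few-base slack is
absorbed by the classification band.  Forward wins orientation ties
(recorded in a `tie` column).  Coordinates are 0-based half-open
everywhere; only human-readable reports are 1-based.

## Fragment classification

Deconcatenated fragments fall into the populations the assay produces:
single-base remnants of hairpin-adapter ligation (removed by
`filter_short()` before alignment),
expected-size fragments, and oversized fragments carrying truncated
terminal adapters.  The expected-size band defaults to 181–190 bp for
the 187 bp design: the assay's descriptions give both 181–190 and
180–190; the package takes the former and leaves the band
configurable.

`detect_partial_adapter()` explains oversized *terminal* fragments: it
compares the fragment's outermost bases against adapter prefixes and
suffixes (both orientations, lengths 8..30) at the length-scaled
*relaxed* threshold `ceiling(6 * len / 30)`.  The relaxed bound is
used because the canonical case is an adapter eroded just past the
scanner's limit (5–6 edits).  Both prefixes and suffixes are tested
because either end of the adapter can survive depending on which side
was eroded.  Remnants shorter than 8 bases are undetectable in
principle (at scaled thresholds every short string matches), so
oversized fragments whose excess is below 8 bases remain unexplained —
a detection floor, not a bug.

## Alignment, hybrids, and allele frequencies

Fragments are aligned to the amplicon panel local-in-query (spacers
and any residual adapter bases soft-clip off; scoring +2/−3, gap
$5 + 2g$), in both orientations, against every amplicon.  The
alignment engine is `Biostrings::pairwiseAlignment()`; score ties are
resolved by its deterministic traceback rather than a bespoke rule —
adopting the engine's convention avoids re-implementing a DP for the
sake of a tie-break that no result in the package depends on.

An alignment *passes* at identity ≥ 0.8 over at least half the
reference; both thresholds are package choices, set so that error-free fragments always pass, uniform-random
187-mers essentially never do, and a fused unit missing up to 20 bp of
spacer still passes.  The best passing alignment is the *primary*
record; query flanks of ≥ 25 bases left uncovered are re-aligned
against the whole panel and passing flank alignments become
*secondary* records.  Re-aligning the uncovered remainder (rather than
keeping suboptimal whole-fragment alignments) is what lets fusions of
two copies of the *same* amplicon produce a secondary.  Role and
orientation encode bijectively as SAM flags 0/16/256/272.

`call_hybrids()` separates true fusions from eroded junction adapters:
for each multi-aligned fragment the query gap between neighbouring
aligned intervals is rescanned at 6 edits.  An adapter found there
means the fragment is *rescued* — re-split at the hit and re-mapped;
no adapter means a *hybrid* (units fused outside the adapter region).

`pileup()` counts bases per reference position from primary alignments
only, mapping query bases through the alignment path; insertions are
ignored and deletions counted in a `del` channel, the standard
contingency-table convention.  `extract_af()` reports alternate count
over depth at known variant positions; depth-0 positions are reported
with undefined frequency and a flag rather than dropped.
`amplicon_coverage()` normalises primary-alignment counts to
fractions.

Allele-frequency recovery is assessed on error-free simulations: the
estimator is then exactly binomial and its bias separable from the
error model.  With substitution errors on, a pileup-based estimator
acquires a bias of order the per-base substitution rate toward the
specific alternate base (~0.002 at default rates), which dominates at
the 1% frequency floor; correcting for it (e.g. background
subtraction) is out of scope.

## Run statistics

`degree_of_concatenation()` is fragments (after the 1 bp filter) per
read — the throughput multiplier; `on_target_rate()` is primary-
aligned fragments over fragments.  Reports print the degree to 2
decimals and rates as percentages to 1 decimal; machine-readable
output keeps full precision.  `build_run_stats()` cross-checks stage
outputs (alignments must reference known fragments, fragments known
reads) before summarising.

## Problem sizes and numerical choices

The test suite validates the statistical guarantees at sizes chosen to
make the relevant intervals tight while keeping the default run
comfortably interactive: round-trip identity on 1,000 mixed-size clean
reads; scanner–oracle equivalence on 500 planted reads up to 1 kb;
junction recovery and the length law at 1% error on 500 reads; allele
frequencies at 1%, 5%, 10% and 24.5% over 50 replicate libraries of
2,000 fragments (pooled exact-binomial 99% intervals); hybrid calling
on a 2,000-read library at the default per-junction rate.  Statistical
assertions use exact binomial (or pooled-binomial) 99% acceptance
intervals under fixed seeds; nothing is asserted to tolerances tighter
than those intervals.

## Known limitations

* Reads longer than the scan window but shorter than 10 bases are
  emitted unscanned as single fragments.
* The package calls substitution variants only; indel and structural
  calling, mapping-quality modelling and diploid genotyping are out of
  scope.
* Secondary-alignment discovery recurses through uncovered flanks at
  most six rounds; pathological many-way fusions beyond that are
  truncated.
* Interoperability with external aligners is not guaranteed; the SAM
  writer emits a minimal, valid subset (header, flags, soft-clip
  CIGARs) for inspection rather than as an exchange format.
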