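---
title: "Integrating and benchmarking deletion calls across callers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating and benchmarking deletion calls across callers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svunify)
```

## The problem

Deletion callers built on different signals have sharply size-dependent
accuracy. Assembly-based callers (GATK HaplotypeCaller and kin) resolve events
below ~100 bp at base-pair resolution but degrade quickly above that;
split-read callers (Pindel-style) dominate roughly 100 bp to 30 kb; read-pair
callers (BreakDancer, Delly) need discordant insert sizes and only become
reliable above ~1 kb. No single algorithm covers the whole spectrum, so a
practical pipeline runs several callers, keeps each one only where it is
trustworthy, and merges the survivors into one non-redundant call list. This
package implements that post-calling machinery — filtering, merging, and the
evaluation metric needed to calibrate both — together with a simulator and a
caller emulator so the whole stack can be exercised and tested with known
ground truth and no external binaries.

All coordinates are 0-based half-open (the BED convention). VCF's 1-based
inclusive coordinates, including the padding-base convention for
sequence-resolved deletions and `END`/`SVLEN` for symbolic `<DEL>` alleles,
are converted at the I/O boundary by `read_deletions_vcf()`.

## The evaluation metric

A called deletion rarely lands exactly on the true breakpoints: mapping
ambiguity at interspersed repeats and low-complexity sequence shifts calls by
a handful of base pairs. To avoid punishing such calls, each region — called
and prepared (truth) alike — is extended symmetrically by a fixed **margin**
(default 50 bp) into an *effective region*, and the match quality of a
(called, prepared) pair is the Jaccard index of the effective regions:

$$ q_{ij} = \frac{|a_i \cap b_j|}{|a_i \cup b_j|} \in [0, 1] $$

where $a_i$ and $b_j$ are the effective regions of called and prepared SVs.
A 1-bp call placed 10 bp from a 1-bp truth has 101-bp effective regions
overlapping in 91 bp of their 111-bp union, so $q = 91/111 \approx 0.82$:

```{r quality}
call_quality(deletion_calls("chr1", 110, 111, "HC"),
             truth_records("chr1", 100, 101, "DEL"), margin = 50)
```

The margin matters exactly where it should: for large deletions its effect
vanishes (at 100 kb the difference between margin 50 and margin 0 is below
0.01), so it rescues small, slightly shifted calls without inflating scores
for large ones.

Per size bin $s$, **precision** is the mean over called deletions of size in
$s$ of each call's best quality against *any* prepared deletion, and
**recall** is the mirror image over prepared deletions; the **F-measure** is
their harmonic mean. Matching is deliberately independent per call — one truth
may be the best match of several calls — exactly as the per-size formulas
state; no assignment problem is solved. Internally the per-call maximum is
found with an interval index over effective regions (IRanges): a truth whose
effective region does not intersect the call's cannot score above 0, so the
index loses nothing and replaces the all-pairs scan; the test suite verifies
equivalence against a brute-force position-set oracle.

Bins with no calls (or no truths) report `NA` precision (recall), not 0, so
curves are only drawn where data exist. The default bin edges are log10-spaced
(1, 10, ..., 10^6 bp); the exact binning used in any published figure is a
free choice, so the scheme is fully configurable via `size_bins()`.

## Filtering and merging

`filter_calls()` keeps each caller's calls only inside its configured size
range (inclusive bounds). The defaults — HC 1–100 bp, Pindel 100–30,000 bp,
BD 1,000–1,000,000 bp — are the ranges over which these caller archetypes keep
precision above 90% in simulation; they are starting points, not constants,
and any serious use should re-derive them from `evaluate_deletions()` on a
simulation matched to the data at hand.

`merge_callsets()` pools the filtered sets and removes duplicates: whenever
two calls overlap each other by **strictly more than** a fraction (default
2/3) of *both* called regions, the one whose caller has the lower per-size
precision prior is dropped. Design choices worth stating:

* **Reciprocity.** "Overlap each other by more than two thirds of their
  regions" is read as reciprocal — both fractions must exceed the threshold —
  matching the BEDTools reciprocal-overlap idiom; an `"either"` mode is
  available in `merge_config()` for the looser reading.
* **Determinism.** The pairwise rule alone does not fix which pair is
  resolved first. Candidate pairs are processed in decreasing order of
  overlap size, then by canonical coordinates; precision ties fall to a
  configured caller priority (default HC > Pindel > BD, the smaller-size
  specialist winning), then smaller start, then larger size. Pooled calls are
  canonically sorted first, so the result is invariant to input order. The
  tests assert idempotence, order-invariance, and equivalence with a
  one-removal-at-a-time fixed-point oracle.
* **No coordinate adjustment.** The surviving call keeps its own breakpoints;
  duplicates are removed, never averaged.

Output is an "extended BED": contig, start, end, caller, precision prior
(3 decimals), size, ploidy.

## The simulator

`inject_svs()` plants non-overlapping deletions and insertions at uniformly
random positions (rejection sampling with a 1-bp guard, avoiding contig
boundaries and N runs), recording truth in *reference* coordinates — the
space in which mapped calls are evaluated. Insertions occupy a single anchor
base and carry a random A/C/G/T payload (whether real insertions should reuse
donor sequence is unspecified in the protocols this emulates; random sequence
is used and flagged here). Only one haplotype is simulated: all SVs are
effectively homozygous, and heterozygous calling is out of scope.

`simulate_reads()` emits `round(depth * L / (2 * read_length))` pairs:
fragment lengths from Normal(350, 50) rounded and redrawn while below two
read lengths, starts uniform per contig, FR orientation, and a 0.1% per-base
substitution-to-a-different-base error by default. Note one numerical
consequence of the redraw rule: the realised insert distribution is a
truncated normal, with mean 350.22 and sd 49.67 rather than 350/50 exactly;
at 150,000 pairs the sd shift is ~3.7 standard errors, so the test suite
checks empirical moments against the truncated-normal closed form. Base
qualities are constant (no quality model), there are no indel errors or PCR
duplicates, and reads are emitted for an *external* mapper — nothing in this
package consumes alignments.

The default SV size spectrum (`default_size_sampler()`) is a declared
synthetic stand-in for the empirical size histograms of population-scale
studies: log-uniform over 1–10^6 bp with excess mass at ~300 bp (Alu) and
~6 kb (LINE), 30% of the mass in the peaks. Real size tables plug in through
`empirical_size_sampler()`.

## The caller emulator

`emulate_calls()` is the test fixture that stands in for real callers: each
true deletion is emitted with a per-bin recall probability, start and size
optionally jittered by rounded Gaussians, and per-bin false positives are
placed as a Poisson process with within-bin uniform sizes. Drawing FP sizes
within-bin makes per-bin precision directly controllable, so a test can target
any point of a precision/recall-versus-size curve. Feeding zero-jitter,
zero-FP, recall-$p$ emulated calls through the metric stack must return
precision 1 and recall $\approx p$ per bin — the parameter-recovery test that
validates the whole pipeline. The emulator does not model mapping artifacts or
repeat-context-dependent errors; passing tests demonstrate the *integration
machinery* is correct, not that any real caller achieves these numbers on
real data.

## Scale of the bundled checks

The test suite runs everything at desk scale, chosen so the full suite
completes in minutes on one CPU: parameter recovery uses a 5-Mb genome with
500 deletions up to 10 kb (larger sizes cannot fit 500 events into 5 Mb);
read-model checks use a 1-Mb genome at 30x (150,000 pairs); the
depth-series check emulates noise scaling as 5/depth over ~600 truths per
bin on a coordinate-only virtual contig. Whole-genome, real-caller
benchmarking is exactly what this package replaces with emulation and is out
of scope, as are SV types other than deletions in evaluation and merging
(the simulator does inject insertions, but they are excluded from the
deletion metrics), genotype concordance, and breakpoint refinement.

## Reproducibility

Every random stage takes a seed; `run_end_to_end()` derives per-stage seeds
from one global seed salted with the stage name, so adding a stage never
shifts another stage's stream, and each run writes a JSON manifest with the
config snapshot, seeds, and output checksums. Identical config + seed yields
byte-identical outputs.
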