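---
title: "Transposon paleontology with tepaleo: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transposon paleontology with tepaleo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tepaleo)
```

# The problem

Tc1-mariner DNA transposons are ~1.3-kb Class II elements bounded by ~28-bp
terminal inverted repeats (TIRs) and flanked, after insertion, by a
duplicated TA target site. Over time a family decays: copies accumulate
substitutions, the transposase open reading frame (ORF) breaks, and
internally deleted but TIR-bearing derivatives (MITEs, typically 500-600
bp) can amplify to thousands of copies in trans. Because every copy is a
fossil of the element that inserted it, the copy set of a genome records
*when* the family arrived and amplified; and because a transposon acquired
by horizontal transfer has had less time to diverge between two host
species than the hosts' own genes, comparing element divergence with
host-gene divergence diagnoses *how* it arrived.

`tepaleo` implements that whole chain on plain FASTA input: mine copies of
a query consensus from an assembly, annotate their structure (TIRs, TSD,
ORFs), reconstruct a per-species majority consensus, convert copy-to-
consensus divergence into insertion ages, and test for horizontal transfer
against a distribution of single-copy ortholog divergences. A simulator
with known ground truth makes every stage testable end to end without any
external data.

# Models and procedures

## Sequence evolution and the K2P distance

Divergence is measured with the Kimura two-parameter (K2P) distance. With
`P` the fraction of transitions and `Q` the fraction of transversions over
usable sites,

$$ d = -\tfrac{1}{2}\ln\bigl((1 - 2P - Q)\sqrt{1 - 2Q}\bigr). $$

Sites where either sequence carries a gap or an ambiguous base are excluded
(pairwise deletion, as in EMBOSS distmat). This matters for MITE-bearing
families: complete deletion would discard most of the alignment wherever a
single internally deleted copy is present. When the logarithm's argument is
non-positive the distance is *saturated*; `k2p()` reports `status =
"saturated"` with `k = NA` rather than a silent `NaN`, and downstream
tables flag such copies instead of dropping them.

The simulator (`evolve_sequence()`) is the exact generative inverse of this
estimator: each site substitutes with the closed-form K2P probabilities for
the requested expected divergence and transition/transversion rate ratio
`kappa` (default 2). Applying `k2p()` to a simulated pair therefore
recovers the requested divergence without bias, which the test suite checks
to within three binomial standard errors up to `d = 0.3`.

## Dating: T = k / (2r)

A copy inserted `T` My ago and the (reconstructed) ancestral consensus have
each evolved independently for `T` My, so their expected divergence is
`k = 2 r T` for a neutral substitution rate `r` (substitutions/site/My).
`age_from_divergence()` inverts this, and `plant_copies()` applies the same
convention generatively (a planted copy of age `T` receives expected
divergence `2 r T`), so simulation and dating invert each other exactly.
The rates are per-species point estimates (`avian_rate_table()`: 1.9e-3
for *G. gallus*-like genomes up to 2.3e-3, with a 1.6e-3 "water bird"
floor for sensitivity re-dating via `rescale_ages()`). The source
literature never states whether such rates are per-lineage or per-pair;
the package adopts the `T = k/2r`-consistent convention throughout and
treats the choice as part of the model definition.

Amplification waves are read from the age histogram
(`age_histogram_peaks()`). The default bin width of 6.25 My puts the
conventionally reported wave endpoints (18.75, 37.5, 87.5 My) on bin
edges. Peaks are strict local maxima holding at least 5% of all dated
copies; runs of equal-count adjacent maxima merge into one plateau peak,
so a flat-topped wave is one wave, not two.

## Mining: seed-and-extend with Karlin-Altschul statistics

`te_search()` re-implements a blastn-like nucleotide search rather than
shelling out to an external binary, so the pipeline is self-contained and
its statistics are inspectable. Exact 11-mers shared between query and
genome (both strands) seed ungapped X-drop extensions under +2/-3
scoring; extension clusters that could plausibly reach the E-value cutoff
are refined by gapped affine local dynamic programming (gap open 5, extend
2) in a padded window. Significance uses the Karlin-Altschul expectation
`E = K m n e^{-lambda S}` with `lambda` solved numerically from the scoring
scheme and the genome's observed base composition, and `K` computed with
the lattice-case formula by truncated convolution of the score
distribution; for the classic +1/-2 scheme this machinery reproduces the
published `lambda = 1.33`, `K = 0.621`. Two approximations are deliberate
and documented: gapped scores reuse the ungapped `lambda` and `K` (standard
practice for seeded nucleotide searches), and the search space is `m x n`
without edge-effect correction. Only HSPs with `E <= 1e-10` are kept —
the screening threshold for reporting a genuine homolog.

Overlapping or near-adjacent HSPs on the same contig and strand merge into
loci (`merge_hits()`, default gap 100 bp): a single decayed copy often
yields several HSPs, and the merge distance is exposed because no principle
fixes it. `extract_copies()` then returns each locus with up to 200 bp of
flanking context, reverse-complemented into element orientation for
minus-strand copies, with truncation at contig edges flagged.

## Structural annotation and the four-way classification

`detect_tirs()` scans the first 60 bp of a copy against the reverse
complement of its last 60 bp for the best ungapped inverted repeat with
length 20-40 bp and identity >= 0.8. "Best" maximizes matches minus
mismatches; ties prefer longer, then outermost placement. The identity
floor operationalizes "conserved TIRs": old copies have imperfect TIRs, and
a hard exact-match rule would class almost everything as partial. Note one
consequence of scoring rather than anchoring: a perfect 28-bp TIR may be
reported a few bases longer when flanking bases match by chance; the
planted repeat is still recovered at full identity.

`find_orfs()` follows getorf semantics (`-minsize 900 -find 1 -methionine
Y`): six frames, ATG-to-stop spans, minimum 300 translated residues
excluding the stop, ambiguous codons translating to X and never acting as
start or stop; an ORF still open at the sequence end is reported without a
stop. The 300-residue boundary is inclusive — the source text is
contradictory about ties at exactly 300 aa, and the package resolves the
tie toward coding capability, matching getorf's inclusive minimum.

Classification is the total four-way partition: TIRs + ORF >= 300 aa ->
`potential_autonomous`; TIRs only -> `potential_non_autonomous`; ORF only
-> `potential_coding`; neither -> `partial`. Size classes are separate
(full_length 1200-1400 bp, mite 450-650 bp, otherwise partial_size) so a
report never conflates structural completeness with length. The TSD is
annotated (`detect_tsd()`) but deliberately not used in classification —
whether the original analysis required it is unstated, so it is kept as
evidence, not as a gate. `conservation_matrix()` provides the numeric
logo stand-in (per-column frequencies and information content `IC = 2 +
sum f log2 f`, no small-sample correction by default).

## Consensus by star alignment

`build_majority_consensus()` aligns every copy semiglobally to a reference
(the query consensus, or the longest copy) and stacks the pairwise
alignments into a star alignment — replacing a full multiple-sequence
alignment, which for majority voting against a fixed reference adds cost
but little information. Columns are reference positions plus insertion
columns supported by more than half the copies. The consensus base is the
most frequent non-gap base (alphabetical tie-break, so results are
deterministic); a gap wins only when gaps strictly outnumber every base.
Columns with non-gap coverage below 0.2 are dropped from the emitted
sequence, which is what makes a MITE-dominated family yield a MITE-length
consensus while the full per-column profile remains available via
`tidy()`. A single copy is its own consensus (the operation is
idempotent), so rebuilding from an emitted consensus returns it unchanged.

One numerical choice deserves emphasis: consensus building and K2P pair
alignment default to gap costs of 12 (open) and 0.25/base (extend),
*not* the mining scheme's 5/2. A MITE differs from its full-length parent
by an internal deletion of several hundred bp; at 2/base extension that
gap would cost more than the alignment of the retained arms earns, and the
optimal alignment smears the 3' arm through the reference middle as
mismatches — corrupting both the consensus and every pair distance. Cheap
long gaps fix this while still preferring a mismatch over a 1-bp gap.
Mining keeps 5/2 because HSPs are merged at the locus level, where within-
HSP gap placement is irrelevant.

## The horizontal-transfer quantile test

`ht_quantile_test()` compares the K2P distance between two species'
element consensuses against the distances of single-copy ortholog pairs
(50 by default). The exceedance fraction is the proportion of genes
*strictly* more divergent than the element; ties count against horizontal
transfer (conservative). The published analysis judged an observed 92%
exceedance to indicate transfer without stating a rule; the package makes
the implicit judgment explicit with a default threshold of 0.90, and the
call is three-way: `HT` at or above the threshold, `vertical` within the
gene bulk (0.25-0.90), and `inconclusive` below 0.25 — an element *more*
divergent than most host genes is anomalous and flagged, never silently
called vertical. Both thresholds are parameters.

## Neighbor joining

`nj_tree()` is a convenience clustering view of a consensus distance
matrix: standard neighbor joining (via ape) with negative branch lengths
clamped to zero. It deliberately is not a maximum-likelihood phylogeny
and carries no support values.

# What the simulator does and does not emulate

`plant_copies()` and `simulate_ht_scenario()` generate: an i.i.d. host
background at a configurable GC fraction (default 0.42, avian-like);
full-length elements with perfect 28-bp TIRs; MITE derivatives keeping
both arms; TA target-site duplications at every insertion; copies on both
strands; copy divergence by the exact K2P process at `2 r T`; two-lineage
scenarios where founder elements diverge according to the *younger*
invasion age while 50 ortholog pairs diverge according to the host split
time, with lognormal per-gene rate multipliers (log-sd 0.25) reproducing
the bulk-with-tail shape of empirical gene-distance distributions.

It does not emulate: selection, recombination, nested insertions, indel
accumulation inside copies (substitution-only by default — K2P is defined
on substitutions), codon structure in "genes", segmental duplications, or
assembly artifacts. Passing tests therefore demonstrate that the
implementation is correct under the stated model, not that real assemblies
are free of the usual complications (collapsed repeats, chimeric contigs,
diverged families below the E-value floor). In particular, mining recall
measured on simulations (>= 95% at divergence <= 0.25) is an upper bound
on what a fragmented draft assembly would give.

# Reproducibility and problem sizes

Every stochastic operation takes a seed or inherits the caller's RNG
stream; `run_pipeline()` seeds once and writes a byte-reproducible JSON
report (the run log carries versions and parameters; rounding happens only
in the human-readable TSVs). The test suite and the acceptance script use
deliberately desk-scale problem sizes, chosen as the package's own
validation conditions: 1-5-Mb genomes with up to 200 planted copies for
mining recall; 50-copy bursts for age recovery; 20 seeded replicates each
for the transfer and vertical-control scenarios with 20 copies per lineage
and 50 ortholog pairs of 1.5 kb. Published copy counts in the tens of
thousands come from whole-genome screens of real assemblies and are out of
scope here; the printed per-species class counts are, however, used
directly to reproduce the reported MITE fractions.

# Known limitations

* Gapped E-values reuse ungapped Karlin-Altschul parameters; absolute
  E-values near the cutoff are approximate (the package's own tests show
  the practical consequence is nil at the 1e-10 screening threshold).
* The star alignment never revises the reference: insertions shared by
  most copies appear as consensus columns, but a reference much shorter
  than the true element would truncate the profile.
* `detect_tirs()` is ungapped; a TIR interrupted by an indel is found only
  if one ungapped run still clears the identity floor.
* Dating assumes a single constant neutral rate per species; rate
  variation among copies widens age peaks beyond the binomial expectation.
* The HT test is a quantile comparison, not a coalescent model; it flags
  incongruence but does not estimate a transfer time or direction.
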