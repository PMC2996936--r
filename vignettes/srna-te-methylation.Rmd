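---
title: "Profiling sRNA targeting of transposable elements and dating its methylation footprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling sRNA targeting of transposable elements and dating its methylation footprint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnascan)
```

## The model in brief

Transposable elements (TEs) dominate large plant genomes and are
silenced by small RNAs (sRNAs): the 24-nt class recruits RNA-directed
DNA methylation, the 21-nt class degrades transcripts. `srnascan`
implements two linked analyses:

* **Where do sRNAs hit?** An exhaustive perfect-match scan of annotated
  sequence against a consolidated sRNA abundance database, followed by
  per-feature, per-superfamily and positional (decile) profiling.
* **What does methylation leave behind?** Methylcytosine deaminates to
  thymine faster than cytosine, so regions kept methylated over long
  times accumulate excess transitions at potentially methylated sites
  (PMS). Classifying every aligned column of an orthologous pair into
  CG/CHG/CHH contexts and tallying substitutions per context turns a
  pairwise alignment into a methylation proxy; Kimura two-parameter
  (K2P) arithmetic converts substitution counts into rates and ages.

## Scanning: the contract is brute force

`scan_region()` must return exactly the set of matches a naive
enumerator would: every `(start, length, strand)` whose substring (or
reverse complement) equals a database sequence, for every length in the
18–33 nt window, at 1-nt increments. The implementation hashes windows
per length (`match()` against the per-length slice of the database), but
the contract — and the property test — is equality with the brute-force
definition. `N` never matches, because matching is defined over A/C/G/T.

Counting is abundance-weighted throughout: a genomic occurrence
contributes the full database abundance of the matching sRNA, and a
multi-copy repeat accrues that abundance at every occurrence. Matches
are not divided among loci. Reverse-strand scanning is on by default
(sRNAs derive from both strands of double-stranded RNA); restricting to
`strands = "+"` reproduces a strict single-strand reading.

## Hit assignment and positional profiles

Nested insertions are the norm in repeat-rich regions, so a hit often
lies inside several concentric elements. `assign_hits()` requires full
containment and awards the hit to the innermost (highest nesting level)
element — the most recent insertion, which is the one whose sequence the
sRNA actually matches. A hit that straddles a boundary is assigned by
its start position and flagged (`boundary`), a documented tie-break
rather than a biological claim.

`decile_profile()` bins a hit by the floored decile of its **start
offset** within the element. Start-offset binning matches a 1-nt
scanner's natural coordinate; its one visible consequence is that a
footprint mirrored about the element midpoint lands in the mirror bin
exactly when the read length equals the bin width, which the symmetric
terminal-inverted-repeat (TIR) test exploits deliberately.

`uniformity_test()` is a chi-square goodness-of-fit against the uniform
expectation. LTR retroelements carry the same long terminal repeat at
both ends, so their mirrored terminal bins measure the same sequence
twice; `merge_terminal_bins = k` averages bin *i* with bin *11 − i* for
the *k* outer pairs before testing, leaving `10 − k` categories and
`9 − k` degrees of freedom (k = 2 suits elements whose LTRs span ~20% of
each end, k = 1 those with ~10%). Zero-hit features are retained with
zero density so group tests (`compare_group_density()`, Welch's t, with
a one-sided option for the top-of-nest vs lower-layer contrast) see the
full feature population.

## Methylation contexts on an alignment

`classify_methylation_sites()` classifies each sequence of the pair in
its **own ungapped coordinates** — a methylation context is a property
of a physical chromosome, not of an alignment column — then combines the
two per-column classes under the precedence CG > CHG > CHH > nonPMS
(a C in `CGG` is CG, not CHG; a motif in either genome suffices, and
both the C and the G of a CG/CHG motif take the motif's class). Columns
with a gap in either sequence are excluded from everything; columns with
an `N` are excluded into a separate bucket.

Numerical edge rules, chosen once and tested:

* a terminal C (or leading G) with no neighbour at all is `nonPMS`;
* a truncated motif with at least one usable neighbour that cannot be
  completed to CG/CHG is `CHH`;
* an `N` neighbour never completes a motif (the site falls through to
  whatever its remaining neighbours support).

A consequence worth stating plainly: **every interior C or G belongs to
some context**, so non-PMS columns hold A/T in both genomes, and the
only possible non-PMS mismatch is the A↔T transversion. Non-PMS
transition frequencies are structurally zero — any transition creates a
C or G and with it a context. Methylation contrasts must therefore
compare PMS frequencies **between strata** (e.g. TE vs intron/UTR
footprints, supplied as alignment-column intervals to
`tally_substitutions()`), not PMS against non-PMS within one stratum.

### Estimating the transition elevation

If methylation multiplies the transition rate by *m* at PMS, the
observed ratio of PMS transition frequencies between a methylated and an
unmethylated stratum is compressed below *m*: transitions arising at
ancestral A/T sites create a C/G and flow into the PMS class of both
strata at the baseline rate. With PMS site share *s*, the expected raw
ratio is `R = (s·m + (1 − s)) / (s + (1 − s))`, which
`estimate_transition_elevation()` inverts as `m̂ = (R − (1 − s))/s`,
taking *s* from the reference stratum. Residual biases (mismatch
saturation at high *m·p*, double hits, context turnover) are a few
percent at the divergences this package targets (≲ 5% per lineage); the
simulator-recovery test bounds the total error at 15% for 100 kb per
stratum.

## K2P dating

`k2p_distance()` computes `d = −½·ln[(1 − 2P − Q)·√(1 − 2Q)]` from
transition and transversion proportions per aligned non-gap site, and
raises a typed saturation error outside the formula's domain rather than
returning infinity. All datings use the factor 2 — `T = d/(2r)`,
`r = d/(2T)` — because both use cases involve two independently
accumulating copies: two genomes after a split, or two LTRs after an
insertion (`ltr_insertion_time()` assumes the LTR pair was identical at
insertion). No rate is hard-coded: the conventional defaults are
5.5e-9 substitutions·site⁻¹·yr⁻¹ for grass genic/low-copy sequence and
1.67e-8 for TE sequence, both exposed as arguments.

## What the synthetic generator does and does not emulate

`simulate_genome()` builds an i.i.d. background (GC 0.46, typical of
Triticeae gene islands), splices in gene intervals, then inserts TE
copies one at a time; an insertion landing inside an existing element
extends that element and nests one level deeper, up to 4 layers. Family
consensus sequences are generated once and copied with 2% per-copy
substitutions, so perfect multi-copy sRNA matches arise naturally. The
default catalogue (about 60% TE sequence; Copia LTRs ~1.1 kb, Gypsy
~2 kb, CACTA terminal repeats opening with the CACTA motif,
Stowaway-like MITEs that are mostly TIR) mirrors the published anatomy
of wheat gene-rich regions.

`simulate_srna_library()` draws reads from an origin mixture
(terminal-repeat subregions 55%, TE bodies 15%, genes 2%, genomic
background 18%, non-genomic sequencing background 10%) with a bimodal
length mixture (17.7% at 21 nt, 28.7% at 24 nt, the remainder spread
evenly) and a Mariner-specific override (54% / 27%) reflecting the
21-nt dominance of MITE-derived sRNAs. Reads are exact genome substrings
(either strand), so scanner sensitivity is 100% by construction and any
missed read is a scanner bug.

`evolve_pair()` evolves two descendants from one ancestor under a
single-hit model: per-site transition probability `r_ts·T` (times *m* at
ancestral PMS inside methylated strata) and transversion probability
`r_tv·T`, with defaults `3.5e-9 + 2.0e-9 = 5.5e-9` summing to the genic
rate and `m = 10` for the deamination acceleration. Deletions (optional)
appear as `-` in the emitted alignment, which is the **true** alignment
— no realignment step, hence no aligner artefacts. The returned truth
tally is computed by an independent position-by-position enumerator and
doubles as a test oracle.

What this does not model: realistic TE sequence composition (no
HMM/profile realism), solo-LTR formation, insertion-site preferences,
sequencing error, multiple hits per site (so divergences above ~10% per
lineage would be biased), and more than two lineages. Passing tests
therefore validate the pipeline's arithmetic and bookkeeping on data
with the right broad structure, not its behaviour on every artefact of
real libraries.

## Problem sizes and calibrations used by the test suite

The suite validates the scanner against the brute-force oracle on 1,000
random regions of up to 5 kb; the context tally against exhaustive
enumeration of all ≤ 3-column alignments over {A, C, G, −} plus randomised
longer cases, and against simulator truth; the chi-square uniformity
test's type-I error (5% ± 2%) on 1,000 uniform decile profiles of 200
hits each; the elevation estimator at 100 kb per stratum (within 15% of
m = 10); and LTR age recovery on 200 simulated 2-kb LTR pairs aged
1.0 MY (median within 5%, with spread shrinking as length grows). These
sizes were chosen so the full suite exercises every contract at
comfortable statistical resolution.

## Known limitations

* The scanner considers perfect matches only; sRNAs acting on
  near-matches are invisible to it, so targeting is underestimated for
  diverged elements.
* Decile profiles use start offsets, so the last bin covers slightly
  fewer possible start positions for long reads; positional nulls used
  in calibration draw point positions for exactly this reason.
* The elevation estimator assumes a shared base composition between the
  contrasted strata and low per-lineage divergence.
* `filter_te_database()` trusts header metadata; records lacking it fail
  the corresponding criterion rather than being guessed.
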