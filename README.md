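# srnascan

Small RNA targeting of transposable elements, and the mutational
footprint methylation leaves behind.

In large plant genomes such as wheat, most of the DNA is transposable
elements (TEs), and most small RNAs (sRNAs) are made from them: 21-nt
sRNAs guide post-transcriptional silencing, 24-nt sRNAs guide
RNA-directed DNA methylation. Methylated cytosines deaminate to thymine
faster than unmethylated ones, so sustained methylation shows up, over
evolutionary time, as an excess of transitions at potentially methylated
sites (PMS: any C or G in a CG, CHG or CHH context, H = A/T/C).
`srnascan` implements the full analysis chain connecting these two
observations, for epigenomics and genome-evolution researchers working
with repeat-rich genomes:

1. **sRNA database** — consolidate adapter-trimmed libraries (FASTA/FASTQ,
   18–33 nt) into one abundance table of distinct sequences.
2. **Perfect-match scanning** — an exhaustive scrolling-window scan that
   finds every exact occurrence of any database sRNA on both strands of a
   query sequence, equivalent by construction to brute-force enumeration
   of all substrings.
3. **TE profiling** — assign hits to nested TE/gene annotations
   (innermost element wins), compute per-feature densities and 21/24-nt
   shares, positional decile profiles with chi-square uniformity tests
   (mirrored terminal bins can be averaged for LTR elements), Welch
   group contrasts and correlation tests, and TREP-style reference
   filtering.
4. **Methylation-context mutation tallies** — classify every column of a
   pairwise-aligned orthologous pair as CG / CHG / CHH / nonPMS on either
   strand (contexts read in each genome's own gapped-free coordinates)
   and count transitions and transversions per context.
5. **K2P dating** — Kimura two-parameter distances
   `d = -1/2 ln[(1 - 2P - Q) sqrt(1 - 2Q)]`, substitution rates
   `r = d/(2T)`, divergence times `T = d/(2r)`, and LTR-pair insertion
   ages.
6. **Synthetic data** — generators for nested-TE genomes, sRNA libraries
   with bimodal length structure and terminal-repeat targeting, and
   diverged orthologous pairs with elevated transitions at methylated
   sites, so the whole pipeline is testable offline.

## Worked example

Date a divergence from substitution counts, then scan a simulated genome:

```r
library(srnascan)

# K2P dating: 76 transitions, 51 transversions over 10,397 aligned bp,
# at a genic substitution rate of 5.5e-9 per site per year
k2p_distance(76, 51, 10397) |>
  divergence_time(rate = 5.5e-9) |>
  dplyr::select(d, rate, time_my)
#> # A tibble: 1 × 3
#>        d         rate time_my
#>    <dbl>        <dbl>   <dbl>
#> 1 0.0123 0.0000000055    1.12
```

The two sequences differ by about 1.23 substitutions per 100 sites;
at 5.5e-9 substitutions/site/year on each of the two lineages, that
places their split roughly 1.1 million years ago.

```r
# simulate a nested-TE genome, an sRNA library, and profile the matches
sim <- simulate_genome(genome_sim_config(seed = 7))
lib <- simulate_srna_library(sim, library_sim_config(seed = 3))
db  <- build_srna_db(lib$reads)
hits <- scan_region(db, sim$region$sequence, sim$region$region_id)
prof <- profile_features(assign_hits(hits, sim$annotations),
                         sim$annotations)
dplyr::arrange(prof, dplyr::desc(density))[1:3,
  c("feature_id", "superfamily", "length_bp", "total_count", "density")]
#> # A tibble: 3 × 5
#>   feature_id superfamily length_bp total_count density
#>   <chr>      <chr>           <int>       <int>   <dbl>
#> 1 Thalos_06  Mariner           163        4484    27.5
#> 2 Thalos_07  Mariner           163        4430    27.2
#> 3 Thalos_08  Mariner           163        4066    24.9
```

Short Stowaway-like MITEs carry by far the highest sRNA match density —
their terminal inverted repeats are dense sRNA targets — while long LTR
retroelements accumulate large absolute counts at much lower density.
(Numbers depend on the simulation seed and configuration.)

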