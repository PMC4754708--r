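# mitocomp

Comparative analysis of insect mitochondrial genomes in R, built around
the questions that recur in descriptions of sawfly (basal Hymenoptera)
mitogenomes: how biased is the base composition, which codons are
preferred, how fast are the protein-coding genes evolving, which tRNAs
have moved relative to the ancestral insect arrangement, how tidy are
the gene junctions, and which alignment partitions are saturated.

For whom: anyone describing or comparing annotated animal mitogenomes —
typically from GenBank flat files — who wants the standard comparative
statistics reproducibly, with tidy tibbles in and out.

## What it computes

- **Composition and strand skews.** For a region with base percentages
  A%, C%, G%, T%: AT-skew = (A − T)/(A + T), GC-skew = (G − C)/(G + C),
  per region (whole genome, concatenated PCGs, rRNAs, tRNAs, codon
  positions), with ambiguity codes excluded and undefined skews flagged
  rather than zeroed.
- **Codon usage.** Codon counts, RSCU (`k·n_c / Σ n_family`),
  missing-codon lists, start/stop classification including incomplete
  stops (T/TA completed by polyadenylation, called only when the next
  feature abuts), and ranked amino-acid usage — all under the
  invertebrate mitochondrial code (translation table 5).
- **Ka/Ks.** Nei–Gojobori (1986) counting with equal-weight pathway
  averaging, stop-pathway exclusion, and Jukes–Cantor correction
  (Ks = −¾ ln(1 − 4/3 pS)), per gene and concatenated against a
  reference taxon; undefined ratios are flagged, never printed as 0.
- **Gene order.** Circular signed permutations compared against the
  ancestral insect arrangement: per-gene calls (translocated,
  remote-inverted, inverted in place), conserved blocks, and breakpoint
  distances under the standard signed-adjacency convention.
- **tRNA structure and junctions.** A deterministic cloverleaf folder
  with a mismatched-pair census (G-U counts as canonical), a
  dot-bracket parser for curated structures, and an intergenic
  spacer/overlap census with junction-motif search (e.g. the ATGATAA
  atp8/atp6 overlap).
- **Phylogenetic matrix preparation.** Codon-position splitting,
  table-5 translation, P123/P123R/P12T/AA supermatrix variants with
  charset tables, NEXUS/PHYLIP/FASTA export with RAxML-style partition
  files, and a K80-based substitution-saturation screen.
- **Synthetic data.** A generator that emits annotated GenBank records
  with full ground truth (gene order and events, spacer/overlap totals,
  planted tRNA structures and mismatches, composition targets), plus
  codon-pair and K80 alignment simulators — every analysis stage is
  testable without downloads.

## Worked example

Simulate a sawfly-like genome carrying the classic trnC/trnY relocation,
then run the pipeline:

```r
library(mitocomp)

ev <- list(list(type = "translocation",   gene = "trnC", after = "AT_rich"),
           list(type = "remote_inversion", gene = "trnY", after = "AT_rich"))
sim <- simulate_mitogenome(simulation_spec(seed = 1, events = ev,
                                           incomplete_stop = "nad5"))
g <- sim$genome
g
#> <mitogenome> SYN000001 (Synthetica exempli), circular, 15253 bp, 38 features, complete gene set

region_composition(g, "PCGs")[, c("length", "at_content", "at_skew", "gc_skew")]
#> # A tibble: 1 × 4
#>   length at_content at_skew  gc_skew
#>    <int>      <dbl>   <dbl>    <dbl>
#> 1  11176       79.4  -0.110 -0.00348

compare_to_ancestor(extract_gene_order(g))
#> <rearrangement_report> at least 2 event(s), 4 breakpoint(s)
#>  - remote inversion of trnY to downstream of AT_rich
#>  - translocation of trnC to downstream of trnY

glance(spacer_overlap_scan(g))[, 1:4]
#> # A tibble: 1 × 4
#>   total_intergenic_bp n_gap_locations longest_gap longest_gap_junction
#>                 <int>           <int>       <int> <chr>
#> 1                  70               6          27 cox3/trnG

p <- simulate_codon_pair(2000, omega = 0.2, t = 0.3, seed = 1)
ng86(p$cds1, p$cds2)
#> <ng86> 2000 codons | S=1087.17 N=4912.83 | Sd=143.00 Nd=90.00 | Ks=0.1446 Ka=0.01855 Ka/Ks=0.1282
```

Reading the output: the simulated PCGs are strongly A+T-biased
(A+T ≈ 79%) with the negative AT-skew typical of insect majority-strand
protein genes; the rearrangement report recovers exactly the two
injected events; the junction census totals match the generator's plan;
and a codon pair evolved under purifying selection (ω = 0.2) yields a
Ka/Ks estimate close to the simulated ω and well below 1.

Real data enters through `read_genbank("record.gb")`, which returns the
same `mitogenome` object; `scatter3d_table()`, `rscu()`,
`classify_terminal_codons()`, `trna_mismatch_report()`,
`rates_vs_reference()`, `build_matrix()` and `saturation_scan()` cover
the rest of the pipeline, each returning tibbles (with `tidy()` /
`glance()` methods and `plot_*()` helpers for the figures).

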