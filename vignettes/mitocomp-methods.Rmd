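---
title: "Methods: comparative mitogenomics with mitocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mitogenomics with mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

mitocomp implements the comparative-analysis stages that recur in
descriptions of insect mitochondrial genomes — particularly the sawfly
(basal Hymenoptera) literature, where partial genomes, tRNA
rearrangements and strong A+T bias are the norm. This vignette explains
the models and procedures, the tunable parameters, what the synthetic
generator does and does not emulate, and the design choices made where
conventions in the field are genuinely open.

## Data model and coordinates

A `mitogenome` couples one deposited sequence with a tibble of features
over the 37 canonical genes (13 protein-coding genes, 2 rRNAs, 22 tRNAs)
plus the A+T-rich control region. Internally all coordinates are 0-based
half-open, so gap and overlap arithmetic at junctions is plain
subtraction; GenBank's 1-based inclusive convention is converted at the
I/O boundary only. Genes absent from a partially sequenced molecule are
represented as absent and never imputed. Duplicate annotations of one
gene keep the longest copy; the rest are retained but flagged and
excluded from comparative statistics.

The duplicated leucine and serine tRNAs follow the standard convention:
`trnL1` decodes CUN codons (anticodon UAG), `trnL2` decodes UUR (UAA),
`trnS1` decodes AGN (UCU/GCU), `trnS2` decodes UCN (UGA). Some
published tables attach the superscripts the other way around; we keep
the standard and resolve ambiguous records by anticodon, falling back to
the gene's position relative to the ancestral arrangement (flagged
`inferred`).

The genetic code is fixed to translation table 5 (invertebrate
mitochondrial: ATA = Met, AGA/AGG = Ser, TGA = Trp; stops TAA/TAG).
Mitogenome annotation pipelines for insects uniformly assume this code,
so no per-genome override is offered.

## Composition and skews

For a region with base percentages A%, C%, G%, T%,

- AT-skew = (A% − T%) / (A% + T%),
- GC-skew = (G% − C%) / (G% + C%).

Ambiguity codes are excluded from both numerator and denominator, and a
zero denominator yields an explicit undefined flag rather than zero.
Protein-coding regions are concatenated on each gene's coding
orientation (sense strand); a `j_strand_only` flag recomputes everything
on the deposited majority strand, since published tables do not always
state their convention. Sense-strand concatenation reproduces the
qualitative pattern reported for sawflies (T > A and C > G in PCGs,
i.e. negative AT-skew with GC-skew near zero). Report tables round
half-away-from-zero to 2 decimals (contents) and 3 decimals (skews),
matching the precision of published tables.

Nucleotides shared by overlapping genes (the 7-bp atp8/atp6 overlap)
are counted once per gene, because regions are built from per-gene
extraction; published "PCG length" totals may differ by a few bp
depending on the authors' choice, which is rarely stated.

## Codon usage

Codons are read in frame 0 from each CDS start. A trailing 1–2 nt
remainder is treated as an incomplete stop codon (completed to TAA by
polyadenylation) and dropped; terminal complete stops are tallied
separately and excluded from sense counts, as RSCU figures
conventionally do. RSCU for codon *c* in a synonymous family of size
*k* is `k * n_c / sum(n_family)`; a family with zero usage is undefined
(`NA`), never zero. Two exact laws are asserted in the tests: family
sums equal family sizes whenever the family is used, and the
membership-weighted mean RSCU over used families is 1.

Incomplete stops are only called when the CDS length remainder matches
(T or TA) *and* the next annotated feature abuts or overlaps the CDS
end — the tRNA-punctuation context in which polyadenylation completes
the codon. Anything else is flagged nonstandard rather than guessed.

## Ka/Ks (Nei–Gojobori 1986, Jukes–Cantor corrected)

The counting method is fixed as NG86 with equal pathway weighting; the
comparative literature this package serves typically names only the
software used (DnaSP-family tools), and NG86 is the method those tools
apply. Site counting follows the convention in which each codon
contributes S = Σ (synonymous single-base changes at each position)/3
and N = 3 − S; mutations to stop codons are thereby counted as
nonsynonymous, and S + N = 3 per codon exactly. Codon pairs differing
at *d* positions are averaged over all *d*! substitution pathways,
excluding pathways through stop codons; in the degenerate case where
every pathway passes through a stop, the *d* differences are split in
proportion to the pair's site counts (a documented fallback that keeps
totals conserved). pS = Sd/S and pN = Nd/N are mapped to Ks and Ka by
the Jukes–Cantor correction −(3/4)·ln(1 − (4/3)p); a non-positive log
argument or Ks = 0 yields an undefined ratio with a saturation flag,
never a printed zero.

Codon pairs containing gaps, ambiguity codes, or stop codons in either
sequence are excluded pairwise. `rates_vs_reference()` reports per-gene
rows and a concatenated row against a designated reference taxon;
whether a published figure pooled or averaged genes is rarely stated,
so both are emitted. Unequal-length inputs are truncated to the shared
codon span, appropriate only for length-conserved mitochondrial PCGs or
pre-aligned input.

The implementation is table-driven (memoized per-codon-pair counts);
the test suite checks it against an independently coded brute-force
pathway enumerator over the exhaustive 62 × 62 sense-codon sweep plus
300 random two-codon pairs, and against two hand-worked examples to
1e-9.

## Gene order and rearrangements

Orders are circular signed permutations (+ = majority/J strand). The
bundled ancestral insect arrangement is the *Drosophila yakuba*-type
order. Comparison first projects the ancestor onto the observed gene
set, so missing genes can never be reported as rearranged; a
maximum-length common circular signed subsequence (computed by LCS over
all rotations) anchors the in-place genes, and the remainder are
classified: moved + sign flip = remote inversion, moved = translocation,
sign flip between unchanged neighbours = in-place inversion. The event
narrative is a heuristic "at least N events" statement, not a provably
minimal sorting scenario — optimal inversion/DCJ distances are out of
scope.

A signed circular adjacency (x → y) is considered shared with
(−y → −x), the standard signed-permutation convention; consequently a
full reversal of the circle has breakpoint distance 0. The A+T-rich
region participates in order extraction but is excluded from breakpoint
counting because its boundaries are unreliable in partial genomes.

## tRNA cloverleaves and the mismatch census

The folder is a deterministic heuristic, not a thermodynamic method: it
anchors the anticodon at the centre of a 7-nt loop, extends the
anticodon stem (4–6 pairs), pairs the termini into an acceptor stem
(6–8 pairs, one unpaired 3' discriminator), and then searches D-arm
(0–4 pairs) and TΨC-arm (3–5 pairs) hairpins maximizing a pairing score
(canonical +2, G-U +1, mismatch −1) subject to non-crossing and the
arm-size ranges; ties break 5'-most, then longest. A D-arm is accepted
only at a net score of at least two canonical pairs' worth; otherwise
the region is reported as a plain loop with a degenerate-D-arm flag,
the common reduction in metazoan mitochondrial tRNAs.

The mismatch census counts every stem pair outside {A-U, U-A, G-C,
C-G, G-U, U-G}. G-U wobble is deliberately canonical here — published
mismatch tables list only pairs like U-U, A-C, A-A — and the set is
configurable in code. T in DNA input is read as U; loop positions are
unpaired by definition and never counted.

## Spacers and overlaps

The junction walk visits consecutive features in genomic order,
wrapping across the origin for circular molecules; each junction's
signed length is `next.start − current.end` (positive gap, negative
overlap, zero abutment). Nested features are excluded with a message.
The A+T-rich region is a feature — its flanks are junctions — but is an
annotated region, not a spacer. Published spacer counts for the same
genome sometimes differ by 2–3 depending on whether the control-region
flanks and sub-threshold gaps are counted; we report every gap ≥ 1 bp as
a location and do not tune to any particular published total. Motif
search runs on the junction-local sequence in both orientations and
reports the orientation, so N-strand motifs (e.g. ATTATAA between nad4
and nad4l) are found from their J-strand complement.

## Supermatrices and saturation

Four matrix variants follow mitogenome practice: P123 (all codon
positions of the PCGs, genes as contiguous blocks with `gene_p1/2/3`
charsets of stride 3 — the `start-end\3` layout RAxML and
PartitionFinder use), P123R (plus rRNA and tRNA genes), P12T (P123R
minus the saturated partitions, by default every PCG third position and
both rRNAs, with the kept columns re-packed into contiguous stride-1
charsets), and AA (translated PCGs). `trnI` and `trnQ` are excluded
from RNA blocks by default, being missing from too many partial
genomes. Structural identities hold on any input and are tested
exactly: charsets tile the matrix, and n_sites(P123) = 3 × n_sites(AA).
Alignment itself (MAFFT-class tools) is deliberately external — the
module consumes aligned FASTA — because wrapping an aligner adds only
glue and its run-to-run variability would break byte-stable outputs.

The saturation screen computes, per taxon pair, the p-distance
(pairwise deletion), transition/transversion proportions, and the
K80-corrected distance, then regresses p on the corrected distance.
Unsaturated data lies near the 1:1 line; saturated data plateaus. The
partition is flagged when the slope drops below 0.6 (exposed as
`slope_threshold`) or the correction is undefined for more than 10% of
pairs. This is a deliberately simple, documented heuristic; formal
tests such as Xia's index are out of scope.

## The synthetic generator

`simulate_mitogenome()` builds a complete annotated genome with full
ground truth. Defaults are fixed once to the study conditions typical
of sawfly mitogenomes: ~15.3 kb; 13 PCGs totalling ~11.2 kb with a PCG
base-composition target of A 35.2 / C 10.4 / G 10.3 / T 44.1 percent
(A+T ≈ 79.4%, negative AT-skew); rRNAs of 1350 and 800 nt at A+T 84%;
a 400 nt control region at A+T 85%; ATN starts and TAA stops; the 7-bp
atp8/atp6 "ATGATAA" overlap; a junction plan with gaps of 2–27 bp, two
overlaps and the rest abutting. Composition targets are realized by
shuffled exact base multisets (largest-remainder rounding), so realized
composition matches the target to rounding; in-frame stops are removed
by composition-preserving swaps.

tRNAs are built from planted cloverleaf plans. Stems use fixed,
shift-unique G/C patterns and every loop/spacer base is A: because A
pairs only with T/U, which never occurs outside anticodons and planted
mismatches, the planted structure is the unique optimum of the
structure search and fold round-trips are exact by construction. The
price is that tRNA regions are not composition-targeted and look
nothing like real tRNA sequence beyond their topology — passing fold
round-trips therefore demonstrates the folder's bookkeeping, not its
accuracy on real tRNAs. Planted mismatches sit interior to their stems
(and away from the loop-proximal end of the anticodon stem) so that
score-maximizing extension necessarily includes them.

`simulate_codon_pair()` evolves a daughter CDS from an A/T-biased
ancestor by per-codon Poisson proposals (`t` expected proposals per
codon) with a κ-fold transition bias; nonsynonymous proposals are
accepted with probability min(1, ω), synonymous proposals are thinned
by 1/ω when ω > 1, and stop-creating proposals are rejected (a simple,
documented bias at desk scale). `simulate_k80_alignment()` evolves a
star tree under K80 with `t` defined as the expected *pairwise*
divergence; per-taxon branch lengths vary uniformly ±50% around t/2 so
that pairwise distances spread enough for the saturation regression to
be meaningful.

One integer seed drives everything; per-gene sub-streams are derived by
fixed offsets keyed to the canonical gene list, so a gene's sequence
does not depend on what else is simulated. Neither indels, nor
among-site rate variation, nor phylogenetic structure are simulated.

## Problem sizes and numerical choices

The test suite and the acceptance script use: full 38-feature genomes
(~15.3 kb) for census/round-trip checks; 2000-codon pairs over 50 seeds
at t = 0.3 for Ka/Ks recovery (ω ∈ {0.1, 0.5}); the exhaustive 62 × 62
sense-codon sweep plus 300 random two-codon pairs for the NG86 oracle;
111 systematic single events and 20 disjoint pairs for rearrangement
round-trips, with 100 random 10-gene instances against the adjacency
oracle; and 8-taxon, 2000-site K80 alignments over 20 seeds at t = 0.05
and t = 2.0 for the saturation screen. These sizes give stable
statistics while keeping a full run in the low minutes on one core.

Floating-point comparisons in exact laws use 1e-12; the hand-worked
NG86 examples are asserted to 1e-9; stochastic recovery uses ±0.05 on
mean Ka/Ks against the independent recount on identical replicates.

## Known limitations

- The event classifier is heuristic; complex overlapping rearrangements
  can be narrated non-minimally (the breakpoint count is exact).
- The cloverleaf folder is a scoring heuristic tuned to canonical
  metazoan arm sizes; real tRNAs with unusual arms may fold differently
  than curated structures, and `parse_structure_string()` exists
  precisely to consume curated dot-brackets instead.
- `rates_vs_reference()` does not align; diverged, length-variable
  genes must be pre-aligned upstream.
- Published matrix site counts depend on the authors' alignments and
  cannot be reproduced bit-exactly without them; only the structural
  identities are asserted.
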