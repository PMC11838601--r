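---
title: "segfam: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{segfam: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models behind each `segfam` module, the tunable
parameters that matter, the design decisions taken where the design was
genuinely open, and what the synthetic-data generator does and does not
emulate. Nothing here states an empirical result that the test suite does
not itself compute.

## The problem

High-identity multicopy gene families inside segmental duplications (the
*NPIP*/LCR16a family on human chromosome 16p is the motivating case) have
copies of roughly 20 kbp at 0.3–5% pairwise divergence, interspersed over
megabases, with copy number differing between the two haplotypes of a
single individual. Interlocus gene conversion (IGC) moves sequence between
copies, inversion polymorphisms re-order the unique genes between them,
and an in-frame coding VNTR changes protein length allele by allele.
`segfam` works from *phased assemblies*: every haplotype is a fully
resolved sequence, so copies can be located exactly, assigned to paralog
clades, and compared structurally — the analyses that short-read pipelines
cannot do in these regions.

## The simulator and its truth set

`simulate_family()` generates, deterministically from one seed:

1. an ancestral duplicon (default 20 kbp) and marker genes (5 kbp);
2. per-paralog consensus sequences, substitutions drawn at a configured
   divergence from the ancestor (default 1% per branch, so ~2% pairwise);
3. per haplotype: copy numbers per paralog (configurable distributions,
   defaults spanning CN 0–3), per-copy private substitutions (default
   5×10⁻⁴ — an order of magnitude below inter-paralog divergence, the
   separation that makes clade assignment well-posed), IGC events
   (Poisson, default rate 0.5/haplotype; tract length min 500 bp, mean
   2 kbp, applied as whole-tract replacement from the donor consensus,
   within subfamilies only), optional VNTR tails, and inversion genotypes
   (default one polymorphism at allele frequency 0.4);
4. contigs assembled with 40 kbp unique spacers — wide enough that every
   locus passes the 30 kbp flanking-uniqueness validation rule.

Deliberate simplifications, and what they imply for the tests: mutations
inside copies are substitutions only, so every copy stays colinear with
the ancestral duplicon. This keeps PSV bookkeeping exact and makes
"alignment" trivial — which is precisely why discovery recall/precision
of 100% and exact coordinate recovery are *attainable* in the tests. Real
assemblies contain indels, mobile-element insertions and assembly errors;
passing tests here demonstrate the logic of each method, not robustness
to those artefacts. Random RNG streams are namespaced per component
(ancestral sequence, paralogs, per-haplotype copy number, IGC, VNTR,
spacers), so enabling one feature never perturbs another's draws and a
configuration is reproducible byte for byte.

The VNTR tail is appended after the duplicon core (the repeat sits in the
final coding exon), so core coordinates remain ancestral coordinates. The
DNA units are deterministic reverse-translations of the three repeat
motifs (19- and 23-residue SADD-type, 25-residue MIISR-type; lengths
divisible by three), concatenated as a SADD run (the two lengths
alternating), a MIISR run, and a second SADD run with counts drawn from
the configured ranges (defaults 7–15 / 6–14 / 5–11).

### Coalescent windows

`sim_coalescent_window()` provides the nulls for the selection scans.
Mutations are Poisson(θ·L/2) on a genealogy of total length L, under the
convention E[π] = θ; positions are uniform (infinite sites), there is no
recombination within a window, and θ defaults to 10 per 30 kbp window so
window statistics are directly interpretable. Three modes:

* **neutral** — the standard n-coalescent;
* **star** — equal terminal branches (default 2a₁/n, matching the neutral
  E[S] = θa₁), the limiting genealogy immediately after a completed hard
  sweep; every variant is a singleton;
* **sweep** — a partial hard sweep: a swept class (frequency 0.7)
  coalesces in a recent star (depth 0.02), and its stem — the selected
  haplotype — joins the background coalescent only after a minimum age of
  0.7 coalescent units.

The sweep mode exists because a *complete* star cannot be scored by a
polarized haplotype statistic: with every variant a singleton, the derived
class has one member and no pairs, so nS_L is undefined at every site.
Tajima's D, which is folded, has its full power on star windows (they are
the textbook rare-allele-excess case), and the suite tests it there. The
nS_L power property is tested on sweep windows instead. The sweep
parameters were fixed once at a strong recent partial sweep; without
recombination a 30 kbp window is a single genealogy, and neutral windows
occasionally mimic weak sweeps (a deep clade split produces exactly the
high-frequency extended haplotype the statistic looks for), which bounds
the achievable separation for weaker sweep settings.

## Discovery

`find_copies()` is an anchor-chaining search: exact 21-mers shared with
the ancestral query, scanned every 10 bp on both strands, grouped by
alignment diagonal and chained when gaps are < 5 kbp. Because divergence
is substitution-dominated, a copy lies on one diagonal and its
coordinates follow from it; anchor ends within 5k (105 bp) of the query
boundary are snapped to the full extent, since substitution noise leaves
short anchor-free margins. Hits shorter than 15 kbp or with estimated
identity below 80% (identity ≈ (anchor fraction)^(1/k)) are dropped.
This replaces a general-purpose aligner and is adequate at ≤ 10%
divergence; it is not a substitute for split or gapped alignment.

`validate_locus()` passes a copy only when its contig continues ≥ 30 kbp
beyond both ends with no other copy in that flank. `flag_collapse()`
marks positions whose second-most-frequent base has ≥ 5 reads and ≥ 10%
of coverage, clustered within 500 bp (≥ 2 sites): on a collapsed
duplication the PSVs of the merged copies appear at ~50% allele balance,
far above the sequencing-error background at these thresholds.

`estimate_copy_number()` re-implements read-depth CN estimation: reads
are cut into non-overlapping 36 bp segments, each placed at every
reference position within Hamming distance 2 (pigeonhole-seeded with
three 12-mers), multi-mapping segments contributing weight 1/sites —
fractional weighting preserves depth linearity inside duplications, which
the linearity test (slope 1.0 ± 0.1 over CN 1–10) checks directly. Window
CN is 2 × depth / control-window depth; gene-level CN is the median over
non-excluded windows (VNTR windows excluded upstream). There is no GC
correction: simulated reads are GC-uniform, real fastCN-style pipelines
need one.

## Trees, assignment, dating

Distances are p or JC69 (−¾ ln(1 − 4p/3)) over anchored columns with
pairwise deletion of gaps/N; VNTR-overlapping columns and columns > 20%
gaps are excluded before computation. Trees are classical neighbor
joining (negative branches clamped to zero) midpoint-rooted; support is
the percentage of column-bootstrap replicates containing each bipartition,
with ~zero-length internal branches collapsed first so tie-broken
resolutions never receive support.

`assign_paralogs()` turns a supported tree into labels: maximal clades
with support > 75 containing anchors of exactly one reference label
inherit that label. A candidate clade that properly contains a supported
*anchorless* clade is rejected in favour of the next candidate — that
anchorless clade is what the field names as a distinct "L" paralog, and
it receives the nearest anchor's label with an L suffix (numbered by
descending clade size). Anchor labels merge into "X/Y" when no supported
clade separates them or their cophenetic separation is below
`merge_distance` (default 3× the median intra-anchor-clade distance; no
numeric threshold exists in the field for this, so the default ties the
decision to the observed within-paralog diversity). Copies outside any
supported clade fall back to their nearest anchor with provenance
`nearest-neighbor`.

`date_nodes()` is strict-clock proportional dating: after rooting on the
outgroup, a node's age is the calibration age times its mean root-to-tip
path fraction, ages clamped monotone from root to tips. It is exactly
scale-invariant and recovers simulated clock splits; it is *not* a
substitute for least-squares or relaxed-clock dating when rates vary
across branches.

## Configurations and the DCJ-indel distance

A locus configuration is the ordered, signed token string of copies and
marker genes (features < 1 kbp dropped; reverse-assembled haplotypes
flipped so the distal marker leads). Catalogs keep configurations seen in
≥ 2 haplotypes, at least once on a QC-pass haplotype, with frequencies
over all encodable haplotypes.

The rearrangement distance is the DCJ-indel model on linear chromosomes,
capping-free: double-cut-and-join operations (circular intermediates
allowed) plus insertions/deletions, each indel handling one contiguous
run of tokens private to one configuration. Duplicate token names are
matched positionally (k-th occurrence to k-th occurrence; leftovers
become indel material) — the full multiplicity-aware model needs ILP and
is out of scope for these small, marker-anchored strings.

Implementation: the adjacency graph over common markers gives
d_DCJ = N − C − I/2 and two bounds — lower max(d_DCJ, pending indel
sides), upper d_DCJ + one operation per run. When the bounds agree the
formula is the answer; when they disagree (instances with several private
runs, where run-merge credits apply) an IDA* search resolves the credit
exactly, using the deletions-before-insertions normal form: the distance
is the shortest joint move sequence bringing both configurations to a
common middle genome, each side applying DCJs or deletions of its own
private runs. The admissible heuristic is the same adjacency-graph bound,
which no single move improves by more than one. The independent oracle
(`dcj_distance_oracle()`) is a plain meet-in-the-middle breadth-first
search over the identical move model, kept free of the formula and of the
IDA* machinery; the suite asserts equality on every tested instance.
Closed-form run-count corrections alone (with or without run merging)
were each wrong on a few percent of random instances — the recombination
credit is not a function of the run pattern alone — hence the exact
refinement rather than a fitted correction table.

Two properties worth stating precisely: the distance is symmetric and
zero exactly on equivalent configurations, and over a fixed token
multiset it is the exact DCJ metric (triangle inequality included). Across
*different* token contents, plain DCJ-indel distances are known in the
rearrangement literature to admit triangle violations — deleting and
re-inserting a block can undercut pure rearrangement — and the suite
asserts the triangle property over shared-multiset triples accordingly.

Inversions are called against a reference configuration on the
marker-gene projection (marker content is copy-number invariant, unlike
the full token string): a haplotype whose projected tokens equal the
reference with one interval reversed and sign-flipped is inverted; the
interval is refined to full token coordinates when an exact-match
haplotype exists. Allele frequency is inverted / encodable haplotypes.

## IGC

PSV catalogs record every ancestral column where ≥ 2 paralog consensuses
disagree. For a copy labelled P and candidate donor Q, the caller walks
the P/Q-discriminating PSVs: a tract is a maximal run of ≥ `min_run`
consecutive discriminating PSVs carrying Q's allele, flanked by PSVs
matching P; overlapping donors resolve by longest run then lexicographic
label. `min_run = 5` balances power against conversion-like runs arising
from recurrent mutation — at the default divergence (~2% pairwise, so
~40 discriminating sites per kbp tract) a genuine 500 bp tract is
essentially always detectable, while five consecutive coincidental
matches from independent substitutions are vanishingly rare. Detection
operates on ancestral coordinates; hotspot binning projects through the
copy anchoring. Hotspots are bins above the 95th percentile of non-zero
bins (no threshold exists in the field for this; ties across all bins
yield no hotspot).

## Selection scans

`call_variants()` reads substitution columns off anchored haplotypes
(biallelic only; polarity from an outgroup base when it matches one of
the two alleles). Tajima's D uses the standard 1989 constants; windows
are non-overlapping 30 kbp tiles (independence of the percentile null),
and S = 0 windows yield missing — not zero — so empty windows cannot
dilute the percentile tails.

nS_L scores a polarized site as ln(SL_A/SL_D), where SL_A (SL_D) is the
mean, over haplotype pairs sharing the ancestral (derived) allele, of the
number of consecutive segregating sites in the maximal interval of
pairwise identity around the site. Sites need ≥ 2 carriers on both sides;
unknown-polarity sites are excluded (D is folded and keeps them). Scores
are standardised to mean 0, variance 1 within derived-frequency bins —
within the run by default, or against a supplied background
(`nsl_bin_stats()` on chromosome-wide windows), which is how the scan is
used in practice and how the power test runs: sweep-window sites would
otherwise dominate their own frequency bins and standardise themselves
away. The window statistic is the fraction of sites with |z| > 2
(windows with < 10 scored sites get none). Identity runs never extend
across separately simulated windows.

## Transcripts and the VNTR

The spliced aligner is seed-and-chain (15-mer anchors, diagonal blocks,
locus gaps ≥ 30 bp free as introns, smaller gaps absorbed as mismatches);
it expects the clean junctions of simulated reads and is not a general
spliced aligner. The mismatch-delta rule makes a call unique only when
the second-best locus has at least one more mismatch; ties are ambiguous
and abstention is the designed behaviour — the precision property (unique
calls never mislabel error-free reads) is what the paper's rule
guarantees. ORFs are the longest ATG-initiated frame among the three
forward frames (full-length cDNA is orientation-resolved; reverse-strand
scanning can be obtained by passing the reverse complement), ties to the
5′-most start, floor 50 codons (the family's proteins are ≥ 155 aa;
configurable). Gene models need ≥ 5 supporting molecules with identical
exon-junction chains, mono-exonic chains are excluded, isoforms rank by
abundance then length.

`segment_vntr_protein()` anchors repeat units on "SADD" and on "ISR"
(offset 2 inside the MIISR-type motif), takes unit lengths from
consecutive start distances (two lengths may alternate within a SADD
run), counts a trailing unit when at least the shortest unit length of
its run remains, and reports (a, b, c) — first SADD run, MIISR run,
second SADD run. `find_vntr_dna()` detects arrays by offset
self-matching: for each candidate period the best-scoring window
(match +1, mismatch −3 — the weighting that stops arrays from bleeding
into random flanks) is kept if ≥ 90% of offsets match, arrays whose
fundamental period (any divisor of p) is below 40 bp are rejected, and
the longest array wins with ties to the smallest period. Boundaries can
jitter by a few bases when flank positions match the offset by chance.

## Expression

The k-mer index takes all 31-mers of the gene models (canonical,
strand-collapsed — short-read RNA-seq is unstranded in general), removes
any k-mer present in the background genome on either strand, and marks a
transcript position uniquely identifying for a paralog when its k-mer
occurs in that paralog's models only. `merge_groups()` merges the
deficient group with the fewest unique positions into the group sharing
the most of its k-mers (ties lexicographic) until every group has ≥ 5
uniquely identifying positions — the stopping rule is the method's
defining constant; the partner rule is this package's choice, since only
the stopping criterion is fixed by the method. Reads are assigned to a
group only when they contain identifying k-mers of exactly that group;
identifying k-mers of two groups make a read family-ambiguous rather than
double-counted, preserving counts ≤ totals. Shares are computed against
family-classified totals (relative enrichment, not absolute
quantification); z-scores standardise each group's share across samples,
with one-sided normal p-values and UPGMA (average-linkage on 1 − Pearson
of z-profiles) clustering. Classification is performed directly on reads
without a prior genome alignment step; with an error-free simulator and a
background-filtered index the prefilter would be a no-op, but on real
data it removes sequencing-error k-mers this package would simply leave
unmatched. All validated isoforms feed the index.

## Problem sizes in the test suite

The suite exercises: the default simulation (20 samples / 40 haplotypes,
six paralogs, ~115 copies) end to end; 5,000 neutral and 500 star
coalescent windows for Tajima's D (plus 1,000 windows against an
independently coded closed form at 10⁻⁹); 500 + 500 neutral/sweep windows
for nS_L calibration and AUC; ≥ 110 random DCJ instances (≤ 8 tokens)
against the exhaustive oracle plus 300 shared-multiset triples for the
metric property; and 100,000 short reads for expression-share recovery.
These sizes were chosen so each property is measured with comfortable
statistical margin while the whole suite stays quick to run.

## Known limitations

* No indel mutation model, no recombination within windows, no base
  qualities; real-data robustness is untested by design.
* The homology search and spliced aligner assume substitution-dominated
  divergence and clean junctions.
* Dating assumes a strict clock; assignments assume anchors exist.
* The DCJ-indel model disambiguates duplicate tokens positionally, not by
  ILP over all matchings.
* Expression estimates are relative shares, never TPM-like absolute
  quantification.
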