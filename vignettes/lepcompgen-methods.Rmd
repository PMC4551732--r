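---
title: "Methods: heterozygosity profiling, haplotig merging and the gene-order phylogeny"
author: "lepcompgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heterozygosity profiling, haplotig merging and the gene-order phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lepcompgen)
```

# Scope

`lepcompgen` implements the bespoke computations used in comparative
analyses of highly heterozygous butterfly genomes: a 17-mer coverage
survey, a coverage-based haplotig merging rule, diploid-region SNP-rate
profiling with a one- versus two-component Gaussian mixture, per-protein
substitution enrichment statistics with GO-term follow-up, a
gene-rearrangement phylogeny built from four-state relative-orientation
characters, and an ortholog-family expansion criterion. Heavy external
stages — read assembly, gene prediction, SNP calling, disorder
prediction, maximum-likelihood/Bayesian tree inference — are out of
scope; the package consumes their outputs (FASTA, GFF3, VCF, BED-like
tables, Newick) and prepares inputs for them (relaxed PHYLIP character
matrices).

Every analysis stage is paired with a synthetic-data generator that knows
its own ground truth, so the whole pipeline is testable end to end
without any sequencing data.

# Coordinate conventions

All intervals are 0-based half-open internally. GFF3 (1-based inclusive)
and VCF (1-based positions) are converted at the boundary by `read_gff3()`
and `read_vcf()`. When a gene has several isoforms the one with the
longest total CDS is kept — a deterministic rule where annotation
pipelines disagree. Genes whose CDS length is not a multiple of 3 are
kept but flagged non-coding so codon arithmetic stays total. Ambiguity
codes other than `N` are rejected outright.

# The k-mer coverage survey

`kmer_histogram()` counts canonical 17-mers (2-bit encoding, the smaller
of a k-mer and its reverse complement; `k` must be odd so no k-mer is its
own reverse complement). In a diploid sequenced at depth $c$, k-mers from
homozygous sequence occur about $c$ times while each haplotype-specific
k-mer near a heterozygous site occurs about $c/2$ times, so the histogram
shows two peaks whose height ratio tracks heterozygosity.

`detect_peaks()` smooths the histogram with a centered moving average
(window 3), drops multiplicities below `min_depth = 3` (the error-k-mer
spike in real data), and keeps the two tallest local maxima subject to two guards: accepted
peaks must differ in multiplicity by at least a factor 1.5 (counting
noise can produce two adjacent ripples on the flank of the homozygous
peak, while a genuine heterozygous peak sits at a factor 2), and a
secondary peak must reach at least 5 % of the tallest peak's smoothed
height (otherwise a homozygous genome's noise bumps would register as
heterozygous peaks). Note the k-mer peak sits at
$c\,(L-k+1)/L$ for read length $L$, not at $c$ itself; the bundled
simulations use 500 bp reads so this factor is 0.97 and the peaks sit
essentially at $c$ and $c/2$.

`scaffold_coverage()` defines the expected diploid depth as the modal
window depth (length-weighted, integer-binned) and the diploid interval
as $[0.75, 1.25] \times$ mode — a symmetric bracket that excludes the
half-coverage peak at $0.5\times$. `flag_high_coverage()` marks runs of
windows above 4 times the mode, the coverage signature of collapsed
repeats.

# Haplotig merging

Highly heterozygous regions often assemble as two separate sequences: one
haplotype embedded in a long scaffold, the other as a standalone short
scaffold at half coverage. `merge_haplotigs()` implements the merge rule:
a candidate (mean depth in $[0.3, 0.75]\times$ the homozygous depth and
length below the assembly N50) is merged into a longer scaffold when it
is fully aligned — coverage $> 90\,\%$ and uncovered region $< 500$ bp —
to a significantly less covered region with identity $> 95\,\%$. All
inequalities are strict, exactly as stated. Two quantities the rule
leaves open are fixed as:

* *"significantly less covered"*: target-region depth below
  $0.75 \times$ homozygous depth (configurable via `depth_frac`, since
  one could argue for anything below diploid);
* *homozygous depth*: the modal window depth over scaffolds of at least
  N50 length. Restricting to the long-scaffold backbone keeps the
  estimate away from the half-coverage peak even when haplotigs make up
  a large share of the scaffold count.

Alignment is semi-global (whole query against the best local region of
the target, free end gaps on the target) with match 1, mismatch −2,
gap −2 through `Biostrings::pairwiseAlignment()`; identity is matches
over aligned columns. When one haplotig matches several targets the
highest identity wins, ties broken by longer target, then lexicographic
id; a consumed scaffold cannot serve as a target, and mutual merge
requests are an error.

# SNP-rate profiling and the mixture model

Analysis is restricted to diploid-coverage regions, partitioned into
exons, introns, repeats and intergenic sequence with precedence
exon > intron > repeat > intergenic, so the class lengths sum exactly to
the diploid length. SNP rates are computed in overlapping 1000 bp
windows; the step defaults to 100 bp (the window overlap is stated
upstream, the step is not) and windows are anchored within one
region-class interval only — windows never straddle a class boundary, so
every window rate is a pure-class rate. SNP-free segments are the maximal
zero-SNP sub-intervals of the diploid regions of length ≥ 1000 bp.

Omitting the SNP-free windows (rate exactly 0), window rates are fitted
with Gaussian mixtures: $k = 1$ in closed form and $k = 2$ by EM with a
deterministic quantile initialization (component $j$ at the
$(2j-1)/2k$ quantile), tolerance $10^{-8}$, at most 500 iterations. A
second EM start collapses both components onto the $k = 1$ solution,
whose likelihood equals the single-Gaussian likelihood exactly; keeping
the better of the two starts guarantees the nesting property
$\ell_2 \ge \ell_1$ that a single start cannot. Model order is chosen by
BIC ($-2\ell + p\ln n$ with 2 or 5 parameters) — histograms can be
eyeballed, a selection criterion cannot. Degenerate input (all rates
identical) is an error for $k = 2$.

Coding SNPs are classified synonymous / non-synonymous by locating the
codon through CDS coordinate arithmetic (minus-strand genes are read on
the coding strand after reverse complementation) and comparing
translations under the standard genetic code; a REF base that contradicts
the scaffold sequence is an error, not a silent skip. The classifier is
validated against brute-force translation of all 576 single-base codon
changes.

# Substitution enrichment

For protein $i$ with $m_i$ substitutions over $N_i$ sites, the p-value is
the binomial upper tail $P[X \ge m_i]$, $X \sim \mathrm{Bin}(N_i,
\bar p)$, with $\bar p$ the pooled substitution rate over all proteins
computed *in the same mode* as the test (all sites, or ordered-only with
disordered segments masked out of both counts and lengths).
Benjamini–Hochberg adjustment follows, flagging $q < 0.1$ (strict).
GO-term enrichment repeats the binomial construction at term level
($P$ = term frequency in the universe, $N$ = number of enriched
proteins), annotations treated as flat sets without ontology
propagation. Cross-species agreement uses the product of a term's
p-values in the two genomes, and the overlap of two enriched-term sets
is scored with the hypergeometric upper tail.

# The gene-order rearrangement phylogeny

Starting from a per-species ortholog table, families are kept when
present in every species with at most 4 copies in each. In a given
species a family is *single-locus resolvable* when all of its copies sit
on one scaffold with one consistent strand; a family pair is usable when
both families are resolvable and co-scaffolded in **every** species. The
relative orientation of the (lexicographically ordered) pair takes four
states, encoded A = $[a+, b+]$, B = $[a-, b-]$, C = $[a+, b-]$,
D = $[a-, b+]$. The letter map itself is arbitrary (any bijection gives
the same Hamming distances); what matters is that inversions act on it
predictably — flipping one member of a pair exchanges A↔D or C↔B (first
member) and A↔C or B↔D (second member). States are read relative to the
assembled scaffold orientation as given; no scaffold-flip
canonicalization is attempted (a documented caveat of draft-genome
synteny characters). All co-scaffolded pairs are enumerated, not only
adjacent ones (`adjacent only` would discard most of the signal on long
scaffolds).

Because each family may appear in many pairs, a one-pair-per-family
restriction is applied by deterministic greedy matching over pairs sorted
by family ids. Per-species state strings over the selected pairs give
Hamming distances, and the tree is built with BioNJ: standard
neighbor-joining pair selection $Q_{ij} = (r-2)d_{ij} - S_i - S_j$, NJ
two-point branch lengths, and the variance-weighted reduction
$d_{uk} = \lambda(d_{ik}-b_i) + (1-\lambda)(d_{jk}-b_j)$ with $\lambda$
chosen to minimize the variance of the reduced matrix, clamped to
$[0,1]$. Ties in $Q$ break lexicographically so results are reproducible.
On additive matrices the generating tree is recovered exactly for any
$\lambda$, which the tests exploit as an oracle; on noisy matrices the
implementation is cross-checked against an independent BioNJ.

The sequence-analysis side utilities mirror the alignment-sampling
protocol: `consistent_columns()` keeps a global-MSA column iff every
(sequence, residue) homology it asserts is also asserted by a second
aligner's output (columns asserting no pair — all-gap or single-residue —
are kept vacuously; a `min` non-gap filter can be layered on top);
`sample_column_groups()` splits a random permutation of columns into
contiguous near-equal chunks (sizes differ by ≤ 1; 570,686 columns into
100 groups gives 86 of 5,707 and 14 of 5,706) repeated 10 times for
1,000 column samples; `majority_consensus()` retains splits in strictly
more than half of a tree sample, with occurrence fractions as supports;
`topology_report()` classifies a 7-taxon tree against the two published
arrangements of skippers and swallowtails relative to the other
butterflies.

# Family merging and expansion

Ortholog families whose members share a modal closest reference homolog
(ties to the lexicographically smallest entry) are joined via connected
components and merged. A family is *expanded* in a focal species when
both its copy number and its total protein length are strictly more than
1.5 times the averages over the other species — the conjunction is
deliberate, so a burst of short fragments (count up, length flat) does
not count. Family sharing categories (1:1:1, N:N:N, clade-specific,
patchy, species-specific, unclustered) are assigned in that order with
clade definitions supplied by the caller, and always partition the
family set.

# What the synthetic data emulates — and what it does not

* `simulate_diploid()` tiles a genome with geometric-length blocks; a
  fraction is SNP-free (identity-by-descent) and each remaining block
  draws a per-site SNP rate from a two-component Gaussian mixture
  (defaults 0.35 % and 2.5 %, the two observed regimes), truncated at 0
  by resampling. Mismatches between haplotypes are independent Bernoulli
  draws.
* `simulate_reads()` draws error-free uniform reads, alternating
  haplotypes with probability ½. No sequencing errors, indels or
  coverage biases are modelled: the object of study is the peak
  structure, not error correction.
* `simulate_split_assembly()` emits blocks whose realized SNP rate
  exceeds a threshold twice — the second haplotype as a standalone
  half-coverage haplotig — and builds a 100 bp coverage track in which
  the embedded copy of a split block also has half coverage, because the
  reads of the other haplotype map to the haplotig. Optional decoy
  scaffolds (unrelated sequence at half depth) exercise specificity.
* `simulate_gene_orders()` evolves an ancestral arrangement along a
  species tree with Poisson numbers of inversions (segment reversal with
  strand flips), translocations and in-place duplications; duplications
  cap family size at 5 so the ≤ 4-copy filter has something to remove.
* `simulate_sub_profiles()` draws per-protein substitution counts
  binomially at base rate `p0 = 0.007` per amino acid — the value implied
  by a ~1 % coding SNP rate of which about a quarter is non-synonymous
  (3 nt/codon × 0.96 % × ~25 %) — with a planted enriched 5 % of
  proteins and a disordered segment at twice its protein's rate.

Passing tests on these generators show that the statistics and the
pipeline logic behave as designed under their stated models. They do not
show robustness to real-data pathologies: sequencing error, mapping
bias, assembly chimeras, annotation errors, or scaffold-orientation flips
in draft genomes.

# Problem sizes and numerical choices

The bundled end-to-end checks run at desk scale, chosen so the whole
suite completes in minutes while every estimate stays in its asymptotic
regime: 80 kb diploid genomes at depth 60 with 500 bp reads for the
coverage survey and haplotig merging (10 replicates each); 2,000
families on 16 scaffolds with Poisson(5.5) inversions per branch
(segments of geometric mean 8 genes) for the 7-taxon tree recovery (50
replicates) — small gene sets leave too few orientation flips per branch
for any distance method, so the family count is the knob that sets the
character signal; 5,000 window rates for mixture recovery; 200 null
replicates of 400 proteins for FDR calibration. EM runs to a relative
tolerance of $10^{-8}$; mixture SDs are floored at $10^{-10}$; identical
all-gap handling, tie-breaks and seeds are documented at each function.
All generators are deterministic functions of an integer seed.

# Known limitations

* Orientation characters ignore scaffold-flip ambiguity; with draft
  assemblies whose scaffolds are arbitrarily oriented, between-scaffold
  comparisons of raw states would be biased (within this package's
  simulations scaffold orientation is fixed).
* Hamming distances are not corrected for multiple hits; at high
  rearrangement rates they saturate and tree recovery degrades.
* The gene-order generator does not model gene loss, so "universal
  family" filtering is only exercised through duplication.
* GO enrichment treats annotations as flat sets; no graph propagation.
* The mixture model assumes Gaussian components on the rate scale;
  window rates are discrete multiples of 1/window, which matters only
  for very low rates.
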