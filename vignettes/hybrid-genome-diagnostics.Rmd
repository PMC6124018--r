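---
title: "Diagnosing an inter-specific hybrid genome: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing an inter-specific hybrid genome: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridseer)
```

# The problem

A first-generation (F1) inter-specific hybrid carries one complete haplotype
set from each parental species. Short-read resequencing of such an
individual, and of candidate parents and relatives, leaves several
independent signatures that this package computes and cross-checks:

* the k-mer spectrum of the hybrid's reads splits into a *heterozygous* peak
  at the per-haplotype coverage and a *homozygous* peak at twice that depth;
* genes in a haplotype-fused draft assembly can be assigned a parent of
  origin from the read support of the two candidate parents at diagnostic
  SNPs;
* in genotype space the hybrid sits midway between the two parental
  clusters, at comparable distance to both;
* at the S-locus, gametophytic self-incompatibility (GSI) forces
  heterozygosity and constrains which S-haplotype either parent can have
  donated.

The package implements each signature as an independent module and ships a
synthetic-data generator that produces all required inputs with recorded
ground truth, so every module is validated end to end.

# The synthetic cross

`simulate_parents()` draws a uniform-random ancestral chromosome and mutates
it into two species: differing sites arise i.i.d. at rate
`interspecies_divergence` (default 0.01) and each is assigned to one species,
so the species differ pairwise at that rate; each parent then receives
private heterozygosity at `intraspecies_heterozygosity` (default 0.002)
between its two haplotypes. A fraction `indel_fraction` (default 0.1) of
variant sites become 1--10 bp InDels (uniform length); the rest are
substitutions drawn with a transition probability of 0.608, which puts the
expected transition/transversion ratio near 1.55 -- the regime reported for
resequencing panels of closely related cherry taxa. Mutations are placed
i.i.d. uniform with no hotspots: the downstream statistics assume nothing
about clustering, and modelling it would buy no additional test power.

The default divergence of 1% is a free parameter of the generator, not an
empirical estimate for any particular species pair: it is large relative to
within-species heterozygosity (5:1), small enough that reads still map
trivially, and produces clearly separated k-mer peaks -- the qualitative
situation the diagnostics are designed for.

`simulate_offspring()` builds an F1 by donating one randomly chosen
haplotype per parent, or a BC1 by recombining the two F1 haplotypes at
Poisson(`bc_recomb_rate`) crossovers and pairing the gamete with one
recurrent (maternal) haplotype. `simulate_reads()` draws single-end reads
uniformly from both haplotypes at `coverage` per haplotype copy with i.i.d.
substitution errors (default 0.5%), and writes a *read-origin sidecar*
(true haplotype and start coordinate per read). The sidecar replaces an
aligner on the synthetic path: pileups are constructed exactly, so tests
measure the statistics, not mapping artifacts. Real data enters the
classifier through VCF or pileup tables instead (`read_parent_sites_vcf()`,
`read_pileup_tsv()`); re-implementing an aligner is out of scope. What the
generator deliberately does not emulate: paired-end/mate-pair structure,
quality-score error models, recombination hotspots, structural variants
beyond short InDels, and repeat-rich sequence. Passing tests therefore
demonstrate correctness of the statistics under clean mapping, not
robustness to repeat-induced mismapping.

# K-mer spectrum and genome size

`count_kmers()` counts canonical k-mers (default k = 17, odd so no k-mer is
its own reverse complement) exactly, with an overflow bin at multiplicity
10,000 -- deep repeats contribute volume but cannot form peaks there.
`fit_peaks()` smooths the histogram with a 3-bin moving average (the
published spectra are smooth curves but name no method; a minimal smoother
avoids shape distortion), takes the first local minimum as the error trough
(multiplicity 0 when the curve rises from the start), and collects local
maxima beyond the trough as candidates. Two numerical guards matter in
practice:

* candidates below 5% of the tallest candidate are dropped (`peak_floor`):
  even a random 1 Mb genome contains a hundred-odd duplicated 17-mers whose
  bump at twice the main depth would otherwise be mistaken for the
  homozygous peak of a heterozygous genome;
* a heterozygous peak is accepted only inside 0.35--0.65 times the
  homozygous depth (theory says 0.5; the window absorbs sampling noise) and
  above 10% of the homozygous peak height.

The homozygous peak is the higher-multiplicity member of the top two
candidates by height; the heterozygous peak is the remaining candidate
nearest half the homozygous depth.

`estimate_genome_size()` divides the signal k-mer volume (total instances
minus the error mass below the trough) by the homozygous peak depth for the
haploid size, and by the heterozygous peak depth for the diploid size. The
diploid formula is a deliberate design choice: every position of the diploid
genome is sequenced at the per-haplotype depth, which is exactly the
heterozygous peak depth, so volume over that depth measures the total
(two-haplotype) sequence length. It also makes the diploid/haploid ratio
equal the depth ratio of the two peaks (about 2 for a true F1), which is the
observable the published 525/257 Mb-style figures reproduce. The additive
alternative (haploid size plus heterozygous volume over heterozygous depth)
undercounts whenever only a minority of k-mers span a heterozygous site --
at 1% divergence barely 16% of 17-mers do, which would cap the ratio near
1.3 and contradict the near-2 ratio an F1 must show. Under
`basis = "read_length"` sizes use total read bases with the depth converted
by `read_length / (read_length - k + 1)`; no error mass can be subtracted
there, so with 0.5% errors it runs about 9% high -- both bases are exposed
because published methods are often ambiguous about which was used.

# Phase classification

Candidate sites are positions where parental reads may disagree. A site is
*diagnostic* when, after depth filtering (at least 2 reads per allele, the
published minimum-depth rule), the supported-allele sets of the two parents
are non-empty and disjoint. Disjointness is the load-bearing choice: at a
site where one parent is heterozygous, that parent supports both alleles, so
the site is shared rather than diagnostic, and two identical parental
species produce no diagnostic sites at all -- the control condition in which
(nearly) every covered gene must come out `COMMON`. A diagnostic site votes
for the parent whose supported allele matches the reference (assembly)
allele; votes are counted once per passing site, not per read, which keeps
the twofold rule robust to depth imbalance between parental libraries
(`--support-unit reads` would be the obvious extension; site-level is the
default and the tested path).

`classify_phase()` applies the ladder: no coverage from either parent gives
`NO_DATA`; coverage from exactly one parent (breadth at least
`min_breadth = 0.5`, so a single stray read cannot trigger the call) gives
`UNIQUE_*`; at least `fold = 2` times as many site votes for one parent
(and at least `min_support = 1` of them -- no phasing on zero evidence)
gives `PHASED_*`; otherwise `COMMON`. The boundary is sharp: 4 votes
against 2 phases, 3 against 2 does not.

The synthetic experiment (`sim_phase_experiment()`) models the
haplotype-fused assembly by picking one child haplotype per gene as the
reference; the truth donor of a gene is the donor of the picked haplotype.
In an F1 every gene carries both parental haplotypes, so phase classes
describe the haplotype the assembly happens to show -- which is why roughly
half the genes phase maternal and half paternal, and why a maternal
backcross (three quarters of gene copies maternal) shows a maternal excess.
Summaries report counts and percentages per class with `NO_DATA` excluded
from the denominator and reported separately: genes invisible to both
parents say nothing about phase, and folding them into the denominator
would make percentages depend on coverage rather than ancestry.

# Variome

The genotype matrix holds unordered diploid allele pairs against a
reference. Summaries count heterozygous SNPs, homozygous non-reference
SNPs, InDel calls, and transitions/transversions per non-reference allele
copy at biallelic SNPs (a homozygous alternate contributes two copies);
sites with more than one alternate allele stay in the totals but are
excluded from Ti/Tv and their count is attached to the result.

The distance between two samples is the number of differing alleles across
jointly called sites: per site, 2 minus the multiset intersection of the
two genotypes. Missing genotypes are skipped pairwise (per-pair
denominators, the convention of PLINK-style identity-by-state pipelines);
`normalize` divides by the denominator. InDels are included by default with
a `snps_only` switch, because the published distance matrices were built
from SNPs and InDels together.

Classical MDS goes through `stats::cmdscale` (double-centering plus
eigendecomposition); allele-count distances need not be Euclidean, so
negative eigenvalues beyond the requested axes are reported with a warning
rather than an error, and each axis is oriented so its first nonzero
loading is positive -- plots reproduce across runs and BLAS backends. The
tree is neighbor joining, implemented in the package because the published
distance-based "ML tree" is not a standard construct and because two
behaviors needed pinning down: negative branch lengths are clamped to zero
with the excess moved to the sister branch (leaf-to-leaf path lengths are
preserved, so additive inputs are still recovered exactly), and Q-criterion
ties break lexicographically on cluster labels, making the topology
deterministic. `ape::nj` serves as the independent cross-check in the test
suite, never as the implementation.

# S-locus

S haplotype units are the linked (S-RNase, SFB) pairs of each accession.
Pairwise identity uses global alignment with free end gaps (match +1,
mismatch -1, gap -2): alleles of a class differ modestly in length, so end
overhangs should not be penalized, but identity is never computed over
fewer columns than the shorter sequence -- otherwise two unrelated
sequences can "align" over a chance 10 bp overlap at 100% identity. Units
belong to one class when *both* genes reach `identity_threshold = 0.99`
(single-linkage closure); the published classification names no numeric
criterion, so the threshold is configurable and recorded in output headers.
The simulator separates classes by about 15% and allele copies within a
class by about 0.2%, so the 0.99 threshold sits far from both shoulders.
One gene linking without the other flags a putative recombinant S-locus;
an accession whose two units share a class is flagged a putative homozygote
(a GSI violation) but reported, not dropped.

Trio consistency enumerates both donor assignments of the child's pair and
requires the paternal donation to be absent from the mother (pollen
rejection); cross compatibility counts pollen classes escaping the seed
parent, keeping *semi-compatible* as its own level because inter-specific
crosses being reduced-but-not-blocked is precisely what lets hybrids arise.
The sharing network has one edge per shared class per accession pair.

# Problem sizes and reproducibility

All randomness flows from a single integer seed; identical configurations
give byte-identical FASTA/FASTQ/GFF3/TSV outputs, which the pipeline
manifest (MD5 checksums per stage) makes checkable. The validation suite
runs the k-mer stage on 1 Mb genomes at 50-fold coverage, phasing on 500
genes at 30-fold per parent, the variome panel on six accessions at 100 kb,
backcross replicates at 120 kb, and the S-locus population at 12
accessions -- sizes chosen so that every statistic is estimated well away
from its decision boundaries while a full run completes in minutes on one
core.

# Known limitations

Single chromosome by default (multi-record FASTA is supported structurally
but the experiments use one coordinate system); no repeat or hotspot
modelling, so peak fitting is untested against heavy repeat spectra; the
phase classifier consumes site tables, not BAMs -- alignment quality is the
caller's responsibility on real data; ploidy is fixed at 2 throughout; and
the S-locus clustering threshold is a tunable, so class counts on real
data are threshold-dependent.
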