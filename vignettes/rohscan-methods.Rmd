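---
title: "Methods: binned ROH detection, consequence annotation, and genotype concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binned ROH detection, consequence annotation, and genotype concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscan)
library(dplyr)
```

## The problem

A run of homozygosity (ROH) is a continuous stretch of a diploid genome
without heterozygous genotypes. In livestock, long ROHs shared within a breed
mark genomic regions swept by artificial selection; genes inside them — and
in particular genes carrying protein-affecting variants — are candidates for
the traits the breed was selected for. `rohscan` implements a complete desk
pipeline around this idea for multi-breed resequencing studies: a ROH caller
for dense genotype data, variant consequence annotation with NS/SS/I
filtering (non-synonymous SNPs, splice-site variants, coding indels),
consensus SNP-array genotyping, cross-platform and cross-breed ROH set
algebra, and chip-versus-sequencing concordance metrics. A synthetic-data
module generates every input with known ground truth, so each stage is tested
against either an exact oracle or a planted signal.

## The ROH model

Each chromosome is tiled by fixed-width bins of `bin_size` bp (default
400 kb, which is also the minimum ROH size since calls are unions of whole
bins). Within bin $i$, with $n_i$ called genotypes of which $h_i$ are
homozygous, the *degree of homozygosity* is

$$d_i = h_i / n_i,$$

undefined (`NA`) when $n_i$ falls below `min_sites_per_bin`. Missing
genotypes are excluded upstream: the degree is a ratio over called sites.
Zygosity is judged from the genotype's allele-index pair, so homozygous
reference and homozygous alternate both count as homozygous — on a SNP array
the same rule makes AA and BB homozygous and AB heterozygous.

To favour runs of high-degree bins over isolated one-bin peaks, the degree is
smoothed by a moving average over the `smooth_halfwidth = 2` neighbour bins
on each side:

$$s_i = \mathrm{mean}\{d_j : j \in [i-w,\, i+w],\ d_j\ \text{defined}\},$$

truncated at chromosome ends, with `NA` bins contributing nothing. The
window *includes* the centre bin by default. A defensible alternative reads
"the two neighbour bins on each side" as excluding the centre; we include it
because the exclusive variant lets a fully heterozygous bin sit inside a
called ROH, which contradicts the intent of a homozygosity threshold. The
exclusive variant is available via `roh_config(include_center = FALSE)`.

A ROH is a maximal run of consecutive bins with $s_i \ge \tau$, with
$\tau = 0.8$ by default — that is, up to 20% heterozygous calls are tolerated
per bin. Ties at the threshold are inside the run; an `NA` smoothed degree
breaks a run (a SNP-free bin carries no evidence of homozygosity). The
threshold is applied to the smoothed degree, not the raw one: smoothing is
what turns "a series of high-degree bins" into a single region.

Derived set algebra:

* **Specific ROHs (sROHs)** — a breed's ROH overlapping (≥ 1 bp) no ROH of
  any other breed on the same platform (`specific_rohs()`). A fragment view
  (`subtract_rohs()`) instead removes the overlapped portions, which can
  split one interval into several fragments — this is how a specific-ROH
  count can exceed the ROH count it derives from, and both counts are
  reported by `summarize_rohs()`.
* **Common ROHs** — pairwise interval intersections, used both across
  platforms within a breed and across breeds (`common_rohs()`).
* **Genes in ROHs** — a gene belongs to a ROH iff its genomic span overlaps
  it partially or completely, i.e. by at least 1 bp (`genes_in_rohs()`).

All overlap semantics are ≥ 1 bp on half-open intervals; coordinates are
0-based half-open internally, with 1-based conventions only at the VCF, GFF3
and array-TSV file boundaries.

## Consensus array genotypes

Within a breed, the consensus genotype at an array site is the modal call
among AA/AB/BB across individuals, ignoring NN. A site where everything is NN
stays NN, and a tie is NN as well: a tie carries no majority evidence, and a
deterministic, conservative rule keeps the caller reproducible. Consensus
calls feed the same binned caller as sequencing genotypes.

## Consequence annotation and NS/SS/I filters

Each variant receives exactly one category per overlapping representative
gene model (one transcript per gene; a variant overlapping no gene is
intergenic):

* SNP in CDS: the affected codon is rebuilt from the reference sequence on
  the coding strand and translated (standard nuclear code) with the
  reference versus alternate base. Same amino acid → synonymous; stop gained
  → nonsense; stop lost → readthrough; otherwise missense.
* Indel touching CDS: frameshift iff the net length change is not a multiple
  of 3, else in-frame. Net length, not affected width, decides — a deletion
  plus insertion of equal length is in-frame.
* The first and last two bases of each intron (the canonical GT/AG donor and
  acceptor dinucleotides) are splice sites. Splice-site takes precedence
  over intron and UTR; coding categories take precedence over splice-site
  only when an affected base itself lies in CDS.
* Exonic non-coding positions are 5' or 3' UTR by transcript coordinate
  relative to the CDS on the coding strand.
* Multiallelic records collapse to the most severe category across their
  alternate alleles (frameshift > nonsense > readthrough > splice >
  missense > in-frame > synonymous > UTR > intron).

The NS/SS/I set keeps missense, nonsense, readthrough, splice-site and coding
indel records. Three flags follow:

* **novel** — the site is absent from the supplied known-variant catalogue;
* **damaging** — the deleteriousness score (a SIFT-style value in $[0,1]$,
  supplied as input) is *strictly* below 0.05; a score of exactly 0.05 is not
  damaging;
* **breed-specific** — the non-reference allele is carried by exactly one
  breed, *and* at the position every breed has pooled read depth ≥ 10, *and*
  in every breed the most abundant allele's depth is at least 1.5× the depth
  of each other allele ("50% more abundant"). We read "more abundant than
  the other alleles" as a comparison against each other allele rather than
  their sum; ties fail. Candidates with missing depth in any breed cannot be
  evaluated and are excluded into a skipped-site log rather than silently
  labelled.

## Concordance metrics

`concordance_table()` matches array sites to sequencing genotypes on
(chromosome, position), reconciling alleles as A = reference, B = alternate;
allele mismatches between platforms are excluded and reported. On the
3×3+missing confusion grid:

* **overall concordance** — agreeing co-called sites / all co-called sites;
* **non-reference sensitivity (NRS)** — among truth-role variant calls
  (AB or BB), the fraction also called variant by the evaluated platform.
  Which platform is "truth" is ambiguous in chip-validation designs; the
  array is the truth role by default and `truth = "seq"` swaps it;
* **non-reference discrepancy (NRD)** — discordant co-called genotypes
  divided by co-called genotypes excluding concordant homozygous-reference
  cells (the standard definition used by variant-evaluation tools);
* **hom/het discordance** — the fraction of array-homozygous calls that are
  heterozygous in sequencing, and vice versa.

Zero denominators yield `NA`, never a silent 0. Sites called by only one
platform are excluded from concordance denominators (optionally counted as
homozygous-reference via `assume_hom_ref = TRUE`).

## The synthetic-data generator

`generate_reference()` builds random chromosomes carrying non-overlapping
2–4-exon gene models whose CDS starts with ATG, contains no internal stop,
ends with a stop codon, and whose introns carry canonical GT/AG dinucleotides
(strand-aware). `simulate_callsets()` then draws variant sites as a Bernoulli
process along the genome and assigns genotypes by tract membership:

* outside planted tracts a genotype is heterozygous with probability
  `het_frac_outside` (default 0.65) and homozygous-alternate otherwise, so
  among variant genotypes the het:hom split is 65:35 — the zygosity
  proportions typical of a deeply sequenced outbred bull;
* inside tracts, residual heterozygotes occur at `het_frac_inside` (default
  0.05) and the remaining genotypes split evenly between homozygous-reference
  and homozygous-alternate.

Read depth is Poisson (mean 45.6, emulating deep resequencing; companion
breeds in such studies are often shallower, and the depth is a plan
parameter); allele depths split the total binomially — 95% major allele for
homozygotes, 50/50 in expectation for heterozygotes — which gives the
specific-NS/SS/I depth filter realistic values to cut on. A fraction of
sites (7.5%) are indels with lengths uniform on −14..+22 bp excluding 0,
placed only where the affected bases lie wholly inside one CDS interval or
wholly outside all genes, so frameshift truth is unambiguous. Each site
enters the known-variant catalogue with probability 0.488 (the fraction of
SNPs a deeply sequenced bull shares with the public catalogue) and carries a
uniform deleteriousness score. `derive_array_matrix()` mirrors a fraction of
the SNP sites onto an array matrix (A = ref, B = alt, NN = missing) and
perturbs each cell with probability `array_error_rate` (default 0.04,
matching the few-percent discordance seen between arrays and sequencing),
recording perturbed cells as truth.

What the generator does **not** emulate: linkage disequilibrium and pedigree
structure (sites are independent given tract membership), read-level errors
(depth is summarised per site), mapping artefacts, GC or repeat-content bias,
allele-frequency spectra across individuals, and chip clustering failures.
Passing tests therefore demonstrate the correctness of the algorithms under
a clean noise model, not the field performance of ROH detection on real
data, where LD and variable SNP density blur bin degrees.

## Benchmark design

The recovery benchmark plants, per breed, two 4-bin (1.6 Mb) tracts at the
two ends of a 10-bin (4 Mb) chromosome, with a tract-free second chromosome
as negative control, at `het_frac_inside = 0.05` and
`het_frac_outside = 0.65`. The geometry follows from the smoothing
arithmetic. With background degree $\approx 0.35$ and in-tract degree
$\approx 0.95$, an interior tract shorter than five bins can never reach the
0.8 threshold after 5-bin smoothing — its best smoothed value is
$(0.35 + 3 \times 0.95 + 0.35)/5 = 0.71$ — so short-tract recovery is only
meaningful where window truncation helps, i.e. at chromosome ends. For a
4-bin edge tract the expected smoothed profile over its bins is
$(0.95, 0.95, 0.83, 0.71)$: three of four bins are called and the expected
Jaccard index against truth is 0.75, comfortably above the 0.6 the tests
require and robust to binomial noise at ~800 sites per bin. The tests run
this over 10 simulation seeds; the acceptance script over 5.

Problem sizes throughout the suite (4 Mb chromosomes, one site per 500 bp,
60 kb genomes for the classification oracles, 100 randomized instances per
brute-force comparison) are chosen so the whole suite exercises every code
path in well under a minute of simulation per scenario while keeping
binomial tolerances (3 SD) tight enough to be meaningful.

## Numerical and formatting choices

* Boundary at the threshold: $s_i = \tau$ is inside a ROH (the 20% het
  allowance is attainable, e.g. 8 hom + 2 het in a bin).
* Bins with no called sites: degree `NA`; `NA` breaks runs rather than
  bridging them.
* Consensus ties → NN; skipped depth-less specificity candidates are logged,
  not guessed.
* Mean ROH lengths are reported both rounded (round-half-even, 2 dp) and
  truncated (2 dp): published tables of this kind are sometimes produced by
  truncation — e.g. a 176.8 Mb total over 78 ROHs prints as 2.26 under
  truncation but 2.27 under rounding — and `summarize_rohs()` emits both so
  either convention can be reproduced. Totals are in Mb at 1 dp,
  percentages at 1 dp, ratios at 2 dp.
* Indel normalization trims shared trailing bases, then shared leading bases
  beyond the single anchor base, advancing the position accordingly.

## A worked example

```{r example}
ref <- generate_reference(n_chrom = 1, chrom_len = 4e6, n_genes = 10, seed = 7)
tracts <- tibble(breed = "HW", chrom = "chr1",
                 start = c(0L, 2400000L), end = c(1600000L, 4000000L))
plan <- sim_plan(breeds = c(HW = 1L), planted_rohs = tracts, seed = 11)
cs <- simulate_callsets(ref, plan)

cfg <- roh_config()
prof <- bin_profile(genotype_calls(cs$variants), ref$lengths, cfg) |>
  smooth_profile()
rohs <- call_rohs(prof, cfg, breed = "HW")
rohs

arr <- derive_array_matrix(cs, plan)
glance(concordance_table(arr$matrix, cs$variants))
```

```{r plot, fig.width = 7, fig.height = 3}
autoplot(prof, rohs = rohs)
```

## Known limitations

* One representative transcript per gene; no isoform expansion, no HGVS
  nomenclature, no computation of deleteriousness scores (they are inputs).
* The caller assumes dense, approximately uniform site coverage; sparse
  array data should use `min_sites_per_bin` deliberately.
* No LD-aware or likelihood-based ROH model (as in PLINK's scanning window
  or HMM callers); the binned degree is the method under study.
* Genome-scale published counts (millions of SNPs, genome-wide ROH numbers)
  require the original reads and chip intensities and are out of scope; the
  package reproduces the *arithmetic* of such summaries exactly and the
  *behaviour* of the methods on calibrated synthetic data.
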