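---
title: "Methods behind kelpscan: window statistics, gain/loss parsimony and molecular-evolution estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind kelpscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kelpscan)
```

kelpscan implements the downstream computational analyses of a kelp
(brown-algal) genome project as one tested pipeline: selective-sweep
scanning of cultivated versus wild populations, accession trees from
resequencing SNPs, gene-family gain/loss under Dollo parsimony,
transposable-element (TE) age distributions, Ka/Ks for duplicated genes,
family-expansion and tandem-duplication detection, and a contamination
filter for assembled contigs. This vignette explains the models, the
defaults and why they were chosen, the numerical conventions, and what the
bundled simulators do and do not emulate.

## The sliding-window sweep scan

For a window of a chromosome carrying `n` sampled allele copies and `S`
segregating sites, the package computes two estimators of the population
mutation rate θ:

* **π (nucleotide diversity)** — the mean number of pairwise differences
  between haplotypes, computed in the unbiased frequency form
  $\pi = \sum_{\text{sites}} 2 \frac{k(n_s-k)}{n_s(n_s-1)}$ with per-site
  derived count $k$ and called-allele count $n_s$. With no missing data
  this equals the all-pairs mean exactly (the test suite checks the two
  forms against each other to 1e-10).
* **θ~W~ (Watterson)** — $S / a_1$ with $a_1 = \sum_{i=1}^{n-1} 1/i$.

**Tajima's D** is their normalized difference,
$D = (\pi - \theta_W)/\sqrt{e_1 S + e_2 S(S-1)}$, with the standard
variance constants as functions of `n` only (`tajima_constants()`).
Negative D indicates an excess of rare variants (sweeps, expansions);
positive D an excess of intermediate frequencies (balancing selection,
bottlenecks). D is undefined for `S = 0` or `n < 3`; undefined windows
are excluded from all empirical quantiles and are never sweep candidates.

Sweep candidates are windows beyond the empirical tail quantiles of the
per-population D distribution (`empirical_thresholds()`, default 5% each
side, linear interpolation between order statistics — R's type-7
quantile). Consecutive or overlapping same-tail windows merge into
regions (`candidate_regions()`), labelled CN/CP for the cultivated
population's negative/positive tails and WN/WP for the wild population.
Genes overlap a region if their half-open intervals share at least 1 bp
(`genes_in_regions()`); a gene exactly abutting a region boundary does not
overlap.

Choices the underlying study leaves open, fixed here:

* **Window and step size** are not published; the defaults are 10 kb
  windows with a 5 kb step, both configurable. Because of this the
  study's published region and gene counts are not recoverable even in
  principle; the scan is validated on simulations instead.
* **Trailing windows** shorter than the window size are kept and flagged
  `partial`: S and π are window totals and D's constants depend on `n`,
  not on window length.
* **Missing data**: the `n` used for D's constants counts allele copies
  with ≤ 20% missing calls in the window; π uses per-site called counts;
  S counts any site segregating among called alleles. Missing genotypes
  are never imputed.
* **Per-population thresholds**: each population's tails are taken from
  its own D distribution, matching the four-label design; a pooled
  variant is available via the pipeline's `pool_populations` flag.
* Internally every coordinate is 0-based half-open; conversion to the
  1-based conventions of VCF happens only at file boundaries.

## The coalescent simulator

Each window is an independent Kingman coalescent genealogy: with `k`
active lineages in a population of relative size `s`, the waiting time to
the next coalescence is exponential with rate `k(k-1)/(2s)`; sizes may
change over epochs (`demography()`). Mutations are Poisson with mean
`θ/2 ×` total branch length, placed on branches proportionally to length
under the infinite-sites model (every mutation a new biallelic site, no
recurrent mutation — which makes `E[S] = θ a₁` and `E[π] = θ` exact
analytic oracles for the tests). There is no recombination within a
window; windows are independent loci. Diploid individuals are formed by
pairing consecutive haplotypes; the hom/het genotype codes flow through
the same VCF reader/writer as external data.

`simulate_two_pop()` is a joint structured coalescent for one species
sampled from two populations: a wild population at equilibrium (size 1)
and a cultivated lineage that split from it `split_time` coalescent units
ago and has since had relative size `bottleneck_severity`, with no
migration after the split. Defaults are 9 wild and 7 cultivated diploid
individuals — the sample sizes of a kelp resequencing design — with
θ = 10 per 10 kb window, severity 0.05 and split time 0.1. The study
provides no demographic estimates for cultivars; severity and split time
are free parameters chosen once to represent a severe, recent
domestication bottleneck, and they produce the qualitative contrast the
scan is designed around (cultivated π far below wild π, positive-shifted
cultivated D). They are not estimates of kelp history.

What the simulator does **not** emulate: recombination and linkage
between windows, gene conversion, selection, sequencing error, reference
bias, or missing-data structure of real pipelines. Passing tests
demonstrate correctness of the estimators and the machinery under the
stated neutral model — not robustness to those real-data complications.

## Trees from homozygous SNPs

`snp_distance_matrix()` implements the accession-level p-distance: for a
sample pair, the proportion of differing sites among sites where **both**
samples are homozygous; het or missing calls exclude the site for that
pair. A pair with no comparable site is an error naming the pair rather
than a silent zero.

`neighbor_joining()` is the classical Saitou–Nei agglomeration with two
conventions fixed for determinism: ties in the Q-criterion are broken
towards the lexicographically smallest label pair (making output
invariant to input row order), and negative branch lengths are clamped to
zero with the deficit moved to the sister branch, preserving path
lengths. On additive (tree-derived) distances NJ is consistent: the suite
verifies exact recovery of topology and branch lengths (to 1e-9) on 100
random trees of 4–12 leaves, and cross-checks the topology against the
independent implementation in ape.

`bootstrap_support()` resamples SNP columns with replacement, rebuilds
distance and tree per replicate, and reports per-bipartition frequencies
(0–100) on the full-data tree; replicates in which some pair loses all
comparable sites are skipped and counted. The default of 1,000 replicates
is the conventional choice for accession trees; tests use fewer.

## Dollo parsimony gain/loss

Under Dollo parsimony a gene family is gained exactly once and can only
be lost afterwards. For each family the gain branch is the branch above
the most recent common ancestor (MRCA) of all possessing taxa, and the
losses are the roots of the maximal absent subtrees below it — the unique
minimal-loss single-gain reconstruction (any higher gain adds at least
one loss; any lower gain cannot cover all possessing taxa). The suite
confirms this equals exhaustive search over all gain placements on random
trees. Absence is treated as true absence; annotation gaps are not
modelled.

`simulate_family_evolution()` draws each family's gain uniformly from the
branches plus the root stem, then drops Poisson(`loss_rate ×` branch
length) loss events below it, each silencing its subtree. Recovery of the
true gain branch degrades exactly when a loss silences an entire child
clade of the gain node and relocates the MRCA; on a 7-taxon tree this
makes recovery ≥ 99% only at genuinely low loss intensity (the tests use
loss rate 0.01 on 0.3-unit branches, about 0.3% of branches hit per
family), while the demo pipeline uses a richer 0.02/0.5-unit setting on
which no recovery claim is made.

## Molecular evolution

* **p-distance and Jukes–Cantor correction.** `p_distance()` counts
  mismatches over columns free of gaps and ambiguity codes in both
  sequences (indels never contribute to substitution counts).
  `jc_distance()` applies the one-parameter correction
  $d = -\tfrac{3}{4}\ln(1-\tfrac{4}{3}p)$, defined for `p < 0.75`;
  saturated inputs are an error, not a silent cap.
* **TE insertion ages.** Repeat copies aligned to their family consensus
  yield `d` per copy; `te_age_distribution()` bins copies per family
  (default bin width 0.01 substitutions/site — the published figures do
  not state a bin width), with saturated copies in an overflow bin so
  total mass is conserved. Because per-site substitution is i.i.d. in the
  simulator, `d` estimated from a 10 kb consensus recovers the true age
  within ±0.01.
* **Ka/Ks.** The underlying study used an external calculator with an
  unstated model and reports only a mean synonymous rate; kelpscan
  implements the classical Nei–Gojobori (1986) counting method as a
  documented substitution and makes no attempt to match the published
  mean. Per-codon synonymous site fractions are averaged over the two
  sequences; changes that would create a stop codon are not counted as
  synonymous opportunities but the per-position denominator stays 3, so
  `S + N = 3 ×` codons always. Differences at multi-position codon
  changes are averaged over all orderings of the single-nucleotide steps,
  excluding pathways through stop codons (falling back to all pathways if
  every ordering is blocked). `ps` and `pn` are then Jukes–Cantor
  corrected. Note that the method is undefined on very short alignments:
  a single two-fold-degenerate codon pair has `S = 1/3` site, so one
  synonymous difference gives `ps = 3`, beyond the correction's domain —
  the package raises its saturation error there.
* **Percent identity** (for tandem-duplication detection) is matches over
  aligned columns with terminal gap overhangs excluded and internal gaps
  counted as mismatches.

## Family expansion and tandem clusters

`expansion_test()` is the two-sided Fisher exact test by the
minimum-likelihood rule (the p-value sums hypergeometric probabilities of
tables no more probable than the observed one), delegated to R's
`fisher.test` and verified against exhaustive enumeration in the tests.
The conventional pre-filter keeps large families only (≥ 10 genes summed
across the two genomes — the published criterion does not state the
combination rule; the sum is used). The published "corrected P-value"
does not name a correction; Benjamini–Hochberg is the default (the usual
choice in comparative genomics) with Bonferroni available. BH output is
monotone along the sorted p-values but not idempotent — re-adjusting
adjusted values is not a no-op, which is why no such invariant is
asserted.

`tandem_clusters()` links same-scaffold gene pairs with sequence identity
≥ 0.85 (the published cut-off) and at most `max_intervening` genes
between them (default 5; the study says only "clustered … in tandem
order"), then reports connected components of size ≥ 2. Transitive
closure means a cluster may contain pairs below the threshold; the
reported `min_identity` is the minimum over linked pairs, which is the
quantity guaranteed ≥ the threshold.

## Contamination filter

For each contig, GC content is (G+C)/(A+C+G+T) with ambiguity codes
excluded, and ORF density is the union length of ATG-to-stop open reading
frames ≥ 300 nt across all six frames, divided by contig length (overlap
counted once, so density ≤ 1 — a multiply-counted "density" could exceed
1). The published rule does not define an ORF; ATG-to-stop with a 300 nt
minimum makes bacterial coding density discriminative, and a stop-to-stop
mode is available behind a flag. The filter removes a contig iff its
taxonomy hint is `candidate_bacterial` **and** (ORF density ≥ 0.60 —
inclusive — or GC strictly above 0.60 or strictly below 0.40), exactly
the published boundary semantics. Taxonomy assignment itself (BLAST
best-hit classification) is out of scope; hints arrive as labels, and the
simulator emits perfect hints so the filter's sensitivity and specificity
are measured against recorded truth.

## The demo pipeline and reproducibility

`run_pipeline()` executes simulate → scan → thresholds → regions → NJ
tree → Dollo → TE ages → QC in order, each stage writing its artifact
(VCF, TSV, Newick, JSON manifest) into the run directory; stages
communicate only via these files. All randomness flows from one top-level
seed expanded per stage by a fixed rule, so reruns with the same
configuration are byte-identical — asserted in the tests. The manifest
records every tunable with its provenance (default or user-set).

Problem sizes used by the test suite and the acceptance script — 2,000
neutral windows of 10 kb at `n = 20`, 20 replicates of 200 two-population
windows, 10 kb TE consensus, 2,000-codon Ka/Ks pairs, 100 random NJ
metrics, 200 Dollo fixtures plus 2,000 simulated families, 1,000 random
Fisher tables on top of the exhaustive small-margin stratum, 120 labelled
contigs — are the package's chosen desk-scale study conditions: large
enough that the analytic expectations bind tightly (5 standard errors on
2,000 windows distinguishes a bias of about 2%), small enough to run
comfortably on one CPU.

## Known limitations

* The simulator's independence assumptions (no recombination, no linkage
  across windows) make window statistics i.i.d., which real genomes are
  not; empirical-tail thresholds on real data select correlated window
  runs.
* NJ bootstrap resamples sites treating them as exchangeable columns;
  with linkage this overstates independence.
* NG86 undercounts at high divergence (no transition/transversion or
  codon-frequency weighting); Ks values near saturation are errors by
  design rather than extrapolations.
* Dollo treats every absence as a loss; incomplete annotations in real
  proteomes inflate loss counts.
* The contamination filter is only as good as its taxonomy hints; it
  never removes an unhinted contig no matter how biased its composition.

## A worked call

```{r example, eval = FALSE}
tp <- simulate_two_pop(n_windows = 60, seed = 1)
lens <- setNames(rep(10000, 60), paste0("w", 1:60))
scan <- sliding_scan(tp$variants, window_size = 10000, step = 5000,
                     samples = subset(tp$pops, population == "wild")$sample,
                     chrom_lengths = lens)
thr <- empirical_thresholds(scan$D, 0.05)
regions <- candidate_regions(scan, thr["low"], thr["high"], "W")
autoplot(scan, thresholds = thr)
```
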