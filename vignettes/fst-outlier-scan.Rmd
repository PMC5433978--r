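---
title: "Detecting outlier loci with density-matched bootstrap FST scans"
author: "FstScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting outlier loci with density-matched bootstrap FST scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FstScan)
```

## Scope and model

FstScan detects candidate loci under divergent selection between two
closely related populations from exonic SNP genotypes. The setting it is
designed for: small diploid samples (single digits per population),
RNAseq-derived biallelic SNPs concentrated in genes and spread over many
genome scaffolds, weak genome-wide differentiation, and a hypothesis that a
small number of genes harbour strongly differentiated clusters. The package
starts from called genotypes: read processing, variant calling and effect
annotation happen upstream, and their outputs (VCF, a sample-to-population
map, an optional per-site annotation table, scaffold lengths) are the
package's inputs.

### Per-SNP differentiation

Differentiation is measured with the two-population Weir–Cockerham moment
estimator, computed from per-population called-diploid counts $n_i$, alt
frequencies $p_i$ and observed heterozygote proportions $h_i$. The three
variance components — among populations ($a$), among individuals within
populations ($b$), within individuals ($c$) — give
$\hat\theta = a/(a+b+c)$. Properties the implementation preserves and the
tests pin down:

* $\hat\theta$ is undefined exactly when $a+b+c=0$, i.e. both populations
  monomorphic for the same allele; such sites are excluded from window
  means and from the bootstrap pool rather than zero-filled.
* $\hat\theta$ may be negative (finite-sample behaviour near zero
  differentiation); negative values are retained unmodified.
* $\hat\theta \le 1$, with equality only at a heterozygote-free fixed
  difference.
* The estimator is invariant to allele relabelling and population order.

The same equations are exercised in the test suite against an independent
oracle: a nested analysis of variance run directly on individual allele
indicators (raw sums of squares, no frequency algebra), which agrees with
the closed form to $10^{-12}$ relative tolerance. That equivalence also
covers the small-panel use case: applying `wcFstSite()` to a handful of
validation genotypes uses the identical estimator, no separate code path.

One consequence of using a per-site ratio estimator with 7 + 8 diploids is
worth knowing: the *mean of per-SNP* $\hat\theta$ values is a biased
estimate of the underlying differentiation. Under the package's own
Balding–Nichols generator with $F = 0.008$, the genome-wide
component-ratio $\sum a / \sum (a+b+c)$ recovers $0.008 \pm 0.002$, while
the mean of per-SNP ratios sits near $0.003$. Both are reported
(`MEAN_FST` and `WEIGHTED_FST` per window; both genome-wide numbers in the
acceptance script) so users can compare like with like.

### Windows

Per-SNP values are summarised in 10 kb windows advanced by 5 kb (defaults),
windows starting at 1, 1+step, ... while the start lies on the scaffold,
with the final window truncated at the scaffold end. Narrow windows are
appropriate when linkage disequilibrium decays fast, as it does in
honeybee-like genomes; both the window and step are plain arguments. Each
window reports the arithmetic mean of defined per-SNP values (the statistic
the bootstrap consumes) and the component-ratio form, since genome-scan
tools conventionally print both and they diverge for unbalanced windows.
With one SNP per window the two coincide, which the tests assert.

### The density-matched bootstrap null

Exonic SNP density varies by orders of magnitude between genes, so windows
with different SNP counts have incomparable sampling noise. The null model
treats per-SNP FST values as exchangeable across the genome: for an
empirical window with $k$ SNPs, $B$ pseudo-replicate means of $k$ values
drawn with replacement from the genome-wide pool of defined per-SNP values
form its null distribution. The exceedance count
$m = \#\{\text{replicate mean} \ge \text{observed mean}\}$ yields
$p = m/B$, and a window is declared significant only when $m = 0$ — no
simulation as extreme as observed — so a significant window has
$p < 1/B$; at the default $B = 500{,}000$ that is $p < 2\times10^{-6}$,
an appropriately severe rule given the thousands of windows scanned.

Numerical and design choices:

* One-sided upper tail, because the scan targets *elevated*
  differentiation; `lowerTail = TRUE` flips the scan.
* Ties count as exceedances ($\ge$, not $>$): conservative, and it makes a
  constant pool yield $p = 1$ rather than 0.
* The add-one estimate $(m+1)/(B+1)$ is reported alongside $m/B$, since
  $m/B = 0$ understates the attainable resolution; the decision rule stays
  $m = 0$.
* Windows sharing a SNP count share one simulated null by default —
  identical in distribution, large speedup. Per-window independent streams
  (`sharedNulls = FALSE`) derive each window's substream from the pool seed
  and the window's rank in (scaffold, start) order, so results never depend
  on iteration order. The calibration test (empirical $p$ uniform when
  windows are themselves drawn from the pool; the fraction below 0.05
  within 3 Monte-Carlo standard errors at $B = 10^4$, 500 windows) uses
  independent streams, where the binomial error bound is exact.
* The pool defaults to the full defined-FST set; a minor-allele-frequency
  filter is available (`filterMaf()`, threshold 0.05) but is off for the
  scan by default, since rare variants belong to the null the windows are
  drawn from.

### Ranking and per-gene counts

The top fraction (default 0.5%) of SNPs by FST uses the ceiling convention
— $\lceil 0.005 \times 17{,}450\rceil = 88$ — with ties broken by scaffold
then position, a deterministic stable order. Counts of top SNPs per gene,
split synonymous / nonsynonymous / other, summarise whether outliers
cluster in a gene; unannotated sites are grouped under `"(unannotated)"`.

### Comparable scaffolds

For visual comparison of a candidate region against its peers on a
fragmented assembly, scaffolds are double-ranked: all scaffolds by length
(keep ±10 ranks around the target), then that subset by SNP density (keep
±4 ranks). Bands truncate at the ends of the list; untruncated bands give
$2\times4+1 = 9$ scaffolds. Ties in length or density are broken by
scaffold id so the selection is reproducible.

### Tajima's D

Computed in nonoverlapping 10 kb windows containing at least 10 segregating
sites, and per whole scaffold. $S$ counts sites segregating in the chosen
sample (pooled by default; one population via a flag, since with both
populations in one call set the pooled sample is what a single-file run of
standard tooling would use). The pairwise-diversity term is the sum of
per-site $\pi = x(n-x)/\binom{n}{2}$ values, each using that site's called
haplotypes. Under missing data a window needs one haplotype count $n$ for
the normalising constants; the package uses $2\times$ the *minimum* called
diploid count across the window's sites — a conservative convention, chosen
because no single $n$ is exact when calls vary per site. $D$ is NA for
$S=0$ or fewer than 4 haplotypes, and is exactly 0 when the diversity sum
equals $S/a_1$.

### The haplotype network

Phased, gap-free haplotype alignments are collapsed to unique haplotypes
(multiplicity and per-population composition retained; non-ACGT characters
are rejected with the offending column, because imputing or dropping sites
silently would change distances). Connection proceeds in nondecreasing
Hamming distance order up to the parsimony limit $j_{\max}$: at each
distance $d$, every pair of haplotypes in different components — components
as they stood *before* any edge at $d$ — gains an edge, so equal-distance
alternative connections are all retained (reticulation) and the edge set is
invariant to input order. Clusters unconnectable within $j_{\max}$ remain
separate subnetworks. Each edge at $d$ steps implies $d-1$ unobserved
intermediates. With unique pairwise distances the result is the minimum
spanning tree, which the tests verify against an independent graph-library
implementation on small fixtures.

The connection limit follows the statistical-parsimony framework: the
probability that $j$ observed differences over $L$ sites arose without
superimposed change is evaluated as
$P_j = \prod_{i=1}^{j} \frac{2(L-i)}{2L-i}$ — each successive difference
must hit a previously unhit site among the remaining opportunities along
two $L$-site lineages — and $j_{\max}$ is the largest $j$ with
$P_j \ge \alpha$ (default $\alpha = 0.90$). At $\alpha = 0.95$ and
$L \approx 600$ this gives the familiar ~10-step limit. Published
implementations of the original algorithm differ in their exact internals,
so `buildNetwork()` accepts an explicit `jMax` override; the formula above
is validated in the tests against an independent log-space evaluation.

## The synthetic generator

`simulateSnpDataset()` emulates the study conditions the pipeline is meant
for, and its defaults *are* those conditions: 7 + 8 diploids, 17,450 SNPs
on 261 scaffolds, background differentiation $F = 0.008$, and a 13-SNP
cluster planted in a single gene-sized span with a 7/6
synonymous/nonsynonymous split. Where the emulated design does not fix a
value, one realistic choice was made once:

* scaffold lengths log-uniform on 50 kb–2 Mb, to exercise window truncation
  and length ranking across a realistic spread;
* genes of 5 kb placed about every 50 kb, with background SNPs allocated to
  genes by gamma-distributed weights, giving the gene-to-gene density
  variation that motivates the density-matched null;
* cluster gene span 17 kb (a typical multi-exon gene), on the
  median-length scaffold so the comparable-scaffold bands are untruncated;
* cluster allele frequencies $p_1 \sim U(0.08, 0.22)$ vs
  $p_2 \sim U(0.78, 0.92)$, calibrated once so realized per-SNP FST at
  these sample sizes centres near 0.6 within the emulated 0.38–0.79 band
  (binomial sampling noise at 15 diploids has SD ≈ 0.15, so individual
  SNPs scatter around that band; the cluster mean sits inside it);
* genotype missingness 2%, with at least one call per population retained
  per site;
* ancestral frequencies uniform on 0.05–0.95 and Balding–Nichols
  population frequencies, chosen because the construction's expected
  differentiation is the single parameter $F$ with no further machinery.

Sites that come out monomorphic across the pooled sample are redrawn — the
scan's input is by definition a set of *variable* sites. The generator
writes VCF/popmap/annotation/length/truth files and round-trips losslessly
through the reader.

What the generator does *not* emulate: linkage between nearby SNPs (sites
are independent draws, whereas real exonic SNPs are correlated within
genes), allele-frequency spectra shaped by selection and demography,
RNAseq-specific artefacts (allele-specific expression, coverage-dependent
genotype quality), or reference bias. Passing tests on synthetic data
therefore demonstrate the statistical machinery — calibration of the null,
recovery of a planted cluster over background — not robustness to those
real-data complications.

`simulateHaplotypes()` builds the network fixture: two haplogroup cores a
fixed number of steps apart, each observed (the first sequence of each
group is its core) plus per-sequence private mutations at globally unused
sites, so all pairwise distances are additive and the planted bridge is
recovered exactly.

## Reproducibility and problem sizes

A single seed governs each simulated dataset and each scan; the pipeline
expands its top-level seed into named per-stage streams, so adding a stage
never shifts another stage's draws, and reruns are byte-identical. The test
suite sizes its simulations to run in minutes on one CPU: oracle checks on
~100 fixtures of 10–25 sites, calibration at $B = 10^4$ with 500 windows,
and planted-cluster recovery over 50 seeds at 3,000 SNPs and
$B = 10^5$. The acceptance script runs the full default scale (17,450
SNPs, $B = 5\times10^5$) in about a minute.

## Limitations

* Exactly two populations; the multi-population estimator, haplotype-based
  selection statistics and LD are out of scope.
* The exchangeable-pool null ignores linkage: adjacent windows share SNPs
  and real SNPs are locally correlated, so empirical p-values are
  calibrated marginally, not jointly — the $m=0$ rule and the per-window
  floor $1/B$ are the intended safeguards.
* The parsimony connection limit is one defensible evaluation of the
  statistical-parsimony probability; exact step-limit equality with legacy
  network software is not claimed, and `jMax` can be set explicitly.
* The estimator-scale gap between mean-of-ratios and ratio-of-sums FST
  (above) means genome-wide "mean FST" numbers from different tools should
  be compared with care.
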