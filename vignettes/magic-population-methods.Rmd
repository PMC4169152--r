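---
title: "Design, simulation and analysis of eight-founder MAGIC wheat populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design, simulation and analysis of eight-founder MAGIC wheat populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magicwheat)
```

## The population and the problem

A MAGIC (Multiparent Advanced Generation Inter-Cross) population combines the
allelic diversity of many founders with the recombination accumulated over
several generations of intercrossing, making it a platform for fine-mapping
quantitative trait loci. This package implements the full desk-side workflow
for an eight-founder winter wheat MAGIC population: enumerating and selecting
the funnel crossing design, simulating realistic recombinant inbred line
(RIL) genotypes through that design, quality-controlling and summarizing
marker data, quantifying linkage disequilibrium (LD) decay, predicting
segregation ratios for monogenic recessive traits under selfing, and running
a pedigree-aware single-marker association scan.

## Funnel combinatorics and the replicated design

Founders are combined through a funnel
`{[(A×B) × (C×D)] × [(E×F) × (G×H)]}`. Excluding reciprocals, eight founders
admit `choose(8, 2) = 28` two-way (F1) crosses; pairs of founder-disjoint F1s
give `n(n-1)(n-2)(n-3)/8 = 210` four-way crosses; and pairing four-ways with
complementary founder sets gives 315 eight-way crosses, because a four-way on
`ABCD` can meet `EFGH` paired in three internal ways. The package enumerates
all three tiers explicitly and verifies them against brute-force oracles in
its tests.

A full 315-cross programme over-uses each four-way three times. The balanced
subset in which **every four-way is used exactly twice** has a clean graph
description: on the pairing graph (vertices = 210 four-ways, edges = 315
eight-ways, 3-regular), it is the complement of a perfect matching.
`select_replicated_eight_ways()` therefore removes a perfect matching (105
edges) found by a seeded randomized greedy pass with alternating-path
augmentation; the graph decomposes into 35 disjoint K3,3 blocks, on which
this repair is exact. Usage 1 returns a perfect matching itself and usage 3
the full set. Which particular 105 crosses are omitted is not determined by
the balance constraint; any valid subset is accepted, and the seed fixes one
reproducibly.

Failed crosses are replaced by the most closely related cross of the same
tier. "Most closely related" is formalized as maximal founder-set overlap,
refined by the number of shared sub-cross components (shared four-ways, then
shared two-ways) and tie-broken lexicographically, because relatedness between
crosses has no unique definition and this one is deterministic and matches
intuition (a cross sharing three founders is closer than one sharing two).

RILs are allocated to the selected eight-way families as equally as possible
(counts differ by at most one; the larger counts go to lexicographically
first families, a deterministic stand-in for the seed-set vagaries of a real
programme). Each RIL then descends from its own eight-way F1 individual
through single seed descent (SSD). Eight-way progeny are labelled F1 and each
selfing increments the label, so six SSD generations produce F7 lines.

## The forward simulator

The simulator is the package's synthetic-data engine: it emulates the
statistical structure of an iSelect-style dataset — eight fully inbred
founders, biallelic SNPs on a multi-chromosome centiMorgan map,
founder-private alleles, F7 RILs bred through the replicated funnel — without
any sequence-level detail.

* **Meiosis** uses the Haldane (no-interference) map function: recombination
  between adjacent markers $d$ cM apart occurs with probability
  $(1 - e^{-2d/100})/2$, independently across intervals; chromosomes assort
  independently and the starting haplotype is random. The map function had to
  be chosen here (centiMorgan maps do not pin one down); Haldane is the
  conventional default and makes expected crossover counts exactly one per
  Morgan, which the tests verify.
* **Descent tracking.** Founders are homozygous, so simulation happens on
  founder-origin labels; alleles are read off the founder panel afterwards.
  Every allele in every RIL therefore traces exactly to a founder, and the
  founder mosaic comes for free.
* **Residual heterozygosity is retained**: lines are not forced homozygous at
  F7, matching real F7 RILs (about 1.6% expected, $(1/2)^6$ of the eight-way
  F1 heterozygosity). The recorded per-generation mean heterozygosity lets
  tests confirm the halving law (log2 slope $-1$).
* **Founder panels.** Per marker, the number of founders carrying the minor
  allele is drawn uniformly on 1..4 by default (a flat folded site-frequency
  spectrum — a pragmatic choice, not an estimate from data); designated
  markers can be made private to a designated founder, which is how a
  monogenic recessive trait carried by exactly one founder (allele frequency
  1/8) is planted.
* **Degradation** adds independent missingness and genotyping error (a call
  is replaced by a uniformly chosen different state), enabling QC-filter
  testing.
* **Dwarf-line filtering.** Lines homozygous for designated "dwarfing"
  alleles at two loci can be flagged for elimination, mirroring the removal
  of extreme dwarfs from real programmes; this is off by default and purely
  optional.
* What the simulator does **not** model: genotyping of progeny bulks rather
  than single plants, multi-allelic markers, crossover interference, and
  selection during SSD. Passing tests therefore demonstrate correctness of
  the pipeline's logic and calibration under these idealizations, not
  faithfulness to every artefact of array data.

The default study scale (8 founders, 21 chromosomes of 150 cM, 240 markers
per chromosome, 700 F7 lines) echoes the analyzed real dataset (710 lines,
8,920 SNPs) at desk size. Tests and examples use smaller slices of the same
machinery; the sizes quoted in each test are the package's own choices to
keep the suite quick while leaving enough resolution for the property being
checked.

## Marker QC and diversity

Filters follow the printed boundary semantics exactly:

* variety-panel filter: keep markers with maf $\ge$ 0.01 **and** missing
  fraction strictly $<$ 10%;
* MAGIC analysis filter, applied in a fixed order: (1) delete lines with
  call rate $<$ 75%; (2) delete markers with call rate $\le$ 0.91 or maf
  $\le$ 0.05; (3) of every pair of remaining markers that correlate
  perfectly, remove the one later in map order (unmapped markers order after
  mapped ones, lexicographically).

Whether line filtering preceded marker filtering in the original analysis is
not stated; lines-first was chosen and is documented here — it prevents bad
lines from dragging down marker call rates. "Correlated perfectly" is
interpreted as identical genotype patterns over jointly non-missing lines,
allowing a global allele relabelling; with complete data this is computed by
a flip-invariant hash, otherwise by the exact pairwise test (quadratic in
marker count, so intended for post-QC panels).

Expected heterozygosity per biallelic marker is $H_e = 2p(1-p)$ with $p$
estimated from allele counts (heterozygotes contributing one copy of each);
no small-sample correction is applied, matching descriptive use, and the same
formula serves panels of any size, including two-founder comparisons. Panel
comparisons (`diversity_ratio`) report the $H_e$ ratio and the
segregating-marker fraction as whole percentages.

## Linkage disequilibrium

Advanced-generation RILs are treated as inbred: only lines homozygous and
non-missing at both markers of a pair contribute, each giving its single
two-locus haplotype, and no EM phasing is attempted — at about 1.6% residual
heterozygosity per line the information discarded is negligible and the
estimator stays transparent. From haplotype frequencies, $D = p_{AB} - p_A
p_B$, $r^2 = D^2 / (p_A(1-p_A)p_B(1-p_B))$ and $D' = |D|/D_{max}$ (sign
discarded, as in heatmap displays). Undefined pairs (monomorphic margins,
too few informative lines) are flagged, never silently dropped. For
genome-wide heatmaps, chromosomes are concatenated after padding each to a
nominal 250 cM, in genome order 1A, 1B, 1D, ..., 7D, and the dense matrix
carries $D'$ above the diagonal with $r^2$ below. Decay curves are lowess
fits of the statistic against intra-chromosome distance with span 0.1; the
tricube weighting and three robustifying iterations are the smoother's
standard settings — only the span was externally fixed.

## Recessive segregation under selfing

For a recessive allele at frequency $q$ in a random-mated base, $t$
generations of selfing decay heterozygosity by $2^{-t}$, half of the lost
heterozygotes becoming recessive homozygotes, so the recessive phenotypic
class has frequency

$$f(q, t) = q^2 + q(1-q)\left(1 - 2^{-t}\right),$$

running from $q^2$ (pure random mating) to $q$ (full inbreeding). The
random-mated base is taken as exact Hardy–Weinberg at the eight-way F1 — the
funnel approximates random mating among founders — and $t$ counts selfings
from that F1 to the scored generation. At $q = 1/8$, $t = 3$:
$f = 0.1113$, an expected dominant:recessive ratio of 7.98:1. Goodness of
fit uses the Pearson chi-square (1 df, no continuity correction). Ratios and
p-values are displayed at two decimals, mirroring conventional reporting;
exact values are always retained alongside.

```{r}
model <- segregation_model(q = 0.125, t = 3)
expected_ratio(model)$ratio
observed_ratio(643, 67)$ratio
round(gof_chisq(643, 67, model)$p_value, 2)
```

## The association scan

The scan fits, per marker, phenotype ~ mean + marker dosage with random
intercepts for **funnel** (eight-way family) and **cross within funnel** (the
eight-way F1 plant), the two strata through which the crossing design leaves
structure in the population. Binary traits are analyzed on the linear scale
as line means, not by logistic regression — the variance-component machinery
operates on line means, and for a nearly Mendelian trait the ranking of
markers is unaffected.

How p-values are extracted from such a model is a genuine implementation
choice. The package estimates the variance components once under the null
model (lme4, maximum likelihood), then tests each marker with a 1-df
likelihood-ratio chi-square **conditional on those components**, computed by
whitened least squares — the covariance is block-diagonal by funnel, so the
whitening is cheap. This two-stage scheme is the standard fast approach for
genome scans under a fixed covariance (the same idea as EMMAX-style mixed
models) and makes a 1,000-marker scan of 700 lines take seconds rather than
refitting a mixed model per marker. If the null fit fails, the scan falls
back to funnel strata as fixed effects with per-marker F-tests and records
that in its metadata. Missing dosages are mean-imputed per marker (the usual
GWAS convention); markers monomorphic in the scanned lines are flagged and
given no p-value, and a constant phenotype returns p = 1 everywhere.

Multiple testing uses the Bonferroni threshold $-\log_{10}(\alpha/m)$,
reported to two decimals. The peak's support interval is spanned by the
mapped markers immediately flanking it in map order (no LOD-drop method);
ties in peak selection break by map order. Conditioning on the peak marker
(`covariate_rescan`) removes it from testing and, for a single-locus trait,
removes all significant associations. Diagnostic-marker performance is
summarized by a phenotype-by-genotype concordance table with a user-supplied
rule (e.g. homozygous-alternate predicts presence), counting discordant
lines. Founder-probability (identity-by-descent) mapping is deliberately out
of scope: single-marker association suffices to localize a major locus in
this design.

## Numerical and degenerate-input conventions

* All stochastic operations take explicit seeds; identical seeds give
  bit-identical output, and temporary seeding restores the caller's RNG
  state.
* Zero-distance markers never recombine; markers on different chromosomes
  recombine freely (probability 0.5 switch at each chromosome start).
* All-missing markers carry call rate 0 and undefined maf; they are excluded
  from diversity means and counted.
* Infeasible design requests (usage outside 1..3, incomplete cross tables,
  odd vertex counts) fail with diagnostic errors rather than returning
  partial designs.
* Totals smaller than the family count allocate zero lines to the
  lexicographically last families.

## Worked example

```{r, eval = FALSE}
# design + simulate a 700-line F7 population on a 21-chromosome map
sim <- simulate_magic_study(n_lines = 700, markers_per_chromosome = 48,
                            seed = 11)

# plant a recessive trait on a founder-private allele and scan for it
causal <- sim$map$marker[sim$map$chrom == "5A"][24]
panel <- generate_founders(sim$map, 8,
                           private_allele_spec = data.frame(marker = causal,
                                                            founder = "G"),
                           seed = 12)
sim <- simulate_magic(sim$plan, sim$pedigree, panel, sim$map, seed = 13)
phen <- attach_recessive_trait(sim, causal)
scan <- magic_scan(sim$geno, phen, derive_strata(sim$pedigree), map = sim$map)
print(scan)
summary(scan, alpha = 0.01)
support_interval(scan, sim$map)
```

## Known limitations

* No crossover interference; genetic distances are honoured in expectation
  but coincidence patterns of real wheat meiosis are not reproduced.
* Founder panels are synthetic; absolute diversity values from real variety
  panels (e.g. reference $H_e$ levels) are inputs to ratio arithmetic, not
  reproducible from simulation.
* The duplicate-marker pruning step is quadratic in marker count when
  missing data are present.
* The mixed-model scan assumes a single phenotype record per line and
  homoscedastic residuals across funnels.
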