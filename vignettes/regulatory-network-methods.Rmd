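---
title: "Methods: stress-responsive miRNA-TF-gene regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stress-responsive miRNA-TF-gene regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressgrn)
```

## Overview

Plants reprogram gene expression under abiotic stress (drought, cold, salt)
through two coupled regulatory layers: transcription factors (TFs) acting on
promoters, and microRNAs (miRNAs) guiding ARGONAUTE1 (AGO1)-mediated cleavage
of target transcripts, with endogenous target mimics sequestering miRNAs in
turn. `stressgrn` implements a complete, testable pipeline that assembles a
stress-specific directed heterogeneous network from these layers and
characterizes its structure: rank-product meta-analysis of multi-study
expression data, reads-per-million (RPM) normalization and AGO1-enrichment
filtering of small-RNA libraries, complementarity-based target-site scanning,
degradome-tag validation of cleavage sites (Categories 0-4), five-edge-type
network assembly, and the structural measures (power-law degree fits,
small-world-ness, directed assortativity, strongly connected components,
centralities).

Because the original public datasets are large and external, the package
ships a seeded synthetic-data generator that reproduces the *statistical
structure* each stage assumes. Every stage is validated against planted
ground truth and independent brute-force oracles.

## Rank-product meta-analysis

Each study contributes one contrast: the per-gene difference of case and
control mean log2 intensities. Genes are ranked per contrast (rank 1 = most
extreme in the requested direction, average ranks on ties) and combined with
the rank product

$$RP_g = \left(\prod_{i=1}^{K} r_{gi}\right)^{1/K},$$

the geometric mean of the gene's ranks over the $K$ contrasts. Significance
uses the permutation-based percentage of false positives (PFP): each
contrast's rank column is shuffled independently, rank products are
recomputed, and

$$E(g) = \frac{\#\{\text{permuted } RP \le RP_g\}}{n_\text{perm}}, \qquad
  \text{PFP}(g) = \frac{E(g)}{\text{rank-position of } g}.$$

Two numerical choices matter:

* **Monotonization.** The raw ratio $E(g)/\text{rank}(g)$ is not guaranteed
  to be non-decreasing along the RP ordering, while the estimand (expected
  fraction of false positives among genes called at or before $g$) is. We
  therefore apply a running maximum in increasing-RP order, analogous to the
  step-up envelope used for q-values. The estimate stays uncapped (values
  above 1 are reported as computed).
* **Ties.** Tied effect values receive average ranks, so rank products can be
  non-integers; tied rank products share a common (maximal) PFP.

Genes with PFP below the threshold (default 0.01) in either direction are
called; a gene "significant" in both directions is contradictory and is
rejected with a warning. With three contrasts and 2000 genes the permutation
null gives $E(g) \approx N (g/N)^3 \bigl(\tfrac{1}{2}\ln^2 + \ln + 1\bigr)$
for the geometric mean of uniform ranks, which places an intrinsic ceiling
of roughly 85% on recall at PFP < 0.01 when 2.5% of genes are planted per
direction -- more studies sharpen the statistic quickly, which is why
meta-analyses of a dozen or more studies resolve far more genes than any
single pair of arms. The packaged operating point (effect size 2 on the log2
scale, replicate noise 0.5, three studies, 200 permutations) sits inside the
saturation regime of that ceiling.

## Small-RNA quantification and AGO1 enrichment

Counts are normalized as $\text{RPM} = 10^6 \cdot \text{count} /
\text{total mapped reads}$. Differential expression of miRNAs uses a
deliberately simple, documented caller: counts are pooled per arm and each
miRNA's pooled case count is tested with a two-sided exact binomial test
against the depth-proportional expectation; calls additionally require
$|\log_2 FC| \ge 1$, with a pseudo-count of 0.5 RPM used for the fold change
only. The caller is pluggable -- externally computed DE tables can be passed
straight to the downstream stages -- so a negative-binomial caller can be
substituted without touching the pipeline.

The AGO1-enrichment filter keeps a DE miRNA iff there is at least one
AGO1-associated library in which it is detectable (count > 0) **and**
accumulates at $\ge 3$ RPM. Both conditions are evaluated in the *same*
library: an accumulation rule is meaningless for an undetected miRNA, so
this is the strictest consistent reading; the bound is inclusive (exactly
3.0 RPM passes). Requiring 3 RPM in a single library rather than the mean
over libraries is the other defensible reading of the rule; single-library
is assumed and exposed via `min_rpm` only as a threshold, not a rule switch.

## Target-site scanning

The scan is a gapless, antiparallel complementarity search in the style of
plant target-prediction servers: a window of miRNA length slides along the
sense strand of each transcript and the duplex is scored per miRNA position
(0 for a Watson-Crick pair, 0.5 for a G:U wobble, 1 for a mismatch), with
penalties doubled over miRNA positions 2-13 (the seed-pairing region). The
sum is the expectation score $E$; $E = 0$ is perfect complementarity and
sites with $E \le$ cutoff (default 5.0) are reported. Gaps/bulges are not
modelled in this release: a gapless scheme keeps an exact exhaustive-window
oracle feasible, and the dominant cleavable plant sites are near-perfect
duplexes. Server defaults have historically used expectation cutoffs of
3.0-5.0; the cutoff is a configuration knob with 5.0 as default. The
cleavage position is reported as the transcript base paired with miRNA
position 10, the canonical AGO slicing geometry. `U` and `T` are
interchangeable on input.

## Degradome validation

Degradome 5'-tag profiles are mapped by exact substring match (the tag's
5'-most transcript coordinate is incremented; a tag matching several
transcripts counts once per transcript; non-matching tags are tallied). A
predicted cleavage site with tag count $t$, transcript maximum $M$, occupied
median $med$ and $u$ maxima is classified:

| Category | Rule |
|---|---|
| none | $t = 0$ |
| 4 | $t = 1$ |
| 0 | $t > 1$, $t = M$, unique maximum |
| 1 | $t > 1$, $t = M$, $u > 1$ |
| 2 | $t > 1$, $t < M$, $t > med$ |
| 3 | $t > 1$, $t \le med$ |

The median is computed over *occupied* positions only: including the zero
positions of a long transcript would make Category 2 nearly automatic, and
occupied-median is the established degradome convention. Category 4 sites
(single raw tag) still count as validated -- they are weak but real evidence
and dominate real degradome validations. When several degradome libraries
are available the best (lowest-numbered) category wins, the most permissive
reading consistent with "validated". The rules are mutually exclusive and
exhaustive for $t \ge 1$ (property-tested over random profiles), and
raising $t$ never weakens the category.

## Network assembly

Five relationship types are assembled into one directed graph: TF→gene,
TF→TF, TF→miRNA (from the regulon tables), miRNA→gene (degradome-validated
interactions of AGO1-enriched miRNAs; a miRNA targeting a TF keeps edge
type miRNA→gene with target type TF), and mimic→miRNA (target-mimic pairs
restricted to enriched miRNAs). TF edges are restricted to stress-responsive
targets (DEGs and enriched miRNAs) plus TFs on a regulatory path to one
within a configurable closure depth (default 1 hop) -- a middle ground that
yields a stress-specific subnetwork without either inventing global
inclusion or orphaning regulators. Duplicate `(source, target, type)`
triples are collapsed, orphan nodes dropped, and node types follow the
precedence TF > miRNA > targetMimic > gene so per-type counts partition the
node set. Edges are unweighted and unsigned: all downstream measures are
purely structural.

## Structural measures

* **Directed vs projected.** Assortativity, SCCs, betweenness and closeness
  are computed on the directed graph; transitivity, characteristic path
  length, diameter and small-world-ness on the undirected simple projection
  (small-world-ness is defined for undirected graphs). The average neighbor
  count uses distinct undirected neighbors, so reciprocal edge pairs count
  once.
* **Paths on disconnected graphs.** The characteristic path length averages
  over reachable ordered pairs only and the diameter is the largest finite
  distance; these networks are disconnected, so unreachable pairs are
  excluded rather than propagating infinities.
* **Assortativity.** Four flavors (in/out × in/out): the Pearson correlation
  over directed edges of source and target degrees, using total degrees at
  the endpoints (the common directed-profile convention; excess-degree
  variants are one flag away in principle but not exposed). Coefficients are
  undefined (NA) when an endpoint-degree variance is zero.
* **Closeness.** The disconnected-safe variant
  $(r/(n-1)) \cdot (r/\sum d)$ over the $r$ reachable nodes, on outgoing
  paths; nodes reaching nothing score 0.
* **Power-law fits.** Discrete maximum likelihood
  $\hat\alpha = 1 + n / \sum \ln(x_i/(x_{\min}-0.5))$ per candidate
  $x_{\min}$, selecting the $x_{\min}$ that minimizes the Kolmogorov-Smirnov
  distance between the tail's empirical CDF and the fitted law (Hurwitz-zeta
  normalization with an Euler-Maclaurin tail). Zeros are excluded and a
  reported fit requires a tail of at least 10 observations. The optional
  bootstrap goodness-of-fit p-value is not computed: the structural claim is
  about the exponent and tail shape. `igraph::fit_power_law` serves as an
  independent cross-check in the test suite, never as the implementation.
* **Small-world-ness.** $S = (T_G/T_{ER}) / (ASL_G/ASL_{ER})$, with
  $T_{ER}$, $ASL_{ER}$ averaged over Erdős–Rényi $G(n, m)$ replicates
  matched to the projection's order and size (default 100 replicates;
  replicate means control baseline variance). $S > 1$ flags a small-world
  topology; $S$ is undefined when the baseline transitivity is 0.

## The synthetic-data generator

The generator emulates, per stage: multi-study case/control log2 expression
with planted up/down genes (conserved direction, Gaussian noise);
negative-binomial sRNA counts with planted fold changes and AGO1 libraries
with a designated detectable subset (forced to ≥ 3 RPM in at least one AGO1
library, complement capped below); random transcripts with embedded
(optionally mutated) reverse-complement sites at recorded coordinates;
degradome profiles with Poisson(0.05) background and peaks placed so each
planted category is *computed and verified*, not assumed (generation retries
and fails loudly on an unrealizable plan); binomial TF regulons with a
target expected out-degree; and reference graphs (Erdős–Rényi,
preferential-attachment, ring and rewired lattices) for metric validation.

Defaults are the package's study conditions: 1000 genes, 3 studies, 3
replicates per arm, 5% planted DE entities, effect size 2 (log2), expression
noise SD 0.5 (the typical replicate residual spread of post-normalization
oligonucleotide-array log2 intensities is roughly 0.2-0.5; we use the
conservative end), 200 miRNAs at an expected depth of $10^6$ with NB
dispersion 0.1, 21-nt miRNAs, and 3 AGO1 libraries. A single RNG stream per
generator, sub-seeded from the master seed on a fixed schedule, keeps every
generator byte-reproducible and mutually independent.

What the generator does *not* emulate -- and what passing tests therefore do
not show about real data: probe effects and normalization artifacts,
read-level errors and adaptor content, multi-mapping small RNAs, miRNA
families with shared seeds, 3' UTR composition bias, and correlated
biological replicates. Recovery rates on synthetic data are upper bounds on
real-data performance of the same operating points.

## Problem sizes used in the checks

The automated checks run at sizes chosen to make sampling error small while
keeping the suite quick on a single CPU: null calibration uses 20 replicates
of 1000 genes with 200 permutations; recall uses 2000 genes; the degradome
recovery check plants 50 sites per category; metric oracles use 50 random
digraphs of up to 40-50 nodes; power-law recovery uses $10^4$ samples;
baseline checks use ER graphs up to $n = 2000$ and a rewired lattice of
$n = 1000$.

## Known limitations

* Gapless duplex scoring: bulged sites (a real minority of plant miRNA
  targets) are invisible to the scanner.
* The binomial DE caller ignores biological overdispersion between
  replicate libraries; it is calibrated for the pooled-count model it
  states, not for strongly overdispersed real libraries.
* The TF-edge closure rule is a modelling choice; published stress networks
  rarely document their inclusion rule, and different choices change node
  counts (though not the downstream measures' definitions).
* PFP resolution is bounded by `n_perm`; calls at PFP < 0.01 need at least a
  few hundred permutations to be stable.
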