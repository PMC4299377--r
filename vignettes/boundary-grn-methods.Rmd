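---
title: "Models and methods behind boundaryGRN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind boundaryGRN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boundaryGRN)
```

`boundaryGRN` reconstructs a gene-centered regulatory network for
*Arabidopsis* organ-boundary cells from three kinds of evidence:
cell-type-specific translatome counts, pooled yeast one-hybrid (Y1H)
screens of promoter fragments against a transcription-factor (TF) library,
and genotype expression series for individual TF–target pairs. This
vignette explains each model, the tunable parameters and the numerical
choices, and what the synthetic-data generator does and does not emulate.

## Translatome quantification and differential calling

Expression is quantified in RPKM units,
$\mathrm{RPKM}_{gs} = c_{gs} \cdot 10^9 / (L_g M_s)$, with $c_{gs}$ the
read count, $L_g$ the transcript length in bp and $M_s$ the sample's
column sum. A gene counts as *expressed* in a domain when its
replicate-mean RPKM is strictly above 0.5. The detection rule could also
be applied per replicate; the mean was chosen because it is robust to a
single dropout replicate, and the strict inequality makes the boundary
case (exactly 0.5) unambiguous.

Differential calling models counts as negative binomial with variance
$\mu + \phi\mu^2$. Three numerical choices matter:

* **Normalization** is median-of-ratios against the geometric-mean
  reference profile, falling back to total-count ratios when no gene has
  positive counts in every sample (tiny matrices). This guards the domain
  comparison against composition shifts that raw column sums would absorb
  into every gene's fold change.
* **A single common dispersion** is estimated by method of moments: every
  gene × domain cell with normalized mean ≥ 5 contributes its excess
  squared coefficient of variation, $v/m^2 - 1/m$, with *equal weight*.
  An earlier ratio-of-sums form ($\sum(v-m)/\sum m^2$) is unbiased too but
  lets a single very highly expressed gene dominate the estimate, which
  with three replicates makes $\hat\phi$ unstable; the equal-weight mean
  keeps its sampling error at the $\phi/\sqrt{\#\text{genes}}$ scale. With
  three replicates per domain there is no information to fit per-gene
  dispersions, so a common $\phi$ is the honest model; the test suite
  cross-checks the estimate against edgeR's common-dispersion fit.
* **The test statistic** is a per-gene likelihood-ratio test of a domain
  effect (group means fitted as count sums over size-factor sums) against
  $\chi^2_1$, followed by Benjamini–Hochberg adjustment over the tested
  genes, i.e. those expressed in at least one domain.

A call requires *both* an adjusted $p < 10^{-3}$ (strict, resolving the
printed $\le$/$<$ ambiguity conservatively) and at least a twofold change.
The reported score $\log_2((\mathrm{RPKM}_b + \varepsilon)/(\mathrm{RPKM}_l
+ \varepsilon))$ uses a pseudocount of $\varepsilon = 0.1$ RPKM so dropout
genes get finite scores; $\varepsilon$ never enters the significance test.
With $\varepsilon = 0$ a zero denominator yields an infinite score, which
is permitted but flagged with a warning.

## Set statistics

Category enrichment uses the exact hypergeometric tail
($P(X \ge k)$ for enrichment, $P(X \le k)$ for depletion). Within
`enrich_sets()` both tails are evaluated and the reported *p* is the
doubled smaller tail, capped at 1: reporting the raw minimum tail would
run at twice the nominal level on null data, which the suite verifies on
label-shuffled queries. The universe defaults to the genes expressed in
either domain — the conservative standard when the original background is
unstated. Depletion is reported through the lower tail of the same table
rather than by testing the complement list.

Association strength is the Haldane–Anscombe-corrected log odds ratio,
$LR = \log_2\frac{(k+\frac12)/(n-k+\frac12)}{(K-k+\frac12)/(N-n-K+k+\frac12)}$,
finite for every table including empty cells. The exact formula used by
the prior work this convention follows is not printed anywhere we could
verify, so the standard corrected form was adopted.

Significance conventions follow the figure-legend tiers of the original
analysis: $q < 0.01$ for GO categories, $q < 0.05$ for TF families and
hormone-response sets; `enrich_sets()` takes the cutoff as an argument.

Kernel density curves use a Gaussian kernel with Silverman's
rule-of-thumb bandwidth and a default grid spanning the data ± 5
bandwidths, so the trapezoid integral is 1 to within $10^{-2}$.
Zero-variance input is an error (the bandwidth rule is undefined), as is a
single value.

## Cis-element enrichment

The scanner counts start positions where an IUPAC pattern or its reverse
complement matches the forward strand; palindromic sites (G-box CACGTG)
are counted once, overlapping occurrences all count, and `N` in the
sequence never matches. The statistic is the *total occurrence count*
(not promoters-with-a-hit): the per-position background rate $\lambda$ is
estimated from the background collection over its scannable positions
(length − motif length + 1 per promoter, strands collapsed), and the query
total is tested with an upper-tail binomial over the query's scannable
positions. The expect value is $E = p \times \#\text{motifs tested}$ and
the reporting cutoff is $E < 10^{-4}$. A motif never seen in the
background gets a rate floored at $1/(2 \cdot \text{background
positions})$ — half an occurrence — and a log message. The binomial null
treats positions as independent, which degenerate patterns (e.g. WGATAR)
violate slightly through overlapping hits; for the rare elements this
pipeline targets the approximation is standard.

The shipped dictionary is deliberately small (G-box, ABRE, GATA box) and
user-extensible via a two-column table; it is a starting point, not a
curated genome-wide catalog.

## Pooled Y1H deconvolution

The screening model mirrors the bench protocol: baits are tested for
auto-activation first and excluded; prey TFs are transformed in pools of
four; a pool is *positive* only if it grew on selective medium **and**
its transformation control grew; a failed control makes the pool invalid
— queued for one repeat in the simulator, since the real repeat policy is
not documented — and never positive. Members of positive pools are
screened individually, and a PDI is reported only when the individual and
its retest both pass (one retest round; more were not documented).
Positive pools whose individuals all fail are logged as discordant rather
than silently dropped. Growth is binary; colony size and antibiotic
dose–response are out of scope.

## Network summaries and hub detection

The network is bipartite (TF → fragment) with screen dimensions $T$ (TFs
screened) and $F$ (usable fragments) carried separately from the bound
counts, because the published percentages are quoted against the screen,
not against the bound sets. Percentages are kept unrounded internally and
rounded half-up to one decimal only at presentation (`round_half_up()`);
R's default half-to-even rounding does not reproduce printed values like
63.1. One printed figure (67.7% of regions bound, where 23/34 = 67.65%)
cannot be reproduced under any single rounding convention, so that
statistic is summarized but never asserted against the printed value.

Hub detection scores each fragment's degree $k$ against a uniform-edge
null: the $n$ observed edges are treated as draws without replacement
from the $F \times T$ pair population, of which $T$ pairs involve the
fragment, giving $p = P(X \ge k)$, $X \sim \mathrm{Hypergeometric}(FT, T,
n)$, BH-adjusted across fragments. The test names only "hypergeometric";
uniform edges over the screened pair population is the natural
gene-centered null. An explicit fragment → region map can merge adjacent
fragments before testing (a hub can span two overlapping fragments); a
merged region's null share scales with the number of fragments it covers.
Ties in the ranking are broken by degree.

## Regulatory direction and edge classes

For each TF–target pair, target expression $y$ is regressed on TF
expression $x$ across genotypes (wild type, loss-of-function mutant,
over-expressor) by weighted least squares; the slope's sign gives
activation or repression, its two-sided $t$-test ($\mathrm{df} = n - 2$)
the confidence, at $\alpha = 0.05$ — the single-asterisk convention of
the underlying qPCR figures. Design choices:

* Weights are inverse within-genotype replicate variances of $y$, with
  the variance floored at $(0.05\,\bar y)^2$: an accidentally noiseless
  genotype would otherwise receive unbounded weight. On perfectly
  collinear data the fit is weight-invariant (verified in the suite).
* The mutant contributes points at its *measured* near-zero TF
  expression; it is not forced to $x = 0$, since knockouts retain
  transcript background.
* All-identical $x$ is an error (slope unidentifiable), as are fewer
  than three points.

Classification combines the call with the TF's boundary status from the
translatome: enriched activator or depleted repressor → *regenerative*
(the regulation reinforces the target's boundary expression); enriched
repressor or depleted activator → *degenerative*; any no-effect call or
status-neutral TF → *neutral*. Summaries report unrounded percentages
(8/30 is 26.67%, whatever a rounded figure elsewhere may say).

## The synthetic-data generator

The generator exists so that every stage can be scored against a planted
truth; the truth objects are emitted alongside the data and are never
read by any pipeline stage. Defaults encode the study conditions the
pipeline assumes: three biological replicates per domain; 1.7% of genes
planted boundary-enriched and 3.2% depleted at fourfold; negative
binomial counts at dispersion $\phi = 0.05$ (a typical replicate-level
value for this kind of data); pools of four; a hub fragment holding 50%
of the 40 planted PDIs; observation-level false-positive/negative rates
of 1%/5% for the growth assay; and genotype series at WT $x \approx 1$,
mutant $x \approx 0.02$, over-expressor $x \approx 4$ with replicate
noise $\sigma = 0.1$ and planted slopes $\pm 2$ mixed 50/23/27
activation/repression/no-effect. Gene, TF and fragment numbers are
desk-scale (2,000 genes at a library size of $2\times10^5$; 120 TFs × 12
fragments) so the full suite runs in minutes; the genome-scale dimensions
(≈27k genes, $2\times10^7$ reads, 1,184 TFs × 34 fragments) remain
reachable by configuration. One global seed feeds fixed per-generator
substreams, so each module's data can be regenerated in isolation.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: GC and mappability bias, length-dependent
counting noise, correlated replicates, per-gene dispersion trends,
positional or strand bias of cis-elements, plate-layout artifacts of the
Y1H screen, and TF cross-talk in genotype series (each pair is simulated
independently, one TF at a time). Promoter backgrounds are i.i.d. bases,
so motif clustering in real promoters is absent. Boundary status in the
regulatory truth is planted per TF, not derived from the simulated
counts, so end-to-end label recovery measures the modeling chain, not the
translatome caller (which is scored separately).

## Problem sizes and runtime

The default validation sizes — 2,000-gene null matrices (20 replicate
simulations), 100 power simulations at 500 genes, 50-seed screen
round-trips at 120 × 12, 100 + 100 hub simulations, 200-seed slope
recovery, 50 + 50 motif-enrichment simulations and a 10-seed end-to-end
run — were chosen so the complete suite finishes in about two minutes on
one CPU while keeping every Monte-Carlo acceptance margin several
standard errors wide. The acceptance script uses the same machinery at
slightly smaller replication and runs in seconds.

## Known limitations

* The differential engine assumes a common dispersion; strongly
  gene-specific overdispersion would inflate its error rates (use the
  dedicated count-model packages for such data).
* The hub null ignores fragment-specific bindability (length, chromatin
  context) — a fragment may rank as a hub because it is easy to bind in
  yeast.
* The motif model is enumerative: no position-weight matrices, no
  positional preference, no de-novo discovery.
* The list-overlap test is exact but its famous printed significance
  levels depend on the chosen universe; with a different background the
  same overlap gives a different $p$, so no particular printed value is
  claimed reproducible.
* WLS fits are per-pair, linear and single-TF; combinatorial regulation
  and saturation are not modeled.
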