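---
title: "Auditing GWAS associations against expression and chromatin: methods"
author: "regaudit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing GWAS associations against expression and chromatin: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regaudit)
```

# The problem

Most trait-associated variants found by GWAS are non-coding, and the
standard model holds that they act by changing the expression of nearby
genes. `regaudit` implements a gene-anchored audit of that model: start
from genes already known to be causally linked to a trait through their
coding variants (Mendelian cognate disorders, burden tests), and ask,
stage by stage, whether the GWAS signal at those genes can actually be
tied to expression — or at least to regulatory chromatin. The stages
are:

1. **Coding-variant conditioning** — remove coding effects so the
   remaining signal is non-coding.
2. **Proximity enrichment** — are the candidate genes closer to GWAS
   loci than random genes?
3. **eQTL discovery** — do the genes have eQTLs in trait-relevant
   tissues, at an FDR that honestly accounts for unreported tests?
4. **Colocalization** — are the GWAS and eQTL associations driven by
   the same variant (ABF posteriors, CLPP on fine-mapping posteriors)?
5. **Chromatin** — do fine-mapped variants fall in regulatory DNA, and
   does the activity-by-distance (ABD) score tie the strongest feature
   to the gene?

Everything runs on synthetic studies produced by the package's own
generator, so the full pipeline is testable on a laptop with no
external data.

# Data containers and coordinates

Summary statistics live in `AssocTable` (S4, validity-checked: `se >
0`, `z = beta/se`, `p` consistent with the two-sided normal, unique
variant ids, positions inside the locus span). LD is an `LDMatrix`
(symmetric, unit diagonal, positive semi-definite within `1e-8`).
Interval data — narrowPeak tracks, ChromHMM segments, regulatory
features, blacklists — are `GRanges`.

BED input is 0-based half-open; point positions (variant `pos`, gene
TSS) are 1-based. The single conversion lives at the read/write
boundary: BED `[start, end)` becomes GRanges `[start+1, end]`, so a
1-based point `p` lies in a BED interval iff `start < p <= end`, which
is exactly native GRanges containment. Round-trips through the writers
reproduce BED coordinates byte-for-byte.

# The synthetic-study generator

`simulateLocusPair()` draws the GWAS and eQTL z-vectors from
$z \sim \mathcal{N}(R\lambda,\; R)$ where $R$ is AR(1) LD
($R_{ij} = \rho^{|i-j|}$, positive semi-definite by construction) and
$\lambda$ carries the causal variant's non-centrality. Effects are on
the standardized scale, $se = 1/\sqrt{n}$, $\beta = z \cdot se$, which
is the scale every downstream operation consumes. Cholesky
factorization gets a `1e-8` diagonal jitter if it fails (edited
matrices may be numerically indefinite).

Defaults are chosen once to emulate the study's conditions: 50 variants
per locus, $\rho = 0.9$ (dense local LD), GWAS $n = 10{,}000$, eQTL
$n = 500$ (GWAS an order of magnitude better powered than a
tissue-level eQTL panel), causal non-centrality 8 (a clearly
genome-wide-significant locus), half of the genes sharing a causal
variant between trait and expression. Histone peaks are exactly 150 bp
wide — the imputed-track width the feature builder extends — with
log-normal signal strengths; DHS widths are 100–400 bp; ChromHMM tiles
partition each locus with about 20% enhancer states.

Two structural choices matter for interpretation:

* The causal variant and its AR(1) neighbours (within 10 positions) are
  forced to be *non-coding* in the pext table. The audit's premise is
  that the signal surviving coding-variant conditioning is non-coding;
  if the generator let the causal variant be coding, conditioning would
  (correctly) erase the locus and the emulated study structure — most
  genes staying near a GWAS locus after conditioning — would not hold.
* The truth table records, per gene, which causal variants were planted
  and whether they are shared, so recovery rates are measurable without
  any circularity.

What the generator does **not** emulate: realistic human LD (block
structure, allele-frequency-dependent correlation), genotype-level
sampling noise in the LD reference, allelic heterogeneity, sample
overlap between GWAS and eQTL panels, or winner's-curse effects.
Passing tests therefore demonstrate correctness of the statistics and
the pipeline's logic under a clean generative model, not performance on
real cohort data.

# Stage methods and their parameters

## Coding-variant selection and conditioning

Two pext filters (`selectCodingVariants()`): a gene is excluded when
its expression in the trait-relevant tissue is below 50% of its
maximum across tissues; among retained genes, a variant counts as
commonly coding when it falls in the coding sequence of at least 25% of
splice isoforms ("less than 25%" is a strict exclusion, so exactly
0.25 passes).

`conditionalZ()` removes selected variants' effects using only summary
statistics and LD:
$$z_{t|C} = \frac{z_t - R_{tC} R_{CC}^{-1} z_C}
                 {\sqrt{1 - R_{tC} R_{CC}^{-1} R_{Ct}}}.$$
A ridge term $\lambda = 10^{-4}$ on $\mathrm{diag}(R_{CC})$ guards
near-singular conditioning sets, and targets whose residual variance
falls below $\varepsilon = 0.01$ are dropped as collinear and reported.
Both guards are explicit package choices: the conditioning literature
delegates collinearity handling to tool internals without printing the
cutoffs. On small loci with $\lambda = 0$ the implementation agrees
with a least-squares projection oracle to $10^{-6}$.

## Locus calling and enrichment

`callGwasLoci()` clumps greedily: smallest p below $5\times10^{-8}$
becomes a lead, absorbs everything within 1 Mb, repeat. Both the
threshold and radius are exposed; they are field conventions, since no
published locus-calling rule accompanies the audit design.
Gene-to-locus distance is TSS-to-lead (one anchoring convention
throughout, matching the TSS-anchored ABD machinery), and "within the
window" is inclusive. Enrichment is a two-sided Fisher exact test on
the candidate/background x near/far table plus a resampled null: draws
of $|$candidates$|$ genes without replacement from the pooled gene
list, summarized by the null mean and a 2.5–97.5 percentile interval.
The interval is taken from the resampled distribution directly —
resampling genes, not loci — with no distributional assumption.
Mismatched-trait controls re-run the test for a fixed-point-free
rotation of gene sets against other traits' loci.

## eQTL FDR with an inflated test count

Public eQTL releases report only part of the variant-gene tests
actually performed, so a BH correction over the observed list alone is
anti-conservative. `adjustedBH()` runs the BH step-up as if the test
count were $c \cdot m$:
$$q_{(i)} = \min_{j \ge i} \min\!\left(1,\; p_{(j)} \frac{c\,m}{j}\right),$$
with $c = 20$ by default (the factor that calibrates against
genome-wide eQTL FDR results). The factor multiplies the test count
inside the procedure — not the p-values after adjustment — which is the
reading that reduces exactly to textbook BH at $c = 1$ (verified
against a brute-force oracle and `p.adjust`). The unit entering FDR is
the minimum variant p per gene-tissue pair; a gene has an eQTL if any
relevant tissue is significant at $Q < 0.05$. Applying min-p per
gene-tissue (rather than per gene across tissues) is a documented
choice; both readings are defensible and the per-pair one keeps
tissue-level calls available downstream.

## Fine-mapping and colocalization

Per variant, the Wakefield approximate Bayes factor uses
$V = se^2$ and a normal effect prior with $\sqrt{W} = 0.15$
(quantitative-trait convention):
$$\log ABF = \tfrac12\log\frac{V}{V+W} + \tfrac12 z^2\frac{W}{V+W}.$$

`finemapPIPs()` with `L = 1` is the exact single-causal-variant
posterior: PIPs are the softmax of log-ABFs. For `L > 1` it repeats the
single-effect computation, residualizing the z-scores by conditioning
on the accumulated top variants, and combines rounds as
$PIP_i = 1 - \prod_l (1 - PIP_{il})$. This stepwise scheme is a
deliberate, documented approximation to a sum-of-single-effects model:
it keeps the per-round posterior exact and is transparent to test, but
it lacks the variational refinement of the full algorithm and can
misattribute mass when effects sit in strong mutual LD. The default is
`L = 3` for GWAS loci and `L = 1` inside CLPP.

`colocABF()` combines the two traits' ABFs into five hypothesis
posteriors with priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$
(the cited defaults; the audit does not print its settings). All sums
run through log-sum-exp; H3 excludes same-variant pairs exactly via a
log-space difference, so a single-variant locus has $PP_3 = 0$
identically and normalization holds to $10^{-9}$ even at extreme
z-scores. CLPP is the per-variant product of the two PIP vectors,
summarized by its maximum. Hit thresholds: $PP_4 \ge 0.8$ and
$\max CLPP \ge 0.01$ (community conventions, config-exposed).
High-confidence fine-mapped variants are those with $PIP > 0.7$ within
100 kb of the gene TSS. Because the audit's headline colocalization
counts were reported without a full multiple-testing correction, the
hit flags here are raw per-locus calls; users can apply `adjustedBH()`
to the per-locus evidence if a corrected count is wanted.

## Chromatin features and ABD

`buildHistoneFeatures()` follows, per mark: extend 150 bp peaks by
175 bp on both sides (500 bp candidates) → drop features overlapping
the blacklist by ≥ 1 bp → re-center a 500 bp window on the summit
(interval midpoint if the summit is absent; the summit offset is
shifted along with the extended start) → merge overlaps within the
mark → union and merge across the three marks. The activity $A_F$ is
the geometric mean of per-mark strengths over the marks actually
present (a strict three-mark mean would zero any feature lacking one
mark, contradicting the cross-mark merge), where a mark's strength is
the maximum signalValue among its peaks overlapping the feature
(order-independent and merge-stable). Non-150 bp inputs are processed
with a warning, still extended by 175 bp.

DHS features keep sites within 100 kb of a candidate TSS, re-center in
350 bp windows, merge, and average strengths arithmetically.

The ABD score of feature $F$ for gene $G$ is
$$ABD_{F,G} = \frac{A_F / d_{F,G}}{\sum_{f \in W} A_f / d_{f,G}},$$
with $d$ the TSS-to-feature-midpoint distance floored at 250 bp (half
the feature width) so a TSS-spanning feature cannot dominate through a
vanishing denominator. The histone denominator window $W$ is ±5 Mb; for
DHS the denominator runs over the ±100 kb-selected set by default
(`window` argument), since the published description is ambiguous
between the two readings — the package defaults to the selected set and
exposes the switch, making no claim about original intent. A gene is
top-ABD-implicated iff a high-PIP variant lies inside its single
highest-scoring feature (ties: smaller distance, then leftmost start).

Enhancer annotation matches ChromHMM state labels by substring against
`{"Enh", "EnhG", "EnhBiv"}` — enhancer, genic enhancer, bivalent
enhancer — because label spellings vary across model releases.

**Known limitation.** Re-processing the feature builder's own output is
a no-op for unmerged 500 bp features (the symmetric extension preserves
the midpoint, so re-centering reproduces the window). A merged feature
wider than 500 bp, however, is re-centered back to 500 bp on a second
pass; idempotence is therefore guaranteed — and tested — only for
non-merging output.

## Verdicts

`geneVerdicts()` collapses tissue-level results by "any relevant
tissue" and enforces, rather than repairs, the logical contract: a
colocalization hit implies an eQTL and a nearby locus; a top-ABD hit
implies a high-PIP variant. The pipeline satisfies the first clause by
construction, attempting colocalization only for genes near a called
locus with an eQTL — which is also the only regime where a
colocalization result is interpretable. The tissue-trait map is a
config table, not code: tissue relevance is prior biological knowledge,
a user input.

# Numerical choices, degenerate inputs, problem sizes

* Log-sum-exp throughout coloc and fine-mapping; `log1p`-based
  log-space subtraction for H3 with clamping at zero mass.
* Cholesky jitter `1e-8`; conditioning ridge `1e-4`; collinearity floor
  `0.01`; ABD distance floor 250 bp; LD PSD tolerance `1e-8`.
* Empty inputs return empty, typed results (empty peak files, loci
  without significant variants, genes without features in window);
  misaligned variant lists raise errors rather than intersecting
  silently.
* Ties in locus calling resolve by the smallest p first (greedy order);
  ties in top-ABD by distance then start.
* The test suite and acceptance script use Monte-Carlo sizes of
  200–2000 replicates at loci of 10–50 variants, and end-to-end runs of
  2–10 genes — sizes at which every stochastic bound was pre-registered
  from oracle runs and at which the whole suite completes in a few
  minutes on one core.

# What the tests do and do not establish

The oracle equivalences (BH, Fisher, coloc enumeration, least-squares
conditioning), normalization contracts, and structural invariants are
exact statements about the implementation. The recovery rates (type-I
calibration, residual z after conditioning, shared-vs-distinct
colocalization separation, fine-mapping recovery) are statements about
the implementation *under the generator's clean MVN/AR(1) model*. They
show the statistics are wired correctly and powerful in the regime they
were designed for; they do not certify behaviour under real LD
mismatch, allelic heterogeneity, or sample overlap, which the generator
deliberately does not model.
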