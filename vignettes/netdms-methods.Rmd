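---
title: "netdms: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{netdms: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Single-marker GWAS analysis discards the many weakly associated markers
between genome-wide significance and noise. `netdms` implements a
network-assisted gene-set strategy for such data: SNP-level P-values are
combined into gene-wise P-values, the genes become weighted nodes of a
protein–protein interaction network, and densely connected high-weight
subnetworks ("modules") are extracted, standardized against an empirical
null, and evaluated by SNP-resampling and pathway enrichment.

## Gene-wise P-values

A SNP maps to a gene when it lies within the gene body extended by a
50 kb flank on both sides (1-based, closed intervals); a SNP may map to
several genes, and analysis is restricted to autosomes by default because
the LD machinery does not handle sex chromosomes. Three combination
strategies are provided:

* **all** — the observed statistic is $T = \sum_i q_i$, where $q_i$ is the
  upper-tail 1-df $\chi^2$ quantile of SNP $i$'s P-value. Its null
  distribution is simulated by drawing $z \sim \mathrm{MVN}(0, R)$, with $R$
  the LD (correlation) matrix of the mapped SNPs estimated from a reference
  genotype panel, and forming $T^* = \sum_j z_j^2$.
* **top** — the same construction on the $m = \max(1, \lceil 0.1 k \rceil)$
  largest $q_i$; each null draw contributes the sum of *its own* $m$
  largest $z_j^2$, so the selection step is part of the null and the test
  stays calibrated.
* **minp** — the smallest SNP P-value, uncorrected. This classical strategy
  is included as the comparison baseline; it is deliberately *not*
  adjusted, so its gene-length and SNP-density bias is visible in the
  `length_bias_diagnostic()` output.

The empirical P-value is $(1 + \#\{T^* \ge T\}) / (1 + B)$ — never zero, so
the weight transform stays finite. $B$ follows an adaptive schedule
(1,000 draws, escalated to 10,000 when $p < 0.1$ and to 100,000 when
$p < 0.01$, capped by `max_sims`): cheap for the uniform bulk, stable for
the small P-values that determine seeds and node weights. Each gene draws
from an RNG substream derived from `(seed, gene id)`, so results are
independent of gene processing order.

Node weights are $z = \Phi^{-1}(1 - p)$ with $p$ clamped into
$[10^{-12}, 1 - 10^{-12}]$.

### LD estimation

Pairwise Pearson correlation of additive genotype codes on
pairwise-complete samples; monomorphic SNPs and SNPs absent from the
reference are dropped with a report. Pairwise-complete correlation
matrices need not be positive semi-definite, so the estimate is repaired
by clipping negative eigenvalues at zero and re-normalizing to a unit
diagonal; the same eigendecomposition then provides the square-root factor
used for the MVN draws.

## Module search

The module score is Stouffer's combination
$Z_m = \sum_{i=1}^k z_i / \sqrt{k}$. The source material typesets the
denominator ambiguously ($\sum z_i / k$), but names Stouffer's method and
builds on prior work using $\sqrt{k}$; the package therefore uses
$\sqrt{k}$ (a plain-mean mode is available via
`search_params(denominator = "k")` for comparison — with a mean,
equal-weight growth can never satisfy a proportional improvement rule, so
it is not the default).

`grow_module()` grows greedily from a seed: all nodes within shortest-path
distance $d = 2$ of the *current module* are candidates (the
module-anchored reading; a seed-anchored mode exists for sensitivity
analysis), the best candidate is the one maximizing the new score (ties:
lexicographically smallest gene id), and a step is accepted only when
$Z_{m+1} > Z_m (1 + r)$ with $r = 0.1$. For $Z_m \le 0$ the rule is applied
as $Z_{m+1} > Z_m + |Z_m| r$, which is identical for positive scores and
avoids the pathology where any less-negative score would pass.

`restricted_search()` takes seeds in descending weight order; a grown
module with at least `min_size = 5` members is recorded and its members
removed from the background network, so recorded modules are pairwise
disjoint and each node is used at most once. A seed whose module stays
below the minimum size is disqualified *as a seed* but remains available
as a member of later modules. All tie-breaks are lexicographic: the search
is fully deterministic.

### A structural consequence of the growth rule

With near-equal member weights, the score grows like $\sqrt{k}$, and the
acceptance ratio for the $(k{+}1)$-th member of a fully visible candidate
set is at most $\sqrt{k/(k{+}1)} \cdot (k{+}1)/k$, which drops below
$1 + r = 1.1$ exactly at $k = 5$. A planted *clique* of equal weights is
therefore always truncated to 5 members, for any weight level — provable
from the greedy order, and covered by tests against an independent
step-by-step calculator. Modules larger than 5 arise only when high-weight
nodes enter the candidate frontier *after* lower-weight ones (chains,
rings, hub attachments), which is also why the end-to-end planted-module
test wires its module as a ring with chords rather than a clique.

## Module significance

Greedy selection inflates module scores, so raw $Z_m$ values are
standardized against an empirically fitted null: scores are centered at
their median, and a normal $N(\delta, \sigma)$ is fitted to the central
50% by maximum likelihood with the scores outside the central quantile
window entering only through their counts (censoring). Tail magnitudes —
where genuinely enriched modules live — cannot distort the fit, while the
window-mass information keeps the estimate efficient. A pure
truncated-window likelihood was evaluated and rejected: it has spurious
flat directions (distant location, huge scale) that occasionally diverge
on real module-score sets, and even at its best it is an order of
magnitude noisier. The location is constrained to the window and the
scale to a band around the window width; if the score distribution is
degenerate ($\sigma < 10^{-6}$) the fit aborts with a diagnostic. Runs
with fewer than 20 modules fall back to an exact standard-normal null
(`null_fit_exact()`).

Module P-values are $P = 1 - \Phi(Z_S)$ with
$Z_S = (Z_m' - \delta)/\sigma$ and $Z_m'$ the median-centered score.
Modules with raw $P < 0.05$ are selected (no multiple-testing correction
at this step: observed selection fractions around 5% match that reading),
and their genes are pooled into one gene set.

## SNP-resampling evaluation

The pooled module genes — and a pathway collection size-filtered to
[5, 300] — are evaluated by the resampling scheme of the ALIGATOR family:
the *real* significant genes are those with at least one mapped SNP with
$P$ strictly below 0.05; each resample draws SNPs uniformly without
replacement and collects the genes containing a drawn SNP until their
number reaches the real count. A drawn SNP hits its gene regardless of its
own P-value: the resampling null models where a random SNP collection
lands, which is what corrects the real count for gene length and SNP
density. (Making resampled hits conditional on the drawn SNP's P-value
degenerates the procedure — resampled sets then reproduce the real set
exactly and every category P-value is 1 — so that reading was rejected.)

Per category $C$, the empirical P-value is
$\max(1, \#\{b: \text{count}_b \ge x_C\})/B$ with $x_C$ the real overlap;
the $1/B$ floor reproduces the published behaviour of the procedure at
$B = 10{,}000$ ($P = 1.0\times10^{-4}$). Benjamini–Hochberg correction is
applied across all tested sets with an explicit total test count
`m_total` (the count of tested sets by default; exposed as a flag because
the effective family size in published analyses is not always
recoverable).

## Pathway enrichment

Upper-tail hypergeometric test of the pooled module genes against each
pathway, with the background-network node set as the gene universe
(configurable to the scored-gene universe); set members outside the
universe are discarded before testing. Bonferroni correction across the
collection.

## The synthetic world

`synthetic_config()` defaults describe the standing test world:

| parameter | default | meaning |
|---|---|---|
| `n_samples` | 1000 | reference-panel samples |
| `n_genes` | 500 | autosomal genes, log-normal lengths (median ≈ 20 kb) |
| `snps_per_gene` | 3–8 | SNP count, increasing with gene length |
| `ld_block_rho` | 0.7 | exchangeable latent LD within a gene block |
| `pa_m`, `pa_power` | 2, 1 | preferential-attachment network density/exponent |
| `planted_module_size` | 8 | genes in the planted module (ring + chords) |
| `planted_effect` | 3 | mean shift of causal SNP statistics |
| `polygenic_frac` | 0 | fraction of SNPs with weak dispersed effects |
| `polygenic_effect` | 1.5 | absolute size of those effects (random sign) |

Genotypes: one LD block per gene; two latent haplotypes per sample with
exchangeable correlation, thresholded at a drawn minor-allele frequency in
[0.05, 0.5] — Hardy–Weinberg marginally, realistic attenuation of latent
correlation into genotype LD. Association statistics are drawn per block
from $\mathrm{MVN}(0, R_g)$ with $R_g$ the block's *observed genotype*
correlation, so the simulated statistics carry exactly the LD that
`estimate_ld()` later recovers; with independent draws instead, the
combination test would be miscalibrated by construction and the package's
own calibration tests could not pass. Marginal null P-values are exactly
uniform either way.

The dispersed polygenic component exists because the inflation-ordering
property (all ≤ top ≤ minP) is about a *real* GWAS background: on a
literally complete null both simulation-based methods are exact
Monte-Carlo tests with 5% expected exceedance, and their ordering would be
a coin flip. With weak scattered signals, the all-SNP statistic dilutes
what the top-fraction statistic captures, and the ordering becomes a
genuine, stable property.

What a green test does **not** establish: the generator has no real human
LD map (exchangeable blocks, no inter-gene LD), no population structure,
no genotyping artifacts, and its network is a preferential-attachment
sketch, not a curated interactome. Green means the algorithms implement
the stated mathematics and recover planted structure in this stylized
world — not that biological findings on real data are reproduced.

## Numerical choices

* Empirical P-values use $(x+1)/(B+1)$ in gene scoring (finite weights)
  but the $1/B$ floor in the resampling evaluation (matches the published
  floor); the asymmetry is deliberate.
* P = 0 is rejected at parse time; P = 1 is accepted and clamped at the
  z-transform.
* PSD repair tolerance $10^{-10}$; MVN factorization refuses matrices
  that remain indefinite beyond $10^{-8}$.
* Written tables print 6 significant digits (scientific below $10^{-4}$)
  and round-trip through the readers.
* All randomized stages derive per-unit substreams (gene, resample) from
  the master seed via a 31-bit string hash, so outputs are independent of
  processing order and stable across runs.

## Known limitations

* The greedy cap described above means equal-weight dense structures are
  recovered as 5-member cores, not in full; this is a property of the
  published growth rule, not of the implementation.
* The module-significance step assumes the bulk of module scores is
  normal after median centering; very small networks (< 20 modules) fall
  back to the exact standard-normal null, which ignores greedy selection
  inflation and is anti-conservative.
* Sex chromosomes are excluded from scoring; identifier systems are not
  reconciled (gene ids are opaque strings).
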