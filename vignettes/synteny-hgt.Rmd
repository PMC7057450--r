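---
title: "Detecting horizontal gene transfer from loss of synteny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting horizontal gene transfer from loss of synteny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sihgt)
```

## The problem

Horizontal gene transfer (HGT) between closely related genomes is hard to
see in sequences: the donor and recipient are so similar that a transferred
gene is neither compositionally atypical nor phylogenetically discordant.
It is, however, *positionally* atypical. A genome is modelled here as a
circular sequence of unique gene-family identifiers; an HGT inserts a gene
between two essentially random genes of the recipient. Comparing the local
gene order of each shared gene across two genomes therefore exposes recent
arrivals, and the statistical work of this package is to say *how* unusual
an observed loss of local order is, and to separate true transfers from
within-genome rearrangements that mimic them.

## Synteny index and its chance threshold

For a gene $g$ in the core set of genomes $G_1, G_2$ the $k$-neighborhood
$N_k(G, g)$ is the set of $2k$ genes within $k$ positions of $g$ on the
circle, and the synteny index is
$SI(g, G_1, G_2) = |N_k(G_1, g) \cap N_k(G_2, g)| \in \{0, \dots, 2k\}$.
SI is symmetric in the two genomes and invariant under rotation of either
circle (both properties are tested against a brute-force positional oracle).

Low SI is only evidence if it is unlikely by chance. When the two gene
contents differ — gene gain and loss — a fraction
$p = |G_1 \triangle G_2| / (2n)$ of neighborhood positions holds singular
genes that can never contribute to SI. The count of non-shared neighbors
concentrates around its mean $2kp$, and a Chernoff/Hoeffding bound on its
upper tail gives: with probability at most $\delta_{SI}$, by chance

$$SI < 2k(1-p) - \sqrt{-k \ln \delta_{SI}}.$$

`si_random_threshold()` evaluates this; `flag_suspected()` applies it with
a *strict* comparison, matching the strict inequality of the bound. Two
consequences shape the interface:

* **Minimum radius.** The threshold is negative unless
  $k \ge -\ln(\delta_{SI}) / (4(1-p)^2)$ (`min_k()`). At $p = 0.8,
  \delta_{SI} = 0.05$ that is $k \ge 19$: a radius of 10 gives threshold
  $-1.47$ and can flag nothing. Because a silent empty result in this
  regime is a pitfall, `flag_suspected()` and `si_hgt()` *refuse* an
  undersized $k$ and name the required minimum; `k = "auto"` uses exactly
  `min_k`. Larger $k$ buys sensitivity at the cost of diluting the local
  signal, so the automatic choice is the smallest defensible radius.
* **Unequal genome sizes.** The bound assumes $|G_1| = |G_2| = n$. We take
  $n$ as the arithmetic mean of the two sizes (preserving
  $p = |\triangle|/2n$) and warn; for the closely related pairs the method
  targets, sizes are near-equal anyway.

Positions are 0-based internally, circular distance is
$\min(|i-j|, n-|i-j|)$, and genomes are circular throughout — a linear mode
is deliberately not offered since the model and the simulator both assume
wrap-around. Duplicate identifiers are rejected at construction: the model
has no paralogs, and silently keeping one copy would corrupt neighborhoods.

## Sifting transfers from translocations: the CRM witness test

A translocated (or duplicated) gene also has $SI \approx 0$ — for a
singleton move the chance its destination overlaps the old neighborhood is
about $4k/n$. SI alone cannot distinguish this from HGT. The discriminating
signal is sequence divergence: a translocated gene has been in its genome
since the strains split, so its strain-pair distance should match vertical
expectation, whereas a gene recently transferred *between the strains* is
far too similar.

The expectation is built on *constant relative mutability* (CRM): under the
universal-pacemaker approximation, two genes' mutation rates keep an
approximately constant ratio $\rho$ across lineages even as the rates
themselves change. Working in Jukes–Cantor distance space
($corr(h) = -\tfrac34 \ln(1 - \tfrac43 h)$, inverse
$corr^{-1}(d) = \tfrac34(1 - e^{-4d/3})$), a witness gene $w$ and two
reference organisms $R_1, R_2$ calibrate
$\rho = corr(\hat h_g(R)) / corr(\hat h_w(R))$, and the expected strain
distance of the suspected gene is
$d_g(S) = \rho \cdot corr(\hat h_w(S))$. Back in Hamming space — where
sites are i.i.d. Bernoulli and concentration applies — the observed strain
distance of a gene with $n$ aligned sites obeys

$$\Pr\left[\,|\hat h_g(S) - corr^{-1}(d_g(S))| > \varepsilon\,\right]
  \le 2 e^{-2 n \varepsilon^2},$$

so the refutation cutoff at level $\delta_r$ is
$\varepsilon(\delta_r) = \sqrt{-\ln(\delta_r/2) / (2n)}$
(`deviation_cutoff()`), the exact inversion of the two-sided bound — the
$\delta_r/2$ inside the logarithm carries the factor 2 of the bound. The
test and cutoff invert each other to machine precision (a tested
invariant).

Numerical and design choices:

* **Two-sided test, signed report.** The bound is two-sided, but only a
  *negative* deviation (direction `"closer"`) supports transfer between the
  strains; `"farther"` flags a CRM violation elsewhere (e.g. a transfer
  involving a reference lineage). Both are reported; only `"closer"`
  refutations produce an `hgt` verdict.
* **$n$ is the used sites.** Masked sites (non-ACGT in either sequence)
  drop out of both numerator and denominator of the Hamming distance, and
  the concentration bound uses the post-masking count — the Bernoulli
  interpretation holds only for sites actually compared.
* **Saturation guard.** $corr$ diverges at $h = 3/4$; inputs at or above
  $3/4 - 10^{-9}$ raise (scalar API) or mark the test `skipped_saturated`
  (pipeline), keeping downstream ratios finite. A witness with
  $\hat h_w(R) = 0$ is `skipped_witness_zero` — a zero denominator carries
  no rate information.
* **Caps and correction.** Chernoff bounds can exceed 1 and are capped
  before reporting. Bonferroni correction multiplies each bound by the
  gene's number of *completed* tests (skipped tests are excluded — they
  contributed no opportunity for a false refutation).

## The pipeline

`si_hgt()` chains the layers: SI profile of the strain pair → chance
threshold → for each suspected gene, every eligible witness test (witness
present and aligned in both strains and both references; reference pairs
unordered; the suspected gene aligned in the references) → Bonferroni →
verdict. `hgt` requires at least one corrected refutation with direction
`"closer"`; a suspected gene with completed tests but no such refutation is
`translocation-like` (its divergence fits vertical descent within the
genome — including the case where only `"farther"` refutations occurred);
no completed tests is `untestable`; SI at or above threshold is
`not-significant`. Whether *one* refuted test should suffice or a quorum be
required is genuinely open; "any refuted test" was chosen as the more
conservative reading *for the null*, and because Bonferroni already prices
the number of attempts. Lowering $\delta_r$ can only shrink the `hgt` set
(a tested monotonicity).

In the report, `min_deviation` and `direction` describe the witness test
with the smallest absolute deviation — the strongest defender of vertical
descent — while `best_corrected_bound` is the smallest corrected bound over
all tests; the verdict is driven by the latter. Per-gene witness tables are
kept in `$tests` for inspection. All Hamming distances for a genome pair
are computed once and shared across tests, so the SI scan is linear in the
core size for fixed $k$ and witness testing is at most quadratic in the
taxa set ($|W| \cdot \binom{r}{2}$ tests per gene).

## What the simulator emulates

`simulate_quartet()` reproduces the standard four-genome evaluation design:

* **Root GA**: `genome_size` genes named by initial position, i.i.d.
  uniform ACGT sequences of `gene_length`, per-gene rates
  $\sim N(\mu, \sigma)$ truncated below at 0 (clamping, not resampling —
  with the defaults the truncation is almost never active).
* **Witnesses GWA, GWB**: independent point-mutated copies of GA with
  identical gene order. Each copy substitutes every site independently with
  probability $\min(1, \text{rate})$ to a uniformly chosen different base —
  the single-step Jukes–Cantor kernel, so "rate" is the per-site
  substitution probability per parent→child copy; no separate branch-length
  time scale is introduced. Because each gene's rate is shared across all
  branches, CRM holds exactly in simulated data.
* **GB**: a point-mutated copy of GA followed by `n_events` block-swap
  rearrangements on the circle. `event_size_mean`/`sd` parameterize the
  *block size in genes* (a size-$b$ block is the focal gene plus
  $\lfloor (b-1)/2 \rfloor$ genes upstream and the remainder downstream;
  sizes are rounded and floored at 1). Blocks are kept disjoint within and
  across events by resampling the (focal, size, partner) triple —
  overlapping swaps would make the truth set ill-defined. Every gene in
  either block is additionally mutated at rate × `hgt_factor`, emulating
  the elevated divergence of transferred genes, and enters the truth set.
* One seeded stream drives all draws in a fixed order (root sequences,
  root rates, GWA, GWB, GB mutation, events), so a quartet is
  byte-reproducible from its seed.

Defaults are `genome_size = 1000`, `gene_length = 1000`, `n_events = 10`,
`event_size_mean = 7`, `event_size_sd = 1`, `hgt_factor = 10`. The
mutation-rate defaults, `rate_mean = 0.05` and `rate_sd = 0.01`, are the
package's own choice of a realistic strain-level regime: a few percent
per-site divergence between close strains, an order of magnitude more for
transferred genes — far from Jukes–Cantor saturation yet clearly separable.

What the simulator does **not** emulate: gene gain and loss (so simulated
pairs have $p = 0$ and the automatic radius is $k = 1$; real pairs with
substantial content divergence exercise the large-$k$ regime instead),
duplications, indels and alignment error, ambiguity characters, rate
variation across sites, and CRM *violations*. Passing simulation tests
therefore demonstrates correctness of the statistics under the model's own
assumptions — specificity on real data additionally depends on how well
orthology calls, alignments and the pacemaker approximation hold.

## Validation problem sizes

The test suite checks the closed-form layers exhaustively (inversion
identities to $10^{-12}$; SI against a brute-force oracle on 100 random
circular pairs of up to ~50 genes at $k \le 5$) and the stochastic layers
at deliberately moderate scale: 10 full-default quartets for the
false-positive rate (observed FP fraction $\le 5\%$ of non-truth core
genes, in practice 0), 20 rearrangement-free quartets for type-I control of
the SI layer, 500 vertically evolved replicates for type-I control of the
witness test, and 200 seeds for the singleton-translocation property
($SI = 0$ in $\ge 95\%$ of cases at $k = 5$, genome size 1000 — the
collision probability is $\approx 4k/n$). These sizes give comfortable
margins on all bounds while keeping a full run in tens of seconds.

## Known limitations

* One copy per gene family per genome; paralogs must be resolved upstream.
* Jukes–Cantor only. Under strong base-composition bias or rate
  heterogeneity the corrected distances — and hence $\rho$ — are biased;
  the Chernoff bound itself does not account for estimation noise in
  $\rho$, which is why distant, long witnesses make better calibrators.
* The deviation test refutes *vertical descent of the gene given CRM*; a
  `"farther"` refutation localizes the violation only up to "somewhere in
  the quartet".
* Verdicts are per gene; a transferred multi-gene segment appears as a run
  of adjacent calls rather than a single event, and donor/recipient
  direction is not inferred.
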