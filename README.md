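# sihgt — synteny-index detection of horizontal gene transfer

`sihgt` detects horizontal gene transfer (HGT) between closely related
prokaryotic genomes — strains of one species, or species of one genus —
where sequence-based and phylogeny-based detectors have little signal to
work with: most genes are nearly identical, so a transferred gene does not
look compositionally or phylogenetically foreign. What *does* change is the
gene's neighborhood. A transferred gene is inserted at an essentially random
position in the recipient genome, so its local gene order differs between
the two genomes even when its sequence does not.

The package is for comparative genomicists who have, for a set of genomes,
(a) circular gene orders over shared ortholog families and (b) per-family
aligned nucleotide sequences, and who want per-gene HGT calls with explicit
probabilistic guarantees rather than heuristic scores.

## The method

**Synteny index.** For a gene g in the core set (gene families present in
both genomes) of genomes G1 and G2, with N_k(G, g) the set of genes at
circular distance at most k from g in G (its *k-neighborhood*, 2k genes),
the synteny index is

    SI(g, G1, G2) = | N_k(G1, g) ∩ N_k(G2, g) |  ∈  {0, ..., 2k}.

**Chance threshold.** Low SI can arise without transfer when gene
gain/loss has made the two gene contents diverge. With p =
|G1 △ G2| / (2n) the probability that a random gene is "singular" (present
in only one genome; n is the genome size), a Chernoff concentration bound
gives: with probability at most δ_SI a core gene shows by chance

    SI < 2k(1 − p) − sqrt(−k · ln δ_SI).

Genes strictly below the threshold are *SI suspected*. The threshold is only
usable when k ≥ −ln(δ_SI) / (4(1 − p)²) (`min_k()`); e.g. at p = 0.8 and
δ_SI = 0.05, k = 10 yields a threshold of −1.47 (useless), k = 30 yields 2.5.

**Witness test.** A translocated or duplicated gene also has SI ≈ 0, but it
has lived in its genome since the strains diverged, so its sequence
divergence matches vertical descent. Under the universal-pacemaker view two
genes keep an approximately constant ratio ρ between their mutation rates
(*constant relative mutability*, CRM). Given a witness gene w and two
reference organisms R1, R2, with corr the Jukes–Cantor correction
d = −(3/4) ln(1 − (4/3) h), the expected strain distance of the suspected
gene is

    d_g(S) = corr(ĥ_g(R)) / corr(ĥ_w(R)) · corr(ĥ_w(S)),

and for a gene of n aligned sites the observed strain Hamming distance
ĥ_g(S) satisfies

    Pr[ | ĥ_g(S) − corr⁻¹(d_g(S)) | > ε ]  ≤  2 e^(−2 n ε²),

so a deviation beyond ε(δ_r) = sqrt(−ln(δ_r / 2) / (2n)) refutes vertical
descent at level δ_r (Bonferroni-corrected over all witness/reference
choices for the gene). The *sign* of the deviation matters: only
"closer" (observed below expectation — the strains too similar, as after a
recent transfer between them) supports HGT between the strains; "farther"
indicates a CRM violation elsewhere. Verdicts per core gene: `hgt`,
`translocation-like`, `not-significant`, `untestable`.

**Simulator.** `simulate_quartet()` builds the four-genome evaluation
design: root GA; witness genomes GWA, GWB (point-mutated copies with
identical gene order); GB point-mutated and subjected to circular block-swap
rearrangements whose genes are hyper-mutated by an HGT rate factor. The
swapped genes form the truth set for specificity (false-positive) studies.

## Worked example

```r
library(sihgt)
q <- simulate_quartet(sim_config(genome_size = 300, gene_length = 600,
                                 n_events = 4, event_size_mean = 1,
                                 event_size_sd = 0, seed = 42))
res <- si_hgt(quartet_genomes(q), quartet_alignments(q),
              strains = c("GA", "GB"), references = c("GWA", "GWB"))
res
#> <si_hgt> GA vs GB (k=1, p=0)
#>   core genes: 300; hgt: 2; translocation-like: 6; untestable: 0; not-significant: 292
res$report[res$report$suspected, c("gene_id", "si", "si_threshold",
                                   "n_tests", "verdict")]
#>     gene_id si si_threshold n_tests            verdict
#> 16    g0015  0    0.2691816     299                hgt
#> 63    g0062  0    0.2691816     299 translocation-like
#> ...
evaluate_false_positives(res, q$truth)
#> [1] 0
```

GA and GB share their full gene set, so p = 0 and the automatic neighborhood
radius is k = 1 with chance threshold 0.269: only genes whose two immediate
neighbors both changed (SI = 0) are suspected. Here the 8 suspected genes
are exactly the 8 planted singleton swaps; each is then tried against all
299 other genes as witnesses. Every witness test refutes vertical descent —
the swapped genes were hyper-mutated — and no unswapped gene is called
(`evaluate_false_positives` returns 0). `write_report()` serializes the
table as TSV; `write_manifest()` records seeds and input checksums.

A shell entry point is installed at `inst/scripts/si-hgt`:

```sh
Rscript inst/scripts/si-hgt simulate --genome-size 300 --seed 42 --out-dir quartet
Rscript inst/scripts/si-hgt detect --orders quartet/orders.tsv \
    --fasta quartet/sequences.fasta --strains GA,GB --references GWA,GWB \
    --out report.tsv
```

## Scope and limits

Gene orders must be paralog-free (one copy per family per genome) and
pre-aligned ortholog sequences are required — ortholog inference and
alignment are upstream of this package. The substitution model is
Jukes–Cantor; distances at or beyond h = 3/4 saturate and such tests are
skipped. Donor/recipient direction and multi-gene transferred segments are
not inferred. See `vignettes/synteny-hgt.Rmd` for the full methods account.
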