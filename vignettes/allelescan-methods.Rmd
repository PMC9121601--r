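---
title: "Methods: allele-specific motif scanning and downstream statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific motif scanning and downstream statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelescan)
```

## The problem and the model

GWAS index SNPs tag risk loci; the causal variant is usually one of their
linkage-disequilibrium partners, and in non-coding loci the leading causal
hypothesis is allele-specific transcription-factor binding: one allele
completes a TF's recognition motif inside a bound regulatory element, the
other destroys it. `allelescan` operationalizes that hypothesis as a
two-criterion classifier and carries the surviving SNPs into association
and allelic-expression evidence. This vignette records the statistical
model at each stage, the tunable parameters and their defaults, what the
synthetic generator does and does not emulate, and the design decisions
taken where the procedure admitted more than one reasonable reading.

## LD extraction

r² between two sites is computed by direct counting on phased haplotypes:
with allele-1 frequencies $p_A$, $p_B$ and joint frequency $p_{AB}$,
$D = p_{AB} - p_A p_B$ and $r^2 = D^2 / (p_A(1-p_A)p_B(1-p_B))$. Only
phased input is accepted; an EM estimator for unphased genotypes would be
a silently different statistic, so unphased VCFs are rejected rather than
approximated (an `assume_phased` escape hatch exists for data known to be
phased but written with `/` separators). The extraction threshold is
strict (`r2 > 0.6` by default, a widely used cutoff that trades the size
of the candidate set against LD strength), with one boundary exception:
a variant in *perfect* LD (r² exactly 1) always qualifies, so the
degenerate setting `r2_min = 1` retains exact duplicates of the index.
No distance window is applied — the supplied VCF defines the locus. A
variant in LD with several indices is assigned to the index with the
highest r², ties to the first index in input order; this rule is plumbing
(overlapping loci are rare) but is fixed so output is deterministic.
Monomorphic sites leave r² undefined and are skipped with a warning.

## Motif scanning with exact p-values

A PWM column $i$ gives base $a$ probability $p(i,a)$. Scores are log-odds
in bits against a zero-order background $b$:

$$s(i,a) = \log_2 \frac{p(i,a) + pc \cdot b(a)}{(1 + pc)\, b(a)}$$

with pseudocount fraction $pc = 0.01$ (prevents $-\infty$ for zero
entries; with $pc = 0$ a zero probability is an error rather than a silent
clip). The default background is uniform 0.25 — reproducible and matching
the default GC of the synthetic reference; a per-run background is
configurable. Scores are rounded onto an integer lattice at granularity
$\varepsilon = 10^{-4}$ bits. The null distribution of the total integer
score of a random background word is built exactly by per-column
convolution over the lattice (cost: width × lattice size, guarded at
5×10⁷ cells with an error advising a larger $\varepsilon$), and
$p(s) = P(S \ge s)$. Scanning uses the *same* rounded matrix, so reported
p-values are exact for the scored object — there is no sampling or
asymptotic approximation anywhere in the scan.

Window scanning evaluates every offset on the forward strand and (by
default) the reverse complement, mapping reverse-strand hits back to
forward coordinates. A candidate hit needs $p < 0.001$ (strict) and, by
default, must cover the SNP base: an occurrence that does not contain the
SNP cannot differ between alleles, so non-covering hits carry no
disruption information. Whether the original procedure imposed the
coverage requirement, and whether the threshold was applied per allele,
is not documented; both behaviors exist behind `require_snp_overlap` and
the defaults are the conservative ones. Ties between candidate hits are
broken by highest score, then leftmost forward start, then `+` strand.
`N` positions contribute score 0 (background-equivalent); an offset
consisting entirely of `N` is never a hit, since it carries no sequence
evidence at all.

Windows are ±20 bp around the SNP (41-mers), clamped at contig ends with
the SNP index adjusted. The reference base at the SNP must equal the
variant's REF allele; a mismatch is an error naming both, because a
silently shifted or mispositioned window would invalidate every
downstream call.

`motif_similarity()` (for matching derived motifs against reference PWM
collections) maximizes the mean column-wise Pearson correlation of
probability vectors over ungapped offsets with ≥ 5 aligned columns and
both orientations; zero-variance columns contribute 0, ties prefer the
smallest |offset| then the `+` orientation.

## Disruption classification

A call is made per (SNP, motif): `no_peak` when the SNP is outside every
peak of the motif's TF (peak matching is per-TF — TF X's motif must fall
in TF X's peak); otherwise `disrupting` when exactly one allele has a
significant covering hit, `motif_retained` when both do, `no_motif` when
neither does. "Disrupting" is operationalized as allele-*discordant*
occurrence: literal occurrence-plus-peak would label SNPs functional even
when both alleles bind equally well, which contradicts the intent of the
term. A permissive mode (off by default) additionally labels calls
disrupting when both alleles hit but the score shift is ≥ 2 bits, for
users who want strong-affinity changes without loss of significance.
Coordinates: a SNP at 1-based position $p$ occupies 0-based coordinate
$p-1$; peak intervals are half-open `[start, end)`; chromosome names are
compared after stripping a leading `chr` on both sides. Summaries count a
SNP once per TF regardless of how many of that TF's motifs it disrupts.

## Association statistics

The eQTL scan is ordinary least squares of (log2) expression on
alternate-allele dosage; $\hat\beta = \mathrm{cov}(g,y)/\mathrm{var}(g)$,
two-sided p from $t = \hat\beta/\mathrm{se}$ with $n-2$ df. This is a
deliberate stand-in for the heterogeneous published pipelines behind real
eQTL resources (covariates, PEER factors, mixed models) and is documented
as non-equivalent; the faithful reproduction path ingests precomputed
association tables and applies only correction and tally logic. Degenerate
policies are explicit: zero dosage variance skips the pair with a warning;
a perfect fit (zero residual variance, nonzero slope) reports the smallest
representable positive p and a `degenerate` flag; a constant response
reports $\hat\beta = 0$, $p = 1$. BH-FDR and Bonferroni go through
`stats::p.adjust`; the consensus tally supports the two significance rules
the workflow needs (FDR < 0.05, or raw p < 0.01) because published
resources differ in whether they ship FDR values — when an ingested table
lacks them, Bonferroni within dataset fills the gap. Differential
expression is a Welch t-test on log2 values with BH-FDR across genes;
log2FC is the case-minus-control mean difference.

## ASE tests

Per SNP, the read-count balance test is the exact binomial test of
`count_allele1` out of the total against 0.5. Set-level enrichment among
$n$ functional SNPs with $k$ ASE-positive uses null probability $K/N$
from a genome-wide resource ($K$ and $N$ are inputs, not computed). Both
tests use the minimum-likelihood two-sided convention — sum $P(X=j)$ over
all $j$ whose point probability is at most $(1+10^{-7})$ times the
observed one — which is the default semantics of R's `binom.test` and is
required to reproduce reference values computed with it; the suite checks
the hand-rolled tail against `binom.test` exhaustively for all $n \le 30$.
Per-SNP significance defaults to raw $p < 0.05$ with optional BH-FDR
across SNPs, matching the common practice of consuming precomputed ASE
calls.

## The synthetic generator

The generator emulates the *statistical structure* the pipeline consumes,
not the biology that produced it:

- **Reference**: i.i.d. bases, default 20 kb, GC 0.5 (consistent with
  the uniform scan background; both are configurable together).
- **Motifs**: one per TF (default 2, named after commonly profiled
  factors), width 6, per-column information 1.86 bits (consensus
  probability ≈ 0.985). These defaults are chosen so the planted
  consensus is significant under the exact null ($p = 4^{-6}\cdot 1 \approx
  2.4\times10^{-4} < 0.001$) while any single-base break is not
  ($p \approx 19/4096 \approx 4.6\times10^{-3} > 0.001$): disruption
  recovery is then a structural property of the exact score
  distribution, with margin on both sides, not a knife-edge.
- **Planted classes**: disrupting SNPs sit at the maximum-information
  motif column with the alternate allele minimizing the column
  probability (guaranteeing a large log-odds delta), inside a same-TF
  peak (±100 bp); decoys cover in-peak-without-motif,
  motif-without-peak, and plain background; all classes occupy disjoint
  loci so labels cannot bleed into each other.
- **LD block**: each partner copies the index haplotype and resamples
  each entry from the marginal with probability $m = 1-\sqrt{r^2_{target}}$,
  giving expected allele correlation $\sqrt{r^2}$ — transparent and
  analytically checkable, unlike a coalescent simulation; default
  targets {0.9, 0.7, 0.5, 0.3} straddle the 0.6 cutoff, panel 500
  diploids. Realized r² is recorded in the truth table by the package's
  own `r_squared()`.
- **eQTL cohorts**: 5 datasets × 200 samples, β = 1, noise SD 1,
  dosages Binomial(2, 0.3); the first 3 SNPs share β across all
  datasets, the next 2 have β in exactly one, the rest are null.
- **ASE counts**: depth 100; ASE-positive SNPs draw allele-1 counts at
  0.5 + 0.2, others at 0.5.
- **Case/control**: 50 + 50 samples, shift 0.5 on log2 scale, noise
  SD 0.2.

It does *not* emulate recombination maps or demography, mapping bias,
covariate structure, overlapping regulatory elements, or realistic motif
libraries; passing tests demonstrate that the *logic* of each stage is
correct under its stated model, not that the pipeline's power on real
data matches any particular study. Every generator is a pure function of
(config, seed): regeneration is byte-identical, and the truth table lists
every SNP exactly once.

Problem sizes in the test suite (20 recovery scenarios, 1000-replicate
calibration checks, exhaustive enumeration for motif widths ≤ 6, panels
of 1000 haplotypes) were chosen as the smallest sizes at which the
binomial/sampling noise of each property is comfortably inside its
asserted band.

## Pipeline and determinism

`run_pipeline()` executes ld → scan → classify → (eqtl) → (ase) → report;
each stage writes a TSV, so stages can be rerun or audited alone, and
optional stages missing their inputs are marked "skipped" in the report
rather than failing. Any stage error aborts with a message naming the
stage. All randomness lives in the generators (seeded through the
configuration); the pipeline itself is deterministic, and two runs on the
same inputs produce byte-identical outputs.

## Known limitations

- The exact-p-value machinery assumes a zero-order background; higher
  order backgrounds would change both scores and the null convolution.
- The OLS eQTL model ignores covariates and relatedness; its p-values
  are calibrated only under its own assumptions.
- Per-TF peak matching treats peak files as truth; no signal-strength
  weighting or summit distance is used.
- Motif p-values are per-window; no genome-wide q-value calibration is
  attempted.
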