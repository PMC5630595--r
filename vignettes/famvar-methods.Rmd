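---
title: "Position-wise variant enrichment in protein families: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position-wise variant enrichment in protein families: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famvar)
```

# The scientific question

Diploid genomes of healthy individuals carry hundreds of thousands of
missense variants. When proteins belong to large, functionally redundant
families, variants can recur at the *same position of the family
alignment* across many members — a signature of positions where loss or
alteration of function differentiates individuals rather than causing
disease. The canonical case is the arginine of the class-A GPCR "DRY"
motif in olfactory receptors: variants there are enriched beyond any
other proteome position, screening data show arginine-less receptors are
essentially never activated by odorants, and the spectrum of broken
receptors is effectively a personal fingerprint.

`famvar` implements the complete analysis chain — enrichment statistics,
receptor pharmacology scoring, fingerprint clustering, and an
agent-based simulation of odor-driven behaviour — against synthetic data
whose ground truth is planted and therefore testable.

# The enrichment model

For a family alignment position (column) let $O$ be the pooled
alternate-allele count of missense variants mapping to that column and

$$E = \frac{\text{total alleles}}{\text{proteome length}} \times
      n_\text{instances} \times \text{span},$$

the expectation under uniform placement of alleles over the proteome
(span = model length for a whole family, 1 for a column). Enrichment is
$\log_2(O/E)$; the package uses base 2 throughout and exposes it as a
convention, with $O=0$ reported as $-\infty$.

Significance does not come from the crude uniform expectation but from a
**shuffle prior**: each individual's missense alleles are relocated
uniformly at random within their own protein (collisions allowed), and
the mean fraction of alleles landing on the target column across
shuffles estimates the per-allele success probability $p_0$. The test is
an upper-tail binomial $P(X \ge O)$, $X \sim \mathrm{Bin}(N, p_0)$ with
$N$ the total pooled allele count, since enrichment is a one-sided
question. This conditions on each protein's variant load and so controls
for protein-level mutability (long proteins, CpG-rich genes) while
remaining sensitive to positional concentration.

Benjamini–Hochberg correction is applied **once, genome-wide**, over the
tested set — columns with at least 50 observed or 5 expected alleles
(inclusive OR, applied *before* correction so the tested family is the
filtered set). Enriched positions additionally require log-odds $\ge 1$
and $Q \le 0.01$, both inclusive, plus an optional floor of 10 distinct
genes with variants.

Decisions worth flagging because the underlying convention is not
universal:

* **BH scope.** Correction could be per protein family or global; the
  package corrects globally because one Q-value per position across the
  proteome is the quantity of interest. The choice is configurable only
  through subsetting the input.
* **Number of shuffles.** Default 100 (seeded). The prior is a mean over
  `shuffles × alleles` indicators, so its Monte-Carlo error is far below
  the effect sizes of interest at any realistic allele count.
* **Conservation.** A column is "conserved" when the modal residue
  frequency among aligned members reaches 0.5 (configurable); ties break
  alphabetically so results are deterministic. The threshold is a
  definition, not an estimate — profile HMM "strong consensus" has no
  single numeric equivalent.
* **Loss-of-function variants** (stop-gain, frameshift) are excluded
  from enrichment counting — they are fewer and positionally
  uninformative — but retained for fingerprints and anosmia scoring.

# Receptor pharmacology

Screen positivity is weighted by potency: $w = -\log_{10}\mathrm{EC50}/9$
clamped to $[0,1]$, so 1 nM (the strongest observed potency) weighs 1
and an inactive screen 0. At a conserved column the canonical
(consensus-residue) and non-canonical receptors are contrasted by the
ratio of positive rates, and by the *lower*-tail hypergeometric
probability of seeing this many or fewer positives among the
non-canonical screens — the deficit of activity is the hypothesis.
On the published DRY contingency (1/1089 vs 102/8815) this yields a
fold enrichment of 12.6 and $p = 8.0\times10^{-5}$, which the test suite
pins against exact enumeration.

Individual odorant response treats each (receptor, allele copy) pair as
a contribution: $w$ if functional, 0 if the allele carries a
loss-of-function variant (DRY-type missense, stop-gain or frameshift).
Heterozygous LoF therefore halves and homozygous LoF zeroes a receptor's
contribution, and the response is the mean over all allele-pair
contributions of receptors binding the odorant. The averaging
denominator (allele pairs, rather than receptors or screens) is a
documented reading of an ambiguous convention; it makes the response of
a fully functional individual equal the mean potency weight, and
response monotone non-increasing in LoF allele count — both property-
tested. Population matrices average individual responses per group and
normalize each odorant row by its maximum group mean.

# Fingerprints and clustering

Fingerprints are fixed-order binary carrier vectors over selected
variants ("bits"); a diploid variant using allele counts is available
but binary is the default since cut depths are counted in bits.
Distance is the sum of absolute differences (Hamming in binary mode),
clustering is complete linkage via `stats::hclust`, and depth cuts
(e.g. 35 bits for DRY-only fingerprints, 100 for all variants) use
`stats::cutree` on merge heights. Per-cluster variant enrichment is
$\log_2$ of carrier frequency inside vs outside the cluster, flagged at
$\pm 0.6$; a zero outside-frequency reports $+\infty$ rather than being
dropped. Enrichment against externally supplied labels (super-
populations) is supported by passing the labels as the cluster
assignment.

# The synthetic-data generator

The generator's defaults are the emulated study conditions, chosen once:

* **Cohort**: 2,504 individuals; super-population weights
  AFR 0.26 / EUR 0.20 / EAS 0.20 / SAS 0.20 / AMR 0.14.
* **Missense rate**: $4\times10^{-4}$ per haplotype per residue — about
  23M alleles over an 11M-residue proteome across 5,008 haplotypes.
* **Planted hotspot**: one conserved column (family 1, column 10) at 10×
  the base rate, emulating the DRY arginine.
* **Loss of function**: stop-gain and frameshift each at 0.005 per gene
  per haplotype, recorded as gene-level class markers with a position
  (downstream analysis needs only the class, not a sequence edit).
* **Screen**: canonical positive rate 102/8815, non-canonical 1/1089,
  log₁₀ EC50 uniform in $[-9, -3]$ for positives.
* **Families**: 20 families, 8–12 members, 80–120 columns, residue
  conservation 0.95 at conserved columns and 0.40 elsewhere, 3% gap and
  2% insertion rates, flanks up to 10 residues.

Diploidy is two independent haplotypes; homozygotes arise by chance,
which reproduces the heterozygote-dominated counts seen in real
cohorts without a frequency-spectrum model. The generator deliberately
omits linkage disequilibrium, recombination, mutation-spectrum realism
(CpG bias enters only through planted multipliers) and realistic gene
names — so passing tests demonstrate correctness of the statistics and
machinery, not calibration against population-genetic forces the
generator does not simulate.

Property tests run at reduced sizes chosen as the package's standard
operating points: 1,000 individuals × 20 families for calibration and
recovery (20 seeded replicates), 500 individuals for clustering
recovery, and toy proteomes of ≤ 5 proteins for exact brute-force
oracles.

# The agent-based simulation

A 200×200 grid holds 50 uniformly placed odorant sources and 40 founder
animals in a centred block. Each animal carries 100 diploid receptor
genes; an allele responds to 1–14 odorants with attraction or repulsion
($\pm 1$) with equal probability. Movement follows

$$\vec m_a = \sum_{i\,\text{odorants}} \sum_{j\,\text{receptors}}
  \frac{AR_{ij}}{d_{ia}}
  \frac{\vec o_i - \vec p_a}{\lVert \vec o_i - \vec p_a \rVert},$$

with the unit vector of $\vec m_a$ discretized by rounding each
component to $\{-1, 0, 1\}$ — one grid step per axis at most. Each step,
every animal moves once (random permutation order) either randomly (8
neighbours) or along its vector, with probability `fractionOdorDriven`;
moves into occupied or out-of-bounds cells are cancelled. Adjacent
opposite-sex pairs mate with probability 0.3 when a parent has ≥ 5 empty
neighbouring cells; offspring inherit one allele per gene from each
parent with a 5% per-allele chance of replacement by a fresh random
allele, and are placed on an empty cell adjacent to that parent.

Conventions the underlying description leaves open, decided here:

* **Ploidy in behaviour**: an animal's response to an odorant sums, per
  gene, the sign of its two alleles' responses — heterozygous
  attraction/repulsion conflicts cancel.
* **Boundaries** are hard walls, not a torus; an animal exactly on a
  source skips that term ($d_{ia}=0$).
* **Update order** is a fresh random permutation per step; blocked moves
  are cancelled, not re-drawn; each female mates at most once per step.
* **Genetic diversity** is the mean pairwise per-gene multiset mismatch
  of allele ids (clones 0, fully disjoint 1), sampled above 2,000 pairs.
* **Communities** are connected components of animals within Chebyshev
  distance 2.

The world's mutable state lives in an environment slot so that a
simulation step is O(population), not O(population²) in copies; the
functional interface (`worldStep` returns the world) is kept, but
independent replicates need independent `initWorld` calls.

# Numerical and degenerate-input behaviour

* `logOdds(0, E)` returns $-\infty$; `expectedCount` with a zero-length
  proteome is an error; a zero non-canonical positive rate reports
  fold enrichment $+\infty$.
* Consensus on a column with no aligned member is NA ("undefined").
* An odorant with no binding receptor has NA response.
* All generators and the simulation are deterministic given their seed;
  identical seeds give byte-identical outputs (tested).
* Genotype decoding accepts phased and unphased diploid GT; any other
  ploidy is a parse error with the record reported.

# Known limitations

The enrichment null conditions on protein-level variant load but not on
residue identity, so codon-level mutability (CpG arginines) appears as
signal, exactly as in the real analysis — `codonCgFraction` exists to
quantify it rather than correct for it. The anosmia model ignores
cell-surface-expression defects and non-canonical signalling. The
simulation has no death process, so populations grow until crowding
throttles mating; long runs measure the crowded regime.
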