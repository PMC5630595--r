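# famvar

Variant enrichment at equivalent protein-family alignment positions, and
what it implies for olfactory-receptor function in human populations.

## The problem

Members of large protein families (olfactory receptors, cadherins,
cytochromes P450, ...) perform overlapping functions, so nonsynonymous
variants in healthy individuals can pile up at the *same* alignment
position across many family members without harming their carriers. The
flagship example is the arginine of the GPCR DRY motif (R3.50 in
Ballesteros–Weinstein numbering): in olfactory receptors it is hit by so
many missense variants that every sequenced genome carries at least one,
and screening data show receptors lacking that arginine almost never
respond to odorants. `famvar` packages the full analysis chain for this
kind of question, exercisable end to end on synthetic cohorts with known
planted structure:

1. **Synthetic study generator** — diploid cohorts with sub-population
   labels, family alignments with residue→column maps, coding sequences,
   diploid variant tables (missense + stop-gain/frameshift), and
   receptor×odorant EC50 screens, all with configurable planted signal.
2. **Mapping** — protein changes onto family alignment columns; per-column
   consensus residues and conservation calls; canonical/non-canonical
   residue status of individual receptors.
3. **Position enrichment** — for a column with observed pooled allele
   count *O* and uniform-placement expectation
   *E* = (total alleles / proteome length) × n_instances × span,
   the enrichment is log₂(*O*/*E*); significance comes from an upper-tail
   binomial test with trials = total alleles and success probability
   estimated by shuffling each individual's missense variants uniformly
   within their own proteins, followed by Benjamini–Hochberg correction.
   Positions pass with log-odds ≥ 1, Q ≤ 0.01 and a count floor
   (≥ 50 observed or ≥ 5 expected).
4. **Receptor pharmacology** — EC50 potency weights (−log₁₀EC50 / 9, so
   1 nM ⇒ 1), canonical vs non-canonical positive rates with fold
   enrichment and a lower-tail hypergeometric test, and per-individual
   odorant responses where heterozygous loss-of-function halves and
   homozygous zeroes a receptor's contribution (predicted anosmia).
5. **Population fingerprints** — binary carrier fingerprints over selected
   variants, Manhattan (sum of absolute differences) distances, complete
   linkage clustering with depth cuts, Newick export, and per-cluster
   variant enrichment at ±0.6 log₂ odds.
6. **Odor-driven agent-based simulation** — genotyped diploid animals on a
   grid move by the net attraction/repulsion vector
   m⃗ₐ = Σᵢ Σⱼ (ARᵢⱼ/dᵢₐ)·(o⃗ᵢ−p⃗ₐ)/‖o⃗ᵢ−p⃗ₐ‖, mate when adjacent, and
   mutate; the package records population growth, spatial community
   structure and genetic diversity.

## Worked example

```r
library(famvar)

cfg <- syntheticConfig(nIndividuals = 1000, nFamilies = 20, seed = 42)
cohortDf <- generateCohort(cfg)
proteome <- generateProteome(cfg)
vs <- generateVariants(proteome, cohortDf, cfg)
vs
#> VariantSet: 12331 variants x 1000 individuals
#>   missense: 11935  stop_gain: 198  frameshift: 198

enr <- positionEnrichment(vs, proteome, nShuffles = 50, seed = 1)
enrichedPositions(enr, minMembersWithVariants = NA)
#>    family column observed expected logOdds   qValue conserved
#> 10  FAM01     10       69     8.85    2.96 1.02e-33      TRUE
```

The default configuration plants a 10× variant hotspot at the conserved
column 10 of family 1 (a DRY-arginine-like position); the enrichment
scan recovers exactly that column: 69 pooled alleles against an
expectation of 8.85, log₂ odds 2.96, Q ≈ 10⁻³³, and nothing else passes
the filters. Descriptive statistics for the same position:

```r
idx <- domainIndex(proteome)
populationFraction(vs, "FAM01", 10, idx)       # 0.066 of the cohort carries one
identicalSpectrumPairs(vs, "FAM01", 10, idx)   # 435890 of 499500 pairs identical
```

The published DRY screen contingency — 1 positive of 1089 screens on
receptors lacking the arginine versus 102 of 8815 on receptors bearing
it — is reproduced directly:

```r
st <- positionActivityStats(screenDf, status)   # see ?positionActivityStats
st$foldEnrichment   # 12.60
st$hypergeomP       # 8.0e-05
```

A full pipeline run (synthesis → enrichment → pharmacology → clustering
→ simulation), writing all artifacts plus a checksummed manifest:

```r
runPipeline("out", config = syntheticConfig(nIndividuals = 200, nFamilies = 5))
```

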