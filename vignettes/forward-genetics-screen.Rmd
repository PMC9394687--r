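---
title: "Forward-genetics resistance screens: from variant calls to candidate targets"
author: "ForwardScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward-genetics resistance screens: from variant calls to candidate targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressMessages(library(ForwardScreen))
```

## The experimental design this package analyses

A forward-genetics resistance screen selects spontaneously resistant clones
from a hypermutator cell line (here, a mismatch-repair-deficient line in
which point mutation rates are strongly elevated) under continuous exposure
to a cytotoxic compound. The logic is that mutations conferring resistance
frequently alter the compound's direct protein target, so recurrently
mutated genes across independently derived resistant clones point at the
target. Because MMR-deficient clones carry hundreds of passenger mutations
each, the analytical problem is one of filtering and recurrence statistics,
not of single-variant interpretation.

The pipeline starts at jointly genotyped variant calls (a multi-sample VCF
with the parental line, the resistant clones, and a counter-screen panel of
clones resistant to an unrelated compound) and proceeds in four stages:

1. **Site hard filters.** Records are removed when QD < 2, FS > 60,
   MQ < 40, clone DP < 3 or clone GQ < 7. All inequalities are strict
   *removal* conditions (GATK hard-filtering semantics), so boundary values
   pass. A missing annotation fails its comparison by default
   (`missingAnnotationFails`), the conservative choice; set it to `FALSE`
   to let unannotated sites through.
2. **Acquired somatic calls.** A variant is an acquired somatic mutation of
   a clone iff clone VAF > 0.2, parental VAF < 0.01, and VAF < 0.05 in
   every counter-screen sample, with VAF = altDepth / (refDepth +
   altDepth). Non-coding variants are excluded.
3. **Clone relatedness.** Pairwise counts of shared somatic variants (exact
   chrom:pos:ref:alt identity). Clones sharing at least `shareThreshold`
   mutations are grouped (connected components): such clones descend from a
   common ancestor that existed before selection and are not independent
   evidence.
4. **Recurrence and ranking.** Per gene, the number of clones carrying a
   qualifying variant, both raw and *collapsed* (each related group votes
   once); per codon, the distinct amino-acid substitutions observed.
   A codon is *recurrent* when hit in two or more unrelated clones — the
   same residue altered independently, often to different amino acids, is
   the strongest single signal of positive selection. Genes are ranked by
   collapsed count, then number of recurrent codons, then name.

```{r example, eval = FALSE}
sim <- simulateScreen(simulationConfig(seed = 1), "sim_out")
res <- runScreen(sim$paths$vcf, sim$paths$fasta, sim$paths$geneModels,
                 parental = sim$samples$parental,
                 clones = sim$samples$clones,
                 counterScreen = sim$samples$counterScreen,
                 outDir = "screen_out")
head(geneTable(res$report))
```

## Parameters that matter, and their defaults

| parameter | default | meaning |
|---|---|---|
| `qdMin`, `fsMax`, `mqMin`, `dpMin`, `gqMin` | 2, 60, 40, 3, 7 | site/genotype hard filters (removal beyond threshold, strict) |
| `vafCloneMin` | 0.2 | clone VAF must strictly exceed this; captures subclonal sweeps down to ~1/3-of-alleles events at typical exome depth |
| `vafParentalMax` | 0.01 | parental VAF must be strictly below this; separates acquired events from pre-existing heterozygous background (VAF ~0.5) and from low-level parental subclones |
| `vafCounterMax` | 0.05 | applied per counter-screen sample, not pooled — each unrelated-compound clone must independently lack the variant |
| `parentalMinDepth` | 10 reads | callability guard: a parental site with no informative allele depths counts as VAF 0 only if at least this deep; otherwise the site is *uncallable* and the variant is excluded (and logged in provenance) |
| `countSpliceAsCoding` | TRUE | splice-site variants (±2 intronic bases, the canonical donor/acceptor footprint) count as coding |
| `shareThreshold` | 20 mutations | clone pairs at or above this are related; chosen between the coincidental overlap expected for independent hypermutated clones (around ten) and the sharing of a genuinely related pair (tens to hundreds) |

Two places where the underlying analysis convention is genuinely open are
exposed as toggles rather than decided silently: whether VAFs derive from
allele depths (AD) or a pileup — AD is used, because DP can count
uninformative reads and AD keeps VAF ≤ 1 — and whether synonymous and
splice variants count as "coding" — both are retained by default (only
non-coding variants are excluded), and the report carries consequence
classes so users can restrict further. Both raw and collapsed clone counts
are always reported, since relatedness-collapsing is a judgment the
analyst should see, not a silent transformation.

## Coding annotation

Gene models are single canonical transcripts (one per gene, enforced at
read-in, so codon numbering is unambiguous) with CDS exons in a simple TSV
dialect. Internally all coordinates are 1-based inclusive — the
R/Bioconductor convention, which is also the convention of both on-disk
formats (VCF, TSV), so no coordinate conversion exists anywhere in the
package.

SNVs inside the CDS are mapped to codon index `offset %/% 3 + 1`, the
affected codon is read base-by-base from the genome (strand-aware), and
both codons are translated with the standard genetic code. Indels are
frameshift when the length change is not a multiple of 3, in-frame
otherwise, assigned to the first affected codon; indels spanning an
exon boundary are classified frameshift with a warning. The annotation is
verified in the test suite against an independent brute-force oracle that
splices the entire CDS out of the reference, applies the mutation, and
translates both full proteins end-to-end.

## Dose-response quantification

Viability curves use the normalized log-logistic ("log inhibitor vs
normalized response") model

$$y = \frac{100}{1 + 10^{(x - \log_{10} IC_{50})\,h}},\qquad
x = \log_{10}(\text{concentration}),$$

with the top fixed at 100 (vehicle-normalized) and bottom at 0; a
4-parameter variant with free asymptotes is available behind
`fixedAsymptotes = FALSE`. The Hill slope is fitted per curve, not fixed.
Readings are first normalized so the vehicle-well mean maps to 100; the
operation is idempotent. Fold-resistance is the mutant/parental IC50 ratio
and is invariant under any common unit rescaling.

Numerical choices: fitting is ordinary least squares on log10
concentration via Levenberg–Marquardt; initialization puts the log-IC50 at
the tested concentration whose mean response is nearest 50% with Hill
slope 1 (robust for monotone sigmoids); standard errors come from the
curvature (information) approximation, with no bootstrap by default.
Degenerate inputs never throw: a failed optimization, a non-positive
fitted slope, an IC50 outside [min conc/100, max conc×100], or a fitted
dynamic range below 25 percentage points (a curve flat within noise) all
return `converged = FALSE`, and downstream fold computations refuse
non-converged fits explicitly.

Reporting conventions mirror bench practice: screen bracket concentrations
(`screenConcentrationBracket`, the IC100^1wk divided and multiplied by
1.25) are reported in µM to two decimals using decimal-correct
round-half-even — 0.98 × 1.25 = 1.225 must report as 1.22, which naive
binary rounding misses — and folds at two significant figures.

```{r desk, eval = TRUE}
screenConcentrationBracket(0.98)
designDilutionSeries(50e-6, 10, ratio = 2)[6] * 1e6   # µM
```

## What the simulator emulates — and what it does not

`simulateScreen` generates a complete synthetic screen on a fixed toy
genome: one ~134 kb chromosome with ten two-exon, 452-codon genes,
including a TUBA1B gene whose codons 47 and 142 encode Asp and Gly so the
hallmark α-tubulin resistance substitutions (D47G/H, G142A/S) are
reachable by single nucleotide changes. Per clone it plants:

- Poisson(`lambdaPassenger` = 300) private passenger mutations — SNVs with
  a 2:1 transition:transversion bias plus 10% single-base indels anchored
  in homopolymer runs of length ≥ 4 (the MMR-deficiency mutational
  signature in caricature);
- a shared lineage branch of `branchSize` (default 91) mutations carried
  by one designated clone pair, representing divergence after a common
  ancestor but before selection;
- driver SNVs at configured codons and zygosities (true VAF 1, 1/2 or 1/3,
  the three zygosity classes observable in near-triploid lines), planted
  in 4 of 6 clones by default;
- parental heterozygous background variants (VAF 0.5 everywhere) and
  low-VAF parental artifact sites (true VAF < 0.01 in every sample);
- a configurable fraction (2%) of records with one hard-filter annotation
  drawn from its failing region.

Observed depths are Poisson(`depthMean` = 80) and alt reads
Binomial(depth, true VAF); QD/FS/MQ/GQ are drawn phenomenologically from
passing-region distributions — the pipeline only thresholds them, so
read-level realism would add nothing the filters can see. Output
(VCF + FASTA + gene models + JSON truth set) is byte-reproducible from the
seed.

Two deliberate departures from naive uniformity:

- **Passenger dilution.** `codingFraction` defaults to 0.0014, the coding
  share of an exome-scale mutational target (~13.5 kb of toy CDS standing
  in for roughly 10 Mb), not the toy chromosome's literal 9% coding
  content. With only ten genes, using the literal fraction would pile
  passengers into every gene and make per-gene recurrence meaninglessly
  dense; the default reproduces a realistic per-gene per-clone passenger
  hit rate of a few percent.
- **The lineage branch is coding.** Shared-mutation counts are measured on
  the coding-only somatic sets (exome sequencing observes exonic
  mutations), so the branch that the relatedness stage must detect is
  planted in coding sequence. A branch diluted at the passenger
  codingFraction would be invisible to the measurement it exists to
  exercise.

What passing tests on simulated screens do **not** show about real data:
the simulator has no mutation-rate heterogeneity beyond the homopolymer
indel rule, no mapping artifacts or strand-bias structure behind its
annotation fields, no germline CNVs or loss-of-heterozygosity (so VAF
classes are exact), no multi-nucleotide variants, and a single canonical
transcript per gene. Hard-filter behaviour against pathological real-world
VCFs is exercised only at the level the filters themselves operate.

## Problem sizes used in the shipped checks

The test suite and acceptance script run entirely on generated data, sized
so the whole suite completes in a few minutes on one core: twenty
end-to-end simulated screens (six clones, λ = 300, ~2,200 records each)
for driver-recovery and relatedness checks; 1,000+ random SNVs for the
annotation oracle; 50 replicate curve pairs at the duplicate 15-point
dilution design (50 µM to 1.58 nM, 2% multiplicative noise) for IC50 and
fold-resistance recovery. These sizes are statements of what was checked,
and the simulation conditions above are the conditions under which the
recovery claims hold.

## Known limitations

- Indels are reduced to minimal representation at read-in (shared suffix
  then prefix trimmed), but not left-aligned against the reference; two
  spellings of the same homopolymer indel anchored at different run
  positions would not match. The simulator always emits left-anchored,
  minimal indels.
- Counter-screen samples with indeterminate VAF (no informative reads) are
  treated as VAF 0; only the parental sample has an explicit depth guard,
  as the parental criterion is the one that defines "acquired".
- One transcript per gene: variants in overlapping genes annotate against
  whichever transcript footprint contains them first.
- No statistical significance model for recurrence and no
  driver/passenger probabilistic scoring — the ranking is deliberately the
  transparent count-based statistic the screen design licenses.
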