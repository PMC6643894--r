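---
title: "Mapping-by-sequencing: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping-by-sequencing: model, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ectamapper)
```

## The mapping model

A homozygous recessive mutant, isolated from an EMS screen, is crossed to a
mapping strain that differs from the laboratory background at a catalog of
known SNVs (the markers). F1 animals are heterozygous everywhere. F2 animals
showing the mutant phenotype are homozygous for the causal allele, so every
gamete that formed them carries the mutant (non-mapping) allele at the causal
site. Such a gamete carries the *mapping* allele at a marker only if a
recombination separated the two loci; under a no-interference crossover
process the probability of that is the Haldane recombination fraction

$$ r(d) = \tfrac{1}{2}\left(1 - e^{-2d/100}\right), \qquad d \text{ in cM}, $$

so the expected mapping-strain allele frequency in the selected pool rises
from 0 at the causal locus toward 0.5 with genetic distance, and is 0.5 on
unlinked chromosomes. This closed form is the package's central oracle: the
simulator is checked against it, and the mapping stage exploits it in
reverse — the chromosome whose smoothed frequency curve dips lowest carries
the causal locus, and the depressed region around the dip is the candidate
interval.

Genetic distance comes from physical position through a uniform map,
`cm_per_mb` (default 5 cM/Mb, the right order for *C. elegans* autosome
averages). A uniform map is the minimal model that supports recombination
simulation; real chromosome-arm/center structure is deliberately out of
scope, and only relative distances matter to the mapping logic.

## What the simulator emulates — and what it does not

`mutagenize()` draws a Poisson(μ × genome size) number of point mutations
(default μ = 10⁻⁵/bp, giving genome-scale-realistic SNV densities on toy
genomes), with substitution classes from a configurable spectrum defaulting
to the canonical EMS bias: 87% G:C→A:T transitions, the remaining 13% split
uniformly over the other five classes. Positions are drawn uniformly among
bases compatible with the drawn class. One variant is designated causal,
optionally constrained to coding sequence.

`simulate_cross()` models each F2 as two independent F1 gametes. Per gamete,
crossover counts are Poisson with mean equal to the chromosome's
genetic length in Morgans, crossover positions uniform, starting parent a
fair coin — exactly the process whose two-locus marginal is Haldane's
formula. Selection retains animals homozygous non-mapping at the causal site
(the genetic meaning of scoring a recessive phenotype) until the configured
pool size N (default 50) is reached.

`simulate_pool_readcounts()` draws per-marker total depth Poisson(D) (default
D = 30) and each read's allele Bernoulli from the pool frequency convolved
with a per-read miscall rate ε (default 0.002), so the observed frequency has
expectation $f(1-\varepsilon) + (1-f)\varepsilon$.

Not modeled, by design: read-level sequencing (alignment, base quality,
duplicates), crossover interference, depth overdispersion, X-chromosome/male
inheritance, dominance, balancers, and heterozygous residual variation —
strains are treated as homozygous lines. Passing tests therefore demonstrate
correctness of the allele-count-level analysis under these idealizations, not
robustness to alignment artifacts or coverage pathologies in real data.

## The Loess smoother

The smoother is implemented from first principles rather than wrapped, since
local regression of marker frequencies *is* the mapping step. For each point
the ⌈αn⌉ nearest neighbours by |x − xᵢ| get tricube weights
$w = (1 - (\Delta/\Delta_{max})^3)^3$ and a weighted least-squares polynomial
of degree 0 or 1 is evaluated at xᵢ. Defaults are degree 1 and span α = 0.3
with no robustness iterations — classic first-degree Loess. The test suite
holds it to ≤ 10⁻⁸ against an independent per-point `lm(weights = )` oracle,
and to exact reproduction of constants and collinear data. Degenerate
duplicate-x neighbourhoods fall back to the local (weighted) mean, so fitted
values are finite everywhere. Fitting is unweighted by depth; depth-weighted
smoothing would privilege high-coverage markers but the reference analysis
plots plain frequencies, so the default follows it (the depth column is
retained for users who want to filter harder).

## Thresholds and numerical choices

- `min_depth = 5`: markers below 5 reads are excluded (and counted) before
  smoothing, suppressing error-driven outliers at near-zero coverage.
- `link_threshold = interval_threshold = 0.25`: the midpoint between the
  causal expectation (0) and the unlinked expectation (0.5). A chromosome is
  called linked only if its fitted minimum falls below the threshold; the
  candidate interval is the contiguous sub-threshold run containing the
  argmin, never empty. Ties on the minimum break to the first chromosome in
  genome order, with a warning — determinism is preferred to an arbitrary
  alternative.
- Sibling threshold 0.5 (Jaccard on exact (chrom, pos, ref, alt) keys):
  strains descending from one mutagenized genome share most induced variants
  (overlap near 1 − 2 × private fraction), while independent EMS strains
  collide essentially never at genome scale, so any threshold well inside
  (0, 1) separates them; 0.5 is the documented, configurable default. The
  grouping is single-linkage, which is order-invariant. The overlap rule is
  this package's operationalization of sibling calling; no published
  criterion was available to copy.
- Wilson score intervals for penetrance (not Wald): screen penetrances sit
  near 0% or 100%, where Wald intervals degenerate. Two-proportion contrasts
  use the Newcombe hybrid interval and Fisher's exact test. Published-style
  displays round half-up to one decimal; `check_reported_percent()` inverts a
  printed (percent, n) pair to the unique consistent count k when one exists
  and flags rows where none does.
- Ploidy classes are powers of two times 2N (endoreduplication rounds), via
  `2^round(log2(ploidy/2)) · 2` with R's round-half-to-even on exact ties;
  continuous estimates are reported alongside. Estimates are invariant to
  intensity rescaling.

## Effect annotation

Consequences are called per overlapping transcript (no most-severe-per-gene
collapsing): CDS position by summing exon offsets in transcription order,
reverse-strand transcripts via reverse-complemented alleles, translation with
the standard nuclear code. The splice-site window is the first/last 2 bp of
each intron (donor/acceptor dinucleotides) and overrides intronic; positions
inside a transcript but outside its CDS (UTR exons, CDS-less genes) follow
the intronic logic, as the class set carries no separate UTR label. Any SNV
in the initiator codon is `start_lost` regardless of the encoded alternative.
REF alleles are verified against the genome sequence and mismatches are
errors naming the position. Shortlists rank nonsense/splice/start-lost/
stop-lost above missense above synonymous above intronic, stable by position;
which classes are candidate-worthy is an explicit policy of this package, not
an imported convention.

## Problem sizes used in validation

The recovery studies run at the package's default study conditions — 5
chromosomes × 20 Mb, markers every 100 kb, N = 50 pooled F2s, 30× depth,
ε = 0.002, span 0.3 — with 100 seeded replicates for linkage accuracy and
interval coverage, 200 pools for the Haldane-law check, 100 replicates for
sibling grouping, and the full 1,800-SNV enumeration (300-bp CDS, both
strands) for annotation. Smaller toy genomes (hundreds of kb) are used where
sequence is needed, since `mutagenize()` and annotation index the genome
string; the genotype-level cross simulator needs no sequence and scales to
the 100 Mb layout directly.

## Known limitations

Single causal locus per strain (no two-gene mapping); biallelic SNVs only —
indels are parsed, counted and skipped, never silently dropped; no
bootstrap/confidence machinery on the candidate interval; the uniform
genetic map ignores arm/center recombination-rate structure, so simulated
intervals are symmetric in a way real *C. elegans* data are not.
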