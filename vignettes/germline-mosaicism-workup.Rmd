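---
title: "The germline-mosaicism workup: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The germline-mosaicism workup: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microseqr)
```

## The problem

An apparent de novo mutation in a proband — present in the child, absent
from both parents' blood — leaves genetic counseling in the dark. If the
variant truly arose in a single gamete, the recurrence risk for a future
sibling is negligible; if one parent is a germline (gonadal) mosaic, a
substantial fraction of their gametes carry the variant and the risk can be
orders of magnitude higher. With a single affected patient, three questions
must be answered in sequence:

1. **Which parental chromosome carries the de novo allele?** Haploid
   sequence from one homolog — obtained by microdissecting the chromosome
   region from a metaphase spread and amplifying it (WGA) — links the
   mutant base to nearby SNP alleles that can be attributed to one parent.
   When a second, inherited pathogenic variant is segregating (here: a
   recessive collagen-IV nephropathy with one maternally inherited
   frameshift), the same linkage resolves whether the two variants are in
   *trans* (compound heterozygote, disease-causing) or in *cis*.
2. **Is the mutation detectable in the gametes?** Deep targeted sequencing
   of sperm DNA measures the mutant allele fraction directly, with a
   detection limit set by the sequencing error rate and read depth.
3. **What is the recurrence risk?** The gamete mutant fraction, scaled by
   the transmission probability of any second pathogenic allele, bounds
   the risk for the next conception and drives the PGD/PND recommendation.

`microseqr` implements all three stages plus a seeded synthetic-cohort
generator that produces every input with known ground truth, so the whole
pipeline is testable without wet-lab data.

## Quantification model

A pileup at the mutation site reports `k` mutant-supporting reads out of
depth `D`. A read supports the mutant allele either because it comes from a
mutant molecule and is read correctly, or from a wild-type molecule
miscalled towards the specific mutant base:

$$p_{obs} = f\,(1-\varepsilon_{tot}) + (1-f)\,\varepsilon_{tgt},
\qquad K \sim \mathrm{Binom}(D, p_{obs}).$$

* `eps_total` (default 0.001) — probability a sequenced base is miscalled
  as *any* wrong base; a typical short-read substitution rate.
* `eps_target` (default `eps_total/3`) — probability of miscalling towards
  the one mutant base, i.e. substitution errors spread evenly over the
  three wrong bases.

The headline estimate is the **raw fraction** `k/D`, matching how deep
amplicon results are reported in practice; the error-corrected inversion
`(k/D - eps_target) / (1 - eps_total - eps_target)`, clamped to `[0, 1]`,
is carried as a secondary field. The inversion composed with the forward
model is the identity to numerical precision away from the clamp, which the
test suite asserts at `1e-12`.

### Detection rule

The source material labels counts "detected" or "0" without stating a
rule, so the package makes one explicit. A site is **detected** when all
three hold:

1. `k >= k_min` (default 3) — a handful of reads is never trusted alone;
2. one-sided exact binomial `P(K >= k | D, eps_target) < alpha`
   (default 0.01, strict inequality) — significance against the error
   null;
3. `k/D >= lod_fraction` (default 1%) — a practical limit of detection
   below which amplicon artefacts dominate.

All three conditions are upper sets in `k`, so the rule reduces to one
count threshold per depth; `analytic_power()` sums the binomial mass above
it exactly, and `sensitivity_grid()` estimates the same quantity by
Monte-Carlo (1,000 replicates per cell by default), flagging a cell
"detectable" at empirical power ≥ 0.90 — single-run success is too noisy
to define a limit of detection. With the default error model this rule
reproduces the qualitative depth-sensitivity pattern of the source data:
a 3% mixture is detectable from 200X up, a 0.1% mixture is undetectable
even at 10,000X, and the smallest detectable fraction at 500X is 2%.

Confidence intervals are exact Clopper–Pearson (beta quantiles): counts
near the error floor are far too small for asymptotic intervals.

A boundary subtlety: power is non-decreasing in depth only for fractions
strictly above `lod_fraction`. Exactly at the boundary the integer
threshold `ceiling(lod * D)` makes power wobble between depths (e.g. a 1%
sample is *less* often called at 1,000X than at 500X). This is a real
property of LOD-thresholded calling, not an artefact.

## Phasing model

A microdissected fragment is one contiguous homolog piece, so every allele
it reports is in *cis* with every other. Each covered SNP is scored
against the parents' constitutional genotypes:

* allele in father only → `PATERNAL_ONLY`;
* in mother only → `MATERNAL_ONLY`;
* in both → `AMBIGUOUS` (kept in the report, excluded from the count);
* in neither → `INCONSISTENT` (WGA artefact or mix-up).

`infer_origin()` calls a parent only when all non-ambiguous verdicts agree
and at least `min_informative` of them exist (default 1; the worked case
had 6). Any disagreement or inconsistency degrades to *indeterminate* with
`conflict = TRUE` rather than majority-voting, because recombination
between fragment ends or WGA error cannot be excluded; majority voting
exists only behind an explicit flag. Phase versus the known inherited
mutation is then parity: different parent → *trans*, same → *cis*.

Fragment sets are first classified into interpretation scenarios: both de
novo alleles seen across fragments (`BOTH_ALLELES`); one fragment covering
both mutation sites (`MUT_WITH_KNOWN_WT` / `WT_WITH_KNOWN_MUT` — direct
phase evidence); the mutant or wild-type de novo allele with linked SNPs
only (`MUT_WITH_SNPS`, the worked case, and `WT_WITH_SNPS`); otherwise
`UNINFORMATIVE`. A `WT_WITH_SNPS` fragment phases only the non-mutant
homolog, and the pipeline deliberately refuses to invert it into a
mutant-origin call — the recommendation is to continue dissection. A
two-site fragment with an unexpected allele pair (both mutant or both
wild-type) fits neither direct scenario and falls through to the SNP
rules; the scenario names here are the package's own, chosen to be
unambiguous.

Candidate SNPs are listed from a panel within a window of the mutation
site (default 5 Mb each side), filtered by population heterozygosity and
ranked heterozygosity-descending with distance and position as
deterministic tie-breaks.

### Known limitation

With `min_informative = 1`, a single WGA miscall that happens to mimic a
parent-private allele is information-theoretically indistinguishable from
truth: no rule can reject it, and the call can name the wrong parent. The
conflict guard only fires when a second informative SNP disagrees.
Demanding `min_informative = 2` restores the never-wrong property under
per-site miscall rates around 1%, at the cost of more indeterminate calls;
the worked case's six concordant SNPs are comfortably beyond either
threshold. The tests verify: noise-free, resolved calls are 100% correct
and degradation is only to indeterminate; under noise, the conflict rate
rises monotonically with the miscall rate and wrong calls never carry
multi-SNP support.

## Paternity and risk

Paternity is checked by Mendelian exclusion counting over the standard
16-marker forensic STR panel: a marker is compatible if the child's allele
pair can be split into one maternal and one paternal allele. Two or more
incompatible markers exclude paternity (one is allowed for a germline STR
mutation and yields *inconclusive*); zero confirm it. The Amel sex marker
is checked for sex consistency only. No likelihood-ratio paternity index
is computed.

Recurrence risk is `sperm_fraction × t` per conception, with transmission
factor `t`: 1 for autosomal dominant, 1/2 for autosomal recessive with a
carrier partner (the second allele transmits with probability 1/2) and 0
without one; X-linked dominant and Y-linked use 1, X-linked recessive
mirrors the AR factor. Risk is reported unconditional on offspring sex;
sex-specific caveats live in the narrative string. The worked case's
bound — sperm fraction below 3%, AR mode, carrier mother — gives a risk
below 1.5%, and the measured 2.65% gives 1.325%.

`plan_case()` is a pure decision engine over the case's evidence state:
paternity first; then deep blood sequencing of the parents; a positive
blood result is somatic mosaicism; blood-negative demands fragment-based
origin determination (the only option in a single patient, and required
for the trans/cis proof under recessive modes); paternal origin with semen
available leads to sperm deep sequencing, risk estimation and — when the
sperm call is positive — a PGD/PND recommendation; maternal origin can
only be supported indirectly, since oocytes cannot be sampled. A negative
sperm result is reported as de novo with the explicit caveat that
mosaicism below the configured LOD is not excluded.

## The synthetic cohort

The generator emulates, with known truth: phased parental haplotypes over
a SNP panel (per-site independent draws whose alt-allele probability `q`
solves `2q(1-q) = pop_het`); a known inherited mutation on one haplotype
of the non-mosaic parent; a de novo allele on the transmitted haplotype of
the mosaic parent, absent from that parent's blood; fragment capture
(default 1/8 per fragment, 4 cells — calibrated to the observed one
informative product among eight), per-site dropout (0.2) and per-site WGA
miscalls (0.01, unstated in the source and chosen so multi-SNP fragments
stay informative while dropout paths are exercised); binomial pileups
under the forward error model; heterozygote/wild-type DNA mixtures (a
mass proportion `m` of carrier DNA has allele fraction `m/2`; printed
mixture percentages are treated as allele fractions, which matches the
reported readouts, with `mixture_allele_fraction()` converting the other
parametrization); and STR trios drawn from eight equifrequent repeat
alleles per marker (heterozygosity 0.875).

What it does **not** emulate: linkage disequilibrium (the SNPs serve only
as linkage anchors within one un-recombined fragment), recombination
within a fragment, indel-specific read errors (the frameshift is carried
as a genotype, never as reads), strand bias, or site-specific error
recalibration. Passing tests therefore demonstrate the statistical
machinery under idealized independence assumptions, not performance on
real amplicon data. The proband always carries the de novo allele
regardless of the simulated gamete fraction — the patient is ascertained;
the fraction governs sperm pileups only.

Every simulator takes an integer seed and is bit-reproducible;
coordinates are 1-based on the forward strand throughout.

## Numerical choices and problem sizes

Exact binomial tails come from `pbinom`, beta quantiles from `qbeta`;
ties at the `alpha` boundary are resolved by strict inequality. The test
suite validates tails against brute-force mass summation and intervals
against `binom.test`. Monte-Carlo checks run at 1,000 replicates per grid
cell (10,000 for the false-positive calibration), 1,000 simulated trios
for origin accuracy, and 1,000 STR trios for paternity exclusion — sizes
at which three Monte-Carlo standard errors separate every asserted
pattern.

## Worked example

```{r example, eval = FALSE}
pileup <- read_pileup_tsv(system.file("extdata", "sperm_tngs.pileup.tsv",
                                      package = "microseqr"))
quantify_pileup(pileup)

trio <- read_trio_vcf(system.file("extdata", "trio_2q36.vcf",
                                  package = "microseqr"))
frags <- read_fragments_tsv(system.file("extdata", "fragments_2q36.tsv",
                                        package = "microseqr"))
phase_de_novo(frags, trio, known_site = "c.1322delT",
              de_novo_site = "c.2939T>A", known_mutation_parent = "mother")

recurrence_risk(0.0265, mode = "AR", partner_carrier = TRUE)
```

The packaged trio genotypes and SNP coordinates are synthetic: they are
constructed to be consistent with the published haplotype string and the
paternal-origin conclusion, not transcribed from any primary data (which
exist only as figure images), and the rsID positions are plausible 2q36
placements, not database coordinates.
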