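---
title: "Quantifying donor-derived cell-free DNA: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying donor-derived cell-free DNA: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddcfdna)
```

## The problem

After a solid-organ transplant, cells of the graft release DNA fragments
into the recipient's plasma as they die; during acute rejection the
release accelerates. Because donor and recipient are distinct
individuals, any site where their genotypes differ lets a sequencing
read be attributed to one of them, and the percentage of plasma
cell-free DNA (cfDNA) that is donor-derived becomes a blood-based
rejection marker. This package implements that quantification for a
donor–recipient pair given (i) annotated, optionally phased genotype
VCFs for both individuals and (ii) a site-level allele-count table from
the recipient's cfDNA, together with a synthetic-data generator that
provides ground truth for every stage.

## The mixture model

At an informative SNP let the recipient be homozygous for allele $b$
and let the donor carry a discriminating allele $a \neq b$ in $c \in
\{1, 2\}$ copies. Reads at the site are a mixture: with probability $f$
(the donor fraction) a read derives from the graft, otherwise from the
recipient. A donor read carries $a$ with probability $c/2$; a recipient
read never does. With a per-read allele-flip error $\varepsilon$, the
probability that a read shows $a$ is

$$q = f\,\tfrac{c}{2}(1-\varepsilon) + f\,(1-\tfrac{c}{2})\varepsilon +
(1-f)\,\varepsilon .$$

### The read-fraction estimator

`estimateFractionReadfraction()` computes, over usable sites (donor has
a discriminating allele, recipient homozygous for a non-discriminating
one),

$$\hat f_{\text{raw}} = \frac{\sum_i w_i k_i}{\sum_i n_i},
\qquad w_i = \frac{2}{c_i},$$

with $k_i$ the reads carrying discriminating alleles and $n_i$ the site
depth. The weight $w$ undoes the zygosity dilution: a heterozygous donor
transmits its discriminating allele on only half its reads, so those
counts are doubled. Without error, $E[\hat f_{\text{raw}}] = f$
exactly.

With error the expectation becomes
$f(1-2\varepsilon) + \varepsilon \bar W$, where
$\bar W = \sum w_i n_i / \sum n_i$: recipient reads flipped onto the
discriminating allele inflate the estimate by roughly $2\varepsilon$ at
heterozygous-donor sites, which at $\varepsilon = 10^{-3}$ is a +0.2
percentage-point bias — far larger than the sampling error at the depths
this assay uses. The estimator therefore measures the background flip
rate on *shared-homozygous* sites (both individuals homozygous for the
same allele, where every discordant read is an error):
$\hat\varepsilon$ is the discordant-read share there, and the reported
value is the first-order-exact correction

$$\hat f = \frac{\hat f_{\text{raw}} - \hat\varepsilon\,\bar W}
{1 - 2\hat\varepsilon},$$

clamped at zero. Both the raw and corrected values are kept (the raw
one in `details$rawPercent`), and at $\varepsilon = 0$ they coincide, so
an error-free zero-donor mixture estimates exactly 0. This background
subtraction is the package's own design choice; it is standard practice
in cfDNA assays, where the error floor otherwise sets the detection
limit.

### The site-count estimator

`estimateFractionSitecount()` follows the genotype-matching phrasing of
the method: cfDNA alleles are first *called* (an allele is present iff
supported by at least `minSupport = 5` reads, inclusive), and the
estimate is the share of informative sites whose donor-discriminating
allele is called, among sites positive for either individual's
discriminating allele. Sites with no called allele are excluded from
denominators and counted (`details$noCallInformativeSites`). This
estimator is monotone in $f$ and in depth, but its value depends on the
support threshold and the depth distribution — at high depth nearly
every discriminating allele of both individuals is detected and the
ratio tends towards the composition of informative sites rather than
$f$. The two estimators are therefore tagged distinctly
(`unphased-readfraction` vs `unphased-sitecount`) and never mixed; the
read-fraction estimator is the parameter-recovery surface.

### The phased method

`buildPhasedSets()` consumes phased genotypes (phase is *consumed*, not
computed — read-backed phasing is a separate tool's job) and builds
disjoint donor-derived and recipient-derived variant sets: an allele at
a site is donor-derived iff it occurs on at least one donor haplotype
and neither recipient haplotype. Restricted to left-normalised biallelic
SNPs, this coincides exactly with the unphased discriminating sets —
phase adds no information at a single biallelic site — and the test
suite asserts that equivalence; divergence could only arise from
multiallelic or representation-normalisation cases, which the simulator
deliberately does not produce. `matchCfdnaToSets()` then counts set
members whose allele is called in the cfDNA, and
`estimateFractionPhased()` reports
$100 \cdot d/(d + r)$ per chromosome and pooled.

### Concordance between methods

`concordanceReport()` correlates the two methods' per-chromosome percent
vectors (percent donor-derived, and its within-denominator complement
for recipient-derived). With these definitions the donor and recipient
correlations coincide numerically; both are reported because they answer
for the two variant-set origins. Per-chromosome percentages are the
natural unit: each chromosome is an independent replicate of the
composition and sampling noise.

## Hard filtering

`filterStream()` applies the strict hard-filter predicates per variant
class: SNPs fail on QD < 2.0, QUAL < 30.0, SOR > 3.0, FS > 60.0,
MQ < 40.0, MQRankSum < −12.5 or ReadPosRankSum < −8.0; INDELs on
QD < 2.0, QUAL < 30.0, FS > 200.0 or ReadPosRankSum < −20.0. Three
numerical choices matter:

* every inequality is strict, so boundary values (QD = 2.0, FS = 60.0 /
  200.0, MQRankSum = −12.5, ReadPosRankSum = −8.0 / −20.0) **pass**;
* a missing statistic cannot be evaluated and never fails its predicate
  — the evaluation is counted (`missingEvaluations`) so silent
  leniency is visible. How missing annotations should be treated is not
  prescribed anywhere; pass-with-log keeps the rule set total without
  inventing evidence;
* records that are neither SNP nor INDEL (e.g. same-length
  multi-nucleotide substitutions) are excluded as `malformed` with their
  rows returned, never silently dropped.

## The informative-site index

`classifySite()` works on genotypes as unordered allele pairs with
set semantics: shared iff identical; otherwise the set differences give
the discriminating alleles and the class (donor-unique,
recipient-unique, both-unique). Genotype-level uniqueness (the printed
definition of the index) and allele-level discriminating sets are both
stored, because cfDNA evidence arrives per allele: the quantifiers need
an allele to look for. A residual `uninformative` class keeps the
classification total, though for diploid genotypes under set semantics
it is unreachable (differing unordered pairs always leave a
discriminating allele on some side) — the exhaustive-enumeration test
documents this. Sites called in only one individual are counted as
half-called and excluded from quantification; folding missingness into
uniqueness would bias the index. Coordinates are 1-based inclusive (VCF
convention) throughout.

## Fragment-size statistics

`meanFragmentSize()` averages sizes inside a **closed** window,
default [40, 10000] bp — the measurement range of the sizing instrument;
closedness is a choice the range notation leaves open, and it is applied
consistently. Empty or fully out-of-window samples are *flagged*, never
reported as 0. `compareConditions()` is the paired Student's t-test,
one-tailed for endpoint > baseline (apoptotic release increases
fragment size); zero-variance differences are an error because the test
is undefined there.

## Rejection-marker statistics

`rejectionMarkerStats()` reproduces the marker statistics from the
packaged six-animal table: Pearson r of unphased percent ddcfDNA
against log troponin, against time to rejection, and against endpoint
fragment size, plus the paired fragment-size test. Choices made where
the analysis was open, each verified against the printed statistics:

* troponin is log-transformed with the natural log — Pearson r is
  invariant to the log base, so the choice is cosmetic;
* the unphased percent column drives the correlations (the phased
  column does not reproduce the troponin and rejection-time
  coefficients to printed precision);
* the non-rejecting animal enters the rejection-time correlation at its
  sacrifice day (106) with a censoring flag, and a sensitivity
  recomputation without it is always emitted;
* all p-values are two-tailed except the paired fragment-size test,
  which is one-tailed by design.

## What the generator emulates — and what it does not

`simulationConfig()` defaults are the study conditions the package
models, chosen once:

| parameter | default | rationale |
|---|---|---|
| chromosomes | 18 × 120 kb + 10 kb control | autosome count of the pig; desk-scale lengths |
| `snpDensity` | 3.42 /kb | the pairwise SNP density observed in the cohort |
| alt allele frequency | Beta(1, 1) | unrelated outbred pair, uninformative prior |
| `donorFraction` | 0.05 | centre of the observed 1.8–7.4 % range |
| `meanDepth` | 1000 | cfDNA depth at which single-SNP genotyping is reliable |
| `errorRate` | 0.001 | short-read substitution-error scale |
| fragment log-normal | meanlog log(2500)/log(4300), sdlog 0.35 | centres near the cohort's baseline/endpoint mean sizes |
| support threshold | 5 reads, inclusive | "at least five reads of support" |

The generator draws site counts Poisson per chromosome, places sites
uniformly, draws two independent phased diploid genotypes, mixes reads
donor/recipient at fraction $f$ with Poisson depth, flips alleles with
probability $\varepsilon$, and draws condition-specific log-normal
fragment sizes. The control chromosome is declared in headers but
receives no sites and no reads, standing in for a Y-chromosome negative
control in an all-female cohort.

Deliberate simplifications: biallelic SNPs only (the index is
SNP-driven); reads are single-site observations (the comparison is
per-SNP, so linked multi-SNP fragments add nothing to what is tested);
the error model flips to the one alternative allele (the simplest model
that can create false donor signal at $f = 0$); donor and recipient are
unrelated draws (study pairs were deliberately mismatched — no kinship
knob). Consequently, passing tests demonstrate correctness of the
estimators under the mixture model, not robustness to mapping artefacts,
GC or fragment-length coverage biases, index hopping, or related donors
— all of which real data can contain. The observed fragment-size means
in the study table (2.2–5.5 kb) are also far above the canonical
~167 bp plasma cfDNA mode; the generator exposes location parameters
rather than asserting a biological size model.

## Numerical and degenerate-input conventions

* Zero denominators (no informative coverage) yield a *flagged* `NA`
  percent, never 0; a zero numerator over nonzero coverage is an honest
  0.
* Pooled estimates are always recomputed from pooled counts — never the
  mean of per-chromosome values — so pooling conserves the
  depth-weighted combination.
* Fixed seed implies byte-identical simulator output and pipeline
  manifests; every operation takes its seed deterministically from the
  configuration.
* Sorted-input checking follows VCF semantics: one contiguous block per
  chromosome, strictly increasing positions within it; violations name
  the first offending record.

## Problem sizes used by the test suite

The suite exercises: the exhaustive 3 × 3 biallelic genotype-pair
enumeration and all pairs over three alleles, 1 000 random multiallelic
symmetry cases, 10 000 randomized annotation records against a
re-evaluating oracle, an 18-chromosome pair at depth 1000 (every
chromosome with ≥ 100 covered informative sites) for method
concordance, read-fraction recovery at donor fractions
0.018/0.05/0.074 with 10 000 usable sites at depth 1000 across five
seeds (each within 3 standard errors of truth by a delta-method oracle),
and SNP-density recovery over 1 000 simulated 100-kb chromosomes. These
sizes make every law-of-large-numbers band tight enough to detect an
estimator bias of the size the error model predicts, while the whole
suite stays fast enough to run routinely.

## Known limitations

* `vcfeval`-style haplotype-path equivalence is reduced to
  left-normalised allele matching; indel-containing haplotype blocks and
  complex-variant representation differences are out of scope.
* The site-count estimator's absolute value is threshold- and
  depth-dependent by construction; only the read-fraction estimator
  should be read as an estimate of the donor fraction.
* The background error correction assumes the flip rate at
  shared-homozygous sites equals the rate at informative sites; locus-
  or context-specific error variation is not modelled.
* No clinical decision threshold is provided or implied.
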