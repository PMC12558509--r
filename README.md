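# ddcfdna

Quantification of donor-derived cell-free DNA (ddcfDNA) after solid-organ
transplantation, from whole-genome genotypes of the donor–recipient pair
and site-level allele counts in the recipient's plasma cfDNA.

When an allograft's cells die — as they do at an accelerating rate during
acute rejection — they shed short DNA fragments into the recipient's
circulation. At any genomic site where the donor carries an allele the
recipient lacks (a *discriminating allele* at an *informative SNP*), a
cfDNA read carrying that allele can be attributed to the graft. The
fraction of plasma cfDNA that is donor-derived is therefore a
non-invasive rejection biomarker, and this package implements the full
analysis that turns a pair of genotype VCFs and a cfDNA allele-count
table into that percentage.

## What the package computes

* **Hard filtering** of annotated variant calls with the standard strict
  thresholds — SNPs fail on QD < 2.0, QUAL < 30.0, SOR > 3.0, FS > 60.0,
  MQ < 40.0, MQRankSum < −12.5 or ReadPosRankSum < −8.0; INDELs on
  QD < 2.0, QUAL < 30.0, FS > 200.0 or ReadPosRankSum < −20.0 (all
  inequalities strict; boundary values pass; missing statistics are
  non-evaluable and counted).
* **An informative-SNP index** (`buildIndex`): every jointly-called site
  is classified as shared, donor-unique, recipient-unique or both-unique,
  with the allele-level discriminating sets recorded.
* **A haplotype-aware comparison** (`buildPhasedSets`): from phased
  genotypes, disjoint donor-derived and recipient-derived variant sets;
  at biallelic SNPs these coincide with the unphased discriminating sets,
  and the package verifies that equivalence.
* **cfDNA allele calling** under a minimum-support rule (an allele is
  present iff covered by at least 5 reads, inclusive).
* **Two estimators of percent ddcfDNA**, per chromosome and pooled:
  * *site-count* — the share of informative sites whose
    donor-discriminating allele is seen among sites positive for either
    individual's discriminating allele (the genotype-matching
    formulation; monotone in the donor fraction but threshold-dependent);
  * *read-fraction* — the zygosity-weighted share of reads carrying
    donor-discriminating alleles, f̂ = Σ w·k / Σ n with w = 2 at
    donor-heterozygous sites and w = 1 at homozygous ones, corrected for
    the background error rate measured on shared-homozygous sites. Its
    expectation equals the true donor fraction under the mixture model,
    and it is the estimator used for parameter recovery.
* **Fragment-size statistics**: windowed (40–10 000 bp, closed) mean
  fragment sizes and the paired one-tailed t-test of endpoint vs
  baseline.
* **Rejection-marker statistics** (`rejectionMarkerStats`): Pearson
  correlations of percent ddcfDNA with log troponin, time to rejection
  and endpoint fragment size, from the packaged six-animal study table.
* **A synthetic-data generator** (`simulateDataset`, `emitDataset`) that
  emulates a transplant pair — 3.42 SNPs/kb, phased diploid genotypes,
  Poisson depth, donor/recipient read mixing at a known fraction,
  allele-flip sequencing error, log-normal fragment sizes and a
  read-free control chromosome — so every stage is testable against
  ground truth.

## Worked example

```r
library(ddcfdna)

cfg <- simulationConfig(donorFraction = 0.05, seed = 11L)
ds  <- simulateDataset(cfg)
idx <- buildIndex(ds$donor, ds$recipient)
idx
#> InformativeSiteIndex
#>   7350 jointly-called sites on 18 chromosomes; 0 half-called (excluded)
#>     both-unique       503
#>     donor-unique      1530
#>     recipient-unique  1469
#>     shared            3848

estimateFractionReadfraction(idx, ds$counts)
#> DonorFractionEstimate [unphased-readfraction]
#>   pooled: 4.981% ddcfDNA (101191 / 2031434)
#>   18 chromosomes
```

The pooled estimate recovers the simulated 5 % donor fraction; the
background flip-rate estimate it used (0.000997) matches the configured
sequencing error of 0.001. The study-table statistics print as:

```r
stats <- rejectionMarkerStats()
stats$troponinLog
#> Pearson r = 0.797 (n = 6, t = 2.642, df = 4, p = 0.05746) ns
stats$endpointFragment
#> Pearson r = 0.947 (n = 6, t = 5.870, df = 4, p = 0.004207) **
```

i.e. percent ddcfDNA correlates with log troponin (r = 0.80, not
significant at n = 6) and strongly with endpoint fragment size
(r = 0.95, p = 0.004). `runPipeline(cfg, outDir)` chains every stage —
simulate, write, re-read, filter, index, call, quantify by all three
methods, concordance and the negative control — and writes a manifest
whose digests are reproducible from the seed.

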