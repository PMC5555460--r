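# multisiteQTL

Simulation framework for studying how linkage disequilibrium (LD) between
multiple causal regulatory variants biases cis-eQTL discovery,
localization, and effect-size estimation.

## Who this is for

Statistical geneticists and eQTL methodologists who want to quantify what
the standard mapping pipeline — univariate scan, then sequential
conditional ("stepwise") analysis at *P* < 10⁻⁵, then a joint
multivariable refit — actually delivers when a gene's expression is
driven by several linked variants, and how often an *untyped* causal
variant splits into spurious multiple associations.

## The core quantities

A trait is simulated as *y* = Σⱼ sⱼ βⱼ gⱼ + N(0,1), with dosages
gⱼ ∈ {0,1,2}, signs sⱼ = ±1 and effects βⱼ in trait SD units (sdu). Per
variant, VE = 2p(1−p)β² is the variance explained relative to unit
environmental noise, so β = √(VE / 2p(1−p)).

Two closed forms anchor the analysis:

* **Omitted-variable bias.** With a correlated co-causal site omitted,
  E[β̂₁] − β₁ = r β₂ √(p₂(1−p₂)/p₁(1−p₁)) — largest for
  frequency-matched pairs (where it is r·β₂), positive or negative with
  the sign coupling (`expectedUnivariateBias()`).
* **LD feasibility.** |r| ≤ √(p_min(1−p_max)/(p_max(1−p_min))): a rare
  and a common allele cannot be in high LD (`maxAbsR()`).

Around these sit an exact two-locus genotype sampler (`samplePair()`), a
block-LD locus simulator with frequency-correlated variants
(`simulateLocus()`), VCF/dosage-TSV readers (`readGenotypes()`), the
association stack (`univariateScan()`, `stepwiseConditional()`,
`jointFit()`), power and sample-size calculators (`univariatePower()`,
`requiredSampleSize()`), replicate scoring (credible-set tagging at
r² > 0.8, causal capture, RTC = (N_SNPs − rank)/N_SNPs, variance
decomposition, bias surfaces), and the masked-causal experiment
(`spuriousSignalTrial()`, `aggregateByMafBin()`).

## Worked example

Four causal variants with same-direction effects (scenario `"4:0"`,
VE ~ U(0.02, 0.10) each) in 400 kb loci of 50 variants, 600 samples,
40 replicates:

```r
library(multisiteQTL)
res <- runExperiment(reps = 40, nSamples = 600, nSnps = 50,
                     scenario = "4:0", seed = 11)
res$table1
#>   detected percent proportionTagged
#> 1        0       0               NA
#> 2        1       5        1.0000000
#> 3        2      30        1.0000000
#> 4        3      60        0.9027778
#> 5        4       5        1.0000000
#> 6       >4       0               NA
```

Each row is the percentage of replicates in which that many independent
peaks were detected; the bracketed column is the mean proportion of those
peaks whose r² > 0.8 credible set contains a true causal variant. At this
small sample size the stepwise procedure usually finds only two or three
of the four simulated sites — power, not procedure, is binding — while
nearly every reported peak tags a real signal. At n = 1839 the detected
count concentrates on 4 and a small excess of replicates (about 1–2% on
this synthetic LD panel) reports *more* peaks than simulated sites:
statistical artifacts of conditioning in LD.

The planning question "how many samples to estimate a tightly linked
pair accurately?" has a direct answer:

```r
rs <- requiredSampleSize(r2 = 0.9, veEach = 0.1, tol = 0.1,
                         reps = 1000, seed = 1)
rs$requiredN
#> [1] 1600
```

i.e. with two variants at r² = 0.9, each explaining 10% of variance
(β = 0.5 sdu), the joint fit needs ~1600 samples before the mean
absolute estimation error drops to 0.1 sdu; the full error-vs-n curve is
in `rs$curve`.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/multisiteqtl.R` (subcommands `simulate`, `run-scenario`,
`mask-experiment`, `bias-tools`), taking YAML/JSON configs and writing
TSV/JSON outputs with a reproducibility manifest.

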