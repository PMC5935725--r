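# chipcalib

Quantitative, globally calibrated ChIP-seq normalization and twofold
expression classification.

## The problem

Conventional ChIP-seq normalization scales every sample to a common
read depth, which silently erases genuine genome-wide changes in a
histone mark: a condition in which H3K36me2 is uniformly depleted by
70% looks identical to its control after depth scaling. `chipcalib`
implements a calibration chain that keeps such global changes
quantitative, together with the RNA-seq fold-change classifications
used to interpret them (mutant-sensitive vs -resistant induced genes,
set overlaps, depot-selectivity rankings), and a synthetic-data
generator with planted ground truth so the whole pipeline is testable
end to end without external data.

## The method

For a ChIP sample with binned coverage $x_b$ over $B$ genome bins:

1. **Unit-mean scaling** — $x_b \leftarrow x_b \cdot B / \sum_b x_b$,
   so the genome-wide mean intensity is exactly 1 for every sample.
2. **Poisson input subtraction** — with the input control rescaled to
   the ChIP sample's read depth giving rate $\lambda_b$ per bin,
   subtract the upper $1-p$ Poisson quantile
   $u(\lambda_b) = \min\{k : F_{\mathrm{Pois}(\lambda_b)}(k) \ge 1-p\}$
   (default $p = 0.001$), flooring at 0.
3. **Global calibration** — multiply by the sample's global
   modification level relative to a reference sample (the quantity a
   quantitative Western blot measures), restoring the global
   differences that step 1 removed.

Calibrated tracks feed per-gene body means, strand-flipped TSS metagene
profiles, and mark-ratio curves (e.g. H3K36me2/H3K27me3 around the
TSS). On the expression side, RPKM-based calls use
$(\mathrm{to}+c)/(\mathrm{from}+c) \ge T$ with $T = 2$ and pseudocount
$c = 0.5$; induced genes that fail to re-induce in a mutant are
*sensitive*, the rest *resistant*.

## Worked example

```r
library(chipcalib)

spec <- syntheticSpec(seed = 1)          # 2 x 1 Mb, 200 bp bins, depletion 0.3
gm   <- makeGenome(spec)
ctrl <- simulateChipReads(gm, spec, mark = "H3K36me2", condition = "CTRL")
mut  <- simulateChipReads(gm, spec, mark = "H3K36me2", condition = "MUT")

scale <- function(reads, sid)
  scaleToUnitMean(computeCoverage(reads, gm, 200, sampleId = sid,
                                  mark = "H3K36me2"))
tc <- scale(ctrl$reads, "CTRL")
tm <- scale(mut$reads,  "MUT")
trackMean(tc); trackMean(tm)
#> [1] 1
#> [1] 1                                  # depth scaling hides the depletion

cal <- CalibrationTable(data.frame(
  sample_id = c("CTRL", "MUT"), mark = "H3K36me2",
  global_level = c(1, length(mut$reads) / length(ctrl$reads))))
trackMean(applyGlobalCalibration(tm, cal))
#> [1] 0.3055543                          # calibration restores it (planted 0.3)

sim <- simulateExpression(gm, spec)
e   <- computeRPKM(sim$expr)
reg <- callRegulated(e, "WT_D0", "WT_D2")
partitionSensitivity(reg, e, "MUT_D0", "MUT_D2")
#> GenePartition 'sensitivity':
#>   sensitive    10 gene(s)
#>   resistant    10 gene(s)
#>   params: mutantFrom=MUT_D0, mutantTo=MUT_D2, threshold=2, pseudocount=0.5, rule=fold
summarizeFractions(reg, 100)
#>        up      down unchanged
#>        20         0        80
```

The two unit-mean tracks are indistinguishable globally (both mean 1);
after calibration the mutant's genome-wide mean equals its measured
global level, recovering the planted 0.3 depletion. The classifier
recovers the planted 20 induced / 10 sensitive genes.

`makeDemo(seed = 1)` builds a complete on-disk workspace (BED/bedGraph/
TSV/YAML), runs both pipeline arms, writes manifests with every factor
applied plus md5 checksums, and draws summary figures.

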