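---
title: "Globally calibrated ChIP-seq quantification and twofold expression classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Globally calibrated ChIP-seq quantification and twofold expression classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipcalib)
```

## The problem

Standard ChIP-seq normalization makes every sample's track comparable by
forcing them onto a common scale — and in doing so erases genuine global
differences. If a histone mark such as H3K36me2 is uniformly depleted in
one condition (for example by a dominant-negative histone mutant or by
knockdown of the responsible methyltransferase), read-depth scaling will
make the depleted sample look identical to the control: relative peak
shapes survive, but the genome-wide loss disappears. `chipcalib`
implements a calibration chain that keeps global changes quantitative by
anchoring each sample's track to an independently measured global
modification level (in practice, a Western-blot quantification), and a
companion expression module for the fold-change gene classifications that
such experiments use downstream.

## The normalization chain

For each ChIP sample the chain is:

1. **Binned coverage** (`computeCoverage`). The value of a bin is the
   total base overlap between reads and the bin divided by the bin size;
   at bin size 1 this is per-nucleotide read coverage. Bin size defaults
   to 200 bp — typical practice for broad histone marks — and is a
   parameter because statistics at nucleotide versus binned resolution
   are equivalent here (`rebinTrack` of a 1 bp track reproduces direct
   binning exactly, and a test asserts it).
2. **Unit-mean scaling** (`scaleToUnitMean`). Multiply by
   \(B / \sum_b x_b\) (with \(B\) the number of genome bins) so the
   genome-wide mean intensity is exactly 1. This removes sequencing
   depth; it also removes real global differences, which step 4 restores.
3. **Poisson input subtraction** (`subtractInput`). The input control's
   intensity in each bin, rescaled to the ChIP sample's read depth,
   gives a Poisson background rate \(\lambda_b\). The subtracted
   background is the upper \(1 - p\) quantile of
   \(\mathrm{Poisson}(\lambda_b)\) — the smallest integer \(k\) with
   CDF \(\ge 1 - p\) — converted back to intensity units, and the result
   is floored at 0. With the default \(p = 0.001\), signal survives only
   where background alone would essentially never reach it. This is a
   deliberately conservative quantile rule; a cheaper mean-subtraction
   would preserve between-sample ratios but lets background noise
   through.
4. **Global calibration** (`applyGlobalCalibration`). Multiply the track
   by the sample's global modification level relative to the reference
   sample — the quantity a quantitative Western blot measures. The
   reference (level 1) is unchanged; a sample with a genuine 70% global
   loss ends with genome-wide mean 0.3 rather than 1.

Summaries on the calibrated tracks are per-gene body means
(`geneBodySignal`, overlap-weighted at gene edges), strand-flipped TSS
metagene profiles (`tssProfile`), and the pointwise ratio of two marks'
curves (`ratioProfile`), e.g. H3K36me2/H3K27me3 around the TSS.

### Numerical choices

* **Order of operations** is fixed as scale → subtract → calibrate. The
  steps do not commute (subtraction is non-linear), so the order is part
  of the method definition.
* **Why the calibration property is stated before subtraction.** After
  unit-mean scaling, the calibrated mutant/control total-signal ratio
  equals the measured global level — that is the entire point of the
  calibration step, and the recovery test asserts it on simulated pairs
  with planted depletion factors 0.3, 0.5 and 1.0. The quantile
  subtraction, being non-linear in rate (\(E[(X-u(\lambda))^+]\) does
  not scale proportionally with \(\lambda\)), does not preserve
  total-signal ratios between samples of different depth; it is a
  per-bin background gate, and its own correctness check is exact
  equality against an independent term-by-term Poisson CDF enumeration.
* **TSS window** defaults to ±2,500 bp in 50 bp sub-windows; offsets are
  sub-window centres, symmetric about 0. Minus-strand rows are flipped so
  positive offsets are downstream in the transcription sense. Genes whose
  window crosses a chromosome boundary are dropped (and counted) rather
  than zero-padded, avoiding edge artefacts in group means.
* **Ratio guard.** Ratio curves use `me2 / (me3 + eps)` with
  `eps = 0.01` (1% of a unit-mean genome average) disclosed in the
  result, keeping the curve finite over regions where the denominator
  mark is absent.
* **Degenerate inputs.** An all-zero ChIP track cannot be unit-mean
  scaled (error); an all-zero input track is treated as zero background
  everywhere, with a warning.

## Expression classification

`computeRPKM` computes reads per kilobase of exonic length per million
mapped reads. Classification then works on RPKM with a pseudocount
\(c\) (default 0.5 RPKM) so zero-baseline genes are callable:

* `callRegulated`: up if \((\mathrm{to}+c)/(\mathrm{from}+c) \ge T\),
  down if \(\le 1/T\), unchanged otherwise; \(T = 2\) by default
  (twofold calls). The boundary is included (`>=`) for reproducibility;
  on continuous RPKM the choice is immaterial.
* `partitionSensitivity`: of the control-up genes, *sensitive* genes
  fail to be induced in the mutant, *resistant* genes still are. Two
  readings of "fails to be induced" exist and both are implemented:
  the default `rule = "fold"` requires the mutant's own fold change to
  stay below the same \(T\); `rule = "level"` requires the mutant's
  final level to stay below the control's final level divided by
  \(T\). The fold reading is the default because it re-uses the exact
  rule that defined induction in the control.
* `overlapSets`: exact three-way set algebra between two partitions'
  sets (e.g. mutant-sensitive vs knockdown-dependent genes).
* `rankSelectivity` / `heatmapMatrix`: per-gene
  \(\log_2((A+c)/(B+c))\), top-N most positive and most negative genes
  flagged per direction (N = 1000 by default, as in depot-selectivity
  analyses), ordering made deterministic by breaking ties on gene id;
  the heatmap matrix evaluates any list of contrasts in ranking order.
* `summarizeFractions`: set sizes as percentages of a stated gene
  total, one decimal.

The pseudocount deserves one caveat: adding \(c\) can soften a call to
*unchanged* for genes whose ratio sits within a factor \((1 + c/v)\) of
the threshold (where \(v\) is the smaller RPKM), but it can never flip
up to down or vice versa. The property test asserts exactly that, plus
call identity for genes with both values \(\ge 10c\) and a ratio at
least a factor 1.1 away from the threshold.

## What the synthetic generator emulates

`syntheticSpec`/`makeGenome`/`simulateChipReads`/`simulateInputReads`/
`simulateExpression` build a toy version of the full experimental
design: two conditions (control, mutant) × two marks of ChIP with a
shared input, and a four-sample expression table (WT/mutant × day 0/day
2) with planted induced and mutant-sensitive genes.

Reference conditions (defaults, chosen once): 2 chromosomes × 1 Mb in
200 bp bins (10<sup>4</sup> bins), Poisson background of 5 reads per
bin, single-end 50 bp reads, a 4-fold enrichment domain over the bodies
of 10% of genes, a global mutant depletion factor of 0.3, and 100 genes
of which 20% are 4-fold induced with half of those sensitive.
Expression noise is multiplicative log-normal (sd 0.1 on the natural-log
scale); sd 0 is the noiseless mode in which classification recovers the
planted truth exactly. These sizes keep every end-to-end check in
seconds on one CPU while leaving sampling error small relative to the
planted effects.

One integer seed drives everything through labelled substreams (one per
sample and purpose), so adding a sample never changes another sample's
draws and any run is byte-reproducible. Ground truth (the planted
factor, enriched gene sets, induced/sensitive labels) is returned with
the data and written as a sidecar TSV so recovery tests never re-derive
it.

What the generator does **not** model: fragment-size distributions, GC
and mappability bias, duplicate reads, paired ends, overdispersed
(non-Poisson) counts, replicate structure, or correlated noise between
samples. Passing recovery tests therefore demonstrate the pipeline's
arithmetic and invariants, not robustness to the failure modes of real
libraries.

## Pipeline orchestration

`readRunConfig` validates a YAML run configuration (unknown keys are
errors, so a typo in a threshold name cannot silently revert to a
default), `runChipPipeline` and `runExpressionPipeline` execute the two
arms against files on disk, and `makeDemo` generates a synthetic
workspace and runs both end to end. Every numeric factor applied to the
data — scaling factor, subtraction depth and tail probability,
calibration level — is recorded in a YAML manifest together with md5
checksums of all data outputs; a rerun with the same seed is
hash-identical. Figures (PDF) are excluded from the checksum manifest
because the PDF device embeds a creation timestamp.

```{r demo, eval = FALSE}
demo <- makeDemo(seed = 1)
demo$expression$summary
```

## Known limitations

* The Poisson subtraction rule is this package's concrete choice of a
  "Poisson model" background gate; other published variants exist, and
  the rule (with `pUpper`) is therefore exposed as a parameter and
  logged in the manifest.
* Calibration quality is bounded by the accuracy of the supplied global
  levels; the package treats them as exact.
* No dispersion-aware differential testing: twofold classification is a
  thresholding rule, not a significance statement.
* Peak/domain calling is out of scope; gene-body and TSS summaries are
  annotation-driven.
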