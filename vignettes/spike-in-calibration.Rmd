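---
title: "Absolute quantitation of small RNAs with spike-in calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute quantitation of small RNAs with spike-in calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mindspike)
```

## The measurement problem

Small RNA sequencing counts reads, not molecules. The usual normalisation
— reads per million mapped reads (RPM) — is purely relative: it assumes
the total miRNA content per sample is comparable, which breaks down when
comparing biofluids or extraction protocols with different RNA
compositions. Worse, the two ligation steps of library preparation are
strongly sequence-dependent, so different miRNAs are captured with
efficiencies spanning orders of magnitude.

The remedy implemented here is a panel of exogenous spike-in
oligonucleotides added to each sample, before library preparation, at
known attomolar amounts spanning the endogenous concentration range. Each
spike-in has a fixed 13-nt core (its identity for read classification)
flanked by four randomized nucleotides on both ends, making it a pool of
$4^8 = 65{,}536$ sequences whose randomized termini average out
ligation-sequence effects. Cores are screened against mammalian genomes so
that no endogenous read can be mistaken for a spike-in.

## The calibration model

For spike-in $s$ with known amount $C_s$ (amol) and observed read count
$RC_s$, the model is linear without intercept:

$$ RC_s = \beta\, C_s + \varepsilon_s, \qquad
   \hat\beta = \frac{\sum_s C_s\, RC_s}{\sum_s C_s^2}. $$

The through-origin form encodes the physical constraint that zero
molecules yield zero reads; $\beta$ (reads per attomole) is the sample's
capture efficiency and absorbs depth, library efficiency and loading in a
single per-sample constant. Any feature's absolute amount is then
$RC/\hat\beta$, and volumes convert it onward:
molecules $= \text{amol} \times 10^{-18} N_A$, per µL RNA divides by the
RNA input volume, per µL biofluid multiplies by elution volume over
biofluid volume.

Two deliberate choices:

* **Fit scale.** `fit_calibration()` fits unweighted least squares on the
  *linear* scale, which the closed form above solves exactly. On the
  linear scale the highest oligo dominates the fit; this is intentional —
  it matches the plainly stated model — but a log-scale variant
  (`log_scale = TRUE`) is available, which weights the decades equally.
* **Goodness of fit.** The headline correlation `r_log` is the Pearson
  correlation of $\log_{10} RC$ vs $\log_{10} C$ over oligos with nonzero
  counts, because calibration quality is judged across decades;
  `r_linear` is also reported.

A fit is refused when fewer than two oligos are detected: an all-zero (or
single-point) spike-in profile indicates a failed spike-in addition, and
refusing the fit is itself the QC signal.

## What the synthetic generator emulates

`simulate_library()` draws per-feature read counts with expected share
proportional to $\text{amount} \times \text{bias}$:

* **Endogenous amounts** are log-normal, default $\log_{10}$ mean $-0.5$
  and sd $1.0$ amol. This places the bulk of features inside the panel's
  0.005–50 amol ladder with tails beyond it on both sides, the situation
  the ladder was designed for in plasma. An equimolar mode (all amounts
  equal, default 1 amol) emulates a synthetic equimolar reference pool of
  ~1006 miRNAs, the standard instrument for exposing ligation bias.
* **Ligation bias** is a per-miRNA multiplicative factor, log-normal
  centred at 1 with default $\log_{10}$ sd 0.5. With sd 0.5, about 95% of
  fold changes fall within the 0.1–10 window — a moderately biased
  protocol. Spike-ins carry bias 1: their randomized flanks are the design
  feature that justifies exactly this assumption.
* **Counts** are multinomial at a fixed total depth (default $10^6$), so
  depth is exact and subsampling checks close exactly; a Poisson mode
  (independent counts at $\beta \cdot \text{amount} \cdot \text{bias}$,
  default $\beta = 1000$ reads/amol, which puts the lowest oligo at an
  expected count of 5) and a noiseless mode (rounded means) exist for
  calibration tests. In multinomial mode the true slope is the implied
  $\beta = \text{depth} / \sum_f \text{amount}_f \cdot \text{bias}_f$,
  reported in the returned truth object.
* **Reads** are the mature sequence (endogenous) or
  flank + core + flank with per-read uniform random flanks (spike-ins),
  with a 3′ adapter appended and padding to a 75 nt machine read; quality
  strings are constant. Defaults: the common Illumina small-RNA 3′
  adapter and a 75 nt single-end read, the configuration of a typical
  benchtop sequencer used for miRNA work.

What the generator does *not* emulate — and hence what green tests do not
demonstrate about real data: sequencing errors and indels, quality decay,
UMI chemistry, adapter dimers, non-miRNA RNA classes, genome-wide
multi-mapping, and operator/batch effects. Metrics that depend on those
(e.g. the fraction of miRNAs with CV < 50% across operators) will be
optimistic on simulation relative to bench data.

## Read processing choices

* **Quality trimming** removes the 3′ tail by the standard partial-sum
  rule at Q20, mirroring common trimmer behaviour, before adapter search.
* **Adapter removal** takes the leftmost match: either the full adapter
  anywhere in the read with ≤ 10% mismatches, or a ≥ 3 nt prefix of the
  adapter anchored at the read's 3′ end with ≤ 10% mismatches; everything
  from the match start is removed. Reads without a match pass through.
* **Length filter**: inserts shorter than 17 nt are discarded (below this
  length miRNA assignment is unreliable), longer than 30 nt are discarded
  as non-miRNA.
* **Classification** gives spike-ins precedence: exact containment of a
  panel core assigns the oligo — the 13-mer core is the oligo's only
  fixed sequence, and cores were selected for genome non-overlap, so
  precedence cannot steal genuine miRNA reads. Mature matching is
  5′-anchored and gap-free with ≤ 1 mismatch over the overlap and a ± 2 nt
  3′-length tolerance, the dominant isomiR mode; best hits are ranked by
  (mismatches, |length difference|) and remaining ties resolve to the
  lexicographically smallest name, flagged as ambiguous rather than
  silently assigned. This internal matcher replaces a genome-then-catalogue
  aligner cascade; at the scale of a spike-in panel plus a mature
  catalogue it captures the quantitative behaviour while staying fully
  deterministic and dependency-free.

## Panel design choices

Candidate cores are random 13-mers constrained to GC fraction 0.40–0.60
and homopolymer runs ≤ 3 — composition bounds that keep candidates
miRNA-like, synthesizable, and free of slippage-prone runs; both
constraints are configurable. Screening transcribes U→T and counts all
windows within the mismatch allowance on both strands (presence on either
strand compromises exogeneity); overlapping windows all count, the
simplest well-defined rule. Selection is greedy: lowest hit count first,
ties broken by the larger minimum Hamming distance to already-selected
cores (mutually dissimilar cores minimise classification cross-talk),
then lexicographically — fully deterministic and invariant to input
order.

## Validation statistics and their conventions

The boundary conventions are explicit because they change reported
numbers:

* *Detected* means count ≥ 1 (equivalently RPM > 0); no RPM floor.
* The ligation-bias window 0.1–10× of the median is inclusive; the
  percentage is computed over detected features.
* *Inconsistency* is the percentage of features detected in exactly one
  replicate among those detected in at least one.
* CV% uses the sample standard deviation, computed by default on absolute
  (amol) abundances restricted to features detected in all replicates;
  the repeatability fraction counts CV *strictly* below the threshold, so
  a feature at exactly 50% does not pass.
* The analytical measurement range is evaluated on the RPM scale against
  each sample's own lowest/highest spike-in RPM, bounds inclusive. An
  undetected low spike-in makes the range undefined for that sample and
  is raised as an error rather than imputed.
* Dilution-series accuracy: expected value $p A + (1-p) B$ per feature,
  recovery $100 \cdot \text{observed}/\text{expected}$, per-feature
  Pearson $r$ over the dilution points with Fisher $z = \operatorname{atanh} r$
  (capped at $|r| = 1 - 10^{-12}$); features with an expected value of 0
  are excluded and listed. Per-feature $z$ values are summarised by the
  arithmetic mean.
* Subsampling is multivariate-hypergeometric on the count vector —
  distributionally identical to drawing a read subset without
  replacement, and orders of magnitude faster; a nested mode draws one
  read permutation and takes prefixes, making detection monotone in depth
  within a replicate.

## Numerical and reproducibility notes

All stochastic entry points take explicit seeds and restore the caller's
RNG state; identical configurations give byte-identical FASTQ and tables.
The pipeline fans a single run seed out to per-stage child seeds via one
`sample.int()` draw, recorded in the QC summary, so stages are
independently reproducible. Problem sizes used in the shipped tests and
acceptance script — libraries of $10^4$ to $10^6$ reads, 8–1006 features,
up to 20 replicates — were chosen as the smallest sizes at which the
statistical checks (slope recovery within 5%, bias-recovery correlation
≥ 0.95) are comfortably identifiable.

## Known limitations

The calibration slope converts *captured* reads to amounts; per-miRNA
ligation bias therefore propagates into absolute estimates (a strongly
under-ligated miRNA is under-quantified even with perfect calibration).
This is a property of the assay, visible in the simulator when
`bias_log10_sd > 0`, and the reason the bias statistics exist. The
measurement range narrows when the lowest spike-in drops out at shallow
depth. Mature matching ignores 5′ isomiRs and templated/untemplated
distinctions at the 3′ end. Differential expression, between-sample
normalisation schemes and novel miRNA discovery are out of scope.
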