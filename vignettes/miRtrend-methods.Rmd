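---
title: "miRtrend: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{miRtrend: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRtrend)
```

miRtrend analyses pooled small RNA sequencing of three ordered tissue
states — normal, tumor-adjacent, tumor — and calls miRNAs whose expression
changes monotonically across them. This vignette documents the models
behind each stage, the parameters that matter, the numerical choices, and
what the synthetic-data validation does and does not demonstrate.

## Quantification: the isomiR rule

Mature miRNAs are excised from hairpin precursors with heterogeneous ends,
so reads from one miRNA form a family of *isomiRs* around the canonical
sequence. A read is accepted as an isomiR of a mature miRNA when it equals
the precursor's mature region with each end shifted by at most 4 nt
(extension into the precursor positive, truncation negative) and at most
one substitution. Both ends may vary simultaneously; real isomiR profiles
show concurrent 5' and 3' variants, with 3' heterogeneity dominating.
Indels are not isomiR events — only substitutions count toward the
mismatch budget.

Operational decisions:

* **Tie-breaking.** Among admissible windows of one precursor:
  fewest mismatches, then smallest `|offset5| + |offset3|`, then smallest
  `|offset5|`. Across precursors a read is assigned once (single-count
  policy) to the match with fewest mismatches, ties broken
  lexicographically by mature id; multi-matching sequences are logged in
  the `multimap` table rather than fractionally split.
* **Strandedness.** Reads are assumed sense-strand and adapter-trimmed
  (directional small RNA libraries); no reverse-complement search.
* **Read-length domain.** Reads outside 15–35 nt are reported as
  unassigned, not errors; nothing is dropped silently.
* **Coordinates.** All user-facing coordinates are 1-based inclusive, the
  R/IRanges idiom, so GFF3 mature annotations pass through unchanged.

For speed, every offset window of every precursor is indexed once;
mismatch-free reads resolve by dictionary lookup and only mutated reads
fall back to a per-precursor scan.

## Differential expression

With one pooled library per tissue there are no replicates, so expression
differences are assessed per miRNA from a single pair of counts under
Poisson sampling.

**Normalization.** Counts per million (`count * 1e6 / N`, `N` the
library's total copy number), so every library scales to 1,000,000.

**Reliability filter.** A miRNA is removed only when it has ≤ `min_count`
(default 10) copies in *both* compared libraries at the same time — a
strictly-more-than-10 count in either library keeps it. A stricter
per-library variant (`filter_mode = "both"`) is available.

**Exact test.** Conditional on `x`, the partner count follows

$$P(Y = y \mid x) = \frac{(N_B/N_A)^y \,(x+y)!}{x!\,y!\,(1 + N_B/N_A)^{x+y+1}},$$

the negative-binomial law `NegBin(x + 1, N_A/(N_A+N_B))`. The two-sided
p-value doubles the smaller of the two *opposing* one-sided tails,
$P(Y \ge y \mid x)$ and the role-swapped $P(X \ge x \mid y)$, capped at 1.
By the negative-binomial/binomial tail identity this equals the exact
conditional binomial test on $y \sim \mathrm{Bin}(x+y,\, N_B/(N_A+N_B))$,
which makes the p-value symmetric under swapping the libraries — doubling
the two tails of the *same* x-conditioned law is not symmetric (it gives
0.0625 for (0, 5) but 0.03125 for (5, 0)), an asymmetry we consider a
defect for a two-sample comparison. Tails are evaluated through
`pnbinom()` in log-stable form; the test suite checks agreement with a
direct log-gamma tail summation to 1e-10 for all counts ≤ 50.

**Multiplicity and gating.** Benjamini–Hochberg q-values are computed per
pairwise comparison (not pooled across the three comparisons) over the
filter-surviving miRNAs; a call requires `q < 0.01` and a ≥ 2-fold CPM
change in either direction. A pseudocount of 1 CPM on both sides of the
fold ratio prevents division by zero for counts that are zero on one side;
the reliability filter makes it numerically negligible for retained
miRNAs.

## Gradient calling

"Gradually changed" is operationalized as: both normal-referenced
comparisons called (FDR < 0.01, ≥ 2-fold) with the same direction, *and*
strictly monotone CPM across normal → adjacent → tumor. Ties break
monotonicity (class `none`): a gradient implies change at every step. The
tumor-vs-adjacent comparison is deliberately not required to pass the
fold gate — intermediate adjacent expression may sit less than 2-fold from
either neighbor; `strict = TRUE` adds that requirement. The two DE sets
against normal are also partitioned into tumor-only / adjacent-only /
shared (`venn_partition()`), the bookkeeping from which gradient
candidates are usually drawn.

## qPCR validation

Per sample, `dCt = AvgCt_target − AvgCt_U6` over (typically) triplicate
wells; per contrast, `ddCt = mean dCt(case) − mean dCt(control)` and fold
change `2^−ddCt`. Group comparisons use a two-sided t-test on per-sample
dCt values: Welch by default (`var_equal = TRUE` for pooled Student,
`paired = TRUE` for patient-matched designs — summaries over group means ±
SD are reported either way). On degenerate zero-variance data (noise-free
simulations) the t statistic's limit is used: p = 1 for equal means,
p = 0 otherwise.

## Hairpin plausibility

Candidate precursors are screened by folding with base-pair maximization:
Watson–Crick plus G·U wobble pairs, hairpin loops of at least `min_loop = 3`
unpaired bases, no pseudoknots, and **no isolated pairs** — every helix
must contain at least two stacked pairs. Unconstrained pair maximization
plants thermodynamically negligible single pairs inside loops and flanks,
splitting the terminal loop of a true hairpin; the no-lonely-pair
constraint removes that artifact. Note that G·U wobble breaks the
reverse-complement symmetry of the pair count (a G·U pair maps to an
unpairable C·A); `wobble = FALSE` restores it.

A fold passes `stemloop_check()` when it has exactly one terminal loop,
the mature region does not overlap it, and at least 60% of mature bases
are paired. The single-loop and 60% thresholds are operational choices
(config-exposed) for "hairpin-shaped, mature far from loops and bulges".
Base-pair maximization is a deliberate simplification: free-energy folding
would need external parameter tables and is out of scope, so pass/fail
verdicts are plausibility screens, not thermodynamic predictions.

## Over-representation analysis

`hypergeom_ora()` is a one-sided hypergeometric (Fisher) test of a target
gene list against each set of a GMT collection, BH-corrected across sets.
The background universe must be supplied explicitly — enrichment p-values
are meaningless without a stated universe, so none is guessed. Target
prediction itself is out of scope; `intersect_target_lists()` reproduces
the usual intersect-several-predictors step for users who bring their own
lists.

## The synthetic-data generator

The generator is the package's test bed and defines the simulated study
conditions:

* **Precursors** (60–90 nt): 4 nt A/C flanks, a mature-bearing arm
  (mature 20–23 nt + 4–6 nt stem pad), an 8–12 nt A/C terminal loop, and
  the opposite arm as the reverse complement with 0–2 planted point
  changes. A/C loops and flanks cannot pair with each other, keeping the
  designed stem the dominant fold; flanks and pads leave ≥ 4 nt of
  template so every ±4 isomiR window exists.
* **Reads**: a precursor is drawn with probability proportional to the
  design's length weight at its mature length (each length's weight split
  across the precursors carrying it), so the canonical length spectrum
  follows `read_length_weights` — peaking at 22 nt by default, the
  hallmark of mature miRNA libraries. End offsets are drawn per end from
  `isomir_offset_probs` (default 60% canonical per end), and one random
  substitution is planted at `mismatch_rate` (default 0.01). Offset pairs
  leaving the 15–35 nt matching domain are resampled. The generating
  truth travels in the FASTQ header comments; qualities are constant
  (`I`) and never used.
* **Counts**: independent Poisson draws per miRNA and library — the same
  sampling model the exact test assumes, a deliberate match so that
  calibration failures indicate implementation errors, not model
  mismatch. Null miRNAs sit at `baseline_mean` (default 100, a
  mid-abundance miRNA); gradient miRNAs multiply or divide by
  `gradient_step` (≥ 2, default 2) at each tissue step. Library sizes
  default equal; unequal depths scale the means and are exercised in the
  normalization tests.
* **qPCR**: true Ct decreases one cycle per doubling of expected
  expression (`Ct = 30 − log2(mean)`), U6 constant at Ct 18, Gaussian
  per-replicate noise (default 0.25 cycles, a typical technical SD).

What the generator does *not* emulate — and hence what passing tests do
not show about real data: biological overdispersion between replicates
(the Poisson choice matches the pooled, replicate-free design; it
understates variance for replicated designs), adapter contamination and
quality artifacts, non-uniform sequence-dependent error, cross-mapping
between paralogous miRNA families, amplification-efficiency differences
in qPCR, and RNA degradation. Constant null means are a simplification;
real expression spans orders of magnitude.

## Numerical and testing choices

* All randomness flows from explicit integer seeds through an isolated
  RNG scope; identical seeds give byte-identical FASTQ, count and report
  output. The JSON run report carries no timestamps for the same reason.
* Exact-test tails via `pnbinom()`; oracle agreement required to 1e-10.
  BH via `stats::p.adjust`; hypergeometric tails via `stats::phyper`.
* Validation scales were chosen to give tight checks in seconds: 2,000
  miRNAs × 50 replicates for null calibration and FDR control, 10,000
  reads for length-spectrum and round-trip checks, 1,000 random
  read/precursor pairs against the exhaustive window oracle, and
  exhaustive structure enumeration up to 14 nt for the folder.
* The null-FDP estimator prescribed for calibration is coarse: under a
  global null a replicate's FDP is 0 or 1 (a single false call makes it
  1), so a 50-replicate mean moves in steps of 0.02 around its true value
  (~0.004 here, well under the 0.01 target).

## Known limitations

Single-count multi-mapping (rather than fractional assignment) slightly
deflates counts of paralogous families; the exact test is anti-conservative
if real biological replicates are collapsed into pooled libraries;
gradient calling requires strict monotonicity and will miss plateaued
trajectories; the hairpin screen is qualitative; and the ORA module tests
over-representation only (no depletion, no gene-length or expression bias
correction).
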