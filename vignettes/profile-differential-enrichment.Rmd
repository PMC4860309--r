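---
title: "Position-wise differential enrichment of ChIP-seq profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position-wise differential enrichment of ChIP-seq profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(profdiff)
```

# Overview

`profdiff` compares histone-modification enrichment profiles around a class
of genomic anchors (typically transcription start sites) between two
experimental groups, position by position. The pipeline has three stages:
chromatin Input counts become position-specific normalization factors; a
negative-binomial GLM with a minimum fold-change threshold is tested at each
position; and local false discovery rates convert the resulting p-values into
per-position significance. This vignette explains the model, every tunable
parameter, the synthetic-data generator behind the test suite, and the design
decisions taken where reasonable alternatives existed.

# Data model

The unit of analysis is a pair of positions × samples count matrices (ChIP
and Input) sharing one relative-position axis from `-upstream` to
`+downstream` with the anchor at 0, plus a sample annotation (condition,
window extents). Profiles can be supplied directly, summarized from
feature-level tables, or counted from alignments.

**Fragment-midpoint counting.** For paired-end MNase data each sequenced
fragment is reduced to the middle base of the interval its read pair spans;
midpoints of even-length fragments take the lower central base (integer
division), so counting is deterministic. Each proper pair is counted once,
from the alignment record with positive template length. Single-end reads are
extended from their 5' end by a caller-supplied fragment length in read
orientation before the midpoint is taken. Default filters skip unmapped,
secondary, supplementary and duplicate-flagged records and mapping quality
below 10; all are arguments. SAM/GFF coordinates are treated as 1-based
inclusive throughout, and a fragment whose midpoint falls in the windows of
two overlapping anchors is counted once per window (documented behaviour;
anchored windows rarely overlap at TSS spacing).

**Summarization.** A feature-level table is collapsed by (i) dropping
features whose total count is below `min_total` (default 1 — only all-zero
features), then (ii) taking a trimmed mean across retained features at each
position (default `trim = 0.15` per tail) and multiplying by the number of
retained features. The trim fraction is a compromise: large enough to blunt
the heavy right tail of per-feature counts (a handful of very highly covered
genes would otherwise dominate every position), small enough to keep at least
70% of the data. With `trim = 0` and `min_total = 0` the summary equals the
plain column sum, which the tests exploit as an exact oracle. Features are
filtered on their table-wide totals, not per position: per-position filtering
would change the feature set along the axis and with it the meaning of the
resulting counts. Non-integer metafeature values (e.g. supplied matrices) are
rounded half-up, since the downstream count model needs integers.

# Normalization

Each Input profile is rescaled so its total equals the total of its paired
ChIP profile; the scaled Input, plus a pseudocount (default 1, needed for
strict positivity at sparse positions), is the matrix of position-specific
normalization factors. By default each position's row of factors is divided
by its geometric mean, so the factors carry only relative within-position
information and leave the overall count scale — and with it the dispersion
estimation — undistorted; this is the standard contract for normalization
factors in NB count models. Centering is exposed as an argument because it
does not affect the fitted contrast (column-constant factor rescalings cancel
in the condition coefficient), only the interpretability of base means and
dispersions.

A shared Input (one whole-cell extract for all samples) is expressed by
repeating one Input column; the generator supports this design too.

**A caveat that matters: composition bias.** Matching Input totals to ChIP
totals assumes the two libraries differ only in depth. When one condition
gains substantial signal somewhere in the profile, its ChIP total grows, its
scaled Input grows with it, and every *null* position of that condition is
normalized down: the null log2 fold changes shift by about
`-log2(1 + f·(FC-1))`, where `f` is the fraction of the profile that is
differential and `FC` the fold change there. With a 200-bp window at log2FC
1.5 inside a 2501-bp profile this is about −0.2; inside a 1000-bp profile it
is about −0.45, enough to swamp a per-position standard error of ~0.3. This
is intrinsic to total-count matching (the same phenomenon as composition bias
in RNA-seq library-size normalization) and is the practical reason the
testing stage carries a minimum fold-change threshold: θ absorbs small
systematic shifts so that only changes beyond them can score.

# Testing

At each position the ChIP counts follow an NB GLM with natural-log link,
`mu_ij = s_ij * exp(b0 + b1 * treatment_j)`, fitted by iteratively
reweighted least squares (convergence `max |Δβ| < 1e-8`, at most 100
iterations); `b1` is reported in log2. Standard errors come from the observed
information. If one group is all zeros the fit is stabilized with a ridge of
1e-6 on the coefficients so the estimate stays finite; all-zero positions are
reported with p = 1.

**Dispersion.** Per position, a method-of-moments value on normalized counts
initializes a profile-likelihood estimate: the GLM is fitted, the NB
likelihood is maximized in α at the fitted means, and the cycle is run twice.
Estimates are clamped to [1e-8, 10]. A parametric trend `α(μ) = a1/μ + a0`
is fitted across positions by iteratively reweighted gamma-family regression
on the reciprocal mean, excluding gross outliers (ratio to trend outside
[1e-4, 15]) between iterations, with coefficients clamped at zero; under 50
usable positions the trend falls back to the flat median with a warning.
Each raw estimate is then shrunk toward its trend value by maximizing the
likelihood plus a log-normal prior (`prior_sd = 0.5` by default); raw values
more than `2 * prior_sd` above the trend in log space are kept unshrunken, so
genuinely noisy positions are not forced optimistic. The prior width trades
stability at few replicates against responsiveness to real dispersion
structure; 0.5 (a factor ~1.6 one-sigma band) works well at the 3–5
replicates typical of these designs, and it is an argument.

Independent filtering and count-outlier replacement, familiar from
genome-scale count pipelines, are deliberately absent: a profile has few
positions and all of them are of interest.

**Threshold Wald test.** The null hypothesis is `|log2FC| <= theta`. Inside
the threshold the statistic is 0 and p = 1; outside, `(|lfc| - theta)/se` is
referred to the standard normal, two-sided. With `theta = 0` this is the
ordinary Wald test. The default `theta = 0.05` log2 units rejects only
changes beyond ~3.5%, a floor against vanishingly small but significant
shifts; analyses with expected composition bias or weak-effect tolerance
should raise it (the test suite's recovery runs use values from 0.05 to 0.5).

# Local false discovery rates

Under the two-groups model the p-value density is non-increasing, so its
Grenander estimator — the left derivative of the least concave majorant of
the empirical CDF on [0, 1], computed by weighted pool-adjacent-violators on
the ECDF increments — is the natural nonparametric fit. The local fdr at p is
`min(1, eta0 / f(p))` with `f` the fitted density. Because `f` is
non-increasing, the local fdr is monotone in p and thresholding it always
calls a prefix of the p-sorted positions.

The null proportion eta0 is estimated as the average fitted density over the
upper tail `[lambda, 1]` (default `lambda = 0.5`), i.e. the monotone-CDF
version of the standard tail-count estimator. The rightmost *step height* of
the Grenander fit was considered and rejected: the final hull segment is the
minimum chord slope into the last observation, which simulation shows to be
highly variable and strongly downward-biased on pure-null data (mean ≈ 0.67
at n = 1000), whereas the tail-average version is tightly concentrated just
below 1 and errs conservative. P-values exactly equal to 1 — produced in
bulk by the threshold test's inside-null branch — are retained in the
estimation sample; removing them would bias eta0 downward.

The default significance cutoff is local fdr < 0.2 (strict inequality, so a
cutoff of 0 calls nothing); it is always a user parameter, and more lenient
cutoffs (e.g. 0.3) are appropriate for subtle profiles.

# Plotting

`plot_profiles()` shows smoothed per-condition enrichment —
`ChIP / (scaled Input + pseudocount)` per position, summarized over
replicates by a Huber M-estimate (tuning `k = 1.345`, the 95%-efficiency
choice; median returned when the MAD is zero) and smoothed by a centered
running mean (default window 51 bp, shrinking symmetrically at the edges so
constants are preserved and interior mass is conserved). A linear smoother
was chosen over kernel or loess alternatives precisely so that the
mass-conservation property remains testable. `plot_significance()` shows the
unsmoothed profiles with positions below the fdr cutoff highlighted. The
plot *data* (a tidy per-position table) is the tested artifact and is always
returned and exportable; PNG/SVG files are best-effort rendering.

# The synthetic-data generator

`simulate_dataset()` draws Input counts as NB(mean = baseline × input_bias,
dispersion α) and ChIP counts from the same mean times `2^effect_lfc` inside
a contiguous effect window for the treatment condition; variance is
`mu + alpha * mu^2`, matching the test's likelihood exactly, and everything
is reproducible from a mandatory seed. `simulate_feature_tables()`
additionally spreads each position's expectation over features with
heavy-tailed (lognormal) weights so the import and summarization paths are
exercised on realistic feature-count skew.

What the generator emulates: replicated NB counts, a position-dependent
baseline (optionally peak-shaped), a shared Input bias profile, a known
differential window, shared-Input designs. What it does not: read-level
artifacts (mappability, duplicated reads), correlated noise along the
position axis, Input bias *realizations* shared between ChIP and Input of
the same sample (Input noise is independent sampling noise here, which the
dispersion estimate absorbs — visible as fitted dispersions above the
nominal α), or multi-factor designs. Passing tests therefore demonstrate
calibration and recovery under the count model's own assumptions, not
robustness to alignment-level artifacts.

Test and acceptance runs use deliberately moderate sizes — null calibration
on 2000 positions with 3 vs 3 replicates at μ = 50, α = 0.1; recovery of a
200-position window at log2FC 1.5 inside a 2501-position profile (the
classic −1000..+1500 TSS window) with 5 vs 5 replicates at μ = 100,
α = 0.05, θ = 0.05, over ten seeds. The 2501-position geometry keeps the
composition bias of total-count matching (≈ −0.2 log2 here) within what θ
plus the per-position standard error tolerate, which is exactly the regime
the method is designed for; making the differential window a quarter of the
profile instead would push the bias past the standard error and the
empirical FDR visibly up — a limitation users should keep in mind when their
expected changes span much of the profile.

# Numerical choices and degenerate inputs

* Dispersions clamped to [1e-8, 10]; α-optimizations run on the log scale
  with `optimize()` (tolerance 1e-6).
* IRLS tolerance 1e-8 on coefficients; non-converged positions retried with
  a 1e-6 ridge, and reported with p = 1 if still unstable.
* Even-length fragment midpoints round down; mirror symmetry of counting is
  exact for odd-length fragments.
* Zero Input totals are an error (nothing to scale); zero entries are
  handled by the pseudocount, and a zero pseudocount with zeros present is
  an explicit positivity error.
* Empty alignment files yield an all-zero table with a warning, not an
  error; fewer than 10 p-values refuse a Grenander fit.
* Ties in p-values (including the atom at 1) are pooled into single ECDF
  increments before PAVA.

# Limitations

Two-condition designs only; no likelihood-ratio or quasi-likelihood tests;
no peak calling, nucleosome positioning, or genome-wide window scanning; no
GC or mappability correction; the Input-as-second-sample ("ratio of
ratios") formulation is not implemented. Numerical parity with other NB
testing engines is not claimed — the dispersion estimator and eta0 choice
are this package's own documented variants — though per-position fold
changes and Wald p-values agree closely with an independent engine when
dispersions are held equal (see the test suite).
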