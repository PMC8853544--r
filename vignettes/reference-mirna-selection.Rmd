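---
title: "Selecting reference miRNAs from nCounter counts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting reference miRNAs from nCounter counts: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirstab)
```

## The analysis model

`mirstab` ranks endogenous miRNAs by the stability of their normalized
expression in NanoString nCounter count data, to propose candidate
reference genes for downstream qPCR. The pipeline assumes a
probes-by-samples matrix of non-negative integer molecule counts with
annotated probe classes (endogenous miRNA, housekeeping mRNA, positive
and negative spike-in controls) and annotated sample groups, analysed
per group and pooled over all groups.

**Filtering.** Within a group of $n$ samples, probe $p$ is excluded
when $\#\{s : c_{ps} < m\} > f\,n$ with defaults $m = 50$ molecules and
$f = 0.5$. Both inequalities are strict: a count of exactly 50 is not
low, and exactly $n/2$ low samples does not exclude; for odd $n$,
exclusion needs at least $\lceil (n+1)/2 \rceil$ low samples. Only
endogenous miRNAs are subject to (or survive) the rule. Filtering is
per analysis group, so the pooled group re-applies the rule over the
union of samples rather than intersecting per-group survivor sets.

**Normalization.** Normalized values are differences of binary
logarithms, $x_{ps} = \log_2 c_{ps} - \log_2 \sum_{q \in N} c_{qs}$,
where $N$ is the normalizer set of the chosen strategy. The normalizer
total is a plain sum of molecule counts — digital counts are additive —
not the geometric mean used by some vendor software. The four
strategies resolve $N$ as: the 5 housekeeping mRNAs; all retained
miRNAs ("total miRNA content", reading "all miRNAs found" as the
detection-filter survivors); the `top_k = 75` retained miRNAs with the
largest total count over the group's samples (ties broken by probe id);
or the 6 positive controls. The top-75 set is resolved *after*
filtering, consistent with the analysis order (filter first, then
normalize). Since every strategy normalizes within sample, multiplying
a sample's counts by a constant leaves its normalized values unchanged.

**Stability ranking.** For each retained miRNA the package computes
four scale measures of its normalized series: SD (with the $n-1$
denominator), range, interquartile range, and the mean absolute
deviation from the median (MADM). Under each of the two ranking
strategies (housekeeping and total-miRNA — the two the combined rank is
defined on), probes are ranked 1 = least variable per measure, ties
averaged, and the $4 \times 2 = 8$ ranks are summed with equal weights
into the combined rank sum. All measures being translation invariant,
the ranking is unaffected by global shifts, and since ranks depend only
on order it is invariant to monotone transformations of any measure.

**Composite normalizer tests.** The candidate reference normalizer is
the mean of the log2 values of the 5 most stable miRNAs (equivalently
the log2 of their geometric mean); the package asks whether it really
disperses less than the same construction over the next 5, on the same
samples (paired):

* *paired Grambsch test* (variances): with $D_i = x_i - y_i$,
  $S_i = x_i + y_i$, and $u_i = (D_i - \bar D)(S_i - \bar S)$, the
  statistic is $T = \sqrt{n}\,\bar u / s_u$, standard-normal under
  $\mathrm{var}(x) = \mathrm{var}(y)$ (the Pitman–Morgan identity
  $\mathrm{var}(x)-\mathrm{var}(y) = \mathrm{cov}(D, S)$ made robust by
  self-normalizing the products rather than assuming normality).
* *paired Bonett–Seier test* (MADMs): with $a_i = |x_i -
  \mathrm{med}(x)|$, $b_i = |y_i - \mathrm{med}(y)|$, the statistic is
  $z = \ln(\bar a/\bar b)/SE$ with $SE^2 = [\mathrm{var}(a)/\bar a^2 +
  \mathrm{var}(b)/\bar b^2 - 2\,\mathrm{cov}(a,b)/(\bar a \bar b)]/n$.

Both are two-sided (the hypotheses are differences, not directions).

**Strategy comparison.** Whether two normalization strategies select
the same stable miRNAs is tested on the union $L$ of their five
least-*variance* probes (variance, not the rank sum, is the selection
measure here). Each strategy ranks $L$'s members $1..|L|$ by ascending
variance; the discordance statistic is $T = \sum_i |r_A(i) - r_B(i)|$
and the p-value is the fraction of the $|L|!$ equally likely
permutations of one rank vector with $T$ at least the observed value
("as or more extreme" includes equality, so perfect concordance gives
$p = 1$). The six pairwise p-values are Benjamini–Hochberg adjusted
(via `stats::p.adjust`).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_molecules` | 50 | low-count threshold (molecules) |
| `max_low_fraction` | 0.5 | strict fraction of low samples tolerated |
| `top_k` | 75 | size of the "most represented" normalizer set |
| `count_floor` | 1 | numerator floor before `log2` (counts) |
| `k` (comparison) | 5 | "best miRNAs" per strategy in the union list |
| `top`, `nxt` | 5, 5 | composite sizes (ranking positions 1–5, 6–10) |

The floor only guards the numerator — a zero count has no binary
logarithm — and is rarely hit because retained probes passed the
50-molecule filter; floored cells are counted in the output
(`n_floored`). Normalizer totals are used as-is and must be positive.

## Numerical and procedural choices

* **Quantiles.** Q1/Q3 interpolate linearly between order statistics at
  position $h = (n-1)p + 1$. One documented convention, applied
  everywhere.
* **Ties.** Measure ranks use average ranks (keeps rank sums
  comparable); the final ordering breaks rank-sum ties by the SD under
  total-miRNA normalization, then probe id; within-union-list ranks
  must form a permutation, so exact variance ties there are resolved
  deterministically by probe id.
* **Exhaustive permutation p.** The null distribution of $T$ depends
  only on $|L|$ (relabel the fixed ranking to the identity), and the
  exact counts of permutations per $T$ value are computed by a dynamic
  program over subsets of assigned ranks — identical to enumerating all
  $|L|! \le 10!$ permutations, at a tiny fraction of the work. The
  literal enumeration is kept in the test suite as the oracle for
  $|L| \le 6$. Monte-Carlo mode (for longer lists) uses the add-one
  estimator $(\#\{T^\ast \ge T\} + 1)/(n_{mc} + 1)$ with a recorded
  seed.
* **Degenerate inputs.** Paired tests require $n \ge 3$ and error on
  degenerate input rather than returning unstable asymptotics:
  identical series (Grambsch, $u \equiv 0$) and zero MADM
  (Bonett–Seier) are errors. Two boundary cases of the Bonett–Seier
  statistic are well-defined limits rather than errors: a pure shift
  ($y = x + c$) gives identical deviation vectors and returns $z = 0$,
  $p = 1$; exactly collinear deviations ($y = cx$, where the paired
  covariance term cancels the variance terms identically and
  $SE = 0$) mean the MADM ratio is measured without sampling error and
  return $z = \pm\infty$, $p = 0$.
* **Merged probes.** Codeset probes that measure the summed content of
  two miRNAs (names joined by "+") are atomic throughout; the name is
  preserved verbatim.

## The simulator: what it emulates, and what it does not

`simulate_counts()` draws counts from a negative binomial
($\mathrm{var} = \mu + \phi\mu^2$), the standard overdispersed model
for digital counting data, with mean
$f_s\,\mu_p\,g_{ps}$: lognormal per-sample size factors $f_s$
(`size_factor_sd` = 0.25 log2 units, mimicking per-lane binding-density
variation), per-probe base abundances spanning $2^{6.6}$–$2^{14.3}$
counts for expressed probes, and a mean-1 lognormal biological term
$g_{ps}$ whose CV is 0.05 for planted stable miRNAs, 0.4 for planted
group-differential miRNAs (which additionally carry a $2^{1.0}$ shift
in one randomly assigned group), and 0.2 for the remaining expressed
bulk. Housekeeping mRNAs track $f_s$ at fixed levels; positive controls
follow the 128/32/8/2/0.5/0.125 fM ladder at 200 counts/fM; negative
controls and non-expressed miRNAs sit at a background mean of 10
counts. Dispersion defaults to $\phi = 0.02$; $\phi = 0$ selects a
noise-free limit with deterministic rounded means, used to test that
normalized stable probes are then constant up to rounding. The default
design is three cohorts of 32 + 12 + 12 samples with 800 miRNA probes,
200 expressed, 10 planted stable and 40 planted variable; a single
seeded RNG stream (sample-level draws, then probe-level, then counts
probe by probe) makes every matrix bit-reproducible.

These choices are stand-ins: no distributional information about real
cartridge noise is encoded, batch/codeset effects, background
cross-hybridization structure, and probe-specific capture efficiencies
are absent, and group effects are single-group shifts. Passing the
planted-truth tests therefore shows the pipeline's machinery is
correct and well-calibrated on a faithful count-noise model — not that
any particular real tissue panel will yield stable normalizers.

## Test and calibration problem sizes

The package's statistical guarantees are exercised at sizes chosen to
make Monte-Carlo error negligible while keeping the default test run
fast: filter equivalence on 1000 random matrices; type-I error of both
paired tests from 20,000 null replicates at $n = 30$, $\rho = 0.5$
(empirical size must lie in [0.035, 0.065] at $\alpha = 0.05$);
planted-gap power (probe CVs 0.02 vs 0.4) over 200 simulated pooled
studies of $56$ samples, requiring both tests to reject at
$\alpha = 0.001$ in at least 95%; stable-set recovery over 100 default
simulations, requiring the top 5 to contain at least 4 planted stable
miRNAs in at least 90%; Monte-Carlo vs exhaustive permutation
agreement within three binomial standard errors at $n_{mc} = 10^5$.

The pooled 56-sample design is used for the power characterization
because that is the design in which the composite comparison is run:
the Grambsch statistic self-normalizes the products $u_i$, so its
magnitude cannot exceed $\approx\sqrt{n/2}$ no matter how large the
true variance ratio is — at $n = 36$ even a noise-free infinite gap
rejects at $\alpha = 0.001$ only ~96.5% of the time, while at $n = 56$
the ceiling is ~99.9% and the realistic planted-gap rate ~96–98%.

## Known limitations

* The top-5/next-5 composites are selected *on the same data* the
  paired tests are then run on; under a global null (no planted gap)
  this selection inflates the apparent dispersion difference, so the
  tests' nominal size applies to pre-specified composites, not to
  post-selection ones. The package follows the published procedure and
  makes no selection-adjusted inference.
* Rank sums can be non-integer when measure ties occur (average
  ranks); reported tables keep them as reals.
* The pooled group assumes a common probe set; when cohorts were run
  on different codeset versions the matrix should be restricted to the
  probe intersection before analysis.
* Exhaustive permutation inference is limited to union lists of at
  most 10 probes (always the case for $k = 5$); Monte-Carlo mode
  covers anything larger.
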