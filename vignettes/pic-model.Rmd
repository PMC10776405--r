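---
title: "Paired-Insertion Counting and the ssPoisson model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired-Insertion Counting and the ssPoisson model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picount)
```

## Why counting strategy matters

A single-nucleus ATAC-seq fragment is bounded by two Tn5 insertion events;
the unit of observation is the *pair* of insertions.  The two counting
strategies in common use disagree on how to score a fragment against a
peak or bin:

* **insertion-based counting** scores each insertion locus inside the region
  (0, 1 or 2 per fragment), which depletes odd counts except at region
  boundaries and double-counts insertion loci shared by two adjacent
  fragments;
* **fragment-based counting** scores any interval overlap, so a long
  fragment whose two insertions both lie *outside* a peak still counts — a
  false positive for the peak in between.

**Paired-Insertion Counting (PIC)** scores one unit per fragment with at
least one insertion locus inside the region: fragments fully inside count
once (the second locus is masked), boundary-spanning fragments count once,
and long-spanning fragments with both insertions outside count zero.  On
fragments that lie fully inside their regions, insertion-based counting is
exactly twice PIC and fragment-based counting equals PIC, which is the
consistency property the package's tests enforce.

`build_count_matrix()` implements all three modes over a fragment file,
region set (BED) and barcode list, with an optional flanking window around
each insertion locus (0 by default; 37 or 75 bp match common peak-caller
smoothing so quantification can stay consistent with peak calling).

## The generative model

Within a region of width $L_p$ we assume a uniform per-base insertion
probability, hence a Poisson($\lambda$) number of insertions per allele.
Two mechanisms thin the insertions down to sequenced fragments:

1. **Primer configuration.**  Each insertion carries two adapter sides;
   a gap between adjacent insertions becomes an amplifiable fragment only
   when the facing adapter ends are compatible, which happens with
   probability 1/2 independently per gap.  Given $n$ insertions the number
   of amplifiable pairs $W$ is Binomial($n-1$, 1/2); mixing over Poisson
   $n$ gives the *signed Poisson* distribution with
   $E[W] = (\lambda - 1 + e^{-\lambda})/2$ and
   $\mathrm{Var}(W) = (2\lambda + 2e^{-\lambda} - 2\lambda e^{-\lambda}
   - e^{-2\lambda} - 1)/4$ — a mean below Poisson and variance above the
   mean.
2. **Size selection.**  Amplification, library construction and alignment
   keep fragments whose insertion distance lies in $[s_1, s_2]$.  Defaults
   are $s_1 = 25$ bp (the post-overhang-correction lower limit used by
   standard pipelines) and $s_2 = 600$ bp (ATAC libraries show no
   nucleosome-ladder spike beyond 600 bp, indicating a library-prep size
   cutoff).  $s_1$ affects the distribution much more than $s_2$; both
   should be set from the library protocol (e.g. raised $s_2$ for
   long-read open-chromatin assays).

The resulting count distribution is the *size-filtered signed Poisson*
(ssPoisson).  Diploid cells contribute the sum of two independent alleles
with a shared rate (`pmf_diploid()`), and sequencing observes each fragment
independently with a per-cell capture rate $q$ (`pmf_observed()`), so
$E[W_o] = q\,E[W_s']$.

### Numerical form of the size filter

The size filter admits several defensible formulas and we chose the one the
generative mechanism itself follows.  A constant per-pair retention based on
exponential insertion spacing,
$r = (e^{-s_1\lambda/L_p} - e^{-s_2\lambda/L_p})/(1 - e^{-\lambda})$,
exceeds 1 for small $\lambda$ at the default constants (its limit is
$(s_2-s_1)/L_p = 1.15$) and must be clamped, at which point it erases size
selection entirely over most of the working rate range; measured against
the fragment-level simulator it leaves a total-variation gap of 0.015-0.026
at $\lambda \in [1, 2.5]$.  The package therefore stratifies by the latent
insertion count $n$: for $n$ uniformly placed insertions the probability
that $j$ specific adjacent gaps are all at least $s$ bases long is exactly
$\binom{L_p - j(s-1)}{n}\big/\binom{L_p}{n}$, inclusion–exclusion yields
the distribution of the number of gaps passing the size bound, and each
passing gap is amplifiable with probability 1/2.  This *spacing* variant —
the package default, used by all estimators and tests — agrees with the
mechanism to total variation below 0.005 across the working range.  The
constant-retention form is retained as `variant = "exponential"`
(normalized) and `variant = "printed"` (literal non-complementary series,
which does not normalize); both are exposed through `pmf_sspoisson()` for
comparison.  When $s_2 < L_p - 1$ the upper bound is handled by the
independent-thinning approximation; the default constants ($s_2 > L_p$)
take the exact path.

Other numerical choices: infinite series are truncated at the
$1 - 10^{-12}$ Poisson quantile of the insertion count (normalization then
holds to well under $10^{-8}$); the inclusion–exclusion path is used for
$n - 1 \le 30$ gaps and the independent-thinning approximation beyond,
where the alternating sum would lose precision; likelihood values are
floored at $10^{-300}$ before logging.

## Capture rates and open probabilities

Zeros mix biological closure with technical dropout.  The zero-adjusted
model treats the binarized matrix as
$y_{jc} = Z_{jc} T_c$ with $Z_{jc} \sim \mathrm{Bernoulli}(p_j)$ (region
open probability) and $T_c \sim \mathrm{Bernoulli}(q_c)$ (cell capture
rate), and fits both by alternating moment updates
$q_c = \sum_j y_{jc} / \sum_j p_j$ and $p_j = \sum_c y_{jc} / \sum_c q_c$.
Only the products $p_j q_c$ are identified — $(p/\alpha, \alpha q)$ fits
equally well — so the free scale is fixed at $\max_c q_c = 1$, which is
precisely where the iteration with a $q \le 1$ clamp converges, reached
directly by rescaling each iteration (the clamped iteration itself
approaches that point only geometrically at rate $1 - \max_c S_c / \sum S$,
too slowly to be practical).  At the fixed point the row and column sum
identities $\sum_j p_j q_c = \sum_j y_{jc}$ and
$\sum_c p_j q_c = \sum_c y_{jc}$ hold exactly; both are asserted in the
tests.  Initialization is the per-region nonzero fraction (the fitted
products do not depend on it), tolerance $10^{-6}$ on the largest parameter
change, at most 100 iterations.  The moment updates are not guaranteed
coordinate-*ascent* steps of the Bernoulli likelihood, so the objective
trace is monitored rather than proved monotone; an all-zero matrix is
reported non-identifiable and an all-ones matrix returns the boundary
solution $p = q = 1$.

## Rate estimation and the DAR test

With per-cell capture rates in hand, the missing-corrected mean count
$\bar{\bar w} = (\sum_i w_i/q_i)/c$ inverts the expected-count curve to
give the moment estimator (`moment_estimate()`); the inversion is
restricted to $\lambda \le L_p/s_1$, the range on which the expected count
is increasing before the size filter turns it over, and caps with a warning
beyond.  The MLE (`mle_estimate()`) maximizes
$\sum_i \log P_\lambda(W_o = w_i)$ by Brent search on $\log\lambda \in
[\log 10^{-4}, \log 50]$, bracketed around the moment estimate and expanded
when the optimum lands on an edge; tolerance $10^{-6}$.  A Poisson baseline
(`poisson_baseline()`) fits the plain Poisson mean with the twofold
fragment-to-insertion correction; in simulations it underestimates the true
rate increasingly with $\lambda$ while the ssPoisson estimators track it,
which is the comparison the acceptance tests re-run.  Whether the moment or
the ML estimator backs a published comparison is generally not knowable
from a figure alone, so both are provided; the DAR test uses the MLE.

Differential accessibility between two cell groups is a generalized
likelihood ratio test (`dar_test_matrix()`): the pooled model M0 fits one
rate to both groups, M1 one rate per group, and
$\chi^2 = -2(\mathrm{LL}_{M_0} - \mathrm{LL}_{M_1})$ is referred to a
chi-square distribution with 1 degree of freedom.  Small optimizer noise
can leave $\chi^2$ marginally negative; it is clamped to zero.  Regions
with no counts in either group carry no information and are reported
degenerate with $p = 1$, excluded from the Benjamini–Hochberg adjustment
(applied over tested regions only); DARs are regions with adjusted
$p \le 0.05$.  Capture rates default to per-group estimation on each
group's binarized matrix — groups may legitimately differ in open
probabilities, and with hundreds of cells the per-group scale anchors
($\max q = 1$) agree closely — with pooled estimation and a
sequencing-depth-proportional fallback available.

## The simulator and what the tests show

`simulate_region_fragments()` / `simulate_cell_counts()` implement the
mechanism directly: per-bp Bernoulli insertions with probability
$\lambda/L_p$ (indistinguishable from Poisson at the working
$\lambda/L_p \le 0.005$), two independent adapter sides per insertion,
gap viability 1/2, size selection on the insertion distance, diploid
summation and per-fragment capture.  Batched cell counts group alleles by
insertion count so position sampling and gap logic vectorize; conditional
on the count, insertion loci are a uniform draw without replacement, which
is what the grouped sampler draws.

`simulate_dar_scenario()` reproduces the three study designs used for test
evaluation: (1) 500 + 500 cells, 5,000 null and 6,000 DAR regions with
balanced fold-change signs, (2) 500 + 200 cells, and (3) 500 + 500 cells
with 2,000 up- and 4,000 down-regulated DAR regions.  Rates cycle over a
grid spanning 0.05–2.5 and DAR regions multiply the group-2 rate by
$e^{\pm \mathrm{logFC}}$ with magnitudes 0.1, 0.15, 0.2, 0.25.  The
capture-rate distribution is not pinned down by the published designs; we
draw $q \sim U(0.2, 0.8)$ per cell, which yields sparsity in the range
typical of droplet snATAC matrices, and expose group-specific ranges for
unbalanced-capture experiments.  Regions are independent; the simulator
does not emulate chromatin-structure correlation along the genome,
overlapping peaks, doublets or barcode collisions, so passing tests
validate the counting rules and the statistical machinery, not robustness
to those real-data complications.

The evaluation harness computes type I error and power against simulated
truth (`type1_power()`), calibrates per-method critical values by label
permutation pooling per-region p-values and taking the fifth rank
percentile (`permutation_critical_value()`; 20 permutations by default —
the protocol's permutation count is a free parameter), and, where truth is
unknown, scores each method against the union DAR set of all methods at
their calibrated thresholds (`pseudotrue_union_power()`).  A
depth-normalized two-sided Wilcoxon rank-sum test (`wilcoxon_dar_test()`)
is built in as the rank-based comparator so that power comparisons run
offline.

### Problem sizes used by the checks

The packaged acceptance checks run the null type-I experiment at 2,000
null regions per round for 5 rounds (500 + 500 cells), distribution–
simulator agreement at $10^5$ replicates, estimator recovery at 500 cells
over 5 rounds, capture recovery at 2,000 regions by 500 cells, null
p-value uniformity at 2,000 regions at the top of the rate grid
($\lambda = 2.5$, where the chi-square reference is appropriate; at very
low rates the p-value distribution is discrete and conservative by
construction), and the power comparison on a scaled setting-(1) layout of
800 null plus 1,600 DAR regions per seed, with power compared in the
bottom third of the rate grid ($\lambda \le 0.25$) at matched calibrated
thresholds.  These sizes were chosen so that each check has enough
resolution to be meaningful at desk scale.

## Preprocessing rules

Quality control follows three rules: fragments with interval length below
10 bp are removed as likely misalignments (`qc_filter_fragments()`);
regions where any cell reaches a fragment-based count of 7 or an
insertion-based count of 14 are dropped as likely repetitive/blacklist
regions (`qc_filter_peaks()`); and cells with regions whose per-base
coverage exceeds 3 are flagged as potential doublets
(`flag_doublets()`) — the number of such regions that triggers the flag is
not standardized, so it defaults to "any region" and is exposed as a
parameter.  Duplicate fragment records are collapsed by default with an
option to retain them (useful for bead-based assays); counts can optionally
be capped at 4 to mirror pipelines that ceiling their matrices.
Coordinates follow the fragment-file dialect: 0-based half-open intervals
whose insertion loci are `start` and `end - 1`; inputs are assumed already
Tn5-shifted by the producing pipeline.

## Known limitations

The model assumes a uniform insertion rate within a region, equal rates on
the two alleles, and a capture rate that acts identically on every region
of a cell; sequence composition, region-specific capture and covariate
effects (e.g. depth as a regression covariate) are out of scope.  The
likelihood treats cells as independent given the group label.  At very low
rates most regions are all-zero and the DAR test is conservative there by
construction.  Allele-specific estimation with unequal rates is not
supported.
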