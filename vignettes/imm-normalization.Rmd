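---
title: "Iterated median of M-values: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterated median of M-values: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The sampling model

For gene $g$ in library $k$, the observed count $Y_{gk}$ is modelled as
Poisson with mean proportional to the gene's share of the sample's total RNA
output:

$$E[Y_{gk}] = \frac{\mu_{gk}}{S_k} N_k, \qquad S_k = \sum_g \mu_{gk},$$

where $N_k$ is the (known) total read count and $S_k$ the (unknown) total
RNA output. Gene length is absorbed into $\mu_{gk}$ throughout — it cancels
from every between-library comparison of the same gene, so the package
carries no length term. Comparing proportions $Y_{gk}/N_k$ across libraries
is biased whenever $S_k$ differs between samples, which happens exactly when
expression changes are abundant or one-sided (RNA composition bias). The
normalization factor is an estimate of the relative output of the pair.

All inference here is Poisson, i.e. technical replication; biological
overdispersion (negative binomial) is out of scope.

## Factor estimators

With pair totals $T_k, T_r$, per-gene
$M_g = \log_2\frac{Y_{gk}/T_k}{Y_{gr}/T_r}$ and
$A_g = \tfrac12 \log_2\left(\frac{Y_{gk}}{T_k}\cdot\frac{Y_{gr}}{T_r}\right)$.
Genes with a zero in either library have no defined $M$ and are excluded
from factor estimation (they are still tested — exact tests handle zeros).

**Library size** (`libsize_norm`): all factors 1; the adjustment is carried
entirely by $N_k$. **TMM** (`tmm_norm`): after removing, per tail, the 30%
most extreme genes by $M$ and the 5% most extreme by $A$ (rank-based;
genes tied at a boundary are retained, deterministically in input order),
the factor is $2$ to the weighted mean of the surviving $M$ with weights
$w_g^{-1}$, $w_g = \frac{N_k - Y_{gk}}{N_k Y_{gk}} + \frac{N_r - Y_{gr}}{N_r Y_{gr}}$
(inverse approximate binomial variance of $M$). **IMM** (`imm_norm`): the
median of $M$ over an iteratively refined invariant set, described next.

The trim fractions (0.30 / 0.05), the iteration threshold ($Q < 0.005$) and
the final call threshold ($Q < 10^{-4}$) are all exposed as arguments and as
command-line flags with these defaults.

## The IMM iteration

1. Over the currently retained genes (initially: all genes positive in both
   libraries), recompute totals as the *retained-gene column sums* and take
   $f = 2^{\mathrm{median}(M)}$. For $K > 2$ libraries, one factor per
   non-reference library against the reference, assembled into a vector.
2. Test every retained gene at *effective totals*: the target's total
   multiplied by $\sqrt f$ and the reference's divided by $\sqrt f$. The
   wording "multiplying/dividing the square root" does not by itself assign
   sides; this package multiplies the target because that is the direction
   under which a gene whose $M$ equals $\log_2 f$ — i.e. a gene moving
   exactly with the estimated global fold change — sits exactly on the null
   of the exact test. (The opposite assignment doubles, rather than
   removes, the bias and makes the iteration exclude the invariant genes
   themselves.) For factor vectors the equivalent per-library form
   $T_k f_k$ is used; only ratios of effective totals enter any test.
3. Benjamini–Hochberg-adjust the p-values and exclude genes with
   $Q < 0.005$ from subsequent factor estimation. Exclusion is cumulative:
   a gene once excluded does not re-enter, which makes the excluded set
   monotone and the iteration a fixed-point search on a shrinking set.
4. Stop when an iteration adds no exclusions (the factor is then a fixed
   point of step 1; the package additionally checks
   $|\Delta \log_2 f| < 10^{-6}$, since exact floating-point equality is
   not a reliable stopping rule) or at a hard cap of 20 iterations, in
   which case the fit is flagged non-converged with a warning rather than
   an error. In practice convergence takes 2–3 iterations.
5. Finally, *all* genes — including those excluded along the way — are
   re-tested (`de_test`) with the final factor and retained-gene totals,
   and DE is called at the final threshold.

A consequence worth understanding: the converged factor is computed
*relative to invariant-set totals* and is therefore typically close to 1
even under strong composition bias — the bias has been moved into the
totals, which no longer count the excluded genes. The induced correction on
the library-size scale is $\log_2 f + \log_2(T_k/T_r) - \log_2(N_k/N_r)$;
that quantity, not $f$ alone, is what the test suite compares against the
true null-gene M-center on asymmetric simulations.

## Tests

* `two_library_exact_p`: conditional on $n = y_k + y_r$, $y_k$ is binomial
  with $p_0 = T^{\mathrm{eff}}_k / (T^{\mathrm{eff}}_k + T^{\mathrm{eff}}_r)$;
  the two-sided p-value sums all outcome probabilities not exceeding the
  observed one. Outcomes tied with the observed probability in exact
  arithmetic can differ by an ulp in floating point, so ties are recognised
  at a relative tolerance of $10^{-7}$ — adjacent binomial probability
  ratios are rationals that are either exactly 1 or far from 1 at desk
  scales, so the tolerance changes nothing else. Enumeration is exact by
  default; a guarded flag (`max_exact_n`) switches to a
  continuity-corrected normal approximation for very large totals.
* `poisson_exact_group_p`: condition sums are Poisson, so the same binomial
  argument applies to the group sums with summed effective totals; with one
  library per condition it reduces to the pairwise test exactly.
* `poisson_lr_p`: Poisson likelihood ratio with closed-form MLEs (group
  count sum over group effective-total sum), $0 \log 0 = 0$, referred to
  $\chi^2_1$. An all-zero gene carries no information: $p = 1$, never DE.
* `bh_adjust`: the raw rank formula $Q = p \cdot \mathrm{count} /
  \mathrm{rank}$ (average ranks for ties) followed by the step-up
  cumulative minimum and clipping at 1. The step-up is applied by default
  because without it $Q$ is not monotone in $p$ and threshold calls are not
  nested; `stepup = FALSE` exposes the literal raw formula. DE calls use
  strict inequality ($Q <$ threshold) with ties in rank broken by input
  position.

## The simulator

`sim_config` / `simulate_counts` implement the benchmarking frame: baseline
expression is drawn with replacement from an empirical count vector if one
is supplied, otherwise from a log-normal surrogate ($\mathrm{meanlog} = 4$,
$\mathrm{sdlog} = 2$, i.e. a spread of about 2.9 on the log2 scale — a
heavy-tailed shape typical of bulk transcriptomes), normalized to
proportions, modified by truth multipliers, renormalized per condition, and
scaled to the target library size, so the expected library sum is $N_k$ and
asymmetric DE induces a genuine composition bias of known size
($S$ ratios recorded in the truth object; `true_factor` returns the factor
a normalization should recover).

Category assignment: unique-to-group genes first (exact rounded count,
condition-2 mean zero), then DE among the remainder (exact rounded count);
DE direction is Bernoulli(`prop_up`) per gene, with `exact_counts = TRUE`
for a deterministic split. Categories are disjoint by construction, so the
label partition invariant holds. Counts are independent Poisson draws;
replicate libraries share their condition's means. Everything is
bit-reproducible given a seed.

`fd_curve` ranks genes by p-value (stable in input order) and counts
truly-null genes among the top $n$; unique-to-group genes are removed first
by default, matching the convention of scoring only genes common to both
conditions. `run_comparison` crosses normalizations with tests over seeded
replicate simulations and averages curves pointwise.

## Problem sizes and what the tests show

The suite exercises the claims at deliberately moderate sizes chosen to
mirror realistic per-gene sequencing depth: the benchmark scenarios use
3,000–5,000 genes at 1.2–2 million reads per library (about 400 reads per
gene on average — the depth regime of the deep lane-level libraries this
kind of normalization is designed for), 20 seeds per scenario; factor
recovery without DE uses 2,000 genes, and calibration checks 2,000 null
genes. Per-gene depth matters scientifically, not just for runtime: the
invariant-set search separates the null cluster from the DE clusters on the
$M$ axis, and when median coverage drops to a few reads per gene the
Poisson noise in $M$ (sd $\approx \sqrt{2/\bar Y}/\ln 2$) smears the
clusters together, degrading any M-value-based normalization — IMM's
iteration included — well before the tests themselves lose power.

Passing these simulations shows the estimators do what they claim under the
Poisson technical-replicate model with a log-normal expression profile. It
does not certify behavior on biologically replicated (overdispersed) data,
on UMI single-cell matrices dominated by zeros, or on datasets whose
composition bias violates the majority-non-DE assumption (more than half
the common genes DE); the iteration's own robustness limit is an
invariant-set majority, consistent with the rule of thumb that the DE
fraction stay at or below one half.

## Known limitations

* Poisson only; no dispersion estimation, no moderated statistics.
* Normalization is pairwise against a single reference (default: first
  library, overridable); no between-pair shrinkage for many-library
  designs.
* The exact test's enumeration cost grows with the gene's total count;
  the normal-approximation flag exists for extreme totals but is off by
  default.
* Excluded genes never re-enter the invariant set; an alternative
  re-admission rule would be a different estimator and is deliberately not
  implemented.
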