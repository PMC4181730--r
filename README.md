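# immnorm

Normalization of RNA-seq count libraries by the **iterated median of
M-values (IMM)**, with the trimmed mean of M-values (TMM) and library-size
baselines, exact and likelihood-ratio tests for two-condition comparisons,
and a Poisson simulation framework for benchmarking normalizations by their
false-discovery behavior.

## The problem

RNA-seq summarizes each library as per-gene read counts `Y_gk`. The expected
count is proportional to the gene's true expression relative to the
library's *total RNA output* `S_k`:

    E[Y_gk] = (mu_gk / S_k) * N_k,   S_k = sum_g mu_gk

`N_k` (total reads) is known but `S_k` is not, and when the two samples
differ in RNA composition — many genes up-regulated in one condition, or
genes expressed in only one tissue — dividing by `N_k` alone biases every
between-library comparison. A scaling factor estimating the relative output
`S_k / S_r` must be inferred from the counts themselves.

For a pair of libraries (k = target, r = reference) define per gene

    M_g = log2( (Y_gk / T_k) / (Y_gr / T_r) )   (log fold change)
    A_g = 1/2 * log2( (Y_gk / T_k) * (Y_gr / T_r) )   (average abundance)

with totals `T`. **TMM** removes genes with a zero in either library, trims
the top and bottom 30% by `M` and 5% by `A`, and averages the surviving `M`
with inverse-variance weights — a symmetric trim that goes wrong when
differential expression is abundant and one-sided.

**IMM** instead looks for an *invariant set* of non-DE genes:

1. Take the median of `M` over all genes positive in both libraries (with
   totals summed over those genes) as the factor; for a library against
   itself this is exactly 1.
2. Test every retained gene with an exact binomial test whose null
   proportion uses *effective totals* — the target total multiplied and the
   reference divided by the square root of the current factor.
3. Adjust p-values (Benjamini–Hochberg, `Q = p * count / rank` with step-up
   enforcement) and exclude genes with `Q < 0.005` from factor estimation.
4. Recompute the median over the reduced set; stop when no new genes are
   excluded and the factor is stable (typically within 5 iterations), then
   test **all** genes with the final factor and call DE at the final
   threshold (default `Q < 1e-4`).

Replicated designs use a group-summed exact Poisson test or a Poisson
likelihood-ratio test (chi-squared, 1 df) in place of the pairwise test.

## Worked example

Simulate a hard case — half the common genes DE at 4-fold, 90% of them up in
condition 1, plus 10% of genes unique to condition 1 — then normalize, test,
and count false discoveries among the top 500 genes:

```r
library(immnorm)
cfg <- sim_config(n_genes = 2000, lib_sizes = 1e6, prop_de = 0.5,
                  prop_up = 0.9, prop_unique = 0.1, fold = 4, seed = 42)
d <- simulate_counts(cfg)
fit <- imm_norm(d$counts, d$truth$design)
summary(fit)
#> IMM normalization fit
#>   reference: A1
#>   test: fisher
#>   converged: TRUE in 2 iterations
#>   genes excluded during iteration: 1132
#>   factors:
#>     A1     B1
#> 1.0000 1.0361
#>   iteration trace:
#>    library B1:
#>  iter   factor n_excluded
#>     1 1.202464       1132
#>     2 1.036096       1132

res <- de_test(d$counts, d$truth$design, fit, q_threshold = 1e-4)
res
#> de_test (imm+fisher): 2000 genes, 840 called DE at Q < 0.0001

fd_curve(res$table$p, d$truth)$false_discoveries[500]
#> [1] 4
```

The final factor is close to 1 *relative to the invariant-set totals*: the
normalization is carried jointly by the factor and the retained-gene totals,
which exclude the genes driving the composition bias. The same data
normalized by TMM or by library size put 96 and 129 truly-null genes,
respectively, among the top 500 — against 4 for IMM.

The command-line front end exposes the same pipeline:

```sh
Rscript inst/scripts/immnorm simulate --genes 2000 --seed 1 --out counts.tsv
Rscript inst/scripts/immnorm test --counts counts.tsv --method imm --out results.tsv
Rscript inst/scripts/immnorm benchmark --seed 1 --out curves.tsv
```

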