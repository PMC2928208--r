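# ebPatterns

Empirical Bayes detection of **patterns of differential expression** in
sequence count data (SAGE, RNA-seq, small RNA — anything that yields a
tuple-by-sample table of counts).

Most differential-expression tools answer a pairwise question. When an
experiment has several sample groups, the interesting questions multiply:
is a tuple (a tag, or an aggregate of tags such as a locus) equivalently
expressed everywhere, different in one condition only, or different in all
of them? `ebPatterns` treats each such pattern as a **model** — a
partition $\{E_1,\dots,E_m\}$ of the samples into sets sharing identical
distribution parameters — and returns, for every tuple and every model, a
posterior probability

$$P(M \mid D_c) = \frac{P(D_c \mid M)\,P(M)}{P(D_c)},\qquad
P(D_c \mid M) \approx \prod_q \frac{1}{|\Theta_q|}\sum_{\theta\in\Theta_q}
\prod_{i\in E_q} \mathrm{NB}\!\left(u_{ic};\; l_i\mu_q,\ \phi_q\right),$$

where counts are negative binomial with mean $l_i\mu_q$ (library size
$l_i$ times expression rate $\mu_q$) and dispersion $\phi_q$. The prior
sample $\Theta_q$ is *empirical*: per-tuple dispersions are estimated by
quasi-likelihood under the replicate structure, per-set means by maximum
likelihood at fixed dispersion, over thousands of randomly sampled tuples
of the same dataset. Model priors $P(M)$ are estimated by iterating the
mean posterior across tuples (or fixed from external knowledge). Because
models are mutually exclusive, posteriors can be summed — e.g. into one
probability of differential expression of any type.

The package also ships seeded simulators for three benchmark designs
(pairwise with random gamma dispersions, ten-library fixed dispersion,
and three-condition multi-group) with exact truth labels, FDR/ROC
benchmarking utilities, and a per-tuple Poisson-vs-negative-binomial
overdispersion likelihood-ratio diagnostic.

## Worked example

```r
library(ebPatterns)

# two conditions x five libraries, 10 000 tuples, 1000 truly DE at b = 8
sim <- simulatePairwiseRandomDispersion(nTuples = 10000, n1 = 5, n2 = 5,
                                        b = 8, seed = 1)
pt  <- runAnalysis(sim, priorSampleSize = 5000, seed = 2)
pt
#> PosteriorTable: 10000 tuples x 2 models (15 iterations)
#> model priors:
#>  {A,B} {A}{B}
#> 0.8364 0.1636

deProb <- combineModels(pt, "{A}{B}")   # P(differential expression)
head(rankTuples(deProb), 3)
#>         tuple score rank
#> 1 tuple_04522     1    1
#> 2 tuple_04844     1    2
#> 3 tuple_08950     1    3

truth <- setNames(SummarizedExperiment::rowData(sim)$pattern != "none",
                  rownames(sim))
fdrCurve(rankTuples(deProb)$tuple, truth, depths = c(100, 200, 1000))
#>   depth fp_count   fdr
#> 1   100        0 0.000
#> 2   200        0 0.000
#> 3  1000      118 0.118
aucROC(rocCurve(deProb, truth[names(deProb)]))
#> [1] 0.9805673
```

The converged prior for the DE model (0.164) overshoots the true DE
fraction (0.10): the mean-posterior iteration is known to feed back
positively. Rankings are unaffected — in a two-model analysis they are
monotone in the likelihood ratio.

`readCounts()` imports a plain TSV (tuple ids in the first column, one
column per sample; library sizes default to column totals or come from an
override file), and `runAnalysis(..., outputDir =)` writes the posterior
table (converged priors as `# prior:` comments, plus an `any_DE` column)
and a reproducibility manifest. With three conditions, `runAnalysis`
considers all five partitions of the condition labels and
`combineModels()` aggregates any subset of interest;
`enumerateModels(..., exclude =)` drops biologically implausible
partitions.

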