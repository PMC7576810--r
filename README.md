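# hynet

Hypernetwork analysis of transcriptome co-expression organisation.

Two perturbations can change similar numbers of genes yet act very
differently: one drives a focussed, coordinated programme, the other
scatters diffuse changes. `hynet` quantifies that difference for any
differentially expressed (DE) gene set. It is aimed at transcriptomics
analysts who already have a replicated, multi-condition count matrix and
want a calibrated answer to *"how organised are this gene set's
relationships with the rest of the transcriptome?"*

## The method

For a DE set *S* (|S| = n) and the N transcripts of the filtered
transcriptome, within one condition's replicate columns (log2(x+1) scale):

1. Manhattan distances `d(i,j) = Σ_s |x_is − x_js|` for i ∈ S, all j
   (self-pairs masked);
2. binarisation at the 30th centile of all distances — only the closest
   30% of relationships are kept — giving a binary incidence matrix **M**
   (n × N);
3. the hypernetwork **H = M Mᵀ**, where `H[i,j]` counts transcripts to
   which genes i and j are *both* close (shared relationships);
4. **connectivity** = mean of H, and per-gene Shannon **entropy** of each
   row's normalised off-diagonal profile (low entropy = concentrated,
   coordinated connections);
5. a randomised null — the same construction on (by default) 1000 random
   gene sets of size n — yields add-one empirical p-values
   `p = (1 + k)/(1 + B)`, and a two-sided Mann–Whitney U test compares
   per-gene entropy between conditions.

Upstream, the package provides the standard selection stages
(median-of-ratios size factors, expression filter, moderated-t pairwise
contrasts with |log2FC| > 0.6 and FDR < 0.05, three-group ANOVA, and the
exclusive/concordant Venn partition whose exclusive sets feed the
hypernetworks), plus a negative-binomial simulator with a tunable
coordinated co-expression module that stands in for unavailable real data.

## Worked example

```r
library(hynet)
sim <- simulate_counts(simulation_config(n_genes = 2000, seed = 42))
sim$matrix
#> expression_matrix: 2000 genes x 9 samples (raw counts)
#> conditions: mut (n=3), vector (n=3), wt (n=3)

report <- run_pipeline(pipeline_config(counts = sim$matrix, n_iter = 200,
                                       truth = sim$truth, seed = 7))
report
#> run_report: 2000 genes in, 1941 after filtering
#>   wt_vs_vector: 41 significant (31 up / 10 down)
#>   mut_vs_vector: 53 significant (38 up / 15 down)
#>   partition: 41 / 53 exclusive, 0 concordant, 0 discordant
#>   wt: n=41, connectivity 204.7, median entropy 4.455 bits, p_conn=0.5274, p_entropy(low)=0.3632
#>   mut: n=53, connectivity 194.0, median entropy 4.732 bits, p_conn=0.9303, p_entropy(low)=0.06965
#>   entropy comparison: p = 0.00367 (medians 4.455 vs 4.732)
```

Reading the output: 1941 of 2000 simulated genes pass the expression
filter; 41 genes respond exclusively to the coordinated perturbation (wt)
and 53 to the diffuse one (mut). The wt hypernetwork's median per-gene
entropy (4.455 bits) is significantly lower than the mut one's
(4.732 bits, Mann–Whitney p = 0.0037): the coordinated set's shared
relationships are more concentrated. Neither set's connectivity exceeds
what random sets of the same size achieve (`p_conn`), and the report also
carries ground-truth recall because the simulation's truth was supplied.
Individual stages are available as plain functions
(`size_factors()`, `de_pairwise()`, `manhattan_distance_matrix()`,
`binarise()`, `build_hypernetwork()`, `null_distribution()`,
`compare_entropy()`), and all stage outputs are written as TSV/JSON when
`out_dir` is set.

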