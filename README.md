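# rewireHMRF

Prioritizes genes for association with a binary phenotype (the motivating
application is drought stress in *Sorghum* root transcriptomes) from
two-condition expression data alone — no GWAS signals, no external
networks. The principle is **guilt by rewiring**: genes whose co-expression
pattern with other genes *changes* between treatment and control are likely
involved in the response, even when their own mean expression barely moves.

## Method

Given an expression matrix X (M genes x n samples) and a binary response Y
(treatment / control), per developmental stage:

1. **Mean-variance (MV) screen.** For each gene the model-free MV index

   T = Σ_θ Σ_j p̂_θ { F̂_θ(x_j) − F̂(x_j) }²

   contrasts the conditional empirical CDF F̂_θ of expression given Y = θ
   with the marginal CDF F̂. A permutation test (K = 5000 shuffles of Y)
   yields P_MV per gene; genes with P_MV ≤ 0.01 become candidates.

2. **Weighted gene differential co-expression network (WGDCN).** Pairwise
   similarity between candidates is the grey correlation coefficient (GCC,
   resolution ratio ρ = 0.5, symmetrized as (r_pq + r_qp)/2), computed
   separately on treatment and control samples — robust at the small
   per-condition sample sizes where Pearson/Spearman are unstable. Genes p,
   q get an edge when their GCCs cross the hard threshold r0 = 0.9 in
   opposite directions, (r_pq^treat − r0)(r_pq^control − r0) ≤ 0, weighted
   by the rewiring strength |r_pq^treat − r_pq^control|.

3. **Hidden Markov random field.** Binary association labels ω ∈ {−1, +1}
   on the WGDCN carry an Ising prior with external field h and couplings
   τ1 = τ2 = 0.01 (τ2 acting only on strong edges with rewiring > δ = 0.95).
   Evidence is ξ_p = Φ⁻¹(1 − P_MV(p)): standard normal under the null (f0),
   a Student-t prior-predictive under association (f1). Labels are
   initialized at P_MV ≤ 0.005, h is the 90th percentile of the association
   potentials, and iterated conditional modes (ICM) maximizes each gene's
   conditional

   logit P(ω_p = +1 | ξ, ω_−p) = ln(f1/f0) − h + τ1 Σ rewire·I(ω_q = +1)
                                  + τ2 Σ_{rewire>δ} rewire·I(ω_q = −1)

   until no label flips. Genes are ranked by the converged posterior; the
   top 20 per stage are reported as crucial.

4. **Multilayer analysis.** Stage-wise subnetworks over the top-ranked
   genes are stacked with interlayer edges joining the same gene across
   stages; per-layer density / degree / path length / clustering and the
   Jaccard overlap matrix between stage gene sets summarize how rewiring
   shifts over development.

A synthetic generator (`syntheticDesign()` / `simulateExpression()`) plants
null, mean-shifted and co-expression-rewired genes with known truth so the
entire pipeline is testable without downloading data.

## Worked example

```r
library(rewireHMRF)

sim <- simulateExpression(syntheticDesign(seed = 1))   # 200 genes, 12+12
res <- runPipeline(list(K = 500L, seed = 1L, topK = 10L), se = sim$se)
st  <- res$stages[["1"]]
st$network
st$fit
head(st$ranking, 5)
```

```
MV screen: 40 of 200 genes retained at alpha = 0.01
WGDCN: 40 genes, 111 rewiring edges (stage 1)
  rewiring-strength range: [0.002977, 0.2045]
HMRFFit: 40 genes, 40 labelled associated; 1 ICM sweep(s), converged
  h = 0.0135
        gene_id   xi label potential posterior rank
1      g0177_de 3.09     1    0.0169     0.977    1
2 g0190_rewired 3.09     1    0.0161     0.977    2
3      g0175_de 3.09     1    0.0161     0.977    3
4 g0195_rewired 3.09     1    0.0136     0.977    4
5 g0196_rewired 3.09     1    0.0135     0.977    5
```

The screen keeps 40 of 200 genes — exactly the planted signal carriers. All
permutation p-values at the floor give identical evidence scores ξ, yet the
network term separates the genes: posteriors differ through each gene's
rewiring neighborhood (potential column). On this run the discrimination
ability R = U/m (unique values / genes) is 0.075 for the lattice-valued MV
p-values against 0.875 for the HMRF posteriors — the resolution gain the
model is built for.

A thin CLI over the same functions ships in
`inst/scripts/rewire-pipeline.R` (subcommands `simulate`, `mv-screen`,
`build-network`, `prioritize`, `multilayer`, `run-all`).

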