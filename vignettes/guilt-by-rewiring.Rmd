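---
title: "Guilt-by-rewiring gene prioritization: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guilt-by-rewiring gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rewireHMRF)
```

# The problem

Two-condition expression experiments (stressed vs. well-watered plants,
sampled over developmental stages) ask which genes drive the response.
Differential expression alone misses regulators whose mean barely moves but
whose *relationships* to other genes reorganize. rewireHMRF ranks genes by
combining per-gene evidence of condition dependence with network evidence
of co-expression rewiring, producing a posterior probability of association
for every candidate gene.

# The model, stage by stage

## Mean-variance screening

For gene i with expression vector X_i and binary response Y, the MV index

$$T_n(i) = \sum_{\theta} \sum_{j=1}^{n} \hat p_\theta
  \{\hat F_\theta(x_{ji}) - \hat F(x_{ji})\}^2$$

is n times the mean-variance measure of dependence: it accumulates squared
gaps between the conditional and marginal empirical CDFs (both using
$\le$), weighted by the class proportions. It is zero iff the empirical
conditional distributions coincide, needs no moments or linearity, and
depends on ranks only (any strictly increasing transform of the data leaves
it unchanged — so the optional log2 transform never changes the screen).
Because per-stage sample sizes are small, significance comes from a
permutation test: K uniform shuffles of Y, with
$P = K^{-1}\sum_k I(T^*_k \ge T_0)$. P is therefore lattice-valued (a
multiple of 1/K, possibly exactly 0). Genes with $P \le 0.01$ (boundary
inclusive) proceed.

Per-gene permutation streams are derived deterministically from the master
seed and the gene index, so a gene's p-value does not depend on how many
genes are screened or in which order — batch and single-gene runs agree
bit-for-bit.

## Grey-correlation rewiring networks

Within one condition, the grey correlation coefficient between reference
gene p and gene q is

$$r_{pq} = \frac1n \sum_{k=1}^{n}
  \frac{\Delta_{\min} + \rho\,\Delta_{\max}}
       {|x_{kp} - x_{kq}| + \rho\,\Delta_{\max}}$$

with $\Delta_{\min}, \Delta_{\max}$ the global extremes of
$|x_{tp} - x_{ts}|$ over *all* comparison genes s and samples t, and
resolution ratio $\rho = 0.5$. Since the reference gene belongs to the
comparison set, $\Delta_{\min} = 0$ identically; the formula is implemented
literally nonetheless, and a pairwise-extremes variant is available as a
non-default option (`pairwiseExtremes`). The comparison set is the stage's
candidate set: the network is only ever built after screening. Because the
extremes are global, each r_pq depends on the whole candidate matrix; the
implementation streams one reference row at a time (O(m·n) extra memory).

GCC is reference-dependent, so the matrix is symmetrized as
$(r_{pq} + r_{qp})/2$. An edge joins p and q when the corrected GCCs cross
the hard threshold $r_0 = 0.9$ in opposite directions between conditions,
$(r^{treat}_{pq} - r_0)(r^{control}_{pq} - r_0) \le 0$, with weight
$\mathrm{rewire}_{pq} = |r^{treat}_{pq} - r^{control}_{pq}|$. Pairs whose
GCCs both sit exactly at $r_0$ satisfy the crossing condition with zero
rewiring strength; they are dropped, because every downstream use of an
edge multiplies by its weight — a zero-weight edge is inert in the Ising
model and only inflates the edge count. Degenerate conditions in which all
candidate genes are identical give $\Delta_{\max} = 0$; the GCC is then
defined as 1 (indistinguishable sequences) with a warning.

## The Ising/HMRF prioritizer

Labels $\omega_p \in \{-1, +1\}$ on the WGDCN follow an Ising prior whose
log-density sums $-h$ per associated gene, $+\tau_1\,\mathrm{rewire}_{pq}$
per edge with both ends associated, and
$-\tau_2\,\mathrm{rewire}_{pq}$ per *strong* edge
($\mathrm{rewire} > \delta = 0.95$) with both ends unassociated. Evidence
enters through $\xi_p = \Phi^{-1}(1 - P_{MV}(p))$: standard normal under
the null (p-values are uniform there), and for associated genes a normal
with unknown mean and variance carrying a conjugate Normal/Inverse-Gamma
prior ($\mu\,|\,\sigma^2 \sim N(\bar\mu, \sigma^2/a)$,
$\sigma^2 \sim \mathrm{InvGamma}(g/2, gd/2)$).

The single-site conditional is then

$$\mathrm{logit}\,P(\omega_p = +1 \mid \xi, \omega_{-p}) =
  \ln\frac{f_1(\xi_p)}{f_0(\xi_p)} - h
  + \tau_1 \sum_{e_{pq}=1} \mathrm{rewire}_{pq}\, I(\omega_q = +1)
  + \tau_2 \sum_{e_{pq}=1,\ \mathrm{rewire}_{pq} > \delta}
      \mathrm{rewire}_{pq}\, I(\omega_q = -1).$$

The test suite verifies this closed form against exhaustive enumeration of
the joint (explicit partition function over all $2^m$ configurations) on
small random graphs — the primary guard on the sign conventions.

Inference is iterated conditional modes: initialize $\omega_p = +1$ iff
$P_{MV}(p) \le 0.005$, compute the association potentials
$\mathrm{Potential}(p) = \tau_1 \sum_{\omega_q=+1} \mathrm{rewire}_{pq} +
\tau_2 \sum_{\omega_q=-1,\,\mathrm{rewire}>\delta} \mathrm{rewire}_{pq}$
at those initial labels, set h to their 0.90 quantile, then sweep the genes
in fixed ascending order setting each label to its conditional mode
(posterior $\ge 0.5 \Rightarrow +1$) until a sweep makes no flip. The
reported posterior is the conditional at the converged configuration, and
genes are ranked by it (ties broken by larger $\xi$, then gene id).

# Parameters

| parameter | default | role |
|---|---|---|
| K | 5000 | permutations per gene; p-value resolution is 1/K |
| alpha | 0.01 | candidate threshold on P_MV (inclusive) |
| rho | 0.5 | GCC resolution ratio; damps the global-max term |
| r0 | 0.9 | hard GCC threshold; tunes network density (see below) |
| delta | 0.95 | rewiring strength above which the tau2 penalty acts |
| tau1, tau2 | 0.01 | Ising couplings (reward / penalty per unit weight) |
| hQuantile | 0.90 | potential quantile defining the external field h |
| initAlpha | 0.005 | P_MV threshold for the initial "+1" labels |
| muBar, a, g, d | 2, 1, 1, 1 | evidence-prior hyperparameters |
| topK | 20 | genes reported per stage |

# Design choices where the formulation was open

**f1 as a prior-predictive marginal.** The associated-evidence model gives
each gene its own $(\mu_p, \sigma_p^2)$ under a Normal/Inverse-Gamma prior,
but a single observation per gene cannot support per-gene estimation.
Integrating the parameters out gives the closed-form marginal — a
Student-t with $g$ degrees of freedom, location $\bar\mu$, squared scale
$d(1 + 1/a)$ — which is what `evidenceDensities()` evaluates. The defaults
($\bar\mu = 2$: associated genes concentrate near small p-values; unit
scale) matter little in practice since the network terms dominate ties;
all four are configurable.

**Parameters held fixed during ICM.** $\tau_1, \tau_2$ stay at their
initial values and h is computed once from the initial labels. Updating h
each sweep is available (`computeH` on the current labels), but a moving
field couples the fixed point to sweep order; the fixed-h variant is
deterministic and converges in a handful of sweeps on all tested inputs.

**Tie at posterior 0.5** resolves to $+1$, consistent with the belief
behind h that marginal genes may still be associated.

**p-value clamping.** $\Phi^{-1}(1 - 0) = \infty$, and permutation
p-values of exactly 0 occur by construction. P is clamped into
$[1/(2K), 1 - 1/(2K)]$ — half a lattice step — before the normal-score
transform, keeping $\xi$ finite without reordering any p-values.

**Quantile convention.** h uses linear interpolation between order
statistics (R's type 7), fixed and tested against a sort-based oracle.

**Monotonicity domain.** Because the Student-t tails are heavier than the
normal's, $\ln(f_1/f_0)$ is non-monotone far in the left tail
($\xi \lesssim -0.6$ at the defaults). Every screened candidate has
$P_{MV} \le 0.01$, i.e. $\xi \ge 2.33$, so over the operational range the
posterior is strictly increasing in the evidence score; tests assert
monotonicity there.

**Numerical stability.** Conditionals are computed on the log scale and
mapped through `plogis`, which is stable for large |logit|.

# The synthetic generator

`simulateExpression()` plants three gene classes: nulls (i.i.d. across
conditions), DE genes (treatment mean shifted by `deShift` SD units), and
one rewired module sharing a latent factor with pairwise correlation
`corrTreat` under treatment and `corrCtrl` under control (single-factor
construction: loading $\sqrt{r}$ gives exact target correlation; negative
targets are rejected as unrealizable by a shared factor). By default the
Gaussian values are exponentiated, giving non-negative log-normal
abundances that resemble processed RNA-seq intensities.

Module genes also receive the treatment mean shift by default
(`moduleShift = deShift`). This is deliberate: the MV screen tests each
gene's marginal conditional distribution, and a module whose genes are
marginally null — same mean, same variance, only the correlation changes —
is invisible to any per-gene screen and could never reach the network
stage. The module therefore emulates responsive genes whose co-expression
additionally rewires, which is the regime the prioritizer exploits.

Defaults (200 genes = 160/20/20, 12+12 samples, shift 2 SD, correlations
0.9/0.1) mimic a single three-week stage of a two-condition field design.

**What passing tests do and do not show.** The generator produces exact
log-normal marginals, a single clean module and balanced arms. Real
RNA-seq brings count noise, library-size artifacts, correlated nulls and
unbalanced replication; recovery rates measured here (AUROC ≈ 0.98, top-k
recovery ≈ 95% at the defaults) are upper bounds on field performance, not
estimates of it.

**The hard threshold r0 is scale-dependent.** GCC levels depend on the
data's value scale and sample count, and the crossing rule only detects
rewiring when r0 falls between the two conditions' GCC levels for rewired
pairs and outside the null range. On the generator's Gaussian scale, null
pairs concentrate near 0.70 and the planted module's treatment-side GCC
near 0.87, so the module-detection property is exercised at r0 = 0.8; on
empirical expression scales (and in the pipeline defaults) r0 = 0.9 is the
canonical choice. Practitioners should inspect the per-condition GCC
distributions before trusting any fixed threshold — the same advice that
applies to hard correlation cutoffs in ordinary co-expression networks.

# Problem sizes used in the test and acceptance suites

All checks run on synthetic data at desk scale, chosen as the package's
own test design: oracle comparisons on hundreds of random instances with
n ≤ 12 samples and m ≤ 8 genes (where $2^m$ enumeration of the Ising joint
is exact), permutation calibration on 1000 null genes at K = 500, and ten
seeded pipeline replicates of the 200-gene default design (K = 500 for
recovery, K = 100 for the discrimination comparison, where the coarser
p-value lattice makes the resolution gap visible). Real stage-level
analyses (m in the thousands) use the same code paths; the GCC stage is
the bottleneck at O(m²n).

# Known limitations

- ICM finds a local maximum; no uncertainty is attached to the labels
  beyond the converged conditionals, and no MCMC alternative is provided.
- τ1, τ2 and the Normal/Inverse-Gamma hyperparameters are not estimated
  from data; sensitivity should be checked per dataset.
- The per-gene screen precedes the network stage, so genes whose only
  signal is a correlation change (no marginal shift) are not recoverable —
  an intrinsic property of the screen-then-network architecture.
- Expression values are used as provided; the package performs no
  normalization beyond an optional log2(x+1) flag, and GCC (unlike the MV
  screen) is not invariant to nonlinear rescaling.
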