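---
title: "Methods: order-of-acquisition diffusion analysis over candidate baboon social networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: order-of-acquisition diffusion analysis over candidate baboon social networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SocialDiffusion)
```

## The scientific problem

When a wild baboon discovers an ephemeral food patch, information about the
patch's location spreads to other troop members who watch the discoverer.
Whether an individual then benefits from that information unfolds in three
steps — *acquisition* (gazing at a patch occupant), *application* (entering
the patch) and *exploitation* (eating from it) — and each step can be
constrained by the individual's phenotype: dominance rank, sex, age,
boldness and position in the troop's social networks.

This package implements the full inference chain for such experiments:

1. construction of five candidate association networks per troop from
   field-style scan and interaction records;
2. order-of-acquisition diffusion analysis (OADA) to identify which network
   carries the information and how strong social transmission is;
3. Poisson count models identifying phenotypic constraints on each step of
   information use;
4. a synthetic-data generator with known ground truth so that every stage
   is testable without access to field data.

## Candidate association networks

Five association rules are quantified per troop, yielding eight candidate
matrices:

* **10 m rule** and **5 m chain rule** — undirected proximity networks
  weighted by the simple ratio index,
  $\mathrm{SRI} = x / (x + y_{ab} + y_a + y_b)$, the fraction of sampling
  occasions on which a dyad was observed in the same group. A *sampling
  occasion* is one (troop, timestamp) scan event; a scan row's group is the
  focal plus its listed associates, and rows that share a `scan_id` with
  overlapping membership are merged, because field observers may record one
  5 m chain over several rows. The chain rule's groups are accepted as
  listed (observers resolve the chain in the field), so no further
  transitive closure is applied across rows.
* **nearest neighbour**, **grooming**, **dominance** — directed count
  matrices (A named B as nearest neighbour; A groomed B; A was aggressive
  toward B), each also analysed undirected after symmetrization
  $w'(A,B) = w(A,B) + w(B,A)$.

Centrality uses two measures. *Strength* sums an individual's weighted
edges; for directed matrices the default convention is in + out (edges the
individual "has", given and received), switchable to out-only. *Weighted
betweenness* counts shortest paths through a node after converting
association weights to distances as $1/w$ — the standard transform for
association indices, under which strong ties are short — with zero-weight
dyads as non-edges, fractional counting across tied shortest paths, no
normalization, and unreachable pairs contributing nothing. The distance
transform and the absence of normalization are package choices (several
conventions exist); both are isolated behind `betweenness()` and validated
against exhaustive path enumeration in the tests.

## The OADA model

For each diffusion experiment the discoverer is seeded as informed, and the
experiment contributes a partial likelihood over the observed acquisition
order. Naive individual $i$ acquires at relative rate

* additive: $R_i = s\,T_i + e^{\Gamma_i}$
* multiplicative: $R_i = e^{\Gamma_i}(s\,T_i + 1)$
* asocial: $R_i = e^{\Gamma_i}$

where $T_i = \sum_{k \in \text{informed}} w_{ik}$ is the summed connection
to informed individuals, $\Gamma_i = \sum_m \beta_m x_{im}$ collects the
individual-level variables (ILVs: relative rank, sex coded female = 0 /
male = 1, age in years, boldness in seconds — unstandardized, so
coefficients are in the natural units of each covariate), and $s \ge 0$ is
the social-transmission parameter. At each acquisition event the likelihood
contribution is $R_{\text{acquirer}} / \sum_{j\,\text{naive}} R_j$; because
this ratio cancels any per-experiment baseline, experiments ("tasks") are
independent likelihood factors, and each troop's own matrix enters through
its experiments.

Properties maintained by construction and enforced by tests:

* the order probabilities over all complete orders sum to one;
* at $s = 0$ the social models reduce *exactly* to the asocial model, and
  with no ILVs the additive and multiplicative forms coincide;
* with no ILVs and no transmission every complete order has probability
  $1/N!$.

**Ties.** Individuals recorded as acquiring simultaneously form a tie
group. The default Breslow method puts each tied acquirer's rate over the
common pre-event denominator; the exact method averages the full sequential
probability over all orderings of the tie group (supported to size 6,
factorially many orderings beyond that). The two coincide when no ties
exist. Exposures $T_i$ update only after the whole group under Breslow, and
within each ordering under the exact method.

**Direction.** On directed networks the default transmission convention
sums the naive individual's *outgoing* edges toward informed individuals —
the attention interpretation, i watches those it directs associations at —
with an `direction = "incoming"` switch, since both conventions are
defensible and the directed/undirected contrast is itself part of the model
comparison.

**Estimation.** The published estimates report social transmission on a
bounded $[0,1)$ scale, while the rate model is naturally parameterized by
an unbounded rate ratio. The package optimizes $\log s$ (a fixed,
deterministic multi-start grid at $\log s \in \{-8,-2,0,2,5\}$, box
constraints $\log s \in [-15, 15]$, L-BFGS-B with a final polishing pass,
convergence well below $10^{-6}$ on the log-likelihood) and reports both
$s$ and $s/(1+s)$; the bounded scale is a monotone bijection of the
unbounded one, so no information is lost. Fits that exhaust the schedule
are returned flagged (`converged = FALSE`), never silently. The ILV
coefficients are box-constrained to $\pm 20$, far outside any plausible
value for unstandardized covariates on these scales, purely to keep
$e^{\Gamma}$ finite during the search.

**Model comparison.** Model selection uses
$\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$ with $n$ the total number
of individual acquisition events (tied acquirers each count once) and
$k = |\text{ILVs}| + 1_{\text{social}}$. `compareNetworks()` fits the eight
candidate networks under both ILV forms plus one asocial model — 17
candidates with the same diffusions and ILVs. `ilvSubsetSearch()` then
fits all $2^4$ ILV subsets under both forms on the winning network, and
`modelAverage()` averages coefficients over the models within
$\Delta\mathrm{AICc} \le 2$ by renormalized Akaike weights, substituting
$\beta = 0$ where an ILV is absent (full-model averaging).

**Unidentified acquirers.** An acquirer that field observers could not
identify is representable by the reserved id `UNKNOWN`; such events are
dropped from tallies and likelihoods with a warning. The original analysis
does not state how its two unidentifiable acquirers were handled, so
dropping-with-warning is this package's documented choice.

## Phenotypic constraint models

Per-individual counts of acquisition, application and exploitation — each
excluding the trials the individual discovered itself, which are tallied
separately — are regressed on six predictors (relative rank, boldness,
age, sex, and the strengths in the 10 m and directed grooming networks;
betweenness is excluded as strongly rank-correlated with strength) using a
log-link Poisson model with a random intercept per troop. With only two
troops the random intercept is weakly identified and frequently sits at the
boundary, so a fixed troop intercept is available side by side
(`method = "fixed"`); with a single troop the grouping degenerates and the
model reduces to a plain GLM. p-values use the large-sample normal
approximation on the coefficient scale.

`backwardEliminate()` iteratively removes the least significant term with
$p \ge \alpha$ (default $\alpha = 0.05$) until all retained terms are
significant, then re-adds every dropped term singly to confirm it remains
non-significant; a re-added term turning significant is flagged as an
inconsistency in the trace rather than silently re-included. When p-values
are distinct the procedure does not depend on predictor column order.
`collinearityScreen()` reports pairwise Spearman correlations (asymptotic
t p-values, adequate at n up to ~48 per troop and far cheaper than exact
permutation) and flags $|\rho| \ge 0.7$.

## What the synthetic generator emulates — and what it does not

`simScenario()` fixes the study conditions at the field design scale: two
troops of 46 and 48 animals with the observed adult/juvenile and sex
composition, 24 sampling occasions per individual per proximity rule,
25 diffusion experiments per troop, grooming and dominance totals of the
observed magnitude (~1384 and ~737 events per troop), and an expected two
unidentifiable acquirers per 50 experiments.

Space is the shared latent structure: each individual holds a 2-D home
position (scatter 10 m) jittered by 8 m at every occasion, and the 10 m
radius, 5 m chain and nearest-neighbour rules are applied to the same
positions, so the three proximity networks are correlated as they are in
the field. These two scatter parameters were chosen once as a plausible
foraging spread for a baboon troop; they control network density, not any
tested identity. Ages are uniform within class (juveniles 2–6 y, adults
6–25 y), ranks are a uniform permutation, and boldness is lognormal with a
Gaussian-copula correlation of $-0.3$ with age, reproducing the sign of
the observed age–boldness rank correlation.

Diffusions are generated from the OADA rate model itself on the designated
true network (default: the troop's constructed 10 m matrix, so estimation
error in the network does not enter recovery experiments). The default
true transmission is $s/(1+s) = 0.9$ — strong social transmission of the
kind the experiments detected — and the default ILV effects are the
published model-averaged magnitudes (rank 0.26, sex 0.15, age −0.01,
boldness 0). The discoverer is drawn with probability increasing in rank
and maleness and decreasing in age (the published asocial-learning
pattern); the published work gives no quantitative discoverer model, so
this is a construction for testing only. Patch depletion is modelled as a
random stopping count (lognormal, median 10, clamped to the observed range
2–27) rather than a timed process, because OADA uses order only. Patch
entries and feeding flags are drawn with rank- and sex-dependent
probabilities, dominants entering first.

Not emulated: spatially explicit movement and demography/turnover; any
observability bias (every individual is "seen" at every occasion, so the
SRI denominators contain no $y_a$/$y_b$ terms — real scan data are
sparser); public information about patch quality; and the co-feeding
micro-structure (the packaged patch-entry table carries the published
marginal tallies with synthetic individual detail). Passing recovery tests
therefore demonstrates that the estimators recover truth under the stated
generative model at the study's design scale — not that field data meet
those assumptions.

## Problem sizes used in the tests

Unit tests run on troops of 10–15 with handfuls of diffusions; oracle
checks (likelihood normalization, exhaustive betweenness, brute-force SRI)
use networks of at most 8 nodes where enumeration is exact. The
parameter-recovery suite runs 100 replicate studies at the full design
scale (2 troops of 46/48, 25 diffusions each, true network 10 m,
$s/(1+s) = 0.9$) and requires the median absolute error of the bounded
transmission estimate below 0.05 with the true network attaining lowest
AICc in over 60% of replicates; the count-model recovery uses 94
individuals replicated tenfold with the published rank-effect magnitude
(1.4). The acceptance script repeats the chain at the same design scale
with 20 recovery replicates.

## Known limitations

* The exact tie method enumerates orderings and is limited to tie groups
  of six; larger groups require Breslow.
* With two troops the random intercept of the count models is often
  singular; the fixed-intercept variant is the robust reading.
* The bounded transmission scale compresses near 1: data generated with
  essentially pure transmission can drive the unbounded $s$ to its box
  bound, where the reported bounded value saturates at ~0.9999997. Such
  fits are flagged by their boundary value rather than prevented.
* Time-of-acquisition variants, untransmitted social effects,
  network-permutation null models and observability corrections are out of
  scope.
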