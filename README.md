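# SocialDiffusion

Network-based diffusion analysis of social information use in primate
troops.

When a foraging baboon discovers an ephemeral food patch, knowledge of the
patch's location can spread to troop mates who watch the discoverer. This
package implements the complete inference chain for such field experiments,
for behavioural ecologists asking two questions: **through which social
network does the information travel**, and **which phenotypes constrain who
can acquire, apply and exploit it**?

## What it computes

**Candidate networks.** From proximity scan records and dyadic interaction
records it builds, per troop, two undirected proximity networks weighted by
the simple ratio index

    SRI = x / (x + y_ab + y_a + y_b)

(10 m radius and 5 m chain rules), and three directed count networks
(nearest neighbour, grooming, dominance), each also symmetrized — eight
candidate matrices per troop — plus weighted strength and betweenness
centralities and Spearman screens.

**Order-of-acquisition diffusion analysis (OADA).** Each experiment's
observed acquisition order contributes a partial likelihood in which a
naive individual *i* acquires at rate

    additive:        R_i = s * T_i + exp(Γ_i)
    multiplicative:  R_i = exp(Γ_i) * (s * T_i + 1)
    asocial:         R_i = exp(Γ_i)

with `T_i` the summed network connection to already-informed individuals,
`Γ_i` a linear predictor over individual-level variables (rank, sex, age,
boldness) and `s ≥ 0` the social-transmission parameter (also reported on
the bounded scale `s/(1+s)`). Candidate networks are compared by AICc;
all-subsets ILV searches are summarised by Akaike-weight model averaging
over models with ΔAICc ≤ 2. Ties are handled by the Breslow or exact
method.

**Phenotypic constraints.** Per-individual counts of acquisition,
application (patch entry) and exploitation (feeding) — excluding each
individual's own discoveries — are modelled by log-link Poisson
regressions with a troop random intercept and backward elimination to the
minimal model.

**Synthetic data.** A generator reproduces the study design (troops of
46/48, 24 scans per individual per rule, 25 diffusions per troop,
interaction totals of the observed magnitude) from a latent spatial
affinity model with known ground truth, so transmission parameters,
network identity and count-model coefficients are all recoverable in
tests.

## Worked example

```r
library(SocialDiffusion)

scen  <- simScenario(seed = 2)                 # the study design, truth s/(1+s) = 0.9 on the 10 m network
study <- simulateStudy(scen)                   # population, records, networks, 50 diffusions

tab <- compareNetworks(study$logs, study$networks, study$population,
                       rules = c("ten_m", "five_m_chain", "groom_directed"),
                       forms = "multiplicative")
tab
#> OADA model table: 4 candidate(s)
#>                           model k    loglik     aicc delta_aicc akaike_weight s_bounded
#> 1          ten_m/multiplicative 5 -1801.425 3612.970      0.000             1     0.900
#> 2   five_m_chain/multiplicative 5 -1812.706 3635.532     22.561             0     0.793
#> 3 groom_directed/multiplicative 5 -1830.434 3670.988     58.017             0     0.109
#> 4                       asocial 4 -1841.280 3690.639     77.669             0     0.000

attr(tab, "fits")[[tab$model[1]]]
#> OADAFit [ten_m/multiplicative]: s = 9.039 (bounded 0.9004), logLik = -1801.425, k = 5, AICc = 3612.97
#>   ILV coefficients:
#>     rank      sex      age boldness
#>   0.3982   0.1167  -0.0215   0.0027
```

The 10 m proximity network that generated the data wins by 22.6 AICc over
the next network and by 77.7 over asocial learning, and the bounded
transmission estimate 0.900 recovers the generating value 0.9. The
packaged patch-entry table reproduces the published co-feeding tallies:

```r
cofeedSummary(patchEntryEvents())
#>   entries cofeeds protested tolerated cofeed_pct tolerated_pct
#> 1     293      14         5         9        4.8           3.1
```

`runPipeline()` chains every stage (networks, comparison, ILV averaging,
tallies, constraint models) from a single config and writes all tables,
edge lists, a run log and a plain-text report; see
`vignettes/diffusion-methods.Rmd` for the model, its assumptions, and
every numerical choice.

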