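# bmkin

Bayesian multilevel prediction of enzyme kinetic parameters — values *and*
calibrated uncertainties — from categorical annotations, with optional
thermodynamic parameter balancing.

## What problem this solves, and for whom

Dynamic and enzyme-cost models of metabolism need KM (Michaelis constants)
and kcat (turnover numbers) for every reaction, but measured values cover
only a small fraction of enzymes, and repeated measurements of the same
parameter can span orders of magnitude. Modellers therefore need, per query
parameter, a predictive *distribution* — narrow when the training data
contain that very parameter, wide when only the substrate or EC class is
shared — suitable as a prior in Bayesian kinetic models.

bmkin fits hierarchical Bayesian multilevel location-scale models on the
log10 scale. For observation $i$:

$$y_i \sim \mathcal N(\mu_i, \sigma_i), \quad
\mu_i = \beta_0 + \textstyle\sum_\ell u_{\ell, g_\ell(i)}, \quad
u_{\ell,\cdot} \sim \mathcal N(0, \tau_\ell)$$

$$\log \sigma_i = \gamma_{r(i)} + w_{s(i)}, \quad
w_\cdot \sim \mathcal N(0, \tau_w)$$

The nested grouping levels are, for KM: substrate → (EC, reaction) →
protein family → protein; for kcat: the EC prefixes → (EC, reaction,
direction) → family → protein. The residual sd has two intercepts
($\gamma$) for records with/without a protein identifier and a group effect
($w$) per reaction. Predictions marginalize over every hierarchy level not
seen in training, so uncertainty grows in calibrated steps as the overlap
with the training data shrinks. A balancing step can then condition the
joint Gaussian of predicted log parameters and equilibrium constants on the
Haldane constraints
$\ln K_{eq} = \ln k^+_{cat} - \ln k^-_{cat} + \sum_i n_i \ln K_{M,i}$,
returning a thermodynamically consistent multivariate normal.

Everything runs from plain TSV files; identifier canonicalization uses
local two-column mapping tables (no web clients).

## Worked example

```r
library(bmkin)

# synthetic KM study with known ground truth: 6 substrates x 3 reactions
# x 2 families x 2 proteins, 6 observations per leaf (432 records)
sim <- simulate_kinetics(sim_config("KM", level_counts = c(6, 3, 2, 2),
                                    obs_per_leaf = 6, seed = 42))
fit <- fit_bmm(build_design(sim$records, group_schema("KM")),
               chains = 2, warmup = 500, iter = 500, seed = 7)
print(fit)
#> bmm fit (KM): 432 obs, 2 chains x 500 draws (seed 7)
#>                    mean     sd    q2.5   q97.5
#> b0              -3.7621 0.3350 -4.4633 -3.1386
#> tau_substrate    0.6876 0.3439  0.1481  1.4996
#> tau_ec_reaction  0.5472 0.1396  0.3302  0.8716
#> tau_family       0.2324 0.0548  0.1455  0.3511
#> tau_protein      0.1356 0.0232  0.0976  0.1874
#> gamma_with      -1.6740 0.0682 -1.8064 -1.5428
#> gamma_without   -0.4611 0.0823 -0.6298 -0.3102
#> tau_w            0.1981 0.0590  0.0986  0.3288
```

The generating values (group sds 0.8/0.4/0.2/0.1, residual sds 0.2 and 0.6,
i.e. $\gamma$ of −1.61 and −0.51, scale sd 0.3) all sit inside the 95%
intervals. Convergence and variance shares:

```r
diagnose(fit, rhat_threshold = 1.05)
#> MCMC diagnostics: max R-hat 1.0281 (threshold 1.050), 0 divergence(s), min ESS 101 -> pass
round(variance_decomposition(fit), 3)
#>   substrate ec_reaction      family     protein    residual
#>       0.518       0.280       0.050       0.017       0.136
```

Most explainable variance sits at the substrate and reaction levels — the
annotation a query almost always has. Prediction for a fully matched query
versus one with an unseen substrate:

```r
q <- as.data.frame(sim$records)[1, ]
predictive_distribution(fit, q[names(q) != "value_log10"])
#> predicted log10 KM: -1.880 +/- 0.229 (matched: substrate, ec_reaction, family, protein)

q$substrate_id <- "unseen-metabolite"
predictive_distribution(fit, q[names(q) != "value_log10"])
#> predicted log10 KM: -3.762 +/- 1.069 (matched: )
```

The matched query is pinned near its training measurements with roughly the
residual scatter; the novel substrate falls back to the population
intercept with the full hierarchy variance (±1.07 log10 units ≈ one order
of magnitude). The same pipeline is scriptable from a shell via
`exec/bmkin` (`simulate`, `fit`, `predict`, `evaluate`, `balance`
subcommands), and `balance_parameters()` projects predictions onto the
Haldane-consistent manifold.

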