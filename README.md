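# dataflush

Distribution-preserving data perturbation for privacy-protected synthetic
data release and exact Monte-Carlo pivotal inference.

## The problem

Adding noise to microdata protects privacy but distorts the data's
distribution, so every analysis run on the released copy inherits a bias
with no obvious correction. `dataflush` implements a perturbation scheme
that decouples the two concerns: the released values follow a prescribed
target distribution *exactly*, at **any** noise level, so downstream
statistics remain valid while the noise scale is chosen purely for privacy.

The core map, for raw values `Z_1, ..., Z_n` and target CDF `R`, is

    Z*_ij = H(U_i + e_ij),    H(.) = R^-1(G(.))

where `U_1, ..., U_n` are i.i.d. Uniform[0,1] values relabelled to carry the
ranks of the raw sample, `e_ij` is independent continuous noise (Laplace,
Gaussian or uniform), and `G` is the CDF of `U_i + e_ij`. Since
`U_i + e_ij ~ G`, the composed value follows `R` exactly; the rank coupling
keeps the released record positively rank-correlated with its source, so
record identifiers survive perturbation. Mixed-type tables go through the
probability chain rule with smoothed empirical CDFs (exact at every jump
value) and per-type conditional models; an ε-differential-privacy mode adds
Laplace noise at per-variable scale `p/ε` with a strict never-released
holdout used to fit all targets.

The same machinery powers an inference procedure: perturbed copies of a
sample with plug-in target `F(θ)|θ=θ̂` reproduce the *exact* conditional law
of a pivotal quantity at any sample size, giving Monte-Carlo confidence
intervals with a bias-correction step — including for post-selection
inference in high-dimensional regression via a truncated-L1 (L0-surrogate)
constrained estimator.

## Worked example

Perturb a sample under very strong noise (Laplace scale 100, i.e. privacy
factor ε = 0.01), then recover an exact-level confidence interval for its
mean from the perturbed pivotal draws:

```r
library(dataflush)
set.seed(42)
z <- rnorm(500, mean = 50, sd = 10)

plan <- perturbation_plan(make_noise_model("laplace", 100), m = 1, seed = 1)
zs <- perturb_univariate(z, target_normal(mean(z), sd(z)), plan)

mean(zs$values); sd(zs$values)       # 48.99 / 9.70  (raw: 49.70 / 9.72)
ks_check(zs$values[, 1], target_normal(mean(z), sd(z)))$statistic  # 0.057
spearman_check(z, zs$values[, 1])    # 0.053 — noise this large unlinks records

flush_mean_ci(z, D = 10000, epsilon = 0.01, alpha = 0.05, seed = 7)
#> <Monte-Carlo pivotal inference>
#>   estimate 49.6995 (se 0.4348), bias -0.004598, corrected 49.6949
#>   95% CI [48.8537, 50.55]  (D = 10000 draws)
```

Despite a noise scale 100 times the width of the uniform carrier, the
perturbed sample still passes a Kolmogorov check against its target, and
the Monte-Carlo interval matches the classical t interval
`[48.845, 50.554]` to two decimals — the perturbed pivotal is *exactly*
t-distributed on `n - 1` degrees of freedom, so the agreement is by
construction, not luck. At small noise scales the Spearman correlation
instead approaches 1 and released records stay linked to their source rows.

Privatizing a mixed-type survey table end to end:

```r
sim <- gen_survey_microdata(1000, seed = 1)           # 17 variables + weight
priv <- privatize(sim$data, sim$schema, epsilon = 1, seed = 2)
priv$budget
#> <privacy budget: epsilon 1 over 17 variables, per-variable Laplace scale 17; 17 consumed>
audit_perturbation(sim$data[priv$release_rows, ], priv$perturbed$values[[1]],
                   sim$schema)
```

A command-line interface wrapping the same functions ships in
`inst/cli/dataflush.R` with subcommands `perturb`, `privatize`, `infer`,
`validate` and `simulate`.

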