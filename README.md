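# mycometa

Phylogenetic mixed-model meta-analysis of plant growth responses to
mycorrhizal fungi.

Most land plants trade carbon for soil nutrients with mycorrhizal fungi,
yet the outcome of inoculating a plant with a fungus ranges from strong
growth promotion to growth depression. `mycometa` is for synthesists who
want to ask, across a database of inoculation trials spanning hundreds of
host species and dozens of fungal genera, how much of that variation is
explained by evolutionary history — early phylogenetic divergence of hosts
and symbionts, recent diversification, independent evolutionary origins of
the ectomycorrhizal lifestyle, evolved host–symbiont specificity — versus
ecological context such as N/P fertilization, soil sterilization, and
additional microbes.

## The model

Each trial contributes a log response ratio
`LRR = ln(x̄_inoc / x̄_ctrl)` with sampling variance
`σ̂² = SD²_inoc/(n_inoc x̄²_inoc) + SD²_ctrl/(n_ctrl x̄²_ctrl)`; rows
without reported SDs get the median coefficient of variation of their
analysis subset (flagged as imputed). Effect sizes are modelled with the
multilevel meta-analytic mixed model

    y = Xβ + Σ_k Z_k u_k + e,   u_k ~ N(0, σ²_k R_k),   e ~ N(0, diag(v̂_i))

where the random-effect terms carry identity correlations (species, genus,
study, control set, paper, EM origin clades), Brownian-motion phylogenetic
correlations built from Newick trees (entry = shared root-to-MRCA path /
tree depth), or tensor-product correlations over realized plant × fungus
combinations (`R[(p,f),(p',f')] = R_P[p,p'] · R_F[f,f']`) for evolved
specificity. Fitting is by REML or ML with non-negativity-constrained
variance components; the package computes profile-likelihood confidence
intervals, BLUPs (deviations of species/genus/clade/combination means from
the overall weighted mean), marginal and partial conditional R², AICc model
selection with Akaike weights and per-predictor relative variable
importance (RVI), overall percent growth responses `100(e^LRR − 1)`, and
funnel-plot exports. A synthetic-data generator with known ground truth
(`sim_config()` / `simulate_dataset()` / `recovery_experiment()`) makes
every stage testable end to end.

## Worked example

Simulate an AM-style dataset at known truth (components 0.15 / 0.10 /
0.16 / 0.15 for plant species, study, control set, paper; overall mean
`ln 1.62` ≈ 62% growth response), recompute effect sizes, build the random
effect structures from the trees, and fit the pure random-effects model:

```r
library(mycometa)

cfg <- sim_config(seed = 42, n_papers = 60, mean_effects_per_paper = 8,
                  effects_per_paper_dist = "fixed", control_fanout = 2,
                  true_sigma2 = c(plant_species = 0.15, study_id = 0.10,
                                  control_set = 0.16, paper = 0.15))
sim     <- simulate_dataset(cfg)
eff     <- compute_effect_sizes(sim$trials)
structs <- build_structures(eff, sim$plant_tree, sim$fungal_tree,
                            dataset = "am_sub")
fit <- fit_meta_model(eff, structs, mode = "REML",
                      random_terms = c("plant_species", "study_id",
                                       "control_set", "paper"))
fit
#> Multilevel meta-analytic mixed model (REML)
#> n = 480, fixed coefficients = 1, variance components = 4
#> log-likelihood (REML): -400.6797
#>
#> Variance components:
#> plant_species      study_id   control_set         paper
#>        0.1751        0.0773        0.1120        0.1854
#>
#> Fixed effects:
#>             estimate    se      z
#> (Intercept)   0.3603 0.076 4.7408

profile_ci(fit, "plant_species")
#> plant_species 95% profile CI: [ 0.13 , 0.236 ]
```

At n = 480 the four components are recovered to within sampling error of
their true values (the recovery experiment in the test suite quantifies
this at n = 2000 over 20 replicate worlds), and the intercept back-
transforms to a 43% mean growth response for this particular simulated
world:

```r
overall_mean(eff, structs[c("plant_species", "study_id",
                            "control_set", "paper")])
#> Overall weighted mean growth response: 43.380% ± 10.898 SE (delta method)
#>   LRR 0.360 ± 0.076; back-transformed 95% CI on percent scale: [23.536, 66.412]
```

Model selection over ecological predictors and the derived reports follow
the same pattern: `select_fixed_effects()` returns the AICc table, weights
and RVIs; `variance_table()`, `meta_blups()`, `blup_matrix()`,
`marginal_means()` and `funnel_data()` produce the summary tables;
`write_fit_report()` / `write_blups()` serialize them.

Real data plug in the same way: `read_trials()` for the flat trial table
(columns documented in `?compute_effect_sizes`), `partition_datasets()`
for the AM-full / AM-sub / EM split, `read_phylogeny()` for the two Newick
trees.

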