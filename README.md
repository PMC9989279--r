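# progmapper

Topological progression analysis of longitudinal clinical scores.

`progmapper` is aimed at biostatisticians modelling the year-on-year
progression of a clinical severity score — the motivating case is the motor
score (MDS-UPDRS part III) of early Parkinson's disease cohorts — from
routinely collected visit tables.  Instead of regressing next year's score
on this year's covariates, it:

1. normalizes each clinical feature to `[0, 1]` (optionally clamping the
   score axis) so the patient-visits form a point cloud *S* ⊂ ℝ^8;
2. optionally prunes features by **persistent homology**: a feature whose
   removal barely perturbs the Vietoris–Rips persistence diagrams of *S*
   carries no independent geometric information (backward elimination under
   the bottleneck distance);
3. builds a **mapper graph**: the filter f = (updrs3, age) : S → ℝ² is
   covered by overlapping boxes (n₁ × n₂ intervals, overlap fraction p);
   each box's visits are clustered in the full feature space; clusters
   become nodes, shared visits become edges;
4. estimates, per medication regimen i ∈ {0..7}, a **Markov chain** on the
   clusters from consecutive-year visit pairs (x, y):

       M[i,j] = #{(x,y) : x ∈ C_i, y ∈ C_j} / #{(x,y) : x ∈ C_i},

   with identity rows for clusters that source no pair;
5. derives the **expected one-year growth** Δ = Σ_j w_j Σ_l M[j,l](E_l − E_j)
   (w = cluster occupancy of the regimen, E_j = mean score of cluster j) and
   the **un-biased medication effect** Δ′ − Δ, where Δ′ applies the
   *un-medicated* chain to the medicated group's occupancy;
6. predicts a patient's **next-year score** p(x) = Σ_j (vM)_j E_j, where v is
   a Gaussian-kernel weight vector over the clusters containing the μ = 14
   nearest neighbours of x (bandwidth σ = 0.0378), and evaluates the model
   leave-one-out (R², signed mean error, MAE, MSE, max error, and the
   "hit-in" percentage: predictions within ±5 absolute points, i.e. ±0.0625
   normalized on a score range of 80).

A synthetic-cohort generator (`generate_cohort()`) emulates the structure
such pipelines assume — archetypal disease states, per-regimen annual drift,
visit dropout — so every stage is testable without access to gated clinical
databases.

## Worked example

```r
library(progmapper)

cohort <- generate_cohort(cohort_spec(n_patients = 200, n_years = 4,
                                      noise_sd = 0.01, seed = 7))
cohort
#> <visit_table> 554 visits, 200 patients, 8 features (normalized)
#> features: age, updrs3, np1apat, np1fatg, np1anxs, moca, scopa, symptom

pairs <- build_pair_sets(cohort)           # one pair set per regimen 0..7
graph <- build_mapper_graph(cohort)        # filter (updrs3, age), 20x40, p=0.05
graph
#> <mapper_graph> 207 cluster(s), 60 edge(s) over 554 points; filter (updrs3, age)

scores <- cohort$data$updrs3
model  <- build_transition_model(graph, pairs[["0"]], scores)
expected_growth(model, cluster_type_counts(graph, cohort, 0))
#> <growth_report> med_type 0: expected growth 0.01854 (normalized)

report <- loo_evaluate(pairs[["0"]], feature_matrix(cohort), graph, model,
                       scores = scores)
report
#> <eval_report> med_type 0: n=97 (failed 0)  R2=0.986  mean_err=-0.001967
#>   MAE=0.01565  MSE=0.000371  max=0.04554  hit-in=100.0%
```

The growth report says un-medicated synthetic patients gain ≈ 0.0185
normalized score units per year (× 80 ≈ 1.5 absolute points; the generator
injected 0.0275, and the estimate is shrunk by occupancy mass sitting in
clusters without outgoing pairs — see the methods vignette).  The
leave-one-out report says that with a held-out current-year visit the model
predicts next year's score within ±5 absolute points for 100% of pairs in
this low-noise cohort.

`growth_table(cohort, graph, pairs)` assembles the per-regimen Δ, Δ′ and
Δ′ − Δ (normalized and × 80) in one data frame;
`tune_cover_parameters()` grid-searches the cover (n₁, n₂, p) by hit-in
percentage.  Exporters write mapper graphs as GraphML/JSON, transition
models as CSV + JSON and evaluation tables as CSV.

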