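# painfreq

How often does a longitudinal pain outcome need to be measured? `painfreq`
implements, as a tested R pipeline, the analysis used to answer that
question for weekly SMS follow-up of low back pain: subjects report a
weekly **Number of Bothersome Days** (NBD, 0–7) for 26 weeks, and the
package compares what six measurement schedules — from all 26 weeks down
to 8 — preserve of the full schedule's conclusions. It is aimed at
biostatisticians and epidemiologists planning repeated-measures follow-up
who need to trade measurement burden against information.

## What it computes

For each subject the pain course is fit as a continuous two-phase linear
spline with an estimated trend break (the knot):

```
y(t) = β₀ + β₁ (t − t₁) + (β₂ − β₁) (t − κ)₊
```

estimated by exhaustive integer-knot search with per-knot least squares.
The four trajectory parameters per subject feed a deterministic two-stage
clustering — Ward's minimum-variance linkage seeding a K-means
consolidation — with the Calinski–Harabasz criterion `CH =
(B/(k−1))/(W/(n−k))` selecting the number of clusters. Cluster solutions
obtained under reduced schedules are compared with the full-schedule
reference via Cohen's kappa and quadratic-weighted kappa (weights `w_ij =
1 − (i−j)²/(k−1)²`), cluster trajectories are extrapolated to week 26
along the post-knot lines, and the week-wise relative risk of a
bothersome day (long vs short prior pain duration) is estimated from a
per-week log-binomial GLM, `NBD ~ Binomial(7, p)` with log link.

Because the underlying patient data are not deposited anywhere, the
package ships a synthetic-cohort generator (`simulate_cohort()`) that
emulates the cohort's structure — four archetype recovery trajectories,
binomial weekly counts, ~3% missingness, constant repliers, and a
prognostic duration covariate — so every stage is testable end to end.
The five printed 4×4 agreement tables of the motivating study are
included as data and reproduce exactly.

## Worked example

```r
library(painfreq)

# exactly reproducible anchor: agreement statistics recomputed from the
# motivating study's printed contingency tables
kappa_reference()
#> # A tibble: 5 × 4
#>   design kappa weighted_kappa interpretation
#>   <chr>  <dbl>          <dbl> <chr>
#> 1 B      0.272          0.548 fair-to-good
#> 2 C      0.348          0.611 fair-to-good
#> 3 D      0.618          0.720 fair-to-good
#> 4 E      0.642          0.823 excellent
#> 5 F      0.611          0.708 fair-to-good

# full synthetic study: simulate 129 subjects, clean, fit, cluster per
# design, compare designs, estimate week-wise relative risks
study <- run_study(seed = 1)
study
#> Measurement-frequency study: 124 subjects, designs A,B,C,D,E,F (reference A)
#> Fixed k = 4 agreement vs A:
#> # A tibble: 6 × 4
#>   design kappa weighted_kappa interpretation
#>   <chr>  <dbl>          <dbl> <chr>
#> 1 A      1              1     excellent
#> 2 B      0.394          0.762 excellent
#> 3 C      0.888          0.945 excellent
#> 4 D      0.962          0.986 excellent
#> 5 E      0.936          0.975 excellent
#> 6 F      0.913          0.953 excellent
#> Free-k solutions (Calinski-Harabasz):
#> # A tibble: 6 × 3
#>   design k_free ch_score
#>   <chr>   <dbl>    <dbl>
#> 1 A           4     425.
#> 2 B           4     277.
#> 3 C           2     331.
#> 4 D           5     341.
#> 5 E           4     371.
#> 6 F           4     354.
```

Reading the output: five of 129 simulated subjects fall to the
eligibility/constant-replier filters (124 analysed). Forcing four
clusters everywhere, the 8-week design B agrees worst with the reference
partition (weighted kappa 0.76) while the sparser-but-longer designs D
and E agree almost perfectly (0.99, 0.98) — measuring *longer* beats
measuring *more often*, the study's central finding. Freed from the
four-cluster assumption, the reference design recovers exactly the four
planted archetypes (CH peak at k = 4), while the truncated design C
collapses to two clusters: it cannot see the late trend breaks.
Per-design trajectories, CH profiles, RR profiles, spline fits and
exclusion logs are in the `study` object (`study$trajectories`,
`study$rr`, …); `autoplot()` methods draw the CH profile, cluster
trajectories and RR curve, and `write_study(study, dir)` serializes the
report as deterministic CSVs.

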