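# mtalong

Longitudinal analysis of medial temporal atrophy (MTA) ratings and volumes
in preclinical dementia cohorts.

Radiologists grade medial temporal lobe atrophy on Scheltens' ordinal MTA
scale — an integer 0–4 per hemisphere — while automated tools produce
continuous ratings or hippocampal (HC) and inferior lateral ventricle (ILV)
volumes. For memory-clinic patients with subjective cognitive decline (SCD)
or mild cognitive impairment (MCI), followed over several scans and
stratified by CSF biomarkers (A⁺ if Aβ42/40 < 0.10, T⁺ if p-tau > 72
pg/ml), `mtalong` answers, with tested code:

* **Agreement** — Cohen's weighted kappa
  κ\_w = 1 − Σ w\_ij O\_ij / Σ w\_ij E\_ij between raters, with linear
  (|i−j|/4), quadratic or unweighted disagreement weights and Landis–Koch
  labels; Spearman correlations between ratings, volumes and cognition on
  one independent visit per subject.
* **Progression** — per-subject ordinary least-squares annual change
  (ΔMTA/year, ΔHC/year, …) against age; tie-corrected Kruskal–Wallis
  comparison of CSF groups with Bonferroni correction (α/m); the
  enumeration showing that a single-step discrete rating over visits at
  0/2/4/6 years can only realise slopes {0, 0.15, 0.2}.
* **Rating sensitivity** — kernel-density estimates of ΔHC and ΔILV by
  rating-change class, and the prior-weighted crossover threshold: the
  volume change at which p(ΔMTA ≥ 1) · f₊ first exceeds p(ΔMTA = 0) · f₀
  out to the tail, i.e. the point where a higher rating becomes more likely
  than an unchanged one.
* **Progression times** — years for a full continuous MTA point (1/rate),
  years to the crossover threshold (|T|/|ΔHC·year⁻¹|), and their
  reconciliation ratio under the latent-uniform assumption (integer
  rating k ↔ continuous score uniform on [k, k+1)).
* **Synthetic cohorts** — a seeded generator producing cohorts with the
  study's statistical structure (three CSF groups 54/18/21, four visits
  over six years, a latent per-hemisphere MTA trait with group-specific
  rates, linear HC and exponential ILV volume links, two biased
  discretising human raters, one continuous automated rater, ~9 % QC
  failures), so the whole pipeline is testable without patient data.

The methods vignette (`vignettes/mta-longitudinal-methods.Rmd`) documents
every model, default and numerical convention.

## Worked example

```r
library(mtalong)

cohort <- make_fixture("paper_like")   # 93 simulated subjects, fixed seed
cohort
#> <mta_cohort>
#>   subjects: 93 (AnTn=54, ApTn=18, ApTp=21, AnTp=0)
#>   images  : 372 (subject x visit)
#>   raters  : avra[cont], rad1[disc], rad2[disc]

qc_filter(cohort)
#> <mta_cohort_views> 337/372 images pass QC (35 excluded from volume analyses)

wide <- tidyr::pivot_wider(cohort$ratings, names_from = rater, values_from = mta)
weighted_kappa(wide$rad1, wide$rad2)
#> Cohen's weighted kappa (linear weights): 0.311 [fair], n = 744

sl <- subject_slopes(cohort, "avra", "left")
group_rate_summary(sl, cohort$subjects)
#> Group annual-change summary (all): H = 7.91, p = 0.0191
#> # A tibble: 3 x 4
#>   at_group     n   mean     sd
#> 1 AnTn        54 0.0498 0.0495
#> 2 ApTn        18 0.0688 0.0639
#> 3 ApTp        21 0.107  0.100
```

The two simulated radiologists agree only fairly (κ_w 0.31) despite both
being reliable — they differ by a systematic bias, exactly the situation
weighted kappa penalises. The automated rating advances by ~0.05 scale
units/year in biomarker-normal subjects and roughly twice that with full
CSF pathology; the Kruskal–Wallis p at study scale (n = 93) does not clear
the Bonferroni bar of 0.05/66 ≈ 7.6e−4, showing why group separation needs
either larger samples or the volume measures.

Progression times from the bundled published group rates and thresholds:

```r
conversion_summary()
#> # A tibble: 3 x 6
#>   at_group rating_rate hc_rate full_score_years threshold_years ratio
#> 1 AnTn           0.04     37.8            25               6.26  4.00
#> 2 ApTn           0.075    54.4            13.3             4.35  3.07
#> 3 ApTp           0.12     96.4             8.33            2.45  3.39
```

A biomarker-normal subject needs ~25 years to advance a full continuous
MTA point but only ~6.3 years of typical HC loss before a higher discrete
rating becomes the more likely call; with full CSF pathology those times
shrink to 8.3 and 2.5 years.

A full run — simulate (or load a cohort CSV), QC-split, agreement,
slopes, group tables, densities, thresholds, conversion times, run
report — is one call:

```r
run_pipeline(pipeline_config(out_dir = "results/run1", seed = 1))
```

or from a shell via the thin wrapper `inst/cli/mta.R`
(`simulate | validate | run | agreement | progression | sensitivity |
convert-time`).

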