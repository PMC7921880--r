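# pollendiary

Grass pollen allergy is the most widespread pollen allergy, yet sufferers do
not react uniformly across the season: some peak early (when *Poa* and
*Dactylis* flower), most in the main pollination period (*Arrhenatherum*,
*Festuca*, *Lolium*), and a few late (*Phleum*, *Cynodon*). `pollendiary`
implements, as a reusable and tested pipeline, the analysis needed to
characterise such profiles from two data streams: daily airborne pollen
concentrations from a Hirst-type trap, and crowd-sourced hay-fever diary
entries (eye / nose / lung symptom severity plus medication use per
user-day). Because individual diary data are personal and not redistributable,
the package ships a synthetic pollen-season and cohort generator with known
ground truth, so every stage can be exercised and validated end to end.

The pipeline:

1. **Season delimitation** — the grass pollen season of a year starts on the
   day the running sum of daily concentrations *c(d)* first reaches 1% of
   the annual total and ends on the day it reaches 95%; both endpoints
   inclusive. The Annual Pollen Integral is
   APIn = Σ<sub>d∈season</sub> c(d) (pollen·day/m³).
2. **User filtering** — a user counts as a grass pollen allergy sufferer if
   their daily total score s<sub>u</sub>(d) has a positive Spearman rank
   correlation with same-day pollen, one-sided p < 0.05, over at least 15
   observed in-season days.
3. **Imputation** — missing season days are filled per user by k-nearest
   neighbours (k = 3) over day-of-season and pollen concentration with a
   range-normalised Manhattan (Gower-style) distance; the imputed value is
   the median of the neighbours' scores.
4. **Three season partitions** — (i) APIn tertiles: cuts where the
   within-season pollen sum reaches APIn/3 and 2·APIn/3; (ii) phenology:
   sections delimited by the earliest flowering onset of the main- and
   late-flowering grass groups; (iii) per-user symptom-load (SLI) tertiles
   of the user's own cumulative score.
5. **Classification** — each user-year is assigned to the section with the
   highest mean daily score (argmax, ties to the earliest section), and a
   one-way ANOVA confirms the section effect on daily scores.
6. **Reporting** — count/percentage tables per section, cross-year profile
   stability for users present in all years, and cumulative-SLI versus
   cumulative-APIn profile curves with fast/slow reactor flags.

## Worked example

```r
library(pollendiary)

ps     <- gen_pollen_year(default_taxon_specs(), 2015, seed = 1)
season <- define_season(ps, 2015)
season
#> <season 2015 (Poaceae)> 05.05.2015 (doy 125) to 20.07.2015 (doy 201), 77 days, APIn 2704

part <- apin_tertile_partition(ps, season)
part
#> <section_partition method=apin>
#>   section 1: 2015-05-05 .. 2015-06-05 (32 days)
#>   section 2: 2015-06-06 .. 2015-06-19 (14 days)
#>   section 3: 2015-06-20 .. 2015-07-20 (31 days)

users  <- gen_user_specs(100, ps, part, seed = 2)
cohort <- gen_cohort(users, ps, part, seed = 3)
series <- build_user_series(cohort$entries, season)
kept   <- filter_users(series, ps)      # 65 of 100 users pass the filter

assignments <- classify_cohort(kept, ps, periods = default_phenology(2015))
section_table(assignments, "apin")
#> # A tibble: 3 x 3
#>   section count percentage
#>     <int> <int>      <dbl>
#> 1       1     7       10.8
#> 2       2    54       83.1
#> 3       3     4        6.2
```

The synthetic season lasts 77 days with an APIn of 2704 pollen·day/m³, in
the range of observed urban Poaceae seasons (81–98 days, APIn 2154–3467).
The middle tertile of the pollen mass is the shortest section (14 days)
because that is when concentrations peak; most filtered users are classified
into it. Comparing assignments with the generator's ground truth,

```r
rec <- merge(assignments[assignments$method == "apin", ],
             cohort$truth$users, by = "user_id")
mean(rec$section == rec$true_section)
#> [1] 0.9846154
```

i.e. 98.5% of the noisy, 70%-adherent users are put back into their true
section. Profile curves (`profile_curves()`, `plot_profile_curves()`)
additionally flag each user as a fast or slow reactor depending on whether
their cumulative symptom load runs above or below the cohort mean curve at
mid-APIn.

See the vignette (`vignettes/pollen-symptom-profiles.Rmd`) for the model,
parameter and design details.

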