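# omscreen

Lexicon-based screening of free-text primary care consultation records for
visits where **otitis media (OM)** was a diagnosis under consideration —
plus the clinician-review workflow and diagnostic-accuracy evaluation used
to validate such a screen, and a seeded synthetic note generator so the
whole pipeline is testable with no real patient data.

## Who this is for

Researchers working with *uncoded* general-practice records, where the
outcome ("was OM considered at this visit?") exists only inside a free-text
note. Reading every note by clinicians is accurate but does not scale;
naive keyword search fails on ambiguous abbreviations ("ROM" = right otitis
media *or* range of movement) and ignored context ("brother has otitis
media", "TM normal"). The screen implemented here is a deliberate
compromise: a transparent exact-match rule set tuned for high sensitivity
and negative predictive value, which triages the corpus down to a small
flagged subset that clinicians then review.

## The algorithm

A **lexicon** = search terms (literal surfaces, each with a case rule) +
one global list of exclusion words + a **combination policy**. Every
boundary-respecting occurrence of a search term is found in the raw note
(flanking characters must be non-alphanumeric, so `tm` never fires inside
"treatment"); a found term is suppressed when an exclusion word occurs
within the policy's scope (adjacent token / ±3-token window (default) /
same sentence / whole record). Exclusion is per match: "TM normal but L ear
AOM" stays flagged through its AOM match. A visit is flagged iff at least
one match survives.

The evaluation module computes, for screen output vs. gold-standard
clinician labels with confusion cells tp, fp, fn, tn:

- sensitivity tp/(tp+fn), specificity tn/(tn+fp), PPV tp/(tp+fp),
  NPV tn/(tn+fn) — Clopper–Pearson exact 95% CIs;
- LR⁺ = sens/(1−spec), LR⁻ = (1−sens)/spec — log-method CIs with
  var(ln LR⁺) = 1/tp − 1/(tp+fn) + 1/fp − 1/(fp+tn);
- workload reduction = 1 − (tp+fp)/total.

## Worked example

Screen the shipped 8-visit demo corpus with the seed lexicon and evaluate
against its gold labels:

```r
library(omscreen)
lx      <- seed_lexicon()
records <- read_visit_records(system.file("extdata", "demo_visits.csv", package = "omscreen"))
screen  <- screen_corpus(records, lx)
screen
#> <om_screen_set> 8 visits, 4 flagged, 2 excluded matches
subset(screen$flags, flagged)
#>   visit_id flagged
#> 1     v001    TRUE
#> 4     v004    TRUE
#> 5     v005    TRUE
#> 7     v007    TRUE
screen$audit
#>   visit_id surface start end excl_surface excl_start excl_end
#> 1     v002      TM    27  28       normal         30       35
#> 2     v008     t/m    27  29       pearly         31       36
```

Four visits are flagged: the two genuine OM visits (v001 "AOM", v007
"otitis media likely") and the two *designed* false positives the screen
intentionally leaves for the clinician stage — v004 uses "ROM" for range of
movement and v005 says "brother has otitis media". The audit table shows
the exclusion rule at work: "TM normal" (v002) and "t/m pearly" (v008) were
matched and suppressed.

```r
gold <- read_gold_labels(system.file("extdata", "demo_gold.csv", package = "omscreen"))
build_confusion(screen, gold)
#> <om_confusion>            gold + gold -
#>   flagged                  2       2
#>   not flagged              0       4
#>   total 8
```

On the published validation corpus the screen's confusion matrix was
(tp = 801, fp = 412, fn = 116, tn = 8705); the package reproduces the full
published panel from those cells:

```r
print(diagnostic_stats(confusion_matrix(801, 412, 116, 8705)))
#> Diagnostic performance (n = 10034 visits, 1213 flagged, 95% CIs)
#>   Sensitivity                87.35% (85.02% to 89.43%)
#>   Specificity                95.48% (95.03% to 95.90%)
#>   Positive predictive value  66.03% (63.29% to 68.70%)
#>   Negative predictive value  98.68% (98.42% to 98.91%)
#>   Positive likelihood ratio  19.33 (17.53 to 21.31)
#>   Negative likelihood ratio  0.13 (0.11 to 0.16)
#>   Workload reduction         88% (1213 of 10034 visits need review)
```

A reviewer need read only 1213 of 10,034 visits — an 88% workload
reduction — while missing 116 of 917 true OM visits (the screen is a triage
step, not a replacement for review).

## Command line

```sh
SCRIPTS=$(Rscript -e 'cat(system.file("scripts", "omscreen", package = "omscreen"))')
Rscript "$SCRIPTS" simulate --seed 42 --out-dir sim/
Rscript "$SCRIPTS" screen --records sim/visits.jsonl \
    --lexicon "$(Rscript -e 'cat(system.file("extdata","seed_lexicon.yaml",package="omscreen"))')" \
    --out sim/results.jsonl --audit sim/audit.csv
Rscript "$SCRIPTS" evaluate --results sim/results.jsonl --gold sim/gold.csv --out sim/report.json
Rscript "$SCRIPTS" discrepancies --results sim/results.jsonl --gold sim/gold.csv \
    --records sim/visits.jsonl --lexicon ... --out sim/disc.csv
```

Subcommands: `screen`, `evaluate`, `simulate`, `discrepancies`,
`adjudicate`, `lexicon-validate`. All randomness requires an explicit
`--seed`; repeated runs are byte-identical.

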