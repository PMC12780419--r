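---
title: "Screening free-text primary care records for otitis media: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening free-text primary care records for otitis media: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omscreen)
```

## The problem

Primary care consultation records are often uncoded: the diagnosis lives
only in a free-text note ("Pulling at R ear, TM red and bulging, AOM —
amoxicillin"). Research that needs visit-level outcomes — here, whether
otitis media (OM) was a diagnosis the clinician considered — must either
have clinicians read every note, which does not scale, or screen the notes
by software. Free clinical text makes naive keyword search unreliable for
two documented reasons:

* **Ambiguous abbreviations.** "ROM" means *right otitis media* in an ear
  consultation and *range of movement* in a musculoskeletal one. Expansion
  is impossible precisely because the abbreviation has several meanings.
* **Ignored context.** "brother has otitis media" is about a sibling;
  "TM normal" is an examination finding that *rules out* OM.

`omscreen` implements a transparent, auditable compromise: an exact-match
lexicon screen designed for high sensitivity and high negative predictive
value, whose false positives are accepted by design and resolved by a
downstream clinician review of only the flagged visits. The package also
implements that review workflow and the diagnostic-accuracy evaluation
used to validate the screen.

## The screening algorithm

A **lexicon** has three parts:

1. **Search terms** — literal surfaces (words, phrases, abbreviations) each
   with its own case-sensitivity flag. The shipped seed lexicon enumerates
   the tympanic-membrane variants `T/M`, `t/m`, `tm`, `TM` as *distinct
   case-sensitive terms*; case sensitivity defaults to strict because the
   variants are listed separately rather than folded. Plural and inflected
   forms are separate surfaces (`TMs`), never stemmed, which keeps every
   match auditable as a literal substring of the note.
2. **Exclusion words** — one *global* list (not per-term pairs): every
   found search term is compared against all exclusion words, matching the
   original algorithm's description of its exclusion stage.
3. **A combination policy** — the textual scope within which an exclusion
   word suppresses a found term.

**Matching.** The matcher reports every occurrence of every search term
whose flanking characters (where they exist) are non-alphanumeric. This
word-boundary rule is what stops the two-letter abbreviation `tm` from
firing inside "trea**tm**ent" while still matching `tm,`, `tm)` or a
line-final `tm`. `/` inside a term is a literal character. No other
normalization is applied — matching runs on the raw stored note, so results
are bit-reproducible against the source record. Overlapping occurrences of
different terms are all reported.

**Exclusion.** The original description says only that a "search term +
exclusion term combination" in the visit text suppresses the term; whether
that meant strict adjacency or any co-occurrence is not recoverable. All
four readings are implemented as policy modes:

| mode | exclusion word must be | default |
|---|---|---|
| `phrase` | the immediately adjacent token | |
| `window` | within `window_tokens` tokens (default 3) | yes |
| `sentence` | in the same sentence (`.`, `!`, `?`, newline) | |
| `record` | anywhere in the note | |

The default — `window`, 3 tokens, bidirectional — covers "TM normal",
"normal TM" and "TM looks normal" without the over-broad `record` mode,
which would let a single "normal" anywhere in a long note erase a genuine
OM finding; a screen built for sensitivity should err toward keeping
matches. `bidirectional = TRUE` is a deliberate choice on another point the
original leaves open (an exclusion word *before* the term): clinical notes
write both "TM normal" and "normal TM". Tokens are maximal alphanumeric
runs with internal `/` (so `T/M` is one token), and whitespace runs
separate tokens; newlines end sentences because these notes use line breaks
as separators.

Two further semantics matter:

* **Exclusion is per match, not per visit.** In "TM normal but L ear AOM"
  the negated TM finding is suppressed while the independent AOM match
  keeps the visit flagged. Per-visit exclusion would trade sensitivity for
  nothing.
* **Provenance.** Every suppressed match records the nearest qualifying
  exclusion occurrence (character distance, earlier offset on ties), giving
  a deterministic audit trail, and `screen_corpus()` accumulates an audit
  table of all suppressions.

Match offsets are reported 1-based inclusive (R's `substr()` convention):
`substr(text, start, end)` always reproduces the matched surface under the
term's case rule.

Contextual false positives — "brother has otitis media", non-otological
"ROM" — are *flagged on purpose*. The screen's contract is to rule visits
out, not in; the clinician review of flagged visits resolves the rest.

## Evaluation

`build_confusion()` cross-tabulates screen output against gold-standard
clinician labels (orphan ids on either side are an error, never silently
dropped), and `diagnostic_stats()` derives the panel:

* sensitivity, specificity, PPV, NPV with **Clopper–Pearson exact**
  intervals (`qbeta` formulation; the lower bound is exactly 0 at $k=0$ and
  the upper exactly 1 at $k=n$). The source publication does not name its
  proportion CI method; Clopper–Pearson is adopted because the printed
  proportion intervals are slightly wider than Wilson intervals on the same
  counts, and it reproduces every printed proportion bound at 2 decimal
  places.
* LR⁺ and LR⁻ with the **log method**:
  $\operatorname{var}(\ln \widehat{LR}^{+}) = \frac{1}{tp} - \frac{1}{tp+fn} + \frac{1}{fp} - \frac{1}{fp+tn}$
  (and the mirrored form for LR⁻), bounds
  $\exp(\ln \widehat{LR} \pm z_{1-\alpha/2}\sqrt{\operatorname{var}})$.
  This method reproduces the published LR⁻ interval (0.11–0.16) and LR⁺
  upper bound (21.31) exactly at printed rounding. One printed digit does
  not reproduce: the published LR⁺ lower bound is 17.54 while the formula
  on the exact cells gives 17.533 (the published figure was most plausibly
  computed from rounded intermediates). We report the computed value and
  document the 0.007 gap rather than adjusting anything.
* **workload reduction** $1 - (tp+fp)/\text{total}$: the fraction of visits
  the screen removes from clinician review.

Zero cells make an LR undefined; such estimates are returned as an explicit
degenerate signal rather than `Inf`/`NaN`, and the rest of the panel is
unaffected. An optional Haldane (+0.5) correction exists but is off by
default — transparency over smoothing. Machine output keeps full precision;
the print method rounds percentages to 2 decimals (`style = "table"`) or
whole percentages (`style = "abstract"`), matching the two presentation
styles used in the source publication.

## The review workflow

`adjudicate()` models the consensus stage: unanimous visits adopt the
shared label; discordant visits require an explicitly supplied resolution
and otherwise stay `unresolved`. There is **no automatic majority vote** —
the original consensus came from discussion against the term list, and
silently deciding 2-vs-1 splits by arithmetic would fabricate a gold
standard. `discrepancy_report()` lists false positives first (they drive
lexicon refinement), with snippets of ±40 characters around each match —
enough context for the documented error modes without copying whole notes
into reports. `suggest_exclusion_candidates()` is explicitly tooling
*beyond* the original study: it automates the human scan of FP
neighbourhoods and sits off the validation path.

## The synthetic corpus generator

No real records can ship, so `generate_corpus()` builds seeded corpora with
known ground truth emulating the validation cohort's shape: 200 children,
negative-binomially dispersed visit counts with mean 50 (dispersion
`size = 25`, a mild overdispersion chosen once — the true per-practice
distribution is not public), and 9% prevalence of OM-considered visits.
Negative visits are decorated on disjoint subsets with the documented
constructions:

* `negation_rate = 0.15`: a search term immediately followed by an
  exclusion word ("TM normal"), suppressed under every policy mode —
  negated examination findings are common in real notes, and 0.15 makes
  the exclusion stage do visible work in every corpus;
* `confounder_rate = 0.03`: "ROM" in a musculoskeletal context (the
  lexicon must contain `ROM` for this construction — it is the canonical
  ambiguity being modelled);
* `family_mention_rate = 0.01`: OM attributed to a relative;
* `misspelling_rate = 0.01`: per-character typos on filler text only.

The three decoration rates are not published quantities; they are the
package's own declared world, picked once at plausible clinical magnitudes
and not revisited. Misspellings never touch planted terms by default
because the matcher is exact by design and the original treats misspellings
as a clinician-stage problem (`corrupt_planted_terms = TRUE` demonstrates
the sensitivity loss).

Two guarantees keep gold labels exact: filler templates contain no lexicon
term, and a generation-time assertion re-checks the rendered text (typos
that accidentally create a term or an in-scope exclusion word are rolled
back). Gold labels are a pure function of the construction assignment,
which is drawn before any text is rendered — regenerating with a different
lexicon changes the text but never the labels, so label leakage from the
matcher is structurally impossible.

**What a green closed-loop test establishes — and what it does not.** With
all noise rates zero the screen is perfect by construction, so
`closed_loop_check()` validates the *pipeline plumbing* (every planted term
found, nothing else flagged), and with planted errors it validates that
measured operating points track designed ones within binomial error. It
does not establish performance on real notes: template text has none of
the spelling noise on terms, novel abbreviations, or grammatical fragments
of real general-practice records, which is exactly why the published
validation used clinician review as its gold standard.

## Numerical and degenerate-input choices

* Duplicate `(surface, start)` matches (the same surface listed under both
  case rules) are reported once.
* `excluded_by` tie-break: nearest by character gap, then earlier offset.
* Empty text screens to an empty match set, `flagged = FALSE`.
* `trials = 0` in `proportion_ci()` and an empty confusion matrix are
  errors; degenerate LRs are signalled, not `NaN`.
* All generator randomness flows from one required integer seed; the CLI
  refuses to simulate without `--seed`.

## Known limitations

* Exact matching only: misspelled terms in real notes are missed by design
  (the published discussion reports this whole class of methods shares the
  limitation); there is no stemming, no fuzzy matching, no
  abbreviation expansion, no NegEx-style negation parsing.
* The shipped seed lexicon transcribes the terms attested in the source's
  running text and completes the list with standard OM abbreviations; the
  full original term tables are not public, so the completion is labelled
  synthetic in the data file.
* The screen is validated for one condition, one country, one era of
  records; the pipeline (not the lexicon) is the reusable artifact, and any
  new setting needs its own piloting loop: screen, review discrepancies,
  refine the lexicon, re-run.
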