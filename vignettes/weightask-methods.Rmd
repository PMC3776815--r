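---
title: "Methods: mining weight-perception questions from Q&A text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining weight-perception questions from Q&A text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weightask)
```

`weightask` studies the gap between *perceived* and *actual* body weight
in social Q&A text, and what that gap predicts about later posting
behaviour. This vignette explains the models and procedures behind each
stage, the parameters that matter, what the synthetic corpus does and
does not emulate, and the numerical conventions the implementation fixes.

## The analysis in one paragraph

An asker posts a question of the form "Am I fat?" and, typically, reports
age, gender, height and weight in the text. The package extracts those
measurements, computes BMI, and classifies the asker's actual weight
status — adult BMI bands for ages 20 and over, CDC-style BMI-for-age
percentile bands for teens 13–19. Crossing the inquired term (skinny,
thin, fat, obese) with the actual class gives a congruence flag: did the
asker question a category they actually belong to? Downstream, the asker's
*later* posts are scanned for topical categories (diabetes, fertility,
mental health, ...) and for bullying mentions, and the per-stratum posting
rates are compared against the pooled asker population. A county layer
links askers through their registration zip code to county obesity
prevalence and median income for ecological comparisons.

## Precision-first extraction

The extractor is deliberately rule-based and tuned for precision rather
than recall. A field is populated only when a number carries its unit or
keyword context:

* weight: `180 pounds`, `180 lbs`, `58.1 kg` (converted at 2.20462 lb/kg);
* height: `5 foot 9 inches`, `5'9"`, `163.2 cm` (2.54 cm/in); bare
  numbers are never read as heights;
* age: `15 years old`, `15 yrs old`, `age: 15`; a bare `I am 15` is not
  accepted;
* gender: explicit tokens only (`male/female/man/woman/boy/girl`);
  pronouns and slang are ignored.

Anything ambiguous — `"I weigh 128"`, conflicting duplicate values, both
gender tokens in one post — yields an *absent* field. Absence is an
explicit state, not zero, and incomplete profiles are excluded before any
record exists. The consequence, mirrored by the validation audit
(`validate_extraction()`), is that omissions can be plentiful while
errors stay rare; the test suite requires a field error rate at or below
2.5% with omissions at least an order of magnitude more common on
ambiguity-injected corpora.

The rendering dialects that the synthetic generator uses are shipped as a
versioned YAML fixture (`inst/extdata/dialects.yaml`). The pattern
inventory is a reconstruction — real forums exhibit more dialects than
any fixture can list — which is exactly why the extractor's contract is
framed as precision-first rather than recall-complete.

## Weight classification

BMI is computed in imperial units as 703·lb/in². Interval conventions are
half-open everywhere, `[lo, hi)`: BMI 25.0 is overweight and 30.0 obese.
The reference description of the adult bands overlaps at the edges
("18.5 to 25", "25 to 30"), so a convention had to be fixed; half-open
intervals make the bands a partition, and the choice is surfaced here
rather than buried in code.

Teens are classified by LMS BMI-for-age percentile:
z = ((BMI/M)^L − 1)/(L·S) (log form when L = 0), percentile =
100·Φ(z), with L, M and S interpolated linearly in age within sex.
Integer reported ages are converted to months as 12·years + 6 (mid-year).
The percentile bands `<5 / 5–85 / 85–95 / 95+` map onto
underweight/normal/overweight/obese so teens and adults share one
four-level classification downstream.

Two conventions deserve emphasis:

* **Teen/adult boundary.** Teens are 13–19 and adults 20+, following the
  reference table layout of the analytic sample rather than the looser
  "under 18" phrasing that also circulates; the choice is configurable in
  spirit (the records carry `age_class`) but 13–19/20+ is the default
  everywhere.
* **The LMS table is synthetic.** The bundled
  `lms_bmi_synthetic.csv` is a smooth surrogate with realistic L/M/S
  magnitudes on a 6-month grid, 13–19 years, both sexes — shipped so the
  package is self-contained offline. It is *labelled* synthetic
  deliberately: substantive use should swap in a real growth reference
  via `lms_reference(path=)`. Every percentile computation is validated
  against a brute-force numerical inversion of the LMS quantile function
  (agreement to 0.1 percentile points), so the machinery is exact even
  though the coefficients are surrogates.

Congruence uses the mapping {fat, obese} ↔ overweight-or-obese and
{skinny, thin} ↔ underweight-or-normal. The mapping is an explicit,
replaceable object (`congruence_mapping()`) because the exact rule behind
published accuracy figures of this kind is rarely printed; no numeric
claim in this package depends on the default mapping being "the" right
one.

## Posting ratios and FDR control

For a stratum S (any combination of gender, actual class, inquired term)
and category c, the statistic is a ratio of user-level probabilities:

> ratio(S, c) = (k_S / n_S) / (k_all / n_all)

where k counts *users* who posted at least one later question to c. The
user, not the post, is the unit of analysis: heavy posters would
otherwise dominate the ratio. The pooled denominator is the entire asker
population, including the stratum itself — the literal reading of
"compared with the whole population of askers" — so the ratio of the pool
against itself is exactly 1.

Each ratio gets a two-sided exact binomial p-value of k_S out of n_S
against the pooled rate. The test behind such ratios is genuinely
underdetermined in verbal descriptions; the exact binomial was chosen
because it stays valid at the small counts that stratified screens
produce. Benjamini–Hochberg q-values are then computed within each
gender's family of tests (the families are configurable to a single
global family), and a category is *over-expressed* when ratio > 1 and
q ≤ 0.05. The BH step is `stats::p.adjust`; the test suite pins it
against an independent brute-force step-up oracle on all short p-vectors,
and a 100-replicate null simulation keeps the screen's realised false
discovery rate at its nominal level.

## Bullying and the interaction test

Bullying-related posts are found by a word-boundary term matcher
(`bully|bullied|bullying|bullies`). This is intentionally high-recall: a
question about a bullying dog matches. The generator therefore carries an
annotation model — a latent "genuinely bullied" flag drawn at 0.68, the
plausible yield of a manual audit of such matches — so that analyses
which need annotated positives can be exercised; the association
analyses in this package operate at the term-match level, as the
corresponding real-data analyses did.

Per gender × term, the package reports the fraction of askers with a
later bullying post, each stratum compared with the rest of its gender by
a 2×2 chi-squared without continuity correction (Fisher fallback with a
warning when an expected cell drops below 1). The gender × term
interaction is tested as heterogeneity of term effects across genders: a
likelihood-ratio chi-squared between `bullied ~ gender + term` and
`bullied ~ gender * term`. This construction is a reconstruction — the
verbal description "interaction ... significant, chi-squared" admits
several formalisations, and the LRT is the one that generalises cleanly.

A power caveat worth stating plainly: with a realistic term distribution,
"obese" inquirers are a small minority (well under 10% of male askers),
so at 20,000 askers a planted male-obese excess of 1.8% against 0.6%
yields only ~60% power for the df = 3 interaction LRT. The planted
*fractions* themselves are recovered within binomial error at that size;
detecting the interaction reliably needs either stronger heterogeneity or
more askers, and the test suite checks power in a regime where 90%
detection is actually attainable.

## The county layer

Askers are linked to counties via a zip → county map (first-wins on
duplicate zips, with a warning; unlinked records are counted, never
dropped silently). County obesity prevalence — the percentage of obese
residents — is the sole county exposure; "mean county BMI" phrasings are
treated as the same variable. The analyses:

* **Bullying curve.** Equal-width bins (10 by default) over the observed
  obesity range; per-bin bullying fraction, overall and split into
  low-term (skinny/thin) vs high-term (fat/obese) inquirers. U-shape is
  operationalised as a positive quadratic coefficient in a bin-midpoint
  fit weighted by bin size — a verbal "bimodal" claim needs a concrete
  detector, and quadratic curvature is the simplest falsifiable one.
* **Deviation transform.** |x − mean(x)| over the *sample* counties (the
  natural reference when no national figure is supplied).
* **Accuracy split.** Counties split at the median observed prevalence
  (mean-split available); congruence rates compared high vs low per
  gender × actual class, and for normal-weight askers the share asking a
  high-weight term is compared the same way.
* **Income.** Direction from a logistic fit of the bullying flag on
  median income; p-value from a Cochran–Armitage-style trend test over
  income quartiles.

## The synthetic corpus

The generator emulates, with planted ground truth: inquiry posts with
configurable per-field omission and ambiguous-dialect rates; true
anthropometrics drawn lognormally around piecewise-linear median curves
by age and gender (so median reported weight tracks the reference curve
by construction — the default dispersion is sdlog 0.18 for weight and
0.025 for height, a deliberately generous spread); an inquiry-term model
conditioned on gender and true class; later topical posts with
stratum-specific rate multipliers; bullying posts with per-stratum
probabilities and optional county modifiers; and a synthetic county
system (60 counties, obesity 15–45%, income declining with obesity).

Three generator conventions matter for interpretation:

* **Multipliers are pooled-relative.** A planted multiplier m for
  stratum S and category c sets S's rate to m times the configured
  baseline while *deflating* the complement so the population-average
  rate stays at the baseline. The downstream ratio estimator therefore
  converges to m — the property every planted-effect check relies on. If
  planted effects are too large for the population to absorb, the
  complement clamps at zero with a warning.
* **Timestamps.** The inquiry happens at t0; future and bullying posts
  are uniform in (t0, t0 + 365 days]. A one-year horizon is a choice,
  not a given: nothing downstream is sensitive to it because analyses
  condition only on "later than the inquiry".
* **Rendering precision.** Posters report integers (whole pounds and
  inches); metric dialects render at one decimal, so unit round-trips
  carry ≤ 0.11 lb / 0.02 in of representation error. Zero-ambiguity
  corpora reproduce the truth table exactly except for the measure-zero
  set of records whose BMI or percentile sits within that precision of a
  band boundary.

What the generator does **not** emulate: answer posts and voting,
multi-question askers beyond the future-post mechanism, real geography
(county ids are synthetic), non-English text, misspellings, or the
correlation structure of real omissions (fields are omitted
independently). Passing tests on this corpus therefore demonstrate that
the *pipeline* is correct and that planted signals of realistic size are
recoverable — not that the extraction rules would achieve any particular
recall on a real archive.

## Problem sizes and numerical choices

The recovery checks run at 20,000 askers — large enough that planted
ratios of 3–5× on a 1% baseline are estimated with ~10–15% relative
standard error — and the reference-correlation check at 5,000 askers aged
13–20. Null calibrations use 100 replicates at moderate sizes; planted
county-shape checks use 20 replicates at 4,000 askers. Tolerances follow
the statistic: ±3 standard errors for planted-effect recovery (delta
method on the log ratio), binomial error for fractions, 0.1 percentile
points for LMS agreement, and exact equality for deterministic
arithmetic (the keyed-in contingency table, BH vs its oracle at 1e-12).

Ties and degenerate inputs are resolved explicitly: band edges go to the
higher band; duplicate zips resolve first-wins; empty bins carry NA
fractions; a stratum with zero pooled events is flagged not-evaluable
rather than given a ratio; a single-income county system makes the income
association not-evaluable; malformed corpus lines are skipped and counted,
with failure above 1%.

## Known limitations

* The dialect inventory and the congruence mapping are reconstructions;
  both are data (a YAML fixture, an R object) precisely so they can be
  replaced.
* The bundled LMS table is a synthetic surrogate, adequate for exercising
  the percentile machinery but not for clinical classification.
* The interaction test is underpowered at realistic stratum sizes (see
  above); report fractions with their binomial errors alongside any
  interaction p-value.
* Ecological associations over synthetic counties demonstrate estimator
  behaviour only; they carry no substantive claim about real geography.
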