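---
title: "Conversion-funnel engagement analytics for on-demand SMS health services"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conversion-funnel engagement analytics for on-demand SMS health services}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m4rhfunnel)
```

## The problem

m4RH (Mobile for Reproductive Health) is an on-demand ("pull") SMS service:
a subscriber texts the keyword `m4RH` to short code 15014, receives a welcome
menu, and navigates by texting numeric codes — first a submenu code, then a
content code (contraceptive methods, youth topics, role-model stories), or a
3–4 letter ward-name prefix for the clinic locator. Nothing is ever pushed;
every message in the system log is a deliberate user request. That makes the
raw query log — subscriber identifier, timestamp, message text — a complete
census of engagement, and the e-commerce *conversion funnel* a natural frame
for it.

This package turns such a log into the funnel and loyalty indicators used to
evaluate the Tanzanian deployment (September 2013 – August 2016, 4.1 million
queries from about 410,000 subscribers), and pairs the analysis with a
generative simulator so every stage can be validated against known ground
truth without access to any real subscriber data.

## The funnel model

Each user is assigned the deepest stage their cleaned query history ever
reaches:

* **initiated** — texted the keyword (or otherwise entered) but never
  requested a submenu;
* **activated** — requested at least one submenu code;
* **active** — requested at least one content-level item: a content code or
  a ward prefix.

Stages are *nested*: an active user counts as activated in every
denominator. This is forced by the arithmetic of the deployment's own
figures (409,768 → 188,904 → 169,218 users form a chain) and by a practical
feature of the system: experienced users re-entered by texting a content
code directly ("2-step access"), skipping keyword and submenu. A user whose
only event is a bare content code is therefore both activated and active.

With $N$ new users, $A$ activated and $C$ active, the indicators are

* activation rate $= 100\,A/N$, churn (step 1) $= 100\,(N-A)/N$;
* active-use rate $= 100\,C/A$, churn (step 2) $= 100\,(A-C)/A$;
* conversion rate $= 100\,C/N$.

`rate()` and `churn_rate()` round half-up to two decimals, the convention of
the deployment's published tables; the Tanzanian values are 46.10, 53.90,
89.58, 10.42 and 41.30 respectively.

Cohorts are fixed by first contact: a user is "new" exactly once, in the
period (default: calendar year clipped to the study window) containing
their first event, and all later activity attributes depth to that cohort —
this is how the deployment's yearly tables are denominated.

## Cleaning rules

Three exclusion rules are applied in a fixed, documented order, and the
report is a conservation ledger (`raw = kept + removed`, enforced):

1. **Invalid queries** — texts matching no catalog code active on the query
   date, and *compound* messages (keyword and code in one SMS, e.g.
   `m4RH 66`), which the live system answered with nothing.
2. **Successive duplicate menu selections** — within a user's time-ordered
   stream, an event whose parsed code equals the immediately preceding kept
   event's code *on the same local calendar day*. The first occurrence is
   always kept. A day boundary resets the rule, so a next-day revisit of the
   same menu survives; repeated bare keywords are not menu selections and
   are never collapsed. Duplicates are judged on the post-invalid stream, so
   an interleaved garbage message does not shield a duplicate.
3. **Misspelled keywords** — the four recognized variants (`mr4h`, `m4hr`,
   `mrh4`, `mfrh`) are removed, not corrected; no other typos are matched.

The day-boundary reading was chosen because no time window is on record and
because the loyalty indicators elsewhere are month-based; a window-free
calendar-day rule is reproducible and conservative. Cleaning is idempotent
and order-insensitive across users (property-tested).

## Menu catalog and date gating

The catalog is a tree: keyword root, welcome menu, submenus, content codes,
and a ward-lookup node under the clinic submenu. Nodes carry an
`active_from` date: the "About family planning" and "Youth" menus were added
in 2015, and their codes classify as invalid before that date, exactly as
the live system would have behaved. Depth shares for a cohort whose period
predates a node's activation are reported `NA` ("not applicable"), never 0.

Only code 66 (pregnancy-prevention / family-planning methods) is documented
for the production system; the remaining numeric codes in the bundled
catalog are plausible stand-ins, as is the ward-prefix → district map
(`synthetic_ward_districts.csv`), since real ward names are not public.
Both are configuration, not code: any deployment's real catalog can be
supplied as YAML/CSV.

## Interaction and loyalty indicators

* **Return user**: activity in ≥ 2 distinct local calendar months (a global,
  once-per-user property).
* **Repeat user** (month-local): more than one query in the month, *and*
  the in-month queries span at least two distinct items — the published
  definition excludes users "who accessed the same menu items twice". The
  looser reading (any second query) is available behind
  `require_distinct_items = FALSE`; the strict reading is the default
  because it is the most literal one.
* **Acquisition**: everyone active in a month, partitioned exactly into
  new-that-month and returning (property-tested).
* **Inter-query tempo**: per user-day, the first-to-last span (a
  single-query day contributes span 0) and the gaps between consecutive
  same-day queries (singleton days contribute none). The published
  "duration between each query" is read as a pooled mean over all pairs;
  the mean-of-user-means variant is available via `per_user = TRUE`. The
  same dual reading applies to queries-per-user-day and per-month in
  `engagement_summary()`.
* **Temporal profile**: local-time (Africa/Dar_es_Salaam, UTC+3 — all
  timestamps are interpreted in deployment local time) hour-of-day
  histograms in 1 h or 3 h bins, with peak bins flagged.
* **Promotion association**: the share of each year's new (and return)
  users acquired in promotion-flagged months. Years without promotion get
  `NA`. This is purely descriptive — the deployment's promotion schedule is
  too unbalanced for any significance claim, and none is computed.

## The simulator

`simulate_log()` emulates the structure the analysis consumes, with every
generative quantity either taken from the deployment or chosen once and
fixed:

* **Arrivals**: day-level Poisson, 381 new users/day (the deployment's
  average), times 1.5 in promotion months. The multiplier is a compromise:
  the deployment's 2014 promo/non-promo monthly ratio is ≈ 1.1 and its 2015
  ratio ≈ 3; 1.5 gives clearly visible surges without dominating cohorts.
  The default promotion calendar has the recorded 4/10/1/0 months per year;
  the specific months are not on record, so Sep–Dec 2013, Jan–Oct 2014 and
  Jun 2015 were fixed as defaults.
* **Funnel**: latent stage per user with $p(\text{activate}) = 0.4610$ and
  $p(\text{active}\mid\text{activated}) = 0.8958$ — the deployment's
  overall rates; 30% of active users use 2-step direct content access.
* **Retention**: geometric month-to-month continuation at 0.37, matching
  the 36.83% return-user share ($P(\ge 2\text{ months}) = r$). The
  deployment also reports "about 3 months" mean tenure, which a geometric
  model cannot reconcile with that share (it implies 1.6); the observable
  share was chosen as the anchor.
* **Sessions**: each active month holds 1 + Poisson(0.3) sessions, each on
  its own calendar day; queries per session follow a shifted Poisson with
  mean ≈ 5 (the reported within-24 h intensity), with exponential
  inter-query gaps of mean 17 min truncated to 1–45 min. Session start
  times come from a midday (12–14 h) / evening (18–20 h) / uniform mixture
  with weights 0.15/0.13/0.72, reproducing the reported ≈ 22% and ≈ 20%
  peak-bin shares.
* **Noise**: injected post hoc at the deployment's observed rates (invalid
  35,978, successive duplicates 402,780, misspelled keywords 5,663 — each
  over 4,112,460 raw queries). The pre-noise base log is duplicate-free by
  construction (codes never immediately repeat within a session, one
  session per user-day, sessions never cross midnight), so the realized
  injection counts recorded in the ground truth must equal the cleaning
  ledger *exactly*, which the tests assert.

What the simulator deliberately does **not** emulate: message delivery
failure, content comprehension, demographic structure, inter-user
correlation, seasonal drift in tempo, or real ward-name prefixes. Passing
tests therefore demonstrate that the pipeline measures what the generator
encodes — not that real Tanzanian logs satisfy the generator's independence
assumptions.

## Numerical and degenerate-input conventions

* Percentages round half-up to 2 decimals on the 0–100 scale (with an
  epsilon guard against binary-representation ties); all internal
  comparisons use unrounded values.
* A rate with an empty denominator is an error in `rate()` and `NA`
  ("undefined-marked") in tables; `NA` is never conflated with 0.
* Timestamps parse to the second; ties within a user cannot arise from the
  simulator and are broken by input order otherwise.
* A single unparseable row in a raw log is recorded as rejected; a
  multi-row file with *nothing* parseable aborts, since that indicates a
  wrong column mapping rather than a bad row.
* Empty logs flow through every operation, yielding empty tables and `NA`
  statistics rather than errors.

## Validation design and problem sizes

Validation has two halves. First, worked-example reproduction: every
internally consistent published indicator (about 55 numerator/denominator
pairs spanning the funnel, loyalty, promotion, depth, environment and
access-time tables) is re-derived with `rate()`/`churn_rate()`. The
published tables contain a few arithmetic inconsistencies — the removal
counts sum to 3,668,039 kept queries while 3,673,702 is reported; the 2015
repeat-user share prints 67.64 where its own counts give 66.32; one yearly
table pairs the 2013 conversion count with its neighbour's percentage; and
the 2016 active-use pair appears with two different denominators in
different places. These are documented here, asserted nowhere, and never
"reproduced": the package always computes rates from counts.

Second, simulation-based properties: cleaning-ledger conservation on random
logs; funnel monotonicity (new ≥ activated ≥ active) and rate/churn
complementarity on simulated logs; equivalence of `funnel_summary()` with
an independent brute-force per-user scan on logs of ≤ 50 events; exact
equality of injected noise and cleaning removals; byte-identical end-to-end
reruns under a fixed seed; and parameter recovery — about 10,000 simulated
users per scenario (a 90-day window at 115 arrivals/day) at activation
probabilities 0.2, 0.46 and 0.9, each recovered within 4 binomial standard
errors (≈ 2 percentage points at this size). The analysis workflow under
`analysis/` runs the full 36-month window at 12 arrivals/day (≈ 16,000
users); rates are arrival-rate-free, so the scale-down affects only Monte
Carlo error.

## Known limitations

* The parser is stateless: a bare 3–4 letter token is read as a ward prefix
  wherever it occurs, not only after a clinic-submenu prompt. On real logs
  this can misclassify stray short words as ward lookups (and, since ward
  lookups are content-level, upgrade a user's stage). With the bundled
  misspelling list and numeric codes the ambiguity is confined to
  alphabetic 3–4 letter tokens.
* Only the four recorded keyword misspellings are recognized; any other
  typo is invalid. That matches the deployment's cleaning but undercounts
  attempted initiations if other typos were common.
* Return/repeat and all month-based logic use calendar months in local
  time; users active across a month boundary within days are "return"
  users, which inflates loyalty relative to a sliding-window definition.
  This is the published definition, applied literally.
* The repeat-user exclusion is ambiguous in its source; both readings are
  implemented, and the strict one is the default.
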