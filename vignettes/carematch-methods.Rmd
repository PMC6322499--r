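---
title: "Methods: address matching and diagnostic test accuracy in carematch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: address matching and diagnostic test accuracy in carematch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carematch)
```

## The problem

Population health registers record a patient's free-text address but no
dependable structured marker of care-home residency. Classifying each
address as "care-home address" or not is a diagnostic testing problem: a
candidate method (an *index test*) is compared against a manually
adjudicated *reference standard*, and characterised by sensitivity,
specificity, positive predictive value (PPV) and negative predictive value
(NPV). `carematch` implements five index tests, the evaluation machinery,
and a synthetic-data generator so that the full pipeline is runnable and
testable without confidential register data.

## Text canonicalization

All matchers share one canonical form: uppercase, every non-alphanumeric
character replaced by a space, whitespace collapsed, lines joined in order
followed by the postcode. The cleaning rule is deliberately conservative
(punctuation to space, nothing else), because the register's real cleaning
rules are unknown; it is a design choice of this package, not a property of
any source data. Postcodes are handled as opaque keys: uppercased,
space-stripped, and *missing* is a distinct sentinel (`NA`), never the
empty string, so downstream rules treat "no postcode" explicitly — a record
with a missing postcode is classified *negative* by the postcode matcher
rather than excluded, since routine data always contains such records and
exclusion would silently change denominators. The same convention applies
to absent institution-flag codes.

## The five index tests

**Institution flag.** Positive iff the record's flag code is 93
(residential) or 98 (nursing).

**Exact address matching.** Positive iff the normalized concatenated
address equals that of an eligible registry service character for
character. Eligibility means: service type in a configurable care-home
vocabulary, client group in a configurable older-people vocabulary;
sheltered housing, supported accommodation and similar services are out.
Cancelled (historic) services are *included* by default because historic
care-home names are widespread in real address data; they carry a
`cancelled` status so callers can restrict to active registrations.

**Postcode matching.** Positive iff the space-removed postcode equals an
eligible service's postcode.

**Phonics score.** Each word token is encoded with both classic Metaphone
and classic American Soundex (both implemented here, verified against an
independent reference implementation; pure-number tokens get sentinel codes
because house numbers carry no phonetic content). For a record $r$ and
care-home service $s$ with non-stop name tokens $T_s$:

$$\mathrm{score}(r) = 100 \cdot \max_s \Big[ w_{pc}\,\mathbf{1}(\text{postcodes equal})
 + w_{name}\, Q_q\!\big(f(r,s)\big) \Big]$$

where $f$ is the fraction of $T_s$ whose Metaphone *or* Soundex code occurs
among the record's token codes, and $Q_q$ rounds $f$ to $q$ equal levels.
Defaults: $w_{pc} = 0.25$, $w_{name} = 0.75$, $q = 4$, stop tokens
{CARE, HOME, NURSING, THE}. The published description of this method names
the techniques but not the arithmetic, so this formula is a declared
stand-in: every constant is exposed in `phonics_config()`, and the package
makes no attempt to reproduce the original implementation's exact score
lattice or historical cut-off values. The quantization is what gives the
score its characteristic small set of distinct values (about 6 under
defaults on synthetic data; the soft expectation is order 5–20).
Candidates are restricted to the record's health board by default (homes in
different regions often share similar names); `all_boards = TRUE` widens
the search. Ties in the maximum are broken by lowest service id, for
reproducibility.

**Markov score.** Address words and adjacent word pairs are treated as
predictors of a known training flag in a per-board naive Bayes model. For
feature $t$ within a board and feature family (unigram or bigram):

$$w(t) = \log\frac{c_+(t)+\alpha}{M_+ + \alpha V} -
         \log\frac{c_-(t)+\alpha}{M_- + \alpha V}$$

with class feature masses $M_\pm$, the board's class-shared vocabulary size
$V$, and smoothing pseudo-count $\alpha = 1$. A record scores
$100\cdot\mathrm{logistic}(\log(n_+/n_-) + \sum_t w(t))$; unknown features
and unknown boards contribute zero. "Word pairs" are implemented as
adjacent-token bigrams — the simplest reading of the published sketch —
and the score does not consult the registry: linking score-positive
records to a service is a separate reporting join. The intended training
label is a routinely available proxy (the institution flag), not the
reference standard; the model therefore inherits the flag's imperfections,
which is exactly the realistic setting.

## Evaluation statistics

*Exact confidence intervals* are Clopper–Pearson via beta quantiles, the
standard referent of "exact" for binomial proportions (the construction is
config-free; the boundary cases $x=0$ and $x=n$ pin the respective limit).
A zero denominator (e.g. PPV of a method that never calls positive) raises
a typed condition and is reported as "–" rather than NaN.

*ROC/AUROC.* The positivity convention is score ≥ threshold, matching
"cut-off ≥ x" reporting. The ROC curve evaluates every distinct observed
score plus a sentinel above the maximum, carrying the full confusion table
at each threshold. AUROC is computed exactly as the Mann–Whitney
probability (ties count one half) via mid-ranks; with that tie convention
it equals the trapezoidal area under the computed curve, and both are
tested against an exhaustive pairwise oracle. The standard error is
Hanley–McNeil by default — the conventional choice of the statistical
suites this analysis style comes from — with a DeLong placement-value
option (`se_method = "delong"`); limits are Wald, clipped to [0, 1].

*Cut-off rules.* (i) constrained: among thresholds with PPV above a floor
(default 0.90), maximize sensitivity; if none qualifies, fall back to the
max-PPV threshold and flag `constraint_met = FALSE`; thresholds that call
nobody positive are inadmissible. (ii) Youden: maximize
$J = \mathrm{sens} + \mathrm{spec} - 1$. (iii) sensitivity = specificity:
minimize the gap, reporting *no* threshold when the best gap exceeds a
tolerance (default 0.02) — coarse score lattices genuinely may have no
crossing, and the rule must be able to say so. All ties break to the
lowest threshold.

*Sample size.* $n = \mathrm{round}\!\left(z_{1-\alpha/2}^2\,
S(1-S) / (d^2\,\mathrm{prev})\right)$ for anticipated sensitivity $S$,
marginal error $d$ and prevalence $\mathrm{prev}$. Rounding is to the
nearest integer, not the ceiling: with $S=0.85$, $d=0.05$,
$\mathrm{prev}=0.04$ the formula gives 4897.86, and only nearest-integer
rounding reproduces the published planning figure 4898 this package uses
as a worked-example target.

## The synthetic world

`generate_registry()` builds home names from a small versioned stem-by-
suffix grammar, gives each home a three-line site address and a UK-shaped
postcode, adds cancelled predecessors (same site, different name) for a
configurable fraction of homes, and a share of ineligible sheltered-housing
services. `generate_sample()` then makes each of `n_records` records a true
care-home address with probability `prevalence`; positives copy a home's
address and are corrupted by independent noise processes; negatives are
private addresses from a mostly-disjoint street-name pool (15% of street
names reuse home-name stems — the realistic source of phonetic false
positives), with a small share placed on a care-home postcode.

Default rates are the package's stated world, chosen once as plausible for
GP-recorded addresses and not tuned to any test outcome:

| parameter | default | role |
|---|---|---|
| `prevalence` | preset 0.043–0.111 | per-sample care-home share of 5,000 records |
| `flag_sensitivity` | preset 0.558–0.893 | flag code present on a true resident |
| `flag_false_rate` | preset 0.0002–0.002 | flag code on a non-resident; fixed values implying flag PPV ≈ 0.977–0.996, computed once from the implied PPVs and then frozen (no run-time calibration) |
| `typo_rate` | 0.35 | one character swap/delete/insert in one line |
| `abbreviation_rate` | 0.30 | dictionary substitution (HOUSE→HSE, STREET→ST, …) |
| `dropped_line_rate` | 0.15 | one address line blanked |
| `missing_postcode_rate` | 0.02 | postcode blanked |
| `shared_postcode_rate` | 0.016 | negative household on a care-home postcode — the sole designed source of postcode false positives |
| `historic_name_rate` | 0.10 | positive recorded under the cancelled predecessor's name |

What a green test establishes — and what it does not. The generator
reproduces the *qualitative* structure: postcode matching more sensitive
but less precise than the flag; phonetic and probabilistic scores
discriminating strongly (AUROC > 0.85); flag metrics recovering their
configured values within exact CIs across replicates. It does **not**
reproduce real address-noise distributions: real registers contain free-
text idiosyncrasies (flat numbering, resident names, non-standard line
order) that no small grammar captures. In particular, under default noise
roughly 40% of synthetic positives survive all perturbations and still
match exactly, whereas on real data exact matching failed essentially
completely; the package covers that published finding as a limiting
property (with per-record perturbation probability 1, exact-match
sensitivity is exactly 0) rather than as the default world. Accuracy
numbers obtained on synthetic samples test the machinery, not any real
method's field performance.

## Numerical choices and degenerate inputs

- All rounding uses R's `round()` (round-half-to-even), including the
  Phonics quantization and final integer score; the brute-force oracle in
  the test suite applies the same convention independently.
- Phonics with an empty candidate set, an empty address, or a service name
  consisting only of stop tokens scores 0; `best_service` is reported only
  for strictly positive scores.
- Markov training requires both classes and a positive `alpha`; a board
  seen only at scoring time contributes nothing beyond the prior.
- `roc_curve()` and `auroc()` refuse single-class truth with a typed
  validation error.
- Determinism everywhere: a single seed drives registry, sample, and all
  downstream outputs; byte-identical reruns are an acceptance criterion.
- CSV/JSON round-trips preserve calls and models exactly; the CLI maps
  typed conditions to exit codes (2 config, 3 data).

## Known limitations

- The Phonics arithmetic and the Markov feature/normalization details are
  this package's concrete instantiations of briefly described techniques;
  published historical cut-offs (≥13, ≥29.6) are intentionally out of
  scope and should not be expected to transfer.
- Whether the original Markov method modulated its score by registry
  proximity is unclear from the published wording; here the score is
  registry-free by design, with linkage as a separate join.
- The registry eligibility vocabularies are configurable stand-ins; the
  real regulator's service-type taxonomy is richer.
- No UK postcode grammar validation, no geocoding, no gazetteer
  standardization; postcodes are opaque keys.
- The exact-CI construction used by the original analysis suite is not
  named in the source material. Clopper–Pearson reproduces all the
  recoverable point estimates at printed precision and most interval
  limits within 0.1–0.2 percentage points, but PPV limits can differ by up
  to ~0.5pp — consistent with a different exact-interval variant having
  been used there.
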