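---
title: "Screened association-rule mining between drugs and laboratory adverse events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screened association-rule mining between drugs and laboratory adverse events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrmine)
```

## The problem

Hospital EHR data yield, per patient, a set of administered drugs
(normalized to active ingredients) and a set of laboratory-derived
adverse events (AEs). Two questions matter for pharmacovigilance: which
drugs or drug pairs are followed by an AE *more* often than the cohort
baseline (harmful, "positive" rules), and which are followed by an AE
*less* often (protective, "negative" rules — e.g. an adjuvant
co-medication that spares the hematopoietic system). A plain
support/confidence Apriori miner answers neither question well: it
retains any frequent pairing however unremarkable its conditional rate,
and it has no notion of direction at all.

`adrmine` implements the two-step screened miner this package is built
around, together with everything needed to exercise it end to end:
severity grading of laboratory values, the conventional baseline miner,
a rank-sum comparison report, and a synthetic cohort generator with
known ground truth.

## The model and its assumptions

**Step 1 — frequent itemsets.** Transactions are per-patient drug
*sets*: a patient contributes at most one count to an itemset's support
regardless of repeat prescriptions. Frequent itemsets up to
`max_antecedent` drugs are found by the classic level-wise
join/prune/count loop (`mine_frequent_itemsets()`), exploiting
anti-monotonicity of support. Supports are exact, not sampled.

**Step 2 — the screen.** Every frequent itemset is crossed with every
AE term and summarized as the 2×2 table (a, b, c, d) of exposure by
occurrence, with the *full cohort* as denominator. The screening
statistic is the signed root of the Pearson chi-square,

$$\mathrm{comp} = \operatorname{sign}(ad-bc)\,\sqrt{\frac{n(ad-bc)^2}{(a+b)(c+d)(a+c)(b+d)}} = \sqrt{n}\,\varphi,$$

where $\varphi$ is the phi coefficient. A rule is kept when its
confidence $100\,a/(a+b)$ reaches `min_cof` and $|\mathrm{comp}|$
exceeds the threshold `min_tev`; its sign classifies the direction.
Being a per-pair independence test, the screen assumes the usual 2×2
chi-square conditions; `validity_check()` (n > 40, all expected counts
≥ 5) is evaluated per rule and carried on the output rather than used to
drop rules silently.

The rules are *associational only*. Exposure precedes nothing in this
data model — no temporal sequencing, confounder adjustment, or causal
claim is made, and none should be read into the output.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `min_sup` | 165 | patients (or fraction of n) | minimum antecedent support; fractions convert by `floor(f·n)`, so 0.01 on a 16,527-patient cohort gives the default 165 |
| `min_cof` | 10 | % | minimum rule confidence |
| `alpha` | 0.05 | — | significance level behind `min_tev` |
| `threshold_mode` | `"paper"` | — | `"paper"` compares \|comp\| to the χ²(1) critical value (3.841 at 0.05); `"sqrt_scale"` to its root (1.960) |
| `max_antecedent` | 2 | drugs | largest antecedent itemset |
| `support_def` | `"antecedent"` | — | rule support = antecedent support / n; `"joint"` uses a/n |
| `p_adjust` | `"none"` | — | optional Benjamini–Hochberg screen on the implied two-sided p-values |

Two of these deserve comment, because the method's original formulation
left them genuinely open and the package had to fix a reading.

**The form of `comp`.** The statistic is implemented as
$\operatorname{sign}(ad-bc)\sqrt{\chi^2}$, i.e. on the root (signed-z)
scale. The alternative reading — a signed χ² itself — is irreconcilable
with the reference worked examples this package reproduces: for the
reconstructed cisplatin→anemia table the signed root gives 27.3 against
a published 26.897 (1.5% off, consistent with the rounding in the
published marginals), while a signed χ² would give ≈ 746. The root-scale
reading is also the one under which `comp` has a clean interpretation as
$\sqrt{n}\,\varphi$, a z-like quantity.

**The threshold scale.** `threshold_mode = "paper"` follows the
method's stated comparison of `comp` against 3.841 — literal, but
conservative, since it compares a root-scale statistic with a
χ²-scale critical value (equivalent to a two-sided test at
α ≈ 1.2 × 10⁻⁴). `"sqrt_scale"` compares against
$\sqrt{3.841} = 1.960$ and is the calibrated choice: under the null the
flag rate is α. Both are offered; the default stays literal, and the
type-I simulations below quantify the difference instead of hiding it.

**Rule support.** Published worked examples show near-constant support
across different AEs for a fixed drug, which identifies support as the
*antecedent* support fraction, not the joint one; `support_def`
preserves the joint alternative for users who want the
Agrawal–Srikant convention.

## Severity grading

`derive_ae_records()` maps laboratory results to graded AEs through
user-supplied rules (`grade_rule()`, YAML config): per rule a direction
(above/below), up to four boundaries ordered toward severity, and a
boundary type (absolute, multiple-of-reference-limit, or offset).
Conventions fixed here: a value exactly on a boundary takes the more
severe grade; a patient's record is the worst grade across their
measurements (idempotent rollup); relative rules applied to measurements
without a reference limit are tallied as ungradeable rather than guessed.
The shipped `grading_example.yaml` is an illustrative set of thresholds
in the shape of CTCAE v4.03 laboratory criteria — deliberately *not*
asserted to be the official table, which institutions license and
maintain themselves. Whether grading should use absolute or
baseline-adjusted reference ranges is a study-design question the config
format leaves to the user (both boundary types are expressible).

`incidence_table()` reports per (SOC, term) the worst-grade counts,
their sum as the grand total, and the percentage of the cohort rounded
half-up to two decimals — the rounding convention under which published
incidence percentages (e.g. 6,426/16,527 → 38.88%) reproduce exactly.

## The synthetic cohort generator

`generate_cohort()` draws, per patient: independent Bernoulli exposures
per drug; optional co-prescription pairs lifted toward a target joint
probability (`boost` × product of marginals, capped at the smaller
marginal) by promoting non-joint patients — a deliberately simple
mechanism that creates the two-drug antecedents the miner must find
without a full dependence model; AE occurrence from a logistic model,
$\operatorname{logit} p = \operatorname{logit}(\text{baseline}) +
\sum_{\text{exposed}} \log \mathrm{OR}$, effects combining additively on
the log-odds scale; and a grade from a per-AE distribution over 1..4
(default 0.60/0.25/0.10/0.05, the mild-skewed profile typical of
laboratory AEs). Everything is reproducible from `seed`, and the truth
object records every non-unit odds ratio for scoring with
`evaluate_against_truth()`.

What the generator does *not* emulate: longitudinal dosing and
per-cycle attribution, correlated lab panels, time-to-event structure,
or confounding by indication (an exposure–AE link induced by disease
severity rather than the drug). Tests passing on this generator
therefore show that the machinery is correct and calibrated under clean
Bernoulli/logistic sampling — not that mined rules on real EHR data are
causal or unconfounded.

## Simulation design and problem sizes

The validation suite runs at sizes chosen to make binomial noise small
relative to the effects being checked while keeping the full suite quick
to run routinely:

- **Type-I calibration**: 200 null cohorts (all OR = 1), n = 2,000,
  20 drugs at prevalence 0.2, 10 AEs at baseline 0.2, singleton
  antecedents. Singletons are used deliberately: the calibration target
  is the per-2×2-test size of the screen, and two-drug antecedents add
  correlated tests (shared margins) without changing that size. Observed
  flag rate at `sqrt_scale` is compared to α within twice its standard
  error over replicates; the `paper`-mode rate sits far below it, as its
  effective α predicts.
- **Recovery**: 50 cohorts of n = 5,000 with planted OR = 3 (baseline
  0.2) and OR = 1/3 (baseline 0.3) pairs, exposure prevalence 0.2. The
  protective baseline of 0.3 is an arithmetic necessity, not a tuning
  choice: a rule's confidence under OR = 1/3 is
  $\operatorname{plogis}(\operatorname{logit}(0.3) - \log 3) \approx 0.125$,
  which clears the 10% confidence filter, whereas a 0.2 baseline would
  put protective rules *below* the filter — a real interaction between
  `min_cof` and negative-rule discovery that users should keep in mind
  (negative rules are systematically low-confidence; consider lowering
  `min_cof` when hunting them).
- **Oracle equivalence**: the miner is checked against an independent
  exhaustive enumerator (a superset-sum transform over transaction
  bitmasks) on 100 random databases of up to 12 items and 200
  transactions; the algebraic identities comp² = χ² and shortcut-χ² =
  expected-count-χ² are asserted to 10⁻⁹ relative on 1,000 random
  tables.

## Numerical and degenerate-case choices

- A candidate pair with a zero table margin (e.g. an antecedent absent
  from the cohort, or an AE everyone has) has no defined statistic; it
  is carried with `NA` statistics and can never be retained, and
  `chi_square()` on such a table raises an error rather than returning
  0/0.
- Ties in rule ranking (equal |comp|) break lexicographically by
  antecedent then consequent, making every output ordering
  deterministic.
- `rank_sum_test()` wraps the standard Wilcoxon–Mann–Whitney
  machinery: exact enumeration for combined samples ≤ 12 without ties,
  otherwise the normal approximation with tie and continuity
  correction. Which variant produced any particular published p-value
  is generally unknowable; the report prints the variant used.
- Record validation implements case deletion only (drop rows failing
  consistency, count per rule). Estimation and variable/pairwise
  deletion are procedures that cannot be reproduced mechanically from a
  spec and are rejected with a clear message rather than approximated.
- The patient universe of a database built from files is the union of
  ids across tables; when the true cohort includes silent patients
  (neither exposures nor AEs), the roster can be supplied explicitly
  (`patients =`, or `--patients` in the CLI) so denominators are
  honest. The generator writes this roster alongside its tables.

## Known limitations

Rules are correlational; no multiple-testing control is applied by
default (matching the method as formulated — the `p_adjust = "BH"`
switch exists for responsible exploratory use); wall-clock comparisons
between the two miners are reported but hardware-dependent; and the
conventional miner's "direction" labels are post-hoc sign annotations
added for comparability, not something a support/confidence miner can
itself distinguish.
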