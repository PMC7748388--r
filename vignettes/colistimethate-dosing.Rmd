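---
title: "Colistimethate dosing: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colistimethate dosing: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colidose)
```

## The clinical problem

Colistimethate (CMS) is the intravenous prodrug of colistin, a last-line
antibiotic for multidrug-resistant gram-negative infections. Its dosing is
unusually error-prone for three reasons: the prodrug is renally cleared
while the active moiety is not, so the maintenance dose must track renal
function and any dialysis; the therapeutic window is narrow, with
nephrotoxicity the dose-limiting toxicity; and the same physical dose is
labelled in three conventions (mg colistin base activity, million
international units, mg CMS) that differ by large factors. `colidose`
implements the published bedside algorithm for adults — loading dose,
renal-function-banded maintenance dose with dialysis supplements, a hard
safety cap — with the unit handling made explicit and testable.

## The dosing model

**Loading dose.** `CBA (mg) = Css,avg (mg/L) × 2.0 × IBW (kg)`. The factor
2.0 L/kg plays the role of an apparent volume term per unit target
concentration; `Css,avg` is the target average steady-state concentration
of formed colistin. Ideal body weight (Devine: 50 kg for males, 45.5 kg for
females, + 2.3 kg per inch over 60) is used in all cases, not the lower of
actual and ideal weight. The first regular daily dose follows 12 hours
after the load, since formed colistin accumulates slowly.

**Target concentration.** `Css,avg` is restricted to the grid 0.5–4.0 mg/L
in 0.5 mg/L steps, default 2.0 mg/L — a suitable initial target when the
pathogen's colistin MIC is ≤ 2 mg/L. Off-grid values are rejected rather
than silently rounded: on a drug this toxic, a typo should fail loudly.

**Maintenance dose.** The baseline daily dose is `Css,avg × f(CrCl)` with
CrCl from Cockcroft–Gault and `f` a non-decreasing band table in mg CBA/day
per mg/L of target. The table is *configuration data*, not code
(`dosing_model()`, `read_dosing_model()`): the engine validates any table
for gap-free coverage of `[0, ∞)` and monotonicity at load time and is
otherwise agnostic to the coefficients. The packaged default
(`inst/extdata/nation2017_model.yaml`) transcribes the 2017 population-PK
dosing guidance for intravenous colistin (Nation et al., *Clin Infect Dis*
2017), whose published table is stated for a 2 mg/L target; we store it per
mg/L since the recommended dose scales linearly in the target.
Institutions should review that file against the publication — it is a
plain, commented YAML file precisely so that it can be audited and swapped.

**Dialysis supplements.** All three modalities remove CMS, so sessions are
compensated by a supplement of 10% of the baseline daily dose per hour of
dialysis. The published IHD recommendations (20% after a 2-h session, 50%
after a 5-h session, added after the session on dialysis days only) both
lie exactly on this 10%/h line, and SLED/CRRT are stated as 10%/h, so a
single rule reproduces every published value. IHD session lengths outside
2–5 h are computed on the same line but flagged with a warning, since they
fall outside the published range. On an IHD non-dialysis day the supplement
is zero and only the baseline applies.

**Safety cap.** The cap (default 300 mg CBA/day = 9.0 million IU) is
applied to the loading dose and to the *post-supplement* daily total — we
read "the calculated daily dose" as the dose actually administered. The
uncapped value is preserved in every record for transparency, and a capped
recommendation always carries the "Immediate Attention" warning. Whether
the baseline should additionally be capped before supplementation is
genuinely open; capping only the final total is the more conservative
reading (it never yields a *larger* administered dose).

## Parameters and units

| Parameter | Units | Default | Notes |
|---|---|---|---|
| `css` | mg/L | 2.0 | grid 0.5–4.0 by 0.5 |
| height | in or cm | — | cm ÷ 2.54 |
| weight | kg or lb | — | lb × 0.45359237 |
| serum creatinine | mg/dL or µmol/L | mg/dL | µmol/L ÷ 88.4 |
| `max_daily_cba` | mg CBA | 300 | loading and daily ceiling |
| dose units | — | — | 33.3 mg CBA = 1 MIU = 80 mg CMS |

The conversion factors are pinned at exactly 33.3 and 80. Physically they
are approximations (the IU is defined microbiologically), but pinning the
printed constants makes every conversion reproducible and exactly
invertible, which matters more in a calculator than a fourth significant
figure. All engine arithmetic runs in mg CBA; conversion happens only at
the boundaries, and display rounds mg to the nearest integer *before*
converting to million IU (one decimal), so 300 mg CBA always reads 9.0 MIU.

## Numerical and design choices

- **Cockcroft–Gault body weight**: actual body weight, matching a single
  bedside weight input. The canonical CG form is used; CKD-EPI/MDRD
  estimate GFR in normalised units and are not substitutes here.
- **CrCl clamp**: ages ≥ 140 y make the CG numerator non-positive; the
  result clamps to 0 mL/min with a warning instead of raising, because
  end-stage inputs are clinically real. CrCl is not capped above: any
  ceiling on high clearances belongs to the band table, and the default
  table is flat above 90 mL/min.
- **IBW floor**: below 60 inches the Devine line extrapolates downward and
  can produce absurd loading doses; the result is floored at the
  sex-specific base constant with a warning.
- **Age plausibility**: ages outside 18–120 y warn rather than error (the
  tool targets adults).
- **Band semantics**: with `interpolate = FALSE` the table is a step
  function with exclusive upper bounds and an unbounded top band; with
  `interpolate = TRUE` the rows are piecewise-linear knots held constant
  beyond the range. The step form matches how banded dose tables are
  published; the interpolating form exists for models stated as continuous
  functions (and makes the identity table `f(CrCl) = CrCl` expressible for
  testing).
- **Determinism**: there is no randomness anywhere in a dosing path; the
  only RNG in the package is the synthetic patient generator, which takes
  an explicit seed and restores the caller's RNG state.
- **History store**: one JSON object per line in a local file. Plain text
  was chosen over a database deliberately: the privacy contract is "local,
  private, permanently deletable", and a greppable file the user can read
  and `purge_store()` can delete wholesale satisfies it transparently.
  Timestamps are UTC; patient identifiers are free text and the
  documentation advises pseudonyms.

## The synthetic panel and the oracle

The engine is validated the way bedside calculators are: against
independent manual arithmetic. `generate_panel()` draws reproducible
synthetic adults — uniformly in age 18–90 y, height 55–78 in, weight
40–150 kg, serum creatinine 0.4–8 mg/dL, targets from the 0.5–4 grid — in
a balanced default design of 8 patients with 2 on each modality
(none/IHD/SLED/CRRT), mirroring the validation layout of the original
calculator; IHD sessions are 2 or 5 h, SLED 6–12 h, CRRT 24 h.
`oracle_dose()` recomputes the loading dose and capped daily total as one
straight-line arithmetic pass sharing no code with the engine, and
`run_validation()` compares the two at a 0.5 mg CBA tolerance — the level
at which display rounding could explain a difference.

```{r validation}
res <- run_validation(generate_panel(seed = 1), default_dosing_model())
res
attr(res, "all_pass")
```

The test suite runs this comparison on the 8-patient panel and on 1000
random patients. What such a pass shows is *internal* consistency — the
engine implements the stated equations exactly. What it cannot show is
anything about real patients: the generator samples covariates uniformly
and independently (no age–creatinine correlation, no realistic case mix),
and the published appendix of concrete validation patients is not
reproduced here. Clinical accuracy rests on the published equations and on
the correctness of the transcribed band table, not on these tests.

## Problem sizes

The property suites run the full pipeline on panels of 8, 200 and 1000
synthetic patients, sizes at which the whole suite completes in seconds
while still exercising every modality and the cap on both sides.

## Known limitations

- The default maintenance table should be verified against its source
  publication before clinical use; the package deliberately keeps it in an
  auditable data file.
- No therapeutic drug monitoring, exposure simulation, inhalational or
  pediatric dosing, and no polymyxin B: the scope is the intravenous adult
  colistimethate algorithm.
- This is decision support, not a prescriber: outputs are recommendations
  in both unit conventions with their warnings, and clinical judgement
  remains with the user.
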