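# colidose

Intravenous colistimethate dosing for critically ill adults, as an R
package with a command-line interface.

Colistin (polymyxin E) is a last-line antibiotic against multidrug-resistant
gram-negative pathogens. It is administered intravenously as the inactive
prodrug colistimethate (CMS), which is predominantly renally cleared while
the formed colistin is not — so the maintenance dose depends strongly on
renal function and on any renal replacement therapy (RRT). Adding to the
difficulty, the same dose is labelled three different ways around the world
(mg of colistin base activity, million international units, mg of CMS), a
known source of serious prescribing errors. `colidose` packages the
published bedside dosing algorithm for this drug:

- **Loading dose** (all patients):
  `CBA (mg) = Css,avg (mg/L) × 2.0 × IBW (kg)`,
  where `Css,avg` is the target average steady-state colistin concentration
  (selectable 0.5–4.0 mg/L in 0.5 steps, default 2.0) and IBW is the Devine
  ideal body weight `50 kg (45.5 kg for females) + 2.3 × inches over 60`.
  The first regular daily dose follows 12 h later.
- **Maintenance daily dose**: creatinine clearance by Cockcroft–Gault
  (`(140 − age) × weight / (72 × SCr)`, ×0.85 for females), then a baseline
  daily dose `Css,avg × f(CrCl)` from a configurable renal-function band
  table (the packaged default transcribes the 2017 population-PK dosing
  guidance, Nation et al., *Clin Infect Dis* 2017), given as two divided
  doses 12 h apart.
- **Dialysis supplements**: 10% of the baseline daily dose per hour of
  dialysis — 20% after a 2-h and 50% after a 5-h intermittent hemodialysis
  session on a dialysis day, and 10%/h during SLED or CRRT.
- **Safety cap**: any loading or daily total above 300 mg CBA (9.0 million
  IU) is capped at 300 mg with an "Immediate Attention" warning; the
  uncapped value is kept in the record.
- **Dual-unit output**: every dose is reported in both mg CBA and million
  IU (33.3 mg CBA = 1 million IU = 80 mg CMS).
- **Local history**: calculations can be saved to, listed from and
  permanently purged from a plain JSON-lines file on the local machine; no
  operation ever touches the network.

## Worked example

From R:

```r
library(colidose)
loading_dose(css = 2.0, ibw = ideal_body_weight("male", 70))
#> Loading dose recommendation
#>   Recommended dose:     292 mg CBA (8.8 million IU)
#>   - Administer the first regular daily dose 12 hours after the loading dose.
```

2 mg/L × 2.0 × 73 kg = 292 mg CBA: the loading dose for a 70-inch male
targeting 2 mg/L, shown in both unit conventions.

From the shell (the CLI lives at `inst/cli/colidose.R`; after installation,
`system.file("cli", "colidose.R", package = "colidose")`):

```sh
$ Rscript inst/cli/colidose.R daily --sex female --age 70 --weight 60 --scr 2.2 --css 2
Daily maintenance dose recommendation
  Creatinine clearance: 22.5 mL/min
  Baseline daily dose:  175 mg CBA (5.3 million IU)
  RRT supplement:       0 mg CBA (0.0 million IU)
  Recommended dose:     175 mg CBA (5.3 million IU)
  Give 88 mg CBA (2.6 million IU) per 12 h
  - Give as two divided doses 12 hours apart.
```

Cockcroft–Gault gives 22.5 mL/min for this patient, which falls in the
20–30 mL/min band of the default table (87.5 mg/day per mg/L of target);
at a 2 mg/L target that is 175 mg CBA/day, split 12-hourly. A 5-h dialysis
session would add 50% of that baseline afterwards:

```sh
$ Rscript inst/cli/colidose.R daily --sex male --age 65 --weight 72 --scr 1.5 \
    --css 2 --rrt ihd --hours 5 --dialysis-day
Daily maintenance dose recommendation
  Creatinine clearance: 50.0 mL/min
  Baseline daily dose:  245 mg CBA (7.4 million IU)
  RRT supplement:       122 mg CBA (3.7 million IU)
  Recommended dose:     300 mg CBA (9.0 million IU)
  Give 150 mg CBA (4.5 million IU) per 12 h
  ! Immediate Attention: the calculated dose exceeds the maximum recommended
    300 mg CBA (9.0 million IU) and has been capped at 300 mg CBA due to
    safety considerations.
  - Give as two divided doses 12 hours apart.
  - Add the supplemental dose after the dialysis session ends.
```

Here the supplemented total (367.5 mg) exceeds the ceiling, so the
administered dose is capped at 300 mg CBA and the warning banner is raised.

Other subcommands: `loading`, `history` (`--save/--patient-id/--store`,
`--purge --yes`), `convert` (between `mg_cba`, `miu`, `mg_cms`) and
`validate` (run the synthetic mock-patient panel through the engine and the
independent arithmetic oracle; `--seed`, `--n`, `--out table.csv`). Exit
codes: 0 success, 1 runtime/storage error, 2 usage/validation error.

## History store schema

One JSON object per line: `id` (integer, monotonically increasing),
`patient_id` (free text — use pseudonyms), `timestamp` (ISO-8601 UTC),
`app_version`, `inputs` (the demographic/target/RRT snapshot) and
`recommendation` (uncapped, capped, supplement and per-12-h doses in mg
CBA, warnings and notes). The file is local and plain text; `purge_store()`
deletes it permanently.

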