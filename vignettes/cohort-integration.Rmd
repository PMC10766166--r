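---
title: "Integrating annotated cohort databases into SDTM: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating annotated cohort databases into SDTM: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdtmbridge)
```

## The conversion model

`sdtmbridge` treats SDTM conversion as a metadata-driven rewrite of a long
table of field values. An ODM export is reduced to two tables: an item
table (field oid, name, data type, code-list reference, SDTM annotation)
and a record table with one row per `(subject, item group, repeat, item)`
value. The annotation attached to a field is a triple
`DOMAIN.VARIABLE[.TESTCODE]`; parsing it yields a *mapping directive*, and
the set of directives is the entire specification of the conversion.
Everything else is mechanical:

1. every annotated value is normalized (code-list recoding for coded
   fields, ISO 8601 for dates, whitespace trimming otherwise);
2. values are grouped into logical records: all directives sharing
   `(domain, testcode)` for a given `(subject, repeat)` populate one row.
   This grouping rule is what makes `CM.CMOCCUR.PSL` and `CM.CMSTDTC.PSL`
   describe a single prednisolone row, and what turns one horizontal
   record carrying *k* distinct test codes into *k* vertical findings
   rows;
3. rows receive identifiers (`STUDYID`, `DOMAIN`,
   `USUBJID = study_id + "-" + subject_key`) and, for findings,
   interventions and events domains, a within-subject `--SEQ`.

The assumptions are deliberately minimal: one annotation per field, a
closed world of implemented domains (`DM`, `LB`, `VS`, `CM`, `MH` and
their `SUPP--` companions), and subject-level linkage for supplemental
qualifiers. Supplemental rows carry empty `IDVAR`/`IDVARVAL` because the
disease-specific items they hold (histology scores, family history,
therapy counts) describe the subject, not a particular parent record —
there need not even be a parent dataset for the referenced domain, and in
the motivating use case `SUPPMH` exists with no `MH` dataset at all.

## Domain classes and row shapes

`classify_domain()` assigns each code one of five observation classes,
which select the row constructor:

* **special purpose** (`DM`) — subject-level; directives pivot into one
  row per subject, no `--SEQ`;
* **findings** (`LB`, `VS`) — vertical; `--TESTCD` is the annotation's
  test code, each directive fills its own variable (`LBORRES`, `LBDTC`)
  within the keyed row. A date-only mapping such as a biopsy date emits a
  row with an empty `--ORRES` rather than attaching the date to other
  tests' rows: there is no defensible cross-test join rule, and local
  grouping keeps every cell auditable back to one source field;
* **interventions** (`CM`) and **events** (`MH`) — keyed like findings,
  with the test code as the topic (`CMTRT`/`MHTERM`, optionally replaced
  by a configured display label);
* **supplemental** (`SUPP--`) — one `QNAM`/`QVAL` row per value, `QNAM`
  limited to 8 characters by the SDTM naming rule, `QLABEL` from a
  configurable label map.

Variable order is the SDTM identifier block first
(`STUDYID, DOMAIN, USUBJID, --SEQ`) followed by the remaining variables
alphabetically; `SUPP--` datasets instead use the fixed SDTMIG column
sequence (`STUDYID, RDOMAIN, USUBJID, IDVAR, IDVARVAL, QNAM, QLABEL,
QVAL`), which readers of supplemental datasets expect.

## Numerical and degenerate-input choices

* **Sequence tie-break.** `--SEQ` sorts by source repeat key, then test
  code alphabetically, then source field oid — fully deterministic, so two
  runs on the same input produce byte-identical CSVs.
* **Missing values.** A blank or absent `ItemData` value produces no cell
  and no row; the package never invents a missing-value code. A
  consequence worth knowing: the conservation property (number of
  non-missing annotated source values equals the number of populated
  mapped cells) holds exactly whenever no row-level errors occur.
* **Collisions.** Two source fields competing for the same logical cell is
  a mapping defect, reported per row with both oids named. An identical
  value restated by the *same* field across repeats of a subject-level
  domain collapses silently (a vertical study restates sex at every
  visit); genuinely conflicting restatements are collisions.
* **Row-level vs run-level failures.** Unmapped codes and unparseable
  dates abort the affected value and accumulate in a run report (the
  batch-audit convention of clinical data management); structural defects
  — unresolvable code lists, annotations violating class rules, `QNAM`
  over 8 characters, an empty directive set — abort the run.
* **Dates.** Four dialects (`slash`, `hyphen`, `compact`, `auto`), reduced
  precision preserved (`1985/03` becomes `1985-03`), full calendar
  validation (February 30th is an error, not a wish).
* **Error taxonomy for the CLI.** Exit 0 success, 1 data errors, 2
  usage/configuration errors — so a pipeline can distinguish "fix your
  data" from "fix your config".

## Controlled terminology

Only a minimal CT subset ships with the package (`SEX`: M/F/U; `NY`: Y/N),
used to validate that a ct-flavoured code list does not invent submission
values. The full CT catalog is versioned and external, so all other lists
come from configuration (YAML; a commented example ships in
`inst/extdata/`). Consistency across studies is judged by the *image* of a
code list — the set of submission values it can produce — not by its
source codes, since recoding differently coded sources onto one value set
is precisely what makes them compatible. The CT version in use is a
configuration concern with no default semantics.

## Define-XML

`write_define()` emits Define-XML 2.0 with ItemDef OIDs mirroring the
annotation syntax (`IT.LB.LBORRES.CREAT`), which keeps the mapping legible
in both directions: an OID in the Define document reads as the annotation
that produced the data. Value-level metadata is emitted for findings
domains only, where test codes genuinely partition a variable's meaning.
Define code lists enumerate submission values (what is in the data), so an
integrated database gets one shared `SEX` list rather than one per
source coding. The invariant the tests enforce is exact two-way agreement
between the Define inventory and the CSV headers.

## The synthetic cohorts

The built-in profiles emulate the structural situation the package is
designed for: three databases on the same disease (IgA nephropathy
fixtures: biopsy-centred labs, Oxford M/E/S/T lesion scores, tonsillectomy
and steroid-therapy history) built by different groups.

* **Cohort A** is vertical with repeated measurements — its lab and
  vital-sign fields sit in a repeating item group (1–3 repeats per
  subject) — and writes slash dates; sex is coded 1/2, yes/no flags 1/0,
  Oxford scores numerically.
* **Cohort B** is horizontal, hyphen-dated, codes sex 0/1 and flags 1/2,
  and does not collect serum creatinine, age, or tonsillectomy dates.
* **Cohort C** is horizontal, compact-dated (`19850312`), codes flags and
  Oxford scores as literal strings, and is the broadest collector.

The 14 items present in all three profiles, under divergent local names,
are exactly the shared rows of `key_item_map()`; cohorts A and C
additionally carry a family-history item (`SUPPDM`) and a steroid-pulse
count (`SUPPCM`), so the three cohorts integrate into seven domain
datasets. Unannotated filler fields bring the item counts to 20/18/40 —
deliberately desk-scale stand-ins for real cohorts holding tens to
hundreds of items, chosen so the full test suite converts hundreds of
studies in seconds.

Generator knobs and defaults: 5% missingness per value (absent fields are
how real exports express missingness), repeats uniform on 1–3, labs from
plausible uniform ranges (creatinine 0.4–3.0 mg/dL, eGFR 15–120
mL/min/1.73m², systolic BP 90–180 mmHg, urinary protein 0.05–6 g), birth
dates 1940–1990, biopsy dates 1995–2015. These are plausibility ranges,
not fitted clinical distributions: the generator reproduces the
*structural* hazards of integration (naming, coding, date-dialect and
layout divergence; missingness; repeats), and deliberately not the joint
distribution of real nephrology data, informative missingness, free-text
medication fields, or longitudinal visit schedules. Passing tests
therefore demonstrate correctness of the conversion machinery, not
robustness to every artefact of a particular legacy database.

## Problem sizes used in the checks

The test suite converts the three 20-subject cohorts for the end-to-end
domain check, 50 generated studies of 5–20 subjects for the conservation
properties, and 15 study/seed combinations for the pivot-oracle
equivalence (an independent enumeration of
`(subject, testcode, variable, value)` tuples compared with the tuples
recovered from the emitted datasets). The acceptance script uses 20
subjects per cohort. These sizes were chosen as the smallest at which
every structural feature (repeats, missingness, all seven domains, all
divergent codings) occurs with comfortable margin.

## Known limitations

* One annotation per field; fields feeding several domains need
  duplication upstream.
* No trial-design domains (`TA`/`TE`/`TV`), no `RELREC`, no per-domain
  SDTMIG variable catalogs — variables exist because a directive or an
  identifier rule produced them.
* `AGE` is copied when mapped, never derived from `BRTHDTC`; derivation
  policies belong to analysis, not tabulation.
* Integration does not deduplicate subjects enrolled in several cohorts;
  `USUBJID` uniqueness is the only identity model.
* Define-XML output targets version 2.0 without stylesheets or
  analysis-results metadata.
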