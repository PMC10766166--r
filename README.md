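# sdtmbridge

Converting independently designed clinical-research databases into one
analysis-ready database is hard for mundane reasons: every study names its
variables differently (`Creatinine`, `Cr`), codes its categories differently
(male = 1 in one cohort, 0 in another), writes dates in its own dialect
(`1985/03/12`, `19850312`), and stores repeated measurements either
vertically or spread across columns. The CDISC **Study Data Tabulation
Model (SDTM)** solves the target side of the problem — a fixed set of
two-letter domains (`DM` demographics, `LB` laboratory tests, `VS` vital
signs, `CM` concomitant medications, `SUPP--` supplemental qualifiers) with
fixed variable names and controlled terminology (CT). What remains is the
bridge.

`sdtmbridge` is that bridge for studies exported in the CDISC
**Operational Data Model (ODM 1.3)** format whose item definitions carry an
SDTM mapping triple — domain, variable, and optional test code — as a field
annotation:

```
DM.SEX                 a variable with a unique meaning per subject
LB.LBORRES.CREAT       a findings result, distinguished by test code
SUPPMH.QNAM.OPE        a supplemental qualifier of medical history
```

From the annotated export the package:

1. **normalizes** every value — recodes local category codes to CT
   submission values (so 1/2-coded and 0/1-coded sex both become `M`/`F`)
   and rewrites dates to ISO 8601;
2. **pivots** horizontal records into vertical findings rows — one row per
   test code, with directives that share a test code (a result field and a
   date field both coded `CREAT`) filling one row — and assigns `--SEQ`;
3. **emits** one CSV per domain plus a **Define-XML 2.0** metadata document
   whose ItemDef OIDs (`IT.LB.LBORRES.CREAT`) mirror the annotation syntax;
4. **integrates** several independently mapped studies into one database,
   reporting the items common to all studies and checking that their
   metadata (code-list images, data types) are consistent.

A synthetic-data module generates three cohort profiles with realistic
structural divergence (one vertical with repeated measurements, two
horizontal; different local names, codes and date dialects), so the whole
pipeline is testable without access to any patient data.

## Worked example

```r
library(sdtmbridge)

profiles <- builtin_profiles()
study <- generate_study(profiles$A, n_subjects = 10, seed = 7)
study
#> <odm_study> COHORTA: 20 items (19 SDTM-annotated), 6 code lists, 229 values across 10 subjects

db <- convert_study(study, config = profiles$A$config)
head(db$datasets$LB, 5)
#> # A tibble: 5 × 7
#>   STUDYID DOMAIN USUBJID     LBSEQ LBDTC        LBORRES LBTESTCD
#> 1 COHORTA LB     COHORTA-001 1     "2005-11-20" ""      BIOPSY
#> 2 COHORTA LB     COHORTA-001 2     ""           "1.39"  CREAT
#> 3 COHORTA LB     COHORTA-001 3     ""           "67.3"  EGFR
#> 4 COHORTA LB     COHORTA-001 4     ""           "5.04"  PROT1
#> 5 COHORTA LB     COHORTA-001 5     ""           "4.81"  PROT24
```

The cohort's horizontal laboratory fields have become vertical `LB` rows:
each subject's creatinine, eGFR and urinary-protein values are separate
rows keyed by `LBTESTCD`, the biopsy date is its own `BIOPSY` row carrying
only `LBDTC` (normalized from the cohort's `2005/11/20` dialect), and
`LBSEQ` numbers the rows within the subject.

```r
glance(db)
#> # A tibble: 1 × 5
#>   n_studies n_domains n_rows n_subjects n_errors
#> 1         1         7    210         10        0

dbs <- lapply(profiles, function(p)
  convert_study(generate_study(p, 10, seed = 7), config = p$config))
merged <- integrate_studies(unname(dbs))
merged
#> <sdtm_database> COHORTA + COHORTB + COHORTC
#>   DM         30 rows x 6 variables
#>   CM         79 rows x 7 variables
#>   LB        163 rows x 7 variables
#>   VS         37 rows x 6 variables
#>   SUPPCM     17 rows x 8 variables
#>   SUPPDM     20 rows x 8 variables
#>   SUPPMH    164 rows x 8 variables

common_items(dbs)$triples[1:5, 1:4]
#> # A tibble: 5 × 4
#>   domain variable testcode COHORTA
#> 1 CM     CMOCCUR  PSL      IS_bx
#> 2 CM     CMOCCUR  RAS      rasb_prior
#> 3 DM     BRTHDTC  <NA>     Birth_date(Y/M/D)
#> 4 DM     SEX      <NA>     Sex
#> 5 LB     LBDTC    BIOPSY   date_bx
```

The three cohorts integrate into a seven-domain database; `n_errors = 0`
means every value recoded and every date parsed. `common_items()` returns
the 14 mapping triples all three cohorts share, with each cohort's local
field name — the ledger a data manager needs to confirm metadata
consistency before pooling. `write_sdtm(merged, "out/")` writes the CSVs,
`define.xml` and the run report; `autoplot(merged)` and `tidy(merged)`
summarize the result.

A thin command-line wrapper (`exec/sdtmbridge`) exposes the same pipeline
as `convert`, `integrate` and `simulate` subcommands with a stable
exit-code contract (0 success, 1 data errors, 2 usage errors).

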