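#' Key-item mapping ledger for the three IgA-nephropathy cohorts
#'
#' The shared clinical items of the three cohort databases, with each
#' cohort's local variable name and the SDTM mapping annotation the data
#' managers assigned: demographics (sex, birth date, age), systolic blood
#' pressure at biopsy, concomitant-medication flags (RAS inhibitors,
#' prednisolone and other immunosuppressants), tonsillectomy, laboratory
#' values around the kidney biopsy (serum creatinine, eGFR, urinary
#' protein), and the Oxford-classification lesion scores (M/E/S/T) carried
#' as supplemental qualifiers of medical history. `NA` in a cohort column
#' means that cohort did not collect the item; 14 of the items are present
#' in all three cohorts.
#'
#' @return Tibble with columns `item` (clinical meaning), `cohort_a`,
#'   `cohort_b`, `cohort_c` (local variable names, `NA` where not
#'   collected), `annotation` (the SDTM mapping triple) and `value_kind`
#'   (which generator template the item uses).
#' @export
key_item_map <- function() {
  tibble::tribble(
    ~item,                                     ~cohort_a,               ~cohort_b,         ~cohort_c,            ~annotation,            ~value_kind,
    "Sex",                                     "Sex",                   "Sex",             "Sex",                "DM.SEX",               "sex",
    "Birthday",                                "Birth_date(Y/M/D)",     "Birth_date(Y/M/D)", "birth date",       "DM.BRTHDTC",           "date_birth",
    "Age",                                     NA,                      NA,                "Age",                "DM.AGE",               "int_age",
    "Systolic blood pressure",                 "sbp_bx",                "sbp_bx",          "Sbp",                "VS.VSORRES.SYSBP",     "num_sbp",
    "Renin-angiotensin system inhibitor",      "rasb_prior",            "rasb_prior",      "Ras",                "CM.CMOCCUR.RAS",       "ny",
    "Date of first immunosuppressants",        NA,                      NA,                "Day",                "CM.CMSTDTC.PSL",       "date_treat",
    "Prednisolone (yes or no)",                "IS_bx",                 "fuSteroids_bx",   "ral steroid p or a", "CM.CMOCCUR.PSL",       "ny",
    "Immunosuppressants without prednisolone", "Non_steroid_IS",        NA,                "immuno therapy",     "CM.CMOCCUR.PSLOTH",    "ny",
    "Tonsillectomy (yes or no)",               "tonsillectomy",         "fu_tonsillectomy", "Tonsil",            "SUPPMH.QNAM.OPE",      "ny",
    "Date of tonsillectomy",                   "tonsillectomy_dt",      NA,                "tonsil date",        "SUPPMH.QNAM.OPEDATE",  "date_treat",
    "Date of kidney biopsy",                   "date_bx",               "date_bx",         "kidney_biopsy_date", "LB.LBDTC.BIOPSY",      "date_biopsy",
    "Serum creatinine",                        "Creatinine",            NA,                "Cr",                 "LB.LBORRES.CREAT",     "num_creat",
    "eGFR",                                    "eGFR",                  "gfr_bx_provided", "Egfr",               "LB.LBORRES.EGFR",      "num_egfr",
    "Urinary protein (spot)",                  "uprot_bx",              "uprot",           "urinprotein1",       "LB.LBORRES.PROT1",     "num_uprot",
    "Urinary protein (24 h)",                  "uprot_24h_bx_provided", "uprot_24h",       "Urinprotein",        "LB.LBORRES.PROT24",    "num_uprot",
    "Oxford classification M",                 "m",                     "m",               "Oxford1",            "SUPPMH.QNAM.M",        "oxford_m",
    "Oxford classification E",                 "e",                     "e",               "Oxford2",            "SUPPMH.QNAM.E",        "oxford_e",
    "Oxford classification S",                 "s",                     "s",               "Oxford3",            "SUPPMH.QNAM.S",        "oxford_s",
    "Oxford classification T",                 "t",                     "t",               "Oxford4",            "SUPPMH.QNAM.T",        "oxford_t"
  )
}
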