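# Shared fixtures for the unit tests: a tiny hand-written study with fully
# known expected outcomes, independent of the simulator.

tiny_metadata <- function() {
  dq_metadata(data.frame(
    VAR_NAMES = c("id", "sbp", "smoking", "visit"),
    DATA_TYPE = c("integer", "integer", "integer", "datetime"),
    HARD_LIMITS = c(NA, "[60;300]", NA, "[1999-01-01;2001-12-31]"),
    SOFT_LIMITS = c(NA, "[80;220]", NA, NA),
    VALUE_LABELS = c(NA, NA, "0 = never | 1 = former | 2 = current", NA),
    MISSING_LIST = c(NA, "99900 = not assessable | 99901 = refusal",
                     "99901 = refusal", NA),
    JUMP_LIST = c(NA, NA, "99903 = jump", NA),
    STUDY_SEGMENT = c(NA, "EXAM", "INTERVIEW", NA),
    stringsAsFactors = FALSE
  ), id_var = "id")
}

tiny_study <- function() {
  tibble::tibble(
    id = 1:8,
    sbp = c(120L, 99901L, NA, 400L, 230L, 125L, 99900L, 118L),
    smoking = c(0L, 1L, 2L, 9L, 99901L, 99903L, NA, 1L),
    visit = c("1999-06-01", "2000-01-15", "2000-07-01", "2002-03-01",
              "2001-11-30", "1999-02-28", "2000-05-05", "2001-01-01")
  )
}

# all-zero defect specification: generator output stays byte-identical to
# the clean draw
zero_defects <- function() {
  dq_defect_spec(
    type_mismatch = list(var = "waist", rate = 0, pool = "x"),
    unit_missing_rate = 0, unit_refusal_rate = 0, roster_extra_rate = 0,
    segment_missing_rate = 0,
    item_missing = list(vars = character(), rate_refusal = 0,
                        rate_not_assessable = 0, rate_system = 0),
    hard_violation = list(vars = character(), rate = 0),
    soft_violation = list(vars = character(), rate = 0),
    category_violation = list(vars = character(), rate = 0, value = "9"),
    contradiction = list(R1 = 0, R2 = 0),
    outlier = list(var = "weight", n = 0, sigma = 6)
  )
}

# stage classification of a simulation ledger, using only ledger contents:
#   unit-stage:    every measurement variable system-missing (or all refusal)
#   segment-stage: a segment's full variable set system-missing
#   item-stage:    every other missingness row
ledger_stages <- function(ledger, meas_vars, segs) {
  by_rec <- split(ledger, ledger$record_id)
  unit_sys <- names(Filter(function(l) {
    all(meas_vars %in% l$var_name[l$defect_type == "system-missing"])
  }, by_rec))
  unit_ref <- names(Filter(function(l) {
    all(meas_vars %in% l$var_name[l$defect_type == "coded-missing:99901"])
  }, by_rec))
  seg_recs <- lapply(segs, function(vars) {
    hit <- names(Filter(function(l) {
      all(vars %in% l$var_name[l$defect_type == "system-missing"])
    }, by_rec))
    setdiff(hit, c(unit_sys, unit_ref))
  })
  list(unit_sys = unit_sys, unit_ref = unit_ref, segments = seg_recs)
}
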