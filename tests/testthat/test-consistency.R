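test_that("hard and soft limit deviations are split and code-aware", {
  r <- limit_deviations(tiny_study(), tiny_metadata(), "sbp")
  hard <- r[r$indicator_id == "DQI-3001", ]
  soft <- r[r$indicator_id == "DQI-3006", ]
  # observed values: 120, 400, 230, 125, 118 (codes 99901/99900 and NA stripped)
  expect_equal(hard$denominator, 5L)
  expect_equal(hard$n_flagged, 1L)        # 400 outside [60;300]
  expect_equal(hard$flagged[[1]]$record_id, "4")
  expect_equal(soft$n_flagged, 1L)        # 230 outside [80;220] but inside hard
  expect_equal(soft$flagged[[1]]$record_id, "5")
  expect_equal(hard$descriptor[[1]]$n_above, 1L)
  expect_equal(hard$descriptor[[1]]$n_below, 0L)
})

test_that("datetime limits use the time-date indicators", {
  r <- limit_deviations(tiny_study(), tiny_metadata(), "visit")
  expect_equal(r$indicator_id, "DQI-3002")
  expect_equal(r$n_flagged, 1L)           # 2002-03-01 after 2001-12-31
  expect_equal(r$flagged[[1]]$record_id, "4")
})

test_that("detection limits are reported as censoring, not inadmissibility", {
  md <- dq_metadata(data.frame(VAR_NAMES = c("id", "x"),
                               DATA_TYPE = c("integer", "float"),
                               DETECTION_LIMITS = c(NA, "[1;100]")),
                    id_var = "id")
  r <- limit_deviations(data.frame(id = 1:4, x = c(0.5, 50, 200, 3)), md, "x")
  expect_equal(r$grading, "ok")
  expect_equal(r$n_flagged, 0L)
  expect_equal(r$descriptor[[1]]$censoring$n_below, 1L)
  expect_equal(r$descriptor[[1]]$censoring$n_above, 1L)
})

test_that("open interval endpoints flag boundary values", {
  md <- dq_metadata(data.frame(VAR_NAMES = c("id", "x"),
                               DATA_TYPE = c("integer", "float"),
                               HARD_LIMITS = c(NA, "(0;10)")), id_var = "id")
  r <- limit_deviations(data.frame(id = 1:4, x = c(0, 5, 10, 9.999)), md, "x")
  expect_equal(r$n_flagged, 2L)  # 0 and 10 sit on the open endpoints
})

test_that("inadmissible categorical values are flagged, codes are not", {
  r <- inadmissible_categorical(tiny_study(), tiny_metadata(), "smoking")
  expect_equal(r$indicator_id, "DQI-3003")
  expect_equal(r$n_flagged, 1L)            # the stray 9
  expect_equal(r$flagged[[1]]$record_id, "4")
  expect_equal(r$denominator, 5L)          # 99901/99903/NA not assessed
  expect_equal(r$descriptor[[1]]$surplus_levels, "9")
})

test_that("the predicate catalog is the full outer product of side types", {
  p <- dq_predicates()
  sides <- c("set", "range", "trange", "miss")
  expect_setequal(p, as.vector(outer(sides, sides, paste, sep = "_")))
  expect_equal(anyDuplicated(p), 0)
})

# --- brute-force truth-table oracle over all 16 predicates -------------------

test_that("every predicate agrees with a brute-force oracle on enumerated domains", {
  md <- dq_metadata(data.frame(
    VAR_NAMES = c("id", "n1", "n2", "t1", "t2"),
    DATA_TYPE = c("integer", "integer", "integer", "datetime", "datetime"),
    MISSING_LIST = c(NA, "99900 = not assessable", "99900 = not assessable",
                     "99900 = not assessable", "99900 = not assessable"),
    JUMP_LIST = c(NA, "99903 = jump", "99903 = jump", NA, NA),
    stringsAsFactors = FALSE
  ), id_var = "id")

  num_domain <- c(NA, "1", "2", "5", "15", "16", "99900", "99903")
  dt_domain <- c(NA, "1999-06-01", "2000-06-15", "2001-12-31", "2002-01-01",
                 "99900")
  num_codes <- c("99900", "99903")
  dt_codes <- "99900"

  params_for <- list(set = "1|2", range = "[2;16)",
                     trange = "[2000-01-01;2001-12-31]", miss = "")

  # side condition recomputed from first principles
  oracle_side <- function(v, type, codes) {
    if (is.na(v)) return(FALSE)
    is_code <- v %in% codes
    switch(type,
      miss = is_code,
      set = !is_code && v %in% c("1", "2"),
      range = {
        x <- suppressWarnings(as.numeric(v))
        !is_code && !is.na(x) && x >= 2 && x < 16
      },
      trange = {
        !is_code && !is.na(dqscreen:::parse_iso_datetime(v)) &&
          v >= "2000-01-01" && v <= "2001-12-31"
      })
  }

  for (code in dq_predicates()) {
    types <- strsplit(code, "_", fixed = TRUE)[[1]]
    dom_a <- if (types[1] == "trange") dt_domain else num_domain
    dom_b <- if (types[2] == "trange") dt_domain else num_domain
    var_a <- if (types[1] == "trange") "t1" else "n1"
    var_b <- if (types[2] == "trange") "t2" else "n2"
    grid <- expand.grid(a = dom_a, b = dom_b, stringsAsFactors = FALSE)
    study <- tibble::tibble(id = seq_len(nrow(grid)),
                            n1 = "1", n2 = "1", t1 = "2000-06-15",
                            t2 = "2000-06-15")
    study[[var_a]] <- grid$a
    study[[var_b]] <- grid$b
    rules <- dq_rules(tibble::tibble(
      rule_id = paste0("r_", code), predicate_code = code,
      var_a = var_a, params_a = params_for[[types[1]]],
      var_b = var_b, params_b = params_for[[types[2]]],
      class = "logical"))
    got <- contradictions(study, rules, md, id_var = "id")
    codes_a <- if (types[1] == "trange") dt_codes else num_codes
    codes_b <- if (types[2] == "trange") dt_codes else num_codes
    want <- mapply(function(a, b) {
      oracle_side(a, types[1], codes_a) && oracle_side(b, types[2], codes_b)
    }, grid$a, grid$b)
    expect_equal(got$n_flagged, sum(want), info = code)
    expect_setequal(got$flagged[[1]]$record_id,
                    as.character(study$id[want]))
  }
})

test_that("rule class routes to logical vs empirical indicators", {
  study <- tibble::tibble(id = 1:3, x = c(1, 1, 2), y = c(5, 20, 5))
  rules <- dq_rules(tibble::tibble(
    rule_id = c("L", "E"), predicate_code = "set_range",
    var_a = "x", params_a = "1", var_b = "y", params_b = c("[0;10]", "[0;10]"),
    class = c("logical", "empirical")))
  r <- contradictions(study, rules, id_var = "id")
  expect_equal(r$indicator_id[r$variable == "L"], "DQI-3008")
  expect_equal(r$indicator_id[r$variable == "E"], "DQI-3009")
  expect_equal(r$n_flagged, c(1L, 1L))
  expect_equal(r$denominator, c(3L, 3L))
})

test_that("rule validation rejects malformed tables; unknown variables skip", {
  base <- tibble::tibble(rule_id = "R", predicate_code = "set_set",
                         var_a = "x", params_a = "1", var_b = "y",
                         params_b = "1", class = "logical")
  expect_error(dq_rules(dplyr::select(base, -"params_b")), "lacks column")
  expect_error(dq_rules(dplyr::mutate(base, predicate_code = "foo_bar")),
               "unknown predicate")
  expect_error(dq_rules(dplyr::mutate(base, var_b = "x")), "distinct")
  expect_error(dq_rules(dplyr::mutate(base, class = "maybe")), "logical")
  study <- tibble::tibble(id = 1, x = 1)
  expect_warning(r <- contradictions(study, base, id_var = "id"), "skipped")
  expect_equal(nrow(r), 0L)
})
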