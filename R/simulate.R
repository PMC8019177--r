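# Synthetic-study generator: emulates the structure of a population-based
# examination survey (somatometry, blood pressure, interview variables,
# examiner IDs, exam dates) and injects defects recorded in a ground-truth
# ledger, so every check is testable without access to real study data.

# stable per-stream sub-seeds: a fixed counter per (variable, purpose) key,
# so adding a stream never reshuffles the draws of existing ones
.stream_offsets <- c(
  sex = 1, age = 2, height = 3, weight = 4, waist = 5, sbp = 6, dbp = 7,
  smoking = 8, marital = 9, contraceptives = 10, examiner = 11, exam_date = 12,
  unit_missing = 20, unit_refusal = 21, segment_missing = 22,
  item_missing = 23, type_mismatch = 24, hard_violation = 25,
  soft_violation = 26, category_violation = 27, contradiction = 28,
  outlier = 29, examiner_shift = 30, digit_preference = 31, drift = 32,
  roster = 33
)

sub_seed <- function(seed, key) {
  off <- .stream_offsets[[key]]
  as.integer((as.numeric(seed) * 1009 + off * 9973) %% 2147483647)
}

with_stream <- function(seed, key, expr) {
  set.seed(sub_seed(seed, key))
  expr
}

rnorm_trunc <- function(n, mean, sd, lower, upper) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

#' Default defect specification for the synthetic study
#'
#' Rates are per eligible cell (or unit) and injected by independent
#' Bernoulli draws, so realized counts are binomial. Defaults emulate a
#' moderately dirty survey: a handful of unparsable entries in the waist
#' column, 1% unit nonentry plus 1% all-refusal units, 5% nonparticipation
#' per examination segment, per-item refusals and technical missings,
#' 1% inadmissible and 1% improbable measurement values, a few contradictory
#' interview combinations and planted extreme outliers. Examiner shift,
#' digit preference and drift default to zero and can be switched on for
#' power studies.
#'
#' @param ... Named overrides of the defaults listed in the source.
#' @return A named list (`dq_defect_spec`).
#' @export
dq_defect_spec <- function(...) {
  spec <- list(
    type_mismatch = list(var = "waist", rate = 0.005,
                         pool = c("n/a", "abc", "x999")),
    unit_missing_rate = 0.01,
    unit_refusal_rate = 0.01,
    roster_extra_rate = 0.02,
    segment_missing_rate = 0.05,
    item_missing = list(vars = c("height", "weight", "sbp", "dbp", "age",
                                 "smoking", "marital", "contraceptives"),
                        rate_refusal = 0.015,   # code 99901
                        rate_not_assessable = 0.01,  # code 99900
                        rate_system = 0.005),   # bare NA
    hard_violation = list(vars = c("sbp", "dbp", "height"), rate = 0.01),
    soft_violation = list(vars = c("sbp", "weight"), rate = 0.01),
    category_violation = list(vars = c("smoking", "marital"), rate = 0.005,
                              value = "9"),
    contradiction = list(R1 = 7, R2 = 5),
    outlier = list(var = "weight", n = 5, sigma = 6),
    examiner_shift = list(var = "sbp", class = "3", sd_shift = 0),
    digit_preference = list(var = "sbp", rate = 0),
    drift = list(var = "dbp", class = "2", sd_per_year = 0)
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(spec))
  if (length(bad)) stop("unknown defect spec field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  utils::modifyList(spec, dots)
}

sim_metadata <- function() {
  miss <- "99900 = not assessable | 99901 = refusal | 99902 = technical problem"
  dq_metadata(data.frame(
    VAR_NAMES = c("id", "sex", "age", "height", "weight", "waist", "sbp",
                  "dbp", "smoking", "marital", "contraceptives", "examiner",
                  "exam_date"),
    LABEL = c("participant ID", "sex", "age at examination", "body height",
              "body weight", "waist circumference", "systolic blood pressure",
              "diastolic blood pressure", "smoking status", "marital status",
              "intake of contraceptives", "examiner ID", "examination date"),
    DATA_TYPE = c("integer", "integer", "integer", "float", "float", "float",
                  "integer", "integer", "integer", "integer", "integer",
                  "integer", "datetime"),
    HARD_LIMITS = c(NA, NA, "[0;125]", "[100;250]", "[30;300]", "[40;200]",
                    "[60;300]", "[30;200]", NA, NA, NA, NA,
                    "[1997-01-01;2001-12-31]"),
    SOFT_LIMITS = c(NA, NA, NA, "[130;210]", "[40;180]", "[50;150]",
                    "[80;220]", "[50;130]", NA, NA, NA, NA, NA),
    DETECTION_LIMITS = NA,
    VALUE_LABELS = c(NA, "1 = female | 2 = male", NA, NA, NA, NA, NA, NA,
                     "0 = never | 1 = former | 2 = current",
                     "1 = single | 2 = married | 3 = divorced | 4 = widowed",
                     "0 = no | 1 = yes",
                     "1 = examiner 1 | 2 = examiner 2 | 3 = examiner 3 | 4 = examiner 4 | 5 = examiner 5",
                     NA),
    MISSING_LIST = c(NA, miss, miss, miss, miss, miss, miss, miss, miss,
                     miss, miss, NA, NA),
    JUMP_LIST = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, NA,
                  "99903 = jump: question not applicable", NA, NA),
    STUDY_SEGMENT = c(NA, "INTERVIEW", "INTERVIEW", "SOMATOMETRY",
                      "SOMATOMETRY", "SOMATOMETRY", "BLOOD_PRESSURE",
                      "BLOOD_PRESSURE", "INTERVIEW", "INTERVIEW", "INTERVIEW",
                      NA, NA),
    KEY_OBSERVER = c(NA, NA, NA, NA, NA, NA, "examiner", "examiner",
                     NA, NA, NA, NA, NA),
    KEY_DATETIME = c(NA, NA, NA, NA, NA, NA, "exam_date", "exam_date",
                     NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  ), id_var = "id")
}

sim_rules <- function() {
  dq_rules(tibble::tibble(
    rule_id = c("R1", "R2"),
    predicate_code = c("set_set", "set_range"),
    var_a = c("sex", "marital"),
    params_a = c("2", "2"),
    var_b = c("contraceptives", "age"),
    params_b = c("1", "[0;16)"),
    class = c("logical", "empirical"),
    label = c("male taking contraceptives",
              "married before the age of 16")
  ))
}

#' Generate a synthetic study with a ground-truth defect ledger
#'
#' Draws a clean examination survey of `n` observational units -- interview
#' (sex, age, smoking, marital status, contraceptives with questionnaire
#' routing for men), somatometry (height, weight, waist circumference) and
#' blood pressure (systolic/diastolic) with five examiners and ISO-8601
#' examination dates across 1997--2001 -- then applies [dq_inject_issues()].
#' Clean draws are truncated normals inside the declared soft limits, so a
#' zero-rate defect specification yields data in which every deterministic
#' check is clean.
#'
#' One global seed feeds fixed per-stream sub-seeds, so the same seed always
#' reproduces the same bytes.
#'
#' @param n Number of observational units (default 2154).
#' @param seed Integer seed.
#' @param defects A [dq_defect_spec()].
#' @return A list: `study` (tibble), `metadata`, `rules`, `ledger` (tibble
#'   `record_id`, `var_name`, `defect_type`, `true_value`), `roster`
#'   (eligible IDs incl. never-responding ones) and `segment_order`.
#' @examples
#' sim <- dq_simulate_study(n = 200, seed = 42)
#' dplyr::count(sim$ledger, defect_type)
#' @export
dq_simulate_study <- function(n = 2154, seed = 1, defects = dq_defect_spec()) {
  rates <- c(defects$unit_missing_rate, defects$unit_refusal_rate,
             defects$roster_extra_rate, defects$segment_missing_rate,
             defects$type_mismatch$rate, defects$hard_violation$rate,
             defects$soft_violation$rate, defects$category_violation$rate,
             defects$item_missing$rate_refusal,
             defects$item_missing$rate_not_assessable,
             defects$item_missing$rate_system, defects$digit_preference$rate)
  if (any(rates < 0 | rates > 1)) {
    stop("defect rates must lie in [0, 1]", call. = FALSE)
  }
  metadata <- sim_metadata()
  rules <- sim_rules()

  sex <- with_stream(seed, "sex", sample(c(1L, 2L), n, replace = TRUE, prob = c(0.52, 0.48)))
  age <- with_stream(seed, "age", round(rnorm_trunc(n, 50, 15, 20, 79)))
  height <- with_stream(seed, "height", round(rnorm_trunc(n, 170, 10, 130, 210), 1))
  weight <- with_stream(seed, "weight", round(rnorm_trunc(n, 78, 15, 40, 180), 1))
  waist <- with_stream(seed, "waist", round(rnorm_trunc(n, 88, 13, 50, 150), 1))
  sbp <- with_stream(seed, "sbp", round(rnorm_trunc(n, 130, 18, 80, 220)))
  dbp <- with_stream(seed, "dbp", round(rnorm_trunc(n, 80, 11, 50, 130)))
  smoking <- with_stream(seed, "smoking", sample(0:2, n, replace = TRUE, prob = c(0.45, 0.25, 0.3)))
  marital <- with_stream(seed, "marital", sample(1:4, n, replace = TRUE, prob = c(0.25, 0.55, 0.12, 0.08)))
  contraceptives <- with_stream(seed, "contraceptives", {
    out <- rep(99903L, n)  # routing jump for men
    fem <- sex == 1L
    out[fem] <- sample(c(0L, 1L), sum(fem), replace = TRUE, prob = c(0.7, 0.3))
    out
  })
  examiner <- with_stream(seed, "examiner", sample(1:5, n, replace = TRUE))
  exam_date <- with_stream(seed, "exam_date", {
    d0 <- as.Date("1997-01-01")
    format(d0 + sample.int(as.integer(as.Date("2001-12-31") - d0) + 1L, n,
                           replace = TRUE) - 1L, "%Y-%m-%d")
  })

  study <- tibble::tibble(
    id = seq_len(n),
    sex = sex, age = age, height = height, weight = weight,
    waist = format(waist, nsmall = 1, trim = TRUE),
    sbp = sbp, dbp = dbp, smoking = smoking, marital = marital,
    contraceptives = contraceptives, examiner = examiner,
    exam_date = exam_date
  )

  injected <- dq_inject_issues(study, metadata, rules, defects, seed,
                               id_var = "id")

  n_extra <- with_stream(seed, "roster", stats::rbinom(1, n, defects$roster_extra_rate))
  roster <- as.character(seq_len(n + n_extra))

  list(study = injected$study, metadata = metadata, rules = rules,
       ledger = injected$ledger, roster = roster,
       segment_order = c("INTERVIEW", "SOMATOMETRY", "BLOOD_PRESSURE"),
       seed = seed)
}

#' Inject defects into a clean study table
#'
#' Every injected cell is logged in the returned ledger together with its
#' defect type and the overwritten clean value; injected values are
#' guaranteed to actually violate the targeted rule (hard violations fall
#' strictly outside the hard limits, soft violations inside hard but outside
#' soft limits, planted outliers at `sigma` standard deviations, and so on).
#' Cells not in the ledger are left byte-identical to the clean draw.
#'
#' @param study Clean study tibble (as from the generator).
#' @param metadata,rules As returned by the generator.
#' @param defects A [dq_defect_spec()].
#' @param seed Integer seed (sub-seeded per defect stream).
#' @param id_var Identifier column.
#' @return A list with the modified `study` and the `ledger` tibble.
#' @export
dq_inject_issues <- function(study, metadata, rules, defects = dq_defect_spec(),
                             seed = 1, id_var = "id") {
  n <- nrow(study)
  ids <- record_ids(study, id_var)
  meas_vars <- vars_with_role(metadata, study, "measurement")
  segs <- segment_vars(metadata, study)
  ledger <- list()
  log1 <- function(rid, var, type, true_value = NA) {
    ledger[[length(ledger) + 1]] <<- tibble::tibble(
      record_id = as.character(rid), var_name = var, defect_type = type,
      true_value = as.character(true_value))
  }
  # eligibility: cells still carrying their clean observed value
  touched <- matrix(FALSE, n, length(meas_vars), dimnames = list(NULL, meas_vars))

  # --- stage 1: unit missingness (system NA and all-refusal units) ----------
  u_sys <- with_stream(seed, "unit_missing", which(stats::runif(n) < defects$unit_missing_rate))
  pool <- setdiff(seq_len(n), u_sys)
  u_ref <- with_stream(seed, "unit_refusal", pool[stats::runif(length(pool)) < defects$unit_refusal_rate])
  for (i in u_sys) for (v in meas_vars) {
    log1(ids[i], v, "system-missing", study[[v]][i])
    study[[v]][i] <- NA
  }
  for (i in u_ref) for (v in meas_vars) {
    log1(ids[i], v, "coded-missing:99901", study[[v]][i])
    study[[v]][i] <- if (is.character(study[[v]])) "99901" else 99901L
  }
  unit_units <- c(u_sys, u_ref)
  touched[unit_units, ] <- TRUE

  # --- stage 3: segment nonparticipation (disjoint across segments) ---------
  seg_assign <- with_stream(seed, "segment_missing", {
    avail <- setdiff(seq_len(n), unit_units)
    out <- list()
    for (s in names(segs)) {
      take <- avail[stats::runif(length(avail)) < defects$segment_missing_rate]
      out[[s]] <- take
      avail <- setdiff(avail, take)  # a unit misses at most one segment
    }
    out
  })
  for (s in names(seg_assign)) for (i in seg_assign[[s]]) for (v in segs[[s]]) {
    log1(ids[i], v, "system-missing", study[[v]][i])
    study[[v]][i] <- NA
    touched[i, v] <- TRUE
  }

  # --- stage 4: item missingness -------------------------------------------
  im <- defects$item_missing
  with_stream(seed, "item_missing", {
    for (v in intersect(im$vars, meas_vars)) {
      mdr <- md_row(metadata, v)
      seg <- mdr$segment
      seg_units <- if (!is.na(seg) && seg %in% names(seg_assign)) seg_assign[[seg]] else integer()
      elig <- which(!touched[, v])
      elig <- setdiff(elig, c(unit_units, seg_units))
      # only observed clean cells can become item-missing
      elig <- elig[classify_cells(study[[v]][elig], mdr) == "observed"]
      u <- stats::runif(length(elig))
      tgt <- list(`coded-missing:99901` = elig[u < im$rate_refusal],
                  `coded-missing:99900` = elig[u >= im$rate_refusal &
                                                 u < im$rate_refusal + im$rate_not_assessable],
                  `system-missing` = elig[u >= im$rate_refusal + im$rate_not_assessable &
                                            u < im$rate_refusal + im$rate_not_assessable + im$rate_system])
      others <- if (!is.na(seg)) setdiff(segs[[seg]], v) else character()
      for (ty in names(tgt)) for (i in tgt[[ty]]) {
        # never let item injection wipe out a unit's whole segment: that
        # would silently promote the defect to segment level
        if (length(others) > 0) {
          alive <- any(vapply(others, function(o) {
            classify_cells(study[[o]][i], md_row(metadata, o)) == "observed"
          }, logical(1)))
          if (!alive) next
        }
        log1(ids[i], v, ty, study[[v]][i])
        newval <- switch(ty, `coded-missing:99901` = 99901L,
                         `coded-missing:99900` = 99900L, NA)
        study[[v]][i] <- if (is.character(study[[v]]) && !is.na(newval))
          as.character(newval) else newval
        touched[i, v] <- TRUE
      }
    }
  })

  # --- type mismatches (unparsable strings) --------------------------------
  tm <- defects$type_mismatch
  if (!is.null(tm) && tm$rate > 0 && tm$var %in% meas_vars) {
    with_stream(seed, "type_mismatch", {
      v <- tm$var
      if (!is.character(study[[v]])) study[[v]] <- as.character(study[[v]])
      elig <- which(!touched[, v])
      elig <- elig[classify_cells(study[[v]][elig], md_row(metadata, v)) == "observed"]
      take <- elig[stats::runif(length(elig)) < tm$rate]
      vals <- sample(tm$pool, length(take), replace = TRUE)
      for (k in seq_along(take)) {
        log1(ids[take[k]], v, "type-mismatch", study[[v]][take[k]])
        study[[v]][take[k]] <- vals[k]
        touched[take[k], v] <- TRUE
      }
    })
  }

  # --- hard and soft limit violations --------------------------------------
  hv <- defects$hard_violation
  with_stream(seed, "hard_violation", {
    for (v in intersect(hv$vars, meas_vars)) {
      mdr <- md_row(metadata, v)
      if (is.null(mdr$hard_limits)) {
        stop("hard-violation injection targets ", sQuote(v),
             " which has no hard limits", call. = FALSE)
      }
      elig <- which(!touched[, v])
      take <- elig[stats::runif(length(elig)) < hv$rate]
      h <- mdr$hard_limits
      for (i in take) {
        above <- stats::runif(1) < 0.5 || !is.finite(h$lower)
        val <- if (above && is.finite(h$upper)) round(h$upper + stats::runif(1, 5, 80))
               else round(max(0, h$lower - stats::runif(1, 5, min(50, h$lower))))
        log1(ids[i], v, "hard-violation", study[[v]][i])
        study[[v]][i] <- if (is.character(study[[v]])) as.character(val) else val
        touched[i, v] <- TRUE
      }
    }
  })
  sv <- defects$soft_violation
  with_stream(seed, "soft_violation", {
    for (v in intersect(sv$vars, meas_vars)) {
      mdr <- md_row(metadata, v)
      if (is.null(mdr$soft_limits) || is.null(mdr$hard_limits)) {
        stop("soft-violation injection targets ", sQuote(v),
             " without soft and hard limits", call. = FALSE)
      }
      elig <- which(!touched[, v])
      take <- elig[stats::runif(length(elig)) < sv$rate]
      s <- mdr$soft_limits; h <- mdr$hard_limits
      for (i in take) {
        # strictly between soft upper and hard upper
        val <- round(stats::runif(1, s$upper + 2, h$upper - 2))
        log1(ids[i], v, "soft-violation", study[[v]][i])
        study[[v]][i] <- if (is.character(study[[v]])) as.character(val) else val
        touched[i, v] <- TRUE
      }
    }
  })

  # --- inadmissible categorical values -------------------------------------
  cv <- defects$category_violation
  with_stream(seed, "category_violation", {
    for (v in intersect(cv$vars, meas_vars)) {
      elig <- which(!touched[, v])
      take <- elig[stats::runif(length(elig)) < cv$rate]
      for (i in take) {
        log1(ids[i], v, "category-violation", study[[v]][i])
        study[[v]][i] <- if (is.character(study[[v]])) cv$value else as.integer(cv$value)
        touched[i, v] <- TRUE
      }
    }
  })

  # --- contradictions (both cells overwritten to the firing combination) ----
  ct <- defects$contradiction
  with_stream(seed, "contradiction", {
    clean_units <- which(rowSums(touched) == 0)
    k1 <- min(ct$R1, length(clean_units))
    pick1 <- sample(clean_units, k1)
    for (i in pick1) {
      log1(ids[i], "sex", "contradiction:R1", study$sex[i])
      log1(ids[i], "contraceptives", "contradiction:R1", study$contraceptives[i])
      study$sex[i] <- 2L
      study$contraceptives[i] <- 1L
      touched[i, c("sex", "contraceptives")] <- TRUE
    }
    clean_units <- which(rowSums(touched) == 0)
    k2 <- min(ct$R2, length(clean_units))
    pick2 <- sample(clean_units, k2)
    for (i in pick2) {
      log1(ids[i], "marital", "contradiction:R2", study$marital[i])
      log1(ids[i], "age", "contradiction:R2", study$age[i])
      study$marital[i] <- 2L
      study$age[i] <- 12L
      touched[i, c("marital", "age")] <- TRUE
    }
  })

  # --- planted outliers (inside hard and soft limits, 6 sigma out) ----------
  ol <- defects$outlier
  with_stream(seed, "outlier", {
    v <- ol$var
    mdr <- md_row(metadata, v)
    base <- observed_numeric(study[[v]][!touched[, v]], mdr)$values
    mu <- mean(base); s <- stats::sd(base)
    elig <- which(!touched[, v])
    elig <- elig[classify_cells(study[[v]][elig], mdr) == "observed"]
    take <- sample(elig, min(ol$n, length(elig)))
    for (i in take) {
      val <- round(mu + ol$sigma * s, 1)
      log1(ids[i], v, "outlier", study[[v]][i])
      study[[v]][i] <- if (is.character(study[[v]])) as.character(val) else val
      touched[i, v] <- TRUE
    }
  })

  # --- process-variable effects (off by default) ----------------------------
  es <- defects$examiner_shift
  if (es$sd_shift > 0) with_stream(seed, "examiner_shift", {
    v <- es$var
    mdr <- md_row(metadata, v)
    base <- observed_numeric(study[[v]], mdr)$values
    shift <- es$sd_shift * stats::sd(base)
    obs_var <- metadata$key_observer[metadata$var_name == v]
    in_class <- as.character(study[[obs_var]]) == es$class
    hit <- which(in_class & !touched[, v] &
                   classify_cells(study[[v]], mdr) == "observed")
    for (i in hit) {
      log1(ids[i], v, paste0("examiner-shift:", es$class), study[[v]][i])
      study[[v]][i] <- round(as.numeric(study[[v]][i]) + shift)
      touched[i, v] <- TRUE
    }
  })
  dp <- defects$digit_preference
  if (dp$rate > 0) with_stream(seed, "digit_preference", {
    v <- dp$var
    mdr <- md_row(metadata, v)
    elig <- which(!touched[, v] & classify_cells(study[[v]], mdr) == "observed")
    take <- elig[stats::runif(length(elig)) < dp$rate]
    for (i in take) {
      log1(ids[i], v, "digit-preference", study[[v]][i])
      study[[v]][i] <- round(as.numeric(study[[v]][i]) / 10) * 10
      touched[i, v] <- TRUE
    }
  })
  dr <- defects$drift
  if (dr$sd_per_year > 0) with_stream(seed, "drift", {
    v <- dr$var
    mdr <- md_row(metadata, v)
    base <- observed_numeric(study[[v]], mdr)$values
    slope <- dr$sd_per_year * stats::sd(base)
    obs_var <- metadata$key_observer[metadata$var_name == v]
    tvar <- metadata$key_datetime[metadata$var_name == v]
    t0 <- min(parse_iso_datetime(study[[tvar]]), na.rm = TRUE)
    yrs <- as.numeric(parse_iso_datetime(study[[tvar]]) - t0) / (365.25 * 86400)
    in_class <- as.character(study[[obs_var]]) == dr$class
    hit <- which(in_class & !touched[, v] &
                   classify_cells(study[[v]], mdr) == "observed" & !is.na(yrs))
    for (i in hit) {
      log1(ids[i], v, "drift", study[[v]][i])
      study[[v]][i] <- round(as.numeric(study[[v]][i]) + slope * yrs[i])
      touched[i, v] <- TRUE
    }
  })

  ledger <- if (length(ledger)) dplyr::bind_rows(ledger) else
    tibble::tibble(record_id = character(), var_name = character(),
                   defect_type = character(), true_value = character())
  list(study = study, ledger = ledger)
}

#' Write a simulated study to disk
#'
#' Writes `study.csv`, `metadata.csv`, `rules.csv`, `ledger.csv` and
#' `roster.csv` into `out_dir`.
#'
#' @param sim Result of [dq_simulate_study()].
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
dq_write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(sim$study, file.path(out_dir, "study.csv"))
  md <- sim$metadata
  flat <- tibble::tibble(
    VAR_NAMES = md$var_name, LABEL = md$label, DATA_TYPE = md$data_type,
    HARD_LIMITS = purrr::map_chr(md$hard_limits, ~ if (is.null(.x)) NA_character_ else format(.x)),
    SOFT_LIMITS = purrr::map_chr(md$soft_limits, ~ if (is.null(.x)) NA_character_ else format(.x)),
    DETECTION_LIMITS = purrr::map_chr(md$detection_limits, ~ if (is.null(.x)) NA_character_ else format(.x)),
    VALUE_LABELS = purrr::map_chr(md$categories, format_code_map),
    MISSING_LIST = purrr::map_chr(md$missing_codes, format_code_map),
    JUMP_LIST = purrr::map_chr(md$jump_codes, format_code_map),
    STUDY_SEGMENT = md$segment, KEY_OBSERVER = md$key_observer,
    KEY_DATETIME = md$key_datetime, ROLE = md$role)
  readr::write_csv(flat, file.path(out_dir, "metadata.csv"))
  readr::write_csv(tibble::as_tibble(sim$rules), file.path(out_dir, "rules.csv"))
  readr::write_csv(sim$ledger, file.path(out_dir, "ledger.csv"))
  readr::write_csv(tibble::tibble(id = sim$roster), file.path(out_dir, "roster.csv"))
  invisible(out_dir)
}
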