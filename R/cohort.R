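# Cohort construction: stitch raw visits into admissions, apply the study
# exclusions in attrition order, attach the composite outcome, and split
# patients into train/validation/test sets.

#' Stitch consecutive visits into admissions
#'
#' Two consecutive visits of one patient are merged into the same admission
#' iff the gap between them is at most `gap_hours` (boundary included), so a
#' department transfer is not counted as two separate hospital stays. Merging
#' is transitive and idempotent.
#'
#' @param visits table with columns `visit_id`, `patient_id`, `start`, `end`
#'   (integer minutes), `ward`, `patient_type`, `acuity`.
#' @param gap_hours maximal merging gap in hours (default 24).
#' @return list with `admissions` (one row per stitched admission:
#'   `admission_id`, `patient_id`, `start`, `end`, `n_segments`) and
#'   `segments` (the visits annotated with `admission_id` and `segment`,
#'   ordered within each admission).
#' @export
stitch_admissions <- function(visits, gap_hours = 24) {
  v <- data.table::as.data.table(visits)
  assert_cols(v, c("patient_id", "start", "end"), "visits")
  if (!"visit_id" %in% names(v)) v[, visit_id := seq_len(.N)]
  if (any(v$end < v$start)) {
    stop_data("negative-duration visit(s): %s",
              paste(v$visit_id[v$end < v$start], collapse = ", "))
  }
  data.table::setorder(v, patient_id, start, end)
  v[, prev_end := data.table::shift(cummax(end)), by = patient_id]
  overlap <- !is.na(v$prev_end) & v$start < v$prev_end
  if (any(overlap)) {
    stop_data("overlapping visits for one patient: visit id(s) %s",
              paste(v$visit_id[overlap], collapse = ", "))
  }
  gap_min <- gap_hours * HOUR_MIN
  v[, new_adm := is.na(prev_end) | (start - prev_end) > gap_min]
  v[, adm_local := cumsum(new_adm), by = patient_id]
  v[, admission_id := .GRP, by = c("patient_id", "adm_local")]
  v[, segment := seq_len(.N), by = admission_id]
  adm <- v[, .(patient_id = patient_id[1L], start = min(start),
               end = max(end), n_segments = .N), by = admission_id]
  v[, c("prev_end", "new_adm", "adm_local") := NULL]
  list(admissions = adm[], segments = v[])
}

#' Apply the study exclusions and report attrition
#'
#' Rules are applied in order; the attrition table therefore reports
#' order-dependent counts:
#' \enumerate{
#'   \item `direct_icu` — admissions whose first segment is an ICU stay, i.e.
#'     ICU admissions not preceded by any other contact within the stitching
#'     gap (these cannot be unplanned transfers from a ward);
#'   \item `outpatient` — admissions consisting solely of outpatient contacts;
#'   \item `acute_ed` — acute admissions through the emergency department;
#'   \item `minor` — age below 16 years at admission start (fractional years);
#'   \item `disconnected` — patients flagged with a disconnected record
#'     history.
#' }
#'
#' @param stitched result of [stitch_admissions()].
#' @param patients table with `patient_id`, `sex`, `birth_time`,
#'   `disconnected`.
#' @return list with `admissions` (eligible admissions, augmented with
#'   `age_at_admission`, `sex`, `n_prior_admissions`), `segments` (their
#'   segments) and `attrition` (rule, n_removed, in application order).
#' @export
apply_exclusions <- function(stitched, patients) {
  adm <- data.table::copy(stitched$admissions)
  seg <- data.table::as.data.table(stitched$segments)
  pat <- data.table::as.data.table(patients)
  assert_cols(pat, c("patient_id", "sex", "birth_time", "disconnected"),
              "patients")
  # admission-level context, computed before any exclusion
  data.table::setorder(adm, patient_id, start)
  adm[, n_prior_admissions := seq_len(.N) - 1L, by = patient_id]
  adm <- merge(adm, pat[, c("patient_id", "sex", "birth_time", "disconnected")],
               by = "patient_id", sort = FALSE)
  adm[, age_at_admission := (start - birth_time) / YEAR_MIN]
  first_seg <- seg[segment == 1L,
                   .(admission_id, first_ward = ward,
                     first_type = patient_type, first_acuity = acuity)]
  all_out <- seg[, .(all_outpatient = all(patient_type == "outpatient")),
                 by = admission_id]
  adm <- merge(adm, first_seg, by = "admission_id", sort = FALSE)
  adm <- merge(adm, all_out, by = "admission_id", sort = FALSE)

  rules <- list(
    direct_icu = function(a) a$first_ward == "ICU",
    outpatient = function(a) a$all_outpatient,
    acute_ed = function(a) a$first_ward == "ED" & a$first_acuity == "acute",
    minor = function(a) a$age_at_admission < 16,
    disconnected = function(a) a$disconnected
  )
  removed <- integer(length(rules))
  names(removed) <- names(rules)
  for (r in names(rules)) {
    hit <- rules[[r]](adm)
    removed[[r]] <- sum(hit)
    adm <- adm[!hit]
  }
  adm[, c("birth_time", "disconnected", "first_ward", "first_type",
          "first_acuity", "all_outpatient") := NULL]
  seg <- seg[admission_id %in% adm$admission_id]
  attrition <- data.table::data.table(rule = names(removed),
                                      n_removed = unname(removed))
  list(admissions = adm[], segments = seg[], attrition = attrition)
}

#' Attach the composite deterioration outcome to admissions
#'
#' An admission is labelled `icu_transfer` when an acute ICU segment begins
#' during the stay after a non-ICU segment, or when a separate acute ICU
#' admission starts within 24 hours after discharge from a non-ICU ward;
#' `death` when the patient's death timestamp falls inside `[start, end]`.
#' When both candidate events exist the earlier one defines the outcome.
#' Otherwise the admission ends in discharge and has no event time.
#'
#' @param eligible result of [apply_exclusions()] (or any list with
#'   `admissions` and `segments`).
#' @param icu_visits table of acute ICU visits (`patient_id`, `start`,
#'   `ward`, `acuity`) used for the post-discharge transfer rule; typically
#'   the raw visits table filtered to `ward == "ICU"`.
#' @param deaths table with `patient_id`, `death_time`.
#' @return the admissions table augmented with `outcome` (one of
#'   `discharge`, `icu_transfer`, `death`) and `event_time` (NA for
#'   discharge).
#' @export
detect_outcome <- function(eligible, icu_visits, deaths) {
  adm <- data.table::copy(eligible$admissions)
  seg <- data.table::as.data.table(eligible$segments)
  icu <- data.table::as.data.table(icu_visits)
  dth <- data.table::as.data.table(deaths)

  # mid-stay transfer: first acute ICU segment preceded by a non-ICU segment
  seg2 <- data.table::copy(seg)
  data.table::setorder(seg2, admission_id, segment)
  seg2[, prev_ward := data.table::shift(ward), by = admission_id]
  mid_src <- seg2[ward == "ICU" & acuity == "acute" & !is.na(prev_ward) &
                    prev_ward != "ICU"]
  if (nrow(mid_src)) {
    mid <- mid_src[, .(icu_seg_time = min(start)), by = admission_id]
    adm <- merge(adm, mid, by = "admission_id", all.x = TRUE, sort = FALSE)
  } else {
    adm[, icu_seg_time := NA_integer_]
  }

  # post-discharge transfer: acute ICU admission within 24 h of a non-ICU end
  last_seg <- seg2[, .SD[.N], by = admission_id][, .(admission_id,
                                                     last_ward = ward)]
  adm <- merge(adm, last_seg, by = "admission_id", sort = FALSE)
  if (nrow(icu)) {
    icu_acute <- icu[ward == "ICU" & acuity == "acute",
                     .(patient_id, icu_start = start)]
    post <- icu_acute[adm[, .(admission_id, patient_id, end, last_ward)],
                      on = "patient_id", allow.cartesian = TRUE, nomatch = NULL]
    post <- post[last_ward != "ICU" & icu_start >= end &
                   icu_start - end <= 24 * HOUR_MIN]
    if (nrow(post)) {
      post <- post[, .(icu_post_time = min(icu_start)), by = admission_id]
      adm <- merge(adm, post, by = "admission_id", all.x = TRUE, sort = FALSE)
    } else {
      adm[, icu_post_time := NA_integer_]
    }
  } else {
    adm[, icu_post_time := NA_integer_]
  }

  if (nrow(dth)) {
    dth_min <- dth[, .(death_time = min(death_time)), by = patient_id]
    adm <- merge(adm, dth_min, by = "patient_id", all.x = TRUE, sort = FALSE)
    bad <- !is.na(adm$death_time) & adm$death_time < adm$start
    if (any(bad)) {
      stop_data("death before admission start for admission id(s) %s",
                paste(adm$admission_id[bad], collapse = ", "))
    }
    adm[, death_in := !is.na(death_time) & death_time >= start &
          death_time <= end]
  } else {
    adm[, `:=`(death_time = NA_integer_, death_in = FALSE)]
  }

  icu_time <- pmin(adm$icu_seg_time, adm$icu_post_time, na.rm = TRUE)
  death_time <- ifelse(adm$death_in, adm$death_time, NA_integer_)
  has_icu <- !is.na(icu_time)
  has_death <- !is.na(death_time)
  outcome <- rep("discharge", nrow(adm))
  event_time <- rep(NA_integer_, nrow(adm))
  both <- has_icu & has_death
  outcome[both] <- ifelse(icu_time[both] <= death_time[both],
                          "icu_transfer", "death")
  event_time[both] <- pmin(icu_time[both], death_time[both])
  only_icu <- has_icu & !has_death
  outcome[only_icu] <- "icu_transfer"
  event_time[only_icu] <- icu_time[only_icu]
  only_death <- has_death & !has_icu
  outcome[only_death] <- "death"
  event_time[only_death] <- death_time[only_death]
  adm[, `:=`(outcome = outcome, event_time = as.integer(event_time))]
  adm[, c("icu_seg_time", "icu_post_time", "last_ward", "death_time",
          "death_in") := NULL]
  adm[]
}

#' Split patients into train / validation / test sets
#'
#' The split is performed at the patient level so that every admission of a
#' patient inherits that patient's set, preventing information leakage across
#' sets. Deterministic given `seed`.
#'
#' @param patient_ids vector of unique patient ids.
#' @param fractions numeric length-3 vector (train, validation, test) summing
#'   to 1; default `c(0.64, 0.16, 0.20)` — an 80/20 development/holdout split
#'   with the development set split 80/20 again.
#' @param seed integer seed.
#' @return `data.table` with `patient_id` and `split` in
#'   `{train, validation, test}`.
#' @export
split_patients <- function(patient_ids, fractions = c(0.64, 0.16, 0.20),
                           seed = 1L) {
  ids <- unique(patient_ids)
  if (!length(ids)) stop_config("patient id list is empty")
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8) {
    stop_config("split fractions must be three numbers summing to 1")
  }
  with_seed(seed, {
    ids <- sample(ids)
    n <- length(ids)
    n_test <- round(fractions[3] * n)
    n_val <- round(fractions[2] * n)
    split <- rep("train", n)
    if (n_test > 0) split[seq_len(n_test)] <- "test"
    if (n_val > 0) split[n_test + seq_len(n_val)] <- "validation"
    data.table::data.table(patient_id = ids, split = split)[order(patient_id)]
  })
}

#' Build the full cohort from a synthetic EHR
#'
#' Convenience wrapper: stitch, exclude, attach outcomes and split.
#'
#' @param ehr a `wardflow_ehr` from [generate_ehr()].
#' @param gap_hours stitching gap in hours.
#' @param fractions patient-level split fractions (train, validation, test).
#' @param seed split seed.
#' @return list with `admissions` (eligible, with outcome, event_time and
#'   split), `segments`, `attrition`, `splits`.
#' @export
build_cohort <- function(ehr, gap_hours = 24, fractions = c(0.64, 0.16, 0.20),
                         seed = 1L) {
  stitched <- stitch_admissions(ehr$visits, gap_hours = gap_hours)
  elig <- apply_exclusions(stitched, ehr$patients)
  adm <- detect_outcome(elig, ehr$visits[ehr$visits$ward == "ICU", ],
                        ehr$deaths)
  splits <- split_patients(unique(adm$patient_id), fractions, seed)
  adm <- merge(adm, splits, by = "patient_id", sort = FALSE)
  data.table::setorder(adm, admission_id)
  list(admissions = adm, segments = elig$segments,
       attrition = elig$attrition, splits = splits)
}
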