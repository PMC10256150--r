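mk_visits <- function(starts_h, ends_h, patient_id = 1L, ward = "ward",
                      patient_type = "inpatient", acuity = "planned") {
  data.table::data.table(
    visit_id = seq_along(starts_h), patient_id = patient_id,
    start = as.integer(starts_h * 60), end = as.integer(ends_h * 60),
    ward = ward, patient_type = patient_type, acuity = acuity)
}

test_that("visits merge iff the gap is at most 24 hours", {
  one <- stitch_admissions(mk_visits(c(0, 60), c(50, 100)))
  expect_equal(nrow(one$admissions), 1L)
  expect_equal(one$admissions$start, 0L)
  expect_equal(one$admissions$end, 100L * 60L)
  two <- stitch_admissions(mk_visits(c(0, 80), c(50, 100)))
  expect_equal(nrow(two$admissions), 2L)
  # gap of exactly 24 h merges
  edge <- stitch_admissions(mk_visits(c(0, 74), c(50, 80)))
  expect_equal(nrow(edge$admissions), 1L)
  # chain with gaps 20 h and 23 h merges transitively
  chain <- stitch_admissions(mk_visits(c(0, 30, 76), c(10, 53, 100)))
  expect_equal(nrow(chain$admissions), 1L)
  expect_equal(chain$admissions$end, 100L * 60L)
})

test_that("stitching matches a transitive-closure oracle on random inputs", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(2:7, 1)
    starts <- sort(sample(0:300, n)) * 60L
    durs <- sample(1:48, n, replace = TRUE) * 60L
    ends <- starts + durs
    # drop overlapping configurations
    if (any(starts[-1] < cummax(ends[-n]))) next
    v <- data.table::data.table(visit_id = seq_len(n), patient_id = 1L,
                                start = starts, end = ends, ward = "ward",
                                patient_type = "inpatient",
                                acuity = "planned")
    got <- stitch_admissions(v)$segments
    oracle <- brute_stitch_groups(starts, ends, 24 * 60)
    expect_equal(length(unique(got$admission_id)), length(unique(oracle)))
    expect_equal(as.integer(factor(got$admission_id[order(got$visit_id)])),
                 as.integer(factor(oracle)))
  }
})

test_that("stitching is idempotent and rejects overlaps", {
  v <- mk_visits(c(0, 30, 200), c(10, 53, 250))
  first <- stitch_admissions(v)
  again <- stitch_admissions(first$admissions[, .(
    visit_id = admission_id, patient_id, start, end,
    ward = "ward", patient_type = "inpatient", acuity = "planned")])
  expect_equal(nrow(again$admissions), nrow(first$admissions))
  expect_equal(again$admissions$start, first$admissions$start)
  expect_equal(again$admissions$end, first$admissions$end)
  bad <- mk_visits(c(0, 5), c(10, 20))
  expect_error(stitch_admissions(bad), "overlapping")
})

test_that("age boundary at 16 years is exclusive below and inclusive at 16", {
  yr <- 525960
  patients <- data.table::data.table(
    patient_id = 1:2, sex = "F",
    birth_time = as.integer(c(-15.9 * yr, -16 * yr)),
    disconnected = FALSE)
  visits <- data.table::data.table(
    visit_id = 1:2, patient_id = 1:2, start = 0L, end = 60L * 60L,
    ward = "ward", patient_type = "inpatient", acuity = "planned")
  res <- apply_exclusions(stitch_admissions(visits), patients)
  expect_equal(res$admissions$patient_id, 2L)
  expect_equal(res$attrition[rule == "minor"]$n_removed, 1L)
})

test_that("attrition equals the generator's planted per-rule counts", {
  w <- fixture_world()
  att <- w$cohort$attrition
  planted <- w$ehr$truth$planted_attrition
  expect_equal(att$rule, planted$rule)
  expect_equal(att$n_removed, planted$n)
})

test_that("outcome detection follows the transfer and death rules", {
  # acute ICU admission 20 h after non-ICU discharge -> transfer
  mk_case <- function(icu_gap_h) {
    visits <- data.table::data.table(
      visit_id = 1:2, patient_id = 1L,
      start = as.integer(c(0, (100 + icu_gap_h) * 60)),
      end = as.integer(c(100 * 60, (100 + icu_gap_h + 48) * 60)),
      ward = c("ward", "ICU"), patient_type = "inpatient",
      acuity = c("planned", "acute"))
    patients <- data.table::data.table(patient_id = 1L, sex = "M",
                                       birth_time = -40L * 525960L,
                                       disconnected = FALSE)
    elig <- apply_exclusions(stitch_admissions(visits), patients)
    detect_outcome(elig, visits[ward == "ICU"],
                   data.table::data.table(patient_id = integer(),
                                          death_time = integer()))
  }
  near <- mk_case(20)
  ward_row <- near[order(start)][1]
  expect_equal(ward_row$outcome, "icu_transfer")
  expect_equal(ward_row$event_time, as.integer(120 * 60))
  far <- mk_case(30)
  expect_equal(far[order(start)][1]$outcome, "discharge")
  expect_true(is.na(far[order(start)][1]$event_time))

  # mid-stay transfer to an acute ICU segment at hour 35
  visits <- data.table::data.table(
    visit_id = 1:2, patient_id = 1L,
    start = as.integer(c(0, 35 * 60)), end = as.integer(c(35, 80) * 60),
    ward = c("ward", "ICU"), patient_type = "inpatient",
    acuity = c("planned", "acute"))
  patients <- data.table::data.table(patient_id = 1L, sex = "M",
                                     birth_time = -40L * 525960L,
                                     disconnected = FALSE)
  elig <- apply_exclusions(stitch_admissions(visits), patients)
  out <- detect_outcome(elig, visits[ward == "ICU"],
                        data.table::data.table(patient_id = integer(),
                                               death_time = integer()))
  expect_equal(out$outcome, "icu_transfer")
  expect_equal(out$event_time, as.integer(35 * 60))

  # death inside the stay; death before admission start errors
  visits2 <- mk_visits(0, 100)
  elig2 <- apply_exclusions(stitch_admissions(visits2), patients)
  out2 <- detect_outcome(elig2, visits2[0],
                         data.table::data.table(patient_id = 1L,
                                                death_time = 50L * 60L))
  expect_equal(out2$outcome, "death")
  expect_equal(out2$event_time, 50L * 60L)
  expect_error(
    detect_outcome(elig2, visits2[0],
                   data.table::data.table(patient_id = 1L,
                                          death_time = -10L)),
    "death before admission")
})

test_that("cohort outcomes agree with the generator's ground truth", {
  w <- fixture_world()
  m <- merge(
    w$cohort$admissions[, .(patient_id, start, outcome_c = outcome,
                            et_c = event_time)],
    w$ehr$truth$admissions[, .(patient_id, start, outcome_t = outcome,
                               et_t = event_time)],
    by = c("patient_id", "start"))
  expect_equal(nrow(m), nrow(w$cohort$admissions))
  expect_equal(m$outcome_c, m$outcome_t)
  expect_equal(m$et_c[!is.na(m$et_c)], m$et_t[!is.na(m$et_t)])
  adm <- w$cohort$admissions
  expect_true(all(adm$start < adm$end))
  ev <- adm[!is.na(event_time)]
  expect_true(all(ev$event_time > ev$start &
                    ev$event_time <= ev$end + 24 * 60))
  expect_true(all((adm$outcome == "discharge") == is.na(adm$event_time)))
  prev <- mean(adm$outcome != "discharge")
  expect_lt(abs(prev - 0.022), 3 * sqrt(0.022 * 0.978 / nrow(adm)) + 0.002)
})

test_that("patient split is a seeded partition with the requested sizes", {
  sp <- split_patients(1:100, seed = 1)
  expect_equal(sum(sp$split == "test"), 20L)
  expect_equal(sum(sp$split == "validation"), 16L)
  expect_equal(sum(sp$split == "train"), 64L)
  expect_setequal(sp$patient_id, 1:100)
  expect_identical(sp, split_patients(1:100, seed = 1))
  sp2 <- split_patients(1:100, seed = 2)
  expect_false(identical(sp$split, sp2$split))
  expect_equal(table(sp$split), table(sp2$split))
  expect_error(split_patients(1:10, fractions = c(0.5, 0.2, 0.2)),
               "summing to 1")
  expect_error(split_patients(integer(0)), "empty")
})
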