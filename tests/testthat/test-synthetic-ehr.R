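test_that("configuration is validated", {
  expect_error(synth_config(0), "positive count")
  expect_error(synth_config(10, target_death_prev = 0.6,
                            target_icu_prev = 0.5), "sum to < 1")
  expect_error(synth_config(10, target_death_prev = 0), "\\(0,1\\)")
})

test_that("seeded generation is reproducible and exclusion-free configs are clean", {
  cfg <- synth_config(n_patients = 300, seed = 7)
  e1 <- generate_ehr(cfg)
  e2 <- generate_ehr(cfg)
  for (nm in c("patients", "visits", "diagnoses", "labs", "notes", "deaths")) {
    expect_identical(e1[[nm]], e2[[nm]], label = nm)
  }
  cfg0 <- synth_config(n_patients = 300, seed = 7,
                       exclusion_fracs = list(minor = 0, disconnected = 0,
                                              outpatient = 0, acute_ed = 0,
                                              direct_icu = 0, late_icu = 0))
  e0 <- generate_ehr(cfg0)
  expect_true(all(e0$truth$admissions$eligible))
  expect_true(all(e0$truth$planted_attrition$n == 0))
})

test_that("empirical outcome prevalence matches configured targets at large n", {
  cfg <- synth_config(n_patients = 20000, seed = 13)
  pop <- generate_population(cfg)
  adm <- pop$truth$admissions[pop$truth$admissions$eligible, ]
  p_death <- mean(adm$outcome == "death")
  p_icu <- mean(adm$outcome == "icu_transfer")
  expect_lt(abs(p_death - 0.015), 0.005)
  expect_lt(abs(p_icu - 0.007), 0.004)
})

test_that("admission-course hazard behaves at its limits", {
  cfg0 <- synth_config(n_patients = 10, event_hazard_scale = 0, seed = 1)
  set.seed(1)
  res <- replicate(100, simulate_admission_course(0, 72, cfg0)$event)
  expect_false(any(res))
  cfg1 <- synth_config(n_patients = 10, seed = 1)
  set.seed(1)
  res1 <- replicate(50, {
    r <- simulate_admission_course(50, 72, cfg1, hazard_intercept = 0)
    c(r$event, r$event_offset_h)
  })
  expect_true(all(res1[1, ] == 1))      # hazard ~ 1: every admission events
  expect_true(all(res1[2, ] <= 6))      # in the very first 6 h step
})

test_that("planted severity separates event from discharge admissions", {
  pop <- generate_population(synth_config(n_patients = 4000, seed = 21))
  adm <- pop$truth$admissions
  m_event <- mean(adm$s0[adm$outcome != "discharge"])
  m_disc <- mean(adm$s0[adm$outcome == "discharge"])
  expect_gt(m_event, m_disc)
})

test_that("emitted records respect the observation window", {
  w <- fixture_world()
  truth <- w$ehr$truth$admissions
  streams <- list(labs = w$ehr$labs, notes = w$ehr$notes)
  for (nm in names(streams)) {
    s <- streams[[nm]]
    j <- s[truth, on = "patient_id", allow.cartesian = TRUE, nomatch = NULL]
    inside <- j[time >= start & time <= end]
    expect_true(all(inside$time <= inside$start + inside$obs_end_off),
                label = sprintf("%s timestamps before event/discharge", nm))
  }
  dx <- w$ehr$diagnoses[w$ehr$truth$patients_info, on = "patient_id",
                        nomatch = NULL]
  expect_true(all(dx$time < dx$first_start))
})

test_that("symmetric token pools emit symmetrically at zero severity", {
  pools <- default_token_pools()
  pools$note <- data.table::data.table(
    token = c("up1", "up2", "down1", "down2", "neut1", "neut2"),
    weight = c(1.5, 0.8, -1.5, -0.8, 0, 0),
    base = c(0.5, 0.5, 0.5, 0.5, 1, 1))
  cfg <- synth_config(n_patients = 400, seed = 5,
                      frailty_sd = 0, age_link = 0, baseline_noise = 0,
                      severity_drift = 0, severity_noise = 0,
                      event_hazard_scale = 0,
                      risk_token_pools = pools)
  ehr <- generate_ehr(cfg)
  toks <- unlist(strsplit(ehr$notes$text, " "), use.names = FALSE)
  n_up <- sum(toks %in% c("up1", "up2"))
  n_dn <- sum(toks %in% c("down1", "down2"))
  expect_lt(abs(n_up - n_dn) / (n_up + n_dn), 0.05)
})

test_that("planted risk tokens correlate with the outcome", {
  w <- fixture_world()
  risk <- w$ehr$truth$token_effects[domain == "note" & weight > 0]$token
  adm <- w$ehr$truth$admissions
  notes <- w$ehr$notes[adm, on = "patient_id", allow.cartesian = TRUE,
                       nomatch = NULL][time >= start & time <= end]
  notes[, n_risk := vapply(strsplit(text, " "),
                           function(x) sum(x %in% risk), numeric(1))]
  per_adm <- notes[, .(n_risk = sum(n_risk)), by = admission_uid]
  per_adm <- merge(per_adm,
                   adm[, .(admission_uid, y = outcome != "discharge")],
                   by = "admission_uid")
  expect_gt(cor(per_adm$n_risk, as.numeric(per_adm$y)), 0)
})

test_that("the EHR round-trips through its CSV representation", {
  cfg <- synth_config(n_patients = 50, seed = 3)
  ehr <- generate_ehr(cfg)
  dir <- withr::local_tempdir()
  write_ehr(ehr, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "patients.csv", "visits.csv", "diagnoses.csv", "labs.csv", "notes.csv",
    "deaths.csv", "truth_admissions.csv", "meta.json")))))
  back <- data.table::fread(file.path(dir, "visits.csv"))
  expect_equal(nrow(back), nrow(ehr$visits))
})
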