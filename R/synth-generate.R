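# Synthetic event-stream EHR generator.
#
# Mechanism: each patient carries a latent frailty; each admission adds an
# age-linked, noisy baseline severity and then follows a random walk on a 6 h
# grid. The per-step hazard of the composite deterioration event is a logistic
# function of current severity; the hazard intercept is calibrated so that the
# expected composite prevalence among eligible admissions matches the
# configured target. Diagnosis, laboratory and note streams are emitted with
# token probabilities tied to severity, planting a recoverable signal.

.hazard_prob <- function(s, intercept, cfg) {
  pmin(1, cfg$event_hazard_scale * logistic(intercept + cfg$severity_link * s))
}

.gen_patients <- function(cfg) {
  n <- cfg$n_patients
  ef <- cfg$exclusion_fracs
  minor <- stats::runif(n) < ef$minor
  age0 <- pmin(pmax(stats::rnorm(n, cfg$age_mean, cfg$age_sd), 16), 100)
  age0[minor] <- stats::runif(sum(minor), 1, 15.9)
  data.table::data.table(
    patient_id = seq_len(n),
    sex = ifelse(stats::runif(n) < 0.55, "F", "M"),
    age0 = age0,
    minor = minor,
    disconnected = stats::runif(n) < ef$disconnected,
    frailty = stats::rnorm(n, 0, cfg$frailty_sd),
    has_outpatient = stats::runif(n) < ef$outpatient,
    has_acute_ed = stats::runif(n) < ef$acute_ed,
    has_direct_icu = stats::runif(n) < ef$direct_icu
  )
}

# Ward admissions with non-overlapping, well-separated stays per patient.
.gen_admission_frame <- function(patients, cfg) {
  n_adm <- 1L + stats::rpois(nrow(patients), cfg$adm_rate)
  adm <- data.table::data.table(
    patient_id = rep(patients$patient_id, n_adm)
  )
  adm <- merge(adm, patients, by = "patient_id", sort = TRUE)
  n <- nrow(adm)
  los_h <- pmax(pmin(stats::rlnorm(n, cfg$los_log_median_h, cfg$los_log_sigma),
                     cfg$max_los_days * 24), 2)
  adm[, los_min := h2min(los_h)]
  # inter-admission gap: at least 21 days so later contacts never overlap
  gap_min <- 21L * DAY_MIN + as.integer(round(stats::rexp(n, 1 / (120 * DAY_MIN))))
  first_start <- as.integer(round(stats::runif(n, 0, YEAR_MIN)))
  adm[, `:=`(gap = gap_min, fs = first_start)]
  adm[, start := {
    s <- cumsum(data.table::shift(as.numeric(los_min) + gap, fill = 0))
    as.integer(fs[1] + s)
  }, by = patient_id]
  adm[, `:=`(gap = NULL, fs = NULL)]
  adm[, admission_uid := seq_len(.N)]
  adm[, age_at_start := age0 + (start - start[1]) / YEAR_MIN, by = patient_id]
  adm[, s0 := frailty + cfg$age_link * (age_at_start - 60) / 20 +
        stats::rnorm(.N, 0, cfg$baseline_noise)]
  adm[, eligible := !(age_at_start < 16) & !disconnected]
  adm[]
}

.gen_severity <- function(adm, cfg) {
  K <- ceiling(adm$los_min / (6 * HOUR_MIN))
  sev <- data.table::data.table(
    admission_uid = rep(adm$admission_uid, K),
    patient_id = rep(adm$patient_id, K),
    s0 = rep(adm$s0, K),
    los_min = rep(adm$los_min, K),
    start = rep(adm$start, K)
  )
  sev[, k := seq_len(.N), by = admission_uid]
  inc <- cfg$severity_drift + cfg$severity_noise * stats::rnorm(nrow(sev))
  sev[, inc := inc]
  sev[, s := s0 + cumsum(c(0, inc[-1])), by = admission_uid]
  sev[, inc := NULL]
  sev[]
}

.calibrate_intercept <- function(sev, eligible_uids, cfg) {
  target <- cfg$target_death_prev + cfg$target_icu_prev
  sv <- sev[sev$admission_uid %in% eligible_uids, ]
  f <- function(ic) {
    p <- .hazard_prob(sv$s, ic, cfg)
    ls <- rowsum(log1p(-pmin(p, 1 - 1e-12)), sv$admission_uid)
    mean(1 - exp(ls)) - target
  }
  out <- tryCatch(
    stats::uniroot(f, c(-30, 10), tol = 1e-9),
    error = function(e) stop_config(
      "cannot calibrate hazard intercept to prevalence %.4f (%s)", target,
      conditionMessage(e))
  )
  out$root
}

.assign_events <- function(adm, sev, cfg) {
  if (cfg$event_hazard_scale == 0) {
    intercept <- cfg$hazard_intercept %||% -Inf
    adm[, `:=`(event_off = NA_integer_, outcome = "discharge")]
    return(list(adm = adm, intercept = intercept))
  }
  intercept <- cfg$hazard_intercept %||%
    .calibrate_intercept(sev, adm$admission_uid[adm$eligible], cfg)
  p <- .hazard_prob(sev$s, intercept, cfg)
  hit <- stats::runif(nrow(sev)) < p
  u_in <- stats::runif(nrow(sev))
  sev_hit <- sev[hit, c("admission_uid", "k", "los_min")]
  sev_hit[, u := u_in[hit]]
  first <- sev_hit[, .SD[1L], by = admission_uid]
  ivl_start <- (first$k - 1L) * 6L * HOUR_MIN
  len <- pmin(6L * HOUR_MIN, first$los_min - ivl_start)
  first[, event_off := as.integer(ivl_start + pmax(1, ceiling(u * len)))]
  adm[, event_off := NA_integer_]
  adm[first$admission_uid, event_off := first$event_off]
  p_death <- cfg$target_death_prev / (cfg$target_death_prev + cfg$target_icu_prev)
  is_ev <- !is.na(adm$event_off)
  type <- ifelse(stats::runif(nrow(adm)) < p_death, "death", "icu_transfer")
  adm[, outcome := ifelse(is_ev, type, "discharge")]
  list(adm = adm, intercept = intercept)
}

.materialize <- function(adm, patients, cfg) {
  # drop admissions after an in-hospital death of the same patient
  death_adm <- adm[outcome == "death", .(patient_id, death_start = start)]
  if (nrow(death_adm)) {
    first_death <- death_adm[, .(death_start = min(death_start)), by = patient_id]
    adm <- merge(adm, first_death, by = "patient_id", all.x = TRUE)
    adm <- adm[is.na(death_start) | start <= death_start]
    adm[, death_start := NULL]
  }
  n <- nrow(adm)
  is_icu <- adm$outcome == "icu_transfer"
  icu_los <- h2min(pmin(stats::rlnorm(n, cfg$icu_los_log_median_h,
                                      cfg$icu_los_log_sigma), 14 * 24))
  post <- is_icu & stats::runif(n) < cfg$icu_post_discharge_frac
  # ward discharge 1-24 h before the post-discharge ICU admission
  pre_gap <- as.integer(round(stats::runif(n, 1, 23.9) * HOUR_MIN))
  dch_off <- ifelse(post, adm$event_off - pre_gap, NA_integer_)
  post[!is.na(dch_off) & dch_off <= 0] <- FALSE
  dch_off[!post] <- NA_integer_

  adm[, `:=`(
    icu_mid = is_icu & !post,
    icu_post = post,
    dch_off = as.integer(dch_off),
    icu_los = as.integer(ifelse(is_icu, icu_los, NA_integer_))
  )]
  adm[, ward_end_off := data.table::fcase(
    outcome == "death", event_off,
    icu_post, dch_off,
    icu_mid, event_off,
    default = los_min
  )]
  adm[, obs_end_off := data.table::fcase(
    outcome == "death", event_off,
    icu_post, dch_off,
    icu_mid, event_off,
    default = los_min
  )]
  adm[, end := data.table::fcase(
    icu_mid | icu_post, start + event_off + icu_los,
    outcome == "death", start + event_off,
    default = start + los_min
  )]
  adm[, event_time := ifelse(is.na(event_off), NA_integer_,
                             start + event_off)]

  late <- adm$outcome == "discharge" &
    stats::runif(n) < cfg$exclusion_fracs$late_icu

  ward_visits <- data.table::data.table(
    patient_id = adm$patient_id,
    start = adm$start,
    end = adm$start + adm$ward_end_off,
    ward = "ward", patient_type = "inpatient", acuity = "planned"
  )
  icu_visits <- data.table::data.table(
    patient_id = adm$patient_id[is_icu],
    start = adm$start[is_icu] + adm$event_off[is_icu],
    end = adm$start[is_icu] + adm$event_off[is_icu] + adm$icu_los[is_icu],
    ward = "ICU", patient_type = "inpatient", acuity = "acute"
  )
  late_gap <- as.integer(round(stats::runif(sum(late), 25, 71) * HOUR_MIN))
  late_los <- as.integer(round(stats::runif(sum(late), 24, 96) * HOUR_MIN))
  late_visits <- data.table::data.table(
    patient_id = adm$patient_id[late],
    start = adm$end[late] + late_gap,
    end = adm$end[late] + late_gap + late_los,
    ward = "ICU", patient_type = "inpatient", acuity = "acute"
  )

  pts <- patients[patients$patient_id %in% adm$patient_id |
                    patients$has_outpatient | patients$has_acute_ed |
                    patients$has_direct_icu, ]
  firsts <- adm[, .(first_start = min(start)), by = patient_id]
  pts <- merge(patients, firsts, by = "patient_id", all.x = TRUE)
  pts[is.na(first_start), first_start := 0L]

  op <- pts[pts$has_outpatient, ]
  n_op <- if (nrow(op)) 1L + stats::rpois(nrow(op), 0.5) else integer(0)
  # distinct, >= 2 days apart so separate contacts never stitch together
  op_days <- unlist(lapply(seq_len(nrow(op)), function(i)
    sample(seq(30L, 150L, by = 2L), n_op[i])), use.names = FALSE)
  op_visits <- data.table::data.table(
    patient_id = rep(op$patient_id, n_op),
    start = rep(op$first_start, n_op) - op_days * DAY_MIN,
    end = rep(op$first_start, n_op) - op_days * DAY_MIN +
      as.integer(round(stats::runif(sum(n_op), 2, 6) * HOUR_MIN)),
    ward = "ward", patient_type = "outpatient", acuity = "planned"
  )
  ed <- pts[pts$has_acute_ed, ]
  ed_visits <- data.table::data.table(
    patient_id = ed$patient_id,
    start = ed$first_start - sample(160:290, nrow(ed), replace = TRUE) * DAY_MIN,
    end = NA_integer_, ward = "ED", patient_type = "inpatient", acuity = "acute"
  )
  ed_visits[, end := start + as.integer(round(stats::runif(.N, 6, 48) * HOUR_MIN))]
  di <- pts[pts$has_direct_icu, ]
  di_visits <- data.table::data.table(
    patient_id = di$patient_id,
    start = di$first_start - sample(300:400, nrow(di), replace = TRUE) * DAY_MIN,
    end = NA_integer_, ward = "ICU", patient_type = "inpatient", acuity = "acute"
  )
  di_visits[, end := start + as.integer(round(stats::runif(.N, 24, 120) * HOUR_MIN))]

  visits <- data.table::rbindlist(list(ward_visits, icu_visits, late_visits,
                                       op_visits, ed_visits, di_visits))
  visits[, `:=`(start = as.integer(start), end = as.integer(end))]
  data.table::setorder(visits, patient_id, start)
  visits[, visit_id := seq_len(.N)]
  data.table::setcolorder(visits, "visit_id")

  deaths <- adm[outcome == "death",
                .(patient_id, death_time = as.integer(event_time))]

  # patient table with birth time (age at first admission = age0)
  pat_out <- merge(patients, firsts, by = "patient_id", all.x = TRUE)
  pat_out[is.na(first_start), first_start := 0L]
  pat_out[, birth_time := as.integer(round(first_start - age0 * YEAR_MIN))]

  # planted attrition, in the order the cohort module applies its rules
  n_late <- nrow(late_visits)
  n_di <- nrow(di_visits)
  n_op_units <- nrow(op_visits)
  n_ed <- nrow(ed_visits)
  minors_adm <- sum(adm$age_at_start < 16)
  disc_adm <- sum(adm$disconnected & !(adm$age_at_start < 16))
  planted <- data.table::data.table(
    rule = c("direct_icu", "outpatient", "acute_ed", "minor", "disconnected"),
    n = c(n_di + n_late, n_op_units, n_ed, minors_adm, disc_adm)
  )
  list(adm = adm, visits = visits, deaths = deaths, patients = pat_out,
       planted_attrition = planted)
}

#' Generate the synthetic population: patients, visits and deaths
#'
#' Simulates patients, their ward admissions with latent severity courses and
#' composite deterioration events, plus contacts exercising every cohort
#' exclusion arm (direct ICU admissions, outpatient contacts, acute emergency
#' admissions, minors, disconnected histories). Deterministic given
#' `config$seed`.
#'
#' @param config a [synth_config()].
#' @return list with `patients`, `visits`, `deaths` tables and `truth`, a
#'   `wardflow_truth` object carrying the latent severity trajectories,
#'   per-admission outcomes, planted token effects and planted attrition.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    patients <- .gen_patients(config)
    adm <- .gen_admission_frame(patients, config)
    sev <- .gen_severity(adm, config)
    ev <- .assign_events(adm, sev, config)
    mat <- .materialize(ev$adm, patients, config)
    adm <- mat$adm
    sev <- sev[sev$admission_uid %in% adm$admission_uid, ]
    sev <- merge(sev,
                 adm[, c("admission_uid", "obs_end_off")],
                 by = "admission_uid")
    sev[, ivl_start := (k - 1L) * 6L * HOUR_MIN]
    sev <- sev[ivl_start < obs_end_off]
    sev[, ivl_end := pmin(k * 6L * HOUR_MIN, obs_end_off)]
    truth <- structure(list(
      admissions = adm[, c("admission_uid", "patient_id", "start", "end",
                           "los_min", "obs_end_off", "outcome", "event_time",
                           "s0", "age_at_start", "eligible", "icu_mid",
                           "icu_post")],
      severity = sev[, c("admission_uid", "patient_id", "k", "s", "start",
                         "ivl_start", "ivl_end")],
      token_effects = .token_effect_table(config),
      planted_attrition = mat$planted_attrition,
      patients_info = mat$patients[, c("patient_id", "frailty", "first_start")],
      hazard_intercept = ev$intercept,
      config = config
    ), class = "wardflow_truth")
    list(patients = mat$patients[, c("patient_id", "sex", "birth_time",
                                     "disconnected")],
         visits = mat$visits,
         deaths = mat$deaths,
         truth = truth)
  })
}

.token_effect_table <- function(cfg) {
  pools <- cfg$risk_token_pools
  eff <- data.table::rbindlist(lapply(names(pools), function(d)
    data.table::data.table(domain = d, token = pools[[d]]$token,
                           weight = pools[[d]]$weight)))
  lp <- cfg$lab_panel
  lab_eff <- data.table::data.table(
    domain = "lab",
    token = paste(lp$component, lp$specimen, lp$unit, sep = "_"),
    weight = lp$direction * cfg$lab_shift
  )
  data.table::rbindlist(list(eff, lab_eff))
}

#' Simulate the latent severity course and event of a single admission
#'
#' Standalone version of the admission-course mechanism used inside
#' [generate_population()]: a severity random walk on the 6 h grid and a
#' per-step logistic hazard for the composite deterioration event. Uses the
#' current RNG state; seed the caller for reproducibility.
#'
#' @param s0 baseline severity at admission start.
#' @param duration_h planned admission duration in hours (> 0).
#' @param config a [synth_config()].
#' @param hazard_intercept logistic hazard intercept; defaults to the value in
#'   `config` or -6 when unset.
#' @return list with `severity` (one value per 6 h interval), `event`
#'   (logical), `event_offset_h` (NA when no event) and `event_type`.
#' @export
simulate_admission_course <- function(s0, duration_h, config,
                                      hazard_intercept = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.finite(duration_h) || duration_h <= 0) {
    stop_config("admission duration must be positive")
  }
  intercept <- hazard_intercept %||% config$hazard_intercept %||% -6
  K <- ceiling(duration_h / 6)
  inc <- config$severity_drift + config$severity_noise * stats::rnorm(K)
  s <- s0 + cumsum(c(0, inc[-1]))
  p <- .hazard_prob(s, intercept, config)
  hit <- which(stats::runif(K) < p)
  if (length(hit) == 0L) {
    return(list(severity = s, event = FALSE, event_offset_h = NA_real_,
                event_type = "discharge"))
  }
  k <- hit[1L]
  len <- min(6, duration_h - (k - 1) * 6)
  off <- (k - 1) * 6 + stats::runif(1) * len
  p_death <- config$target_death_prev /
    (config$target_death_prev + config$target_icu_prev)
  type <- if (stats::runif(1) < p_death) "death" else "icu_transfer"
  list(severity = s, event = TRUE, event_offset_h = off, event_type = type)
}

.clamp_grid <- function(x, lim = 3, step = 0.25) {
  pmin(lim, pmax(-lim, round(x / step) * step))
}

.emit_diagnoses <- function(truth, cfg) {
  pool <- cfg$risk_token_pools$diag
  info <- data.table::as.data.table(truth$patients_info)
  n_dx <- stats::rnbinom(nrow(info), size = cfg$n_dx_size, mu = cfg$n_dx_mean)
  info[, `:=`(n_dx = n_dx, fr_g = .clamp_grid(frailty))]
  out <- vector("list", length(unique(info$fr_g)))
  i <- 0L
  for (g in sort(unique(info$fr_g))) {
    sub <- info[fr_g == g & n_dx > 0]
    if (!nrow(sub)) next
    tot <- sum(sub$n_dx)
    pr <- pool$base * exp(cfg$diag_link * g * pool$weight)
    toks <- sample(pool$token, tot, replace = TRUE, prob = pr)
    i <- i + 1L
    out[[i]] <- data.table::data.table(
      patient_id = rep(sub$patient_id, sub$n_dx),
      first_start = rep(sub$first_start, sub$n_dx),
      token = toks
    )
  }
  dx <- data.table::rbindlist(out[seq_len(i)])
  if (!nrow(dx)) {
    return(data.table::data.table(patient_id = integer(), time = integer(),
                                  code = character()))
  }
  suf <- sample(c("", "1", "9", "0M", "21", "4B"), nrow(dx), replace = TRUE,
                prob = c(0.4, 0.15, 0.15, 0.1, 0.1, 0.1))
  dx[, code := paste0(token, suf)]
  dx[, time := as.integer(first_start -
                            round(stats::runif(.N, DAY_MIN, 10 * YEAR_MIN)))]
  data.table::setorder(dx, patient_id, time)
  dx[, c("patient_id", "time", "code")]
}

.emit_labs <- function(truth, cfg) {
  sev <- truth$severity
  panel <- cfg$lab_panel
  len <- sev$ivl_end - sev$ivl_start
  counts <- stats::rpois(nrow(sev), cfg$lab_rate_6h * len / (6 * HOUR_MIN))
  idx <- rep(seq_len(nrow(sev)), counts)
  if (!length(idx)) {
    return(data.table::data.table(patient_id = integer(), time = integer(),
                                  component = character(),
                                  specimen = character(), unit = character(),
                                  value = numeric()))
  }
  a <- sample(nrow(panel), length(idx), replace = TRUE, prob = panel$base)
  s <- sev$s[idx]
  value <- stats::rnorm(length(idx),
                        panel$mu[a] + panel$direction[a] * cfg$lab_shift * s *
                          panel$sd[a],
                        panel$sd[a])
  labs <- data.table::data.table(
    patient_id = sev$patient_id[idx],
    time = as.integer(sev$start[idx] + sev$ivl_start[idx] +
                        pmax(1, floor(stats::runif(length(idx)) * len[idx]))),
    component = panel$component[a],
    specimen = panel$specimen[a],
    unit = panel$unit[a],
    value = round(pmax(value, 0.01), 2)
  )
  data.table::setorder(labs, patient_id, time)
  labs
}

.note_noise_tokens <- c("og", "i", "paa", "the", "in", "of", "at",
                        ".", ",", ";", "Dr-Jensen", "Dr-Nielsen",
                        "Dr-Sorensen")

.emit_notes <- function(truth, cfg) {
  sev <- data.table::copy(truth$severity)
  pool <- cfg$risk_token_pools$note
  len <- sev$ivl_end - sev$ivl_start
  emit <- stats::runif(nrow(sev)) < cfg$note_prob_6h * len / (6 * HOUR_MIN)
  notes <- sev[emit]
  nlen <- len[emit]
  n_tok <- stats::rpois(nrow(notes), cfg$note_token_rate_6h)
  keep <- n_tok > 0
  notes <- notes[keep]
  nlen <- nlen[keep]
  n_tok <- n_tok[keep]
  if (!nrow(notes)) {
    return(data.table::data.table(patient_id = integer(), time = integer(),
                                  text = character()))
  }
  notes[, `:=`(note_id = seq_len(.N), n_tok = n_tok,
               s_g = .clamp_grid(s))]
  parts <- list()
  for (g in sort(unique(notes$s_g))) {
    sub <- notes[s_g == g]
    tot <- sum(sub$n_tok)
    pr <- pool$base * exp(cfg$note_link * g * pool$weight)
    toks <- sample(pool$token, tot, replace = TRUE, prob = pr)
    parts[[length(parts) + 1L]] <- data.table::data.table(
      note_id = rep(sub$note_id, sub$n_tok), token = toks)
  }
  tok_dt <- data.table::rbindlist(parts)
  # occasional trailing punctuation on content tokens
  punct <- stats::runif(nrow(tok_dt)) < 0.08
  tok_dt[punct, token := paste0(token, ",")]
  # injected stopwords, punctuation and clinician signatures
  n_noise <- stats::rpois(nrow(notes), cfg$note_noise_frac * cfg$note_token_rate_6h)
  noise_dt <- data.table::data.table(
    note_id = rep(notes$note_id, n_noise),
    token = sample(.note_noise_tokens, sum(n_noise), replace = TRUE))
  tok_dt <- data.table::rbindlist(list(tok_dt, noise_dt))
  tok_dt[, ord := stats::runif(.N)]
  data.table::setorder(tok_dt, note_id, ord)
  texts <- tok_dt[, .(text = paste(token, collapse = " ")), by = note_id]
  notes <- merge(notes, texts, by = "note_id")
  out <- data.table::data.table(
    patient_id = notes$patient_id,
    time = as.integer(notes$start + notes$ivl_start +
                        pmax(1, floor(stats::runif(nrow(notes)) *
                                        (notes$ivl_end - notes$ivl_start)))),
    text = notes$text
  )
  data.table::setorder(out, patient_id, time)
  out
}

#' Emit diagnosis, laboratory and note record streams
#'
#' Emission probabilities are tied to the latent severity trajectories in the
#' ground truth: directional analyte values shift with severity, risk tokens
#' are over-emitted when severity is high, and pre-admission diagnosis
#' histories reflect patient frailty. All in-stay timestamps lie inside the
#' admission's observation window (they never exceed the event or discharge
#' time). Uses the current RNG state; [generate_ehr()] seeds it.
#'
#' @param truth a `wardflow_truth` from [generate_population()].
#' @param config the [synth_config()] used to generate it.
#' @return list with `diagnoses`, `labs`, `notes` tables.
#' @export
emit_observations <- function(truth, config) {
  stopifnot(inherits(truth, "wardflow_truth"))
  list(diagnoses = .emit_diagnoses(truth, config),
       labs = .emit_labs(truth, config),
       notes = .emit_notes(truth, config))
}

#' Generate a complete synthetic EHR
#'
#' Runs [generate_population()] and [emit_observations()] under one seed.
#'
#' @param config a [synth_config()].
#' @return a `wardflow_ehr` object: list with `patients`, `visits`,
#'   `diagnoses`, `labs`, `notes`, `deaths`, `truth`, `config`.
#' @export
generate_ehr <- function(config) {
  pop <- generate_population(config)
  obs <- with_seed(config$seed + 1L,
                   emit_observations(pop$truth, config))
  structure(c(pop["patients"], pop["visits"], obs,
              pop["deaths"], pop["truth"], list(config = config)),
            class = "wardflow_ehr")
}

#' Write a synthetic EHR to a directory of CSV files
#'
#' Emits `patients.csv`, `visits.csv`, `diagnoses.csv`, `labs.csv`,
#' `notes.csv`, `deaths.csv` plus ground-truth tables
#' (`truth_admissions.csv`, `truth_severity.csv`, `token_effects.csv`) and
#' `meta.json`.
#'
#' @param ehr a `wardflow_ehr`.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_ehr <- function(ehr, dir) {
  stopifnot(inherits(ehr, "wardflow_ehr"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("patients", "visits", "diagnoses", "labs", "notes", "deaths")) {
    data.table::fwrite(ehr[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  data.table::fwrite(ehr$truth$admissions, file.path(dir, "truth_admissions.csv"))
  data.table::fwrite(ehr$truth$severity, file.path(dir, "truth_severity.csv"))
  data.table::fwrite(ehr$truth$token_effects, file.path(dir, "token_effects.csv"))
  jsonlite::write_json(list(seed = ehr$config$seed,
                            hazard_intercept = ehr$truth$hazard_intercept),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}
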