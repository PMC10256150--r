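#' Default planted token pools for the synthetic generator
#'
#' Each domain gets risk-raising (positive weight), risk-lowering (negative
#' weight) and neutral (zero weight) tokens. Weights act on the log scale of
#' the emission probability: a token with weight w is emitted with probability
#' proportional to `base * exp(link * severity * w)`, so risk tokens are
#' over-represented in deteriorating admissions and protective tokens in
#' uneventful ones. Diagnosis tokens are level-3 ICD-like stems; the generator
#' appends code suffixes so that roll-up is exercised downstream.
#'
#' @return named list of `data.table`s with columns `token`, `weight`, `base`.
#' @export
default_token_pools <- function() {
  diag_risk <- c(
    J96 = 1.6, A41 = 1.5, C34 = 1.4, J18 = 1.3, I50 = 1.2, N17 = 1.2,
    K72 = 1.1, I21 = 1.1, C18 = 1.0, I63 = 0.9
  )
  diag_prot <- c(
    O80 = -1.4, H25 = -1.2, Z38 = -1.2, O26 = -1.1, M17 = -1.0, J35 = -1.0,
    K40 = -0.9, S52 = -0.8, M23 = -0.7, N20 = -0.6
  )
  diag_neutral <- c(
    "I10", "E11", "K21", "E78", "M54", "J45", "F32", "G47", "L20", "H52",
    "K58", "M16", "E03", "F41", "I48", "J30", "K29", "M75", "N39", "R10",
    "E66", "G43", "H66", "I25", "J32", "K80", "L40", "M79", "N40", "R51",
    "D50", "E05", "F10", "G40", "H81", "I83", "J44", "K57", "M25", "R42"
  )
  note_risk <- c(
    severely = 2.0, sepsis = 1.9, deteriorating = 1.8, intensive = 1.8,
    unresponsive = 1.7, palliative = 1.7, hypotension = 1.6, respiratory = 1.5,
    dyspnea = 1.4, metastatic = 1.4, oxygen = 1.3, tachycardia = 1.3,
    confusion = 1.2, lactate = 1.2, febrile = 1.1, relatives = 1.1,
    transfusion = 1.0, chronic = 0.8, edema = 0.8, fatigue = 0.7
  )
  note_prot <- c(
    stable = -1.8, discharge = -1.7, normal = -1.6, home = -1.5,
    improved = -1.5, recovered = -1.4, mobilised = -1.4, ambulating = -1.3,
    walking = -1.2, afebrile = -1.2, control = -1.2, comfortable = -1.1,
    followup = -1.1, independent = -1.1, appetite = -1.0, planned = -1.0,
    rehabilitation = -1.0, eating = -0.9, pain = -0.9, wellbeing = -0.8
  )
  note_neutral <- c(
    "patient", "ward", "nurse", "doctor", "morning", "evening", "medication",
    "dose", "tablet", "blood", "sample", "test", "result", "plan", "review",
    "examination", "abdomen", "chest", "heart", "lung", "skin", "temperature",
    "pressure", "pulse", "breathing", "sleep", "night", "day", "family",
    "report", "record", "note", "status", "observation", "routine",
    "standard", "continued", "assessment", "round", "team", "consultation",
    "fluid", "intake", "output", "diet", "wound", "dressing", "catheter",
    "intravenous", "oral", "injection", "scan", "xray", "ultrasound",
    "referral", "surgery", "anesthesia", "recovery", "bed", "chair",
    "physiotherapy", "social", "summary", "history", "allergy", "weight",
    "height", "admission", "department", "transfer", "arrival", "seen",
    "today", "yesterday", "week", "hours", "stable-angle", "baseline",
    "ongoing", "unchanged"
  )
  list(
    diag = data.table::data.table(
      token = c(names(diag_risk), names(diag_prot), diag_neutral),
      weight = c(unname(diag_risk), unname(diag_prot),
                 rep(0, length(diag_neutral))),
      base = c(rep(0.5, length(diag_risk) + length(diag_prot)),
               rep(1.0, length(diag_neutral)))
    ),
    note = data.table::data.table(
      token = c(names(note_risk), names(note_prot), note_neutral),
      weight = c(unname(note_risk), unname(note_prot),
                 rep(0, length(note_neutral))),
      base = c(rep(0.35, length(note_risk) + length(note_prot)),
               rep(1.0, length(note_neutral)))
    )
  )
}

#' Default laboratory panel for the synthetic generator
#'
#' Eight common analytes with population mean/SD in conventional units and a
#' planted direction: the emitted value is shifted by
#' `direction * lab_shift * severity` standard deviations, so extreme quantile
#' tokens of directional analytes carry outcome signal.
#'
#' @return `data.table` with columns `component`, `specimen`, `unit`, `mu`,
#'   `sd`, `direction`, `base`.
#' @export
default_lab_panel <- function() {
  data.table::data.table(
    component = c("HEMOGLOBIN", "CRP", "CREATININE", "LEUKOCYTES",
                  "POTASSIUM", "SODIUM", "ALBUMIN", "LDH"),
    specimen  = c("B", "P", "P", "B", "P", "P", "P", "P"),
    unit      = c("mmol/L", "mg/L", "umol/L", "10^9/L",
                  "mmol/L", "mmol/L", "g/L", "U/L"),
    mu        = c(8.5, 20, 80, 8, 4.0, 139, 38, 200),
    sd        = c(1.0, 15, 25, 3, 0.45, 4, 5, 60),
    direction = c(-1, 1, 1, 1, 1, -1, -1, 1),
    base      = c(1.2, 1.2, 1.0, 1.2, 1.0, 1.0, 0.8, 0.6)
  )
}

#' Configuration for the synthetic EHR generator
#'
#' Defaults emulate the statistical structure of a large inpatient cohort:
#' composite outcome prevalence 2.2% of admissions (1.5% in-hospital death,
#' 0.7% unplanned ICU transfer), lognormal lengths of stay with median 31 h
#' and quartiles roughly 9-98 h, long pre-admission diagnosis histories
#' (median ~23 codes), sparse irregular laboratory measurements (~19 tokens in
#' the first 24 h) and denser clinical-note token streams (~200 tokens in the
#' first 24 h). A latent per-admission severity random walk on a 6 h grid
#' links the planted token pools to the outcome.
#'
#' @param n_patients number of patients to simulate.
#' @param target_death_prev target in-hospital death prevalence per eligible
#'   admission.
#' @param target_icu_prev target unplanned ICU-transfer prevalence per
#'   eligible admission.
#' @param los_log_median_h lognormal meanlog of length of stay in hours.
#' @param los_log_sigma lognormal sdlog of length of stay.
#' @param max_los_days administrative cap on length of stay, days.
#' @param adm_rate Poisson rate for admissions per patient beyond the first.
#' @param age_mean,age_sd adult age distribution at first admission (years),
#'   truncated to [16, 100].
#' @param frailty_sd SD of the patient-level latent frailty shared by that
#'   patient's admissions.
#' @param age_link severity increase per 20 years of age above 60.
#' @param baseline_noise SD of the admission-specific severity offset.
#' @param severity_drift,severity_noise drift and innovation SD of the
#'   severity random walk per 6 h step.
#' @param severity_link logistic slope of the per-step event hazard in
#'   severity units.
#' @param event_hazard_scale multiplier on the per-step hazard; 0 disables
#'   events entirely.
#' @param hazard_intercept logistic intercept of the per-step hazard; `NULL`
#'   (default) means calibrate by root-finding so the expected composite
#'   prevalence among eligible admissions equals
#'   `target_death_prev + target_icu_prev`.
#' @param icu_post_discharge_frac fraction of ICU-transfer events realized as
#'   an acute ICU admission shortly after ward discharge rather than a
#'   mid-stay transfer.
#' @param icu_los_log_median_h,icu_los_log_sigma lognormal parameters of the
#'   ICU stay that follows a transfer.
#' @param exclusion_fracs named list of planted exclusion-arm fractions:
#'   `minor` (patients aged under 16), `disconnected` (patients with
#'   disconnected history), `outpatient` (patients with extra outpatient
#'   contacts), `acute_ed` (patients with extra acute emergency admissions),
#'   `direct_icu` (patients with an isolated direct ICU admission), and
#'   `late_icu` (uneventful admissions followed by an acute ICU admission
#'   more than 24 h after discharge, which must *not* count as a transfer).
#' @param n_dx_mean,n_dx_size negative-binomial parameters of the number of
#'   pre-admission diagnosis codes per patient.
#' @param diag_link log-linear link from patient frailty to diagnosis-token
#'   emission.
#' @param lab_rate_6h expected laboratory measurements per 6 h interval.
#' @param lab_shift planted value shift per severity unit, in analyte SDs.
#' @param note_prob_6h probability that a clinical note is written in a 6 h
#'   interval.
#' @param note_token_rate_6h expected content tokens per note.
#' @param note_link log-linear link from current severity to note-token
#'   emission.
#' @param note_noise_frac expected fraction of extra stopword, punctuation
#'   and clinician-signature tokens injected into each note.
#' @param risk_token_pools planted token pools, see [default_token_pools()].
#' @param lab_panel analyte panel, see [default_lab_panel()].
#' @param seed integer seed; all generator randomness derives from it.
#' @return a validated `synth_config` object (a list).
#' @export
synth_config <- function(n_patients,
                         target_death_prev = 0.015,
                         target_icu_prev = 0.007,
                         los_log_median_h = log(31),
                         los_log_sigma = 1.75,
                         max_los_days = 28,
                         adm_rate = 0.8,
                         age_mean = 57,
                         age_sd = 20,
                         frailty_sd = 0.7,
                         age_link = 0.35,
                         baseline_noise = 0.5,
                         severity_drift = 0.02,
                         severity_noise = 0.25,
                         severity_link = 1.1,
                         event_hazard_scale = 1,
                         hazard_intercept = NULL,
                         icu_post_discharge_frac = 0.15,
                         icu_los_log_median_h = log(48),
                         icu_los_log_sigma = 0.8,
                         exclusion_fracs = list(minor = 0.03,
                                                disconnected = 0.01,
                                                outpatient = 0.08,
                                                acute_ed = 0.06,
                                                direct_icu = 0.02,
                                                late_icu = 0.03),
                         n_dx_mean = 23,
                         n_dx_size = 3,
                         diag_link = 0.8,
                         lab_rate_6h = 4.5,
                         lab_shift = 0.6,
                         note_prob_6h = 0.9,
                         note_token_rate_6h = 50,
                         note_link = 0.7,
                         note_noise_frac = 0.15,
                         risk_token_pools = default_token_pools(),
                         lab_panel = default_lab_panel(),
                         seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L ||
      !is.finite(n_patients) || n_patients < 1) {
    stop_config("n_patients must be a positive count, got %s",
                deparse(substitute(n_patients)))
  }
  prevs <- c(target_death_prev, target_icu_prev)
  if (any(!is.finite(prevs)) || any(prevs <= 0) || any(prevs >= 1) ||
      sum(prevs) >= 1) {
    stop_config("outcome prevalences must lie in (0,1) and sum to < 1")
  }
  for (d in names(risk_token_pools)) {
    w <- risk_token_pools[[d]]$weight
    if (any(!is.finite(w))) stop_config("non-finite token weight in pool '%s'", d)
  }
  defaults <- list(minor = 0, disconnected = 0, outpatient = 0,
                   acute_ed = 0, direct_icu = 0, late_icu = 0)
  exclusion_fracs <- utils::modifyList(defaults, exclusion_fracs)
  if (any(unlist(exclusion_fracs) < 0) || any(unlist(exclusion_fracs) > 1)) {
    stop_config("exclusion fractions must lie in [0,1]")
  }
  if (event_hazard_scale < 0) stop_config("event_hazard_scale must be >= 0")
  cfg <- as.list(environment())
  cfg$prevs <- NULL
  cfg$defaults <- NULL
  cfg$d <- NULL
  cfg$w <- NULL
  cfg$n_patients <- as.integer(n_patients)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "synth_config"
  cfg
}

#' Strong-signal generator preset
#'
#' A [synth_config()] with the severity-to-observation links raised (lab
#' value shift 0.9 SD, note link 1.05, diagnosis link 1.2, frailty SD 0.8)
#' so that signal-recovery experiments have a clearly learnable planted
#' effect. Outcome prevalences and stay structure are unchanged.
#'
#' @param n_patients number of patients.
#' @param seed integer seed.
#' @param ... further overrides passed to [synth_config()].
#' @return a `synth_config`.
#' @export
synth_config_strong <- function(n_patients, seed = 1L, ...) {
  synth_config(n_patients = n_patients, seed = seed,
               lab_shift = 0.9, note_link = 1.05, diag_link = 1.2,
               frailty_sd = 0.8, ...)
}
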