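# Risk-assessment sampling: materialize (admission, assessment-time) samples
# for an assessment rate (hours between assessments) and prediction window
# (horizon within which the composite outcome is sought). Sequences contain
# only records timestamped at or before the assessment time, so samples are
# leakage-free by construction.

#' Assessment times of an admission
#'
#' Assessments happen at `t = 0` (the doorstep), then every `delta_hours`,
#' strictly before the event or discharge so no sample can contain
#' outcome-coincident data.
#'
#' @param start,end admission start and end, integer minutes.
#' @param event_time event timestamp in minutes or `NA`.
#' @param delta_hours assessment rate in hours (6, 12 or 24 in the default
#'   grid).
#' @param include_doorstep include `t = 0` (default TRUE).
#' @return numeric vector of assessment offsets `t` in hours.
#' @export
assessment_times <- function(start, end, event_time = NA, delta_hours,
                             include_doorstep = TRUE) {
  limit_min <- min(end, event_time, na.rm = TRUE) - start
  if (limit_min <= 0) return(numeric(0))
  t <- seq(0, by = delta_hours,
           length.out = ceiling(limit_min / (delta_hours * HOUR_MIN)))
  t <- t[t * HOUR_MIN < limit_min]
  if (!include_doorstep) t <- t[t > 0]
  t
}

#' Label one risk assessment
#'
#' The label is 1 iff the admission's event falls inside the half-open
#' prediction window `(start + t, start + t + W]`. Discharge alive is 0 even
#' when discharge precedes the window's end.
#'
#' @param event_time event timestamp in minutes, or `NA` for discharge.
#' @param start admission start in minutes.
#' @param t assessment offset in hours.
#' @param window_hours prediction window W in hours.
#' @return integer 0/1 (vectorized over `event_time`, `start`, `t`).
#' @export
label_sample <- function(event_time, start, t, window_hours) {
  lo <- start + t * HOUR_MIN
  hi <- lo + window_hours * HOUR_MIN
  as.integer(!is.na(event_time) & event_time > lo & event_time <= hi)
}

# per-admission record streams as (time, encoded token id) pairs sorted by
# time; ids encoded against the fitted vocabulary once up front.
.collect_streams <- function(ehr, cohort, tokenizer) {
  adm <- data.table::as.data.table(cohort$admissions)
  vocabs <- tokenizer$vocabs

  dx <- data.table::as.data.table(ehr$diagnoses)
  dx <- dx[dx$patient_id %in% adm$patient_id]
  dx[, id := encode_tokens(rollup_icd(code, tokenizer$icd_level),
                           vocabs$diag)]
  data.table::setorder(dx, patient_id, time)

  lb <- data.table::as.data.table(ehr$labs)
  lb <- lb[lb$patient_id %in% adm$patient_id]
  lb[, id := encode_tokens(lab_token(lb, tokenizer$binning), vocabs$lab)]
  data.table::setorder(lb, patient_id, time)

  nt <- data.table::as.data.table(ehr$notes)
  nt <- nt[nt$patient_id %in% adm$patient_id]
  data.table::setorder(nt, patient_id, time)
  toks <- preprocess_notes(nt$text, tokenizer$lexicons)
  lens <- lengths(toks)
  nt_flat <- data.table::data.table(
    patient_id = rep.int(nt$patient_id, lens),
    time = rep.int(nt$time, lens),
    id = encode_tokens(unlist(toks, use.names = FALSE), vocabs$note))

  list(diag = dx[, c("patient_id", "time", "id")],
       lab = lb[, c("patient_id", "time", "id")],
       note = nt_flat)
}

#' Build the assessment-sample set for one (rate, window) cell
#'
#' One sample is created per (admission, assessment time). Each sample's
#' diagnosis sequence uses only codes recorded before the admission start;
#' lab and note sequences use only in-stay records timestamped at or before
#' the assessment time. Static features are age (z-scored with training-split
#' statistics), sex (0/1) and the z-scored number of prior admissions.
#'
#' @param ehr a `wardflow_ehr`.
#' @param cohort a [build_cohort()] result.
#' @param tokenizer a [fit_tokenizer()] result.
#' @param delta_hours assessment rate in hours.
#' @param window_hours prediction window in hours.
#' @param pad_sizes named list of per-domain sequence lengths (defaults
#'   `diag = 9`, `lab = 28`, `note = 48`).
#' @param include_doorstep include the `t = 0` assessment.
#' @param static_stats optional list with `age` and `n_prior` mean/sd to
#'   reuse (e.g. the training statistics of another cell); computed from the
#'   training split when `NULL`.
#' @return a `wardflow_samples` object: list with `meta` (sample metadata,
#'   label, split), `domains` (per-domain `ids` and `mask` integer matrices),
#'   `static` (numeric matrix with columns age, sex, n_prior),
#'   `static_stats`, `delta_hours`, `window_hours`, `pad_sizes`.
#' @export
build_samples <- function(ehr, cohort, tokenizer, delta_hours, window_hours,
                          pad_sizes = list(diag = 9L, lab = 28L, note = 48L),
                          include_doorstep = TRUE, static_stats = NULL) {
  adm <- data.table::as.data.table(cohort$admissions)
  assert_cols(adm, c("admission_id", "patient_id", "start", "end",
                     "event_time", "outcome", "split", "age_at_admission",
                     "sex", "n_prior_admissions"), "admissions")
  streams <- .collect_streams(ehr, cohort, tokenizer)

  # assessment times per admission
  t_list <- mapply(assessment_times, adm$start, adm$end, adm$event_time,
                   MoreArgs = list(delta_hours = delta_hours,
                                   include_doorstep = include_doorstep),
                   SIMPLIFY = FALSE)
  n_per <- lengths(t_list)
  keep <- n_per > 0L
  adm_rep <- adm[rep(which(keep), n_per[keep])]
  t_h <- unlist(t_list[keep], use.names = FALSE)
  n <- nrow(adm_rep)
  meta <- data.table::data.table(
    sample_id = seq_len(n),
    admission_id = adm_rep$admission_id,
    patient_id = adm_rep$patient_id,
    t = t_h,
    label = label_sample(adm_rep$event_time, adm_rep$start, t_h, window_hours),
    outcome = adm_rep$outcome,
    split = adm_rep$split,
    sex = adm_rep$sex,
    age = adm_rep$age_at_admission,
    n_prior = adm_rep$n_prior_admissions
  )

  cut_time <- adm_rep$start + as.integer(round(t_h * HOUR_MIN))
  domains <- list(
    diag = .fill_domain(streams$diag, adm_rep$patient_id,
                        lo = NULL, hi = adm_rep$start - 1L,
                        pad = pad_sizes$diag),
    lab = .fill_domain(streams$lab, adm_rep$patient_id,
                       lo = adm_rep$start, hi = cut_time,
                       pad = pad_sizes$lab),
    note = .fill_domain(streams$note, adm_rep$patient_id,
                        lo = adm_rep$start, hi = cut_time,
                        pad = pad_sizes$note)
  )

  if (is.null(static_stats)) {
    tr <- meta$split == "train"
    if (!any(tr)) tr <- rep(TRUE, nrow(meta))
    static_stats <- list(
      age = c(mean = mean(meta$age[tr]), sd = max(stats::sd(meta$age[tr]), 1e-8)),
      n_prior = c(mean = mean(meta$n_prior[tr]),
                  sd = max(stats::sd(meta$n_prior[tr]), 1e-8)))
  }
  static <- cbind(
    age = (meta$age - static_stats$age[["mean"]]) / static_stats$age[["sd"]],
    sex = as.numeric(meta$sex == "M"),
    n_prior = (meta$n_prior - static_stats$n_prior[["mean"]]) /
      static_stats$n_prior[["sd"]])

  structure(list(meta = meta, domains = domains, static = static,
                 static_stats = static_stats, delta_hours = delta_hours,
                 window_hours = window_hours, pad_sizes = pad_sizes),
            class = "wardflow_samples")
}

# Fill (n_samples x pad) id/mask matrices: for sample i keep the last `pad`
# stream records of patient_i with lo_i <= time <= hi_i (lo NULL = no lower
# bound). Streams are sorted by patient then time; window end/start positions
# come from rolling joins so the per-sample work is a short slice copy.
.fill_domain <- function(stream, patient_id, lo, hi, pad) {
  n <- length(patient_id)
  ids <- matrix(PAD_ID, n, pad)
  mask <- matrix(0L, n, pad)
  if (!nrow(stream)) return(list(ids = ids, mask = mask))
  s <- stream[, c("patient_id", "time", "id")]
  tok <- s$id
  # last stream row with time <= hi within the sample's patient
  q_hi <- data.table::data.table(patient_id = patient_id, time = hi)
  idx_hi <- s[q_hi, on = c("patient_id", "time"), roll = Inf,
              mult = "last", which = TRUE]
  if (is.null(lo)) {
    q_lo <- data.table::data.table(patient_id = patient_id,
                                   time = rep(-.Machine$integer.max, n))
  } else {
    q_lo <- data.table::data.table(patient_id = patient_id, time = lo)
  }
  # first stream row with time >= lo within the sample's patient
  idx_lo <- s[q_lo, on = c("patient_id", "time"), roll = -Inf,
              mult = "first", which = TRUE]
  ok <- !is.na(idx_hi) & !is.na(idx_lo) & idx_hi >= idx_lo
  take_lo <- pmax(idx_lo, idx_hi - pad + 1L)
  len <- idx_hi - take_lo + 1L
  for (i in which(ok)) {
    li <- len[i]
    ids[i, seq_len(li)] <- tok[take_lo[i]:idx_hi[i]]
    mask[i, seq_len(li)] <- 1L
  }
  list(ids = ids, mask = mask)
}

#' Relabel a sample set for a different prediction window
#'
#' Sequences depend only on the assessment rate, so one sample set per rate
#' can be relabelled for every window of the grid.
#'
#' @param samples a `wardflow_samples`.
#' @param cohort the cohort the samples were built from.
#' @param window_hours new prediction window in hours.
#' @return a `wardflow_samples` with updated labels and `window_hours`.
#' @export
relabel_samples <- function(samples, cohort, window_hours) {
  adm <- data.table::as.data.table(cohort$admissions)
  idx <- match(samples$meta$admission_id, adm$admission_id)
  samples$meta$label <- label_sample(adm$event_time[idx], adm$start[idx],
                                     samples$meta$t, window_hours)
  samples$window_hours <- window_hours
  samples
}

#' Subset a sample set by row index
#' @param samples a `wardflow_samples`.
#' @param idx integer row indices into `samples$meta`.
#' @return a `wardflow_samples` restricted to those samples.
#' @export
subset_samples <- function(samples, idx) {
  samples$meta <- samples$meta[idx]
  samples$domains <- lapply(samples$domains, function(d)
    list(ids = d$ids[idx, , drop = FALSE], mask = d$mask[idx, , drop = FALSE]))
  samples$static <- samples$static[idx, , drop = FALSE]
  samples
}

#' Number of samples
#' @param samples a `wardflow_samples`.
#' @return integer count.
#' @export
n_samples <- function(samples) nrow(samples$meta)
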