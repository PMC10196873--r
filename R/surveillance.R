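# Electronic NV-HAP surveillance definition.
#
# An admission meets the definition when, after >= 2 days of stable or
# improving oxygenation, oxygenation worsens (escalated oxygen device or a
# drop in minimum SpO2 of at least `spo2_drop` points relative to the
# baseline day) sustained for >= 2 days, AND an abnormal temperature
# (<=36 or >=38 C) or white-cell count (<4 or >=12 x10^3/mm^3) occurs near
# onset, AND chest imaging is completed near onset, AND a new antimicrobial
# course of >= 3 days begins on the first or second day of deterioration.
# Patients on a ventilator at baseline are excluded (that is VAP, not NV-HAP).

#' Oxygen-device escalation ladder
#'
#' Devices in increasing order of support; the rank of a device is its
#' 0-based position (room air 0 ... ventilator 7).
#' @return character vector of the 8 accepted device names.
#' @export
oxygen_devices <- function() {
  c("none", "nasal cannula", "simple mask", "oxygen conserving device",
    "nonrebreather mask", "high flow nasal cannula", "bipap", "ventilator")
}

#' Rank an oxygen device on the escalation ladder
#'
#' @param device character vector of device names (case-insensitive); `NA`
#'   is treated as no supplemental oxygen (rank 0).
#' @return integer ranks 0-7.
#' @export
rank_oxygen_device <- function(device) {
  lv <- oxygen_devices()
  d <- tolower(as.character(device))
  r <- match(d, lv) - 1L
  bad <- unique(d[!is.na(d) & is.na(r)])
  if (length(bad))
    .stop_cls("nvhap_vocab_error",
              "unknown oxygen device(s): %s (accepted: %s)",
              paste(bad, collapse = ", "), paste(lv, collapse = ", "))
  r[is.na(d)] <- 0L
  r
}

#' Surveillance tuning parameters
#'
#' @param spo2_drop SpO2 decrease (percentage points vs the baseline day)
#'   counted as deterioration; default 3.
#' @param temp_wbc_window half-width (days) of the window around onset in
#'   which an abnormal temperature/WBC may occur; default 2.
#' @param imaging_window relative window (days from onset) for chest imaging;
#'   default `c(-1, 2)`.
#' @param abx_lookback antimicrobial-free days required before a course
#'   counts as new; default 2.
#' @param abx_min_run minimum length (days) of the new course; default 3.
#' @param normal_spo2 saturation imputed for unmeasured days; default 97.
#' @return a list of class `nvhap_surv_params`.
#' @export
surveillance_params <- function(spo2_drop = 3, temp_wbc_window = 2,
                                imaging_window = c(-1, 2), abx_lookback = 2,
                                abx_min_run = 3, normal_spo2 = 97) {
  stopifnot(spo2_drop > 0, temp_wbc_window >= 0, length(imaging_window) == 2,
            imaging_window[1] <= imaging_window[2], abx_lookback >= 1,
            abx_min_run >= 1)
  structure(list(spo2_drop = spo2_drop, temp_wbc_window = temp_wbc_window,
                 imaging_window = imaging_window, abx_lookback = abx_lookback,
                 abx_min_run = abx_min_run, normal_spo2 = normal_spo2),
            class = "nvhap_surv_params")
}

# worse-than comparison between two oxygenation states
.oxy_worse <- function(rank_a, spo2_a, rank_b, spo2_b, delta) {
  (rank_a > rank_b) | (spo2_a <= spo2_b - delta)
}

#' Candidate onset days of sustained oxygenation deterioration
#'
#' Day `d` is a candidate when days `d` and `d+1` are both worse than the
#' baseline day `d-1` (device rank above baseline, or SpO2 at least `delta`
#' points below baseline) and the preceding days were stable or improving
#' (day `d-1` not worse than `d-2`, and, when day `d-3` exists, `d-2` not
#' worse than `d-3`). Requires `d >= 3` and `d+1 <= los`.
#'
#' @param device_rank,spo2_min per-day vectors for contiguous days `1..los`
#'   (post-imputation: no missing values).
#' @param delta SpO2 deterioration margin in percentage points.
#' @return integer vector of candidate onset days (ascending; possibly empty).
#' @export
detect_sustained_deterioration <- function(device_rank, spo2_min, delta = 3) {
  los <- length(device_rank)
  stopifnot(length(spo2_min) == los, delta > 0)
  if (los < 4L) return(integer())
  d <- 3:(los - 1L)
  worse_vs <- function(a, b) .oxy_worse(device_rank[a], spo2_min[a],
                                        device_rank[b], spo2_min[b], delta)
  cand <- worse_vs(d, d - 1L) & worse_vs(d + 1L, d - 1L) &
    !worse_vs(d - 1L, d - 2L) &
    (d == 3L | !worse_vs(pmax(d - 2L, 2L), pmax(d - 3L, 1L)))
  d[cand]
}

#' Abnormal temperature / white-cell count near onset
#'
#' True when any day in `[onset - window, onset + window]` (within the stay)
#' has `temp_min <= 36`, `temp_max >= 38` (degrees C), `wbc < 4` or
#' `wbc >= 12` (10^3 cells/mm^3). Missing values never satisfy.
#'
#' @param daily daily table (one admission) with `day`, `temp_min`,
#'   `temp_max`, `wbc`.
#' @param onset_day candidate onset day.
#' @param window half-width in days (default 2).
#' @return list with `met` and, when met, the first qualifying `day` and
#'   `trigger` (`"temperature"` or `"wbc"`).
#' @export
check_temp_wbc <- function(daily, onset_day, window = 2) {
  daily <- as.data.table(daily)
  w <- daily[day >= onset_day - window & day <= onset_day + window]
  temp_hit <- (!is.na(w$temp_min) & w$temp_min <= 36) |
              (!is.na(w$temp_max) & w$temp_max >= 38)
  wbc_hit  <- !is.na(w$wbc) & (w$wbc < 4 | w$wbc >= 12)
  hit <- temp_hit | wbc_hit
  if (!any(hit)) return(list(met = FALSE, day = NA_integer_, trigger = NA_character_))
  i <- which(hit)[1]
  list(met = TRUE, day = w$day[i],
       trigger = if (temp_hit[i]) "temperature" else "wbc")
}

#' Chest imaging near onset
#'
#' @param daily daily table (one admission) with `day`, `chest_imaging`.
#' @param onset_day candidate onset day.
#' @param window relative window, default `c(-1, 2)` days from onset.
#' @return list with `met` and first qualifying `day`.
#' @export
check_imaging <- function(daily, onset_day, window = c(-1, 2)) {
  daily <- as.data.table(daily)
  w <- daily[day >= onset_day + window[1] & day <= onset_day + window[2] &
               !is.na(chest_imaging) & chest_imaging]
  list(met = nrow(w) > 0, day = if (nrow(w)) min(w$day) else NA_integer_)
}

#' New multi-day antimicrobial course starting at deterioration
#'
#' True when a course starts on the first or second day of deterioration
#' (`s` in `{onset, onset+1}`), is *new* (no antimicrobial administration in
#' the `lookback` days before `s`), and covers `min_run` consecutive days
#' (`s .. s+min_run-1`, agents may differ across days). Courses truncated by
#' discharge or death count only if at least `min_run` days were observed.
#'
#' @param meds medication table (one admission) with `day`, `agent_id`.
#' @param onset_day candidate onset day.
#' @param los length of stay (days observed).
#' @param lookback antimicrobial-free days required before the start.
#' @param min_run minimum course length in days.
#' @return list with `met`, `start_day`, `days`, `agents`.
#' @export
check_new_antimicrobials <- function(meds, onset_day, los, lookback = 2,
                                     min_run = 3) {
  meds <- as.data.table(meds)
  covered <- sort(unique(meds$day))
  for (s in c(onset_day, onset_day + 1L)) {
    if (s + min_run - 1L > los) next
    run_days <- s:(s + min_run - 1L)
    prior <- max(1L, s - lookback):(s - 1L)
    if (all(run_days %in% covered) && !any(prior %in% covered)) {
      return(list(met = TRUE, start_day = s, days = run_days,
                  agents = sort(unique(meds[day %in% run_days, agent_id]))))
    }
  }
  list(met = FALSE, start_day = NA_integer_, days = integer(), agents = character())
}

# evaluate full conjunction for one admission; daily must be imputed & sorted
.detect_one <- function(daily, meds, params) {
  los <- nrow(daily)
  rk <- rank_oxygen_device(daily$o2_device)
  cands <- detect_sustained_deterioration(rk, daily$spo2_min, params$spo2_drop)
  for (d in cands) {
    if (rk[d - 1L] == 7L || rk[d - 2L] == 7L) next  # ventilated at baseline
    tw <- check_temp_wbc(daily, d, params$temp_wbc_window)
    if (!tw$met) next
    im <- check_imaging(daily, d, params$imaging_window)
    if (!im$met) next
    ab <- check_new_antimicrobials(meds, d, los, params$abx_lookback,
                                   params$abx_min_run)
    if (!ab$met) next
    return(data.table(
      hosp_id = daily$hosp_id[1], onset_day = as.integer(d),
      baseline_device = daily$o2_device[d - 1L],
      temp_wbc_day = as.integer(tw$day), temp_wbc_trigger = tw$trigger,
      imaging_day = as.integer(im$day),
      abx_start_day = as.integer(ab$start_day),
      abx_agents = paste(ab$agents, collapse = ";")))
  }
  NULL
}

#' Detect an NV-HAP surveillance event in one admission
#'
#' Applies the full conjunction to each candidate onset day in order and
#' returns the first day on which every criterion holds (at most one event
#' per admission). Admissions ventilated on either stable baseline day are
#' excluded at that candidate.
#'
#' @param daily daily records for a single admission (imputed; days 1..los).
#' @param meds medication rows for the same admission (may be empty).
#' @param params a [surveillance_params()] list.
#' @return one-row `data.table` of evidence, or `NULL` when no event.
#' @export
detect_nvhap <- function(daily, meds = NULL, params = surveillance_params()) {
  daily <- as.data.table(daily)[order(day)]
  if (!"hosp_id" %in% names(daily)) daily[, hosp_id := "(admission)"]
  daily <- impute_normal_oxygenation(daily, params$normal_spo2)
  if (is.null(meds)) meds <- data.table(hosp_id = character(),
                                        day = integer(), agent_id = character())
  .detect_one(daily, as.data.table(meds), params)
}

#' Apply the surveillance definition to a whole dataset
#'
#' Vectorized screening: candidate deterioration days are located for every
#' admission at once; the remaining criteria are evaluated only for the
#' (few) admissions with candidates. Equivalent to [detect_nvhap()] per
#' admission.
#'
#' @param ds a validated `nvhap_dataset`.
#' @param params a [surveillance_params()] list.
#' @return `data.table` of events (zero rows when none), columns: `hosp_id`,
#'   `onset_day`, `baseline_device`, `temp_wbc_day`, `temp_wbc_trigger`,
#'   `imaging_day`, `abx_start_day`, `abx_agents`.
#' @export
detect_events <- function(ds, params = surveillance_params()) {
  daily <- impute_normal_oxygenation(ds$daily, params$normal_spo2)
  daily <- daily[order(hosp_id, day)]
  daily[, rk := rank_oxygen_device(o2_device)]
  delta <- params$spo2_drop
  # lag-k comparisons within admission
  daily[, `:=`(
    rk1 = shift(rk, 1L), sp1 = shift(spo2_min, 1L),
    rk2 = shift(rk, 2L), sp2 = shift(spo2_min, 2L),
    rk3 = shift(rk, 3L), sp3 = shift(spo2_min, 3L),
    rk_next = shift(rk, -1L), sp_next = shift(spo2_min, -1L)), by = hosp_id]
  daily[, los := max(day), by = hosp_id]
  daily[, cand :=
    day >= 3L & day + 1L <= los &
    .oxy_worse(rk, spo2_min, rk1, sp1, delta) &
    .oxy_worse(rk_next, sp_next, rk1, sp1, delta) &
    !.oxy_worse(rk1, sp1, rk2, sp2, delta) &
    (day == 3L | !.oxy_worse(rk2, sp2, rk3, sp3, delta))]
  flagged <- unique(daily[cand == TRUE, hosp_id])
  out <- vector("list", length(flagged))
  meds <- ds$medications
  for (i in seq_along(flagged)) {
    h <- flagged[i]
    out[[i]] <- .detect_one(daily[hosp_id == h], meds[hosp_id == h], params)
  }
  daily[, c("rk", "rk1", "sp1", "rk2", "sp2", "rk3", "sp3", "rk_next",
            "sp_next", "los", "cand") := NULL]
  ev <- rbindlist(out[!vapply(out, is.null, logical(1))])
  if (!nrow(ev))
    ev <- data.table(hosp_id = character(), onset_day = integer(),
                     baseline_device = character(), temp_wbc_day = integer(),
                     temp_wbc_trigger = character(), imaging_day = integer(),
                     abx_start_day = integer(), abx_agents = character())
  ev[]
}
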