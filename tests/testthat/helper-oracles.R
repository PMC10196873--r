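# Independent brute-force oracles and shared fixtures. These are written as
# plain loops, deliberately independent of the package's vectorized paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- discrete-time Aalen-Johansen by day-by-day tabulation -------------------
aj_oracle <- function(pd, w = rep(1, nrow(pd)), horizon = max(pd$t)) {
  days <- seq.int(min(pd$t), horizon)
  surv_prev <- 1
  F_death <- F_discharge <- 0
  out <- data.frame(t = days, F_death = NA_real_, F_discharge = NA_real_,
                    surv = NA_real_)
  for (k in seq_along(days)) {
    d <- days[k]
    rows <- which(pd$t == d & w > 0)
    denom <- sum(w[rows])
    ld <- if (denom > 0) sum(w[rows][pd$death_today[rows]]) / denom else 0
    ls <- if (denom > 0) sum(w[rows][pd$discharge_today[rows]]) / denom else 0
    F_death <- F_death + ld * surv_prev
    F_discharge <- F_discharge + ls * surv_prev
    surv_prev <- surv_prev * (1 - ld - ls)
    out$F_death[k] <- F_death
    out$F_discharge[k] <- F_discharge
    out$surv[k] <- surv_prev
  }
  out
}

# random competing-risks person-day table for estimator equivalence checks
random_pd <- function(n_subj, max_t = 8, p_death = 0.12, p_dis = 0.25,
                      weighted = TRUE) {
  rows <- list()
  for (i in seq_len(n_subj)) {
    t <- 1L
    repeat {
      u <- runif(1)
      death <- u < p_death
      dis <- !death && u < p_death + p_dis
      rows[[length(rows) + 1L]] <- data.frame(
        hosp_id = sprintf("S%03d", i), t = t,
        death_today = death, discharge_today = dis,
        nvhap_onset_today = FALSE, at_risk = TRUE)
      if (death || dis || t >= max_t) break
      t <- t + 1L
    }
  }
  pd <- do.call(rbind, rows)
  pd$weight <- if (weighted) rexp(nrow(pd)) + 0.05 else 1
  pd
}

# -- brute-force surveillance oracle ----------------------------------------
# enumerates every day as a potential onset and re-derives each criterion
# with naive scans; returns the first qualifying onset day or NA.
surveillance_oracle <- function(daily, meds, delta = 3, tw_window = 2,
                                img_window = c(-1, 2), lookback = 2,
                                min_run = 3, normal_spo2 = 97) {
  daily <- daily[order(daily$day), ]
  los <- nrow(daily)
  spo2 <- ifelse(is.na(daily$spo2_min), normal_spo2, daily$spo2_min)
  dev <- ifelse(is.na(daily$o2_device), "none", daily$o2_device)
  ladder <- c("none", "nasal cannula", "simple mask", "oxygen conserving device",
              "nonrebreather mask", "high flow nasal cannula", "bipap",
              "ventilator")
  rk <- match(tolower(dev), ladder) - 1L
  worse <- function(a, b) rk[a] > rk[b] || spo2[a] <= spo2[b] - delta
  med_days <- sort(unique(meds$day))
  for (d in seq_len(los)) {
    if (d < 3 || d + 1 > los) next
    if (!(worse(d, d - 1) && worse(d + 1, d - 1))) next
    if (worse(d - 1, d - 2)) next
    if (d - 3 >= 1 && worse(d - 2, d - 3)) next
    if (rk[d - 1] == 7 || rk[d - 2] == 7) next
    # temp / wbc
    tw <- FALSE
    for (k in max(1, d - tw_window):min(los, d + tw_window)) {
      tm <- daily$temp_min[k]; tx <- daily$temp_max[k]; wb <- daily$wbc[k]
      if ((!is.na(tm) && tm <= 36) || (!is.na(tx) && tx >= 38) ||
          (!is.na(wb) && (wb < 4 || wb >= 12))) { tw <- TRUE; break }
    }
    if (!tw) next
    # imaging
    img <- FALSE
    for (k in max(1, d + img_window[1]):min(los, d + img_window[2]))
      if (isTRUE(daily$chest_imaging[k])) { img <- TRUE; break }
    if (!img) next
    # new antimicrobials
    abx <- FALSE
    for (s in c(d, d + 1)) {
      if (s + min_run - 1 > los) next
      run_ok <- all((s:(s + min_run - 1)) %in% med_days)
      new_ok <- !any((max(1, s - lookback):(s - 1)) %in% med_days)
      if (run_ok && new_ok) { abx <- TRUE; break }
    }
    if (!abx) next
    return(d)
  }
  NA_integer_
}

# -- shared planted fixtures -------------------------------------------------
# canonical detectable event: stable room air days 1-2, nasal cannula with
# SpO2 drop days 3-5, fever + imaging day 3, new antimicrobial days 3-5
event_fixture <- function(los = 5) {
  daily <- data.frame(
    day = 1:los,
    o2_device = c("none", "none", rep("nasal cannula", los - 2)),
    spo2_min = c(97, 97, rep(92, los - 2)),
    temp_min = rep(36.6, los), temp_max = c(37, 37, 38.6, rep(37, los - 3)),
    wbc = rep(8, los),
    chest_imaging = c(FALSE, FALSE, TRUE, rep(FALSE, los - 3)))
  meds <- data.frame(day = 3:5, agent_id = "agent_a")
  plant_fixture(daily, meds)
}

zero_noise <- function() list(spo2_jitter_sd = 0, background_abx_prob = 0,
                              background_imaging_rate = 0,
                              background_fever_rate = 0)

truth_events <- function(truth) truth[!is.na(truth$true_nvhap_day), ]
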