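# Attributable mortality of NV-HAP under hypothetical elimination.
#
# Discrete-time competing-risk analysis on a person-day file: cumulative
# incidence of inpatient death (competing event: alive discharge, hospice
# included) to a 60-day horizon is estimated with a weighted Aalen-Johansen
# estimator under (1) current care (unit weights, events left in place) and
# (2) hypothetical elimination of NV-HAP (follow-up censored at onset,
# inverse-probability weights from a pooled daily logistic propensity model
# so that the remaining NV-HAP-free person-days stand in for the full
# population). Confidence intervals come from a clustered nonparametric
# bootstrap resampling hospitalizations with replacement.

#' Parameters of the attributable-mortality pipeline
#'
#' @param horizon follow-up horizon in days (60 primary, 30 sensitivity).
#' @param day_effect `"spline"` (restricted cubic spline on hospital day,
#'   default) or `"categorical"` (one parameter per day).
#' @param spline_df degrees of freedom of the natural spline day effect
#'   (3 df = 4 knots).
#' @param truncation_quantile upper quantile at which elimination weights
#'   are truncated (default 0.99).
#' @param stabilized multiply weights by the marginal probability of
#'   remaining NV-HAP-free (default `FALSE`: unstabilized).
#' @param normal_spo2 imputation constant for unmeasured oxygenation.
#' @return list of class `nvhap_causal_params`.
#' @export
causal_params <- function(horizon = 60, day_effect = c("spline", "categorical"),
                          spline_df = 3, truncation_quantile = 0.99,
                          stabilized = FALSE, normal_spo2 = 97) {
  structure(list(horizon = as.integer(horizon),
                 day_effect = match.arg(day_effect),
                 spline_df = spline_df,
                 truncation_quantile = truncation_quantile,
                 stabilized = stabilized, normal_spo2 = normal_spo2),
            class = "nvhap_causal_params")
}

.routine_labs <- c("wbc", "hematocrit", "platelets", "sodium", "glucose",
                   "creatinine")

#' Cohort eligible for the weighted analysis
#'
#' Keeps hospitalizations of at least 3 days with a recorded value on day 1
#' or day 2 for each of: hospital service, white blood cell count,
#' hematocrit, platelets, sodium, glucose, creatinine.
#'
#' @param ds a validated `nvhap_dataset`.
#' @return character vector of eligible `hosp_id`s.
#' @export
eligible_cohort <- function(ds) {
  hosp <- ds$hospitalizations
  early <- ds$daily[day <= 2L]
  ok <- early[, c(list(service_ok = any(!is.na(service))),
                  lapply(.SD, function(x) any(!is.na(x)))),
              by = hosp_id, .SDcols = .routine_labs]
  complete <- ok[rowSums(as.matrix(ok[, -1])) == ncol(ok) - 1L, hosp_id]
  sort(intersect(hosp[los >= 3L, hosp_id], complete))
}

# restrict a dataset to a set of admissions
subset_dataset <- function(ds, ids) {
  structure(list(
    facilities = ds$facilities,
    hospitalizations = ds$hospitalizations[hosp_id %in% ids],
    daily = ds$daily[hosp_id %in% ids],
    medications = ds$medications[hosp_id %in% ids]
  ), class = "nvhap_dataset")
}

# accept detector output (onset_day) or ground truth (true_nvhap_day)
.normalize_events <- function(events) {
  ev <- as.data.table(events)
  col <- intersect(c("onset_day", "true_nvhap_day"), names(ev))[1]
  if (!nrow(ev) || is.na(col))
    return(data.table(hosp_id = character(), onset_day = integer()))
  ev <- ev[!is.na(get(col)), .(hosp_id, onset_day = as.integer(get(col)))]
  if (any(ev$onset_day < 3L))
    .stop_cls("nvhap_integrity_error", "event onset before day 3")
  ev
}

.ordinal_lab_cat <- function(x, kind) {
  lev <- c("not_measured", "normal", "abnormal")
  out <- rep("not_measured", length(x))
  abn <- switch(kind, alt = x > 40, bilirubin = x > 1.2, albumin = x < 3)
  out[!is.na(x)] <- ifelse(abn[!is.na(x)], "abnormal", "normal")
  factor(out, levels = lev)
}

#' Build the person-day analysis file
#'
#' One row per hospitalization-day for days 3..min(los, horizon). Each row
#' carries the outcome indicators of that day (onset / death / discharge,
#' terminal events only inside the horizon — later stays are
#' administratively censored), baseline covariates, and time-varying
#' covariates as of two days prior: last-observation-carried-forward labs
#' (with days since the last routine panel), service, ICU status, oxygen
#' device rank and minimum SpO2 (missing oxygenation imputed normal), and
#' ordered categories (not measured / normal / abnormal) for the nonroutine
#' labs ALT, bilirubin and albumin. A value recorded only on day 2 backs
#' up the day-3 row, where no observation two days prior exists yet.
#'
#' @param ds a validated `nvhap_dataset` (already restricted to the
#'   eligible cohort).
#' @param events event table (`hosp_id`, `onset_day`) from [detect_events()]
#'   or ground truth.
#' @param horizon follow-up horizon in days.
#' @param normal_spo2 oxygenation imputation constant.
#' @return a `data.table`, one row per person-day, ordered by (hosp_id, t).
#' @export
build_person_days <- function(ds, events, horizon = 60, normal_spo2 = 97) {
  ev <- .normalize_events(events)
  daily <- impute_normal_oxygenation(ds$daily, normal_spo2)
  daily <- daily[order(hosp_id, day)]
  daily[, device_rank := rank_oxygen_device(o2_device)]
  daily[, panel_day := fifelse(
    rowSums(!is.na(as.matrix(.SD))) > 0, day, NA_integer_),
    .SDcols = .routine_labs]
  lag_cols <- c(.routine_labs, "alt", "bilirubin", "albumin",
                "spo2_min", "device_rank")
  daily[, (paste0(lag_cols, "_lag2")) := lapply(.SD, function(v) {
    locf <- nafill(v, type = "locf")
    l2 <- shift(locf, 2L)
    first_v <- v[which(!is.na(v))[1]]
    if (!is.na(first_v)) l2[is.na(l2)] <- first_v
    l2
  }), by = hosp_id, .SDcols = lag_cols]
  daily[, `:=`(service_lag2 = shift(service, 2L),
               icu_lag2 = shift(icu, 2L),
               last_panel_lag2 = shift(nafill(panel_day, type = "locf"), 2L)),
        by = hosp_id]
  # days from the last routine panel known two days prior to the current day
  daily[, days_since_lab := day - fifelse(is.na(last_panel_lag2), 0L,
                                          last_panel_lag2)]

  hosp <- ds$hospitalizations[ds$facilities, on = "facility_id", nomatch = NULL]
  pd <- daily[day >= 3L][hosp, on = "hosp_id", nomatch = NULL]
  pd <- pd[day <= pmin(los, horizon)]
  pd <- pd[ev, on = "hosp_id", onset_day := i.onset_day]
  pd[, `:=`(
    t = day,
    at_risk = is.na(onset_day) | day <= onset_day,
    nvhap_onset_today = !is.na(onset_day) & day == onset_day,
    death_today = day == los & los <= horizon & disposition == "death",
    discharge_today = day == los & los <= horizon & disposition != "death",
    alt_cat = .ordinal_lab_cat(alt_lag2, "alt"),
    bilirubin_cat = .ordinal_lab_cat(bilirubin_lag2, "bilirubin"),
    albumin_cat = .ordinal_lab_cat(albumin_lag2, "albumin"))]
  keep <- c("hosp_id", "t", "at_risk", "nvhap_onset_today", "death_today",
            "discharge_today", "onset_day",
            "bed_size_class", "teaching", "region", "age", "race", "sex",
            .comorbidity_flags, "elixhauser_index", "prior_90d_admission",
            "service_lag2", "icu_lag2", "device_rank_lag2", "spo2_min_lag2",
            paste0(setdiff(.routine_labs, "wbc"), "_lag2"),
            "days_since_lab", "alt_cat", "bilirubin_cat", "albumin_cat")
  out <- pd[, keep, with = FALSE]
  setorder(out, hosp_id, t)
  out[]
}

#' Default covariate terms of the daily propensity model
#'
#' Time-fixed terms (facility size, teaching status, region, age, race,
#' sex, comorbidity flags, comorbidity index, prior 90-day admission) and
#' lag-2 time-varying terms (service, ICU, oxygen device rank, SpO2,
#' routine labs — right-skewed labs on the log scale — days since the last
#' routine panel, and nonroutine lab categories).
#'
#' @return character vector of model terms.
#' @export
propensity_covariates <- function() {
  c("bed_size_class", "teaching", "region", "age", "race", "sex",
    .comorbidity_flags, "elixhauser_index", "prior_90d_admission",
    "service_lag2", "icu_lag2", "device_rank_lag2", "spo2_min_lag2",
    "hematocrit_lag2", "log(platelets_lag2)", "sodium_lag2",
    "log(glucose_lag2)", "log(creatinine_lag2)", "days_since_lab",
    "alt_cat", "bilirubin_cat", "albumin_cat")
}

#' Fit the pooled daily propensity model for NV-HAP onset
#'
#' Pooled logistic regression over at-risk (in hospital, alive,
#' NV-HAP-free through the previous day) person-days: the outcome is onset
#' on the day, with a flexible hospital-day effect (natural cubic spline by
#' default, or one parameter per day) plus the confounder terms. With a
#' categorical day effect and no covariates the fitted probability equals
#' the empirical onset hazard of each day. With no onsets at all the model
#' degenerates to probability 0 (all weights 1).
#'
#' @param person_days output of [build_person_days()].
#' @param params a [causal_params()] list.
#' @param covariates character vector of model terms (default
#'   [propensity_covariates()]; `character(0)` for a day-effect-only model).
#' @return object of class `nvhap_propensity`: the fitted model plus
#'   `p_hat`, a `data.table` (`hosp_id`, `t`, `p_hat`) for every at-risk row.
#' @export
fit_daily_propensity <- function(person_days, params = causal_params(),
                                 covariates = propensity_covariates()) {
  ar <- person_days[at_risk == TRUE]
  n_onset <- sum(ar$nvhap_onset_today)
  if (n_onset == 0L) {
    return(structure(list(fit = NULL, n_onset = 0L,
                          p_hat = ar[, .(hosp_id, t, p_hat = 0)]),
                     class = "nvhap_propensity"))
  }
  day_term <- if (params$day_effect == "categorical") "factor(t)"
              else sprintf("splines::ns(t, df = %d)", params$spline_df)
  fml <- as.formula(paste("nvhap_onset_today ~",
                          paste(c(day_term, covariates), collapse = " + ")))
  dat <- as.data.frame(ar)
  # fixed factor levels so bootstrap resamples keep a consistent design
  for (col in c("bed_size_class", "region", "race", "sex", "service_lag2"))
    if (col %in% names(dat))
      dat[[col]] <- factor(dat[[col]], levels = sort(unique(person_days[[col]])))
  fit <- suppressWarnings(glm(fml, family = binomial(), data = dat,
                              model = FALSE, y = FALSE,
                              na.action = stats::na.fail))
  p <- as.numeric(fit$fitted.values)
  if (!fit$converged || any(p >= 1 - 1e-10)) {
    p <- .ridge_propensity(fml, dat, p)
  }
  structure(list(fit = fit, n_onset = n_onset, formula = fml,
                 p_hat = data.table(hosp_id = ar$hosp_id, t = ar$t, p_hat = p)),
            class = "nvhap_propensity")
}

# weak ridge fallback when the MLE separates
.ridge_propensity <- function(fml, dat, p_default) {
  if (!requireNamespace("glmnet", quietly = TRUE)) {
    warning("propensity model did not converge and glmnet is unavailable; ",
            "capping fitted probabilities")
    return(pmin(p_default, 1 - 1e-8))
  }
  warning("propensity model separation detected; refitting with weak ridge penalty")
  mm <- model.matrix(fml, dat)[, -1, drop = FALSE]
  y <- dat$nvhap_onset_today
  fit <- glmnet::glmnet(mm, y, family = "binomial", alpha = 0, lambda = 1e-4)
  as.numeric(predict(fit, mm, type = "response"))
}

#' Inverse-probability weights for the elimination scenario
#'
#' Under hypothetical elimination of NV-HAP, follow-up is censored at onset
#' (the onset day and all later days receive weight 0) and each remaining
#' NV-HAP-free person-day of subject *i* at day *t* is weighted by
#' `W_i(t) = prod_{k=3..t} 1 / (1 - p_hat_i(k))`, the inverse probability of
#' having remained NV-HAP-free. Weights are truncated at the configured
#' upper quantile. A fitted probability of 1 anywhere is a positivity
#' violation and aborts.
#'
#' @param person_days output of [build_person_days()].
#' @param model a fitted `nvhap_propensity`.
#' @param truncation_quantile upper truncation quantile (default 0.99; 1
#'   disables truncation).
#' @param stabilized use the marginal NV-HAP-free probability as numerator.
#' @return copy of `person_days` with columns `p_hat` and `weight`.
#' @export
elimination_weights <- function(person_days, model,
                                truncation_quantile = 0.99,
                                stabilized = FALSE) {
  pd <- copy(person_days)
  pd[model$p_hat, on = c("hosp_id", "t"), p_hat := i.p_hat]
  pd[is.na(p_hat), p_hat := 0]  # post-onset rows: not in the at-risk fit
  if (any(pd$p_hat >= 1))
    .stop_cls("nvhap_positivity_error",
              "fitted daily onset probability reached 1; positivity violated")
  setorder(pd, hosp_id, t)
  pd[, uncensored := at_risk & !nvhap_onset_today]
  if (stabilized) {
    marg <- pd[at_risk == TRUE,
               .(h = sum(nvhap_onset_today) / .N), keyby = t]
    marg[, s_free := cumprod(1 - h)]
    pd[marg, on = "t", s_marg := i.s_free]
  }
  pd[, weight := 0]
  pd[uncensored == TRUE, weight := cumprod(1 / (1 - p_hat)), by = hosp_id]
  if (stabilized) pd[uncensored == TRUE, weight := weight * s_marg]
  if (truncation_quantile < 1 && any(pd$uncensored)) {
    cap <- quantile(pd[uncensored == TRUE, weight], truncation_quantile,
                    names = FALSE)
    pd[weight > cap, weight := cap]
  }
  pd[, uncensored := NULL]
  pd[]
}

#' Weighted Aalen-Johansen cumulative incidence of death and discharge
#'
#' Discrete-time estimator on person-days: at each day `t` the
#' cause-specific hazard of event `e` is the weighted share of day-`t`
#' person-days ending in `e`; overall survival is the running product of
#' `1 - hazard_death - hazard_discharge`; the cumulative incidence of `e`
#' accumulates `hazard_e(t) * S(t-1)`. Days with an empty risk set carry
#' zero hazards (the curves stay flat). Weights enter only as ratios, so
#' rescaling all weights leaves the curves unchanged.
#'
#' @param person_days person-day table with `t`, `death_today`,
#'   `discharge_today` (and `weight` unless supplied separately).
#' @param weights optional numeric vector (one per row); defaults to the
#'   `weight` column, or unit weights if absent.
#' @param horizon last day of the curve.
#' @return `data.table` of class `nvhap_cuminc`: `t`, `n_at_risk`,
#'   `haz_death`, `haz_discharge`, `surv`, `F_death`, `F_discharge`.
#' @export
weighted_aalen_johansen <- function(person_days, weights = NULL, horizon = 60) {
  pd <- as.data.table(person_days)
  w <- if (!is.null(weights)) as.numeric(weights)
       else if ("weight" %in% names(pd)) pd$weight
       else rep(1, nrow(pd))
  stopifnot(length(w) == nrow(pd), all(w >= 0))
  t0 <- if (nrow(pd)) min(pd$t) else 1L
  grid <- data.table(t = seq.int(t0, horizon))
  evd <- data.table(t = pd$t, w = w, death = pd$death_today,
                    discharge = pd$discharge_today)[w > 0]
  daily <- evd[, .(n_at_risk = sum(w), d_death = sum(w * death),
                   d_discharge = sum(w * discharge)), keyby = t]
  cur <- daily[grid, on = "t"]
  for (col in c("n_at_risk", "d_death", "d_discharge"))
    cur[is.na(get(col)), (col) := 0]
  cur[, haz_death := fifelse(n_at_risk > 0, d_death / n_at_risk, 0)]
  cur[, haz_discharge := fifelse(n_at_risk > 0, d_discharge / n_at_risk, 0)]
  cur[, surv := cumprod(1 - haz_death - haz_discharge)]
  cur[, s_prev := shift(surv, 1L, fill = 1)]
  cur[, `:=`(F_death = cumsum(haz_death * s_prev),
             F_discharge = cumsum(haz_discharge * s_prev))]
  out <- cur[, .(t, n_at_risk, haz_death, haz_discharge, surv,
                 F_death, F_discharge)]
  setattr(out, "class", c("nvhap_cuminc", class(out)))
  out
}

#' Summarize an attributable-mortality contrast
#'
#' @param risk_current,risk_eliminated cumulative death risks (%) at the
#'   horizon under current care / hypothetical elimination.
#' @param risk_ratio eliminated-to-current risk ratio; computed from the
#'   risks unless supplied (e.g. when re-deriving from published values).
#' @return list of class `nvhap_attributable` with `risk_current`,
#'   `risk_eliminated`, `risk_difference` (percentage points),
#'   `risk_ratio`, `attributable_fraction` (= 1 - risk_ratio).
#' @export
attributable_summary <- function(risk_current, risk_eliminated,
                                 risk_ratio = risk_eliminated / risk_current) {
  structure(list(risk_current = risk_current,
                 risk_eliminated = risk_eliminated,
                 risk_difference = risk_current - risk_eliminated,
                 risk_ratio = risk_ratio,
                 attributable_fraction = 1 - risk_ratio),
            class = "nvhap_attributable")
}

#' @export
print.nvhap_attributable <- function(x, ...) {
  cat(sprintf(paste0(
    "Cumulative inpatient death risk (horizon):\n",
    "  current care:          %6.3f%%\n",
    "  NV-HAP eliminated:     %6.3f%%\n",
    "  risk difference:       %6.3f percentage points\n",
    "  risk ratio:            %6.4f\n",
    "  attributable fraction: %6.2f%%\n"),
    x$risk_current, x$risk_eliminated, x$risk_difference, x$risk_ratio,
    100 * x$attributable_fraction))
  invisible(x)
}

# core pipeline on a prebuilt person-day file
.estimate_from_pd <- function(pd, params) {
  cur <- weighted_aalen_johansen(pd, weights = rep(1, nrow(pd)),
                                 horizon = params$horizon)
  model <- fit_daily_propensity(pd, params)
  wpd <- elimination_weights(pd, model,
                             truncation_quantile = params$truncation_quantile,
                             stabilized = params$stabilized)
  elim <- weighted_aalen_johansen(wpd, horizon = params$horizon)
  est <- attributable_summary(100 * cur[.N, F_death], 100 * elim[.N, F_death])
  est$curves <- list(current = cur, eliminated = elim)
  est$n_hospitalizations <- uniqueN(pd$hosp_id)
  est$n_events <- sum(pd$nvhap_onset_today)
  est
}

#' Estimate the inpatient mortality attributable to NV-HAP
#'
#' Runs the full pipeline: eligibility filter, person-day construction,
#' daily propensity model, elimination weights, and the weighted
#' Aalen-Johansen estimator under current care and under hypothetical
#' elimination of NV-HAP.
#'
#' @param ds a validated `nvhap_dataset`.
#' @param events event table from [detect_events()] (or ground truth with
#'   `true_nvhap_day`).
#' @param params a [causal_params()] list.
#' @return an `nvhap_attributable` with both cumulative-incidence curves
#'   attached (`$curves`).
#' @export
estimate_attributable <- function(ds, events, params = causal_params()) {
  ids <- eligible_cohort(ds)
  sub <- subset_dataset(ds, ids)
  pd <- build_person_days(sub, events, horizon = params$horizon,
                          normal_spo2 = params$normal_spo2)
  .estimate_from_pd(pd, params)
}

#' Clustered bootstrap confidence intervals
#'
#' Resamples hospitalizations (the clustering unit) with replacement,
#' re-running the entire pipeline — propensity refit included — on each
#' replicate, and forms percentile intervals. Replicates with zero events
#' are recorded at risk ratio 1 and flagged. Deterministic given `seed`.
#'
#' @param ds a validated `nvhap_dataset`.
#' @param events event table.
#' @param params a [causal_params()] list.
#' @param B number of bootstrap replicates (default 500).
#' @param seed integer RNG seed.
#' @param conf confidence level.
#' @return list with `estimate` (point estimate on the full data),
#'   `ci` (`data.table`: quantity, low, high), `replicates` (`data.table`,
#'   one row per replicate), `B`, `seed`, `n_zero_event_replicates`.
#' @export
bootstrap_attributable <- function(ds, events, params = causal_params(),
                                   B = 500, seed = 1, conf = 0.95) {
  stopifnot(B >= 2)
  ids <- eligible_cohort(ds)
  sub <- subset_dataset(ds, ids)
  pd <- build_person_days(sub, events, horizon = params$horizon,
                          normal_spo2 = params$normal_spo2)
  point <- .estimate_from_pd(pd, params)
  setkey(pd, hosp_id)
  set.seed(seed)
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    samp <- data.table(hosp_id = sample(ids, length(ids), replace = TRUE))
    samp[, bid := sprintf("B%07d", .I)]
    rpd <- pd[samp, on = "hosp_id", allow.cartesian = TRUE]
    rpd[, hosp_id := bid][, bid := NULL]
    setorder(rpd, hosp_id, t)
    if (sum(rpd$nvhap_onset_today) == 0L) {
      cur <- weighted_aalen_johansen(rpd, weights = rep(1, nrow(rpd)),
                                     horizon = params$horizon)
      r <- 100 * cur[.N, F_death]
      reps[[b]] <- data.table(rep = b, risk_current = r, risk_eliminated = r,
                              risk_difference = 0, risk_ratio = 1,
                              attributable_fraction = 0, zero_events = TRUE)
    } else {
      e <- .estimate_from_pd(rpd, params)
      reps[[b]] <- data.table(rep = b, risk_current = e$risk_current,
                              risk_eliminated = e$risk_eliminated,
                              risk_difference = e$risk_difference,
                              risk_ratio = e$risk_ratio,
                              attributable_fraction = e$attributable_fraction,
                              zero_events = FALSE)
    }
  }
  reps <- rbindlist(reps)
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  qs <- c("risk_current", "risk_eliminated", "risk_difference",
          "risk_ratio", "attributable_fraction")
  ci <- rbindlist(lapply(qs, function(q) {
    v <- quantile(reps[[q]], probs, names = FALSE)
    data.table(quantity = q, low = v[1], high = v[2])
  }))
  list(estimate = point, ci = ci, replicates = reps, B = B, seed = seed,
       n_zero_event_replicates = sum(reps$zero_events))
}

#' Pool site-specific estimates by sample size
#'
#' Each quantity is pooled as a weighted average with weights proportional
#' to the number of unique hospitalizations per site; when bootstrap
#' replicates are supplied they are pooled replicate-wise (replicate `b` of
#' the pooled analysis is the weighted average of replicate `b` across
#' sites) before taking percentile intervals.
#'
#' @param site_estimates list of `nvhap_attributable` objects or
#'   [bootstrap_attributable()] results (one per site).
#' @param site_sizes numeric vector of hospitalization counts per site.
#' @param conf confidence level for pooled intervals.
#' @return an `nvhap_attributable` (with `$ci` when replicates were pooled).
#' @export
pool_sites <- function(site_estimates, site_sizes, conf = 0.95) {
  stopifnot(length(site_estimates) >= 1,
            length(site_estimates) == length(site_sizes), all(site_sizes > 0))
  w <- site_sizes / sum(site_sizes)
  get_est <- function(s) if (inherits(s, "nvhap_attributable")) s else s$estimate
  fields <- c("risk_current", "risk_eliminated", "risk_ratio")
  pooled_vals <- sapply(fields, function(f)
    sum(w * vapply(site_estimates, function(s) get_est(s)[[f]], numeric(1))))
  out <- attributable_summary(pooled_vals[["risk_current"]],
                              pooled_vals[["risk_eliminated"]],
                              risk_ratio = pooled_vals[["risk_ratio"]])
  has_reps <- vapply(site_estimates,
                     function(s) !is.null(s$replicates), logical(1))
  if (all(has_reps)) {
    nb <- vapply(site_estimates, function(s) nrow(s$replicates), integer(1))
    if (length(unique(nb)) != 1L)
      .stop_cls("nvhap_integrity_error",
                "sites have mismatched bootstrap replicate counts")
    probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
    qs <- c("risk_current", "risk_eliminated", "risk_difference",
            "risk_ratio", "attributable_fraction")
    out$ci <- rbindlist(lapply(qs, function(q) {
      mat <- sapply(site_estimates, function(s) s$replicates[[q]])
      pooled <- as.numeric(mat %*% w)
      v <- quantile(pooled, probs, names = FALSE)
      data.table(quantity = q, low = v[1], high = v[2])
    }))
  }
  out
}

# built-in stratification variables, one label per hospitalization
.stratum_variable <- function(ds, spec) {
  hosp <- ds$hospitalizations
  if (is.data.frame(spec)) {
    s <- as.data.table(spec)
    return(setNames(as.character(s$stratum), s$hosp_id))
  }
  val <- switch(spec,
    age_group = ifelse(hosp$age <= 65, "age<=65", "age>65"),
    service = {
      d1 <- ds$daily[day == 1L, .(hosp_id, service)]
      setNames(d1$service, d1$hosp_id)[hosp$hosp_id]
    },
    icu_day3 = {
      d3 <- ds$daily[day == 3L, .(hosp_id, icu)]
      v <- setNames(ifelse(d3$icu, "icu_day3", "ward_day3"), d3$hosp_id)
      v[hosp$hosp_id]
    },
    elix_quartile = {
      q <- quantile(hosp$elixhauser_index, c(.25, .5, .75), names = FALSE, type = 1)
      paste0("elix_q", findInterval(hosp$elixhauser_index, unique(q)) + 1L)
    },
    bed_size = {
      fa <- setNames(ds$facilities$bed_size_class, ds$facilities$facility_id)
      unname(fa[hosp$facility_id])
    },
    region = {
      fa <- setNames(ds$facilities$region, ds$facilities$facility_id)
      unname(fa[hosp$facility_id])
    },
    teaching = {
      fa <- setNames(ifelse(ds$facilities$teaching, "teaching", "nonteaching"),
                     ds$facilities$facility_id)
      unname(fa[hosp$facility_id])
    },
    .stop_cls("nvhap_config_error", "unknown stratification '%s'", spec))
  if (is.null(names(val))) names(val) <- hosp$hosp_id
  val
}

#' Stratified attributable-mortality estimates
#'
#' Re-runs the full pipeline within each stratum. Strata in which the
#' pipeline cannot run (no admissions, no events, or an estimation error)
#' are reported as not estimable rather than aborting the whole analysis.
#'
#' @param ds a validated `nvhap_dataset`.
#' @param events event table.
#' @param strata a built-in name (`"age_group"`, `"service"`, `"icu_day3"`,
#'   `"elix_quartile"`, `"bed_size"`, `"region"`, `"teaching"`) or a data
#'   frame with `hosp_id`, `stratum`.
#' @param params a [causal_params()] list (set `horizon = 30` for the
#'   30-day sensitivity analysis).
#' @return `data.table`: one row per stratum with admission/event counts,
#'   the five summary quantities, and an `estimable` flag.
#' @export
stratified_estimates <- function(ds, events, strata,
                                 params = causal_params()) {
  lab <- .stratum_variable(ds, strata)
  ev <- .normalize_events(events)
  out <- lapply(sort(unique(lab[!is.na(lab)])), function(lv) {
    ids <- names(lab)[!is.na(lab) & lab == lv]
    base <- data.table(stratum = lv, n_hospitalizations = length(ids),
                       n_events = nrow(ev[hosp_id %in% ids]))
    est <- tryCatch({
      e <- estimate_attributable(subset_dataset(ds, ids),
                                 ev[hosp_id %in% ids], params)
      if (e$n_events == 0L || e$risk_current == 0) stop("not estimable")
      e
    }, error = function(err) NULL)
    if (is.null(est)) {
      base[, `:=`(risk_current = NA_real_, risk_eliminated = NA_real_,
                  risk_difference = NA_real_, risk_ratio = NA_real_,
                  attributable_fraction = NA_real_, estimable = FALSE)]
    } else {
      base[, `:=`(risk_current = est$risk_current,
                  risk_eliminated = est$risk_eliminated,
                  risk_difference = est$risk_difference,
                  risk_ratio = est$risk_ratio,
                  attributable_fraction = est$attributable_fraction,
                  estimable = TRUE)]
    }
    base
  })
  rbindlist(out)
}
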