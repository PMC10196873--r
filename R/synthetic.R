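# Synthetic multi-facility inpatient cohort generator.
#
# Emulates the structure the surveillance and attributable-mortality
# pipeline consumes: admissions across facilities, daily oxygenation /
# vitals / lab trajectories, NV-HAP onset as a covariate-dependent
# discrete-time hazard from day 3, competing inpatient-death and
# alive-discharge hazards, and the surveillance-observable signatures of
# each true event (device escalation or SpO2 drop sustained 2 days after a
# stable baseline; fever or leukocytosis; chest imaging; a new >= 3-day
# antimicrobial course). Ground truth (onset day, outcome cause) is
# returned separately and never written into the analysis tables.
#
# Within a day the three transitions are mutually exclusive: death, then
# alive discharge, then (from day 3, if still NV-HAP-free) NV-HAP onset.
# After onset the death hazard is multiplied by theta_death and the
# discharge hazard by theta_discharge. Onset, death and discharge hazards
# depend on severity covariates (age, comorbidity index, lagged ICU status,
# lagged log-creatinine), so onset is confounded with outcome by design.
# The onset and death models use the most recent *recorded* creatinine as
# of two days prior (the same feature the propensity model later uses).

#' Simulation configuration
#'
#' Defaults describe a mid-sized multi-hospital cohort: admission-level
#' covariates anchored to large published inpatient case mixes, a median
#' length of stay near 4 days, in-hospital mortality near 2%, an NV-HAP
#' onset hazard of roughly 0.7-1 per 100 at-risk days (about 3-4 events per
#' 100 eligible admissions), a doubled post-onset death hazard and a halved
#' post-onset discharge hazard.
#'
#' @param n_facilities number of facilities.
#' @param n_hospitalizations number of admissions.
#' @param seed integer RNG seed (the generator is deterministic given it).
#' @param baseline_death_hazard,baseline_discharge_hazard per-day
#'   probabilities at reference covariates.
#' @param theta_death,theta_discharge multiplicative effect of prevalent
#'   NV-HAP on the death / discharge hazard (1 = no effect).
#' @param onset_coefficients named vector for the per-day logistic onset
#'   model: `intercept`, `age10` (per decade above 65), `elixhauser`,
#'   `icu`, `log_creatinine` (all on lag-2 covariates).
#' @param death_coefficients,discharge_coefficients named severity
#'   log-hazard-ratio vectors (subset of the same names, no intercept).
#' @param facility_sd SD of a facility-level random intercept on the onset
#'   model (creates between-facility incidence variation; onset-only, so it
#'   is not a confounder).
#' @param signal_completeness probability that each of the fever/WBC,
#'   imaging and antimicrobial signatures is emitted for a true event (the
#'   oxygenation deterioration itself is always emitted).
#' @param max_followup administrative cap on length of stay, days.
#' @param noise list of background-noise controls: `spo2_jitter_sd`
#'   (day-to-day SpO2 SD, points), `background_abx_prob` (per-admission
#'   probability of an incidental antimicrobial course),
#'   `background_imaging_rate`, `background_fever_rate` (per-day rates).
#'   Set all to 0 for noise-free runs.
#' @param lab_day1_prob,lab_panel_rate probability the routine lab panel is
#'   drawn on day 1 / on each later day.
#' @return a list of class `nvhap_sim_config`.
#' @export
sim_config <- function(n_facilities = 20, n_hospitalizations = 5000,
                       seed = 1,
                       baseline_death_hazard = 0.004,
                       baseline_discharge_hazard = 0.16,
                       theta_death = 2, theta_discharge = 0.5,
                       onset_coefficients = c(intercept = -5, age10 = 0.25,
                                              elixhauser = 0.04, icu = 0.7,
                                              log_creatinine = 0.5),
                       death_coefficients = c(age10 = 0.3, elixhauser = 0.05,
                                              icu = 0.9, log_creatinine = 0.5),
                       discharge_coefficients = c(elixhauser = -0.03,
                                                  icu = -0.5),
                       facility_sd = 0.3,
                       signal_completeness = 1,
                       max_followup = 90,
                       noise = list(spo2_jitter_sd = 0.7,
                                    background_abx_prob = 0.15,
                                    background_imaging_rate = 0.01,
                                    background_fever_rate = 0.01),
                       lab_day1_prob = 0.97, lab_panel_rate = 0.6) {
  cfg <- as.list(environment())
  if (!(baseline_death_hazard > 0 && baseline_death_hazard < 1) ||
      !(baseline_discharge_hazard > 0 && baseline_discharge_hazard < 1))
    .stop_cls("nvhap_config_error", "baseline hazards must lie in (0,1)")
  if (theta_death <= 0 || theta_discharge <= 0)
    .stop_cls("nvhap_config_error", "theta parameters must be > 0")
  base_onset <- plogis(onset_coefficients[["intercept"]])
  if (baseline_death_hazard + baseline_discharge_hazard + base_onset >= 1)
    .stop_cls("nvhap_config_error",
              "per-day hazard sum >= 1 at baseline; infeasible configuration")
  if (n_hospitalizations < 0 || n_facilities < 1 || max_followup < 3)
    .stop_cls("nvhap_config_error", "invalid cohort dimensions")
  structure(cfg, class = "nvhap_sim_config")
}

.coef0 <- function(v, nm) if (nm %in% names(v)) v[[nm]] else 0

#' Generate a synthetic cohort with ground truth
#'
#' @param config a [sim_config()] object.
#' @return list with `dataset` (a validated `nvhap_dataset`) and `truth`
#'   (a `data.table` with `hosp_id`, `true_nvhap_day`, `true_cause` in
#'   death/discharge/censored, and `fully_observed`: whether the stay lasted
#'   to onset+2 so that every surveillance signature could be expressed).
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "nvhap_sim_config"))
  set.seed(config$seed)
  n <- config$n_hospitalizations
  Tmax <- config$max_followup
  nz <- config$noise

  # facilities ---------------------------------------------------------
  nf <- config$n_facilities
  fac <- data.table(
    facility_id = sprintf("F%03d", seq_len(nf)),
    bed_size_class = sample(.nvhap_vocab$bed_size_class, nf, TRUE,
                            prob = c(.37, .29, .16, .18)),
    teaching = runif(nf) < 0.70,
    region = sample(.nvhap_vocab$region, nf, TRUE,
                    prob = c(.16, .11, .56, .17)))
  fac_eff <- rnorm(nf, 0, config$facility_sd)
  fac_wt <- rgamma(nf, shape = 2)

  if (n == 0L) {
    empty <- ehr_dataset(
      fac, data.table(hosp_id = character(), facility_id = character(),
        age = integer(), sex = character(), race = character(),
        admit_day = character(), los = integer(), disposition = character(),
        congestive_heart_failure = logical(), chronic_lung_disease = logical(),
        diabetes = logical(), chronic_liver_disease = logical(),
        cancer = logical(), neurological_disease = logical(),
        chronic_kidney_disease = logical(), elixhauser_index = integer(),
        prior_90d_admission = logical()),
      data.table(hosp_id = character(), day = integer(), service = character(),
        icu = logical(), temp_min = numeric(), temp_max = numeric(),
        wbc = numeric(), spo2_min = numeric(), o2_device = character(),
        hematocrit = numeric(), platelets = numeric(), sodium = numeric(),
        glucose = numeric(), creatinine = numeric(), alt = numeric(),
        bilirubin = numeric(), albumin = numeric(), chest_imaging = logical()),
      data.table(hosp_id = character(), day = integer(), agent_id = character()))
    return(list(dataset = empty,
                truth = data.table(hosp_id = character(),
                                   true_nvhap_day = integer(),
                                   true_cause = character(),
                                   fully_observed = logical())))
  }

  # admissions ---------------------------------------------------------
  hosp_id <- sprintf("H%06d", seq_len(n))
  fidx <- sample.int(nf, n, TRUE, prob = fac_wt)
  age <- pmin(pmax(round(rnorm(n, 65, 15)), 18L), 100L)
  sex <- sample(.nvhap_vocab$sex, n, TRUE, prob = c(.30, .70))
  race <- sample(.nvhap_vocab$race, n, TRUE, prob = c(.014, .186, .704, .096))
  flag_p <- c(congestive_heart_failure = .16, chronic_lung_disease = .17,
              diabetes = .33, chronic_liver_disease = .06, cancer = .09,
              neurological_disease = .13, chronic_kidney_disease = .18)
  flags <- matrix(runif(n * length(flag_p)) < rep(flag_p, each = n),
                  nrow = n, dimnames = list(NULL, names(flag_p)))
  nflag <- rowSums(flags)
  elix <- as.integer(round(pmax(0, rnorm(n, 1 + 3 * nflag, 3))))
  prior90 <- runif(n) < 0.20
  service <- sample(.nvhap_vocab$service, n, TRUE,
                    prob = c(.031, .581, .271, .009, .005, .103))
  admit_day <- as.character(as.Date("2019-01-01") + sample.int(365, n, TRUE) - 1L)

  lung <- flags[, "chronic_lung_disease"]
  ckd <- flags[, "chronic_kidney_disease"]
  lcre0 <- log(0.9) + 0.35 * ckd + rnorm(n, 0, 0.25)

  # exogenous daily processes (precomputed so covariates are pre-exposure)
  icu <- matrix(FALSE, n, Tmax)
  icu[, 1] <- runif(n) < plogis(-2 + 0.04 * elix)
  meas <- matrix(FALSE, n, Tmax)
  meas[, 1] <- runif(n) < config$lab_day1_prob
  lcre <- matrix(0, n, Tmax)
  ar <- rnorm(n, 0, 0.15)
  lcre[, 1] <- lcre0 + ar
  for (t in 2:Tmax) {
    icu[, t] <- ifelse(icu[, t - 1], runif(n) < 0.75, runif(n) < 0.02)
    meas[, t] <- runif(n) < config$lab_panel_rate
    ar <- 0.8 * ar + rnorm(n, 0, 0.1)
    lcre[, t] <- lcre0 + ar
  }
  # LOCF log-creatinine as recorded (fallback: baseline before first draw)
  lcre_locf <- matrix(lcre0, n, Tmax)
  last_meas <- matrix(NA_integer_, n, Tmax)
  cur <- lcre0; curd <- rep(NA_integer_, n)
  for (t in seq_len(Tmax)) {
    cur <- ifelse(meas[, t], lcre[, t], cur)
    curd <- ifelse(meas[, t], t, curd)
    lcre_locf[, t] <- cur
    last_meas[, t] <- curd
  }

  # daily competing transitions ----------------------------------------
  oc <- config$onset_coefficients
  dc <- config$death_coefficients
  sc <- config$discharge_coefficients
  age10 <- (age - 65) / 10
  los <- rep(NA_integer_, n)
  cause <- rep(NA_character_, n)
  onset_day <- rep(NA_integer_, n)
  in_hosp <- rep(TRUE, n)
  for (t in seq_len(Tmax)) {
    lag <- max(t - 2L, 1L)
    icu_l2 <- icu[, lag]
    lcre_l2 <- lcre_locf[, lag]
    post <- !is.na(onset_day) & t > onset_day
    lp_d <- .coef0(dc, "age10") * age10 + .coef0(dc, "elixhauser") * elix +
      .coef0(dc, "icu") * icu_l2 + .coef0(dc, "log_creatinine") * lcre_l2
    hd <- pmin(config$baseline_death_hazard * exp(lp_d) *
                 ifelse(post, config$theta_death, 1), 0.5)
    lp_s <- .coef0(sc, "age10") * age10 + .coef0(sc, "elixhauser") * elix +
      .coef0(sc, "icu") * icu_l2 + .coef0(sc, "log_creatinine") * lcre_l2
    hs <- config$baseline_discharge_hazard * exp(lp_s) *
      ifelse(post, config$theta_discharge, 1)
    po <- rep(0, n)
    elig <- t >= 3L & is.na(onset_day)
    if (any(elig)) {
      lp_o <- oc[["intercept"]] + .coef0(oc, "age10") * age10 +
        .coef0(oc, "elixhauser") * elix + .coef0(oc, "icu") * icu_l2 +
        .coef0(oc, "log_creatinine") * lcre_l2 + fac_eff[fidx]
      po[elig] <- plogis(lp_o[elig])
    }
    hs <- pmin(hs, pmax(0.98 - hd - po, 0))
    u <- runif(n)
    die <- in_hosp & u < hd
    dis <- in_hosp & !die & u < hd + hs
    ons <- in_hosp & !die & !dis & u < hd + hs + po
    los[die | dis] <- t
    cause[die] <- "death"; cause[dis] <- "discharge"
    onset_day[ons] <- t
    in_hosp <- in_hosp & !die & !dis
    if (!any(in_hosp)) break
  }
  los[in_hosp] <- Tmax
  cause[in_hosp] <- "censored"

  # admission table -----------------------------------------------------
  had_event <- !is.na(onset_day)
  disposition <- character(n)
  disposition[cause == "death"] <- "death"
  alive <- cause == "discharge"
  disposition[alive & !had_event] <-
    sample(c("home", "rehabilitation", "skilled_nursing", "hospice", "other"),
           sum(alive & !had_event), TRUE, prob = c(.85, .02, .09, .014, .026))
  disposition[alive & had_event] <-
    sample(c("home", "rehabilitation", "skilled_nursing", "hospice", "other"),
           sum(alive & had_event), TRUE, prob = c(.45, .05, .25, .10, .15))
  disposition[cause == "censored"] <- "other"
  hosp <- data.table(hosp_id = hosp_id, facility_id = fac$facility_id[fidx],
    age = age, sex = sex, race = race, admit_day = admit_day, los = los,
    disposition = disposition)
  for (fl in .comorbidity_flags) set(hosp, j = fl, value = flags[, fl])
  hosp[, `:=`(elixhauser_index = elix, prior_90d_admission = prior90)]

  # daily table ---------------------------------------------------------
  dd <- data.table(hosp_id = rep(hosp_id, los), i = rep(seq_len(n), los))
  dd[, day := seq_len(.N), by = hosp_id]
  m <- nrow(dd)
  ij <- cbind(dd$i, dd$day)
  dd[, `:=`(service = service[i], icu = icu[ij], panel = meas[ij])]
  tb <- 36.8 + rnorm(m, 0, 0.25)
  dd[, `:=`(temp_min = round(tb - abs(rnorm(m, 0.2, 0.1)), 1),
            temp_max = round(tb + abs(rnorm(m, 0.3, 0.15)), 1))]
  if (nz$background_fever_rate > 0)
    dd[runif(m) < nz$background_fever_rate, temp_max := temp_max + 1.6]
  dd[, `:=`(wbc = NA_real_, hematocrit = NA_real_, platelets = NA_real_,
            sodium = NA_real_, glucose = NA_real_, creatinine = NA_real_,
            creat_true = exp(lcre[ij]))]
  dd[panel == TRUE, `:=`(
    wbc = round(exp(rnorm(.N, log(8), 0.3)), 1),
    hematocrit = round(rnorm(.N, 33, 5), 1),
    platelets = round(exp(rnorm(.N, log(200), 0.35))),
    sodium = round(rnorm(.N, 138, 4)),
    glucose = round(exp(rnorm(.N, log(140), 0.35))),
    creatinine = round(creat_true, 2))]
  nonroutine <- runif(m) < 0.15
  dd[, `:=`(alt = NA_real_, bilirubin = NA_real_, albumin = NA_real_)]
  dd[nonroutine, `:=`(alt = round(exp(rnorm(.N, log(25), 0.6))),
                      bilirubin = round(exp(rnorm(.N, log(0.7), 0.5)), 1),
                      albumin = round(rnorm(.N, 3.1, 0.6), 1))]
  dd[, chest_imaging := runif(m) < nz$background_imaging_rate]
  base_rank <- ifelse(lung & runif(n) < 0.35, 1L, 0L)
  spo2_base <- 96.5 - 1.5 * lung
  dd[, dev_rank := base_rank[i]]
  dd[, spo2_min := pmin(pmax(round(spo2_base[i] +
                               rnorm(m, 0, nz$spo2_jitter_sd)), 85), 100)]

  # surveillance signatures of true events ------------------------------
  ev <- which(had_event)
  if (length(ev)) {
    sig <- config$signal_completeness
    # sustained oxygenation deterioration from onset to end of stay
    dd[onset_day[i] <= day & i %in% ev,
       `:=`(dev_rank = pmin(base_rank[i] + 2L, 6L),
            spo2_min = pmin(pmax(round(spo2_base[i] - 5 +
                      rnorm(.N, 0, nz$spo2_jitter_sd)), 80), 100))]
    emit_fw <- runif(length(ev)) < sig
    fever <- runif(length(ev)) < 0.6
    fw_fever <- ev[emit_fw & fever]
    fw_wbc <- ev[emit_fw & !fever]
    dd[i %in% fw_fever & day == onset_day[i],
       temp_max := round(38.3 + abs(rnorm(.N, 0, 0.4)), 1)]
    dd[i %in% fw_wbc & day == onset_day[i],
       `:=`(panel = TRUE, wbc = round(13 + rexp(.N, 1 / 3), 1))]
    img <- ev[runif(length(ev)) < sig]
    dd[i %in% img & day == onset_day[i], chest_imaging := TRUE]
  }
  dd[, o2_device := oxygen_devices()[dev_rank + 1L]]

  # medications ---------------------------------------------------------
  med_list <- list()
  bg <- which(runif(n) < nz$background_abx_prob)
  if (length(bg)) {
    st <- 1L + as.integer(floor(runif(length(bg)) * los[bg]))
    len <- sample(3:7, length(bg), TRUE)
    agent <- sample(c("vancomycin", "cefepime", "ceftriaxone", "azithromycin",
                      "piperacillin-tazobactam"), length(bg), TRUE)
    bgm <- data.table(i = rep(bg, len), agent_id = rep(agent, len),
                      day = unlist(lapply(seq_along(bg),
                              function(k) st[k]:(st[k] + len[k] - 1L))))
    bgm <- bgm[day <= los[i]]
    # background courses must not mask the "new" lookback of a true event
    if (length(ev))
      bgm <- bgm[!(i %in% ev & day >= onset_day[i] - 2L & day <= onset_day[i] - 1L)]
    med_list$background <- bgm
  }
  if (length(ev)) {
    abx_ev <- ev[runif(length(ev)) < config$signal_completeness]
    if (length(abx_ev)) {
      evm <- data.table(i = rep(abx_ev, 3L),
                        day = as.integer(outer(onset_day[abx_ev], 0:2, `+`)),
                        agent_id = "levofloxacin")
      med_list$event <- evm[day <= los[i]]
    }
  }
  meds <- rbindlist(med_list, use.names = TRUE, fill = TRUE)
  if (is.null(meds) || !nrow(meds)) {
    meds <- data.table(hosp_id = character(), day = integer(),
                       agent_id = character())
  } else {
    meds[, hosp_id := hosp_id[i]]
    meds <- unique(meds[, .(hosp_id, day, agent_id)])[order(hosp_id, day, agent_id)]
  }

  daily <- dd[, .(hosp_id, day, service, icu, temp_min, temp_max, wbc,
                  spo2_min, o2_device, hematocrit, platelets, sodium, glucose,
                  creatinine, alt, bilirubin, albumin, chest_imaging)]
  truth <- data.table(hosp_id = hosp_id, true_nvhap_day = onset_day,
                      true_cause = cause,
                      fully_observed = had_event & los >= onset_day + 2L)
  list(dataset = ehr_dataset(fac, hosp, daily, meds), truth = truth)
}

#' Plant a deterministic single-admission fixture
#'
#' Builds a one-admission dataset from an explicit per-day specification,
#' with no randomness, for rule-engine unit tests.
#'
#' @param daily data frame with a contiguous `day` column starting at 1 and
#'   any subset of the daily-table columns; unspecified vitals/labs are
#'   missing, `icu`/`chest_imaging` default `FALSE`, `service` defaults
#'   `"medicine"`.
#' @param meds optional data frame with `day`, `agent_id`.
#' @param hosp_id,age,sex,race,disposition,elixhauser_index admission fields.
#' @return a validated one-admission `nvhap_dataset`.
#' @export
plant_fixture <- function(daily, meds = NULL, hosp_id = "H1", age = 70,
                          sex = "male", race = "White", disposition = "home",
                          elixhauser_index = 3) {
  daily <- as.data.table(daily)
  if (!"day" %in% names(daily))
    .stop_cls("nvhap_schema_error", "fixture spec needs a 'day' column")
  if (anyDuplicated(daily$day))
    .stop_cls("nvhap_integrity_error", "fixture spec has duplicated days")
  daily <- daily[order(day)]
  if (!identical(as.integer(daily$day), seq_len(nrow(daily))))
    .stop_cls("nvhap_integrity_error", "fixture days must be contiguous from 1")
  los <- nrow(daily)
  defaults <- list(service = "medicine", icu = FALSE, temp_min = NA_real_,
    temp_max = NA_real_, wbc = NA_real_, spo2_min = NA_real_,
    o2_device = NA_character_, hematocrit = NA_real_, platelets = NA_real_,
    sodium = NA_real_, glucose = NA_real_, creatinine = NA_real_,
    alt = NA_real_, bilirubin = NA_real_, albumin = NA_real_,
    chest_imaging = FALSE)
  daily <- copy(daily)
  for (col in names(defaults))
    if (!col %in% names(daily)) set(daily, j = col, value = defaults[[col]])
  hid <- hosp_id
  set(daily, j = "hosp_id", value = hid)
  meds <- if (is.null(meds) || !nrow(as.data.table(meds))) {
    data.table(hosp_id = character(), day = integer(), agent_id = character())
  } else {
    m <- as.data.table(meds)
    if (!"agent_id" %in% names(m)) m[, agent_id := "agent_a"]
    set(m, j = "hosp_id", value = hid)
    m[, .(hosp_id, day = as.integer(day), agent_id)]
  }
  fac <- data.table(facility_id = "F001", bed_size_class = "100-199",
                    teaching = TRUE, region = "South")
  hosp <- data.table(hosp_id = hosp_id, facility_id = "F001", age = age,
    sex = sex, race = race, admit_day = "2019-01-01", los = los,
    disposition = disposition)
  for (fl in .comorbidity_flags) set(hosp, j = fl, value = FALSE)
  hosp[, `:=`(elixhauser_index = as.integer(elixhauser_index),
              prior_90d_admission = FALSE)]
  ehr_dataset(fac, hosp, daily, meds)
}
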