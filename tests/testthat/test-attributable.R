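make_daily_row <- function(hosp_id, day, wbc = 8, creat = 1, service = "medicine") {
  data.frame(hosp_id = hosp_id, day = day, service = service, icu = FALSE,
             temp_min = 36.5, temp_max = 37, wbc = wbc, spo2_min = 96,
             o2_device = NA_character_, hematocrit = 33, platelets = 200,
             sodium = 138, glucose = 120, creatinine = creat,
             alt = NA_real_, bilirubin = NA_real_, albumin = NA_real_,
             chest_imaging = FALSE)
}

make_cohort <- function(spec) {
  # spec: data.frame(hosp_id, los, disposition, drop_creatinine_early)
  fac <- data.frame(facility_id = "F001", bed_size_class = "100-199",
                    teaching = TRUE, region = "South")
  hosp <- data.frame(hosp_id = spec$hosp_id, facility_id = "F001", age = 70,
                     sex = "male", race = "White", admit_day = "2019-01-01",
                     los = spec$los, disposition = spec$disposition,
                     congestive_heart_failure = FALSE,
                     chronic_lung_disease = FALSE, diabetes = FALSE,
                     chronic_liver_disease = FALSE, cancer = FALSE,
                     neurological_disease = FALSE,
                     chronic_kidney_disease = FALSE, elixhauser_index = 3L,
                     prior_90d_admission = FALSE)
  daily <- do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    d <- do.call(rbind, lapply(seq_len(spec$los[i]), function(t)
      make_daily_row(spec$hosp_id[i], t)))
    if (isTRUE(spec$drop_creatinine_early[i])) d$creatinine[d$day <= 2] <- NA
    d
  }))
  ehr_dataset(fac, hosp, daily,
              data.frame(hosp_id = character(), day = integer(),
                         agent_id = character()))
}

no_events <- data.frame(hosp_id = character(), onset_day = integer())

test_that("eligibility requires 3 days and early completeness of routine data", {
  spec <- data.frame(
    hosp_id = c("A", "B", "C", "D"),
    los = c(2L, 5L, 3L, 10L),
    disposition = c("home", "home", "home", "death"),
    drop_creatinine_early = c(FALSE, TRUE, FALSE, FALSE))
  ds <- make_cohort(spec)
  expect_identical(eligible_cohort(ds), c("C", "D"))
})

test_that("person-day file has the right rows, lags, and horizon censoring", {
  spec <- data.frame(hosp_id = c("A", "B"), los = c(4L, 70L),
                     disposition = c("death", "death"),
                     drop_creatinine_early = FALSE)
  ds <- make_cohort(spec)
  # creatinine measured on day 1 only for admission A
  ds$daily[hosp_id == "A" & day > 1, creatinine := NA]
  pd <- build_person_days(ds, no_events, horizon = 60)

  a <- pd[hosp_id == "A"]
  expect_identical(a$t, 3:4)                       # los=4 -> rows t=3,4
  expect_true(a[t == 4, death_today])

  b <- pd[hosp_id == "B"]
  expect_identical(b$t, 3:60)                      # administrative censoring
  expect_false(any(b$death_today))                 # death on day 70 unseen

  # LOCF + lag: day-1 creatinine carried to t=5 with 4 days since measurement
  spec5 <- data.frame(hosp_id = "E", los = 6L, disposition = "home",
                      drop_creatinine_early = FALSE)
  ds5 <- make_cohort(spec5)
  ds5$daily[, creatinine := c(1.4, NA, NA, NA, NA, NA)]
  ds5$daily[, `:=`(wbc = c(8, NA, NA, NA, NA, NA),
                   hematocrit = c(33, NA, NA, NA, NA, NA),
                   platelets = c(200, NA, NA, NA, NA, NA),
                   sodium = c(138, NA, NA, NA, NA, NA),
                   glucose = c(120, NA, NA, NA, NA, NA))]
  pd5 <- build_person_days(ds5, no_events, horizon = 60)
  expect_equal(pd5[t == 5, creatinine_lag2], 1.4)
  expect_equal(pd5[t == 5, days_since_lab], 4)
  # day-2-only measurement backs up the day-3 row
  ds2 <- make_cohort(spec5)
  ds2$daily[, creatinine := c(NA, 2.2, 2.2, 2.2, 2.2, 2.2)]
  pd2 <- build_person_days(ds2, no_events, horizon = 60)
  expect_equal(pd2[t == 3, creatinine_lag2], 2.2)
  expect_equal(pd2[t == 4, creatinine_lag2], 2.2)

  expect_error(build_person_days(ds, data.frame(hosp_id = "A", onset_day = 2L)),
               class = "nvhap_integrity_error")
})

test_that("saturated day-only propensity equals the empirical hazard; no onsets give unit weights", {
  spec <- data.frame(hosp_id = sprintf("H%03d", 1:100), los = 6L,
                     disposition = "home", drop_creatinine_early = FALSE)
  ds <- make_cohort(spec)
  ev <- data.frame(hosp_id = c("H001", "H002"), onset_day = c(4L, 4L))
  pd <- build_person_days(ds, ev)
  m <- fit_daily_propensity(pd, causal_params(day_effect = "categorical"),
                            covariates = character())
  # day 4: 2 onsets among 100 still at risk
  expect_equal(m$p_hat[t == 4, unique(round(p_hat, 10))], 0.02)
  expect_equal(m$p_hat[t == 3, unique(round(p_hat, 10))], 0)

  pd0 <- build_person_days(ds, no_events)
  m0 <- fit_daily_propensity(pd0, causal_params())
  expect_true(all(m0$p_hat$p_hat == 0))
  w0 <- elimination_weights(pd0, m0)
  expect_true(all(w0$weight == 1))
})

test_that("propensity model recovers the generator's onset coefficients", {
  g <- generate_cohort(sim_config(n_hospitalizations = 12000, seed = 61,
                                  facility_sd = 0))
  ids <- eligible_cohort(g$dataset)
  pd <- build_person_days(subset_dataset <- nvhap:::subset_dataset(g$dataset, ids),
                          truth_events(g$truth))
  fit <- fit_daily_propensity(pd, causal_params())$fit
  sm <- summary(fit)$coefficients
  truth <- c(elixhauser_index = 0.04, icu_lag2TRUE = 0.7,
             `log(creatinine_lag2)` = 0.5)
  for (nm in names(truth)) {
    est <- sm[nm, "Estimate"]; se <- sm[nm, "Std. Error"]
    expect_lt(abs(est - truth[[nm]]), 2.5 * se, label = nm)
  }
  # age enters per year in the analysis, per decade in the generator
  expect_lt(abs(sm["age", "Estimate"] - 0.025), 2.5 * sm["age", "Std. Error"])
})

test_that("elimination weights follow the sequential product and truncation rules", {
  spec <- data.frame(hosp_id = "A", los = 6L, disposition = "home",
                     drop_creatinine_early = FALSE)
  pd <- build_person_days(make_cohort(spec), no_events)
  model <- structure(list(
    p_hat = data.table::data.table(hosp_id = "A", t = 3:6,
                                   p_hat = c(0.1, 0.2, 0, 0))),
    class = "nvhap_propensity")
  w <- elimination_weights(pd, model, truncation_quantile = 1)
  expect_equal(w$weight, c(1 / 0.9, 1 / 0.9 / 0.8, 1 / 0.9 / 0.8, 1 / 0.9 / 0.8))
  # truncation caps the upper tail
  wt <- elimination_weights(pd, model, truncation_quantile = 0.5)
  expect_true(all(wt$weight <= stats::quantile(w$weight, 0.5)))
  # positivity violation aborts
  bad <- structure(list(
    p_hat = data.table::data.table(hosp_id = "A", t = 3:6,
                                   p_hat = c(0.1, 1, 0, 0))),
    class = "nvhap_propensity")
  expect_error(elimination_weights(pd, bad), class = "nvhap_positivity_error")
})

test_that("mean elimination weight tracks the inverse probability of remaining event-free", {
  g <- generate_cohort(sim_config(n_hospitalizations = 8000, seed = 71,
                                  theta_death = 1, theta_discharge = 1))
  ids <- eligible_cohort(g$dataset)
  pd <- build_person_days(nvhap:::subset_dataset(g$dataset, ids),
                          truth_events(g$truth))
  m <- fit_daily_propensity(pd, causal_params())
  w <- elimination_weights(pd, m, truncation_quantile = 1)
  # among subjects still under follow-up at day t, the average weight
  # estimates 1 / P(NV-HAP-free through t | in hospital)
  for (tt in c(4L, 6L, 8L)) {
    rows <- w[t == tt]
    frac_free <- nrow(rows[weight > 0]) / nrow(rows)
    expect_equal(mean(rows$weight), 1, tolerance = 0.05 / frac_free)
  }
})

test_that("weighted Aalen-Johansen matches the hand-computed fixture", {
  pd <- data.frame(
    hosp_id = rep(c("a", "b", "c", "d"), c(1, 2, 3, 3)),
    t = c(1, 1, 2, 1, 2, 3, 1, 2, 3),
    death_today = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE,
                    FALSE, FALSE, FALSE),
    discharge_today = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                        FALSE, FALSE, FALSE))
  cur <- weighted_aalen_johansen(pd, weights = rep(1, nrow(pd)), horizon = 3)
  expect_equal(cur$haz_death, c(1 / 4, 0, 1 / 2))
  expect_equal(cur[t == 3, F_death], 0.5)
  expect_equal(cur[t == 3, F_discharge], 0.25)
  expect_equal(cur[t == 3, surv], 0.25)
  # doubling all weights changes nothing
  dbl <- weighted_aalen_johansen(pd, weights = rep(2, nrow(pd)), horizon = 3)
  expect_equal(dbl$F_death, cur$F_death)
  # with a single event type the CIF is one minus Kaplan-Meier survival
  pd_km <- pd; pd_km$discharge_today <- FALSE
  km <- weighted_aalen_johansen(pd_km, weights = rep(1, nrow(pd)), horizon = 3)
  expect_equal(km$F_death, 1 - km$surv)
})

test_that("estimator conserves probability and matches survfit on unweighted data", {
  skip_if_not_installed("survival")
  set.seed(91)
  for (rep in 1:5) {
    pd <- random_pd(60, weighted = FALSE)
    aj <- weighted_aalen_johansen(pd, horizon = 8)
    expect_true(all(abs(aj$F_death + aj$F_discharge + aj$surv - 1) < 1e-12))
    expect_true(all(diff(aj$F_death) >= -1e-12))
    expect_true(all(diff(aj$F_discharge) >= -1e-12))
    last <- aggregate(cbind(death_today, discharge_today) ~ hosp_id, pd, sum)
    tmax <- aggregate(t ~ hosp_id, pd, max)
    status <- factor(ifelse(last$death_today > 0, "death",
                     ifelse(last$discharge_today > 0, "discharge", "censor")),
                     levels = c("censor", "death", "discharge"))
    sf <- survival::survfit(survival::Surv(tmax$t, status) ~ 1)
    idx <- match(sf$time, aj$t)
    expect_equal(unname(sf$pstate[, "death"]), aj$F_death[idx],
                 tolerance = 1e-12)
    expect_equal(unname(sf$pstate[, "discharge"]), aj$F_discharge[idx],
                 tolerance = 1e-12)
  }
})

test_that("with no NV-HAP events the two scenarios coincide exactly", {
  spec <- data.frame(hosp_id = sprintf("H%02d", 1:40),
                     los = rep(c(3L, 5L, 8L, 12L), 10),
                     disposition = rep(c("home", "death", "home", "hospice"), 10),
                     drop_creatinine_early = FALSE)
  est <- estimate_attributable(make_cohort(spec), no_events)
  expect_equal(est$risk_ratio, 1)
  expect_equal(est$risk_difference, 0)
  expect_identical(est$curves$current$F_death, est$curves$eliminated$F_death)
  # hospice counts as alive discharge, not death
  expect_equal(est$risk_current,
               100 * est$curves$current[.N, F_death])
  expect_lt(est$risk_current, 100 * 10 / 40 + 1e-9)
})

test_that("IPW removes the confounding bias of simply dropping event admissions", {
  wins <- 0L
  for (s in 1:4) {
    g <- generate_cohort(sim_config(n_hospitalizations = 8000, seed = 100 + s,
                                    theta_death = 1, theta_discharge = 1))
    ev <- truth_events(g$truth)
    ipw <- estimate_attributable(g$dataset, ev)
    ids <- eligible_cohort(g$dataset)
    keep <- setdiff(ids, ev$hosp_id)
    pdn <- build_person_days(nvhap:::subset_dataset(g$dataset, keep),
                             no_events)
    naive_risk <- 100 * weighted_aalen_johansen(
      pdn, weights = rep(1, nrow(pdn)))[.N, F_death]
    naive_rr <- naive_risk / ipw$risk_current
    # dropping the (sicker) event admissions understates the death risk
    if (naive_rr < ipw$risk_ratio) wins <- wins + 1L
  }
  expect_gte(wins, 3L)
})

test_that("pooling is a size-weighted average with replicate-wise intervals", {
  s1 <- attributable_summary(2.0, 1.8)   # risk ratio 0.9
  s2 <- attributable_summary(2.0, 2.0)   # risk ratio 1.0
  pooled <- pool_sites(list(s1, s2), c(100000, 300000))
  expect_equal(pooled$risk_ratio, 0.975)
  expect_equal(pooled$attributable_fraction, 0.025)
  expect_equal(pool_sites(list(s1), 10)$risk_ratio, s1$risk_ratio)
  sym <- pool_sites(list(s1, s2), c(5, 5))
  expect_equal(sym$risk_ratio, (0.9 + 1) / 2)

  reps <- function(v) list(estimate = attributable_summary(2, 2 * v),
                           replicates = data.table::data.table(
                             risk_current = 2, risk_eliminated = 2 * v,
                             risk_difference = 2 - 2 * v, risk_ratio = v,
                             attributable_fraction = 1 - v)[rep(1, 10)])
  pb <- pool_sites(list(reps(0.9), reps(1.0)), c(1, 3))
  expect_equal(unlist(pb$ci[quantity == "risk_ratio", .(low, high)]),
               c(low = 0.975, high = 0.975))
  bad <- reps(0.9); bad$replicates <- bad$replicates[1:5]
  expect_error(pool_sites(list(reps(0.9), bad), c(1, 1)),
               class = "nvhap_integrity_error")
})

test_that("stratified runs reproduce the unstratified estimate and flag empty strata", {
  g <- generate_cohort(sim_config(n_hospitalizations = 3000, seed = 111))
  ev <- truth_events(g$truth)
  all_strat <- data.frame(hosp_id = g$dataset$hospitalizations$hosp_id,
                          stratum = "all")
  st <- stratified_estimates(g$dataset, ev, all_strat)
  ref <- estimate_attributable(g$dataset, ev)
  expect_equal(st$risk_ratio, ref$risk_ratio)
  expect_equal(st$risk_current, ref$risk_current)

  byage <- stratified_estimates(g$dataset, ev, "age_group")
  expect_setequal(byage$stratum, c("age<=65", "age>65"))
  expect_true(all(byage$estimable))

  # a stratum with no admissions above the cut is reported, not an abort
  young <- data.table::copy(g$dataset$hospitalizations)[, age := 40L]
  ds2 <- g$dataset; ds2$hospitalizations <- young
  byage2 <- stratified_estimates(ds2, ev, "age_group")
  expect_identical(nrow(byage2), 1L)
  expect_identical(byage2$stratum, "age<=65")

  # 30-day sensitivity horizon runs and gives lower absolute risks
  st30 <- stratified_estimates(g$dataset, ev, all_strat,
                               causal_params(horizon = 30))
  expect_lte(st30$risk_current, ref$risk_current)
})
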