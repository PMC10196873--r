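test_that("oxygen device ranks follow the escalation ladder", {
  expect_identical(rank_oxygen_device("none"), 0L)
  expect_identical(rank_oxygen_device("ventilator"), 7L)
  expect_identical(rank_oxygen_device(NA), 0L)
  expect_identical(rank_oxygen_device(c("BIPAP", "Simple Mask")), c(6L, 2L))
  err <- expect_error(rank_oxygen_device("scuba"), class = "nvhap_vocab_error")
  expect_match(conditionMessage(err), "nasal cannula")
})

test_that("sustained deterioration requires 2 worse days after 2 stable days", {
  # no change -> no candidates
  expect_identical(detect_sustained_deterioration(rep(0L, 6), rep(96, 6)),
                   integer())
  # stable days 1-2, escalation days 3-4 -> onset day 3
  expect_identical(detect_sustained_deterioration(c(0L, 0L, 1L, 1L),
                                                  rep(96, 4)), 3L)
  # single-day blip is not sustained
  expect_identical(detect_sustained_deterioration(c(0L, 0L, 1L, 0L),
                                                  rep(96, 4)), integer())
  # SpO2 route: drop must reach the margin relative to the baseline day
  expect_identical(detect_sustained_deterioration(rep(0L, 5),
                                                  c(96, 96, 93, 93, 96)), 3L)
  expect_identical(detect_sustained_deterioration(rep(0L, 5),
                                                  c(96, 96, 94, 94, 96)),
                   integer())
  # no stable baseline: escalation already under way on day 2
  expect_identical(detect_sustained_deterioration(c(0L, 1L, 2L, 2L, 2L),
                                                  rep(96, 5)), integer())
  # day-4 onset needs days 1-2 and 2-3 both non-worsening
  expect_identical(detect_sustained_deterioration(c(0L, 0L, 0L, 1L, 1L),
                                                  rep(96, 5)), 4L)
  # short stays cannot qualify
  expect_identical(detect_sustained_deterioration(c(0L, 0L, 1L), rep(96, 3)),
                   integer())
})

test_that("temperature and WBC thresholds are applied with stated inclusivity", {
  base <- data.frame(day = 1:7, temp_min = 37, temp_max = 37, wbc = 8)
  hot <- base; hot$temp_max[4] <- 38.4
  expect_true(check_temp_wbc(hot, 4)$met)
  expect_identical(check_temp_wbc(hot, 4)$trigger, "temperature")
  boundary <- base; boundary$wbc[5] <- 12.0
  expect_true(check_temp_wbc(boundary, 4)$met)       # >= 12.0 inclusive
  low <- base; low$wbc[4] <- 3.99
  expect_true(check_temp_wbc(low, 4)$met)            # < 4.0 exclusive at 4
  at4 <- base; at4$wbc[4] <- 4.0
  expect_false(check_temp_wbc(at4, 4)$met)
  cold <- base; cold$temp_min[2] <- 36.0
  expect_true(check_temp_wbc(cold, 4)$met)           # <= 36 inclusive, day in window
  expect_false(check_temp_wbc(base, 4)$met)
  outside <- base; outside$temp_max[7] <- 39
  expect_false(check_temp_wbc(outside, 4)$met)       # beyond onset+2
  missing <- base; missing$temp_max <- NA; missing$wbc <- NA
  expect_false(check_temp_wbc(missing, 4)$met)       # nulls never satisfy
})

test_that("imaging window is onset-1 .. onset+2", {
  base <- data.frame(day = 1:8, chest_imaging = FALSE)
  for (d in 3:6) {
    x <- base; x$chest_imaging[d] <- TRUE
    expect_true(check_imaging(x, 4)$met)
  }
  late <- base; late$chest_imaging[7] <- TRUE
  expect_false(check_imaging(late, 4)$met)
  early <- base; early$chest_imaging[2] <- TRUE
  expect_false(check_imaging(early, 4)$met)
  expect_false(check_imaging(base, 4)$met)
})

test_that("antimicrobial criterion needs a new >=3-day run starting day 1-2 of deterioration", {
  m <- function(days, agent = "a") data.frame(day = days, agent_id = agent)
  # run on onset day, nothing before -> met
  expect_true(check_new_antimicrobials(m(3:5), 3, los = 6)$met)
  # run starting on second deterioration day -> met
  expect_true(check_new_antimicrobials(m(4:6), 3, los = 6)$met)
  # run starting day 3 of deterioration -> not met
  expect_false(check_new_antimicrobials(m(5:7), 3, los = 8)$met)
  # continuous prior use is not "new"
  expect_false(check_new_antimicrobials(m(1:5), 3, los = 6)$met)
  # administration 2 days before start blocks newness at default lookback
  expect_false(check_new_antimicrobials(m(c(1, 3, 4, 5)), 3, los = 6)$met)
  # truncated by discharge before 3 observed days -> not met
  expect_false(check_new_antimicrobials(m(3:4), 3, los = 4)$met)
  # agents may differ across the run days
  mixed <- data.frame(day = 3:5, agent_id = c("a", "b", "c"))
  expect_true(check_new_antimicrobials(mixed, 3, los = 6)$met)
  # gap inside the run breaks it
  expect_false(check_new_antimicrobials(m(c(3, 5, 6)), 3, los = 7)$met)
})

test_that("full conjunction fires only when every criterion holds", {
  fx <- event_fixture()
  ev <- detect_nvhap(fx$daily, fx$medications)
  expect_identical(ev$onset_day, 3L)
  expect_identical(ev$temp_wbc_trigger, "temperature")
  expect_identical(ev$imaging_day, 3L)
  expect_identical(ev$abx_start_day, 3L)

  no_img <- event_fixture()
  no_img$daily[, chest_imaging := FALSE]
  expect_null(detect_nvhap(no_img$daily, no_img$medications))

  vented <- event_fixture()
  vented$daily[day <= 2, o2_device := "ventilator"]
  expect_null(detect_nvhap(vented$daily, vented$medications))

  no_meds <- event_fixture()
  expect_null(detect_nvhap(no_meds$daily, NULL))
})

test_that("dataset-level detection equals per-admission detection and the brute-force oracle", {
  g <- generate_cohort(sim_config(n_hospitalizations = 1000, seed = 77,
                                  signal_completeness = 0.8))
  ev <- detect_events(g$dataset)
  daily <- g$dataset$daily
  meds <- g$dataset$medications
  got <- setNames(ev$onset_day, ev$hosp_id)
  for (h in unique(daily$hosp_id)) {
    d1 <- daily[hosp_id == h]
    m1 <- meds[hosp_id == h]
    oracle <- surveillance_oracle(as.data.frame(d1), as.data.frame(m1))
    single <- detect_nvhap(d1, m1)
    expect_identical(single$onset_day %||% NA_integer_, oracle,
                     label = paste("admission", h))
    expect_identical(unname(got[h]), oracle, label = paste("engine", h))
  }
})

test_that("a detected event implies a deterioration candidate at the same day", {
  g <- generate_cohort(sim_config(n_hospitalizations = 400, seed = 88))
  ev <- detect_events(g$dataset)
  daily <- impute_normal_oxygenation(g$dataset$daily)
  for (k in seq_len(nrow(ev))) {
    d1 <- daily[hosp_id == ev$hosp_id[k]][order(day)]
    cands <- detect_sustained_deterioration(rank_oxygen_device(d1$o2_device),
                                            d1$spo2_min)
    expect_true(ev$onset_day[k] %in% cands)
  }
})
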