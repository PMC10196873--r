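# Flat-table EHR data model: schemas, readers/writers, validation, imputation.
#
# The analysis operates on four flat tables:
#   facilities        one row per facility (size class, teaching, region)
#   hospitalizations  one row per admission (demographics, comorbidities,
#                     length of stay, disposition)
#   daily             one row per hospitalization-day (service, ICU, vitals,
#                     oxygenation, labs, chest-imaging flag)
#   medications       one row per hospitalization-day-antimicrobial
#
# Hospital days are 1-based calendar days with admission day = 1; all window
# logic downstream is expressed in these units. Dates live only on the
# admission record. Missing numeric cells are empty strings in CSV, NA in R.

.ehr_schema <- list(
  facilities = list(
    character = c("facility_id", "bed_size_class", "region"),
    logical   = "teaching"
  ),
  hospitalizations = list(
    character = c("hosp_id", "facility_id", "sex", "race", "admit_day",
                  "disposition"),
    integer   = c("age", "los", "elixhauser_index"),
    logical   = c(.comorbidity_flags, "prior_90d_admission")
  ),
  daily = list(
    character = c("hosp_id", "service", "o2_device"),
    integer   = "day",
    logical   = c("icu", "chest_imaging"),
    numeric   = c("temp_min", "temp_max", "wbc", "spo2_min", "hematocrit",
                  "platelets", "sodium", "glucose", "creatinine", "alt",
                  "bilirubin", "albumin")
  ),
  medications = list(
    character = c("hosp_id", "agent_id"),
    integer   = "day"
  )
)

.schema_cols <- function(tab) unlist(.ehr_schema[[tab]], use.names = FALSE)

.coerce_table <- function(df, tab) {
  dt <- as.data.table(df)
  setnames(dt, tolower(names(dt)))
  sch <- .ehr_schema[[tab]]
  missing <- setdiff(unlist(sch), names(dt))
  if (length(missing))
    .stop_cls("nvhap_schema_error", "table '%s' is missing column(s): %s",
              tab, paste(missing, collapse = ", "))
  for (col in sch$character) set(dt, j = col, value = as.character(dt[[col]]))
  for (col in sch$integer)   set(dt, j = col, value = as.integer(dt[[col]]))
  for (col in sch$numeric %||% character()) {
    set(dt, j = col, value = as.numeric(dt[[col]]))
  }
  for (col in sch$logical %||% character()) {
    v <- dt[[col]]
    if (!is.logical(v)) {
      v <- tolower(as.character(v))
      v <- c("true" = TRUE, "t" = TRUE, "1" = TRUE,
             "false" = FALSE, "f" = FALSE, "0" = FALSE)[v]
    }
    set(dt, j = col, value = unname(v))
  }
  dt[, intersect(names(dt), unlist(sch)), with = FALSE]
}

.check_vocab <- function(x, set, what, nullable = FALSE) {
  bad <- setdiff(unique(x[!is.na(x)]), set)
  if (length(bad))
    .stop_cls("nvhap_vocab_error",
              "invalid %s value(s): %s (accepted: %s)", what,
              paste(bad, collapse = ", "), paste(set, collapse = ", "))
  if (!nullable && anyNA(x))
    .stop_cls("nvhap_vocab_error", "%s must not be missing", what)
  invisible(TRUE)
}

#' Assemble and validate an EHR dataset from in-memory tables
#'
#' Bundles the four flat tables into a validated `nvhap_dataset`. Validation
#' enforces key uniqueness, referential integrity, closed category
#' vocabularies, `age >= 18`, `los >= 1`, `1 <= day <= los`, contiguous daily
#' rows `1..los` per admission, and medication days within the stay.
#'
#' @param facilities,hospitalizations,daily,medications data frames matching
#'   the documented schemas (column name matching is case-insensitive).
#' @param validate run the full validation pass (default `TRUE`).
#' @return An object of class `nvhap_dataset`: a list of four `data.table`s
#'   keyed by their identifiers.
#' @export
ehr_dataset <- function(facilities, hospitalizations, daily, medications,
                        validate = TRUE) {
  ds <- structure(list(
    facilities       = .coerce_table(facilities, "facilities"),
    hospitalizations = .coerce_table(hospitalizations, "hospitalizations"),
    daily            = .coerce_table(daily, "daily"),
    medications      = .coerce_table(medications, "medications")
  ), class = "nvhap_dataset")
  setkey(ds$daily, hosp_id, day)
  setkey(ds$hospitalizations, hosp_id)
  if (validate) validate_ehr(ds)
  ds
}

#' Validate an EHR dataset
#'
#' @param ds an `nvhap_dataset`.
#' @return `ds`, invisibly; errors of class `nvhap_schema_error`,
#'   `nvhap_integrity_error` or `nvhap_vocab_error` otherwise.
#' @export
validate_ehr <- function(ds) {
  fac <- ds$facilities; hosp <- ds$hospitalizations
  daily <- ds$daily; meds <- ds$medications

  if (anyDuplicated(fac$facility_id))
    .stop_cls("nvhap_integrity_error", "duplicate facility_id")
  .check_vocab(fac$bed_size_class, .nvhap_vocab$bed_size_class, "bed_size_class")
  .check_vocab(fac$region, .nvhap_vocab$region, "region")

  if (anyDuplicated(hosp$hosp_id))
    .stop_cls("nvhap_integrity_error", "duplicate hosp_id")
  if (nrow(hosp)) {
    if (any(hosp$los < 1L, na.rm = TRUE) || anyNA(hosp$los))
      .stop_cls("nvhap_integrity_error", "los must be an integer >= 1")
    if (any(hosp$age < 18L, na.rm = TRUE))
      .stop_cls("nvhap_integrity_error", "age must be >= 18 (adult cohort)")
    unk <- setdiff(hosp$facility_id, fac$facility_id)
    if (length(unk))
      .stop_cls("nvhap_integrity_error", "hospitalizations reference unknown facility_id: %s",
                paste(head(unk, 5), collapse = ", "))
  }
  .check_vocab(hosp$sex, .nvhap_vocab$sex, "sex")
  .check_vocab(hosp$race, .nvhap_vocab$race, "race")
  .check_vocab(hosp$disposition, .nvhap_vocab$disposition, "disposition")

  for (tb in list(daily = daily, medications = meds)) {
    unk <- setdiff(tb$hosp_id, hosp$hosp_id)
    if (length(unk))
      .stop_cls("nvhap_integrity_error", "daily/medication rows reference unknown hosp_id: %s",
                paste(head(unk, 5), collapse = ", "))
  }
  if (anyDuplicated(daily, by = c("hosp_id", "day")))
    .stop_cls("nvhap_integrity_error", "duplicate (hosp_id, day) in daily table")
  .check_vocab(daily$service, .nvhap_vocab$service, "service")
  .check_vocab(daily$o2_device, oxygen_devices(), "o2_device", nullable = TRUE)

  if (nrow(daily)) {
    chk <- daily[hosp[, .(hosp_id, los)], on = "hosp_id"][
      , .(n = .N, dmin = min(day), dmax = max(day), los = los[1]), by = hosp_id]
    if (any(chk$dmax > chk$los))
      .stop_cls("nvhap_integrity_error", "daily rows with day > los (e.g. %s)",
                chk[dmax > los, hosp_id][1])
    if (any(chk$dmin < 1L))
      .stop_cls("nvhap_integrity_error", "daily rows with day < 1")
    bad <- chk[n != los | dmin != 1L | dmax != los]
    if (nrow(bad))
      .stop_cls("nvhap_integrity_error",
                "daily rows must form a contiguous 1..los sequence (violated for %s)",
                bad$hosp_id[1])
    miss <- setdiff(hosp$hosp_id, daily$hosp_id)
    if (length(miss))
      .stop_cls("nvhap_integrity_error", "no daily rows for hosp_id %s", miss[1])
  }

  if (nrow(meds)) {
    if (anyDuplicated(meds, by = c("hosp_id", "day", "agent_id")))
      .stop_cls("nvhap_integrity_error", "duplicate (hosp_id, day, agent_id) in medications")
    mchk <- meds[hosp[, .(hosp_id, los)], on = "hosp_id", nomatch = NULL]
    if (any(mchk$day < 1L | mchk$day > mchk$los))
      .stop_cls("nvhap_integrity_error", "medication day outside 1..los")
  }
  invisible(ds)
}

#' Read the four EHR tables from CSV
#'
#' @param dir directory containing `facilities.csv`, `hospitalizations.csv`,
#'   `daily.csv`, `medications.csv`, or a named list/vector of the four paths.
#' @param validate validate after reading (default `TRUE`).
#' @return a validated `nvhap_dataset`.
#' @export
read_ehr_tables <- function(dir, validate = TRUE) {
  tabs <- c("facilities", "hospitalizations", "daily", "medications")
  paths <- if (is.character(dir) && length(dir) == 1L && dir.exists(dir)) {
    setNames(file.path(dir, paste0(tabs, ".csv")), tabs)
  } else unlist(dir)[tabs]
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    .stop_cls("nvhap_schema_error", "input file(s) not found: %s",
              paste(missing, collapse = ", "))
  raw <- lapply(paths, fread, na.strings = "", colClasses = NULL,
                showProgress = FALSE)
  ehr_dataset(raw$facilities, raw$hospitalizations, raw$daily,
              raw$medications, validate = validate)
}

#' Write an EHR dataset to CSV
#'
#' Inverse of [read_ehr_tables()]; missing values become empty cells so the
#' round trip is lossless.
#'
#' @param ds an `nvhap_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_ehr_tables <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tab in names(ds))
    fwrite(ds[[tab]], file.path(dir, paste0(tab, ".csv")), na = "", quote = "auto")
  invisible(dir)
}

#' Treat missing oxygenation as normal
#'
#' Missing pulse oximetry and missing supplemental-oxygen device are treated
#' as normal: `spo2_min` gaps are filled with `normal_spo2` and `o2_device`
#' gaps with `"none"`. All other missing values are left untouched.
#'
#' @param ds an `nvhap_dataset` (or a daily `data.table`).
#' @param normal_spo2 the saturation imputed for unmeasured days (default 97).
#' @return object of the same shape with oxygenation gaps filled.
#' @export
impute_normal_oxygenation <- function(ds, normal_spo2 = 97) {
  daily <- if (inherits(ds, "nvhap_dataset")) ds$daily else as.data.table(ds)
  daily <- copy(daily)
  daily[is.na(spo2_min), spo2_min := as.numeric(normal_spo2)]
  daily[is.na(o2_device), o2_device := "none"]
  if (inherits(ds, "nvhap_dataset")) { ds$daily <- daily; ds } else daily
}

#' @export
print.nvhap_dataset <- function(x, ...) {
  cat("<nvhap_dataset>\n")
  cat(sprintf("  facilities:       %6d\n", nrow(x$facilities)))
  cat(sprintf("  hospitalizations: %6d\n", nrow(x$hospitalizations)))
  cat(sprintf("  daily records:    %6d\n", nrow(x$daily)))
  cat(sprintf("  medication rows:  %6d\n", nrow(x$medications)))
  invisible(x)
}
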