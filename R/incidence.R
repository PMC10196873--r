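# Descriptive incidence reporting: event rates per 100 admissions and per
# 1000 patient-days with Wilson score intervals, facility-level caterpillar
# tables, and outcome (disposition / length-of-stay) summaries.

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x successes.
#' @param n trials.
#' @param conf confidence level (default 0.95).
#' @return named numeric vector `c(low, high)` on the proportion scale.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}

.rate_scale <- c("per100" = 100, "per1000" = 1000)

#' Event rate with confidence interval
#'
#' Rate = scale x numerator / denominator, with a 95% Wilson score interval
#' on the underlying proportion rescaled to the same units. The denominator
#' counts admissions (per-100) or patient-days (per-1000); patient-days
#' count every calendar day of the stay, admission and discharge days
#' included (`los` days per admission).
#'
#' @param numerator event count.
#' @param denominator admissions or patient-days; must be > 0.
#' @param scale `"per100"` or `"per1000"`.
#' @param conf confidence level.
#' @param method `"wilson"` (default) or `"clopper-pearson"` (exact).
#' @return one-row `data.frame`: `numerator`, `denominator`, `scale`,
#'   `rate`, `ci_low`, `ci_high` (all on the requested scale, unrounded).
#' @export
rate <- function(numerator, denominator, scale = c("per100", "per1000"),
                 conf = 0.95, method = c("wilson", "clopper-pearson")) {
  scale <- match.arg(scale)
  method <- match.arg(method)
  if (is.na(denominator) || denominator <= 0)
    .stop_cls("nvhap_rate_error", "rate undefined: denominator must be > 0")
  stopifnot(numerator >= 0)
  s <- .rate_scale[[scale]]
  ci <- if (method == "wilson") {
    wilson_ci(numerator, denominator, conf)
  } else {
    bt <- stats::binom.test(round(numerator), round(denominator),
                            conf.level = conf)
    c(low = bt$conf.int[1], high = bt$conf.int[2])
  }
  data.frame(numerator = numerator, denominator = denominator, scale = scale,
             rate = s * numerator / denominator,
             ci_low = s * ci[["low"]], ci_high = s * ci[["high"]])
}

#' Facility-level incidence table
#'
#' One row per facility (facilities without events included at rate 0),
#' events per 100 admissions with Wilson CIs, sorted ascending by rate —
#' the table behind a caterpillar plot — plus the median and IQR of the
#' facility rates.
#'
#' @param events event table with `hosp_id` (e.g. from [detect_events()]).
#' @param hospitalizations admission table with `hosp_id`, `facility_id`.
#' @param conf confidence level.
#' @return list with `rates` (a `data.table`: `facility_id`, `events`,
#'   `admissions`, `rate`, `ci_low`, `ci_high`), `median`, `iqr`.
#' @export
facility_incidence <- function(events, hospitalizations, conf = 0.95) {
  hosp <- as.data.table(hospitalizations)
  ev <- as.data.table(events)
  if (nrow(ev)) {
    unknown <- setdiff(ev$hosp_id, hosp$hosp_id)
    if (length(unknown))
      .stop_cls("nvhap_integrity_error",
                "events reference unknown hosp_id: %s", unknown[1])
  }
  hosp[, has_event := hosp_id %in% ev$hosp_id]
  tab <- hosp[, .(events = sum(has_event), admissions = .N), by = facility_id]
  tab[, c("rate", "ci_low", "ci_high") := {
    ci <- mapply(function(x, n) wilson_ci(x, n, conf), events, admissions)
    .(100 * events / admissions, 100 * ci["low", ], 100 * ci["high", ])
  }]
  setorder(tab, rate, facility_id)
  q <- quantile(tab$rate, c(0.25, 0.5, 0.75), names = FALSE)
  list(rates = tab[], median = q[2], iqr = c(q[1], q[3]))
}

#' Disposition and length-of-stay summary, event vs all admissions
#'
#' Counts and percentages per discharge disposition for admissions meeting
#' the NV-HAP definition and for all admissions, plus median (IQR) length
#' of stay per group. Percentages are rounded half-up to one decimal.
#'
#' @param events event table with `hosp_id` (zero rows allowed).
#' @param hospitalizations admission table.
#' @return list with `dispositions` (a `data.table`: `group`,
#'   `disposition`, `n`, `pct`) and `los` (`group`, `median`, `q1`, `q3`).
#' @export
outcome_table <- function(events, hospitalizations) {
  hosp <- as.data.table(hospitalizations)
  ev_ids <- unique(as.data.table(events)$hosp_id)
  groups <- list(nvhap = hosp[hosp_id %in% ev_ids], all = hosp)
  disp <- rbindlist(lapply(names(groups), function(g) {
    h <- groups[[g]]
    if (!nrow(h)) return(NULL)
    d <- h[, .(n = .N), by = .(disposition)]
    d[, `:=`(group = g, pct = round_half_up(100 * n / sum(n), 1))]
    d[, .(group, disposition, n, pct)]
  }))
  if (is.null(disp) || !nrow(disp))
    disp <- data.table(group = character(), disposition = character(),
                       n = integer(), pct = numeric())
  los <- rbindlist(lapply(names(groups), function(g) {
    h <- groups[[g]]
    if (!nrow(h)) return(NULL)
    q <- quantile(h$los, c(0.25, 0.5, 0.75), names = FALSE, type = 1)
    data.table(group = g, median = q[2], q1 = q[1], q3 = q[3])
  }))
  list(dispositions = disp, los = los)
}

#' Caterpillar plot of facility incidence
#'
#' @param fi result of [facility_incidence()].
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plot_facility_rates <- function(fi) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_facility_rates requires ggplot2")
  tab <- copy(fi$rates)
  tab[, ord := seq_len(.N)]
  ggplot2::ggplot(tab, ggplot2::aes(x = ord, y = rate)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = ci_low, ymax = ci_high),
                           width = 0, colour = "grey55") +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::labs(x = "Facility (ranked by incidence)",
                  y = "NV-HAP events per 100 admissions") +
    ggplot2::theme_minimal()
}
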