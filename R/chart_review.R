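# Validation statistics for dual-physician chart review of
# surveillance-flagged cases.

#' Positive predictive value with Wilson interval
#'
#' @param positives reviewed cases judged true positives.
#' @param reviewed total cases reviewed (> 0).
#' @param conf confidence level.
#' @return one-row `data.frame`: `positives`, `reviewed`, `ppv` (proportion),
#'   `ppv_pct` (whole-percent display value, half-up), `ci_low`, `ci_high`.
#' @export
ppv <- function(positives, reviewed, conf = 0.95) {
  if (is.na(reviewed) || reviewed <= 0)
    .stop_cls("nvhap_rate_error", "ppv undefined: no reviewed cases")
  stopifnot(positives >= 0, positives <= reviewed)
  ci <- wilson_ci(positives, reviewed, conf)
  p <- positives / reviewed
  data.frame(positives = positives, reviewed = reviewed, ppv = p,
             ppv_pct = round_half_up(100 * p),
             ci_low = ci[["low"]], ci_high = ci[["high"]])
}

#' Simple agreement and Cohen kappa for paired binary judgments
#'
#' `po` is the observed agreement proportion; `pe` the chance agreement from
#' the two raters' marginal proportions; `kappa = (po - pe) / (1 - pe)`,
#' reported as `NA` (not estimable) when `pe = 1`.
#'
#' @param rater1,rater2 equal-length logical (or coercible) judgment vectors.
#' @return list with `n`, `agreement` (po), `pe`, `kappa`.
#' @export
cohen_kappa <- function(rater1, rater2) {
  r1 <- as.logical(rater1); r2 <- as.logical(rater2)
  stopifnot(length(r1) == length(r2))
  keep <- !is.na(r1) & !is.na(r2)
  r1 <- r1[keep]; r2 <- r2[keep]
  n <- length(r1)
  if (n == 0L)
    .stop_cls("nvhap_rate_error", "kappa undefined: no complete rating pairs")
  po <- mean(r1 == r2)
  pe <- mean(r1) * mean(r2) + mean(!r1) * mean(!r2)
  kap <- if (abs(1 - pe) < .Machine$double.eps^0.5) NA_real_ else (po - pe) / (1 - pe)
  list(n = n, agreement = po, pe = pe, kappa = kap)
}
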