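#' Define an observation window
#'
#' A study window is the half-open day interval `[start, start + length_days)`.
#' All interval arithmetic in the package is integer day arithmetic on offsets
#' from the window start, which keeps coverage unions additive and avoids any
#' timezone ambiguity.
#'
#' @param start Window start (`Date` or ISO-8601 string).
#' @param length_days Window length in days, default 365.
#' @return An object of class `study_window`.
#' @export
#' @examples
#' study_window("2010-03-01")
study_window <- function(start, length_days = 365L) {
  start <- as.Date(start)
  stopifnot(!is.na(start), length(start) == 1L, length_days >= 1)
  structure(list(start = start, length_days = as.integer(length_days)),
            class = "study_window")
}

#' @export
print.study_window <- function(x, ...) {
  cat(sprintf("<study_window> [%s, %s) (%d days)\n", x$start,
              x$start + x$length_days, x$length_days))
  invisible(x)
}

#' Baseline and follow-up windows of a pre/post design
#'
#' The follow-up window starts exactly where the baseline window ends; both
#' have the same length (365 days by default, two consecutive observation
#' years).
#'
#' @param baseline_start Start of the baseline window.
#' @param length_days Length of each window in days.
#' @return Named list with `baseline` and `follow_up` study windows.
#' @export
study_windows <- function(baseline_start, length_days = 365L) {
  baseline <- study_window(baseline_start, length_days)
  list(
    baseline = baseline,
    follow_up = study_window(baseline$start + baseline$length_days, length_days)
  )
}

# Coverage intervals [start, end) in day offsets for one fill stream.
# shift_forward: a fill dispensed while prior supply remains is deferred to
# start when that supply runs out, so no supply is wasted; closed form via
# running maxima on the cumulated supply.
# truncate_overlap: overlapping supply is simply lost; coverage is the plain
# interval union.
stream_intervals <- function(d, s, carryover) {
  o <- order(d, method = "radix")
  d <- as.numeric(d[o]); s <- as.numeric(s[o])
  if (carryover == "shift_forward") {
    cs <- cumsum(s)
    end <- cs + cummax(d - c(0, cs[-length(cs)]))
    list(start = end - s, end = end)
  } else {
    e <- d + s
    prev <- c(-Inf, cummax(e)[-length(e)])
    list(start = pmax(d, prev), end = pmax(e, prev))
  }
}

clip_length <- function(iv, lo, hi) {
  sum(pmax(0, pmin(iv$end, hi) - pmax(iv$start, lo)))
}

#' Days of medication supply within a window
#'
#' Counts the distinct days inside `window` on which supply is available,
#' given the fill dates and days of supply of a single patient x subclass
#' stream. Under the `shift_forward` carryover policy (the prevailing PDC
#' convention) an early refill is deferred to start the day after the prior
#' fill's supply is exhausted; under `truncate_overlap` overlapping supply is
#' discarded and coverage is the plain union of the fill intervals. Supply
#' never extends beyond the window end. A fill on day `d` with supply `s`
#' covers days `d ... d + s - 1` (half-open interval convention).
#'
#' @param fill_dates `Date` vector of fill dates (any order).
#' @param days_supply Integer vector of days supplied, parallel to
#'   `fill_dates`.
#' @param window A [study_window()].
#' @param carryover `"shift_forward"` (default) or `"truncate_overlap"`.
#' @return Integer number of covered days in `[0, window$length_days]`.
#'   An empty fill set gives 0. Fills dated outside the window are dropped
#'   with a warning.
#' @export
#' @examples
#' w <- study_window("2010-03-01")
#' covered_days(as.Date("2010-03-01") + c(0, 60), c(90, 90), w)  # 180
covered_days <- function(fill_dates, days_supply,
                         window, carryover = c("shift_forward", "truncate_overlap")) {
  carryover <- match.arg(carryover)
  stopifnot(length(fill_dates) == length(days_supply))
  if (length(fill_dates) == 0L) return(0L)
  if (any(days_supply < 1)) {
    stop_validation("days_supply must be >= 1")
  }
  d <- as.integer(as.Date(fill_dates) - window$start)
  keep <- d >= 0L & d < window$length_days
  if (any(!keep)) {
    warning(sprintf("%d fill(s) dated outside the window were ignored",
                    sum(!keep)), call. = FALSE)
    d <- d[keep]; days_supply <- days_supply[keep]
    if (length(d) == 0L) return(0L)
  }
  iv <- stream_intervals(d, days_supply, carryover)
  as.integer(clip_length(iv, 0, window$length_days))
}

#' Proportion of days covered for one subclass stream
#'
#' `covered_days / window$length_days`; bounded in `[0, 1]` by construction
#' because covered days are distinct days within the window.
#'
#' @inheritParams covered_days
#' @return PDC value in `[0, 1]`; 0 for an empty fill set.
#' @export
pdc_subclass <- function(fill_dates, days_supply, window,
                         carryover = c("shift_forward", "truncate_overlap")) {
  covered_days(fill_dates, days_supply, window, carryover) / window$length_days
}

#' Drug-class PDC from subclass PDCs
#'
#' When a patient fills more than one therapeutic subclass of a drug class in
#' a period (for example a beta blocker and a thiazide), one PDC is computed
#' per subclass and the class-level PDC is their unweighted arithmetic mean.
#'
#' @param per_subclass_pdc Numeric vector of subclass PDC values (optionally
#'   named by subclass).
#' @return Mean PDC, guaranteed to lie between the minimum and maximum input.
#' @export
pdc_class <- function(per_subclass_pdc) {
  if (length(per_subclass_pdc) == 0L) {
    stop_validation("pdc_class: at least one subclass PDC is required")
  }
  if (any(is.na(per_subclass_pdc))) {
    stop_validation("pdc_class: NA subclass PDC")
  }
  mean(per_subclass_pdc)
}

#' Dichotomise adherence at the PDC breakpoint
#'
#' A patient is adherent when PDC is at or above the threshold (inclusive at
#' the boundary: PDC of exactly 0.80 is adherent). 0.80 is the breakpoint
#' widely used for antihypertensive and antihyperlipidemic agents.
#'
#' @param pdc Numeric vector of PDC values in `[0, 1]`.
#' @param threshold Adherence breakpoint, default 0.80.
#' @return Logical vector.
#' @export
classify_adherent <- function(pdc, threshold = 0.80) {
  if (any(is.na(pdc)) || any(pdc < 0 | pdc > 1)) {
    stop_validation("classify_adherent: pdc must lie in [0, 1]")
  }
  pdc >= threshold
}

#' Per-patient PDC over classes, subclasses and periods
#'
#' The workhorse of the PDC engine: takes a fills table (as from
#' [read_fills()]) and the baseline/follow-up windows, computes one PDC per
#' patient x drug class x period by averaging subclass-level PDCs, and
#' dichotomises at the threshold. Each period's PDC uses only fills dated
#' within that period; with `cross_period_carryover = TRUE` (not the default)
#' supply left over at the baseline/follow-up boundary seeds coverage in the
#' follow-up window.
#'
#' @param fills Tibble of fill records.
#' @param windows A list as from [study_windows()].
#' @param carryover Carryover policy, see [covered_days()].
#' @param threshold Adherence breakpoint, default 0.80.
#' @param cross_period_carryover If `TRUE`, supply dispensed in the baseline
#'   window may extend coverage into the follow-up window. Default `FALSE`:
#'   the two periods are independent 365-day observation units.
#' @return Tibble with columns `patient_id, drug_class, period, covered_days,
#'   pdc, adherent, n_subclasses`. Rows exist only for patient x class x
#'   period combinations with at least one fill in that period.
#' @export
compute_pdc <- function(fills, windows,
                        carryover = c("shift_forward", "truncate_overlap"),
                        threshold = 0.80, cross_period_carryover = FALSE) {
  carryover <- match.arg(carryover)
  bl <- windows$baseline; fu <- windows$follow_up
  stopifnot(fu$start == bl$start + bl$length_days)
  empty <- tibble::tibble(
    patient_id = character(), drug_class = character(), period = character(),
    covered_days = integer(), pdc = numeric(), adherent = logical(),
    n_subclasses = integer()
  )
  if (nrow(fills) == 0L) return(empty)

  dt <- data.table::as.data.table(fills)
  dt[, day := as.integer(fill_date - bl$start)]
  total_len <- bl$length_days + fu$length_days
  dt <- dt[day >= 0L & day < total_len]
  if (nrow(dt) == 0L) return(empty)
  dt[, period := ifelse(day < bl$length_days, "baseline", "follow_up")]

  if (!cross_period_carryover) {
    # independent periods: stream = patient x class x subclass x period
    sub <- dt[, {
      off <- if (period[1L] == "baseline") 0L else bl$length_days
      len <- if (period[1L] == "baseline") bl$length_days else fu$length_days
      iv <- stream_intervals(day - off, days_supply, carryover)
      list(covered = clip_length(iv, 0, len), len = len)
    }, by = .(patient_id, drug_class, subclass, period)]
  } else {
    # one stream across both windows; count coverage falling in each
    sub <- dt[, {
      iv <- stream_intervals(day, days_supply, carryover)
      pers <- unique(period)
      covs <- vapply(pers, function(p) {
        if (p == "baseline") clip_length(iv, 0, bl$length_days)
        else clip_length(iv, bl$length_days, total_len)
      }, numeric(1))
      lens <- ifelse(pers == "baseline", bl$length_days, fu$length_days)
      list(period = pers, covered = covs, len = lens)
    }, by = .(patient_id, drug_class, subclass)]
  }
  sub[, pdc_sub := covered / len]
  out <- sub[, .(
    covered_days = as.integer(round(mean(covered))),
    pdc = mean(pdc_sub),
    n_subclasses = .N
  ), by = .(patient_id, drug_class, period)]
  out[, adherent := pdc >= threshold]
  data.table::setorder(out, patient_id, drug_class, period)
  tibble::as_tibble(out[, .(patient_id, drug_class, period, covered_days,
                            pdc, adherent, n_subclasses)])
}
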