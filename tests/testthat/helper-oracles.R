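# Independent brute-force oracles for the PDC engine, plus small fixture
# builders. These deliberately share no code with the package internals:
# coverage is decided by marking individual days of a boolean calendar.

# truncate_overlap oracle: a day is covered if any fill interval contains it.
oracle_union_days <- function(offsets, supplies, len = 365L) {
  days <- logical(len)
  for (i in seq_along(offsets)) {
    d <- offsets[i]
    if (d >= len) next
    span <- seq.int(d, min(d + supplies[i] - 1L, len - 1L))
    days[span + 1L] <- TRUE
  }
  sum(days)
}

# shift_forward oracle: walk day by day, dispensing queued supply; a fill
# encountered while supply remains is banked and starts when the tank empties.
oracle_queue_days <- function(offsets, supplies, len = 365L) {
  o <- order(offsets)
  offsets <- offsets[o]; supplies <- supplies[o]
  tank <- 0L
  covered <- 0L
  i <- 1L
  for (day in seq_len(len) - 1L) {
    while (i <= length(offsets) && offsets[i] == day) {
      tank <- tank + supplies[i]
      i <- i + 1L
    }
    if (tank > 0L) {
      covered <- covered + 1L
      tank <- tank - 1L
    }
  }
  covered
}

# Mantel-Haenszel common risk ratio over strata of 2x2 tables.
oracle_mh_rr <- function(a, n1, c, n2) {
  N <- n1 + n2
  sum(a * n2 / N) / sum(c * n1 / N)
}

random_fill_set <- function(max_fills = 20L, supply_range = c(1L, 120L),
                            offset_range = c(0L, 364L)) {
  k <- sample.int(max_fills, 1L)
  list(
    offsets = sample(offset_range[1]:offset_range[2], k, replace = TRUE),
    supplies = sample(supply_range[1]:supply_range[2], k, replace = TRUE)
  )
}

# fills tibble for one patient/subclass from day offsets
fills_from_offsets <- function(offsets, supplies, start = as.Date("2010-03-01"),
                               patient_id = "p1",
                               drug_class = "antihypertensive",
                               subclass = "ACE") {
  tibble::tibble(
    patient_id = patient_id, drug_class = drug_class, subclass = subclass,
    fill_date = start + offsets, days_supply = as.integer(supplies)
  )
}

# roster row builder with sensible defaults
roster_row <- function(patient_id, group = "control", age = 60L,
                       enroll_start = as.Date("2009-01-01"),
                       enroll_end = as.Date("2012-06-30"),
                       sex = "female", race_white = TRUE, diabetes = FALSE,
                       bmi = 30, pcp_visits_per_year = 3.3, charlson = 1) {
  tibble::tibble(
    patient_id = patient_id, group = group, age = age, sex = sex,
    race_white = race_white, diabetes = diabetes, bmi = bmi,
    pcp_visits_per_year = pcp_visits_per_year, charlson = charlson,
    enroll_start = enroll_start, enroll_end = enroll_end
  )
}

# cohort tibble from explicit per-member transition levels
cohort_from_levels <- function(groups, levels) {
  bl <- levels %in% c("adherent_to_adherent", "adherent_to_nonadherent")
  fu <- levels %in% c("adherent_to_adherent", "nonadherent_to_adherent")
  tibble::tibble(
    patient_id = sprintf("m%03d", seq_along(groups)),
    group = groups, drug_class = "antihypertensive",
    baseline_adherent = bl, followup_adherent = fu,
    baseline_pdc = ifelse(bl, 0.9, 0.5), followup_pdc = ifelse(fu, 0.9, 0.5)
  )
}

# expand a 2x2(xK) specification into a patient-level tibble for the
# regression estimators: one row per patient with group and outcome
expand_counts <- function(a, n1, c, n2, stratum = NULL) {
  rows <- list()
  K <- length(a)
  for (k in seq_len(K)) {
    rows[[k]] <- tibble::tibble(
      group = rep(c("intervention", "control"), c(n1[k], n2[k])),
      outcome = c(rep(c(TRUE, FALSE), c(a[k], n1[k] - a[k])),
                  rep(c(TRUE, FALSE), c(c[k], n2[k] - c[k]))),
      stratum = if (is.null(stratum)) NA else stratum[k]
    )
  }
  dplyr::bind_rows(rows)
}
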