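TRANSITION_LEVELS <- c("nonadherent_to_adherent", "adherent_to_adherent",
                       "nonadherent_to_nonadherent", "adherent_to_nonadherent")

#' A 2x2 comparison of adherence counts
#'
#' @param a Adherent count in the intervention arm.
#' @param n1 Intervention arm size.
#' @param c Adherent count in the control arm.
#' @param n2 Control arm size.
#' @return Object of class `two_by_two`.
#' @export
two_by_two <- function(a, n1, c, n2) {
  vals <- c(a = a, n1 = n1, c = c, n2 = n2)
  if (any(vals != floor(vals)) || any(vals < 0) || n1 < 1 || n2 < 1 ||
      a > n1 || c > n2) {
    stop_validation("two_by_two: need integer counts with 0 <= a <= n1, 0 <= c <= n2")
  }
  structure(as.list(vals), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  cat(sprintf("<two_by_two> intervention %d/%d (%.1f%%), control %d/%d (%.1f%%)\n",
              x$a, x$n1, 100 * x$a / x$n1, x$c, x$n2, 100 * x$c / x$n2))
  invisible(x)
}

effect_estimate <- function(measure, estimate, ci_low, ci_high, p, method,
                            adjusted, comparison, class = NA_character_,
                            period = NA_character_) {
  tibble::tibble(
    comparison = comparison, class = class, period = period,
    measure = measure, estimate = estimate, ci_low = ci_low,
    ci_high = ci_high, p = p, method = method, adjusted = adjusted
  )
}

#' Adherence rate of a cohort in one period
#'
#' @param cohort Cohort tibble from [build_cohort()].
#' @param period `"baseline"` or `"follow_up"`.
#' @param group Optional arm (`"intervention"`/`"control"`) to restrict to.
#' @return List with `count`, `n` and `proportion`.
#' @export
adherence_rate <- function(cohort, period = c("follow_up", "baseline"),
                           group = NULL) {
  period <- match.arg(period)
  if (!is.null(group)) cohort <- cohort[cohort$group == group, ]
  if (nrow(cohort) == 0L) stop_validation("adherence_rate: empty cohort")
  flag <- if (period == "baseline") cohort$baseline_adherent else cohort$followup_adherent
  list(count = sum(flag), n = length(flag), proportion = mean(flag))
}

#' Unadjusted risk ratio with Katz log-method confidence interval
#'
#' Point estimate `(a/n1)/(c/n2)`; 95% CI on the log scale with standard
#' error `sqrt(1/a - 1/n1 + 1/c - 1/n2)` (Katz method, z = 1.96 at the
#' default level, no continuity correction); two-sided p from the Wald
#' statistic on the log scale. With a zero numerator cell the point estimate
#' is still returned but CI and p are non-finite.
#'
#' @param t A [two_by_two()].
#' @param conf_level Confidence level, default 0.95.
#' @param comparison Label carried into the result.
#' @param method Method tag, default `"katz_log"`.
#' @return One-row effect-estimate tibble.
#' @export
rr_unadjusted <- function(t, conf_level = 0.95,
                          comparison = "intervention_vs_control",
                          method = "katz_log") {
  stopifnot(inherits(t, "two_by_two"))
  rr <- (t$a / t$n1) / (t$c / t$n2)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (t$a == 0L || t$c == 0L) {
    return(effect_estimate("RR", rr, NA_real_, NA_real_, NA_real_,
                           method, FALSE, comparison))
  }
  se <- sqrt(1 / t$a - 1 / t$n1 + 1 / t$c - 1 / t$n2)
  ci <- exp(log(rr) + c(-1, 1) * z * se)
  p <- 2 * stats::pnorm(-abs(log(rr)) / se)
  effect_estimate("RR", rr, ci[1], ci[2], p, method, FALSE, comparison)
}

#' Covariate-adjusted risk ratio (modified Poisson)
#'
#' Fits a log-link Poisson model to the binary outcome (modified Poisson
#' regression) and reports the intervention-vs-control risk ratio with a
#' robust (HC0 sandwich) variance estimator, the standard way to obtain
#' adjusted risk ratios for a common binary outcome. Members with a missing
#' value in any requested covariate are excluded; the count is attached as
#' attribute `"n_excluded_missing"`.
#'
#' @param data Tibble with a logical/0-1 `outcome` column, a `group` column
#'   (`"intervention"`/`"control"`) and any covariate columns.
#' @param outcome Name of the outcome column.
#' @param covariates Character vector of covariate column names (may be
#'   empty: the model then reproduces the crude risk ratio).
#' @param conf_level Confidence level, default 0.95.
#' @param comparison Label carried into the result.
#' @param method Method tag, default `"modified_poisson_robust"`.
#' @return One-row effect-estimate tibble.
#' @export
rr_adjusted <- function(data, outcome = "followup_adherent",
                        covariates = character(), conf_level = 0.95,
                        comparison = "intervention_vs_control",
                        method = "modified_poisson_robust") {
  stopifnot(all(c(outcome, covariates, "group") %in% names(data)))
  cols <- c(outcome, "group", covariates)
  use <- stats::complete.cases(data[cols])
  n_excluded <- sum(!use)
  d <- data[use, cols]
  d$.y <- as.integer(d[[outcome]])
  d$group <- factor(d$group, levels = c("control", "intervention"))
  fml <- stats::reformulate(c("group", covariates), response = ".y")
  fit <- stats::glm(fml, data = d, family = stats::poisson(link = "log"),
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  if (!fit$converged) {
    abort("modified Poisson fit did not converge", class = "pdcadhere_fit_error")
  }
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    abort(sprintf("rank-deficient model; aliased terms: %s",
                  paste(names(beta)[is.na(beta)], collapse = ", ")),
          class = "pdcadhere_fit_error")
  }
  vc <- sandwich::vcovHC(fit, type = "HC0")
  i <- "groupintervention"
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(vc[i, i])
  est <- effect_estimate(
    "RR", exp(beta[[i]]), exp(beta[[i]] - z * se), exp(beta[[i]] + z * se),
    2 * stats::pnorm(-abs(beta[[i]] / se)), method, TRUE, comparison
  )
  attr(est, "n_excluded_missing") <- n_excluded
  attr(est, "n_used") <- nrow(d)
  est
}

#' Four-level adherence transition table
#'
#' Cross-classifies every cohort member by baseline and follow-up adherence
#' into the four levels nonadherent-to-adherent, adherent-to-adherent,
#' nonadherent-to-nonadherent and adherent-to-nonadherent (the reference
#' level of the transition analysis). Per arm the four counts partition the
#' arm exactly.
#'
#' @param cohort Cohort tibble from [build_cohort()].
#' @return Tibble with columns `group`, `level`, `n`.
#' @export
transition_classify <- function(cohort) {
  lv <- ifelse(
    cohort$baseline_adherent,
    ifelse(cohort$followup_adherent, "adherent_to_adherent", "adherent_to_nonadherent"),
    ifelse(cohort$followup_adherent, "nonadherent_to_adherent", "nonadherent_to_nonadherent")
  )
  tab <- table(
    group = factor(cohort$group, levels = GROUPS),
    level = factor(lv, levels = TRANSITION_LEVELS)
  )
  out <- tibble::as_tibble(tab, n = "n")
  out$n <- as.integer(out$n)
  out
}

transition_counts <- function(tab, level, group) {
  tab$n[tab$group == group & tab$level == level]
}

#' Conditional pairwise transition risk ratio
#'
#' Among members falling in either `level` or the reference level, forms per
#' arm the conditional probability of `level` and returns their ratio
#' (intervention / control) as a Katz risk ratio. This is the pairwise
#' contrast of a multinomial outcome against its reference level.
#'
#' @param tab Transition table from [transition_classify()].
#' @param level Transition level of interest.
#' @param reference Reference level, default `"adherent_to_nonadherent"`.
#' @param conf_level Confidence level.
#' @return One-row effect-estimate tibble (method `"conditional_pairwise"`).
#' @export
transition_rr <- function(tab, level, reference = "adherent_to_nonadherent",
                          conf_level = 0.95) {
  stopifnot(level %in% TRANSITION_LEVELS, reference %in% TRANSITION_LEVELS)
  if (level == reference) stop_validation("level must differ from reference")
  a <- transition_counts(tab, level, "intervention")
  r1 <- transition_counts(tab, reference, "intervention")
  c <- transition_counts(tab, level, "control")
  r2 <- transition_counts(tab, reference, "control")
  t <- two_by_two(a, a + r1, c, c + r2)
  rr_unadjusted(t, conf_level,
                comparison = sprintf("%s_vs_%s", level, reference),
                method = "conditional_pairwise")
}

#' Covariate-adjusted conditional transition risk ratio
#'
#' Restricts the cohort to members in `level` or `reference`, then fits the
#' modified Poisson estimator of [rr_adjusted()] with membership of `level`
#' as the outcome.
#'
#' @inheritParams transition_rr
#' @param cohort Cohort tibble from [build_cohort()].
#' @param covariates Covariate names passed to [rr_adjusted()].
#' @param conf_level Confidence level.
#' @return One-row effect-estimate tibble
#'   (method `"modified_poisson_robust_conditional"`).
#' @export
transition_rr_adjusted <- function(cohort, level,
                                   reference = "adherent_to_nonadherent",
                                   covariates = character(),
                                   conf_level = 0.95) {
  stopifnot(level %in% TRANSITION_LEVELS, reference %in% TRANSITION_LEVELS)
  lv <- ifelse(
    cohort$baseline_adherent,
    ifelse(cohort$followup_adherent, "adherent_to_adherent", "adherent_to_nonadherent"),
    ifelse(cohort$followup_adherent, "nonadherent_to_adherent", "nonadherent_to_nonadherent")
  )
  sub <- cohort[lv %in% c(level, reference), ]
  sub$.level_hit <- lv[lv %in% c(level, reference)] == level
  rr_adjusted(sub, outcome = ".level_hit", covariates = covariates,
              conf_level = conf_level,
              comparison = sprintf("%s_vs_%s", level, reference),
              method = "modified_poisson_robust_conditional")
}

#' Absolute risk difference and number needed to treat
#'
#' `RD = a/n1 - c/n2` with a Wald confidence interval; `NNT = 1/RD` computed
#' from the unrounded risk difference and rounded to the nearest integer,
#' reported only when RD is positive (undefined/infinite at RD = 0, not
#' reported for negative RD).
#'
#' @param t A [two_by_two()].
#' @param conf_level Confidence level, default 0.95.
#' @param comparison Label carried into the result.
#' @return Two-row effect-estimate tibble: an `RD` row and an `NNT` row.
#' @export
risk_difference_and_nnt <- function(t, conf_level = 0.95,
                                    comparison = "intervention_vs_control") {
  stopifnot(inherits(t, "two_by_two"))
  p1 <- t$a / t$n1; p2 <- t$c / t$n2
  rd <- p1 - p2
  se <- sqrt(p1 * (1 - p1) / t$n1 + p2 * (1 - p2) / t$n2)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- if (se > 0) 2 * stats::pnorm(-abs(rd / se)) else NA_real_
  rd_row <- effect_estimate("RD", rd, rd - z * se, rd + z * se, p,
                            "wald", FALSE, comparison)
  nnt <- if (rd > 0) round(1 / rd) else NA_real_
  nnt_row <- effect_estimate("NNT", nnt, NA_real_, NA_real_, NA_real_,
                             "reciprocal_rd", FALSE, comparison)
  dplyr::bind_rows(rd_row, nnt_row)
}

#' Baseline characteristics table with group comparison tests
#'
#' Summarises each declared variable per arm and tests for a group
#' difference: pooled two-sample t test (mean/SD) for symmetric continuous
#' variables, Kruskal-Wallis (median/IQR) for asymmetric continuous
#' variables, and Pearson's chi-square without continuity correction (n/%)
#' for categorical variables.
#'
#' @param data Tibble with a `group` column and the declared variables.
#' @param specs Named character vector mapping variable name to one of
#'   `"symmetric"`, `"asymmetric"`, `"categorical"`.
#' @return Tibble with one row per variable: per-arm summary strings, the
#'   test used and the two-sided p-value.
#' @export
baseline_table <- function(data, specs) {
  stopifnot(all(names(specs) %in% names(data)),
            all(specs %in% c("symmetric", "asymmetric", "categorical")))
  g <- factor(data$group, levels = GROUPS)
  rows <- lapply(names(specs), function(v) {
    x <- data[[v]]
    type <- specs[[v]]
    xi <- x[g == "intervention"]; xc <- x[g == "control"]
    safe_p <- function(expr) tryCatch(expr, error = function(e) NA_real_)
    if (type == "symmetric") {
      p <- safe_p(stats::t.test(x ~ g, var.equal = TRUE)$p.value)
      summ <- function(z) sprintf("%.1f (%.1f)", mean(z, na.rm = TRUE),
                                  stats::sd(z, na.rm = TRUE))
      test <- "t_test"
    } else if (type == "asymmetric") {
      p <- safe_p(stats::kruskal.test(x, g)$p.value)
      summ <- function(z) {
        q <- stats::quantile(z, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
        sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
      }
      test <- "kruskal_wallis"
    } else {
      xb <- as.logical(x)
      tab <- table(g, factor(xb, levels = c(FALSE, TRUE)))
      if (any(colSums(tab) == 0L)) {
        return(tibble::tibble(variable = v, type = type,
                              intervention = NA_character_,
                              control = NA_character_,
                              test = "chi_square", p = NA_real_,
                              valid = FALSE))
      }
      p <- safe_p(stats::chisq.test(tab, correct = FALSE)$p.value)
      summ <- function(z) sprintf("%d (%.1f)", sum(z, na.rm = TRUE),
                                  100 * mean(z, na.rm = TRUE))
      xi <- as.logical(xi); xc <- as.logical(xc)
      test <- "chi_square"
    }
    tibble::tibble(variable = v, type = type, intervention = summ(xi),
                   control = summ(xc), test = test, p = p, valid = !is.na(p))
  })
  dplyr::bind_rows(rows)
}

# --- display-style rounding helpers (internal values are never rounded) ---

#' Format numbers the way epidemiology tables print them
#'
#' `format_rr()` rounds risk ratios and CI bounds to two decimals;
#' `format_rate()` gives percentages at one decimal; `format_p()` prints
#' two-decimal p-values without the leading zero (`".04"`), switching to
#' three decimals below .05 boundaries only when needed to avoid ".00".
#'
#' @param x Numeric value(s).
#' @return Character vector.
#' @export
format_rr <- function(x) sprintf("%.2f", x)

#' @rdname format_rr
#' @export
format_rate <- function(x) sprintf("%.1f", 100 * x)

#' @rdname format_rr
#' @export
format_p <- function(x) {
  out <- sprintf("%.2f", x)
  small <- !is.na(x) & x < 0.005
  out[small] <- sprintf("%.3f", x[small])
  sub("^0", "", out)
}
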