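test_that("Katz risk ratios reproduce the published adherence comparisons", {
  # follow-up antihypertensive: 447/561 vs 759/1008
  est <- rr_unadjusted(two_by_two(447L, 561L, 759L, 1008L))
  expect_equal(format_rr(est$estimate), "1.06")
  expect_equal(format_rr(est$ci_low), "1.00")
  expect_equal(format_rr(est$ci_high), "1.12")
  expect_equal(format_p(est$p), ".04")
  # follow-up antihyperlipidemic: 368/474 vs 706/913
  est2 <- rr_unadjusted(two_by_two(368L, 474L, 706L, 913L))
  expect_equal(format_rr(est2$estimate), "1.00")
  expect_equal(format_p(est2$p), ".90")
  # identical groups give exactly 1
  est3 <- rr_unadjusted(two_by_two(50L, 100L, 50L, 100L))
  expect_identical(est3$estimate, 1)
  expect_true(est3$ci_low <= 1 && est3$ci_high >= 1)
})

test_that("swapping the arms inverts the risk ratio", {
  set.seed(21)
  for (i in 1:50) {
    n1 <- sample(20:500, 1); n2 <- sample(20:500, 1)
    a <- sample(seq_len(n1), 1); c <- sample(seq_len(n2), 1)
    rr <- rr_unadjusted(two_by_two(a, n1, c, n2))$estimate
    rr_swapped <- rr_unadjusted(two_by_two(c, n2, a, n1))$estimate
    expect_equal(rr * rr_swapped, 1, tolerance = 1e-12)
  }
})

test_that("zero cells flag a non-finite interval instead of failing", {
  est <- rr_unadjusted(two_by_two(0L, 50L, 10L, 50L))
  expect_equal(est$estimate, 0)
  expect_true(is.na(est$ci_low) && is.na(est$p))
})

test_that("modified Poisson with only the group term equals the crude risk ratio", {
  dat <- expand_counts(447L, 561L, 759L, 1008L)
  adj <- rr_adjusted(dat, outcome = "outcome")
  crude <- rr_unadjusted(two_by_two(447L, 561L, 759L, 1008L))
  expect_equal(adj$estimate, crude$estimate, tolerance = 1e-8)
  expect_true(adj$adjusted)
  expect_equal(adj$method, "modified_poisson_robust")
})

test_that("modified Poisson with a homogeneous binary confounder matches Mantel-Haenszel", {
  # constructed 2x2x2 with identical stratum-specific RR (1.5), so the
  # log-additive model fits the cells exactly and must agree with the
  # closed-form MH common risk ratio
  a <- c(30L, 24L); n1 <- c(80L, 80L)
  c_ <- c(25L, 20L); n2 <- c(100L, 100L)
  dat <- expand_counts(a, n1, c_, n2, stratum = c(0, 1))
  adj <- rr_adjusted(dat, outcome = "outcome", covariates = "stratum")
  expect_equal(adj$estimate, oracle_mh_rr(a, n1, c_, n2), tolerance = 1e-6)
  expect_equal(oracle_mh_rr(a, n1, c_, n2), 1.5, tolerance = 1e-12)
})

test_that("missing covariates exclude members with a count; collinearity errors", {
  dat <- expand_counts(40L, 100L, 30L, 100L)
  dat$bmi <- rnorm(200, 30)
  dat$bmi[1:5] <- NA
  adj <- rr_adjusted(dat, outcome = "outcome", covariates = "bmi")
  expect_equal(attr(adj, "n_excluded_missing"), 5L)
  expect_equal(attr(adj, "n_used"), 195L)
  dat$bmi2 <- dat$bmi * 2
  expect_error(
    rr_adjusted(dat, outcome = "outcome", covariates = c("bmi", "bmi2")),
    class = "pdcadhere_fit_error"
  )
})

test_that("transition classification partitions each arm exactly", {
  lv <- c("adherent_to_adherent", "adherent_to_nonadherent",
          "nonadherent_to_adherent", "nonadherent_to_nonadherent",
          "adherent_to_adherent", "adherent_to_adherent",
          "nonadherent_to_adherent", "adherent_to_nonadherent")
  gr <- rep(c("intervention", "control"), each = 4)
  tab <- transition_classify(cohort_from_levels(gr, lv))
  expect_equal(sum(tab$n), 8L)
  get <- function(g, l) tab$n[tab$group == g & tab$level == l]
  expect_equal(get("intervention", "adherent_to_adherent"), 1L)
  expect_equal(get("intervention", "adherent_to_nonadherent"), 1L)
  expect_equal(get("intervention", "nonadherent_to_adherent"), 1L)
  expect_equal(get("intervention", "nonadherent_to_nonadherent"), 1L)
  expect_equal(get("control", "adherent_to_adherent"), 2L)
  expect_equal(get("control", "nonadherent_to_adherent"), 1L)
  expect_equal(get("control", "adherent_to_nonadherent"), 1L)
  expect_equal(get("control", "nonadherent_to_nonadherent"), 0L)
  # a member adherent at baseline and not at follow-up is the reference level
  one <- transition_classify(cohort_from_levels("control", "adherent_to_nonadherent"))
  expect_equal(one$n[one$level == "adherent_to_nonadherent" &
                       one$group == "control"], 1L)
  # persistently adherent cohort loads a single level
  all_aa <- transition_classify(cohort_from_levels(gr, rep("adherent_to_adherent", 8)))
  expect_equal(sum(all_aa$n[all_aa$level != "adherent_to_adherent"]), 0L)
})

test_that("conditional pairwise transition RRs reproduce the published values", {
  mk_tab <- function(int, ctl) {
    tibble::tibble(
      group = rep(c("intervention", "control"), each = 4),
      level = rep(c("nonadherent_to_adherent", "adherent_to_adherent",
                    "nonadherent_to_nonadherent", "adherent_to_nonadherent"), 2),
      n = c(int, ctl)
    )
  }
  htn <- mk_tab(c(63L, 384L, 59L, 55L), c(93L, 666L, 116L, 133L))
  est <- transition_rr(htn, "nonadherent_to_adherent")
  expect_equal(format_rr(est$estimate), "1.30")
  expect_equal(format_p(est$p), ".03")
  est2 <- transition_rr(htn, "adherent_to_adherent")
  expect_equal(format_rr(est2$estimate), "1.05")
  lipid <- mk_tab(c(45L, 323L, 57L, 49L), c(95L, 611L, 127L, 80L))
  est3 <- transition_rr(lipid, "nonadherent_to_adherent")
  expect_equal(format_rr(est3$estimate), "0.88")
  # identical conditional proportions give exactly 1
  same <- mk_tab(c(20L, 50L, 30L, 40L), c(10L, 25L, 15L, 20L))
  expect_equal(transition_rr(same, "nonadherent_to_adherent")$estimate, 1)
  expect_error(transition_rr(htn, "adherent_to_nonadherent"),
               class = "pdcadhere_validation_error")
})

test_that("adjusted conditional transition RR equals the crude one without covariates", {
  set.seed(22)
  lv <- sample(c("nonadherent_to_adherent", "adherent_to_adherent",
                 "nonadherent_to_nonadherent", "adherent_to_nonadherent"),
               400, replace = TRUE, prob = c(0.1, 0.65, 0.12, 0.13))
  gr <- sample(c("intervention", "control"), 400, replace = TRUE)
  cohort <- cohort_from_levels(gr, lv)
  tab <- transition_classify(cohort)
  crude <- transition_rr(tab, "nonadherent_to_adherent")
  adj <- transition_rr_adjusted(cohort, "nonadherent_to_adherent")
  expect_equal(adj$estimate, crude$estimate, tolerance = 1e-8)
  expect_equal(adj$method, "modified_poisson_robust_conditional")
})

test_that("risk difference and NNT reproduce the published transition benefit", {
  pair <- risk_difference_and_nnt(two_by_two(63L, 561L, 93L, 1008L))
  rd <- pair[pair$measure == "RD", ]
  nnt <- pair[pair$measure == "NNT", ]
  expect_equal(round(rd$estimate, 3), 0.020)
  expect_equal(nnt$estimate, 50)
  # follow-up adherence difference prints as 4.4%
  pair2 <- risk_difference_and_nnt(two_by_two(447L, 561L, 759L, 1008L))
  expect_equal(format_rate(pair2$estimate[pair2$measure == "RD"]), "4.4")
  # equal rates: RD 0, NNT undefined
  pair3 <- risk_difference_and_nnt(two_by_two(10L, 50L, 20L, 100L))
  expect_equal(pair3$estimate[pair3$measure == "RD"], 0)
  expect_true(is.na(pair3$estimate[pair3$measure == "NNT"]))
})

test_that("baseline table picks the declared test per variable type", {
  # identical arms: t test p is exactly 1, chi-square approximately 1
  dat <- tibble::tibble(
    group = rep(c("intervention", "control"), each = 50),
    age = rep(rnorm(50, 60, 10), 2),
    diabetes = rep(c(TRUE, FALSE), 50),
    visits = rep(rlnorm(50, log(3.3), 0.5), 2)
  )
  tab <- baseline_table(dat, c(age = "symmetric", diabetes = "categorical",
                               visits = "asymmetric"))
  expect_equal(tab$p[tab$variable == "age"], 1)
  expect_gt(tab$p[tab$variable == "diabetes"], 0.99)
  expect_equal(tab$test, c("t_test", "chi_square", "kruskal_wallis"))

  # published diabetes counts give the published p at 2-decimal rounding
  dia <- expand_counts(160L, 561L, 231L, 1008L)
  tab2 <- baseline_table(
    tibble::tibble(group = dia$group, diabetes = dia$outcome),
    c(diabetes = "categorical")
  )
  expect_equal(format_p(tab2$p), ".01")

  # chi-square statistic matches the closed form on a constructed 2x2
  counts <- expand_counts(30L, 60L, 20L, 60L)
  tab3 <- baseline_table(
    tibble::tibble(group = counts$group, flag = counts$outcome),
    c(flag = "categorical")
  )
  m <- matrix(c(30, 30, 20, 40), 2, byrow = TRUE)
  expected <- sum((m - outer(rowSums(m), colSums(m)) / sum(m))^2 /
                    (outer(rowSums(m), colSums(m)) / sum(m)))
  expect_equal(tab3$p, 1 - pchisq(expected, 1))
})

test_that("p-value display drops the leading zero like epidemiology tables", {
  expect_equal(format_p(0.0429), ".04")
  expect_equal(format_p(0.8957), ".90")
  expect_equal(format_p(0.0009), ".001")
})
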