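# Death-anchored panel construction, log transform, currency conversion,
# descriptive summaries, concentration curve and monthly trends.

toy_patients <- function() {
  data.frame(patient_id = c("A", "B"),
             death_date = c("2015-03-20", "2015-01-05"),
             stringsAsFactors = FALSE)
}

test_that("claims land in the death-anchored month bins", {
  claims <- data.frame(
    patient_id = "A",
    billing_month = c("2015-03", "2015-02", "2010-04", "2015-04", "2009-01"),
    category = "inpatient",
    amount_yen = c(10, 20, 30, 40, 50),
    stringsAsFactors = FALSE
  )
  p <- build_panel(claims, toy_patients())
  expect_equal(p$values["A", 1, "inpatient"], 10)   # death month
  expect_equal(p$values["A", 2, "inpatient"], 20)   # one month earlier
  expect_equal(p$values["A", 60, "inpatient"], 30)  # earliest month kept
  # billed after death and before the window: dropped
  expect_equal(sum(p$values["A", , "inpatient"]), 60)
  # a patient with no claims keeps a row of zeros in every category
  expect_true(all(p$values["B", , ] == 0))
})

test_that("panel equals brute-force aggregation on random claim sets", {
  for (seed in 1:8) {
    rc <- random_claims(n_pat = 4, n_claims = 40, seed = seed)
    p <- build_panel(rc$claims, rc$patients)
    arr <- brute_panel(rc$claims, rc$patients)
    expect_equal(p$values[, , eol_categories()], arr, ignore_attr = FALSE)
    # hierarchy identities hold exactly in every cell
    expect_identical(p$values[, , "medical"],
                     p$values[, , "inpatient"] + p$values[, , "outpatient"])
    expect_identical(p$values[, , "total"],
                     p$values[, , "medical"] + p$values[, , "long_term_care"])
  }
})

test_that("panel construction validates its inputs", {
  claims <- data.frame(patient_id = "Z", billing_month = "2015-01",
                       category = "inpatient", amount_yen = 5,
                       stringsAsFactors = FALSE)
  expect_error(build_panel(claims, toy_patients()), "unknown patient")
  claims2 <- claims; claims2$patient_id <- "A"; claims2$amount_yen <- -1
  expect_error(build_panel(claims2, toy_patients()), "non-negative")
  claims3 <- claims; claims3$patient_id <- "A"; claims3$category <- "dental"
  expect_error(build_panel(claims3, toy_patients()), "unknown claim categor")
})

test_that("log transform codes zeros as zero and rejects negatives", {
  claims <- data.frame(patient_id = "A",
                       billing_month = c("2015-03", "2015-02", "2015-01"),
                       category = "outpatient",
                       amount_yen = c(0, 1, 92), stringsAsFactors = FALSE)
  p <- build_panel(claims, toy_patients())
  lp <- log_transform(p)
  expect_equal(lp$values["A", 1, "outpatient"], 0)          # 0 -> 0
  expect_equal(lp$values["A", 2, "outpatient"], 0)          # ln 1 collides
  expect_equal(lp$values["A", 3, "outpatient"], log(92))    # 4.52179...
  expect_equal(lp$values["A", 3, "outpatient"], 4.5217885770490405)
  p$values[1, 1, 1] <- -5
  expect_error(log_transform(p), "negative")
})

test_that("currency conversion divides by the fixed rate", {
  expect_equal(to_usd(92), 1)
  expect_equal(to_usd(0), 0)
  expect_equal(to_usd(12498292), 135851)
  expect_error(to_usd(100, 0), "positive")
  expect_error(to_usd(100, -3), "positive")
})

test_that("summary reproduces hand-computed window statistics", {
  # single patient, constant 100/month in one category
  claims <- data.frame(patient_id = "A",
                       billing_month = sprintf("20%02d-%02d",
                                               rep(11:15, each = 12),
                                               rep(1:12, 5)),
                       category = "inpatient", amount_yen = 100,
                       stringsAsFactors = FALSE)
  pat <- data.frame(patient_id = "A", death_date = "2015-12-15",
                    stringsAsFactors = FALSE)
  # 2011-01..2015-12 is exactly the 60-month window before death (2015-12)
  p <- build_panel(claims, pat)
  st <- panel_summary(p, windows = 60)
  row <- st[st$category == "inpatient", ]
  expect_equal(row$mean, 6000)
  expect_true(is.na(row$sd) || row$sd == 0)  # single patient: sd undefined/0
  expect_equal(row$min, 6000)
  expect_equal(row$max, 6000)

  # three-patient toy panel against hand-computed values
  claims3 <- data.frame(
    patient_id = c("A", "A", "B", "C"),
    billing_month = c("2015-03", "2015-01", "2015-01", "2014-06"),
    category = c("inpatient", "ltc_home", "outpatient", "inpatient"),
    amount_yen = c(100, 50, 200, 70), stringsAsFactors = FALSE
  )
  pats3 <- data.frame(patient_id = c("A", "B", "C"),
                      death_date = c("2015-03-01", "2015-02-10", "2015-01-20"),
                      stringsAsFactors = FALSE)
  p3 <- build_panel(claims3, pats3)
  st3 <- panel_summary(p3, windows = c(60, 12))
  tot60 <- st3[st3$category == "total" & st3$window_months == 60, ]
  expect_equal(tot60$mean, mean(c(150, 200, 70)))
  expect_equal(tot60$sd, stats::sd(c(150, 200, 70)))
  expect_equal(tot60$min, 70)
  expect_equal(tot60$max, 200)
  med12 <- st3[st3$category == "medical" & st3$window_months == 12, ]
  expect_equal(med12$mean, mean(c(100, 200, 70)))
  expect_equal(st3[st3$category == "ltc_home" & st3$window_months == 60, "n_zero"], 2)

  # additivity of means and invariance to claim-row order
  expect_equal(tot60$mean,
               st3[st3$category == "medical" & st3$window_months == 60, "mean"] +
                 st3[st3$category == "long_term_care" & st3$window_months == 60, "mean"])
  p3b <- build_panel(claims3[c(3, 1, 4, 2), ], pats3)
  expect_equal(panel_summary(p3b, windows = c(60, 12)), st3)
})

test_that("pareto curve matches hand enumeration and validates input", {
  pc <- pareto_curve(c(1, 1, 1, 1))
  expect_equal(pc$curve$cumulative_share, c(0.25, 0.5, 0.75, 1))
  pc2 <- pareto_curve(c(4, 3, 2, 1), query_shares = c(0.4, 0.9))
  expect_equal(pc2$curve$cumulative_share, c(0.4, 0.7, 0.9, 1))
  expect_equal(pc2$queries$rank, c(1, 3))
  expect_equal(pc2$queries$percentile, c(25, 75))
  pc3 <- pareto_curve(c(0, 0, 10))
  expect_equal(pc3$curve$cumulative_share[1], 1)
  expect_error(pareto_curve(c(0, 0)), "all totals are zero")
  expect_error(pareto_curve(c(-1, 2)), "non-negative")
  # shares are nondecreasing and end at 1 on random inputs
  for (seed in 1:5) {
    set.seed(seed)
    x <- stats::rgamma(50, 0.5)
    sh <- pareto_curve(x)$curve$cumulative_share
    expect_true(all(diff(sh) >= -1e-12))
    expect_equal(sh[length(sh)], 1)
  }
})

test_that("monthly trends equal per-group hand means and flag empty groups", {
  claims <- data.frame(
    patient_id = c("A", "B"), billing_month = c("2015-03", "2015-01"),
    category = "inpatient", amount_yen = c(300, 100),
    stringsAsFactors = FALSE
  )
  p <- build_panel(claims, toy_patients())
  # single group: trend equals the overall monthly mean
  tr1 <- monthly_trend(p, c(1, 1))
  inp <- tr1[tr1$category == "inpatient", ]
  expect_equal(inp$mean[1], 200)   # month 1: (300 + 100)/2
  expect_equal(sum(inp$mean), 200) # total mass / 2 patients
  # two groups: per-group means
  tr2 <- monthly_trend(p, stats::setNames(c(1, 2), c("A", "B")))
  expect_equal(tr2[tr2$category == "inpatient" & tr2$group == "1", "mean"][1], 300)
  expect_equal(tr2[tr2$category == "inpatient" & tr2$group == "2", "mean"][1], 100)
  # empty level flagged
  tr3 <- monthly_trend(p, factor(c("g1", "g1"), levels = c("g1", "g2")))
  expect_equal(attr(tr3, "empty_groups"), "g2")
})

test_that("trend curves from the calibrated cohort behave like the study pattern", {
  co <- generate_cohort(default_calibration("total", n_patients = 800, seed = 21))
  p <- build_panel(co$claims, co$patients)
  tr <- monthly_trend(p, stats::setNames(co$truth$true_group,
                                         co$truth$patient_id))
  # inpatient spending rises toward death for the rising groups; LTC does not
  # explode near death
  g6_in <- tr[tr$category == "inpatient" & tr$group == "6", ]
  expect_gt(mean(g6_in$mean[g6_in$month_index <= 6]),
            mean(g6_in$mean[g6_in$month_index >= 54]))
  ltc <- tr[tr$category == "long_term_care" & tr$group == "1", ]
  expect_lt(max(ltc$mean[ltc$month_index <= 4]) /
              stats::median(ltc$mean), 3)
})
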