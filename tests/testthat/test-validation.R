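test_that("published 2x2s yield the published metrics, kappa and prevalence", {
  for (id in names(paper_tables)) {
    p <- paper_tables[[id]]; e <- paper_expected[[id]]
    m <- contingency_matrix(p$cells[1], p$cells[2], p$cells[3], p$cells[4],
                            p$no_answer, id)
    expect_equal(unname(fmt_metric(diagnostic_metrics(m))), e$metrics, info = id)
    expect_equal(round(cohens_kappa(m), 3), e$kappa, info = id)
    if (!is.null(e$prev_survey))
      expect_equal(unname(prevalence_per_1000(m$tp + m$fp, m$n_total)),
                   e$prev_survey, info = id)
  }
})

test_that("five statistics agree with the brute-force oracle on small grids", {
  # exhaustive 2x2s with cells <= 6 (skipping the empty table)
  for (tp in 0:6) for (fp in 0:6) for (fn in 0:6) for (tn in 0:6) {
    if (tp + fp + fn + tn == 0) next
    m <- contingency_matrix(tp, fp, fn, tn)
    got <- suppressWarnings(diagnostic_metrics(m))
    k <- suppressWarnings(cohens_kappa(m))
    o <- oracle_stats(tp, fp, fn, tn)
    for (nm in c("sensitivity", "specificity", "ppv", "npv")) {
      if (is.finite(o[[nm]]))
        expect_equal(unname(got[nm]), o[[nm]], tolerance = 1e-12,
                     ignore_attr = TRUE)
      else expect_true(is.na(got[[nm]]))
    }
    if (!is.na(o$kappa) && is.finite(o$kappa))
      expect_equal(k, o$kappa, tolerance = 1e-12)
  }
})

test_that("kappa endpoints, hand-worked value, and degenerate cases", {
  expect_equal(cohens_kappa(contingency_matrix(2, 1, 1, 2)), 1 / 3,
               tolerance = 1e-12)  # po = 4/6, pe = 1/2
  expect_equal(cohens_kappa(contingency_matrix(5, 0, 0, 7)), 1)
  expect_equal(cohens_kappa(contingency_matrix(0, 3, 3, 0)), -1)
  expect_warning(k <- cohens_kappa(contingency_matrix(4, 0, 0, 0)),
                 "undefined")
  expect_true(is.na(k))
  expect_error(cohens_kappa(contingency_matrix(0, 0, 0, 0)), "no valid")
})

test_that("kappa and metric symmetries hold under axis swap", {
  set.seed(99)
  for (i in 1:25) {
    cells <- stats::rpois(4, lambda = sample(c(3, 20, 200), 1)) + c(1, 0, 0, 1)
    m <- contingency_matrix(cells[1], cells[2], cells[3], cells[4])
    # swapping survey and clinical axes transposes the table: fp <-> fn
    mt <- contingency_matrix(cells[1], cells[3], cells[2], cells[4])
    expect_equal(cohens_kappa(m), cohens_kappa(mt), tolerance = 1e-12)
    a <- suppressWarnings(diagnostic_metrics(m))
    b <- suppressWarnings(diagnostic_metrics(mt))
    expect_equal(a[["sensitivity"]], b[["ppv"]], tolerance = 1e-12)
    expect_equal(a[["specificity"]], b[["npv"]], tolerance = 1e-12)
    expect_true(abs(cohens_kappa(m)) <= 1 + 1e-12)
  }
})

test_that("metrics with zero denominators are NA-flagged, not zeroed", {
  m <- contingency_matrix(0, 0, 0, 5)
  expect_warning(got <- diagnostic_metrics(m), "sensitivity.*ppv|ppv")
  expect_true(is.na(got[["sensitivity"]]))
  expect_true(is.na(got[["ppv"]]))
  expect_equal(got[["specificity"]], 100)
  expect_setequal(attr(got, "undefined"), c("sensitivity", "ppv"))
  # perfect agreement limit
  perfect <- suppressWarnings(diagnostic_metrics(contingency_matrix(9, 0, 0, 91)))
  expect_equal(unname(perfect), rep(100, 4))
})

test_that("metric formatting trims trailing zeros at 2 decimals", {
  expect_equal(fmt_metric(c(97.0041, 50, 66.955, 99.625)),
               c("97", "50", "66.96", "99.63"))
  expect_equal(fmt_metric(NA_real_), NA_character_)
})

test_that("Wald intervals are symmetric pre-rounding and shrink with n", {
  widths <- sapply(c(500, 5000, 50000), function(n) {
    ci <- prevalence_per_1000(round(0.1 * n), n)
    ci[["upper"]] - ci[["lower"]]
  })
  expect_true(all(diff(widths) <= 0))
  expect_equal(unname(prevalence_per_1000(0, 100)), c(0, 0, 0))
  # symmetry about p up to integer rounding of the bounds
  ci <- prevalence_per_1000(396, 11323)
  expect_lte(abs((ci[["upper"]] + ci[["lower"]]) / 2 - 1000 * 396 / 11323), 1)
  expect_error(prevalence_per_1000(5, 0), "denominator")
  expect_error(prevalence_per_1000(11, 10), "case_count")
  # wilson stays inside [0, 1000] and covers the point
  w <- prevalence_per_1000(1, 50, method = "wilson")
  expect_true(w[["lower"]] >= 0 && w[["upper"]] <= 1000)
  expect_true(w[["lower"]] <= w[["point"]] && w[["point"]] <= w[["upper"]])
})

test_that("non-response rates reproduce published percentages", {
  expect_equal(non_response_rate(560, 11323), 4.95)
  expect_equal(non_response_rate(464, 11323), 4.10)
  expect_equal(non_response_rate(631, 11323), 5.57)
  expect_equal(non_response_rate(0, 10), 0)
  expect_error(non_response_rate(1, 0), "positive")
})

test_that("build_contingency places persons by answer and case status", {
  alfs <- sprintf("p%d", 1:6)
  survey <- tiny_survey(alfs, "asthma",
                        c("yes", "yes", "no", "no", "no_answer", "no_answer"))
  tags <- data.frame(alf = alfs, condition_id = "asthma",
                     is_case = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
                     stringsAsFactors = FALSE)
  m <- build_contingency(survey, tags, "asthma")
  expect_equal(c(m$tp, m$fp, m$fn, m$tn, m$no_answer), c(1, 1, 1, 1, 2))
  expect_equal(m$n_valid, 4)
  expect_equal(m$n_total, 6)
  # all-no-answer corner
  m2 <- build_contingency(tiny_survey(alfs, "asthma", rep("no_answer", 6)),
                          tags, "asthma")
  expect_equal(c(m2$tp, m2$fp, m2$fn, m2$tn), c(0, 0, 0, 0))
  expect_equal(m2$no_answer, 6)
  # integrity: tag without survey row
  expect_error(build_contingency(survey[-1, ], tags, "asthma"),
               "integrity error")
})

test_that("validate_condition assembles policies correctly", {
  p <- paper_tables$angina
  m <- contingency_matrix(p$cells[1], p$cells[2], p$cells[3], p$cells[4],
                          p$no_answer, "angina")
  r <- validate_condition(m, n_clinical_total = 124)
  expect_equal(unname(r$prevalence_survey), c(35, 32, 38))
  expect_equal(round(r$kappa, 3), 0.290)
  expect_equal(r$non_response_pct, 4.95)
  # contingency policy: numerator tp + fn = 115
  expect_equal(r$prevalence_clinical[["point"]],
               unname(prevalence_per_1000(115, 11323)[["point"]]))
  r2 <- validate_condition(m, n_clinical_total = 124,
                           clinical_numerator_policy = "all_identified")
  expect_equal(r2$prevalence_clinical[["point"]], 11)  # 124 / 11,323
  r3 <- validate_condition(m, prevalence_denominator_policy = "valid_only")
  expect_equal(r3$prevalence_survey[["point"]],
               unname(prevalence_per_1000(396, m$n_valid)[["point"]]))
  expect_error(validate_condition(m, clinical_numerator_policy =
                                    "all_identified"), "n_clinical_total")
  # perfect agreement end-to-end
  rp <- validate_condition(contingency_matrix(10, 0, 0, 90, 0, "x"))
  expect_equal(rp$kappa, 1)
  expect_equal(unname(rp$metrics), rep(100, 4))
})
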