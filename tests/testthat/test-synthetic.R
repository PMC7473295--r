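test_that("generation is reproducible and schema-complete", {
  cfg <- cohort_config(n_persons = 500, seed = 11,
                       conditions = list(asthma = condition_sim()))
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a[c("persons", "survey", "gp_events", "hospital_episodes",
                       "truth")],
                   b[c("persons", "survey", "gp_events", "hospital_episodes",
                       "truth")])
  expect_equal(nrow(a$persons), 500)
  expect_false(anyDuplicated(a$persons$alf) > 0)
  expect_true(all(a$survey$alf %in% a$persons$alf))
  expect_true(all(a$survey$answer %in% c("yes", "no", "no_answer")))
  # GP events only for covered persons, and date floors respected
  covered <- a$persons$alf[a$persons$gp_covered]
  expect_true(all(a$gp_events$alf %in% covered))
  expect_true(all(a$gp_events$event_date >= as.Date("2010-01-01")))
  expect_true(all(a$hospital_episodes$admission_date >= as.Date("2002-01-01")))
  expect_true(all(a$persons$interview_date >= as.Date("2013-04-01") &
                  a$persons$interview_date <= as.Date("2014-12-31")))
  # a different seed actually changes the draw
  expect_false(identical(
    a$truth, generate_cohort(cohort_config(n_persons = 500, seed = 12))$truth))
})

test_that("the error-free limit produces a diagonal contingency", {
  cfg <- cohort_config(
    n_persons = 800, seed = 3, gp_coverage = 1,
    conditions = list(asthma = condition_sim(
      true_prevalence = 0.2, survey_sensitivity = 1, survey_specificity = 1,
      non_response_rate = 0, p_record_gp = 1, p_record_hospital = 1,
      p_in_window = 1)))
  co <- generate_cohort(cfg)
  pf <- build_platform(co)
  m <- build_contingency(pf$survey, ascertain(pf, demo_asthma()), "asthma")
  expect_equal(m$fp, 0)
  expect_equal(m$fn, 0)
  expect_equal(m$no_answer, 0)
  expect_equal(m$tp, sum(co$truth$true_case))
})

test_that("configured misreport rates are recovered within binomial error", {
  sens <- 0.6886; spec <- 0.965
  cfg <- cohort_config(
    n_persons = 20000, seed = 5,
    conditions = list(asthma = condition_sim(
      true_prevalence = 0.105, survey_sensitivity = sens,
      survey_specificity = spec, non_response_rate = 0.05)))
  co <- generate_cohort(cfg)
  d <- merge(co$survey, co$truth, by = c("alf", "condition_id"))
  d <- d[d$answer != "no_answer", ]
  s_hat <- mean(d$answer[d$true_case] == "yes")
  p_hat <- mean(d$answer[!d$true_case] == "no")
  n1 <- sum(d$true_case); n0 <- sum(!d$true_case)
  expect_lt(abs(s_hat - sens), 3 * sqrt(sens * (1 - sens) / n1))
  expect_lt(abs(p_hat - spec), 3 * sqrt(spec * (1 - spec) / n0))
})

test_that("generation fails on conditions without a code set", {
  cfg <- cohort_config(n_persons = 10, seed = 1,
                       conditions = list(gout = condition_sim()))
  expect_error(generate_cohort(cfg), "no code set for condition 'gout'")
})

test_that("planted contingencies reproduce exactly through the pipeline", {
  cs <- demo_code_sets()
  for (id in names(paper_tables)) {
    p <- paper_tables[[id]]
    co <- plant_paper(id, seed = 9, code_sets = cs)
    expect_equal(nrow(co$persons), sum(p$cells) + p$no_answer)
    expect_true(all(table(co$survey$alf) == 1))  # conservation, one row each
    pf <- build_platform(co)
    m <- build_contingency(pf$survey, ascertain(pf, cs$sets[[id]]), id)
    expect_equal(c(m$tp, m$fp, m$fn, m$tn, m$no_answer),
                 c(p$cells, p$no_answer), info = id)
  }
})

test_that("planted mode handles the degenerate and deterministic cases", {
  cs <- demo_asthma()
  co <- plant_contingency(0, 0, 0, 0, 0, cs, seed = 1)
  expect_equal(nrow(co$persons), 0)
  expect_equal(nrow(co$gp_events), 0)
  a <- plant_contingency(5, 2, 3, 40, 4, cs, seed = 21, no_answer_cases = 2)
  b <- plant_contingency(5, 2, 3, 40, 4, cs, seed = 21, no_answer_cases = 2)
  expect_identical(a[names(a) != "config"], b[names(b) != "config"])
  expect_error(plant_contingency(1, 1, 1, 1, 0, cs, no_answer_cases = 1),
               "no_answer_cases")
  expect_error(plant_contingency(2, 0, 0, 0, 0, cs,
                                 source_counts = c(gp_only = 1,
                                                   hospital_only = 0, both = 0)),
               "sum to")
})

test_that("planted windows are disciplined: decoys never flip status", {
  cs <- demo_asthma()  # CURRENT_12M
  co <- plant_contingency(30, 10, 20, 200, 15, cs, seed = 13,
                          no_answer_cases = 5, decoy_rate = 0.8)
  pf <- build_platform(co)
  tags <- ascertain(pf, cs)
  truth <- co$truth[match(tags$alf, co$truth$alf), ]
  expect_equal(tags$is_case, truth$true_case)
  # positives: >=1 matching record inside the closed 12-month window
  for (i in which(truth$true_case)) {
    alf <- tags$alf[i]
    expect_true(tags$via_gp[i] || tags$via_hospital[i])
    expect_false(is.na(tags$first_event_date[i]))
    iv <- pf$persons$interview_date[pf$persons$alf == alf]
    expect_true(tags$first_event_date[i] >= subtract_months(iv, 12) &&
                tags$first_event_date[i] <= iv)
  }
})

test_that("cohorts round-trip through the four-CSV layout", {
  co <- plant_contingency(4, 2, 1, 30, 3, demo_asthma(), seed = 2)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(
    dir, c("persons.csv", "survey.csv", "gp_events.csv",
           "hospital_episodes.csv", "truth.csv")))))
  back <- read_cohort(dir)
  expect_equal(back$persons, co$persons)
  expect_equal(back$survey, co$survey)
  expect_equal(back$gp_events, co$gp_events)
  expect_equal(back$hospital_episodes, co$hospital_episodes)
})

test_that("probability parameters are validated", {
  expect_error(condition_sim(true_prevalence = 1.2), "\\[0, 1\\]")
  expect_error(condition_sim(survey_sensitivity = -0.1), "\\[0, 1\\]")
  expect_error(cohort_config(n_persons = 0), "n_persons")
})
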