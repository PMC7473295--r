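test_that("calendar-month subtraction clamps at month end", {
  expect_equal(subtract_months(as.Date("2014-03-31"), 12), as.Date("2013-03-31"))
  expect_equal(subtract_months(as.Date("2014-03-31"), 1), as.Date("2014-02-28"))
  expect_equal(subtract_months(as.Date("2016-03-31"), 1), as.Date("2016-02-29"))
  expect_equal(subtract_months(as.Date("2014-01-15"), 12), as.Date("2013-01-15"))
  expect_equal(subtract_months(as.Date("2013-01-10"), 13), as.Date("2011-12-10"))
})

make_pf <- function(gp = empty_gp(), hosp = empty_hospital(),
                    interview = as.Date("2014-06-15"), answers = "yes",
                    alfs = "p1", gp_covered = TRUE) {
  build_platform(tiny_persons(alfs, interview, gp_covered),
                 tiny_survey(alfs, "asthma", answers), gp, hosp)
}

gp_row <- function(alf, date, code) data.frame(
  alf = alf, event_date = as.Date(date), read_code = code,
  stringsAsFactors = FALSE)

hosp_row <- function(alf, date, codes) data.frame(
  alf = alf, admission_date = as.Date(date), icd10_codes = codes,
  stringsAsFactors = FALSE)

test_that("single in-window GP medication event makes a case via GP only", {
  pf <- make_pf(gp = gp_row("p1", "2013-12-15", "c111."))  # 6 months before
  t <- ascertain(pf, demo_asthma())
  expect_true(t$is_case)
  expect_true(t$via_gp)
  expect_false(t$via_hospital)
  expect_equal(t$first_event_date, as.Date("2013-12-15"))
})

test_that("the 12-month window is closed and calendar-exact", {
  cs <- demo_asthma()
  # 13 months before interview: outside CURRENT_12M
  t <- ascertain(make_pf(gp = gp_row("p1", "2013-05-14", "H33..")), cs)
  expect_false(t$is_case)
  expect_true(is.na(t$first_event_date))
  # boundary day (exactly 12 months before) and interview day both count
  for (d in c("2013-06-15", "2014-06-15")) {
    t <- ascertain(make_pf(gp = gp_row("p1", d, "H33..")), cs)
    expect_true(t$is_case, info = d)
  }
  # one day before the boundary does not
  t <- ascertain(make_pf(gp = gp_row("p1", "2013-06-14", "H33..")), cs)
  expect_false(t$is_case)
})

test_that("EVER windows reach back to the source data start", {
  cs_ha <- demo_code_sets()$sets$heart_attack
  pf <- build_platform(tiny_persons("p1"),
                       tiny_survey("p1", "heart_attack", "yes"),
                       empty_gp(), hosp_row("p1", "2003-07-01", "I21.9"))
  t <- ascertain(pf, cs_ha)
  expect_true(t$is_case)
  expect_true(t$via_hospital)
  # but not before the hospital lookback floor
  pf2 <- build_platform(tiny_persons("p1"),
                        tiny_survey("p1", "heart_attack", "yes"),
                        empty_gp(), hosp_row("p1", "2001-12-31", "I21.9"))
  expect_false(ascertain(pf2, cs_ha)$is_case)
})

test_that("all ICD-10 positions in an episode are eligible, prefix dialect", {
  cs <- demo_asthma()
  pf <- make_pf(hosp = hosp_row("p1", "2014-01-01", "Z380;J45.9"))
  expect_true(ascertain(pf, cs)$via_hospital)
  # category-level J45 matches subdivision only in prefix mode
  pf2 <- make_pf(hosp = hosp_row("p1", "2014-01-01", "J459"))
  expect_true(ascertain(pf2, cs, icd_prefix_matching = TRUE)$is_case)
  expect_false(ascertain(pf2, cs, icd_prefix_matching = FALSE)$is_case)
})

test_that("min_gp_events enables the stricter case definition", {
  gp2 <- rbind(gp_row("p1", "2014-01-10", "H33.."),
               gp_row("p1", "2014-02-10", "H33.."))
  pf1 <- make_pf(gp = gp2[1, ])
  pf2 <- make_pf(gp = gp2)
  expect_false(ascertain(pf1, demo_asthma(), min_gp_events = 2)$is_case)
  expect_true(ascertain(pf2, demo_asthma(), min_gp_events = 2)$is_case)
  # one hospitalisation still suffices under the stricter definition
  pfh <- make_pf(hosp = hosp_row("p1", "2014-01-01", "J45"))
  expect_true(ascertain(pfh, demo_asthma(), min_gp_events = 2)$is_case)
})

test_that("malformed record codes are counted, never matched", {
  gp <- rbind(gp_row("p1", "2014-01-10", ""), gp_row("p1", "2014-02-10", NA))
  pf <- make_pf(gp = gp)
  expect_warning(t <- ascertain(pf, demo_asthma()), "2 malformed")
  expect_false(t$is_case)
})

test_that("monotonicity: adding records never untags a case", {
  set.seed(31)
  cs <- demo_asthma()
  co <- plant_contingency(25, 10, 15, 150, 10, cs, seed = 31,
                          no_answer_cases = 3, decoy_rate = 0.5)
  pf <- build_platform(co)
  before <- ascertain(pf, cs)
  extra_alfs <- sample(pf$persons$alf, 40)
  iv <- pf$persons$interview_date[match(extra_alfs, pf$persons$alf)]
  pf$gp_events <- rbind(pf$gp_events,
                        gp_row(extra_alfs, iv - 30, "H33.."))
  pf$persons$gp_covered[pf$persons$alf %in% extra_alfs] <- TRUE
  after <- ascertain(pf, cs)
  expect_true(all(after$is_case[before$is_case]))
})

test_that("window nesting: every CURRENT_12M case is an EVER case", {
  cs <- demo_asthma()
  cs_ever <- condition_code_set("asthma", cs$diagnosis_codes, cs$event_codes,
                                cs$medication_codes, window = "EVER")
  for (seed in 1:3) {
    cfg <- cohort_config(n_persons = 400, seed = seed,
                         conditions = list(asthma = condition_sim(
                           true_prevalence = 0.2, p_in_window = 0.6)))
    pf <- build_platform(generate_cohort(cfg))
    cur <- ascertain(pf, cs)
    ever <- ascertain(pf, cs_ever)
    expect_true(all(ever$is_case[cur$is_case]), info = seed)
  }
})

test_that("removing medication codes can only shrink the case set", {
  cs <- demo_asthma()
  cs_nomed <- condition_code_set("asthma", cs$diagnosis_codes, cs$event_codes,
                                 character(), window = cs$window)
  for (seed in 4:6) {
    cfg <- cohort_config(n_persons = 400, seed = seed,
                         conditions = list(asthma = condition_sim(
                           true_prevalence = 0.25)))
    pf <- build_platform(generate_cohort(cfg))
    with_med <- ascertain(pf, cs)
    without <- ascertain(pf, cs_nomed)
    expect_true(all(with_med$is_case[without$is_case]), info = seed)
    expect_lte(sum(without$is_case), sum(with_med$is_case))
  }
})

test_that("attribute_sources partitions cases and matches the planted split", {
  cs <- demo_code_sets()
  for (id in c("angina", "asthma")) {
    p <- paper_tables[[id]]
    pf <- build_platform(plant_paper(id, seed = 17, code_sets = cs))
    tags <- ascertain(pf, cs$sets[[id]])
    at <- attribute_sources(tags, id)
    expect_equal(at$gp_only + at$hospital_only + at$both, at$total)
    expect_equal(at$total, sum(tags$is_case))
    expect_equal(c(at$gp_only, at$hospital_only, at$both),
                 unname(p$sources), info = id)
  }
  # degenerate: zero cases
  at0 <- attribute_sources(
    data.frame(alf = "p1", condition_id = "x", is_case = FALSE,
               via_gp = FALSE, via_hospital = FALSE), "x")
  expect_equal(at0$total, 0)
  expect_equal(unname(at0$percentages), c(0, 0, 0))
})

test_that("coverage undercount follows the floor rule", {
  expect_equal(coverage_undercount(1079, 0.8), 269L)
  expect_equal(coverage_undercount(32, 0.8), 8L)   # 32 * 0.25 exactly
  expect_equal(coverage_undercount(21, 0.8), 5L)
  expect_equal(coverage_undercount(500, 1.0), 0L)
  expect_equal(coverage_undercount(0, 0.5), 0L)
  expect_error(coverage_undercount(10, 0), "coverage")
  expect_error(coverage_undercount(10, -0.2), "coverage")
})
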