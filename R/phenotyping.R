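# Case ascertainment from coded records, source attribution, and the
# partial-GP-coverage undercount estimator.

#' Ascertain clinical case status for one condition
#'
#' Tags every person in the platform as a clinical case or not. A person is a
#' case via the GP route when at least `min_gp_events` GP events carry a Read
#' code from the condition's event or medication lists and fall inside the
#' ascertainment window; via the hospital route when at least one episode
#' carries a matching ICD-10 code (any diagnostic position) in the window.
#' The window is the closed interval from the source's data start to the
#' interview date for `EVER` conditions, and the closed 12 calendar months
#' before interview (interview-day events count) for `CURRENT_12M`.
#'
#' @param platform a `platform_record_set` from [build_platform()].
#' @param code_set a [condition_code_set()].
#' @param icd_prefix_matching ICD-10 prefix mode, see [code_matches()].
#' @param min_gp_events qualifying GP events required (default 1, matching a
#'   single-record case definition; set 2 for the stricter
#'   two-GP-visits-or-one-hospitalisation definition).
#' @param gp_data_start,hospital_data_start lower bounds of each source's
#'   lookback (defaults 2010-01-01 and 2002-01-01).
#' @return data.frame of case tags, one row per person: `alf`, `condition_id`,
#'   `is_case`, `via_gp`, `via_hospital`, `first_event_date` (`NA` for
#'   non-cases).
#' @export
ascertain <- function(platform, code_set, icd_prefix_matching = TRUE,
                      min_gp_events = 1,
                      gp_data_start = "2010-01-01",
                      hospital_data_start = "2002-01-01") {
  stopifnot(inherits(platform, "platform_record_set"),
            inherits(code_set, "condition_code_set"), min_gp_events >= 1)
  if (length(all_codes_of(code_set)) == 0) stop("empty code set")
  persons <- platform$persons

  gp <- platform$gp_events
  malformed <- 0L
  gp_hits <- data.frame(alf = character(), date = as.Date(character()))
  if (nrow(gp)) {
    bad <- is.na(gp$read_code) | !nzchar(trimws(gp$read_code))
    malformed <- malformed + sum(bad)
    gp <- gp[!bad, , drop = FALSE]
    interview <- persons$interview_date[match(gp$alf, persons$alf)]
    lower <- window_lower(interview, code_set$window, gp_data_start)
    hit <- read_match_any(gp$read_code,
                          c(code_set$event_codes, code_set$medication_codes)) &
      !is.na(interview) & gp$event_date >= lower & gp$event_date <= interview
    gp_hits <- data.frame(alf = gp$alf[hit], date = gp$event_date[hit])
  }

  hosp <- platform$hospital_episodes
  hosp_hits <- data.frame(alf = character(), date = as.Date(character()))
  if (nrow(hosp)) {
    bad <- is.na(hosp$icd10_codes) | !nzchar(trimws(hosp$icd10_codes))
    malformed <- malformed + sum(bad)
    hosp <- hosp[!bad, , drop = FALSE]
    # episodes carry an ordered ";"-separated code list; all positions eligible
    codes <- strsplit(hosp$icd10_codes, ";", fixed = TRUE)
    lens <- lengths(codes)
    flat <- data.frame(alf = rep(hosp$alf, lens),
                       date = rep(hosp$admission_date, lens),
                       code = unlist(codes), stringsAsFactors = FALSE)
    interview <- persons$interview_date[match(flat$alf, persons$alf)]
    lower <- window_lower(interview, code_set$window, hospital_data_start)
    hit <- icd_match_any(flat$code, code_set$diagnosis_codes,
                         icd_prefix_matching) &
      !is.na(interview) & flat$date >= lower & flat$date <= interview
    hosp_hits <- data.frame(alf = flat$alf[hit], date = flat$date[hit])
  }
  if (malformed)
    warning(malformed, " malformed record code(s) ignored during ascertainment",
            call. = FALSE)

  gp_n <- table(gp_hits$alf)
  via_gp <- persons$alf %in% names(gp_n)[gp_n >= min_gp_events]
  via_hospital <- persons$alf %in% hosp_hits$alf

  qual <- rbind(if (min_gp_events <= 1) gp_hits else
    gp_hits[gp_hits$alf %in% names(gp_n)[gp_n >= min_gp_events], , drop = FALSE],
    hosp_hits)
  first <- if (nrow(qual))
    tapply(qual$date, qual$alf, min) else NULL
  first_event_date <- as.Date(rep(NA, nrow(persons)))
  if (!is.null(first)) {
    i <- match(persons$alf, names(first))
    first_event_date[!is.na(i)] <- as.Date(first[i[!is.na(i)]],
                                           origin = "1970-01-01")
  }
  is_case <- via_gp | via_hospital
  first_event_date[!is_case] <- as.Date(NA)

  data.frame(alf = persons$alf, condition_id = code_set$condition_id,
             is_case = is_case, via_gp = via_gp, via_hospital = via_hospital,
             first_event_date = first_event_date, stringsAsFactors = FALSE)
}

#' Attribute ascertained cases to their data source
#'
#' Partitions a condition's clinical cases into GP-only, hospital-only, and
#' both-source counts with whole-number percentage shares of the clinical
#' total.
#'
#' @param tags case-tag data.frame from [ascertain()] (may hold several
#'   conditions).
#' @param condition_id condition to summarise.
#' @return a `source_attribution` list: `gp_only`, `hospital_only`, `both`,
#'   `total`, and `percentages` (rounded to integers; 0 when there are no
#'   cases).
#' @export
attribute_sources <- function(tags, condition_id) {
  t <- tags[tags$condition_id == condition_id & tags$is_case, , drop = FALSE]
  gp_only <- sum(t$via_gp & !t$via_hospital)
  hospital_only <- sum(!t$via_gp & t$via_hospital)
  both <- sum(t$via_gp & t$via_hospital)
  total <- nrow(t)
  pct <- if (total > 0)
    round_half_up(100 * c(gp_only, hospital_only, both) / total) else c(0, 0, 0)
  structure(list(condition_id = condition_id, gp_only = gp_only,
                 hospital_only = hospital_only, both = both, total = total,
                 percentages = stats::setNames(pct, c("gp_only",
                                                      "hospital_only", "both"))),
            class = "source_attribution")
}

#' @export
print.source_attribution <- function(x, ...) {
  cat(sprintf("Source attribution for '%s' (total %d clinical cases)\n",
              x$condition_id, x$total))
  cat(sprintf("  GP records only     %6d  (%d%%)\n", x$gp_only,
              x$percentages["gp_only"]))
  cat(sprintf("  Hospital only       %6d  (%d%%)\n", x$hospital_only,
              x$percentages["hospital_only"]))
  cat(sprintf("  Both sources        %6d  (%d%%)\n", x$both,
              x$percentages["both"]))
  invisible(x)
}

#' Estimate cases missed through partial GP-practice coverage
#'
#' When only a fraction of GP practices contribute data, cases ascertainable
#' solely from GP records are undercounted. Assuming missing practices would
#' have contributed GP-only cases at the same rate, the additional cases had
#' all practices contributed is `floor(gp_only_count * (1/coverage - 1))` —
#' e.g. 1,079 GP-only cases at 80% coverage imply 269 more.
#'
#' @param gp_only_count cases ascertained from GP records only.
#' @param coverage fraction of practices contributing, in (0, 1].
#' @return estimated additional case count (integer, floor-rounded).
#' @examples
#' coverage_undercount(1079, 0.8)  # 269
#' @export
coverage_undercount <- function(gp_only_count, coverage) {
  if (!is.numeric(coverage) || coverage <= 0 || coverage > 1)
    stop("coverage must lie in (0, 1]")
  stopifnot(gp_only_count >= 0)
  # epsilon guards the floor against 1/coverage rounding a hair low in floats
  as.integer(floor(gp_only_count * (1 / coverage - 1) + 1e-9))
}
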