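# Platform-file construction: one linked record set joining every survey
# respondent to their (possibly empty) GP and hospital event streams.

required_cols <- list(
  persons = c("alf", "gender", "age_group", "interview_date", "gp_covered",
              "match_quality"),
  survey = c("alf", "condition_id", "answer"),
  gp_events = c("alf", "event_date", "read_code"),
  hospital_episodes = c("alf", "admission_date", "icd10_codes"))

check_schema <- function(df, what) {
  miss <- setdiff(required_cols[[what]], names(df))
  if (length(miss))
    stop(what, " table is missing column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}

#' Build the linked platform record set
#'
#' Joins survey responses to clinical event streams per person, retaining
#' every linked survey respondent — including those with zero clinical
#' records. Survey respondents lacking a linkage identifier (missing/empty
#' `alf`) are removed when `drop_unmatched` (they cannot be validated), and
#' clinical records whose `alf` is absent from the person table are discarded
#' with a warning. Fuzzy linkage matches are retained by default to maximise
#' the sample; `drop_fuzzy` supports a sensitivity analysis excluding them.
#'
#' @param persons,survey,gp_events,hospital_episodes input tables (see
#'   [generate_cohort()] for schemas), or a `linked_cohort` passed as
#'   `persons` with the rest `NULL`.
#' @param drop_unmatched drop person/survey rows with missing `alf`.
#' @param drop_fuzzy drop persons whose `match_quality` is `"fuzzy"`.
#' @return a `platform_record_set`: the four tables restricted to retained
#'   persons plus a `manifest` (row counts, discard counts).
#' @export
build_platform <- function(persons, survey = NULL, gp_events = NULL,
                           hospital_episodes = NULL, drop_unmatched = TRUE,
                           drop_fuzzy = FALSE) {
  if (inherits(persons, "linked_cohort")) {
    cohort <- persons
    persons <- cohort$persons; survey <- cohort$survey
    gp_events <- cohort$gp_events; hospital_episodes <- cohort$hospital_episodes
  } else if (inherits(persons, "platform_record_set")) {
    p <- persons
    persons <- p$persons; survey <- p$survey
    gp_events <- p$gp_events; hospital_episodes <- p$hospital_episodes
  }
  check_schema(persons, "persons"); check_schema(survey, "survey")
  check_schema(gp_events, "gp_events")
  check_schema(hospital_episodes, "hospital_episodes")

  n_in <- nrow(persons)
  unmatched <- is.na(persons$alf) | !nzchar(as.character(persons$alf))
  if (drop_unmatched && any(unmatched)) persons <- persons[!unmatched, , drop = FALSE]
  n_unmatched <- if (drop_unmatched) sum(unmatched) else 0L
  n_fuzzy_dropped <- 0L
  if (drop_fuzzy) {
    fuzzy <- persons$match_quality == "fuzzy"
    n_fuzzy_dropped <- sum(fuzzy)
    persons <- persons[!fuzzy, , drop = FALSE]
  }
  if (anyDuplicated(persons$alf))
    stop("integrity error: duplicate alf in persons table: ",
         paste(utils::head(unique(persons$alf[duplicated(persons$alf)]), 5),
               collapse = ", "))

  dup <- duplicated(survey[, c("alf", "condition_id")])
  if (any(dup))
    stop("integrity error: duplicate (alf, condition_id) survey rows: ",
         paste(utils::head(paste(survey$alf[dup], survey$condition_id[dup],
                                 sep = "/"), 5), collapse = ", "))

  keep_alf <- persons$alf
  drop_tab <- function(df, what) {
    orphan <- !df$alf %in% keep_alf
    if (any(orphan))
      warning(sum(orphan), " ", what,
              " row(s) discarded: alf not in person table", call. = FALSE)
    list(df = df[!orphan, , drop = FALSE], n = sum(orphan))
  }
  s <- drop_tab(survey, "survey"); g <- drop_tab(gp_events, "gp_events")
  h <- drop_tab(hospital_episodes, "hospital_episodes")

  structure(list(
    persons = persons, survey = s$df, gp_events = g$df,
    hospital_episodes = h$df,
    manifest = list(
      n_persons_in = n_in, n_persons = nrow(persons),
      n_unmatched_dropped = n_unmatched, n_fuzzy_dropped = n_fuzzy_dropped,
      n_survey = nrow(s$df), n_gp_events = nrow(g$df),
      n_hospital_episodes = nrow(h$df),
      n_discarded = c(survey = s$n, gp_events = g$n, hospital_episodes = h$n))),
    class = "platform_record_set")
}

#' @export
print.platform_record_set <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Platform record set: %d persons (%d in, %d unmatched dropped%s)\n",
              m$n_persons, m$n_persons_in, m$n_unmatched_dropped,
              if (m$n_fuzzy_dropped) sprintf(", %d fuzzy dropped", m$n_fuzzy_dropped)
              else ""))
  cat(sprintf("  survey rows: %d   GP events: %d   hospital episodes: %d\n",
              m$n_survey, m$n_gp_events, m$n_hospital_episodes))
  if (sum(m$n_discarded))
    cat("  discarded orphan rows:",
        paste(names(m$n_discarded), m$n_discarded, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a platform record set
#'
#' The four-CSV layout of [write_cohort()] plus `manifest.json` carrying row
#' counts, discard counts and a content hash.
#'
#' @param platform a `platform_record_set`.
#' @param dir directory.
#' @export
write_platform <- function(platform, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(required_cols))
    utils::write.csv(platform[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  manifest <- platform$manifest
  manifest$content_hash <- digest::digest(
    platform[c("persons", "survey", "gp_events", "hospital_episodes")])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_platform
#' @export
read_platform <- function(dir) {
  cohort <- read_cohort(dir)
  build_platform(cohort$persons, cohort$survey, cohort$gp_events,
                 cohort$hospital_episodes, drop_unmatched = FALSE)
}
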