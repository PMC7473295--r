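# Synthetic linked survey + GP + hospital data.
#
# Two entry points:
#   * generate_cohort(): a stochastic world with configurable latent
#     true-condition status, survey misreporting, clinical recording and
#     timing probabilities, and partial GP-practice coverage;
#   * plant_contingency(): a deterministic world engineered so that the full
#     linkage -> phenotyping -> validation pipeline reproduces a specified
#     survey-vs-clinical 2x2 exactly (used to verify that the ascertainment
#     logic does not distort planted status, and to replay published tables).

# Age-band x gender joint counts of the linked survey sample used as default
# demographic marginals (5 bands 16-29 .. 75+; male column first).
DEFAULT_AGE_GENDER <- matrix(
  c(731, 935, 1304, 1565, 709,
    1014, 1229, 1559, 1543, 734),
  ncol = 2, dimnames = list(c("16-29", "30-44", "45-59", "60-74", "75+"),
                            c("male", "female")))

#' Per-condition simulation parameters
#'
#' Defaults describe an asthma-like condition in a linked survey/EHR setting:
#' roughly 10.5% true prevalence, imperfect self-report (sensitivity 0.70,
#' specificity 0.96 — over-reporting driven by recall/telescoping), ~5%
#' item non-response, GP records much more likely than hospital records, and
#' most records falling inside the 12-month pre-interview window.
#'
#' @param true_prevalence probability a person truly has the condition.
#' @param survey_sensitivity P(answer yes | true case).
#' @param survey_specificity P(answer no | not a case).
#' @param non_response_rate probability the answer is blanked to
#'   no-answer/refused, applied after the yes/no draw, independent of status.
#' @param p_record_gp probability a true case has a matching GP record
#'   (suppressed when the person's practice does not contribute data).
#' @param p_record_hospital probability a true case has a matching hospital
#'   episode.
#' @param p_in_window probability an emitted record falls inside the 12-month
#'   pre-interview window (only relevant for `CURRENT_12M` conditions).
#' @return a `condition_sim` parameter list.
#' @export
condition_sim <- function(true_prevalence = 0.105, survey_sensitivity = 0.70,
                          survey_specificity = 0.96, non_response_rate = 0.05,
                          p_record_gp = 0.90, p_record_hospital = 0.15,
                          p_in_window = 0.90) {
  p <- list(true_prevalence = true_prevalence,
            survey_sensitivity = survey_sensitivity,
            survey_specificity = survey_specificity,
            non_response_rate = non_response_rate,
            p_record_gp = p_record_gp, p_record_hospital = p_record_hospital,
            p_in_window = p_in_window)
  bad <- names(p)[!vapply(p, function(v)
    is.numeric(v) && length(v) == 1 && v >= 0 && v <= 1, TRUE)]
  if (length(bad)) stop("probabilities must lie in [0, 1]: ",
                        paste(bad, collapse = ", "))
  structure(p, class = "condition_sim")
}

#' Cohort generation configuration
#'
#' @param n_persons cohort size; the linked two-sweep survey sample this
#'   emulates held 11,323 adults.
#' @param seed RNG seed; the generated tables are fully reproducible from it.
#' @param conditions named list of [condition_sim()] blocks; names must match
#'   condition ids in the code set collection passed to [generate_cohort()].
#' @param gp_coverage fraction of persons whose GP practice contributes data
#'   (default 0.8 — roughly 80% of practices supplied GP records).
#' @param survey_period interview-date range (default the 21-month window
#'   2013-04-01 to 2014-12-31, consent having started part-way through 2013).
#' @param gp_data_start earliest GP event date (default 2010-01-01).
#' @param hospital_data_start earliest hospital admission date (default
#'   2002-01-01).
#' @param age_gender_marginals 5x2 matrix of age-band by gender weights.
#' @param fuzzy_match_rate fraction of persons flagged as fuzzy linkage
#'   matches (carried as metadata, never filtered by default).
#' @param condition_correlation optional latent-status correlation across
#'   conditions via a shared Gaussian factor; 0 (independent) by default.
#' @param background_gp_rate,background_hospital_rate per-person probability
#'   of a non-condition decoy record, exercising non-matching codes.
#' @return a `cohort_config`.
#' @export
cohort_config <- function(n_persons = 11323, seed = 1,
                          conditions = list(asthma = condition_sim()),
                          gp_coverage = 0.8,
                          survey_period = c("2013-04-01", "2014-12-31"),
                          gp_data_start = "2010-01-01",
                          hospital_data_start = "2002-01-01",
                          age_gender_marginals = DEFAULT_AGE_GENDER,
                          fuzzy_match_rate = 0.05,
                          condition_correlation = 0,
                          background_gp_rate = 0.3,
                          background_hospital_rate = 0.1) {
  stopifnot(n_persons >= 1, gp_coverage >= 0, gp_coverage <= 1,
            length(conditions) >= 1, !is.null(names(conditions)),
            all(nzchar(names(conditions))),
            condition_correlation >= 0, condition_correlation < 1)
  for (cc in conditions)
    if (!inherits(cc, "condition_sim")) stop("conditions must be condition_sim blocks")
  structure(list(
    n_persons = as.integer(n_persons), seed = as.integer(seed),
    conditions = conditions, gp_coverage = gp_coverage,
    survey_period = as.Date(survey_period),
    gp_data_start = as.Date(gp_data_start),
    hospital_data_start = as.Date(hospital_data_start),
    age_gender_marginals = age_gender_marginals,
    fuzzy_match_rate = fuzzy_match_rate,
    condition_correlation = condition_correlation,
    background_gp_rate = background_gp_rate,
    background_hospital_rate = background_hospital_rate),
    class = "cohort_config")
}

empty_persons <- function() data.frame(
  alf = character(), gender = character(), age_group = character(),
  interview_date = as.Date(character()), gp_covered = logical(),
  match_quality = character(), stringsAsFactors = FALSE)

empty_survey <- function() data.frame(
  alf = character(), condition_id = character(), answer = character(),
  stringsAsFactors = FALSE)

empty_gp <- function() data.frame(
  alf = character(), event_date = as.Date(character()),
  read_code = character(), stringsAsFactors = FALSE)

empty_hospital <- function() data.frame(
  alf = character(), admission_date = as.Date(character()),
  icd10_codes = character(), stringsAsFactors = FALSE)

sample_demographics <- function(n, marginals) {
  cells <- expand.grid(age_group = rownames(marginals),
                       gender = colnames(marginals),
                       stringsAsFactors = FALSE)
  idx <- sample.int(nrow(cells), n, replace = TRUE, prob = as.vector(marginals))
  cells[idx, c("gender", "age_group")]
}

make_persons <- function(n, config) {
  demo <- sample_demographics(n, config$age_gender_marginals)
  data.frame(
    alf = sprintf("A%07d", seq_len(n)),
    gender = demo$gender,
    age_group = demo$age_group,
    interview_date = random_dates(n, config$survey_period[1], config$survey_period[2]),
    gp_covered = stats::runif(n) < config$gp_coverage,
    match_quality = ifelse(stats::runif(n) < config$fuzzy_match_rate,
                           "fuzzy", "good"),
    stringsAsFactors = FALSE)
}

# Decoy codes guaranteed not to match a collection's code sets (Read: exact;
# ICD-10: no mutual prefix relation). Returns character(0) if none survive.
read_decoys <- function(sets) {
  cand <- c("22A..", "246..", "65E..", "9OX1.", "XaXaX", "1371.")
  used <- norm_read(unlist(lapply(sets, function(s)
    c(s$event_codes, s$medication_codes))))
  cand[!norm_read(cand) %in% used]
}

icd_decoys <- function(sets) {
  cand <- c("Z380", "S525", "K590", "M545", "N390", "H109")
  used <- norm_icd10(unlist(lapply(sets, function(s) s$diagnosis_codes)))
  keep <- vapply(norm_icd10(cand), function(k) {
    !any(startsWith(k, used) | startsWith(used, k))
  }, TRUE)
  cand[keep]
}

# Ascertainment window lower bound for one condition on given interview dates.
window_lower <- function(interview_date, window, source_start) {
  if (window == "CURRENT_12M")
    pmax(subtract_months(interview_date, 12), as.Date(source_start))
  else rep(as.Date(source_start), length(interview_date))
}

#' Generate a synthetic linked cohort
#'
#' Draws, for each person and configured condition, a latent true status at
#' `true_prevalence`; a survey answer (`yes` with probability
#' `survey_sensitivity` for true cases, `1 - survey_specificity` otherwise),
#' overwritten to `no_answer` with probability `non_response_rate`; and, for
#' true cases, GP/hospital records carrying condition codes, dated inside or
#' outside the 12-month pre-interview window per `p_in_window`. GP records are
#' suppressed for persons whose practice does not contribute data
#' (`gp_covered = FALSE`). Background decoy records with non-matching codes
#' are added independently of status.
#'
#' @param config a [cohort_config()].
#' @param code_sets a [code_set_collection()] providing codes for every
#'   configured condition (an empty code set is a configuration error).
#' @return a `linked_cohort` list with data.frames `persons`, `survey`,
#'   `gp_events`, `hospital_episodes`, and `truth` (per person x condition:
#'   latent `true_case`), plus the `config` used.
#' @export
generate_cohort <- function(config, code_sets = demo_code_sets()) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(code_sets, "code_set_collection"))
  for (id in names(config$conditions)) {
    cs <- code_sets$sets[[id]]
    if (is.null(cs))
      stop("configuration error: no code set for condition ", sQuote(id))
    if (length(all_codes_of(cs)) == 0)
      stop("configuration error: empty code set for condition ", sQuote(id))
  }
  set.seed(config$seed)
  n <- config$n_persons
  persons <- make_persons(n, config)

  survey <- list(); gp <- list(); hosp <- list(); truth <- list()
  rho <- config$condition_correlation
  z_shared <- if (rho > 0) stats::rnorm(n) else NULL

  for (id in names(config$conditions)) {
    par <- config$conditions[[id]]
    cs <- code_sets$sets[[id]]

    if (rho > 0) {
      z <- sqrt(rho) * z_shared + sqrt(1 - rho) * stats::rnorm(n)
      true_case <- z < stats::qnorm(par$true_prevalence)
    } else {
      true_case <- stats::runif(n) < par$true_prevalence
    }

    p_yes <- ifelse(true_case, par$survey_sensitivity, 1 - par$survey_specificity)
    answer <- ifelse(stats::runif(n) < p_yes, "yes", "no")
    answer[stats::runif(n) < par$non_response_rate] <- "no_answer"
    survey[[id]] <- data.frame(alf = persons$alf, condition_id = id,
                               answer = answer, stringsAsFactors = FALSE)
    truth[[id]] <- data.frame(alf = persons$alf, condition_id = id,
                              true_case = true_case, stringsAsFactors = FALSE)

    lower <- window_lower(persons$interview_date, cs$window, config$gp_data_start)
    gp_code_pool <- c(cs$event_codes, cs$medication_codes)
    has_gp <- true_case & persons$gp_covered &
      stats::runif(n) < par$p_record_gp & length(gp_code_pool) > 0
    if (any(has_gp)) {
      idx <- which(has_gp)
      in_win <- cs$window == "EVER" | stats::runif(length(idx)) < par$p_in_window
      dates <- rand_window_dates(persons$interview_date[idx], lower[idx], in_win,
                                 config$gp_data_start)
      keep <- !is.na(dates)
      gp[[paste0(id, "_case")]] <- data.frame(
        alf = persons$alf[idx][keep], event_date = dates[keep],
        read_code = sample(gp_code_pool, sum(keep), replace = TRUE),
        stringsAsFactors = FALSE)
    }

    lower_h <- window_lower(persons$interview_date, cs$window,
                            config$hospital_data_start)
    has_hosp <- true_case & stats::runif(n) < par$p_record_hospital &
      length(cs$diagnosis_codes) > 0
    if (any(has_hosp)) {
      idx <- which(has_hosp)
      in_win <- cs$window == "EVER" | stats::runif(length(idx)) < par$p_in_window
      dates <- rand_window_dates(persons$interview_date[idx], lower_h[idx], in_win,
                                 config$hospital_data_start)
      keep <- !is.na(dates)
      hosp[[paste0(id, "_case")]] <- data.frame(
        alf = persons$alf[idx][keep], admission_date = dates[keep],
        icd10_codes = sample(cs$diagnosis_codes, sum(keep), replace = TRUE),
        stringsAsFactors = FALSE)
    }
  }

  rd <- read_decoys(code_sets$sets); id_ <- icd_decoys(code_sets$sets)
  bg_gp <- persons$gp_covered & stats::runif(n) < config$background_gp_rate
  if (any(bg_gp) && length(rd)) {
    k <- sum(bg_gp)
    gp[["background"]] <- data.frame(
      alf = persons$alf[bg_gp],
      event_date = random_dates(k, config$gp_data_start,
                                persons$interview_date[bg_gp]),
      read_code = sample(rd, k, replace = TRUE), stringsAsFactors = FALSE)
  }
  bg_h <- stats::runif(n) < config$background_hospital_rate
  if (any(bg_h) && length(id_)) {
    k <- sum(bg_h)
    hosp[["background"]] <- data.frame(
      alf = persons$alf[bg_h],
      admission_date = random_dates(k, config$hospital_data_start,
                                    persons$interview_date[bg_h]),
      icd10_codes = sample(id_, k, replace = TRUE), stringsAsFactors = FALSE)
  }

  assemble_cohort(persons, survey, gp, hosp, truth, config)
}

# Dates inside the closed window [lower, interview] or strictly before it
# (bounded below by the source start); NA when no legal out-of-window day
# exists, in which case no record is emitted.
rand_window_dates <- function(interview, lower, in_window, source_start) {
  out <- as.Date(rep(NA, length(interview)))
  if (any(in_window)) {
    i <- which(in_window)
    span <- as.integer(interview[i] - lower[i]) + 1L
    out[i] <- lower[i] + floor(stats::runif(length(i)) * span)
  }
  if (any(!in_window)) {
    i <- which(!in_window)
    hi <- lower[i] - 1L
    lo <- as.Date(source_start)
    ok <- hi >= lo
    if (any(ok)) {
      j <- i[ok]
      span <- as.integer(hi[ok] - lo) + 1L
      out[j] <- lo + floor(stats::runif(length(j)) * span)
    }
  }
  out
}

sort_cohort_tables <- function(x) {
  x$persons <- x$persons[order(x$persons$alf), , drop = FALSE]
  x$survey <- x$survey[order(x$survey$condition_id, x$survey$alf), , drop = FALSE]
  x$gp_events <- x$gp_events[order(x$gp_events$alf, x$gp_events$event_date,
                                   x$gp_events$read_code), , drop = FALSE]
  x$hospital_episodes <- x$hospital_episodes[
    order(x$hospital_episodes$alf, x$hospital_episodes$admission_date,
          x$hospital_episodes$icd10_codes), , drop = FALSE]
  x$truth <- x$truth[order(x$truth$condition_id, x$truth$alf), , drop = FALSE]
  for (nm in c("persons", "survey", "gp_events", "hospital_episodes", "truth"))
    rownames(x[[nm]]) <- NULL
  x
}

assemble_cohort <- function(persons, survey, gp, hosp, truth, config) {
  x <- list(
    persons = persons,
    survey = if (length(survey)) do.call(rbind, unname(survey)) else empty_survey(),
    gp_events = if (length(gp)) do.call(rbind, unname(gp)) else empty_gp(),
    hospital_episodes = if (length(hosp)) do.call(rbind, unname(hosp))
                        else empty_hospital(),
    truth = if (length(truth)) do.call(rbind, unname(truth)) else
      data.frame(alf = character(), condition_id = character(),
                 true_case = logical(), stringsAsFactors = FALSE),
    config = config)
  structure(sort_cohort_tables(x), class = "linked_cohort")
}

#' @export
print.linked_cohort <- function(x, ...) {
  cat(sprintf(
    "Linked cohort: %d persons, %d survey rows, %d GP events, %d hospital episodes\n",
    nrow(x$persons), nrow(x$survey), nrow(x$gp_events),
    nrow(x$hospital_episodes)))
  invisible(x)
}

#' Plant an exact survey-vs-clinical contingency table
#'
#' Emits `tp + fp + fn + tn + no_answer` persons whose survey answers and
#' clinical records, when run through linkage, phenotyping and validation,
#' reproduce the given 2x2 exactly: every clinical-positive person receives at
#' least one in-window matching record, clinical-negative persons receive none
#' (out-of-window matching decoys and in-window non-matching decoys are added
#' at `decoy_rate` and must not flip status). Record-level detail — dates,
#' demographics, which source — is randomized under `seed`.
#'
#' Published tables sometimes count clinical positives among item
#' non-responders too (the clinical total then exceeds `tp + fn`);
#' `no_answer_cases` plants that many clinical-positive persons inside the
#' no-answer group. `source_counts` fixes the GP-only / hospital-only / both
#' attribution over all clinical positives.
#'
#' @param tp,fp,fn,tn cell counts (survey yes/no x clinical yes/no).
#' @param no_answer persons answering no-answer/refused (excluded from cells).
#' @param code_set the [condition_code_set()] whose codes and window to use.
#' @param seed RNG seed.
#' @param no_answer_cases clinical-positive persons among the no-answer group.
#' @param source_counts optional named vector
#'   `c(gp_only=, hospital_only=, both=)` summing to
#'   `tp + fn + no_answer_cases`.
#' @param decoy_rate probability a clinical-negative person gets a harmless
#'   decoy record.
#' @param gp_coverage fraction of non-GP-case persons flagged as covered.
#' @param survey_period,gp_data_start,hospital_data_start as [cohort_config()].
#' @param age_gender_marginals demographic weights, as [cohort_config()].
#' @return a `linked_cohort` (truth carries the planted clinical status and
#'   source).
#' @export
plant_contingency <- function(tp, fp, fn, tn, no_answer, code_set, seed = 1,
                              no_answer_cases = 0, source_counts = NULL,
                              decoy_rate = 0.1, gp_coverage = 0.8,
                              survey_period = c("2013-04-01", "2014-12-31"),
                              gp_data_start = "2010-01-01",
                              hospital_data_start = "2002-01-01",
                              age_gender_marginals = DEFAULT_AGE_GENDER) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn, no_answer = no_answer)
  if (any(counts < 0) || no_answer_cases < 0 || no_answer_cases > no_answer)
    stop("cell counts must be non-negative and no_answer_cases <= no_answer")
  stopifnot(inherits(code_set, "condition_code_set"))
  id <- code_set$condition_id
  n <- sum(counts)
  config <- cohort_config(n_persons = max(n, 1), seed = seed,
                          conditions = stats::setNames(list(condition_sim()), id),
                          gp_coverage = gp_coverage,
                          survey_period = survey_period,
                          gp_data_start = gp_data_start,
                          hospital_data_start = hospital_data_start,
                          age_gender_marginals = age_gender_marginals)
  if (n == 0) {
    x <- assemble_cohort(empty_persons(), list(), list(), list(), list(), config)
    return(x)
  }

  set.seed(seed)
  persons <- make_persons(n, config)

  grp <- rep(c("tp", "fp", "fn", "tn", "na"), times = counts)
  grp <- sample(grp)                        # shuffle assignment across persons
  answer <- c(tp = "yes", fp = "yes", fn = "no", tn = "no", na = "no_answer")[grp]
  is_case <- grp %in% c("tp", "fn")
  if (no_answer_cases > 0) {
    na_idx <- which(grp == "na")
    is_case[sample(na_idx, no_answer_cases)] <- TRUE
  }

  n_pos <- sum(is_case)
  source <- rep(NA_character_, n)
  if (n_pos > 0) {
    if (!is.null(source_counts)) {
      sc <- source_counts[c("gp_only", "hospital_only", "both")]
      if (anyNA(sc) || sum(sc) != n_pos)
        stop("source_counts must name gp_only/hospital_only/both and sum to ",
             "the number of clinical positives (", n_pos, ")")
      pool <- rep(c("gp_only", "hospital_only", "both"), times = sc)
    } else {
      pool <- sample(c("gp_only", "hospital_only", "both"), n_pos,
                     replace = TRUE, prob = c(0.5, 0.3, 0.2))
    }
    source[is_case] <- sample(pool)
  }
  gp_code_pool <- c(code_set$event_codes, code_set$medication_codes)
  if (length(gp_code_pool) == 0 && any(source %in% c("gp_only", "both"), na.rm = TRUE))
    stop("code set has no GP (event/medication) codes but GP attribution requested")
  if (length(code_set$diagnosis_codes) == 0 &&
      any(source %in% c("hospital_only", "both"), na.rm = TRUE))
    stop("code set has no diagnosis codes but hospital attribution requested")

  # GP-ascertained persons must be covered, or phenotyping could not see them.
  persons$gp_covered[source %in% c("gp_only", "both")] <- TRUE

  lower_gp <- window_lower(persons$interview_date, code_set$window, gp_data_start)
  lower_h  <- window_lower(persons$interview_date, code_set$window,
                           hospital_data_start)

  gp <- list(); hosp <- list()
  need_gp <- which(source %in% c("gp_only", "both"))
  if (length(need_gp)) {
    dates <- rand_window_dates(persons$interview_date[need_gp],
                               lower_gp[need_gp],
                               rep(TRUE, length(need_gp)), gp_data_start)
    gp[["case"]] <- data.frame(
      alf = persons$alf[need_gp], event_date = dates,
      read_code = sample(gp_code_pool, length(need_gp), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  need_h <- which(source %in% c("hospital_only", "both"))
  if (length(need_h)) {
    dates <- rand_window_dates(persons$interview_date[need_h], lower_h[need_h],
                               rep(TRUE, length(need_h)), hospital_data_start)
    hosp[["case"]] <- data.frame(
      alf = persons$alf[need_h], admission_date = dates,
      icd10_codes = sample(code_set$diagnosis_codes, length(need_h),
                           replace = TRUE),
      stringsAsFactors = FALSE)
  }

  # Decoys for clinical negatives: never flip status.
  neg <- which(!is_case)
  if (length(neg) && decoy_rate > 0) {
    pick <- neg[stats::runif(length(neg)) < decoy_rate]
    rd <- read_decoys(list(code_set)); idd <- icd_decoys(list(code_set))
    for (i in pick) {
      mode <- sample(c("out_window_gp", "out_window_hosp", "junk_gp", "junk_hosp"), 1)
      if (mode == "out_window_gp" && code_set$window == "CURRENT_12M" &&
          persons$gp_covered[i] && length(gp_code_pool) &&
          lower_gp[i] - 1L >= as.Date(gp_data_start)) {
        gp[[paste0("d", i)]] <- data.frame(
          alf = persons$alf[i],
          event_date = random_dates(1, gp_data_start, lower_gp[i] - 1L),
          read_code = sample(gp_code_pool, 1), stringsAsFactors = FALSE)
      } else if (mode == "out_window_hosp" && code_set$window == "CURRENT_12M" &&
                 length(code_set$diagnosis_codes) &&
                 lower_h[i] - 1L >= as.Date(hospital_data_start)) {
        hosp[[paste0("d", i)]] <- data.frame(
          alf = persons$alf[i],
          admission_date = random_dates(1, hospital_data_start, lower_h[i] - 1L),
          icd10_codes = sample(code_set$diagnosis_codes, 1),
          stringsAsFactors = FALSE)
      } else if (mode == "junk_gp" && persons$gp_covered[i] && length(rd)) {
        gp[[paste0("d", i)]] <- data.frame(
          alf = persons$alf[i],
          event_date = random_dates(1, gp_data_start, persons$interview_date[i]),
          read_code = sample(rd, 1), stringsAsFactors = FALSE)
      } else if (length(idd)) {
        hosp[[paste0("d", i)]] <- data.frame(
          alf = persons$alf[i],
          admission_date = random_dates(1, hospital_data_start,
                                        persons$interview_date[i]),
          icd10_codes = sample(idd, 1), stringsAsFactors = FALSE)
      }
    }
  }

  survey <- list(data.frame(alf = persons$alf, condition_id = id,
                            answer = answer, stringsAsFactors = FALSE))
  truth <- list(data.frame(alf = persons$alf, condition_id = id,
                           true_case = is_case, source = source,
                           stringsAsFactors = FALSE))
  assemble_cohort(persons, survey, gp, hosp, truth, config)
}

#' Write / read a linked cohort as four CSV tables
#'
#' Serializes `persons.csv`, `survey.csv`, `gp_events.csv`,
#' `hospital_episodes.csv` (ISO-8601 dates; hospital ICD-10 code lists joined
#' with `;`, primary code first) plus `truth.csv` when latent status is known.
#'
#' @param cohort a `linked_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$persons, file.path(dir, "persons.csv"), row.names = FALSE)
  utils::write.csv(cohort$survey, file.path(dir, "survey.csv"), row.names = FALSE)
  utils::write.csv(cohort$gp_events, file.path(dir, "gp_events.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$hospital_episodes,
                   file.path(dir, "hospital_episodes.csv"), row.names = FALSE)
  if (!is.null(cohort$truth))
    utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  rd <- function(f, dates = NULL) {
    df <- utils::read.csv(file.path(dir, f), colClasses = "character")
    for (d in dates) df[[d]] <- as.Date(df[[d]])
    df
  }
  persons <- rd("persons.csv", "interview_date")
  persons$gp_covered <- as.logical(persons$gp_covered)
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) {
    t <- rd("truth.csv")
    t$true_case <- as.logical(t$true_case)
    t
  } else NULL
  structure(list(persons = persons,
                 survey = rd("survey.csv"),
                 gp_events = rd("gp_events.csv", "event_date"),
                 hospital_episodes = rd("hospital_episodes.csv", "admission_date"),
                 truth = truth, config = NULL),
            class = "linked_cohort")
}
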