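# Condition code sets: loading, normalisation, exclusivity checks and matching.
#
# Two coding systems are supported: ICD-10 (hospital diagnoses; uppercase,
# dot-insensitive, optionally prefix-matched so a 3-character category such as
# "J45" captures "J45.9") and Read v2 (GP events and medications; exact match
# after trimming and stripping trailing-dot padding, case preserved).

norm_icd10 <- function(x) gsub("\\.", "", toupper(trimws(x)))
norm_read  <- function(x) sub("\\.+$", "", trimws(x))

ICD10_PATTERN <- "^[A-Z][0-9]{2}[0-9A-Z]*$"

#' Create a normalized clinical code
#'
#' @param system `"ICD10"` or `"READ"`.
#' @param code the raw code string; normalized per system (ICD-10: uppercased,
#'   dots removed; Read: trailing-dot padding stripped, case preserved).
#' @param description optional free-text label.
#' @return a `clinical_code` list with fields `system`, `code`, `description`.
#' @examples
#' clinical_code("ICD10", "j45.9")
#' clinical_code("READ", "H33..")
#' @export
clinical_code <- function(system, code, description = NA_character_) {
  system <- match.arg(system, c("ICD10", "READ"))
  if (length(code) != 1 || is.na(code)) stop("code must be a single string")
  norm <- if (system == "ICD10") norm_icd10(code) else norm_read(code)
  if (!nzchar(norm) || grepl("\\s", norm))
    stop("clinical code must be non-empty and contain no whitespace: ", sQuote(code))
  if (system == "ICD10" && !grepl(ICD10_PATTERN, norm))
    stop("not a valid ICD-10 code (letter + 2 digits + optional subdivision): ",
         sQuote(code))
  structure(list(system = system, code = norm, description = description),
            class = "clinical_code")
}

#' @export
print.clinical_code <- function(x, ...) {
  cat(sprintf("<%s> %s%s\n", x$system, x$code,
              if (is.na(x$description)) "" else paste0("  # ", x$description)))
  invisible(x)
}

#' Create a condition code set
#'
#' Bundles the diagnosis (ICD-10), GP event (Read) and medication (Read) codes
#' identifying one chronic condition, together with its ascertainment-window
#' rule: `"EVER"` (any record since the source's data start, matching an
#' "ever been treated for" survey question) or `"CURRENT_12M"` (records in the
#' closed 12-month window before interview, matching "currently being treated").
#'
#' @param condition_id identifier, e.g. `"asthma"`.
#' @param diagnosis_codes character vector of ICD-10 codes (hospital).
#' @param event_codes character vector of Read codes (GP events).
#' @param medication_codes character vector of Read codes (GP prescriptions);
#'   may be empty — it is for cardiovascular conditions, where shared
#'   medications cannot distinguish between conditions.
#' @param window `"EVER"` or `"CURRENT_12M"`.
#' @param question_text the survey question wording, for reporting.
#' @return a `condition_code_set`.
#' @export
condition_code_set <- function(condition_id, diagnosis_codes = character(),
                               event_codes = character(),
                               medication_codes = character(),
                               window = c("CURRENT_12M", "EVER"),
                               question_text = "") {
  window <- match.arg(window)
  stopifnot(is.character(condition_id), length(condition_id) == 1,
            nzchar(condition_id))
  dg <- unique(vapply(diagnosis_codes,  function(k) clinical_code("ICD10", k)$code, ""))
  ev <- unique(vapply(event_codes,      function(k) clinical_code("READ",  k)$code, ""))
  md <- unique(vapply(medication_codes, function(k) clinical_code("READ",  k)$code, ""))
  if (length(dg) + length(ev) == 0)
    stop("condition ", sQuote(condition_id),
         " has no diagnosis or event codes: nothing could ever be ascertained")
  structure(list(condition_id = condition_id,
                 diagnosis_codes = unname(dg), event_codes = unname(ev),
                 medication_codes = unname(md), window = window,
                 question_text = question_text),
            class = "condition_code_set")
}

#' @export
print.condition_code_set <- function(x, ...) {
  cat(sprintf("Condition code set '%s' [%s]\n", x$condition_id, x$window))
  cat(sprintf("  diagnosis (ICD-10): %d   event (Read): %d   medication (Read): %d\n",
              length(x$diagnosis_codes), length(x$event_codes),
              length(x$medication_codes)))
  if (nzchar(x$question_text)) cat("  question: ", x$question_text, "\n", sep = "")
  invisible(x)
}

#' Create a collection of condition code sets
#'
#' @param sets list of [condition_code_set()] objects.
#' @param exclusivity_groups list of character vectors of condition ids whose
#'   code sets must be pairwise disjoint (the cardiovascular conditions in the
#'   shipped fixtures: a code that could indicate more than one of them must
#'   not tag any).
#' @return a `code_set_collection`; sets are retrievable by `x$sets[[id]]`.
#' @export
code_set_collection <- function(sets, exclusivity_groups = list()) {
  ids <- vapply(sets, function(s) s$condition_id, "")
  if (anyDuplicated(ids))
    stop("duplicate condition_id in collection: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(sets) <- ids
  for (g in exclusivity_groups) {
    missing <- setdiff(g, ids)
    if (length(missing))
      stop("exclusivity group names unknown condition(s): ",
           paste(missing, collapse = ", "))
  }
  structure(list(sets = sets, exclusivity_groups = exclusivity_groups),
            class = "code_set_collection")
}

#' @export
print.code_set_collection <- function(x, ...) {
  cat(sprintf("Code set collection: %d condition(s)\n", length(x$sets)))
  for (s in x$sets) print(s)
  if (length(x$exclusivity_groups))
    cat("Exclusivity groups:",
        paste(vapply(x$exclusivity_groups, paste, "", collapse = "+"),
              collapse = "; "), "\n")
  invisible(x)
}

ROLES <- c("diagnosis", "event", "medication")

#' Load condition code sets from CSV or JSON
#'
#' The CSV schema has header `condition_id,system,code,role,description` with
#' `system` in `ICD10`/`READ` and `role` in `diagnosis`/`event`/`medication`;
#' the JSON mirror is an array of objects with the same fields, optionally
#' wrapped as `{"codes": [...], "exclusivity_groups": [[...], ...]}`. Codes are
#' normalized per system and duplicate rows collapsed.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @param exclusivity_groups optional list of character vectors (overrides any
#'   groups carried in a JSON file).
#' @param windows optional named character vector mapping condition_id to
#'   `"EVER"`/`"CURRENT_12M"`; CSV carries no window column, so unlisted
#'   conditions default to `"CURRENT_12M"`.
#' @param question_texts optional named character vector of survey wordings.
#' @return a [code_set_collection()].
#' @export
load_code_sets <- function(path, format = c("auto", "csv", "json"),
                           exclusivity_groups = NULL, windows = NULL,
                           question_texts = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (!file.exists(path)) stop("code set file not found: ", path)

  file_groups <- list()
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  } else {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyMatrix = FALSE)
    if (is.list(raw) && !is.data.frame(raw) && !is.null(raw$codes)) {
      df <- as.data.frame(raw$codes, stringsAsFactors = FALSE)
      file_groups <- lapply(raw$exclusivity_groups %||% list(), as.character)
    } else df <- as.data.frame(raw, stringsAsFactors = FALSE)
  }
  need <- c("condition_id", "system", "code", "role")
  if (!all(need %in% names(df)))
    stop("code set schema error: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (!"description" %in% names(df)) df$description <- NA_character_
  if (nrow(df) == 0) stop("code set file has no rows: ", path)

  bad_sys  <- !df$system %in% c("ICD10", "READ")
  bad_role <- !df$role %in% ROLES
  if (any(bad_sys))
    stop("schema error: unknown system ", sQuote(df$system[bad_sys][1]),
         " at data row ", which(bad_sys)[1])
  if (any(bad_role))
    stop("schema error: unknown role ", sQuote(df$role[bad_role][1]),
         " at data row ", which(bad_role)[1])
  mismatch <- (df$role == "diagnosis" & df$system != "ICD10") |
              (df$role != "diagnosis" & df$system != "READ")
  if (any(mismatch))
    stop("schema error: role/system mismatch at data row ", which(mismatch)[1],
         " (diagnosis codes are ICD10; event/medication codes are READ)")
  for (i in seq_len(nrow(df))) {
    ok <- tryCatch({ clinical_code(df$system[i], df$code[i]); TRUE },
                   error = function(e) e)
    if (!isTRUE(ok))
      stop("parse error at data row ", i, ": ", conditionMessage(ok))
  }

  sets <- lapply(split(df, df$condition_id), function(d) {
    id <- d$condition_id[1]
    condition_code_set(
      condition_id = id,
      diagnosis_codes  = d$code[d$role == "diagnosis"],
      event_codes      = d$code[d$role == "event"],
      medication_codes = d$code[d$role == "medication"],
      window = unname(if (!is.null(windows) && id %in% names(windows))
        windows[[id]] else "CURRENT_12M"),
      question_text = unname(if (!is.null(question_texts) &&
                                 id %in% names(question_texts))
        question_texts[[id]] else ""))
  })
  code_set_collection(unname(sets),
                      exclusivity_groups = exclusivity_groups %||% file_groups)
}

#' Write a code set collection to CSV or JSON
#'
#' Inverse of [load_code_sets()]; `load(write(x))` round-trips to an equal
#' collection (window/question metadata is preserved only by the JSON format).
#'
#' @param collection a [code_set_collection()].
#' @param path output file.
#' @param format `"auto"`, `"csv"` or `"json"`.
#' @export
write_code_sets <- function(collection, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  rows <- do.call(rbind, lapply(collection$sets, function(s) {
    data.frame(
      condition_id = s$condition_id,
      system = c(rep("ICD10", length(s$diagnosis_codes)),
                 rep("READ", length(s$event_codes) + length(s$medication_codes))),
      code = c(s$diagnosis_codes, s$event_codes, s$medication_codes),
      role = c(rep("diagnosis", length(s$diagnosis_codes)),
               rep("event", length(s$event_codes)),
               rep("medication", length(s$medication_codes))),
      description = NA_character_, stringsAsFactors = FALSE)
  }))
  if (format == "csv") {
    utils::write.csv(rows, path, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(
      list(codes = rows,
           exclusivity_groups = collection$exclusivity_groups,
           windows = lapply(collection$sets, function(s) s$window),
           question_texts = lapply(collection$sets, function(s) s$question_text)),
      path, dataframe = "rows", auto_unbox = TRUE, na = "null", pretty = TRUE)
  }
  invisible(path)
}

all_codes_of <- function(set) {
  c(set$diagnosis_codes, set$event_codes, set$medication_codes)
}

#' Check code exclusivity within declared groups
#'
#' For each exclusivity group, reports every code appearing in more than one
#' member's code sets. The check is scoped to declared groups only: an overlap
#' between conditions never grouped together is permitted (the disjointness
#' requirement applies to the cardiovascular conditions, not globally).
#'
#' @param collection a [code_set_collection()].
#' @return data.frame with columns `condition_a`, `condition_b`, `code`
#'   (zero rows when all groups are pairwise disjoint). Pairs are reported
#'   once, ordered alphabetically.
#' @export
validate_exclusivity <- function(collection) {
  out <- data.frame(condition_a = character(), condition_b = character(),
                    code = character(), stringsAsFactors = FALSE)
  for (g in collection$exclusivity_groups) {
    g <- sort(g)
    if (length(g) < 2) next
    for (i in seq_len(length(g) - 1)) for (j in seq((i + 1), length(g))) {
      shared <- intersect(all_codes_of(collection$sets[[g[i]]]),
                          all_codes_of(collection$sets[[g[j]]]))
      if (length(shared))
        out <- rbind(out, data.frame(condition_a = g[i], condition_b = g[j],
                                     code = shared, stringsAsFactors = FALSE))
    }
  }
  out
}

#' Match a record code against a code-list entry
#'
#' Read codes match by exact equality after trimming and trailing-dot
#' normalisation. ICD-10 codes match dot-insensitively; with
#' `icd_prefix_matching = TRUE` (the default) a category-level entry such as
#' `"I21"` matches any subdivision (`"I21.9"`), reflecting that hospital
#' episodes carry 4-character codes while code lists are often written at
#' category level.
#'
#' @param record_code character vector of codes as found in records.
#' @param entry_code single code-list entry.
#' @param system `"ICD10"` or `"READ"`.
#' @param icd_prefix_matching logical; ICD-10 prefix mode.
#' @return logical vector along `record_code`.
#' @examples
#' code_matches("I21.9", "I21", "ICD10")            # TRUE
#' code_matches("I219", "I21.9", "ICD10", FALSE)    # TRUE (dot-insensitive)
#' code_matches("I22", "I21", "ICD10")              # FALSE
#' @export
code_matches <- function(record_code, entry_code, system = c("ICD10", "READ"),
                         icd_prefix_matching = TRUE) {
  system <- match.arg(system)
  stopifnot(length(entry_code) == 1)
  if (system == "READ")
    return(norm_read(record_code) == norm_read(entry_code))
  rec <- norm_icd10(record_code)
  ent <- norm_icd10(entry_code)
  if (icd_prefix_matching) startsWith(rec, ent) else rec == ent
}

# Vectorized many-records vs many-entries matching used by the phenotyper.
icd_match_any <- function(record_codes, entries, icd_prefix_matching = TRUE) {
  rec <- norm_icd10(record_codes)
  if (!length(entries)) return(rep(FALSE, length(rec)))
  ent <- norm_icd10(entries)
  if (!icd_prefix_matching) return(rec %in% ent)
  hit <- rep(FALSE, length(rec))
  for (e in ent) hit <- hit | startsWith(rec, e)
  hit
}

read_match_any <- function(record_codes, entries) {
  if (!length(entries)) return(rep(FALSE, length(record_codes)))
  norm_read(record_codes) %in% norm_read(entries)
}

#' Demo code set collection shipped with the package
#'
#' Loads the illustrative code lists under `inst/extdata/` for angina, heart
#' attack, heart failure (no medication codes; "currently treated" windows
#' except heart attack, which is "ever treated") and asthma (with a medication
#' list). These are synthetic stand-ins assembled for testing and examples,
#' not a clinically curated phenotype library.
#'
#' @return a [code_set_collection()] with the cardiovascular exclusivity group.
#' @export
demo_code_sets <- function() {
  path <- system.file("extdata", "demo_code_sets.csv", package = "phenolink")
  load_code_sets(
    path,
    exclusivity_groups = list(c("angina", "heart_attack", "heart_failure")),
    windows = c(angina = "CURRENT_12M", heart_attack = "EVER",
                heart_failure = "CURRENT_12M", asthma = "CURRENT_12M"),
    question_texts = c(
      angina = "Are you currently being treated for angina?",
      heart_attack = "Have you ever been treated for a heart attack?",
      heart_failure = "Are you currently being treated for heart failure?",
      asthma = "Are you currently being treated for asthma?"))
}
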