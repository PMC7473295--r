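# Survey-vs-clinical contingency matrices and the validation statistics
# reported from them: sensitivity/specificity/PPV/NPV, Cohen's kappa on valid
# responses, prevalence per 1,000 with binomial confidence intervals, and item
# non-response rates.

#' Construct a 2x2 survey-vs-clinical contingency matrix
#'
#' Clinical case status is the gold standard. Persons answering
#' no-answer/refused are excluded from the four cells and counted separately;
#' everyone else is placed by (survey answer, clinical status).
#'
#' @param survey survey-response table (`alf`, `condition_id`, `answer`).
#' @param case_tags case-tag table from [ascertain()].
#' @param condition_id condition to tabulate.
#' @return a `contingency_matrix`: `tp`, `fp`, `fn`, `tn`, `no_answer`,
#'   `n_valid`, `n_total`.
#' @export
build_contingency <- function(survey, case_tags, condition_id) {
  s <- survey[survey$condition_id == condition_id, , drop = FALSE]
  t <- case_tags[case_tags$condition_id == condition_id, , drop = FALSE]
  missing_survey <- setdiff(t$alf, s$alf)
  if (length(missing_survey))
    stop("integrity error: ", length(missing_survey),
         " person(s) tagged but missing a survey row, e.g. ",
         paste(utils::head(missing_survey, 3), collapse = ", "))
  missing_tag <- setdiff(s$alf, t$alf)
  if (length(missing_tag))
    stop("integrity error: ", length(missing_tag),
         " survey person(s) missing a case tag, e.g. ",
         paste(utils::head(missing_tag, 3), collapse = ", "))
  is_case <- t$is_case[match(s$alf, t$alf)]
  na <- s$answer == "no_answer"
  yes <- s$answer == "yes"
  contingency_matrix(
    tp = sum(yes & is_case & !na), fp = sum(yes & !is_case & !na),
    fn = sum(!yes & is_case & !na), tn = sum(!yes & !is_case & !na),
    no_answer = sum(na), condition_id = condition_id)
}

#' Create a contingency matrix from counts
#'
#' @param tp,fp,fn,tn survey-yes/clinical-yes ... survey-no/clinical-no cell
#'   counts.
#' @param no_answer excluded no-answer/refused count.
#' @param condition_id optional label.
#' @return a `contingency_matrix`.
#' @export
contingency_matrix <- function(tp, fp, fn, tn, no_answer = 0,
                               condition_id = NA_character_) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn, no_answer = no_answer)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("cell counts must be non-negative integers")
  structure(list(condition_id = condition_id, tp = as.integer(tp),
                 fp = as.integer(fp), fn = as.integer(fn), tn = as.integer(tn),
                 no_answer = as.integer(no_answer),
                 n_valid = as.integer(tp + fp + fn + tn),
                 n_total = as.integer(tp + fp + fn + tn + no_answer)),
            class = "contingency_matrix")
}

#' @export
print.contingency_matrix <- function(x, ...) {
  if (!is.na(x$condition_id)) cat("Condition:", x$condition_id, "\n")
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, byrow = TRUE,
              dimnames = list(c("survey yes", "survey no"),
                              c("clinical yes", "clinical no")))
  print(m)
  cat("no answer/refused:", x$no_answer, "   total:", x$n_total, "\n")
  invisible(x)
}

#' Sensitivity, specificity, PPV and NPV of survey report
#'
#' Computed against clinical status as gold standard, as percentages:
#' sensitivity `100*tp/(tp+fn)`, specificity `100*tn/(tn+fp)`, PPV
#' `100*tp/(tp+fp)`, NPV `100*tn/(tn+fn)`. A metric whose denominator is zero
#' is undefined and returned as `NA` (with the names flagged in the
#' `undefined` attribute), never silently zeroed.
#'
#' @param m a `contingency_matrix`.
#' @return named numeric vector `sensitivity`, `specificity`, `ppv`, `npv`
#'   (full precision; see [fmt_metric()] for the 2-decimal trimmed rendering).
#' @export
diagnostic_metrics <- function(m) {
  stopifnot(inherits(m, "contingency_matrix"))
  safe <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  out <- c(sensitivity = safe(m$tp, m$tp + m$fn),
           specificity = safe(m$tn, m$tn + m$fp),
           ppv = safe(m$tp, m$tp + m$fp),
           npv = safe(m$tn, m$tn + m$fn))
  if (anyNA(out)) {
    warning("undefined metric(s) (zero denominator): ",
            paste(names(out)[is.na(out)], collapse = ", "), call. = FALSE)
    attr(out, "undefined") <- names(out)[is.na(out)]
  }
  out
}

#' Format a percentage metric the way validation tables print it
#'
#' Two decimal places with trailing zeros trimmed: 97.00 prints as "97",
#' 66.955 as "66.96".
#'
#' @param x numeric vector of percentages.
#' @return character vector.
#' @export
fmt_metric <- function(x) fmt_trim(x, 2)

#' Cohen's kappa for a 2x2 table, valid responses only
#'
#' Chance-corrected agreement between survey report and clinical status over
#' the `n = tp+fp+fn+tn` valid responders: observed agreement
#' `po = (tp+tn)/n`, chance agreement
#' `pe = ((tp+fp)(tp+fn) + (fn+tn)(fp+tn))/n^2`, kappa `(po-pe)/(1-pe)`.
#'
#' @param m a `contingency_matrix`.
#' @return kappa in `[-1, 1]` at full precision; `NA` (undefined) when
#'   `pe = 1`, i.e. both classifications are constant.
#' @export
cohens_kappa <- function(m) {
  stopifnot(inherits(m, "contingency_matrix"))
  n <- m$n_valid
  if (n == 0) stop("kappa undefined: no valid responses")
  po <- (m$tp + m$tn) / n
  pe <- ((m$tp + m$fp) * (m$tp + m$fn) + (m$fn + m$tn) * (m$fp + m$tn)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 4) {
    warning("kappa undefined: chance agreement is 1", call. = FALSE)
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Prevalence per 1,000 with a binomial confidence interval
#'
#' Point estimate `round(1000 * k/n)` and a 95% interval per 1,000, rounded to
#' integers. `"wald"` (default) is the normal approximation
#' `p +/- z * sqrt(p(1-p)/n)`; `"wilson"` is the score interval, better
#' behaved near 0.
#'
#' @param case_count numerator `k`.
#' @param denominator `n > 0`.
#' @param alpha two-sided error rate (default 0.05).
#' @param method `"wald"` or `"wilson"`.
#' @return named numeric `point`, `lower`, `upper` (integers per 1,000;
#'   bounds clamped to `[0, 1000]`).
#' @examples
#' prevalence_per_1000(396, 11323)   # 35 (32, 38)
#' @export
prevalence_per_1000 <- function(case_count, denominator, alpha = 0.05,
                                method = c("wald", "wilson")) {
  method <- match.arg(method)
  if (denominator <= 0) stop("denominator must be positive")
  if (case_count < 0 || case_count > denominator)
    stop("case_count must lie in [0, denominator]")
  p <- case_count / denominator
  z <- stats::qnorm(1 - alpha / 2)
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / denominator)
    lo <- p - half; hi <- p + half
  } else {
    n <- denominator
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    lo <- centre - half; hi <- centre + half
  }
  c(point = round_half_up(1000 * p),
    lower = max(0, round_half_up(1000 * lo)),
    upper = min(1000, round_half_up(1000 * hi)))
}

#' Item non-response rate
#'
#' @param no_answer no-answer/refused count.
#' @param n_total all respondents (valid + no answer).
#' @return percentage rounded to 2 decimals.
#' @examples
#' non_response_rate(560, 11323)  # 4.95
#' @export
non_response_rate <- function(no_answer, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  round_half_up(100 * no_answer / n_total, 2)
}

#' Full validation report for one condition
#'
#' Assembles the per-condition block: the 2x2, diagnostic metrics, kappa,
#' survey and clinical prevalence per 1,000 with confidence intervals, and
#' the non-response rate.
#'
#' Survey prevalence uses the survey-yes count. The clinical numerator policy
#' is configurable because published practice is ambiguous: `"contingency"`
#' counts clinical positives among valid responders (`tp + fn`);
#' `"all_identified"` counts every ascertained case including those who did
#' not answer the survey item. The denominator policy defaults to all matched
#' respondents (`n_total`, non-response included); `"valid_only"` restricts to
#' valid responders.
#'
#' @param m a `contingency_matrix` (e.g. from [build_contingency()]).
#' @param n_clinical_total total ascertained cases for the condition
#'   (required for `clinical_numerator_policy = "all_identified"`; e.g.
#'   `attribute_sources(...)$total`).
#' @param prevalence_denominator_policy `"all_matched"` or `"valid_only"`.
#' @param clinical_numerator_policy `"contingency"` or `"all_identified"`.
#' @param ci_method passed to [prevalence_per_1000()].
#' @return a `validation_report` list.
#' @export
validate_condition <- function(m, n_clinical_total = NULL,
                               prevalence_denominator_policy =
                                 c("all_matched", "valid_only"),
                               clinical_numerator_policy =
                                 c("contingency", "all_identified"),
                               ci_method = c("wald", "wilson")) {
  stopifnot(inherits(m, "contingency_matrix"))
  prevalence_denominator_policy <- match.arg(prevalence_denominator_policy)
  clinical_numerator_policy <- match.arg(clinical_numerator_policy)
  ci_method <- match.arg(ci_method)

  denom <- if (prevalence_denominator_policy == "all_matched") m$n_total
           else m$n_valid
  clin_num <- if (clinical_numerator_policy == "contingency") m$tp + m$fn
  else {
    if (is.null(n_clinical_total))
      stop("clinical_numerator_policy='all_identified' needs n_clinical_total")
    n_clinical_total
  }
  structure(list(
    condition_id = m$condition_id,
    matrix = m,
    metrics = diagnostic_metrics(m),
    kappa = cohens_kappa(m),
    prevalence_clinical = prevalence_per_1000(clin_num, denom,
                                              method = ci_method),
    prevalence_survey = prevalence_per_1000(m$tp + m$fp, denom,
                                            method = ci_method),
    non_response_pct = non_response_rate(m$no_answer, m$n_total),
    policies = list(denominator = prevalence_denominator_policy,
                    clinical_numerator = clinical_numerator_policy,
                    ci_method = ci_method)),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation report: %s\n", x$condition_id %||% "?"))
  mt <- x$metrics
  cat(sprintf("  sensitivity %s  specificity %s  PPV %s  NPV %s\n",
              fmt_metric(mt["sensitivity"]), fmt_metric(mt["specificity"]),
              fmt_metric(mt["ppv"]), fmt_metric(mt["npv"])))
  cat(sprintf("  kappa %.3f (valid responses n = %d)\n", x$kappa,
              x$matrix$n_valid))
  pc <- x$prevalence_clinical; ps <- x$prevalence_survey
  cat(sprintf("  prevalence per 1,000: clinical %d (%d/%d)  survey %d (%d/%d)\n",
              pc["point"], pc["lower"], pc["upper"],
              ps["point"], ps["lower"], ps["upper"]))
  cat(sprintf("  non-response %.2f%%  [numerator policy: %s]\n",
              x$non_response_pct, x$policies$clinical_numerator))
  invisible(x)
}

#' Tabulate validation reports (summary-table analogue)
#'
#' @param reports list of `validation_report` objects.
#' @return data.frame, one row per condition, with formatted metric columns,
#'   kappa to 3 decimals, and prevalence columns with CI pairs.
#' @export
validation_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    mt <- r$metrics; pc <- r$prevalence_clinical; ps <- r$prevalence_survey
    data.frame(
      condition_id = r$condition_id,
      sensitivity = fmt_metric(mt[["sensitivity"]]),
      specificity = fmt_metric(mt[["specificity"]]),
      ppv = fmt_metric(mt[["ppv"]]), npv = fmt_metric(mt[["npv"]]),
      prev_clinical = pc[["point"]],
      prev_clinical_ci = sprintf("(%d/%d)", pc[["lower"]], pc[["upper"]]),
      prev_survey = ps[["point"]],
      prev_survey_ci = sprintf("(%d/%d)", ps[["lower"]], ps[["upper"]]),
      kappa = sprintf("%.3f", r$kappa),
      non_response_pct = r$non_response_pct,
      stringsAsFactors = FALSE)
  }))
}
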