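# End-to-end pipeline driver and config handling.
#
# A run config (YAML or JSON) selects exactly one input mode:
#   files:    read an existing four-CSV cohort directory;
#   generate: simulate a cohort (cohort_config block);
#   plant:    engineer cohorts reproducing specified 2x2 cell counts,
#             one block per condition.
# Flags mirror the analysis knobs: icd_prefix_matching, min_gp_events,
# ci_method, prevalence_denominator_policy, clinical_numerator_policy,
# drop_fuzzy, gp_coverage.

default_flags <- function() list(
  icd_prefix_matching = TRUE, min_gp_events = 1, ci_method = "wald",
  prevalence_denominator_policy = "all_matched",
  clinical_numerator_policy = "contingency", drop_fuzzy = FALSE,
  gp_coverage = 0.8)

#' Load and validate a pipeline run configuration
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return validated config list (class `run_config`).
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

#' @rdname load_run_config
#' @param cfg a config list built in code.
#' @export
validate_run_config <- function(cfg) {
  modes <- intersect(c("files", "generate", "plant"), names(cfg))
  if (length(modes) != 1)
    stop("config error: exactly one input mode (files | generate | plant) ",
         "must be given; found: ",
         if (length(modes)) paste(modes, collapse = ", ") else "none")
  cfg$mode <- modes
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$flags <- utils::modifyList(default_flags(), cfg$flags %||% list())
  ok_ci <- cfg$flags$ci_method %in% c("wald", "wilson")
  ok_den <- cfg$flags$prevalence_denominator_policy %in%
    c("all_matched", "valid_only")
  ok_num <- cfg$flags$clinical_numerator_policy %in%
    c("contingency", "all_identified")
  if (!ok_ci || !ok_den || !ok_num)
    stop("config error: unknown flag value in ",
         paste(c("ci_method", "prevalence_denominator_policy",
                 "clinical_numerator_policy")[!c(ok_ci, ok_den, ok_num)],
               collapse = ", "))
  if (cfg$mode == "plant") {
    for (id in names(cfg$plant)) {
      b <- cfg$plant[[id]]
      need <- c("tp", "fp", "fn", "tn", "no_answer")
      if (!all(need %in% names(b)))
        stop("config error: plant block ", sQuote(id), " missing ",
             paste(setdiff(need, names(b)), collapse = ", "))
    }
  }
  if (cfg$mode == "files" && is.null(cfg$files$dir))
    stop("config error: files mode needs files$dir")
  structure(cfg, class = c("run_config", "list"))
}

resolve_code_sets <- function(cfg) {
  if (is.null(cfg$code_sets)) demo_code_sets()
  else load_code_sets(cfg$code_sets)
}

build_generate_config <- function(cfg) {
  g <- cfg$generate
  conds <- lapply(g$conditions %||% list(asthma = list()),
                  function(b) do.call(condition_sim, b))
  cohort_config(
    n_persons = g$n_persons %||% 11323, seed = cfg$seed, conditions = conds,
    gp_coverage = cfg$flags$gp_coverage,
    condition_correlation = g$condition_correlation %||% 0)
}

#' Run the full validation pipeline from a config
#'
#' Stages: acquire the cohort (read, generate, or plant), build the platform
#' file, ascertain cases per condition, attribute sources and estimate the
#' GP-coverage undercount, build contingency matrices, and compute the
#' validation reports. All artifacts are written under `out_dir` as CSV/JSON
#' with a `run.log`; warnings are logged, never dropped.
#'
#' @param config a `run_config` (from [load_run_config()] /
#'   [validate_run_config()]) or a path to one.
#' @param out_dir output directory (default `config$out_dir`, else tempdir).
#' @return invisibly, a list with `platforms`, `tags`, `attributions`,
#'   `matrices`, `reports`, `table` (the summary-table analogue).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- load_run_config(config)
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  out_dir <- out_dir %||% config$out_dir %||% tempfile("phenolink_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(out_dir, "run.log")
  cat("", file = log_file)
  cfg_hash <- digest::digest(unclass(config))
  log_msg("run start: mode=%s seed=%d config_hash=%s", config$mode,
          config$seed, cfg_hash, log_file = log_file)

  code_sets <- resolve_code_sets(config)
  flags <- config$flags
  withCallingHandlers({
    if (config$mode == "plant") {
      condition_ids <- names(config$plant)
      platforms <- list()
      for (id in condition_ids) {
        b <- config$plant[[id]]
        cs <- code_sets$sets[[id]]
        if (is.null(cs)) stop("plant stage: no code set for ", sQuote(id))
        sc <- if (!is.null(b$source_counts)) unlist(b$source_counts)
        cohort <- plant_contingency(
          b$tp, b$fp, b$fn, b$tn, b$no_answer, cs, seed = config$seed,
          no_answer_cases = b$no_answer_cases %||% 0, source_counts = sc,
          gp_coverage = flags$gp_coverage)
        write_cohort(cohort, file.path(out_dir, paste0("cohort_", id)))
        platforms[[id]] <- build_platform(cohort, drop_fuzzy = flags$drop_fuzzy)
        write_platform(platforms[[id]], file.path(out_dir, paste0("platform_", id)))
        log_msg("plant[%s]: %d persons", id, nrow(platforms[[id]]$persons),
                log_file = log_file)
      }
    } else {
      cohort <- if (config$mode == "generate") {
        cc <- build_generate_config(config)
        log_msg("generate: n=%d conditions=%s", cc$n_persons,
                paste(names(cc$conditions), collapse = ","),
                log_file = log_file)
        generate_cohort(cc, code_sets)
      } else read_cohort(config$files$dir)
      if (config$mode == "generate")
        write_cohort(cohort, file.path(out_dir, "cohort"))
      condition_ids <- intersect(unique(cohort$survey$condition_id),
                                 names(code_sets$sets))
      platform <- build_platform(cohort, drop_fuzzy = flags$drop_fuzzy)
      write_platform(platform, file.path(out_dir, "platform"))
      log_msg("platform: %d persons retained", nrow(platform$persons),
              log_file = log_file)
      platforms <- stats::setNames(rep(list(platform), length(condition_ids)),
                                   condition_ids)
    }

    conflicts <- validate_exclusivity(code_sets)
    if (nrow(conflicts)) {
      utils::write.csv(conflicts, file.path(out_dir, "exclusivity_conflicts.csv"),
                       row.names = FALSE)
      warning(nrow(conflicts), " code exclusivity conflict(s); see ",
              "exclusivity_conflicts.csv", call. = FALSE)
    }

    tags <- list(); attributions <- list(); matrices <- list(); reports <- list()
    attr_rows <- list(); nr_rows <- list()
    for (id in condition_ids) {
      pf <- platforms[[id]]
      tg <- ascertain(pf, code_sets$sets[[id]],
                      icd_prefix_matching = flags$icd_prefix_matching,
                      min_gp_events = flags$min_gp_events)
      tags[[id]] <- tg
      at <- attribute_sources(tg, id)
      attributions[[id]] <- at
      uc <- coverage_undercount(at$gp_only, flags$gp_coverage)
      attr_rows[[id]] <- data.frame(
        condition_id = id, gp_only = at$gp_only,
        hospital_only = at$hospital_only, both = at$both, total = at$total,
        pct_gp_only = at$percentages[["gp_only"]],
        pct_hospital_only = at$percentages[["hospital_only"]],
        pct_both = at$percentages[["both"]],
        coverage = flags$gp_coverage, est_undercount = uc,
        stringsAsFactors = FALSE)
      m <- build_contingency(pf$survey, tg, id)
      matrices[[id]] <- m
      utils::write.csv(
        data.frame(survey = c("yes", "no"), clinical_yes = c(m$tp, m$fn),
                   clinical_no = c(m$fp, m$tn),
                   total = c(m$tp + m$fp, m$fn + m$tn)),
        file.path(out_dir, paste0("contingency_", id, ".csv")),
        row.names = FALSE)
      reports[[id]] <- validate_condition(
        m, n_clinical_total = at$total,
        prevalence_denominator_policy = flags$prevalence_denominator_policy,
        clinical_numerator_policy = flags$clinical_numerator_policy,
        ci_method = flags$ci_method)
      nr_rows[[id]] <- data.frame(condition_id = id, no_answer = m$no_answer,
                                  n_total = m$n_total,
                                  pct = non_response_rate(m$no_answer, m$n_total),
                                  stringsAsFactors = FALSE)
      log_msg("validate[%s]: 2x2=(%d,%d,%d,%d) no_answer=%d kappa=%.3f", id,
              m$tp, m$fp, m$fn, m$tn, m$no_answer, reports[[id]]$kappa,
              log_file = log_file)
    }

    all_tags <- do.call(rbind, unname(tags))
    all_tags$first_event_date <- as.character(all_tags$first_event_date)
    utils::write.csv(all_tags, file.path(out_dir, "case_tags.csv"),
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, unname(attr_rows)),
                     file.path(out_dir, "source_attribution.csv"),
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, unname(nr_rows)),
                     file.path(out_dir, "non_response.csv"), row.names = FALSE)
    tab <- validation_table(reports)
    utils::write.csv(tab, file.path(out_dir, "validation_report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      lapply(reports, function(r) list(
        condition_id = r$condition_id,
        matrix = r$matrix[c("tp", "fp", "fn", "tn", "no_answer")],
        metrics = as.list(r$metrics), kappa = r$kappa,
        prevalence_clinical = as.list(r$prevalence_clinical),
        prevalence_survey = as.list(r$prevalence_survey),
        non_response_pct = r$non_response_pct, policies = r$policies)),
      file.path(out_dir, "validation_report.json"), auto_unbox = TRUE,
      pretty = TRUE, digits = NA)
    log_msg("run complete: %d condition(s), artifacts in %s",
            length(condition_ids), out_dir, log_file = log_file)

    invisible(list(platforms = platforms, tags = tags,
                   attributions = attributions, matrices = matrices,
                   reports = reports, table = tab, out_dir = out_dir))
  }, warning = function(w) {
    log_msg("warning: %s", conditionMessage(w), log_file = log_file)
    invokeRestart("muffleWarning")
  })
}

#' Command-line entry point
#'
#' Drives the pipeline from a shell:
#' `Rscript -e 'phenolink::phenolink_main()' <subcommand> --config cfg.yaml
#' --out dir [--seed N]`, or via the wrapper script installed at
#' `system.file("cli", "phenolink.R", package = "phenolink")`. Subcommands
#' `generate`, `plant`, `phenotype`, `validate`, `report` and `all` currently
#' run the stages up to and including the named one (artifacts of earlier
#' stages are always written).
#'
#' @param args command-line arguments (default `commandArgs(trailingOnly)`).
#' @return exit status 0 on success (invisibly); errors propagate with a
#'   stage-named message.
#' @export
phenolink_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  subcommands <- c("generate", "plant", "phenotype", "validate", "report", "all")
  if (length(args) == 0 || !args[1] %in% subcommands)
    stop("usage: phenolink <", paste(subcommands, collapse = "|"),
         "> --config <file> [--out <dir>] [--seed <int>]")
  sub <- args[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character"),
    optparse::make_option("--out", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NA)))
  opts <- optparse::parse_args(parser, args = args[-1])
  if (is.null(opts$config)) stop("--config is required")
  cfg <- load_run_config(opts$config)
  if (!is.na(opts$seed)) cfg$seed <- as.integer(opts$seed)
  if ((sub == "generate" && cfg$mode != "generate") ||
      (sub == "plant" && cfg$mode != "plant"))
    stop("subcommand ", sQuote(sub), " requires config mode ", sQuote(sub),
         " (found ", sQuote(cfg$mode), ")")
  run_pipeline(cfg, out_dir = opts$out)
  invisible(0L)
}
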