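#' Pipeline run configuration
#'
#' Validates the parameters of an end-to-end run: either a simulation
#' scenario or a pair of claims/patients CSV paths, the disease family,
#' and the grid of methods, periods and outcomes to evaluate.
#'
#' @param scenario scenario name/YAML path for [load_scenario()], or
#'   \code{NULL} when reading claims from files.
#' @param admissions_path,patients_path claims CSV paths (used when
#'   \code{scenario} is \code{NULL}).
#' @param disease \code{"AMI"} or \code{"COPD"}.
#' @param methods character vector of comorbidity method names.
#' @param periods character vector of period kinds.
#' @param outcomes character vector of outcomes.
#' @param n_patients cohort size for simulation (overrides the scenario).
#' @param n_bootstrap bootstrap replications per model (>= 1).
#' @param comparisons also run paired bootstrap comparisons between
#'   methods.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(scenario = "ami",
                       admissions_path = NULL, patients_path = NULL,
                       disease = "AMI",
                       methods = c("charlson_deyo", "charlson_romano",
                                   "elixhauser"),
                       periods = c("index_only", "index_plus_prior"),
                       outcomes = c("in_hospital", "one_year"),
                       n_patients = NULL,
                       n_bootstrap = 200L,
                       comparisons = TRUE,
                       seed = 1L) {
  if (length(methods) < 1L || length(periods) < 1L || length(outcomes) < 1L) {
    stop("config needs at least one method, period and outcome",
         call. = FALSE)
  }
  stopifnot(n_bootstrap >= 1L)
  stopifnot(all(methods %in% c("charlson_deyo", "charlson_romano",
                               "elixhauser")),
            all(periods %in% c("index_only", "index_plus_prior")),
            all(outcomes %in% c("in_hospital", "one_year")))
  if (is.null(scenario) &&
      (is.null(admissions_path) || is.null(patients_path))) {
    stop("either a scenario or both claims file paths are required",
         call. = FALSE)
  }
  structure(list(scenario = scenario,
                 admissions_path = admissions_path,
                 patients_path = patients_path,
                 disease = disease, methods = methods, periods = periods,
                 outcomes = outcomes, n_patients = n_patients,
                 n_bootstrap = as.integer(n_bootstrap),
                 comparisons = isTRUE(comparisons),
                 seed = as.integer(seed)),
            class = "run_config")
}

audit_log <- function(con, stage, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
}

#' Run the full evaluation pipeline
#'
#' Executes simulate (or read) -> cohort build -> comorbidity mapping per
#' (method, period) -> model evaluation per (outcome, method, period) ->
#' paired method comparisons, writing every intermediate and final table
#' under \code{out_dir}:
#' \code{cohort.csv}, \code{exclusions.json}, \code{table1.csv}, one
#' \code{comorbidity_matrix_<method>_<period>.csv} per mapping,
#' \code{evaluation_results.csv}, \code{comparisons.csv} and a JSON-lines
#' \code{audit.jsonl}. Identical config and seed yield byte-identical
#' outputs.
#'
#' @param config a [run_config()] (or a YAML path/list with its fields).
#' @param out_dir output directory.
#' @return invisibly, the evaluation results data.frame.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(out_dir, "audit.jsonl"), open = "wt")
  on.exit(close(con), add = TRUE)
  audit_log(con, "start", seed = config$seed,
            package_version = as.character(utils::packageVersion("comorbidikit")))

  if (!is.null(config$scenario)) {
    cfg <- load_scenario(config$scenario, n_patients = config$n_patients,
                         seed = config$seed)
    sim <- simulate_population(cfg)
    dataset <- sim$dataset
    config$disease <- cfg$disease  # the scenario defines the population
    audit_log(con, "simulate", scenario = config$scenario,
              n_patients = cfg$n_patients)
  } else {
    dataset <- read_claims(config$admissions_path, config$patients_path)
    audit_log(con, "read_claims", admissions = config$admissions_path)
  }

  cohort <- build_cohort(dataset, disease_definition(config$disease))
  if (nrow(cohort) == 0L) {
    stop("cohort_builder: no patients retained", call. = FALSE)
  }
  write_df <- function(df, file) {
    utils::write.csv(df, file.path(out_dir, file), row.names = FALSE, na = "")
  }
  cohort_out <- cohort
  cohort_out$admit_date <- format(cohort_out$admit_date)
  cohort_out$discharge_date <- format(cohort_out$discharge_date)
  write_df(cohort_out, "cohort.csv")
  ledger <- attr(cohort, "exclusion_ledger")
  jsonlite::write_json(as.list(ledger), file.path(out_dir, "exclusions.json"),
                       auto_unbox = TRUE)
  write_df(table1_summary(dataset, cohort), "table1.csv")
  audit_log(con, "cohort", n = nrow(cohort),
            excluded = sum(ledger))

  profiles <- list()
  for (m in config$methods) {
    method <- load_method(m)
    for (p in config$periods) {
      mat <- profile_matrix(cohort, dataset, method, p)
      profiles[[paste(m, p, sep = ".")]] <- mat
      write_df(cbind(data.frame(patient_id = rownames(mat)),
                     as.data.frame(mat)),
               sprintf("comorbidity_matrix_%s_%s.csv", m, p))
      audit_log(con, "map", method = m, period = p,
                flagged = sum(mat))
    }
  }

  fmt <- function(x, d = 6) formatC(x, digits = d, format = "f")
  rows <- list(); fits <- list()
  seed_i <- 0L
  for (o in config$outcomes) {
    base <- comorbidity_model(cohort, outcome = o, method = NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      population = config$disease, outcome = o, period = "",
      method = "baseline", n = base$fit$n, events = sum(base$y),
      g2 = NA, df_diff = NA, df_total = base$fit$n_parameters, p = NA,
      c = fmt(base$c_statistic), ci_low = NA, ci_high = NA,
      n_reps = 0L, dropped = "", stringsAsFactors = FALSE)
    for (m in config$methods) {
      method <- load_method(m)
      for (p in config$periods) {
        seed_i <- seed_i + 1L
        fit <- comorbidity_model(
          cohort, outcome = o, method = method, period = p,
          profile = profiles[[paste(m, p, sep = ".")]],
          n_bootstrap = config$n_bootstrap,
          seed = config$seed + seed_i)
        fits[[paste(o, m, p, sep = ".")]] <- fit
        rows[[length(rows) + 1L]] <- data.frame(
          population = config$disease, outcome = o, period = p,
          method = m, n = fit$fit$n, events = sum(fit$y),
          g2 = fmt(fit$g2$g2, 3), df_diff = fit$g2$df_diff,
          df_total = fit$g2$df_total, p = fmt(fit$g2$p, 8),
          c = fmt(fit$c_statistic),
          ci_low = fmt(fit$ci[1]), ci_high = fmt(fit$ci[2]),
          n_reps = fit$n_bootstrap,
          dropped = paste(fit$dropped, collapse = ";"),
          stringsAsFactors = FALSE)
        audit_log(con, "evaluate", outcome = o, method = m, period = p,
                  c_statistic = fit$c_statistic)
      }
    }
  }
  results <- do.call(rbind, rows)
  write_df(results, "evaluation_results.csv")

  if (config$comparisons && length(config$methods) > 1L) {
    comp_rows <- list()
    pairs <- utils::combn(config$methods, 2, simplify = FALSE)
    for (o in config$outcomes) {
      y <- if (o == "in_hospital") cohort$died_in_hospital else
        cohort$died_within_1yr
      base_design <- cbind(age = cohort$age_years,
                           male = as.numeric(cohort$male),
                           aborigine = as.numeric(cohort$aborigine),
                           surgery = as.numeric(cohort$surgery))
      for (p in config$periods) {
        for (pr in pairs) {
          seed_i <- seed_i + 1L
          da <- cbind(base_design, profiles[[paste(pr[1], p, sep = ".")]])
          db <- cbind(base_design, profiles[[paste(pr[2], p, sep = ".")]])
          cmp <- paired_bootstrap_compare(
            da, db, y, n_reps = config$n_bootstrap,
            seed = config$seed + seed_i)
          comp_rows[[length(comp_rows) + 1L]] <- data.frame(
            population = config$disease, outcome = o, period = p,
            method_a = pr[1], method_b = pr[2],
            win_frac_a = fmt(cmp$win_frac_a, 4),
            tie_frac = fmt(cmp$ties, 4),
            mean_c_diff = fmt(mean(cmp$diff)),
            n_reps = config$n_bootstrap, stringsAsFactors = FALSE)
        }
      }
    }
    write_df(do.call(rbind, comp_rows), "comparisons.csv")
  }
  audit_log(con, "done", models = length(fits))
  invisible(results)
}

na_or <- function(x, f) if (is.na(x) || x == "") "N/A" else f(x)

#' Render human-readable report tables
#'
#' Turns the result CSVs of [run_pipeline()] into a Markdown report with a
#' cohort-characteristics table, a G-squared (df) grid, a c (95% CI) grid
#' formatted as \code{0.737 (0.729-0.753)}, and the pairwise win-fraction
#' summary. Every number is read from the CSVs; nothing is recomputed.
#' Missing strata render as \code{N/A} with a warning.
#'
#' @param out_dir directory written by [run_pipeline()].
#' @param file optional path for the report (default
#'   \code{out_dir/report.md}); \code{NULL} to skip writing.
#' @return the report as a character vector of lines, invisibly.
#' @export
render_tables <- function(out_dir, file = file.path(out_dir, "report.md")) {
  res_path <- file.path(out_dir, "evaluation_results.csv")
  if (!file.exists(res_path)) {
    stop("no evaluation_results.csv under ", out_dir, call. = FALSE)
  }
  res <- utils::read.csv(res_path, stringsAsFactors = FALSE)
  lines <- c("# Comorbidity measure evaluation", "")

  t1_path <- file.path(out_dir, "table1.csv")
  if (file.exists(t1_path)) {
    t1 <- utils::read.csv(t1_path, stringsAsFactors = FALSE)
    lines <- c(lines, "## Cohort characteristics", "",
               "| Characteristic | Value |", "|---|---|")
    for (i in seq_len(nrow(t1))) {
      v <- if (!is.na(t1$count[i]) && !is.na(t1$percent[i])) {
        sprintf("%d (%.2f%%)", t1$count[i], t1$percent[i])
      } else if (!is.na(t1$mean[i])) {
        sprintf("%.2f ± %.2f", t1$mean[i], t1$sd[i])
      } else {
        sprintf("%d", t1$count[i])
      }
      lines <- c(lines, sprintf("| %s | %s |", t1$characteristic[i], v))
    }
    lines <- c(lines, "")
  }

  outcomes <- unique(res$outcome)
  periods <- setdiff(unique(res$period), "")
  methods <- setdiff(unique(res$method), "baseline")
  cell <- function(o, p, m, f) {
    r <- res[res$outcome == o & res$method == m &
               (m == "baseline" | res$period == p), , drop = FALSE]
    if (nrow(r) == 0L) {
      warning("missing stratum: ", paste(o, p, m), call. = FALSE)
      return("N/A")
    }
    f(r[1, ])
  }
  g2_cell <- function(r) {
    if (is.na(r$g2) || r$g2 == "") sprintf("N/A (%d)", r$df_total)
    else sprintf("%.0f (%d)", as.numeric(r$g2), r$df_total)
  }
  c_cell <- function(r) {
    if (is.na(r$ci_low) || r$ci_low == "") sprintf("%.3f", as.numeric(r$c))
    else sprintf("%.3f (%.3f-%.3f)", as.numeric(r$c),
                 as.numeric(r$ci_low), as.numeric(r$ci_high))
  }
  grid <- function(title, f) {
    out <- c(sprintf("## %s", title), "",
             paste0("| Model | ", paste(outcomes, collapse = " | "), " |"),
             paste0("|---", strrep("|---", length(outcomes)), "|"),
             paste0("| Baseline | ",
                    paste(vapply(outcomes, function(o)
                      cell(o, "", "baseline", f), character(1)),
                      collapse = " | "), " |"))
    for (p in periods) {
      out <- c(out, paste0("| **", p, "** |",
                           strrep(" |", length(outcomes))))
      for (m in methods) {
        out <- c(out, paste0("| Baseline + ", m, " | ",
                             paste(vapply(outcomes, function(o)
                               cell(o, p, m, f), character(1)),
                               collapse = " | "), " |"))
      }
    }
    c(out, "")
  }
  lines <- c(lines,
             grid("G-squared statistics, G2 (total df)", g2_cell),
             grid("C-statistics, c (95% CI)", c_cell))

  cmp_path <- file.path(out_dir, "comparisons.csv")
  if (file.exists(cmp_path)) {
    cmp <- utils::read.csv(cmp_path, stringsAsFactors = FALSE)
    lines <- c(lines, "## Paired bootstrap comparisons", "",
               paste("| Outcome | Period | A | B | frac(c_A > c_B) |"),
               "|---|---|---|---|---|")
    for (i in seq_len(nrow(cmp))) {
      lines <- c(lines, sprintf("| %s | %s | %s | %s | %.3f |",
                                cmp$outcome[i], cmp$period[i],
                                cmp$method_a[i], cmp$method_b[i],
                                cmp$win_frac_a[i]))
    }
    lines <- c(lines, "")
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
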