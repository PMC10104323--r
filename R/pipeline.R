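#' Configuration for an end-to-end screening run
#'
#' Exactly one input source must be given: either generator parameters
#' (synthetic trial) or the path of an existing tidy trial CSV.
#'
#' @param design A [trial_design()].
#' @param params A [generator_params()], or `NULL` when reading a table.
#' @param input Path to a canonical trial CSV, or `NULL` when generating.
#' @param traits Traits for the CV analysis (default: the six
#'   morphological traits).
#' @param theta Consistency threshold for parent-pair selection.
#' @param correction Multiple-testing correction for the significance
#'   table (`"none"` or `"holm"`).
#' @param outdir Output directory (created if absent).
#' @param seed Integer seed (used only when generating).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(design, params = NULL, input = NULL,
                            traits = morph_traits(), theta = 0.7,
                            correction = "none", outdir = tempfile("kscreen_"),
                            seed = 1) {
  stopifnot(inherits(design, "trial_design"))
  if (is.null(params) == is.null(input)) {
    abort("Exactly one of `params` (generator) or `input` (trial CSV) must be given.")
  }
  if (!is.null(params)) stopifnot(inherits(params, "generator_params"))
  structure(list(design = design, params = params, input = input,
                 traits = traits, theta = theta, correction = correction,
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full screening pipeline
#'
#' Composes the stages in analysis order: obtain observations (generate or
#' read), validate against the design, summarize treatments, compute
#' relative traits, CV profiles and the optimal screening concentration,
#' rank tolerance and select the parent pair, annotate the pair's
#' significance table, and assemble the per-variety index reports.
#' Deterministic given the config (including seed).
#'
#' Writes under `config$outdir`: `trial.csv` (when generated), `truth.json`
#' (planted ground truth, when generated), `indices.csv`,
#' `cv_profile.csv`, `relative_traits.csv`, `screening.json`, and
#' `run_log.txt` (package version, seed, config hash).
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages (default TRUE).
#' @return Invisibly, a list: `observations`, `summary`, `cv`, `optimal`,
#'   `ranking`, `pair`, `significance`, `indices`, `relative`, `truth`
#'   (NULL for file input), `paths`.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  design <- config$design
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$outdir, "run_log.txt")
  log_lines <- character(0)
  say <- function(stage, msg) {
    line <- sprintf("[%s] %s", stage, msg)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  say("config", sprintf("seed=%d hash=%s", config$seed, rlang::hash(
    list(unclass(design), if (is.null(config$params)) config$input
         else unclass(config$params), config$traits, config$theta,
         config$correction, config$seed))))

  truth <- NULL
  paths <- list(log = log_path)
  obs <- stage("input", {
    if (!is.null(config$params)) {
      truth <- planted_truth(config$params, design, traits = config$traits)
      paths$trial <- file.path(config$outdir, "trial.csv")
      paths$truth <- file.path(config$outdir, "truth.json")
      o <- generate_trial(design, config$params, seed = config$seed)
      write_trial_table(o, paths$trial)
      jsonlite::write_json(
        list(ranking = truth$ranking, s = as.list(truth$s),
             cv_argmax = truth$cv_argmax, consensus = truth$consensus),
        paths$truth, auto_unbox = TRUE, digits = NA)
      say("input", sprintf("generated %d plants (seed %d)", nrow(o), config$seed))
      o
    } else {
      o <- read_trial_table(config$input)
      say("input", sprintf("read %d plants from %s", nrow(o), config$input))
      o
    }
  })

  problems <- stage("validate", validate_trial(obs, design))
  if (nrow(problems) > 0) {
    say("validate", sprintf("%d finding(s); first: %s", nrow(problems),
                            problems$message[1]))
  } else {
    say("validate", "table is a complete, valid realization of the design")
  }

  summary <- stage("summarize", summarize_treatments(obs))
  rel <- stage("relative", relative_traits(summary, design, config$traits))
  cvp <- stage("cv", cv_profile(summary, config$traits))
  opt <- stage("cv", optimal_concentration(
    cvp, reference = design$reference_concentration))
  say("cv", sprintf("consensus optimal screening concentration: %g mg/L",
                    opt$consensus))
  ranking <- stage("ranking", rank_tolerance(summary, design))
  pair <- stage("ranking", select_parent_pair(ranking, theta = config$theta))
  say("ranking", sprintf("tolerant: %s, sensitive: %s",
                         pair$tolerant, pair$sensitive))
  sig <- stage("significance", significance_table(
    obs, c(pair$tolerant, pair$sensitive), design, traits = config$traits,
    correction = config$correction))
  indices <- stage("indices", index_report_all(summary, design))

  paths$indices <- file.path(config$outdir, "indices.csv")
  paths$cv_profile <- file.path(config$outdir, "cv_profile.csv")
  paths$relative <- file.path(config$outdir, "relative_traits.csv")
  paths$screening <- file.path(config$outdir, "screening.json")
  readr::write_csv(indices, paths$indices)
  readr::write_csv(cvp, paths$cv_profile)
  readr::write_csv(rel, paths$relative)
  jsonlite::write_json(
    list(optimal_concentration = opt$consensus,
         per_trait = opt$per_trait,
         ranking = ranking,
         tolerant = pair$tolerant, sensitive = pair$sensitive,
         theta_used = pair$theta_used, relaxed = pair$relaxed,
         significance = sig),
    paths$screening, auto_unbox = TRUE, digits = NA)
  writeLines(c(sprintf("kscreen %s", as.character(utils::packageVersion("kscreen"))),
               log_lines), log_path)
  say("done", sprintf("outputs in %s", config$outdir))

  invisible(list(observations = obs, summary = summary, cv = cvp,
                 optimal = opt, ranking = ranking, pair = pair,
                 significance = sig, indices = indices, relative = rel,
                 truth = truth, problems = problems, paths = paths))
}
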