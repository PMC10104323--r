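#' Define a hydroponic screening trial design
#'
#' A trial design fixes the treatment grid of a variety screening experiment:
#' which varieties are grown, the potassium concentrations of the culture
#' medium, which level serves as the potassium-replete reference for relative
#' values, which two low levels feed the response index, and the replication
#' structure.
#'
#' The default grid follows common practice for low-K screening of rice
#' seedlings: ten K levels from starvation (0 mg/L) to saturating
#' (60 mg/L), a 40 mg/L reference ("normal potassium"), 1 mg/L as the
#' very-low and 4 mg/L as the low screening level, three replicate trays of
#' six plants each, grown for four weeks.
#'
#' @param varieties Character vector of variety identifiers.
#' @param concentrations Numeric vector of medium K concentrations (mg/L).
#'   Must be unique and nonnegative; stored sorted ascending.
#' @param reference_concentration K-replete reference level (mg/L); relative
#'   values are ratios to the trait value at this level.
#' @param very_low_concentration Very-low K level (mg/L) used by the 1-K
#'   indices and the response-index denominator.
#' @param low_concentration Low K screening level (mg/L) used by the 4-K
#'   indices.
#' @param replicates Number of replicate trays per variety and level (>= 2).
#' @param plants_per_replicate Plants measured per replicate tray (>= 1).
#' @param duration_days Treatment duration in days (>= 1); enters the
#'   potassium absorption rate.
#'
#' @return An object of class `trial_design` (a named list of the fields
#'   above, with `concentrations` sorted).
#' @export
#' @examples
#' d <- trial_design(varieties = c("A", "B"))
#' d$reference_concentration
trial_design <- function(varieties,
                         concentrations = c(0, 1, 2, 3, 4, 5, 10, 20, 40, 60),
                         reference_concentration = 40,
                         very_low_concentration = 1,
                         low_concentration = 4,
                         replicates = 3,
                         plants_per_replicate = 6,
                         duration_days = 28) {
  varieties <- as.character(varieties)
  if (length(varieties) < 1 || anyDuplicated(varieties)) {
    abort("`varieties` must be a nonempty vector of unique identifiers.")
  }
  concentrations <- as.numeric(concentrations)
  if (anyDuplicated(concentrations) || any(concentrations < 0) ||
      any(!is.finite(concentrations))) {
    abort("`concentrations` must be unique, finite and nonnegative.")
  }
  concentrations <- sort(concentrations)
  for (lvl in c(reference_concentration, very_low_concentration, low_concentration)) {
    if (!lvl %in% concentrations) {
      abort(sprintf("Level %s mg/L is not among the design concentrations.", lvl))
    }
  }
  if (replicates < 2) abort("`replicates` must be at least 2.")
  if (plants_per_replicate < 1) abort("`plants_per_replicate` must be at least 1.")
  if (duration_days < 1) abort("`duration_days` must be at least 1.")
  structure(
    list(
      varieties = varieties,
      concentrations = concentrations,
      reference_concentration = as.numeric(reference_concentration),
      very_low_concentration = as.numeric(very_low_concentration),
      low_concentration = as.numeric(low_concentration),
      replicates = as.integer(replicates),
      plants_per_replicate = as.integer(plants_per_replicate),
      duration_days = as.numeric(duration_days)
    ),
    class = "trial_design"
  )
}

#' @export
print.trial_design <- function(x, ...) {
  cat("<trial_design>\n")
  cat("  varieties:           ", paste(x$varieties, collapse = ", "), "\n")
  cat("  K levels (mg/L):     ", paste(x$concentrations, collapse = ", "), "\n")
  cat(sprintf("  reference / low / very low: %g / %g / %g mg/L\n",
              x$reference_concentration, x$low_concentration,
              x$very_low_concentration))
  cat(sprintf("  replication:          %d replicates x %d plants, %g days\n",
              x$replicates, x$plants_per_replicate, x$duration_days))
  invisible(x)
}

#' Read or write a trial design as a YAML/JSON config file
#'
#' The design is serialized as a flat mapping of the `trial_design` fields.
#' The format is chosen by file extension: `.yaml`/`.yml` or `.json`.
#'
#' @param path File path.
#' @return `read_design()` returns a `trial_design`; `write_design()` returns
#'   `path` invisibly.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) abort(sprintf("Design file not found: %s", path))
  fields <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  needed <- c("varieties", "concentrations", "reference_concentration",
              "very_low_concentration", "low_concentration", "replicates",
              "plants_per_replicate", "duration_days")
  missing <- setdiff(needed, names(fields))
  if (length(missing) > 0) {
    abort(sprintf("Design file is missing field(s): %s",
                  paste(missing, collapse = ", ")))
  }
  do.call(trial_design, fields[needed])
}

#' @param design A `trial_design`.
#' @rdname read_design
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "trial_design"))
  x <- unclass(design)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}
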