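#' Canonical column schema of a tidy trial table
#'
#' One row per plant. Units are encoded in the column names: lengths in cm,
#' weights in g, tissue potassium concentrations in g K per 100 g dry weight.
#'
#' @return Character vector of the sixteen canonical column names, in order.
#' @export
trial_columns <- function() {
  c("variety", "concentration_mg_per_l", "replicate", "plant",
    "plant_height_cm", "root_length_cm", "root_number",
    "fresh_weight_root_g", "fresh_weight_sheath_g", "fresh_weight_blade_g",
    "dry_weight_root_g", "dry_weight_sheath_g", "dry_weight_blade_g",
    "k_conc_root_g_per_100g", "k_conc_sheath_g_per_100g",
    "k_conc_blade_g_per_100g")
}

#' Morphological trait columns used in the screening analyses
#'
#' The six measured growth parameters: plant height, root length, root
#' number, and the fresh weights of root, sheath and blade.
#'
#' @return Character vector of six column names.
#' @export
morph_traits <- function() {
  c("plant_height_cm", "root_length_cm", "root_number",
    "fresh_weight_root_g", "fresh_weight_sheath_g", "fresh_weight_blade_g")
}

#' The three traits used for the tolerance ranking
#'
#' Plant height and the fresh weights of sheath and blade: height is the
#' most visible growth indicator, and aboveground biomass integrates the
#' K-limited photosynthetic capacity of the shoot.
#'
#' @return Character vector of three column names.
#' @export
ranking_traits <- function() {
  c("plant_height_cm", "fresh_weight_sheath_g", "fresh_weight_blade_g")
}

#' Read a tidy per-plant trial table from CSV
#'
#' The file must carry exactly the canonical header (see [trial_columns()]);
#' every non-key column must be numeric, and the
#' (variety, concentration, replicate, plant) key must be unique. Row order
#' is preserved.
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per plant and the canonical columns.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Trial table not found: %s", path))
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                                  name_repair = "minimal"))
  missing <- setdiff(trial_columns(), header)
  if (length(missing) > 0) {
    abort(sprintf("Trial table schema error: missing column(s) %s",
                  paste(missing, collapse = ", ")))
  }
  extra <- setdiff(header, trial_columns())
  if (length(extra) > 0) {
    abort(sprintf("Trial table schema error: unexpected column(s) %s",
                  paste(extra, collapse = ", ")))
  }
  obs <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  obs <- obs[, trial_columns()]
  # parse numbers with base R (correctly rounded) so values round-trip
  # bit-exactly through write_trial_table()
  for (col in setdiff(trial_columns(), "variety")) {
    parsed <- suppressWarnings(as.numeric(obs[[col]]))
    bad <- which(is.na(parsed) & !is.na(obs[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("Trial table parse error at row %d, column '%s': got '%s'",
                    bad[1], col, obs[[col]][bad[1]]))
    }
    obs[[col]] <- if (col %in% c("replicate", "plant")) {
      as.integer(parsed)
    } else {
      parsed
    }
  }
  key <- paste(obs$variety, obs$concentration_mg_per_l, obs$replicate,
               obs$plant, sep = "\r")
  if (anyDuplicated(key)) {
    first <- which(duplicated(key))[1]
    abort(sprintf(
      "Duplicate (variety, concentration, replicate, plant) key at row %d: (%s, %g, %d, %d)",
      first, obs$variety[first], obs$concentration_mg_per_l[first],
      obs$replicate[first], obs$plant[first]))
  }
  obs
}

#' Write a tidy per-plant trial table to CSV
#'
#' Values are serialized with full precision so that
#' `read_trial_table(write_trial_table(x, path))` reproduces `x` exactly.
#'
#' @param observations Nonempty tibble with the canonical columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(observations, path) {
  if (!is.data.frame(observations) || nrow(observations) == 0) {
    abort("`observations` must be a nonempty trial table.")
  }
  missing <- setdiff(trial_columns(), names(observations))
  if (length(missing) > 0) {
    abort(sprintf("Trial table schema error: missing column(s) %s",
                  paste(missing, collapse = ", ")))
  }
  out <- observations[, trial_columns()]
  # serialize doubles via %.17g so that reading reproduces them bit-exactly
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Validate a trial table against its design
#'
#' All problems are collected and reported, never raised: missing
#' (variety, concentration, replicate) cells relative to the design grid,
#' per-plant invariant violations (negative weights, dry weight exceeding
#' fresh weight, tissue K concentration outside 0--10 g/100 g, non-integer
#' or negative root number), and varieties or concentrations absent from
#' the design.
#'
#' @param observations Trial table (canonical columns).
#' @param design A [trial_design()].
#' @return A tibble of findings with columns `check`, `variety`,
#'   `concentration`, `replicate`, `plant`, `message`. Zero rows iff the
#'   table is a complete, valid realization of the design.
#' @export
validate_trial <- function(observations, design) {
  stopifnot(inherits(design, "trial_design"))
  finding <- function(check, variety = NA_character_, concentration = NA_real_,
                      replicate = NA_integer_, plant = NA_integer_, message) {
    tibble::tibble(check = check, variety = variety,
                   concentration = concentration,
                   replicate = as.integer(replicate),
                   plant = as.integer(plant), message = message)
  }
  out <- list()

  unknown_v <- setdiff(unique(observations$variety), design$varieties)
  for (v in unknown_v) {
    out[[length(out) + 1]] <- finding("unknown_variety", variety = v,
      message = sprintf("Variety '%s' is not in the design.", v))
  }
  unknown_c <- setdiff(unique(observations$concentration_mg_per_l),
                       design$concentrations)
  for (cc in unknown_c) {
    out[[length(out) + 1]] <- finding("unknown_concentration",
      concentration = cc,
      message = sprintf("Concentration %g mg/L is not in the design.", cc))
  }

  expected <- tidyr::expand_grid(
    variety = design$varieties,
    concentration_mg_per_l = design$concentrations,
    replicate = seq_len(design$replicates)
  )
  present <- dplyr::distinct(observations, .data$variety,
                             .data$concentration_mg_per_l, .data$replicate)
  miss <- dplyr::anti_join(expected, present,
                           by = c("variety", "concentration_mg_per_l", "replicate"))
  for (i in seq_len(nrow(miss))) {
    out[[length(out) + 1]] <- finding("missing_cell",
      variety = miss$variety[i], concentration = miss$concentration_mg_per_l[i],
      replicate = miss$replicate[i],
      message = sprintf("No plants for (%s, %g mg/L, replicate %d).",
                        miss$variety[i], miss$concentration_mg_per_l[i],
                        miss$replicate[i]))
  }

  tissues <- c("root", "sheath", "blade")
  for (i in seq_len(nrow(observations))) {
    row <- observations[i, ]
    where <- function(msg) finding("invariant", variety = row$variety,
      concentration = row$concentration_mg_per_l, replicate = row$replicate,
      plant = row$plant, message = msg)
    for (t in tissues) {
      fw <- row[[paste0("fresh_weight_", t, "_g")]]
      dw <- row[[paste0("dry_weight_", t, "_g")]]
      kc <- row[[paste0("k_conc_", t, "_g_per_100g")]]
      if (fw < 0 || dw < 0) {
        out[[length(out) + 1]] <- where(sprintf("Negative %s weight.", t))
      }
      if (dw > fw) {
        out[[length(out) + 1]] <- where(sprintf(
          "Dry %s weight (%g g) exceeds fresh weight (%g g).", t, dw, fw))
      }
      if (kc < 0 || kc > 10) {
        out[[length(out) + 1]] <- where(sprintf(
          "%s K concentration %g g/100 g outside [0, 10].", t, kc))
      }
    }
    if (row$root_number < 0 || row$root_number != round(row$root_number)) {
      out[[length(out) + 1]] <- where("Root number is not a nonnegative integer.")
    }
  }

  if (length(out) == 0) {
    finding("none", message = character(0))[0, ]
  } else {
    dplyr::bind_rows(out)
  }
}

#' Summarize a trial table to treatment-level statistics
#'
#' Aggregation is two-stage, matching tray-level replication: plant values
#' are averaged within each replicate, then the mean, sample (n-1) standard
#' deviation and count are taken across replicate means for every
#' (variety, concentration). All numeric measurement columns are summarized,
#' plus two derived per-plant totals: `total_fresh_weight_g` and
#' `total_dry_weight_g` (sums over root, sheath, blade).
#'
#' @param observations Nonempty trial table (canonical columns).
#' @return A tibble of class `treatment_summary` with columns `variety`,
#'   `concentration`, `trait`, `mean`, `sd`, `n` (n = number of contributing
#'   replicates).
#' @export
summarize_treatments <- function(observations) {
  if (!is.data.frame(observations) || nrow(observations) == 0) {
    abort("`observations` must be a nonempty trial table.")
  }
  obs <- dplyr::mutate(
    observations,
    total_fresh_weight_g = .data$fresh_weight_root_g +
      .data$fresh_weight_sheath_g + .data$fresh_weight_blade_g,
    total_dry_weight_g = .data$dry_weight_root_g +
      .data$dry_weight_sheath_g + .data$dry_weight_blade_g
  )
  traits <- c(setdiff(trial_columns(),
                      c("variety", "concentration_mg_per_l", "replicate", "plant")),
              "total_fresh_weight_g", "total_dry_weight_g")
  long <- tidyr::pivot_longer(
    obs[, c("variety", "concentration_mg_per_l", "replicate", traits)],
    dplyr::all_of(traits), names_to = "trait", values_to = "value")
  rep_means <- dplyr::summarise(
    dplyr::group_by(long, .data$variety, .data$concentration_mg_per_l,
                    .data$replicate, .data$trait),
    value = mean(.data$value), .groups = "drop")
  out <- dplyr::summarise(
    dplyr::group_by(rep_means, .data$variety, .data$concentration_mg_per_l,
                    .data$trait),
    mean = mean(.data$value),
    sd = stats::sd(.data$value),
    n = dplyr::n(), .groups = "drop")
  out <- dplyr::rename(out, concentration = "concentration_mg_per_l")
  class(out) <- c("treatment_summary", class(out))
  out
}

#' Replicate-level means of every trait
#'
#' First-stage aggregation only (plants averaged within replicate); used by
#' the paired significance tests, which pair varieties by replicate index.
#'
#' @inheritParams summarize_treatments
#' @return Tibble with columns `variety`, `concentration`, `replicate`,
#'   `trait`, `value`.
#' @export
replicate_means <- function(observations) {
  if (!is.data.frame(observations) || nrow(observations) == 0) {
    abort("`observations` must be a nonempty trial table.")
  }
  traits <- setdiff(trial_columns(),
                    c("variety", "concentration_mg_per_l", "replicate", "plant"))
  long <- tidyr::pivot_longer(
    observations[, c("variety", "concentration_mg_per_l", "replicate", traits)],
    dplyr::all_of(traits), names_to = "trait", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$variety, .data$concentration_mg_per_l,
                    .data$replicate, .data$trait),
    value = mean(.data$value), .groups = "drop")
  dplyr::rename(out, concentration = "concentration_mg_per_l")
}
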