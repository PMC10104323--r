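#' Potassium mass bookkeeping per treatment cell
#'
#' From treatment-mean tissue dry weights and tissue K concentrations,
#' computes per-tissue K masses \eqn{m_t = q_t/100 \times w_t} (g), the
#' aboveground (sheath + blade) and whole-plant aggregates, and the
#' dry-mass-weighted whole-plant K concentration
#' \eqn{q_{plant} = 100\, m_{total} / w_{total}} (g/100 g).
#'
#' @param summary A `treatment_summary` (see [summarize_treatments()])
#'   containing dry weights and tissue K concentrations.
#' @return A tibble of class `k_mass_profile`, one row per
#'   (variety, concentration), with columns `q_root`, `q_sheath`, `q_blade`,
#'   `w_root`, `w_sheath`, `w_blade`, `m_root`, `m_sheath`, `m_blade`,
#'   `m_above`, `m_total`, `w_above`, `w_total`, `q_plant`.
#' @export
k_mass_profile <- function(summary) {
  needed <- c("dry_weight_root_g", "dry_weight_sheath_g", "dry_weight_blade_g",
              "k_conc_root_g_per_100g", "k_conc_sheath_g_per_100g",
              "k_conc_blade_g_per_100g")
  have <- unique(summary$trait)
  missing <- setdiff(needed, have)
  if (length(missing) > 0) {
    abort(sprintf("Treatment summary lacks trait(s): %s",
                  paste(missing, collapse = ", ")))
  }
  wide <- tidyr::pivot_wider(
    dplyr::filter(summary, .data$trait %in% needed)[
      , c("variety", "concentration", "trait", "mean")],
    names_from = "trait", values_from = "mean")
  out <- dplyr::transmute(
    wide,
    variety = .data$variety,
    concentration = .data$concentration,
    q_root = .data$k_conc_root_g_per_100g,
    q_sheath = .data$k_conc_sheath_g_per_100g,
    q_blade = .data$k_conc_blade_g_per_100g,
    w_root = .data$dry_weight_root_g,
    w_sheath = .data$dry_weight_sheath_g,
    w_blade = .data$dry_weight_blade_g,
    m_root = .data$q_root / 100 * .data$w_root,
    m_sheath = .data$q_sheath / 100 * .data$w_sheath,
    m_blade = .data$q_blade / 100 * .data$w_blade,
    m_above = .data$m_sheath + .data$m_blade,
    m_total = .data$m_root + .data$m_sheath + .data$m_blade,
    w_above = .data$w_sheath + .data$w_blade,
    w_total = .data$w_root + .data$w_sheath + .data$w_blade
  )
  if (any(out$w_total == 0)) {
    bad <- out[out$w_total == 0, ][1, ]
    abort(sprintf("Zero total dry weight for (%s, %g mg/L).",
                  bad$variety, bad$concentration))
  }
  out$q_plant <- 100 * out$m_total / out$w_total
  class(out) <- c("k_mass_profile", class(out))
  out
}

#' Relative value of a trait against the K-replete reference
#'
#' The relative value of a trait at a treatment level is its value divided
#' by the same trait's value at the reference concentration; comparing
#' relative rather than absolute values removes constitutive size
#' differences between varieties.
#'
#' @param x Trait value(s) at the treatment level.
#' @param x_ref Value(s) of the same trait at the reference level; must be
#'   strictly positive.
#' @return `x / x_ref`.
#' @export
relative_value <- function(x, x_ref) {
  if (any(x_ref <= 0)) abort("Reference value must be strictly positive.")
  x / x_ref
}

#' Potassium absorption efficiency (KAE)
#'
#' Whole-plant K concentration divided by the K concentration of the
#' culture medium. The units are deliberately mixed (g/100 g over mg/L),
#' as conventional for this index; only ratios of KAE between levels
#' (RKAE) are unit-free.
#'
#' @param q_plant Whole-plant K concentration (g/100 g dry weight).
#' @param c_medium Medium K concentration (mg/L); must be positive, so the
#'   0 mg/L starvation level is excluded from KAE.
#' @return `q_plant / c_medium`.
#' @export
absorption_efficiency <- function(q_plant, c_medium) {
  if (any(c_medium <= 0)) {
    abort("KAE is undefined at nonpositive medium concentration; the 0 mg/L level is excluded.")
  }
  q_plant / c_medium
}

#' Potassium absorption rate (KAR)
#'
#' Difference in whole-plant K mass between the reference and very-low
#' levels, per unit mean root dry weight, per unit time:
#' \deqn{KAR = \frac{m_{high} - m_{low}}{scale \cdot d \cdot (w_{r,high}+w_{r,low})/2}}
#' with `scale = 100` (the g/100 g unit convention) and `d` the treatment
#' duration in days (default 28, i.e. four weeks).
#'
#' @param m_total_high,m_total_low Whole-plant K mass (g) at the reference
#'   and very-low levels.
#' @param w_root_high,w_root_low Root dry weights (g) at the two levels;
#'   their mean must be positive.
#' @param scale Unit-convention constant (default 100).
#' @param duration_days Treatment duration (default 28).
#' @return The absorption rate.
#' @export
absorption_rate <- function(m_total_high, m_total_low,
                            w_root_high, w_root_low,
                            scale = 100, duration_days = 28) {
  if (w_root_high + w_root_low <= 0) {
    abort("Root dry weights must not both be zero.")
  }
  (m_total_high - m_total_low) /
    (scale * duration_days * (w_root_high + w_root_low) / 2)
}

#' Potassium translocation rates between tissues
#'
#' Ratios of tissue K concentrations, proxies for long-distance K
#' transport: root to aboveground (KT-RTA, using the dry-mass-weighted
#' aboveground concentration), root to sheath (KT-RTS), and sheath to
#' blade (KT-STB).
#'
#' @param profile A `k_mass_profile` (any number of rows).
#' @return The profile with columns `kt_rta`, `kt_rts`, `kt_stb` appended.
#' @export
translocation_rates <- function(profile) {
  if (any(profile$q_root <= 0)) {
    abort("Zero root K concentration: translocation from root is undefined.")
  }
  if (any(profile$q_sheath <= 0)) {
    abort("Zero sheath K concentration: translocation from sheath is undefined.")
  }
  q_above <- 100 * profile$m_above / profile$w_above
  dplyr::mutate(profile,
                kt_rta = q_above / .data$q_root,
                kt_rts = .data$q_sheath / .data$q_root,
                kt_stb = .data$q_blade / .data$q_sheath)
}

#' Potassium distribution rate (KD)
#'
#' Fraction of whole-plant K mass residing in the aboveground part
#' (sheath + blade); lies in `[0, 1]`.
#'
#' @param profile A `k_mass_profile`.
#' @return Numeric vector `m_above / m_total`.
#' @export
distribution_rate <- function(profile) {
  if (any(profile$m_total <= 0)) {
    abort("Zero whole-plant K mass: distribution rate is undefined.")
  }
  profile$m_above / profile$m_total
}

#' Potassium utilization efficiency (KUE, KUEA)
#'
#' Dry matter produced per unit of plant K mass: whole-plant (KUE =
#' w_total/m_total) and aboveground (KUEA = w_above/m_total), both in
#' g dry weight per g K. KUEA is strictly below KUE whenever the root has
#' mass.
#'
#' @param profile A `k_mass_profile`.
#' @return The profile with columns `kue` and `kuea` appended.
#' @export
utilization_efficiency <- function(profile) {
  if (any(profile$m_total <= 0)) {
    abort("Zero whole-plant K mass: utilization efficiency is undefined.")
  }
  dplyr::mutate(profile,
                kue = .data$w_total / .data$m_total,
                kuea = .data$w_above / .data$m_total)
}

#' Potassium response index (KRI)
#'
#' Change in total plant dry weight per unit change in supplied K
#' concentration between the low and very-low levels.
#'
#' @param w_total_low Total dry weight (g) at the low level.
#' @param w_total_verylow Total dry weight (g) at the very-low level.
#' @param delta_k Concentration difference (mg/L), low minus very-low;
#'   must be positive (default 3, i.e. 4 - 1 mg/L).
#' @return `(w_total_low - w_total_verylow) / delta_k`.
#' @export
response_index <- function(w_total_low, w_total_verylow, delta_k = 3) {
  if (delta_k <= 0) abort("`delta_k` must be positive.")
  (w_total_low - w_total_verylow) / delta_k
}

# Canonical order of the 24 report parameters.
index_parameters <- c(
  "RKAE-1K", "RKC-1K", "DW-4K", "RDW-4K", "RKAE-4K", "RKA-4K", "KAR",
  "RKT-RTA-1K", "KT-RTS-1K", "RKT-RTS-1K", "RKT-STB-1K",
  "RKT-RTA-4K", "KT-RTS-4K", "RKT-RTS-4K", "RKT-STB-4K",
  "KD-1K", "KD-4K", "RKD-1K", "RKD-4K",
  "KUE-1K", "KUE-4K", "KUEA-1K", "KUEA-4K", "KRI")

#' Full potassium-efficiency index report for one variety
#'
#' Assembles the 24-parameter panel from the treatment summary: relative
#' absorption efficiency and K concentration at the very-low level;
#' absolute and relative dry weight, absorption efficiency and K
#' accumulation at the low level; the absorption rate; absolute and
#' relative translocation rates (root-to-aboveground, root-to-sheath,
#' sheath-to-blade) at both low levels; absolute and relative distribution
#' rates; utilization efficiencies (whole-plant and aboveground); and the
#' response index. Parameters prefixed `R` are the value at the very-low
#' (`-1K`) or low (`-4K`) level divided by the value at the reference
#' level.
#'
#' @param summary A `treatment_summary` containing the variety's cells at
#'   the design's very-low, low and reference concentrations.
#' @param design A [trial_design()].
#' @param variety Variety identifier.
#' @param tissue_mean How the whole-plant K concentration is formed:
#'   `"weighted"` (dry-mass-weighted, the default) or `"arithmetic"`
#'   (plain mean of the three tissue concentrations).
#' @param scale,duration_days Passed to [absorption_rate()]; duration
#'   defaults to the design's.
#' @return Tibble with columns `variety`, `parameter`, `value` (24 rows, in
#'   canonical order).
#' @export
index_report <- function(summary, design, variety,
                         tissue_mean = c("weighted", "arithmetic"),
                         scale = 100, duration_days = design$duration_days) {
  tissue_mean <- match.arg(tissue_mean)
  stopifnot(inherits(design, "trial_design"))
  levels_needed <- c(very_low = design$very_low_concentration,
                     low = design$low_concentration,
                     ref = design$reference_concentration)
  sub <- dplyr::filter(summary, .data$variety == !!variety,
                       .data$concentration %in% levels_needed)
  present <- unique(sub$concentration)
  absent <- setdiff(levels_needed, present)
  if (length(absent) > 0) {
    abort(sprintf("Missing treatment cell(s) for variety '%s' at %s mg/L.",
                  variety, paste(absent, collapse = ", ")))
  }
  prof <- k_mass_profile(sub)
  if (tissue_mean == "arithmetic") {
    prof$q_plant <- (prof$q_root + prof$q_sheath + prof$q_blade) / 3
  }
  prof <- utilization_efficiency(translocation_rates(prof))
  prof$kd <- distribution_rate(prof)
  at <- function(lvl) prof[prof$concentration == lvl, ]
  p1 <- at(levels_needed[["very_low"]])
  p4 <- at(levels_needed[["low"]])
  pr <- at(levels_needed[["ref"]])

  kae <- function(p, cc) absorption_efficiency(p$q_plant, cc)
  value <- c(
    "RKAE-1K" = relative_value(kae(p1, levels_needed[["very_low"]]),
                               kae(pr, levels_needed[["ref"]])),
    "RKC-1K" = relative_value(p1$q_plant, pr$q_plant),
    "DW-4K" = p4$w_total,
    "RDW-4K" = relative_value(p4$w_total, pr$w_total),
    "RKAE-4K" = relative_value(kae(p4, levels_needed[["low"]]),
                               kae(pr, levels_needed[["ref"]])),
    "RKA-4K" = relative_value(p4$m_total, pr$m_total),
    "KAR" = absorption_rate(pr$m_total, p1$m_total, pr$w_root, p1$w_root,
                            scale = scale, duration_days = duration_days),
    "RKT-RTA-1K" = relative_value(p1$kt_rta, pr$kt_rta),
    "KT-RTS-1K" = p1$kt_rts,
    "RKT-RTS-1K" = relative_value(p1$kt_rts, pr$kt_rts),
    "RKT-STB-1K" = relative_value(p1$kt_stb, pr$kt_stb),
    "RKT-RTA-4K" = relative_value(p4$kt_rta, pr$kt_rta),
    "KT-RTS-4K" = p4$kt_rts,
    "RKT-RTS-4K" = relative_value(p4$kt_rts, pr$kt_rts),
    "RKT-STB-4K" = relative_value(p4$kt_stb, pr$kt_stb),
    "KD-1K" = p1$kd,
    "KD-4K" = p4$kd,
    "RKD-1K" = relative_value(p1$kd, pr$kd),
    "RKD-4K" = relative_value(p4$kd, pr$kd),
    "KUE-1K" = p1$kue,
    "KUE-4K" = p4$kue,
    "KUEA-1K" = p1$kuea,
    "KUEA-4K" = p4$kuea,
    "KRI" = response_index(p4$w_total, p1$w_total,
                           delta_k = levels_needed[["low"]] -
                             levels_needed[["very_low"]])
  )
  tibble::tibble(variety = variety, parameter = index_parameters,
                 value = unname(value[index_parameters]))
}

#' Index reports for every variety in a summary
#'
#' @inheritParams index_report
#' @param varieties Varieties to report (default: all in the summary).
#' @return Long tibble `variety`, `parameter`, `value`.
#' @export
index_report_all <- function(summary, design,
                             varieties = unique(summary$variety), ...) {
  dplyr::bind_rows(lapply(varieties, function(v)
    index_report(summary, design, v, ...)))
}
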