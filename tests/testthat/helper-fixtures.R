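# Shared fixture builders; everything is generated in code.

default_design <- function(n_varieties = 12) {
  trial_design(sprintf("V%02d", seq_len(n_varieties)))
}

# Minimal hand-built observation row with sane values; override any field.
make_obs <- function(variety = "A", concentration = 4, replicate = 1L,
                     plant = 1L, ...) {
  row <- tibble::tibble(
    variety = variety, concentration_mg_per_l = concentration,
    replicate = as.integer(replicate), plant = as.integer(plant),
    plant_height_cm = 30, root_length_cm = 10, root_number = 8,
    fresh_weight_root_g = 0.05, fresh_weight_sheath_g = 0.08,
    fresh_weight_blade_g = 0.09, dry_weight_root_g = 0.006,
    dry_weight_sheath_g = 0.012, dry_weight_blade_g = 0.018,
    k_conc_root_g_per_100g = 2.0, k_conc_sheath_g_per_100g = 1.5,
    k_conc_blade_g_per_100g = 1.6)
  over <- list(...)
  for (nm in names(over)) row[[nm]] <- over[[nm]]
  row
}

# A random but internally valid treatment summary covering the three levels
# an index report needs, for any number of varieties.
random_summary <- function(varieties = c("A", "B"), levels = c(1, 4, 40),
                           rng = NULL) {
  grid <- tidyr::expand_grid(variety = varieties, concentration = levels)
  traits <- c("plant_height_cm", "root_length_cm", "root_number",
              "fresh_weight_root_g", "fresh_weight_sheath_g",
              "fresh_weight_blade_g", "dry_weight_root_g",
              "dry_weight_sheath_g", "dry_weight_blade_g",
              "k_conc_root_g_per_100g", "k_conc_sheath_g_per_100g",
              "k_conc_blade_g_per_100g", "total_fresh_weight_g",
              "total_dry_weight_g")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    dw <- runif(3, 0.002, 0.05)
    fw <- dw / runif(3, 0.1, 0.3)
    q <- runif(3, 0.2, 4)
    vals <- c(runif(1, 10, 60), runif(1, 5, 20), round(runif(1, 3, 15)),
              fw, dw, q, sum(fw), sum(dw))
    tibble::tibble(variety = grid$variety[i],
                   concentration = grid$concentration[i],
                   trait = traits, mean = vals,
                   sd = abs(vals) * 0.05, n = 3L)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("treatment_summary", class(out))
  out
}

# Straight-line independent recomputation of the 24-parameter report,
# written directly from the index definitions (no package helpers).
oracle_index_report <- function(summary, design, variety) {
  cell <- function(lvl, trait) {
    summary$mean[summary$variety == variety &
                   summary$concentration == lvl & summary$trait == trait]
  }
  prof <- function(lvl) {
    q <- c(cell(lvl, "k_conc_root_g_per_100g"),
           cell(lvl, "k_conc_sheath_g_per_100g"),
           cell(lvl, "k_conc_blade_g_per_100g"))
    w <- c(cell(lvl, "dry_weight_root_g"), cell(lvl, "dry_weight_sheath_g"),
           cell(lvl, "dry_weight_blade_g"))
    m <- q / 100 * w
    list(q = q, w = w, m = m, m_above = m[2] + m[3], m_total = sum(m),
         w_above = w[2] + w[3], w_total = sum(w),
         q_plant = 100 * sum(m) / sum(w),
         q_above = 100 * (m[2] + m[3]) / (w[2] + w[3]))
  }
  vl <- design$very_low_concentration; lo <- design$low_concentration
  rf <- design$reference_concentration
  p1 <- prof(vl); p4 <- prof(lo); pr <- prof(rf)
  kae1 <- p1$q_plant / vl; kae4 <- p4$q_plant / lo; kaer <- pr$q_plant / rf
  rta <- function(p) p$q_above / p$q[1]
  rts <- function(p) p$q[2] / p$q[1]
  stb <- function(p) p$q[3] / p$q[2]
  kd <- function(p) p$m_above / p$m_total
  c("RKAE-1K" = kae1 / kaer,
    "RKC-1K" = p1$q_plant / pr$q_plant,
    "DW-4K" = p4$w_total,
    "RDW-4K" = p4$w_total / pr$w_total,
    "RKAE-4K" = kae4 / kaer,
    "RKA-4K" = p4$m_total / pr$m_total,
    "KAR" = (pr$m_total - p1$m_total) /
      (100 * design$duration_days * (pr$w[1] + p1$w[1]) / 2),
    "RKT-RTA-1K" = rta(p1) / rta(pr),
    "KT-RTS-1K" = rts(p1),
    "RKT-RTS-1K" = rts(p1) / rts(pr),
    "RKT-STB-1K" = stb(p1) / stb(pr),
    "RKT-RTA-4K" = rta(p4) / rta(pr),
    "KT-RTS-4K" = rts(p4),
    "RKT-RTS-4K" = rts(p4) / rts(pr),
    "RKT-STB-4K" = stb(p4) / stb(pr),
    "KD-1K" = kd(p1),
    "KD-4K" = kd(p4),
    "RKD-1K" = kd(p1) / kd(pr),
    "RKD-4K" = kd(p4) / kd(pr),
    "KUE-1K" = p1$w_total / p1$m_total,
    "KUE-4K" = p4$w_total / p4$m_total,
    "KUEA-1K" = p1$w_above / p1$m_total,
    "KUEA-4K" = p4$w_above / p4$m_total,
    "KRI" = (p4$w_total - p1$w_total) / (lo - vl))
}

# Random positive K-mass profile row for invariant sweeps.
random_profile <- function(n = 1) {
  q <- matrix(runif(3 * n, 0.05, 5), ncol = 3)
  w <- matrix(runif(3 * n, 0.001, 0.1), ncol = 3)
  m <- q / 100 * w
  tibble::tibble(
    variety = sprintf("R%03d", seq_len(n)), concentration = 4,
    q_root = q[, 1], q_sheath = q[, 2], q_blade = q[, 3],
    w_root = w[, 1], w_sheath = w[, 2], w_blade = w[, 3],
    m_root = m[, 1], m_sheath = m[, 2], m_blade = m[, 3],
    m_above = m[, 2] + m[, 3], m_total = rowSums(m),
    w_above = w[, 2] + w[, 3], w_total = rowSums(w),
    q_plant = 100 * rowSums(m) / rowSums(w))
}
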