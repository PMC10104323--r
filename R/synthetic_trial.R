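#' Parameters of the synthetic trial generator
#'
#' The generator plants a known tolerance structure into an otherwise
#' realistic seedling trial so that every downstream stage of the screening
#' pipeline can be checked against ground truth.
#'
#' Growth traits follow a saturating (Michaelis-Menten-type) dose response
#' in medium K concentration \eqn{c}:
#' \deqn{\mu_{v}(c) = T_{max} (b + (1-b) \frac{c+\epsilon}{c+\epsilon+K_{50}(1-\gamma s_v)})}
#' where \eqn{s_v \in [0,1]} is the planted tolerance score of variety
#' \eqn{v}: tolerant varieties half-saturate at lower K. The floor
#' \eqn{\epsilon = 0.05} mg/L keeps growth nonzero at the 0 mg/L starvation
#' level. Each per-plant value multiplies an independent lognormal factor
#' with log-sd `sigma`.
#'
#' Root K concentration saturates as \eqn{Q_{min} + (Q_{max}-Q_{min})
#' c/(c+K_q)}; the sheath:root concentration ratio is
#' \eqn{\min(r_0 + \delta s_v K_{50}/(c+K_{50}),\ r_{cap})}, so tolerant
#' varieties translocate relatively more K from root to shoot under low K;
#' blade K is a fixed multiple of sheath K. Dry weights are fresh weights
#' times a per-tissue dry-matter fraction.
#'
#' @param varieties Character vector of variety identifiers.
#' @param s Per-variety tolerance scores in `[0, 1]`, same length as
#'   `varieties`. Default: evenly spaced from 0 (sensitive) to 1 (tolerant).
#' @param t_max Named vector of trait maxima (trait units) for the six
#'   morphological traits.
#' @param k50 Named vector of base half-saturation concentrations (mg/L),
#'   one per morphological trait.
#' @param gamma Tolerance leverage in `[0, 1)`: a variety with score `s`
#'   half-saturates at `k50 * (1 - gamma * s)`.
#' @param baseline Trait value at 0 mg/L as a fraction of the maximum,
#'   in `[0, 1)`.
#' @param q_min,q_max Root K concentration range (g/100 g dry weight).
#' @param k_q Half-saturation (mg/L) of root K concentration.
#' @param r0 Baseline sheath:root K concentration ratio.
#' @param delta Tolerance gain of the sheath:root ratio at low K.
#' @param r_cap Upper cap on the sheath:root ratio.
#' @param blade_sheath_ratio Fixed blade:sheath K concentration ratio.
#' @param dry_fraction Named per-tissue dry-matter fractions (root, sheath,
#'   blade), each in `(0, 1)`.
#' @param sigma Log-sd of the multiplicative per-plant lognormal noise
#'   (>= 0).
#'
#' @return An object of class `generator_params` (named list).
#' @export
generator_params <- function(varieties = sprintf("V%02d", 1:12),
                             s = NULL,
                             t_max = c(plant_height_cm = 50,
                                       root_length_cm = 15,
                                       root_number = 12,
                                       fresh_weight_root_g = 0.08,
                                       fresh_weight_sheath_g = 0.12,
                                       fresh_weight_blade_g = 0.12),
                             k50 = c(plant_height_cm = 10,
                                     root_length_cm = 10,
                                     root_number = 10,
                                     fresh_weight_root_g = 10,
                                     fresh_weight_sheath_g = 10,
                                     fresh_weight_blade_g = 10),
                             gamma = 0.70,
                             baseline = 0.10,
                             q_min = 0.3, q_max = 3.5, k_q = 8,
                             r0 = 0.8, delta = 1.0, r_cap = 2.0,
                             blade_sheath_ratio = 1.1,
                             dry_fraction = c(root = 0.12, sheath = 0.15,
                                              blade = 0.20),
                             sigma = 0.05) {
  varieties <- as.character(varieties)
  if (is.null(s)) {
    s <- if (length(varieties) == 1) 0.5 else
      seq(0, 1, length.out = length(varieties))
  }
  if (length(s) != length(varieties)) {
    abort("`s` must have one tolerance score per variety.")
  }
  if (any(s < 0 | s > 1)) abort("Tolerance scores `s` must lie in [0, 1].")
  if (sigma < 0) abort("`sigma` must be nonnegative.")
  if (!(q_min < q_max)) abort("`q_min` must be below `q_max`.")
  if (any(k50 <= 0) || k_q <= 0 || r0 <= 0) {
    abort("`k50`, `k_q` and `r0` must be positive.")
  }
  if (gamma < 0 || gamma >= 1) abort("`gamma` must lie in [0, 1).")
  if (baseline < 0 || baseline >= 1) abort("`baseline` must lie in [0, 1).")
  needed <- morph_traits()
  if (!all(needed %in% names(t_max)) || !all(needed %in% names(k50))) {
    abort("`t_max` and `k50` must name all six morphological traits.")
  }
  structure(
    list(varieties = varieties, s = setNames(as.numeric(s), varieties),
         t_max = t_max[needed], k50 = k50[needed], gamma = gamma,
         baseline = baseline, q_min = q_min, q_max = q_max, k_q = k_q,
         r0 = r0, delta = delta, r_cap = r_cap,
         blade_sheath_ratio = blade_sheath_ratio,
         dry_fraction = dry_fraction, sigma = sigma),
    class = "generator_params"
  )
}

# c = 0 guard: minimal but nonzero growth at the starvation level
.gen_eps <- 0.05

# Noise-free expected value of one growth trait for every variety at one
# concentration (vector over varieties).
.expected_trait <- function(params, trait, concentration) {
  k_v <- params$k50[[trait]] * (1 - params$gamma * params$s)
  x <- concentration + .gen_eps
  params$t_max[[trait]] * (params$baseline + (1 - params$baseline) * x / (x + k_v))
}

# Noise-free tissue K concentrations (list of vectors over varieties).
.expected_k_conc <- function(params, concentration) {
  q_root <- params$q_min + (params$q_max - params$q_min) *
    concentration / (concentration + params$k_q)
  ratio <- pmin(params$r0 + params$delta * params$s *
                  mean(params$k50) / (concentration + mean(params$k50)),
                params$r_cap)
  q_root <- rep(q_root, length(params$s))
  list(root = q_root, sheath = q_root * ratio,
       blade = q_root * ratio * params$blade_sheath_ratio)
}

#' Generate a synthetic per-plant trial table
#'
#' Deterministic given `(design, params, seed)`. With `sigma = 0` every
#' plant in a (variety, concentration) cell is identical to the noise-free
#' expectation. Values are clipped so that all trial-table invariants hold
#' by construction: weights nonnegative, dry below fresh, tissue K within
#' 0--10 g/100 g, root number a rounded nonnegative integer.
#'
#' @param design A [trial_design()]; its varieties must all have parameters.
#' @param params A [generator_params()].
#' @param seed Integer seed controlling all randomness.
#' @return A trial table tibble (canonical columns, one row per plant).
#' @export
generate_trial <- function(design, params = generator_params(design$varieties),
                           seed = 1) {
  stopifnot(inherits(design, "trial_design"),
            inherits(params, "generator_params"))
  unknown <- setdiff(design$varieties, params$varieties)
  if (length(unknown) > 0) {
    abort(sprintf("No generator parameters for variety(ies): %s",
                  paste(unknown, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(
    variety = design$varieties,
    concentration_mg_per_l = design$concentrations,
    replicate = seq_len(design$replicates),
    plant = seq_len(design$plants_per_replicate)
  )
  n <- nrow(grid)
  s_of <- unname(params$s[grid$variety])
  withr::with_seed(seed, {
    noise <- function() {
      if (params$sigma == 0) rep(1, n) else exp(rnorm(n, 0, params$sigma))
    }
    for (trait in morph_traits()) {
      k_v <- params$k50[[trait]] * (1 - params$gamma * s_of)
      x <- grid$concentration_mg_per_l + .gen_eps
      mu <- params$t_max[[trait]] *
        (params$baseline + (1 - params$baseline) * x / (x + k_v))
      grid[[trait]] <- pmax(mu * noise(), 0)
    }
    grid$root_number <- round(grid$root_number)
    q_root_mu <- params$q_min + (params$q_max - params$q_min) *
      grid$concentration_mg_per_l / (grid$concentration_mg_per_l + params$k_q)
    ratio <- pmin(params$r0 + params$delta * s_of * mean(params$k50) /
                    (grid$concentration_mg_per_l + mean(params$k50)),
                  params$r_cap)
    grid$k_conc_root_g_per_100g <- pmin(pmax(q_root_mu * noise(), 0), 10)
    grid$k_conc_sheath_g_per_100g <- pmin(pmax(q_root_mu * ratio * noise(), 0), 10)
    grid$k_conc_blade_g_per_100g <-
      pmin(pmax(q_root_mu * ratio * params$blade_sheath_ratio * noise(), 0), 10)
  })
  grid$dry_weight_root_g <- grid$fresh_weight_root_g * params$dry_fraction[["root"]]
  grid$dry_weight_sheath_g <- grid$fresh_weight_sheath_g * params$dry_fraction[["sheath"]]
  grid$dry_weight_blade_g <- grid$fresh_weight_blade_g * params$dry_fraction[["blade"]]
  grid[, trial_columns()]
}

#' Ground truth planted by the generator
#'
#' Returns the true tolerance order of the varieties and, per trait, the
#' concentration at which the noise-free between-variety coefficient of
#' variation is largest, found by direct evaluation of the response
#' function over the design grid. When all tolerance scores are equal the
#' between-variety CV is zero everywhere and the argmax is undefined
#' (reported as `NA`).
#'
#' @param params A [generator_params()].
#' @param design A [trial_design()] supplying the concentration grid.
#' @param traits Traits to profile (default: the six morphological traits).
#' @return A list with `ranking` (varieties ordered from most tolerant to
#'   most sensitive), `s` (named scores), `cv_argmax` (tibble: trait,
#'   concentration), and `consensus` (modal per-trait argmax, ties broken
#'   toward the lower concentration; `NA` if undefined).
#' @export
planted_truth <- function(params, design, traits = morph_traits()) {
  stopifnot(inherits(params, "generator_params"), inherits(design, "trial_design"))
  ord <- order(params$s, decreasing = TRUE)
  ranking <- params$varieties[ord]
  rows <- lapply(traits, function(trait) {
    cv <- vapply(design$concentrations, function(cc) {
      mu <- .expected_trait(params, trait, cc)
      m <- mean(mu)
      if (m == 0) return(NA_real_)
      100 * stats::sd(mu) / m
    }, numeric(1))
    arg <- if (all(is.na(cv)) || max(cv, na.rm = TRUE) == 0) {
      NA_real_
    } else {
      # ties broken toward the lower concentration (grid is ascending)
      design$concentrations[which.max(cv)]
    }
    tibble::tibble(trait = trait, concentration = arg)
  })
  cv_argmax <- dplyr::bind_rows(rows)
  consensus <- .modal_lowest(cv_argmax$concentration)
  list(ranking = ranking, s = params$s, cv_argmax = cv_argmax,
       consensus = consensus)
}

# Modal value of a numeric vector, ties broken toward the smallest;
# NA entries dropped, all-NA -> NA.
.modal_lowest <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  tab <- table(x)
  min(as.numeric(names(tab)[tab == max(tab)]))
}
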