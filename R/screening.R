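#' Coefficient of variation across varieties
#'
#' The dispersion of treatment means across genotypes at one level, as a
#' percentage: `100 * sd / mean` with the sample (n-1) standard deviation.
#' The inverted variant `mean / sd` (as sometimes printed) is available via
#' `formula = "printed"` for forensic comparison; the standard definition
#' is the default because a mean-over-sd statistic would rise, not
#' collapse, at saturating K.
#'
#' @param values Numeric vector of treatment means (length >= 2).
#' @param formula `"standard"` (default) or `"printed"`.
#' @return CV as a percentage; `NA` (undefined) if the mean is zero.
#' @export
cv <- function(values, formula = c("standard", "printed")) {
  formula <- match.arg(formula)
  if (length(values) < 2) abort("CV needs at least 2 values.")
  m <- mean(values)
  s <- stats::sd(values)
  if (formula == "standard") {
    if (m == 0) return(NA_real_)
    100 * s / m
  } else {
    if (s == 0) return(NA_real_)
    m / s
  }
}

#' CV profile over traits and concentrations
#'
#' For each requested trait and each concentration, the coefficient of
#' variation across the varieties' treatment means. A large CV at a level
#' means the level separates genotypes well.
#'
#' @param summary A `treatment_summary`.
#' @param traits Traits to profile (default: the six morphological traits).
#' @param formula Passed to [cv()].
#' @return Tibble of class `cv_profile`: `trait`, `concentration`, `cv`,
#'   `n_varieties`, `undefined` (TRUE where the across-variety mean was
#'   zero; such cells are flagged, not dropped).
#' @export
cv_profile <- function(summary, traits = morph_traits(),
                       formula = c("standard", "printed")) {
  formula <- match.arg(formula)
  sub <- dplyr::filter(summary, .data$trait %in% traits)
  found <- unique(sub$trait)
  if (length(setdiff(traits, found)) > 0) {
    abort(sprintf("Summary lacks trait(s): %s",
                  paste(setdiff(traits, found), collapse = ", ")))
  }
  n_var <- length(unique(summary$variety))
  counts <- dplyr::count(sub, .data$trait, .data$concentration)
  short <- counts[counts$n < n_var, ]
  if (nrow(short) > 0) {
    abort(sprintf("Missing treatment mean(s) for trait '%s' at %g mg/L.",
                  short$trait[1], short$concentration[1]))
  }
  out <- dplyr::summarise(
    dplyr::group_by(sub, .data$trait, .data$concentration),
    cv = cv(.data$mean, formula = formula),
    n_varieties = dplyr::n(), .groups = "drop")
  out$undefined <- is.na(out$cv)
  out$trait <- factor(out$trait, levels = traits)
  out <- dplyr::arrange(out, .data$trait, .data$concentration)
  out$trait <- as.character(out$trait)
  class(out) <- c("cv_profile", class(out))
  out
}

#' Optimal screening concentration from a CV profile
#'
#' Per trait, the concentration with the largest CV; the consensus is the
#' modal per-trait argmax, with ties broken toward the lower (cheaper, more
#' stringent) concentration. By default concentrations at or above the
#' reference are excluded from candidacy (`exclude_saturated`), since
#' saturating levels exert no selection pressure. Undefined CV cells are
#' never candidates.
#'
#' @param profile A [cv_profile()].
#' @param reference Reference concentration (mg/L) used by
#'   `exclude_saturated`; required when that rule is on.
#' @param exclude_saturated Drop levels `>= reference` from candidacy
#'   (default TRUE).
#' @return List with `consensus` (mg/L), and `per_trait` (tibble: `trait`,
#'   `argmax`, `argmin` concentrations).
#' @export
optimal_concentration <- function(profile, reference = NULL,
                                  exclude_saturated = TRUE) {
  cand <- profile[!profile$undefined, ]
  if (exclude_saturated) {
    if (is.null(reference)) {
      abort("`reference` is required when `exclude_saturated` is on.")
    }
    cand <- cand[cand$concentration < reference, ]
  }
  if (nrow(cand) == 0) abort("No defined CV cells to choose from.")
  per_trait <- dplyr::summarise(
    dplyr::group_by(cand, .data$trait),
    argmax = min(.data$concentration[.data$cv == max(.data$cv)]),
    argmin = min(.data$concentration[.data$cv == min(.data$cv)]),
    .groups = "drop")
  list(consensus = .modal_lowest(per_trait$argmax), per_trait = per_trait)
}

#' Relative trait table
#'
#' Treatment means divided by the same variety's mean at the reference
#' concentration, per trait.
#'
#' @param summary A `treatment_summary`.
#' @param design A [trial_design()].
#' @param traits Traits to include (default: the six morphological traits).
#' @return Tibble `variety`, `concentration`, `trait`, `relative_value`.
#' @export
relative_traits <- function(summary, design, traits = morph_traits()) {
  sub <- dplyr::filter(summary, .data$trait %in% traits)
  ref <- dplyr::filter(sub, .data$concentration == design$reference_concentration)
  if (nrow(ref) == 0) abort("Summary lacks the reference concentration.")
  ref <- dplyr::select(ref, "variety", "trait", ref_mean = "mean")
  joined <- dplyr::inner_join(sub, ref, by = c("variety", "trait"))
  dplyr::transmute(joined, variety = .data$variety,
                   concentration = .data$concentration, trait = .data$trait,
                   relative_value = relative_value(.data$mean, .data$ref_mean))
}

#' Rank varieties by low-potassium tolerance
#'
#' Each variety's score on a trait is the mean of its relative values over
#' the low-K subset of concentrations; varieties are ranked per trait
#' (rank 1 = largest relative value = most tolerant), the overall score is
#' the mean of the per-trait ranks, and the consistency score is
#' `1 - range(per-trait ranks) / (n_varieties - 1)`: a variety ranked
#' identically on every trait scores 1, a variety ranked first on one
#' trait and last on another scores 0.
#'
#' The default low-K subset is the strictly positive levels below half the
#' reference: the starvation level carries no discriminating signal and
#' near-reference levels are already saturating.
#'
#' @param summary A `treatment_summary`.
#' @param design A [trial_design()].
#' @param traits Ranking traits (default [ranking_traits()]).
#' @param concentrations Low-K subset (default: `0 < c < reference / 2`).
#' @return Tibble of class `tolerance_ranking`, one row per variety:
#'   `variety`, one `rank_<trait>` column per trait, `overall_score` (mean
#'   rank; lower is more tolerant), `consistency`, `rank` (dense order of
#'   `overall_score`).
#' @export
rank_tolerance <- function(summary, design, traits = ranking_traits(),
                           concentrations = NULL) {
  if (is.null(concentrations)) {
    concentrations <- design$concentrations[
      design$concentrations > 0 &
        design$concentrations < design$reference_concentration / 2]
  }
  varieties <- unique(summary$variety)
  if (length(varieties) < 2) abort("Ranking needs at least 2 varieties.")
  rel <- relative_traits(summary, design, traits)
  rel <- dplyr::filter(rel, .data$concentration %in% concentrations)
  scores <- dplyr::summarise(
    dplyr::group_by(rel, .data$variety, .data$trait),
    score = mean(.data$relative_value), .groups = "drop")
  ranks <- dplyr::mutate(
    dplyr::group_by(scores, .data$trait),
    trait_rank = rank(-.data$score, ties.method = "average"))
  ranks <- dplyr::ungroup(ranks)
  wide <- tidyr::pivot_wider(ranks[, c("variety", "trait", "trait_rank")],
                             names_from = "trait", values_from = "trait_rank",
                             names_prefix = "rank_")
  rank_cols <- paste0("rank_", traits)
  rmat <- as.matrix(wide[, rank_cols])
  out <- dplyr::mutate(
    wide,
    overall_score = rowMeans(rmat),
    consistency = 1 - (apply(rmat, 1, max) - apply(rmat, 1, min)) /
      (length(varieties) - 1))
  out <- dplyr::arrange(out, .data$overall_score)
  out$rank <- rank(out$overall_score, ties.method = "min")
  class(out) <- c("tolerance_ranking", class(out))
  out
}

#' Select the tolerant/sensitive parent pair
#'
#' The tolerant parent is the best overall score among varieties whose
#' consistency reaches `theta`; the sensitive parent is the worst such.
#' If no variety reaches `theta`, the threshold is relaxed to the maximum
#' consistency attained (with a warning). A pair of genotypes that behave
#' consistently across traits, yet sit at opposite extremes, makes an
#' informative cross for QTL mapping.
#'
#' @param ranking A [rank_tolerance()] result.
#' @param theta Consistency threshold in `[0, 1]` (default 0.7).
#' @return List with `tolerant`, `sensitive`, `theta_used`, `relaxed`.
#' @export
select_parent_pair <- function(ranking, theta = 0.7) {
  if (nrow(ranking) < 2) abort("Need at least 2 varieties to select a pair.")
  relaxed <- FALSE
  pass <- ranking$consistency >= theta
  if (!any(pass)) {
    theta <- max(ranking$consistency)
    pass <- ranking$consistency >= theta
    relaxed <- TRUE
    warn(sprintf("No variety reached the consistency threshold; relaxed to %.3f.",
                 theta))
  }
  pool <- ranking[pass, ]
  if (nrow(pool) < 2) {
    abort("Fewer than 2 varieties pass the consistency filter.")
  }
  tolerant <- pool$variety[which.min(pool$overall_score)]
  sensitive <- pool$variety[which.max(pool$overall_score)]
  list(tolerant = tolerant, sensitive = sensitive, theta_used = theta,
       relaxed = relaxed)
}

#' Significance stars for a p-value
#'
#' `***` below 0.001, `**` below 0.01, `*` below 0.05, empty otherwise.
#'
#' @param p P-value(s).
#' @return Character vector of star annotations.
#' @export
p_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}

#' Paired t test with star annotation
#'
#' The classical paired t statistic on the differences
#' \eqn{d_i = a_i - b_i}: \eqn{t = \bar d / (s_d / \sqrt n)} with
#' \eqn{n - 1} degrees of freedom and a two-sided p-value. Pairs are
#' matched by position (replicate index). When every difference is zero
#' the test is degenerate: no stars, p reported as 1.
#'
#' @param a,b Numeric vectors of equal length (>= 2), paired by index.
#' @return List with `t`, `df`, `p`, `stars`, `degenerate`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  n <- length(a)
  if (n < 2) abort("Paired t test needs at least 2 pairs.")
  d <- a - b
  if (all(d == 0)) {
    return(list(t = NA_real_, df = n - 1, p = 1, stars = "",
                degenerate = TRUE))
  }
  s <- stats::sd(d)
  if (s == 0) {
    # equal nonzero differences: infinitely strong evidence
    t <- sign(mean(d)) * Inf
    p <- 0
  } else {
    t <- mean(d) / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df = n - 1)
  }
  list(t = t, df = n - 1, p = p, stars = p_stars(p), degenerate = FALSE)
}

#' Significance table for a variety pair
#'
#' For each trait and concentration, a paired t test between the two
#' varieties on replicate means of relative values (each replicate mean
#' divided by its variety's treatment mean at the reference level), paired
#' by replicate index. No multiple-testing correction is applied by
#' default (each cell is annotated on its own); Holm correction over the
#' whole table is available.
#'
#' @param observations Trial table containing both varieties, complete at
#'   every concentration.
#' @param pair Character vector of two variety identifiers `(a, b)`; the
#'   test is `a - b`.
#' @param design A [trial_design()].
#' @param traits Traits to test (default: the six morphological traits).
#' @param correction `"none"` (default) or `"holm"`.
#' @return Tibble: `trait`, `concentration`, `t`, `df`, `p`, `stars`,
#'   `degenerate`.
#' @export
significance_table <- function(observations, pair, design,
                               traits = morph_traits(),
                               correction = c("none", "holm")) {
  correction <- match.arg(correction)
  if (length(pair) != 2 || pair[1] == pair[2]) {
    abort("`pair` must name two distinct varieties.")
  }
  obs <- dplyr::filter(observations, .data$variety %in% pair)
  if (length(unique(obs$variety)) != 2) {
    abort("Both varieties of the pair must be present in the observations.")
  }
  reps <- dplyr::filter(replicate_means(obs), .data$trait %in% traits)
  ref <- dplyr::summarise(
    dplyr::filter(reps, .data$concentration == design$reference_concentration),
    ref_mean = mean(.data$value),
    .by = c("variety", "trait"))
  rel <- dplyr::inner_join(reps, ref, by = c("variety", "trait"))
  rel$relative <- relative_value(rel$value, rel$ref_mean)
  cells <- tidyr::expand_grid(trait = traits,
                              concentration = sort(unique(rel$concentration)))
  rows <- purrr::pmap(cells, function(trait, concentration) {
    cell <- rel[rel$trait == trait & rel$concentration == concentration, ]
    a <- cell[cell$variety == pair[1], ]
    b <- cell[cell$variety == pair[2], ]
    a <- a$relative[order(a$replicate)]
    b <- b$relative[order(b$replicate)]
    if (length(a) != length(b) || length(a) < 2) {
      abort(sprintf("Incomplete replicates for trait '%s' at %g mg/L.",
                    trait, concentration))
    }
    res <- paired_t_test(a, b)
    tibble::tibble(trait = trait, concentration = concentration,
                   t = res$t, df = res$df, p = res$p,
                   degenerate = res$degenerate)
  })
  out <- dplyr::bind_rows(rows)
  if (correction == "holm") {
    out$p <- stats::p.adjust(out$p, method = "holm")
  }
  out$stars <- ifelse(out$degenerate, "", p_stars(out$p))
  out[, c("trait", "concentration", "t", "df", "p", "stars", "degenerate")]
}
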