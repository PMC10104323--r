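test_that("cv implements 100 * sd / mean with a printed-variant option", {
  expect_equal(cv(c(5, 5, 5)), 0)
  expect_equal(cv(c(1, 2, 3)), 50)  # mean 2, sample sd 1
  withr::local_seed(10)
  x <- runif(8, 1, 5)
  expect_equal(cv(7.3 * x), cv(x), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(cv(x + 2), cv(x))))  # shift is not invariant
  expect_error(cv(1), "at least 2")
  expect_true(is.na(cv(c(-1, 1))))
  expect_equal(cv(c(1, 2, 3), formula = "printed"), 2)
})

test_that("cv_profile matches a direct two-loop recomputation", {
  d <- default_design(4)
  withr::local_seed(31)
  s <- random_summary(d$varieties[1:4], levels = c(1, 4, 40))
  prof <- cv_profile(s, traits = c("plant_height_cm", "root_length_cm"))
  for (trait in c("plant_height_cm", "root_length_cm")) {
    for (cc in c(1, 4, 40)) {
      vals <- s$mean[s$trait == trait & s$concentration == cc]
      expect_equal(prof$cv[prof$trait == trait & prof$concentration == cc],
                   100 * sd(vals) / mean(vals), tolerance = 1e-12)
    }
  }
  # identical mean curves across varieties -> all-zero profile
  s2 <- random_summary("A", levels = c(1, 4, 40))
  s2b <- s2; s2b$variety <- "B"
  flatprof <- cv_profile(dplyr::bind_rows(s2, s2b),
                         traits = "plant_height_cm")
  expect_true(all(flatprof$cv == 0))
  expect_error(cv_profile(s, traits = "no_such_trait"), "no_such_trait")
})

test_that("optimal concentration applies mode, tie-break and saturation rules", {
  mk <- function(trait, conc, cvv) {
    out <- tibble::tibble(trait = trait, concentration = conc, cv = cvv,
                          n_varieties = 5L, undefined = is.na(cvv))
    class(out) <- c("cv_profile", class(out))
    out
  }
  single <- mk("h", c(1, 2, 3, 4, 5, 40), c(1, 2, 3, 9, 3, 2))
  got <- optimal_concentration(single, reference = 40)
  expect_equal(got$consensus, 4)
  expect_equal(got$per_trait$argmin, 1)

  three <- dplyr::bind_rows(
    mk("a", c(3, 4), c(1, 2)), mk("b", c(3, 4), c(1, 2)),
    mk("c", c(3, 4), c(2, 1)))
  expect_equal(optimal_concentration(three, reference = 40)$consensus, 4)
  two <- dplyr::bind_rows(mk("a", c(3, 4), c(2, 1)),
                          mk("b", c(3, 4), c(1, 2)))
  expect_equal(optimal_concentration(two, reference = 40)$consensus, 3)

  # saturated levels are dropped from candidacy unless the rule is off
  sat <- mk("h", c(2, 4, 40, 60), c(1, 2, 9, 8))
  expect_equal(optimal_concentration(sat, reference = 40)$consensus, 4)
  expect_equal(optimal_concentration(sat, exclude_saturated = FALSE)$consensus,
               40)

  # undefined cells are never candidates
  undef <- mk("h", c(2, 4), c(NA, 1))
  expect_equal(optimal_concentration(undef, reference = 40)$consensus, 4)
  expect_error(optimal_concentration(mk("h", 2, NA), reference = 40),
               "No defined")
})

test_that("tolerance ranking matches a brute-force recomputation", {
  d <- default_design(5)
  lowk <- d$concentrations[d$concentrations > 0 & d$concentrations < 20]
  withr::local_seed(55)
  for (i in 1:5) {
    s <- random_summary(d$varieties[1:5], levels = d$concentrations)
    r <- rank_tolerance(s, d)
    # brute force, straight from the definition
    for (v in d$varieties[1:5]) {
      per_trait <- sapply(ranking_traits(), function(trait) {
        score_of <- function(vv) {
          vals <- sapply(lowk, function(cc)
            s$mean[s$variety == vv & s$concentration == cc & s$trait == trait] /
              s$mean[s$variety == vv & s$concentration == 40 & s$trait == trait])
          mean(vals)
        }
        scores <- sapply(d$varieties[1:5], score_of)
        rank(-scores, ties.method = "average")[[v]]
      })
      row <- r[r$variety == v, ]
      expect_equal(row$overall_score, mean(per_trait))
      expect_equal(row$consistency,
                   1 - (max(per_trait) - min(per_trait)) / 4)
    }
  }
})

test_that("a uniformly dominant variety ranks first with full consistency", {
  d <- default_design(3)
  s <- random_summary(d$varieties[1:3], levels = d$concentrations)
  # variety V01 dominates every ranking trait at every level below reference
  for (trait in ranking_traits()) {
    base <- s$trait == trait & s$concentration < 40
    s$mean[base & s$variety == "V01"] <-
      2 * max(s$mean[s$trait == trait])
    # equalize the reference cells so relative values follow the boost
    s$mean[s$trait == trait & s$concentration == 40] <- 1
  }
  r <- rank_tolerance(s, d)
  top <- r[r$variety == "V01", ]
  expect_equal(top$rank, 1L)
  expect_equal(top$consistency, 1)
})

test_that("parent-pair selection honors the consistency filter", {
  d <- default_design(2)
  s <- random_summary(c("A", "B"), levels = d$concentrations)
  r <- rank_tolerance(s, trial_design(c("A", "B")))
  pick <- select_parent_pair(r)
  expect_equal(sort(c(pick$tolerant, pick$sensitive)), c("A", "B"))
  expect_true(pick$tolerant != pick$sensitive)
  better <- r$variety[which.min(r$overall_score)]
  expect_equal(pick$tolerant, better)

  # a variety ranked 1st on two traits and 12th on the third has
  # consistency 1 - 11/11 = 0 and is excluded at theta = 0.7
  fake <- tibble::tibble(
    variety = sprintf("V%02d", 1:12),
    rank_plant_height_cm = c(1, 2:12),
    rank_fresh_weight_sheath_g = c(1, 2:12),
    rank_fresh_weight_blade_g = c(12, 1:11))
  fake$overall_score <- rowMeans(fake[, 2:4])
  rmat <- as.matrix(fake[, 2:4])
  fake$consistency <- 1 - (apply(rmat, 1, max) - apply(rmat, 1, min)) / 11
  fake$rank <- rank(fake$overall_score, ties.method = "min")
  class(fake) <- c("tolerance_ranking", class(fake))
  expect_equal(fake$consistency[1], 0)
  pick2 <- select_parent_pair(fake)
  expect_false("V01" %in% c(pick2$tolerant, pick2$sensitive))

  solo <- fake[1:2, ]
  solo$consistency <- c(0.9, 0.9)
  expect_warning(p3 <- select_parent_pair(solo, theta = 0.95), "relaxed")
  expect_true(p3$relaxed)
  solo$consistency <- c(0.1, 0.9)
  expect_error(suppressWarnings(select_parent_pair(solo, theta = 0.95)),
               "Fewer than 2")
})

test_that("paired t test reproduces the textbook statistic", {
  # d = (1, 2, 3): t = 2 / (1/sqrt(3)) = 3.4641, df = 2, p ~ 0.0742
  res <- paired_t_test(c(2, 4, 6), c(1, 2, 3))
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-4)
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)
  expect_equal(res$stars, "")

  swap <- paired_t_test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(swap$t, -res$t)
  expect_equal(swap$p, res$p)

  same <- paired_t_test(c(1, 2), c(1, 2))
  expect_true(same$degenerate)
  expect_equal(same$p, 1)
  expect_equal(same$stars, "")

  expect_error(paired_t_test(1:3, 1:2), "equal length")

  # oracle: stats::t.test on random paired samples
  withr::local_seed(99)
  for (i in 1:100) {
    n <- sample(3:10, 1)
    a <- rnorm(n); b <- rnorm(n)
    ref <- t.test(a, b, paired = TRUE)
    got <- paired_t_test(a, b)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter))
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("star thresholds follow the 0.05 / 0.01 / 0.001 convention", {
  expect_equal(p_stars(c(0.0009, 0.001, 0.009, 0.01, 0.049, 0.05, 0.5)),
               c("***", "**", "**", "*", "*", "", ""))
})

test_that("significance table matches per-cell recomputation", {
  d <- trial_design(c("A", "B"), concentrations = c(1, 4, 40),
                    replicates = 3, plants_per_replicate = 2)
  p <- generator_params(c("A", "B"), s = c(0, 1), sigma = 0.05)
  obs <- generate_trial(d, p, seed = 8)
  tab <- significance_table(obs, c("B", "A"), d)
  reps <- replicate_means(obs)
  for (i in seq_len(nrow(tab))) {
    trait <- tab$trait[i]; cc <- tab$concentration[i]
    val <- function(v, conc) {
      x <- reps[reps$variety == v & reps$trait == trait &
                  reps$concentration == conc, ]
      x$value[order(x$replicate)]
    }
    relof <- function(v) val(v, cc) / mean(val(v, 40))
    ref <- paired_t_test(relof("B"), relof("A"))
    expect_equal(tab$t[i], ref$t, tolerance = 1e-12)
    expect_equal(tab$p[i], ref$p, tolerance = 1e-12)
  }
  expect_error(significance_table(obs, c("A", "A"), d), "distinct")
})

test_that("identical varieties give an all-degenerate significance table", {
  d <- trial_design(c("A", "B"), concentrations = c(1, 4, 40),
                    replicates = 3, plants_per_replicate = 2)
  p <- generator_params(c("A", "B"), s = c(0.5, 0.5), sigma = 0)
  obs <- generate_trial(d, p, seed = 1)
  tab <- significance_table(obs, c("A", "B"), d)
  expect_true(all(tab$degenerate))
  expect_true(all(tab$stars == ""))
  expect_true(all(tab$p == 1))
})

test_that("a planted tolerance gap lights up low K but not the reference", {
  d <- trial_design(c("S", "T"))
  p <- generator_params(c("S", "T"), s = c(0, 1), sigma = 0.02)
  obs <- generate_trial(d, p, seed = 12)
  tab <- significance_table(obs, c("T", "S"), d,
                            traits = c("plant_height_cm",
                                       "fresh_weight_sheath_g"))
  low <- tab[tab$concentration %in% c(1, 2), ]
  ref <- tab[tab$concentration == 40, ]
  expect_true(all(low$stars == "***"))
  expect_true(all(ref$stars != "***"))
})
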