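test_that("trial tables round-trip through CSV exactly", {
  obs <- dplyr::bind_rows(
    make_obs(plant = 1L, plant_height_cm = 31.23456789012345),
    make_obs(plant = 2L, k_conc_blade_g_per_100g = 1 / 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_table(obs, path)
  back <- read_trial_table(path)
  expect_equal(nrow(back), 2)
  expect_identical(as.data.frame(back), as.data.frame(obs))

  d <- default_design()
  big <- generate_trial(d, generator_params(d$varieties), seed = 5)
  expect_equal(nrow(big), 12 * 10 * 3 * 6)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_trial_table(big, path2)
  expect_identical(as.data.frame(read_trial_table(path2)), as.data.frame(big))
})

test_that("schema, parse and key errors are reported with context", {
  obs <- dplyr::bind_rows(make_obs(plant = 1L), make_obs(plant = 2L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_table(obs, path)

  crippled <- readr::read_csv(path, show_col_types = FALSE)
  crippled$k_conc_sheath_g_per_100g <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(crippled, path2)
  expect_error(read_trial_table(path2), "k_conc_sheath")

  mangled <- readr::read_csv(path, show_col_types = FALSE)
  mangled$plant_height_cm <- as.character(mangled$plant_height_cm)
  mangled$plant_height_cm[2] <- "tall"
  path3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(mangled, path3)
  expect_error(read_trial_table(path3), "row 2")

  dup <- dplyr::bind_rows(make_obs(plant = 1L), make_obs(plant = 1L))
  path4 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dup, path4)
  expect_error(read_trial_table(path4), "Duplicate")

  expect_error(write_trial_table(obs[0, ], tempfile()), "nonempty")
})

test_that("validate_trial reports completeness and invariant findings", {
  d <- trial_design(c("A", "B"), concentrations = c(1, 4, 40),
                    replicates = 2, plants_per_replicate = 1)
  obs <- dplyr::bind_rows(lapply(c("A", "B"), function(v)
    dplyr::bind_rows(lapply(c(1, 4, 40), function(cc)
      dplyr::bind_rows(lapply(1:2, function(r)
        make_obs(variety = v, concentration = cc, replicate = r)))))))
  expect_equal(nrow(validate_trial(obs, d)), 0)

  gap <- obs[!(obs$variety == "A" & obs$concentration_mg_per_l == 4 &
                 obs$replicate == 2), ]
  rep <- validate_trial(gap, d)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$check, "missing_cell")
  expect_equal(rep$replicate, 2L)

  bad <- obs
  bad$dry_weight_root_g[3] <- bad$fresh_weight_root_g[3] + 0.01
  rep2 <- validate_trial(bad, d)
  expect_equal(nrow(rep2), 1)
  expect_equal(rep2$check, "invariant")
  expect_equal(rep2$plant, bad$plant[3])
  expect_match(rep2$message, "root")

  alien <- dplyr::bind_rows(obs, make_obs(variety = "Z", concentration = 1))
  expect_true("unknown_variety" %in% validate_trial(alien, d)$check)
})

test_that("summarize_treatments aggregates plants then replicates", {
  # replicate means 10, 20, 30 -> mean 20, sample sd 10, n 3
  obs <- dplyr::bind_rows(lapply(1:3, function(r)
    make_obs(replicate = r, plant_height_cm = 10 * r)))
  s <- summarize_treatments(obs)
  h <- s[s$trait == "plant_height_cm", ]
  expect_equal(h$mean, 20)
  expect_equal(h$sd, 10)
  expect_equal(h$n, 3L)

  # identical plants -> sd 0 for every trait
  same <- dplyr::bind_rows(lapply(1:3, function(r) make_obs(replicate = r)))
  expect_true(all(summarize_treatments(same)$sd == 0))

  # within-replicate spread but equal replicate means -> sd 0 across reps:
  # only visible under two-stage aggregation
  spread <- dplyr::bind_rows(lapply(1:3, function(r) dplyr::bind_rows(
    make_obs(replicate = r, plant = 1L, plant_height_cm = 20 - r),
    make_obs(replicate = r, plant = 2L, plant_height_cm = 20 + r))))
  h2 <- summarize_treatments(spread)
  h2 <- h2[h2$trait == "plant_height_cm", ]
  expect_equal(h2$mean, 20)
  expect_equal(h2$sd, 0)

  expect_error(summarize_treatments(obs[0, ]), "nonempty")
})

test_that("summaries include per-plant totals and are order-invariant", {
  d <- trial_design(c("A", "B"), concentrations = c(1, 4, 40),
                    replicates = 2, plants_per_replicate = 2)
  obs <- generate_trial(d, generator_params(d$varieties), seed = 3)
  s1 <- summarize_treatments(obs)
  expect_true(all(c("total_fresh_weight_g", "total_dry_weight_g") %in%
                    s1$trait))
  tfw <- s1$mean[s1$trait == "total_fresh_weight_g"]
  parts <- sapply(c("fresh_weight_root_g", "fresh_weight_sheath_g",
                    "fresh_weight_blade_g"),
                  function(t) s1$mean[s1$trait == t])
  expect_equal(tfw, rowSums(parts))

  shuffled <- obs[rev(seq_len(nrow(obs))), ]
  s2 <- summarize_treatments(shuffled)
  expect_equal(dplyr::arrange(as.data.frame(s1), variety, concentration, trait),
               dplyr::arrange(as.data.frame(s2), variety, concentration, trait))
})

test_that("scaling a trait scales its treatment means and sds linearly", {
  d <- trial_design(c("A", "B"), concentrations = c(1, 4, 40),
                    replicates = 3, plants_per_replicate = 2)
  obs <- generate_trial(d, generator_params(d$varieties), seed = 9)
  a <- 7.3
  scaled <- obs
  scaled$plant_height_cm <- scaled$plant_height_cm * a
  s1 <- summarize_treatments(obs)
  s2 <- summarize_treatments(scaled)
  h1 <- s1[s1$trait == "plant_height_cm", ]
  h2 <- s2[s2$trait == "plant_height_cm", ]
  expect_equal(h2$mean, a * h1$mean)
  expect_equal(h2$sd, a * h1$sd)
})

test_that("design round-trips through YAML and JSON config files", {
  d <- default_design()
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_design(d, path)
    expect_equal(read_design(path), d)
  }
  expect_error(trial_design("A", reference_concentration = 39), "not among")
  expect_error(trial_design(c("A", "B"), replicates = 1), "at least 2")
})
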