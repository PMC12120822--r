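test_that("noiseless trend fits reproduce the generator exactly", {
  np <- noiseless_pipeline()
  m <- np$cohort$model
  tm <- fit_trend(np$features, "ccs")
  expect_equal(unname(tm$coefficients["cc"]), m$ccs_per_carbon,
               tolerance = 1e-8)
  expect_equal(unname(tm$coefficients["db"]), m$ccs_per_db, tolerance = 1e-8)
  expect_equal(unname(tm$coefficients["alkyl"]), m$ccs_ether,
               tolerance = 1e-7)
  expect_equal(unname(tm$coefficients["alkenyl"]), m$ccs_ether + m$ccs_delta1,
               tolerance = 1e-7)
  expect_equal(tm$rss, 0, tolerance = 1e-10)
  tr <- fit_trend(np$features, "rt", transform = "log")
  expect_equal(unname(tr$coefficients["cc"]), m$rt_per_carbon_log,
               tolerance = 1e-8)
  expect_equal(unname(tr$coefficients["db"]), m$rt_per_db_log,
               tolerance = 1e-8)
  expect_equal(unname(tr$coefficients["alkenyl"]),
               m$rt_ether_log + m$rt_delta1_log, tolerance = 1e-7)
  expect_equal(tr$rss, 0, tolerance = 1e-10)
})

test_that("degenerate and constant designs behave as specified", {
  np <- noiseless_pipeline()
  flat <- np$features
  flat$ccs <- 268.4
  tm <- fit_trend(flat, "ccs")
  expect_equal(unname(tm$coefficients[c("cc", "db", "alkyl", "alkenyl")]),
               rep(0, 4), tolerance = 1e-10)
  acyl_only <- np$features[etherims:::species_info(
    np$features$species)$linkage == "acyl", ]
  expect_error(fit_trend(acyl_only, "ccs"), "linkage")
  one_cc <- np$features[etherims:::species_info(
    np$features$species)$cc == 34, ]
  expect_error(fit_trend(one_cc, "ccs"), "CC|linkage|species")
})

test_that("deletion SS decomposition and scale equivariance hold", {
  p <- default_pipeline()
  tm <- fit_trend(p$features, "ccs")
  expect_true(all(tm$ss_deleted >= 0))
  # scaling the response by c scales coefficients by c and SS by c^2
  scaled <- p$features
  scaled$ccs <- scaled$ccs * 3
  tm3 <- fit_trend(scaled, "ccs")
  expect_equal(unname(tm3$coefficients), unname(tm$coefficients) * 3,
               tolerance = 1e-8)
  expect_equal(tm3$rss, tm$rss * 9, tolerance = 1e-8)
  expect_equal(unname(tm3$ss_deleted), unname(tm$ss_deleted) * 9,
               tolerance = 1e-8)
  # the extended (interaction) model can only reduce the RSS
  ti <- fit_trend(p$features, "ccs", interactions = TRUE)
  expect_lte(ti$rss, tm$rss + 1e-10)
})

test_that("predict evaluates the linear model", {
  np <- noiseless_pipeline()
  tm <- fit_trend(np$features, "ccs")
  # zero-residual fit: predictions reproduce training values
  sm <- tm$species_means
  expect_equal(predict(tm, sm$species), sm$value, tolerance = 1e-8)
  expect_equal(predict(tm, "PE 36:1") - predict(tm, "PE 34:1"),
               2 * unname(tm$coefficients["cc"]), tolerance = 1e-10)
  # monotone decrease in DB when the DB coefficient is negative
  preds <- predict(tm, sprintf("PE 36:%d", 0:7))
  expect_true(all(diff(preds) < 0))
  # log-transform model predicts on the original (minutes) scale
  tr <- fit_trend(np$features, "rt", transform = "log")
  expect_equal(predict(tr, tr$species_means$species),
               tr$species_means$value, tolerance = 1e-8)
})

test_that("measured-vs-predicted comparison recovers proportional bias", {
  p <- default_pipeline()
  f <- p$features
  sp_means <- stats::aggregate(ccs ~ species, data = f, FUN = mean)
  # perfect agreement: slope 1, zero residual
  perfect <- data.frame(species = sp_means$species,
                        ccs_pred_a2 = sp_means$ccs)
  fits <- compare_to_predictions(sp_means, perfect)
  expect_equal(fits$slope, rep(1, 3), tolerance = 1e-10)
  expect_identical(fits$subclass, c("acyl", "alkyl", "alkenyl"))
  # constructed subclass bias is recovered exactly as the slope
  biased <- synthetic_predicted_table(p$cohort,
                                      bias = c(acyl = 1.01, alkyl = 1.09,
                                               alkenyl = 1.17))
  sp_true <- data.frame(species = p$cohort$species$species,
                        ccs = p$cohort$species$true_ccs)
  fits2 <- compare_to_predictions(sp_true, biased)
  expect_equal(fits2$slope, c(1.01, 1.09, 1.17), tolerance = 1e-9)
  # on measured (noisy) values the slope still lands within its own SD
  fits3 <- compare_to_predictions(sp_means, biased)
  expect_true(all(abs(fits3$slope - c(1.01, 1.09, 1.17)) <=
                    3 * fits3$slope_sd))
  # noise raises RSS, hence the AIC relative to the noiseless comparison
  expect_true(all(fits3$aic > fits2$aic))
  # molecular-level predictions are averaged to species level first
  mol <- generate_cohort(cohort_design(seed = 9), noiseless(),
                         molecular = TRUE)
  mol_pred <- synthetic_predicted_table(mol, bias = c(acyl = 1, alkyl = 1,
                                                      alkenyl = 1))
  mol_meas <- data.frame(species = etherims:::to_species_level(
    mol$species$species), ccs = mol$species$true_ccs)
  fits4 <- compare_to_predictions(mol_meas, mol_pred)
  expect_equal(fits4$slope, rep(1, 3), tolerance = 1e-9)
  # subclasses below the match threshold are skipped with a warning
  few <- sp_means[etherims:::species_info(sp_means$species)$linkage !=
                    "alkenyl" | sp_means$species == "PE P-38:5", ]
  expect_warning(fits5 <- compare_to_predictions(few, perfect),
                 "subclass-skipped")
  expect_identical(fits5$subclass, c("acyl", "alkyl"))
})
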