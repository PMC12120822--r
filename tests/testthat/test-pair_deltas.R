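test_that("pair enumeration follows the matching rules", {
  expect_identical(
    enumerate_pairs(c("PE 34:1", "PE 36:1"), "plus2CH2")$species_b, "PE 36:1")
  iso <- enumerate_pairs(c("PE O-38:6", "PE P-38:5"),
                         "alkenyl_vs_alkyl_isobar")
  expect_identical(nrow(iso), 1L)
  expect_identical(iso$species_a, "PE O-38:6")
  expect_identical(iso$species_b, "PE P-38:5")
  expect_equal(mz_deprotonated(iso$species_a), mz_deprotonated(iso$species_b))
  d1 <- enumerate_pairs(c("PE O-38:5", "PE P-38:5"), "plusDB_delta1")
  expect_identical(nrow(d1), 1L)
  # no cross-linkage or cross-DB matches sneak in
  expect_identical(nrow(enumerate_pairs(c("PE 34:1", "PE O-36:1"),
                                        "plus2CH2")), 0L)
  expect_identical(nrow(enumerate_pairs(c("PE O-38:5", "PE P-38:4"),
                                        "plusDB_delta1")), 0L)
  # expected counts on the default grid (4 CC x 8 DB x 3 linkages)
  grid <- sprintf("PE %s%d:%d",
                  rep(c("", "O-", "P-"), each = 32),
                  rep(rep(c(34, 36, 38, 40), each = 8), 3), 0:7)
  expect_identical(nrow(enumerate_pairs(grid, "plus2CH2")), 72L)
  expect_identical(nrow(enumerate_pairs(grid, "plusDB_downstream")), 84L)
  expect_identical(nrow(enumerate_pairs(grid, "plusDB_delta1")), 32L)
  expect_identical(nrow(enumerate_pairs(grid, "alkenyl_vs_alkyl_isobar")),
                   28L)
})

test_that("zero-noise deltas equal the generating effects exactly", {
  np <- noiseless_pipeline()
  f <- np$features
  deltas <- compute_deltas(f, enumerate_all_pairs(unique(f$species)))
  s <- summarize_deltas(deltas)
  get <- function(tr, dim) s$mean[s$transformation == tr & s$dimension == dim]
  expect_equal(get("plus2CH2", "ccs"), 5.4, tolerance = 1e-9)
  expect_equal(get("plusDB_downstream", "ccs"), -1.0, tolerance = 1e-9)
  expect_equal(get("plusDB_delta1", "ccs"), 0.3, tolerance = 1e-9)
  expect_equal(get("alkenyl_vs_alkyl_isobar", "ccs"), 1.3, tolerance = 1e-9)
  expect_equal(get("plusDB_delta1", "rt_pct"), -2.0, tolerance = 1e-9)
  expect_equal(get("plusDB_downstream", "rt_pct"), -11.7, tolerance = 1e-9)
  expect_equal(get("alkenyl_vs_alkyl_isobar", "rt_pct"),
               100 * (0.980 / 0.883 - 1), tolerance = 1e-9)
  # per-pair deltas are exact too, not just means
  ccs_2ch2 <- deltas$delta_ccs[deltas$transformation == "plus2CH2"]
  expect_equal(ccs_2ch2, rep(5.4, length(ccs_2ch2)), tolerance = 1e-9)
  # composition identity: isobar == delta1 - downstream (additive CCS)
  expect_equal(get("alkenyl_vs_alkyl_isobar", "ccs"),
               get("plusDB_delta1", "ccs") - get("plusDB_downstream", "ccs"),
               tolerance = 1e-9)
  # and the log-RT analogue
  expect_equal(log(1 + get("alkenyl_vs_alkyl_isobar", "rt_pct") / 100),
               log(1 + get("plusDB_delta1", "rt_pct") / 100) -
                 log(1 + get("plusDB_downstream", "rt_pct") / 100),
               tolerance = 1e-9)
})

test_that("sign expectations hold on the default noisy cohort", {
  p <- default_pipeline()
  s <- summarize_deltas(compute_deltas(p$features,
                                       enumerate_all_pairs(
                                         unique(p$features$species))))
  get <- function(tr, dim) s$mean[s$transformation == tr & s$dimension == dim]
  expect_gt(get("plus2CH2", "ccs"), 0)
  expect_lt(get("plusDB_downstream", "ccs"), 0)
  expect_lt(get("plusDB_downstream", "rt_pct"), 0)
  expect_gt(get("alkenyl_vs_alkyl_isobar", "ccs"), 0)
})

test_that("pairs without common samples are bridged or dropped", {
  np <- noiseless_pipeline()
  f <- np$features
  # isobar pairs span genotypes: bridged through tissue means, n = tissues
  iso <- compute_deltas(f, enumerate_pairs(unique(f$species),
                                           "alkenyl_vs_alkyl_isobar"))
  expect_true(all(iso$n_samples_used == 3L))
  # a pair whose transformed species is absent everywhere is dropped
  pairs <- data.frame(species_a = "PE 34:1", species_b = "PE 34:2",
                      transformation = "plusDB_downstream")
  sub <- f[f$species != "PE 34:2", ]
  expect_warning(res <- compute_deltas(sub, pairs), "pair-dropped")
  expect_identical(nrow(res), 0L)
  # summary over remaining pairs is unaffected by the dropped one
  keep <- enumerate_pairs(c("PE 34:1", "PE 36:1"), "plus2CH2")
  both <- rbind(keep, pairs)
  expect_warning(res2 <- compute_deltas(sub, both), "pair-dropped")
  expect_equal(summarize_deltas(res2)$n_pairs, c(1L, 1L))
  expect_error(compute_deltas(np$cohort$features, keep), "calibrated")
})
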