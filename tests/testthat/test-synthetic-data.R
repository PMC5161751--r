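test_that("ground truth honours proportions, determinism and the RNG protocol", {
  ## degenerate mixture: everything nonsubstrate, no kinetic parameters
  cfg0 <- sim_config(n_sites = 40, seed = 2, class_proportions =
                       c(early = 0, mid = 0, late = 0, nonsubstrate = 1))
  gt0 <- make_ground_truth(cfg0)
  expect_true(all(gt0$temporal_class_true == "nonsubstrate"))
  expect_true(all(is.na(gt0$K_true)))

  ## determinism: same config, byte-identical output
  cfg <- sim_config(n_sites = 200, seed = 7)
  expect_identical(make_ground_truth(cfg), make_ground_truth(cfg))

  ## documented protocol: class draw is the first draw of the seeded stream,
  ## reproduced here independently
  cfg2 <- sim_config(n_sites = 1000, seed = 7, class_proportions =
                       c(early = .1, mid = .1, late = .4, nonsubstrate = .4))
  gt <- make_ground_truth(cfg2)
  set.seed(cdkphos:::sub_seed(7L, "ground_truth"))
  expected <- sample(c("early", "mid", "late", "nonsubstrate"), 1000,
                     replace = TRUE, prob = c(.1, .1, .4, .4))
  expect_identical(gt$temporal_class_true, expected)

  ## invariants: substrates have +1 P and positive half-life
  sub <- gt$temporal_class_true != "nonsubstrate"
  expect_true(all(substr(gt$window[sub], 17, 17) == "P"))
  expect_true(all(substr(gt$window, 16, 16) %in% c("S", "T", "Y")))
  expect_true(all(log(2) / gt$K_true[sub] > 0))
  ## threshold ordering is built in: early > mid > late median IC50
  med <- tapply(gt$ic50_true[sub], gt$temporal_class_true[sub], median)
  expect_gt(med[["early"]], med[["mid"]])
  expect_gt(med[["mid"]], med[["late"]])

  expect_error(sim_config(class_proportions = c(early = 1, mid = 1,
                                                late = 0, nonsubstrate = 0)),
               "simplex")
})

test_that("decay simulation matches the closed form and handles stages", {
  truth <- manual_truth(c("late", "nonsubstrate"),
                        K = c(log(2) / 2.2, NA), plateau = c(0, NA))
  cfg <- noiseless_config()
  m <- simulate_decay_experiment(truth, cfg, "mitosis",
                                 times = c(0, 2.2, 6))
  expect_equal(m[1, 2], 0.5, tolerance = 1e-12)  # half-life identity
  expect_equal(unname(m[2, ]), c(1, 1, 1))       # nonsubstrate flat at 1

  truth2 <- manual_truth("late", K = 0.3151, plateau = 0.1)
  m2 <- simulate_decay_experiment(truth2, cfg, "mitosis")
  expect_equal(m2[1, "M06"], (1 - 0.1) * exp(-0.3151 * 6) + 0.1,
               tolerance = 1e-12)

  ## S-phase flavour: late sites sit flat below the criterion-i bound
  ms <- simulate_decay_experiment(truth2, cfg, "sphase")
  expect_true(all(ms[1, ] == cfg$sphase_late_level))

  expect_error(simulate_decay_experiment(truth2, cfg, times = c(-1, 0, 3)),
               "negative")
})

test_that("titration simulation matches the four-parameter logistic", {
  truth <- manual_truth("late", ic50 = 0.2, hill = -1.4, top = 1,
                        bottom = 0.1)
  cfg <- noiseless_config()
  m <- simulate_titration_experiment(truth, cfg,
                                     doses = c(0, 0.05, 0.2, 1, 5, 20))
  expect_equal(m[1, 1], 1)                        # zero dose = top
  expect_equal(m[1, 3], (1 + 0.1) / 2, tolerance = 1e-12)  # midpoint at IC50
  ## saturation limit: far above IC50 the curve sits at bottom
  truth2 <- manual_truth("late", ic50 = 0.01, hill = -4)
  m2 <- simulate_titration_experiment(truth2, cfg,
                                      doses = c(0, 0.005, 0.05, 0.5, 2, 5, 20))
  expect_equal(m2[1, "T06"], 0.1, tolerance = 1e-3)
  expect_error(simulate_titration_experiment(truth, cfg,
                                             doses = c(0, -1, 2)), "positive")
  expect_error(simulate_titration_experiment(truth, cfg,
                                             doses = c(1, 2, 3)), "control")
})

test_that("cell-cycle simulation orders classes and respects genotypes", {
  cfg <- noiseless_config()
  ## activity below every threshold: push cycle start levels to zero
  truth <- manual_truth(c("early", "late"), ic50 = c(3.7, 0.2),
                        hill = c(-3.6, -1.4))
  cfg_low <- cfg
  cfg_low$cycle_model$start_levels <- rep(1e-9, 3)
  m0 <- simulate_cell_cycle_experiment(truth, cfg_low, "single_cyclin",
                                       times = 0)
  expect_equal(unname(m0[, 1]), truth$bottom_true, tolerance = 1e-6)

  ## zero-boost wild type is byte-identical to the single-cyclin baseline
  cfgn <- cfg
  cfgn$cycle_model$wt_generic_boost <- 1
  cfgn$cycle_model$wt_mid_boost <- 1
  expect_identical(simulate_cell_cycle_experiment(truth, cfgn, "wt"),
                   simulate_cell_cycle_experiment(truth, cfgn,
                                                  "single_cyclin"))

  ## an early site (10x the late IC50) reaches half-occupancy earlier under
  ## the rising ramp; oracle = direct evaluation of the trajectories
  tr <- manual_truth(c("early", "late"), ic50 = c(2.0, 0.2),
                     hill = c(-1.4, -1.4))
  mm <- simulate_cell_cycle_experiment(tr, cfg, "single_cyclin")
  tms <- attr(mm, "times")
  in2 <- tms >= 25 & tms <= 110     # second (full) cycle
  half_cross <- function(y) {
    yy <- y[in2] / max(y[in2])
    tms[in2][which(yy >= 0.5)[1]]
  }
  expect_lt(half_cross(mm[1, ]), half_cross(mm[2, ]))
  expect_error(simulate_cell_cycle_experiment(tr, cfg, "mutant"))
})

test_that("rate simulation is linear in stage activity", {
  truth <- manual_truth(rep("early", 5), sensitivity = c(0.5, 0.8, 1, 1.2, 1.5))
  cfg <- noiseless_config()
  slope_of <- function(m, tms) {
    apply(m, 1, function(y) coef(lm(y[tms <= 2] ~ tms[tms <= 2]))[2])
  }
  ## stage activity zero: flat at the 0-min value
  cfg0 <- cfg; cfg0$stage_activity <- c(G1 = 0, M = 1)
  m0 <- simulate_rate_experiment(truth, cfg0, "G1")
  expect_true(all(m0 == m0[, 1]))
  ## doubling activity doubles the 0-2 min slope
  cfg2 <- cfg; cfg2$stage_activity <- c(A = 0.1, B = 0.2)
  tms <- cfg$rate_times
  sA <- slope_of(simulate_rate_experiment(truth, cfg2, "A"), tms)
  sB <- slope_of(simulate_rate_experiment(truth, cfg2, "B"), tms)
  expect_equal(unname(sB / sA), rep(2, 5), tolerance = 1e-9)
  ## configured stage ratios recovered from noiseless slopes within 2%
  stages <- c("G1", "S", "G2", "M")
  slopes <- sapply(stages, function(s)
    median(slope_of(simulate_rate_experiment(truth, cfg, s), tms)))
  rel <- 100 * slopes / slopes[["M"]]
  expect_equal(unname(rel), c(1.7, 7.3, 36, 100), tolerance = 0.02)
  expect_error(simulate_rate_experiment(truth, cfg, "G0"), "unknown stage")
})

test_that("noise and missingness behave as configured", {
  cfg <- sim_config(n_sites = 400, seed = 9, noise_sd = 0.05,
                    missing_rate = 0.1)
  gt <- make_ground_truth(cfg)
  m <- simulate_decay_experiment(gt, cfg, "mitosis")
  ## realized missing fraction within 3 binomial SDs of the target
  n <- length(m)
  sd3 <- 3 * sqrt(0.1 * 0.9 / n)
  expect_lt(abs(mean(is.na(m)) - 0.1), sd3)
  ## same config => identical matrices
  expect_identical(m, simulate_decay_experiment(gt, cfg, "mitosis"))
  ## low-biased mode prefers removing low values
  cfgb <- cfg; cfgb$missing_mode <- "low_biased"
  mb <- simulate_decay_experiment(gt, cfgb, "mitosis")
  m0 <- simulate_decay_experiment(gt, noiseless_config(n_sites = 400, seed = 9),
                                  "mitosis")
  expect_lt(mean(m0[is.na(mb)]), mean(m0[!is.na(mb)]))
})

test_that("site tables round-trip through the reader", {
  cfg <- sim_config(n_sites = 60, seed = 5)
  gt <- make_ground_truth(cfg)
  m <- simulate_decay_experiment(gt, cfg, "mitosis")
  map <- experiment_map(colnames(m), "decay_mitosis",
                        timepoint = cfg$decay_times)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(gt, m, path, map, decoys = 10)
  expect_equal(length(readLines(path)), 60 + 10 + 1)  # rows + decoys + header
  got <- read_site_table(path, map)
  keep <- gt$localization_prob > 0.9
  expect_identical(rownames(got$ratios), gt$site_id[keep])
  expect_equal(got$ratios, m[keep, ], tolerance = 1e-6)
  expect_false(any(grepl("^REV__", rownames(got$ratios))))
})
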