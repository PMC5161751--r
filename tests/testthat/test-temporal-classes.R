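test_that("hierarchical clustering separates groups and is monotone", {
  set.seed(14)
  g1 <- matrix(rep(c(1, 1, 1), each = 5), nrow = 5)
  g2 <- matrix(rep(c(5, 5, 5), each = 5), nrow = 5)
  m <- rbind(g1, g2) + rnorm(30, 0, 0.01)
  rownames(m) <- paste0("s", 1:10); colnames(m) <- paste0("t", 1:3)
  hc <- hierarchical_cluster(m, k = 2)
  expect_equal(length(unique(hc$clusters[1:5])), 1)
  expect_equal(length(unique(hc$clusters[6:10])), 1)
  expect_false(hc$clusters[1] == hc$clusters[10])

  ## average-linkage merge heights never decrease
  m2 <- matrix(rnorm(30), 10,
               dimnames = list(paste0("r", 1:10), paste0("c", 1:3)))
  hc2 <- hierarchical_cluster(m2)
  expect_true(all(diff(hc2$tree$height) >= -1e-12))
  expect_error(hierarchical_cluster(m2[1, , drop = FALSE]), "at least 2")
})

test_that("clustering agrees with a brute-force agglomeration oracle", {
  set.seed(15)
  m <- matrix(rnorm(20 * 5), 20,
              dimnames = list(paste0("r", 1:20), paste0("c", 1:5)))
  hc <- hierarchical_cluster(m, k = 4)
  ref <- brute_average_linkage(m, k = 4)
  expect_true(same_partition(hc$clusters, ref$membership))
  expect_equal(hc$tree$height[1:16], ref$heights, tolerance = 1e-9)
})

test_that("temporal classes recover the generating archetypes", {
  ## archetype sites drawn at the class-median dose-response parameters
  n_per <- 25
  cls <- rep(c("early", "mid", "late"), each = n_per)
  tr <- manual_truth(cls,
                     ic50 = rep(c(3.7, 1.7, 0.2), each = n_per),
                     hill = rep(c(-3.6, -1.33, -1.41), each = n_per))
  cfg <- sim_config(n_sites = length(cls), seed = 19, noise_sd = 0.05,
                    missing_rate = 0)
  m <- simulate_cell_cycle_experiment(tr, cfg, "single_cyclin")
  tms <- attr(m, "times")
  hc <- hierarchical_cluster(m, k = 6)
  got <- assign_temporal_classes(m, hc$clusters, tms,
                                 list(g1s = 45, g2m = 60),
                                 cycle_window = c(25, 110))
  acc <- mean(got$label[match(tr$site_id, got$site_id)] == cls)
  expect_gte(acc, 0.95)

  ## class assignment is invariant to uniform rescaling
  got2 <- assign_temporal_classes(m * 3.7, hc$clusters, tms,
                                  list(g1s = 45, g2m = 60),
                                  cycle_window = c(25, 110))
  expect_identical(got$label, got2$label)

  ## flat trajectories are unassigned; manual overrides win
  flat <- matrix(1 + rnorm(40, 0, 0.005), 4,
                 dimnames = list(paste0("f", 1:4), NULL))
  colnames(flat) <- paste0("C", 1:10)
  gotf <- assign_temporal_classes(
    flat, setNames(rep(1L, 4), rownames(flat)), seq(10, 100, 10),
    list(g1s = 45, g2m = 60))
  expect_true(all(gotf$label == "unassigned"))
  over <- data.frame(site_id = "f2", label = "mid")
  goto <- assign_temporal_classes(
    flat, setNames(rep(1L, 4), rownames(flat)), seq(10, 100, 10),
    list(g1s = 45, g2m = 60), override = over)
  expect_equal(goto$label[goto$site_id == "f2"], "mid")
  expect_equal(goto$source[goto$site_id == "f2"], "manual_override")
  expect_error(assign_temporal_classes(flat, setNames(rep(1L, 4),
                                                      rownames(flat)),
                                       seq(10, 100, 10), list(g1s = 45)),
               "g2m")
})

test_that("specificity score is exactly 1 for identical genotypes", {
  dose <- c(0.005, 0.015, 0.05, 0.15, 0.3, 1, 2.5, 5, 7.5, 10, 20)
  cf <- fit_four_pl(dose, four_pl(dose, 1, 0.1, log10(1.7), -1.3))
  lf <- fit_four_pl(dose, four_pl(dose, 1, 0.08, log10(0.2), -1.4))
  vals <- expand.grid(genotype = c("wt", "dCCP"), timepoint = c(48, 56))
  cvals <- cbind(vals, value = c(0.5, 0.5, 0.62, 0.62))
  lvals <- cbind(vals, value = c(0.3, 0.3, 0.41, 0.41))
  sc <- specificity_score(cf, lf, cvals, lvals, pair = c("wt", "dCCP"))
  expect_equal(sc$score, c(1, 1), tolerance = 1e-9)

  ## hand-verified arithmetic: scores reduce to ratios of interpolated doses
  cvals2 <- cvals; cvals2$value[cvals2$genotype == "wt"] <- c(0.7, 0.8)
  sc2 <- specificity_score(cf, lf, cvals2, lvals, pair = c("wt", "dCCP"))
  inv <- function(f, y) 10^(f$logIC50 - log10((f$Top - y) / (y - f$Bottom)) / f$Hill)
  for (i in seq_len(2)) {
    tp <- sc2$timepoint[i]
    expected <- (inv(lf, 0.3 + 0.11 * (tp == 56)) /
                   inv(cf, cvals2$value[cvals2$genotype == "wt" &
                                          cvals2$timepoint == tp])) /
      (inv(lf, 0.3 + 0.11 * (tp == 56)) /
         inv(cf, 0.5 + 0.12 * (tp == 56)))
    expect_equal(sc2$score[i], expected, tolerance = 1e-12)
  }

  ## out-of-range medians are flagged, never clamped
  cvals3 <- cvals; cvals3$value[1] <- 0.05   # below Bottom
  sc3 <- specificity_score(cf, lf, cvals3, lvals, pair = c("wt", "dCCP"))
  expect_true(sc3$flagged[sc3$timepoint == 48])
})

test_that("a boosted mid class scores above 1 while early stays near 1", {
  cfg <- sim_config(n_sites = 300, seed = 23, noise_sd = 0.02,
                    missing_rate = 0, class_proportions =
                      c(early = 0.2, mid = 0.2, late = 0.6, nonsubstrate = 0))
  gt <- make_ground_truth(cfg)
  m_wt <- simulate_cell_cycle_experiment(gt, cfg, "wt")
  m_d <- simulate_cell_cycle_experiment(gt, cfg, "dCCP")
  tms <- attr(m_wt, "times")
  s_tp <- tms[tms >= 45 & tms <= 60]
  doses <- cfg$dose_grid
  tit <- simulate_titration_experiment(gt, cfg)
  med_fit <- function(ids) {
    med <- apply(tit[ids, , drop = FALSE], 2, median)
    fit_four_pl(doses, med / med[1])
  }
  med_vals <- function(ids) {
    rbind(data.frame(genotype = "wt", timepoint = tms,
                     value = apply(m_wt[ids, , drop = FALSE], 2, median)),
          data.frame(genotype = "dCCP", timepoint = tms,
                     value = apply(m_d[ids, , drop = FALSE], 2, median)))
  }
  ids <- split(gt$site_id, gt$temporal_class_true)
  lf <- med_fit(ids$late)
  lv <- med_vals(ids$late); lv <- lv[lv$timepoint %in% s_tp, ]
  scores <- sapply(c("early", "mid"), function(cl) {
    cv <- med_vals(ids[[cl]]); cv <- cv[cv$timepoint %in% s_tp, ]
    median(specificity_score(med_fit(ids[[cl]]), lf, cv, lv,
                             pair = c("wt", "dCCP"))$score, na.rm = TRUE)
  })
  expect_gt(scores[["mid"]], 1.5)
  expect_lt(abs(scores[["early"]] - 1), 0.35)
})

test_that("genotype ratio screen excludes bad controls and flags losses", {
  test_r <- c(a = 1, b = 0.95, c = 0.1, d = 1.05, e = 0.08, f = 0.15)
  ctrl <- c(a = 1, b = 0.4, c = 1.1, d = 1, e = 0.9, f = 1)
  got <- genotype_ratio_screen(test_r, ctrl,
                               positive_controls = c("e", "f"))
  expect_false("b" %in% got$site_id)            # control outside [0.5, 2]
  expect_false("e" %in% got$site_id)            # positive control not reported
  expect_true(got$flagged[got$site_id == "c"])  # at least as decreased
  expect_false(got$flagged[got$site_id == "a"])

  ## all ratios 1: nothing flagged
  got1 <- genotype_ratio_screen(setNames(rep(1, 3), letters[1:3]),
                                setNames(rep(1, 3), letters[1:3]),
                                threshold = 0.5)
  expect_false(any(got1$flagged))
  expect_error(genotype_ratio_screen(test_r, ctrl), "positive_controls")
})
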