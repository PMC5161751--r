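grid7 <- c(0, 1, 3, 6, 9, 12, 24)

decay_y <- function(K, plateau, t = grid7, y0 = 1)
  (y0 - plateau) * exp(-K * t) + plateau

test_that("decay fits recover closed-form parameters", {
  f <- fit_one_phase_decay(grid7, decay_y(log(2) / 2.2, 0))
  expect_true(f$ok)
  expect_equal(f$half_life, 2.2, tolerance = 1e-6)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  expect_identical(f$half_life * f$K, log(2))      # exact identity

  ## parameterised over a grid of truths
  for (K in c(0.12, 0.3151, 0.9)) for (pl in c(0, 0.2, 0.4)) {
    f <- fit_one_phase_decay(grid7, decay_y(K, pl))
    expect_equal(f$K, K, tolerance = 1e-4)
    expect_equal(f$Plateau, pl, tolerance = 1e-4)
  }

  ## constant series: no decay signal
  f0 <- fit_one_phase_decay(grid7, rep(1, 7))
  expect_true(f0$ok)
  expect_equal(f0$r2, 0, tolerance = 1e-6)
  expect_true(f0$non_decaying)

  ## too few points
  expect_false(fit_one_phase_decay(c(0, 1, 3), c(1, .5, .2))$ok)
  expect_error(fit_one_phase_decay(c(-1, 0, 1, 2), rep(1, 4)),
               "non-negative")
})

test_that("K is recovered within 0.05 on noisy series (Monte-Carlo)", {
  ## truth K = 0.2, plateau = 0.3, multiplicative noise sd 0.02 (log2)
  set.seed(101)
  ok <- replicate(200, {
    y <- decay_y(0.2, 0.3) * 2^rnorm(7, 0, 0.02)
    f <- fit_one_phase_decay(grid7, y)
    abs(f$K - 0.2) < 0.05
  })
  expect_gte(mean(ok), 0.95)
})

test_that("criteria i-iv gate substrate calls as specified", {
  ## give both sites a consensus window so neither is prefiltered away
  spwin <- paste0(strrep("A", 15), "SPAK", strrep("A", 12))
  tr <- manual_truth(c("late", "nonsubstrate"), K = c(0.4, NA),
                     plateau = c(0.05, NA), window = spwin)
  cfg <- noiseless_config()
  m <- simulate_decay_experiment(tr, cfg, "mitosis")
  calls <- call_substrates(m, records = tr)
  expect_equal(calls$is_substrate, c(TRUE, FALSE))
  expect_false(calls$rescued[1])
  expect_false(calls$pass_iii[2])                   # flat fails criterion iii
  expect_equal(calls$half_life[1], log(2) / 0.4, tolerance = 1e-4)

  ## criterion ii: three measured timepoints fail regardless of values
  m2 <- m[1, , drop = FALSE]
  m2[1, 4:7] <- NA
  c2 <- call_substrates(m2, records = tr[1, ])
  expect_false(c2$pass_ii)
  expect_false(c2$is_substrate)

  ## criterion i, mitosis flavour: 0-min value out of (0.5, 2)
  m3 <- m[1, , drop = FALSE] * 2.5
  expect_false(call_substrates(m3, records = tr[1, ])$pass_i)
  ## criterion i, S-phase flavour: lower bound 0.25, no upper bound
  c4 <- call_substrates(NULL, sphase = m3, records = tr[1, ])
  expect_true(c4$pass_i)
  c5 <- call_substrates(NULL, sphase = m[1, , drop = FALSE] * 0.2,
                        records = tr[1, ])
  expect_false(c5$pass_i)

  ## consensus prefilter removes non-S/T-P sites before calling
  tr_no <- tr; tr_no$window[1] <- paste0(strrep("A", 15), "S", strrep("A", 15))
  expect_equal(nrow(call_substrates(m[1, , drop = FALSE],
                                    records = tr_no[1, ])), 0)
  expect_error(call_substrates(m[, 1:5], records = tr), "grid mismatch")
})

test_that("anomaly screening rescues single corrupted points only", {
  tr <- manual_truth("late", K = 0.4, plateau = 0.05)
  cfg <- noiseless_config()
  m <- simulate_decay_experiment(tr, cfg, "mitosis")

  ## corruption at 6 min: rescued with that timepoint removed
  mc <- m; mc[1, grid7 == 6] <- 1.5
  call <- call_substrates(mc, records = tr)
  expect_true(call$is_substrate)
  expect_true(call$rescued)
  expect_equal(call$removed_timepoint, 6)
  expect_equal(call$half_life, log(2) / 0.4, tolerance = 1e-3)

  ## corruption at 0 min: the anchor is never removed, no rescue
  m0 <- m; m0[1, 1] <- 3
  call0 <- call_substrates(m0, records = tr)
  expect_false(call0$is_substrate)

  ## a plainly-passing site is never altered by screening
  expect_false(call_substrates(m, records = tr)$rescued)

  ## tie-break: among several passing removals the highest r2 wins
  y <- decay_y(0.4, 0.05)
  y[grid7 == 6] <- y[grid7 == 6] + 0.25
  y[grid7 == 9] <- y[grid7 == 9] + 0.05
  passes <- lapply(grid7[-1], function(tp) {
    keep <- grid7 != tp
    cdkphos:::eval_decay_criteria(grid7[keep], y[keep], "mitosis")
  })
  passing <- which(vapply(passes, `[[`, TRUE, "pass"))
  scr <- anomaly_screen(grid7, y, "mitosis")
  if (length(passing) >= 2) {
    best <- passing[which.max(vapply(passes[passing],
                                     function(p) p$fit$r2, 0))]
    expect_equal(scr$removed_timepoint, grid7[-1][best])
  }
  expect_false(is.null(scr))
})

test_that("repeat half-lives agree between replicates", {
  set.seed(77)
  tr <- manual_truth(rep("late", 200),
                     K = exp(runif(200, log(0.15), log(1))),
                     plateau = runif(200, 0, 0.3))
  cfgA <- sim_config(n_sites = 200, seed = 31, noise_sd = 0.05,
                     missing_rate = 0)
  cfgB <- cfgA; cfgB$seed <- 32L
  mA <- simulate_decay_experiment(tr, cfgA, "mitosis")
  mB <- simulate_decay_experiment(tr, cfgB, "mitosis")
  pairs <- halflife_repeat_comparison(mA, mB)
  expect_gt(nrow(pairs), 150)
  expect_gt(cor(log(pairs$half_life_a), log(pairs$half_life_b)), 0.9)

  ## noiseless replicates give identical half-lives
  cfg0 <- noiseless_config(n_sites = 5)
  tr0 <- manual_truth(rep("late", 5), K = 0.3, plateau = 0.1)
  m0 <- simulate_decay_experiment(tr0, cfg0, "mitosis")
  p0 <- halflife_repeat_comparison(m0, m0)
  expect_equal(p0$half_life_a, p0$half_life_b)

  ## a site passing in one replicate only is excluded
  mB2 <- mA; mB2[1, 1] <- NA                       # kill criterion i in B
  pX <- halflife_repeat_comparison(mA, mB2)
  expect_false(tr$site_id[1] %in% pX$site_id)
})
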