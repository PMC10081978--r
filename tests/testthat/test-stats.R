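test_that("condition pooling yields the four strata with balanced cells", {
  sums <- make_summaries(n_participants = 5)
  tab <- build_condition_table(sums)
  expect_equal(nrow(tab), 900)
  expect_equal(as.integer(table(tab$stratum)), rep(225L, 4))
  one <- tab[tab$stratum == "in_phase_750", ]
  expect_equal(as.integer(table(one$load_condition)), rep(25L, 9))
  expect_equal(levels(tab$load_condition)[1], "none/none")
  expect_equal(nlevels(tab$load_condition), 9)
})

test_that("excluded trials are dropped and bad inputs rejected", {
  sums <- make_summaries(2)
  sums$excluded[1:10] <- TRUE
  expect_message(tab <- build_condition_table(sums), "10 excluded")
  expect_equal(nrow(tab), nrow(sums) - 10)
  allex <- make_summaries(1)
  allex$excluded <- TRUE
  expect_warning(suppressMessages(build_condition_table(allex)), "empty")
  dup <- make_summaries(1)
  dup$trial[2] <- dup$trial[1]
  expect_error(build_condition_table(dup), "duplicate")
  bad <- make_summaries(1)
  bad$load_left[1] <- "magnetic"
  expect_error(build_condition_table(bad), "unknown")
})

test_that("the mixed model recovers injected condition structure", {
  # null data: non-intercept coefficients stay within sampling error of zero
  outside <- 0
  for (s in 1:3) {
    tab <- simulate_condition_table(10, seed = s)
    fit <- suppressMessages(fit_lme(tab, "mean"))
    td <- tidy(fit)
    fx <- td[td$effect == "fixed" & td$term != "(Intercept)", ]
    outside <- outside + sum(abs(fx$estimate) > 2 * fx$std_error)
  }
  expect_lte(outside, 4) # 24 null coefficients, ~5% expected outside 2 SE

  # a +5 degree offset on viscous/none is recovered with a covering CI
  tab <- simulate_condition_table(
    20, seed = 1, condition_offsets_deg = c("viscous/none" = 5))
  fit <- suppressMessages(fit_lme(tab, "mean"))
  td <- tidy(fit)
  row <- td[grepl("viscous/none", td$term, fixed = TRUE), ]
  expect_lt(abs(row$estimate - 5), 2 * row$std_error)
  expect_lt(row$p_value, 0.001)

  # balanced design: intercept tracks the none/none cell mean
  cellmean <- mean(tab$mean_crp_deg[tab$load_condition == "none/none"])
  ic <- td[td$term == "(Intercept)", ]
  expect_lt(abs(ic$estimate - cellmean), 2 * ic$std_error)

  # tidy() carries the random-effect SDs and glance() the residual
  expect_true(any(td$effect == "random" & grepl("participant", td$term)))
  expect_gt(glance(fit)$sigma_residual, 0)
})

test_that("singular trial variance downgrades to a participant-only model", {
  # zero generating trial variance; this draw lands the REML estimate on the
  # boundary so the singular full model is refit without the trial intercept
  tab <- simulate_condition_table(6, seed = 3, trial_sd_deg = 0, reps = 2)
  expect_message(fit <- fit_lme(tab, "mean"), "participant-only")
  expect_true(fit$downgraded)
  # with a real trial variance component the full model is kept
  tab2 <- simulate_condition_table(8, seed = 3, trial_sd_deg = 2)
  fit2 <- fit_lme(tab2, "mean")
  expect_false(fit2$downgraded)
  expect_true(any(grepl("sd_trial", tidy(fit2)$term)))
})

test_that("model preconditions are enforced", {
  tab <- simulate_condition_table(4, seed = 4)
  expect_error(fit_lme(tab[tab$participant == 1, ], "mean"),
               "2 participants")
  expect_error(fit_lme(tab[tab$load_condition != "viscous/none", ], "mean"),
               "9 load-condition levels")
  two <- rbind(simulate_condition_table(3, seed = 5),
               simulate_condition_table(3, seed = 6, cycle_ms = 1200))
  expect_error(fit_lme(two, "mean"), "single stratum")
})

test_that("Tukey contrasts cover all 36 pairs and never undercut raw p", {
  tab <- simulate_condition_table(
    10, seed = 7, condition_offsets_deg = c("elastic/viscous" = 6))
  fit <- suppressMessages(fit_lme(tab, "mean"))
  pw <- pairwise_emm(fit)
  expect_equal(nrow(pw$contrasts), 36)
  expect_equal(nrow(pw$emmeans), 9)
  expect_true(all(pw$contrasts$p_adj >= pw$contrasts$p_value - 1e-12))
  # the shifted level dominates the strongest contrasts
  top <- pw$contrasts[order(pw$contrasts$p_adj), ][1:8, ]
  expect_true(all(grepl("elastic/viscous", top$contrast, fixed = TRUE)))
  expect_true(all(pw$contrasts$lower <= pw$contrasts$upper))
})

test_that("learning-effect checks detect drift only when present", {
  tab <- simulate_condition_table(12, seed = 8)
  out <- learning_effect_check(tab, "mean")
  expect_true(out$lower <= 0 && out$upper >= 0)
  drift <- simulate_condition_table(20, seed = 9,
                                    trend_deg_per_trial = -0.05)
  outd <- learning_effect_check(drift, "mean")
  expect_lt(outd$slope_per_trial, 0)
  expect_true(outd$significant)
  # invariant to relabeling participants
  relab <- drift
  relab$participant <- max(relab$participant) + 1 - relab$participant
  outr <- learning_effect_check(relab, "mean")
  expect_equal(outr$slope_per_trial, outd$slope_per_trial, tolerance = 1e-6)
})

test_that("laterality quotients classify by the inventory cutoffs", {
  expect_equal(classify_handedness(c(-100, -80, -61)), rep("left", 3))
  expect_equal(classify_handedness(c(-60, 0, 60)), rep("mixed", 3))
  expect_equal(classify_handedness(c(61, 88, 100)), rep("right", 3))
  expect_error(classify_handedness(101), "100")
  expect_error(classify_handedness(NA_real_), "100")
})
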