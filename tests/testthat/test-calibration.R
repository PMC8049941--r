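# Calibration fits are slow-ish; tests here use small simulated data sets
# and fixed seeds.

test_that("build_design produces branch-interaction columns and drops empty ones", {
  f <- data.frame(level = c(1, 2), heard_range = c(2, 3),
                  probe_trueim_absdiff = c(0, 2),
                  probe_accuracy = c(TRUE, FALSE))
  X <- build_design(f, c("level", "probe_trueim_absdiff"))
  expect_identical(colnames(X),
                   c("intercept", "incorrect:level", "correct:level",
                     "incorrect:probe_trueim_absdiff"))
  expect_equal(X[, "correct:level"], c(1, 0))
  expect_equal(X[, "incorrect:level"], c(0, 2))
  # no correct-branch column for a feature that is zero on that branch
  expect_false("correct:probe_trueim_absdiff" %in% colnames(X))
  # main-effects design
  Xm <- build_design(f, "level", interact = FALSE)
  expect_identical(colnames(Xm), c("intercept", "level"))
  # null design
  expect_identical(colnames(build_design(f, character(0))), "intercept")
})

test_that("fit_model with c=0, d=1 and no random effect equals logistic regression", {
  cal <- small_calibrated()
  feats <- bank_features(small_bank())
  sim <- simulate_calibration_data(cal, n_respondents = 40, per_level = 6,
                                   seed = 31)
  fit <- fit_model(sim$responses, feats, canonical_subset,
                   guessing = 0, inattention = 1, random_effects = FALSE)
  dat <- merge(sim$responses, feats, by = "item_id")
  X <- build_design(dat, canonical_subset)
  oracle <- glm(dat$correct ~ X - 1, family = binomial())
  expect_lt(max(abs(unname(coef(oracle)) -
                      unname(fit$coefficients[colnames(X)]))), 1e-4)
  expect_equal(fit$logLik, as.numeric(logLik(oracle)), tolerance = 1e-8)
  expect_identical(fit$convergence, 0L)
  # BIC identity
  expect_equal(fit$bic, -2 * fit$logLik + fit$n_params * log(fit$n_obs))
})

test_that("the null model on balanced coin-flip data has intercept near zero", {
  set.seed(12)
  resp <- data.frame(
    participant_id = rep(sprintf("P%02d", 1:20), each = 40),
    item_id = rep(sprintf("i%02d", 1:40), times = 20),
    correct = rbinom(800, 1, 0.5)
  )
  feats <- data.frame(item_id = sprintf("i%02d", 1:40))
  fit <- fit_model(resp, feats, character(0), guessing = 0, inattention = 1,
                   random_effects = FALSE)
  expect_lt(abs(fit$coefficients[["intercept"]]), 0.15)
  expect_error(
    fit_model(transform(resp, correct = 1), feats, character(0)),
    "degenerate"
  )
})

test_that("fit_model recovers generating coefficients from mixed 4PL data", {
  cal <- small_calibrated()
  feats <- bank_features(small_bank())
  sim <- simulate_calibration_data(cal, n_respondents = 120, per_level = 8,
                                   seed = 77)
  fit <- fit_model(sim$responses, feats, canonical_subset)
  truth <- piat_model_params()$coefficients
  for (nm in names(truth)) {
    expect_lt(abs(fit$coefficients[[nm]] - truth[[nm]]), 3 * fit$se[[nm]])
  }
  # the participant-ability SD (generated as 1) is recovered roughly
  expect_gt(fit$sigma, 0.6)
  expect_lt(fit$sigma, 1.5)
})

test_that("optimize_asymptotes maximizes the profile likelihood over the grid", {
  cal <- small_calibrated()
  feats <- bank_features(small_bank())
  sim <- simulate_calibration_data(cal, n_respondents = 100, per_level = 8,
                                   seed = 55)
  best <- optimize_asymptotes(sim$responses, feats, c("level"),
                              c_grid = c(0, 0.15, 0.3, 0.45),
                              d_grid = c(0.85, 0.95),
                              random_effects = FALSE)
  tab <- best$asymptote_table
  expect_identical(nrow(tab), 8L)
  expect_equal(best$logLik, max(tab$logLik))
  # data were generated with c = 0.3, d = 0.95: the selected cell is at
  # or adjacent to the truth
  expect_lte(abs(best$guessing - 0.3), 0.15 + 1e-9)
  expect_lte(abs(best$inattention - 0.95), 0.1 + 1e-9)
})

test_that("random-forest screening puts the signal feature first and nulls constants", {
  set.seed(200)
  n <- 1500
  feats <- data.frame(
    item_id = sprintf("i%04d", 1:n),
    signal = runif(n, -2, 2),
    noise1 = runif(n), noise2 = rnorm(n),
    flat = rep(1, n)
  )
  resp <- data.frame(
    participant_id = rep(sprintf("P%02d", 1:10), length.out = n),
    item_id = feats$item_id,
    correct = rbinom(n, 1, plogis(2.5 * feats$signal))
  )
  for (s in 1:3) {
    ranked <- screen_predictors(resp, feats,
                                candidates = c("signal", "noise1", "noise2",
                                               "flat"),
                                seed = s, num_trees = 300)
    expect_identical(ranked[1], "signal")
    imp <- attr(ranked, "importance")
    expect_lt(abs(imp[["flat"]]), 0.01)
  }
  # n_keep truncates the ranking
  top2 <- screen_predictors(resp, feats,
                            candidates = c("signal", "noise1", "noise2"),
                            n_keep = 2, seed = 1, num_trees = 200)
  expect_length(top2, 2)
})

test_that("subset search enumerates the power set and prefers the true predictor", {
  # simulate from a model where only level matters, and strongly
  strong <- piat_model_params(
    coefficients = c("intercept" = 1.2, "correct:level" = -0.8,
                     "incorrect:level" = -0.8)
  )
  cal <- calibrate_bank(small_bank(), strong)
  feats <- bank_features(small_bank())
  set.seed(88)
  feats$noise <- rnorm(nrow(feats))
  sim <- simulate_calibration_data(cal, n_respondents = 80, per_level = 8,
                                   seed = 88)
  out <- subset_search(sim$responses, feats, c("level", "noise"),
                       random_effects = FALSE)
  expect_identical(nrow(out$table), 4L)  # 2^2 subsets
  expect_true(grepl("level", out$table$subset[which.min(out$table$bic)]))
  null_bic <- out$table$bic[out$table$subset == ""]
  expect_lt(out$best$bic, null_bic)
  expect_error(
    subset_search(sim$responses, feats, c("level", "noise"), budget = 2),
    "budget"
  )
})

test_that("cross-validated accuracy behaves at the two signal extremes", {
  # strong signal, no asymptotes: accuracy far above chance
  set.seed(61)
  n <- 1200
  feats <- data.frame(item_id = sprintf("i%04d", 1:n),
                      level = runif(n, -3, 3))
  resp <- data.frame(
    participant_id = rep(sprintf("P%02d", 1:12), length.out = n),
    item_id = feats$item_id,
    correct = rbinom(n, 1, plogis(4 * feats$level))
  )
  acc <- cv_accuracy(resp, feats, "level", k = 5, guessing = 0,
                     inattention = 1, interact = FALSE,
                     random_effects = FALSE, seed = 2)
  expect_gt(acc, 0.85)
  # zero signal, balanced: accuracy near one half
  resp$correct <- rbinom(n, 1, 0.5)
  acc0 <- cv_accuracy(resp, feats, "level", k = 5, guessing = 0,
                      inattention = 1, interact = FALSE,
                      random_effects = FALSE, seed = 2)
  expect_lt(abs(acc0 - 0.5), 0.08)
})

test_that("participant effects help prediction when abilities vary widely", {
  cal <- small_calibrated()
  feats <- bank_features(small_bank())
  sim <- simulate_calibration_data(cal, n_respondents = 60, per_level = 8,
                                   ability_sd = 2, seed = 91)
  acc_with <- cv_accuracy(sim$responses, feats, c("level"), k = 4,
                          with_participant_effects = TRUE, seed = 3)
  acc_without <- cv_accuracy(sim$responses, feats, c("level"), k = 4,
                             with_participant_effects = FALSE, seed = 3)
  expect_gt(acc_with, acc_without)
})

test_that("the split-then-joint driver returns the three published model shapes", {
  cal <- small_calibrated()
  feats <- bank_features(small_bank())
  sim <- simulate_calibration_data(cal, n_respondents = 60, per_level = 8,
                                   seed = 14)
  fits <- fit_split_then_joint(
    sim$responses, feats,
    correct_subset = c("probability_probe_last_heard", "level"),
    incorrect_subset = c("probe_trueim_absdiff", "heard_range"),
    random_effects = FALSE
  )
  expect_named(fits, c("correct", "incorrect", "joint"))
  expect_identical(names(fits$correct$coefficients),
                   c("intercept", "probability_probe_last_heard", "level"))
  expect_identical(names(fits$incorrect$coefficients),
                   c("intercept", "probe_trueim_absdiff", "heard_range"))
  # joint interaction design: intercept + 7 branch coefficients (no
  # correct-branch absdiff column, which is identically zero)
  expect_identical(length(fits$joint$coefficients), 8L)
  expect_false("correct:probe_trueim_absdiff" %in%
                 names(fits$joint$coefficients))
})
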