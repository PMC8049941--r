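test_that("easiness matches an independent matrix-product oracle on both branches", {
  params <- piat_model_params()
  cf <- params$coefficients
  # zero features: only the intercept survives, either branch
  zero <- data.frame(level = 0, heard_range = 0,
                     probability_probe_last_heard = 0,
                     probe_trueim_absdiff = 0,
                     probe_accuracy = c(TRUE, FALSE))
  expect_equal(easiness(zero, params), c(-0.918, -0.918))
  # correct branch, hand-checkable values
  f_cor <- data.frame(level = 3, heard_range = 3,
                      probability_probe_last_heard = 0.2,
                      probe_trueim_absdiff = 0, probe_accuracy = TRUE)
  oracle_cor <- cf[["intercept"]] +
    cf[["correct:probability_probe_last_heard"]] * 0.2 +
    cf[["correct:level"]] * 3 + cf[["correct:heard_range"]] * 3
  expect_equal(easiness(f_cor, params), oracle_cor)
  expect_equal(easiness(f_cor, params), -0.4194, tolerance = 1e-12)
  # incorrect branch
  f_inc <- data.frame(level = 2, heard_range = 2,
                      probability_probe_last_heard = 0.1,
                      probe_trueim_absdiff = 2, probe_accuracy = FALSE)
  oracle_inc <- cf[["intercept"]] +
    cf[["incorrect:probability_probe_last_heard"]] * 0.1 +
    cf[["incorrect:level"]] * 2 +
    cf[["incorrect:probe_trueim_absdiff"]] * 2 +
    cf[["incorrect:heard_range"]] * 2
  expect_equal(easiness(f_inc, params), oracle_inc)
  # design-matrix oracle on random feature vectors
  set.seed(9)
  acc <- sample(c(TRUE, FALSE), 20, TRUE)
  rnd <- data.frame(level = sample(1:6, 20, TRUE),
                    heard_range = sample(2:5, 20, TRUE),
                    probability_probe_last_heard = runif(20),
                    probe_trueim_absdiff = ifelse(acc, 0L,
                                                  sample(1:2, 20, TRUE)),
                    probe_accuracy = acc)
  X <- build_design(rnd, c("probability_probe_last_heard", "level",
                           "probe_trueim_absdiff", "heard_range"))
  expect_equal(easiness(rnd, params), drop(X %*% cf[colnames(X)]))
})

test_that("easiness is linear in the features and errors on missing inputs", {
  params <- piat_model_params()
  f1 <- data.frame(level = 2, heard_range = 3,
                   probability_probe_last_heard = 0.3,
                   probe_trueim_absdiff = 0, probe_accuracy = TRUE)
  f2 <- f1; f2$level <- 5
  # the level contribution is the coefficient times the difference,
  # independent of everything else
  expect_equal(easiness(f2, params) - easiness(f1, params),
               params$coefficients[["correct:level"]] * 3)
  expect_error(easiness(data.frame(probe_accuracy = TRUE), params),
               "missing feature")
})

test_that("response_probability is a bounded increasing logistic between c and d", {
  params <- piat_model_params()
  expect_equal(response_probability(0, 0, params), 0.625)  # c + (d-c)/2
  expect_equal(response_probability(-50, 0, params), 0.3, tolerance = 1e-10)
  expect_equal(response_probability(50, 0, params), 0.95, tolerance = 1e-10)
  theta <- seq(-6, 6, by = 0.25)
  p <- response_probability(theta, 0.5, params)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0.3 & p < 0.95))
  # decreasing in difficulty
  expect_true(all(diff(response_probability(0, theta, params)) < 0))
  # c = 0, d = 1 reduces to the plain logistic
  std <- piat_model_params(guessing = 0, inattention = 1)
  expect_equal(response_probability(theta, 0.7, std), plogis(theta - 0.7))
})

test_that("log_likelihood matches term-by-term summation", {
  params <- piat_model_params()
  expect_equal(log_likelihood(0, 0, 1, params), log(0.625))
  set.seed(4)
  b <- runif(25, -3, 3); x <- rbinom(25, 1, 0.6)
  manual <- sum(vapply(seq_along(b), function(i) {
    p <- response_probability(0.4, b[i], params)
    if (x[i] == 1) log(p) else log(1 - p)
  }, numeric(1)))
  expect_equal(log_likelihood(0.4, b, x, params), manual, tolerance = 1e-12)
  # all-correct response sets: likelihood increasing in theta
  ll <- vapply(seq(-3, 3, by = 0.5), log_likelihood, numeric(1),
               b = b, x = rep(1, 25), params = params)
  expect_true(all(diff(ll) > 0))
})

test_that("item_information matches a finite-difference construction", {
  params <- piat_model_params()
  h <- 1e-5
  set.seed(5)
  for (i in 1:25) {
    theta <- runif(1, -4, 4); b <- runif(1, -3, 3)
    p <- response_probability(theta, b, params)
    dp_num <- (response_probability(theta + h, b, params) -
                 response_probability(theta - h, b, params)) / (2 * h)
    expect_equal(item_information(theta, b, params),
                 dp_num^2 / (p * (1 - p)), tolerance = 1e-6)
  }
  # 1PL limit: I = P(1-P), maximal at theta = b
  std <- piat_model_params(guessing = 0, inattention = 1)
  p <- response_probability(0.3, 1.2, std)
  expect_equal(item_information(0.3, 1.2, std), p * (1 - p))
  grid <- seq(-3, 3, by = 0.1)
  info <- item_information(grid, 1.2, std)
  expect_equal(grid[which.max(info)], 1.2)
  # information vanishes far from the item
  expect_lt(item_information(30, 0, params), 1e-8)
})

test_that("calibrate_bank maps easiness to difficulty through the ability scale", {
  bank <- small_bank()
  cal1 <- calibrate_bank(bank, piat_model_params(scale = 1))
  expect_equal(cal1$items$difficulty, -cal1$items$easiness)
  cal2 <- calibrate_bank(bank, piat_model_params(scale = 2))
  expect_equal(cal2$items$difficulty, cal1$items$difficulty / 2)
  # monotone map: difficulty ranks reverse easiness ranks (ties average)
  expect_equal(rank(cal1$items$difficulty), rank(-cal1$items$easiness))
})

test_that("published coefficient signs shape difficulty as the cognitive model predicts", {
  params <- piat_model_params()
  base <- data.frame(level = 3, heard_range = 3,
                     probability_probe_last_heard = 0.1,
                     probe_trueim_absdiff = 0, probe_accuracy = TRUE)
  easier <- base; easier$probability_probe_last_heard <- 0.4
  harder <- base; harder$level <- 5
  expect_gt(easiness(easier, params), easiness(base, params))
  expect_lt(easiness(harder, params), easiness(base, params))
  # two-step incorrect probes are easier to reject than one-step probes
  inc1 <- data.frame(level = 3, heard_range = 3,
                     probability_probe_last_heard = 0.1,
                     probe_trueim_absdiff = 1, probe_accuracy = FALSE)
  inc2 <- inc1; inc2$probe_trueim_absdiff <- 2
  expect_gt(easiness(inc2, params), easiness(inc1, params))
})
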