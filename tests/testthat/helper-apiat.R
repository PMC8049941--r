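# Shared fixtures and independent oracles. Everything is generated in
# code; the full calibration bank is built lazily and cached so only the
# tests that need it pay for it.

.fixture_cache <- new.env(parent = emptyenv())

small_bank <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- generate_bank(
      levels = 1:3, n_heard = 3:4, keys = c("C", "D"),
      variations = 3, seed = 101
    )
  }
  .fixture_cache$small
}

small_calibrated <- function() {
  if (is.null(.fixture_cache$small_cal)) {
    .fixture_cache$small_cal <- calibrate_bank(small_bank())
  }
  .fixture_cache$small_cal
}

full_bank <- function() {
  if (is.null(.fixture_cache$full)) {
    main <- generate_bank(seed = 20260919)
    ext <- generate_bank(levels = 6, seed = 20260920)
    .fixture_cache$full <- combine_banks(main, ext)
    .fixture_cache$main <- main
    .fixture_cache$ext <- ext
  }
  .fixture_cache$full
}

calibration_bank <- function() { full_bank(); .fixture_cache$main }
extension_bank <- function() { full_bank(); .fixture_cache$ext }

full_calibrated <- function() {
  if (is.null(.fixture_cache$full_cal)) {
    fb <- full_bank()
    .fixture_cache$full_cal <- calibrate_bank(fb, piat_model_params(),
                                              bank_features(fb))
  }
  .fixture_cache$full_cal
}

canonical_subset <- c("probability_probe_last_heard", "level",
                      "probe_trueim_absdiff", "heard_range")

# independent step-string parser (does not reuse package internals)
string_to_steps_test <- function(s) {
  ifelse(strsplit(s, "", fixed = TRUE)[[1]] == "+", 1L, -1L)
}

# ---- independent estimator oracles -----------------------------------------

# MAP oracle: brute-force argmax of the log posterior on a 4001-point grid.
map_grid_oracle <- function(b, x, params, prior_mean = 0, prior_sd = 1,
                            bounds = c(-4, 4)) {
  grid <- seq(bounds[1], bounds[2], length.out = 4001)
  post <- vapply(grid, function(th) {
    ll <- if (length(b)) {
      p <- response_probability(th, b, params)
      sum(x * log(p) + (1 - x) * log1p(-p))
    } else 0
    ll + dnorm(th, prior_mean, prior_sd, log = TRUE)
  }, numeric(1))
  grid[which.max(post)]
}

# WLE oracle: Warm's corrected score assembled purely from finite
# differences of the response-probability function, scanned on a
# 4001-point grid for its downward zero crossing (linear interpolation).
wle_grid_oracle <- function(b, x, params, bounds = c(-4, 4)) {
  h <- 1e-5
  W <- function(th) {
    p <- response_probability(th, b, params)
    dp <- (response_probability(th + h, b, params) -
             response_probability(th - h, b, params)) / (2 * h)
    d2p <- (response_probability(th + h, b, params) -
              2 * p + response_probability(th - h, b, params)) / h^2
    pq <- p * (1 - p)
    sum(dp * (x - p) / pq) +
      sum(dp * d2p / pq) / (2 * sum(dp^2 / pq))
  }
  grid <- seq(bounds[1], bounds[2], length.out = 4001)
  w <- vapply(grid, W, numeric(1))
  down <- which(w[-length(w)] > 0 & w[-1] <= 0)
  if (length(down) == 0) {
    return(if (w[1] <= 0) bounds[1] else bounds[2])
  }
  i <- down[1]
  grid[i] + (grid[i + 1] - grid[i]) * w[i] / (w[i] - w[i + 1])
}

# Draw a random (difficulty, response) set from the 4PL at a random theta.
random_response_set <- function(n, params, theta = rnorm(1)) {
  b <- runif(n, -3, 3)
  x <- rbinom(n, 1, response_probability(theta, b, params))
  list(b = b, x = x, theta = theta)
}
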