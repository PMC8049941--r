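# The explanatory 4PL response model: difficulty from item features,
# response probability, likelihood and information.

#' Default joint-model coefficients
#'
#' The published coefficients of the joint explanatory model: each
#' predictor enters in interaction with probe accuracy, so every
#' coefficient (except the intercept) belongs either to the correct-probe
#' branch or the incorrect-probe branch. `probe_trueim_absdiff` has no
#' correct-probe coefficient because it is identically 0 on correct-probe
#' trials.
#'
#' @return Named numeric vector of eight coefficients.
#' @export
piat_joint_coefficients <- function() {
  c(
    "intercept" = -0.918,
    "incorrect:probability_probe_last_heard" = 0.228,
    "correct:probability_probe_last_heard" = 2.778,
    "incorrect:level" = -0.157,
    "correct:level" = -0.176,
    "incorrect:probe_trueim_absdiff" = 1.151,
    "incorrect:heard_range" = -0.553,
    "correct:heard_range" = 0.157
  )
}

#' Model parameters of the explanatory 4PL
#'
#' Bundles the feature coefficients with the four structural constants of
#' the response model: guessing asymptote `c` (floor), inattention
#' asymptote `d` (ceiling), constant discrimination `a`, and the ability
#' scale `s` used to convert easiness into difficulty (`b = -eta / s`; one
#' unit of difficulty corresponds to `s` units of the linear predictor,
#' conventionally one standard deviation of ability in a calibration
#' sample). Defaults: the published joint coefficients, `c = 0.3`,
#' `d = 0.95` (the only published asymptote values), `a = 1` (Rasch-style
#' unit discrimination in the natural logistic metric), `s = 1`.
#'
#' @param coefficients named numeric vector; see [piat_joint_coefficients()].
#' @param guessing lower asymptote in \[0, 1).
#' @param inattention upper asymptote in (guessing, 1\].
#' @param discrimination positive slope constant.
#' @param scale positive ability-SD scale factor.
#' @return Object of class `piat_model_params`.
#' @examples
#' params <- piat_model_params()
#' @export
piat_model_params <- function(coefficients = piat_joint_coefficients(),
                              guessing = 0.3, inattention = 0.95,
                              discrimination = 1, scale = 1) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            guessing >= 0, guessing < 1,
            inattention > guessing, inattention <= 1,
            discrimination > 0, scale > 0)
  if (!"intercept" %in% names(coefficients)) {
    stop("coefficients must include an 'intercept'", call. = FALSE)
  }
  structure(
    list(coefficients = coefficients, guessing = guessing,
         inattention = inattention, discrimination = discrimination,
         scale = scale),
    class = "piat_model_params"
  )
}

#' @export
print.piat_model_params <- function(x, ...) {
  cat("Explanatory 4PL model parameters\n")
  cat(sprintf("  guessing c = %.3g, inattention d = %.3g, discrimination a = %.3g, scale s = %.3g\n",
              x$guessing, x$inattention, x$discrimination, x$scale))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Easiness (linear predictor) of items from their features
#'
#' The easiness of an item is the linear predictor
#' `eta = intercept + sum(branch-matched coefficient * feature)`, where
#' the branch is the correct-probe set of coefficients when
#' `probe_accuracy` is `TRUE` and the incorrect-probe set otherwise.
#' Larger `eta` means an easier item (higher success probability at any
#' ability).
#'
#' @param features data frame of feature rows (as from [bank_features()]);
#'   must contain `probe_accuracy` and every feature named in the
#'   coefficients.
#' @param params a [piat_model_params()].
#' @return numeric vector of easiness values, one per feature row.
#' @examples
#' params <- piat_model_params()
#' f <- data.frame(level = 3, heard_range = 3,
#'                 probability_probe_last_heard = 0.2,
#'                 probe_trueim_absdiff = 0, probe_accuracy = TRUE)
#' easiness(f, params)  # -0.4194
#' @export
easiness <- function(features, params) {
  stopifnot(inherits(params, "piat_model_params"))
  cf <- params$coefficients
  if (!"probe_accuracy" %in% names(features)) {
    stop("features must contain 'probe_accuracy'", call. = FALSE)
  }
  acc <- as.logical(features$probe_accuracy)
  eta <- rep(cf[["intercept"]], nrow(features))
  for (nm in setdiff(names(cf), "intercept")) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !parts[1L] %in% c("correct", "incorrect")) {
      stop("coefficient name '", nm,
           "' is not of the form correct:<feature> or incorrect:<feature>",
           call. = FALSE)
    }
    feat <- parts[2L]
    if (!feat %in% names(features)) {
      stop("missing feature '", feat, "' required by coefficient '", nm, "'",
           call. = FALSE)
    }
    on_branch <- if (parts[1L] == "correct") acc else !acc
    eta <- eta + ifelse(on_branch, cf[[nm]] * features[[feat]], 0)
  }
  unname(eta)
}

#' 4PL response probability
#'
#' `P(theta) = c + (d - c) * logistic(a * (theta - b))`: the probability
#' of a correct response for a respondent of ability `theta` on an item of
#' difficulty `b`, bounded below by the guessing floor `c` and above by
#' the inattention ceiling `d`. Strictly increasing in `theta` and
#' strictly inside `(c, d)` for finite arguments.
#'
#' @param theta ability (vectorized).
#' @param b item difficulty (vectorized).
#' @param params a [piat_model_params()].
#' @return probability vector.
#' @examples
#' response_probability(0, 0, piat_model_params())  # 0.625
#' @export
response_probability <- function(theta, b, params) {
  params$guessing + (params$inattention - params$guessing) *
    stats::plogis(params$discrimination * (theta - b))
}

# derivative of response_probability in theta
response_probability_deriv <- function(theta, b, params) {
  a <- params$discrimination
  l <- stats::plogis(a * (theta - b))
  (params$inattention - params$guessing) * a * l * (1 - l)
}

# second derivative in theta
response_probability_deriv2 <- function(theta, b, params) {
  a <- params$discrimination
  l <- stats::plogis(a * (theta - b))
  (params$inattention - params$guessing) * a^2 * l * (1 - l) * (1 - 2 * l)
}

#' Log-likelihood of a response set
#'
#' Bernoulli log-likelihood of responses `x` (0/1) on items of difficulty
#' `b` at ability `theta`. Finite on any bounded interval whenever
#' `c > 0` and `d < 1`.
#'
#' @param theta scalar ability.
#' @param b difficulty vector.
#' @param x 0/1 response vector, same length as `b`.
#' @param params a [piat_model_params()].
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(theta, b, x, params) {
  stopifnot(length(b) == length(x), length(b) >= 1L, all(x %in% c(0, 1)))
  p <- response_probability(theta, b, params)
  sum(x * log(p) + (1 - x) * log1p(-p))
}

#' Fisher information of one item
#'
#' `I(theta) = P'(theta)^2 / (P(theta) (1 - P(theta)))`, the expected
#' information a single item contributes about ability at `theta`.
#' Nonnegative, and vanishing far from the item's difficulty.
#'
#' @inheritParams response_probability
#' @return nonnegative information vector.
#' @export
item_information <- function(theta, b, params) {
  p <- response_probability(theta, b, params)
  dp <- response_probability_deriv(theta, b, params)
  dp^2 / (p * (1 - p))
}

#' Calibrate a bank: easiness and difficulty from the explanatory model
#'
#' Computes each item's easiness `eta` (via [easiness()]) and its IRT
#' difficulty `b = -eta / s`, where `s` is the ability scale in `params`.
#' With `s = 1`, difficulty is simply negated easiness.
#'
#' @param bank a `piat_bank`.
#' @param params a [piat_model_params()].
#' @param features feature table for the bank; computed with defaults if
#'   omitted.
#' @return Object of class `piat_calibrated_bank`: the bank with an
#'   `items` data frame augmented by `easiness` and `difficulty` columns,
#'   plus the `params` used.
#' @examples
#' bank <- generate_bank(levels = 1:2, n_heard = 3, keys = "C",
#'                       variations = 2, seed = 1)
#' cal <- calibrate_bank(bank, piat_model_params())
#' head(cal$items[, c("item_id", "easiness", "difficulty")])
#' @export
calibrate_bank <- function(bank, params = piat_model_params(),
                           features = bank_features(bank)) {
  stopifnot(inherits(bank, "piat_bank"))
  ord <- match(bank$items$item_id, features$item_id)
  if (anyNA(ord)) stop("features do not cover all bank items", call. = FALSE)
  eta <- easiness(features[ord, , drop = FALSE], params)
  items <- bank$items
  items$easiness <- eta
  items$difficulty <- -eta / params$scale
  structure(
    list(items = items, config = bank$config, params = params),
    class = c("piat_calibrated_bank", "piat_bank")
  )
}
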