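# Respondent simulator and experiment harness.

#' Simulate a cohort of respondents
#'
#' Draws `n` latent abilities independently from Normal(`mean`, `sd`).
#'
#' @param n cohort size.
#' @param mean,sd ability distribution parameters (`sd > 0`).
#' @param seed optional integer seed (restores the caller's RNG state).
#' @return Data frame with columns `respondent_id` and `theta`.
#' @examples
#' simulate_cohort(5, seed = 1)
#' @export
simulate_cohort <- function(n, mean = 0, sd = 1, seed = NULL) {
  stopifnot(n >= 1L, sd > 0)
  draw <- function() stats::rnorm(n, mean, sd)
  theta <- if (is.null(seed)) draw() else with_seed(seed, draw())
  data.frame(
    respondent_id = sprintf("R%04d", seq_len(n)),
    theta = theta,
    stringsAsFactors = FALSE
  )
}

#' Simulate responses of a cohort to calibrated items
#'
#' Each response is Bernoulli with success probability given by the 4PL
#' response model at the respondent's true ability and the item's
#' difficulty. By default every respondent answers every item; pass
#' `sessions` (a list of item-id vectors named by respondent id) to give
#' each respondent their own item set.
#'
#' @param cohort data frame from [simulate_cohort()].
#' @param calibrated_items a `piat_calibrated_bank` or its `items` data
#'   frame (must have `item_id` and `difficulty`).
#' @param params a [piat_model_params()].
#' @param sessions optional named list: respondent id -> item ids.
#' @param seed optional integer seed.
#' @return Long-format data frame `(participant_id, item_id, correct)`.
#' @export
simulate_responses <- function(cohort, calibrated_items,
                               params = piat_model_params(),
                               sessions = NULL, seed = NULL) {
  items <- if (inherits(calibrated_items, "piat_bank")) {
    calibrated_items$items
  } else {
    calibrated_items
  }
  stopifnot(all(c("item_id", "difficulty") %in% names(items)))
  draw <- function() {
    out <- lapply(seq_len(nrow(cohort)), function(i) {
      rid <- cohort$respondent_id[i]
      ids <- if (is.null(sessions)) items$item_id else sessions[[rid]]
      b <- items$difficulty[match(ids, items$item_id)]
      p <- response_probability(cohort$theta[i], b, params)
      data.frame(participant_id = rid, item_id = ids,
                 correct = stats::rbinom(length(ids), 1L, p),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  res <- if (is.null(seed)) draw() else with_seed(seed, draw())
  rownames(res) <- NULL
  res
}

#' Sample a quasi-random calibration session
#'
#' Draws an equal number of items from each level without replacement and
#' shuffles the result, mirroring the quasi-random presentation of the
#' calibration study (six items from each of five levels = 30 trials).
#'
#' @param bank a `piat_bank`.
#' @param per_level items per level (default 6).
#' @param levels levels to draw from (default: all levels in the bank).
#' @param seed optional integer seed.
#' @return character vector of item ids, length `per_level * length(levels)`.
#' @export
calibration_session_sampler <- function(bank, per_level = 6L, levels = NULL,
                                        seed = NULL) {
  items <- bank$items
  levels <- levels %||% sort(unique(items$level))
  draw <- function() {
    picked <- unlist(lapply(levels, function(lv) {
      pool <- items$item_id[items$level == lv]
      if (length(pool) < per_level) {
        stop("level ", lv, " has only ", length(pool),
             " items; cannot draw ", per_level, call. = FALSE)
      }
      pool[sample.int(length(pool), per_level)]
    }))
    picked[sample.int(length(picked))]
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate a full calibration study
#'
#' Draws a Normal cohort, gives each respondent an independent
#' quasi-random session ([calibration_session_sampler()]) and simulates
#' their responses under the 4PL model. This is the standard input for
#' parameter-recovery checks of [fit_model()].
#'
#' @param calibrated_bank a `piat_calibrated_bank`.
#' @param n_respondents cohort size.
#' @param per_level items per level in each session (default 6).
#' @param levels levels to draw from (default: all levels in the bank).
#' @param ability_mean,ability_sd cohort ability distribution.
#' @param params response-model parameters (default: the bank's).
#' @param seed integer seed (required: calibration data should be
#'   reproducible).
#' @return List with `cohort` and `responses`.
#' @export
simulate_calibration_data <- function(calibrated_bank, n_respondents,
                                      per_level = 6L, levels = NULL,
                                      ability_mean = 0, ability_sd = 1,
                                      params = calibrated_bank$params,
                                      seed = 1L) {
  with_seed(seed, {
    cohort <- simulate_cohort(n_respondents, ability_mean, ability_sd)
    sessions <- lapply(seq_len(n_respondents), function(i) {
      calibration_session_sampler(calibrated_bank, per_level, levels)
    })
    names(sessions) <- cohort$respondent_id
    responses <- simulate_responses(cohort, calibrated_bank, params,
                                    sessions = sessions)
    list(cohort = cohort, responses = responses)
  })
}

#' Reliability and recovery as a function of test length
#'
#' Runs simulated adaptive sessions for a Normal cohort at each requested
#' test length and reports, per length: the mean IRT standard error of
#' the final WLE scores, the RMSE and Pearson correlation of the scores
#' against the true simulated abilities, optionally the test-retest
#' correlation (two independent sessions per respondent, same bank,
#' different tie-break streams), and optionally the mean standard error
#' under uniform-random item selection as a non-adaptive baseline.
#'
#' @param calibrated_bank a `piat_calibrated_bank`.
#' @param n_respondents cohort size (default 200).
#' @param lengths test lengths (default `c(5, 10, 15, 20, 25)`).
#' @param ability_mean,ability_sd cohort distribution.
#' @param params response-model parameters (default: the bank's).
#' @param retest also run an independent second session per respondent
#'   and report the retest correlation (default `TRUE`).
#' @param random_baseline also run random-selection sessions and report
#'   their mean standard error (default `FALSE`).
#' @param prior_mean,prior_sd,bounds passed to [run_session()].
#' @param seed integer master seed; every session seed derives from it.
#' @return Data frame with one row per length: `length`, `mean_se`,
#'   `rmse`, `truth_cor`, `retest_cor`, `mean_se_random`.
#' @export
recovery_experiment <- function(calibrated_bank, n_respondents = 200L,
                                lengths = c(5L, 10L, 15L, 20L, 25L),
                                ability_mean = 0, ability_sd = 1,
                                params = calibrated_bank$params,
                                retest = TRUE, random_baseline = FALSE,
                                prior_mean = 0, prior_sd = 1,
                                bounds = c(-4, 4), seed = 1L) {
  cohort <- simulate_cohort(n_respondents, ability_mean, ability_sd,
                            seed = seed)
  session_seeds <- with_seed(seed + 1L,
                             matrix(sample.int(.Machine$integer.max - 1L,
                                               n_respondents * 3L),
                                    nrow = n_respondents))
  run_batch <- function(len, col, selection) {
    vapply(seq_len(n_respondents), function(i) {
      s <- run_session(calibrated_bank,
                       simulated_respondent(cohort$theta[i], params),
                       n_items = len, params = params,
                       prior_mean = prior_mean, prior_sd = prior_sd,
                       bounds = bounds, selection = selection,
                       seed = session_seeds[i, col])
      c(s$final$theta, s$final$se)
    }, numeric(2))
  }
  out <- lapply(lengths, function(len) {
    first <- run_batch(len, 1L, "urry")
    retest_cor <- NA_real_
    if (retest) {
      second <- run_batch(len, 2L, "urry")
      retest_cor <- stats::cor(first[1L, ], second[1L, ])
    }
    mean_se_random <- NA_real_
    if (random_baseline) {
      rnd <- run_batch(len, 3L, "random")
      mean_se_random <- mean(rnd[2L, ])
    }
    data.frame(
      length = len,
      mean_se = mean(first[2L, ]),
      rmse = sqrt(mean((first[1L, ] - cohort$theta)^2)),
      truth_cor = stats::cor(first[1L, ], cohort$theta),
      retest_cor = retest_cor,
      mean_se_random = mean_se_random
    )
  })
  do.call(rbind, out)
}
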