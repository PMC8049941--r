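# Fitting the explanatory item-response model from long-format response
# data: asymptote-modified logistic regression with a Normal random
# intercept per participant, marginalized by Gauss-Hermite quadrature.

#' Design matrix for the explanatory model
#'
#' Builds the fixed-effects design for a set of feature rows. With
#' `interact = TRUE` every feature enters in interaction with probe
#' accuracy, producing `correct:<feature>` and `incorrect:<feature>`
#' columns (columns that are identically zero, such as
#' `correct:probe_trueim_absdiff`, are dropped); with `interact = FALSE`
#' features enter as plain main effects.
#'
#' @param features data frame of feature rows.
#' @param subset character vector of feature names (may be empty for a
#'   null, intercept-only design).
#' @param interact logical.
#' @return numeric matrix with an `intercept` column.
#' @export
build_design <- function(features, subset, interact = TRUE) {
  n <- nrow(features)
  X <- matrix(1, n, 1L, dimnames = list(NULL, "intercept"))
  if (length(subset) == 0L) return(X)
  missing <- setdiff(subset, names(features))
  if (length(missing)) {
    stop("features lack columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (interact) {
    if (!"probe_accuracy" %in% names(features)) {
      stop("interaction design requires a 'probe_accuracy' column",
           call. = FALSE)
    }
    acc <- as.numeric(features$probe_accuracy)
    for (f in subset) {
      v <- as.numeric(features[[f]])
      for (branch in c("incorrect", "correct")) {
        col <- if (branch == "correct") v * acc else v * (1 - acc)
        if (any(col != 0)) {
          X <- cbind(X, col)
          colnames(X)[ncol(X)] <- paste0(branch, ":", f)
        }
      }
    }
  } else {
    for (f in subset) {
      X <- cbind(X, as.numeric(features[[f]]))
      colnames(X)[ncol(X)] <- f
    }
  }
  X
}

# Merge long-format responses with per-item features; validates columns.
merge_responses <- function(responses, features) {
  need <- c("participant_id", "item_id", "correct")
  if (!all(need %in% names(responses))) {
    stop("responses must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(responses$correct %in% c(0, 1))) {
    stop("'correct' must be binary 0/1", call. = FALSE)
  }
  idx <- match(responses$item_id, features$item_id)
  if (anyNA(idx)) {
    stop("responses reference items missing from the feature table",
         call. = FALSE)
  }
  cbind(responses, features[idx, setdiff(names(features), "item_id"),
                            drop = FALSE])
}

#' Fit the asymptote-modified mixed logistic model
#'
#' Maximum (approximate) marginal likelihood fit of
#' `P = c + (d - c) * logistic(X beta + u)`, with a Normal(0, sigma^2)
#' random intercept `u` per participant integrated out by Gauss-Hermite
#' quadrature, for fixed asymptotes `c < d`. With `c = 0`, `d = 1` and
#' `sigma` forced to 0 this reduces exactly to ordinary logistic
#' regression. The fit is deterministic given the data and optimizer
#' settings.
#'
#' @param responses data frame `(participant_id, item_id, correct)`.
#' @param features per-item feature table (keyed by `item_id`).
#' @param feature_subset feature names for the fixed effects; empty for
#'   the null (intercept + participant effect) model.
#' @param guessing,inattention fixed asymptotes, `0 <= c < d <= 1`.
#' @param interact interact features with probe accuracy (default `TRUE`).
#' @param random_effects estimate the participant random-intercept SD;
#'   `FALSE` forces `sigma = 0`.
#' @param n_quad number of Gauss-Hermite nodes (default 21).
#' @param control passed to [stats::optim()] (method BFGS).
#' @return Object of class `piat_fit`: coefficients, `sigma`,
#'   `participant_effect_sd`, `logLik`, `bic`
#'   (`-2 logLik + n_params log(n_obs)`), `n_obs`, `n_params`, standard
#'   errors and covariance of the coefficients, asymptotes, and a
#'   `convergence` flag (0 = converged; a non-zero optimizer code is kept,
#'   not silently discarded).
#' @examples
#' \donttest{
#' bank <- generate_bank(levels = 1:2, n_heard = 3, keys = "C",
#'                       variations = 4, seed = 1)
#' cal <- calibrate_bank(bank)
#' sim <- simulate_calibration_data(cal, n_respondents = 30,
#'                                  per_level = 4, seed = 2)
#' fit_model(sim$responses, bank_features(bank), c("level"))
#' }
#' @export
fit_model <- function(responses, features, feature_subset = character(0),
                      guessing = 0.3, inattention = 0.95,
                      interact = TRUE, random_effects = TRUE,
                      n_quad = 21L, control = list()) {
  stopifnot(guessing >= 0, guessing < inattention, inattention <= 1)
  dat <- merge_responses(responses, features)
  y <- as.numeric(dat$correct)
  if (all(y == 0) || all(y == 1)) {
    stop("degenerate data: all responses identical", call. = FALSE)
  }
  X <- build_design(dat, feature_subset, interact = interact)
  pid <- as.integer(factor(dat$participant_id))
  m <- max(pid)
  p <- ncol(X)
  c0 <- guessing
  d0 <- inattention
  span <- d0 - c0

  gh <- pracma::gaussHermite(n_quad)
  lw <- log(gh$w) - 0.5 * log(pi)
  nodes <- sqrt(2) * gh$x

  nll <- function(par) {
    beta <- par[seq_len(p)]
    eta <- drop(X %*% beta)
    if (random_effects) {
      sig <- exp(par[p + 1L])
      M <- outer(eta, sig * nodes, `+`)
      P <- c0 + span * stats::plogis(M)
      LL <- y * log(P) + (1 - y) * log1p(-P)
      A <- rowsum(LL, pid)
      -sum(row_logsumexp(A, lw))
    } else {
      P <- c0 + span * stats::plogis(eta)
      -sum(y * log(P) + (1 - y) * log1p(-P))
    }
  }

  # deterministic start: rescale the response into the (c, d) band and use
  # a working logistic fit
  y_adj <- pmin(pmax((mean(y) - c0) / span, 0.05), 0.95)
  start_int <- stats::qlogis(y_adj)
  beta0 <- c(start_int, rep(0, p - 1L))
  par0 <- if (random_effects) c(beta0, log(0.5)) else beta0

  ctrl <- utils::modifyList(list(maxit = 1000L, reltol = 1e-12), control)
  opt <- stats::optim(par0, nll, method = "BFGS", control = ctrl)
  hess <- try(stats::optimHess(opt$par, nll), silent = TRUE)
  vc <- if (!inherits(hess, "try-error")) try(solve(hess), silent = TRUE) else hess

  beta <- opt$par[seq_len(p)]
  names(beta) <- colnames(X)
  sigma <- if (random_effects) exp(opt$par[p + 1L]) else 0
  n_params <- p + as.integer(random_effects)
  logL <- -opt$value
  se <- rep(NA_real_, p)
  vcov_beta <- NULL
  if (!inherits(vc, "try-error") && is.matrix(vc)) {
    vcov_beta <- vc[seq_len(p), seq_len(p), drop = FALSE]
    dimnames(vcov_beta) <- list(colnames(X), colnames(X))
    se <- sqrt(pmax(diag(vcov_beta), 0))
  }
  names(se) <- colnames(X)

  structure(
    list(
      coefficients = beta, se = se, vcov = vcov_beta,
      sigma = sigma, participant_effect_sd = sigma,
      guessing = c0, inattention = d0,
      logLik = logL, bic = -2 * logL + n_params * log(length(y)),
      n_obs = length(y), n_params = n_params,
      feature_subset = feature_subset, interact = interact,
      random_effects = random_effects, n_quad = n_quad,
      convergence = opt$convergence,
      participant_levels = levels(factor(dat$participant_id)),
      data = list(y = y, X = X, pid = pid)
    ),
    class = "piat_fit"
  )
}

#' @export
print.piat_fit <- function(x, ...) {
  cat(sprintf("Explanatory 4PL fit: c = %.3g, d = %.3g, sigma = %.3g\n",
              x$guessing, x$inattention, x$sigma))
  cat(sprintf("  logLik = %.3f, BIC = %.3f (n = %d, k = %d)%s\n",
              x$logLik, x$bic, x$n_obs, x$n_params,
              if (x$convergence != 0) "  [DID NOT CONVERGE]" else ""))
  print(round(cbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

# Posterior-mode participant effects given a fit (empirical Bayes).
participant_effects <- function(fit) {
  if (fit$sigma <= 1e-8) {
    u <- rep(0, length(fit$participant_levels))
    names(u) <- fit$participant_levels
    return(u)
  }
  y <- fit$data$y; X <- fit$data$X; pid <- fit$data$pid
  eta <- drop(X %*% fit$coefficients)
  c0 <- fit$guessing; span <- fit$inattention - fit$guessing
  u <- vapply(seq_along(fit$participant_levels), function(j) {
    rows <- pid == j
    obj <- function(uu) {
      P <- c0 + span * stats::plogis(eta[rows] + uu)
      -(sum(y[rows] * log(P) + (1 - y[rows]) * log1p(-P)) +
          stats::dnorm(uu, 0, fit$sigma, log = TRUE))
    }
    stats::optimize(obj, c(-6 * fit$sigma, 6 * fit$sigma))$minimum
  }, numeric(1))
  names(u) <- fit$participant_levels
  u
}

# Predicted success probabilities for merged rows under a fit.
predict_prob <- function(fit, dat, u = NULL) {
  X <- build_design(dat, fit$feature_subset, interact = fit$interact)
  X <- X[, names(fit$coefficients), drop = FALSE]
  eta <- drop(X %*% fit$coefficients)
  if (!is.null(u)) {
    uu <- u[as.character(dat$participant_id)]
    uu[is.na(uu)] <- 0
    eta <- eta + uu
  }
  fit$guessing + (fit$inattention - fit$guessing) * stats::plogis(eta)
}

#' Profile the guessing and inattention asymptotes
#'
#' Outer grid search over the lower asymptote `c` (guessing) and upper
#' asymptote `d` (inattention), refitting the mixed logistic model at each
#' grid point and keeping the profile-likelihood maximizer. The profile
#' surface is flat and bounded, so a grid is robust; the default grid is
#' `c` in 0, 0.05, ..., 0.5 and `d` in 0.8, 0.85, ..., 1 (with `d = 1`
#' nudged to 0.999 so the likelihood stays finite for errors at high
#' ability).
#'
#' @inheritParams fit_model
#' @param c_grid,d_grid numeric grids with `0 <= c < d <= 1`.
#' @return The best `piat_fit`, with `n_params` increased by 2 for the
#'   profiled asymptotes, BIC recomputed accordingly, and the full grid in
#'   `$asymptote_table` (columns `c`, `d`, `logLik`).
#' @export
optimize_asymptotes <- function(responses, features,
                                feature_subset = character(0),
                                c_grid = seq(0, 0.5, by = 0.05),
                                d_grid = seq(0.8, 1, by = 0.05),
                                interact = TRUE, random_effects = TRUE,
                                n_quad = 21L, control = list()) {
  grid <- expand.grid(c = c_grid, d = d_grid)
  grid <- grid[grid$c < grid$d, , drop = FALSE]
  grid$d[grid$d >= 1] <- 0.999
  best <- NULL
  ll <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fit <- fit_model(responses, features, feature_subset,
                     guessing = grid$c[i], inattention = grid$d[i],
                     interact = interact, random_effects = random_effects,
                     n_quad = n_quad, control = control)
    ll[i] <- fit$logLik
    if (is.null(best) || fit$logLik > best$logLik) best <- fit
  }
  best$n_params <- best$n_params + 2L
  best$bic <- -2 * best$logLik + best$n_params * log(best$n_obs)
  best$asymptote_table <- data.frame(c = grid$c, d = grid$d, logLik = ll)
  best
}

#' Screen predictors by random-forest permutation importance
#'
#' Ranks candidate item features by their out-of-bag permutation
#' importance (mean decrease in classification accuracy when the feature
#' is permuted) in a random forest predicting response correctness.
#'
#' @param responses data frame `(participant_id, item_id, correct)`.
#' @param features per-item feature table.
#' @param candidates feature names to rank (default: all numeric/logical
#'   feature columns).
#' @param n_keep how many top names to return (default all).
#' @param seed integer seed for the forest.
#' @param num_trees forest size (default 500).
#' @return Character vector of the top `n_keep` feature names, ranked;
#'   the full importance vector is attached as attribute `"importance"`.
#' @export
screen_predictors <- function(responses, features, candidates = NULL,
                              n_keep = NULL, seed = 1L, num_trees = 500L) {
  dat <- merge_responses(responses, features)
  if (is.null(candidates)) {
    candidates <- setdiff(
      names(features)[vapply(features, function(v)
        is.numeric(v) || is.logical(v), logical(1))],
      "item_id"
    )
  }
  if (length(candidates) < 2L) {
    stop("need at least 2 candidate features to rank", call. = FALSE)
  }
  df <- dat[, candidates, drop = FALSE]
  df[] <- lapply(df, as.numeric)
  df$.y <- factor(dat$correct, levels = c(0, 1))
  rf <- ranger::ranger(
    dependent.variable.name = ".y", data = df,
    importance = "permutation", num.trees = num_trees,
    seed = as.integer(seed), probability = FALSE
  )
  imp <- sort(rf$variable.importance, decreasing = TRUE)
  keep <- utils::head(names(imp), n_keep %||% length(imp))
  attr(keep, "importance") <- imp
  keep
}

#' Exhaustive best-subset search by BIC
#'
#' Fits the mixed logistic model on every subset of the candidate
#' features (optionally profiling the asymptotes per subset) and returns
#' the minimum-BIC model together with the full per-subset table. With
#' `k` candidates and no `max_size` cap the table has exactly `2^k` rows.
#'
#' @inheritParams fit_model
#' @param candidates candidate feature names (enumeration is over their
#'   power set).
#' @param max_size optional cap on subset size.
#' @param budget maximum number of subsets allowed (default 4096); an
#'   error advises `max_size` if exceeded.
#' @param profile_asymptotes profile `(c, d)` per subset via
#'   [optimize_asymptotes()] instead of fixing them (slower).
#' @param c_grid,d_grid grids used when profiling.
#' @return List with `best` (a `piat_fit`) and `table` (data frame with
#'   one row per subset: `subset`, `size`, `logLik`, `bic`, `c`, `d`).
#' @export
subset_search <- function(responses, features, candidates,
                          guessing = 0.3, inattention = 0.95,
                          interact = TRUE, random_effects = TRUE,
                          max_size = NULL, budget = 4096L,
                          profile_asymptotes = FALSE,
                          c_grid = seq(0, 0.5, by = 0.1),
                          d_grid = seq(0.8, 1, by = 0.1),
                          n_quad = 21L) {
  k <- length(candidates)
  sizes <- 0:(max_size %||% k)
  subsets <- unlist(lapply(sizes, function(s) {
    if (s == 0L) return(list(character(0)))
    apply(utils::combn(candidates, s), 2L, identity, simplify = FALSE)
  }), recursive = FALSE)
  if (length(subsets) > budget) {
    stop(sprintf(
      "subset enumeration (%d models) exceeds budget %d; set max_size",
      length(subsets), budget), call. = FALSE)
  }
  best <- NULL
  tab <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    sub <- subsets[[i]]
    fit <- if (profile_asymptotes) {
      optimize_asymptotes(responses, features, sub, c_grid = c_grid,
                          d_grid = d_grid, interact = interact,
                          random_effects = random_effects, n_quad = n_quad)
    } else {
      fit_model(responses, features, sub, guessing = guessing,
                inattention = inattention, interact = interact,
                random_effects = random_effects, n_quad = n_quad)
    }
    tab[[i]] <- data.frame(
      subset = paste(sub, collapse = "+"), size = length(sub),
      logLik = fit$logLik, bic = fit$bic,
      c = fit$guessing, d = fit$inattention, stringsAsFactors = FALSE
    )
    if (is.null(best) || fit$bic < best$bic) best <- fit
  }
  list(best = best, table = do.call(rbind, tab))
}

#' Cross-validated classification accuracy
#'
#' k-fold cross-validated proportion of correctly classified responses
#' (threshold 0.5 on the predicted success probability). Folds are
#' stratified by response class so every training set contains both
#' classes. `with_participant_effects` toggles whether the fitted
#' participant random intercepts (posterior modes from the training fold)
#' are used at prediction time; using them measures accuracy with
#' person-specific ability included, not purely item-driven accuracy.
#'
#' @inheritParams fit_model
#' @param k number of folds (default 10).
#' @param with_participant_effects logical (default `FALSE`).
#' @param seed integer seed for the fold assignment.
#' @return proportion in \[0, 1\].
#' @export
cv_accuracy <- function(responses, features, feature_subset,
                        k = 10L, with_participant_effects = FALSE,
                        guessing = 0.3, inattention = 0.95,
                        interact = TRUE, random_effects = TRUE,
                        n_quad = 21L, seed = 1L) {
  stopifnot(k >= 2L)
  dat <- merge_responses(responses, features)
  n <- nrow(dat)
  fold <- integer(n)
  with_seed(seed, {
    for (cls in unique(dat$correct)) {
      idx <- which(dat$correct == cls)
      if (length(idx) < k) {
        stop("a response class has fewer observations than folds",
             call. = FALSE)
      }
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  hits <- 0L
  for (f in seq_len(k)) {
    train <- dat[fold != f, , drop = FALSE]
    test <- dat[fold == f, , drop = FALSE]
    fit <- fit_model(train[, c("participant_id", "item_id", "correct")],
                     features, feature_subset,
                     guessing = guessing, inattention = inattention,
                     interact = interact, random_effects = random_effects,
                     n_quad = n_quad)
    u <- if (with_participant_effects) participant_effects(fit) else NULL
    p <- predict_prob(fit, test, u = u)
    hits <- hits + sum((p >= 0.5) == (test$correct == 1))
  }
  hits / n
}

#' Separate-then-joint fitting workflow
#'
#' Convenience driver mirroring the calibration workflow: fit the
#' correct-probe and incorrect-probe subsets of the data separately (main
#' effects only), then fit the joint interaction model on the full data.
#' The joint interaction design is the canonical output used to calibrate
#' item banks.
#'
#' @inheritParams fit_model
#' @param correct_subset,incorrect_subset feature names for the two
#'   split models.
#' @return List with elements `correct`, `incorrect` and `joint`
#'   (`piat_fit` objects).
#' @export
fit_split_then_joint <- function(responses, features,
                                 correct_subset, incorrect_subset,
                                 guessing = 0.3, inattention = 0.95,
                                 random_effects = TRUE, n_quad = 21L) {
  dat <- merge_responses(responses, features)
  acc <- as.logical(dat$probe_accuracy)
  resp_cols <- c("participant_id", "item_id", "correct")
  fit_cor <- fit_model(dat[acc, resp_cols], features, correct_subset,
                       guessing = guessing, inattention = inattention,
                       interact = FALSE, random_effects = random_effects,
                       n_quad = n_quad)
  fit_inc <- fit_model(dat[!acc, resp_cols], features, incorrect_subset,
                       guessing = guessing, inattention = inattention,
                       interact = FALSE, random_effects = random_effects,
                       n_quad = n_quad)
  fit_joint <- fit_model(responses, features,
                         union(correct_subset, incorrect_subset),
                         guessing = guessing, inattention = inattention,
                         interact = TRUE, random_effects = random_effects,
                         n_quad = n_quad)
  list(correct = fit_cor, incorrect = fit_inc, joint = fit_joint)
}
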