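#' Generate one arrow walk
#'
#' An arrow walk is a sequence of stepwise pitch moves (+1 = up one scale
#' step, -1 = down): first `n_heard` sounded arrows, then `level` silent
#' (imagined) arrows. The walk is sampled uniformly at random among all
#' sign sequences whose cumulative positions (offsets from the start note,
#' which sits at 0) stay within `range_bound` steps, by rejection sampling.
#' Uses the current RNG state; seed the session for reproducibility.
#'
#' @param level number of silent arrows (1..6).
#' @param n_heard number of heard arrows (3..5).
#' @param range_bound maximum |offset| reachable during the walk (default 4).
#' @return A list of class `piat_walk` with elements `heard_steps`,
#'   `silent_steps` (integer +/-1 vectors), `positions` (cumulative offsets,
#'   excluding the implicit leading 0), `true_final_offset` and
#'   `last_heard_offset`.
#' @examples
#' set.seed(1)
#' generate_walk(level = 2, n_heard = 3)
#' @export
generate_walk <- function(level, n_heard, range_bound = 4L) {
  stopifnot(level >= 1L, level <= 6L, n_heard >= 3L, n_heard <= 5L)
  n <- level + n_heard
  repeat {
    steps <- sample(c(-1L, 1L), n, replace = TRUE)
    pos <- cumsum(steps)
    if (all(abs(pos) <= range_bound)) break
  }
  structure(
    list(
      heard_steps = steps[seq_len(n_heard)],
      silent_steps = steps[n_heard + seq_len(level)],
      positions = pos,
      true_final_offset = pos[n],
      last_heard_offset = pos[n_heard]
    ),
    class = "piat_walk"
  )
}

#' Assign a probe offset to a walk
#'
#' For a correct-probe trial the probe is the true final (imagined) note.
#' For an incorrect-probe trial the probe is sampled uniformly from the
#' offsets one or two scale steps away from the true final note, excluding
#' the start note (offset 0), the true final note itself, and (by default)
#' anything outside the trial's `range_bound`.
#'
#' @param walk a `piat_walk`.
#' @param accuracy logical; `TRUE` for a correct (matching) probe.
#' @param range_bound bound applied to the probe offset; set to `Inf` to
#'   bound only the sounded/imagined notes.
#' @return integer probe offset, or `NA` as a retry signal when a correct
#'   probe is requested for a walk ending on the start note, or when no
#'   admissible incorrect probe exists.
#' @examples
#' set.seed(1)
#' w <- generate_walk(2, 3)
#' assign_probe(w, accuracy = TRUE)
#' @export
assign_probe <- function(walk, accuracy, range_bound = 4L) {
  final <- walk$true_final_offset
  if (accuracy) {
    if (final == 0L) return(NA_integer_)  # probe may never be the start note
    return(final)
  }
  cand <- final + c(-2L, -1L, 1L, 2L)
  cand <- cand[cand != 0L & abs(cand) <= range_bound]
  if (length(cand) == 0L) return(NA_integer_)
  cand[sample.int(length(cand), 1L)]
}

item_id_for <- function(level, n_heard, start_degree, accuracy, key, variation) {
  sprintf(
    "L%d_H%d_%s_%s_%s_v%02d",
    level, n_heard, start_degree, if (accuracy) "cor" else "inc",
    gsub("#", "s", gsub("b", "f", key)), variation
  )
}

#' Generate an item bank
#'
#' Builds one item per cell of the factorial design
#' (level x heard arrows x start degree x probe accuracy x key) times the
#' requested number of variations per cell. Variations within a cell are
#' pairwise distinct (arrow sequence, probe) pairs, found by rejection
#' sampling. The calibration design (levels 1-5, heard 3-5, both start
#' degrees, both accuracies, five keys, ten variations) yields 300 cells
#' and 3000 items; the level-6 extension (`levels = 6`) yields 600 more.
#'
#' @param levels integer vector of silent-arrow counts (default 1:5).
#' @param n_heard integer vector of heard-arrow counts (default 3:5).
#' @param start_degrees subset of `c("tonic", "dominant")`.
#' @param accuracies subset of `c(TRUE, FALSE)` (correct / incorrect probe).
#' @param keys key names (default the five admissible keys).
#' @param variations distinct variations per cell (default 10).
#' @param seed integer seed; the bank is a pure function of the
#'   configuration and this seed.
#' @param range_bound walk range bound in scale steps (default 4).
#' @param probe_in_range logical; if `TRUE` (default) the `range_bound`
#'   also applies to incorrect probe offsets.
#' @param max_tries rejection-sampling cap per cell before an error is
#'   raised naming the exhausted cell (default 10000).
#' @return An object of class `piat_bank`: a list with `items` (data frame,
#'   one row per item) and `config` (the generating configuration,
#'   including the seed and a schema version).
#' @examples
#' bank <- generate_bank(levels = 1:2, n_heard = 3, keys = "C",
#'                       variations = 2, seed = 42)
#' nrow(bank$items)
#' @export
generate_bank <- function(levels = 1:5,
                          n_heard = 3:5,
                          start_degrees = c("tonic", "dominant"),
                          accuracies = c(TRUE, FALSE),
                          keys = piat_keys()$name,
                          variations = 10L,
                          seed = 1L,
                          range_bound = 4L,
                          probe_in_range = TRUE,
                          max_tries = 10000L) {
  stopifnot(all(levels %in% 1:6), all(n_heard %in% 3:5),
            all(start_degrees %in% c("tonic", "dominant")),
            all(keys %in% piat_keys()$name), variations >= 1L)
  cells <- expand.grid(
    level = as.integer(levels), n_heard = as.integer(n_heard),
    start_degree = start_degrees, accuracy = accuracies, key = keys,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  probe_bound <- if (probe_in_range) range_bound else Inf

  rows <- with_seed(seed, {
    out <- vector("list", nrow(cells) * variations)
    k <- 0L
    for (i in seq_len(nrow(cells))) {
      cell <- cells[i, ]
      seen <- character(0)
      tries <- 0L
      while (length(seen) < variations) {
        tries <- tries + 1L
        if (tries > max_tries) {
          stop(sprintf(
            "cell exhausted after %d tries: level=%d heard=%d start=%s accuracy=%s key=%s (%d of %d variations found)",
            max_tries, cell$level, cell$n_heard, cell$start_degree,
            cell$accuracy, cell$key, length(seen), variations
          ), call. = FALSE)
        }
        walk <- generate_walk(cell$level, cell$n_heard, range_bound)
        probe <- assign_probe(walk, cell$accuracy, probe_bound)
        if (is.na(probe)) next
        sig <- paste0(steps_to_string(c(walk$heard_steps, walk$silent_steps)),
                      ":", probe)
        if (sig %in% seen) next
        seen <- c(seen, sig)
        k <- k + 1L
        out[[k]] <- data.frame(
          item_id = item_id_for(cell$level, cell$n_heard, cell$start_degree,
                                cell$accuracy, cell$key, length(seen)),
          key = cell$key,
          start_degree = cell$start_degree,
          level = cell$level,
          n_heard = cell$n_heard,
          heard_steps = steps_to_string(walk$heard_steps),
          silent_steps = steps_to_string(walk$silent_steps),
          probe_offset = probe,
          probe_correct = cell$accuracy,
          true_final_offset = walk$true_final_offset,
          last_heard_offset = walk$last_heard_offset,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, out[seq_len(k)])
  })
  rownames(rows) <- NULL

  structure(
    list(
      items = rows,
      config = list(
        schema_version = 1L,
        levels = as.integer(levels), n_heard = as.integer(n_heard),
        start_degrees = start_degrees, accuracies = accuracies,
        keys = keys, variations = as.integer(variations),
        seed = as.integer(seed), range_bound = range_bound,
        probe_in_range = probe_in_range
      )
    ),
    class = "piat_bank"
  )
}

#' Combine item banks
#'
#' Concatenates the items of several banks (for example the calibration
#' bank and the level-6 extension) into one. Item ids must be unique
#' across the inputs.
#'
#' @param ... `piat_bank` objects.
#' @return A `piat_bank` whose `config` is the list of input configs.
#' @export
combine_banks <- function(...) {
  banks <- list(...)
  stopifnot(length(banks) >= 1L,
            all(vapply(banks, inherits, logical(1), "piat_bank")))
  items <- do.call(rbind, lapply(banks, `[[`, "items"))
  if (anyDuplicated(items$item_id)) {
    stop("duplicate item ids across combined banks", call. = FALSE)
  }
  rownames(items) <- NULL
  structure(
    list(items = items, config = lapply(banks, `[[`, "config")),
    class = "piat_bank"
  )
}

#' @export
print.piat_bank <- function(x, ...) {
  cat("PIAT item bank:", nrow(x$items), "items\n")
  lv <- table(x$items$level)
  cat("  levels:", paste(sprintf("%s (n=%d)", names(lv), lv), collapse = ", "), "\n")
  invisible(x)
}

#' Timed event schedule of a trial
#'
#' Expands one item into its symbolic presentation schedule: the ascending
#' scale (2 s), the start note (2 s), each heard arrow (1 s), each
#' non-final silent arrow (1 s), the final silent arrow carrying the word
#' "hold" (2 s), then the probe.
#'
#' @param item a single-row data frame from a bank's `items` (or any list
#'   with `n_heard` and `level`).
#' @param probe_duration seconds allotted to the probe event (default 1).
#' @return Data frame with columns `event` and `duration` (seconds).
#' @examples
#' bank <- generate_bank(levels = 1, n_heard = 3, keys = "C",
#'                       variations = 1, seed = 1)
#' trial_schedule(bank$items[1, ])
#' @export
trial_schedule <- function(item, probe_duration = 1) {
  n_heard <- as.integer(item$n_heard)
  level <- as.integer(item$level)
  events <- c(
    "scale", "start_note",
    rep("heard_arrow", n_heard),
    rep("silent_arrow", max(level - 1L, 0L)),
    "hold_arrow", "probe"
  )
  durations <- c(
    2, 2,
    rep(1, n_heard),
    rep(1, max(level - 1L, 0L)),
    2, probe_duration
  )
  data.frame(event = events, duration = durations, stringsAsFactors = FALSE)
}
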