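# Cognitive-model predictor variables for generated items.

heard_positions <- function(heard_steps_string) {
  cumsum(string_to_steps(heard_steps_string))
}

#' Number of unique tones heard during set-up
#'
#' Counts the distinct pitches sounded during the set-up phase of an item:
#' the start note (offset 0) plus the notes reached by the heard arrows.
#' A stepwise walk with at least one heard arrow always yields a value of
#' at least 2.
#'
#' @param heard_steps heard arrow signs, either an integer +/-1 vector or
#'   a step string such as `"++-"`.
#' @return integer count.
#' @examples
#' heard_range(c(1, 1, 1))   # offsets {0,1,2,3} -> 4
#' heard_range("+-+")        # offsets {0,1}     -> 2
#' @export
heard_range <- function(heard_steps) {
  if (is.character(heard_steps)) heard_steps <- string_to_steps(heard_steps)
  length(unique(c(0L, cumsum(heard_steps))))
}

#' Empirical probe-distance probability table
#'
#' The relative frequency, across a whole bank, of the signed distance in
#' scale steps between the probe and the last heard note. The signed
#' distance carries both parity (with an even number of imagined steps a
#' correct probe is an even number of steps from the last tone heard) and
#' direction; set `type = "absolute"` to collapse direction.
#'
#' @param bank a `piat_bank`.
#' @param type `"signed"` (default) or `"absolute"`.
#' @return Named numeric vector of probabilities (names are distances)
#'   summing to 1, of class `piat_distance_table`.
#' @examples
#' bank <- generate_bank(levels = 1:2, n_heard = 3, keys = "C",
#'                       variations = 2, seed = 1)
#' distance_table(bank)
#' @export
distance_table <- function(bank, type = c("signed", "absolute")) {
  type <- match.arg(type)
  items <- if (inherits(bank, "piat_bank")) bank$items else bank
  if (is.null(items) || nrow(items) == 0L) {
    stop("cannot build a distance table from an empty bank", call. = FALSE)
  }
  d <- items$probe_offset - items$last_heard_offset
  if (type == "absolute") d <- abs(d)
  tab <- table(d) / length(d)
  structure(as.numeric(tab), names = names(tab),
            type = type, class = "piat_distance_table")
}

#' Probability of the probe given the last heard note
#'
#' Looks up an item's probe-to-last-heard distance in a bank-level
#' [distance_table()]. Distances absent from the table return 0 (the
#' empirical-frequency definition; no smoothing), which cannot occur for
#' items belonging to the table's own bank.
#'
#' @param item single-row item data frame (or list with `probe_offset` and
#'   `last_heard_offset`).
#' @param table a `piat_distance_table`.
#' @return probability in \[0, 1\].
#' @export
probability_probe_last_heard <- function(item, table) {
  d <- item$probe_offset - item$last_heard_offset
  if (identical(attr(table, "type"), "absolute")) d <- abs(d)
  p <- unname(table[as.character(d)])
  ifelse(is.na(p), 0, p)
}

#' Absolute difference between probe and true imagined note
#'
#' 0 on correct-probe trials; 1 or 2 on incorrect-probe trials (an
#' incorrect probe is always one or two scale steps from the note that
#' should have been imagined).
#'
#' @param item single-row item data frame.
#' @return integer in `{0, 1, 2}`.
#' @export
probe_trueim_absdiff <- function(item) {
  abs(item$probe_offset - item$true_final_offset)
}

#' Probability of the probe given the total arrow count
#'
#' The empirical probability of an item's probe offset among all bank
#' items with the same total number of arrows (heard + silent).
#'
#' @param item single-row item data frame.
#' @param bank a `piat_bank` (the conditioning population).
#' @return probability in \[0, 1\].
#' @export
probability_probe <- function(item, bank) {
  items <- if (inherits(bank, "piat_bank")) bank$items else bank
  same <- items[items$n_heard + items$level == item$n_heard + item$level, ]
  if (nrow(same) == 0L) return(0)
  mean(same$probe_offset == item$probe_offset)
}

#' Feature table for a bank
#'
#' Computes the cognitive-model predictors for every item of a bank:
#' `level` (number of imagined tones), `heard_range` (unique tones during
#' set-up), `probability_probe_last_heard` (empirical probability of the
#' probe's signed distance from the last heard note),
#' `probe_trueim_absdiff` (probe distance from the true imagined note),
#' `probe_is_startnote` (always `FALSE` for generated banks, which forbid
#' the start note as probe), `probability_probe` (empirical probability of
#' the probe offset given the total arrow count) and `probe_accuracy`.
#' The function is deterministic: recomputation over the same bank and
#' tables returns the same values.
#'
#' @param bank a `piat_bank`.
#' @param dist_table a [distance_table()]; computed from `bank` itself by
#'   default. Pass the table of a larger reference bank to score items
#'   against it (e.g. score a level-6 extension against the combined bank).
#' @param ref_bank conditioning population for `probability_probe`
#'   (default `bank`).
#' @return Data frame keyed by `item_id`, one row per item.
#' @examples
#' bank <- generate_bank(levels = 1:2, n_heard = 3, keys = "C",
#'                       variations = 2, seed = 1)
#' head(bank_features(bank))
#' @export
bank_features <- function(bank, dist_table = distance_table(bank),
                          ref_bank = bank) {
  items <- bank$items
  if (is.null(items) || nrow(items) == 0L) {
    stop("empty bank", call. = FALSE)
  }
  hr <- vapply(items$heard_steps, heard_range, integer(1), USE.NAMES = FALSE)
  d <- items$probe_offset - items$last_heard_offset
  if (identical(attr(dist_table, "type"), "absolute")) d <- abs(d)
  pp_lh <- unname(dist_table[as.character(d)])
  pp_lh[is.na(pp_lh)] <- 0

  ref_items <- if (inherits(ref_bank, "piat_bank")) ref_bank$items else ref_bank
  total <- items$n_heard + items$level
  ref_total <- ref_items$n_heard + ref_items$level
  pp <- vapply(seq_len(nrow(items)), function(i) {
    same <- ref_total == total[i]
    if (!any(same)) return(0)
    mean(ref_items$probe_offset[same] == items$probe_offset[i])
  }, numeric(1))

  data.frame(
    item_id = items$item_id,
    level = items$level,
    heard_range = hr,
    probability_probe_last_heard = pp_lh,
    probe_trueim_absdiff = abs(items$probe_offset - items$true_final_offset),
    probe_is_startnote = items$probe_offset == 0L,
    probability_probe = pp,
    probe_accuracy = items$probe_correct,
    stringsAsFactors = FALSE
  )
}
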