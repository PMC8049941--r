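# File formats: item banks as versioned JSON, response tables as CSV.

BANK_SCHEMA_VERSION <- 1L

#' Write an item bank to JSON
#'
#' Serializes a (plain or calibrated) bank losslessly: schema version,
#' generating configuration (including the seed), model parameters when
#' present, and one object per item.
#'
#' @param bank a `piat_bank` or `piat_calibrated_bank`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bank <- function(bank, path) {
  stopifnot(inherits(bank, "piat_bank"))
  payload <- list(
    schema_version = BANK_SCHEMA_VERSION,
    calibrated = inherits(bank, "piat_calibrated_bank"),
    config = bank$config,
    items = bank$items
  )
  if (!is.null(bank$params)) {
    payload$params <- list(
      coefficients = as.list(bank$params$coefficients),
      guessing = bank$params$guessing,
      inattention = bank$params$inattention,
      discrimination = bank$params$discrimination,
      scale = bank$params$scale
    )
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Read an item bank from JSON
#'
#' Reads a bank written by [write_bank()]; refuses unknown schema
#' versions explicitly.
#'
#' @param path input file path.
#' @return A `piat_bank` (or `piat_calibrated_bank` if the file carries
#'   difficulty values).
#' @export
read_bank <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- payload$schema_version
  if (is.null(v) || !identical(as.integer(v), BANK_SCHEMA_VERSION)) {
    stop("unsupported bank schema version: ",
         if (is.null(v)) "<missing>" else v,
         " (this build reads version ", BANK_SCHEMA_VERSION, ")",
         call. = FALSE)
  }
  items <- as.data.frame(payload$items, stringsAsFactors = FALSE)
  int_cols <- intersect(
    c("level", "n_heard", "probe_offset", "true_final_offset",
      "last_heard_offset"), names(items))
  items[int_cols] <- lapply(items[int_cols], as.integer)
  bank <- list(items = items, config = payload$config)
  if (isTRUE(payload$calibrated)) {
    if (!is.null(payload$params)) {
      bank$params <- piat_model_params(
        coefficients = unlist(payload$params$coefficients),
        guessing = payload$params$guessing,
        inattention = payload$params$inattention,
        discrimination = payload$params$discrimination,
        scale = payload$params$scale
      )
    }
    class(bank) <- c("piat_calibrated_bank", "piat_bank")
  } else {
    class(bank) <- "piat_bank"
  }
  bank
}

#' Write a response table to CSV
#'
#' @param responses data frame `(participant_id, item_id, correct)`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path) {
  need <- c("participant_id", "item_id", "correct")
  stopifnot(all(need %in% names(responses)))
  utils::write.csv(responses[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a response table from CSV
#'
#' Expects a header `participant_id, item_id, correct` and validates that
#' every `correct` value is 0 or 1, reporting the offending row number
#' otherwise. An empty table (header only) is valid.
#'
#' @param path input file path.
#' @return Data frame `(participant_id, item_id, correct)`.
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character",
                                       item_id = "character"))
  need <- c("participant_id", "item_id", "correct")
  if (!all(need %in% names(df))) {
    stop("response file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!df$correct %in% c(0L, 1L))
  if (length(bad)) {
    stop("non-binary 'correct' value at row ", bad[1L], ": ",
         df$correct[bad[1L]], call. = FALSE)
  }
  df$correct <- as.integer(df$correct)
  df[, need]
}
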