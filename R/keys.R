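#' Admissible key signatures
#'
#' The task uses five major keys: C, C#, D, Eb and E. Each key is anchored
#' at a tonic pitch in the octave around middle C (MIDI convention, middle
#' C = 60), so that walks bounded by +/- 4 diatonic steps stay within a
#' comfortable listening register. The octave placement is a configuration
#' choice; transpose `tonic_pitch` to move the register.
#'
#' @param register integer MIDI pitch of the tonic of C major (default 60,
#'   middle C); the other keys are placed immediately above it.
#' @return A data frame with columns `name` and `tonic_pitch`.
#' @examples
#' piat_keys()
#' @export
piat_keys <- function(register = 60L) {
  data.frame(
    name = c("C", "C#", "D", "Eb", "E"),
    tonic_pitch = as.integer(register) + 0:4,
    stringsAsFactors = FALSE
  )
}

# Major-scale interval pattern (semitones above tonic for degrees 1..7).
MAJOR_SCALE <- c(0L, 2L, 4L, 5L, 7L, 9L, 11L)

# 0-based scale-degree index of the admissible start notes.
START_DEGREE_INDEX <- c(tonic = 0L, dominant = 4L)

#' Pitch of a note a number of diatonic steps from the start note
#'
#' Converts a scale-step offset (0 = the start note) into an integer pitch
#' (semitones, MIDI convention) within the major scale of `key`. The start
#' note is the tonic or the dominant (fifth degree) of the key.
#'
#' @param key key name, one of `piat_keys()$name`.
#' @param start_degree `"tonic"` or `"dominant"`.
#' @param offset integer vector of diatonic step offsets, `|offset| <= 8`.
#' @param keys key table, by default [piat_keys()].
#' @return integer pitch vector, same length as `offset`.
#' @examples
#' degree_to_pitch("C", "tonic", 0)       # middle C, 60
#' degree_to_pitch("C", "tonic", 2)       # E, 64
#' degree_to_pitch("C", "dominant", 4)    # D above the octave, 74
#' @export
degree_to_pitch <- function(key, start_degree, offset, keys = piat_keys()) {
  row <- match(key, keys$name)
  if (is.na(row)) {
    stop("unknown key '", key, "'; expected one of ",
         paste(keys$name, collapse = ", "), call. = FALSE)
  }
  if (!start_degree %in% names(START_DEGREE_INDEX)) {
    stop("unknown start degree '", start_degree,
         "'; expected 'tonic' or 'dominant'", call. = FALSE)
  }
  offset <- as.integer(offset)
  if (any(abs(offset) > 8L)) {
    stop("|offset| must be <= 8", call. = FALSE)
  }
  idx <- START_DEGREE_INDEX[[start_degree]] + offset
  octave <- idx %/% 7L
  degree <- idx %% 7L
  as.integer(keys$tonic_pitch[row] + 12L * octave + MAJOR_SCALE[degree + 1L])
}
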