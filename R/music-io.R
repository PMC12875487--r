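#' Construct a monophonic melody
#'
#' A melody is the symbolic substrate of the whole pipeline: an onset-sorted
#' sequence of pitched note events. Onsets are in seconds relative to the
#' first note (time origin 0), pitches are MIDI note numbers, and velocity
#' defaults to the constant 100 used for all stimuli.
#'
#' @param onset numeric vector of note onsets in seconds (strictly increasing).
#' @param pitch integer vector of MIDI note numbers (0-127).
#' @param duration numeric vector of note durations in seconds (> 0).
#' @param velocity integer vector (0-127), recycled; default 100.
#' @param id melody label.
#' @param condition one of `"real"`, `"shuffled"`, `"synthetic"`.
#' @param tempo_bpm optional tempo in beats per minute.
#' @param sixteenth_duration optional duration of a sixteenth note in seconds.
#' @return An object of class `melody`: a list with a `notes` data frame
#'   (onset, pitch, duration, velocity) plus metadata fields.
#' @export
melody <- function(onset, pitch, duration, velocity = 100L,
                   id = "melody", condition = c("synthetic", "real", "shuffled"),
                   tempo_bpm = NULL, sixteenth_duration = NULL) {
  condition <- match.arg(condition)
  n <- length(onset)
  if (n < 2L) stop_degenerate("a melody needs at least 2 notes")
  if (length(pitch) != n || length(duration) != n) {
    stop_format("onset, pitch and duration must have equal length")
  }
  if (any(!is.finite(onset)) || any(onset < 0)) {
    stop_format("onsets must be finite and non-negative")
  }
  if (any(diff(onset) <= 0)) {
    stop_monophony("note onsets must be strictly increasing (monophonic contract)")
  }
  if (any(pitch < 0 | pitch > 127)) stop_format("pitch outside MIDI range 0-127")
  if (any(duration <= 0)) stop_format("durations must be positive")
  velocity <- rep_len(as.integer(velocity), n)
  structure(
    list(
      id = id, condition = condition,
      notes = data.frame(
        onset = as.numeric(onset), pitch = as.integer(pitch),
        duration = as.numeric(duration), velocity = velocity
      ),
      tempo_bpm = tempo_bpm, sixteenth_duration = sixteenth_duration
    ),
    class = "melody"
  )
}

#' @export
print.melody <- function(x, ...) {
  cat(sprintf(
    "<melody '%s'> %d notes, %.1f s, condition=%s\n",
    x$id, nrow(x$notes), max(x$notes$onset + x$notes$duration), x$condition
  ))
  invisible(x)
}

n_notes <- function(m) nrow(m$notes)

#' Local interval features of a melody
#'
#' Computes, per note: the preceding inter-onset interval (IOI, seconds;
#' undefined for the first note), the subsequent IOI (undefined for the last
#' note), and the absolute inter-pitch interval (IPI, semitones; undefined
#' for the first note). Undefined entries are `NA`.
#'
#' @param m a [melody()].
#' @return data frame with columns `ioi`, `ioi_next`, `ipi`.
#' @export
local_intervals <- function(m) {
  on <- m$notes$onset
  pi_ <- m$notes$pitch
  d <- diff(on)
  data.frame(
    ioi = c(NA_real_, d),
    ioi_next = c(d, NA_real_),
    ipi = c(NA_real_, abs(diff(pi_)))
  )
}

# Symbolization grid for IOI ratios: rounding to 6 decimals keeps
# integer-ratio rhythms as an exact small alphabet.
IOI_RATIO_DIGITS <- 6L

#' Derive discrete viewpoint sequences from a melody
#'
#' Two viewpoints feed the sequence model: `cpitch` (the raw MIDI numbers,
#' defined from the first note) and `ioi_ratio` (the ratio of each note's
#' preceding IOI to the one before it, defined from the third note; ratios
#' are rounded to 6 decimals before symbolization so quantized rhythms yield
#' an exact finite alphabet).
#'
#' @param m a [melody()] with at least 2 notes.
#' @return list with elements `cpitch` and `ioi_ratio` (each a list with
#'   `viewpoint`, `symbols` character vector with `NA` where undefined,
#'   `defined_from`), and `intervals` (the [local_intervals()] table).
#' @export
derive_viewpoints <- function(m) {
  if (n_notes(m) < 2L) stop_degenerate("need at least 2 notes")
  iv <- local_intervals(m)
  cpitch <- as.character(m$notes$pitch)
  n <- n_notes(m)
  ratio <- rep(NA_character_, n)
  if (n >= 3L) {
    r <- iv$ioi[3:n] / iv$ioi[2:(n - 1L)]
    ratio[3:n] <- format_ratio_symbol(r)
  }
  list(
    cpitch = list(viewpoint = "cpitch", symbols = cpitch, defined_from = 1L),
    ioi_ratio = list(viewpoint = "ioi_ratio", symbols = ratio, defined_from = 3L),
    intervals = iv
  )
}

format_ratio_symbol <- function(r) {
  sprintf("%.6f", round(r, IOI_RATIO_DIGITS))
}

#' Read or write a plain-text melody table
#'
#' The tabular exchange format: one row per note with columns
#' `onset_s, pitch, duration_s, velocity` (tab-separated, header line).
#'
#' @param path file path.
#' @param m a [melody()] (for writing).
#' @param ... metadata passed to [melody()] when reading.
#' @return `read_melody_table` returns a [melody()]; `write_melody_table`
#'   returns `path` invisibly.
#' @export
read_melody_table <- function(path, ...) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("onset_s", "pitch", "duration_s", "velocity")
  if (!all(need %in% names(tb))) stop_format("melody table missing columns")
  melody(tb$onset_s, tb$pitch, tb$duration_s, tb$velocity, ...)
}

#' @rdname read_melody_table
#' @export
write_melody_table <- function(m, path) {
  tb <- data.frame(
    onset_s = m$notes$onset, pitch = m$notes$pitch,
    duration_s = m$notes$duration, velocity = m$notes$velocity
  )
  utils::write.table(tb, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
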