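# Minimal standard MIDI file (SMF type 0/1) support for monophonic melodies.
# Only the events the pipeline needs are interpreted: note-on/off, set-tempo,
# time signature and the like are skipped structurally. Ticks are resolved to
# seconds through the full tempo map.

MIDI_PPQ <- 480L

vlq_encode <- function(x) {
  x <- as.integer(x)
  bytes <- x %% 128L
  x <- x %/% 128L
  while (x > 0L) {
    bytes <- c(x %% 128L + 128L, bytes)
    x <- x %/% 128L
  }
  as.raw(bytes)
}

#' Write a melody to a standard MIDI file
#'
#' Emits a type-0 SMF at 480 ticks per quarter note with a single set-tempo
#' event (from `tempo_bpm`, default 120) followed by the note stream.
#'
#' @param m a [melody()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_midi <- function(m, path) {
  bpm <- m$tempo_bpm %||% 120
  us_per_quarter <- round(60e6 / bpm)
  ticks_per_s <- MIDI_PPQ * bpm / 60
  notes <- m$notes
  # event list: (tick, rank, raw bytes); note-offs sort before note-ons at a tick
  ev_tick <- integer(0); ev_rank <- integer(0); ev_bytes <- list()
  add <- function(tick, rank, bytes) {
    ev_tick <<- c(ev_tick, tick); ev_rank <<- c(ev_rank, rank)
    ev_bytes[[length(ev_bytes) + 1L]] <<- bytes
  }
  for (i in seq_len(nrow(notes))) {
    t_on <- as.integer(round(notes$onset[i] * ticks_per_s))
    t_off <- as.integer(round((notes$onset[i] + notes$duration[i]) * ticks_per_s))
    if (t_off <= t_on) t_off <- t_on + 1L
    add(t_on, 1L, as.raw(c(0x90L, notes$pitch[i], notes$velocity[i])))
    add(t_off, 0L, as.raw(c(0x80L, notes$pitch[i], 64L)))
  }
  ord <- order(ev_tick, ev_rank)
  ev_tick <- ev_tick[ord]; ev_bytes <- ev_bytes[ord]
  track <- c(
    vlq_encode(0L),
    as.raw(c(0xFF, 0x51, 0x03)),
    as.raw(c(us_per_quarter %/% 65536L, (us_per_quarter %/% 256L) %% 256L,
             us_per_quarter %% 256L))
  )
  last <- 0L
  for (i in seq_along(ev_tick)) {
    track <- c(track, vlq_encode(ev_tick[i] - last), ev_bytes[[i]])
    last <- ev_tick[i]
  }
  track <- c(track, vlq_encode(0L), as.raw(c(0xFF, 0x2F, 0x00)))
  u32 <- function(x) as.raw(c(x %/% 16777216, (x %/% 65536) %% 256,
                              (x %/% 256) %% 256, x %% 256))
  u16 <- function(x) as.raw(c(x %/% 256, x %% 256))
  out <- c(
    charToRaw("MThd"), u32(6L), u16(0L), u16(1L), u16(MIDI_PPQ),
    charToRaw("MTrk"), u32(length(track)), track
  )
  writeBin(out, path)
  invisible(path)
}

#' Read a monophonic melody from a standard MIDI file
#'
#' Parses a type-0/1 SMF, resolves the tempo map to seconds, and returns an
#' onset-sorted [melody()]. The monophony contract is enforced: overlapping
#' notes or simultaneous onsets raise a `monophony_error`.
#'
#' @param path path to a `.mid` file.
#' @param id,condition metadata for the returned [melody()].
#' @return a [melody()].
#' @export
read_midi <- function(path, id = basename(path), condition = "real") {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 14L || rawToChar(raw[1:4]) != "MThd") {
    stop_format("not a standard MIDI file (missing MThd)")
  }
  u <- function(idx) sum(as.integer(raw[idx]) * 256^((length(idx) - 1):0))
  n_tracks <- u(11:12)
  division <- u(13:14)
  if (division >= 32768L) stop_format("SMPTE time division not supported")
  pos <- 15L
  notes_on <- list() # pitch -> onset tick
  events <- list()   # list of (tick, type, pitch, vel)
  tempo_map <- list(list(tick = 0L, us = 500000))
  for (trk in seq_len(n_tracks)) {
    if (pos + 7L > length(raw) || rawToChar(raw[pos:(pos + 3L)]) != "MTrk") {
      stop_format("corrupt MIDI track header")
    }
    len <- u((pos + 4L):(pos + 7L))
    p <- pos + 8L
    end <- p + len
    tick <- 0L
    status <- 0L
    while (p < end) {
      # delta time (VLQ)
      dt <- 0L
      repeat {
        b <- as.integer(raw[p]); p <- p + 1L
        dt <- dt * 128L + (b %% 128L)
        if (b < 128L) break
      }
      tick <- tick + dt
      b <- as.integer(raw[p])
      if (b >= 128L) { status <- b; p <- p + 1L } # else running status
      hi <- status %/% 16L
      if (status == 255L) { # meta
        type <- as.integer(raw[p]); p <- p + 1L
        mlen <- 0L
        repeat {
          bb <- as.integer(raw[p]); p <- p + 1L
          mlen <- mlen * 128L + (bb %% 128L)
          if (bb < 128L) break
        }
        if (type == 81L && mlen == 3L) {
          us <- u(p:(p + 2L))
          tempo_map[[length(tempo_map) + 1L]] <- list(tick = tick, us = us)
        }
        p <- p + mlen
      } else if (status == 240L || status == 247L) { # sysex
        slen <- 0L
        repeat {
          bb <- as.integer(raw[p]); p <- p + 1L
          slen <- slen * 128L + (bb %% 128L)
          if (bb < 128L) break
        }
        p <- p + slen
      } else if (hi %in% c(8L, 9L)) {
        pitch <- as.integer(raw[p]); vel <- as.integer(raw[p + 1L]); p <- p + 2L
        type <- if (hi == 9L && vel > 0L) "on" else "off"
        events[[length(events) + 1L]] <- list(tick = tick, type = type,
                                              pitch = pitch, vel = vel)
      } else if (hi %in% c(10L, 11L, 14L)) {
        p <- p + 2L
      } else if (hi %in% c(12L, 13L)) {
        p <- p + 1L
      } else {
        stop_format(sprintf("unhandled MIDI status byte 0x%x", status))
      }
    }
    pos <- end
  }
  if (length(events) == 0L) stop_format("MIDI file contains no notes")
  # tick -> seconds through the tempo map
  tm <- tempo_map[order(vapply(tempo_map, `[[`, 0L, "tick"))]
  tick2s <- function(tick) {
    s <- 0
    for (i in seq_along(tm)) {
      t0 <- tm[[i]]$tick
      t1 <- if (i < length(tm)) tm[[i + 1L]]$tick else Inf
      if (tick <= t0) break
      seg <- min(tick, t1) - t0
      s <- s + seg * tm[[i]]$us / 1e6 / division
    }
    s
  }
  ord <- order(vapply(events, `[[`, 0L, "tick"),
               vapply(events, function(e) e$type == "on", TRUE))
  events <- events[ord]
  onset <- c(); pitch <- c(); dur <- c(); vel <- c()
  open <- NULL # single open note (pitch, tick, vel)
  for (e in events) {
    if (e$type == "on") {
      if (!is.null(open)) {
        if (e$tick <= open$tick) {
          stop_monophony("simultaneous note onsets in MIDI file")
        }
        stop_monophony("overlapping notes in MIDI file (polyphony)")
      }
      open <- e
    } else {
      if (is.null(open) || open$pitch != e$pitch) next
      onset <- c(onset, tick2s(open$tick))
      pitch <- c(pitch, open$pitch)
      dur <- c(dur, max(tick2s(e$tick) - tick2s(open$tick), 1e-4))
      vel <- c(vel, open$vel)
      open <- NULL
    }
  }
  if (length(onset) < 2L) stop_degenerate("MIDI file holds fewer than 2 notes")
  t0 <- onset[1L]
  melody(onset - t0, pitch, dur, vel, id = id, condition = condition)
}
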