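# Stimulus generation: shuffled control melodies (the study's control
# condition) and synthetic corpora with tunable Markov structure used as the
# package's ground-truth fixtures.

#' Create a shuffled control melody
#'
#' Disrupts both musical dimensions of a structured melody while matching its
#' surface statistics: the pitch sequence is replaced by a seed-deterministic
#' permutation of the original pitches (identical multiset), and the IOIs are
#' redrawn i.i.d. from a Gaussian centered on the original mean IOI with
#' standard deviation `mean(IOI) - min(IOI)` (the `mean_minus_min` rule).
#' Draws below half a sixteenth duration are rejected and redrawn; accepted
#' draws are snapped to the sixteenth-note grid, preserving integer ratios.
#' Velocity is the constant 100.
#'
#' @param m a [melody()] with at least 3 notes (`condition = "real"` or
#'   `"synthetic"`).
#' @param seed integer.
#' @param sixteenth_duration grid unit in seconds; taken from the melody if
#'   it carries one, else derived from `tempo_bpm`, else 0.125 s.
#' @param ioi_sd_rule currently only `"mean_minus_min"`.
#' @return a [melody()] with `condition = "shuffled"`.
#' @export
shuffle_melody <- function(m, seed = 1L, sixteenth_duration = NULL,
                           ioi_sd_rule = "mean_minus_min") {
  if (n_notes(m) < 3L) stop_degenerate("need at least 3 notes to shuffle")
  sx <- sixteenth_duration %||% m$sixteenth_duration %||%
    (if (!is.null(m$tempo_bpm)) 60 / m$tempo_bpm / 4 else 0.125)
  if (sx <= 0) stop_config("sixteenth_duration must be positive")
  ioi_sd_rule <- match.arg(ioi_sd_rule, "mean_minus_min")
  ioi <- diff(m$notes$onset)
  mu <- mean(ioi)
  sd_ <- max(mu - min(ioi), sx / 4) # degenerate isochronous input still varies
  n <- n_notes(m)
  with_seed(seed, {
    pitches <- sample(m$notes$pitch)
    draw_ioi <- function() {
      repeat {
        x <- stats::rnorm(1L, mu, sd_)
        if (x >= sx / 2) return(x)
      }
    }
    new_ioi <- pmax(round(vapply(seq_len(n - 1L), function(i) draw_ioi(),
                                 0) / sx), 1) * sx
    onsets <- c(0, cumsum(new_ioi))
    dur <- pmin(m$notes$duration[order(stats::runif(n))],
                c(new_ioi, Inf)) # keep monophony: no note past the next onset
    dur <- pmax(dur, sx / 4)
    dur <- pmin(dur, c(new_ioi, max(ioi)))
    melody(onsets, pitches, dur, 100L,
      id = paste0(m$id, "_shuf"), condition = "shuffled",
      tempo_bpm = m$tempo_bpm, sixteenth_duration = sx
    )
  })
}

# 8-symbol IOI-ratio alphabet, closed under reciprocals so that a uniform
# draw has zero log-drift and boundary reflection stays inside the alphabet.
RATIO_ALPHABET <- c(1 / 2, 2 / 3, 3 / 4, 4 / 5, 5 / 4, 4 / 3, 3 / 2, 2)

# Row-stochastic transition matrix: a fixed single-cycle permutation backbone
# softened by temperature. temperature 0 -> deterministic cycle; large ->
# near-uniform rows.
markov_rows <- function(n_states, temperature) {
  perm <- sample(n_states) # one random single cycle via cycle notation
  nxt <- integer(n_states)
  for (i in seq_len(n_states)) {
    nxt[perm[i]] <- perm[if (i == n_states) 1L else i + 1L]
  }
  P <- matrix(0, n_states, n_states)
  if (temperature <= 0) {
    P[cbind(seq_len(n_states), nxt)] <- 1
  } else {
    base <- matrix(stats::rnorm(n_states^2), n_states)
    base[cbind(seq_len(n_states), nxt)] <- base[cbind(seq_len(n_states), nxt)] + 4
    for (i in seq_len(n_states)) {
      z <- base[i, ] / temperature
      P[i, ] <- exp(z - max(z)) / sum(exp(z - max(z)))
    }
  }
  P
}

#' Generate a synthetic melody corpus with controlled statistics
#'
#' Melodies are sampled from one fixed random Markov process (drawn once from
#' `seed`) over a 15-pitch alphabet and an 8-symbol IOI-ratio alphabet.
#' `temperature` scales the transition entropy: 0 gives deterministic
#' repeating patterns, large values approach independent uniform draws.
#' Realized IOIs follow the sampled ratios multiplicatively from a base IOI;
#' when a ratio would push the IOI outside `ioi_range`, its reciprocal (also
#' in the alphabet) is used instead, keeping the walk bounded.
#'
#' @param n_melodies number of melodies.
#' @param n_notes notes per melody.
#' @param pitch_order,rhythm_order Markov order of the generating chains
#'   (0 = i.i.d.; currently orders 0 and 1 are generated, higher orders fall
#'   back to 1 for the backbone while remaining learnable by higher-order
#'   models).
#' @param temperature non-negative number.
#' @param seed integer.
#' @param base_ioi initial IOI in seconds.
#' @param ioi_range numeric length-2; reflection bounds for realized IOIs.
#' @param id_prefix label prefix for melody ids.
#' @return list of [melody()] objects (`condition = "synthetic"`).
#' @export
generate_corpus <- function(n_melodies, n_notes = 60L, pitch_order = 1L,
                            rhythm_order = 1L, temperature = 1,
                            seed = 1L, base_ioi = 0.5,
                            ioi_range = c(0.125, 2),
                            id_prefix = "syn") {
  if (n_melodies < 1L) stop_config("n_melodies must be >= 1")
  if (pitch_order < 0L || rhythm_order < 0L) stop_config("orders must be >= 0")
  pitches <- 60:74
  with_seed(seed, {
    P_pitch <- markov_rows(length(pitches), temperature)
    P_ratio <- markov_rows(length(RATIO_ALPHABET), temperature)
    u_pitch <- rep(1 / length(pitches), length(pitches))
    u_ratio <- rep(1 / length(RATIO_ALPHABET), length(RATIO_ALPHABET))
    lapply(seq_len(n_melodies), function(mi) {
      p_state <- sample.int(length(pitches), 1L)
      r_state <- sample.int(length(RATIO_ALPHABET), 1L)
      pitch_seq <- integer(n_notes)
      ioi_seq <- numeric(n_notes - 1L)
      ioi <- base_ioi
      for (k in seq_len(n_notes)) {
        pr <- if (pitch_order == 0L) u_pitch else P_pitch[p_state, ]
        p_state <- sample.int(length(pitches), 1L, prob = pr)
        pitch_seq[k] <- pitches[p_state]
        if (k > 1L) {
          rr <- if (rhythm_order == 0L) u_ratio else P_ratio[r_state, ]
          r_state <- sample.int(length(RATIO_ALPHABET), 1L, prob = rr)
          ratio <- RATIO_ALPHABET[r_state]
          cand <- ioi * ratio
          if (cand < ioi_range[1] || cand > ioi_range[2]) {
            ratio <- 1 / ratio
            r_state <- match(ratio, RATIO_ALPHABET)
            cand <- ioi * ratio
          }
          ioi <- min(max(cand, ioi_range[1]), ioi_range[2])
          ioi_seq[k - 1L] <- ioi
        }
      }
      onsets <- c(0, cumsum(ioi_seq))
      dur <- pmax(c(ioi_seq * 0.9, 0.3), 0.05)
      melody(onsets, pitch_seq, dur, 100L,
        id = sprintf("%s%02d", id_prefix, mi), condition = "synthetic",
        sixteenth_duration = base_ioi / 4
      )
    })
  })
}

#' Build a matched structured + shuffled study corpus
#'
#' Generates `n_structured` low-temperature melodies and derives shuffled
#' counterparts (via [shuffle_melody()]) for `n_shuffled` of them, selected
#' either as the first `n_shuffled` or by timing-surprise extremes.
#'
#' @param n_structured,n_shuffled corpus composition.
#' @param temperature structure strength of the real melodies (default 0.35).
#' @param n_notes notes per melody.
#' @param seed integer.
#' @param select `"first"` or `"extremes"` (half highest + half lowest mean
#'   timing surprise, mirroring how the study chose melodies to shuffle).
#' @param folds resampling folds used when `select = "extremes"`.
#' @return list with `melodies` (structured, condition `"real"`) and
#'   `shuffled` (their controls).
#' @export
make_study_corpus <- function(n_structured = 10L, n_shuffled = 4L,
                              temperature = 0.35, n_notes = 60L,
                              seed = 1L, select = c("first", "extremes"),
                              folds = 5L) {
  select <- match.arg(select)
  real <- generate_corpus(n_structured, n_notes = n_notes,
                          temperature = temperature, seed = seed,
                          id_prefix = "real")
  for (i in seq_along(real)) real[[i]]$condition <- "real"
  pick <- if (select == "first" || n_shuffled >= n_structured) {
    seq_len(min(n_shuffled, n_structured))
  } else {
    info <- estimate_information(real, folds = min(folds, n_structured),
                                 seed = derive_seed(seed, "select"))
    st <- summarize_information(info)$St
    k_hi <- ceiling(n_shuffled / 2)
    k_lo <- n_shuffled - k_hi
    c(order(st, decreasing = TRUE)[seq_len(k_hi)],
      order(st)[seq_len(k_lo)])
  }
  shuffled <- lapply(seq_along(pick), function(j) {
    shuffle_melody(real[[pick[j]]], seed = derive_seed(seed, paste0("shuf", j)))
  })
  list(melodies = real, shuffled = shuffled, shuffled_from = pick)
}
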