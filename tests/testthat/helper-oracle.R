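# Independent brute-force oracle for the PPM smoothing recursion.
# Counts n-grams by explicitly scanning every training sequence (no shared
# code or data structures with the package implementation) and evaluates the
# escape-method-C interpolated recursion directly.

oracle_count <- function(train_seqs, context, symbol) {
  total <- 0L
  for (s in train_seqs) {
    L <- length(context)
    if (length(s) < L + 1L) next
    for (i in seq_len(length(s) - L)) {
      ctx_match <- L == 0L || identical(s[i:(i + L - 1L)], context)
      if (ctx_match && s[i + L] == symbol) total <- total + 1L
    }
  }
  total
}

oracle_predict <- function(train_seqs, context, alphabet, max_order) {
  rec <- function(ctx) {
    if (length(ctx) == 0L) {
      lower <- rep(1 / length(alphabet), length(alphabet))
    } else {
      lower <- rec(ctx[-1L])
    }
    counts <- vapply(alphabet, function(a) oracle_count(train_seqs, ctx, a), 0L)
    total <- sum(counts)
    if (total == 0L) return(lower)
    types <- sum(counts > 0L)
    counts / (total + types) + types / (total + types) * lower
  }
  ctx <- if (length(context) > max_order) {
    context[(length(context) - max_order + 1L):length(context)]
  } else {
    context
  }
  p <- rec(ctx)
  names(p) <- alphabet
  p / sum(p)
}

# all sequences of a given length over an alphabet
all_sequences <- function(alphabet, len) {
  if (len == 0L) return(list(character(0)))
  grid <- do.call(expand.grid, rep(list(alphabet), len))
  lapply(seq_len(nrow(grid)), function(i) as.character(unlist(grid[i, ])))
}

# smooth random subject-level ERP array (subjects x channels x timepoints):
# temporally lowpassed, spatially correlated Gaussian noise
random_erps <- function(n_sub, n_ch, n_t, sd = 1) {
  out <- array(0, c(n_sub, n_ch, n_t))
  mix <- diag(n_ch) + 0.5 * matrix(stats::rnorm(n_ch^2, 0, 0.1), n_ch)
  for (s in seq_len(n_sub)) {
    w <- matrix(stats::rnorm(n_ch * n_t), n_ch, n_t)
    w <- t(apply(w, 1L, function(x) stats::filter(x, rep(1 / 4, 4),
                                                  circular = TRUE)))
    out[s, , ] <- sd * (mix %*% w)
  }
  out
}

# quick melody constructor for tests
toy_melody <- function(onsets, pitches, id = "toy", condition = "real") {
  dur <- c(diff(onsets) * 0.9, 0.3)
  melody(onsets, pitches, dur, id = id, condition = condition)
}
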