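# Variable-order Markov sequence model with PPM smoothing (escape method C,
# interpolated blending, no update exclusion). This is the predictive engine
# behind the note-by-note surprise and entropy estimates.

KEY_SEP <- "\x1f"

# "k" prefix keeps the empty (order-0) context a legal environment name
ctx_key <- function(symbols) paste0("k", paste(symbols, collapse = KEY_SEP))

#' Create an empty PPM model
#'
#' @param alphabet character vector of admissible symbols (may be empty if
#'   training sequences are supplied later; the alphabet then grows to the
#'   union of observed symbols).
#' @param max_order maximum context length (>= 1). Default 10.
#' @param viewpoint label carried along for bookkeeping.
#' @return object of class `ppm_model`. Counts live in an environment, so the
#'   model updates in place via [ppm_update()].
#' @export
ppm_new <- function(alphabet = character(0), max_order = 10L,
                    viewpoint = "generic") {
  if (max_order < 1L) stop_config("max_order must be >= 1")
  structure(
    list(
      counts = new.env(parent = emptyenv(), hash = TRUE),
      alphabet = unique(as.character(alphabet)),
      max_order = as.integer(max_order),
      viewpoint = viewpoint,
      escape = "C-interpolated",
      n_symbols_seen = 0L
    ),
    class = "ppm_model"
  )
}

#' @export
print.ppm_model <- function(x, ...) {
  cat(sprintf(
    "<ppm_model viewpoint=%s> |alphabet|=%d, max_order=%d, %d symbols seen\n",
    x$viewpoint, length(x$alphabet), x$max_order, x$n_symbols_seen
  ))
  invisible(x)
}

# Register one observation: symbol following `history` (full preceding
# sequence; only the last max_order symbols form contexts).
ppm_observe <- function(model, history, symbol) {
  symbol <- as.character(symbol)
  if (!symbol %in% model$alphabet) {
    model$alphabet <- c(model$alphabet, symbol)
  }
  h <- length(history)
  for (o in 0:min(model$max_order, h)) {
    ctx <- if (o == 0L) character(0) else history[(h - o + 1L):h]
    key <- ctx_key(ctx)
    tab <- model$counts[[key]]
    if (is.null(tab)) tab <- integer(0)
    tab[symbol] <- (if (symbol %in% names(tab)) tab[[symbol]] else 0L) + 1L
    assign(key, tab, envir = model$counts)
  }
  model$n_symbols_seen <- model$n_symbols_seen + 1L
  model
}

#' Update a PPM model with a full sequence
#'
#' Feeds `symbols` one at a time, registering all n-grams up to `max_order`.
#' `NA` symbols (undefined viewpoint positions) break the context: they are
#' skipped and the history restarts after them.
#'
#' @param model a `ppm_model` from [ppm_new()].
#' @param symbols character vector.
#' @return the updated model (also updated in place).
#' @export
ppm_update <- function(model, symbols) {
  symbols <- as.character(symbols)
  run <- character(0)
  for (s in symbols) {
    if (is.na(s)) { run <- character(0); next }
    model <- ppm_observe(model, run, s)
    run <- c(run, s)
  }
  model
}

#' Fit a PPM model to a set of viewpoint sequences
#'
#' Counts equal exhaustive n-gram tallies of the training sequences at all
#' orders `0..max_order`; the alphabet is the union of observed symbols plus
#' any declared seed alphabet.
#'
#' @param sequences list of character vectors (one per melody).
#' @param max_order maximum context length; default 10.
#' @param alphabet optional seed alphabet (used e.g. to fix the symbol set
#'   across cross-validation folds).
#' @param viewpoint label.
#' @return a `ppm_model`.
#' @export
ppm_fit <- function(sequences, max_order = 10L, alphabet = character(0),
                    viewpoint = "generic") {
  model <- ppm_new(alphabet, max_order, viewpoint)
  for (s in sequences) model <- ppm_update(model, s)
  if (length(model$alphabet) == 0L) {
    stop_empty_model("no training symbols and no declared alphabet")
  }
  model
}

#' Predictive distribution of a PPM model
#'
#' Blends maximum-likelihood estimates from the longest matching context down
#' to the order -1 uniform via PPM escape method C with interpolated
#' smoothing: at each order, `p(s|c) = n(c,s)/(T+t) + t/(T+t) * p(s|c')`
#' where `T` is the total count in context `c`, `t` the number of distinct
#' continuations, and `c'` the context shortened by one symbol. Contexts with
#' no observations delegate entirely to the shorter context. The result is a
#' proper distribution over the alphabet (strictly positive, sums to 1).
#'
#' @param model a `ppm_model` with non-empty alphabet.
#' @param context character vector of preceding symbols (possibly empty;
#'   symbols outside the alphabet are allowed and simply never match).
#' @return named numeric vector of probabilities over `model$alphabet`.
#' @export
ppm_predict <- function(model, context = character(0)) {
  a <- model$alphabet
  if (length(a) == 0L) stop_empty_model("model has an empty alphabet")
  context <- as.character(context)
  # drop context back to the last run of defined symbols
  if (anyNA(context)) {
    last_na <- max(which(is.na(context)))
    context <- if (last_na == length(context)) character(0) else
      context[(last_na + 1L):length(context)]
  }
  h <- length(context)
  o <- min(model$max_order, h)
  p <- rep(1 / length(a), length(a))
  names(p) <- a
  orders <- 0:o
  for (oo in orders) { # from short to long so interpolation nests correctly
    ctx <- if (oo == 0L) character(0) else context[(h - oo + 1L):h]
    tab <- model$counts[[ctx_key(ctx)]]
    if (is.null(tab) || length(tab) == 0L) next
    total <- sum(tab)
    types <- length(tab)
    ml <- numeric(length(a))
    names(ml) <- a
    seen <- intersect(names(tab), a)
    ml[seen] <- tab[seen]
    p <- ml / (total + types) + (types / (total + types)) * p
  }
  p / sum(p)
}

#' Combine short-term and long-term predictive distributions
#'
#' Entropy-weighted geometric mixture: each model receives weight
#' `w ~ (H(p)/log2 |A|)^(-bias)` (relative certainty), weights are normalized
#' to sum to 1, and the combined distribution is
#' `p ~ p_stm^w_stm * p_ltm^w_ltm`, renormalized.
#'
#' @param p_stm,p_ltm named probability vectors over the same alphabet.
#' @param bias entropy-weighting exponent `b` (default 2); larger values
#'   trust the more certain model more strongly.
#' @return combined named probability vector.
#' @export
combine_stm_ltm <- function(p_stm, p_ltm, bias = 2) {
  if (length(p_stm) != length(p_ltm) ||
      !identical(sort(names(p_stm)), sort(names(p_ltm)))) {
    stop_alphabet("STM and LTM distributions are over different alphabets")
  }
  p_ltm <- p_ltm[names(p_stm)]
  n <- length(p_stm)
  if (n == 1L) return(stats::setNames(1, names(p_stm)))
  hmax <- log2(n)
  rel <- function(p) max(entropy_bits(p) / hmax, 1e-9)
  w <- c(rel(p_stm)^(-bias), rel(p_ltm)^(-bias))
  w <- w / sum(w)
  lp <- w[1] * log(p_stm) + w[2] * log(p_ltm)
  p <- exp(lp - max(lp))
  p / sum(p)
}
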