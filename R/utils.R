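`%||%` <- function(x, y) if (is.null(x)) y else x

#' Convert milliseconds to a sample count
#'
#' Uses round-half-to-even (base R [round()]), the convention applied
#' throughout the package whenever a duration in milliseconds is mapped onto a
#' discrete sample grid. Needed because several design durations (e.g. 520 ms
#' at 1024 Hz) are not integer numbers of samples.
#'
#' @param ms duration(s) in milliseconds.
#' @param rate sampling rate in Hz.
#' @return integer sample count(s).
#' @export
ms_to_samples <- function(ms, rate) {
  as.integer(round(ms * rate / 1000))
}

# Deterministic per-participant / per-stream substream seed. Keeps every
# derived seed inside 32-bit integer range and makes adding participants not
# perturb existing ones.
participant_seed <- function(seed, participant_index, stream = 0L) {
  s <- (as.double(seed) %% 2147483647) +
    104729 * as.double(participant_index) +
    499979 * as.double(stream)
  as.integer(s %% 2147483646) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stopf("`%s` must be a finite number in [%s, %s]", name,
          format(lower), format(upper))
  }
  invisible(x)
}
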