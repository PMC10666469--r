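# Shared constants and small helpers.

# Canonical tone order; fixed so that error tables and reports are stable.
TONE_LEVELS <- c("rise", "fall", "mid", "low")
GROUP_LEVELS <- c("target", "english", "mandarin")
EXCLUSION_REASONS <- c("recording_error", "non_response",
                       "uncategorizable_tone", "bad_quality")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., class = NULL) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "tonetrace_error"),
                      call = sys.call(-1)))
}

warnf <- function(fmt, ..., class = NULL) {
  warning(warningCondition(sprintf(fmt, ...),
                           class = c(class, "tonetrace_warning"),
                           call = sys.call(-1)))
}

assert_tones <- function(x, allow = TONE_LEVELS, what = "tone") {
  bad <- setdiff(unique(as.character(x)), allow)
  if (length(bad))
    stopf("unknown %s symbol(s): %s (expected %s)", what,
          paste(bad, collapse = ", "), paste(allow, collapse = ", "),
          class = "tonetrace_validation_error")
  invisible(x)
}

sample_cols <- function(n, prefix = "f") sprintf("%s%02d", prefix, seq_len(n))

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is restored afterwards. Used everywhere a `seed`
# argument is offered so that simulations are reproducible without
# clobbering the session RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stage substream seed derived from a master seed.
# Kept below 2^31 - 1 so it is always a valid R integer.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h) %% .Machine$integer.max)
}

trial_key <- function(speaker, day, item, rep = NULL) {
  if (is.null(rep)) paste(speaker, day, item, sep = "|")
  else paste(speaker, day, item, paste0("r", rep), sep = "|")
}
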