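# Internal helpers: seed substreams, logging, validation.

# Derive a reproducible child seed from a master seed and a stream label.
# Keeps independent layers of the generator (counts, labels, noise, images)
# reproducible in isolation under one user-facing seed. Plain 32-bit
# arithmetic; no external hashing dependency.
substream_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower && x < upper else x >= lower && x <= upper)
  if (!ok)
    stop(sprintf("`%s` must be a finite scalar in %s%s, %s%s", name,
                 if (strict) "(" else "[", format(lower),
                 format(upper), if (strict) ")" else "]"),
         call. = FALSE)
  invisible(x)
}

# Structured drop log: every neuron excluded anywhere in the pipeline is
# recorded with a reason code so reports can account for all inputs.
drop_log <- function() {
  data.frame(neuron_id = character(), case_id = character(),
             reason = character(), stringsAsFactors = FALSE)
}

log_drop <- function(log, neuron_id, case_id, reason) {
  rbind(log, data.frame(neuron_id = as.character(neuron_id),
                        case_id = as.character(case_id),
                        reason = reason, stringsAsFactors = FALSE))
}

config_error <- function(msg) {
  stop(errorCondition(msg, class = c("oxphos_config_error", "error")))
}

data_error <- function(msg) {
  stop(errorCondition(msg, class = c("oxphos_data_error", "error")))
}
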