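# Internal helpers: seed derivation, validation, numeric formatting.

# Derive a child seed deterministically from a parent seed and an integer
# key path, staying inside the 32-bit signed range. Used so that every
# stochastic phase (covariates, alter counts, scale items, each simulation
# replicate, ...) consumes its own stream and nothing depends on global
# RNG state.
child_seed <- function(seed, ...) {
  key <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (k in key) {
    s <- (s * 69069 + 12345 + as.double(k)) %% 2147483647
  }
  as.integer(s)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_config(field, "must be a probability in [0, 1]")
  }
  invisible(x)
}

# format doubles so that read.csv(as.numeric(...)) round-trips exactly
format_double <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

is_binary_col <- function(x) all(x %in% c(0, 1))

coerce_binary <- function(y) {
  if (is.logical(y)) return(as.integer(y))
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) y <- suppressWarnings(as.numeric(y))
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("validation error: labels must be binary 0/1", call. = FALSE)
  }
  as.integer(y)
}

# stable descending order (ties keep original position)
order_desc <- function(scores) order(-scores, seq_along(scores))
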