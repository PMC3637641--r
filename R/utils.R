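# Internal helpers shared across modules.

# Normalize gene symbols for comparison: upper case, trimmed whitespace.
# No alias or ortholog resolution is attempted.
normalize_symbols <- function(x) {
  toupper(stringr::str_trim(as.character(x)))
}

# Half-up rounding to `digits` decimals, for display of percentages.
# base round() rounds half to even, which disagrees with how percentage
# tables are conventionally printed (e.g. 13.675 -> 13.7, not 13.68->13.7...).
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x < min || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d, got %s",
                  name, min, paste(x, collapse = ", ")))
  }
  as.integer(x)
}

check_prob <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1]", name))
  }
  as.numeric(x)
}

check_positive <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number", name))
  }
  as.numeric(x)
}

match_direction <- function(direction) {
  d <- tolower(as.character(direction))
  if (!d %in% c("up", "down")) {
    abort("`direction` must be \"up\" or \"down\"")
  }
  d
}

opposite_direction <- function(direction) {
  if (direction == "up") "down" else "up"
}
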