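# Internal helpers shared across the package.

#' @importFrom rlang abort warn inform %||%
#' @importFrom dplyr mutate filter arrange select bind_rows group_by summarise
#'   ungroup n lag lead across all_of first last
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_int map_lgl map2 pmap imap list_rbind
NULL

# Derive a per-stage seed from a global seed; keeps the result in 32-bit
# integer range so set.seed() accepts it.
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer((abs(seed) * 7919 + offset * 104729) %% .Machine$integer.max)
}

with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                 strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_min && x <= min) {
    abort(sprintf("`%s` must be > %s (got %s).", name, min, x))
  }
  if (!strict_min && x < min) {
    abort(sprintf("`%s` must be >= %s (got %s).", name, min, x))
  }
  if (x > max) {
    abort(sprintf("`%s` must be <= %s (got %s).", name, max, x))
  }
  invisible(x)
}

# Centered moving average with edge replication, so the smoothed series has
# the same length as the input and no NA at the boundaries.
moving_average <- function(x, width) {
  width <- as.integer(width)
  if (width <= 1L) return(x)
  half <- (width - 1L) %/% 2L
  padded <- c(rep(x[1], half), x, rep(x[length(x)], width - 1L - half))
  as.numeric(stats::filter(padded, rep(1 / width, width), sides = 1))[
    seq.int(width, length(padded))
  ]
}

# Linear-interpolated time at which `x` (sampled at `t`) first crosses `level`
# in the given direction, scanning indices idx (must be contiguous ascending).
first_crossing_time <- function(t, x, level, direction = c("down", "up")) {
  direction <- match.arg(direction)
  if (direction == "down") {
    hit <- which(x <= level)
  } else {
    hit <- which(x >= level)
  }
  if (length(hit) == 0 || hit[1] == 1) {
    return(if (length(hit)) t[hit[1]] else NA_real_)
  }
  i <- hit[1]
  x0 <- x[i - 1]; x1 <- x[i]
  if (x1 == x0) return(t[i])
  frac <- (level - x0) / (x1 - x0)
  t[i - 1] + frac * (t[i] - t[i - 1])
}
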