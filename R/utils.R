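# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# Leaves the caller's RNG untouched; seed = NULL runs code as-is.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.", class = "physioload_invalid_parameter")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

stop_invalid <- function(msg) {
  abort(msg, class = "physioload_invalid_parameter")
}

# Centered moving average with reflect padding; output length equals input.
moving_average_reflect <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L || length(x) < 2L) {
    return(x)
  }
  if (width >= length(x)) {
    width <- length(x) - 1L + (length(x) %% 2L)
  }
  n <- length(x)
  half <- width %/% 2L
  pad_left <- rev(x[seq_len(half) + 1L])
  pad_right <- rev(x[n - seq_len(half)])
  padded <- c(pad_left, x, pad_right)
  # O(n) centered rolling mean via cumulative sums
  cs <- c(0, cumsum(padded))
  s <- seq_len(n) + (1L - width %% 2L) # window start in padded coordinates
  (cs[s + width] - cs[s]) / width
}

# Trapezoidal integral of y over x.
trapz_ <- function(x, y) {
  n <- length(x)
  if (n < 2L) {
    return(0)
  }
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# Pull a numeric sample vector out of either a signal tibble or a bare vector.
signal_values <- function(signal, column = "value") {
  if (is.data.frame(signal)) {
    if (!column %in% names(signal)) {
      stop_invalid(sprintf("signal data frame has no `%s` column.", column))
    }
    return(signal[[column]])
  }
  as.numeric(signal)
}

# Strict local maxima (ties broken toward the earlier sample).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) {
    return(integer(0))
  }
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

local_minima <- function(x) {
  local_maxima(-x)
}

meta_columns <- function() {
  c("subject_id", "label", "modality", "window_id", "start", "end")
}

feature_columns <- function(df) {
  setdiff(names(df), meta_columns())
}

# Zero-phase filtering with reflected-edge padding to suppress the
# start/end transients of plain filtfilt.
filtfilt_reflect <- function(filt, x, pad = min(length(x) - 1L, 2000L)) {
  if (pad < 1L) {
    return(as.numeric(signal::filtfilt(filt, x)))
  }
  left <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[length(x)] - x[seq(length(x) - 1L, length(x) - pad)]
  y <- as.numeric(signal::filtfilt(filt, c(left, x, right)))
  y[(pad + 1L):(pad + length(x))]
}
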