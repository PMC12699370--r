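# Internal helpers shared across modules.

# Error conditions carry a class so the CLI can map them to exit codes:
# config errors -> 2, data errors -> 1.
stop_config <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("curvassay_config_error", "error", "condition"),
                      call = call))
}

stop_data <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("curvassay_data_error", "error", "condition"),
                      call = call))
}

# Periodic (circular) centered moving average; k must be a positive odd integer.
moving_average_periodic <- function(v, k) {
  k <- as.integer(k)
  if (k <= 1L) return(v)
  if (k %% 2L == 0L) k <- k + 1L
  if (k >= length(v)) stop_config("smoothing window covers the whole profile")
  as.numeric(stats::filter(v, rep(1 / k, k), method = "convolution",
                           sides = 2, circular = TRUE))
}

# Window in physical units -> odd sample count, given sample spacing.
window_samples <- function(window_um, spacing_um) {
  k <- max(1L, as.integer(round(window_um / spacing_um)))
  if (k %% 2L == 0L) k <- k + 1L
  k
}

# Signed shoelace area of a closed polygon (positive <=> counterclockwise in
# the stored coordinate system).
shoelace_area <- function(x, y) {
  xl <- c(x[-1], x[1])
  yl <- c(y[-1], y[1])
  0.5 * sum(x * yl - xl * y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
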