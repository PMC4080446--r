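# Internal helpers shared across modules.

#' @importFrom withr with_seed
NULL

# Run `expr` under a fixed seed without touching the caller's RNG stream.
local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Stage-tagged progress/log line. All filters report dropped-record counts
# through this so pipeline logs are greppable by stage.
log_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

# Canonical unordered edge key, used wherever edges live in plain tables.
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
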