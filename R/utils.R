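# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Boltzmann constant in kcal/(mol K)
#' @keywords internal
.kB <- 0.0019872041

# Deterministic per-operation seed derived from (global seed, operation name),
# so pipeline stages draw from independent, individually reproducible streams.
# Kept below 2^31 - 1 (R integers are 32-bit).
op_seed <- function(seed, op) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- 0
  for (ch in utf8ToInt(op)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) * 2654435761 + h) %% 2147483647)
}

# Evaluate expr with a private RNG stream; the caller's RNG state is untouched.
with_op_seed <- function(seed, op, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(op_seed(seed, op))
  expr
}

stop_allonet <- function(msg, class) {
  stop(structure(class = c(class, "allonet_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Format numbers so that read-back with as.numeric() reproduces the value
# bit-exactly; non-finite values become the sentinel tokens inf/-inf/nan.
format_value <- function(x) {
  out <- character(length(x))
  fin <- is.finite(x)
  out[fin] <- sprintf("%.17g", x[fin])
  out[is.nan(x)] <- "nan"
  out[!fin & !is.nan(x) & x > 0] <- "inf"
  out[!fin & !is.nan(x) & x < 0] <- "-inf"
  out
}

parse_value <- function(s) {
  out <- suppressWarnings(as.numeric(s))
  out[s == "inf"] <- Inf
  out[s == "-inf"] <- -Inf
  out[s == "nan"] <- NaN
  out
}
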