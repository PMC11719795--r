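#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish malformed files (format),
# files that parse but violate a domain invariant (integrity), degenerate
# numerical inputs, and plain usage errors.
psm_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "psm_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1))
  ))
}

stop_format    <- function(msg) psm_stop(msg, "psm_format_error")
stop_io        <- function(msg) psm_stop(msg, "psm_io_error")
stop_integrity <- function(msg) psm_stop(msg, "psm_integrity_error")
stop_degenerate <- function(msg) psm_stop(msg, "psm_degenerate_error")
stop_usage     <- function(msg) psm_stop(msg, "psm_usage_error")

# Run `expr` under a fixed RNG seed without clobbering the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}
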