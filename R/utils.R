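#' @keywords internal
"_PACKAGE"

# Lightweight logging: messages are emitted via message() and can be silenced
# with suppressMessages(); level gate via option(foamfem.log_level).
.log_levels <- c(debug = 10L, info = 20L, warn = 30L, error = 40L)

ff_log <- function(level, ...) {
  threshold <- getOption("foamfem.log_level", "info")
  if (.log_levels[[level]] >= .log_levels[[threshold]]) {
    message(sprintf("[foamfem %s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

# Stop with a classed condition so callers can catch specific failures.
ff_stop <- function(class, fmt, ..., data = list()) {
  cond <- structure(
    class = c(class, "foamfem_error", "error", "condition"),
    c(list(message = sprintf(fmt, ...), call = sys.call(-1)), data)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is_scalar_num(x)) {
    ff_stop("foamfem_invalid_argument", "'%s' must be a finite numeric scalar", name)
  }
  if (positive && x <= 0) {
    ff_stop("foamfem_invalid_argument", "'%s' must be > 0 (got %g)", name, x)
  }
  invisible(x)
}
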