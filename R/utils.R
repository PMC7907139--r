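# Internal helpers shared across modules.

# Classed error constructor so callers can condition on failure mode.
stop_ss <- function(subclass, msg, ...) {
  stop(structure(
    class = c(subclass, "scopesight_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

warn_ss <- function(subclass, msg, ...) {
  warning(structure(
    class = c(subclass, "scopesight_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop_ss("degenerate_geometry_error", "cannot normalize a zero vector")
  v / n
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic operations in the package route through this.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic sub-seed for (stream index i, item index j); stays < 2^31
# and within exact double arithmetic.
derive_seed <- function(seed, i, j = 0L) {
  s <- as.numeric(seed) %% 1e6
  as.integer(((s * 10007 + as.numeric(i) * 131071 + as.numeric(j) * 8191) %% 2147483629) + 1)
}

# Round doubles through IEEE float32, the precision STL stores.
float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
          what = "numeric", size = 4L, n = length(x), endian = "little")
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
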