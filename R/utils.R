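# Internal helpers shared across modules.

.bimeta_env <- new.env(parent = emptyenv())

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run fn() under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
.with_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  fn()
}

# Derive a stream of per-dataset seeds from a master seed, all < 2^31.
.derive_seeds <- function(seed, n) {
  .with_seed(seed, function() sample.int(.Machine$integer.max - 1L, n))
}

.is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x > 0) && all(x < 1)

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Scale descriptors: "continuous" or "discrete:<n>".
.parse_scale <- function(scale) {
  if (is.list(scale)) return(scale)
  if (!is.character(scale) || length(scale) != 1L)
    .stopf("invalid scale specification")
  if (identical(scale, "continuous")) return(list(type = "continuous", n = NA_integer_))
  m <- regmatches(scale, regexec("^discrete:([0-9]+)$", scale))[[1]]
  if (length(m) == 2L) {
    n <- as.integer(m[2])
    if (n < 2L) .stopf("discrete scale needs at least 2 points, got %d", n)
    return(list(type = "discrete", n = n))
  }
  .stopf("invalid scale specification '%s' (use 'continuous' or 'discrete:<n>')", scale)
}

.scale_string <- function(scale) {
  s <- .parse_scale(scale)
  if (s$type == "continuous") "continuous" else sprintf("discrete:%d", s$n)
}

# Pearson/Spearman correlation that tolerates degenerate input.
.safe_cor <- function(x, y, method = "pearson") {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok], method = method)
}
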