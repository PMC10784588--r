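# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

# Scalar checks used by readers and constructors; all fail loudly with a
# message naming the offending argument.
check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min)
    stop_fmt("'%s' must be a single integer >= %d (got %s)", name, min,
             paste(format(x), collapse = ","))
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x))
    stop_fmt("'%s' must be a single finite number", name)
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  if (!lo_ok || !hi_ok)
    stop_fmt("'%s' = %s is outside its allowed range", name, format(x))
  as.numeric(x)
}

check_flag <- function(x, name) {
  if (length(x) != 1L || is.na(x) || !is.logical(x))
    stop_fmt("'%s' must be TRUE or FALSE", name)
  x
}

# Seed handling: functions that consume randomness take an integer `seed`.
# A NULL seed leaves the global RNG stream untouched; otherwise the stream is
# seeded locally and restored on exit, so seeded calls do not perturb the
# caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive per-component substreams from one master seed so that modules can be
# regenerated independently. Kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) + 1009 * as.double(offset)) %% 2147483647)
}
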