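# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so package functions never perturb the global stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# One global seed is expanded into independent per-module substreams so
# that adding a module never perturbs another module's draws. Offsets are
# fixed per module name; the multiplier is Knuth's 2^32 golden-ratio
# constant reduced into the 32-bit signed range R requires of set.seed().
substream_seed <- function(seed, module) {
  offsets <- c(cohort = 101L, rollout = 211L, training = 307L, property = 401L)
  if (!module %in% names(offsets)) {
    stop("unknown RNG substream module: ", module)
  }
  as.integer((as.numeric(seed) %% 2147483647 * 2654435761 +
                offsets[[module]]) %% 2147483647)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Numeric scalars carry constraint flags (clipped at zero, negative
# effective price, ...) as attributes rather than by raising conditions,
# so callers can audit without intercepting warnings.
flagged <- function(x, ...) {
  flags <- list(...)
  for (nm in names(flags)) attr(x, nm) <- flags[[nm]]
  x
}

is_flagged <- function(x, flag) isTRUE(attr(x, flag))

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  }
  if (strict_upper && x >= upper) {
    stop(sprintf("'%s' must be < %g", name, upper), call. = FALSE)
  }
  if (!strict_upper && x > upper) {
    stop(sprintf("'%s' must be <= %g", name, upper), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
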