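# Internal helpers: scoped RNG and argument checks.

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Counter-based replicate seed: replicate r of a run seeded with `seed` gets
# the same stream regardless of how many replicates are drawn in total.
derive_seed <- function(seed, counter) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(counter) * 16807
  as.integer(s %% 2147483647)
}

stopifnot_scalar <- function(x, name, min = -Inf, max = Inf,
                             integer = FALSE, allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (allow_inf || is.finite(x)) && x >= min && x <= max &&
    (!integer || !is.finite(x) || x == round(x))
  if (!ok) {
    stop(sprintf("`%s` must be a %s in [%s, %s], got %s", name,
                 if (integer) "whole number" else "number",
                 format(min), format(max),
                 paste(format(x), collapse = ",")), call. = FALSE)
  }
  invisible(x)
}

is_binary_matrix <- function(m) {
  is.matrix(m) && (is.logical(m) || all(m %in% c(0, 1)))
}

as_mask <- function(m, name = "mask") {
  if (!is.matrix(m)) stop(sprintf("`%s` must be a matrix", name), call. = FALSE)
  storage.mode(m) <- "logical"
  if (anyNA(m)) stop(sprintf("`%s` contains NA", name), call. = FALSE)
  m
}
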