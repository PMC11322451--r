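#' @keywords internal
"_PACKAGE"

# Deterministic 31-bit sub-seed from a master seed and a unit identifier.
# Keeps every derived seed strictly below 2^31 so set.seed() is safe.
derive_seed <- function(master, unit) {
  stopifnot(is.numeric(master), length(master) == 1L)
  m <- 2147483647
  h <- as.numeric(master) %% m
  bytes <- utf8ToInt(paste(as.character(unit), collapse = "|"))
  for (b in bytes) h <- (h * 33 + b) %% m
  as.integer(h)
}

# Evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Round half away from zero (Table-1 style reporting), base round() banks.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dim <- function(msg) stop(msg, call. = FALSE)
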