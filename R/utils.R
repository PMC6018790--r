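# Internal helpers shared across modules.

# Round half away from zero, as clinical tables print percentages.
round_half_out <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library calls never clobber user randomness.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic fan-out of a master seed to per-stage sub-seeds.
# Kept below 2^31 - 1 so the result is always a valid integer seed.
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  offsets <- c(simulate = 1, select = 2, split = 3, hidden = 4,
               ga = 5, bp = 6, evaluate = 7)
  if (is.character(stage)) {
    if (!stage %in% names(offsets)) stop("unknown pipeline stage: ", stage)
    stage <- offsets[[stage]]
  }
  as.integer((abs(master) * 7919 + stage) %% 2147483647L)
}

# FNV-1a hash of a string, hex-encoded; used to fingerprint configs in
# provenance manifests without extra dependencies.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}
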