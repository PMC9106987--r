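#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a base seed and a label, staying within 32-bit ints.
derive_seed <- function(seed, label) {
  h <- fnv1a32(paste0(seed, "/", label))
  as.integer(h %% 2147483647L)
}

# 32-bit FNV-1a hash of a string, returned as a double in [0, 2^32).
# The xor with a byte only touches the low 8 bits, so it can be done on the
# low byte alone while the multiply runs in double precision mod 2^32.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(as.character(x)))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # multiply mod 2^32 in two 16-bit halves to stay inside exact doubles
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

# Stable short hash of an R object (used for provenance stamps).
config_hash <- function(x) {
  s <- paste(deparse(x, control = "exact"), collapse = "")
  h <- fnv1a32(s)
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

stop_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("careops_input_error", "error")))
}

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("careops_config_error", "error")))
}

stop_infeasible <- function(msg, detail = NULL) {
  stop(errorCondition(msg, detail = detail,
                      class = c("careops_infeasible", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
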