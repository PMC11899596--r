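# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Sets the random seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so that seeded package functions never perturb the
#' user's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  code
}

# FNV-1a 32-bit hash of a character scalar, returned as 8 hex digits.
# Used only to stamp configuration/parcellation fingerprints into outputs.
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 2166136261
  for (b in bytes) {
    low8 <- h %% 256
    h <- h - low8 + bitwXor(as.integer(low8), b)
    # 32-bit multiply by the FNV prime 16777619, done in two 16-bit halves
    lo <- h %% 2^16
    hi <- h %/% 2^16
    h <- ((lo * 16777619) %% 2^32 + ((hi * 16777619) %% 2^16) * 2^16) %% 2^32
  }
  # h is a double holding a 32-bit value; format as two 16-bit hex halves
  sprintf("%04x%04x", as.integer(h %/% 2^16), as.integer(h %% 2^16))
}

stop_cerebcpm <- function(msg, class) {
  stop(structure(class = c(class, "cerebcpm_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_finite_num <- function(x) is.numeric(x) && all(is.finite(x))
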