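#' @keywords internal
"_PACKAGE"

# ---- seed splitting -------------------------------------------------------

#' Derive a stage-specific child seed from a master seed
#'
#' All stochastic stages draw their randomness from a single master seed via
#' this splitting scheme, so any stage can be regenerated independently of the
#' others. The child seed is a 32-bit FNV-1a hash of `"<master>/<stage>"`,
#' folded into `[0, 2^31 - 1]`.
#'
#' @param master integer master seed.
#' @param stage character stage label, e.g. `"cohort"`, `"expression"`.
#' @return a non-negative integer seed below 2^31.
#' @export
#' @examples
#' child_seed(1L, "cohort")
child_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  s <- paste0(format(master, scientific = FALSE), "/", stage)
  as.integer(fnv1a32(s) %% 2147483647)
}

# 32-bit FNV-1a in double precision, with 16-bit limbs so the xor and the
# prime multiply never exceed 2^53
fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    lo <- bitwXor(h %% 65536, b %% 65536)
    hi <- bitwXor(h %/% 65536, b %/% 65536)
    # (hi*2^16 + lo) * 16777619 mod 2^32
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

# run `code` under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# ---- small numeric helpers ------------------------------------------------

# column sds without building a centered copy
col_sds <- function(x) {
  n <- nrow(x)
  cm <- colMeans(x)
  v <- (colSums(x * x) - n * cm^2) / (n - 1)
  sqrt(pmax(v, 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# FNV-1a hash of a character scalar, hex string (used for run manifests)
fnv1a_hex <- function(s) {
  h <- fnv1a32(s)
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

stop_mstx <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_mstx <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
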