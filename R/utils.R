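#' @useDynLib ictair, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream. All package randomness flows through this helper so that results
# are a pure function of the user-supplied seed.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

# Deterministic 31-bit sub-seed from a master seed and a string key
# (regulator name, iteration label, ...). FNV-1a over the key bytes, folded
# with the seed; platform-independent integer arithmetic via %% on doubles.
derive_seed <- function(seed, key) {
  h <- 2166136261
  for (b in utf8ToInt(paste0(key, ":", as.integer(seed)))) {
    h <- ((bitwXor(as.integer(h %% 2^31), as.integer(b))) * 16777619) %% 2^31
  }
  as.integer(h %% (2^31 - 1))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ictair <- function(...) {
  stop(paste0(...), call. = FALSE)
}
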