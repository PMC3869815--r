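`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Deterministic rounding used for sparsity -> edge-count conversion, so that
#' edge counts are bit-exact across platforms (base `round()` rounds half to
#' even).
#'
#' @param x numeric vector.
#' @return integer vector, halves rounded away from zero.
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, 2.4))
#' @export
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Derive a stream seed from a master seed
#'
#' Linear-congruential mixing of a master seed and a stream index; every
#' random stage of the pipeline draws its seed through this so a single
#' master seed reproduces the whole analysis. Results stay below 2^31.
#'
#' @param master integer master seed.
#' @param stream integer stream index (>= 0).
#' @return a single integer seed.
#' @export
derive_seed <- function(master, stream) {
  m <- 2147483647
  s <- (abs(as.numeric(master)) %% m)
  as.integer((s * 48271 + as.numeric(stream) * 8951 + 1) %% m)
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

stop_covnet <- function(...) stop(..., call. = FALSE)
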