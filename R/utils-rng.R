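# Deterministic substreams
#
# Reproducibility is organised as one user-facing integer seed expanded into
# named substreams (covariates / structure / per-patient / per-channel /
# per-outcome) via a polynomial rolling hash, so that e.g. adding a pressure
# channel does not perturb the covariate draws.

#' Derive a deterministic 31-bit seed from a base seed and a key path
#'
#' Polynomial rolling hash (base 31, modulus the prime 2147483629) over the
#' string representation of the arguments. Used to give every simulation
#' stage, patient and channel its own reproducible random substream.
#'
#' @param ... scalars (coerced to character) identifying the substream.
#' @return A non-negative integer usable with [set.seed()].
#' @export
#' @examples
#' hash_seed(1, "patient", 12)
hash_seed <- function(...) {
  parts <- vapply(list(...), function(x) paste0(as.character(x), collapse = ","),
                  character(1))
  s <- paste(parts, collapse = "/")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483629
  as.integer(h)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' package internals never disturb the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  code
}

# content hash of a text file (same rolling hash, applied line-wise);
# used for the run manifest.
file_content_hash <- function(path) {
  lines <- readLines(path, warn = FALSE)
  h <- 0
  for (ln in lines) {
    for (b in utf8ToInt(ln)) h <- (h * 31 + b) %% 2147483629
    h <- (h * 31 + 10) %% 2147483629
  }
  sprintf("%010d", h)
}
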