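# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb user RNG.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Diagnostic class labels
#'
#' The three diagnostic classes a recording can carry: `no_murmur`,
#' `stills` (Still's murmur) and `other` (murmurs other than Still's,
#' predominantly pathological).
#' @keywords internal
.pcg_labels <- c("no_murmur", "stills", "other")

#' Chest locations
#' @keywords internal
.pcg_locations <- c("RUSB", "LUSB", "LLSB", "apex")

.murmur_classes <- c("none", "stills", "holosystolic", "ejection",
                     "continuous", "diastolic")
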