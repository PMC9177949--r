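## Internal helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition so callers/tests can match on error type.
#' @noRd
pn_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "presbynet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Round half away from zero (base round() is banker's rounding).
#' @noRd
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Run code with a private, seeded RNG stream; restores global RNG state.
#' @noRd
with_seed <- function(seed, code) {
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
  force(code)
}

#' Deterministic fan-out of one master seed into n substream seeds < 2^31.
#' @noRd
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x) && x >= 0
}

#' @noRd
stopifnot_scalar_prob <- function(x, name, open0 = TRUE, closed1 = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open0) x > 0 else x >= 0) && (if (closed1) x <= 1 else x < 1)
  if (!ok) pn_stop(sprintf("`%s` must be a single value in %s0, 1%s",
                           name, if (open0) "(" else "[",
                           if (closed1) "]" else ")"),
                   "presbynet_config_error")
  invisible(x)
}
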