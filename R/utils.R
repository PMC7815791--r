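#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_bad(what, " must be a probability in [0, 1]")
  }
  invisible(x)
}

#' Derive a purpose-keyed random seed
#'
#' Hashes a purpose label into the master seed so that every source of
#' randomness (other-cause death, onset, attendance, PSA, ...) gets its own
#' reproducible stream. The same `(master_seed, purpose)` pair always yields
#' the same stream, independent of how many other purposes are drawn -- this
#' is what keeps draws aligned across counterfactual arms.
#'
#' @param master_seed Integer master seed.
#' @param purpose Character label of the stream.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
seed_for <- function(master_seed, purpose) {
  stopifnot(length(master_seed) == 1, is.finite(master_seed),
            is.character(purpose), length(purpose) == 1)
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (code in utf8ToInt(purpose)) h <- (h * 31 + code) %% m
  s <- ((abs(master_seed) %% m) * 69069 + h) %% m
  as.integer(if (s == 0) 1 else s)
}
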